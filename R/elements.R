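#' Element property table
#'
#' Constants for the eight elements occurring in the phenyltriazolinone
#' series: Pauling electronegativities, Bondi van der Waals radii and IUPAC
#' standard atomic weights. These are the two pixel-recoding properties used
#' by the MIA encoder plus the masses needed for mg/L to mol/L conversion.
#'
#' @return A data frame with columns \code{symbol}, \code{electronegativity}
#'   (Pauling scale, dimensionless), \code{vdw_radius} (Angstrom) and
#'   \code{atomic_mass} (g/mol), one row per supported element.
#' @examples
#' element_table()
#' @export
element_table <- function() {
  # Pauling electronegativities (Allred revision), Bondi (1964) vdW radii,
  # IUPAC 2021 conventional atomic weights.
  data.frame(
    symbol            = c("H", "C", "N", "O", "F", "S", "Cl", "Br"),
    electronegativity = c(2.20, 2.55, 3.04, 3.44, 3.98, 2.58, 3.16, 2.96),
    vdw_radius        = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.75, 1.85),
    atomic_mass       = c(1.008, 12.011, 14.007, 15.999, 18.998, 32.06,
                          35.45, 79.904),
    stringsAsFactors  = FALSE
  )
}

#' Look up an element property
#'
#' @param symbol Element symbol, one of H, C, N, O, F, S, Cl, Br.
#' @param kind One of \code{"electronegativity"}, \code{"vdw_radius"},
#'   \code{"mass"}.
#' @return The tabulated constant (numeric scalar). Vectorized over
#'   \code{symbol}.
#' @examples
#' element_property("F", "electronegativity") # 3.98
#' element_property("H", "vdw_radius")        # 1.20
#' @export
element_property <- function(symbol,
                             kind = c("electronegativity", "vdw_radius",
                                      "mass")) {
  kind <- match.arg(kind)
  tab <- element_table()
  idx <- match(symbol, tab$symbol)
  if (anyNA(idx)) {
    stop("unsupported element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "),
         "; supported: ", paste(tab$symbol, collapse = ", "))
  }
  col <- switch(kind, mass = "atomic_mass", kind)
  tab[[col]][idx]
}

#' Molecular weight from a Hill-style formula string
#'
#' Parses e.g. \code{"C11H10Cl2F2N4O3S"} and sums standard atomic weights.
#' Used for reference compounds (such as sulfentrazone) whose structure is
#' not assembled from the series template.
#'
#' @param formula Molecular formula string; element symbols with optional
#'   integer counts.
#' @return Molecular weight in g/mol.
#' @examples
#' formula_weight("H2O")                # 18.015
#' formula_weight("C11H10Cl2F2N4O3S")  # sulfentrazone, 387.18
#' @export
formula_weight <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  syms <- sub("[0-9]*$", "", parts)
  cnts <- as.integer(sub("^[A-Za-z]+", "", paste0(parts, "")))
  cnts[is.na(cnts)] <- 1L
  sum(element_property(syms, "mass") * cnts)
}
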