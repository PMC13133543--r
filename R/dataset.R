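#' Read a compound table from CSV
#'
#' Expected columns: \code{id,X,Y,R1,R2,ic50_mg_per_L,pic50}; activity
#' columns may be empty for prediction queries. Slot codes are validated
#' against the template alphabets; duplicate ids are rejected.
#'
#' @param path CSV path.
#' @return A list of \code{\link{compound_spec}} objects (class
#'   \code{compound_series}).
#' @export
read_compound_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character"))
  need <- c("id", "X", "Y", "R1", "R2", "ic50_mg_per_L", "pic50")
  if (!all(need %in% names(df)))
    stop("compound table must have columns: ", paste(need, collapse = ","))
  if (anyDuplicated(df$id))
    stop("duplicate compound ids: ",
         paste(df$id[duplicated(df$id)], collapse = ", "))
  specs <- lapply(seq_len(nrow(df)), function(i)
    compound_spec(df$id[i], df$X[i], df$Y[i], df$R1[i], df$R2[i],
                  ic50_mg_per_L = df$ic50_mg_per_L[i], pic50 = df$pic50[i]))
  structure(specs, class = "compound_series")
}

#' @export
print.compound_series <- function(x, ...) {
  cat("compound_series of", length(x), "compounds:",
      paste(head(vapply(x, `[[`, "", "id"), 8), collapse = ", "),
      if (length(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Packaged phenyltriazolinone PPO-inhibition dataset
#'
#' The 33-compound congeneric series of phenyltriazolinone derivatives with
#' measured half-maximal inhibitory concentrations against Nicotiana tabacum
#' protoporphyrinogen oxidase (IC50 in mg/L) and the corresponding pIC50
#' (mol/L scale). \code{ppo_proposals} returns the eight proposed analogs
#' used as prediction queries (no measured activity).
#'
#' @return A \code{compound_series}.
#' @examples
#' series <- ppo_compounds()
#' length(series)
#' @export
ppo_compounds <- function() {
  read_compound_table(system.file("extdata", "ppo_herbicides.csv",
                                  package = "miaqsar", mustWork = TRUE))
}

#' @rdname ppo_compounds
#' @export
ppo_proposals <- function() {
  read_compound_table(system.file("extdata", "ppo_proposals.csv",
                                  package = "miaqsar", mustWork = TRUE))
}

#' Activity vector of a compound series
#'
#' Extracts pIC50 responses, deriving any missing pIC50 from IC50 and the
#' assembled molecular weight. Also verifies (when both columns are present)
#' that the tabulated IC50 and pIC50 agree within \code{tol} log units given
#' the compound's molar mass.
#'
#' @param series A \code{compound_series}.
#' @param template Template library for molecular weights.
#' @param tol Consistency tolerance in log units (default 0.01, the printed
#'   precision of the source table).
#' @return Named numeric vector of pIC50 values.
#' @export
activity_vector <- function(series, template = default_template(),
                            tol = 0.01) {
  stopifnot(inherits(series, "compound_series"))
  y <- vapply(series, function(sp) {
    mw <- molecular_weight(assemble_molecule(sp, template))
    from_ic50 <- if (!is.na(sp$ic50_mg_per_L))
      ic50_to_pic50(sp$ic50_mg_per_L, mw) else NA_real_
    if (!is.na(sp$pic50) && !is.na(from_ic50) &&
        abs(from_ic50 - sp$pic50) > tol + 1e-12)
      stop("compound ", sp$id, ": IC50 and pIC50 disagree (",
           round(from_ic50, 3), " vs ", sp$pic50, ")")
    if (!is.na(sp$pic50)) sp$pic50 else from_ic50
  }, numeric(1))
  names(y) <- vapply(series, `[[`, "", "id")
  if (any(!is.finite(y)))
    stop("missing activity for: ",
         paste(names(y)[!is.finite(y)], collapse = ", "))
  y
}
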