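#' @importFrom stats cor sd var predict rnorm
#' @importFrom utils read.csv write.csv write.table head
NULL

deg2rad <- function(a) a * pi / 180
udir <- function(a) c(cospi(a / 180), sinpi(a / 180))

# bond lengths (Angstrom) used by the 2D depiction
.BL <- c(ring = 1.40, CC = 1.50, CH = 1.09, CF = 1.35, CCl = 1.77,
         CBr = 1.92, CO_dbl = 1.22, NC = 1.47)

#' Scaffold/substituent template library for the phenyltriazolinone series
#'
#' Builds the 2D template from which every series member (and every proposed
#' analog) is assembled: an N1-aryl 4-methyl-1,2,4-triazol-5(4H)-one core
#' with a methylene linker to a five-membered heteroring. Four substituent
#' slots vary across the series: the heteroring atoms \code{X} (position 1)
#' and \code{Y} (position 5), the para position \code{R1} of the benzene
#' ring, and the heteroring positions 3/5 encoded by \code{R2}.
#'
#' Coordinates are in Angstrom in a fixed frame shared by all compounds, so
#' scaffold atoms overlap exactly (to the bit) across the series - the
#' alignment the pixel descriptors rely on. Ring geometry uses regular
#' pentagons/hexagons with 1.40 A edges; substituent bond lengths are
#' element-typical.
#'
#' @return An object of class \code{mia_template}: a list with
#'   \describe{
#'     \item{scaffold}{data frame \code{element,x,y} of invariant atoms}
#'     \item{bonds}{data frame \code{i,j,order} over scaffold atoms}
#'     \item{slots}{per-slot attachment geometry and allowed codes}
#'   }
#' @examples
#' tpl <- default_template()
#' nrow(tpl$scaffold)
#' @export
default_template <- function() {
  atoms <- list()
  bonds <- list()
  add_atom <- function(el, xy) {
    atoms[[length(atoms) + 1L]] <<- list(element = el, x = xy[1], y = xy[2])
    length(atoms)
  }
  add_bond <- function(i, j, order = 1L) {
    bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = order)
  }

  r5 <- .BL["ring"] / (2 * sinpi(36 / 180))  # pentagon circumradius
  r6 <- .BL["ring"]                          # hexagon circumradius

  # triazolinone ring, center at origin: N1(0 deg), N2(72), C3(144),
  # N4(216), C5(288); carbonyl O on C5
  tri_ang <- c(N1 = 0, N2 = 72, C3t = 144, N4 = 216, C5t = 288)
  tri <- lapply(tri_ang, function(a) r5 * udir(a))
  N1  <- add_atom("N", tri$N1)
  N2  <- add_atom("N", tri$N2)
  C3t <- add_atom("C", tri$C3t)
  N4  <- add_atom("N", tri$N4)
  C5t <- add_atom("C", tri$C5t)
  add_bond(N1, N2); add_bond(N2, C3t, 2L); add_bond(C3t, N4)
  add_bond(N4, C5t); add_bond(C5t, N1)
  O1 <- add_atom("O", tri$C5t + .BL["CO_dbl"] * udir(288))
  add_bond(C5t, O1, 2L)

  # N4-methyl
  cm_xy <- tri$N4 + .BL["NC"] * udir(216)
  Cm <- add_atom("C", cm_xy)
  add_bond(N4, Cm)
  for (a in c(216, 216 + 120, 216 - 120)) {
    h <- add_atom("H", cm_xy + .BL["CH"] * udir(a))
    add_bond(Cm, h)
  }

  # benzene ring off N1 along +x; para carbon carries the R1 slot
  C1p <- add_atom("C", tri$N1 + .BL["ring"] * udir(0))
  bz_c <- tri$N1 + (.BL["ring"] + r6) * udir(0)
  bz_ang <- c(C2p = 120, C3p = 60, C4p = 0, C5p = 300, C6p = 240)
  bz <- lapply(bz_ang, function(a) bz_c + r6 * udir(a))
  C2p <- add_atom("C", bz$C2p); C3p <- add_atom("C", bz$C3p)
  C4p <- add_atom("C", bz$C4p)
  C5p <- add_atom("C", bz$C5p); C6p <- add_atom("C", bz$C6p)
  add_bond(N1, C1p)
  add_bond(C1p, C2p, 2L); add_bond(C2p, C3p); add_bond(C3p, C4p, 2L)
  add_bond(C4p, C5p); add_bond(C5p, C6p, 2L); add_bond(C6p, C1p)
  for (nm in c("C2p", "C3p", "C5p", "C6p")) {
    idx <- get(nm)
    h <- add_atom("H", bz[[nm]] + .BL["CH"] * udir(bz_ang[[nm]]))
    add_bond(idx, h)
  }

  # methylene linker and heteroring along the 144-degree direction
  ch2 <- tri$C3t + .BL["CC"] * udir(144)
  Cl1 <- add_atom("C", ch2)
  add_bond(C3t, Cl1)
  for (a in c(144 + 90, 144 - 90)) {
    h <- add_atom("H", ch2 + .BL["CH"] * udir(a))
    add_bond(Cl1, h)
  }
  c2h <- ch2 + .BL["CC"] * udir(144)
  C2h <- add_atom("C", c2h)
  add_bond(Cl1, C2h)
  het_c <- c2h + r5 * udir(144)
  het_ang <- c(C2h = 324, X = 36, Y = 108, C4h = 180, C3h = 252)
  het <- lapply(het_ang, function(a) het_c + r5 * udir(a))
  C4h <- add_atom("C", het$C4h)
  C3h <- add_atom("C", het$C3h)
  h4 <- add_atom("H", het$C4h + .BL["CH"] * udir(180))
  add_bond(C4h, h4)
  # ring bonds touching the slot atoms are added at assembly time

  scaffold <- do.call(rbind, lapply(atoms, function(a)
    data.frame(element = a$element, x = a$x, y = a$y,
               stringsAsFactors = FALSE)))
  bonds_df <- do.call(rbind, lapply(bonds, function(b)
    data.frame(i = b$i, j = b$j, order = b$order)))

  slots <- list(
    X = list(type = "ring_atom", pos = het$X, out_angle = 36,
             neighbors = c(C2h, NA_integer_),   # NA -> bonded to Y atom
             codes = c("S", "O", "CH", "C")),
    Y = list(type = "ring_atom", pos = het$Y, out_angle = 108,
             neighbors = c(C4h, NA_integer_),   # NA -> bonded to X atom
             codes = c("CH", "S", "C")),
    R1 = list(type = "substituent", parent = C4p, pos = bz$C4p,
              out_angle = 0,
              codes = c("H", "Cl", "CH3", "CF3", "Br", "F")),
    R2_3 = list(type = "substituent", parent = C3h, pos = het$C3h,
                out_angle = 252, codes = c("H", "CH3", "Br")),
    R2_5 = list(type = "on_Y", out_angle = 108, codes = c("H", "CH3"))
  )

  structure(list(scaffold = scaffold, bonds = bonds_df, slots = slots),
            class = "mia_template")
}

#' @export
print.mia_template <- function(x, ...) {
  cat("MIA scaffold template:", nrow(x$scaffold), "scaffold atoms,",
      nrow(x$bonds), "bonds,", length(x$slots), "slots (",
      paste(names(x$slots), collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a template library as JSON
#'
#' The JSON schema mirrors the \code{mia_template} structure: an object with
#' \code{scaffold} (arrays \code{element}, \code{x}, \code{y}), \code{bonds}
#' (\code{i}, \code{j}, \code{order}) and \code{slots} (named objects with
#' \code{type}, \code{pos}, \code{out_angle}, optional \code{parent} /
#' \code{neighbors}, and \code{codes}).
#'
#' @param template An \code{mia_template}.
#' @param path File path.
#' @return \code{read_template} returns an \code{mia_template};
#'   \code{write_template} returns \code{path} invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "mia_template"))
  jsonlite::write_json(
    list(scaffold = template$scaffold, bonds = template$bonds,
         slots = template$slots),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  slots <- lapply(raw$slots, function(s) {
    s$pos <- as.numeric(s$pos)
    if (!is.null(s$neighbors)) s$neighbors <- as.integer(s$neighbors)
    s
  })
  structure(list(scaffold = raw$scaffold, bonds = raw$bonds, slots = slots),
            class = "mia_template")
}

# substituent fragment in local frame: attachment at `pos`, growing along
# `angle`; returns atoms (element,x,y) and bonds relative to the parent
.fragment <- function(code, pos, angle, parent_element = "C") {
  at <- function(el, d, a) data.frame(element = el,
                                      x = pos[1] + d * cospi(a / 180),
                                      y = pos[2] + d * sinpi(a / 180),
                                      stringsAsFactors = FALSE)
  switch(code,
    H   = list(atoms = at("H",  .BL["CH"],  angle), bonds = cbind(0, 1)),
    F   = list(atoms = at("F",  .BL["CF"],  angle), bonds = cbind(0, 1)),
    Cl  = list(atoms = at("Cl", .BL["CCl"], angle), bonds = cbind(0, 1)),
    Br  = list(atoms = at("Br", .BL["CBr"], angle), bonds = cbind(0, 1)),
    CH3 = {
      cc <- pos + .BL["CC"] * udir(angle)
      a <- rbind(data.frame(element = "C", x = cc[1], y = cc[2]),
                 do.call(rbind, lapply(c(angle, angle + 120, angle - 120),
                   function(aa) data.frame(element = "H",
                     x = cc[1] + .BL["CH"] * cospi(aa / 180),
                     y = cc[2] + .BL["CH"] * sinpi(aa / 180)))))
      list(atoms = a, bonds = rbind(c(0, 1), c(1, 2), c(1, 3), c(1, 4)))
    },
    CF3 = {
      cc <- pos + .BL["CC"] * udir(angle)
      a <- rbind(data.frame(element = "C", x = cc[1], y = cc[2]),
                 do.call(rbind, lapply(c(angle, angle + 120, angle - 120),
                   function(aa) data.frame(element = "F",
                     x = cc[1] + .BL["CF"] * cospi(aa / 180),
                     y = cc[2] + .BL["CF"] * sinpi(aa / 180)))))
      list(atoms = a, bonds = rbind(c(0, 1), c(1, 2), c(1, 3), c(1, 4)))
    },
    stop("unknown substituent code: ", code)
  )
}

# parse an R2 code into its position-3 and position-5 substituents
.parse_r2 <- function(r2) {
  switch(r2,
    "H"       = list(p3 = "H",   p5 = NA),
    "3-CH3"   = list(p3 = "CH3", p5 = NA),
    "3-Br"    = list(p3 = "Br",  p5 = NA),
    "5-CH3"   = list(p3 = "H",   p5 = "CH3"),
    "3,5-CH3" = list(p3 = "CH3", p5 = "CH3"),
    stop("unknown R2 code: ", r2,
         "; available: H, 3-CH3, 3-Br, 5-CH3, 3,5-CH3")
  )
}

#' Create a compound specification
#'
#' A compound of the congeneric series is fully determined by its slot codes
#' on the shared scaffold, optionally carrying measured activity.
#'
#' @param id Compound label.
#' @param X Heteroring position-1 atom code: \code{"S"}, \code{"O"},
#'   \code{"CH"} or \code{"C"}.
#' @param Y Heteroring position-5 atom code: \code{"CH"}, \code{"S"} or
#'   \code{"C"}.
#' @param R1 Benzene para substituent: \code{"H"}, \code{"Cl"},
#'   \code{"CH3"}, \code{"CF3"}, \code{"Br"} or \code{"F"}.
#' @param R2 Heteroring substituent code: \code{"H"}, \code{"3-CH3"},
#'   \code{"3-Br"}, \code{"5-CH3"} or \code{"3,5-CH3"}.
#' @param ic50_mg_per_L Optional measured IC50 in mg/L (> 0).
#' @param pic50 Optional pIC50 (-log10 of IC50 in mol/L).
#' @return A \code{compound_spec} object (named list).
#' @examples
#' compound_spec("1", "S", "CH", "H", "H", ic50_mg_per_L = 1.404,
#'               pic50 = 5.29)
#' @export
compound_spec <- function(id, X, Y, R1, R2, ic50_mg_per_L = NA_real_,
                          pic50 = NA_real_) {
  chk <- function(v, allowed, nm) {
    if (!(v %in% allowed))
      stop("invalid ", nm, " code '", v, "'; available: ",
           paste(allowed, collapse = ", "))
  }
  chk(X, c("S", "O", "CH", "C"), "X")
  chk(Y, c("CH", "S", "C"), "Y")
  chk(R1, c("H", "Cl", "CH3", "CF3", "Br", "F"), "R1")
  .parse_r2(R2)
  if (!is.na(ic50_mg_per_L) && ic50_mg_per_L <= 0)
    stop("ic50_mg_per_L must be > 0")
  structure(list(id = as.character(id), X = X, Y = Y, R1 = R1, R2 = R2,
                 ic50_mg_per_L = as.numeric(ic50_mg_per_L),
                 pic50 = as.numeric(pic50)),
            class = "compound_spec")
}

#' Assemble a 2D molecule from a compound specification
#'
#' Places the scaffold atoms at their template coordinates (unchanged, so
#' all compounds overlap exactly at the shared core) and grows the slot
#' substituents at their fixed attachment geometry.
#'
#' @param spec A \code{\link{compound_spec}}.
#' @param template An \code{mia_template}; defaults to
#'   \code{\link{default_template}()}.
#' @return A \code{molecule2d}: list with \code{atoms} (data frame
#'   \code{element,x,y,scaffold}) and \code{bonds} (\code{i,j,order}).
#' @examples
#' mol <- assemble_molecule(compound_spec("1", "S", "CH", "H", "H"))
#' molecular_weight(mol)
#' @export
assemble_molecule <- function(spec, template = default_template()) {
  stopifnot(inherits(spec, "compound_spec"),
            inherits(template, "mia_template"))
  sc <- template$scaffold
  atoms <- data.frame(element = sc$element, x = sc$x, y = sc$y,
                      scaffold = TRUE, stringsAsFactors = FALSE)
  bonds <- data.frame(i = template$bonds$i, j = template$bonds$j,
                      order = as.integer(template$bonds$order))
  add_atoms <- function(df) {
    base <- nrow(atoms)
    df$scaffold <- FALSE
    atoms <<- rbind(atoms, df[, c("element", "x", "y", "scaffold")])
    base + seq_len(nrow(df))
  }
  slots <- template$slots
  r2 <- .parse_r2(spec$R2)

  # ring atoms X and Y (fixed coordinates, variable element)
  x_el <- if (spec$X == "CH") "C" else spec$X
  y_el <- if (spec$Y == "CH") "C" else spec$Y
  Xi <- add_atoms(data.frame(element = x_el, x = slots$X$pos[1],
                             y = slots$X$pos[2]))
  Yi <- add_atoms(data.frame(element = y_el, x = slots$Y$pos[1],
                             y = slots$Y$pos[2]))
  bonds <- rbind(bonds,
                 data.frame(i = slots$X$neighbors[1], j = Xi, order = 1L),
                 data.frame(i = Xi, j = Yi, order = 1L),
                 data.frame(i = slots$Y$neighbors[1], j = Yi, order = 1L))
  if (spec$X == "CH") {
    h <- add_atoms(.fragment("H", slots$X$pos, slots$X$out_angle)$atoms)
    bonds <- rbind(bonds, data.frame(i = Xi, j = h, order = 1L))
  }
  # position 5 = the Y ring atom: explicit H when Y is CH and no 5-CH3;
  # a methyl when R2 requests one (printed Y code C vs CH is equivalent)
  p5 <- r2$p5
  if (is.na(p5) && spec$Y == "CH") p5 <- "H"
  if (!is.na(p5) && spec$Y == "S")
    stop("R2 code '", spec$R2, "' places a substituent on Y = S")
  if (!is.na(p5)) {
    fr <- .fragment(p5, slots$Y$pos, slots$Y$out_angle)
    idx <- add_atoms(fr$atoms)
    bmap <- cbind(ifelse(fr$bonds[, 1] == 0, Yi, idx[fr$bonds[, 1]]),
                  idx[fr$bonds[, 2]])
    bonds <- rbind(bonds, data.frame(i = bmap[, 1], j = bmap[, 2],
                                     order = 1L))
  }
  for (sl in list(list(s = slots$R1, code = spec$R1),
                  list(s = slots$R2_3, code = r2$p3))) {
    fr <- .fragment(sl$code, sl$s$pos, sl$s$out_angle)
    idx <- add_atoms(fr$atoms)
    bmap <- cbind(ifelse(fr$bonds[, 1] == 0, sl$s$parent,
                         idx[fr$bonds[, 1]]),
                  idx[fr$bonds[, 2]])
    bonds <- rbind(bonds, data.frame(i = bmap[, 1], j = bmap[, 2],
                                     order = 1L))
  }
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  structure(list(id = spec$id, atoms = atoms, bonds = bonds),
            class = "molecule2d")
}

#' @export
print.molecule2d <- function(x, ...) {
  tab <- table(x$atoms$element)
  cat("molecule2d '", x$id, "': ", nrow(x$atoms), " atoms (",
      paste0(names(tab), tab, collapse = " "), "), ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Molecular weight of an assembled molecule
#'
#' @param mol A \code{molecule2d}.
#' @return Sum of atomic masses, g/mol.
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "molecule2d"))
  sum(element_property(mol$atoms$element, "mass"))
}

#' Convert IC50 (mg/L) to pIC50 (mol/L)
#'
#' \code{pIC50 = -log10(IC50 / (1000 * MW))}: the mass concentration is
#' turned molar with the compound's molecular weight, then negative
#' log-transformed. Strictly decreasing in IC50.
#'
#' @param ic50 IC50 in mg/L (> 0). Vectorized.
#' @param mw Molecular weight in g/mol (> 0).
#' @return pIC50 value(s).
#' @examples
#' ic50_to_pic50(0.078, 387.18) # sulfentrazone, 6.70
#' @export
ic50_to_pic50 <- function(ic50, mw) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(!is.finite(mw)) || any(mw <= 0)) stop("mw must be > 0")
  -log10(ic50 / (1000 * mw))
}
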