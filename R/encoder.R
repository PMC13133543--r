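#' Raster canvas configuration
#'
#' The fixed pixel frame shared by every image of a run. The default
#' 300 x 348 canvas at 16 px/Angstrom with the template origin mapped to
#' pixel (col 140, row 200) holds the whole series - including the widest
#' members and the proposed analogs - within 90\% of the width.
#'
#' @param width,height Canvas size in pixels.
#' @param scale Pixels per Angstrom.
#' @param origin Length-2 integer-ish vector: pixel (col, row) of the
#'   template frame origin. Row 0 is the top of the image.
#' @param k Ball-and-stick disk proportionality: atom disks have radius
#'   \code{round(k * vdw_radius * scale)} px.
#' @param draw_bonds Paint 1-px bond sticks valued at carbon's property
#'   (off by default; sticks add mostly constant or carbon-valued columns).
#' @return An object of class \code{mia_canvas}.
#' @examples
#' default_canvas()
#' @export
default_canvas <- function(width = 300L, height = 348L, scale = 16,
                           origin = c(140, 200), k = 0.25,
                           draw_bonds = FALSE) {
  stopifnot(width > 0, height > 0, scale > 0, length(origin) == 2, k > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 scale = scale, origin = as.numeric(origin), k = k,
                 draw_bonds = isTRUE(draw_bonds)),
            class = "mia_canvas")
}

#' @export
print.mia_canvas <- function(x, ...) {
  cat("mia_canvas ", x$width, "x", x$height, " px, ", x$scale,
      " px/A, origin (", x$origin[1], ",", x$origin[2], "), k=", x$k,
      if (x$draw_bonds) ", bonds on" else "", "\n", sep = "")
  invisible(x)
}

# round-half-up pixel mapping, frozen convention
.round_half_up <- function(x) floor(x + 0.5)

# Angstrom (x,y) -> pixel (col, row); row 0 at top
.to_pixel <- function(canvas, x, y) {
  list(col = .round_half_up(canvas$origin[1] + x * canvas$scale),
       row = .round_half_up(canvas$origin[2] - y * canvas$scale))
}

#' Rasterize a molecule into a property-coded image
#'
#' Each atom is painted as a filled disk centered at its mapped pixel with
#' radius \code{round(k * vdw_radius * scale)}; the pixel value is the
#' atom's property (Pauling electronegativity or van der Waals radius).
#' Disks are painted in decreasing vdW-radius order so small atoms (H, F)
#' stay visible on top of larger neighbors, mirroring a ball-and-stick
#' depiction; ties are broken by atom index. Background pixels are exactly
#' 0 (all painted values are >= 0.7, so 0 is unambiguous).
#'
#' @param mol A \code{molecule2d}.
#' @param property_kind \code{"electronegativity"} or \code{"vdw_radius"}.
#' @param canvas An \code{mia_canvas}.
#' @return An \code{mia_image}: a \code{height x width} numeric matrix with
#'   attributes \code{property_kind} and \code{canvas}.
#' @examples
#' img <- rasterize(assemble_molecule(compound_spec("1","S","CH","H","H")),
#'                  "vdw_radius")
#' dim(img)
#' @export
rasterize <- function(mol, property_kind = c("electronegativity",
                                             "vdw_radius"),
                      canvas = default_canvas()) {
  property_kind <- match.arg(property_kind)
  stopifnot(inherits(mol, "molecule2d"), inherits(canvas, "mia_canvas"))
  img <- matrix(0, nrow = canvas$height, ncol = canvas$width)
  atoms <- mol$atoms
  if (nrow(atoms) > 0) {
    vdw <- element_property(atoms$element, "vdw_radius")
    val <- element_property(atoms$element, property_kind)
    px <- .to_pixel(canvas, atoms$x, atoms$y)
    rad <- .round_half_up(canvas$k * vdw * canvas$scale)
    bad <- px$col - rad < 0 | px$col + rad > canvas$width - 1 |
           px$row - rad < 0 | px$row + rad > canvas$height - 1
    if (any(bad)) {
      i <- which(bad)[1]
      stop("atom ", i, " (", atoms$element[i], ") of compound '", mol$id,
           "' at (", round(atoms$x[i], 3), ", ", round(atoms$y[i], 3),
           ") A does not fit the canvas")
    }
    if (canvas$draw_bonds && nrow(mol$bonds) > 0) {
      cval <- element_property("C", property_kind)
      for (b in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
        n <- max(abs(px$col[i] - px$col[j]), abs(px$row[i] - px$row[j]), 1)
        tt <- seq(0, 1, length.out = n + 1)
        cc <- .round_half_up(px$col[i] + tt * (px$col[j] - px$col[i]))
        rr <- .round_half_up(px$row[i] + tt * (px$row[j] - px$row[i]))
        img[cbind(rr + 1L, cc + 1L)] <- cval
      }
    }
    for (i in order(-vdw, seq_along(vdw))) {
      r <- rad[i]
      dr <- -r:r
      for (d in dr) {
        w <- floor(sqrt(r * r - d * d))
        rows <- px$row[i] + d + 1L
        img[rows, (px$col[i] - w:(-w)) + 1L] <- val[i]
      }
    }
  }
  structure(img, property_kind = property_kind, canvas = canvas,
            class = c("mia_image", "matrix", "array"))
}

#' Unfold an image into a descriptor row / fold it back
#'
#' \code{unfold} flattens the \code{height x width} grid row-major (row 0
#' first, left to right) into a vector of length \code{width * height};
#' \code{fold} inverts it. The default canvas gives vectors of length
#' 104,400.
#'
#' @param img An \code{mia_image} (or any matrix).
#' @return \code{unfold}: numeric vector; \code{fold}: matrix of shape
#'   \code{height x width}.
#' @examples
#' v <- unfold(matrix(1:6, 2, 3)); fold(v, 3, 2)
#' @export
unfold <- function(img) {
  as.vector(t(img))
}

#' @rdname unfold
#' @param v Numeric vector of length \code{width * height}.
#' @param width,height Target grid shape.
#' @export
fold <- function(v, width, height) {
  if (length(v) != width * height)
    stop("length ", length(v), " does not match ", width, " x ", height)
  t(matrix(v, nrow = width, ncol = height))
}

#' Build the MIA descriptor matrix for a compound series
#'
#' Rasterizes every compound on the shared canvas, unfolds each image and
#' stacks the vectors into the \code{n x p} descriptor matrix
#' (p = width * height; 33 x 104,400 for the packaged dataset on the
#' default canvas). Columns constant across all rows - background pixels
#' and invariant scaffold pixels - are flagged in \code{column_mask} and
#' excluded from modeling.
#'
#' @param series A \code{compound_series} (>= 2 compounds, unique ids).
#' @param property_kind \code{"electronegativity"} or \code{"vdw_radius"}.
#' @param canvas An \code{mia_canvas}.
#' @param template Template library.
#' @return A \code{descriptor_matrix}: list with \code{X} (full n x p
#'   matrix, rows named by compound id), \code{column_mask} (logical,
#'   TRUE = retained/varying), \code{property_kind}, \code{canvas}.
#' @export
build_descriptor_matrix <- function(series,
                                    property_kind = c("electronegativity",
                                                      "vdw_radius"),
                                    canvas = default_canvas(),
                                    template = default_template()) {
  property_kind <- match.arg(property_kind)
  stopifnot(inherits(series, "compound_series"))
  if (length(series) < 2) stop("need at least 2 compounds")
  ids <- vapply(series, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(series, function(sp)
    unfold(rasterize(assemble_molecule(sp, template), property_kind,
                     canvas)))
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  column_mask <- colSums(X != rep(X[1, ], each = nrow(X))) > 0
  structure(list(X = X, column_mask = column_mask,
                 property_kind = property_kind, canvas = canvas),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("descriptor_matrix: ", nrow(x$X), " x ", ncol(x$X), " (",
      x$property_kind, "), ", sum(x$column_mask),
      " varying columns retained\n", sep = "")
  invisible(x)
}

#' Retained (masked) descriptor columns
#'
#' @param dm A \code{descriptor_matrix}.
#' @return The \code{n x p_retained} matrix of varying columns.
#' @export
masked_matrix <- function(dm) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  dm$X[, dm$column_mask, drop = FALSE]
}

#' Export an image as PNG and as a lossless CSV matrix
#'
#' The PNG rescales the property range to 8-bit grey for visualization; the
#' CSV holds the raw property values and is the modeling source of truth.
#'
#' @param img An \code{mia_image}.
#' @param png_path,csv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
export_image <- function(img, png_path = NULL, csv_path = NULL) {
  if (!is.null(png_path)) {
    m <- unclass(img)
    hi <- max(m)
    png::writePNG(if (hi > 0) m / hi else m, png_path)
  }
  if (!is.null(csv_path)) {
    write.table(unclass(img), csv_path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(c(png_path, csv_path))
}
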