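#' Fold a model vector back into image space
#'
#' Inverse of \code{\link{unfold}} restricted to the retained descriptor
#' columns: the VIP vector or regression vector \code{b} of a fitted model
#' (length = number of retained columns) is written back to its pixel
#' positions; masked (constant/background) pixels render as exact 0.
#'
#' @param vec Numeric vector over retained columns.
#' @param column_mask Logical mask of length \code{width * height}
#'   (TRUE = retained), from \code{\link{build_descriptor_matrix}}.
#' @param canvas The \code{mia_canvas} the mask refers to.
#' @param kind Map flavor: \code{"vip"} or \code{"coefficient"}.
#' @return An \code{mia_map}: \code{height x width} matrix with attributes
#'   \code{kind} and \code{canvas}.
#' @export
fold_map <- function(vec, column_mask, canvas = default_canvas(),
                     kind = c("vip", "coefficient")) {
  kind <- match.arg(kind)
  p <- canvas$width * canvas$height
  if (length(column_mask) != p)
    stop("column_mask length ", length(column_mask),
         " does not match canvas (", p, " pixels)")
  if (length(vec) != sum(column_mask))
    stop("vector length ", length(vec), " does not match ",
         sum(column_mask), " retained columns")
  full <- numeric(p)
  full[column_mask] <- vec
  structure(fold(full, canvas$width, canvas$height), kind = kind,
            canvas = canvas, class = c("mia_map", "matrix", "array"))
}

#' Export a MIA map as a heat-map PNG with a raw-value CSV sidecar
#'
#' The CSV sidecar holds the raw grid and is the artifact of record; the
#' PNG is presentation only. Coefficient maps use a diverging blue-white-red
#' scale centered at 0; VIP maps use a sequential white-to-red scale.
#'
#' @param map An \code{mia_map}.
#' @param path PNG output path; the sidecar is \code{path} with a
#'   \code{.csv} extension.
#' @return Invisibly, c(png path, csv path).
#' @export
export_heatmap <- function(map, path) {
  stopifnot(inherits(map, "mia_map"))
  m <- unclass(map)
  kind <- attr(map, "kind")
  if (identical(kind, "coefficient")) {
    hi <- max(abs(m))
    z <- if (hi > 0) m / hi else m            # [-1, 1]
    rgb_arr <- array(1, dim = c(nrow(m), ncol(m), 3))
    rgb_arr[, , 1] <- ifelse(z < 0, 1 + z, 1)  # blue for negative
    rgb_arr[, , 2] <- 1 - abs(z)
    rgb_arr[, , 3] <- ifelse(z > 0, 1 - z, 1)  # red for positive
  } else {
    hi <- max(m)
    z <- if (hi > 0) m / hi else m             # [0, 1]
    rgb_arr <- array(1, dim = c(nrow(m), ncol(m), 3))
    rgb_arr[, , 2] <- 1 - z
    rgb_arr[, , 3] <- 1 - z
  }
  png::writePNG(rgb_arr, path)
  csv_path <- paste0(sub("\\.png$", "", path), ".csv")
  write.table(m, csv_path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(c(path, csv_path))
}
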