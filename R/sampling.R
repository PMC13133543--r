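#' Kennard-Stone representative train/test split
#'
#' Classic maximin selection of the training (calibration) set on Euclidean
#' distances: seed with the globally most distant pair, then iteratively
#' add the candidate whose minimum distance to the already-selected set is
#' largest; the remainder forms the test set. Fully deterministic; all ties
#' break toward the lowest row index.
#'
#' @param X Numeric matrix (rows = samples), typically the masked
#'   descriptor matrix.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#'   The test-set size is round-half-up of \code{n * (1 - train_fraction)}
#'   (33 rows at 0.75 give 25 train / 8 test).
#' @return A \code{split_plan}: list with integer vectors \code{train} and
#'   \code{test} (disjoint, union = all rows) and \code{method}.
#' @examples
#' X <- matrix(c(0, 1, 10), ncol = 1)
#' kennard_stone_split(X, 2/3) # train = {1, 3}, test = {2}
#' @export
kennard_stone_split <- function(X, train_fraction = 0.75) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4 && !(n == 3 && train_fraction >= 2 / 3))
    stop("need at least 4 samples")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_test <- as.integer(floor(n * (1 - train_fraction) + 0.5))
  n_train <- n - n_test
  if (n_train < 2) stop("train_fraction leaves fewer than 2 training rows")
  D <- as.matrix(stats::dist(X))
  if (max(D) == 0) stop("all rows identical; Kennard-Stone is undefined")
  # seed pair: global maximum distance, lowest indices on ties
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- as.integer(idx[1, ])
  remaining <- setdiff(seq_len(n), sel)
  while (length(sel) < n_train) {
    mind <- apply(D[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)]  # which.max -> lowest index on ties
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(train = sort(sel), test = sort(remaining),
                 method = "kennard_stone", seed = NA_integer_),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan (", x$method, "): ", length(x$train), " train / ",
      length(x$test), " test\n", sep = "")
  invisible(x)
}

#' y-randomization permutations
#'
#' Returns \code{n_cycles} uniformly random permutations of the response
#' (descriptors are left untouched by the caller). Reproducible under
#' \code{seed}; each returned vector is a permutation of \code{y}.
#'
#' @param y Response vector.
#' @param n_cycles Number of scrambling cycles (>= 1).
#' @param seed Integer seed.
#' @return List of \code{n_cycles} permuted copies of \code{y}.
#' @export
y_randomize <- function(y, n_cycles = 10L, seed = 1L) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_cycles), function(i) sample(y))
}

#' Random test-set re-selection cycles (bootstrap stability)
#'
#' Each cycle draws a test set of round-half-up \code{n * test_fraction}
#' distinct rows uniformly without replacement; the remainder trains.
#' Seeded and reproducible.
#'
#' @param n Number of samples.
#' @param test_fraction Fraction held out per cycle.
#' @param n_cycles Number of cycles (>= 1).
#' @param seed Integer seed.
#' @return List of \code{split_plan}s.
#' @export
bootstrap_cycles <- function(n, test_fraction = 0.25, n_cycles = 10L,
                             seed = 1L) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- as.integer(floor(n * test_fraction + 0.5))
  if (n_test < 1 || n_test > n - 2) stop("infeasible test_fraction")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_cycles), function(cy) {
    test <- sort(sample.int(n, n_test))
    structure(list(train = setdiff(seq_len(n), test), test = test,
                   method = "bootstrap", seed = seed, cycle = cy),
              class = "split_plan")
  })
}

#' Serialize split plans to a CSV (id, role, cycle)
#'
#' @param plans A \code{split_plan} or list of them.
#' @param ids Row ids the indices refer to.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_split_plans <- function(plans, ids, path) {
  if (inherits(plans, "split_plan")) plans <- list(plans)
  rows <- do.call(rbind, lapply(seq_along(plans), function(k) {
    pl <- plans[[k]]
    data.frame(id = ids[c(pl$train, pl$test)],
               role = rep(c("train", "test"),
                          c(length(pl$train), length(pl$test))),
               cycle = if (!is.null(pl$cycle)) pl$cycle else k,
               method = pl$method)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
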