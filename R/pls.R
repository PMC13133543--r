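#' Fit a single-response PLS model (NIPALS)
#'
#' Classical PLS1 by NIPALS deflation on column-mean-centered X and
#' mean-centered y. For a single response the weight vector of each stage
#' is \code{w_a = X_a' y / ||X_a' y||} - no iteration and no random
#' initialization, so fitting is fully deterministic. No scaling beyond
#' mean-centering is applied: pixel descriptors share one unit within a
#' model.
#'
#' @param X Numeric matrix, n x p (already column-masked).
#' @param y Numeric response vector, length n (pIC50).
#' @param A Number of latent variables, \code{1 <= A <= min(n-1, p)}.
#' @return A \code{pls_model}: list with components \code{A}, \code{x_mean},
#'   \code{y_mean}, \code{W} (p x A unit-norm weights), \code{P}
#'   (x-loadings), \code{q} (y-loadings), \code{T} (n x A training scores),
#'   \code{R} (projection weights \code{W (P'W)^-1}), \code{b} (length-p
#'   regression vector in centered space), \code{fitted}.
#' @examples
#' X <- matrix(rnorm(40), 10, 4); y <- X[, 1] + rnorm(10, sd = 0.1)
#' m <- pls_fit(X, y, A = 2)
#' @export
pls_fit <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n < 3) stop("need at least 3 samples")
  if (A < 1 || A > min(n - 1, p))
    stop("A = ", A, " outside 1..min(n-1, p) = ", min(n - 1, p))
  if (var(y) == 0) stop("zero-variance response")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  Xa <- Xc
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, yc))
    nw <- sqrt(sum(w^2))
    if (a == 1) nw1 <- nw
    if (nw <= 1e-10 * nw1 || nw == 0)
      stop("X deflated to zero covariance with y at component ", a,
           "; reduce A")
    w <- w / nw
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(Xa, t)) / tt
    qa <- sum(yc * t) / tt
    Xa <- Xa - tcrossprod(t, pl)
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  R <- W %*% solve(crossprod(P, W))
  b <- drop(R %*% q)
  fitted <- drop(Xc %*% b) + y_mean
  structure(list(A = A, x_mean = x_mean, y_mean = y_mean, W = W, P = P,
                 q = q, T = Tm, R = R, b = b, fitted = fitted, n = n,
                 p = p),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model: ", x$A, " latent variable(s), n = ", x$n, ", p = ", x$p,
      "\n", sep = "")
  invisible(x)
}

#' Predict activities with a fitted PLS model
#'
#' \code{yhat = (x - x_mean) . b + y_mean} per row.
#'
#' @param object A \code{pls_model}.
#' @param newdata Matrix (rows = samples) with the model's column count, or
#'   a single row vector.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
       else as.matrix(newdata)
  if (ncol(X) != object$p)
    stop("newdata has ", ncol(X), " columns; model expects ", object$p)
  drop(sweep(X, 2, object$x_mean) %*% object$b) + object$y_mean
}

#' Variable importance in projection (VIP)
#'
#' \code{VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)} with
#' \code{SS_a = q_a^2 t_a't_a} (weights are unit-norm). Satisfies
#' \code{sum_j VIP_j^2 = p}.
#'
#' @param model A \code{pls_model}.
#' @return Numeric vector of length p, non-negative.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ss <- model$q^2 * colSums(model$T^2)
  drop(sqrt(model$p * (model$W^2 %*% ss) / sum(ss)))
}

#' Leverage of samples under a fitted PLS model
#'
#' \code{h_i = 1/n + t_i' (T'T)^-1 t_i}, with new-sample scores obtained by
#' projecting centered rows through the model weights
#' (\code{t = (x - x_mean) R}). Training rows reproduce their stored
#' scores; every leverage is >= 1/n.
#'
#' @param model A \code{pls_model}.
#' @param X_rows Matrix of rows to assess (default: training scores).
#' @return Numeric vector of leverages.
#' @export
leverage <- function(model, X_rows = NULL) {
  stopifnot(inherits(model, "pls_model"))
  Tn <- if (is.null(X_rows)) model$T
        else sweep(as.matrix(X_rows), 2, model$x_mean) %*% model$R
  TtT <- crossprod(model$T)
  d <- diag(TtT)
  if (any(d < 1e-12 * max(d)))
    stop("singular score covariance; reduce the number of components")
  # T'T is diagonal for NIPALS scores, but invert the full matrix for safety
  drop(1 / model$n + rowSums((Tn %*% solve(TtT)) * Tn))
}

#' Select the number of PLS components by leave-one-out RMSECV
#'
#' Fits \code{A = 1..A_max}, computes leave-one-out RMSECV for each, and
#' returns the global minimizer; ties break toward the smaller A.
#' Deterministic.
#'
#' @param X Masked descriptor matrix (training rows).
#' @param y Response vector.
#' @param A_max Largest A to consider (\code{<= n - 2}).
#' @return List with \code{A} (the selected count) and \code{rmsecv}
#'   (vector over 1..A_max).
#' @export
select_components <- function(X, y, A_max = min(nrow(X) - 2L, 15L)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (A_max > n - 2) stop("A_max must be <= n - 2")
  if (A_max < 1) stop("A_max must be >= 1")
  A_max <- min(A_max, ncol(X))
  # if X (or a leave-one-out subset) has rank below A_max, NIPALS deflates
  # to zero; shrink the search range and restart
  repeat {
    press <- numeric(A_max)
    ok <- TRUE
    for (i in seq_len(n)) {
      m <- tryCatch(pls_fit(X[-i, , drop = FALSE], y[-i], A_max),
                    error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      # predictions of the held-out row at every truncation 1..A_max
      tnew <- drop(crossprod(X[i, ] - m$x_mean, m$R))
      cum <- cumsum(tnew * m$q) + m$y_mean
      press <- press + (y[i] - cum)^2
    }
    if (ok) break
    A_max <- A_max - 1L
    if (A_max < 1) stop("no feasible number of components")
  }
  rmsecv <- sqrt(press / n)
  list(A = which.min(rmsecv), rmsecv = rmsecv)
}
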