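#' Calibration metrics
#'
#' \code{rmsec = sqrt(mean((y - yhat)^2))}; \code{r2} is the squared
#' Pearson correlation of observed and fitted values.
#'
#' @param y Observed responses.
#' @param y_fit Fitted values (same length, >= 3).
#' @return Named list \code{rmsec}, \code{r2}.
#' @export
calibration_metrics <- function(y, y_fit) {
  if (length(y) != length(y_fit) || length(y) < 3)
    stop("y and y_fit must have equal length >= 3")
  if (sd(y) == 0 || sd(y_fit) == 0)
    stop("zero variance; correlation undefined")
  list(rmsec = sqrt(mean((y - y_fit)^2)), r2 = cor(y, y_fit)^2)
}

#' Leave-one-out cross-validation of a PLS model
#'
#' Refits on each n-1 subset at fixed A and predicts the held-out sample.
#' \code{q2 = 1 - PRESS / sum((y - mean(y))^2)};
#' \code{rmsecv = sqrt(PRESS / n)}.
#'
#' @param X Masked descriptor matrix.
#' @param y Responses (length >= 4).
#' @param A Number of latent variables.
#' @return Named list \code{rmsecv}, \code{q2}, \code{y_cv} (the LOO
#'   predictions).
#' @export
cross_validation <- function(X, y, A) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples for LOO")
  y_cv <- vapply(seq_len(n), function(i) {
    m <- pls_fit(X[-i, , drop = FALSE], y[-i], A)
    predict(m, X[i, ])
  }, numeric(1))
  press <- sum((y - y_cv)^2)
  list(rmsecv = sqrt(press / n), q2 = 1 - press / sum((y - mean(y))^2),
       y_cv = y_cv)
}

# through-origin r0^2 for Roy's r2m: observed regressed on predicted
# (forward) with slope k = sum(obs*pred)/sum(pred^2)
.r0sq <- function(obs, pred) {
  k <- sum(obs * pred) / sum(pred^2)
  1 - sum((obs - k * pred)^2) / sum((obs - mean(obs))^2)
}

#' External (test-set) validation metrics
#'
#' Computes the full external metric suite: RMSEP and MAE; squared Pearson
#' \code{r2_pred}; Roy's modified \code{r2m} pair
#' (\code{r2m = r2 * (1 - sqrt(|r2 - r0^2|))}, forward = observed vs
#' predicted, reverse = axes swapped) with their mean and absolute
#' difference; Lin's concordance correlation coefficient
#' (1/n variances); and \code{Q2F1 = 1 - sum((y - yhat)^2) /
#' sum((y - mean(y_train))^2)}, \code{Q2F2} likewise referenced to the
#' test-set mean.
#'
#' @param y_test Observed test responses (length >= 3).
#' @param y_pred Predicted test responses.
#' @param y_train_mean Mean of the training responses (for Q2F1).
#' @return Named list \code{rmsep}, \code{r2_pred}, \code{r2m_test},
#'   \code{r2m_rev}, \code{avg_r2m}, \code{delta_r2m}, \code{ccc},
#'   \code{q2_f1}, \code{q2_f2}, \code{mae}.
#' @export
external_metrics <- function(y_test, y_pred, y_train_mean) {
  if (length(y_test) != length(y_pred) || length(y_test) < 3)
    stop("test vectors must have equal length >= 3")
  if (sd(y_test) == 0 || sd(y_pred) == 0)
    stop("zero test variance; correlation undefined")
  n <- length(y_test)
  err <- y_test - y_pred
  r2 <- cor(y_test, y_pred)^2
  r2m_fwd <- r2 * (1 - sqrt(abs(r2 - .r0sq(y_test, y_pred))))
  r2m_rev <- r2 * (1 - sqrt(abs(r2 - .r0sq(y_pred, y_test))))
  sx <- mean((y_test - mean(y_test))^2)
  sy <- mean((y_pred - mean(y_pred))^2)
  sxy <- mean((y_test - mean(y_test)) * (y_pred - mean(y_pred)))
  ccc <- 2 * sxy / (sx + sy + (mean(y_test) - mean(y_pred))^2)
  list(rmsep = sqrt(mean(err^2)),
       r2_pred = r2,
       r2m_test = r2m_fwd,
       r2m_rev = r2m_rev,
       avg_r2m = (r2m_fwd + r2m_rev) / 2,
       delta_r2m = abs(r2m_fwd - r2m_rev),
       ccc = ccc,
       q2_f1 = 1 - sum(err^2) / sum((y_test - y_train_mean)^2),
       q2_f2 = 1 - sum(err^2) / sum((y_test - mean(y_test))^2),
       mae = mean(abs(err)))
}

#' Summary of y-randomization cycles
#'
#' Aggregates scrambling-cycle refits into the mean randomized RMSE and
#' r-squared and the corrected randomization statistic
#' \code{c_r2p = r * sqrt(r2 - mean(r2_yrand))} with \code{r = sqrt(r2)}.
#' If the scrambled models are on average as good as the real one
#' (\code{r2 < mean(r2_yrand)}), 0 is returned with a warning.
#'
#' @param r2_cal Calibration r-squared of the real model.
#' @param r2_yrand_cycles Vector of per-cycle calibration r-squared under
#'   scrambled responses.
#' @param rmse_yrand_cycles Optional vector of per-cycle RMSEC under
#'   scrambling.
#' @return Named list \code{rmse_yrand}, \code{r2_yrand} (cycle means) and
#'   \code{c_r2p}.
#' @examples
#' y_randomization_summary(0.9861, 0.3609)$c_r2p # 0.7852
#' @export
y_randomization_summary <- function(r2_cal, r2_yrand_cycles,
                                    rmse_yrand_cycles = NULL) {
  if (length(r2_yrand_cycles) < 1) stop("need at least one cycle")
  m <- mean(r2_yrand_cycles)
  c_r2p <- if (r2_cal >= m) sqrt(r2_cal) * sqrt(r2_cal - m) else {
    warning("model is no better than chance (r2 < mean scrambled r2)")
    0
  }
  list(rmse_yrand = if (is.null(rmse_yrand_cycles)) NA_real_
                    else mean(rmse_yrand_cycles),
       r2_yrand = m, c_r2p = c_r2p)
}

#' Williams-plot applicability domain
#'
#' Screens a dataset for outliers before modeling: a PLS assessment model
#' is fitted on all rows, leverages come from the score space
#' (\code{\link{leverage}}), standardized residuals are calibration
#' residuals divided by the assessment RMSE, and a compound is flagged
#' when \code{h > h* = 3(A+1)/n} or \code{|standardized residual| > 3}.
#'
#' @param model A \code{pls_model} fitted on \code{X_all}, \code{y_all}.
#' @param X_all Masked descriptor matrix of all compounds.
#' @param y_all Their responses.
#' @return An \code{ad_report}: data frame with \code{id}, \code{leverage},
#'   \code{std_residual}, \code{flagged}, plus attributes
#'   \code{h_star} and \code{residual_cutoff}.
#' @export
williams_domain <- function(model, X_all, y_all) {
  stopifnot(inherits(model, "pls_model"))
  X_all <- as.matrix(X_all)
  h <- leverage(model, X_all)
  res <- y_all - predict(model, X_all)
  rmse <- sqrt(mean(res^2))
  if (rmse == 0) rmse <- .Machine$double.eps
  std <- res / rmse
  h_star <- 3 * (model$A + 1) / nrow(X_all)
  out <- data.frame(
    id = if (!is.null(rownames(X_all))) rownames(X_all)
         else as.character(seq_len(nrow(X_all))),
    leverage = h, std_residual = std,
    flagged = h > h_star | abs(std) > 3,
    row.names = NULL)
  attr(out, "h_star") <- h_star
  attr(out, "residual_cutoff") <- 3
  class(out) <- c("ad_report", "data.frame")
  out
}

#' @export
print.ad_report <- function(x, ...) {
  cat("Williams applicability domain: h* = ",
      round(attr(x, "h_star"), 4), ", residual cutoff +/-",
      attr(x, "residual_cutoff"), "; ", sum(x$flagged), " of ", nrow(x),
      " compounds flagged\n", sep = "")
  if (sum(x$flagged) > 0) print(as.data.frame(x)[x$flagged, ])
  invisible(x)
}
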