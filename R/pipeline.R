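#' Study run configuration
#'
#' Bundles every setting of a full MIA-QSAR study. Defaults mirror the
#' source study design: both encoding properties, a 75/25 Kennard-Stone
#' split, leave-one-out component selection, 10 y-randomization cycles and
#' 10 random test-set (bootstrap) cycles on the fixed 300 x 348 canvas.
#'
#' @param properties Character vector of encoding properties to model,
#'   subset of \code{c("vdw_radius", "electronegativity")}.
#' @param canvas An \code{mia_canvas}.
#' @param template Template library.
#' @param train_fraction Kennard-Stone training fraction.
#' @param yrand_cycles Number of y-randomization cycles.
#' @param bootstrap_cycles Number of random test-set cycles.
#' @param A_max Component cap passed to \code{\link{select_components}}
#'   (\code{NULL}: \code{min(n_train - 2, 15)}).
#' @param seed Integer seed driving all stochastic stages (y-randomization
#'   and bootstrap); Kennard-Stone and calibration are deterministic and
#'   unaffected by it.
#' @param output_dir Optional directory; when set, \code{run_study} writes
#'   CSV/JSON reports and PNG maps there.
#' @return A \code{run_config} list.
#' @export
run_config <- function(properties = c("vdw_radius", "electronegativity"),
                       canvas = default_canvas(),
                       template = default_template(),
                       train_fraction = 0.75, yrand_cycles = 10L,
                       bootstrap_cycles = 10L, A_max = NULL, seed = 1L,
                       output_dir = NULL) {
  properties <- match.arg(properties,
                          c("vdw_radius", "electronegativity"),
                          several.ok = TRUE)
  stopifnot(length(properties) >= 1, train_fraction > 0,
            train_fraction < 1)
  structure(list(properties = properties, canvas = canvas,
                 template = template, train_fraction = train_fraction,
                 yrand_cycles = as.integer(yrand_cycles),
                 bootstrap_cycles = as.integer(bootstrap_cycles),
                 A_max = A_max, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

# fit + validate one split at a fixed descriptor matrix; returns the
# flat metric set of one Table-2-style column
.evaluate_split <- function(Xm, y, plan, A_max, yrand_cycles, seed) {
  tr <- plan$train; te <- plan$test
  Xtr <- Xm[tr, , drop = FALSE]; ytr <- y[tr]
  amax <- if (is.null(A_max)) min(length(tr) - 2L, 15L) else A_max
  sel <- select_components(Xtr, ytr, amax)
  model <- pls_fit(Xtr, ytr, sel$A)
  cal <- calibration_metrics(ytr, model$fitted)
  cv <- cross_validation(Xtr, ytr, sel$A)
  ext <- external_metrics(y[te], predict(model, Xm[te, , drop = FALSE]),
                          mean(ytr))
  perms <- y_randomize(ytr, yrand_cycles, seed)
  yr <- vapply(perms, function(yp) {
    m <- pls_fit(Xtr, yp, sel$A)
    c(r2 = cor(yp, m$fitted)^2, rmse = sqrt(mean((yp - m$fitted)^2)))
  }, numeric(2))
  yrs <- y_randomization_summary(cal$r2, yr["r2", ], yr["rmse", ])
  c(list(A = sel$A), cal, cv[c("rmsecv", "q2")], ext, yrs,
    list(model = model, plan = plan))
}

.metric_names <- c("A", "rmsec", "r2", "rmse_yrand", "r2_yrand", "c_r2p",
                   "rmsecv", "q2", "rmsep", "r2_pred", "r2m_test",
                   "avg_r2m", "delta_r2m", "ccc", "q2_f1", "q2_f2", "mae")

#' Run the full MIA-QSAR study on a compound series
#'
#' Executes, per encoding property: descriptor construction, Williams
#' applicability-domain screening on the full series, Kennard-Stone 75/25
#' splitting, LOO component selection, PLS calibration, leave-one-out
#' cross-validation, external validation, y-randomization, bootstrap
#' (random test-set) stability cycles with mean and standard deviation of
#' every metric, and VIP/coefficient MIA maps. Deterministic given the
#' configuration seed; only y-randomization and bootstrap consume it.
#'
#' @param series A \code{compound_series} with measured activities.
#' @param config A \code{\link{run_config}}.
#' @return A \code{study_report}: per-property list with
#'   \code{descriptor} (masked dimensionality), \code{ad} (ADReport),
#'   \code{ks} (Kennard-Stone metrics + model), \code{bootstrap}
#'   (\code{mean}/\code{sd} named vectors and per-cycle table),
#'   \code{maps} (VIP and coefficient \code{mia_map}s), plus shared
#'   \code{y}, \code{ids} and \code{config}.
#' @examples
#' \donttest{
#' report <- run_study(ppo_compounds(), run_config(seed = 1))
#' report$models$vdw_radius$ks$r2
#' }
#' @export
run_study <- function(series, config = run_config()) {
  stopifnot(inherits(series, "compound_series"),
            inherits(config, "run_config"))
  y <- activity_vector(series, config$template)
  ids <- names(y)
  out <- list()
  for (prop in config$properties) {
    stage <- function(what, expr) tryCatch(expr, error = function(e)
      stop("[", prop, "/", what, "] ", conditionMessage(e),
           call. = FALSE))
    dm <- stage("encode",
                build_descriptor_matrix(series, prop, config$canvas,
                                        config$template))
    Xm <- masked_matrix(dm)
    # applicability domain on the full series, before splitting
    amax_all <- if (is.null(config$A_max)) min(nrow(Xm) - 2L, 15L)
                else config$A_max
    sel_all <- stage("ad", select_components(Xm, y, amax_all))
    model_all <- pls_fit(Xm, y, sel_all$A)
    ad <- williams_domain(model_all, Xm, y)
    ks_plan <- stage("split",
                     kennard_stone_split(Xm, config$train_fraction))
    ks <- stage("ks_model",
                .evaluate_split(Xm, y, ks_plan, config$A_max,
                                config$yrand_cycles, config$seed))
    plans <- bootstrap_cycles(nrow(Xm), 1 - config$train_fraction,
                              config$bootstrap_cycles, config$seed)
    boot_rows <- lapply(seq_along(plans), function(k)
      stage(paste0("bootstrap_cycle_", k),
            .evaluate_split(Xm, y, plans[[k]], config$A_max,
                            config$yrand_cycles,
                            config$seed + k)))
    boot_tab <- do.call(rbind, lapply(boot_rows, function(r)
      unlist(r[.metric_names])))
    maps <- list(
      vip = fold_map(vip(ks$model), dm$column_mask, config$canvas,
                     "vip"),
      coefficient = fold_map(ks$model$b, dm$column_mask, config$canvas,
                             "coefficient"))
    out[[prop]] <- list(
      descriptor = list(n = nrow(dm$X), p = ncol(dm$X),
                        p_retained = sum(dm$column_mask),
                        column_mask = dm$column_mask),
      full_model = model_all, ad = ad, ks = ks,
      bootstrap = list(mean = colMeans(boot_tab),
                       sd = apply(boot_tab, 2, sd), cycles = boot_tab),
      maps = maps)
  }
  report <- structure(list(models = out, y = y, ids = ids,
                           config = config),
                      class = "study_report")
  if (!is.null(config$output_dir)) write_study_report(report)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("MIA-QSAR study report:", length(x$ids), "compounds;",
      length(x$models), "property model(s)\n")
  print(summary_table(x), digits = 4)
  invisible(x)
}

#' Table of study statistics
#'
#' One column per property model and split strategy (Kennard-Stone point
#' values, bootstrap mean and sd), one row per statistic.
#'
#' @param report A \code{study_report}.
#' @return A data frame.
#' @export
summary_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  cols <- list()
  for (prop in names(report$models)) {
    m <- report$models[[prop]]
    cols[[paste0(prop, " (K-S)")]] <-
      unlist(m$ks[.metric_names])
    cols[[paste0(prop, " (bootst. mean)")]] <-
      m$bootstrap$mean[.metric_names]
    cols[[paste0(prop, " (bootst. sd)")]] <-
      m$bootstrap$sd[.metric_names]
  }
  df <- as.data.frame(cols, check.names = FALSE,
                      row.names = .metric_names)
  df
}

#' Write a study report to disk
#'
#' Emits, under \code{config$output_dir}: \code{summary.csv} (the
#' statistics table), \code{metrics.json}, \code{ad_<property>.csv},
#' \code{splits_<property>.csv} and the four map files per property.
#'
#' @param report A \code{study_report}.
#' @return The output directory, invisibly.
#' @export
write_study_report <- function(report) {
  dir <- report$config$output_dir
  stopifnot(!is.null(dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- summary_table(report)
  write.csv(cbind(statistic = rownames(tab), tab),
            file.path(dir, "summary.csv"), row.names = FALSE)
  js <- lapply(report$models, function(m)
    list(ks = m$ks[.metric_names], bootstrap_mean =
           as.list(m$bootstrap$mean), bootstrap_sd =
           as.list(m$bootstrap$sd),
         ad = list(h_star = attr(m$ad, "h_star"),
                   n_flagged = sum(m$ad$flagged))))
  jsonlite::write_json(js, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (prop in names(report$models)) {
    m <- report$models[[prop]]
    write.csv(as.data.frame(m$ad),
              file.path(dir, paste0("ad_", prop, ".csv")),
              row.names = FALSE)
    write_split_plans(m$ks$plan, report$ids,
                      file.path(dir, paste0("splits_", prop, ".csv")))
    export_heatmap(m$maps$vip,
                   file.path(dir, paste0("vip_", prop, ".png")))
    export_heatmap(m$maps$coefficient,
                   file.path(dir, paste0("coef_", prop, ".png")))
  }
  invisible(dir)
}

#' Predict activities of proposed analogs
#'
#' Encodes each proposal on the study canvas, predicts with each property
#' model and averages the per-model predictions arithmetically. For
#' prediction, models are refit on all compounds (the full-series models
#' of the report); proposals with leverage above \code{h* = 3(A+1)/n} are
#' flagged as extrapolations.
#'
#' @param report A \code{study_report} from \code{\link{run_study}}.
#' @param proposals A \code{compound_series} of query compounds.
#' @return Data frame with one row per proposal: per-model predictions
#'   (\code{pred_<property>}), \code{average}, and
#'   \code{extrapolation} flag.
#' @export
predict_proposals <- function(report, proposals) {
  stopifnot(inherits(report, "study_report"),
            inherits(proposals, "compound_series"))
  cfg <- report$config
  ids <- vapply(proposals, `[[`, "", "id")
  preds <- list()
  extrap <- rep(FALSE, length(proposals))
  for (prop in names(report$models)) {
    m <- report$models[[prop]]
    rows <- do.call(rbind, lapply(proposals, function(sp)
      unfold(rasterize(assemble_molecule(sp, cfg$template), prop,
                       cfg$canvas))))
    Xq <- rows[, m$descriptor$column_mask, drop = FALSE]
    model <- m$full_model
    preds[[paste0("pred_", prop)]] <- predict(model, Xq)
    h <- leverage(model, Xq)
    h_star <- 3 * (model$A + 1) / model$n
    extrap <- extrap | h > h_star
  }
  avg <- Reduce(`+`, preds) / length(preds)
  out <- data.frame(id = ids, preds, average = avg,
                    extrapolation = extrap, check.names = FALSE,
                    row.names = NULL)
  out
}
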