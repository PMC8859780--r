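#' Root mean square error
#'
#' @param truth,pred Equal-length, non-empty numeric vectors.
#' @return `sqrt(mean((truth - pred)^2))`.
#' @export
rmse <- function(truth, pred) {
  if (length(truth) == 0 || length(truth) != length(pred)) {
    stop("truth and pred must be non-empty vectors of equal length",
         call. = FALSE)
  }
  sqrt(mean((truth - pred)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares about the truth
#' mean (the regression-analysis convention; can be negative, never exceeds
#' 1).
#'
#' @param truth,pred Equal-length numeric vectors; `truth` must have nonzero
#'   variance.
#' @return Scalar `R^2`.
#' @export
r_squared <- function(truth, pred) {
  if (length(truth) == 0 || length(truth) != length(pred)) {
    stop("truth and pred must be non-empty vectors of equal length",
         call. = FALSE)
  }
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("truth has zero variance", call. = FALSE)
  1 - sum((truth - pred)^2) / ss_tot
}

#' Evaluate a trained FPM on test datasets
#'
#' Computes RMSE and R^2 in normalized units for each spike feature on each
#' supplied test set (normalized with the FPM's training extrema; values
#' outside `[0,1]` are not clipped).
#'
#' @param fpm A trained FPM ([train_fpm()]).
#' @param test_sets Named list of [feature_dataset()] objects. Names like
#'   `"noise_L4"` carry the noise level; otherwise the mode is taken from the
#'   samples.
#' @return Data frame with one row per test set:
#'   `model, current_type, noise_level, rmse_vmax, rmse_vmin, rmse_twidth,
#'   r2_vmax, r2_vmin, r2_twidth` (full precision) plus rounded
#'   `r2_*_2dp` columns as displayed in reports.
#' @export
evaluate_fpm <- function(fpm, test_sets) {
  stopifnot(inherits(fpm, "trained_mlp"), fpm$module == "fpm")
  rows <- lapply(names(test_sets), function(nm) {
    ds <- test_sets[[nm]]
    s <- apply_normalization(ds$samples, fpm$norm)
    pred <- mlp_forward(fpm$net, as.matrix(s[, c("V1", "V2", "V3")]))
    truth <- as.matrix(s[, c("Vmax", "Vmin", "Twidth")])
    lvl <- s$noise_level[1]
    data.frame(
      model = s$model[1],
      current_type = s$stim_mode[1],
      noise_level = if (is.null(lvl)) NA else lvl,
      n = nrow(s),
      rmse_vmax = rmse(truth[, 1], pred[, 1]),
      rmse_vmin = rmse(truth[, 2], pred[, 2]),
      rmse_twidth = rmse(truth[, 3], pred[, 3]),
      r2_vmax = r_squared(truth[, 1], pred[, 1]),
      r2_vmin = r_squared(truth[, 2], pred[, 2]),
      r2_twidth = r_squared(truth[, 3], pred[, 3]))
  })
  out <- do.call(rbind, rows)
  out$r2_vmax_2dp <- round(out$r2_vmax, 2)
  out$r2_vmin_2dp <- round(out$r2_vmin, 2)
  out$r2_twidth_2dp <- round(out$r2_twidth, 2)
  rownames(out) <- names(test_sets)
  out
}

#' Run the full pipeline for one model
#'
#' Deterministic end-to-end experiment: build the constant-current training
#' set, train the FPM (and optionally an SPM), build the requested test sets
#' (constant on an offset grid, slope, sinusoidal, noise levels 1-4), and
#' evaluate. Quotas scale down with `quick = TRUE` for fast runs.
#'
#' @param model Registry name or [neuron_model()].
#' @param modes Character vector of test modes; `"noise"` expands to the four
#'   levels.
#' @param train_quota,test_quota Sample quotas (full-scale default 2400).
#' @param seed Master seed; stage seeds are derived from it.
#' @param quick Use 300/300 quotas and 200 training iterations.
#' @param train_spm_too Also train an SPM on a constant-current trace.
#' @param config Optional [training_config()] override.
#' @return List with `train` (dataset), `fpm`, `spm` (or NULL), `test_sets`,
#'   and `report` (from [evaluate_fpm()]).
#' @export
run_experiment <- function(model,
                           modes = c("constant", "slope", "sinusoidal",
                                     "noise"),
                           train_quota = 2400, test_quota = 2400, seed = 1,
                           quick = FALSE, train_spm_too = FALSE,
                           config = NULL) {
  if (is.character(model)) model <- get_model(model)
  if (quick) {
    train_quota <- min(train_quota, 300)
    test_quota <- min(test_quota, 300)
    if (is.null(config)) config <- training_config(iterations = 200,
                                                   seed = seed)
  }
  if (is.null(config)) config <- training_config(seed = seed)

  train <- build_dataset(model, "constant", quota = train_quota, seed = seed)
  fpm <- train_fpm(train, config)

  test_sets <- list()
  for (mode in modes) {
    if (mode == "constant") {
      test_sets$constant <- build_dataset(model, "constant",
                                          quota = test_quota,
                                          seed = seed + 1, offset_grid = TRUE)
    } else if (mode == "noise") {
      for (lvl in 1:4) {
        test_sets[[paste0("noise_L", lvl)]] <-
          build_dataset(model, "noise", quota = test_quota,
                        seed = seed + 10 + lvl, level = lvl)
      }
    } else {
      test_sets[[mode]] <- build_dataset(model, mode, quota = test_quota,
                                         seed = seed + 2)
    }
  }
  report <- evaluate_fpm(fpm, test_sets)

  spm <- NULL
  if (train_spm_too) {
    r <- model$constant_range
    tr <- simulate(model, stim_constant(mean(r), if (quick) 2000 else 5000),
                   settle = 100)
    windows <- build_spm_dataset(tr, model$spike_threshold, seed = seed)
    spm <- train_spm(windows, fpm$norm, config)
  }

  list(model = model$name, train = train, fpm = fpm, spm = spm,
       test_sets = test_sets, report = report, seed = seed)
}

#' Write an evaluation report as CSV + JSON
#'
#' @param report Data frame from [evaluate_fpm()].
#' @param path Output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(report, json, digits = NA, dataframe = "rows")
  invisible(c(csv, json))
}
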