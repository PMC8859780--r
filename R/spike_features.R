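#' Spike peak times in a voltage trace
#'
#' Peak times of every complete spike: for each upward crossing of the
#' threshold, the maximum before the next downward crossing. Unlike
#' [detect_spikes()] this keeps the final spike even when its
#' afterhyperpolarization window is cut off by the trace end, so it is the
#' right primitive for counting spikes (f-I curves, firing-pattern checks).
#'
#' @param trace A [voltage_trace()].
#' @param threshold Detection voltage, mV.
#' @return Numeric vector of peak times (ms), ordered.
#' @export
spike_peaks <- function(trace, threshold = -10) {
  V <- trace$V
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  down <- which(V[-length(V)] >= threshold & V[-1] < threshold)
  if (length(up) == 0) return(numeric(0))
  tt <- trace_times(trace)
  out <- numeric(0)
  for (u in up) {
    d <- down[down >= u]
    if (length(d) == 0) next  # trace ends above threshold: incomplete spike
    seg <- u:(d[1] + 1)
    out <- c(out, tt[seg[which.max(V[seg])]])
  }
  out
}

#' Detect spikes and extract their features
#'
#' Segments a trace at upward threshold crossings. For each crossing, the
#' spike peak (`t_max`, `V_max`) is the maximum up to the next downward
#' crossing; the afterhyperpolarization trough (`t_min`, `V_min`) is the
#' minimum between the peak and the next upward crossing (or, for the final
#' spike, the trace end). Spikes whose trough search is truncated by the
#' trace end -- the minimum falls on the very last sample, so the true trough
#' may lie beyond the trace -- are discarded; a final spike whose
#' afterhyperpolarization demonstrably bottoms out before the trace ends
#' (e.g. an onset spike of a phasic neuron) is kept.
#'
#' @param trace A [voltage_trace()].
#' @param threshold Detection voltage, mV; defaults to -10.
#' @return Data frame with columns `t_max`, `V_max`, `t_min`, `V_min`,
#'   `T_width`, ordered by `t_max`. Zero rows when no spike is found.
#' @export
detect_spikes <- function(trace, threshold = -10) {
  V <- trace$V
  stopifnot(all(is.finite(V)))
  tt <- trace_times(trace)
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  down <- which(V[-length(V)] >= threshold & V[-1] < threshold)
  empty <- data.frame(t_max = numeric(0), V_max = numeric(0),
                      t_min = numeric(0), V_min = numeric(0),
                      T_width = numeric(0))
  if (length(up) < 1) return(empty)
  rows <- vector("list", length(up))
  for (i in seq_along(up)) {
    u <- up[i]
    d <- down[down >= u]
    if (length(d) == 0) next  # trace ends above threshold: incomplete spike
    peak_seg <- u:(d[1] + 1)
    pk <- peak_seg[which.max(V[peak_seg])]
    # trough window ends at the next upward crossing, or the trace end
    w_end <- if (i < length(up)) up[i + 1] else length(V)
    trough_seg <- pk:w_end
    tr_i <- trough_seg[which.min(V[trough_seg])]
    if (i == length(up) && tr_i == length(V)) next  # truncated trough
    rows[[i]] <- data.frame(t_max = tt[pk], V_max = V[pk],
                            t_min = tt[tr_i], V_min = V[tr_i],
                            T_width = tt[tr_i] - tt[pk])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Pre-peak voltage window of a spike
#'
#' The three sequential voltages with 1 ms spacing preceding the spike peak:
#' `V1` at `t_max - 3` ms, `V2` at `t_max - 2` ms, `V3` at `t_max - 1` ms.
#' Sample times are exact multiples of the trace grid.
#'
#' @param trace A [voltage_trace()].
#' @param t_max Spike peak time(s), ms.
#' @return Data frame with columns `V1`, `V2`, `V3` (one row per peak). Peaks
#'   whose window precedes the trace start are dropped; the number dropped is
#'   attached as attribute `"skipped"`.
#' @export
extract_window <- function(trace, t_max) {
  tt0 <- trace$t0
  n <- length(trace$V)
  idx_at <- function(t) round((t - tt0) / trace$dt) + 1
  ok <- idx_at(t_max - 3) >= 1 & idx_at(t_max) <= n
  skipped <- sum(!ok)
  t_ok <- t_max[ok]
  out <- data.frame(V1 = trace$V[idx_at(t_ok - 3)],
                    V2 = trace$V[idx_at(t_ok - 2)],
                    V3 = trace$V[idx_at(t_ok - 1)])
  attr(out, "skipped") <- skipped
  out
}

feature_cols <- c("V1", "V2", "V3", "Vmax", "Vmin", "Twidth")

#' Feature dataset for one model
#'
#' A labelled set of `(V1,V2,V3) -> (Vmax,Vmin,Twidth)` samples plus optional
#' min-max normalization extrema (always derived from a training split).
#'
#' @param samples Data frame with at least the columns
#'   `V1,V2,V3,Vmax,Vmin,Twidth` (plus provenance columns).
#' @param split `"train"` or `"test"`.
#' @param norm Optional normalization extrema (see [fit_normalization()]).
#' @return A `feature_dataset` object.
#' @export
feature_dataset <- function(samples, split = "train", norm = NULL) {
  stopifnot(all(feature_cols %in% names(samples)))
  structure(list(samples = samples, split = split, norm = norm),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d samples (%s split)%s\n",
              nrow(x$samples), x$split,
              if (is.null(x$norm)) "" else ", normalized"))
  invisible(x)
}

#' Min-max normalization of feature datasets
#'
#' All six quantities (the three window voltages and three labels) are scaled
#' to `[0,1]` using extrema recorded from a training split. Test-split values
#' may fall outside `[0,1]` and are not clipped. `denormalize_features()`
#' inverts the scaling exactly.
#'
#' @param dataset A [feature_dataset()] (the training split).
#' @return For `fit_normalization`, a data frame of per-quantity `min`/`max`.
#' @export
fit_normalization <- function(dataset) {
  s <- dataset$samples
  lo <- vapply(feature_cols, function(cc) min(s[[cc]]), numeric(1))
  hi <- vapply(feature_cols, function(cc) max(s[[cc]]), numeric(1))
  if (any(hi - lo <= 0)) {
    stop("degenerate dataset: zero range for ",
         paste(feature_cols[hi - lo <= 0], collapse = ", "), call. = FALSE)
  }
  data.frame(quantity = feature_cols, min = lo, max = hi,
             row.names = feature_cols)
}

#' @rdname fit_normalization
#' @param x A data frame (or [feature_dataset()]) containing some of the six
#'   quantities.
#' @param norm Extrema from [fit_normalization()].
#' @export
apply_normalization <- function(x, norm) {
  if (inherits(x, "feature_dataset")) {
    x$samples <- apply_normalization(x$samples, norm)
    x$norm <- norm
    return(x)
  }
  for (cc in intersect(feature_cols, names(x))) {
    x[[cc]] <- (x[[cc]] - norm[cc, "min"]) / (norm[cc, "max"] - norm[cc, "min"])
  }
  x
}

#' @rdname fit_normalization
#' @param values Matrix or data frame of normalized label columns
#'   (`Vmax`, `Vmin`, `Twidth`).
#' @export
denormalize_features <- function(values, norm) {
  values <- as.data.frame(values)
  for (cc in intersect(feature_cols, names(values))) {
    values[[cc]] <- values[[cc]] * (norm[cc, "max"] - norm[cc, "min"]) +
      norm[cc, "min"]
  }
  values
}

# samples from one trace: windows + labels + provenance
collect_samples <- function(trace, model, stim_mode, noise_level = NA,
                            seed = NA, min_t = NULL) {
  sp <- detect_spikes(trace, model$spike_threshold)
  if (is.null(min_t)) min_t <- trace$t0 + 3
  sp <- sp[sp$t_max >= min_t & sp$t_max > 0, , drop = FALSE]
  if (nrow(sp) == 0) return(NULL)
  w <- extract_window(trace, sp$t_max)
  keep <- round((sp$t_max - 3 - trace$t0) / trace$dt) + 1 >= 1
  sp <- sp[keep, , drop = FALSE]
  intensity <- if (trace$stimulus$mode == "noise") {
    rep(trace$stimulus$I0, nrow(sp))
  } else {
    stimulus_value(trace$stimulus, pmin(sp$t_max, trace$stimulus$duration))
  }
  data.frame(model = model$name, stim_mode = stim_mode,
             noise_level = noise_level, seed = seed, intensity = intensity,
             t_max = sp$t_max, V1 = w$V1, V2 = w$V2, V3 = w$V3,
             Vmax = sp$V_max, Vmin = sp$V_min, Twidth = sp$T_width)
}

#' Build a labelled feature dataset for a model
#'
#' Training data come from a sweep of constant currents across the model's
#' configured range; test data from constant (an offset intensity grid),
#' slope, sinusoidal, or Gaussian-noise current. Traces are simulated at
#' `dt = 0.01` ms with a 100 ms settling period; samples are collected in
#' trace time order until the quota is met (for the constant sweep,
#' round-robin across intensities so per-intensity counts stay balanced).
#'
#' @param model A [neuron_model()] or registry name (needs `constant_range`).
#' @param mode One of `"constant"`, `"slope"`, `"sinusoidal"`, `"noise"`.
#' @param quota Number of samples required (default 2400, the per-model
#'   training size; 2400 per mode / per noise level for testing).
#' @param seed Integer seed (noise draws; recorded as provenance).
#' @param level Noise level 1-4 (noise mode only).
#' @param n_intensities Grid size for the constant sweep.
#' @param offset_grid For `mode = "constant"`: shift the intensity grid by
#'   half a grid step (used to build test sets disjoint from training).
#' @param trace_duration Initial per-trace duration, ms (extended
#'   automatically if the quota is not reached).
#' @param max_sim_time Per-call simulated-time budget, ms; exceeding it with
#'   an unmet quota is an error reporting the samples found.
#' @param settle Settling time before stimulus onset, ms.
#' @param keep_settle Pre-onset margin (ms) retained in each trace so that
#'   pre-peak windows of short-latency onset spikes stay inside it. Zero by
#'   default; required for phasic (onset-only) models, whose spikes fire
#'   within ~3 ms of stimulus onset.
#' @param dt Integration step, ms.
#' @return A [feature_dataset()] with exactly `quota` samples.
#' @export
build_dataset <- function(model, mode = "constant", quota = 2400, seed = 1,
                          level = 4, n_intensities = 64, offset_grid = FALSE,
                          trace_duration = 500, max_sim_time = 4e5,
                          settle = 100, keep_settle = 0, dt = 0.01) {
  if (is.character(model)) model <- get_model(model)
  r <- model$constant_range
  if (is.null(r)) stop("model '", model$name, "' has no constant_range")
  mode <- match.arg(mode, c("constant", "slope", "sinusoidal", "noise"))

  if (mode %in% c("constant", "noise")) {
    # noise rides on the same intensity sweep as the constant protocol: a
    # single-baseline noise set has almost no feature variance, which makes
    # R^2 on it meaningless
    step <- diff(r) / n_intensities
    grid <- r[1] + (seq_len(n_intensities) - 1 + 0.5 * offset_grid) * step
    dur <- trace_duration
    repeat {
      per <- lapply(seq_along(grid), function(i) {
        stim <- if (mode == "constant") stim_constant(grid[i], dur)
                else stim_noise(grid[i], level, r, seed + i, dur, dt)
        tr <- simulate(model, stim, dt = dt, settle = settle,
                       keep_settle = keep_settle)
        collect_samples(tr, model, mode,
                        noise_level = if (mode == "noise") level else NA,
                        seed = seed)
      })
      per <- per[!vapply(per, is.null, logical(1))]
      total <- sum(vapply(per, nrow, integer(1)))
      if (total >= quota) break
      dur <- dur * 2
      if (dur * length(grid) > max_sim_time) {
        stop(sprintf(
          "quota %d unreachable within %g ms simulated (found %d samples)",
          quota, max_sim_time, total), call. = FALSE)
      }
    }
    # round-robin across intensities keeps per-intensity counts balanced
    maxn <- max(vapply(per, nrow, integer(1)))
    order_idx <- unlist(lapply(seq_len(maxn), function(k)
      lapply(seq_along(per), function(j)
        if (k <= nrow(per[[j]])) per[[j]][k, , drop = FALSE])),
      recursive = FALSE)
    samples <- do.call(rbind, order_idx[!vapply(order_idx, is.null,
                                                logical(1))])[seq_len(quota), ]
  } else {
    dur <- trace_duration
    repeat {
      stim <- default_stimulus(model, mode, dur, level = level, seed = seed,
                               dt = dt)
      tr <- simulate(model, stim, dt = dt, settle = settle,
                     keep_settle = keep_settle, seed = seed)
      samples <- collect_samples(tr, model, mode,
                                 noise_level = if (mode == "noise") level
                                               else NA,
                                 seed = seed)
      if (!is.null(samples) && nrow(samples) >= quota) break
      dur <- dur * 2
      if (dur > max_sim_time) {
        stop(sprintf(
          "quota %d unreachable within %g ms simulated (found %d samples)",
          quota, max_sim_time,
          if (is.null(samples)) 0L else nrow(samples)), call. = FALSE)
      }
    }
    samples <- samples[seq_len(quota), ]
  }
  rownames(samples) <- NULL
  feature_dataset(samples, split = if (offset_grid || mode != "constant")
    "test" else "train")
}
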