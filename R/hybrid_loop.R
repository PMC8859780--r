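#' Hybrid SPM/FPM prediction loop
#'
#' Slides a 3-sample window (voltages at `t`, `t+1`, `t+2` ms) along a
#' reference voltage trace. If the SPM output exceeds 0.5 the window is handed
#' to the FPM, a prediction event is emitted, and the window restarts at
#' `t + 3 ms + predicted T_width` (rounded to the integration grid);
#' otherwise the window advances by 0.01 ms. The loop stops once `t + 2 ms`
#' would pass `stop_time`.
#'
#' @param trace A [voltage_trace()] providing the reference voltages.
#' @param spm A trained SPM ([train_spm()]).
#' @param fpm A trained FPM ([train_fpm()]); must share the SPM's
#'   normalization.
#' @param stop_time Stop time, ms; defaults to the trace end.
#' @return A `hybrid_result`: list with `events` (data frame `t`, `spm_out`,
#'   `t_peak = t + 3`, `Vmax`, `Vmin`, `Twidth`), `n_windows` evaluated and
#'   `n_gated`.
#' @export
run_hybrid <- function(trace, spm, fpm, stop_time = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (!identical(dim(spm$norm), dim(fpm$norm)) ||
      max(abs(spm$norm$min - fpm$norm$min),
          abs(spm$norm$max - fpm$norm$max)) > 1e-12) {
    stop("SPM and FPM were trained under different normalizations",
         call. = FALSE)
  }
  tt <- trace_times(trace)
  t_end <- tt[length(tt)]
  if (is.null(stop_time)) stop_time <- t_end
  if (stop_time > t_end + 1e-9 || stop_time - trace$t0 < 2) {
    stop("trace does not cover [t0, stop_time] with a 2 ms window margin",
         call. = FALSE)
  }
  dt <- trace$dt
  steps_ms <- round(1 / dt)
  n <- length(trace$V)
  # candidate window starts on the grid; window spans [t, t+2ms]
  last_start <- floor((stop_time - trace$t0 - 2) / dt + 1e-9) + 1
  starts <- seq_len(min(last_start, n - 2 * steps_ms))
  W <- cbind(trace$V[starts],
             trace$V[starts + steps_ms],
             trace$V[starts + 2 * steps_ms])
  colnames(W) <- c("V1", "V2", "V3")
  spm_out <- spm_output(spm, W)  # vectorized; the loop walks this array

  events <- list()
  i <- 1L
  n_windows <- 0L
  while (i <= length(starts)) {
    n_windows <- n_windows + 1L
    if (spm_out[i] > 0.5) {
      # a continuous gate necessarily crosses 0.5 a step or two before the
      # exact pre-peak alignment; advance to the local maximum of the SPM
      # output (a few hundredths of a ms) before predicting
      while (i < length(starts) && spm_out[i + 1] > spm_out[i]) {
        i <- i + 1L
        n_windows <- n_windows + 1L
      }
      pred <- fpm_predict(fpm, W[i, ])
      t_i <- tt[starts[i]]
      events[[length(events) + 1L]] <- data.frame(
        t = t_i, spm_out = spm_out[i], t_peak = t_i + 3,
        Vmax = pred$Vmax, Vmin = pred$Vmin, Twidth = pred$Twidth)
      jump <- 3 + pred$Twidth
      i <- i + as.integer(round(jump / dt))
    } else {
      i <- i + 1L
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(t = numeric(0), spm_out = numeric(0), t_peak = numeric(0),
               Vmax = numeric(0), Vmin = numeric(0), Twidth = numeric(0))
  structure(list(events = events, n_windows = n_windows,
                 n_gated = nrow(events), stop_time = stop_time),
            class = "hybrid_result")
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf("<hybrid_result> %d events from %d windows (stop %g ms)\n",
              nrow(x$events), x$n_windows, x$stop_time))
  invisible(x)
}

#' Match prediction events to ground-truth spikes
#'
#' Greedy one-to-one nearest-time matching within a tolerance: pairs are
#' considered in order of increasing time difference; each event and each
#' true spike is used at most once.
#'
#' @param events Event data frame from [run_hybrid()] (or any data frame with
#'   a `t_peak` column), or a numeric vector of predicted peak times.
#' @param truth Data frame of true spikes from [detect_spikes()] (column
#'   `t_max`), or a numeric vector of true peak times.
#' @param tolerance_ms Maximum |time difference| for a match (default 1 ms).
#' @return List with `matches` (data frame of paired indices, times, and --
#'   when both sides carry features -- signed per-feature errors), `misses`
#'   (unmatched truth indices), `false_alarms` (unmatched event indices),
#'   `recall` and `precision`.
#' @export
match_events <- function(events, truth, tolerance_ms = 1) {
  stopifnot(tolerance_ms > 0)
  ev_t <- if (is.numeric(events)) events else events$t_peak
  tr_t <- if (is.numeric(truth)) truth else truth$t_max
  ne <- length(ev_t); nt <- length(tr_t)
  pairs <- expand.grid(ev = seq_len(ne), tr = seq_len(nt))
  if (nrow(pairs)) {
    pairs$d <- abs(ev_t[pairs$ev] - tr_t[pairs$tr])
    pairs <- pairs[pairs$d <= tolerance_ms, , drop = FALSE]
    pairs <- pairs[order(pairs$d), , drop = FALSE]
  }
  used_ev <- logical(ne); used_tr <- logical(nt)
  keep <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    e <- pairs$ev[k]; tr <- pairs$tr[k]
    if (!used_ev[e] && !used_tr[tr]) {
      used_ev[e] <- TRUE; used_tr[tr] <- TRUE
      keep <- c(keep, k)
    }
  }
  m <- pairs[keep, , drop = FALSE]
  matches <- data.frame(event = m$ev, truth = m$tr,
                        t_event = ev_t[m$ev], t_truth = tr_t[m$tr],
                        dt = ev_t[m$ev] - tr_t[m$tr])
  if (!is.numeric(events) && !is.numeric(truth) &&
      all(c("Vmax", "Vmin", "Twidth") %in% names(events)) &&
      all(c("V_max", "V_min", "T_width") %in% names(truth))) {
    matches$err_Vmax <- events$Vmax[m$ev] - truth$V_max[m$tr]
    matches$err_Vmin <- events$Vmin[m$ev] - truth$V_min[m$tr]
    matches$err_Twidth <- events$Twidth[m$ev] - truth$T_width[m$tr]
  }
  list(matches = matches,
       misses = which(!used_tr),
       false_alarms = which(!used_ev),
       recall = if (nt == 0) NA_real_ else sum(used_tr) / nt,
       precision = if (ne == 0) NA_real_ else sum(used_ev) / ne)
}
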