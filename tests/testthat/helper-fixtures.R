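# Shared fixtures, all built in code at test time.

# a pure-leak "model": C dV/dt = -g (V - E) + I
leak_model <- function(g = 1, E = 0, C = 1) {
  neuron_model("leak_only", C_m = C, g_leak = g, E_leak = E,
               channels = list(), V_rest_hint = E)
}

# piecewise-linear voltage trace through (t, V) anchor points on a dt grid
anchored_trace <- function(anchors, dt = 0.01) {
  tt <- seq(anchors$t[1], anchors$t[nrow(anchors)], by = dt)
  voltage_trace(approx(anchors$t, anchors$V, xout = tt)$y, dt = dt,
                t0 = anchors$t[1], model = "fixture")
}

# triangular spike fixture: rest -65, peak 40 mV at t=10, trough -80 at t=12,
# partial recovery above threshold (second incomplete spike), then the trace
# ends mid-descent so the trailing spike is dropped
triangle_trace <- function() {
  anchored_trace(data.frame(
    t = c(0, 8, 10, 12, 14, 16),
    V = c(-65, -65, 40, -80, 0, -65)))
}

# brute-force spike-feature oracle: naive forward scan per upward crossing,
# independent of detect_spikes' vectorized bookkeeping
oracle_spikes <- function(trace, threshold) {
  V <- trace$V
  tt <- trace_times(trace)
  n <- length(V)
  out <- NULL
  i <- 2
  while (i <= n) {
    if (V[i - 1] < threshold && V[i] >= threshold) {
      j <- i
      while (j <= n && V[j] >= threshold) j <- j + 1  # scan to down-crossing
      if (j > n) break
      pk <- which.max(V[i:j]) + i - 1
      k <- pk
      nxt <- pk
      while (nxt < n && !(V[nxt] < threshold && V[nxt + 1] >= threshold)) {
        nxt <- nxt + 1
      }
      w_end <- if (nxt < n) nxt else n
      tr_i <- which.min(V[pk:w_end]) + pk - 1
      keep <- !(nxt >= n && tr_i == n)
      if (keep) {
        out <- rbind(out, data.frame(t_max = tt[pk], V_max = V[pk],
                                     t_min = tt[tr_i], V_min = V[tr_i],
                                     T_width = tt[tr_i] - tt[pk]))
      }
      i <- nxt + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(out)) {
    out <- data.frame(t_max = numeric(0), V_max = numeric(0),
                      t_min = numeric(0), V_min = numeric(0),
                      T_width = numeric(0))
  }
  out
}

# lazily cached full-protocol pipelines shared by the acceptance tests
.pipelines <- new.env(parent = emptyenv())
get_pipeline <- function(model_name, quota = 2400) {
  key <- paste0(model_name, "_", quota)
  if (is.null(.pipelines[[key]])) {
    train <- build_dataset(model_name, "constant", quota = quota, seed = 1)
    fpm <- train_fpm(train, training_config(seed = 1))
    test <- build_dataset(model_name, "constant", quota = quota, seed = 2,
                          offset_grid = TRUE)
    .pipelines[[key]] <- list(train = train, fpm = fpm, test = test)
  }
  .pipelines[[key]]
}
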