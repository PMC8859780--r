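#' @useDynLib spikefeat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Flatten a neuron_model into the numeric layout the C++ integrator parses.
compile_model <- function(model) {
  mg <- model_gates(model)
  gate_names <- names(mg)
  gates <- lapply(gate_names, function(nm) {
    k <- mg[[nm]]$kin
    list(name = nm,
         rate_based = (k$type == "rate"),
         instantaneous = k$instantaneous,
         phi = k$phi,
         f1 = list(form = RATE_FORM_CODES[[k$f1$form]], params = k$f1$params),
         f2 = list(form = RATE_FORM_CODES[[k$f2$form]], params = k$f2$params))
  })
  channels <- lapply(model$channels, function(ch) {
    cg <- channel_gates(ch)
    list(g_max = ch$g_max, E = ch$E_ion,
         gate_idx = match(names(cg), gate_names),
         exponent = vapply(cg, `[[`, numeric(1), "exponent"))
  })
  list(C_m = model$C_m, g_leak = model$g_leak, E_leak = model$E_leak,
       gates = gates, channels = channels, gate_names = gate_names)
}

#' Uniformly sampled voltage trace
#'
#' @param V Numeric vector of membrane potentials (mV) at `t0 + (0:n)*dt`.
#' @param dt Sample interval, ms.
#' @param t0 Time of the first sample, ms.
#' @param model Name of the generating model (provenance).
#' @param stimulus The stimulus spec used (provenance).
#' @param gates Optional matrix of gate trajectories (one column per gate).
#' @return A `voltage_trace` object.
#' @export
voltage_trace <- function(V, dt, t0 = 0, model = NA_character_,
                          stimulus = NULL, gates = NULL) {
  stopifnot(dt > 0, all(is.finite(V)))
  structure(list(V = as.numeric(V), dt = dt, t0 = t0, model = model,
                 stimulus = stimulus, gates = gates),
            class = "voltage_trace")
}

#' Sample times of a voltage trace
#' @param trace A [voltage_trace()].
#' @return Numeric vector of times (ms).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$V) - 1) * trace$dt
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %s: %d samples, dt=%g ms, t=[%g, %g] ms, V=[%.1f, %.1f] mV\n",
    x$model, length(x$V), x$dt, x$t0, x$t0 + (length(x$V) - 1) * x$dt,
    min(x$V), max(x$V)))
  invisible(x)
}

#' @export
as.data.frame.voltage_trace <- function(x, ...) {
  df <- data.frame(t_ms = trace_times(x), V_mV = x$V)
  if (!is.null(x$gates)) df <- cbind(df, as.data.frame(x$gates))
  df
}

#' One classical fourth-order Runge-Kutta step (reference implementation)
#'
#' Advances a model state by `dt` using [membrane_rhs()] at the four stages.
#' The stimulus is evaluated at `t`, `t + dt/2` and `t + dt`; a noise stimulus
#' is frozen over the step (its value at `t` is used for every stage). This is
#' the R-level reference; [simulate()] runs the same scheme in compiled code.
#'
#' @param model A [neuron_model()].
#' @param state List with `V` and named `gates` vector.
#' @param stimulus A stimulus spec, or a single number (constant current).
#' @param t Step start time, ms.
#' @param dt Step size, ms (> 0).
#' @return The state after the step.
#' @export
rk4_step <- function(model, state, stimulus, t, dt) {
  stopifnot(dt > 0)
  Iat <- function(tt) {
    if (is.numeric(stimulus)) return(stimulus)
    if (stimulus$mode == "noise") return(stimulus_value(stimulus, t))
    stimulus_value(stimulus, min(tt, stimulus$duration))
  }
  add <- function(s, k, h) {
    list(V = s$V + h * k$dV, gates = s$gates + h * k$dgates)
  }
  k1 <- membrane_rhs(model, state, Iat(t), t)
  k2 <- membrane_rhs(model, add(state, k1, dt / 2), Iat(t + dt / 2), t + dt / 2)
  k3 <- membrane_rhs(model, add(state, k2, dt / 2), Iat(t + dt / 2), t + dt / 2)
  k4 <- membrane_rhs(model, add(state, k3, dt), Iat(t + dt), t + dt)
  V_new <- state$V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
  g_new <- state$gates +
    dt / 6 * (k1$dgates + 2 * k2$dgates + 2 * k3$dgates + k4$dgates)
  if (!is.finite(V_new)) {
    stop(sprintf("integration blow-up at t = %g ms", t + dt), call. = FALSE)
  }
  mg <- model_gates(model)
  for (nm in names(mg)) {
    if (mg[[nm]]$kin$instantaneous) g_new[[nm]] <- gate_inf(mg[[nm]]$kin, V_new)
  }
  list(V = V_new, gates = pmin(pmax(g_new, 0), 1))
}

#' Simulate a neuron model under a stimulus
#'
#' Fixed-step RK4 integration at `dt` (default 0.01 ms). The state is
#' initialized at `V_rest_hint` with gates at steady state; an optional
#' settling period at zero input precedes stimulus onset (the returned trace
#' starts at onset, t = 0). Deterministic given `(model, stimulus, seed, dt)`.
#'
#' @param model A [neuron_model()] or a registry name (see [get_model()]).
#' @param stimulus A stimulus spec (see [stimuli]); its duration caps the
#'   simulated time.
#' @param duration Simulated duration, ms; defaults to the stimulus duration.
#' @param dt Step size, ms.
#' @param seed Seed filled into a noise stimulus that lacks one.
#' @param settle Settling time at zero input before onset, ms.
#' @param keep_settle Portion of the settling period (ms, from its end) to
#'   retain in the returned trace; the trace then starts at `t0 = -keep_settle`
#'   with zero injected current before onset. Lets pre-peak windows of
#'   short-latency onset spikes stay inside the trace.
#' @param record_gates Record gate trajectories in the trace.
#' @param init Optional initial state (list `V`, `gates`) overriding the
#'   steady-state initialization.
#' @return A [voltage_trace()].
#' @examples
#' \donttest{
#' hh <- get_model("ClassII_excitable")
#' tr <- simulate(hh, stim_constant(10, 200))
#' max(tr$V) > 0  # repetitive spiking
#' }
#' @export
simulate <- function(model, stimulus, duration = stimulus$duration, dt = 0.01,
                     seed = NULL, settle = 0, keep_settle = 0,
                     record_gates = FALSE, init = NULL) {
  if (is.character(model)) model <- get_model(model)
  stopifnot(inherits(model, "neuron_model"),
            inherits(stimulus, "stimulus_spec"), duration >= dt)
  if (duration > stimulus$duration + 1e-9) {
    stop("duration exceeds stimulus duration")
  }
  if (stimulus$mode == "noise" && is.null(stimulus$seed)) {
    if (is.null(seed)) stop("noise stimulus needs a seed")
    stimulus$seed <- as.integer(seed)
  }
  cm <- compile_model(model)
  if (is.null(init)) {
    g0 <- steady_state_gates(model, model$V_rest_hint)
    y0 <- c(model$V_rest_hint, g0)
  } else {
    y0 <- c(init$V, init$gates[cm$gate_names])
  }
  stopifnot(keep_settle >= 0, keep_settle <= settle)
  pre_V <- NULL
  pre_G <- NULL
  if (settle > 0) {
    n0 <- round((settle - keep_settle) / dt)
    if (n0 > 0) {
      zero <- rep(0, n0)
      pre <- .rk4_integrate(cm, y0, zero, zero, zero, dt, FALSE, 1e-6)
      y0 <- pre$final_state
    }
    if (keep_settle > 0) {
      nk <- round(keep_settle / dt)
      zero <- rep(0, nk)
      pre <- .rk4_integrate(cm, y0, zero, zero, zero, dt, record_gates, 1e-6)
      y0 <- pre$final_state
      pre_V <- pre$V[-(nk + 1)]  # the last sample doubles as stimulus onset
      if (record_gates) pre_G <- pre$gates[-(nk + 1), , drop = FALSE]
    }
  }
  n_steps <- round(duration / dt)
  ser <- stimulus_series(stimulus, n_steps, dt)
  out <- .rk4_integrate(cm, y0, ser$start, ser$mid, ser$end, dt,
                        record_gates, 1e-6)
  gates <- NULL
  if (record_gates) {
    gates <- rbind(pre_G, out$gates)
    colnames(gates) <- cm$gate_names
  }
  voltage_trace(c(pre_V, out$V), dt = dt, t0 = -keep_settle,
                model = model$name, stimulus = stimulus, gates = gates)
}

#' Firing frequency versus injected current (f-I curve)
#'
#' Simulates the model at each intensity for `duration` ms, discards an
#' initial transient, and reports the steady firing frequency
#' `(n_spikes - 1) / (t_last - t_first)` on the retained window (0 if fewer
#' than two spikes).
#'
#' @param model A [neuron_model()] or registry name.
#' @param intensities Numeric vector of constant currents, uA/cm^2.
#' @param duration Simulated time per intensity, ms.
#' @param transient Initial window to discard, ms.
#' @param dt Step size, ms.
#' @return Data frame with columns `I` and `freq_Hz`.
#' @export
f_i_curve <- function(model, intensities, duration = 1000, transient = 200,
                      dt = 0.01) {
  if (is.character(model)) model <- get_model(model)
  freq <- vapply(intensities, function(I) {
    tr <- simulate(model, stim_constant(I, duration), dt = dt)
    pk <- spike_peaks(tr, model$spike_threshold)
    pk <- pk[pk >= transient]
    if (length(pk) < 2) return(0)
    1000 * (length(pk) - 1) / (pk[length(pk)] - pk[1])
  }, numeric(1))
  data.frame(I = intensities, freq_Hz = freq)
}

#' Rheobase estimate by bisection
#'
#' Coarse bisection on the minimal constant current eliciting sustained
#' firing (>= 2 spikes after the transient) within `duration` ms.
#'
#' @inheritParams f_i_curve
#' @param lower,upper Bracketing intensities, uA/cm^2.
#' @param tol Bisection tolerance, uA/cm^2.
#' @return Estimated rheobase, uA/cm^2.
#' @export
rheobase <- function(model, lower = 0, upper = 20, duration = 1000,
                     tol = 0.05, dt = 0.01) {
  if (is.character(model)) model <- get_model(model)
  fires <- function(I) {
    tr <- simulate(model, stim_constant(I, duration), dt = dt)
    pk <- spike_peaks(tr, model$spike_threshold)
    sum(pk >= 200) >= 2
  }
  if (!fires(upper)) stop("model does not fire at the upper bracket")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (fires(mid)) upper <- mid else lower <- mid
  }
  upper
}
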