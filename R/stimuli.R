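#' Injected-current stimulus protocols
#'
#' Four stimulus modes are used for dataset generation and testing: constant,
#' slope (linear ramp), sinusoidal, and Gaussian noise at four levels. Noise
#' draws are held piecewise-constant over each integration step (one draw per
#' `dt`, the same value seen by all four Runge-Kutta stages), which keeps the
#' integrator deterministic given a seed.
#'
#' @param I0 Baseline / constant amplitude, uA/cm^2.
#' @param duration Stimulus duration, ms (> 0).
#' @name stimuli
NULL

new_stimulus <- function(mode, duration, ...) {
  stopifnot(duration > 0)
  structure(c(list(mode = mode, duration = duration), list(...)),
            class = "stimulus_spec")
}

#' @rdname stimuli
#' @export
stim_constant <- function(I0, duration) new_stimulus("constant", duration, I0 = I0)

#' @rdname stimuli
#' @param I_a,I_b Ramp start and end amplitudes, uA/cm^2.
#' @export
stim_slope <- function(I_a, I_b, duration) {
  new_stimulus("slope", duration, I_a = I_a, I_b = I_b)
}

#' @rdname stimuli
#' @param A Sinusoid amplitude, uA/cm^2.
#' @param f Frequency, Hz.
#' @param phase Phase offset, radians.
#' @export
stim_sinusoidal <- function(I0, A, f, duration, phase = 0) {
  new_stimulus("sinusoidal", duration, I0 = I0, A = A, f = f, phase = phase)
}

#' @rdname stimuli
#' @param level Noise level in `{1,2,3,4}`; the +/- 2 sigma span of the noise
#'   covers 25/50/75/100 percent of `range`.
#' @param range Length-2 numeric, the constant-current sweep range
#'   `(I_min, I_max)` the levels are defined against.
#' @param seed Integer seed for the Gaussian draws (recorded for
#'   reproducibility).
#' @param dt Integration step the draws are frozen over, ms.
#' @export
stim_noise <- function(I0, level, range, seed, duration, dt = 0.01) {
  if (!level %in% 1:4) stop("noise level must be one of 1, 2, 3, 4")
  stopifnot(length(range) == 2, range[2] >= range[1], dt > 0)
  new_stimulus("noise", duration, I0 = I0, level = as.integer(level),
               range = as.numeric(range), seed = as.integer(seed), dt = dt,
               sigma = noise_sigma(level, range))
}

#' Noise standard deviation for a given level
#'
#' Level `L` noise covers `L/4` of the constant-current sweep range with its
#' central +/- 2 sigma span: `sigma = (L/4) * (I_max - I_min) / 4`.
#'
#' @param level Integer in `{1,2,3,4}`.
#' @param range Length-2 numeric `(I_min, I_max)`, uA/cm^2.
#' @return Standard deviation, uA/cm^2.
#' @examples
#' noise_sigma(4, c(7, 15))  # 2.0
#' @export
noise_sigma <- function(level, range) {
  if (!level %in% 1:4) stop("noise level must be one of 1, 2, 3, 4")
  span <- range[2] - range[1]
  if (span < 0) stop("range must satisfy I_max >= I_min")
  if (span == 0) warning("degenerate constant range: sigma = 0")
  (level / 4) * span / 4
}

# the frozen per-step noise draws for steps 1..n_steps
noise_draws <- function(spec, n_steps) {
  stopifnot(spec$mode == "noise")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  spec$I0 + stats::rnorm(n_steps, 0, spec$sigma)
}

#' Evaluate a stimulus at time t
#'
#' For the noise mode the value at `t` is the frozen draw of integration step
#' `floor(t / dt)`, regenerated deterministically from the recorded seed.
#'
#' @param spec A stimulus specification (see [stimuli]).
#' @param t Time(s) within `[0, duration]`, ms.
#' @return Injected current, uA/cm^2 (vectorized over `t`).
#' @export
stimulus_value <- function(spec, t) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (any(t < 0 | t > spec$duration)) {
    stop(sprintf("t outside stimulus domain [0, %g]", spec$duration),
         call. = FALSE)
  }
  switch(spec$mode,
    constant = rep(spec$I0, length(t)),
    slope = spec$I_a + (spec$I_b - spec$I_a) * t / spec$duration,
    sinusoidal = spec$I0 +
      spec$A * sin(2 * pi * spec$f * t / 1000 + spec$phase),
    noise = {
      k <- pmin(floor(t / spec$dt + 1e-9) + 1,
                ceiling(spec$duration / spec$dt))
      draws <- noise_draws(spec, max(k))
      draws[k]
    }
  )
}

# Stage currents for the RK4 integrator: values at t_k, t_k + dt/2, t_k + dt
# for steps k = 0..n_steps-1. Noise is frozen per step (all stages equal).
stimulus_series <- function(spec, n_steps, dt) {
  tk <- (seq_len(n_steps) - 1) * dt
  if (spec$mode == "noise") {
    if (abs(spec$dt - dt) > 1e-12) {
      stop("noise stimulus dt does not match integration dt")
    }
    v <- noise_draws(spec, n_steps)
    return(list(start = v, mid = v, end = v))
  }
  tend <- pmin(tk + dt, spec$duration)  # guard fp overshoot at the last step
  list(start = stimulus_value(spec, tk),
       mid = stimulus_value(spec, pmin(tk + dt / 2, spec$duration)),
       end = stimulus_value(spec, tend))
}

#' @export
print.stimulus_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), c("mode", "duration"))]
  cat(sprintf("<stimulus_spec> %s, %g ms | %s\n", x$mode, x$duration,
              paste(names(pars), vapply(pars, function(p)
                paste(format(p), collapse = ","), character(1)),
                sep = "=", collapse = " ")))
  invisible(x)
}

#' Default stimulus specs spanning a model's constant-current range
#'
#' Conventions used for test-set generation: the ramp spans
#' `I_min -> I_max` over the trace; the sinusoid has baseline at the range
#' midpoint, amplitude half the range and frequency 5 Hz; noise has baseline
#' at the midpoint.
#'
#' @param model A [neuron_model()] with a `constant_range`.
#' @param mode One of `"slope"`, `"sinusoidal"`, `"noise"`.
#' @param duration Trace duration, ms.
#' @param level Noise level (noise mode only).
#' @param seed Seed (noise mode only).
#' @param dt Integration step, ms.
#' @return A stimulus spec.
#' @export
default_stimulus <- function(model, mode, duration, level = 4, seed = 1,
                             dt = 0.01) {
  r <- model$constant_range
  if (is.null(r)) stop("model has no configured constant_range")
  mid <- mean(r)
  switch(mode,
    slope = stim_slope(r[1], r[2], duration),
    sinusoidal = stim_sinusoidal(mid, (r[2] - r[1]) / 2, 5, duration),
    noise = stim_noise(mid, level, r, seed, duration, dt),
    stop("mode must be slope, sinusoidal or noise")
  )
}
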