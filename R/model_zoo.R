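#' Gating-variable kinetics
#'
#' Kinetics of a single gating variable, either rate-based (`alpha(V)`,
#' `beta(V)`) or steady-state-based (`x_inf(V)`, `tau_x(V)` in ms). The two
#' forms are related by `x_inf = alpha/(alpha+beta)`, `tau = 1/(alpha+beta)`.
#'
#' @param name Gate symbol (e.g. `"m"`, `"h"`, `"n"`). Must be unique within a
#'   model.
#' @param type `"rate"` or `"steady"`.
#' @param f1 [rate_fun()]: `alpha(V)` for rate-based, `x_inf(V)` for
#'   steady-state-based kinetics.
#' @param f2 [rate_fun()]: `beta(V)` or `tau_x(V)` respectively.
#' @param phi Dimensionless rate multiplier (temperature-like scaling applied
#'   to `dx/dt`); default 1.
#' @param instantaneous If `TRUE` the gate tracks its steady state
#'   `x_inf(V)` exactly (no ODE is integrated for it).
#' @return A `gating_kinetics` object.
#' @export
gating_kinetics <- function(name, type = c("rate", "steady"), f1, f2,
                            phi = 1, instantaneous = FALSE) {
  type <- match.arg(type)
  stopifnot(inherits(f1, "rate_fun"), inherits(f2, "rate_fun"),
            is.character(name), nzchar(name), phi > 0)
  structure(list(name = name, type = type, f1 = f1, f2 = f2,
                 phi = phi, instantaneous = isTRUE(instantaneous)),
            class = "gating_kinetics")
}

#' Steady-state activation and time constant of a gate
#'
#' @param g A [gating_kinetics()] object.
#' @param V Voltage(s), mV.
#' @return Numeric vector.
#' @export
gate_inf <- function(g, V) {
  if (g$type == "steady") return(eval_rate(g$f1, V))
  a <- eval_rate(g$f1, V); b <- eval_rate(g$f2, V)
  a / (a + b)
}

#' @rdname gate_inf
#' @export
gate_tau <- function(g, V) {
  tau <- if (g$type == "steady") eval_rate(g$f2, V)
         else 1 / (eval_rate(g$f1, V) + eval_rate(g$f2, V))
  tau / g$phi
}

# dx/dt for a gate at voltage V and current value x
gate_deriv <- function(g, V, x) {
  if (g$instantaneous) return(0 * V)
  if (g$type == "rate") {
    a <- eval_rate(g$f1, V); b <- eval_rate(g$f2, V)
    g$phi * (a * (1 - x) - b * x)
  } else {
    g$phi * (eval_rate(g$f1, V) - x) / eval_rate(g$f2, V)
  }
}

#' Ion-channel specification
#'
#' An ionic current of the form
#' `I = g_max * m^p * h^q * (V - E_ion)`, with activation gate `m` (exponent
#' `p`) and optional inactivation gate `h` (exponent `q`).
#'
#' @param name Channel name (unique within a model), e.g. `"Na"`.
#' @param g_max Maximal conductance, mS/cm^2 (>= 0).
#' @param E_ion Reversal potential, mV.
#' @param activation [gating_kinetics()] for the activation gate.
#' @param p Non-negative integer exponent of the activation gate.
#' @param inactivation Optional [gating_kinetics()] for inactivation.
#' @param q Non-negative integer exponent of the inactivation gate.
#' @return A `channel_spec` object.
#' @export
channel_spec <- function(name, g_max, E_ion, activation, p = 1L,
                         inactivation = NULL, q = 1L) {
  stopifnot(g_max >= 0, p >= 0, p == round(p),
            inherits(activation, "gating_kinetics"))
  if (!is.null(inactivation)) {
    stopifnot(inherits(inactivation, "gating_kinetics"), q >= 0, q == round(q))
  }
  structure(list(name = name, g_max = g_max, E_ion = E_ion,
                 activation = activation, p = as.integer(p),
                 inactivation = inactivation,
                 q = if (is.null(inactivation)) 0L else as.integer(q)),
            class = "channel_spec")
}

# all gates of a channel as a named list of (kinetics, exponent)
channel_gates <- function(ch) {
  gates <- list(list(kin = ch$activation, exponent = ch$p))
  if (!is.null(ch$inactivation)) {
    gates <- c(gates, list(list(kin = ch$inactivation, exponent = ch$q)))
  }
  names(gates) <- vapply(gates, function(g) g$kin$name, character(1))
  gates
}

#' Conductance-based point-neuron model specification
#'
#' Membrane equation `C_m dV/dt = -I_leak + I_inj - sum(I_ion)` with
#' `I_leak = g_leak (V - E_leak)` and ionic currents given by the channel
#' specifications.
#'
#' @param name Model name.
#' @param C_m Membrane capacitance, uF/cm^2 (> 0).
#' @param g_leak Leak conductance, mS/cm^2 (>= 0).
#' @param E_leak Leak reversal potential, mV.
#' @param channels List of [channel_spec()] objects; gate names must be
#'   unique across the whole model.
#' @param V_rest_hint Approximate resting potential (mV), used for
#'   initialization.
#' @param spike_threshold Spike detection voltage (mV), default -10.
#' @param citation Free-text provenance note.
#' @param constant_range Length-2 numeric, the constant-current sweep range
#'   (uA/cm^2) over which the model fires repetitively (used for dataset
#'   generation); optional.
#' @param doc_intensity A documented intensity (uA/cm^2) at which the model
#'   produces its characteristic firing pattern; optional.
#' @param extra Named list of additional documented intensities (e.g. the
#'   mixed-mode intensity of a burster); optional.
#' @return A `neuron_model` object.
#' @export
neuron_model <- function(name, C_m, g_leak, E_leak, channels,
                         V_rest_hint, spike_threshold = -10,
                         citation = "", constant_range = NULL,
                         doc_intensity = NULL, extra = list()) {
  stopifnot(C_m > 0, g_leak >= 0)
  stopifnot(all(vapply(channels, inherits, logical(1), "channel_spec")))
  ch_names <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(ch_names)) stop("channel names must be unique")
  gnames <- unlist(lapply(channels, function(ch) names(channel_gates(ch))))
  if (anyDuplicated(gnames)) {
    stop("gate names must be unique across the model: ",
         paste(gnames[duplicated(gnames)], collapse = ", "))
  }
  if (!is.null(constant_range)) {
    stopifnot(length(constant_range) == 2, constant_range[2] > constant_range[1])
  }
  structure(list(name = name, C_m = C_m, g_leak = g_leak, E_leak = E_leak,
                 channels = channels, V_rest_hint = V_rest_hint,
                 spike_threshold = spike_threshold, citation = citation,
                 constant_range = constant_range,
                 doc_intensity = doc_intensity, extra = extra),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model> %s (C_m=%g uF/cm^2, g_leak=%g, E_leak=%g mV)\n",
              x$name, x$C_m, x$g_leak, x$E_leak))
  for (ch in x$channels) {
    gates <- channel_gates(ch)
    gs <- paste(vapply(gates, function(g)
      sprintf("%s^%d", g$kin$name, g$exponent), character(1)), collapse = " ")
    cat(sprintf("  %-6s g_max=%6g mS/cm^2  E=%6g mV  gates: %s\n",
                ch$name, ch$g_max, ch$E_ion, gs))
  }
  if (!is.null(x$constant_range))
    cat(sprintf("  constant range: %g..%g uA/cm^2\n",
                x$constant_range[1], x$constant_range[2]))
  invisible(x)
}

# all gates of a model, named list in state order
model_gates <- function(model) {
  out <- list()
  for (ch in model$channels) out <- c(out, channel_gates(ch))
  out
}

#' Ionic current through one channel
#'
#' @param channel A [channel_spec()].
#' @param gates Named numeric vector of gate values (must contain every gate
#'   the channel declares).
#' @param V Membrane potential, mV.
#' @return Current in uA/cm^2, with the sign convention that this term is
#'   subtracted from the membrane equation's right-hand side.
#' @export
channel_current <- function(channel, gates, V) {
  cg <- channel_gates(channel)
  open <- 1
  for (nm in names(cg)) {
    if (!nm %in% names(gates)) {
      stop(sprintf("channel '%s' requires gate '%s' but it is missing",
                   channel$name, nm), call. = FALSE)
    }
    open <- open * gates[[nm]]^cg[[nm]]$exponent
  }
  channel$g_max * open * (V - channel$E_ion)
}

#' Right-hand side of the membrane equation
#'
#' Computes `dV/dt = (-I_leak + I_inj - sum(I_ion)) / C_m` and the gate
#' derivatives `dx/dt = alpha(1-x) - beta x` (or `(x_inf - x)/tau`).
#' Instantaneous gates are pinned to `x_inf(V)` and have zero derivative.
#'
#' @param model A [neuron_model()].
#' @param state List with elements `V` (mV) and `gates` (named numeric vector
#'   in `[0,1]`).
#' @param I_inj Injected current, uA/cm^2.
#' @param t Time (ms); unused by autonomous models, kept for generality.
#' @return List with `dV` and named vector `dgates`.
#' @export
membrane_rhs <- function(model, state, I_inj, t = 0) {
  V <- state$V
  gates <- state$gates
  mg <- model_gates(model)
  # instantaneous gates track x_inf(V)
  for (nm in names(mg)) {
    if (mg[[nm]]$kin$instantaneous) gates[[nm]] <- gate_inf(mg[[nm]]$kin, V)
  }
  I_ion <- 0
  for (ch in model$channels) {
    Ic <- channel_current(ch, gates, V)
    if (!is.finite(Ic)) {
      stop(sprintf("non-finite current in channel '%s' at V=%g", ch$name, V),
           call. = FALSE)
    }
    I_ion <- I_ion + Ic
  }
  I_leak <- model$g_leak * (V - model$E_leak)
  dV <- (-I_leak + I_inj - I_ion) / model$C_m
  dgates <- vapply(names(mg), function(nm)
    gate_deriv(mg[[nm]]$kin, V, gates[[nm]]), numeric(1))
  list(dV = dV, dgates = dgates)
}

#' Gate steady-state values at a voltage
#'
#' @param model A [neuron_model()].
#' @param V Voltage, mV.
#' @return Named numeric vector of `x_inf(V)` for every gate.
#' @export
steady_state_gates <- function(model, V) {
  mg <- model_gates(model)
  vapply(names(mg), function(nm) gate_inf(mg[[nm]]$kin, V), numeric(1))
}

#' Numerically locate the resting potential
#'
#' Finds the fixed point of the membrane equation with all gates at steady
#' state and `I_inj = 0`, by root-finding on the quasi-steady-state current
#' balance around `V_rest_hint`.
#'
#' @param model A [neuron_model()].
#' @param interval Search interval (mV) around the hint.
#' @return The resting potential (mV).
#' @export
find_rest <- function(model, interval = model$V_rest_hint + c(-15, 15)) {
  f <- function(V) {
    g <- steady_state_gates(model, V)
    membrane_rhs(model, list(V = V, gates = g), 0)$dV
  }
  stats::uniroot(Vectorize(f), interval, extendInt = "yes",
                 tol = 1e-12)$root
}
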