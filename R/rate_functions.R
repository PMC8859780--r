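#' Voltage-dependent rate function registry
#'
#' Gating kinetics in conductance-based models are built from a small set of
#' canonical voltage-dependent functional forms. Model configuration files
#' reference these forms by name (no arbitrary code is ever executed from a
#' config file); the integrator evaluates the same forms in compiled code.
#'
#' Available forms (`V` in mV, all parameters numeric):
#' \describe{
#'   \item{`linoid(a, b, c)`}{`a*(V-b) / (1 - exp(-(V-b)/c))` -- the classical
#'     linear-over-exponential opening rate. The removable singularity at
#'     `V = b` is evaluated by its first-order series `a*(c + (V-b)/2)` within
#'     1e-7 mV of the singular point.}
#'   \item{`expo(a, b, c)`}{`a * exp((V-b)/c)`.}
#'   \item{`logistic(a, b, c)`}{`a / (1 + exp(-(V-b)/c))` -- Boltzmann sigmoid.}
#'   \item{`constant(a)`}{`a`, independent of voltage.}
#'   \item{`biexp_inv(a, b, c, d, e, f)`}{`a / (b*exp((V-c)/d) + e*exp(-(V-c)/f))`
#'     -- bell-shaped time constants (e.g. M-type K+ current).}
#'   \item{`sigtau(a, b, c, d)`}{`a + b / (1 + exp((V-c)/d))` -- offset sigmoid
#'     time constant.}
#'   \item{`prodsigtau(a, b, c, d, e, f, g, h)`}{product of two offset sigmoids,
#'     `(a + b/(1+exp((V-c)/d))) * (e + f/(1+exp(-(V-g)/h)))`.}
#' }
#'
#' @name rate_forms
#' @keywords internal
NULL

# form name -> integer code shared with the C++ integrator
RATE_FORM_CODES <- c(
  linoid = 1L, expo = 2L, logistic = 3L, constant = 4L,
  biexp_inv = 5L, sigtau = 6L, prodsigtau = 7L
)

RATE_FORM_NPAR <- c(
  linoid = 3L, expo = 3L, logistic = 3L, constant = 1L,
  biexp_inv = 6L, sigtau = 4L, prodsigtau = 8L
)

#' Construct a rate-function specification
#'
#' @param form One of the registered form names (see [rate_forms]).
#' @param params Numeric parameter vector of the length the form requires.
#' @return An object of class `rate_fun`.
#' @examples
#' alpha_m <- rate_fun("linoid", c(0.1, -40, 10))
#' eval_rate(alpha_m, c(-60, -40, -20))
#' @export
rate_fun <- function(form, params) {
  form <- match.arg(form, names(RATE_FORM_CODES))
  params <- as.numeric(params)
  if (length(params) != RATE_FORM_NPAR[[form]]) {
    stop(sprintf("rate form '%s' takes %d parameters, got %d",
                 form, RATE_FORM_NPAR[[form]], length(params)), call. = FALSE)
  }
  structure(list(form = form, params = params), class = "rate_fun")
}

#' Evaluate a rate function at given voltages
#'
#' @param f A [rate_fun()] object.
#' @param V Numeric vector of membrane potentials (mV).
#' @return Numeric vector, same length as `V`.
#' @export
eval_rate <- function(f, V) {
  stopifnot(inherits(f, "rate_fun"))
  p <- f$params
  switch(f$form,
    linoid = {
      x <- V - p[2]
      out <- ifelse(abs(x) < 1e-7,
                    p[1] * (p[3] + x / 2),
                    p[1] * x / (1 - exp(-x / p[3])))
      out
    },
    expo = p[1] * exp((V - p[2]) / p[3]),
    logistic = p[1] / (1 + exp(-(V - p[2]) / p[3])),
    constant = rep(p[1], length(V)),
    biexp_inv = p[1] / (p[2] * exp((V - p[3]) / p[4]) +
                        p[5] * exp(-(V - p[3]) / p[6])),
    sigtau = p[1] + p[2] / (1 + exp((V - p[3]) / p[4])),
    prodsigtau = (p[1] + p[2] / (1 + exp((V - p[3]) / p[4]))) *
                 (p[5] + p[6] / (1 + exp(-(V - p[7]) / p[8])))
  )
}

#' @export
print.rate_fun <- function(x, ...) {
  cat(sprintf("<rate_fun> %s(%s)\n", x$form,
              paste(format(x$params), collapse = ", ")))
  invisible(x)
}
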