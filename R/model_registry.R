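#' The nine-model registry
#'
#' Nine conductance-based point-neuron models covering ten firing patterns:
#' regular spiking with/without adaptation, fast spiking with/without
#' adaptation, two bursters (one of which also produces mixed-mode firing at a
#' documented intensity), phasic spiking, and Class I / Class II excitable
#' cells. Each model ships as a declarative YAML config under
#' `inst/models/`; kinetics reference the documented [rate_forms] registry
#' only, so configs cannot execute code.
#'
#' `ClassII_excitable` is the classical Hodgkin-Huxley squid-axon model,
#' `ClassI_excitable` the Traub-Miles pyramidal-cell model, and
#' `FS_NoAdaptation` the Wang-Buzsaki fast-spiking interneuron; these three
#' are exact transcriptions. The remaining six are adapted from their cited
#' sources (see each file's `citation` field for provenance and any
#' simplifications).
#'
#' @name model_registry
#' @keywords internal
NULL

MODEL_NAMES <- c("RS_Adaptation", "RS_NoAdaptation", "FS_Adaptation",
                 "FS_NoAdaptation", "Bursting_RS", "Bursting_FS",
                 "Phasic_Spiking", "ClassI_excitable", "ClassII_excitable")

.registry_env <- new.env(parent = emptyenv())

#' List the names of the registered neuron models
#'
#' @return Character vector of the nine model names.
#' @export
list_models <- function() MODEL_NAMES

#' Retrieve a registered neuron model
#'
#' @param name One of [list_models()].
#' @return A [neuron_model()] object, fully parameterized.
#' @examples
#' hh <- get_model("ClassII_excitable")
#' length(hh$channels)  # Na, K
#' @export
get_model <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% MODEL_NAMES) {
    stop(sprintf("unknown model '%s'; valid names: %s",
                 paste(name, collapse = ","),
                 paste(MODEL_NAMES, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(.registry_env[[name]])) return(.registry_env[[name]])
  path <- system.file("models", paste0(name, ".yaml"), package = "spikefeat")
  if (!nzchar(path)) stop("model config file not found for ", name)
  m <- read_model_yaml(path)
  .registry_env[[name]] <- m
  m
}

# parse one kinetics block from config
parse_kinetics <- function(symbol, k) {
  gating_kinetics(
    name = symbol,
    type = k$type,
    f1 = rate_fun(k$f1$form, unlist(k$f1$params)),
    f2 = rate_fun(k$f2$form, unlist(k$f2$params)),
    phi = if (is.null(k$phi)) 1 else k$phi,
    instantaneous = isTRUE(k$instantaneous)
  )
}

#' Read a neuron model from a YAML config file
#'
#' @param path Path to a model YAML document (see files under
#'   `system.file("models", package = "spikefeat")` for the schema).
#' @return A [neuron_model()].
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  channels <- lapply(doc$channels, function(ch) {
    gs <- ch$gates
    if (length(gs) < 1 || length(gs) > 2) {
      stop("each channel needs 1 or 2 gates (activation [+ inactivation])")
    }
    act <- gs[[1]]
    inact <- if (length(gs) == 2) gs[[2]] else NULL
    channel_spec(
      name = ch$name, g_max = ch$g_max, E_ion = ch$E,
      activation = parse_kinetics(act$symbol, act$kinetics),
      p = act$exponent,
      inactivation = if (!is.null(inact))
        parse_kinetics(inact$symbol, inact$kinetics),
      q = if (!is.null(inact)) inact$exponent else 1L
    )
  })
  neuron_model(
    name = doc$name, C_m = doc$C_m,
    g_leak = doc$leak$g, E_leak = doc$leak$E,
    channels = channels, V_rest_hint = doc$V_rest_hint,
    spike_threshold = if (is.null(doc$spike_threshold)) -10
                      else doc$spike_threshold,
    citation = if (is.null(doc$citation)) "" else doc$citation,
    constant_range = if (is.null(doc$constant_range)) NULL
                     else unlist(doc$constant_range),
    doc_intensity = doc$doc_intensity,
    extra = if (is.null(doc$extra)) list() else doc$extra
  )
}
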