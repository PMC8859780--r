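#' Minimal feed-forward networks
#'
#' Small fully-connected nets with logistic-sigmoid hidden units: the feature
#' prediction module (FPM) is a 3-10-3 regressor with identity output, the
#' spike prediction module (SPM) a 3-10-1 classifier with sigmoid output.
#' Training is full-batch iRPROP- (resilient backpropagation) on the mean
#' squared error, which is deterministic given a seed and needs no
#' learning-rate tuning.
#'
#' @name neural_nets
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize an MLP
#'
#' @param sizes Integer vector of layer sizes, e.g. `c(3, 10, 3)`.
#' @param out_act Output activation: `"identity"` or `"sigmoid"`.
#' @param seed Integer seed for the weight initialization.
#' @return An `mlp` object (weights, biases, activations).
#' @export
mlp <- function(sizes, out_act = c("identity", "sigmoid"), seed = 1) {
  out_act <- match.arg(out_act)
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nl <- length(sizes) - 1
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -0.5, 0.5) /
                       sqrt(sizes[l]), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  structure(list(sizes = as.integer(sizes), W = W, b = b,
                 hidden_act = "sigmoid", out_act = out_act, seed = seed),
            class = "mlp")
}

#' Forward pass
#'
#' @param net An [mlp()].
#' @param X Numeric matrix (rows = samples, columns = inputs) or a vector for
#'   a single sample.
#' @return Output matrix (rows = samples).
#' @export
mlp_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != net$sizes[1]) {
    stop(sprintf("input has %d columns, net expects %d",
                 ncol(X), net$sizes[1]), call. = FALSE)
  }
  A <- X
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    Z <- A %*% net$W[[l]] + matrix(net$b[[l]], nrow(A), length(net$b[[l]]),
                                   byrow = TRUE)
    A <- if (l < nl) sigmoid(Z)
         else if (net$out_act == "sigmoid") sigmoid(Z) else Z
  }
  A
}

# forward keeping activations, for backprop
mlp_forward_full <- function(net, X) {
  A <- list(X)
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% net$W[[l]] +
      matrix(net$b[[l]], nrow(X), length(net$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < nl) sigmoid(Z)
                  else if (net$out_act == "sigmoid") sigmoid(Z) else Z
  }
  A
}

# MSE gradients w.r.t. all weights and biases (full batch)
mlp_gradients <- function(net, X, Y) {
  n <- nrow(X)
  nl <- length(net$W)
  A <- mlp_forward_full(net, X)
  out <- A[[nl + 1]]
  delta <- 2 * (out - Y) / (n * ncol(Y))      # d MSE / d out
  if (net$out_act == "sigmoid") delta <- delta * out * (1 - out)
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * A[[l]] * (1 - A[[l]])
    }
  }
  list(W = gW, b = gb)
}

# full-batch iRPROP- training; returns net + per-iteration train/val MSE
rprop_train <- function(net, X, Y, Xval = NULL, Yval = NULL,
                        iterations = 1000, delta0 = 0.05, delta_max = 1,
                        delta_min = 1e-9, eta_plus = 1.2, eta_minus = 0.7) {
  nl <- length(net$W)
  stepW <- lapply(net$W, function(w) matrix(delta0, nrow(w), ncol(w)))
  stepb <- lapply(net$b, function(bb) rep(delta0, length(bb)))
  prevW <- lapply(net$W, function(w) matrix(0, nrow(w), ncol(w)))
  prevb <- lapply(net$b, function(bb) rep(0, length(bb)))
  history <- data.frame(iteration = seq_len(iterations),
                        train_mse = NA_real_, val_mse = NA_real_)
  mse <- function(net, X, Y) mean((mlp_forward(net, X) - Y)^2)
  for (it in seq_len(iterations)) {
    g <- mlp_gradients(net, X, Y)
    for (l in seq_len(nl)) {
      s <- sign(g$W[[l]] * prevW[[l]])
      stepW[[l]] <- pmin(pmax(
        stepW[[l]] * ifelse(s > 0, eta_plus, ifelse(s < 0, eta_minus, 1)),
        delta_min), delta_max)
      gl <- ifelse(s < 0, 0, g$W[[l]])  # iRPROP-: drop gradient on sign flip
      net$W[[l]] <- net$W[[l]] - sign(gl) * stepW[[l]]
      prevW[[l]] <- gl
      sb <- sign(g$b[[l]] * prevb[[l]])
      stepb[[l]] <- pmin(pmax(
        stepb[[l]] * ifelse(sb > 0, eta_plus, ifelse(sb < 0, eta_minus, 1)),
        delta_min), delta_max)
      gbl <- ifelse(sb < 0, 0, g$b[[l]])
      net$b[[l]] <- net$b[[l]] - sign(gbl) * stepb[[l]]
      prevb[[l]] <- gbl
    }
    tm <- mse(net, X, Y)
    if (!is.finite(tm)) {
      stop("training diverged (non-finite loss); reduce delta_max",
           call. = FALSE)
    }
    history$train_mse[it] <- tm
    if (!is.null(Xval)) history$val_mse[it] <- mse(net, Xval, Yval)
  }
  list(net = net, history = history)
}

#' Training configuration
#'
#' @param iterations Number of full passes over the training split
#'   (default 1000).
#' @param train_fraction Fraction of samples used for training; the rest is
#'   held out for validation (default 0.70).
#' @param hidden Hidden-layer width (default 10).
#' @param seed Integer seed controlling the split and weight initialization.
#' @return A `training_config` list.
#' @export
training_config <- function(iterations = 1000, train_fraction = 0.7,
                            hidden = 10, seed = 1) {
  stopifnot(iterations >= 1, train_fraction > 0, train_fraction < 1,
            hidden >= 1)
  structure(list(iterations = as.integer(iterations),
                 train_fraction = train_fraction, hidden = as.integer(hidden),
                 optimizer = "iRPROP- (full batch, MSE)",
                 seed = as.integer(seed)),
            class = "training_config")
}

split_indices <- function(n, fraction, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(n)
  ntr <- floor(n * fraction)
  list(train = sort(idx[seq_len(ntr)]), val = sort(idx[-seq_len(ntr)]))
}

#' Train the feature prediction module (FPM)
#'
#' Trains the 3-10-3 regressor mapping the normalized pre-peak window
#' `(V1,V2,V3)` to the normalized spike features `(Vmax,Vmin,Twidth)`.
#' The dataset is min-max normalized from its own training split (if not
#' already normalized), split 70/30 at random (seeded), and optimized by
#' full-batch iRPROP- on the MSE for `iterations` passes.
#'
#' @param dataset A [feature_dataset()] (raw or normalized) with >= 50
#'   samples.
#' @param config A [training_config()].
#' @return A `trained_mlp`: list with the fitted `net`, `history` (per
#'   iteration train/validation MSE), the normalization extrema `norm`, the
#'   `config`, and the module tag.
#' @export
train_fpm <- function(dataset, config = training_config()) {
  stopifnot(inherits(dataset, "feature_dataset"))
  if (nrow(dataset$samples) < 50) stop("need at least 50 samples")
  if (is.null(dataset$norm)) {
    norm <- fit_normalization(dataset)
    dataset <- apply_normalization(dataset, norm)
  }
  s <- dataset$samples
  X <- as.matrix(s[, c("V1", "V2", "V3")])
  Y <- as.matrix(s[, c("Vmax", "Vmin", "Twidth")])
  sp <- split_indices(nrow(X), config$train_fraction, config$seed)
  net <- mlp(c(3, config$hidden, 3), out_act = "identity", seed = config$seed)
  fit <- rprop_train(net, X[sp$train, ], Y[sp$train, ],
                     X[sp$val, ], Y[sp$val, ], iterations = config$iterations)
  structure(list(module = "fpm", net = fit$net, history = fit$history,
                 norm = dataset$norm, config = config,
                 split = sp, model = s$model[1]),
            class = "trained_mlp")
}

#' @export
print.trained_mlp <- function(x, ...) {
  h <- x$history
  cat(sprintf("<trained_mlp> %s %s, %d iterations (%s)\n",
              toupper(x$module), paste(x$net$sizes, collapse = "-"),
              nrow(h), x$config$optimizer))
  cat(sprintf("  final train MSE %.3g / validation MSE %.3g\n",
              h$train_mse[nrow(h)], h$val_mse[nrow(h)]))
  invisible(x)
}

#' Build a labelled window set for the SPM
#'
#' Positive examples are pre-peak windows (`V` at `t_peak - 3, -2, -1` ms).
#' Negative examples (1:1 overall ratio) come in two strata: half are "far"
#' windows whose `V3` time has no spike peak within the following 1.5 ms,
#' and half are "near-miss" windows misaligned by up to 0.5 ms around a true
#' pre-peak window. The near-miss stratum teaches the classifier timing
#' precision: without it the SPM gate opens a few grid steps before the
#' exact pre-peak alignment and the downstream feature predictions inherit a
#' systematic shift.
#'
#' @param trace A [voltage_trace()].
#' @param threshold Spike detection threshold, mV.
#' @param seed Seed for the negative sampling.
#' @param stride Grid stride (in samples) when enumerating far-negative
#'   candidates; default 10 (0.1 ms) keeps the candidate set small.
#' @return Data frame with `V1,V2,V3,label` (1 = spike peak exactly 1 ms
#'   after `V3`).
#' @export
build_spm_dataset <- function(trace, threshold = -10, seed = 1, stride = 10) {
  peaks <- spike_peaks(trace, threshold)
  pos <- extract_window(trace, peaks)
  if (nrow(pos) == 0) stop("trace contains no usable spikes")
  tt <- trace_times(trace)
  n <- length(tt)
  steps_ms <- round(1 / trace$dt)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # far negatives: no peak within (t3, t3 + 1.5 ms]
  cand <- seq(3 * steps_ms + 1, n, by = stride)  # index of the would-be peak
  t3 <- tt[cand] - 1
  far <- cand[!vapply(t3, function(t) any(peaks > t & peaks <= t + 1.5),
                      logical(1))]
  n_far <- min(length(far), ceiling(nrow(pos) / 2))
  far <- sample(far, n_far)
  pick_shifted <- function(shifts, k) {
    ts <- as.vector(outer(peaks, shifts, `+`))
    ts <- ts[ts - 3 >= tt[1] & ts <= tt[n]]
    sample(ts, min(length(ts), k))
  }
  n_rest <- nrow(pos) - n_far
  # near-miss negatives (gate sharpness): windows 0.01..0.15 ms off alignment
  near_t <- pick_shifted(setdiff(-15:15, 0) * trace$dt, ceiling(n_rest / 2))
  # overlap negatives: the window's last sample rides the spike itself
  # (its voltages lie far outside the pre-spike manifold; without these the
  # gate misfires on the falling phase of a spike it was too late to claim)
  over_t <- pick_shifted(seq(0.2, 3, by = 0.05), n_rest - length(near_t))
  neg <- rbind(extract_window(trace, tt[far]),
               extract_window(trace, near_t),
               extract_window(trace, over_t))
  rbind(cbind(pos, label = 1), cbind(neg, label = 0))
}

#' Train the spike prediction module (SPM)
#'
#' 3-10-1 sigmoid-output classifier on windows labelled spike / no-spike,
#' trained like the FPM (full-batch iRPROP-, MSE on the 0/1 labels).
#'
#' @param windows Data frame from [build_spm_dataset()] (columns
#'   `V1,V2,V3,label`); raw voltages are normalized with `norm`.
#' @param norm Normalization extrema shared with the FPM training set.
#' @param config A [training_config()].
#' @return A `trained_mlp` with `module = "spm"`.
#' @export
train_spm <- function(windows, norm, config = training_config()) {
  if (length(unique(windows$label)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  w <- apply_normalization(windows, norm)
  X <- as.matrix(w[, c("V1", "V2", "V3")])
  Y <- matrix(w$label, ncol = 1)
  sp <- split_indices(nrow(X), config$train_fraction, config$seed)
  net <- mlp(c(3, config$hidden, 1), out_act = "sigmoid", seed = config$seed)
  fit <- rprop_train(net, X[sp$train, ], Y[sp$train, , drop = FALSE],
                     X[sp$val, ], Y[sp$val, , drop = FALSE],
                     iterations = config$iterations)
  structure(list(module = "spm", net = fit$net, history = fit$history,
                 norm = norm, config = config, split = sp),
            class = "trained_mlp")
}

#' SPM gate decision
#'
#' `TRUE` iff the sigmoid output is strictly greater than 0.5 (an output of
#' exactly 0.5 is classified as no-spike).
#'
#' @param spm A trained SPM ([train_spm()]).
#' @param window Numeric vector `(V1,V2,V3)` in raw mV, or a matrix/data
#'   frame of windows.
#' @return Logical vector.
#' @export
spm_classify <- function(spm, window) {
  stopifnot(inherits(spm, "trained_mlp"), spm$module == "spm")
  as.vector(spm_output(spm, window) > 0.5)
}

#' @rdname spm_classify
#' @export
spm_output <- function(spm, window) {
  X <- normalize_window(window, spm$norm)
  as.vector(mlp_forward(spm$net, X))
}

normalize_window <- function(window, norm) {
  if (is.null(dim(window))) window <- matrix(window, nrow = 1)
  window <- as.matrix(window)
  for (j in 1:3) {
    cc <- c("V1", "V2", "V3")[j]
    window[, j] <- (window[, j] - norm[cc, "min"]) /
      (norm[cc, "max"] - norm[cc, "min"])
  }
  window
}

#' FPM prediction in physical units
#'
#' Forward pass through the trained 3-10-3 net followed by exact inversion of
#' the min-max normalization, giving `Vmax`/`Vmin` in mV and `Twidth` in ms.
#'
#' @param fpm A trained FPM ([train_fpm()]).
#' @param window Numeric vector `(V1,V2,V3)` in raw mV, or a matrix/data
#'   frame of windows.
#' @return Data frame with columns `Vmax`, `Vmin`, `Twidth`.
#' @export
fpm_predict <- function(fpm, window) {
  stopifnot(inherits(fpm, "trained_mlp"), fpm$module == "fpm")
  X <- normalize_window(window, fpm$norm)
  out <- mlp_forward(fpm$net, X)
  colnames(out) <- c("Vmax", "Vmin", "Twidth")
  denormalize_features(out, fpm$norm)
}

#' Serialize / restore trained networks as JSON
#'
#' @param x A `trained_mlp`.
#' @param path Output / input file path.
#' @return `read_mlp_json` returns the restored `trained_mlp`.
#' @export
write_mlp_json <- function(x, path) {
  stopifnot(inherits(x, "trained_mlp"))
  obj <- list(module = x$module, sizes = x$net$sizes,
              hidden_act = x$net$hidden_act, out_act = x$net$out_act,
              W = lapply(x$net$W, identity), b = x$net$b,
              norm = x$norm, config = unclass(x$config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(sizes = as.integer(obj$sizes),
                        W = lapply(obj$W, as.matrix),
                        b = lapply(obj$b, as.numeric),
                        hidden_act = obj$hidden_act, out_act = obj$out_act,
                        seed = obj$config$seed), class = "mlp")
  norm <- as.data.frame(obj$norm)
  rownames(norm) <- norm$quantity
  structure(list(module = obj$module, net = net, history = NULL,
                 norm = norm,
                 config = structure(as.list(obj$config),
                                    class = "training_config")),
            class = "trained_mlp")
}
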