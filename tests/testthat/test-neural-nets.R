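test_that("forward passes compose affine layers and activations correctly", {
  net <- mlp(c(3, 10, 3), out_act = "identity", seed = 1)
  for (l in seq_along(net$W)) net$W[[l]][] <- 0
  expect_equal(as.vector(mlp_forward(net, c(0.1, 0.5, 0.9))), c(0, 0, 0))
  net_s <- mlp(c(3, 10, 1), out_act = "sigmoid", seed = 1)
  for (l in seq_along(net_s$W)) net_s$W[[l]][] <- 0
  expect_equal(as.vector(mlp_forward(net_s, c(1, 2, 3))), 0.5)
  # 1-1-1 net, hand-set weights: out = w2 * sigmoid(w1*x + b1) + b2
  n1 <- mlp(c(1, 1, 1), out_act = "identity", seed = 1)
  n1$W[[1]][] <- 2; n1$b[[1]] <- 0.5; n1$W[[2]][] <- -3; n1$b[[2]] <- 1
  expect_equal(as.vector(mlp_forward(n1, 0.7)),
               -3 / (1 + exp(-(2 * 0.7 + 0.5))) + 1, tolerance = 1e-12)
  expect_error(mlp_forward(net, c(1, 2)), "expects 3")
})

test_that("the FPM recovers a synthetic affine target", {
  set.seed(12)
  n <- 1000
  X <- matrix(runif(3 * n), n, 3)
  A <- matrix(c(2.0, -1.0, 1.5, 0.5, 2.5, -1.5, 1.0, 1.0, 1.0), 3, 3)
  Y <- X %*% A + 0.1 + matrix(rnorm(3 * n, 0, sqrt(1e-4)), n, 3)
  s <- data.frame(V1 = X[, 1], V2 = X[, 2], V3 = X[, 3],
                  Vmax = Y[, 1], Vmin = Y[, 2], Twidth = Y[, 3],
                  model = "synthetic")
  ds <- feature_dataset(s, norm = NULL)
  fpm <- train_fpm(ds, training_config(seed = 1))
  val <- fpm$split$val
  sn <- apply_normalization(s, fpm$norm)
  pred <- mlp_forward(fpm$net, as.matrix(sn[val, c("V1", "V2", "V3")]))
  truth <- as.matrix(sn[val, c("Vmax", "Vmin", "Twidth")])
  expect_lt(mean((pred - truth)^2), 1e-3)
  for (j in 1:3) expect_gt(r_squared(truth[, j], pred[, j]), 0.999)
})

test_that("training is deterministic under a fixed seed and its loss decreases", {
  ds <- get_pipeline("ClassII_excitable", quota = 300)$train
  cfg <- training_config(iterations = 60, seed = 4)
  f1 <- train_fpm(ds, cfg)
  f2 <- train_fpm(ds, cfg)
  expect_identical(f1$net$W, f2$net$W)
  h <- f1$history
  expect_lt(h$train_mse[nrow(h)], h$train_mse[1])
  expect_lte(h$val_mse[nrow(h)], h$val_mse[10])
  expect_equal(nrow(h), 60)
})

test_that("the SPM separates spike from non-spike windows", {
  # perfectly separable synthetic clusters
  set.seed(3)
  n <- 200
  w <- rbind(matrix(rnorm(3 * n, -60, 0.5), ncol = 3),
             matrix(rnorm(3 * n, -40, 0.5), ncol = 3))
  windows <- data.frame(V1 = w[, 1], V2 = w[, 2], V3 = w[, 3],
                        label = rep(c(0, 1), each = n))
  norm <- data.frame(quantity = c("V1", "V2", "V3"),
                     min = rep(-70, 3), max = rep(-30, 3),
                     row.names = c("V1", "V2", "V3"))
  spm <- train_spm(windows, norm, training_config(iterations = 200, seed = 1))
  acc <- mean(spm_classify(spm, windows[, 1:3]) == (windows$label == 1))
  expect_equal(acc, 1.0)
  expect_error(train_spm(windows[windows$label == 1, ], norm),
               "both classes")
})

test_that("the SPM gate uses a strict 0.5 threshold", {
  norm <- data.frame(quantity = c("V1", "V2", "V3"),
                     min = rep(0, 3), max = rep(1, 3),
                     row.names = c("V1", "V2", "V3"))
  net <- mlp(c(3, 10, 1), out_act = "sigmoid", seed = 1)
  for (l in seq_along(net$W)) net$W[[l]][] <- 0   # output exactly 0.5
  spm <- structure(list(module = "spm", net = net, norm = norm,
                        config = training_config()), class = "trained_mlp")
  expect_false(spm_classify(spm, c(0.2, 0.4, 0.9)))  # 0.5 is not a spike
  spm$net$b[[2]] <- 2                                # output 0.88
  expect_true(spm_classify(spm, c(0.2, 0.4, 0.9)))
  spm$net$b[[2]] <- -0.001                           # just below 0.5
  expect_false(spm_classify(spm, c(0.2, 0.4, 0.9)))
})

test_that("fpm_predict denormalizes into physical units consistently", {
  p <- get_pipeline("ClassII_excitable", quota = 300)
  fpm <- p$fpm
  s <- p$train$samples
  pred <- fpm_predict(fpm, s[, c("V1", "V2", "V3")])
  expect_true(all(pred$Vmax > pred$Vmin))
  # training samples are reproduced within a few times the training RMSE
  tr_rmse <- sqrt(fpm$history$train_mse[nrow(fpm$history)])
  nrm <- fpm$norm
  err <- abs(pred$Vmax - s$Vmax) / (nrm["Vmax", "max"] - nrm["Vmax", "min"])
  expect_lt(quantile(err, 0.99), 5 * tr_rmse * sqrt(3))
  # hand-checkable path: identity normalization + zero net
  net <- mlp(c(3, 1, 3), out_act = "identity", seed = 1)
  for (l in seq_along(net$W)) net$W[[l]][] <- 0
  net$b[[2]] <- c(0.5, 0.25, 0.75)
  idnorm <- data.frame(quantity = spikefeat:::feature_cols, min = 0, max = 1,
                       row.names = spikefeat:::feature_cols)
  toy <- structure(list(module = "fpm", net = net, norm = idnorm,
                        config = training_config()), class = "trained_mlp")
  out <- fpm_predict(toy, c(0.1, 0.2, 0.3))
  expect_equal(unlist(out, use.names = FALSE), c(0.5, 0.25, 0.75))
})

test_that("trained networks serialize to JSON and back", {
  p <- get_pipeline("ClassII_excitable", quota = 300)
  path <- tempfile(fileext = ".json")
  write_mlp_json(p$fpm, path)
  back <- read_mlp_json(path)
  x <- c(-58.5, -56.2, -50.4)
  expect_equal(fpm_predict(back, x), fpm_predict(p$fpm, x), tolerance = 1e-12)
})

test_that("validation error late in training never exceeds its early value on any registry model", {
  for (nm in list_models()) {
    phasic <- nm == "Phasic_Spiking"
    ds <- build_dataset(nm, "constant", quota = 100, seed = 2,
                        n_intensities = if (phasic) 110 else 12,
                        keep_settle = if (phasic) 10 else 0,
                        trace_duration = 500)
    fpm <- train_fpm(ds, training_config(iterations = 300, seed = 2))
    h <- fpm$history
    expect_lte(h$val_mse[nrow(h)], h$val_mse[10], label = paste(nm, "converges"))
  }
})
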