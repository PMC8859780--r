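test_that("the triangular-pulse fixture yields the hand-computed spike features", {
  tr <- triangle_trace()
  sp <- detect_spikes(tr, threshold = -10)
  expect_equal(nrow(sp), 1)   # the trailing incomplete spike is dropped
  expect_equal(sp$V_max, 40)
  expect_equal(sp$V_min, -80)
  expect_equal(sp$T_width, 2.0)
  expect_equal(sp$t_max, 10)
})

test_that("flat traces contain no spikes", {
  flat <- voltage_trace(rep(-65, 1000), dt = 0.01)
  expect_equal(nrow(detect_spikes(flat, -10)), 0)
  expect_length(spike_peaks(flat, -10), 0)
})

test_that("detect_spikes agrees exactly with the brute-force oracle on random traces", {
  set.seed(99)
  models <- c("ClassII_excitable", "ClassI_excitable", "FS_NoAdaptation")
  for (k in 1:100) {
    nm <- sample(models, 1)
    m <- get_model(nm)
    r <- m$constant_range
    I <- runif(1, r[1], r[2])
    tr <- simulate(m, stim_constant(I, runif(1, 80, 160)), settle = 50)
    got <- detect_spikes(tr, m$spike_threshold)
    want <- oracle_spikes(tr, m$spike_threshold)
    expect_equal(got, want, label = sprintf("trace %d (%s, I=%.2f)", k, nm, I))
  }
})

test_that("extract_window samples at t_max - 3, -2, -1 ms and skips early peaks", {
  tr <- anchored_trace(data.frame(t = c(0, 7, 8, 9, 10),
                                  V = c(-65, -60, -50, -30, 40)))
  w <- extract_window(tr, 10)
  expect_equal(unlist(w, use.names = FALSE), c(-60, -50, -30))
  w2 <- extract_window(tr, 2)  # window would precede the trace start
  expect_equal(nrow(w2), 0)
  expect_equal(attr(w2, "skipped"), 1)
})

test_that("min-max normalization round-trips and does not clip test values", {
  ds <- get_pipeline("ClassII_excitable", quota = 300)$train
  norm <- fit_normalization(ds)
  nds <- apply_normalization(ds, norm)
  for (cc in spikefeat:::feature_cols) {
    expect_equal(min(nds$samples[[cc]]), 0)
    expect_equal(max(nds$samples[[cc]]), 1)
  }
  back <- denormalize_features(
    nds$samples[, c("Vmax", "Vmin", "Twidth")], norm)
  for (cc in c("Vmax", "Vmin", "Twidth")) {
    expect_equal(back[[cc]], ds$samples[[cc]], tolerance = 1e-12)
  }
  # out-of-range values extrapolate beyond [0,1] rather than clipping
  fake <- data.frame(Vmax = norm["Vmax", "max"] + 1)
  expect_gt(apply_normalization(fake, norm)$Vmax, 1)
  # degenerate range errors out
  degen <- feature_dataset(transform(ds$samples, Twidth = 1.5))
  expect_error(fit_normalization(degen), "degenerate")
})

test_that("build_dataset respects quotas, invariants and determinism", {
  ds <- build_dataset("ClassII_excitable", "constant", quota = 10, seed = 1,
                      n_intensities = 4, trace_duration = 300)
  expect_equal(nrow(ds$samples), 10)
  big <- get_pipeline("ClassII_excitable", quota = 300)$train$samples
  expect_true(all(big$Twidth > 0))
  expect_true(all(big$Vmax > big$Vmin))
  expect_true(all(big$V3 != big$V1))
  a <- build_dataset("FS_NoAdaptation", "constant", quota = 40, seed = 3,
                     n_intensities = 4, trace_duration = 300)
  b <- build_dataset("FS_NoAdaptation", "constant", quota = 40, seed = 3,
                     n_intensities = 4, trace_duration = 300)
  expect_identical(a$samples, b$samples)
  expect_error(build_dataset("Phasic_Spiking", "constant", quota = 500,
                             n_intensities = 8, trace_duration = 300,
                             max_sim_time = 10000),
               "unreachable")
})

test_that("collected samples reproduce their features from the source trace", {
  m <- get_model("FS_NoAdaptation")
  m$constant_range <- c(1.5, 3.0)  # single-point grid at 1.5 below
  tr <- simulate(m, stim_constant(1.5, 400), settle = 100)
  sp <- detect_spikes(tr, m$spike_threshold)
  sp <- sp[sp$t_max >= 3, ]
  w <- extract_window(tr, sp$t_max)
  ds <- build_dataset(m, "constant", quota = 10, seed = 1,
                      n_intensities = 1, trace_duration = 400)
  # the single-intensity dataset must be a prefix of the trace's own spikes
  expect_equal(ds$samples$Vmax, sp$V_max[1:10])
  expect_equal(ds$samples$V1, w$V1[1:10])
  expect_equal(ds$samples$Twidth, sp$T_width[1:10])
})
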