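# hand-built SPM/FPM stubs with controllable outputs
const_spm <- function(p_out, norm) {
  net <- mlp(c(3, 10, 1), out_act = "sigmoid", seed = 1)
  for (l in seq_along(net$W)) net$W[[l]][] <- 0
  net$b[[2]] <- log(p_out / (1 - p_out))
  structure(list(module = "spm", net = net, norm = norm,
                 config = training_config()), class = "trained_mlp")
}
const_fpm <- function(vmax, vmin, twidth, norm) {
  net <- mlp(c(3, 10, 3), out_act = "identity", seed = 1)
  for (l in seq_along(net$W)) net$W[[l]][] <- 0
  net$b[[2]] <- c(vmax, vmin, twidth)  # normalized outputs
  structure(list(module = "fpm", net = net, norm = norm,
                 config = training_config()), class = "trained_mlp")
}
idnorm <- data.frame(quantity = spikefeat:::feature_cols, min = 0, max = 1,
                     row.names = spikefeat:::feature_cols)

test_that("a closed gate slides the window over every grid position", {
  tr <- voltage_trace(rep(-65, 10001), dt = 0.01)  # 100 ms, subthreshold
  res <- run_hybrid(tr, const_spm(0.2, idnorm), const_fpm(0, 0, 0.5, idnorm),
                    stop_time = 100)
  expect_equal(nrow(res$events), 0)
  expect_equal(res$n_windows, floor((100 - 2) / 0.01) + 1)
})

test_that("a gated window restarts the slide at t + 3 ms + T_width", {
  tr <- voltage_trace(rep(-65, 2001), dt = 0.01)  # 20 ms
  # always-open gate; predicted T_width fixed at 1.8 ms
  res <- run_hybrid(tr, const_spm(0.9, idnorm),
                    const_fpm(0.3, 0.1, 1.8, idnorm), stop_time = 20)
  ev <- res$events
  expect_gte(nrow(ev), 3)
  expect_equal(diff(ev$t)[1], 3 + 1.8)      # worked example: 5.00 -> 9.80
  expect_equal(ev$t[1] + 3 + ev$Twidth[1], ev$t[2])
  expect_equal(ev$t_peak, ev$t + 3)
  expect_true(all(ev$spm_out > 0.5))
})

test_that("mismatched SPM/FPM normalizations are rejected", {
  tr <- voltage_trace(rep(-65, 1001), dt = 0.01)
  other <- idnorm
  other$max <- other$max + 1
  expect_error(run_hybrid(tr, const_spm(0.9, other),
                          const_fpm(0, 0, 1, idnorm)),
               "normalization")
})

test_that("match_events performs greedy one-to-one nearest matching", {
  # identical lists: all matched, zero errors
  m0 <- match_events(c(5, 10, 15), c(5, 10, 15), 1)
  expect_equal(nrow(m0$matches), 3)
  expect_equal(m0$matches$dt, c(0, 0, 0))
  expect_equal(m0$recall, 1)
  # no events: everything is a miss
  m1 <- match_events(numeric(0), c(1, 2, 3), 1)
  expect_equal(m1$misses, 1:3)
  expect_equal(m1$recall, 0)
  # hand-enumerated case from tolerance matching
  m2 <- match_events(c(10.0, 30.2), c(10.4, 25.0, 30.0), 1)
  expect_equal(nrow(m2$matches), 2)
  expect_equal(sort(m2$matches$t_truth), c(10.4, 30.0))
  expect_equal(m2$misses, 2L)
  expect_length(m2$false_alarms, 0)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$precision, 1)
})

test_that("the hybrid loop tracks true spikes on a reference trace", {
  p <- get_pipeline("ClassII_excitable", quota = 300)
  m <- get_model("ClassII_excitable")
  w <- build_spm_dataset(simulate(m, stim_constant(11, 2000), settle = 100),
                         m$spike_threshold, seed = 1)
  spm <- train_spm(w, p$fpm$norm, training_config(iterations = 400, seed = 1))
  ref <- simulate(m, stim_constant(10, 400), settle = 100)
  res <- run_hybrid(ref, spm, p$fpm)
  truth <- detect_spikes(ref, m$spike_threshold)
  mt <- match_events(res$events, truth, 1)
  expect_gte(mt$recall, 0.9)
  expect_gte(mt$precision, 0.9)
  # events are strictly ordered and never overlap (the jump rule)
  expect_true(all(diff(res$events$t) >= 3))
  expect_true(all(res$events$Twidth > 0))
  # implied peaks sit within half a millisecond of the matched truth
  expect_lt(median(abs(mt$matches$dt)), 0.05)
})
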