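test_that("channel_current follows g_max * m^p * h^q * (V - E)", {
  m_kin <- gating_kinetics("m", "rate", rate_fun("constant", 1),
                           rate_fun("constant", 1))
  h_kin <- gating_kinetics("h", "rate", rate_fun("constant", 1),
                           rate_fun("constant", 1))
  ch <- channel_spec("Na", g_max = 120, E_ion = 50, activation = m_kin, p = 3,
                     inactivation = h_kin, q = 1)
  # hand arithmetic: 120 * 0.5^3 * 0.6 * (0 - 50) = -450
  expect_equal(channel_current(ch, c(m = 0.5, h = 0.6), 0), -450)
  expect_equal(channel_current(ch, c(m = 0.3, h = 0.9), 50), 0)  # reversal
  ch0 <- channel_spec("dead", g_max = 0, E_ion = 50, activation = m_kin, p = 3)
  expect_equal(channel_current(ch0, c(m = 0.99), -20), 0)        # zero g_max
  expect_error(channel_current(ch, c(m = 0.5), 0), "gate 'h'")
})

test_that("membrane_rhs reproduces equilibria and the pure-capacitor limit", {
  m1 <- leak_model(g = 0.3, E = -65)
  rhs <- membrane_rhs(m1, list(V = -65, gates = numeric(0)), 0)
  expect_equal(rhs$dV, 0)
  m2 <- leak_model(g = 0, E = -65, C = 1)
  expect_equal(membrane_rhs(m2, list(V = -30, gates = numeric(0)), 10)$dV, 10)
})

test_that("the classical HH model rests at its numerically located fixed point", {
  hh <- get_model("ClassII_excitable")
  v_rest <- find_rest(hh)
  st <- list(V = v_rest, gates = steady_state_gates(hh, v_rest))
  rhs <- membrane_rhs(hh, st, 0)
  expect_lt(abs(rhs$dV), 1e-6)
  expect_true(all(abs(rhs$dgates) < 1e-6))
})

test_that("the registry exposes exactly nine models with the canonical structures", {
  expect_length(list_models(), 9)
  expect_error(get_model("RS"), "valid names")
  hh <- get_model("ClassII_excitable")
  # squid axon: Na (m^3 h), K (n^4) plus the leak term
  expect_length(hh$channels, 2)
  expect_equal(hh$channels[[1]]$p, 3L)
  expect_equal(hh$channels[[1]]$q, 1L)
  expect_equal(hh$channels[[2]]$p, 4L)
  expect_gt(hh$g_leak, 0)
  wb <- get_model("FS_NoAdaptation")
  expect_true(wb$channels[[1]]$activation$instantaneous)  # m = m_inf(V)
  expect_equal(wb$channels[[1]]$inactivation$phi, 5)
  for (nm in list_models()) {
    m <- get_model(nm)
    expect_s3_class(m, "neuron_model")
    expect_gt(m$C_m, 0)
  }
})

test_that("every registry model rests stably near its fixed point for 500 ms", {
  for (nm in list_models()) {
    m <- get_model(nm)
    v_rest <- find_rest(m)
    tr <- simulate(m, stim_constant(0, 500))
    expect_lt(max(abs(tr$V - v_rest)), 2, label = paste(nm, "resting drift"))
  }
})

test_that("each registry model produces its documented firing pattern", {
  for (nm in list_models()) {
    m <- get_model(nm)
    tr <- simulate(m, stim_constant(m$doc_intensity, 1500), settle = 100)
    pk <- spike_peaks(tr, m$spike_threshold)
    expect_gt(length(pk), 0, label = paste(nm, "spikes at doc_intensity"))
  }
  # adaptation: interspike intervals lengthen over the train
  for (nm in c("RS_Adaptation", "FS_Adaptation")) {
    m <- get_model(nm)
    isi <- diff(spike_peaks(simulate(m, stim_constant(m$doc_intensity, 1500),
                                     settle = 100), m$spike_threshold))
    expect_gt(isi[length(isi)], 1.5 * isi[1], label = paste(nm, "adapts"))
  }
  # non-adapting controls settle to a steady rate
  for (nm in c("RS_NoAdaptation", "FS_NoAdaptation")) {
    m <- get_model(nm)
    isi <- diff(spike_peaks(simulate(m, stim_constant(m$doc_intensity, 1500),
                                     settle = 100), m$spike_threshold))
    late <- isi[isi > 0 & seq_along(isi) > length(isi) / 2]
    expect_lt(max(late) / min(late), 1.05, label = paste(nm, "steady ISI"))
  }
  # bursting: both intra-burst (short) and inter-burst (long) intervals
  for (nm in c("Bursting_RS", "Bursting_FS")) {
    m <- get_model(nm)
    isi <- diff(spike_peaks(simulate(m, stim_constant(m$doc_intensity, 2000),
                                     settle = 100), m$spike_threshold))
    expect_gt(max(isi), 4 * min(isi), label = paste(nm, "bursts"))
  }
  # phasic: onset spiking only, silent afterwards
  m <- get_model("Phasic_Spiking")
  pk <- spike_peaks(simulate(m, stim_constant(m$doc_intensity, 1500),
                             settle = 100), m$spike_threshold)
  expect_true(length(pk) >= 1 && all(pk < 100))
  # mixed mode: the RS burster emits bursts and isolated single spikes
  m <- get_model("Bursting_RS")
  pk <- spike_peaks(simulate(m, stim_constant(m$extra$mixed_mode_intensity,
                                              3000), settle = 100),
                    m$spike_threshold)
  isi <- diff(pk)
  in_burst <- isi < 10
  # a single spike has long intervals on both sides
  singles <- sum(!in_burst[-length(isi)] & !in_burst[-1])
  expect_gt(sum(in_burst), 3)
  expect_gt(singles, 0)
})

test_that("gate trajectories stay within [0,1] across the registry", {
  for (nm in list_models()) {
    m <- get_model(nm)
    tr <- simulate(m, stim_constant(m$doc_intensity, 300), settle = 50,
                   record_gates = TRUE)
    expect_true(all(tr$gates >= 0 & tr$gates <= 1),
                label = paste(nm, "gates bounded"))
  }
})

test_that("model YAML round-trips through the reader", {
  path <- system.file("models", "ClassII_excitable.yaml", package = "spikefeat")
  m <- read_model_yaml(path)
  expect_equal(m$C_m, 1)
  expect_equal(m$channels[[1]]$g_max, 120)
  expect_equal(eval_rate(m$channels[[1]]$activation$f1, -40), 1, tolerance = 1e-9)
})
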