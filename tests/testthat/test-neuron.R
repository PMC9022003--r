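test_that("subthreshold LIF dynamics match the closed-form charging curve", {
  g <- time_grid(0.01, 20)
  p <- neuron_params()
  stim <- make_stimulus(stimulus_spec("step", amplitude = 1), g)
  tr <- simulate_lif(p, stim, g)
  # V(t) = V_rest + gain*R*I*(1 - exp(-t/tau)), tau = RC = 2 ms, gain 12
  analytic <- -65 + 12 * 1 * (1 - exp(-tr$time_ms / 2))
  expect_lt(max(abs(tr$V_mV - analytic)), 10 * g$dt)
  expect_equal(sum(tr$is_spike), 0)

  # zero input from rest stays at rest exactly
  tr0 <- simulate_lif(p, make_stimulus(stimulus_spec("zero"), g), g)
  expect_true(all(tr0$V_mV == -65))
})

test_that("the membrane relaxes monotonically to rest from any subthreshold start", {
  g <- time_grid(0.01, 40)
  zero <- make_stimulus(stimulus_spec("zero"), g)
  for (V0 in c(-80, -72, -55, -51)) {
    tr <- simulate_lif(neuron_params(V0 = V0), zero, g)
    expect_equal(tr$V_mV[nrow(tr)], -65, tolerance = 1e-3)
    expect_true(all(diff(abs(tr$V_mV + 65)) <= 1e-12))
    # LIF decay is exponential with tau = RC
    analytic <- -65 + (V0 + 65) * exp(-tr$time_ms / 2)
    expect_lt(max(abs(tr$V_mV - analytic)), 10 * g$dt)
  }
  # MLIF: depolarization from -80 and hyperpolarization from -50 both end at rest
  for (V0 in c(-80, -50.5)) {
    trm <- simulate_mlif(mlif_default(V0 = V0), zero, g)
    expect_equal(trm$V_mV[nrow(trm)], -65, tolerance = 0.1)
  }
})

test_that("every spike is one sample at V_spike followed by one at V_reset", {
  for (tr in list(step_lif(), step_mlif())) {
    idx <- which(tr$is_spike)
    expect_gt(length(idx), 0)
    expect_true(all(tr$V_mV[idx] == 20))
    expect_true(all(tr$V_mV[idx + 1] == -80))
    # no two adjacent peak samples
    expect_true(all(diff(idx) >= 2))
    # bounds hold everywhere
    expect_true(all(tr$V_mV >= -80 & tr$V_mV <= 20))
  }
  # detection by value agrees with the simulator's own log
  expect_equal(detect_spikes(step_mlif())$spike_time_ms,
               attr(step_mlif(), "spikes"))
})

test_that("pulse-train amplitudes separate the silent and firing LIF regimes", {
  silent <- sim_point("lif", stimulus_spec("pulse_train", amplitude = 1), T_total = 300)
  firing <- sim_point("lif", stimulus_spec("pulse_train", amplitude = 1.5), T_total = 300)
  expect_equal(sum(silent$is_spike), 0)
  expect_gt(sum(firing$is_spike), 0)
  # the MLIF fires already at 1 nA (larger effective input through M)
  mlif1 <- sim_point("mlif", stimulus_spec("pulse_train", amplitude = 1), T_total = 300)
  expect_gt(sum(mlif1$is_spike), 0)
})

test_that("MLIF adapts under a sustained step while the LIF does not", {
  m <- glance(step_mlif())
  l <- glance(step_lif())
  expect_gte(m$n_spikes, l$n_spikes)
  am <- adaptation_metrics(detect_spikes(step_mlif())$spike_time_ms,
                           attr(step_mlif(), "grid"))
  al <- adaptation_metrics(detect_spikes(step_lif())$spike_time_ms,
                           attr(step_lif(), "grid"))
  expect_true(am$adapting)
  expect_false(al$adapting)
  # the dense initial phase spans a few tens of ms
  expect_gt(am$adaptation_duration_ms, 5)
  expect_lt(am$adaptation_duration_ms, 100)
  # the memristance trajectory is recorded and ends at the lower bound
  expect_equal(step_mlif()$M_ohm[nrow(step_mlif())], 100)
})

test_that("MLIF spike count is non-decreasing over the tested amplitude range", {
  counts <- vapply(c(0.01, 0.25, 0.75, 1, 1.5, 2), function(a) {
    sum(sim_point("mlif", stimulus_spec("pulse_train", amplitude = a),
                  T_total = 400)$is_spike)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_gt(counts[length(counts)], 0)
})

test_that("reversing stimulus, device polarity and firing rule mirrors the trace", {
  g <- time_grid(0.01, 200)
  stim <- make_stimulus(stimulus_spec("pulse_train", amplitude = 2), g)
  fwd <- simulate_mlif(neuron_params(memristor = memristor_model(orientation = 1)),
                       stim, g)
  rev <- simulate_mlif(neuron_params(memristor = memristor_model(orientation = -1),
                                     firing_polarity = "negative"),
                       dplyr::mutate(stim, I_nA = -I_nA), g)
  expect_equal(rev$V_mV, 2 * (-65) - fwd$V_mV, tolerance = 1e-10)
  expect_equal(sum(rev$is_spike), sum(fwd$is_spike))
  expect_equal(rev$M_ohm, fwd$M_ohm, tolerance = 1e-10)
})

test_that("membrane currents satisfy Kirchhoff's law outside masked samples", {
  g <- time_grid(0.01, 100)
  stim <- make_stimulus(stimulus_spec("step", amplitude = 1.5), g)
  p_lif <- neuron_params()
  tr <- simulate_lif(p_lif, stim, g)
  mc <- membrane_currents(tr, p_lif, stim)
  ok <- !mc$masked
  expect_lt(max(abs(mc$I_C_nA[ok] + mc$I_R_nA[ok] - mc$I_input_scaled_nA[ok])), 1e-9)
  # LIF scaled input is gain * I_ext
  expect_equal(unique(mc$I_input_scaled_nA), 12 * 1.5)

  p_m <- mlif_default()
  trm <- simulate_mlif(p_m, stim, g)
  mcm <- membrane_currents(trm, p_m, stim)
  okm <- !mcm$masked
  expect_lt(max(abs(mcm$I_C_nA[okm] + mcm$I_R_nA[okm] - mcm$I_input_scaled_nA[okm]),
                na.rm = TRUE), 1e-9)

  # at rest with zero input both currents vanish
  zero <- make_stimulus(stimulus_spec("zero"), g)
  tr0 <- simulate_lif(p_lif, zero, g)
  mc0 <- membrane_currents(tr0, p_lif, zero)
  expect_lt(max(abs(mc0$I_C_nA), na.rm = TRUE), 1e-12)
  expect_lt(max(abs(mc0$I_R_nA), na.rm = TRUE), 1e-12)
})

test_that("strict SI coupling never bridges the threshold gap at printed values", {
  g <- time_grid(0.01, 300)
  stim <- make_stimulus(stimulus_spec("step", amplitude = 1.5), g)
  tr <- simulate_lif(neuron_params(input_scale = "si", input_gain = 1), stim, g)
  expect_equal(sum(tr$is_spike), 0)
  trm <- simulate_mlif(mlif_default(input_scale = "si", input_gain = 1), stim, g)
  expect_equal(sum(trm$is_spike), 0)
})

test_that("spike counts are grid-converged", {
  # LIF: quantized by the pulse structure; halving dt moves counts by <= 1
  counts_lif <- vapply(c(0.01, 0.005), function(dt) {
    sum(sim_point("lif", stimulus_spec("pulse_train", amplitude = 1.5),
                  T_total = 500, dt = dt)$is_spike)
  }, numeric(1))
  expect_lte(abs(diff(counts_lif)), 1)
  # MLIF burst totals are set by the device flux budget; the per-cycle flux
  # integral carries O(dt) error, so counts converge as dt shrinks: the
  # relative change per halving decreases and stays bounded
  counts_mlif <- vapply(c(0.01, 0.005, 0.0025, 0.00125), function(dt) {
    sum(sim_point("mlif", stimulus_spec("step", amplitude = 1.5),
                  T_total = 100, dt = dt)$is_spike)
  }, numeric(1))
  rel <- abs(diff(counts_mlif)) / counts_mlif[-4]
  expect_lt(rel[1], 0.2)
  expect_lt(rel[2], rel[1])
  expect_lt(rel[3], rel[1])
})

test_that("trace tidiers summarize spikes and rates", {
  tr <- step_mlif()
  td <- tidy(tr)
  expect_equal(nrow(td), sum(tr$is_spike))
  gl <- glance(tr)
  expect_equal(gl$model, "mlif")
  expect_equal(gl$mean_rate_hz, gl$n_spikes / 0.5)
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
})
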