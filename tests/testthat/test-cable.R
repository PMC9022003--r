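test_that("passive electrotonic profile follows v(x) = V0 exp(-x/lambda)", {
  expect_equal(passive_profile(10000, 100, 15, 0), 15)
  lam <- sqrt(10000 / 100)
  expect_equal(lam, 10)
  expect_equal(passive_profile(10000, 100, 15, lam) / 15, exp(-1))
  expect_error(passive_profile(10000, 100, 15, -1), class = "memlif_domain_error")
})

test_that("passive cable steady state matches the analytic profile within 2%", {
  g <- time_grid(0.01, 150)
  cp <- cable_params(n_compartments = 40, M0 = 10000)
  stim <- make_stimulus(stimulus_spec("step", amplitude = 0.2), g)
  tr <- simulate_cable(cp, stim, g, active = FALSE)
  prof <- dplyr::filter(tr, time_ms == max(time_ms))
  v <- prof$V_mV + 65
  analytic <- v[1] * exp(-(prof$compartment - 1) / 10)
  rel <- abs(v[1:15] - analytic[1:15]) / analytic[1:15]
  expect_lt(max(rel), 0.02)
  # attenuation: peak depolarization strictly decreasing with distance
  peaks <- dplyr::summarise(dplyr::group_by(tr, compartment),
                            pk = max(V_mV), .groups = "drop")$pk
  expect_true(all(diff(peaks) < 0))
})

test_that("active propagation regenerates the full spike at every compartment", {
  gl <- glance(cable_active())
  expect_true(all(gl$n_spikes > 0))
  expect_equal(length(unique(gl$n_spikes)), 1)     # distortionless counts
  expect_true(all(gl$V_peak_mV == 20))             # amplitude conservation
})

test_that("compartment memristance saturates at M_min under sustained drive", {
  tr <- cable_active()
  gl <- glance(tr)
  expect_true(all(gl$M_final_ohm == 100))
  # coarse-grained monotone decrease toward saturation (Fig 9D behaviour)
  m1 <- dplyr::filter(tr, compartment == 5)
  coarse <- m1$M_ohm[seq(1, nrow(m1), by = 1000)]
  expect_true(all(diff(coarse) <= 1e-9))
})

test_that("decoupling and config limits behave", {
  g <- time_grid(0.01, 50)
  stim <- make_stimulus(stimulus_spec("step", amplitude = 50), g)
  # huge axial resistance: downstream compartments stay at rest
  cp <- cable_params(n_compartments = 5, r_i = 1e9, M0 = 10000)
  tr <- simulate_cable(cp, stim, g, active = FALSE)
  far <- dplyr::filter(tr, compartment > 1)
  expect_lt(max(abs(far$V_mV + 65)), 0.01)
  expect_error(simulate_cable(cable_params(n_compartments = 1), stim, g),
               class = "memlif_config_error")
})

test_that("the dendrite filters below its switching flux and integrates above", {
  g <- time_grid(0.05, 60)
  t <- (seq_len(g$n_steps) - 1) * g$dt
  v <- rep(0, g$n_steps)
  for (on in c(2, 8, 14)) v[t >= on & t < on + 2] <- 0.00625
  v[t >= 20 & t < 26] <- 0.0125
  for (on in c(30, 36, 42)) v[t >= on & t < on + 2] <- 0.00625
  d <- dendrite_response(memristor_model(), v, g)
  expect_false(any(d$on[t < 18]))                       # off-state filter
  expect_true(any(d$on[t > 26]))                        # switched by the large pulse
  pre <- max(d$i_A[t < 20 & d$v_V > 0])
  post <- max(d$i_A[t > 28 & d$v_V > 0 & d$v_V < 0.01])
  expect_gt(post, pre)                                  # on-state integration
  expect_lt(pre, 0.00625 / (0.9 * 20000))               # off-state current band

  # slow ramp: near-zero current window, then superlinear growth
  dr <- dendrite_response(memristor_model(), 4.5e-4 * t, g)
  switch_t <- dr$time_ms[which(dr$on)[1]]
  expect_gt(switch_t, 15)
  expect_lt(switch_t, 25)
  expect_lt(mean(dr$i_A[t < 10]), 0.05 * mean(dr$i_A[t >= 50]))
})

test_that("the memristive soma integrates and fires at the 20 mV peak", {
  g <- time_grid(0.01, 300)
  soma <- soma_response(soma_params(),
                        make_stimulus(stimulus_spec("step", amplitude = 3), g), g)
  expect_gt(sum(soma$is_spike), 0)
  expect_equal(max(soma$V_mV), 20)
  # a depolarizing upstroke precedes the first spike
  first <- which(soma$is_spike)[1]
  upstroke <- soma$V_mV[(first - 20):(first - 1)]
  expect_true(all(diff(upstroke) > 0))
  # zero input rests at -65; subthreshold input climbs without firing
  z <- soma_response(soma_params(), make_stimulus(stimulus_spec("zero"), g), g)
  expect_true(all(z$V_mV == -65))
  sub <- soma_response(soma_params(),
                       make_stimulus(stimulus_spec("step", amplitude = 0.5), g), g)
  expect_equal(sum(sub$is_spike), 0)
  expect_gt(max(sub$V_mV), -65)
})

test_that("the full neuron chain orders synapse responses and relays spikes", {
  g <- time_grid(0.01, 150)
  mk <- function(a, on) make_stimulus(
    stimulus_spec("single_pulse", amplitude = a, width = 20, onset = on), g)
  ch <- neuron_chain(synapses = list(memristor_model(), memristor_model(),
                                     memristor_model()))
  sim <- simulate_full_neuron(ch, list(mk(2, 0), mk(3, 30), mk(10, 60)), g)
  peaks <- dplyr::summarise(dplyr::group_by(sim$synapses, synapse),
                            pk = max(v_mV), .groups = "drop")$pk
  expect_true(all(diff(peaks) > 0))   # larger stimulus, larger voltage response

  for (axial in c(TRUE, FALSE)) {
    ch2 <- neuron_chain(include_axial = axial)
    sim2 <- simulate_full_neuron(ch2, list(mk(3, 0)), g)
    ax <- dplyr::summarise(dplyr::group_by(sim2$axon, compartment),
                           n = sum(is_spike), pk = max(V_mV), .groups = "drop")
    expect_gt(sum(sim2$soma$is_spike), 0)
    expect_equal(length(unique(ax$n)), 1)   # identical counts along the axon
    expect_true(all(ax$pk == 20))           # no amplitude distortion
  }

  # all-zero stimuli leave every trace flat at rest
  sim0 <- simulate_full_neuron(neuron_chain(), list(mk(0, 0)), g)
  expect_true(all(sim0$soma$V_mV == -65))
  expect_true(all(sim0$axon$V_mV == -65))
  expect_error(simulate_full_neuron(neuron_chain(synapses = list(memristor_model())),
                                    list(mk(1, 0), mk(1, 0)), g),
               class = "memlif_config_error")
  expect_error(neuron_chain(synapses = rep(list(memristor_model()), 4)),
               class = "memlif_config_error")
})
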