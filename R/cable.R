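#' Parameters of the memristive compartmental cable neuron
#'
#' The axon is a chain of "T" units: one MLIF compartment (membrane
#' capacitance `C_m`, memristive leak) coupled to its neighbours through the
#' axial resistance `r_i`. The compartment length is absorbed into `r_i`, so
#' distances are reported in compartment indices times `x_spacing`. The
#' length constant is `lambda = sqrt(M / r_i)` in compartment units and
#' follows the memristance state.
#'
#' @param C_m membrane capacitance per compartment in farads (default 1e-6,
#'   i.e. 1 uF).
#' @param r_i axial resistance per compartment in ohms (default 100).
#' @param memristor a [memristor_model()]; default device spans
#'   100..20000 ohms.
#' @param n_compartments chain length (default 10).
#' @param V_rest,V_th,V_reset,V_spike firing rule potentials in mV.
#' @param input_gain input coupling gain (`gain * M[kOhm] * I[nA]` in mV).
#' @param state_drive_gain flux coupling of the compartment drive
#'   `(V - V_rest)`; the default 0.002 lets a compartment sustain a spike
#'   train over tens of milliseconds before its device saturates at `M_min`.
#' @param M0 initial memristance in ohms (default `M_max`).
#' @param x_spacing length units per compartment.
#' @param peak_hold_ms duration a firing compartment holds its peak at
#'   `V_spike` (the action-potential width; default 0.1 ms). The finite
#'   width is what lets a spike depolarize its neighbour across the axial
#'   coupling time `r_i * C_m` and regenerate — saltatory propagation.
#' @param refractory_ms post-spike clamp at `V_reset` (default 0.2 ms),
#'   preventing re-excitation by the downstream compartment's own peak
#'   (no reflection of action potentials).
#' @return A `cable_params` object.
#' @export
cable_params <- function(C_m = 1e-6, r_i = 100, memristor = memristor_model(),
                         n_compartments = 10, V_rest = -65, V_th = -50,
                         V_reset = -80, V_spike = 20, input_gain = 1,
                         state_drive_gain = 0.002, M0 = NULL, x_spacing = 1,
                         peak_hold_ms = 0.1, refractory_ms = 0.2) {
  if (r_i <= 0) abort("`r_i` must be positive.", class = "memlif_invalid_parameter")
  if (n_compartments < 1) {
    abort("Need at least one compartment.", class = "memlif_invalid_parameter")
  }
  stopifnot(inherits(memristor, "memristor_model"))
  structure(list(C_m = C_m, r_i = r_i, memristor = memristor,
                 n_compartments = n_compartments, V_rest = V_rest,
                 V_th = V_th, V_reset = V_reset, V_spike = V_spike,
                 input_gain = input_gain, state_drive_gain = state_drive_gain,
                 M0 = M0, x_spacing = x_spacing,
                 peak_hold_ms = peak_hold_ms, refractory_ms = refractory_ms),
            class = "cable_params")
}

#' Passive electrotonic attenuation profile
#'
#' Steady-state solution of the passive cable: `v(x) = V0 * exp(-x / lambda)`
#' with length constant `lambda = sqrt(M / r_i)`.
#'
#' @param M membrane (mem)resistance in ohms.
#' @param r_i axial resistance in ohms.
#' @param V0 depolarization at the injection site, mV.
#' @param x distances from the injection site (non-negative, in compartment
#'   length units).
#' @return `v(x)` in mV.
#' @examples
#' passive_profile(10000, 100, 15, 0:5)
#' @export
passive_profile <- function(M, r_i, V0, x) {
  if (M <= 0 || r_i <= 0) {
    abort("`M` and `r_i` must be positive.", class = "memlif_invalid_parameter")
  }
  if (any(x < 0)) abort("Distances must be non-negative.", class = "memlif_domain_error")
  V0 * exp(-x / sqrt(M / r_i))
}

#' Simulate the memristive cable neuron
#'
#' Spatially discretized membrane equation per compartment `k`:
#' `tau_k dV_k/dt = (M_k / r_i) (V_{k-1} - 2 V_k + V_{k+1}) - (V_k - V_rest)
#' + gain * M_k * i_k`, with `tau_k = M_k C_m`, sealed ends (zero axial flux
#' at the boundaries), and the external current injected at `inject_at`.
#' In active mode every compartment applies the MLIF firing rule and its
#' device integrates the local membrane drive; a firing compartment holds
#' its peak for `peak_hold_ms` (so the action potential can regenerate in
#' the neighbouring compartment) and then sits at `V_reset` for
#' `refractory_ms`, which keeps the wave travelling one way. In passive
#' mode the firing rule is off and the memristance is held fixed (the
#' electrotonic, sub-switching regime), so the steady profile can be
#' compared against [passive_profile()].
#'
#' @param params a [cable_params()].
#' @param stimulus current series (nA) injected at `inject_at`.
#' @param grid a [time_grid()].
#' @param active apply the firing rule and device dynamics (default TRUE).
#' @param inject_at compartment index receiving the stimulus (default 1).
#' @param boundary_series optional membrane-potential series (mV) of an
#'   upstream driving compartment (e.g. a soma) axially coupled to
#'   compartment 1.
#' @return A long tibble of class `cable_trace` with columns `time_ms`,
#'   `compartment`, `V_mV`, `M_ohm`, `is_spike`.
#' @export
simulate_cable <- function(params, stimulus, grid, active = TRUE,
                           inject_at = 1, boundary_series = NULL) {
  stopifnot(inherits(params, "cable_params"), inherits(grid, "time_grid"))
  p <- params
  n <- p$n_compartments
  if (n < 2 && is.null(boundary_series)) {
    abort("Axial coupling needs at least 2 compartments.",
          class = "memlif_config_error")
  }
  i_ext <- stimulus_series(stimulus, grid)
  dt <- grid$dt
  n_steps <- grid$n_steps
  model <- p$memristor
  s0 <- if (is.null(p$M0)) model$s_lo else state_for_memristance(model, p$M0)$value
  s <- rep(s0, n)
  V <- rep(p$V_rest, n)
  hold_steps <- max(1L, round(p$peak_hold_ms / dt))
  refr_steps <- max(1L, round(p$refractory_ms / dt))
  # per-compartment firing phase: 0 excitable, >0 remaining peak-hold steps,
  # <0 remaining refractory steps (negated)
  phase <- integer(n)
  Vmat <- matrix(NA_real_, n_steps, n)
  Mmat <- matrix(NA_real_, n_steps, n)
  spk <- matrix(FALSE, n_steps, n)
  inj <- rep(0, n)

  for (k in seq_len(n_steps)) {
    M <- memristance_at(model, s)
    Mmat[k, ] <- M
    tau <- M * p$C_m * 1e3
    a <- pmin(dt / tau, 1)
    left <- c(if (is.null(boundary_series)) V[1] else boundary_series[k],
              V[-n])
    right <- c(V[-1], V[n])
    lap <- left - 2 * V + right
    inj[inject_at] <- i_ext[k]
    u <- p$input_gain * (M / 1e3) * inj
    V_new <- V + a * ((M / p$r_i) * lap - (V - p$V_rest) + u)
    V_new <- pmax(V_new, p$V_reset)
    if (active) {
      holding <- phase > 0L
      refr <- phase < 0L
      V_new[holding] <- p$V_spike
      V_new[refr] <- p$V_reset
      crossed <- phase == 0L & V_new >= p$V_th
      V_new[crossed] <- p$V_spike
      spk[k, ] <- crossed
      phase[crossed] <- hold_steps
      phase[holding] <- phase[holding] - 1L
      phase[phase == 0L & holding] <- -refr_steps
      phase[refr] <- phase[refr] + 1L
      Vmat[k, ] <- V_new
      V <- V_new
      s <- s + model$orientation * p$state_drive_gain * (V - p$V_rest) * dt
    } else {
      Vmat[k, ] <- V_new
      V <- V_new
    }
  }

  t <- grid_times(grid)
  out <- tibble(
    time_ms = rep(t, times = n),
    compartment = rep(seq_len(n), each = n_steps),
    V_mV = as.vector(Vmat),
    M_ohm = as.vector(Mmat),
    is_spike = as.vector(spk))
  structure(out, class = c("cable_trace", class(tibble())),
            params = p, grid = grid, active = active)
}

#' @method tidy cable_trace
#' @export
tidy.cable_trace <- function(x, ...) {
  dplyr::filter(tibble(compartment = x$compartment,
                       spike_time_ms = x$time_ms,
                       keep = x$is_spike), .data$keep)[, 1:2]
}

#' @rdname tidy.cable_trace
#' @param x a `cable_trace`.
#' @param ... unused.
#' @method glance cable_trace
#' @export
glance.cable_trace <- function(x, ...) {
  x |>
    group_by(.data$compartment) |>
    summarise(n_spikes = sum(.data$is_spike),
              V_peak_mV = max(.data$V_mV),
              M_final_ohm = .data$M_ohm[dplyr::n()],
              .groups = "drop")
}

#' @method autoplot cable_trace
#' @export
autoplot.cable_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$V_mV)) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.3) +
    ggplot2::facet_wrap(~compartment, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (ms)", y = "Membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' Memristive dendrite response
#'
#' A flux-controlled memristor as a dendrite: below its switching flux
#' (`s_lo` plus 10% of the breakpoint span) the device stays near `M_max`
#' and filters the input (negligible current); once the accumulated flux
#' crosses the switching level it conducts, and subsequent small inputs
#' produce visibly larger currents (integration).
#'
#' @param dendrite a flux-controlled [memristor_model()].
#' @param v_stimulus voltage series in volts (a tibble from
#'   [make_stimulus()], read as volts, or a numeric vector).
#' @param grid a [time_grid()].
#' @return A tibble of class `dendrite_response`: `time_ms`, `v_V`, `i_A`,
#'   `M_ohm`, `phi`, `on`.
#' @export
dendrite_response <- function(dendrite, v_stimulus, grid) {
  stopifnot(inherits(dendrite, "memristor_model"),
            dendrite$kind == "flux_controlled")
  v <- stimulus_series(v_stimulus, grid)
  switch_level <- dendrite$s_lo + 0.1 * (dendrite$s_hi - dendrite$s_lo)
  n <- grid$n_steps
  s <- dendrite$s_lo
  M <- numeric(n); i <- numeric(n); phi <- numeric(n)
  for (k in seq_len(n)) {
    M[k] <- memristance_at(dendrite, s)
    i[k] <- v[k] / M[k]
    s <- s + dendrite$orientation * v[k] * grid$dt
    phi[k] <- s
  }
  structure(tibble(time_ms = grid_times(grid), v_V = v, i_A = i,
                   M_ohm = M, phi = phi, on = phi > switch_level),
            class = c("dendrite_response", class(tibble())),
            switch_level = switch_level)
}

#' Memristive soma response
#'
#' The soma is an MLIF unit parameterized like the cable compartments
#' (1 uF membrane, device in 100..20000 ohms, rest -65 mV, threshold
#' -50 mV, spike peak 20 mV). A sustained 3 nA drive produces firing with a
#' visible depolarizing upstroke before each spike (the soma's non-linear
#' integration).
#'
#' @param soma a [neuron_params()] with a memristor; [soma_params()] gives
#'   the reference configuration.
#' @param i_stimulus current series in nA.
#' @param grid a [time_grid()].
#' @return A `membrane_trace`.
#' @export
soma_response <- function(soma = soma_params(), i_stimulus, grid) {
  simulate_mlif(soma, i_stimulus, grid)
}

#' @rdname soma_response
#' @export
soma_params <- function() {
  neuron_params(C = 1e-6, memristor = memristor_model(),
                V_rest = -65, V_th = -50, V_reset = -80, V_spike = 20,
                input_gain = 1, state_drive_gain = 0.002)
}

#' Full memristive neuron chain
#'
#' @param synapses list of up to 3 [memristor_model()] synapse devices.
#' @param dendrite dendrite [memristor_model()].
#' @param soma soma [neuron_params()] (memristive).
#' @param n_axon number of axon compartments.
#' @param include_axial couple the axon compartments axially (`TRUE`, the
#'   cable of the full model) or relay spikes unit-to-unit ignoring the
#'   axial resistance (`FALSE`, the simplified chain).
#' @param r_i axial resistance in ohms.
#' @return A `neuron_chain` configuration object.
#' @export
neuron_chain <- function(synapses = list(memristor_model()),
                         dendrite = memristor_model(),
                         soma = soma_params(),
                         n_axon = 3, include_axial = TRUE, r_i = 100) {
  if (length(synapses) > 3) {
    abort("At most 3 synapses are supported.", class = "memlif_config_error")
  }
  structure(list(synapses = synapses, dendrite = dendrite, soma = soma,
                 n_axon = n_axon, include_axial = include_axial, r_i = r_i),
            class = "neuron_chain")
}

#' Simulate the full synapse-dendrite-soma-axon neuron
#'
#' Each stimulus drives one synapse; the synapse voltage response is
#' `M_syn * i` (kOhm x nA read in mV), so larger stimuli produce larger
#' voltage responses. The summed current passes down the dendrite into the
#' soma; soma spikes propagate along the axon chain, every compartment
#' regenerating the action potential at the full peak amplitude
#' (distortionless transmission).
#'
#' @param chain a [neuron_chain()].
#' @param stimuli list of up to `length(chain$synapses)` current series
#'   (tibbles or numeric, nA); the reference protocol offsets their onsets
#'   by 30 ms.
#' @param grid a [time_grid()].
#' @return A list of class `neuron_chain_sim`: `synapses` (long tibble of
#'   voltage responses), `soma` (`membrane_trace`), `axon` (long tibble with
#'   per-compartment traces).
#' @export
simulate_full_neuron <- function(chain, stimuli, grid) {
  stopifnot(inherits(chain, "neuron_chain"), inherits(grid, "time_grid"))
  if (!is.list(stimuli) || is.data.frame(stimuli)) stimuli <- list(stimuli)
  if (length(stimuli) > length(chain$synapses)) {
    abort(sprintf("Got %d stimuli for %d synapses.", length(stimuli),
                  length(chain$synapses)),
          class = "memlif_config_error")
  }
  n_steps <- grid$n_steps
  syn_tabs <- purrr::imap(stimuli, function(stim, j) {
    i <- stimulus_series(stim, grid)
    dev <- chain$synapses[[j]]
    s <- dev$s_lo
    v <- numeric(n_steps); M <- numeric(n_steps)
    for (k in seq_len(n_steps)) {
      M[k] <- memristance_at(dev, s)
      v[k] <- (M[k] / 1e3) * i[k]
      s <- s + dev$orientation * v[k] * 1e-3 * grid$dt
    }
    tibble(time_ms = grid_times(grid), synapse = j, v_mV = v, M_ohm = M)
  })
  i_total <- purrr::reduce(purrr::map(stimuli, stimulus_series, grid = grid), `+`,
                           .init = rep(0, n_steps))
  soma_trace <- simulate_mlif(chain$soma, i_total, grid)

  if (chain$include_axial) {
    cp <- cable_params(memristor = chain$soma$memristor %||% memristor_model(),
                       n_compartments = chain$n_axon, r_i = chain$r_i,
                       state_drive_gain = chain$soma$state_drive_gain)
    axon <- simulate_cable(cp, rep(0, n_steps), grid, active = TRUE,
                           boundary_series = soma_trace$V_mV)
  } else {
    # relay mode: each unit receives a fixed-width current pulse per
    # upstream spike (axial resistance ignored). Because the per-step
    # depolarization is ~ dt * amplitude regardless of the device state,
    # a 0.15 ms / 200 nA pulse always yields exactly one downstream spike
    # (refire would need more climb steps than the pulse has left).
    w_relay <- 0.15; amp_relay <- 200
    upstream <- soma_trace
    parts <- vector("list", chain$n_axon)
    for (kc in seq_len(chain$n_axon)) {
      spikes <- attr(upstream, "spikes")
      i_relay <- rep(0, n_steps)
      t <- grid_times(grid)
      for (ts in spikes) i_relay[t >= ts & t < ts + w_relay] <- amp_relay
      unit <- simulate_mlif(soma_params(), i_relay, grid)
      parts[[kc]] <- mutate(as_tibble(unit), compartment = kc)
      upstream <- unit
    }
    axon <- bind_rows(parts)
  }
  structure(list(synapses = bind_rows(syn_tabs), soma = soma_trace,
                 axon = axon),
            class = "neuron_chain_sim")
}

#' @export
print.neuron_chain_sim <- function(x, ...) {
  cat(sprintf("<neuron_chain_sim> %d synapse(s), soma with %d spikes\n",
              length(unique(x$synapses$synapse)),
              length(attr(x$soma, "spikes"))))
  invisible(x)
}
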