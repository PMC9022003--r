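#' Neuron parameters for LIF and MLIF simulations
#'
#' Membrane constants and firing rule for the leaky integrate-and-fire (LIF)
#' neuron and its memristive variant (MLIF), in which the fixed leak resistor
#' is replaced by a [memristor_model()] so the membrane time constant
#' `tau_M = M(t) * C` and the input coupling follow the device state.
#'
#' Simulations run in model units: millivolts, milliseconds, nanoamperes.
#' With these, `tau = R * C` is in milliseconds (1 MOhm x 2 nF = 2 ms) and
#' the LIF input coupling `input_gain * R[MOhm] * I[nA]` is in millivolts.
#' With the reference resting potential -65 mV the threshold gap is 15 mV,
#' and the default LIF gain 12 brackets it: a 1.0 nA drive is subthreshold
#' (12 mV) and a 1.5 nA drive suprathreshold (18 mV). The MLIF input
#' coupling reads `input_gain * M[kOhm] * I[nA]` in millivolts (gain 1).
#' `input_scale = "si"` instead reads both couplings strictly in SI
#' (`R[Ohm] * I[A]`), which for the printed device values never bridges the
#' threshold gap — supported for completeness, documented as non-firing.
#'
#' `firing_polarity` mirrors the spike rule about `V_rest`: `"positive"`
#' (default) fires on depolarization past `V_th`; `"negative"` fires on the
#' mirrored threshold `2 V_rest - V_th`; `"both"` supports forward and
#' reverse action potentials, as seen under biphasic stimulation.
#'
#' `state_drive_gain` scales the membrane drive `(V - V_rest)` (mV, over ms)
#' before it integrates into the memristor flux. The device's switching-flux
#' scale is a calibration: the default 0.005 makes a 1.5 nA step produce a
#' dense initial burst that relaxes over roughly 25 ms — the spike-frequency
#' adaptation signature of the model.
#'
#' @param C membrane capacitance in farads (default 2e-9).
#' @param R leak resistance in ohms (LIF; default 1e6).
#' @param memristor a [memristor_model()] (MLIF only).
#' @param V_rest,V_th,V_reset,V_spike potentials in mV; the firing rule sets
#'   the threshold-crossing sample to `V_spike` and the next to `V_reset`.
#' @param input_gain dimensionless input scaling; `NULL` picks 12 for LIF
#'   and 1 for MLIF at simulation time.
#' @param input_scale `"model"` (default) or `"si"`, see Details.
#' @param V0 initial membrane potential (defaults to `V_rest`).
#' @param firing_polarity `"positive"`, `"negative"`, or `"both"`.
#' @param state_drive_gain flux coupling of the membrane drive (MLIF).
#' @param M0 initial memristance in ohms; default is `M_max` of the device
#'   (large initial memristance, the adapting configuration).
#' @return A `neuron_params` object.
#' @export
neuron_params <- function(C = 2e-9, R = 1e6, memristor = NULL,
                          V_rest = -65, V_th = -50, V_reset = -80,
                          V_spike = 20, input_gain = NULL,
                          input_scale = c("model", "si"),
                          V0 = NULL, firing_polarity = c("positive", "negative", "both"),
                          state_drive_gain = 0.005, M0 = NULL) {
  input_scale <- match.arg(input_scale)
  firing_polarity <- match.arg(firing_polarity)
  if (!(V_reset < V_rest && V_rest < V_th && V_th < V_spike)) {
    abort("Require V_reset < V_rest < V_th < V_spike.",
          class = "memlif_invalid_parameter")
  }
  if (!is.null(input_gain) && input_gain <= 0) {
    abort("`input_gain` must be positive.", class = "memlif_invalid_parameter")
  }
  if (!is.null(memristor)) stopifnot(inherits(memristor, "memristor_model"))
  structure(list(C = C, R = R, memristor = memristor,
                 V_rest = V_rest, V_th = V_th, V_reset = V_reset,
                 V_spike = V_spike, input_gain = input_gain,
                 input_scale = input_scale, V0 = V0 %||% V_rest,
                 firing_polarity = firing_polarity,
                 state_drive_gain = state_drive_gain, M0 = M0),
            class = "neuron_params")
}

# resistance -> membrane-voltage reading of R*I (model units vs strict SI)
input_coupling <- function(R_ohm, I_nA, gain, scale, memristive) {
  if (scale == "si") return(gain * R_ohm * I_nA * 1e-6)  # Ohm * nA in mV
  if (memristive) gain * (R_ohm / 1e3) * I_nA else gain * (R_ohm / 1e6) * I_nA
}

# Shared forward-Euler engine for LIF and MLIF point neurons.
# The threshold test uses the subthreshold (pre-overwrite) potential; the
# artificial peak sample is cosmetic and excluded from both the Euler update
# and the memristor state drive (the device integrates the true crossing
# value instead).
simulate_neuron_engine <- function(params, i_series, grid, memristive) {
  dt <- grid$dt
  n <- grid$n_steps
  p <- params
  gain <- p$input_gain %||% (if (memristive) 1 else 12)
  th_pos <- p$V_th
  th_neg <- 2 * p$V_rest - p$V_th
  peak_neg <- 2 * p$V_rest - p$V_spike
  reset_neg <- 2 * p$V_rest - p$V_reset
  fire_pos <- p$firing_polarity %in% c("positive", "both")
  fire_neg <- p$firing_polarity %in% c("negative", "both")
  lo_clamp <- if (fire_neg) -Inf else p$V_reset
  hi_clamp <- if (fire_pos) Inf else reset_neg

  if (memristive) {
    model <- p$memristor
    if (is.null(model)) {
      abort("MLIF simulation needs `memristor` in the parameters.",
            class = "memlif_invalid_parameter")
    }
    s <- if (is.null(p$M0)) model$s_lo else {
      state_for_memristance(model, p$M0)$value
    }
  } else {
    if (is.null(p$R)) {
      abort("LIF simulation needs `R` in the parameters.",
            class = "memlif_invalid_parameter")
    }
  }

  V_disp <- numeric(n)
  M_traj <- if (memristive) numeric(n) else NULL
  is_spike <- logical(n)
  spike_sign <- integer(0)
  spike_idx <- integer(0)
  clamped <- logical(n)
  V <- p$V0
  pending <- 0 # 0 none, +1 reset to V_reset, -1 reset to reverse reset

  for (k in seq_len(n)) {
    M <- if (memristive) memristance_at(model, s) else p$R
    if (memristive) M_traj[k] <- M
    if (pending != 0) {
      V <- if (pending > 0) p$V_reset else reset_neg
      pending <- 0
      V_disp[k] <- V
    } else {
      tau <- M * p$C * 1e3 # ms
      a <- dt / tau
      if (a > 1) { a <- 1; clamped[k] <- TRUE }
      u <- input_coupling(M, i_series[k], gain, p$input_scale, memristive)
      V <- V + a * (-V + p$V_rest + u)
      if (V < lo_clamp) { V <- lo_clamp; clamped[k] <- TRUE }
      if (V > hi_clamp) { V <- hi_clamp; clamped[k] <- TRUE }
      if (fire_pos && V >= th_pos) {
        V_disp[k] <- p$V_spike
        is_spike[k] <- TRUE
        spike_idx <- c(spike_idx, k)
        spike_sign <- c(spike_sign, 1L)
        pending <- 1
      } else if (fire_neg && V <= th_neg) {
        V_disp[k] <- peak_neg
        is_spike[k] <- TRUE
        spike_idx <- c(spike_idx, k)
        spike_sign <- c(spike_sign, -1L)
        pending <- -1
      } else {
        V_disp[k] <- V
      }
    }
    if (memristive) {
      s <- s + model$orientation * p$state_drive_gain * (V - p$V_rest) * dt
    }
  }

  t <- grid_times(grid)
  cols <- list(time_ms = t, V_mV = V_disp)
  if (memristive) cols$M_ohm <- M_traj
  cols$is_spike <- is_spike
  structure(as_tibble(cols),
            class = c("membrane_trace", class(tibble())),
            spikes = t[spike_idx], spike_signs = spike_sign,
            params = p, grid = grid, clamped = clamped,
            model = if (memristive) "mlif" else "lif")
}

#' Simulate the LIF neuron
#'
#' Forward-Euler integration of the leaky integrate-and-fire membrane:
#' `V <- V + (dt / tau) * (-V + V_rest + gain * R * I_ext)` with
#' `tau = R * C`. When `V` reaches `V_th`, the sample is set to `V_spike`
#' (an artificial, cosmetic peak) and the next sample to `V_reset`.
#'
#' @param params a [neuron_params()] with `R` set.
#' @param stimulus a tibble from [make_stimulus()] or a numeric current
#'   series in nA with one value per grid step.
#' @param grid a [time_grid()].
#' @return A `membrane_trace` tibble with columns `time_ms`, `V_mV`,
#'   `is_spike`; spike times are available via [tidy()] and as the
#'   `"spikes"` attribute.
#' @export
simulate_lif <- function(params, stimulus, grid) {
  stopifnot(inherits(params, "neuron_params"), inherits(grid, "time_grid"))
  simulate_neuron_engine(params, stimulus_series(stimulus, grid), grid,
                         memristive = FALSE)
}

#' Simulate the MLIF neuron
#'
#' As [simulate_lif()], but the leak resistor is a memristor: at every step
#' the memristance `M` is recomputed from the device state, the time constant
#' is `tau_M = M * C`, the input couples through `M`, and the device state
#' integrates the membrane drive `(V - V_rest)` scaled by
#' `state_drive_gain`. Because the device starts at a large memristance and
#' depolarized episodes push it toward `M_min`, a sustained drive produces a
#' dense initial burst that slows down — spike-frequency adaptation.
#'
#' @inheritParams simulate_lif
#' @param params a [neuron_params()] with `memristor` set.
#' @return A `membrane_trace` tibble, additionally carrying the memristance
#'   trajectory in `M_ohm`.
#' @export
simulate_mlif <- function(params, stimulus, grid) {
  stopifnot(inherits(params, "neuron_params"), inherits(grid, "time_grid"))
  simulate_neuron_engine(params, stimulus_series(stimulus, grid), grid,
                         memristive = TRUE)
}

#' Capacitive and leak membrane currents of a trace
#'
#' Recovers the Kirchhoff decomposition of the membrane equation:
#' `I_C = C dV/dt` (forward finite difference, reported in nA) and
#' `I_R = (V - V_rest) / R` (or `/ M` along the recorded memristance
#' trajectory for MLIF traces). Samples touched by the artificial spike
#' peak, the reset, or a clamped update are masked `NA`; at every unmasked
#' sample `I_C + I_R` equals the gain-scaled external current exactly under
#' the Euler scheme.
#'
#' @param trace a `membrane_trace`.
#' @param params the [neuron_params()] used for the simulation.
#' @param stimulus the current series the trace was simulated with.
#' @return A tibble with `time_ms`, `I_C_nA`, `I_R_nA`, `I_input_scaled_nA`,
#'   and `masked`.
#' @export
membrane_currents <- function(trace, params, stimulus) {
  stopifnot(inherits(trace, "membrane_trace"))
  grid <- attr(trace, "grid")
  i_ext <- stimulus_series(stimulus, grid)
  dt <- grid$dt
  V <- trace$V_mV
  n <- length(V)
  memristive <- attr(trace, "model") == "mlif"
  # the forward difference spans the update step k -> k+1, which the Euler
  # scheme computes with the memristance of step k+1
  R <- if (memristive) c(trace$M_ohm[-1], NA_real_) else rep(params$R, n)
  gain <- params$input_gain %||% (if (memristive) 1 else 12)

  dVdt <- c(diff(V) / dt, NA_real_)
  I_C <- params$C * 1e9 * dVdt              # nA
  I_R <- (V - params$V_rest) / (R * 1e-6)   # mV / MOhm = nA
  u <- input_coupling(R, i_ext, gain, params$input_scale, memristive)
  I_in <- u / (R * 1e-6)

  bad <- trace$is_spike | c(FALSE, head(trace$is_spike, -1)) | attr(trace, "clamped")
  masked <- bad | c(tail(bad, -1), TRUE)
  I_C[masked] <- NA_real_
  I_R[masked] <- NA_real_
  tibble(time_ms = trace$time_ms, I_C_nA = I_C, I_R_nA = I_R,
         I_input_scaled_nA = I_in, masked = masked)
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace> %s, %d samples, %d spikes\n",
              attr(x, "model"), nrow(x), length(attr(x, "spikes"))))
  NextMethod()
}

#' Tidiers for membrane traces
#'
#' `tidy()` returns the spike train (one row per spike, with its sign:
#' +1 forward, -1 reverse action potential). `glance()` returns a one-row
#' summary: model, spike count, mean firing rate in spikes/s, final membrane
#' potential and (for MLIF) final memristance.
#'
#' @param x a `membrane_trace`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy membrane_trace
#' @export
tidy.membrane_trace <- function(x, ...) {
  tibble(spike_time_ms = attr(x, "spikes"),
         sign = attr(x, "spike_signs") %||% rep(1L, length(attr(x, "spikes"))))
}

#' @rdname tidy.membrane_trace
#' @method glance membrane_trace
#' @export
glance.membrane_trace <- function(x, ...) {
  spikes <- attr(x, "spikes")
  horizon_s <- attr(x, "grid")$T / 1000
  tibble(model = attr(x, "model"),
         n_spikes = length(spikes),
         mean_rate_hz = length(spikes) / horizon_s,
         V_final_mV = x$V_mV[nrow(x)],
         M_final_ohm = if ("M_ohm" %in% names(x)) x$M_ohm[nrow(x)] else NA_real_)
}

#' @method autoplot membrane_trace
#' @export
autoplot.membrane_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$V_mV)) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.3) +
    ggplot2::labs(x = "Time (ms)", y = "Membrane potential (mV)",
                  title = sprintf("%s membrane trace",
                                  toupper(attr(object, "model")))) +
    ggplot2::theme_minimal()
}

#' Export a membrane trace as CSV
#'
#' Writes columns `time_ms`, `V_mV`, optionally `M_ohm`, and `is_spike`.
#'
#' @param trace a `membrane_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
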