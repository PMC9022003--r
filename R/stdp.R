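#' Biphasic action-potential template for the STDP synapse
#'
#' A parameterized stand-in for the spike waveform applied across the
#' synaptic memristor: a rectangular positive lobe (`amp_pos` volts for
#' `width_pos` ms) followed by an exponentially decaying negative tail
#' (`-amp_neg * exp(-t / tau_neg)`), truncated at `support` ms. A single
#' template never exceeds the 1 V synaptic threshold; only the
#' superposition of a pre- and a post-synaptic waveform can move the device
#' state, which is what makes the conductance change timing-dependent.
#'
#' @param dt sample step in ms.
#' @param amp_pos,width_pos positive lobe amplitude (V) and width (ms).
#' @param amp_neg,tau_neg negative tail amplitude (V) and decay constant (ms).
#' @param support total waveform support in ms.
#' @return Numeric voltage series sampled every `dt` ms.
#' @export
ap_template <- function(dt = 0.05, amp_pos = 0.9, width_pos = 1,
                        amp_neg = 0.6, tau_neg = 3, support = 15) {
  t <- seq(0, support, by = dt)
  ifelse(t < width_pos, amp_pos,
         -amp_neg * exp(-(t - width_pos) / tau_neg))
}

#' STDP curve of a memristive synapse
#'
#' For each pairing interval `delta_t = t_post - t_pre`, the pre- and
#' post-synaptic action-potential templates are superposed across the
#' synapse (`v = AP_post - AP_pre`), and only the portion of the net voltage
#' exceeding the synaptic threshold (1 V) drives the device flux. The
#' conductance change `delta_G = 1/M_after - 1/M_before` is positive for
#' `delta_t > 0` (pre before post: potentiation), negative for
#' `delta_t < 0`, shrinks as `|delta_t|` grows, and vanishes once the two
#' waveforms no longer overlap.
#'
#' @param delta_ts pairing intervals in ms (post minus pre spike time).
#' @param synapse a flux-controlled [memristor_model()]; the device starts
#'   each episode at the middle of its state range.
#' @param ap_waveform voltage template from [ap_template()] (sampled at
#'   `dt`).
#' @param dt sample step in ms.
#' @param v_threshold synaptic voltage threshold in volts (default 1).
#' @param drive_gain scaling of the super-threshold drive into device flux.
#' @return A tibble of class `stdp_curve` with `delta_t_ms` and
#'   `delta_G_S`.
#' @export
stdp_curve <- function(delta_ts, synapse = memristor_model(),
                       ap_waveform = NULL, dt = 0.05,
                       v_threshold = 1, drive_gain = 0.1) {
  stopifnot(inherits(synapse, "memristor_model"))
  if (length(delta_ts) == 0) {
    return(structure(tibble(delta_t_ms = numeric(0), delta_G_S = numeric(0)),
                     class = c("stdp_curve", class(tibble()))))
  }
  ap <- ap_waveform %||% ap_template(dt = dt)
  support <- length(ap)
  mid <- (synapse$s_lo + synapse$s_hi) / 2
  dG <- vapply(delta_ts, function(d) {
    lag <- round(abs(d) / dt)
    n <- support + lag
    pre <- post <- rep(0, n)
    if (d >= 0) {
      pre[seq_len(support)] <- ap
      post[lag + seq_len(support)] <- ap
    } else {
      post[seq_len(support)] <- ap
      pre[lag + seq_len(support)] <- ap
    }
    v <- post - pre
    eff <- sign(v) * pmax(abs(v) - v_threshold, 0) * drive_gain
    s <- mid + synapse$orientation * sum(eff) * dt
    1 / memristance_at(synapse, s) - 1 / memristance_at(synapse, mid)
  }, numeric(1))
  structure(tibble(delta_t_ms = as.numeric(delta_ts), delta_G_S = dG),
            class = c("stdp_curve", class(tibble())))
}

#' @method autoplot stdp_curve
#' @export
autoplot.stdp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$delta_t_ms, .data$delta_G_S)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(colour = "#b2182b") +
    ggplot2::geom_line(colour = "#b2182b", alpha = 0.5) +
    ggplot2::labs(x = expression(Delta * t ~ "(ms)"),
                  y = expression(Delta * G ~ "(S)"),
                  title = "Memristive STDP curve") +
    ggplot2::theme_minimal()
}
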