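#' Piecewise memristor device model
#'
#' Constructs a charge-controlled or flux-controlled memristor whose
#' memristance is a piecewise-linear function of the accumulated state
#' variable (charge `q` or flux `phi`): `M_max` below the lower breakpoint,
#' `M_min` at and above the upper breakpoint, and the unique straight line
#' through `(s_lo, M_max)` and `(s_hi, M_min)` in between, so the law is
#' continuous and bounded by construction.
#'
#' The default breakpoints are `c(-0.5e-4, 0.5e-4)` for the charge-controlled
#' device and `c(-0.75, 0.25)` for the flux-controlled device. `orientation`
#' flips the device polarity: the drive is multiplied by it before the state
#' integrates, which realizes the four forward/reverse polarity cases of the
#' point-neuron experiments.
#'
#' @param kind `"flux_controlled"` (default) or `"charge_controlled"`.
#' @param M_min,M_max memristance bounds in ohms.
#' @param s_lo,s_hi state breakpoints (state units: coulombs for charge,
#'   volt-seconds for flux). Defaults depend on `kind`.
#' @param orientation device polarity, `+1` or `-1`.
#' @return An object of class `memristor_model`.
#' @examples
#' m <- memristor_model()
#' memristance(m, memristor_state(m, -1))   # 20000
#' memristance(m, memristor_state(m, 0.5))  # 100
#' @export
memristor_model <- function(kind = c("flux_controlled", "charge_controlled"),
                            M_min = 100, M_max = 20000,
                            s_lo = NULL, s_hi = NULL,
                            orientation = 1) {
  kind <- match.arg(kind)
  if (is.null(s_lo)) s_lo <- if (kind == "flux_controlled") -0.75 else -0.5e-4
  if (is.null(s_hi)) s_hi <- if (kind == "flux_controlled") 0.25 else 0.5e-4
  if (!(M_min < M_max)) {
    abort("`M_min` must be smaller than `M_max`.", class = "memlif_invalid_parameter")
  }
  if (!(s_lo < s_hi)) {
    abort("`s_lo` must be smaller than `s_hi`.", class = "memlif_invalid_parameter")
  }
  if (!orientation %in% c(-1, 1)) {
    abort("`orientation` must be +1 or -1.", class = "memlif_invalid_parameter")
  }
  structure(
    list(kind = kind, M_min = M_min, M_max = M_max,
         s_lo = s_lo, s_hi = s_hi, orientation = orientation,
         slope = (M_min - M_max) / (s_hi - s_lo)),
    class = "memristor_model"
  )
}

#' @export
print.memristor_model <- function(x, ...) {
  cat(sprintf(
    "<memristor_model> %s\n  M in [%g, %g] ohm, breakpoints [%g, %g], orientation %+d\n",
    x$kind, x$M_min, x$M_max, x$s_lo, x$s_hi, x$orientation))
  invisible(x)
}

#' Memristor state
#'
#' The state of a memristor is its accumulated charge (charge-controlled
#' device) or flux (flux-controlled device), together with the derived
#' memristance. The default initial state sits at the lower breakpoint, i.e.
#' the device starts at `M_max` (a large initial memristance, the adapting
#' configuration). Use `state_for_memristance()` to start a device at a
#' prescribed memristance instead.
#'
#' @param model a [memristor_model()].
#' @param value initial state-variable value; defaults to `model$s_lo`.
#' @return An object of class `memristor_state`: a list with the active state
#'   variable (`q` or `phi`), and `M` in ohms.
#' @export
memristor_state <- function(model, value = model$s_lo) {
  stopifnot(inherits(model, "memristor_model"))
  if (!is.finite(value)) {
    abort("Memristor state must be finite.", class = "memlif_invalid_state")
  }
  st <- list(value = value, M = memristance_at(model, value))
  names(st)[1] <- if (model$kind == "flux_controlled") "phi" else "q"
  st$value <- value
  structure(st, class = "memristor_state")
}

#' @rdname memristor_state
#' @param M target memristance in ohms, inside `[M_min, M_max]`.
#' @export
state_for_memristance <- function(model, M) {
  stopifnot(inherits(model, "memristor_model"))
  if (!is.finite(M) || M < model$M_min || M > model$M_max) {
    abort("Target memristance must lie in [M_min, M_max].",
          class = "memlif_invalid_parameter")
  }
  memristor_state(model, model$s_lo + (M - model$M_max) / model$slope)
}

# vectorized piecewise law on raw state values
memristance_at <- function(model, value) {
  M <- model$M_max + model$slope * (value - model$s_lo)
  M[value < model$s_lo] <- model$M_max
  M[value >= model$s_hi] <- model$M_min
  pmin(pmax(M, model$M_min), model$M_max)
}

#' Evaluate the memristance law
#'
#' Returns `M_max` below the lower breakpoint, `M_min` at and above the upper
#' breakpoint, and the linear interpolation between them in the middle
#' region; the result is clamped to `[M_min, M_max]`.
#'
#' @param model a [memristor_model()].
#' @param state a [memristor_state()] or a numeric vector of raw state values.
#' @return Memristance in ohms (vectorized over raw state values).
#' @export
memristance <- function(model, state) {
  stopifnot(inherits(model, "memristor_model"))
  value <- if (inherits(state, "memristor_state")) state$value else state
  if (!all(is.finite(value))) {
    abort("Memristor state must be finite.", class = "memlif_invalid_state")
  }
  memristance_at(model, value)
}

#' Advance the memristor state by one time step
#'
#' The active state variable integrates the drive: charge accumulates current,
#' flux accumulates voltage. The device `orientation` multiplies the drive
#' before integration. Memristance is recomputed from the new state.
#'
#' @param model a [memristor_model()].
#' @param state a [memristor_state()].
#' @param drive current (charge-controlled) or voltage (flux-controlled).
#' @param dt time step, in the same time unit as the drive's state units.
#' @return The updated `memristor_state`.
#' @export
advance_state <- function(model, state, drive, dt) {
  stopifnot(inherits(model, "memristor_model"), inherits(state, "memristor_state"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a positive finite scalar.", class = "memlif_invalid_grid")
  }
  if (!is.finite(drive)) {
    abort("Drive must be finite.", class = "memlif_invalid_state")
  }
  memristor_state(model, state$value + model$orientation * drive * dt)
}

#' Current-voltage sweep of a memristor
#'
#' Drives the device with `n_cycles` whole cycles of a sinusoidal voltage and
#' records the sample-wise current `i = v / M`, advancing the state each step
#' (flux-controlled devices integrate the voltage; charge-controlled devices
#' integrate the resulting current). At low frequency the loop is a pinched
#' hysteresis curve through the origin; raising the frequency collapses it
#' toward a straight line because the per-cycle state excursion shrinks as
#' `1/f`.
#'
#' @param model a [memristor_model()].
#' @param amplitude peak voltage, volts.
#' @param frequency hertz.
#' @param n_cycles number of whole cycles (default 1).
#' @param dt time step in seconds; defaults to 1/1000 of a cycle.
#' @param state optional starting [memristor_state()]; defaults to the middle
#'   of the state range so the sweep exercises both branches.
#' @return A tibble of class `iv_sweep` with columns `time_s`, `voltage_V`,
#'   `current_A`, `M_ohm`.
#' @export
iv_sweep <- function(model, amplitude, frequency, n_cycles = 1,
                     dt = NULL, state = NULL) {
  stopifnot(inherits(model, "memristor_model"))
  if (!is.finite(amplitude) || amplitude <= 0) {
    abort("`amplitude` must be positive.", class = "memlif_invalid_parameter")
  }
  if (!is.finite(frequency) || frequency <= 0) {
    abort("`frequency` must be positive.", class = "memlif_invalid_parameter")
  }
  period <- 1 / frequency
  if (is.null(dt)) dt <- period / 1000
  n <- round(n_cycles * period / dt)
  t <- (seq_len(n) - 1) * dt
  v <- amplitude * sin(2 * pi * frequency * t)
  if (is.null(state)) {
    state <- memristor_state(model, (model$s_lo + model$s_hi) / 2)
  }
  M <- numeric(n)
  i <- numeric(n)
  for (k in seq_len(n)) {
    M[k] <- state$M
    i[k] <- v[k] / M[k]
    drive <- if (model$kind == "flux_controlled") v[k] else i[k]
    state <- advance_state(model, state, drive, dt)
  }
  structure(
    tibble(time_s = t, voltage_V = v, current_A = i, M_ohm = M),
    class = c("iv_sweep", class(tibble())))
}

#' Enclosed loop area of an I-V sweep
#'
#' Shoelace area of the closed (voltage, current) path; used to quantify the
#' collapse of the pinched hysteresis loop with rising frequency.
#'
#' @param sweep result of [iv_sweep()].
#' @return Non-negative area in volt-amperes.
#' @export
loop_area <- function(sweep) {
  v <- sweep$voltage_V
  i <- sweep$current_A
  n <- length(v)
  j <- c(seq(2, n), 1L)
  abs(sum(v * i[j] - v[j] * i)) / 2
}

#' Membrane time constant of a memristive RC circuit
#'
#' The LIF time constant `tau = R * C` generalizes to `tau_M = M * C` where
#' `M` is the instantaneous memristance, so the time constant follows the
#' device state through time.
#'
#' @param state a [memristor_state()] or a memristance in ohms.
#' @param C capacitance in farads.
#' @return Time constant in seconds.
#' @examples
#' m <- memristor_model()
#' time_constant(memristor_state(m, -1), 2e-9) # 4e-5 s
#' @export
time_constant <- function(state, C) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    abort("`C` must be a positive capacitance.", class = "memlif_invalid_parameter")
  }
  M <- if (inherits(state, "memristor_state")) state$M else state
  M * C
}

#' @method autoplot iv_sweep
#' @export
autoplot.iv_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$voltage_V, .data$current_A)) +
    ggplot2::geom_path(colour = "#2166ac") +
    ggplot2::labs(x = "Voltage (V)", y = "Current (A)",
                  title = "Memristor pinched hysteresis") +
    ggplot2::theme_minimal()
}

#' Serialize / restore a memristor model configuration
#'
#' @param x a [memristor_model()] (for `memristor_config`) or a named list as
#'   read from a YAML/JSON config (for `as_memristor_model`).
#' @return A plain named list, or a `memristor_model`.
#' @export
memristor_config <- function(x) {
  stopifnot(inherits(x, "memristor_model"))
  x[c("kind", "M_min", "M_max", "s_lo", "s_hi", "orientation")]
}

#' @rdname memristor_config
#' @export
as_memristor_model <- function(x) {
  if (inherits(x, "memristor_model")) return(x)
  do.call(memristor_model, x[intersect(
    names(x), c("kind", "M_min", "M_max", "s_lo", "s_hi", "orientation"))])
}
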