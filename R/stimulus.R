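#' Simulation time grid
#'
#' @param dt time step in milliseconds.
#' @param T_total total simulated time in milliseconds.
#' @return A `time_grid` object with `dt`, `T`, and `n_steps = T / dt`.
#' @export
time_grid <- function(dt, T_total) {
  if (!is.finite(dt) || dt <= 0) {
    abort("`dt` must be positive.", class = "memlif_invalid_grid")
  }
  if (!is.finite(T_total) || T_total < dt) {
    abort("`T_total` must be at least one step.", class = "memlif_invalid_grid")
  }
  structure(list(dt = dt, T = T_total, n_steps = round(T_total / dt)),
            class = "time_grid")
}

grid_times <- function(grid) (seq_len(grid$n_steps) - 1) * grid$dt

#' Stimulus specification
#'
#' Declarative description of an injected current waveform. Supported kinds:
#' * `zero` — no input.
#' * `step` — constant `amplitude` from `onset` onwards.
#' * `single_pulse` — one rectangular pulse (`amplitude`, `width`, `onset`).
#' * `pulse_train` — rectangular pulses of `width` every `period` from `onset`.
#' * `ramp` — current rising at `ramp_slope` from `onset`.
#' * `noise` — Gaussian white noise (`noise_mean`, `noise_sd`), reproducible
#'   from `seed` (required).
#' * `biphasic_train` — the pulse train, forward in the first half of the
#'   horizon and sign-reversed in the second half.
#'
#' Amplitudes are nanoamperes, times milliseconds, the ramp slope nA/ms.
#'
#' @param kind stimulus kind, see above.
#' @param amplitude pulse/step amplitude in nA.
#' @param width pulse width in ms.
#' @param period pulse-train period in ms.
#' @param onset start time in ms.
#' @param ramp_slope nA per ms.
#' @param noise_mean,noise_sd Gaussian noise parameters in nA.
#' @param seed integer seed, required for `noise`.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(kind = c("zero", "pulse_train", "step", "single_pulse",
                                   "ramp", "noise", "biphasic_train"),
                          amplitude = 1.5, width = 40, period = 100, onset = 0,
                          ramp_slope = 0.05, noise_mean = 1.5, noise_sd = 0.5,
                          seed = NULL) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) abort(
                     sprintf("Unsupported stimulus kind '%s'.", kind[1]),
                     class = "memlif_unsupported_stimulus"))
  if (any(c(width, period) <= 0)) {
    abort("Widths and periods must be positive.", class = "memlif_invalid_parameter")
  }
  if (kind == "noise" && is.null(seed)) {
    abort("Noise stimuli require a `seed`.", class = "memlif_invalid_parameter")
  }
  structure(list(kind = kind, amplitude = amplitude, width = width,
                 period = period, onset = onset, ramp_slope = ramp_slope,
                 noise_mean = noise_mean, noise_sd = noise_sd, seed = seed),
            class = "stimulus_spec")
}

#' Realize a stimulus on a time grid
#'
#' @param spec a [stimulus_spec()].
#' @param grid a [time_grid()].
#' @return A tibble of class `stimulus` with columns `time_ms`, `I_nA`
#'   (`grid$n_steps` rows). Identical spec and seed give identical series.
#' @export
make_stimulus <- function(spec, grid) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(grid, "time_grid"))
  t <- grid_times(grid)
  on_train <- function(t) {
    tt <- t - spec$onset
    tt >= 0 & (tt %% spec$period) < spec$width
  }
  i <- switch(spec$kind,
    zero = rep(0, grid$n_steps),
    step = ifelse(t >= spec$onset, spec$amplitude, 0),
    single_pulse = ifelse(t >= spec$onset & t < spec$onset + spec$width,
                          spec$amplitude, 0),
    pulse_train = ifelse(on_train(t), spec$amplitude, 0),
    ramp = ifelse(t >= spec$onset, spec$ramp_slope * (t - spec$onset), 0),
    noise = with_seed(spec$seed, rnorm(grid$n_steps, spec$noise_mean, spec$noise_sd)),
    biphasic_train = ifelse(on_train(t), spec$amplitude, 0) *
      ifelse(t < grid$T / 2, 1, -1)
  )
  structure(tibble(time_ms = t, I_nA = i),
            class = c("stimulus", class(tibble())),
            spec = spec, grid = grid)
}

# run code with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# accept a stimulus tibble or bare numeric series
stimulus_series <- function(stimulus, grid) {
  i <- if (is.data.frame(stimulus)) stimulus$I_nA else as.numeric(stimulus)
  if (length(i) != grid$n_steps) {
    abort(sprintf("Stimulus length %d does not match grid (%d steps).",
                  length(i), grid$n_steps),
          class = "memlif_shape_error")
  }
  i
}
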