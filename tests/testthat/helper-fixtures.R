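# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

mlif_default <- function(...) neuron_params(memristor = memristor_model(), ...)

sim_point <- function(model, spec, T_total = 500, dt = 0.01, ...) {
  g <- time_grid(dt, T_total)
  stim <- make_stimulus(spec, g)
  if (model == "mlif") simulate_mlif(mlif_default(...), stim, g)
  else simulate_lif(neuron_params(...), stim, g)
}

# the step-response pair used by several suites
step_mlif <- function() fixture("step_mlif", sim_point("mlif", stimulus_spec("step", amplitude = 1.5)))
step_lif <- function() fixture("step_lif", sim_point("lif", stimulus_spec("step", amplitude = 1.5)))

# active cable run with the Fig 9 setup (Table 1 parameters, M0 = 10 kOhm)
cable_active <- function() fixture("cable_active", {
  g <- time_grid(0.01, 300)
  cp <- cable_params(n_compartments = 10, M0 = 10000)
  simulate_cable(cp, make_stimulus(stimulus_spec("pulse_train", amplitude = 300), g), g,
                 active = TRUE)
})
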