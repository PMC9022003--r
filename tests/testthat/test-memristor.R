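test_that("piecewise memristance law hits its printed endpoints and midpoint", {
  m <- memristor_model()
  expect_equal(memristance(m, -1), 20000)
  expect_equal(memristance(m, -0.75), 20000)
  expect_equal(memristance(m, 0.25), 100)
  expect_equal(memristance(m, 0.5), 100)
  # continuity-enforced line through the breakpoints: midpoint = mean of bounds
  expect_equal(memristance(m, -0.25), 10050)
  expect_equal(memristance(m, -0.25), (20000 + 100) / 2)

  q <- memristor_model("charge_controlled")
  expect_equal(memristance(q, -1e-4), 20000)
  expect_equal(memristance(q, 1e-4), 100)
  expect_equal(memristance(q, 0), 10050)
  # printed slope of the charge law is preserved by the construction
  expect_equal(q$slope, -1.99e8)

  # continuity at the breakpoints
  eps <- 1e-9
  expect_equal(memristance(m, m$s_lo + eps), 20000, tolerance = 1e-6)
  expect_equal(memristance(m, m$s_hi - eps), 100, tolerance = 1e-4)
})

test_that("invalid device states and parameters are rejected", {
  m <- memristor_model()
  expect_error(memristance(m, NaN), class = "memlif_invalid_state")
  expect_error(advance_state(m, memristor_state(m), 1, dt = 0),
               class = "memlif_invalid_grid")
  expect_error(advance_state(m, memristor_state(m), 1, dt = -0.1),
               class = "memlif_invalid_grid")
  expect_error(time_constant(memristor_state(m), C = -1),
               class = "memlif_invalid_parameter")
  expect_error(memristor_model(M_min = 100, M_max = 50),
               class = "memlif_invalid_parameter")
  expect_error(state_for_memristance(m, 5e5),
               class = "memlif_invalid_parameter")
})

test_that("state integration matches the analytic integral of the drive", {
  m <- memristor_model()
  st <- memristor_state(m)
  expect_equal(advance_state(m, st, 0, 0.1)$value, st$value)

  # n rectangular pulses of amplitude a, width w: phi = n * a * w
  set.seed(11)
  for (rep in 1:5) {
    a <- runif(1, 0.1, 2)
    dt <- 0.01
    w <- sample(50:300, 1) * dt   # grid-aligned width
    n_pulses <- sample(2:6, 1)
    st <- memristor_state(m, 0)
    for (p in seq_len(n_pulses)) {
      for (k in seq_len(round(w / dt))) st <- advance_state(m, st, a, dt)
      for (k in seq_len(50)) st <- advance_state(m, st, 0, dt)  # zero baseline
    }
    expect_equal(st$value, n_pulses * a * w, tolerance = 1e-10)
  }

  # constant positive drive: flux strictly increasing, M non-increasing
  st <- memristor_state(m)
  phis <- Ms <- numeric(50)
  for (k in 1:50) {
    st <- advance_state(m, st, 0.05, 1)
    phis[k] <- st$value
    Ms[k] <- st$M
  }
  expect_true(all(diff(phis) > 0))
  expect_true(all(diff(Ms) <= 0))
})

test_that("memristance is bounded for arbitrary drives and saturates one-sided", {
  set.seed(7)
  for (kind in c("flux_controlled", "charge_controlled")) {
    m <- memristor_model(kind)
    st <- memristor_state(m, (m$s_lo + m$s_hi) / 2)
    for (k in 1:500) {
      st <- advance_state(m, st, rnorm(1, sd = abs(m$s_hi - m$s_lo)), 0.1)
      expect_gte(st$M, m$M_min)
      expect_lte(st$M, m$M_max)
    }
  }
  # sustained one-signed drive saturates at M_min; reversed orientation at M_max
  m <- memristor_model()
  st <- memristor_state(m)
  for (k in 1:200) st <- advance_state(m, st, 0.1, 0.1)
  expect_equal(st$M, 100)
  mr <- memristor_model(orientation = -1)
  str <- memristor_state(mr, mr$s_hi)
  for (k in 1:200) str <- advance_state(mr, str, 0.1, 0.1)
  expect_equal(str$M, 20000)
})

test_that("I-V sweeps are passive, pinched at the origin, and collapse with frequency", {
  m <- memristor_model()
  sweeps <- lapply(c(1, 10, 100), function(f) iv_sweep(m, 1, f))
  for (sw in sweeps) {
    expect_true(all(sw$voltage_V * sw$current_A >= -1e-15))
    near_zero <- abs(sw$voltage_V) < 1e-3
    expect_lt(max(abs(sw$current_A[near_zero])), 1e-6)
  }
  areas <- vapply(sweeps, loop_area, numeric(1))
  expect_true(all(diff(areas) < 0))
  # whole cycles: same number of samples per cycle
  expect_equal(nrow(iv_sweep(m, 1, 1, n_cycles = 2)),
               2 * nrow(iv_sweep(m, 1, 1, n_cycles = 1)))
})

test_that("the memristive time constant generalizes tau = RC", {
  m <- memristor_model()
  expect_equal(time_constant(memristor_state(m, -1), 2e-9), 4e-5)
  expect_equal(time_constant(1e6, 2e-9), 2e-3)  # the LIF limit
  Ms <- c(100, 5000, 20000)
  expect_true(all(diff(time_constant(Ms, 2e-9)) > 0))
})

test_that("device config round-trips through a plain list", {
  m <- memristor_model("charge_controlled", orientation = -1)
  m2 <- as_memristor_model(memristor_config(m))
  expect_equal(m2, m)
})
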