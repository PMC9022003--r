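#!/usr/bin/env Rscript
# Calibration search for the Morse reference configuration.
#
# The pulse program fixes the amplitude (13 nA) and the dot/dash widths
# (0.05 / 0.1 ms); the simulation time step and the device's initial
# memristance are free. This script scans (dt, M0) and keeps combinations
# where a dot evokes exactly 2 spikes and a dash exactly 4 for every letter
# and every symbol position, and the full codec round-trips A-Z and
# "RO SE". The frozen winner lives in morse_reference() and
# inst/extdata/morse_reference.yaml.
#
# Usage: Rscript scripts/calibrate_morse.R

suppressMessages(library(memlif))

timing <- morse_timing()

check_combo <- function(dt, M0) {
  neuron <- morse_params(M0 = M0)
  # per-letter spike totals must match 2*dots + 4*dashes
  for (L in LETTERS) {
    spikes <- morse_spike_train(L, neuron, timing, dt)$spike_time_ms
    if (length(spikes) != letter_spike_total(L)) return(FALSE)
    decoded <- tryCatch(decode_spikes(spikes, timing), error = function(e) "")
    if (!identical(decoded, L)) return(FALSE)
  }
  identical(roundtrip("RO SE", neuron, timing, dt), "RO SE")
}

dts <- c(0.0125, 0.01, 0.005, 0.0025, 0.002, 0.001)
M0s <- seq(1000, 20000, by = 500)
hits <- list()
for (dt in dts) {
  ok <- vapply(M0s, function(m) check_combo(dt, m), logical(1))
  if (any(ok)) {
    cat(sprintf("dt = %g ms: M0 candidates %s\n", dt,
                paste(M0s[ok], collapse = ", ")))
    hits[[as.character(dt)]] <- M0s[ok]
  } else {
    cat(sprintf("dt = %g ms: no candidate\n", dt))
  }
}

if (length(hits)) {
  dt_best <- as.numeric(names(hits)[1])
  m_cand <- hits[[1]]
  # prefer the middle of the widest contiguous candidate run (most robust)
  runs <- split(m_cand, cumsum(c(1, diff(m_cand) != 500)))
  widest <- runs[[which.max(lengths(runs))]]
  M0_best <- widest[ceiling(length(widest) / 2)]
  cat(sprintf("\nselected calibration: dt = %g ms, M0 = %g ohm\n",
              dt_best, M0_best))
} else {
  cat("\nno calibration found in the scanned grid\n")
}
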