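#' International Morse table for A-Z
#'
#' @return A tibble with columns `letter` and `code` (dot/dash strings).
#' @export
morse_table <- function() {
  tibble(
    letter = LETTERS,
    code = c(".-", "-...", "-.-.", "-..", ".", "..-.", "--.", "....",
             "..", ".---", "-.-", ".-..", "--", "-.", "---", ".--.",
             "--.-", ".-.", "...", "-", "..-", "...-", ".--", "-..-",
             "-.--", "--.."))
}

morse_code_of <- function(letter) {
  tab <- morse_table()
  idx <- match(letter, tab$letter)
  if (anyNA(idx)) {
    abort(sprintf("Unsupported character(s): %s",
                  paste(letter[is.na(idx)], collapse = ", ")),
          class = "memlif_encoding_error")
  }
  tab$code[idx]
}

#' Morse pulse timing
#'
#' The reference pulse program: 13 nA pulses, 0.05 ms for a dot and 0.1 ms
#' for a dash, with gaps of 0.02 ms inside a letter (`t_ss`), 0.04 ms
#' between letters (`t_s`) and 0.1 ms between words (`t_l`). All times in
#' ms.
#'
#' @param amplitude pulse amplitude in nA.
#' @param narrow_width,wide_width dot and dash pulse widths.
#' @param t_ss,t_s,t_l intra-letter, inter-letter, inter-word gaps.
#' @return A `morse_timing` object.
#' @export
morse_timing <- function(amplitude = 13, narrow_width = 0.05, wide_width = 0.1,
                         t_ss = 0.02, t_s = 0.04, t_l = 0.1) {
  if (!(t_ss < t_s && t_s < t_l)) {
    abort("Require t_ss < t_s < t_l.", class = "memlif_invalid_parameter")
  }
  if (!(narrow_width < wide_width)) {
    abort("Require narrow_width < wide_width.", class = "memlif_invalid_parameter")
  }
  structure(list(amplitude = amplitude, narrow_width = narrow_width,
                 wide_width = wide_width, t_ss = t_ss, t_s = t_s, t_l = t_l),
            class = "morse_timing")
}

# Reference calibration for the Morse MLIF neuron: time step and initial
# memristance chosen (by the grid search in scripts/calibrate_morse.R) so a
# single 13 nA pulse evokes exactly 2 spikes at 0.05 ms width and exactly 4
# at 0.1 ms, stably across letter positions.
morse_reference <- function() {
  list(dt = 0.0125, M0 = 10500)
}

#' Reference MLIF neuron for the Morse application
#'
#' Point MLIF neuron with rest -65 mV, threshold -50 mV, reset -80 mV and
#' spike peak 20 mV, with the device initialized at the calibrated
#' memristance so dot and dash pulses evoke their two- and four-spike
#' groups.
#'
#' @param M0 initial memristance override in ohms.
#' @return A [neuron_params()] object.
#' @export
morse_params <- function(M0 = morse_reference()$M0) {
  neuron_params(C = 2e-9, memristor = memristor_model(),
                V_rest = -65, V_th = -50, V_reset = -80, V_spike = 20,
                input_gain = 1, M0 = M0)
}

# per-letter pulse schedule: onset/width per symbol, relative to letter start
letter_schedule <- function(code, timing) {
  widths <- ifelse(strsplit(code, "")[[1]] == ".",
                   timing$narrow_width, timing$wide_width)
  onsets <- cumsum(c(0, head(widths, -1) + timing$t_ss))
  tibble(symbol = strsplit(code, "")[[1]], onset = onsets, width = widths)
}

# text -> tibble(letter, word, code, start_ms) on the global timeline
message_schedule <- function(text, timing) {
  if (!grepl("^[A-Z ]*$", text)) {
    abort("Only A-Z and spaces are supported.", class = "memlif_encoding_error")
  }
  words <- strsplit(trimws(text), " +")[[1]]
  out <- list()
  t0 <- 0
  for (w in seq_along(words)) {
    letters_w <- strsplit(words[w], "")[[1]]
    for (l in seq_along(letters_w)) {
      code <- morse_code_of(letters_w[l])
      sched <- letter_schedule(code, timing)
      dur <- max(sched$onset + sched$width)
      out[[length(out) + 1]] <- tibble(letter = letters_w[l], word = w,
                                       code = code, start_ms = t0,
                                       duration_ms = dur)
      t0 <- t0 + dur + if (l < length(letters_w)) timing$t_s else 0
    }
    if (w < length(words)) t0 <- t0 + timing$t_l
  }
  bind_rows(out)
}

#' Encode text as a Morse current-pulse program
#'
#' Dots become narrow pulses, dashes wide pulses, at the fixed amplitude;
#' symbols inside a letter are separated by `t_ss`, letters by `t_s`, words
#' by `t_l`.
#'
#' @param text a string of A-Z and spaces.
#' @param timing a [morse_timing()].
#' @param grid optional [time_grid()]; defaults to the reference `dt` and a
#'   horizon covering the whole message.
#' @return A `stimulus` tibble (`time_ms`, `I_nA`) with the message schedule
#'   attached as attribute `"schedule"`.
#' @export
encode_text <- function(text, timing = morse_timing(), grid = NULL) {
  sched <- message_schedule(text, timing)
  if (is.null(grid)) {
    dt <- morse_reference()$dt
    T_total <- if (nrow(sched)) {
      max(sched$start_ms + sched$duration_ms) + timing$t_s
    } else dt
    grid <- time_grid(dt, max(T_total, 2 * dt))
  }
  t <- grid_times(grid)
  i <- rep(0, grid$n_steps)
  for (r in seq_len(nrow(sched))) {
    pulses <- letter_schedule(sched$code[r], timing)
    for (p in seq_len(nrow(pulses))) {
      on <- sched$start_ms[r] + pulses$onset[p]
      i[t >= on & t < on + pulses$width[p]] <- timing$amplitude
    }
  }
  structure(tibble(time_ms = t, I_nA = i),
            class = c("stimulus", class(tibble())),
            grid = grid, schedule = sched)
}

#' Simulate the MLIF response to a Morse message
#'
#' Each letter is simulated with a freshly initialized memristor state (the
#' per-letter spike totals are position-independent) and the evoked spike
#' times are assembled on the message timeline.
#'
#' @param text a string of A-Z and spaces.
#' @param neuron a [neuron_params()]; default [morse_params()].
#' @param timing a [morse_timing()].
#' @param dt time step in ms; default the reference calibration.
#' @return A tibble of spike times (`spike_time_ms`) with the message
#'   schedule attached as attribute `"schedule"`.
#' @export
morse_spike_train <- function(text, neuron = morse_params(),
                              timing = morse_timing(),
                              dt = morse_reference()$dt) {
  sched <- message_schedule(text, timing)
  spikes <- numeric(0)
  for (r in seq_len(nrow(sched))) {
    grid <- time_grid(dt, sched$duration_ms[r] + timing$t_ss)
    stim <- encode_text(sched$letter[r], timing, grid)
    trace <- simulate_mlif(neuron, stim, grid)
    spikes <- c(spikes, sched$start_ms[r] + detect_spikes(trace)$spike_time_ms)
  }
  structure(tibble(spike_time_ms = spikes), schedule = sched,
            class = class(tibble()))
}

#' Decode an MLIF spike train back to text
#'
#' Spikes are grouped by the gap hierarchy scaled from the timing: gaps
#' larger than `1.5 t_ss` separate symbol groups, larger than
#' `t_s + 0.6 t_ss` separate letters, larger than `(t_s + t_l) / 2 + t_ss`
#' separate words. Groups of 1-2 spikes read as dots and 3-5 as dashes
#' (nearest count); the symbol strings invert through the Morse table.
#'
#' @param spikes spike train tibble or numeric spike times in ms.
#' @param timing a [morse_timing()].
#' @return The decoded string.
#' @export
decode_spikes <- function(spikes, timing = morse_timing()) {
  times <- spike_times_of(spikes)
  if (length(times) == 0) return("")
  times <- sort(times)
  group_thr <- 1.5 * timing$t_ss
  letter_thr <- timing$t_s + 0.6 * timing$t_ss
  word_thr <- (timing$t_s + timing$t_l) / 2 + timing$t_ss
  gaps <- diff(times)
  level <- ifelse(gaps > word_thr, 3L, ifelse(gaps > letter_thr, 2L,
                                              ifelse(gaps > group_thr, 1L, 0L)))
  group_id <- cumsum(c(0L, as.integer(level > 0)))
  sizes <- as.integer(table(group_id))
  boundary_level <- level[level > 0] # separator before each group after the first
  symbols <- vapply(sizes, function(n) {
    if (n <= 2) "." else if (n <= 5) "-" else NA_character_
  }, character(1))
  if (anyNA(symbols)) {
    bad <- which(is.na(symbols))[1]
    abort(sprintf("Cannot map spike group %d (%d spikes) to a Morse symbol.",
                  bad, sizes[bad]),
          class = "memlif_decode_error")
  }
  tab <- morse_table()
  words <- character(0)
  current_word <- character(0)
  current_code <- symbols[1]
  flush_letter <- function(code) {
    letter <- tab$letter[match(code, tab$code)]
    if (is.na(letter)) {
      abort(sprintf("Unmappable Morse symbol string '%s'.", code),
            class = "memlif_decode_error")
    }
    letter
  }
  for (g in seq_along(boundary_level)) {
    lv <- boundary_level[g]
    if (lv == 1L) {
      current_code <- paste0(current_code, symbols[g + 1])
    } else {
      current_word <- c(current_word, flush_letter(current_code))
      if (lv == 3L) {
        words <- c(words, paste(current_word, collapse = ""))
        current_word <- character(0)
      }
      current_code <- symbols[g + 1]
    }
  }
  current_word <- c(current_word, flush_letter(current_code))
  words <- c(words, paste(current_word, collapse = ""))
  paste(words, collapse = " ")
}

#' Total evoked spikes of a letter
#'
#' Each dot evokes a two-spike group and each dash a four-spike group, so a
#' letter's total is `2 * dots + 4 * dashes` of its Morse code.
#'
#' @param letter one or more letters in A-Z.
#' @return Integer spike totals.
#' @examples
#' letter_spike_total(c("T", "S", "E")) # 4 6 2
#' @export
letter_spike_total <- function(letter) {
  code <- morse_code_of(toupper(letter))
  vapply(strsplit(code, ""), function(sym) {
    sum(ifelse(sym == ".", 2L, 4L))
  }, integer(1))
}

#' Morse round trip through the MLIF neuron
#'
#' Encodes `text` as current pulses, simulates the MLIF response letter by
#' letter under the reference calibration, detects the evoked spikes and
#' decodes them back to text. Under the shipped calibration this is the
#' identity on every supported message.
#'
#' @inheritParams morse_spike_train
#' @return The decoded string.
#' @examples
#' roundtrip("SOS")
#' @export
roundtrip <- function(text, neuron = morse_params(), timing = morse_timing(),
                      dt = morse_reference()$dt) {
  if (trimws(text) == "") return("")
  decode_spikes(morse_spike_train(text, neuron, timing, dt), timing)
}
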