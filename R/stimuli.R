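#' Stimulus specification
#'
#' Describes the current injected into the thalamocortical relay (TCR)
#' cells: a delayed sinusoid, a short rectangular pulse, a replayed
#' input-spike drive, or nothing.
#'
#' @param kind one of `"oscillation"`, `"pulse"`, `"replay"`, `"none"`.
#' @param I_inj oscillation amplitude, nA.
#' @param f oscillation frequency, Hz (required for `"oscillation"`).
#' @param t0 stimulus onset delay, ms.
#' @param duration stimulus duration, ms.
#' @param pulse_amplitude pulse height, nA.
#' @param pulse_width pulse width, ms.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("oscillation", "pulse", "replay", "none"),
                          I_inj = 2, f = NULL, t0 = 0, duration = Inf,
                          pulse_amplitude = 3, pulse_width = 2) {
  kind <- match.arg(kind)
  if (kind == "oscillation" && (is.null(f) || f <= 0))
    stop("oscillation stimulus requires a frequency f > 0")
  if (kind == "pulse" && pulse_width <= 0)
    stop("pulse stimulus requires pulse_width > 0")
  structure(list(kind = kind, I_inj = I_inj, f = f, t0 = t0,
                 duration = duration, pulse_amplitude = pulse_amplitude,
                 pulse_width = pulse_width),
            class = "stimulus_spec")
}

#' Delayed sinusoidal injection current
#'
#' I(t) = I_inj * sin(2 pi f (t - t0)) * Theta(t - t0), with f in Hz and
#' t in ms (the argument is `2*pi*f*(t - t0)/1000`).
#'
#' @param I_inj amplitude, nA.
#' @param f frequency, Hz.
#' @param t0 onset, ms.
#' @param t time(s), ms; vectorized.
#' @return current, nA.
#' @examples
#' oscillation_current(2, 12.5, 100, 120)  # quarter period: 2 nA
#' @export
oscillation_current <- function(I_inj, f, t0, t) {
  stopifnot(f > 0)
  ifelse(t < t0, 0, I_inj * sin(2 * pi * f * (t - t0) / 1000))
}

#' Rectangular pulse injection current
#'
#' Amplitude on the half-open interval `[t0, t0 + width)`, zero
#' elsewhere; at a 0.1 ms sampling step the pulse therefore occupies
#' exactly `width / 0.1` samples.
#'
#' @param amplitude pulse height, nA.
#' @param t0 onset, ms.
#' @param width width, ms.
#' @param t time(s), ms; vectorized.
#' @return current, nA.
#' @export
pulse_current <- function(amplitude, t0, width, t) {
  stopifnot(width > 0)
  ifelse(t >= t0 & t < t0 + width, amplitude, 0)
}

#' Evaluate a stimulus waveform on a time vector
#'
#' @param spec a [stimulus_spec()].
#' @param t times, ms.
#' @return current, nA (zero for `"replay"` and `"none"` kinds; replay
#'   drive is delivered as input-spike events, not as a waveform).
#' @export
stimulus_waveform <- function(spec, t) {
  stopifnot(inherits(spec, "stimulus_spec"))
  switch(spec$kind,
    oscillation = {
      w <- oscillation_current(spec$I_inj, spec$f, spec$t0, t)
      w[t >= spec$t0 + spec$duration] <- 0
      w
    },
    pulse = pulse_current(spec$pulse_amplitude, spec$t0, spec$pulse_width, t),
    replay = rep(0, length(t)),
    none = rep(0, length(t)))
}

# Table of the 28 published dataset configurations.
.preset_table <- function() {
  freqs <- c(200, 100, 50, 25, 12.5, 8, 4, 2)
  lab_osc <- sprintf("Oscillations %gHz", freqs)
  data.frame(
    id = 1:28,
    label = c(lab_osc, paste(lab_osc, "no depol"),
              "Oscillations 12.5Hz input pop23",
              "Oscillations 12.5Hz input pop4",
              "Oscillations 12.5Hz input pop5",
              "Oscillations 12.5Hz input pop6",
              "Oscillations 12.5Hz no input",
              "Oscillations 12.5Hz input 20% of TCR",
              "Pulse stimulus",
              "Pulse stimulus 10% model",
              "Pulse stimulus passive current",
              "Pulse stimulus passive soma & axon",
              "Pulse stimulus passive axon",
              "Pulse stimulus blocked Na current"),
    size_fraction = c(rep(1, 23), rep(0.1, 5)),
    stop = c(700, 700, 700, 700, 690, 700, 700, 700,
             rep(700, 8), rep(700, 6), 210, rep(600, 5)),
    stim_delay = c(rep(100, 22), 70, rep(300, 5)),
    stim_duration = c(rep(600, 22), 2, rep(2, 5)),
    depol_pop5 = c(rep(1, 8), rep(0, 8), rep(1, 6), 1, rep(0.5, 5)),
    depol_pop6 = c(rep(0.75, 8), rep(0, 8), rep(0.75, 6), 0.75,
                   rep(0.375, 5)),
    frequency = c(freqs, freqs, rep(12.5, 6), rep(NA, 6)),
    input_source = c(rep(NA, 16), "pop23", "pop4", "pop5", "pop6",
                     "none", "TCR20", rep(NA, 6)),
    records_channel_components = c(rep(FALSE, 23), rep(TRUE, 5)),
    stringsAsFactors = FALSE
  )
}

.make_preset <- function(row) {
  stim <- if (!is.na(row$frequency)) {
    stimulus_spec("oscillation", I_inj = 2, f = row$frequency,
                  t0 = row$stim_delay, duration = row$stim_duration)
  } else {
    stimulus_spec("pulse", t0 = row$stim_delay,
                  pulse_amplitude = 3, pulse_width = row$stim_duration)
  }
  structure(list(id = row$id, label = row$label,
                 size_fraction = row$size_fraction, stop = row$stop,
                 stim_delay = row$stim_delay,
                 stim_duration = row$stim_duration,
                 depol_pop5 = row$depol_pop5, depol_pop6 = row$depol_pop6,
                 stimulus = stim,
                 input_source = if (is.na(row$input_source)) NULL
                                else row$input_source,
                 records_channel_components = row$records_channel_components),
            class = "dataset_preset")
}

#' The 28 published dataset configurations
#'
#' Returns the registry of dataset presets: 22 oscillatory protocols
#' (sinusoidal TCR drive at 200/100/50/25/12.5/8/4/2 Hz, with and
#' without infragranular depolarization, plus the population-replay and
#' 20%-TCR variants) and 6 pulse protocols (3 nA / 2 ms TCR pulse).
#' Presets 24-28 use the 10% model and record per-channel current
#' components.
#'
#' @return list of 28 `dataset_preset` objects.
#' @export
preset_registry <- function() {
  tab <- .preset_table()
  lapply(seq_len(nrow(tab)), function(i) .make_preset(tab[i, ]))
}

#' Fetch one dataset preset by id
#'
#' @param id integer in 1..28.
#' @return a `dataset_preset`.
#' @export
get_preset <- function(id) {
  if (!is.numeric(id) || length(id) != 1 || is.na(id) ||
      id != as.integer(id) || id < 1 || id > 28)
    stop("invalid preset id; valid ids are 1..28")
  .make_preset(.preset_table()[as.integer(id), ])
}

#' @export
print.dataset_preset <- function(x, ...) {
  cat(sprintf("<dataset_preset %d> %s | size %g%% | stop %g ms | %s\n",
              x$id, x$label, 100 * x$size_fraction, x$stop,
              x$stimulus$kind))
  invisible(x)
}

#' Export the preset registry as JSON
#'
#' Flat JSON mirroring the published table columns (id, label, size,
#' stop, stimulus delay/duration, layer-5/6 depolarization currents).
#'
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_presets_json <- function(path) {
  jsonlite::write_json(.preset_table(), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Channel-type label vocabulary for current decomposition
#'
#' The ordered labels under which transmembrane current is decomposed:
#' synaptic (NMDA, AMPA, GABA A), capacitive, passive, the active
#' channel families (potassium, sodium, calcium, low-threshold T-type
#' calcium, anomalous rectifier) and `other` (steady bias plus ectopic
#' drive).
#'
#' @param check optional character vector of labels to validate; unknown
#'   labels raise an error naming them.
#' @return character vector of the 11 labels.
#' @export
channel_labels <- function(check = NULL) {
  labs <- c("nmda", "ampa", "gaba_a", "capacitive", "passive",
            "potassium", "sodium", "calcium", "ca_T_low_threshold",
            "anomalous_rectifier", "other")
  if (!is.null(check)) {
    bad <- setdiff(check, labs)
    if (length(bad))
      stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  }
  labs
}
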