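# Synthetic compartmental activity.
#
# This generator is NOT a biophysical simulator. It is a
# contract-satisfying stand-in for the conductance-based network
# simulation that produced the published datasets: it reproduces the
# structural contracts of those data (per-cell Kirchhoff closure of the
# transmembrane currents, exact per-channel decomposition, spike trains
# locked to the stimulus, the 0.1 ms uniform time base) without any
# claim about the dynamics. Every cell's currents are built from
# balanced event kernels and then re-centred per time sample, so the sum
# over a cell's segments is zero to accumulated float error.

# alpha kernel (peak 1 at tau), sampled at dt, truncated at 8 tau
.alpha_kernel <- function(tau, dt, amp) {
  t <- seq(0, 8 * tau, by = dt)
  amp * (t / tau) * exp(1 - t / tau)
}

# add kernel k to row `seg` of matrix M starting at column `b`
.add_kernel <- function(M, seg, b, k) {
  nT <- ncol(M)
  n <- min(length(k), nT - b + 1L)
  if (n > 0)
    M[seg, b:(b + n - 1L)] <- M[seg, b:(b + n - 1L)] + k[seq_len(n)]
  M
}

# subtract the per-sample mean across a cell's segments: exact Kirchhoff
.balance <- function(M) {
  if (nrow(M) < 2) return(M * 0)
  M - rep(colMeans(M), each = nrow(M))
}

# exponential moving average with time constant tau (ms)
.ema <- function(x, tau, dt) {
  a <- dt / (tau + dt)
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive"))
}

# normalized drive in [0, 1]: rectified stimulus for oscillations, a
# pulse convolved with a 5 ms decay for pulses
.stimulus_drive <- function(preset, t) {
  stim <- preset$stimulus
  if (stim$kind == "pulse") {
    d <- .ema(stimulus_waveform(stim, t) / stim$pulse_amplitude, 5,
              t[2] - t[1])
    if (max(d) > 0) d <- d / max(d)
    d
  } else if (stim$kind == "oscillation") {
    pmax(0, stimulus_waveform(stim, t)) / stim$I_inj
  } else if (stim$kind == "replay") {
    # replayed input spikes drive the same 12.5 Hz modulation machinery
    w <- oscillation_current(2, 12.5, preset$stim_delay, t)
    w[t >= preset$stim_delay + preset$stim_duration] <- 0
    pmax(0, w) / 2
  } else {
    rep(0, length(t))
  }
}

# per-population stimulus gain (Hz at full drive) and baseline factor
.pop_rate_params <- function(pop, cell_class, is_cortical) {
  if (pop == "TCR") return(c(gain = 80, base = 1.5))
  if (pop == "nRT") return(c(gain = 40, base = 1.2))
  if (cell_class == "inhibitory") return(c(gain = 35, base = 1.2))
  c(gain = 25, base = 1)
}

#' Synthesize Kirchhoff-consistent activity for one dataset preset
#'
#' Generates per-segment transmembrane currents, membrane voltages and
#' spike trains for every cell in `segments`, structured like the
#' published ground-truth recordings: per-cell spike trains follow an
#' inhomogeneous Poisson process whose rate is modulated by the preset's
#' stimulus waveform; each synaptic-like input event adds an
#' alpha-kernel current sink on one segment balanced by a distributed
#' source over the cell's remaining segments; each spike adds a brief
#' triphasic balanced soma current; slow channel-family currents are
#' added with segment-specific weights. The voltage trace is a smoothed,
#' scaled echo of each cell's summed synaptic input (bookkeeping, not
#' dynamics).
#'
#' Contracts guaranteed by construction: per cell and per sample the
#' segment currents sum to zero (to accumulated float error); if
#' `preset$records_channel_components`, the labelled component arrays
#' sum to the total current exactly (the total is computed as their
#' sum); identical `(preset, seed)` give bit-identical output.
#'
#' @param segments segment table from [build_morphologies()].
#' @param preset a `dataset_preset` (see [preset_registry()]); its
#'   `stop` bounds the time base at dt = 0.1 ms from 0 ms.
#' @param seed integer RNG seed.
#' @param baseline_rate baseline firing rate before the stimulus, Hz.
#' @param input_rate baseline synaptic input event rate per cell, Hz.
#' @param memory_budget_mb refuse runs whose dense arrays would exceed
#'   this budget (MiB).
#' @return list with `activity` (class `activity_traces`: `dt`,
#'   `time_start`, `n_samples`, matrices `i_total` and `v` of size
#'   segments x samples in nA / mV, optional `components` list, and the
#'   segment/cell bookkeeping columns) and `spikes` (class
#'   `spike_events`: named list of sorted spike times per cell, ms; for
#'   replay presets also an `input_spikes` attribute).
#' @export
synthesize_activity <- function(segments, preset, seed,
                                baseline_rate = 2, input_rate = 30,
                                memory_budget_mb = 1024) {
  stopifnot(inherits(preset, "dataset_preset"))
  dt <- 0.1
  nT <- as.integer(round(preset$stop / dt))
  t <- (seq_len(nT) - 1L) * dt
  nS <- nrow(segments)
  n_arrays <- 2L + if (preset$records_channel_components) 11L else 0L
  need_mb <- nS * as.numeric(nT) * 8 * n_arrays / 2^20
  if (need_mb > memory_budget_mb)
    stop(sprintf(paste0("run of %d segments x %d samples needs ~%.0f MiB, ",
                        "exceeding the memory budget of %g MiB"),
                 nS, nT, need_mb, memory_budget_mb))

  reg <- .population_table()
  rownames(reg) <- reg$abbreviation
  drive <- .stimulus_drive(preset, t)
  labs <- channel_labels()

  # kernels (nA); excitatory sinks are negative (inward current)
  k_ampa <- .alpha_kernel(2, dt, -0.04 * 0.7)
  k_nmda <- .alpha_kernel(10, dt, -0.04 * 0.3)
  k_gaba <- .alpha_kernel(6, dt, 0.035)
  tk <- seq(0, 1, by = dt)
  k_na <- -0.8 * sin(pi * tk)                      # 1 ms inward
  tk2 <- seq(0, 1.4, by = dt)
  k_k <- 0.55 * sin(pi * tk2 / 1.4)                # lagged outward
  k_ca <- .alpha_kernel(15, dt, -0.008)
  k_caT <- .alpha_kernel(25, dt, -0.006)
  k_ar <- .alpha_kernel(20, dt, 0.005)

  cells <- unique(segments$cell_id)
  comp_out <- if (preset$records_channel_components)
    lapply(stats::setNames(labs, labs), function(l)
      matrix(0, nS, nT)) else NULL
  i_total <- matrix(0, nS, nT)
  v <- matrix(0, nS, nT)
  spikes <- stats::setNames(vector("list", length(cells)), cells)

  with_seed(seed, {
    for (ci in seq_along(cells)) {
      cell <- cells[ci]
      rows <- which(segments$cell_id == cell)
      S <- length(rows)
      pop <- segments$population[rows[1]]
      pr <- .pop_rate_params(pop, reg[pop, "cell_class"],
                             reg[pop, "is_cortical"])
      depol <- 0
      if (pop %in% c("tuftIB5", "tuftRS5")) depol <- preset$depol_pop5
      if (pop == "nontuftRS6") depol <- preset$depol_pop6

      rate <- baseline_rate * pr[["base"]] + pr[["gain"]] * drive +
        8 * depol
      sp_bins <- which(runif(nT) < rate * dt / 1000)
      spikes[[cell]] <- t[sp_bins]

      in_rate <- input_rate * (0.5 + drive)
      exc_bins <- which(runif(nT) < in_rate * dt / 1000)
      inh_bins <- which(runif(nT) < 0.6 * in_rate * dt / 1000)
      dend <- if (S > 1) rows[-1] else rows
      exc_seg <- sample(seq_along(dend), length(exc_bins), replace = TRUE)
      inh_seg <- sample(seq_along(dend), length(inh_bins), replace = TRUE)

      cm <- lapply(stats::setNames(labs, labs), function(l)
        matrix(0, S, nT))
      loc <- match(dend, rows)
      for (j in seq_along(exc_bins)) {
        cm$ampa <- .add_kernel(cm$ampa, loc[exc_seg[j]], exc_bins[j], k_ampa)
        cm$nmda <- .add_kernel(cm$nmda, loc[exc_seg[j]], exc_bins[j], k_nmda)
      }
      for (j in seq_along(inh_bins))
        cm$gaba_a <- .add_kernel(cm$gaba_a, loc[inh_seg[j]], inh_bins[j],
                                 k_gaba)
      for (b in sp_bins) {
        cm$sodium <- .add_kernel(cm$sodium, 1L, b, k_na)
        cm$potassium <- .add_kernel(cm$potassium, 1L, b, k_k)
      }

      # membrane potential: smoothed echo of the cell's summed |input|
      syn_in <- colSums(abs(cm$ampa + cm$nmda + cm$gaba_a))
      vc <- -65 + 10 * .ema(syn_in / max(0.05, S * 0.002), 5, dt)
      v[rows, ] <- rep(vc, each = S)
      dv <- c(0, diff(vc))

      # slow channel families: segment-weighted echoes of activity
      w_cap <- runif(S); w_pas <- runif(S)
      w_ca <- runif(S); w_caT <- runif(S); w_ar <- runif(S)
      cm$capacitive <- outer(w_cap, 0.15 * dv)
      cm$passive <- outer(w_pas, -0.01 * (vc + 65))
      slow <- .ema(drive, 20, dt)
      for (b in sp_bins) {
        cm$calcium <- .add_kernel(cm$calcium, 1L, b, k_ca)
        cm$ca_T_low_threshold <- .add_kernel(cm$ca_T_low_threshold, 1L,
                                             b, k_caT)
        cm$anomalous_rectifier <- .add_kernel(cm$anomalous_rectifier, 1L,
                                              b, k_ar)
      }
      cm$calcium <- cm$calcium + outer(w_ca, 0.004 * slow)
      cm$ca_T_low_threshold <- cm$ca_T_low_threshold +
        outer(w_caT, 0.003 * slow)
      cm$anomalous_rectifier <- cm$anomalous_rectifier +
        outer(w_ar, -0.002 * slow)
      if (depol > 0)
        cm$other[1L, ] <- cm$other[1L, ] + depol

      ct <- matrix(0, S, nT)
      for (l in labs) {
        cm[[l]] <- .balance(cm[[l]])
        ct <- ct + cm[[l]]
        if (!is.null(comp_out)) comp_out[[l]][rows, ] <- cm[[l]]
      }
      i_total[rows, ] <- ct
    }
  })

  act <- structure(list(time_start = 0, dt = dt, n_samples = nT,
                        i_total = i_total, v = v, components = comp_out,
                        segment_id = segments$segment_id,
                        cell_id = segments$cell_id,
                        population = segments$population),
                   class = "activity_traces")
  sp <- structure(spikes, stop = preset$stop, class = "spike_events")
  if (!is.null(preset$input_source) && preset$input_source != "none")
    attr(sp, "input_spikes") <- .replay_input_spikes(preset, t)
  list(activity = act, spikes = sp)
}

# input-spike event lists for the replay protocols: Poisson trains from
# the drive for a small nominal source ensemble (config-level only)
.replay_input_spikes <- function(preset, t) {
  drive <- .stimulus_drive(preset, t)
  dt <- t[2] - t[1]
  n_src <- 10L
  src <- sprintf("%s_input_%03d", preset$input_source, seq_len(n_src))
  stats::setNames(lapply(seq_len(n_src), function(i)
    t[runif(length(t)) < (5 + 40 * drive) * dt / 1000]), src)
}

#' Kirchhoff residual of an activity object
#'
#' Maximum over cells and samples of the absolute sum of segment
#' currents, relative to the cell's own current scale.
#'
#' @param activity an `activity_traces`.
#' @return largest relative residual (dimensionless).
#' @export
kirchhoff_residual <- function(activity) {
  worst <- 0
  for (cell in unique(activity$cell_id)) {
    rows <- which(activity$cell_id == cell)
    s <- abs(colSums(activity$i_total[rows, , drop = FALSE]))
    scale <- max(abs(activity$i_total[rows, ]), 1e-12)
    worst <- max(worst, max(s) / scale)
  }
  worst
}

#' @export
print.activity_traces <- function(x, ...) {
  cat(sprintf("<activity_traces> %d segments x %d samples @ %g ms%s\n",
              nrow(x$i_total), x$n_samples, x$dt,
              if (!is.null(x$components))
                sprintf(", %d components", length(x$components)) else ""))
  invisible(x)
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d cells, %d spikes in [0, %g] ms\n",
              length(x), sum(lengths(x)), attr(x, "stop")))
  invisible(x)
}
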