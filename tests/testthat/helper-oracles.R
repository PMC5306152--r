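# Independent oracles, deliberately naive.

# point-source sum as an explicit electrode x segment x sample triple
# loop, independent of the matrix-product implementation
naive_potential <- function(i_total, midpoints, electrode_positions,
                            sigma = 0.3, clamp = 0) {
  nE <- nrow(electrode_positions)
  nS <- nrow(midpoints)
  nT <- ncol(i_total)
  phi <- matrix(0, nE, nT)
  for (e in seq_len(nE)) {
    for (s in seq_len(nS)) {
      r <- sqrt(sum((electrode_positions[e, ] - midpoints[s, ])^2))
      r <- max(r, clamp)
      for (k in seq_len(nT))
        phi[e, k] <- phi[e, k] + i_total[s, k] / (4 * pi * sigma * r)
    }
  }
  phi
}

# analytic 2nd-order Butterworth low-pass magnitude at frequency f
butter2_gain <- function(f, cutoff) 1 / sqrt(1 + (f / cutoff)^4)
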