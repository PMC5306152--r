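# LFP filtering, plane interpolation, raster preparation.

test_that("the low-pass has unit DC gain", {
  rec <- make_recording(matrix(3.7, 2, 500))
  for (mode in c("zero_phase_two_pass", "causal_single_pass")) {
    out <- lowpass_lfp(rec, filter_spec(application = mode))
    expect_equal(max(abs(out$phi - 3.7)), 0, tolerance = 1e-6)
  }
})

test_that("a 250 Hz tone is attenuated per the Butterworth magnitude", {
  # fs = 10 kHz; cutoff 100 Hz; analytic |H| = 1/sqrt(1 + (f/fc)^4)
  t <- (0:4999) * 0.1e-3
  x <- sin(2 * pi * 250 * t)
  rec <- make_recording(matrix(x, 1, byrow = TRUE))
  g1 <- butter2_gain(250, 100)                       # ~0.158
  mid <- 2000:3000
  one <- lowpass_lfp(rec, filter_spec(application = "causal_single_pass"))
  expect_equal(max(abs(one$phi[1, mid])), g1, tolerance = 0.02)
  two <- lowpass_lfp(rec, filter_spec(application = "zero_phase_two_pass"))
  expect_equal(max(abs(two$phi[1, mid])), g1^2, tolerance = 0.02)
  # two-pass output has zero phase lag: peaks align with the input
  w <- 2400:2440  # one full 250 Hz period
  expect_lte(abs(which.max(two$phi[1, w]) - which.max(x[w])), 1)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- make_recording(matrix(0, 1, 100))
  expect_error(lowpass_lfp(rec, filter_spec(cutoff = 5000)), "Nyquist")
  expect_silent(lowpass_lfp(rec, filter_spec(cutoff = 4999)))
})

test_that("filtering is linear and commutes with electrode selection", {
  set.seed(7)
  phi <- matrix(rnorm(3 * 400), 3, 400)
  el <- electrode_array(cbind(1:3, 0, 0))
  rec <- make_recording(phi, el)
  spec <- filter_spec()
  all_f <- lowpass_lfp(rec, spec)
  sub <- make_recording(phi[2:3, , drop = FALSE],
                        electrode_array(cbind(2:3, 0, 0)))
  sub_f <- lowpass_lfp(sub, spec)
  expect_equal(unname(all_f$phi[2:3, ]), unname(sub_f$phi),
               tolerance = 1e-12)
  # linearity
  a <- make_recording(matrix(rnorm(400), 1))
  b <- make_recording(matrix(rnorm(400), 1))
  ab <- make_recording(2 * a$phi - 3 * b$phi)
  expect_equal(lowpass_lfp(ab, spec)$phi,
               2 * lowpass_lfp(a, spec)$phi -
                 3 * lowpass_lfp(b, spec)$phi,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("filtering is time invariant away from the edges", {
  set.seed(8)
  x <- c(rnorm(200), rep(0, 300))
  lag <- 50
  xs <- c(rep(0, lag), x[1:(500 - lag)])
  spec <- filter_spec(application = "causal_single_pass")
  y <- lowpass_lfp(make_recording(matrix(x, 1)), spec)$phi[1, ]
  ys <- lowpass_lfp(make_recording(matrix(xs, 1)), spec)$phi[1, ]
  interior <- 300:450  # past the start-up transient of both runs
  expect_equal(ys[interior], y[interior - lag], tolerance = 1e-3)
})

test_that("bilinear interpolation reproduces electrode values exactly", {
  mea <- mea_grid(n_rows = 2, n_cols = 2, pitch = 100, plane_offset = 25,
                  center_depth = 500)
  vals <- c(1, 1, 1, 1)  # rows fastest within column
  rec <- make_recording(matrix(vals, 4, 3), mea)
  # at an electrode site
  at_el <- interpolate_plane(rec, 0, query = cbind(mea$positions[2, "y"],
                                                   mea$positions[2, "z"]))
  expect_equal(at_el, vals[2])
  # flat field: midpoint of four equal corners
  mid <- interpolate_plane(rec, 0, query = cbind(0, 500))
  expect_equal(mid, 1)
  # bilinear closed form: corners (0, 0, 2, 2) average to 1
  rec2 <- make_recording(matrix(c(0, 0, 2, 2), 4, 1), mea)
  expect_equal(interpolate_plane(rec2, 0, query = cbind(0, 500)), 1)
  fld <- interpolate_plane(rec2, 0, resolution = 2)
  expect_equal(dim(fld$values), c(3, 3))
  expect_equal(fld$values[1, 1], 0)   # shallow-left corner electrode
  expect_equal(fld$values[3, 3], 2)
  # non-grid arrays are refused
  lam <- laminar_probe(n_electrodes = 4)
  expect_error(interpolate_plane(make_recording(matrix(0, 4, 2), lam), 0),
               "grid")
})

test_that("raster rows follow registry order with class-coded markers", {
  fx <- make_fixture()
  reg <- fx$geometry$populations
  rast <- raster(fx$spikes, reg)
  expect_true(all(rast$marker[rast$population == "pyrRS23"] == "up"))
  expect_true(all(rast$marker[rast$population == "bask23"] == "down"))
  expect_true(all(rast$marker[rast$population == "TCR"] == "up"))
  # population blocks are ordered as in the registry (silent cells may
  # contribute no marks, so compare the blocks that did spike)
  expect_lt(max(rast$row[rast$population == "pyrRS23"]),
            min(rast$row[rast$population == "bask23"]))
  if (any(rast$population == "TCR"))
    expect_lt(max(rast$row[rast$population == "bask23"]),
              min(rast$row[rast$population == "TCR"]))
  expect_equal(length(unique(rast$color[rast$population == "bask23"])), 1)
  # empty input and unknown cells
  empty <- structure(list(), class = "spike_events")
  expect_equal(nrow(raster(empty, reg)), 0)
  bad <- structure(list(ghost_001 = c(1, 2)), class = "spike_events")
  expect_error(raster(bad, reg), "ghost")
})

test_that("plot entry points draw without error", {
  fx <- make_fixture()
  reg <- fx$geometry$populations
  f <- withr::local_tempfile(fileext = ".png")
  plot_raster(raster(fx$spikes, reg), stim_onset = 20, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  rec <- make_recording(matrix(rnorm(28 * 50), 28, 50), laminar_probe())
  plot_laminar(rec, file = f)
  expect_true(file.size(f) > 0)
  mea <- mea_grid(n_rows = 4, n_cols = 3, pitch = 100)
  plot_plane(make_recording(matrix(rnorm(12 * 5), 12, 5), mea), 0.2,
             file = f)
  expect_true(file.size(f) > 0)
})
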