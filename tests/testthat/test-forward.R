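# Point-source forward model.

test_that("a unit point source reproduces the closed-form potential", {
  # 1 nA at 100 um in a 0.3 S/m medium: phi = 1/(4 pi * 0.3 * 100) mV
  seg <- point_segments(rbind(c(0, 0, 0)))
  act <- make_activity(seg, matrix(1, 1, 5))
  el <- electrode_array(rbind(c(100, 0, 0)))
  rec <- extracellular_potential(act, seg, el,
                                 medium_model(sigma = 0.3),
                                 populations = "pyrRS23")
  expected <- 1 / (4 * pi * 0.3 * 100)
  expect_equal(unname(rec$phi[1, 1]), expected, tolerance = 1e-12)
  expect_equal(unname(rec$phi[1, 1]), 2.6526e-3, tolerance = 1e-4)
  expect_true(all(rec$phi == rec$phi[1, 1]))
})

test_that("zero currents and opposite co-located sources give zero", {
  seg <- point_segments(rbind(c(0, 0, 0), c(0, 0, 0)))
  el <- electrode_array(rbind(c(50, 0, 0), c(0, 80, 10)))
  act0 <- make_activity(seg, matrix(0, 2, 4))
  expect_equal(max(abs(extracellular_potential(
    act0, seg, el, populations = "pyrRS23")$phi)), 0)
  dipole0 <- make_activity(seg, rbind(rep(1, 4), rep(-1, 4)))
  expect_equal(max(abs(extracellular_potential(
    dipole0, seg, el, populations = "pyrRS23")$phi)), 0)
})

test_that("potential scales inversely with conductivity and linearly in I", {
  seg <- point_segments(rbind(c(0, 0, 0), c(10, 5, -3)))
  el <- electrode_array(rbind(c(60, 10, 5)))
  I1 <- matrix(rnorm(10), 2, 5)
  I2 <- matrix(rnorm(10), 2, 5)
  phi <- function(I, sigma = 0.3)
    extracellular_potential(make_activity(seg, I), seg, el,
                            medium_model(sigma = sigma),
                            populations = "pyrRS23")$phi
  expect_equal(phi(I1, sigma = 0.6), phi(I1) / 2, tolerance = 1e-12)
  expect_equal(phi(2.5 * I1 - 1.5 * I2),
               2.5 * phi(I1) - 1.5 * phi(I2), tolerance = 1e-10)
})

test_that("a single source obeys the monopole law phi * r = const", {
  seg <- point_segments(rbind(c(0, 0, 0)))
  act <- make_activity(seg, matrix(1, 1, 1))
  r <- c(20, 50, 100, 400, 1000)
  el <- electrode_array(cbind(r, 0, 0))
  rec <- extracellular_potential(act, seg, el, populations = "pyrRS23")
  expect_equal(unname(rec$phi[, 1] * r), rep(unname(rec$phi[1, 1]) * r[1], 5),
               tolerance = 1e-12)
})

test_that("a current-conserving cell decays dipole-or-faster far away", {
  # +-1 nA 10 um apart (cell extent 10 um); probe at >= 20x extent
  seg <- point_segments(rbind(c(0, 0, -5), c(0, 0, 5)))
  act <- make_activity(seg, rbind(1, -1))
  for (r in c(200, 500, 2000)) {
    el <- electrode_array(rbind(c(0, 0, r), c(0, 0, 2 * r)))
    rec <- extracellular_potential(act, seg, el, populations = "pyrRS23")
    expect_lte(abs(rec$phi[2, 1]) / abs(rec$phi[1, 1]), 0.26)
  }
})

test_that("the optimized sum equals a naive triple loop on a fixture", {
  set.seed(101)
  n_seg <- 90; n_el <- 10; n_t <- 100
  pos <- cbind(runif(n_seg, -150, 150), runif(n_seg, -150, 150),
               runif(n_seg, 0, 1500))
  seg <- point_segments(pos)
  I <- matrix(rnorm(n_seg * n_t, sd = 0.5), n_seg, n_t)
  act <- make_activity(seg, I)
  el_pos <- cbind(runif(n_el, 200, 400), runif(n_el, -100, 100),
                  runif(n_el, 0, 1500))
  el <- electrode_array(el_pos)
  rec <- extracellular_potential(act, seg, el,
                                 medium_model(min_distance_clamp = 1),
                                 populations = "pyrRS23")
  oracle <- naive_potential(I, pos, el_pos, sigma = 0.3, clamp = 1)
  expect_equal(unname(rec$phi), oracle, tolerance = 1e-10)
})

test_that("electrode-on-source behavior follows the clamp policy", {
  seg <- point_segments(rbind(c(0, 0, 0)), diameter = 4)
  act <- make_activity(seg, matrix(1, 1, 1))
  el <- electrode_array(rbind(c(0, 0, 0)))
  expect_error(extracellular_potential(
    act, seg, el, medium_model(min_distance_clamp = 0),
    populations = "pyrRS23"), "clamp")
  # default clamp: half the segment diameter
  rec <- extracellular_potential(act, seg, el, populations = "pyrRS23")
  expect_equal(unname(rec$phi[1, 1]), 1 / (4 * pi * 0.3 * 2),
               tolerance = 1e-12)
})

test_that("default selection is cortical only and selections validate", {
  fx <- make_fixture()
  el <- laminar_probe(n_electrodes = 4, lateral_offset = 300)
  rec <- extracellular_potential(fx$activity, fx$segments, el)
  expect_setequal(rec$provenance$populations, c("pyrRS23", "bask23"))
  # explicit thalamic selection differs from the cortical default
  rec_all <- extracellular_potential(fx$activity, fx$segments, el,
                                     populations = c("pyrRS23", "bask23",
                                                     "TCR"))
  expect_false(isTRUE(all.equal(rec$phi, rec_all$phi)))
  expect_error(extracellular_potential(fx$activity, fx$segments, el,
                                       populations = "pyrXX"), "pyrXX")
  expect_error(extracellular_potential(fx$activity, fx$segments, el,
                                       components = "kainate"), "kainate")
})

test_that("contributions superpose: component partition sums to the total", {
  fx <- make_fixture()
  el <- laminar_probe(n_electrodes = 5, lateral_offset = 280)
  total <- extracellular_potential(fx$activity, fx$segments, el)
  panels <- list("nmda+ampa" = c("nmda", "ampa"), "gaba" = "gaba_a",
                 "capacitive" = "capacitive", "potassium" = "potassium",
                 "passive" = "passive", "calcium" = "calcium",
                 "sodium" = "sodium", "t-type" = "ca_T_low_threshold",
                 "anomalous rectifier" = "anomalous_rectifier",
                 "other" = "other")
  acc <- 0
  for (p in panels)
    acc <- acc + contribution(fx$activity, fx$segments, el,
                              populations = NULL, components = p)$phi
  scale <- max(abs(total$phi))
  expect_lt(max(abs(acc - total$phi)) / scale, 1e-10)
})

test_that("population contributions match a zero-out oracle", {
  fx <- make_fixture()
  el <- laminar_probe(n_electrodes = 3, lateral_offset = 320)
  one <- contribution(fx$activity, fx$segments, el,
                      populations = "bask23")
  zeroed <- fx$activity
  zeroed$i_total[zeroed$population != "bask23", ] <- 0
  oracle <- extracellular_potential(zeroed, fx$segments, el,
                                    populations = c("pyrRS23", "bask23"))
  expect_equal(one$phi, oracle$phi, tolerance = 1e-12)
  # and the two cortical populations superpose to the cortical total
  two <- contribution(fx$activity, fx$segments, el,
                      populations = "pyrRS23")
  total <- extracellular_potential(fx$activity, fx$segments, el)
  expect_equal(one$phi + two$phi, total$phi, tolerance = 1e-10)
})

test_that("an empty subset yields a zero recording flagged as empty", {
  fx <- make_fixture()
  el <- laminar_probe(n_electrodes = 3)
  rec <- contribution(fx$activity, fx$segments, el,
                      populations = character(0))
  expect_equal(max(abs(rec$phi)), 0)
  expect_true(rec$provenance$empty)
  expect_equal(dim(rec$phi), c(3, fx$activity$n_samples))
})

test_that("laminar probe geometry matches the published layout", {
  probe <- laminar_probe()
  expect_equal(nrow(probe$positions), 28)
  z <- probe$positions[, "z"]
  expect_true(all(diff(z) > 0))
  expect_equal(z[28], 27 * 92.6)       # deepest contact at 2500.2 um
  expect_equal(diff(z), rep(92.6, 27))
  single <- laminar_probe(n_electrodes = 1, top_depth = 123)
  expect_equal(nrow(single$positions), 1)
  expect_equal(single$positions[1, "z"], 123, ignore_attr = TRUE)
})

test_that("MEA grid geometry is regular, offset and centered", {
  mea <- mea_grid(pitch = 100)
  expect_equal(nrow(mea$positions), 320)  # 16 x 20
  expect_true(all(mea$positions[, "x"] == 25))
  expect_equal(mean(mea$positions[, "z"]), 850)  # cortical midline
  expect_equal(mean(mea$positions[, "y"]), 0)
  one <- mea_grid(n_rows = 1, n_cols = 1, pitch = 30, plane_offset = 25)
  expect_equal(unname(one$positions[1, ]), c(25, 0, 850))
  expect_error(mea_grid(), "pitch")
})

test_that("electrode layouts load from a plain-text table", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# label x y z", "e1 10 0 5", "e2 -20 30 400"), path)
  arr <- read_electrode_table(path)
  expect_equal(arr$labels, c("e1", "e2"))
  expect_equal(unname(arr$positions[2, ]), c(-20, 30, 400))
  expect_error(electrode_array(rbind(c(0, 0, 0), c(1, 1, 1)),
                               labels = c("a", "a")), "unique")
})
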