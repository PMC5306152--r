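# NSDF persistence: layout, round trips, validation.

write_fixture_nsdf <- function(fx, path) {
  sp <- fx$spikes
  sp[[1]] <- numeric(0)  # force one silent cell: empty vlen row
  write_nsdf(path, fx$segments, fx$activity, sp)
  sp
}

test_that("the written file follows the published path layout", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  ls_tab <- rhdf5::h5ls(path)
  full <- paste(ls_tab$group, ls_tab$name, sep = "/")
  full <- sub("^//", "/", full)
  expect_true("/data/static/morphology/pyrRS23" %in% full)
  expect_true("/map/static/pyrRS23_names" %in% full)
  expect_true("/data/uniform/pyrRS23/i" %in% full)
  expect_true("/data/uniform/pyrRS23/v" %in% full)
  expect_true("/data/uniform/pyrRS23/ampa" %in% full)
  expect_true("/data/event/bask23/spikes" %in% full)
  expect_true("/map/event/bask23_spikes" %in% full)
  # unit attributes per the format convention
  at <- suppressWarnings(
    rhdf5::h5readAttributes(path, "data/uniform/pyrRS23/i"))
  expect_identical(as.character(at$unit), "nA")
  at <- suppressWarnings(
    rhdf5::h5readAttributes(path, "data/uniform/pyrRS23/v"))
  expect_identical(as.character(at$unit), "mV")
  meta <- rhdf5::h5readAttributes(path, "/")
  expect_identical(as.character(meta$nsdf_version), "1.0")
  expect_equal(as.numeric(meta$dt), 0.1)
  for (nm in c("software", "method", "creator", "license"))
    expect_true(nm %in% names(meta))
  rhdf5::h5closeAll()
})

test_that("morphology rows align with their map ids and segment order", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  ids <- as.character(rhdf5::h5read(path, "map/static/pyrRS23_names"))
  morph <- rhdf5::h5read(path, "data/static/morphology/pyrRS23")
  rhdf5::h5closeAll()
  rows <- which(fx$segments$population == "pyrRS23")
  expect_identical(ids, fx$segments$segment_id[rows])
  expect_match(ids, "^pyrRS23_[0-9]+/", all = TRUE)
  expect_equal(as.numeric(morph$x0), fx$segments$x0[rows])
  expect_equal(as.numeric(morph$d), fx$segments$diameter[rows])
})

test_that("write then read is the identity", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  sp <- write_fixture_nsdf(fx, path)
  back <- read_nsdf(path)
  expect_identical(back$segments$segment_id, fx$segments$segment_id)
  expect_equal(back$segments, fx$segments)
  expect_identical(back$activity$i_total,
                   unname(fx$activity$i_total))
  expect_identical(back$activity$v, unname(fx$activity$v))
  for (l in channel_labels())
    expect_identical(back$activity$components[[l]],
                     fx$activity$components[[l]])
  for (cell in names(sp))
    expect_identical(back$spikes[[cell]], as.double(sp[[cell]]))
  expect_length(back$spikes[[1]], 0)  # silent cell round-trips empty
  expect_length(back$unknown_paths, 0)
})

test_that("overwriting requires an explicit flag", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  expect_error(write_nsdf(path, fx$segments, fx$activity, fx$spikes),
               "overwrite")
  expect_silent(write_nsdf(path, fx$segments, fx$activity, fx$spikes,
                           overwrite = TRUE))
})

test_that("an empty model writes a valid metadata-only file", {
  path <- withr::local_tempfile(fileext = ".h5")
  empty <- point_segments(matrix(numeric(0), 0, 3))[0, ]
  write_nsdf(path, empty, NULL, NULL)
  rep <- validate_nsdf(path)
  expect_true(rep$ok)
})

test_that("unknown extra groups are tolerated and reported", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  rhdf5::h5createGroup(path, "future_extension")
  rhdf5::h5write(1:3, path, "future_extension/stuff")
  rhdf5::h5closeAll()
  expect_message(back <- read_nsdf(path), "future_extension")
  expect_true("future_extension/stuff" %in% back$unknown_paths)
  expect_identical(back$activity$i_total, unname(fx$activity$i_total))
})

test_that("a freshly generated file validates with zero violations", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  rep <- validate_nsdf(path)
  expect_true(rep$ok)
  expect_equal(rep$n_violations, 0)
  expect_true(all(c("file attributes", "monotone time base",
                    "required paths", "row counts", "unit attributes",
                    "dimension scales", "kirchhoff residual",
                    "component closure") %in% rep$checks$rule))
})

test_that("the validator detects a deleted current row", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  im <- rhdf5::h5read(path, "data/uniform/bask23/i")
  rhdf5::h5delete(path, "data/uniform/bask23/i")
  rhdf5::h5write(im[, -1], path, "data/uniform/bask23/i")
  rhdf5::h5closeAll()
  rep <- validate_nsdf(path)
  expect_false(rep$ok)
  bad <- rep$checks[rep$checks$status == "fail", ]
  expect_true(any(bad$rule == "row counts" & bad$path == "bask23"))
})

test_that("the validator detects a Kirchhoff-breaking rescale", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  im <- rhdf5::h5read(path, "data/uniform/bask23/i")
  im[, 1] <- im[, 1] * 2  # one segment's current doubled
  rhdf5::h5write(im, path, "data/uniform/bask23/i")
  rhdf5::h5closeAll()
  rep <- validate_nsdf(path)
  bad <- rep$checks[rep$checks$status == "fail", ]
  expect_true(any(bad$rule == "kirchhoff residual" & bad$path == "bask23"))
  cell1 <- sub("/.*$", "", fx$segments$segment_id[
    fx$segments$population == "bask23"][1])
  expect_match(bad$detail[bad$rule == "kirchhoff residual"], cell1)
  # only that population's closure is flagged
  expect_false(any(bad$rule == "kirchhoff residual" & bad$path == "pyrRS23"))
})

test_that("the validator detects a missing unit attribute", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  rhdf5::h5deleteAttribute(path, "data/uniform/TCR/i", "unit")
  rhdf5::h5closeAll()
  rep <- validate_nsdf(path)
  bad <- rep$checks[rep$checks$status == "fail", ]
  expect_true(any(bad$rule == "unit attributes" & bad$path == "TCR"))
})

test_that("the validator detects a broken Dimension Scale link", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".h5")
  write_fixture_nsdf(fx, path)
  lfpsim:::h5ds_detach(path, "/data/uniform/bask23/i",
                       "/map/uniform/bask23_names")
  rep <- validate_nsdf(path)
  bad <- rep$checks[rep$checks$status == "fail", ]
  expect_true(any(bad$rule == "dimension scales" & bad$path == "bask23"))
  expect_false(any(bad$rule == "dimension scales" & bad$path == "TCR"))
})
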