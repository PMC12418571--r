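test_that("representative centres sit on the axes at the given radius", {
  ctr <- representative_centers(65)
  expect_equal(ctr$location, c("A", "P", "R", "L", "S", "I"))
  expect_equal(as.numeric(ctr[ctr$location == "S", c("x", "y", "z")]),
               c(0, 0, 65))
  expect_equal(as.numeric(ctr[ctr$location == "R", c("x", "y", "z")]),
               c(65, 0, 0))
  # antipodal pairs sum to the origin
  expect_equal(colSums(as.matrix(ctr[, c("x", "y", "z")])), c(x = 0, y = 0, z = 0))
  ctr1 <- representative_centers(1)
  expect_equal(sqrt(rowSums(as.matrix(ctr1[, c("x", "y", "z")])^2)), rep(1, 6))
  expect_error(representative_centers(0), "positive")
})

test_that("zero motion gives 100 percent overlap everywhere", {
  zero <- tibble::as_tibble(matrix(0, 4, 6,
                                   dimnames = list(NULL, names(pure_shift_series()))))
  v <- compute_vvo(zero, dims = 3)
  val_cols <- setdiff(names(v), "volume")
  expect_true(all(as.matrix(v[val_cols]) == 100))
  expect_equal(nrow(v), 4L)
})

test_that("pure-shift overlap matches the closed form at every location", {
  shifts <- c(0.5, 1, 1.5, 2, 2.5, 3)
  m <- pure_shift_series(shifts)
  v <- compute_vvo(m, dims = 3.5)
  expected <- 100 * pmax(0, 1 - shifts / 3.5)
  for (loc in c("A", "P", "R", "L", "S", "I")) {
    expect_equal(v[[paste0("td_vvo_", loc)]][-1], expected, tolerance = 1e-10)
  }
  # translations are spatially homogeneous: all locations identical,
  # median equals any location
  loc_cols <- paste0("td_vvo_", c("A", "P", "R", "L", "S", "I"))
  expect_equal(apply(as.matrix(v[loc_cols]), 1L, function(r) diff(range(r))),
               rep(0, nrow(v)))
  expect_equal(v$td_vvo_median, v$td_vvo_A)
  # first timepoint is 100 by convention
  expect_true(all(as.matrix(v[v$volume == 1, -1]) == 100))
})

test_that("rotations make the six locations differ", {
  m <- pure_shift_series(numeric(0))
  m2 <- dplyr::bind_rows(m, tibble::tibble(trans_x = 0, trans_y = 0,
                                           trans_z = 0, rot_x = 0, rot_y = 0,
                                           rot_z = 0.005))
  v <- compute_vvo(m2, dims = 3)
  loc_cols <- paste0("td_vvo_", c("A", "P", "R", "L", "S", "I"))
  vals <- as.numeric(v[2, loc_cols])
  # a z-rotation displaces axial probes but leaves S/I far less affected
  expect_gt(diff(range(vals)), 1)
})

test_that("TD_VVO tracks drift while STS_VVO tracks increments", {
  # monotone drift with constant 0.3 mm increments
  drift <- pure_shift_series(cumsum(rep(0.3, 6)))
  v <- compute_vvo(drift, dims = 3)
  expect_true(all(diff(v$td_vvo_median) <= 1e-9))
  # constant increments: identical STS_VVO from the second step on
  expect_equal(diff(v$sts_vvo_median[-1]), rep(0, 5), tolerance = 1e-9)
})

test_that("overlap percentages stay in bounds for random motion", {
  motion <- random_motion(15, seed = 9)
  v <- compute_vvo(motion, dims = 3)
  vals <- as.matrix(v[setdiff(names(v), "volume")])
  expect_true(all(vals >= 0 & vals <= 100))
  expect_true(all(as.matrix(v[1, -1]) == 100))
  # medians recompute from the six locations
  loc <- as.matrix(v[paste0("sts_vvo_", c("A", "P", "R", "L", "S", "I"))])
  expect_equal(v$sts_vvo_median, apply(loc, 1L, median))
})

test_that("effective (larger) dims never lower pure-shift overlap", {
  m <- pure_shift_series(c(0.5, 1, 2))
  acq <- compute_vvo(m, dims = 3, label = "acquired")
  eff <- compute_vvo(m, dims = c(4, 4, 5), label = "effective")
  expect_true(all(eff$td_vvo_median >= acq$td_vvo_median - 1e-12))
  expect_equal(attr(eff, "label"), "effective")
})

test_that("user-supplied centres are honoured", {
  ctr <- tibble::tibble(location = c("roi1", "roi2"),
                        x = c(10, -20), y = c(5, 30), z = c(-15, 40))
  v <- compute_vvo(pure_shift_series(1), dims = 3, centers = ctr)
  expect_true(all(c("td_vvo_roi1", "sts_vvo_roi2") %in% names(v)))
  expect_equal(v$td_vvo_median, (v$td_vvo_roi1 + v$td_vvo_roi2) / 2)
})

test_that("out-of-plane proportion is directional", {
  z1 <- pure_shift_series(1, axis = "z")
  expect_equal(out_of_plane(z1, dims = 3, plane = "axial")$out_of_plane[2], 100,
               tolerance = 1e-9)
  expect_equal(out_of_plane(z1, dims = 3, plane = "sagittal")$out_of_plane[2], 0,
               tolerance = 1e-9)
  # mixed (1,0,1) on a 3 mm voxel, axial: 9 of 15 displaced mm^3 through-plane
  m <- pure_shift_series(numeric(0))
  mixed <- dplyr::bind_rows(m, tibble::tibble(trans_x = 1, trans_y = 0,
                                              trans_z = 1, rot_x = 0,
                                              rot_y = 0, rot_z = 0))
  oop <- out_of_plane(mixed, dims = 3, plane = "axial")
  expect_equal(oop$out_of_plane[2], 100 * 9 / 15, tolerance = 1e-9)
  # first timepoint and still series are undefined
  expect_false(oop$defined[1])
  expect_true(is.na(oop$out_of_plane[1]))
  still <- tibble::as_tibble(matrix(0, 3, 6, dimnames = list(NULL, names(m))))
  expect_true(all(!out_of_plane(still, dims = 3, plane = "axial")$defined))
  expect_error(out_of_plane(z1, dims = 3, plane = "oblique"))
})

test_that("voxel-size sweep summarises the default grid", {
  m <- pure_shift_series(c(0.5, 1))
  sw <- voxel_size_sweep(m)
  expect_equal(nrow(sw), 8L)
  expect_equal(sw$size[1], "4x4x4")
  # per-timepoint detail matches a direct computation
  detail <- attr(sw, "per_timepoint")
  direct <- compute_vvo(m, dims = 2)
  expect_equal(detail$td_vvo_median[detail$size == "2x2x2"],
               direct$td_vvo_median)
  # overlap summary is non-decreasing in voxel size for fixed shifts
  sizes <- c(4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5)
  expect_true(all(diff(sw$td_vvo[order(sizes)]) >= -1e-9))
  # zero motion: all 100
  zero <- pure_shift_series(numeric(0))
  sw0 <- voxel_size_sweep(dplyr::bind_rows(zero, zero), sizes = c(3, 1))
  expect_true(all(sw0$td_vvo == 100) && all(sw0$sts_vvo == 100))
  expect_error(voxel_size_sweep(m, sizes = list()), "non-empty")
  expect_error(voxel_size_sweep(m, sizes = c(3, 0)), "positive")
})
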