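test_that("cuboid construction gives the right vertices and volume", {
  cube <- make_cuboid(c(0, 0, 0), c(1, 1, 1))
  expect_equal(nrow(cube$vertices), 8L)
  expect_equal(nrow(cube$edges), 12L)
  expect_equal(polytope_volume(cube), 1)
  expect_equal(polytope_volume(make_cuboid(c(5, -2, 1), c(3, 3, 3))), 27)
  expect_equal(polytope_volume(make_cuboid(c(0, 0, 0), c(2, 2, 4))), 16)
  expect_error(make_cuboid(c(0, 0, 0), c(1, 0, 1)), "positive")
  expect_error(make_cuboid(c(0, 0, 0), c(-1, 1, 1)), "positive")
})

test_that("half-space clipping cuts, keeps or empties correctly", {
  cube <- make_cuboid(c(0.5, 0.5, 0.5), c(1, 1, 1))   # unit cube [0,1]^3
  half <- clip_halfspace(cube, halfspace(c(0.5, 0, 0), c(-1, 0, 0)))
  expect_equal(polytope_volume(half), 0.5)

  # plane entirely below the cube, keeping above: unchanged
  same <- clip_halfspace(cube, halfspace(c(0, 0, -5), c(0, 0, 1)))
  expect_equal(polytope_volume(same), 1)

  # plane above the cube, keeping above: empty remnant, volume 0
  gone <- clip_halfspace(cube, halfspace(c(0, 0, 5), c(0, 0, 1)))
  expect_equal(nrow(gone$vertices), 0L)
  expect_equal(polytope_volume(gone), 0)

  expect_error(halfspace(c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("volume handles closed forms and degenerate vertex sets", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(polytope_volume(tetra), 1 / 6)
  cube_v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(polytope_volume(cube_v), 1)
  expect_equal(polytope_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))), 0)
  # planar quadrilateral: 4 coplanar vertices enclose no 3D volume
  expect_equal(polytope_volume(rbind(c(0, 0, 0), c(1, 0, 0),
                                     c(1, 1, 0), c(0, 1, 0))), 0)
})

test_that("clipping a randomly rotated cube agrees with the MC oracle", {
  set.seed(77)
  for (i in 1:10) {
    p <- c(runif(3, -1.5, 1.5), runif(3, -0.3, 0.3))
    tr <- params_to_transform(p)
    ctr <- c(runif(1, -5, 5), 65, runif(1, -5, 5))
    frac <- overlap_fraction(tr, ctr, c(3, 3, 3))
    est <- mc_overlap_oracle(tr, ctr, c(3, 3, 3), 2e5, seed = 1000 + i)
    se <- sqrt(max(frac * (1 - frac), 1e-9) / 2e5)
    expect_lt(abs(frac - est), 4 * se + 1e-6)
  }
})

test_that("pure translations reproduce the product closed form on a grid", {
  shifts <- c(0.25, 0.5, 1, 1.5, 2.2, 3)
  dims_grid <- list(c(4, 4, 4), c(3.5, 3.5, 3.5), c(2, 2, 4), c(1, 2, 3))
  for (d in dims_grid) for (s in shifts) {
    for (axis in 1:3) {
      sh <- c(0, 0, 0); sh[axis] <- s
      tr <- params_to_transform(c(sh, 0, 0, 0))
      expect_equal(overlap_fraction(tr, c(10, -65, 3), d),
                   shift_overlap(sh, d), tolerance = 1e-12)
    }
    # oblique shift across all three axes at once
    sh <- s * c(0.4, -0.7, 0.2)
    tr <- params_to_transform(c(sh, 0, 0, 0))
    expect_equal(overlap_fraction(tr, c(0, 0, 0), d), shift_overlap(sh, d),
                 tolerance = 1e-12)
  }
})

test_that("overlap is symmetric under transform inversion", {
  set.seed(88)
  for (i in 1:100) {
    tr <- params_to_transform(c(runif(3, -2, 2), runif(3, -0.05, 0.05)))
    ctr <- c(0, 65, 0)
    expect_lt(abs(overlap_fraction(tr, ctr, c(3, 3, 3)) -
                    overlap_fraction(solve(tr), ctr, c(3, 3, 3))), 1e-9)
  }
})

test_that("overlap, slab excess and in-plane excess conserve the voxel volume", {
  set.seed(99)
  dims <- c(3, 3, 3)
  voxvol <- prod(dims)
  for (i in 1:25) {
    tr <- params_to_transform(c(runif(3, -2, 2), runif(3, -0.03, 0.03)))
    ctr <- c(0, 0, 65)
    ov <- voxvol * overlap_fraction(tr, ctr, dims)
    ex <- slab_excess_volumes(tr, ctr, dims, "z")
    non_overlap <- voxvol - ov
    in_plane <- non_overlap - sum(ex)
    expect_gte(in_plane, -1e-9)
    expect_lt(abs(ov + ex[["below"]] + ex[["above"]] + in_plane - voxvol), 1e-9)
    expect_lte(sum(ex), voxvol + 1e-9)
  }
})

test_that("overlap is monotone non-increasing in pure shift magnitude", {
  for (d in c(2, 3.5)) {
    fr <- vapply(seq(0, 4, by = 0.25), function(s) {
      overlap_fraction(params_to_transform(c(s, 0, 0, 0, 0, 0)),
                       c(0, 65, 0), rep(d, 3))
    }, numeric(1))
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("a 90-degree rotation about the cube's own centre overlaps fully", {
  for (axis in 4:6) {
    p <- rep(0, 6); p[axis] <- pi / 2
    expect_equal(overlap_fraction(params_to_transform(p), c(0, 0, 0),
                                  c(3, 3, 3)), 1, tolerance = 1e-9)
  }
})

test_that("slab excess matches axis-aligned hand geometry", {
  # 1 mm z-shift of a 3 mm voxel: a 3x3x1 slab protrudes above
  tr_z <- params_to_transform(c(0, 0, 1, 0, 0, 0))
  expect_equal(slab_excess_volumes(tr_z, c(0, 65, 0), c(3, 3, 3), "z"),
               c(below = 0, above = 9), tolerance = 1e-12)
  # pure x-shift has no through-plane excess along z
  tr_x <- params_to_transform(c(1, 0, 0, 0, 0, 0))
  expect_equal(slab_excess_volumes(tr_x, c(0, 65, 0), c(3, 3, 3), "z"),
               c(below = 0, above = 0))
  # mixed (1,0,1): overlap 12, above 9, in-plane remainder 6 -> 27 total
  tr_m <- params_to_transform(c(1, 0, 1, 0, 0, 0))
  ov <- 27 * overlap_fraction(tr_m, c(0, 65, 0), c(3, 3, 3))
  ex <- slab_excess_volumes(tr_m, c(0, 65, 0), c(3, 3, 3), "z")
  expect_equal(ov, 12, tolerance = 1e-12)
  expect_equal(ex[["above"]], 9, tolerance = 1e-12)
  expect_equal(ov + sum(ex) + (27 - ov - sum(ex)), 27)
  expect_equal(27 - ov - sum(ex), 6, tolerance = 1e-12)
})

test_that("the MC oracle is seeded, reproducible and exact for identity", {
  tr <- params_to_transform(c(0.8, -0.4, 0.3, 0.01, 0, -0.02))
  a <- mc_overlap_oracle(tr, c(0, 65, 0), c(3, 3, 3), 1e4, seed = 42)
  b <- mc_overlap_oracle(tr, c(0, 65, 0), c(3, 3, 3), 1e4, seed = 42)
  expect_identical(a, b)
  expect_equal(mc_overlap_oracle(diag(4), c(0, 0, 0), c(2, 2, 2), 1e4,
                                 seed = 1), 1)
  # 2 mm shift of a 4 mm cube: 0.5 within 3 SE
  tr2 <- params_to_transform(c(2, 0, 0, 0, 0, 0))
  est <- mc_overlap_oracle(tr2, c(0, 0, 0), c(4, 4, 4), 1e6, seed = 7)
  expect_lt(abs(est - 0.5), 3 * sqrt(0.25 / 1e6))
})
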