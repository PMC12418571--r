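#' Six representative voxel centres
#'
#' Probe voxels placed on the coordinate axes at the average adult cortical
#' distance from the image origin (65 mm by default): anterior/posterior,
#' right/left, superior/inferior, under RAS axes (+x right, +y anterior,
#' +z superior). Motion effects are regionally heterogeneous, so overlap is
#' evaluated at all six and summarised by their median.
#'
#' @param radius Distance from the origin in mm (> 0).
#' @return A tibble with columns `location` (A, P, R, L, S, I), `x`, `y`, `z`.
#' @export
representative_centers <- function(radius = 65) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    abort("`radius` must be a single positive distance in mm.")
  }
  tibble::tibble(
    location = c("A", "P", "R", "L", "S", "I"),
    x = c(0, 0, radius, -radius, 0, 0),
    y = c(radius, -radius, 0, 0, 0, 0),
    z = c(0, 0, 0, 0, radius, -radius)
  )
}

vvo_locations <- c("A", "P", "R", "L", "S", "I")

# validate a motion-parameter table and return the n x 6 parameter matrix in
# canonical order (trans_x trans_y trans_z rot_x rot_y rot_z)
motion_params_matrix <- function(motion) {
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (is.matrix(motion) && ncol(motion) == 6L) {
    m <- motion
  } else if (is.data.frame(motion)) {
    missing_cols <- setdiff(cols, names(motion))
    if (length(missing_cols) > 0L) {
      abort(paste0("`motion` lacks column(s): ",
                   paste(missing_cols, collapse = ", "), "."))
    }
    m <- as.matrix(motion[cols])
  } else {
    abort("`motion` must be a data frame with trans_x..rot_z or an n x 6 matrix.")
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 1L) abort("`motion` must contain at least one volume.")
  if (!all(is.finite(m))) abort("`motion` contains non-finite values.")
  dimnames(m) <- list(NULL, cols)
  m
}

# median of six as mean of 3rd/4th order statistics (stats::median does this)
median6 <- function(x) median(x)

#' Voxel volume overlap series (TD_VVO / STS_VVO)
#'
#' For every timepoint and every representative voxel centre, the percent of
#' the voxel's volume that still overlaps its position in the first volume
#' (TD_VVO) or the preceding volume (STS_VVO), computed exactly by the
#' half-space clipping engine. The scan-to-scan overlap applies the relative
#' transform `T_t T_{t-1}^{-1}` to the axis-aligned reference cuboid, which
#' by rigid volume preservation equals the overlap of the two moved cuboids.
#' The first timepoint is 100% everywhere by convention.
#'
#' @param motion Motion-parameter data frame (see [read_motion()]).
#' @param dims Voxel edge lengths `(dx, dy, dz)` in mm; a single value is
#'   recycled to an isotropic voxel.
#' @param radius Representative-voxel distance in mm (default 65).
#' @param centers Optional data frame of probe centres with columns
#'   `location`, `x`, `y`, `z` (e.g. atlas region centres); defaults to the
#'   six axis locations of [representative_centers()].
#' @param label `"acquired"` or `"effective"`, recording which resolution
#'   `dims` describes.
#' @return A `vvo_series` tibble: `volume`, `td_vvo_<loc>` and
#'   `sts_vvo_<loc>` per location, and `td_vvo_median` / `sts_vvo_median`
#'   (percent). Attributes `dims`, `radius`, `label`, `centers`.
#' @examples
#' compute_vvo(pure_shift_series(c(1, 2)), dims = 4)
#' @export
compute_vvo <- function(motion, dims, radius = 65, centers = NULL,
                        label = c("acquired", "effective")) {
  label <- match.arg(label)
  dims <- check_dims(dims)
  params <- motion_params_matrix(motion)
  n <- nrow(params)
  if (is.null(centers)) centers <- representative_centers(radius)
  stopifnot(all(c("location", "x", "y", "z") %in% names(centers)))
  locs <- as.character(centers$location)
  pts <- as.matrix(centers[, c("x", "y", "z")])

  transforms <- lapply(seq_len(n), function(i) params_to_transform(params[i, ]))
  td <- matrix(100, n, length(locs), dimnames = list(NULL, locs))
  sts <- td
  for (t in seq_len(n)[-1]) {
    rel_td <- relative_transform(transforms[[t]], transforms[[1L]])
    rel_sts <- relative_transform(transforms[[t]], transforms[[t - 1L]])
    for (j in seq_along(locs)) {
      td[t, j] <- 100 * overlap_fraction(rel_td, pts[j, ], dims)
      sts[t, j] <- 100 * overlap_fraction(rel_sts, pts[j, ], dims)
    }
  }
  out <- tibble::as_tibble(cbind(
    data.frame(volume = seq_len(n)),
    setNames(as.data.frame(td), paste0("td_vvo_", locs)),
    setNames(as.data.frame(sts), paste0("sts_vvo_", locs))
  ))
  out$td_vvo_median <- apply(td, 1L, median6)
  out$sts_vvo_median <- apply(sts, 1L, median6)
  structure(out,
            dims = dims, radius = radius, label = label,
            centers = centers,
            class = c("vvo_series", class(out)))
}

check_dims <- function(dims) {
  dims <- as.numeric(dims)
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (length(dims) != 3L || !all(is.finite(dims)) || any(dims <= 0)) {
    abort("`dims` must be 1 or 3 strictly positive voxel edge lengths (mm).")
  }
  dims
}

through_plane_axis <- function(plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  c(axial = "z", coronal = "y", sagittal = "x")[[plane]]
}

#' Out-of-plane motion proportion
#'
#' Decomposes the non-overlapping (displaced) part of the moved voxel volume
#' into through-plane and in-plane components. For an axial acquisition the
#' through-plane direction is superior/inferior (z); coronal,
#' anterior/posterior (y); sagittal, left/right (x). The reference is always
#' the first volume, since the acquisition plane does not change over time.
#' The pooled proportion sums displaced and through-plane volumes over all
#' probe centres before forming the ratio, which is robust to near-zero
#' per-centre denominators; per-centre ratios are also returned for
#' inspection. Timepoints with no displaced volume (no motion) are flagged
#' undefined.
#'
#' @inheritParams compute_vvo
#' @param plane Acquisition plane: `"axial"`, `"coronal"` or `"sagittal"`.
#' @return A tibble: `volume`, `out_of_plane` (pooled percent of displaced
#'   volume that left the slab, `NA` when undefined), `defined`, and
#'   per-location `oop_<loc>` percents.
#' @examples
#' m <- pure_shift_series(1, axis = "z")
#' out_of_plane(m, dims = 3, plane = "axial")
#' @export
out_of_plane <- function(motion, dims, plane = c("axial", "coronal", "sagittal"),
                         radius = 65, centers = NULL) {
  plane <- match.arg(plane)
  axis <- through_plane_axis(plane)
  dims <- check_dims(dims)
  params <- motion_params_matrix(motion)
  n <- nrow(params)
  if (is.null(centers)) centers <- representative_centers(radius)
  locs <- as.character(centers$location)
  pts <- as.matrix(centers[, c("x", "y", "z")])
  voxvol <- prod(dims)

  transforms <- lapply(seq_len(n), function(i) params_to_transform(params[i, ]))
  pooled <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  per_loc <- matrix(NA_real_, n, length(locs), dimnames = list(NULL, locs))
  for (t in seq_len(n)[-1]) {
    rel <- relative_transform(transforms[[t]], transforms[[1L]])
    oop <- disp <- numeric(length(locs))
    for (j in seq_along(locs)) {
      ov <- voxvol * overlap_fraction(rel, pts[j, ], dims)
      ex <- slab_excess_volumes(rel, pts[j, ], dims, axis)
      disp[j] <- voxvol - ov
      oop[j] <- sum(ex)
      per_loc[t, j] <- if (disp[j] > 1e-9) 100 * oop[j] / disp[j] else NA_real_
    }
    if (sum(disp) > 1e-9) {
      pooled[t] <- 100 * sum(oop) / sum(disp)
      defined[t] <- TRUE
    }
  }
  out <- tibble::as_tibble(cbind(
    data.frame(volume = seq_len(n), out_of_plane = pooled, defined = defined),
    setNames(as.data.frame(per_loc), paste0("oop_", locs))
  ))
  attr(out, "plane") <- plane
  attr(out, "dims") <- dims
  out
}

#' Voxel-size sweep simulation
#'
#' Re-evaluates the overlap measures for the same motion trace under a grid
#' of assumed voxel sizes, demonstrating the voxel-size sensitivity of the
#' method. The default grid is the eight isotropic sizes 4, 3.5, 3, 2.5, 2,
#' 1.5, 1 and 0.5 mm.
#'
#' @inheritParams compute_vvo
#' @param sizes Numeric vector of isotropic sizes (mm) or a list of
#'   length-3 dims; non-empty.
#' @return A tibble with one row per size: `size` (label), `td_vvo`,
#'   `sts_vvo` — the median over timepoints of the per-timepoint
#'   median-of-six overlap percentages. The per-timepoint medians for every
#'   size are attached as attribute `per_timepoint`.
#' @export
voxel_size_sweep <- function(motion, sizes = c(4, 3.5, 3, 2.5, 2, 1.5, 1, 0.5),
                             radius = 65) {
  if (length(sizes) == 0L) abort("`sizes` must be non-empty.")
  if (!is.list(sizes)) sizes <- as.list(sizes)
  detail <- purrr::map_dfr(sizes, function(s) {
    d <- check_dims(s)
    v <- compute_vvo(motion, d, radius = radius)
    tibble::tibble(
      size = paste(format(d, trim = TRUE), collapse = "x"),
      volume = v$volume,
      td_vvo_median = v$td_vvo_median,
      sts_vvo_median = v$sts_vvo_median
    )
  })
  out <- dplyr::summarise(
    dplyr::group_by(detail, .data$size),
    td_vvo = median(.data$td_vvo_median),
    sts_vvo = median(.data$sts_vvo_median),
    .groups = "drop"
  )
  out <- out[match(unique(detail$size), out$size), ]
  attr(out, "per_timepoint") <- detail
  out
}
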