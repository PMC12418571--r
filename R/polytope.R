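# Convex polytope engine.
#
# A polytope is stored as vertices (n x 3), an explicit edge list (m x 2
# vertex indices) and the accumulated list of bounding half-spaces. Clipping
# against a half-space is 3D Sutherland-Hodgman: vertices on the kept side
# survive, edges crossing the plane are cut by linear interpolation, and the
# cut points are stitched into a new planar cap face. The remnant of a convex
# body clipped by half-spaces is convex, so its volume equals the volume of
# the convex hull of its vertices, computed by fan tetrahedralization from
# the vertex centroid over the face polygons.

# on-plane classification / vertex deduplication tolerance, mm
.vvo_tol <- 1e-9

new_polytope <- function(vertices, edges, planes) {
  structure(
    list(vertices = vertices, edges = edges, planes = planes),
    class = "vvo_polytope"
  )
}

#' Half-space constructor
#'
#' A half-space is an oriented plane: a point on the boundary and a unit
#' normal pointing toward the kept ("potentially inside") side.
#'
#' @param point Numeric length-3 point on the plane (mm).
#' @param normal Numeric length-3 normal; normalised internally, must be
#'   nonzero.
#' @return An object of class `vvo_halfspace`.
#' @export
halfspace <- function(point, normal) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L,
            all(is.finite(point)), all(is.finite(normal)))
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) abort("`normal` must be a nonzero vector.")
  structure(list(point = point, normal = normal / nn),
            class = "vvo_halfspace")
}

#' Axis-aligned cuboid polytope
#'
#' Builds the 8-vertex cuboid `center +/- dims/2`, the reference voxel shape
#' of the overlap computation, with its 12 edges and 6 bounding half-spaces
#' (normals pointing inward).
#'
#' @param center Numeric length-3 centre (mm).
#' @param dims Numeric length-3 edge lengths `(dx, dy, dz)` (mm), all > 0.
#' @return A `vvo_polytope`.
#' @examples
#' polytope_volume(make_cuboid(c(0, 0, 0), c(2, 2, 4)))  # 16
#' @export
make_cuboid <- function(center, dims) {
  center <- as.numeric(center)
  dims <- as.numeric(dims)
  stopifnot(length(center) == 3L, length(dims) == 3L, all(is.finite(center)))
  if (!all(is.finite(dims)) || any(dims <= 0)) {
    abort("`dims` must be three strictly positive voxel edge lengths (mm).")
  }
  half <- dims / 2
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  vertices <- sweep(signs %*% diag(half), 2L, center, `+`)
  colnames(vertices) <- NULL
  # edges connect vertices differing in exactly one sign
  edges <- which(as.matrix(stats::dist(signs, method = "manhattan")) == 2,
                 arr.ind = TRUE)
  edges <- unique(t(apply(edges[edges[, 1] < edges[, 2], , drop = FALSE],
                          1L, sort)))
  planes <- list()
  for (axis in 1:3) {
    e <- c(0, 0, 0); e[axis] <- 1
    planes <- c(planes,
                list(halfspace(center - half * e, e)),    # lower face, keep above
                list(halfspace(center + half * e, -e)))   # upper face, keep below
  }
  new_polytope(vertices, edges, planes)
}

# apply a rigid transform to a polytope (vertices and bounding planes)
transform_polytope <- function(poly, transform) {
  r <- transform[1:3, 1:3]
  t <- transform[1:3, 4]
  vertices <- poly$vertices %*% t(r)
  vertices <- sweep(vertices, 2L, t, `+`)
  planes <- lapply(poly$planes, function(hs) {
    halfspace(as.numeric(r %*% hs$point + t), as.numeric(r %*% hs$normal))
  })
  new_polytope(vertices, poly$edges, planes)
}

same_plane <- function(a, b, tol = 1e-9) {
  sum(abs(a$normal - b$normal)) < tol &&
    abs(sum(a$normal * (a$point - b$point))) < tol
}

#' Clip a convex polytope against a half-space
#'
#' One step of the iterative cutting-plane procedure: vertices on the kept
#' side of the plane are retained, each edge crossing the plane is cut at its
#' linear-interpolation intersection point, and the cut points form a new
#' planar face. Vertices within tolerance (1e-9 mm) of the plane are treated
#' as kept, so grazing contact does not shave slivers off the remnant.
#'
#' @param poly A `vvo_polytope`.
#' @param hs A [halfspace()].
#' @return The clipped `vvo_polytope`; possibly empty (0 vertices), which is
#'   a legitimate "no overlap" outcome with volume 0.
#' @export
clip_halfspace <- function(poly, hs) {
  stopifnot(inherits(poly, "vvo_polytope"), inherits(hs, "vvo_halfspace"))
  v <- poly$vertices
  if (nrow(v) == 0L) return(poly)
  d <- as.numeric(sweep(v, 2L, hs$point, `-`) %*% hs$normal)
  keep <- d >= -.vvo_tol
  if (all(keep)) {
    planes <- poly$planes
    if (!any(vapply(planes, same_plane, logical(1), b = hs))) {
      planes <- c(planes, list(hs))
    }
    return(new_polytope(v, poly$edges, planes))
  }
  if (!any(keep)) {
    return(new_polytope(v[0, , drop = FALSE],
                        matrix(integer(), 0L, 2L), list(hs)))
  }

  new_verts <- v[keep, , drop = FALSE]
  idx_map <- cumsum(keep)               # old index -> new index (kept only)
  out_edges <- list()
  cap <- v[keep & abs(d) <= .vvo_tol, , drop = FALSE]   # grazing vertices
  for (i in seq_len(nrow(poly$edges))) {
    a <- poly$edges[i, 1]; b <- poly$edges[i, 2]
    if (keep[a] && keep[b]) {
      out_edges[[length(out_edges) + 1L]] <- c(idx_map[a], idx_map[b])
    } else if (keep[a] || keep[b]) {
      if (!keep[a]) { tmp <- a; a <- b; b <- tmp }
      s <- d[a] / (d[a] - d[b])         # d[b] < -tol <= d[a], so 0 <= s < 1
      p <- v[a, ] + s * (v[b, ] - v[a, ])
      new_verts <- rbind(new_verts, p)
      out_edges[[length(out_edges) + 1L]] <- c(idx_map[a], nrow(new_verts))
      cap <- rbind(cap, p)
    }
  }
  edges <- do.call(rbind, out_edges)

  # deduplicate vertices, remap edges
  dedup <- dedup_vertices(new_verts)
  vertices <- dedup$vertices
  edges <- matrix(dedup$map[edges], ncol = 2L)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- unique(t(apply(edges, 1L, sort)))

  # stitch the cap face: order its vertices angularly in the cutting plane
  if (nrow(cap) > 0L) {
    cap_d <- dedup_vertices(cap)$vertices
    if (nrow(cap_d) >= 3L) {
      ord <- order_in_plane(cap_d, hs$normal)
      cap_idx <- vapply(seq_len(nrow(cap_d)), function(i) {
        which.min(rowSums(abs(sweep(vertices, 2L, cap_d[i, ], `-`))))
      }, integer(1))[ord]
      ring <- cbind(cap_idx, c(cap_idx[-1], cap_idx[1]))
      ring <- ring[ring[, 1] != ring[, 2], , drop = FALSE]
      edges <- unique(rbind(edges, t(apply(ring, 1L, sort))))
    }
  }

  planes <- Filter(function(p) !same_plane(p, hs), poly$planes)
  new_polytope(vertices, edges, c(planes, list(hs)))
}

dedup_vertices <- function(v, tol = .vvo_tol) {
  n <- nrow(v)
  map <- integer(n)
  kept <- matrix(numeric(), 0L, 3L)
  for (i in seq_len(n)) {
    hit <- 0L
    if (nrow(kept) > 0L) {
      dd <- rowSums(abs(sweep(kept, 2L, v[i, ], `-`)))
      j <- which.min(dd)
      if (dd[j] <= 3 * tol) hit <- j
    }
    if (hit == 0L) {
      kept <- rbind(kept, v[i, ])
      hit <- nrow(kept)
    }
    map[i] <- hit
  }
  list(vertices = kept, map = map)
}

# angular order of (roughly coplanar) points around their centroid, in the
# plane with the given normal
order_in_plane <- function(pts, normal) {
  u <- c(1, 0, 0)
  if (abs(sum(u * normal)) > 0.9) u <- c(0, 1, 0)
  e1 <- u - sum(u * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2L, ctr, `-`)
  order(atan2(rel %*% e2, rel %*% e1))
}

#' Volume of a convex polytope
#'
#' For a clipped polytope the bounding half-spaces are known, so each face
#' polygon is extracted as the vertices lying on its plane and the volume is
#' the sum of fan tetrahedra from the vertex centroid. A bare vertex matrix
#' is also accepted: its hull facets are found by brute-force plane
#' enumeration (all vertices on one side), suitable for small vertex sets.
#' Degenerate inputs (fewer than 4 non-coplanar vertices) have volume 0.
#'
#' @param poly A `vvo_polytope` or an n x 3 numeric matrix of vertices.
#' @return Volume in mm^3, >= 0.
#' @examples
#' polytope_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))  # 1/6
#' @export
polytope_volume <- function(poly) {
  if (inherits(poly, "vvo_polytope")) {
    v <- poly$vertices
    if (nrow(v) < 4L) return(0)
    planes <- poly$planes
  } else {
    v <- as.matrix(poly)
    stopifnot(ncol(v) == 3L)
    v <- dedup_vertices(v)$vertices
    if (nrow(v) < 4L) return(0)
    planes <- enumerate_hull_planes(v)
    if (length(planes) == 0L) return(0)
  }
  ctr <- colMeans(v)
  d_all <- vapply(planes, function(hs) {
    as.numeric(sweep(v, 2L, hs$point, `-`) %*% hs$normal)
  }, numeric(nrow(v)))
  total <- 0
  for (k in seq_along(planes)) {
    on_face <- abs(d_all[, k]) <= 1e-7
    if (sum(on_face) < 3L) next
    face <- v[on_face, , drop = FALSE]
    face <- face[order_in_plane(face, planes[[k]]$normal), , drop = FALSE]
    a <- sweep(face, 2L, ctr, `-`)
    for (i in 2:(nrow(a) - 1L)) {
      total <- total + abs(det(rbind(a[1, ], a[i, ], a[i + 1L, ]))) / 6
    }
  }
  total
}

# hull facet planes of a small vertex set by triple enumeration, outward
# normals flipped inward so the halfspace convention matches clipping
enumerate_hull_planes <- function(v, tol = 1e-9) {
  n <- nrow(v)
  planes <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ab <- v[j, ] - v[i, ]
    ac <- v[k, ] - v[i, ]
    nrm <- c(ab[2] * ac[3] - ab[3] * ac[2],
             ab[3] * ac[1] - ab[1] * ac[3],
             ab[1] * ac[2] - ab[2] * ac[1])
    ln <- sqrt(sum(nrm^2))
    if (ln < tol) next
    nrm <- nrm / ln
    d <- as.numeric(sweep(v, 2L, v[i, ], `-`) %*% nrm)
    scale_tol <- tol * max(1, max(abs(d)))
    hs <- if (all(d <= scale_tol)) {
      halfspace(v[i, ], -nrm)
    } else if (all(d >= -scale_tol)) {
      halfspace(v[i, ], nrm)
    } else {
      NULL
    }
    if (!is.null(hs) &&
        !any(vapply(planes, same_plane, logical(1), b = hs, tol = 1e-7))) {
      planes <- c(planes, list(hs))
    }
  }
  planes
}

#' Exact voxel-overlap fraction under a rigid transform
#'
#' The core quantity of the method: a reference voxel cuboid at `center`
#' with edge lengths `dims` is moved by the rigid transform, the moved
#' cuboid is clipped sequentially against the six half-spaces bounding the
#' unmoved reference cuboid, and the remnant volume is expressed as a
#' fraction of the voxel volume. Identity motion short-circuits to exactly 1;
#' the result is clamped to [0, 1] against round-off.
#'
#' @param transform 4x4 rigid transform (see [params_to_transform()]).
#' @param center Voxel centre (mm).
#' @param dims Voxel edge lengths (mm), all > 0.
#' @return Overlap fraction in `[0, 1]`.
#' @examples
#' tr <- params_to_transform(c(2, 0, 0, 0, 0, 0))
#' overlap_fraction(tr, c(0, 0, 0), c(4, 4, 4))  # 0.5
#' @export
overlap_fraction <- function(transform, center, dims) {
  center <- as.numeric(center)
  dims <- as.numeric(dims)
  if (!all(is.finite(dims)) || any(dims <= 0)) {
    abort("`dims` must be three strictly positive voxel edge lengths (mm).")
  }
  if (max(abs(transform - diag(4))) < 1e-12) return(1)
  ref <- make_cuboid(center, dims)
  poly <- transform_polytope(ref, transform)
  for (hs in ref$planes) {
    poly <- clip_halfspace(poly, hs)
    if (nrow(poly$vertices) == 0L) return(0)
  }
  max(0, min(1, polytope_volume(poly) / prod(dims)))
}

#' Moved-voxel volume beyond the reference slab faces
#'
#' Splits the moved cuboid's volume lying strictly beyond the two reference
#' faces perpendicular to `axis` — the through-plane ("out-of-plane") excess
#' for that axis. For an axial acquisition the z axis separates the volume
#' displaced inferior (`below`) and superior (`above`) to the voxel's slab.
#'
#' @inheritParams overlap_fraction
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Named numeric `c(below = , above = )` in mm^3; both >= 0 and
#'   their sum never exceeds the voxel volume.
#' @export
slab_excess_volumes <- function(transform, center, dims, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  center <- as.numeric(center)
  dims <- as.numeric(dims)
  if (!all(is.finite(dims)) || any(dims <= 0)) {
    abort("`dims` must be three strictly positive voxel edge lengths (mm).")
  }
  a <- match(axis, c("x", "y", "z"))
  e <- c(0, 0, 0); e[a] <- 1
  half <- dims[a] / 2
  moved <- transform_polytope(make_cuboid(center, dims), transform)
  below <- polytope_volume(
    clip_halfspace(moved, halfspace(center - half * e, -e)))
  above <- polytope_volume(
    clip_halfspace(moved, halfspace(center + half * e, e)))
  c(below = below, above = above)
}

#' Monte-Carlo overlap oracle
#'
#' Independent stochastic estimate of [overlap_fraction()]: points sampled
#' uniformly inside the moved cuboid are tested for membership in the
#' reference cuboid. Standard error is approximately `sqrt(p(1-p)/n)`.
#' Intended for verification; the clipping path is the measurement.
#'
#' @inheritParams overlap_fraction
#' @param n_samples Number of uniform samples (>= 1).
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @return Estimated overlap fraction in `[0, 1]`.
#' @export
mc_overlap_oracle <- function(transform, center, dims, n_samples = 1e6,
                              seed = 1L) {
  stopifnot(n_samples >= 1)
  center <- as.numeric(center)
  dims <- as.numeric(dims)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- as.integer(n_samples)
  # uniform in the reference box, mapped by the transform -> uniform in the
  # moved cuboid (rigid maps preserve volume)
  px <- runif(n, -0.5, 0.5) * dims[1] + center[1]
  py <- runif(n, -0.5, 0.5) * dims[2] + center[2]
  pz <- runif(n, -0.5, 0.5) * dims[3] + center[3]
  r <- transform[1:3, 1:3]
  t3 <- transform[1:3, 4]
  mx <- r[1, 1] * px + r[1, 2] * py + r[1, 3] * pz + t3[1]
  my <- r[2, 1] * px + r[2, 2] * py + r[2, 3] * pz + t3[2]
  mz <- r[3, 1] * px + r[3, 2] * py + r[3, 3] * pz + t3[3]
  inside <- abs(mx - center[1]) <= dims[1] / 2 &
    abs(my - center[2]) <= dims[2] / 2 &
    abs(mz - center[3]) <= dims[3] / 2
  mean(inside)
}
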