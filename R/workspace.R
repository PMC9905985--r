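#' Estimate the geometrical workspace boundary
#'
#' All points in the horizontal plane the endpoint can reach given the
#' segment lengths and joint ranges of motion, estimated by densely sweeping
#' the feasible joint box, rasterizing the endpoint images into an occupancy
#' grid at the requested resolution, and extracting the enclosing contour of
#' the (one-cell dilated) occupied region.  The dilation guarantees every
#' sampled endpoint lies inside the returned polygon; the boundary is
#' accurate to about the grid resolution.  Deterministic for fixed inputs.
#'
#' @param model An [arm_model()].
#' @param resolution Raster cell size (m).
#' @param n_per_joint Sweep points per joint (all combinations evaluated).
#' @return A tibble of boundary polygon vertices (`x`, `y`), closed (first
#'   vertex repeated last), of class `workspace_boundary`.
#' @export
estimate_workspace <- function(model, resolution = 0.01, n_per_joint = 60L) {
  stopifnot(resolution > 0, n_per_joint >= 10)
  geom <- model$geometry
  g <- lapply(1:3, function(j)
    seq(geom$joint_min[j], geom$joint_max[j], length.out = n_per_joint))
  q <- as.matrix(expand.grid(q1 = g[[1]], q2 = g[[2]], q3 = g[[3]]))
  L <- geom$segment_lengths
  th1 <- q[, 1]; th2 <- th1 + q[, 2]; th3 <- th2 + q[, 3]
  x <- L[1] * cos(th1) + L[2] * cos(th2) + L[3] * cos(th3)
  y <- L[1] * sin(th1) + L[2] * sin(th2) + L[3] * sin(th3)

  pad <- 3 * resolution
  x0 <- min(x) - pad; y0 <- min(y) - pad
  nx <- ceiling((max(x) + pad - x0) / resolution) + 1L
  ny <- ceiling((max(y) + pad - y0) / resolution) + 1L
  occ <- matrix(0, nx, ny)
  ix <- pmin(pmax(floor((x - x0) / resolution) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((y - y0) / resolution) + 1L, 1L), ny)
  occ[cbind(ix, iy)] <- 1
  # dilate by one cell so all samples end up strictly inside the 0.5-contour
  dil <- occ
  dil[-1, ] <- pmax(dil[-1, ], occ[-nx, ])
  dil[-nx, ] <- pmax(dil[-nx, ], occ[-1, ])
  dil[, -1] <- pmax(dil[, -1], occ[, -ny])
  dil[, -ny] <- pmax(dil[, -ny], occ[, -1])
  cx <- x0 + (seq_len(nx) - 0.5) * resolution
  cy <- y0 + (seq_len(ny) - 0.5) * resolution
  cl <- grDevices::contourLines(cx, cy, dil, levels = 0.5)
  if (length(cl) == 0) stop("workspace contour extraction failed", call. = FALSE)
  lens <- vapply(cl, function(p) length(p$x), numeric(1))
  b <- cl[[which.max(lens)]]
  bx <- c(b$x, b$x[1]); by <- c(b$y, b$y[1])
  structure(tibble::tibble(x = bx, y = by),
            class = c("workspace_boundary", class(tibble::tibble())),
            resolution = resolution, n_per_joint = n_per_joint)
}

# minimum distance from each point to a closed polyline
point_polyline_distance <- function(pts, bnd) {
  a <- bnd[-nrow(bnd), , drop = FALSE]
  b <- bnd[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  vapply(seq_len(nrow(pts)), function(i) {
    ap <- cbind(pts[i, 1] - a[, 1], pts[i, 2] - a[, 2])
    tt <- pmin(pmax(rowSums(ap * ab) / len2, 0), 1)
    sqrt(min((ap[, 1] - tt * ab[, 1])^2 + (ap[, 2] - tt * ab[, 2])^2))
  }, numeric(1))
}

#' Point-in-workspace test
#'
#' Standard point-in-polygon test against the estimated boundary; points on
#' the boundary count as inside.
#'
#' @param points A two-column matrix or data frame of `x`, `y` coordinates,
#'   or a length-2 vector for a single point.
#' @param boundary A [estimate_workspace()] polygon.
#' @return Logical vector, one flag per point.
#' @export
in_workspace <- function(points, boundary) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  bnd <- as.matrix(boundary[, c("x", "y")])
  inside <- mgcv::in.out(bnd, pts)
  # boundary points count as inside: accept points within a hair of an edge
  eps <- 1e-9
  on_edge <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    a <- bnd[-nrow(bnd), , drop = FALSE]
    b <- bnd[-1, , drop = FALSE]
    ab <- b - a
    ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
    tt <- pmin(pmax(rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-300), 0), 1)
    d2 <- (ap[, 1] - tt * ab[, 1])^2 + (ap[, 2] - tt * ab[, 2])^2
    any(d2 < eps^2)
  }, logical(1))
  inside | on_edge
}

#' Generate the study's three target sets
#'
#' Builds the labelled target sets used throughout the workspace-mapping
#' experiments:
#' * `opt_sequence` — a four-target sequence near the edges of the workspace
#'   (distal left, distal forward, distal right, proximal right), used for
#'   controller tuning, where maximal joint angles are unavoidable;
#' * `rect_grid` — a rectangular grid covering the bounding box of the
#'   workspace at `grid_spacing`, for mapping performance everywhere
#'   (out-of-workspace points are kept but flagged);
#' * `boundary_grid` — concentric arcs covering the distal boundary and a
#'   `band_width`-wide band inside it, split into the right side (traced by
#'   the straight arm over the shoulder's range of motion, arcs centred on
#'   the shoulder) and the left side (traced by the straight forearm and
#'   hand over the elbow's range with the shoulder fully flexed, arcs
#'   centred on the fully-flexed elbow position).
#'
#' @param model An [arm_model()].
#' @param boundary A [estimate_workspace()] polygon.
#' @param grid_spacing Spacing of the rectangular grid (m).
#' @param band_width Width of the boundary band (m).
#' @param n_rings Number of concentric rings across the band.
#' @param arc_step Angular spacing along each ring (rad).
#' @param opt_targets Optional 4 x 2 matrix overriding the tuning targets.
#' @return A tibble with columns `target_id`, `x`, `y`, `set_id`,
#'   `in_workspace`, `boundary_side`.
#' @export
make_target_sets <- function(model, boundary, grid_spacing = 0.05,
                             band_width = 0.20, n_rings = 6L,
                             arc_step = 5 * pi / 180, opt_targets = NULL) {
  stopifnot(grid_spacing > 0, band_width > 0, n_rings >= 2)
  geom <- model$geometry
  L <- geom$segment_lengths
  R <- sum(L)

  if (is.null(opt_targets)) {
    # near the edges: maximal joint angles unavoidable
    polar <- function(r, ang) c(r * cos(ang), r * sin(ang))
    # proximal-right target: just inside the proximal boundary along a ray
    ray_ang <- 30 * pi / 180
    rr <- seq(0.05, R, by = 0.005)
    ray <- cbind(rr * cos(ray_ang), rr * sin(ray_ang))
    r_in <- rr[in_workspace(ray, boundary)]
    r_prox <- if (length(r_in) > 0) min(r_in) + 0.05 else 0.5 * R
    opt_targets <- rbind(
      polar(R - 0.05, 135 * pi / 180),  # distal left
      polar(R - 0.05, 75 * pi / 180),   # distal forward
      polar(R - 0.05, 10 * pi / 180),   # distal right
      polar(r_prox, ray_ang))           # proximal right
  }
  stopifnot(nrow(opt_targets) == 4)
  set_i <- tibble::tibble(x = opt_targets[, 1], y = opt_targets[, 2],
                          set_id = "opt_sequence", boundary_side = "none")

  xs <- seq(floor(min(boundary$x) / grid_spacing),
            ceiling(max(boundary$x) / grid_spacing)) * grid_spacing
  ys <- seq(floor(min(boundary$y) / grid_spacing),
            ceiling(max(boundary$y) / grid_spacing)) * grid_spacing
  grid <- expand.grid(x = xs, y = ys)
  set_ii <- tibble::tibble(x = grid$x, y = grid$y, set_id = "rect_grid",
                           boundary_side = "none")

  offs <- seq(0, band_width, length.out = n_rings)
  right <- dplyr::bind_rows(lapply(offs, function(o) {
    ang <- seq(geom$joint_min[1], geom$joint_max[1], by = arc_step)
    tibble::tibble(x = (R - o) * cos(ang), y = (R - o) * sin(ang),
                   set_id = "boundary_grid", boundary_side = "right")
  }))
  elbow0 <- L[1] * c(cos(geom$joint_max[1]), sin(geom$joint_max[1]))
  left <- dplyr::bind_rows(lapply(offs, function(o) {
    q2 <- seq(geom$joint_min[2], geom$joint_max[2], by = arc_step)
    th2 <- geom$joint_max[1] + q2
    tibble::tibble(x = elbow0[1] + (L[2] + L[3] - o) * cos(th2),
                   y = elbow0[2] + (L[2] + L[3] - o) * sin(th2),
                   set_id = "boundary_grid", boundary_side = "left")
  }))

  out <- dplyr::bind_rows(set_i, set_ii, right, left)
  if (nrow(out) == 0) stop("empty target sets", call. = FALSE)
  out$in_workspace <- in_workspace(cbind(out$x, out$y), boundary)
  # the raster boundary over-covers by up to about two cells; refine the flag
  # near the polygon with the exact kinematic test (closest reachable posture)
  res <- attr(boundary, "resolution")
  if (!is.null(res)) {
    bnd <- as.matrix(boundary[, c("x", "y")])
    d_bnd <- point_polyline_distance(cbind(out$x, out$y), bnd)
    near <- which(out$in_workspace & d_bnd < 2.5 * res)
    if (length(near) > 0) {
      # seed each refinement from the nearest endpoint of a dense joint sweep
      gq <- lapply(1:3, function(j)
        seq(geom$joint_min[j], geom$joint_max[j],
            length.out = c(80, 80, 40)[j]))
      qs <- as.matrix(expand.grid(q1 = gq[[1]], q2 = gq[[2]], q3 = gq[[3]]))
      th1 <- qs[, 1]; th2 <- th1 + qs[, 2]; th3 <- th2 + qs[, 3]
      px <- L[1] * cos(th1) + L[2] * cos(th2) + L[3] * cos(th3)
      py <- L[1] * sin(th1) + L[2] * sin(th2) + L[3] * sin(th3)
      for (i in near) {
        k <- which.min((px - out$x[i])^2 + (py - out$y[i])^2)
        sol <- solve_target_posture(model, c(out$x[i], out$y[i]),
                                    seeds = qs[k, ])
        out$in_workspace[i] <- sol$dist < 1e-4
      }
    }
  }
  out$target_id <- paste0(out$set_id, "_", stats::ave(
    rep(1L, nrow(out)), out$set_id, FUN = seq_along))
  dplyr::select(out, "target_id", "x", "y", "set_id", "in_workspace",
                "boundary_side")
}
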