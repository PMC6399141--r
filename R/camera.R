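#' Pinhole camera model
#'
#' A perspective camera defined by its 3D centre of projection `X_COP`, a
#' focal centre `X_FOC` fixing the view axis, a roll angle about that axis,
#' and a focal scale in pixels per unit tangent. The image is
#' `image_size[1] x image_size[2]` pixels at `pixel_mm` per pixel; pixel
#' coordinates are 0-based `(u = col, v = row)` with the optical axis through
#' the image centre `((cols-1)/2, (rows-1)/2)`.
#'
#' @param X_COP 3D camera position (mm).
#' @param X_FOC 3D focal centre (mm); must differ from `X_COP`.
#' @param roll rotation about the view axis, radians.
#' @param focal_scale pixels per unit tangent; defaults to
#'   `|X_FOC - X_COP| / pixel_mm` so that the focal plane is sampled at
#'   `pixel_mm` per pixel.
#' @param image_size `c(rows, cols)`.
#' @param pixel_mm physical pixel pitch at the focal plane, mm.
#' @return a `camera_model`.
#' @export
camera_model <- function(X_COP, X_FOC, roll = 0, focal_scale = NULL,
                         image_size = c(100L, 100L), pixel_mm = 0.7) {
  X_COP <- as.numeric(X_COP); X_FOC <- as.numeric(X_FOC)
  if (vnorm(X_FOC - X_COP) < 1e-9)
    te_stop("degenerate_camera", "X_COP and X_FOC coincide")
  focal_scale <- focal_scale %||% (vnorm(X_FOC - X_COP) / pixel_mm)
  if (focal_scale <= 0) te_stop("invalid_parameter", "focal_scale must be > 0")
  structure(list(X_COP = X_COP, X_FOC = X_FOC, roll = as.numeric(roll),
                 focal_scale = focal_scale,
                 image_size = as.integer(image_size), pixel_mm = pixel_mm),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: COP (%.1f, %.1f, %.1f) -> FOC (%.1f, %.1f, %.1f), roll %.3f rad, scale %.1f px\n",
              x$X_COP[1], x$X_COP[2], x$X_COP[3],
              x$X_FOC[1], x$X_FOC[2], x$X_FOC[3], x$roll, x$focal_scale))
  invisible(x)
}

# orthonormal camera frame: z along view axis, x/y the rolled image axes.
# Reference up is world +y (well-conditioned for the near-axial views of a
# camera looking through the anterior tank wall); +z fallback when d || y.
camera_frame <- function(camera) {
  d <- camera$X_FOC - camera$X_COP
  d <- d / vnorm(d)
  up <- c(0, 1, 0)
  if (vnorm(cross3(d, up)) < 1e-6) up <- c(0, 0, 1)
  r <- cross3(d, up); r <- r / vnorm(r)
  u <- cross3(r, d)
  th <- camera$roll
  r2 <- r * cos(th) + cross3(d, r) * sin(th)
  u2 <- u * cos(th) + cross3(d, u) * sin(th)
  list(x = r2, y = u2, z = d)
}

#' Perspective projection of 3D points
#'
#' Projects world points into the optical frame:
#' `(u, v) = image centre + focal_scale * (x_cam, -y_cam) / z_cam`. A point
#' is visible when its depth `z_cam` is positive and its pixel lies inside
#' the image bounds.
#'
#' @param camera a `camera_model`.
#' @param points `n x 3` matrix of world positions (mm).
#' @return data.frame with `u`, `v` (pixels), `depth` (mm along the view
#'   axis) and `visible`.
#' @export
project <- function(camera, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (any(!is.finite(points))) te_stop("invalid_parameter", "points must be finite")
  fr <- camera_frame(camera)
  rel <- sweep(points, 2, camera$X_COP, `-`)
  z <- as.numeric(rel %*% fr$z)
  x <- as.numeric(rel %*% fr$x)
  y <- as.numeric(rel %*% fr$y)
  ctr <- (camera$image_size - 1) / 2 # (rows, cols)
  u <- ctr[2] + camera$focal_scale * x / z
  v <- ctr[1] - camera$focal_scale * y / z
  visible <- z > 0 & u >= -0.5 & u <= camera$image_size[2] - 0.5 &
    v >= -0.5 & v <= camera$image_size[1] - 0.5
  data.frame(u = u, v = v, depth = z, visible = visible)
}

#' Z-buffer rasterization of a mesh
#'
#' Rasterizes front-facing triangles into the camera's pixel grid, keeping
#' the depth-nearest face per pixel and recording the triangle vertex with
#' the largest barycentric weight as the pixel's visible vertex.
#'
#' @param camera a `camera_model`.
#' @param mesh a `trimesh`.
#' @return list with `zbuf` (rows x cols depth, `Inf` where empty),
#'   `pixel_vertex`, `pixel_face` (linear-pixel vectors, `NA` background) and
#'   the vertex projection `proj`.
#' @export
rasterize_mesh <- function(camera, mesh) {
  proj <- project(camera, mesh$vertices)
  R <- camera$image_size[1]; C <- camera$image_size[2]
  zbuf <- matrix(Inf, R, C)
  pix_v <- rep(NA_integer_, R * C)
  pix_f <- rep(NA_integer_, R * C)
  fn <- face_normals(mesh)
  fctr <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
           mesh$vertices[mesh$faces[, 3], ]) / 3
  front <- rowSums(fn * sweep(fctr, 2, camera$X_COP, `-`)) < 0
  for (k in which(front)) {
    vi <- mesh$faces[k, ]
    if (any(proj$depth[vi] <= 0)) next
    x <- proj$u[vi]; y <- proj$v[vi]; z <- proj$depth[vi]
    c0 <- max(0L, ceiling(min(x))); c1 <- min(C - 1L, floor(max(x)))
    r0 <- max(0L, ceiling(min(y))); r1 <- min(R - 1L, floor(max(y)))
    if (c1 < c0 || r1 < r0) next
    px <- expand.grid(col = c0:c1, row = r0:r1)
    den <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
    if (abs(den) < 1e-12) next
    w1 <- ((y[2] - y[3]) * (px$col - x[3]) + (x[3] - x[2]) * (px$row - y[3])) / den
    w2 <- ((y[3] - y[1]) * (px$col - x[3]) + (x[1] - x[3]) * (px$row - y[3])) / den
    w3 <- 1 - w1 - w2
    inside <- w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9
    if (!any(inside)) next
    depth <- w1[inside] * z[1] + w2[inside] * z[2] + w3[inside] * z[3]
    lin <- px_index(px$row[inside], px$col[inside], camera$image_size)
    better <- depth < zbuf[lin]
    if (any(better)) {
      lb <- lin[better]
      zbuf[lb] <- depth[better]
      wmat <- cbind(w1[inside][better], w2[inside][better], w3[inside][better])
      pix_v[lb] <- vi[max.col(wmat, ties.method = "first")]
      pix_f[lb] <- k
    }
  }
  list(zbuf = zbuf, pixel_vertex = pix_v, pixel_face = pix_f, proj = proj)
}

#' Visible submesh under a camera
#'
#' Keeps mesh vertices that are front-facing (outward normal pointing toward
#' the camera) and depth-nearest along their pixel ray, assigning each kept
#' vertex its image pixel. This removes the posterior surface that the
#' optical window cannot see.
#'
#' @param camera a `camera_model`.
#' @param mesh a `trimesh`.
#' @param depth_tol_mm slack against the z-buffer, mm.
#' @return list with `vertices` (kept indices), `pixels` (`n x 2` 0-based
#'   row/col) and the vertex projection `proj`.
#' @export
visible_submesh <- function(camera, mesh, depth_tol_mm = 3) {
  ras <- rasterize_mesh(camera, mesh)
  proj <- ras$proj
  front <- rowSums(mesh$vertex_normals *
                   sweep(mesh$vertices, 2, camera$X_COP, `-`)) < 0
  row <- round(proj$v); col <- round(proj$u)
  inb <- proj$visible & row >= 0 & row < camera$image_size[1] &
    col >= 0 & col < camera$image_size[2]
  keep <- which(front & inb)
  lin <- px_index(row[keep], col[keep], camera$image_size)
  keep <- keep[proj$depth[keep] <= ras$zbuf[lin] + depth_tol_mm]
  if (!length(keep)) te_stop("empty_view", "no mesh vertex visible to the camera")
  list(vertices = keep,
       pixels = cbind(row = row[keep], col = col[keep]),
       proj = proj)
}

#' Stage-1 alignment cost: mean reprojection distance
#'
#' `J = (1/n) * sum ||E2D_hat - E2D||` over corresponded, camera-visible
#' electrodes, in pixels.
#'
#' @param camera a `camera_model`.
#' @param electrodes `electrode_set` with 3D positions `E_3D`.
#' @param E2D `n x 2` matrix of reference pixel positions `(u, v)`; rows with
#'   `NA` are uncorresponded.
#' @return mean Euclidean pixel distance.
#' @export
electrode_cost <- function(camera, electrodes, E2D) {
  E2D <- matrix(as.numeric(E2D), ncol = 2)
  have <- rowSums(is.na(E2D)) == 0
  if (!any(have)) te_stop("cost_undefined", "no 2D correspondences supplied")
  pr <- project(camera, electrodes$positions)
  use <- have & pr$visible
  if (!any(use)) te_stop("cost_undefined", "no visible corresponded electrodes")
  structure(mean(sqrt((pr$u[use] - E2D[use, 1])^2 +
                      (pr$v[use] - E2D[use, 2])^2)),
            n_used = sum(use))
}

camera_to_par <- function(camera) {
  c(camera$X_COP, camera$X_FOC, camera$roll, log(camera$focal_scale))
}

par_to_camera <- function(p, template) {
  camera_model(p[1:3], p[4:6], roll = p[7], focal_scale = exp(p[8]),
               image_size = template$image_size, pixel_mm = template$pixel_mm)
}

# Nelder-Mead with restarts; returns list(par, value)
nm_restart <- function(par, fn, rounds = 8, maxit = 2000, reltol = 1e-12) {
  best <- list(par = par, value = fn(par))
  for (r in seq_len(rounds)) {
    o <- stats::optim(best$par, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    if (o$value < best$value - 1e-10) {
      best <- list(par = o$par, value = o$value)
    } else {
      if (o$value < best$value) best <- list(par = o$par, value = o$value)
      break
    }
  }
  best
}

#' Stage-1 camera optimization on electrode correspondences
#'
#' Derivative-free simplex minimization of [electrode_cost()] over
#' `(X_COP, X_FOC, roll, log focal_scale)` with seeded multi-starts around
#' the initial camera. Candidates that push corresponded electrodes out of
#' view are rejected (dropping correspondences is a degenerate way to lower
#' a mean cost). The returned camera never has a larger cost than the
#' initial one.
#'
#' @param init initial `camera_model`.
#' @param electrodes `electrode_set` (3D).
#' @param E2D reference pixels, as in [electrode_cost()].
#' @param n_starts number of multi-starts (first is `init` itself).
#' @param seed seed for the start perturbations.
#' @return optimized `camera_model` with attribute `cost_px`.
#' @export
optimize_stage1 <- function(init, electrodes, E2D, n_starts = 5, seed = 1L) {
  E2D <- matrix(as.numeric(E2D), ncol = 2)
  have <- which(rowSums(is.na(E2D)) == 0)
  if (length(have) < 4)
    te_stop("precondition_error", "need >= 4 correspondences")
  P <- electrodes$positions[have, , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 3)
    te_stop("precondition_error", "correspondences are coplanar")
  n0 <- attr(electrode_cost(init, electrodes, E2D), "n_used")
  fn <- function(p) {
    cam <- try(par_to_camera(p, init), silent = TRUE)
    if (inherits(cam, "try-error")) return(1e9)
    j <- try(electrode_cost(cam, electrodes, E2D), silent = TRUE)
    if (inherits(j, "try-error") || attr(j, "n_used") < n0) 1e9
    else as.numeric(j)
  }
  p0 <- camera_to_par(init)
  j0 <- fn(p0)
  set.seed(seed)
  starts <- c(list(p0), lapply(seq_len(n_starts - 1), function(i)
    p0 + c(stats::rnorm(6, sd = 5), stats::rnorm(1, sd = 0.05),
           stats::rnorm(1, sd = 0.05))))
  best <- NULL
  for (s in starts) {
    r <- nm_restart(s, fn)
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (best$value > j0)
    te_stop("optimization_failure", "no start reduced the reprojection cost")
  out <- par_to_camera(best$par, init)
  attr(out, "cost_px") <- best$value
  out
}

#' Stage-2 alignment cost: mean absolute AT difference
#'
#' Projects each visible sock electrode, pairs it to the nearest in-mask
#' optical pixel and returns the mean absolute difference between the
#' sock-derived and optical activation times, ms.
#'
#' @param camera a `camera_model`.
#' @param electrodes sock `electrode_set` (3D).
#' @param sock_at `time_map` on sock electrodes.
#' @param optical_at `time_map` on optical pixels (linear, row-major).
#' @param mask a `data_mask`.
#' @param cutoff_px pairing cutoff in pixels.
#' @return mean |AT_sock - AT_optical|, ms.
#' @export
at_cost <- function(camera, electrodes, sock_at, optical_at, mask,
                    cutoff_px = Inf) {
  pr <- project(camera, electrodes$positions)
  ok <- pr$visible & sock_at$valid
  if (!any(ok)) te_stop("cost_undefined", "no visible electrode maps into the mask")
  pairs <- pair_to_pixels(cbind(pr$u[ok], pr$v[ok]), mask, cutoff_px = cutoff_px)
  idx <- which(ok)[pairs$point]
  pix <- pairs$pixel
  use <- optical_at$valid[pix]
  if (!any(use)) te_stop("cost_undefined", "no paired pixel has a valid optical AT")
  structure(mean(abs(sock_at$times[idx[use]] - optical_at$times[pix[use]])),
            n_pairs = sum(use))
}

#' Stage-2 camera refinement on activation times
#'
#' Refines `(X_COP, X_FOC)` from the stage-1 camera by minimizing
#' [at_cost()], bounded within ±10% of the stage-1 parameter magnitudes.
#' Candidate cameras that lose electrode pairings relative to the stage-1
#' camera are rejected — a mean cost over fewer pairs is not comparable and
#' shrinking the view is a degenerate way to lower it. If the cost cannot be
#' reduced (e.g. a spatially uniform AT field) the stage-1 camera is
#' returned unchanged with a warning.
#'
#' @param stage1_camera `camera_model` from [optimize_stage1()].
#' @inheritParams at_cost
#' @return refined `camera_model` with attribute `cost_ms`.
#' @export
optimize_stage2 <- function(stage1_camera, electrodes, sock_at, optical_at,
                            mask) {
  p0 <- c(stage1_camera$X_COP, stage1_camera$X_FOC)
  halfwidth <- 0.1 * pmax(abs(p0), 10)
  n0 <- attr(at_cost(stage1_camera, electrodes, sock_at, optical_at, mask),
             "n_pairs")
  fn <- function(p) {
    if (any(abs(p - p0) > halfwidth)) return(1e9)
    cam <- try(camera_model(p[1:3], p[4:6], roll = stage1_camera$roll,
                            focal_scale = stage1_camera$focal_scale,
                            image_size = stage1_camera$image_size,
                            pixel_mm = stage1_camera$pixel_mm), silent = TRUE)
    if (inherits(cam, "try-error")) return(1e9)
    j <- try(at_cost(cam, electrodes, sock_at, optical_at, mask), silent = TRUE)
    if (inherits(j, "try-error") || attr(j, "n_pairs") < n0) 1e9
    else as.numeric(j)
  }
  j0 <- fn(p0)
  r <- nm_restart(p0, fn, rounds = 4, maxit = 400)
  if (r$value >= j0 - 1e-12) {
    te_warn("flat_cost", "AT cost not reduced; returning stage-1 camera")
    out <- stage1_camera
    attr(out, "cost_ms") <- j0
    return(out)
  }
  out <- camera_model(r$par[1:3], r$par[4:6], roll = stage1_camera$roll,
                      focal_scale = stage1_camera$focal_scale,
                      image_size = stage1_camera$image_size,
                      pixel_mm = stage1_camera$pixel_mm)
  attr(out, "cost_ms") <- r$value
  out
}
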