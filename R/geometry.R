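#' Triangulated surface meshes
#'
#' A `trimesh` is a closed triangulated surface in millimetre coordinates:
#' an `n x 3` vertex matrix, an `m x 3` face index matrix (1-based, counter
#' clockwise seen from outside) and outward unit vertex normals. Heart and
#' tank surfaces are both represented this way.
#'
#' @param vertices numeric `n x 3` matrix of positions (mm).
#' @param faces integer `m x 3` matrix of vertex indices.
#' @param vertex_normals optional `n x 3` matrix of outward unit normals;
#'   computed by area-weighted face-normal averaging when omitted.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, vertex_normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) te_stop("invalid_parameter", "vertices must be n x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    te_stop("invalid_parameter", "faces index vertices outside the mesh")
  if (is.null(vertex_normals)) {
    vertex_normals <- vertex_normals_from_faces(vertices, faces)
  }
  structure(
    list(vertices = vertices, faces = faces,
         vertex_normals = normalize_rows(as.matrix(vertex_normals))),
    class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces, mean edge %.2f mm\n",
              nrow(x$vertices), nrow(x$faces), mean_edge_length(x)))
  invisible(x)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cross3_rows(a, b) # length = 2 * area
}

face_areas <- function(mesh) row_norms(face_normals(mesh)) / 2

vertex_normals_from_faces <- function(vertices, faces) {
  fn <- cross3_rows(vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE],
                    vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE])
  n <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], faces[, k], sum)
      idx <- as.integer(names(acc))
      n[idx, d] <- n[idx, d] + as.numeric(acc)
    }
  }
  normalize_rows(n)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a `trimesh`.
#' @return two-column integer matrix, each unique edge once, `v1 < v2`.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' @rdname mesh_edges
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  mean(row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                 mesh$vertices[e[, 2], , drop = FALSE]))
}

#' Validate mesh invariants
#'
#' Checks that every face is non-degenerate, vertex normals are unit length
#' (within 1e-6), and the surface is closed (every edge shared by exactly two
#' faces).
#'
#' @param mesh a `trimesh`.
#' @return `TRUE` invisibly; stops with a classed error otherwise.
#' @export
validate_trimesh <- function(mesh) {
  if (any(face_areas(mesh) <= 0))
    te_stop("degenerate_mesh", "mesh contains zero-area faces")
  if (any(abs(row_norms(mesh$vertex_normals) - 1) > 1e-6))
    te_stop("degenerate_mesh", "vertex normals are not unit length")
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(key) != 2L))
    te_stop("open_mesh", "surface is not closed: an edge is not shared by exactly 2 faces")
  invisible(TRUE)
}

# Unit icosahedron with outward-oriented faces.
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# Loop-style midpoint subdivision of a unit sphere, `level` times.
icosphere <- function(level) {
  m <- icosahedron()
  v <- m$vertices; f <- m$faces
  for (l in seq_len(level)) {
    nv <- nrow(v)
    ekey <- new.env(hash = TRUE, parent = emptyenv())
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- ekey[[key]]
      if (!is.null(id)) return(id)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / vnorm(p)
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      ekey[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(k - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  # orient faces outward (unit sphere: normal along centroid)
  fn <- cross3_rows(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(fn * ctr) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  list(vertices = v, faces = f)
}

.icosphere_cache <- new.env(parent = emptyenv())

icosphere_cached <- function(level) {
  key <- as.character(level)
  if (is.null(.icosphere_cache[[key]]))
    .icosphere_cache[[key]] <- icosphere(level)
  .icosphere_cache[[key]]
}

ellipsoid_mesh <- function(semi_axes, center, level) {
  s <- icosphere_cached(level)
  v <- sweep(sweep(s$vertices, 2, semi_axes, `*`), 2, center, `+`)
  # analytic outward normal of an ellipsoid: grad[(x/a)^2+(y/b)^2+(z/c)^2]
  n <- normalize_rows(sweep(sweep(v, 2, center, `-`), 2, semi_axes^2, `/`))
  m <- trimesh(v, s$faces, n)
  attr(m, "ellipsoid") <- list(semi_axes = semi_axes, center = center)
  m
}

#' Generate an ellipsoidal heart surface
#'
#' Builds a closed epicardial stand-in by icosphere subdivision scaled to the
#' requested semi-axes; the subdivision level is chosen so the mean edge
#' length is as close as possible to `target_edge_mm` (4 mm by default,
#' matching fluoroscopy-derived epicardial meshes).
#'
#' @param semi_axes positive lengths (mm) of the three ellipsoid semi-axes.
#' @param center 3D centre (mm).
#' @param target_edge_mm target mean edge length (mm).
#' @param level optional explicit subdivision level, overrides the edge target.
#' @return a `trimesh` with an `ellipsoid` attribute recording the analytic shape.
#' @export
make_heart_mesh <- function(semi_axes = c(30, 30, 35), center = c(0, 0, 0),
                            target_edge_mm = 4, level = NULL) {
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    te_stop("invalid_parameter", "semi_axes must all be > 0")
  if (!is_scalar_num(target_edge_mm) || target_edge_mm <= 0)
    te_stop("invalid_parameter", "target_edge_mm must be > 0")
  if (is.null(level)) {
    # measure the actual mean edge of the scaled icosphere per level
    measured <- vapply(0:5, function(l) {
      s <- icosphere_cached(l)
      e <- rbind(s$faces[, c(1, 2)], s$faces[, c(2, 3)], s$faces[, c(3, 1)])
      v <- sweep(s$vertices, 2, semi_axes, `*`)
      mean(row_norms(v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE]))
    }, 0)
    level <- which.min(abs(log(measured / target_edge_mm))) - 1L
  }
  ellipsoid_mesh(semi_axes, center, level)
}

#' Generate a torso-tank surface enclosing a heart mesh
#'
#' The tank is an ellipsoid scaled up from the heart's analytic semi-axes (or
#' its bounding extents) and must strictly enclose every heart vertex.
#'
#' @param heart the heart `trimesh`.
#' @param scale_factors per-axis ratios tank/heart.
#' @param target_edge_mm target mean edge length of the tank mesh (mm).
#' @return a `trimesh` for the tank surface.
#' @export
make_torso_tank <- function(heart, scale_factors = c(5, 5, 5), target_edge_mm = 40) {
  ell <- attr(heart, "ellipsoid")
  if (!is.null(ell)) {
    base_axes <- ell$semi_axes; center <- ell$center
  } else {
    center <- colMeans(heart$vertices)
    base_axes <- apply(abs(sweep(heart$vertices, 2, center, `-`)), 2, max)
  }
  tank <- make_heart_mesh(base_axes * scale_factors, center, target_edge_mm)
  inside <- points_in_mesh(heart$vertices, tank)
  if (!all(inside))
    te_stop("containment_error",
            sprintf("%d heart vertices lie outside the tank", sum(!inside)))
  tank
}

#' Point-in-mesh test by ray casting
#'
#' Counts intersections of a fixed irrational-direction ray with the surface
#' triangles (Moller-Trumbore); odd parity means interior.
#'
#' @param points `n x 3` matrix of query points (mm).
#' @param mesh a closed `trimesh`.
#' @return logical vector, `TRUE` for strictly interior points.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- c(0.577350269, 0.312347524, 0.754339800) # fixed generic direction
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - v0
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - v0
  dm <- matrix(d, nrow(v0), 3, byrow = TRUE)
  p <- cross3_rows(dm, e2)
  det <- rowSums(e1 * p)
  ok <- abs(det) > 1e-12
  vapply(seq_len(nrow(points)), function(i) {
    tv <- sweep(v0, 2, points[i, ], `-`) * -1
    u <- rowSums(tv * p) / det
    q <- cross3_rows(tv, e1)
    vv <- (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3]) / det
    tt <- rowSums(e2 * q) / det
    hits <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 1e-9
    (sum(hits) %% 2L) == 1L
  }, logical(1))
}

#' Electrode sets
#'
#' Electrodes snapped to mesh vertices with unique labels and per-channel
#' validity, standing in for the epicardial sock and the tank-surface array.
#'
#' @param positions `n x 3` electrode positions (mm).
#' @param labels unique channel identifiers.
#' @param host_vertex nearest mesh vertex index per electrode.
#' @param valid per-channel logical.
#' @param normals optional `n x 3` outward unit surface normals at the
#'   electrodes (needed for Neumann collocation on the tank).
#' @return an `electrode_set`.
#' @export
electrode_set <- function(positions, labels, host_vertex,
                          valid = rep(TRUE, length(labels)), normals = NULL) {
  if (anyDuplicated(labels)) te_stop("invalid_parameter", "electrode labels must be unique")
  structure(list(positions = as.matrix(positions), labels = as.character(labels),
                 host_vertex = as.integer(host_vertex), valid = as.logical(valid),
                 normals = if (!is.null(normals)) normalize_rows(as.matrix(normals))),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("electrode_set: %d electrodes (%d valid)\n",
              length(x$labels), sum(x$valid)))
  invisible(x)
}

# igraph over mesh edges weighted by Euclidean length.
mesh_graph <- function(mesh, weights = NULL) {
  e <- mesh_edges(mesh)
  w <- weights %||% row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                              mesh$vertices[e[, 2], , drop = FALSE])
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Place electrodes by farthest-point sampling
#'
#' Greedy geodesic farthest-point sampling over mesh vertices from a seeded
#' start vertex: each new electrode maximizes its minimum geodesic distance to
#' those already placed. Deterministic given `seed`.
#'
#' @param mesh a `trimesh`.
#' @param n number of electrodes (`n <=` vertex count).
#' @param seed integer seed selecting the start vertex.
#' @param label_prefix prefix for generated channel labels.
#' @return an `electrode_set`; attribute `fps_min_dist` records the
#'   (non-increasing) minimum pairwise geodesic distance after each placement.
#' @export
place_electrodes <- function(mesh, n, seed = 1L, label_prefix = "E") {
  nv <- nrow(mesh$vertices)
  if (n > nv) te_stop("invalid_parameter", "more electrodes requested than mesh vertices")
  if (n < 1) te_stop("invalid_parameter", "n must be >= 1")
  g <- mesh_graph(mesh)
  set.seed(seed)
  start <- sample.int(nv, 1L)
  chosen <- integer(n); chosen[1L] <- start
  dmin <- as.numeric(igraph::distances(g, v = start))
  min_seq <- numeric(n); min_seq[1L] <- Inf
  if (n > 1L) for (k in 2:n) {
    nxt <- which.max(dmin)
    chosen[k] <- nxt
    min_seq[k] <- dmin[nxt]
    dmin <- pmin(dmin, as.numeric(igraph::distances(g, v = nxt)))
  }
  es <- electrode_set(mesh$vertices[chosen, , drop = FALSE],
                      sprintf("%s%03d", label_prefix, seq_len(n)), chosen,
                      normals = mesh$vertex_normals[chosen, , drop = FALSE])
  attr(es, "fps_min_dist") <- min_seq
  es
}
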