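# File formats: ASCII PLY and legacy-VTK polydata for meshes, CSV for
# electrode tables, signal blocks and time maps, JSON for cameras/configs.

#' Mesh, electrode, signal and map serialization
#'
#' @param mesh a `trimesh`.
#' @param path file path.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name tankecgi-io
NULL

#' @rdname tankecgi-io
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c(
    "ply", "format ascii 1.0", "comment tankecgi mesh",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices", "end_header"), con)
  vm <- cbind(mesh$vertices, mesh$vertex_normals)
  writeLines(apply(format(vm, digits = 9, trim = TRUE, scientific = FALSE), 1,
                   paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' @rdname tankecgi-io
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hend <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vm <- do.call(rbind, lapply(strsplit(lines[(hend + 1):(hend + nv)], " "), as.numeric))
  fm <- do.call(rbind, lapply(strsplit(lines[(hend + nv + 1):(hend + nv + nf)], " "),
                              function(x) as.integer(x[2:4]) + 1L))
  trimesh(vm[, 1:3, drop = FALSE], fm,
          if (ncol(vm) >= 6) vm[, 4:6, drop = FALSE] else NULL)
}

#' @rdname tankecgi-io
#' @export
write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "tankecgi mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(apply(format(mesh$vertices, digits = 9, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' @rdname tankecgi-io
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  vm <- do.call(rbind, lapply(strsplit(lines[(ip + 1):(ip + nv)], " +"), as.numeric))
  ifc <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(lines[ifc], " ")[[1]][2])
  fm <- do.call(rbind, lapply(strsplit(lines[(ifc + 1):(ifc + nf)], " +"),
                              function(x) as.integer(x[2:4]) + 1L))
  trimesh(vm[, 1:3, drop = FALSE], fm)
}

#' @rdname tankecgi-io
#' @param electrodes an `electrode_set`.
#' @export
write_electrodes_csv <- function(electrodes, path) {
  utils::write.csv(data.frame(
    label = electrodes$labels,
    x = electrodes$positions[, 1], y = electrodes$positions[, 2],
    z = electrodes$positions[, 3],
    host_vertex = electrodes$host_vertex, valid = electrodes$valid),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tankecgi-io
#' @export
read_electrodes_csv <- function(path) {
  d <- utils::read.csv(path)
  electrode_set(cbind(d$x, d$y, d$z), d$label, d$host_vertex, d$valid)
}

#' @rdname tankecgi-io
#' @param block a `signal_block`.
#' @export
write_signal_csv <- function(block, path) {
  m <- t(block$samples)
  colnames(m) <- block$channel_ids
  d <- cbind(data.frame(t_ms = block$t0 + (seq_len(nrow(m)) - 1) * 1000 / block$rate), m)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  meta <- data.frame(channel = block$channel_ids, valid = block$valid,
                     rate = block$rate, t0 = block$t0)
  utils::write.csv(meta, sub("\\.csv$", "_meta.csv", path), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname tankecgi-io
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  meta <- utils::read.csv(sub("\\.csv$", "_meta.csv", path))
  signal_block(t(as.matrix(d[, -1, drop = FALSE])), rate = meta$rate[1],
               t0 = meta$t0[1], channel_ids = meta$channel,
               valid = meta$valid)
}

#' @rdname tankecgi-io
#' @param tm a `time_map`.
#' @export
write_timemap_csv <- function(tm, path) {
  utils::write.csv(data.frame(id = seq_along(tm$times), time_ms = tm$times,
                              valid = tm$valid),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tankecgi-io
#' @param domain_tag domain of a read time map.
#' @export
read_timemap_csv <- function(path, domain_tag = "mesh_nodes") {
  d <- utils::read.csv(path)
  time_map(d$time_ms, d$valid, domain_tag)
}

#' @rdname tankecgi-io
#' @param camera a `camera_model`.
#' @export
write_camera_json <- function(camera, path) {
  jsonlite::write_json(unclass(camera), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tankecgi-io
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(j$X_COP, j$X_FOC, roll = j$roll, focal_scale = j$focal_scale,
               image_size = j$image_size, pixel_mm = j$pixel_mm)
}

#' @rdname tankecgi-io
#' @param mask a `data_mask`.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.table(mask$grid * 1L, path, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}
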