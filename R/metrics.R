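#' Pair projected points to optical pixels
#'
#' Each point is paired with its nearest in-mask pixel by 2D Euclidean
#' distance in pixel units; ties break to the lowest `(row, col)` and points
#' farther than `cutoff_px` stay unpaired.
#'
#' @param points2D `n x 2` matrix of `(u, v)` pixel positions.
#' @param mask a `data_mask`.
#' @param cutoff_px pairing cutoff, pixels (default 5).
#' @return data.frame with `point` (row of `points2D`), `pixel` (row-major
#'   linear index) and `distance`.
#' @export
pair_to_pixels <- function(points2D, mask, cutoff_px = 5) {
  points2D <- matrix(as.numeric(points2D), ncol = 2)
  grid <- mask$grid
  lin <- which(as.logical(t(grid))) # row-major = (row, col) lexicographic
  if (!length(lin)) te_stop("pairing_error", "mask is empty")
  rc <- px_rowcol(lin, dim(grid))
  pt <- integer(0); px <- integer(0); ds <- numeric(0)
  for (i in seq_len(nrow(points2D))) {
    d2 <- (rc[, 2] - points2D[i, 1])^2 + (rc[, 1] - points2D[i, 2])^2
    k <- which.min(d2) # first minimum = lowest (row, col)
    if (sqrt(d2[k]) <= cutoff_px) {
      pt <- c(pt, i); px <- c(px, lin[k]); ds <- c(ds, sqrt(d2[k]))
    }
  }
  if (!length(pt)) te_stop("pairing_error", "no point paired within the cutoff")
  data.frame(point = pt, pixel = px, distance = ds)
}

#' Compare two time maps over pairs
#'
#' Pearson correlation and RMSE over paired valid entries.
#'
#' @param a,b `time_map`s.
#' @param pairs data.frame with columns indexing `a` (`point` or `i`) and `b`
#'   (`pixel` or `j`).
#' @return a `comparison_result`: `cc`, `rmse` (ms), `n_pairs`, `pairs`.
#'   `cc` is `NA` with a warning when fewer than 3 pairs or either side is
#'   constant.
#' @export
compare_maps <- function(a, b, pairs) {
  ia <- pairs$point %||% pairs$i
  ib <- pairs$pixel %||% pairs$j
  ok <- a$valid[ia] & b$valid[ib]
  if (!any(ok)) te_stop("input_error", "no valid pairs to compare")
  x <- a$times[ia[ok]]; y <- b$times[ib[ok]]
  rmse <- sqrt(mean((x - y)^2))
  cc <- NA_real_
  if (length(x) < 3) {
    te_warn("cc_undefined", "fewer than 3 valid pairs; cc not reported")
  } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    te_warn("cc_undefined", "constant map; cc not reported")
  } else cc <- stats::cor(x, y)
  structure(list(cc = cc, rmse = rmse, n_pairs = length(x),
                 pairs = data.frame(i = ia[ok], j = ib[ok])),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison: cc = %.3f, rmse = %.2f ms over %d pairs\n",
              x$cc, x$rmse, x$n_pairs))
  invisible(x)
}

#' Time-vs-distance gradient profile
#'
#' For every valid in-ROI pixel, pairs its time with its physical distance
#' from a reference pixel — the plot-ready form of the across-border
#' activation/repolarization gradient analysis.
#'
#' @param map `time_map` on optical pixels (row-major linear order).
#' @param roi list or vector `(rmin, rmax, cmin, cmax)`, 0-based inclusive.
#' @param ref_point `c(row, col)` of the reference pixel (the "star").
#' @param pixel_mm pixel pitch, mm.
#' @param image_size `c(rows, cols)`.
#' @param source_tag `optical` or `ecgi`.
#' @return a `gradient_profile` with a `samples` data.frame (`distance_mm`,
#'   `time_ms`, `row`, `col`, `source`), sorted by distance.
#' @export
gradient_profile <- function(map, roi, ref_point, pixel_mm = 0.7,
                             image_size = c(100L, 100L),
                             source_tag = c("optical", "ecgi")) {
  source_tag <- match.arg(source_tag)
  roi <- as.numeric(unlist(roi))
  rc <- px_rowcol(seq_len(prod(image_size)), image_size)
  inroi <- rc[, 1] >= roi[1] & rc[, 1] <= roi[2] &
    rc[, 2] >= roi[3] & rc[, 2] <= roi[4] & map$valid
  if (!any(inroi)) te_stop("roi_error", "no valid pixel inside the ROI")
  idx <- which(inroi)
  d <- pixel_mm * sqrt((rc[idx, 1] - ref_point[1])^2 +
                       (rc[idx, 2] - ref_point[2])^2)
  o <- order(d)
  structure(list(roi = roi, ref_point = ref_point,
                 samples = data.frame(distance_mm = d[o],
                                      time_ms = map$times[idx[o]],
                                      row = rc[idx[o], 1], col = rc[idx[o], 2],
                                      source = source_tag)),
            class = "gradient_profile")
}

#' Paired t-test
#'
#' Classical paired t statistic with two-sided p value, computed in closed
#' form: `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = x - y`.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`.
#' @return list with `t`, `p`, `df`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) te_stop("input_error", "length mismatch")
  n <- length(x)
  if (n < 2) te_stop("input_error", "need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1)
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector, `n >= 1`.
#' @return list with `mean`, `sd` (`NA` for `n = 1`) and `n`.
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) te_stop("input_error", "no finite values to summarize")
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}
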