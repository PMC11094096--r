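# number of crossings of one straight segment with the sphere |p| = r:
# distinct roots of |p0 + t d|^2 = r^2 strictly inside (0, 1). Endpoints
# exactly on the sphere and tangencies count as no crossing (measure-zero,
# deterministic rule).
.segment_sphere_crossings <- function(seg, center, r) {
  p0 <- seg[1:3] - center
  d <- seg[4:6] - seg[1:3]
  a <- sum(d * d)
  if (a == 0) return(0L)
  b <- 2 * sum(p0 * d)
  cc <- sum(p0 * p0) - r^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0L)
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  sum(c(t1, t2) > 0 & c(t1, t2) < 1)
}

#' Sholl analysis of a reconstructed tree
#'
#' Counts crossings of dendritic segments with concentric spheres centered
#' on the soma at fixed radial increments (default 20 um), and the total
#' cable length. Crossings are exact segment-sphere intersections (a segment
#' that enters and leaves a shell between two nodes contributes two). With
#' `mode = "2d"` the z coordinate is ignored, emulating analysis on
#' maximum-intensity projections.
#'
#' @param tree a [morph_tree()].
#' @param step radius increment in um.
#' @param max_radius outermost radius (default: covers the whole tree).
#' @param mode `"3d"` (spheres) or `"2d"` (circles on the projection).
#' @return An object of class `"sholl_result"`: list with `radii`,
#'   `intersections`, `total_intersections`, `total_length`.
#' @export
sholl_analysis <- function(tree, step = 20, max_radius = NULL,
                           mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  if (!inherits(tree, "morph_tree")) stop("'tree' must be a morph_tree")
  if (nrow(tree$nodes) < 2L) stop("tree has no segments")
  center <- .soma_center(tree)
  segs <- .tree_segments(tree)
  if (mode == "2d") {
    segs[, c("z0", "z1")] <- 0
    center[3] <- 0
  }
  if (is.null(max_radius)) {
    dmax <- max(sqrt((segs[, "x1"] - center[1])^2 +
                       (segs[, "y1"] - center[2])^2 +
                       (segs[, "z1"] - center[3])^2))
    # outermost shell that the tree can still reach
    max_radius <- max(step, floor(dmax / step) * step)
  }
  radii <- seq(step, max(step, max_radius), by = step)
  counts <- vapply(radii, function(r)
    sum(apply(segs, 1L, .segment_sphere_crossings, center = center, r = r)),
    numeric(1))
  structure(list(radii = radii, intersections = as.integer(counts),
                 total_intersections = as.integer(sum(counts)),
                 total_length = total_cable_length(tree)),
            class = "sholl_result")
}

#' @export
print.sholl_result <- function(x, ...) {
  cat(sprintf("<sholl_result> %d radii (step %g um), %d total crossings, %.1f um cable\n",
              length(x$radii), diff(x$radii[1:2]), x$total_intersections,
              x$total_length))
  invisible(x)
}

#' Spine density and length metrics over annotated dendritic segments
#'
#' Per-segment spine density (count / segment length) and mean spine length,
#' plus grand means taken as unweighted averages over segments — the
#' per-cell convention when a handful of 15-20 um representative segments
#' is analyzed.
#'
#' @param segments data.frame with columns `segment_id`, `length_um`.
#' @param spines data.frame with columns `segment_id`, `spine_length_um`
#'   (zero rows allowed).
#' @return An object of class `"spine_result"`: list with `per_segment`
#'   (data.frame segment_id, segment_length, n_spines, density_per_um,
#'   mean_spine_length) and `grand_mean_density`, `grand_mean_length`.
#' @export
spine_metrics <- function(segments, spines) {
  stopifnot(all(c("segment_id", "length_um") %in% names(segments)))
  if (any(segments$length_um <= 0))
    stop("zero-length segment: id ",
         segments$segment_id[segments$length_um <= 0][1])
  per <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    sid <- segments$segment_id[i]
    sl <- spines$spine_length_um[spines$segment_id == sid]
    data.frame(segment_id = sid, segment_length = segments$length_um[i],
               n_spines = length(sl),
               density_per_um = length(sl) / segments$length_um[i],
               mean_spine_length = if (length(sl)) mean(sl) else NA_real_)
  }))
  structure(list(per_segment = per,
                 grand_mean_density = mean(per$density_per_um),
                 grand_mean_length = mean(per$mean_spine_length, na.rm = TRUE)),
            class = "spine_result")
}
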