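#' Simulate a branched reconstruction with spines and analytic ground truth
#'
#' Builds a rooted tree of radially outward-growing dendrites: `n_primary`
#' primary branches leave the soma in random directions; each grows in
#' straight sub-segments with small angular jitter and may bifurcate once.
#' Outward growth keeps the distance-to-soma monotone along every branch,
#' which matches real dendritic trees and keeps sphere crossings
#' well-defined. Ground truth stores the exact total cable length, the
#' sphere-crossing counts at 20 um increments (computed by segment-sphere
#' intersection), and a spine-annotation table for five dendritic segments.
#'
#' @param cfg a [sim_config()] (seed only).
#' @param n_primary number of primary branches.
#' @param branch_len_um mean primary branch length (um).
#' @param step_um sub-segment length (um).
#' @param bifurcate_p probability that a branch bifurcates at mid-length.
#' @param sholl_step radius increment for the recorded crossing counts (um).
#' @param spine_density mean planted spine density (per um) for the spine
#'   table.
#' @return list with `tree` ([morph_tree()]), `spines` (data.frame
#'   segment_id, length_um, spine_id, spine_length_um) and `truth`
#'   (list total_length_um, sholl = data.frame(radius, crossings)).
#' @export
simulate_tree <- function(cfg, n_primary = 5, branch_len_um = 150,
                          step_um = 12, bifurcate_p = 0.5, sholl_step = 20,
                          spine_density = 1.0) {
  .sim_seed(cfg)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 5, parent = -1L)
  next_id <- 2L
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  grow <- function(parent_id, pos, dir, remaining, can_split) {
    while (remaining > 0) {
      seg <- min(step_um, remaining)
      # jitter direction but force outward growth (positive radial component)
      repeat {
        d <- dir + 0.25 * stats::rnorm(3)
        d <- d / sqrt(sum(d^2))
        radial <- pos + 1e-9
        if (sum(d * radial) / sqrt(sum(radial^2)) > 0.3) break
      }
      pos <- pos + seg * d
      dir <- d
      nodes[nrow(nodes) + 1L, ] <<- list(next_id, 3L, pos[1], pos[2], pos[3],
                                         0.5, parent_id)
      parent_id <- next_id
      next_id <<- next_id + 1L
      remaining <- remaining - seg
      if (can_split && remaining > 2 * step_um &&
          stats::runif(1) < bifurcate_p) {
        half <- remaining / 2
        grow(parent_id, pos, dir, half, FALSE)
        remaining <- half
        can_split <- FALSE
      }
    }
    parent_id
  }
  for (b in seq_len(n_primary)) {
    len <- branch_len_um * stats::runif(1, 0.7, 1.3)
    grow(1L, c(0, 0, 0), rand_dir(), len, TRUE)
  }
  tree <- morph_tree(nodes)
  tot <- total_cable_length(tree)
  rmax <- max(sqrt(nodes$x^2 + nodes$y^2 + nodes$z^2))
  radii <- seq(sholl_step, max(sholl_step, ceiling(rmax / sholl_step) *
                                 sholl_step), by = sholl_step)
  segs <- .tree_segments(tree)
  crossings <- vapply(radii, function(r)
    sum(apply(segs, 1L, .segment_sphere_crossings, center = c(0, 0, 0),
              r = r)), numeric(1))
  # five spine-annotated segments of 15-20 um
  seg_len <- stats::runif(5, 15, 20)
  spines <- do.call(rbind, lapply(1:5, function(s) {
    ns <- stats::rpois(1, spine_density * seg_len[s])
    if (ns == 0L) return(NULL)
    data.frame(segment_id = s, length_um = seg_len[s], spine_id = seq_len(ns),
               spine_length_um = stats::runif(ns, 0.5, 2.5))
  }))
  if (is.null(spines))
    spines <- data.frame(segment_id = integer(0), length_um = numeric(0),
                         spine_id = integer(0), spine_length_um = numeric(0))
  segments <- data.frame(segment_id = 1:5, length_um = seg_len)
  list(tree = tree, spines = spines, segments = segments,
       truth = list(total_length_um = tot,
                    sholl = data.frame(radius = radii, crossings = crossings)))
}
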