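# shared fixtures and independent oracles, built in code at test time

# one-to-one greedy matching of detected vs planted event times
match_events <- function(detected, planted, tol_ms = 5) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (t in planted) {
    d <- abs(detected - t)
    j <- which(d < tol_ms & !used)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      hits <- hits + 1L
    }
  }
  list(sensitivity = hits / max(1L, length(planted)),
       fdr = if (length(detected)) 1 - sum(used) / length(detected) else 0)
}

# average_event built directly from an analytic kernel (bypasses detection)
kernel_average_event <- function(amp, tau_rise, tau_decay, fs = 20,
                                 dur_ms = 500, normalize_peak = FALSE,
                                 n_events = 100, condition = "dual") {
  tk <- seq(0, dur_ms, by = 1 / fs)
  structure(list(waveform = -biexp_kernel(tk, amp, tau_rise, tau_decay,
                                          normalize_peak),
                 t_ms = tk, n_events = n_events, sampling_rate = fs,
                 condition = condition),
            class = "average_event")
}

# independent dense-sampling Sholl oracle: walk every segment at fine
# resolution and count sign changes of (distance-to-soma - r)
sholl_oracle <- function(tree, radii, step_um = 0.01) {
  center <- c(0, 0, 0)
  soma <- tree$nodes[tree$nodes$parent == -1, ]
  center <- c(soma$x[1], soma$y[1], soma$z[1])
  segs <- slicephys:::.tree_segments(tree)
  counts <- numeric(length(radii))
  for (s in seq_len(nrow(segs))) {
    p0 <- segs[s, 1:3]; p1 <- segs[s, 4:6]
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    nstep <- max(2L, ceiling(len / step_um))
    tt <- seq(0, 1, length.out = nstep + 1L)
    pts <- cbind(p0[1] + tt * (p1[1] - p0[1]) - center[1],
                 p0[2] + tt * (p1[2] - p0[2]) - center[2],
                 p0[3] + tt * (p1[3] - p0[3]) - center[3])
    rr <- sqrt(rowSums(pts^2))
    for (k in seq_along(radii)) {
      sgn <- sign(rr - radii[k])
      counts[k] <- counts[k] + sum(sgn[-1] * sgn[-length(sgn)] < 0)
    }
  }
  counts
}

# smallest max-abs difference between two waveforms over integer shifts,
# absorbing the +-1 sample onset-detection discretization
best_shift_maxdiff <- function(a, b, shifts = -2:2) {
  m <- max(abs(shifts))
  ia <- seq.int(m + 1L, min(length(a), length(b)) - m)
  min(vapply(shifts, function(s) max(abs(a[ia] - b[ia + s])), numeric(1)))
}

# hand-built trees for geometric base cases
straight_branch_tree <- function(length_um = 90, n_nodes = 10) {
  xs <- seq(0, length_um, length.out = n_nodes + 1L)
  morph_tree(data.frame(id = seq_len(n_nodes + 1L),
                        type = c(1L, rep(3L, n_nodes)),
                        x = xs, y = 0, z = 0, radius = 1,
                        parent = c(-1L, seq_len(n_nodes))))
}

y_tree <- function() {
  # stem along +x to (30,0,0), then two daughters fanning out; both tips
  # lie beyond radius 40 so the 40 um sphere is crossed twice
  morph_tree(data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 30, 80, 80), y = c(0, 0, 30, -30), z = 0, radius = 1,
    parent = c(-1L, 1L, 2L, 2L)))
}
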