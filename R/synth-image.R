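# Synthetic fluorescence stacks with planted puncta / blobs and full ground
# truth. Puncta are anti-aliased discs (per-pixel coverage fraction) on a
# smooth background gradient with Gaussian shot-like noise, so that Otsu
# binarization recovers the planted areas to within pixel rounding.

# per-pixel coverage of a disc (center cx, cy in px, radius r px), supersampled
.disc_image <- function(nx, ny, cx, cy, r, supersample = 4L) {
  x0 <- floor(cx - r - 1); x1 <- ceiling(cx + r + 1)
  y0 <- floor(cy - r - 1); y1 <- ceiling(cy + r + 1)
  xs <- max(1L, x0):min(nx, x1); ys <- max(1L, y0):min(ny, y1)
  out <- matrix(0, nx, ny)
  ss <- (seq_len(supersample) - 0.5) / supersample - 0.5
  for (ix in xs) for (iy in ys) {
    px <- ix + ss; py <- iy + ss
    cov <- outer(px - cx, py - cy, function(a, b) a^2 + b^2) <= r^2
    out[ix, iy] <- mean(cov)
  }
  out
}

#' Simulate a two-channel synaptic puncta stack
#'
#' Plants circular pre- and postsynaptic puncta at known, well-separated
#' centers. A configurable fraction of pairs overlaps fully (planted
#' colocalization); the remaining pairs are offset far enough apart to share
#' no pixels. Extra oversize (> 1.2 um^2) and undersize (< 0.1 um^2) fully
#' overlapping pairs can be planted to exercise the size-exclusion rule.
#' Each punctum spans a block of adjacent z planes so the maximum-intensity
#' projection recovers its full footprint; a smooth background gradient and
#' Gaussian noise are added per plane.
#'
#' @param cfg a [sim_config()] (only its seed is used).
#' @param n_pairs number of planted punctum pairs.
#' @param overlap_fraction fraction of pairs planted as fully overlapping.
#' @param shape_px image size c(nx, ny) in pixels.
#' @param n_planes number of z planes.
#' @param pixel_size um per pixel.
#' @param radius_um punctum radius in um (default gives ~0.5 um^2 area).
#' @param n_oversize,n_undersize extra fully overlapping pairs outside the
#'   0.1-1.2 um^2 inclusion band.
#' @param background peak amplitude of the planted background gradient
#'   (fraction of punctum intensity).
#' @param noise_sd Gaussian per-pixel noise SD (intensity units).
#' @return list with `stack` (an [image_stack()] with channels `pre`,
#'   `post`) and `truth` (data.frame: cx, cy (px), radius_px, area_um2,
#'   colocalized, oversize, undersize).
#' @export
simulate_puncta_stack <- function(cfg, n_pairs = 20, overlap_fraction = 1,
                                  shape_px = c(128L, 128L), n_planes = 6L,
                                  pixel_size = 0.1, radius_um = 0.4,
                                  n_oversize = 0L, n_undersize = 0L,
                                  background = 0.08, noise_sd = 0.01) {
  .sim_seed(cfg)
  nx <- shape_px[1]; ny <- shape_px[2]
  r_px <- radius_um / pixel_size
  r_over <- sqrt(2.0 / pi) / pixel_size       # 2.0 um^2 disc
  r_under <- sqrt(0.05 / pi) / pixel_size     # 0.05 um^2 disc
  n_tot <- n_pairs + n_oversize + n_undersize
  # place centers on a jittered grid with generous separation
  min_sep <- 2 * max(r_px, r_over) + 6
  ngrid <- ceiling(sqrt(n_tot))
  margin <- max(r_over, r_px) + 4
  gx <- seq(margin, nx - margin, length.out = max(ngrid, 2))
  gy <- seq(margin, ny - margin, length.out = max(ngrid, 2))
  grid <- expand.grid(cx = gx, cy = gy)
  if (nrow(grid) < n_tot)
    stop("image too small for the requested number of puncta")
  pick <- sample.int(nrow(grid), n_tot)
  cx <- grid$cx[pick] + stats::runif(n_tot, -1, 1)
  cy <- grid$cy[pick] + stats::runif(n_tot, -1, 1)
  radius <- c(rep(r_px, n_pairs), rep(r_over, n_oversize),
              rep(r_under, n_undersize))
  n_co <- round(overlap_fraction * n_pairs)
  coloc <- c(seq_len(n_pairs) <= n_co, rep(TRUE, n_oversize + n_undersize))
  pre <- matrix(0, nx, ny); post <- matrix(0, nx, ny)
  for (i in seq_len(n_tot)) {
    pre <- pre + .disc_image(nx, ny, cx[i], cy[i], radius[i])
    if (coloc[i]) {
      post <- post + .disc_image(nx, ny, cx[i], cy[i], radius[i])
    } else {
      # offset the partner well clear of every planted punctum
      post <- post + .disc_image(nx, ny, cx[i] + 2 * radius[i] + 4, cy[i],
                                 radius[i])
    }
  }
  mk_stack <- function(img2d) {
    arr <- array(0, dim = c(nx, ny, n_planes))
    zmid <- seq_len(n_planes) > n_planes / 4 &
      seq_len(n_planes) <= ceiling(3 * n_planes / 4)
    bg <- background * outer(seq_len(nx) / nx, seq_len(ny) / ny, "+") / 2
    for (z in seq_len(n_planes)) {
      plane <- bg + if (zmid[z]) 0.8 * img2d else 0
      plane <- plane + stats::rnorm(nx * ny, 0, noise_sd)
      arr[, , z] <- pmin(pmax(plane, 0), 1)
    }
    arr
  }
  truth <- data.frame(cx = cx, cy = cy, radius_px = radius,
                      area_um2 = pi * (radius * pixel_size)^2,
                      colocalized = coloc,
                      oversize = pi * (radius * pixel_size)^2 > 1.2,
                      undersize = pi * (radius * pixel_size)^2 < 0.1)
  list(stack = image_stack(list(pre = mk_stack(pre), post = mk_stack(post)),
                           pixel_size, z_step = 0.25),
       truth = truth)
}

#' Simulate a single-channel volume with planted spherical cells
#'
#' Non-touching bright spheres in a dark volume, for 3D cell counting and
#' volume-fraction analyses. Ground truth records centers, radii and the
#' exact voxelized volume of every planted cell.
#'
#' @param cfg a [sim_config()] (seed only).
#' @param n_cells number of planted spheres.
#' @param shape_px volume size c(nx, ny, nz) in voxels.
#' @param pixel_size lateral um/px.
#' @param z_step axial um/plane.
#' @param radius_um sphere radius in um.
#' @param intensity sphere intensity (background is 0.05).
#' @param noise_sd Gaussian voxel noise SD.
#' @param channel channel name in the returned stack.
#' @return list with `stack` ([image_stack()]) and `truth` (data.frame
#'   cx, cy, cz (voxel), radius_um, volume_um3 of the voxelized sphere).
#' @export
simulate_cell_volume <- function(cfg, n_cells = 5, shape_px = c(64L, 64L, 16L),
                                 pixel_size = 0.5, z_step = 0.5,
                                 radius_um = 3, intensity = 0.9,
                                 noise_sd = 0.02, channel = "cells") {
  .sim_seed(cfg)
  nx <- shape_px[1]; ny <- shape_px[2]; nz <- shape_px[3]
  rx <- radius_um / pixel_size; rz <- radius_um / z_step
  ngrid <- ceiling(sqrt(n_cells))
  gx <- seq(rx + 2, nx - rx - 2, length.out = max(ngrid, 2))
  gy <- seq(rx + 2, ny - rx - 2, length.out = max(ngrid, 2))
  grid <- expand.grid(cx = gx, cy = gy)
  if (nrow(grid) < n_cells) stop("volume too small for requested cell count")
  pick <- sample.int(nrow(grid), n_cells)
  cz <- stats::runif(n_cells, rz + 1, nz - rz - 1)
  arr <- array(0.05, dim = c(nx, ny, nz))
  vol <- numeric(n_cells)
  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  for (i in seq_len(n_cells)) {
    dx2 <- ((xs - grid$cx[pick[i]]) * pixel_size)^2
    dy2 <- ((ys - grid$cy[pick[i]]) * pixel_size)^2
    dz2 <- ((zs - cz[i]) * z_step)^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_um^2
    arr[inside] <- intensity
    vol[i] <- sum(inside) * pixel_size^2 * z_step
  }
  if (noise_sd > 0)
    arr <- pmin(pmax(arr + stats::rnorm(length(arr), 0, noise_sd), 0), 1)
  truth <- data.frame(cx = grid$cx[pick], cy = grid$cy[pick], cz = cz,
                      radius_um = radius_um, volume_um3 = vol)
  ch <- list(arr); names(ch) <- channel
  list(stack = image_stack(ch, pixel_size, z_step), truth = truth)
}
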