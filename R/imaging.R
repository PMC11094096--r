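# Fluorescence image quantification. Standard image operations (median
# filter, Otsu threshold, morphological top-hat, 2D labelling) are delegated
# to EBImage; 3D connected components are implemented here (EBImage labels
# per-plane only).

#' Preprocess one channel of a stack to a background-subtracted projection
#'
#' Per-plane 3x3 median filter (despeckle), maximum-intensity projection
#' over z, then rolling-ball-style background subtraction implemented as a
#' grayscale top-hat with a disc structuring element (default radius 10 px).
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param median_radius median filter radius in px (1 = 3x3).
#' @param ball_radius background structuring-element radius in px; 0 skips
#'   background subtraction.
#' @return 2D numeric matrix (the processed projection).
#' @export
preprocess_channel <- function(stack, channel, median_radius = 1,
                               ball_radius = 10) {
  arr <- .get_channel(stack, channel)
  nz <- dim(arr)[3]
  for (z in seq_len(nz))
    arr[, , z] <- as.matrix(EBImage::medianFilter(
      EBImage::Image(arr[, , z]), median_radius))
  proj <- apply(arr, c(1, 2), max)
  if (ball_radius > 0) {
    brush <- EBImage::makeBrush(2L * ball_radius + 1L, shape = "disc")
    proj <- as.matrix(EBImage::whiteTopHat(EBImage::Image(proj), brush))
  }
  proj
}

# single global Otsu threshold over all voxels (EBImage::otsu is per-frame
# on multi-plane images, so the array is flattened to one frame first)
.otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(Inf)
  EBImage::otsu(EBImage::Image(matrix(as.numeric(x), ncol = 1L)),
                range = rng)
}

.otsu_mask <- function(img) {
  thr <- .otsu_threshold(img)
  img > thr
}

#' Count colocalized pre/postsynaptic puncta
#'
#' Each preprocessed channel is binarized by Otsu's threshold; the additive
#' mask is their pixel-wise AND (`method = "sum"` instead thresholds the sum
#' of the two binary masks at 2, which is equivalent, or of intensities —
#' kept as an explicit option). 8-connected components of the mask are
#' candidate synapses; components outside the inclusive size band
#' \[`min_area`, `max_area`\] um^2 are excluded (objects strictly above
#' 1.2 um^2 or strictly below 0.1 um^2 are unlikely to be synapses).
#'
#' @param pre_img,post_img preprocessed 2D matrices (see
#'   [preprocess_channel()]), same shape.
#' @param pixel_size um/px.
#' @param min_area,max_area inclusive component-area band, um^2.
#' @param method `"and"` (AND of per-channel Otsu masks) or `"sum"`
#'   (Otsu on the summed intensities).
#' @return An object of class `"puncta_result"`: list with `n_colocalized`,
#'   `density_per_100um2`, `mean_object_area`, `area_covered` (um^2),
#'   `objects` (data.frame cx, cy px, area_um2), `field_area_um2`.
#' @export
count_colocalized_synapses <- function(pre_img, post_img, pixel_size,
                                       min_area = 0.1, max_area = 1.2,
                                       method = c("and", "sum")) {
  method <- match.arg(method)
  if (!all(dim(pre_img) == dim(post_img)))
    stop("pre and post images must have the same shape")
  mask <- if (method == "and") {
    .otsu_mask(pre_img) & .otsu_mask(post_img)
  } else {
    .otsu_mask(pre_img / max(pre_img, 1e-12) +
                 post_img / max(post_img, 1e-12))
  }
  px_area <- pixel_size^2
  field_area <- length(mask) * px_area
  if (!any(mask)) {
    return(structure(list(n_colocalized = 0L, density_per_100um2 = 0,
                          mean_object_area = NA_real_, area_covered = 0,
                          objects = data.frame(cx = numeric(0),
                                               cy = numeric(0),
                                               area_um2 = numeric(0)),
                          field_area_um2 = field_area),
                     class = "puncta_result"))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labv <- as.integer(as.matrix(lab))
  areas_px <- tabulate(labv)
  areas <- areas_px * px_area
  keep <- which(areas >= min_area & areas <= max_area)
  idx <- which(matrix(labv, nrow(mask)) > 0, arr.ind = TRUE)
  lv <- labv[labv > 0]
  objs <- do.call(rbind, lapply(keep, function(k) {
    pts <- idx[lv == k, , drop = FALSE]
    data.frame(cx = mean(pts[, 1]), cy = mean(pts[, 2]), area_um2 = areas[k])
  }))
  if (is.null(objs))
    objs <- data.frame(cx = numeric(0), cy = numeric(0),
                       area_um2 = numeric(0))
  structure(list(n_colocalized = length(keep),
                 density_per_100um2 = length(keep) / field_area * 100,
                 mean_object_area = if (length(keep)) mean(objs$area_um2)
                 else NA_real_,
                 area_covered = sum(objs$area_um2),
                 objects = objs, field_area_um2 = field_area),
            class = "puncta_result")
}

#' @export
print.puncta_result <- function(x, ...) {
  cat(sprintf("<puncta_result> %d colocalized puncta, %.2f / 100 um^2\n",
              x$n_colocalized, x$density_per_100um2))
  invisible(x)
}

#' Area coverage and mean intensity within an Otsu mask
#'
#' Percentage of the field covered by the Otsu-thresholded signal and the
#' mean intensity of the original (pre-binarization) image within that mask
#' — the standard glial coverage / intensity readout.
#'
#' @param img preprocessed 2D matrix.
#' @param pixel_size um/px.
#' @return list with `percent_area`, `mean_intensity_in_mask`,
#'   `mask_area_um2`.
#' @export
coverage_intensity <- function(img, pixel_size = 1) {
  mask <- .otsu_mask(img)
  list(percent_area = 100 * mean(mask),
       mean_intensity_in_mask = if (any(mask)) mean(img[mask]) else NA_real_,
       mask_area_um2 = sum(mask) * pixel_size^2)
}

#' Ramification index of a binary cell mask
#'
#' Perimeter-to-area ratio normalized by that of a circle of equal area:
#' \deqn{RI = \frac{P/A}{2\sqrt{\pi A}/A} = \frac{P}{2\sqrt{\pi A}}.}
#' The boundary length is measured on the sub-pixel 0.5-level contour of
#' the lightly smoothed mask (Gaussian sigma 1 px), which is unbiased for
#' smooth shapes (a rasterized disc gives RI ~ 1) while preserving straight
#' edges. RI = 1 for a circle; larger values indicate more ramified shapes.
#'
#' @param mask logical/0-1 matrix.
#' @param pixel_size um/px (cancels in the index; kept for reported P and A).
#' @return list with `ri`, `perimeter_um`, `area_um2`.
#' @export
ramification_index <- function(mask, pixel_size = 1) {
  mask <- mask * 1
  if (!any(mask > 0)) stop("empty mask")
  P <- .mask_perimeter(mask) * pixel_size
  A <- sum(mask > 0) * pixel_size^2
  list(ri = P / (2 * sqrt(pi * A)), perimeter_um = P, area_um2 = A)
}

# boundary length of a binary mask: Gaussian-smoothed marching-squares
# contour at level 0.5 (sub-pixel, low-bias for both smooth and straight
# boundaries)
.mask_perimeter <- function(mask, sigma = 1) {
  pad <- 4L
  m <- matrix(0, nrow(mask) + 2 * pad, ncol(mask) + 2 * pad)
  m[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask
  k <- stats::dnorm(-3:3, sd = sigma)
  k <- k / sum(k)
  m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  m <- t(apply(m, 1, function(row) stats::filter(row, k, circular = TRUE)))
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (!length(cl)) return(0)
  sum(vapply(cl, function(ct)
    sum(sqrt(diff(ct$x)^2 + diff(ct$y)^2)), numeric(1)))
}

# 26-connected components of a 3D logical array; returns integer label array
.label_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  # neighbor offsets (26-connectivity) as linear index shifts with bounds
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- ai + offs[o, ]
        if (any(p < 1L) || any(p > d)) next
        li <- p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

#' Count cells in a 3D stack
#'
#' Otsu threshold on the full volume, 26-connected components, components
#' of at least `min_volume_um3` retained. Touching cells merged by a voxel
#' bridge count as one (no watershed splitting; documented limitation).
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param min_volume_um3 minimum object volume, um^3.
#' @return list with `n_cells`, `cells_per_mm3`, `volumes_um3`,
#'   `field_volume_mm3`.
#' @export
count_cells_3d <- function(stack, channel, min_volume_um3 = 10) {
  arr <- .get_channel(stack, channel)
  if (diff(range(arr)) == 0) {
    vol_mm3 <- prod(dim(arr)) * stack$pixel_size_xy^2 * stack$z_step / 1e9
    return(list(n_cells = 0L, cells_per_mm3 = 0, volumes_um3 = numeric(0),
                field_volume_mm3 = vol_mm3))
  }
  lab <- .label_3d(arr > .otsu_threshold(arr))
  voxel_um3 <- stack$pixel_size_xy^2 * stack$z_step
  vols <- tabulate(lab[lab > 0]) * voxel_um3
  vols <- vols[vols >= min_volume_um3]
  vol_mm3 <- prod(dim(arr)) * voxel_um3 / 1e9
  list(n_cells = length(vols), cells_per_mm3 = length(vols) / vol_mm3,
       volumes_um3 = vols, field_volume_mm3 = vol_mm3)
}

#' Synaptic-marker volume fraction within a glial mask
#'
#' Thresholds the glial channel at a configured (manual) threshold,
#' binarizes the puncta channel within the glial mask (Otsu within the mask
#' by default, or a manual threshold), and reports the puncta volume inside
#' the mask as a percentage of the glial mask volume. Group means can be
#' normalized to a control group with [normalize_to_control()].
#'
#' @param stack an [image_stack()].
#' @param glia_ch,puncta_ch channel names.
#' @param glia_threshold manual intensity threshold for the glial channel.
#' @param puncta_threshold manual threshold for the puncta channel; `NULL`
#'   uses Otsu over the whole puncta channel.
#' @return list with `volume_fraction_pct`, `glia_volume_um3`,
#'   `puncta_in_glia_um3`.
#' @export
astro_uptake <- function(stack, glia_ch, puncta_ch, glia_threshold,
                         puncta_threshold = NULL) {
  glia <- .get_channel(stack, glia_ch)
  pun <- .get_channel(stack, puncta_ch)
  gmask <- glia >= glia_threshold
  if (!any(gmask)) stop("empty glial mask at the configured threshold")
  pthr <- if (is.null(puncta_threshold)) .otsu_threshold(pun)
  else puncta_threshold
  pmask <- pun >= pthr & gmask
  voxel_um3 <- stack$pixel_size_xy^2 * stack$z_step
  list(volume_fraction_pct = 100 * sum(pmask) / sum(gmask),
       glia_volume_um3 = sum(gmask) * voxel_um3,
       puncta_in_glia_um3 = sum(pmask) * voxel_um3)
}

#' Normalize per-field values to a control group's mean
#'
#' @param values numeric vector of per-field measurements.
#' @param group group labels.
#' @param control control group label.
#' @return values expressed relative to the control group mean (control
#'   mean = 1).
#' @export
normalize_to_control <- function(values, group, control) {
  if (!control %in% group) stop("control group not present")
  ctrl <- mean(values[group == control])
  if (ctrl == 0) stop("control group mean is zero")
  values / ctrl
}
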