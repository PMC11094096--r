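test_that("channel preprocessing removes speckle and background", {
  # constant image: nothing survives background subtraction
  st <- image_stack(list(a = array(0.5, c(32, 32, 2))), 0.1)
  expect_true(all(abs(preprocess_channel(st, "a")) < 1e-6))
  # single bright pixel is removed by the median filter
  sp <- array(0, c(32, 32, 1)); sp[16, 16, 1] <- 1
  st2 <- image_stack(list(a = sp), 0.1)
  expect_lt(max(preprocess_channel(st2, "a", ball_radius = 0)), 1e-6)
  # a punctum on a linear gradient keeps its peak within 10%
  nx <- 64
  grad <- outer(seq(0, 0.3, length.out = nx), rep(1, nx))
  pun <- slicephys:::.disc_image(nx, nx, 32, 32, 4) * 0.6
  st3 <- image_stack(list(a = array(grad + pun, c(nx, nx, 1))), 0.1)
  out <- preprocess_channel(st3, "a")
  expect_equal(max(out[24:40, 24:40]), 0.6, tolerance = 0.1)
  expect_error(preprocess_channel(st3, "missing"), "unknown channel")
})

test_that("colocalization counting recovers planted counts with size exclusion", {
  cfg <- sim_config(seed = 30)
  ps <- simulate_puncta_stack(cfg, n_pairs = 20, overlap_fraction = 1,
                              n_oversize = 1, n_undersize = 1)
  pre <- preprocess_channel(ps$stack, "pre")
  post <- preprocess_channel(ps$stack, "post")
  res <- count_colocalized_synapses(pre, post, pixel_size = 0.1)
  expect_equal(res$n_colocalized, 20L)
  expect_true(all(res$objects$area_um2 >= 0.1 & res$objects$area_um2 <= 1.2))
  expect_equal(res$density_per_100um2,
               20 / res$field_area_um2 * 100, tolerance = 1e-9)
  # zero overlap: zero colocalization (valid empty result)
  ps0 <- simulate_puncta_stack(sim_config(seed = 31), n_pairs = 10,
                               overlap_fraction = 0)
  r0 <- count_colocalized_synapses(preprocess_channel(ps0$stack, "pre"),
                                   preprocess_channel(ps0$stack, "post"),
                                   0.1)
  expect_equal(r0$n_colocalized, 0L)
})

test_that("AND-mask colocalization is idempotent on a self-pair", {
  cfg <- sim_config(seed = 32)
  ps <- simulate_puncta_stack(cfg, n_pairs = 12, overlap_fraction = 1)
  pre <- preprocess_channel(ps$stack, "pre")
  self_pair <- count_colocalized_synapses(pre, pre, 0.1)
  expect_equal(self_pair$n_colocalized, 12L)
})

test_that("coverage and in-mask intensity follow their definitions", {
  img <- matrix(0, 100, 100)
  img[1:50, ] <- 100
  cov <- coverage_intensity(img)
  expect_equal(cov$percent_area, 50)
  expect_equal(cov$mean_intensity_in_mask, 100)
  # planted blobs covering 12.5% of the field
  img2 <- matrix(0, 80, 80)
  img2[1:40, 1:20] <- 1        # 800 of 6400 px
  cov2 <- coverage_intensity(img2)
  expect_equal(cov2$percent_area, 12.5, tolerance = 0.01)
})

test_that("ramification index is calibrated on disk and square", {
  n <- 121
  xy <- expand.grid(1:n, 1:n)
  disk <- matrix((xy[, 1] - 61)^2 + (xy[, 2] - 61)^2 <= 50^2, n, n)
  expect_equal(ramification_index(disk)$ri, 1, tolerance = 0.03)
  sq <- matrix(0, 120, 120); sq[11:90, 11:90] <- 1
  expect_equal(ramification_index(sq)$ri, 2 / sqrt(pi), tolerance = 0.03)
  # a ramified star exceeds its filled convex-hull disk
  ang <- atan2(xy[, 2] - 61, xy[, 1] - 61)
  rr <- sqrt((xy[, 1] - 61)^2 + (xy[, 2] - 61)^2)
  star <- matrix(rr <= 25 + 20 * cos(6 * ang), n, n)
  expect_gt(ramification_index(star)$ri, ramification_index(disk)$ri)
  expect_error(ramification_index(matrix(0, 10, 10)), "empty mask")
})

test_that("3D cell counting uses 26-connectivity and volume exclusion", {
  cv <- simulate_cell_volume(sim_config(seed = 33), n_cells = 5)
  cc <- count_cells_3d(cv$stack, "cells", min_volume_um3 = 5)
  expect_equal(cc$n_cells, 5L)
  expect_equal(sort(cc$volumes_um3), sort(cv$truth$volume_um3),
               tolerance = 0.05)
  # empty stack
  empty <- image_stack(list(cells = array(0, c(16, 16, 4))), 0.5, 0.5)
  expect_equal(count_cells_3d(empty, "cells")$n_cells, 0L)
  # two blobs joined by a one-voxel bridge merge into one component
  arr <- array(0, c(30, 12, 6))
  arr[3:9, 4:9, 2:5] <- 1
  arr[20:26, 4:9, 2:5] <- 1
  arr[10:19, 6, 3] <- 1
  st <- image_stack(list(cells = arr), 0.5, 0.5)
  expect_equal(count_cells_3d(st, "cells", min_volume_um3 = 1)$n_cells, 1L)
})

test_that("astrocytic uptake reports exact volume fractions", {
  glia <- array(0, c(24, 24, 6)); glia[5:20, 5:20, 2:5] <- 1
  pun <- array(0, c(24, 24, 6)); pun[8:11, 8:11, 3:4] <- 1
  st <- image_stack(list(glia = glia, puncta = pun), 0.25, 0.25)
  up <- astro_uptake(st, "glia", "puncta", glia_threshold = 0.5,
                     puncta_threshold = 0.5)
  expect_equal(up$volume_fraction_pct, 100 * sum(pun) / sum(glia))
  # all puncta outside the mask: zero
  pun2 <- array(0, c(24, 24, 6)); pun2[1:3, 1:3, 1] <- 1
  st2 <- image_stack(list(glia = glia, puncta = pun2), 0.25, 0.25)
  expect_equal(astro_uptake(st2, "glia", "puncta", 0.5, 0.5)$volume_fraction_pct,
               0)
  expect_error(astro_uptake(st2, "glia", "puncta", 2), "empty glial mask")
  expect_equal(normalize_to_control(c(2, 4, 1), c("a", "a", "b"), "a"),
               c(2, 4, 1) / 3)
})

test_that("areas scale with the square of the pixel size", {
  cfg <- sim_config(seed = 34)
  ps <- simulate_puncta_stack(cfg, n_pairs = 8, overlap_fraction = 1)
  pre <- preprocess_channel(ps$stack, "pre")
  post <- preprocess_channel(ps$stack, "post")
  r1 <- count_colocalized_synapses(pre, post, 0.1)
  r2 <- count_colocalized_synapses(pre, post, 0.2,
                                   min_area = 0.4, max_area = 4.8)
  expect_equal(r2$objects$area_um2, 4 * r1$objects$area_um2)
})

test_that("Otsu separates a clean bimodal histogram", {
  set.seed(2)
  img <- matrix(c(rnorm(5000, 0.2, 0.02), rnorm(5000, 0.8, 0.02)), 100, 100)
  mask <- slicephys:::.otsu_mask(img)
  expect_equal(mean(mask), 0.5, tolerance = 0.01)
  expect_true(all(img[mask] > 0.5) && all(img[!mask] < 0.5))
})
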