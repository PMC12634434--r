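cube_stack <- function(val = 100, dims = c(12, 12, 12), vs = c(1, 1, 1)) {
  arr <- array(0, dim = dims)
  arr[2:11, 2:11, 2:11] <- val
  image_stack(arr, vs)
}

test_that("region segmentation labels components above the threshold", {
  uni <- image_stack(array(100, dim = c(6, 6, 4)), c(1, 1, 2))
  lab <- segment_region(uni, "absolute", threshold = 50)
  expect_equal(n_labels(lab), 1)
  expect_true(all(lab$labels == 1L))

  arr <- array(0, dim = c(20, 10, 6))
  arr[2:4, 2:4, 2:3] <- 200
  arr[12:15, 5:8, 4:5] <- 150
  two <- segment_region(image_stack(arr, c(1, 1, 2)), "absolute", 100)
  expect_equal(n_labels(two), 2)

  empty <- segment_region(image_stack(array(0, dim = c(8, 8, 3)), c(1, 1, 2)),
                          "absolute", 10)
  expect_equal(n_labels(empty), 0)

  # min-volume filter removes single-voxel specks by default
  speck <- array(0, dim = c(10, 10, 3))
  speck[5, 5, 2] <- 500
  expect_equal(n_labels(segment_region(image_stack(speck, c(1, 1, 2)),
                                       "absolute", 100)), 0)
  expect_equal(n_labels(segment_region(image_stack(speck, c(1, 1, 2)),
                                       "absolute", 100, min_volume = 1)), 1)

  expect_error(segment_region(uni, "absolute"), "threshold")
})

test_that("rendered network tube is recovered with Dice >= 0.9 at SNR 10", {
  cfg <- sim_config_desk(gel_xy = c(250, 250), gel_depth = 150,
                         network_depth_fraction = 0.5, seed = 21)
  net <- generate_network_geometry(cfg, n_segments = 2, radius_um = 20)
  rn <- render_network(net, extent_um = c(250, 250, 150),
                       voxel_size = c(2, 2, 8), snr = 10, seed = 5)
  lab <- segment_region(rn$stack, "absolute", threshold = 500, min_volume = 10)
  seg <- lab$labels > 0
  dice <- 2 * sum(seg & rn$mask) / (sum(seg) + sum(rn$mask))
  expect_gte(dice, 0.9)
})

test_that("morphometry matches analytic cube and tube values", {
  lab1 <- segment_region(cube_stack(vs = c(1, 1, 1)), "absolute", 50)
  m1 <- measure_volume_surface(lab1)
  expect_equal(m1$total_volume_um3, 1000)
  expect_equal(m1$total_surface_um2, 600)

  lab2 <- segment_region(cube_stack(vs = c(1, 1, 2)), "absolute", 50)
  m2 <- measure_volume_surface(lab2)
  expect_equal(m2$total_volume_um3, 2000)
  # face-area rule: 2 z-faces of 10x10 voxels at dx*dy=1, 4 side faces at 2
  expect_equal(m2$total_surface_um2, 2 * 100 * 1 + 4 * 100 * 2)

  # straight tube r=20, L=400: volume within 10% of pi r^2 L
  straight <- tibble::tibble(segment_id = 1, vertex = 1:2,
                             x_um = c(20, 420), y_um = 60, z_um = 60,
                             radius_um = 20)
  rn <- render_network(straight, extent_um = c(440, 120, 120),
                       voxel_size = c(2, 2, 4), snr = Inf)
  lab <- segment_region(rn$stack, "absolute", 500)
  m <- measure_volume_surface(lab)
  expect_lt(abs(m$total_volume_um3 - pi * 20^2 * 400) / (pi * 20^2 * 400), 0.1)

  empty <- label_volume(array(0L, dim = c(4, 4, 2)), c(1, 1, 1))
  m0 <- measure_volume_surface(empty)
  expect_equal(m0$total_volume_um3, 0)
  expect_equal(nrow(m0$per_label), 0)
})

test_that("volume is exactly voxel count times voxel volume", {
  set.seed(31)
  arr <- array(as.numeric(runif(30 * 20 * 8) > 0.7) * 200, dim = c(30, 20, 8))
  lab <- segment_region(image_stack(arr, c(1.3, 1.3, 7.8)), "absolute", 100,
                        min_volume = 1)
  m <- measure_volume_surface(lab)
  expect_equal(m$total_volume_um3, sum(arr > 0) * 1.3 * 1.3 * 7.8)
  expect_equal(sum(m$per_label$n_voxels), sum(arr > 0))
})

test_that("centroids follow the voxel-center convention", {
  one <- array(0, dim = c(3, 3, 3))
  one[1, 1, 1] <- 10
  lab <- segment_region(image_stack(one, c(1, 1, 1)), "absolute", 5,
                        min_volume = 1)
  pos <- extract_positions(lab)
  expect_equal(c(pos$x_um, pos$y_um, pos$z_um), c(0.5, 0.5, 0.5))

  labc <- segment_region(cube_stack(vs = c(1, 1, 2)), "absolute", 50)
  posc <- extract_positions(labc)
  expect_equal(c(posc$x_um, posc$y_um, posc$z_um), c(6, 6, 12))

  # asymmetric blob: centroid equals brute-force mean of voxel centers
  set.seed(7)
  blob <- array(0, dim = c(15, 12, 6))
  blob[3:9, 2:8, 2:4] <- as.numeric(runif(7 * 7 * 3) > 0.4) * 100
  vs <- c(1.5, 2, 5)
  lab <- segment_region(image_stack(blob, vs), "absolute", 50, min_volume = 1)
  pos <- extract_positions(lab)
  idx <- which(blob > 0, arr.ind = TRUE)
  ctr <- colMeans(sweep(idx - 0.5, 2, vs, "*"))
  agg <- colSums(pos[, c("x_um", "y_um", "z_um")] * pos$n_voxels) / sum(pos$n_voxels)
  expect_equal(unname(agg), unname(ctr), tolerance = 1e-12)
})

test_that("whole-voxel translation shifts centroids by the exact offset", {
  set.seed(13)
  arr <- array(0, dim = c(24, 24, 10))
  arr[4:8, 5:9, 2:4] <- 150
  arr[14:17, 12:16, 5:7] <- 220
  vs <- c(1.3, 1.3, 7.8)
  shift <- c(3L, 2L, 1L)
  arr2 <- array(0, dim = dim(arr))
  arr2[(1 + shift[1]):24, (1 + shift[2]):24, (1 + shift[3]):10] <-
    arr[1:(24 - shift[1]), 1:(24 - shift[2]), 1:(10 - shift[3])]
  p1 <- extract_positions(segment_region(image_stack(arr, vs), "absolute", 100))
  p2 <- extract_positions(segment_region(image_stack(arr2, vs), "absolute", 100))
  expect_equal(p2$x_um - p1$x_um, rep(shift[1] * vs[1], 2))
  expect_equal(p2$y_um - p1$y_um, rep(shift[2] * vs[2], 2))
  expect_equal(p2$z_um - p1$z_um, rep(shift[3] * vs[3], 2))
})

test_that("nucleus detection finds a single rendered spot to sub-voxel accuracy", {
  vs <- c(2, 2, 8)
  truth <- tibble::tibble(cell_id = 1, x_um = 41, y_um = 57, z_um = 44)
  st <- render_cells(truth, extent_um = c(100, 100, 96), voxel_size = vs,
                     radius_um = 6, snr = 20, seed = 3)
  res <- segment_nuclei(st, expected_radius_um = 6, threshold = 150)
  expect_equal(nrow(res$centroids), 1)
  expect_lt(abs(res$centroids$x_um - 41), vs[1])
  expect_lt(abs(res$centroids$y_um - 57), vs[2])
  expect_lt(abs(res$centroids$z_um - 44), vs[3])
})

test_that("two spots below the minimum separation merge into one detection", {
  vs <- c(2, 2, 8)
  r <- 8
  pair <- tibble::tibble(cell_id = 1:2, x_um = c(50, 50 + 0.5 * r),
                         y_um = 50, z_um = 40)
  st <- render_cells(pair, extent_um = c(100, 100, 80), voxel_size = vs,
                     radius_um = r, snr = Inf)
  res <- segment_nuclei(st, expected_radius_um = r, threshold = 150)
  expect_equal(nrow(res$centroids), 1)

  far <- tibble::tibble(cell_id = 1:2, x_um = c(30, 70), y_um = 50, z_um = 40)
  st2 <- render_cells(far, extent_um = c(100, 100, 80), voxel_size = vs,
                      radius_um = r, snr = Inf)
  expect_equal(nrow(segment_nuclei(st2, r, threshold = 150)$centroids), 2)

  blank <- image_stack(array(0, dim = c(10, 10, 4)), vs)
  expect_equal(nrow(segment_nuclei(blank, r, threshold = 50)$centroids), 0)
})

test_that("segmentation round-trip recovers a rendered cell field", {
  extent <- c(300, 300, 120)
  vs <- c(2, 2, 8)
  truth <- spread_cells(200, extent, min_sep = 16, seed = 17)
  st <- render_cells(truth, extent_um = extent, voxel_size = vs,
                     radius_um = 6, snr = 10, seed = 17)
  res <- segment_nuclei(st, expected_radius_um = 6, threshold = 200)
  found <- res$centroids
  expect_lt(abs(nrow(found) - 200), 0.02 * 200 + 1)
  nn <- FNN::get.knnx(as.matrix(found[, c("x_um", "y_um", "z_um")]),
                      as.matrix(truth[, c("x_um", "y_um", "z_um")]), k = 1)
  matched <- nn$nn.dist[, 1] <= 6
  expect_gte(mean(matched), 0.95)
  expect_lte(median(nn$nn.dist[matched, 1]), vs[3])
})
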