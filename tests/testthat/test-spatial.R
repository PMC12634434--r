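test_that("centroid distances match the 3-4-5 case and exclude self", {
  q <- tibble::tibble(cell_id = 1, x_um = 0, y_um = 0, z_um = 0)
  t1 <- tibble::tibble(cell_id = 2, x_um = 3, y_um = 4, z_um = 0)
  expect_equal(min_centroid_distances(q, t1)$distance_um, 5)

  both <- tibble::tibble(cell_id = 1:2, x_um = c(0, 7), y_um = 0, z_um = 0)
  res <- min_centroid_distances(both, both)
  expect_equal(res$distance_um, c(7, 7))
  expect_false(any(res$distance_um == 0))

  expect_warning(res0 <- min_centroid_distances(q, both[0, ]), "empty")
  expect_true(is.na(res0$distance_um))
  expect_equal(res0$flag, "empty_target")
})

test_that("kd-tree distances agree exactly with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    m <- sample(20:120, 1)
    q <- random_cells(n)
    t <- random_cells(m, ids = 1000 + seq_len(m))
    expect_equal(min_centroid_distances(q, t)$distance_um,
                 brute_min_distances(q, t, exclude_same_id = FALSE))
    # self-overlapping query/target with shared ids
    res <- min_centroid_distances(q, q)
    expect_equal(res$distance_um, brute_min_distances(q, q))
  }
})

test_that("distance records are invariant under rigid motion", {
  set.seed(5)
  cells <- random_cells(90)
  cells$cell_type <- rep(c("ALL", "MSC", "EC"), each = 30)
  base <- distance_records(cells)

  theta <- 0.7; phi <- 0.3
  Rz <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(phi), sin(phi), 0, -sin(phi), cos(phi)), 3, 3)
  xyz <- as.matrix(cells[, c("x_um", "y_um", "z_um")]) %*% (Rz %*% Rx)
  moved <- cells
  moved$x_um <- xyz[, 1] + 12.3
  moved$y_um <- xyz[, 2] - 4.5
  moved$z_um <- xyz[, 3] + 100
  rot <- distance_records(moved)
  expect_equal(rot$d_all, base$d_all, tolerance = 1e-9)
  expect_equal(rot$d_msc, base$d_msc, tolerance = 1e-9)
  expect_equal(rot$d_ec, base$d_ec, tolerance = 1e-9)
})

test_that("border distances follow the exposed-face convention", {
  # two unit voxels 10 voxels apart along x, 1 um voxels: face gap = 9 um
  arr_q <- array(0L, dim = c(20, 5, 5)); arr_q[3, 3, 3] <- 1L
  arr_t <- array(0L, dim = c(20, 5, 5)); arr_t[13, 3, 3] <- 1L
  q <- label_volume(arr_q, c(1, 1, 1))
  t <- label_volume(arr_t, c(1, 1, 1))
  expect_equal(min_border_distances(q, t)$distance_um, 9)

  # touching voxels: face centers coincide
  arr_t2 <- array(0L, dim = c(20, 5, 5)); arr_t2[4, 3, 3] <- 1L
  expect_equal(min_border_distances(q, label_volume(arr_t2, c(1, 1, 1)))$distance_um, 0)

  # overlap: distance 0 exactly
  expect_equal(min_border_distances(q, q)$distance_um, 0)

  expect_warning(
    und <- min_border_distances(q, label_volume(array(0L, dim = c(20, 5, 5)),
                                                c(1, 1, 1))),
    "empty"
  )
  expect_true(is.na(und$distance_um))
})

test_that("border distances equal exhaustive surface search on random blobs", {
  set.seed(23)
  vs <- c(1.5, 1.5, 4)
  for (rep in 1:5) {
    mk <- function() {
      arr <- array(0L, dim = c(18, 18, 8))
      cx <- sample(4:14, 1); cy <- sample(4:14, 1); cz <- sample(3:6, 1)
      for (v in seq_len(30)) {
        arr[max(1, min(18, cx + sample(-2:2, 1))),
            max(1, min(18, cy + sample(-2:2, 1))),
            max(1, min(8, cz + sample(-1:1, 1)))] <- 1L
      }
      arr
    }
    a <- mk(); b <- mk()
    b[a > 0] <- 0L  # keep them disjoint for a clean oracle
    if (!any(b > 0)) next
    qv <- label_volume(a, vs); tv <- label_volume(b, vs)
    got <- min_border_distances(qv, tv)$distance_um
    bp <- function(lv) as.matrix(hydroniche:::border_points(lv)[, c("x_um", "y_um", "z_um")])
    oracle <- brute_set_distance(bp(qv), bp(tv))
    overlap <- any(a > 0 & b > 0)
    expect_equal(got, if (overlap) 0 else oracle)
  }
})

test_that("proximity fraction uses strict inequality and is monotone in threshold", {
  expect_equal(proximity_fraction(c(5, 9.9, 10.0, 15), 10), 0.5)
  expect_equal(proximity_fraction(rep(0, 4), 10), 1)
  expect_warning(expect_true(is.na(proximity_fraction(numeric(0)))))
  set.seed(2)
  d <- runif(200, 0, 40)
  fr <- vapply(c(5, 10, 20, 40), function(th) proximity_fraction(d, th),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("bin-centered histogram follows the half-open convention", {
  h <- distance_histogram(c(2.4, 2.6, 7.5), 5)
  expect_equal(h$bin_center, c(0, 5, 10))
  expect_equal(h$count, c(1, 1, 1))
  expect_equal(nrow(distance_histogram(numeric(0), 5)), 0)
  set.seed(3)
  x <- rexp(500, 0.1)
  expect_equal(sum(distance_histogram(x, 2)$count), 500)
  expect_error(distance_histogram(c(-1, 2), 5), "negative")
})

test_that("z profile normalizes per timepoint and summarizes migration", {
  static <- tidyr::expand_grid(cell = 1:40, t_min = c(0, 600, 1800))
  set.seed(4)
  depth <- runif(40, 10, 200)
  static$z_um <- depth[static$cell]
  zp <- z_profile(static)
  expect_equal(zp$delta_median_um, 0)
  expect_equal(zp$sd_t0_um, zp$sd_tend_um)
  norm_med <- tapply(zp$normalized$z_norm_um, zp$normalized$t_min, median)
  expect_true(all(abs(norm_med) < 1e-12))

  shifted <- static
  shifted$z_um[shifted$t_min == 1800] <- shifted$z_um[shifted$t_min == 1800] + 30
  expect_equal(z_profile(shifted)$delta_median_um, 30)

  expect_error(z_profile(static[static$t_min == 0, ]), "2 timepoints")
})

test_that("co-culture drift spreads the depth distribution (sign test over seeds)", {
  grows <- vapply(1:10, function(s) {
    cfg <- sim_config_desk(n_all = 120, n_msc = 40, n_ec = 40,
                           gel_xy = c(400, 400), n_steps = 60,
                           stromal_affinity = 3, aggregation_strength = 1,
                           seed = s)
    obs <- simulate_culture(cfg, mode = "co")
    zp <- z_profile(dplyr::filter(obs, cell_type == "ALL"))
    zp$sd_tend_um > zp$sd_t0_um
  }, logical(1))
  expect_gte(sum(grows), 9)
})

test_that("migration percentages reference the shallowest leukemic cell", {
  cells <- tibble::tibble(
    cell_type = c("ALL", "ALL", "ALL", "EC"),
    z_um = c(20, 180, 100, 120)
  )
  mig <- migration_percent(cells, gel_depth_um = 400)
  expect_equal(mig$migration_pct[1], 0)
  expect_equal(mig$migration_pct[2], 40)
  expect_equal(attr(mig, "z_ref_um"), 20)
  expect_error(migration_percent(dplyr::filter(cells, cell_type == "EC"), 400),
               "no ALL")
})

test_that("network contact fraction counts cells within the depth band", {
  expect_equal(network_contact_fraction(rep(0, 10), 40, 10), 0)
  expect_equal(network_contact_fraction(c(30, 35, 50, 10, 20, 25), 40, 10), 0.5)
  expect_warning(expect_true(is.na(network_contact_fraction(numeric(0)))))
})

test_that("mono-cultures show no network contact, attracted co-cultures do", {
  res <- vapply(1:10, function(s) {
    base <- list(n_all = 100, n_msc = 1, n_ec = 40, gel_xy = c(300, 300),
                 gel_depth = 400, n_steps = 200,
                 diffusion_sigma = c(ALL = 3, MSC = 0.2, EC = 0.8),
                 aggregation_strength = 0, seed = s)
    co <- simulate_culture(do.call(sim_config_desk,
                                   c(base, stromal_affinity = 8)), mode = "co")
    mono <- simulate_culture(do.call(sim_config_desk,
                                     c(base, stromal_affinity = 0)),
                             mode = "mono")
    cf <- function(obs) {
      fin <- dplyr::filter(obs, t_min == max(t_min))
      mig <- migration_percent(fin, 400)
      network_contact_fraction(mig$migration_pct[mig$cell_type == "ALL"], 40, 10)
    }
    c(co = cf(co), mono = cf(mono))
  }, numeric(2))
  expect_gte(sum(res["co", ] > res["mono", ]), 9)
  expect_lt(mean(res["mono", ]), 0.05)
  expect_gt(mean(res["co", ]), 0.2)
})

test_that("B-like cohorts sit closer to MSCs than T-like cohorts", {
  closer <- vapply(1:10, function(s) {
    base <- list(n_all = 100, n_msc = 60, n_ec = 40, gel_xy = c(400, 400),
                 n_steps = 60, aggregation_strength = 1, seed = s)
    b_like <- simulate_culture(do.call(sim_config_desk,
                                       c(base, stromal_affinity = 4)),
                               mode = "co")
    t_like <- simulate_culture(do.call(sim_config_desk,
                                       c(base, stromal_affinity = 0.5)),
                               mode = "co")
    med_dmsc <- function(obs) {
      fin <- dplyr::filter(obs, t_min == max(t_min))
      median(distance_records(fin)$d_msc)
    }
    med_dmsc(b_like) < med_dmsc(t_like)
  }, logical(1))
  expect_gte(sum(closer), 9)
})

test_that("proximity fraction to stroma rises with stromal affinity", {
  levels <- c(0, 3, 8)
  frac <- sapply(1:10, function(s) {
    vapply(levels, function(aff) {
      cfg <- sim_config_desk(n_all = 80, n_msc = 1, n_ec = 40,
                             gel_xy = c(300, 300), gel_depth = 400,
                             n_steps = 200,
                             diffusion_sigma = c(ALL = 3, MSC = 0.2, EC = 0.8),
                             aggregation_strength = 0,
                             stromal_affinity = aff, seed = s)
      obs <- simulate_culture(cfg, mode = "co")
      fin <- dplyr::filter(obs, t_min == max(t_min))
      proximity_fraction(distance_records(fin)$d_ec, 10)
    }, numeric(1))
  })
  means <- rowMeans(frac)
  expect_true(all(diff(means) > 0))
  # per-seed trend: the top affinity level dominates the drift-free one
  expect_gte(mean(frac[3, ] >= frac[1, ]), 0.9)
})
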