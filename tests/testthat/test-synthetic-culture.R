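test_that("config validation enforces the stated invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_all = 0), "n_all")
  expect_error(sim_config(network_depth_fraction = 1.2), "<= 1")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(division_rates = list(
    rates = c(0, 1), weights = c(0.5, 0.4)
  )), "sum to 1")
})

test_that("simulation is byte-reproducible under a fixed seed", {
  cfg <- sim_config_desk(n_all = 60, n_msc = 20, n_ec = 30, n_steps = 10,
                         seed = 42)
  a <- simulate_culture(cfg, mode = "co")
  b <- simulate_culture(cfg, mode = "co")
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- simulate_culture(sim_config_desk(n_all = 60, n_msc = 20, n_ec = 30,
                                        n_steps = 10, seed = 43), mode = "co")
  expect_false(identical(a$x_um, d$x_um))
})

test_that("drift-free co-culture reduces to mono-culture diffusion", {
  cfg0 <- sim_config_desk(n_all = 250, n_msc = 30, n_ec = 30, n_steps = 40,
                          aggregation_strength = 0, stromal_affinity = 0,
                          seed = 5)
  co <- simulate_culture(cfg0, mode = "co")
  mono <- simulate_culture(cfg0, mode = "mono")
  step_disp <- function(obs) {
    obs %>%
      dplyr::filter(cell_type == "ALL") %>%
      dplyr::group_by(cell_id) %>%
      dplyr::arrange(t_min, .by_group = TRUE) %>%
      dplyr::summarise(d = sqrt((dplyr::last(x_um) - dplyr::first(x_um))^2 +
                                  (dplyr::last(y_um) - dplyr::first(y_um))^2),
                       .groups = "drop") %>%
      dplyr::pull(d)
  }
  ks <- compare_distributions(step_disp(co), step_disp(mono))
  expect_gt(ks$p_value, 0.01)
})

test_that("aggregation drift contracts nearest ALL-ALL distances (paired sign test)", {
  closer <- vapply(1:10, function(s) {
    base <- list(n_all = 120, n_msc = 10, n_ec = 10, n_steps = 40,
                 gel_xy = c(400, 400), gel_depth = 300, seed = s)
    drift <- simulate_culture(do.call(sim_config_desk,
                                      c(base, aggregation_strength = 2.5,
                                        stromal_affinity = 0)), mode = "co")
    free <- simulate_culture(do.call(sim_config_desk,
                                     c(base, aggregation_strength = 0,
                                       stromal_affinity = 0)), mode = "co")
    final_dist <- function(obs) {
      fin <- dplyr::filter(obs, cell_type == "ALL", t_min == max(t_min))
      mean(min_centroid_distances(fin, fin)$distance_um)
    }
    final_dist(drift) < final_dist(free)
  }, logical(1))
  expect_true(binom.test(sum(closer), 10, alternative = "greater")$p.value < 0.05)
})

test_that("strong stromal affinity settles ALL cells near the network depth", {
  cfg <- sim_config_desk(n_all = 150, n_msc = 1, n_ec = 60,
                         gel_xy = c(300, 300), gel_depth = 400,
                         n_steps = 300, stromal_affinity = 8,
                         aggregation_strength = 0,
                         diffusion_sigma = c(ALL = 3, MSC = 0.2, EC = 0.8),
                         network_depth_fraction = 0.4, seed = 11)
  obs <- simulate_culture(cfg, mode = "co")
  fin <- dplyr::filter(obs, cell_type == "ALL", t_min == max(t_min))
  start <- dplyr::filter(obs, cell_type == "ALL", t_min == 0)
  target <- 0.4 * cfg$gel_depth
  expect_lt(abs(median(fin$z_um) - target), 0.15 * cfg$gel_depth)
  expect_lt(abs(median(fin$z_um) - target), abs(median(start$z_um) - target) / 2)
})

test_that("network geometry honours the depth target and seed contract", {
  cfg <- sim_config_desk(seed = 3)
  net <- generate_network_geometry(cfg)
  target <- cfg$network_depth_fraction * cfg$gel_depth
  expect_lt(abs(mean(net$z_um) - target), 0.05 * cfg$gel_depth)
  expect_true(all(net$z_um >= 0 & net$z_um <= cfg$gel_depth))
  expect_true(all(net$x_um >= 0 & net$x_um <= cfg$gel_xy[1]))

  surf <- generate_network_geometry(sim_config_desk(seed = 3,
                                                    network_depth_fraction = 0))
  expect_lt(mean(surf$z_um), 0.05 * cfg$gel_depth)

  net2 <- generate_network_geometry(sim_config_desk(seed = 4))
  expect_false(identical(net$x_um, net2$x_um))
  expect_lt(abs(mean(net2$z_um) - target), 0.05 * cfg$gel_depth)
  expect_identical(net, generate_network_geometry(sim_config_desk(seed = 3)))
  expect_error(generate_network_geometry(sim_config_desk(gel_depth = -1)))
})

test_that("XY mean squared displacement grows linearly at the diffusion slope", {
  # pure diffusion: per-axis per-step sd sigma => MSD_xy(t) = 2 sigma^2 t / dt
  sigma <- 2
  cfg <- sim_config_desk(n_all = 3000, n_steps = 30, gel_xy = c(5000, 5000),
                         gel_depth = 2000,
                         diffusion_sigma = c(ALL = sigma, MSC = 0.5, EC = 0.5),
                         seed = 9)
  obs <- simulate_culture(cfg, mode = "mono")
  start <- dplyr::filter(obs, t_min == 0) %>% dplyr::arrange(cell_id)
  # minimal-image displacement: XY is periodic in the simulation box
  wrap_d <- function(d, L) d - L * round(d / L)
  msd <- obs %>%
    dplyr::filter(t_min > 0) %>%
    dplyr::arrange(t_min, cell_id) %>%
    dplyr::group_by(t_min) %>%
    dplyr::summarise(
      msd = mean(wrap_d(x_um - start$x_um, cfg$gel_xy[1])^2 +
                   wrap_d(y_um - start$y_um, cfg$gel_xy[2])^2),
      .groups = "drop"
    )
  fit <- coef(lm(msd ~ t_min + 0, data = msd))
  expect_lt(abs(fit[["t_min"]] - 2 * sigma^2 / cfg$dt), 0.05 * 2 * sigma^2 / cfg$dt)
})

test_that("dye dilution follows halving, mixture and noise contracts", {
  cfg <- sim_config_desk(seed = 2, dye_cv = 0.15)
  d0 <- simulate_dye_dilution(cfg, i0 = 1000, days = 0, n = 4000)
  expect_true(all(d0$generations == 0))
  expect_lt(abs(median(d0$dye_intensity) - 1000) / 1000, 0.02)

  noiseless <- sim_config_desk(seed = 2, dye_cv = 0)
  d3 <- simulate_dye_dilution(noiseless, i0 = 800, days = 3,
                              n = 500, rates = c(only = 1), weights = c(only = 1))
  g3 <- d3[d3$generations == 3, ]
  expect_true(nrow(g3) > 0)
  expect_equal(g3$dye_intensity, rep(800 / 8, nrow(g3)))

  mix <- simulate_dye_dilution(cfg, i0 = 1000, days = 7, n = 20000,
                               rates = c(non = 0, slow = 0.7, high = 3.5),
                               weights = c(non = 0.2, slow = 0.3, high = 0.5))
  expect_lt(max(abs(as.numeric(table(mix$cycle_class)) / 20000 -
                      c(0.2, 0.3, 0.5))), 0.02)
})

test_that("division rates are recoverable from dye intensities", {
  cfg <- sim_config_desk(seed = 6)
  days <- 7
  for (rate in c(0.7, 1.4)) {
    dd <- simulate_dye_dilution(cfg, i0 = 1000, days = days, n = 5000,
                                rates = c(r = rate), weights = c(r = 1))
    g_est <- generations_from_intensity(dd$dye_intensity, 1000)
    expect_lt(abs(median(g_est) / days - rate) / rate, 0.15)
  }
})

test_that("drug-response generator obeys survival mechanics and DMSO contract", {
  cfg <- sim_config(seed = 8, sample_sd = 0)
  plate <- drp_plate_layout("S1", "venetoclax")
  expect_error(
    simulate_drug_response(cfg, dplyr::filter(plate, concentration_nM > 0)),
    "DMSO"
  )
  counts <- simulate_drug_response(cfg, plate)
  expect_true(all(counts$true_survival[counts$concentration_nM == 0] == 1))

  # no-protection limit: expected survival identical across conditions
  cfg1 <- sim_config(seed = 8, sample_sd = 0, protection_factor_3d = 1)
  c1 <- simulate_drug_response(cfg1, plate)
  s2d <- c1$true_survival[c1$condition == "2D" & c1$concentration_nM > 0]
  s3d <- c1$true_survival[c1$condition == "3D" & c1$concentration_nM > 0]
  expect_equal(s2d, s3d)

  # protection: at the 2D EC50 concentration, 3D survives more (20 seeds)
  ec50 <- cfg$drug_params$ec50_nM[cfg$drug_params$drug == "venetoclax"]
  plate_ec <- drp_plate_layout("S1", "venetoclax", concentrations = ec50)
  wins <- vapply(1:20, function(s) {
    cfgp <- sim_config(seed = s, sample_sd = 0, protection_factor_3d = 10)
    cc <- simulate_drug_response(cfgp, plate_ec)
    tr <- dplyr::filter(cc, concentration_nM > 0)
    tr$cell_events[tr$condition == "3D"] > tr$cell_events[tr$condition == "2D"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("event-table round trip preserves counts", {
  cfg <- sim_config(seed = 4, n_seeded = 300, bead_mean = 100)
  counts <- simulate_drug_response(cfg, drp_plate_layout("S1", "venetoclax"))
  ev <- drp_events(counts, seed = 1)
  back <- tally_events(ev)
  joined <- dplyr::inner_join(counts, back, by = "well",
                              suffix = c("", ".tallied"))
  expect_equal(joined$cell_events, joined$cell_events.tallied)
  expect_equal(joined$bead_events, joined$bead_events.tallied)
})
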