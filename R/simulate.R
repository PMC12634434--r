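#' Generate a vasculature-like network geometry
#'
#' Draws a set of tubular segments (centerline polylines plus radius) standing
#' in for the endothelial network that forms in the hydrogel. Segments run
#' roughly horizontally at a depth of `network_depth_fraction * gel_depth`
#' from the top surface, with mild per-segment and per-vertex jitter, so the
#' mean centerline depth stays within 5% of the target.
#'
#' @param config A [sim_config()].
#' @param n_segments Number of tubes; default scales with the endothelial
#'   count (one per ~5,000 cells, minimum 4).
#' @param radius_um Tube radius in micrometres.
#' @param vertex_spacing_um Distance between consecutive centerline vertices.
#' @return Tibble with columns `segment_id`, `vertex`, `x_um`, `y_um`, `z_um`,
#'   `radius_um`; deterministic under `config$seed`.
#' @export
generate_network_geometry <- function(config,
                                      n_segments = NULL,
                                      radius_um = 15,
                                      vertex_spacing_um = 25) {
  stopifnot(inherits(config, "sim_config"))
  if (config$gel_depth <= 0 || any(config$gel_xy <= 0)) {
    abort("degenerate gel dimensions")
  }
  n_segments <- n_segments %||% max(4L, round(config$n_ec / 5000))
  depth0 <- config$network_depth_fraction * config$gel_depth
  with_stage_seed(config$seed, "network", {
    segs <- purrr::map(seq_len(n_segments), function(s) {
      len <- runif(1, 0.3, 0.6) * min(config$gel_xy)
      nv <- max(2L, ceiling(len / vertex_spacing_um) + 1L)
      theta <- runif(1, 0, 2 * pi)
      start <- c(runif(1, 0, config$gel_xy[1]), runif(1, 0, config$gel_xy[2]))
      along <- seq(0, len, length.out = nv)
      # gentle lateral meander + small depth jitter around the segment depth
      meander <- cumsum(rnorm(nv, 0, vertex_spacing_um / 8))
      z_seg <- depth0 + rnorm(1, 0, 0.02 * config$gel_depth)
      z <- z_seg + rnorm(nv, 0, 0.01 * config$gel_depth)
      tibble(
        segment_id = s,
        vertex = seq_len(nv),
        x_um = wrap_periodic(start[1] + along * cos(theta) - meander * sin(theta),
                             config$gel_xy[1]),
        y_um = wrap_periodic(start[2] + along * sin(theta) + meander * cos(theta),
                             config$gel_xy[2]),
        z_um = pmin(pmax(z, 0), config$gel_depth),
        radius_um = radius_um
      )
    })
    bind_rows(segs)
  })
}

#' Simulate tri-culture dynamics in the hydrogel
#'
#' Agent-based random walk over the timelapse. Every agent diffuses
#' isotropically (per-axis Gaussian steps); in co-culture mode each leukemic
#' (ALL) agent additionally drifts toward its nearest ALL neighbour
#' (aggregation) and toward the nearest stromal/network attractor point
#' (stromal affinity), both with an exponential-decay kernel
#' `strength * exp(-d / drift_lambda)`. Endothelial agents relax toward the
#' network centerline; MSC agents diffuse slowly. Depth is reflected at the
#' gel top and bottom; XY is periodic.
#'
#' @param config A [sim_config()].
#' @param mode `"co"` (tri-culture) or `"mono"` (ALL cells only, pure
#'   diffusion).
#' @param well Well label written into the output.
#' @param record_every Record one frame every this many steps (frame 0 and
#'   the final frame are always recorded).
#' @return Tibble of cell observations (`well`, `cell_id`, `cell_type`,
#'   `t_min`, `x_um`, `y_um`, `z_um`, `dye_intensity`), with the network
#'   geometry and the config attached as attributes `network` and `config`.
#' @examples
#' cfg <- sim_config_desk(n_all = 50, n_msc = 20, n_ec = 30, n_steps = 6)
#' obs <- simulate_culture(cfg, mode = "co")
#' dplyr::count(obs, cell_type, t_min)
#' @export
simulate_culture <- function(config, mode = c("co", "mono"), well = "W1",
                             record_every = 1L) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  record_every <- max(1L, as.integer(record_every))

  net <- if (mode == "co") generate_network_geometry(config) else NULL
  net_pts <- if (!is.null(net)) as.matrix(net[, c("x_um", "y_um", "z_um")]) else NULL

  with_stage_seed(config$seed, "culture", {
    Lx <- config$gel_xy[1]; Ly <- config$gel_xy[2]; D <- config$gel_depth
    nA <- config$n_all
    PA <- cbind(runif(nA, 0, Lx), runif(nA, 0, Ly),
                reflect_depth(abs(rnorm(nA, 0, 0.05 * D)), D))
    if (mode == "co") {
      nM <- config$n_msc; nE <- config$n_ec
      PM <- cbind(runif(nM, 0, Lx), runif(nM, 0, Ly), runif(nM, 0, D))
      PE <- cbind(runif(nE, 0, Lx), runif(nE, 0, Ly), runif(nE, 0, 0.1 * D))
    }

    ids_all <- seq_len(nA)
    frames <- list()
    snap <- function(step) {
      t_min <- step * config$dt
      out <- tibble(
        well = well, cell_id = ids_all, cell_type = "ALL", t_min = t_min,
        x_um = PA[, 1], y_um = PA[, 2], z_um = PA[, 3]
      )
      if (mode == "co") {
        out <- bind_rows(
          out,
          tibble(well = well, cell_id = nA + seq_len(nrow(PM)),
                 cell_type = "MSC", t_min = t_min,
                 x_um = PM[, 1], y_um = PM[, 2], z_um = PM[, 3]),
          tibble(well = well, cell_id = nA + nrow(PM) + seq_len(nrow(PE)),
                 cell_type = "EC", t_min = t_min,
                 x_um = PE[, 1], y_um = PE[, 2], z_um = PE[, 3])
        )
      }
      out
    }
    frames[[1]] <- snap(0L)

    sig <- config$diffusion_sigma
    lam <- config$drift_lambda
    drift_toward <- function(P, targets, strength, k_self = 0L) {
      if (strength <= 0 || is.null(targets) || nrow(targets) == 0) {
        return(matrix(0, nrow(P), 3))
      }
      nn <- FNN::get.knnx(targets, P, k = 1L + k_self)
      d <- nn$nn.dist[, 1L + k_self]
      idx <- nn$nn.index[, 1L + k_self]
      vec <- targets[idx, , drop = FALSE] - P
      ok <- is.finite(d) & d > 0
      mag <- ifelse(ok, strength * exp(-d / lam) / d, 0)
      vec * mag
    }

    for (step in seq_len(config$n_steps)) {
      dr <- matrix(0, nA, 3)
      if (mode == "co") {
        if (config$aggregation_strength > 0 && nA > 1) {
          # nearest *other* ALL agent: query the same cloud, skip self (k = 2)
          dr <- dr + drift_toward(PA, PA, config$aggregation_strength, k_self = 1L)
        }
        attract <- rbind(PM, net_pts)
        dr <- dr + drift_toward(PA, attract, config$stromal_affinity)
      }
      dr[!is.finite(dr)] <- 0
      PA <- PA + dr + matrix(rnorm(3 * nA, 0, sig[["ALL"]]), nA, 3)
      PA[, 1] <- wrap_periodic(PA[, 1], Lx)
      PA[, 2] <- wrap_periodic(PA[, 2], Ly)
      PA[, 3] <- reflect_depth(PA[, 3], D)

      if (mode == "co") {
        PM <- PM + matrix(rnorm(3 * nrow(PM), 0, sig[["MSC"]]), nrow(PM), 3)
        PM[, 1] <- wrap_periodic(PM[, 1], Lx)
        PM[, 2] <- wrap_periodic(PM[, 2], Ly)
        PM[, 3] <- reflect_depth(PM[, 3], D)
        nnE <- FNN::get.knnx(net_pts, PE, k = 1)
        PE <- PE + 0.08 * (net_pts[nnE$nn.index[, 1], , drop = FALSE] - PE) +
          matrix(rnorm(3 * nrow(PE), 0, sig[["EC"]]), nrow(PE), 3)
        PE[, 1] <- wrap_periodic(PE[, 1], Lx)
        PE[, 2] <- wrap_periodic(PE[, 2], Ly)
        PE[, 3] <- reflect_depth(PE[, 3], D)
      }

      if (step %% record_every == 0L || step == config$n_steps) {
        frames[[length(frames) + 1L]] <- snap(step)
      }
    }

    out <- bind_rows(frames)
    out$dye_intensity <- NA_real_
    attr(out, "network") <- net
    attr(out, "config") <- config
    attr(out, "mode") <- mode
    out
  })
}

#' Simulate a dye-dilution (CellTrace-style) population
#'
#' Each cell draws a cycling class from the configured mixture, a number of
#' generations from `Poisson(rate_class * days)`, and a measured dye
#' intensity `i0 / 2^generations` times multiplicative lognormal noise
#' (mean 1, coefficient of variation `dye_cv`). True class labels and
#' generation counts are returned for recovery testing.
#'
#' @param config A [sim_config()]; `division_rates` and `dye_cv` are used.
#' @param i0 Initial (generation-0) dye intensity, arbitrary units > 0.
#' @param days Culture duration in days (>= 0).
#' @param n Number of cells; defaults to `config$n_all`.
#' @param rates,weights Optional overrides of `config$division_rates`.
#' @return Tibble with `cell_id`, `cycle_class`, `generations`,
#'   `dye_intensity`.
#' @export
simulate_dye_dilution <- function(config, i0, days, n = NULL,
                                  rates = NULL, weights = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_scalar_num(i0, "i0", lower = 0, strict = TRUE)
  assert_scalar_num(days, "days", lower = 0)
  n <- as.integer(n %||% config$n_all)
  rates <- rates %||% config$division_rates$rates
  weights <- weights %||% config$division_rates$weights
  if (length(rates) != length(weights)) abort("rates/weights length mismatch")
  classes <- names(rates) %||% paste0("class", seq_along(rates))

  with_stage_seed(config$seed, "dye", {
    cls <- sample(seq_along(rates), n, replace = TRUE, prob = weights)
    g <- rpois(n, rates[cls] * days)
    sdlog <- sqrt(log(1 + config$dye_cv^2))
    noise <- rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    tibble(
      cell_id = seq_len(n),
      cycle_class = factor(classes[cls], levels = classes),
      generations = g,
      dye_intensity = i0 / 2^g * noise
    )
  })
}

#' Build a drug-response plate layout
#'
#' One well per sample x condition x drug x concentration, plus dedicated
#' DMSO vehicle-control wells (`drug = "DMSO"`, `concentration_nM = 0`) per
#' sample x condition. The default concentration grid is the assay's
#' 100 / 1,000 / 10,000 nM.
#'
#' @param samples Character vector of sample identifiers (e.g. PDX codes).
#' @param drugs Drugs to lay out; must appear in the config's `drug_params`.
#' @param concentrations Concentrations in nM (0 is reserved for DMSO).
#' @param conditions Culture formats, default `c("2D", "3D")`.
#' @param dmso_replicates DMSO control wells per sample x condition.
#' @return Tibble with `well`, `sample_id`, `condition`, `drug`,
#'   `concentration_nM`.
#' @export
drp_plate_layout <- function(samples, drugs,
                             concentrations = c(100, 1000, 10000),
                             conditions = c("2D", "3D"),
                             dmso_replicates = 3L) {
  if (any(concentrations <= 0)) abort("treatment concentrations must be > 0")
  grid <- tidyr::expand_grid(
    sample_id = samples, condition = conditions, drug = drugs,
    concentration_nM = concentrations
  )
  dmso <- tidyr::expand_grid(
    sample_id = samples, condition = conditions, drug = "DMSO",
    concentration_nM = 0,
    replicate = seq_len(dmso_replicates)
  )
  dmso$replicate <- NULL
  out <- bind_rows(grid, dmso) %>%
    arrange(.data$sample_id, .data$condition, .data$drug, .data$concentration_nM)
  out$well <- sprintf("W%04d", seq_len(nrow(out)))
  select(out, "well", dplyr::everything())
}

#' Simulate cytometry-style drug-response readouts
#'
#' For each well the surviving fraction follows a Hill model,
#' `s = 1 - max_kill * c^h / (c^h + EC50^h)`, with the effective EC50
#' multiplied by `protection_factor_3d` in 3D wells and by a per-sample
#' lognormal potency multiplier (between-sample heterogeneity). Viable-cell
#' events are Binomial(`n_seeded`, s) and counting-bead events
#' Poisson(`bead_mean`).
#'
#' @param config A [sim_config()].
#' @param plate Layout from [drp_plate_layout()]; every sample x condition
#'   must contain DMSO control wells, otherwise a configuration error is
#'   raised.
#' @return Per-well tibble: `well`, `sample_id`, `condition`, `drug`,
#'   `concentration_nM`, `cell_events`, `bead_events`, `beads_added`, and
#'   the generator's `true_survival`.
#' @export
simulate_drug_response <- function(config, plate) {
  stopifnot(inherits(config, "sim_config"))
  assert_cols(plate, c("well", "sample_id", "condition", "drug",
                       "concentration_nM"), "plate")
  has_dmso <- plate %>%
    group_by(.data$sample_id, .data$condition) %>%
    summarise(ok = any(.data$concentration_nM == 0), .groups = "drop")
  if (!all(has_dmso$ok)) {
    abort("configuration error: every sample x condition needs DMSO control wells")
  }
  drugs_used <- setdiff(unique(plate$drug), "DMSO")
  unknown <- setdiff(drugs_used, config$drug_params$drug)
  if (length(unknown)) {
    abort(paste0("drugs missing from drug_params: ", paste(unknown, collapse = ", ")))
  }

  with_stage_seed(config$seed, "drug", {
    combos <- tidyr::expand_grid(
      sample_id = sort(unique(plate$sample_id)),
      drug = sort(drugs_used)
    )
    combos$potency_mult <- rlnorm(nrow(combos), 0, config$sample_sd)

    df <- plate %>%
      left_join(config$drug_params, by = "drug") %>%
      left_join(combos, by = c("sample_id", "drug"))
    pf <- ifelse(df$condition == "3D", config$protection_factor_3d, 1)
    ec50_eff <- df$ec50_nM * ifelse(is.na(df$potency_mult), 1, df$potency_mult) * pf
    s <- ifelse(
      df$concentration_nM == 0, 1,
      1 - df$max_kill * df$concentration_nM^df$hill /
        (df$concentration_nM^df$hill + ec50_eff^df$hill)
    )
    s[is.na(s)] <- 1  # DMSO rows have no drug params

    df$true_survival <- s
    df$cell_events <- rbinom(nrow(df), config$n_seeded, s)
    df$bead_events <- rpois(nrow(df), config$bead_mean)
    df$beads_added <- config$beads_added
    select(df, "well", "sample_id", "condition", "drug", "concentration_nM",
           "cell_events", "bead_events", "beads_added", "true_survival")
  })
}

#' Expand per-well counts into an event-level table
#'
#' Produces the cytometry-export-like long format (`well`, `event_id`,
#' `kind`, `dye_intensity`, `viability_dye`) from a counts table, for format
#' round-trips and IO tests. Cells draw a lognormal dye intensity; beads sit
#' in a fixed bright channel.
#'
#' @param counts Output of [simulate_drug_response()].
#' @param i0 Median cell dye intensity.
#' @param seed Seed for the event-level draws.
#' @return Event tibble, one row per acquired event.
#' @export
drp_events <- function(counts, i0 = 1000, seed = 1L) {
  assert_cols(counts, c("well", "cell_events", "bead_events"), "counts")
  with_stage_seed(seed, "noise", {
    purrr::pmap_dfr(
      counts[, c("well", "cell_events", "bead_events")],
      function(well, cell_events, bead_events) {
        n <- cell_events + bead_events
        tibble(
          well = well,
          event_id = seq_len(n),
          kind = rep(c("cell", "bead"), c(cell_events, bead_events)),
          dye_intensity = c(rlnorm(cell_events, log(i0), 0.4),
                            rep(65000, bead_events)),
          viability_dye = c(rlnorm(cell_events, log(50), 0.3),
                            rep(NA_real_, bead_events))
        )
      }
    )
  })
}

#' Tally an event table back into per-well counts
#'
#' @param events Event tibble as produced by [drp_events()].
#' @return Tibble `well`, `cell_events`, `bead_events`.
#' @export
tally_events <- function(events) {
  assert_cols(events, c("well", "kind"), "events")
  events %>%
    group_by(.data$well) %>%
    summarise(
      cell_events = sum(.data$kind == "cell"),
      bead_events = sum(.data$kind == "bead"),
      .groups = "drop"
    )
}
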