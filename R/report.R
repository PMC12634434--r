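# End-to-end pipelines and figure-style report tables.

#' Spatial phenotyping pipeline on a simulated (or measured) timelapse
#'
#' Runs the full single-cell spatial workflow on an observation table:
#' per-ALL-cell distance records at the final timepoint, proximity fractions
#' (< 10 um) to MSC and endothelial cells, the depth profile (delta median,
#' SDs), migration percentages referenced to the shallowest ALL cell, and
#' the network-contact fraction.
#'
#' @param cells Observation tibble (as from [simulate_culture()] or
#'   position-table CSVs).
#' @param gel_depth_um Gel depth used as the migration-percentage
#'   denominator.
#' @param proximity_um Proximity threshold (default 10 um).
#' @param network_percent Network settling depth as a percentage (default
#'   40).
#' @param band Contact tolerance band in percentage points (default 10).
#' @return List of tibbles: `distances`, `proximity`, `z_profile` (scalars),
#'   `migration`, `contact`.
#' @export
run_spatial_pipeline <- function(cells, gel_depth_um, proximity_um = 10,
                                 network_percent = 40, band = 10) {
  assert_cols(cells, c("cell_id", "cell_type", "t_min", "x_um", "y_um",
                       "z_um"), "cells")
  t_end <- max(cells$t_min)
  final <- filter(cells, .data$t_min == t_end)
  has_support <- any(final$cell_type %in% c("MSC", "EC"))

  dist_rec <- distance_records(final)
  proximity <- tibble(
    target = c("MSC", "EC"),
    fraction_lt_threshold = c(
      if (any(final$cell_type == "MSC")) {
        proximity_fraction(dist_rec$d_msc, proximity_um)
      } else NA_real_,
      if (any(final$cell_type == "EC")) {
        proximity_fraction(dist_rec$d_ec, proximity_um)
      } else NA_real_
    ),
    threshold_um = proximity_um
  )

  zp <- z_profile(filter(cells, .data$cell_type == "ALL"))
  mig <- migration_percent(final, gel_depth_um)
  all_pct <- mig$migration_pct[mig$cell_type == "ALL"]
  contact <- tibble(
    network_percent = network_percent, band = band,
    applicable = has_support,
    contact_fraction = if (has_support) {
      network_contact_fraction(all_pct, network_percent, band)
    } else NA_real_
  )

  list(
    distances = dist_rec,
    proximity = proximity,
    z_profile = tibble(delta_median_um = zp$delta_median_um,
                       sd_t0_um = zp$sd_t0_um, sd_tend_um = zp$sd_tend_um,
                       t0_min = zp$t0_min, tend_min = zp$tend_min),
    migration = select(mig, "cell_id", "cell_type", "z_um", "migration_pct"),
    contact = contact
  )
}

#' Drug-response profiling pipeline on a simulated cohort
#'
#' Simulates the cytometry readout for a cohort, converts events to
#' bead-normalized absolute counts, normalizes to DMSO, and summarizes
#' integrated responses, percentile ranks, decreased-sensitivity flags and
#' the paired 2D-vs-3D test.
#'
#' @param config A [sim_config()].
#' @param samples Sample identifiers (e.g. `sprintf("PDX%02d", 1:16)`).
#' @param drugs Drugs to screen (default: all in `config$drug_params`).
#' @param ... Passed to [drp_response_summary()].
#' @return List with `counts`, `viability` and `summary` (a `drp_summary`).
#' @export
run_drp_pipeline <- function(config, samples, drugs = NULL, ...) {
  drugs <- drugs %||% config$drug_params$drug
  plate <- drp_plate_layout(samples, drugs)
  counts <- simulate_drug_response(config, plate)
  viab <- viability_table(counts)
  list(counts = counts, viability = viab,
       summary = drp_response_summary(viab, ...))
}

#' Figure-style report tables for the spatial workflow
#'
#' Assembles one table per mirrored readout panel (proximity fractions,
#' depth-profile scalars, migration distribution summary, network-contact
#' fraction), each with explicit column provenance. Panels whose inputs are
#' absent (e.g. network contact in a mono-culture) are listed as
#' not-applicable, never fabricated.
#'
#' @param spatial Output of [run_spatial_pipeline()].
#' @return Named list of tibbles.
#' @export
report_spatial <- function(spatial) {
  stopifnot(is.list(spatial), all(c("proximity", "z_profile", "migration",
                                    "contact") %in% names(spatial)))
  mig_all <- filter(spatial$migration, .data$cell_type == "ALL")
  list(
    proximity_panel = mutate(spatial$proximity,
                             provenance = "fraction of ALL cells with nearest-neighbour distance < threshold"),
    z_panel = mutate(spatial$z_profile,
                     provenance = "median depth shift T0 -> T_end and raw-depth SDs"),
    migration_panel = tibble(
      n_all = nrow(mig_all),
      median_migration_pct = median(mig_all$migration_pct),
      q90_migration_pct = unname(quantile(mig_all$migration_pct, 0.9)),
      provenance = "depth below the shallowest ALL cell, % of gel depth"
    ),
    contact_panel = mutate(spatial$contact,
                           provenance = ifelse(.data$applicable,
                                               "fraction of ALL cells within the band of the network depth",
                                               "not applicable (no supporting cells)"))
  )
}

#' Figure-style report tables for the drug-response workflow
#'
#' @param drp Output of [run_drp_pipeline()] (or a `drp_summary`).
#' @return Named list of tibbles: per-sample integrated responses with
#'   ranks and flags, and the per-drug paired-test table.
#' @export
report_drp <- function(drp) {
  s <- if (inherits(drp, "drp_summary")) drp else drp$summary
  stopifnot(inherits(s, "drp_summary"))
  list(
    response_panel = mutate(tidy(s),
                            provenance = "integrated normalized viability over two concentrations"),
    ranking_panel = s$summary %>%
      select("sample_id", "condition", "drug", "percentile_rank") %>%
      mutate(provenance = "percentile rank of integrated response within cohort"),
    paired_panel = mutate(s$paired_tests,
                          provenance = "ratio paired t-test on log viabilities, 3D vs 2D")
  )
}
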