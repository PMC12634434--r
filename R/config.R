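#' Simulation configuration for the synthetic tri-culture
#'
#' Builds and validates the configuration driving every synthetic-data stage:
#' the agent-based tri-culture (ALL blasts + mesenchymal stromal cells +
#' endothelial cells in a PEG hydrogel), the vasculature-like network
#' geometry, dye-dilution proliferation and drug-response event tables.
#'
#' Defaults describe the modelled well: 30,000 ALL and 30,000 endothelial
#' cells with 15,000 co-seeded MSCs in a hydrogel several hundred micrometres
#' deep, imaged every 5 minutes for 30 hours, with the endothelial network
#' settling at 40% of the gel depth from the top. Depth (`z`) is measured
#' from the gel top surface, increasing downward, in micrometres; this
#' convention is shared by every module in the package.
#'
#' @param n_msc,n_ec,n_all Agent counts per well.
#' @param gel_depth Hydrogel depth in micrometres.
#' @param gel_xy Lateral extent of the simulated region, micrometres (length 2).
#' @param dt Time step, minutes.
#' @param n_steps Number of simulation steps (default 360 = 30 h at 5 min).
#' @param diffusion_sigma Named per-axis, per-step Gaussian displacement sd in
#'   micrometres for each cell type (`ALL`, `MSC`, `EC`).
#' @param aggregation_strength Drift magnitude (micrometres/step at zero
#'   distance) of each ALL cell toward its nearest ALL neighbour, co-culture
#'   mode only.
#' @param stromal_affinity Drift magnitude toward the nearest stromal/network
#'   attractor point; tune high for B-lineage-like, low for T-lineage-like
#'   behaviour.
#' @param drift_lambda Length scale (micrometres) of the exponential-decay
#'   attraction kernel: drift = strength * exp(-d / lambda).
#' @param network_depth_fraction Target settling depth of the endothelial
#'   network as a fraction of `gel_depth` from the top (default 0.4).
#' @param division_rates List with `rates` (divisions/day for the non-, slow-
#'   and high-cycling classes) and `weights` (class mixture, sums to 1).
#' @param dye_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise on dye intensity.
#' @param drug_params Tibble with one row per drug: `drug`, `ec50_nM`,
#'   `hill`, `max_kill`. Stylized potencies; the assay grid is
#'   100/1000/10000 nM plus DMSO.
#' @param protection_factor_3d Multiplier applied to EC50 in 3D wells
#'   (microenvironment-mediated protection; 1 = no protection).
#' @param sample_sd Between-sample lognormal sd (log scale) of per-sample
#'   EC50 multipliers in simulated cohorts.
#' @param n_seeded Leukemic cells seeded per drug-response well.
#' @param bead_mean Poisson mean of counting-bead events acquired per well.
#' @param beads_added Nominal number of counting beads added per well.
#' @param seed Integer seed; all stage randomness is fanned out from it
#'   deterministically, and identical configs reproduce outputs bit-for-bit.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_all = 200, n_ec = 100, n_msc = 80, n_steps = 24)
#' cfg$gel_depth
#' @export
sim_config <- function(n_msc = 15000,
                       n_ec = 30000,
                       n_all = 30000,
                       gel_depth = 500,
                       gel_xy = c(5660, 5660),
                       dt = 5,
                       n_steps = 360,
                       diffusion_sigma = c(ALL = 2, MSC = 0.5, EC = 0.8),
                       aggregation_strength = 1.5,
                       stromal_affinity = 1.5,
                       drift_lambda = 50,
                       network_depth_fraction = 0.4,
                       division_rates = list(
                         rates = c(non = 0, slow = 0.25, high = 1),
                         weights = c(non = 0.2, slow = 0.3, high = 0.5)
                       ),
                       dye_cv = 0.15,
                       drug_params = default_drug_params(),
                       protection_factor_3d = 3,
                       sample_sd = 0.5,
                       n_seeded = 10000,
                       bead_mean = 5000,
                       beads_added = 5000,
                       seed = 1L) {
  for (nm in c("n_msc", "n_ec", "n_all")) {
    assert_scalar_num(get(nm), nm, lower = 0, strict = TRUE)
  }
  assert_scalar_num(gel_depth, "gel_depth", lower = 0, strict = TRUE)
  if (length(gel_xy) != 2 || any(!is.finite(gel_xy)) || any(gel_xy <= 0)) {
    abort("`gel_xy` must be two positive extents in micrometres")
  }
  assert_scalar_num(dt, "dt", lower = 0, strict = TRUE)
  assert_scalar_num(n_steps, "n_steps", lower = 1)
  if (!all(c("ALL", "MSC", "EC") %in% names(diffusion_sigma))) {
    abort("`diffusion_sigma` needs named entries ALL, MSC, EC")
  }
  if (any(diffusion_sigma < 0)) abort("`diffusion_sigma` must be >= 0")
  assert_scalar_num(aggregation_strength, "aggregation_strength", lower = 0)
  assert_scalar_num(stromal_affinity, "stromal_affinity", lower = 0)
  assert_scalar_num(drift_lambda, "drift_lambda", lower = 0, strict = TRUE)
  assert_scalar_num(network_depth_fraction, "network_depth_fraction", lower = 0)
  if (network_depth_fraction > 1) abort("`network_depth_fraction` must be <= 1")
  if (!is.list(division_rates) ||
      !all(c("rates", "weights") %in% names(division_rates))) {
    abort("`division_rates` must be a list with `rates` and `weights`")
  }
  if (length(division_rates$rates) != length(division_rates$weights)) {
    abort("`division_rates` rates and weights must have equal length")
  }
  if (any(division_rates$rates < 0)) abort("division rates must be >= 0")
  if (abs(sum(division_rates$weights) - 1) > 1e-9) {
    abort("`division_rates$weights` must sum to 1")
  }
  assert_scalar_num(dye_cv, "dye_cv", lower = 0)
  assert_cols(drug_params, c("drug", "ec50_nM", "hill", "max_kill"), "drug_params")
  if (any(drug_params$max_kill < 0 | drug_params$max_kill > 1)) {
    abort("`max_kill` must lie in [0, 1]")
  }
  assert_scalar_num(protection_factor_3d, "protection_factor_3d",
                    lower = 0, strict = TRUE)
  assert_scalar_num(sample_sd, "sample_sd", lower = 0)
  assert_scalar_num(n_seeded, "n_seeded", lower = 1)
  assert_scalar_num(bead_mean, "bead_mean", lower = 1)
  assert_scalar_num(beads_added, "beads_added", lower = 1)
  assert_scalar_num(seed, "seed", lower = 0)

  structure(
    list(
      n_msc = as.integer(n_msc), n_ec = as.integer(n_ec),
      n_all = as.integer(n_all),
      gel_depth = gel_depth, gel_xy = as.numeric(gel_xy),
      dt = dt, n_steps = as.integer(n_steps),
      diffusion_sigma = diffusion_sigma,
      aggregation_strength = aggregation_strength,
      stromal_affinity = stromal_affinity,
      drift_lambda = drift_lambda,
      network_depth_fraction = network_depth_fraction,
      division_rates = division_rates,
      dye_cv = dye_cv,
      drug_params = as_tibble(drug_params),
      protection_factor_3d = protection_factor_3d,
      sample_sd = sample_sd,
      n_seeded = as.integer(n_seeded),
      bead_mean = bead_mean,
      beads_added = as.integer(beads_added),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Stylized per-drug dose-response parameters
#'
#' Order-of-magnitude potencies for the five compounds of the assay panel
#' (vincristine, doxorubicin, dexamethasone, venetoclax, idasanutlin); the
#' assay reports normalized viability only, so these are generator
#' conventions, not fitted values.
#'
#' @return Tibble with columns `drug`, `ec50_nM`, `hill`, `max_kill`.
#' @export
default_drug_params <- function() {
  tibble(
    drug = c("vincristine", "doxorubicin", "dexamethasone",
             "venetoclax", "idasanutlin"),
    ec50_nM = c(50, 200, 100, 150, 400),
    hill = c(1.5, 1.2, 1, 1.3, 1.1),
    max_kill = c(0.95, 0.9, 0.85, 0.95, 0.9)
  )
}

#' Desk-scale configuration for examples, tests and smoke runs
#'
#' Same stated world as [sim_config()] but scaled to at most a couple of
#' thousand agents and a short timelapse so the full pipeline runs in
#' seconds on one CPU.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @export
sim_config_desk <- function(...) {
  defaults <- list(
    n_msc = 150, n_ec = 300, n_all = 400,
    gel_depth = 400, gel_xy = c(600, 600),
    n_steps = 72
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  agents: %d ALL, %d MSC, %d EC\n", x$n_all, x$n_msc, x$n_ec))
  cat(sprintf("  gel: %.0f x %.0f x %.0f um (depth from top)\n",
              x$gel_xy[1], x$gel_xy[2], x$gel_depth))
  cat(sprintf("  timelapse: %d steps x %.0f min\n", x$n_steps, x$dt))
  cat(sprintf("  network depth fraction: %.2f; seed: %d\n",
              x$network_depth_fraction, x$seed))
  invisible(x)
}
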