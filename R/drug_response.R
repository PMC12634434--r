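# Bead-normalized absolute counts, DMSO normalization, integrated
# two-concentration response, decreased-sensitivity flagging, percentile
# ranking and the paired 2D-vs-3D comparison.

#' Bead-normalized absolute cell counts
#'
#' Counting beads added at a known quantity convert acquired event counts to
#' absolute cells per well:
#' `cells_per_well = cell_events * beads_added / bead_events`.
#'
#' @param cell_events,bead_events Acquired viable-cell and bead event counts
#'   (vectors recycle).
#' @param beads_added Number of beads added per well.
#' @param fraction_acquired_correction Optional known acquired fraction to
#'   divide out in addition to the bead ratio.
#' @return Numeric cells per well; wells with `bead_events == 0` return `NA`
#'   with a warning (excluded, never a sentinel).
#' @examples
#' absolute_counts(1000, 500, 5000)  # 10000
#' @export
absolute_counts <- function(cell_events, bead_events, beads_added,
                            fraction_acquired_correction = NULL) {
  if (any(beads_added <= 0)) abort("`beads_added` must be > 0")
  if (any(cell_events < 0) || any(bead_events < 0)) {
    abort("event counts must be >= 0")
  }
  out <- ifelse(bead_events > 0,
                cell_events * beads_added / bead_events, NA_real_)
  if (any(bead_events == 0)) {
    warn("wells with zero bead events excluded (undefined absolute count)")
  }
  if (!is.null(fraction_acquired_correction)) {
    if (any(fraction_acquired_correction <= 0)) {
      abort("`fraction_acquired_correction` must be > 0")
    }
    out <- out / fraction_acquired_correction
  }
  out
}

#' Normalize viability to DMSO vehicle controls
#'
#' @param treated Absolute cells per well in treated wells.
#' @param dmso_mean Mean absolute count of the matching DMSO control wells.
#' @return Percent of control (may exceed 100); `NA` with a warning when the
#'   control mean is not positive.
#' @export
normalize_viability <- function(treated, dmso_mean) {
  out <- ifelse(is.na(dmso_mean) | dmso_mean <= 0, NA_real_,
                100 * treated / dmso_mean)
  if (any(is.na(out) & !is.na(treated))) {
    warn("non-positive DMSO control mean: normalized viability undefined")
  }
  out
}

#' Per-well viability records from a counts table
#'
#' Applies bead normalization and DMSO normalization well-by-well: absolute
#' counts via [absolute_counts()], then percent-of-control against the mean
#' DMSO absolute count of the same sample x condition. DMSO wells are
#' normalized against their own replicate-set mean (their mean is 100 by
#' construction).
#'
#' @param counts Tibble as from [simulate_drug_response()] (columns `well`,
#'   `sample_id`, `condition`, `drug`, `concentration_nM`, `cell_events`,
#'   `bead_events`, `beads_added`).
#' @return Tibble of viability records with `cells_per_well` and
#'   `normalized_viability`.
#' @export
viability_table <- function(counts) {
  assert_cols(counts, c("well", "sample_id", "condition", "drug",
                        "concentration_nM", "cell_events", "bead_events",
                        "beads_added"), "counts")
  rec <- counts %>%
    mutate(cells_per_well = absolute_counts(.data$cell_events,
                                            .data$bead_events,
                                            .data$beads_added))
  dmso <- rec %>%
    filter(.data$concentration_nM == 0) %>%
    group_by(.data$sample_id, .data$condition) %>%
    summarise(dmso_mean = mean(.data$cells_per_well, na.rm = TRUE),
              .groups = "drop")
  if (nrow(dmso) == 0) abort("no DMSO control wells found")
  rec %>%
    left_join(dmso, by = c("sample_id", "condition")) %>%
    mutate(normalized_viability = normalize_viability(.data$cells_per_well,
                                                      .data$dmso_mean)) %>%
    select(-"dmso_mean")
}

#' Integrated response over two concentrations
#'
#' The arithmetic mean of the normalized viabilities at the two
#' concentrations (equivalently a two-point normalized trapezoid). With one
#' value missing the other is returned, flagged as a single-concentration
#' fallback.
#'
#' @param v_c1,v_c2 Normalized viabilities (%) at the two concentrations;
#'   vectors recycle.
#' @return Tibble `integrated_response`, `flag`.
#' @export
integrated_response <- function(v_c1, v_c2) {
  n <- max(length(v_c1), length(v_c2))
  v1 <- rep_len(v_c1, n); v2 <- rep_len(v_c2, n)
  both <- !is.na(v1) & !is.na(v2)
  out <- ifelse(both, (v1 + v2) / 2,
                ifelse(is.na(v1), v2, v1))
  flag <- ifelse(both, NA_character_,
                 ifelse(is.na(out), "missing_both", "single_concentration"))
  tibble(integrated_response = out, flag = flag)
}

#' Decreased-sensitivity flag for 3D versus 2D response
#'
#' `TRUE` when the 3D normalized viability exceeds the 2D value by more than
#' `delta` percentage points at the comparison concentration (default 10
#' points at 100 nM, the protection readout).
#'
#' @param v_3d,v_2d Normalized viabilities (%) of matched sample/drug pairs.
#' @param delta Difference threshold in percentage points.
#' @return Logical vector.
#' @export
decreased_sensitivity_flag <- function(v_3d, v_2d, delta = 10) {
  if (length(v_3d) != length(v_2d)) abort("unmatched sample/drug pairs")
  v_3d - v_2d > delta
}

#' Percentile ranks within a cohort
#'
#' Rank of each value among the cohort as
#' `100 * (number of values strictly below) / (n - 1)`, ties sharing the
#' mean rank; all-equal cohorts rank 50 throughout.
#'
#' @param values Numeric cohort (n >= 2).
#' @return Ranks in `[0, 100]`; `NA` with a warning when n < 2.
#' @examples
#' percentile_rank(c(10, 20, 30))  # 0 50 100
#' @export
percentile_rank <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) {
    warn("percentile ranking needs a cohort of >= 2")
    return(rep(NA_real_, length(values)))
  }
  out <- rep(NA_real_, length(values))
  out[ok] <- 100 * (rank(values[ok], ties.method = "average") - 1) / (n - 1)
  out
}

#' Ratio paired t-test of 3D versus 2D viabilities
#'
#' Paired t-test on log-transformed normalized viabilities (a "ratio paired"
#' test: the null is a unit 3D/2D ratio). Non-positive pairs are excluded
#' with a warning. Identical vectors give statistic 0 and p = 1; a constant
#' non-zero log-ratio (zero variance) is flagged degenerate rather than
#' reported as a numeric result.
#'
#' @param v_3d,v_2d Matched per-sample normalized viabilities (n >= 3 usable
#'   pairs).
#' @return One-row tibble `statistic`, `p_value`, `df`, `mean_log_ratio`,
#'   `direction` (`"3D > 2D"` / `"2D > 3D"` / `"none"`), `n_pairs`, `flag`.
#' @export
paired_condition_test <- function(v_3d, v_2d) {
  if (length(v_3d) != length(v_2d)) abort("unmatched pairs")
  ok <- !is.na(v_3d) & !is.na(v_2d) & v_3d > 0 & v_2d > 0
  if (any(!ok)) warn("pairs with missing or non-positive viability excluded")
  a <- log(v_3d[ok]); b <- log(v_2d[ok])
  n <- length(a)
  if (n < 3) {
    warn("need >= 3 usable pairs")
    return(tibble(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                  mean_log_ratio = NA_real_, direction = "none",
                  n_pairs = n, flag = "too_few_pairs"))
  }
  d <- a - b
  m <- mean(d)
  if (sd(d) <= 1e-12 * max(1, abs(m))) {
    if (m == 0) {
      return(tibble(statistic = 0, p_value = 1, df = n - 1,
                    mean_log_ratio = 0, direction = "none",
                    n_pairs = n, flag = NA_character_))
    }
    return(tibble(statistic = NA_real_, p_value = NA_real_, df = n - 1,
                  mean_log_ratio = m,
                  direction = if (m > 0) "3D > 2D" else "2D > 3D",
                  n_pairs = n, flag = "zero_variance"))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(
    statistic = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter), mean_log_ratio = m,
    direction = if (m > 0) "3D > 2D" else if (m < 0) "2D > 3D" else "none",
    n_pairs = n, flag = NA_character_
  )
}

#' Cohort response summary: integration, flags, ranks
#'
#' From a viability table, builds the per-sample response summary for one
#' drug: the integrated response over the configured concentration pair per
#' condition, the decreased-sensitivity flag at the flag concentration, and
#' percentile ranks within each condition's cohort.
#'
#' @param viability Tibble from [viability_table()].
#' @param integrate_at Concentration pair (nM) feeding the integration
#'   (default 100 and 10,000 nM, the displayed pair).
#' @param flag_at Concentration (nM) at which decreased sensitivity is
#'   assessed (default 100).
#' @param delta Decreased-sensitivity threshold, percentage points.
#' @return Object of class `drp_summary`: list with `summary` (per sample x
#'   condition x drug tibble), `paired_tests` (per drug), and the settings.
#' @export
drp_response_summary <- function(viability, integrate_at = c(100, 10000),
                                 flag_at = 100, delta = 10) {
  assert_cols(viability, c("sample_id", "condition", "drug",
                           "concentration_nM", "normalized_viability"),
              "viability")
  if (length(integrate_at) != 2) abort("`integrate_at` must name two concentrations")
  treated <- viability %>% filter(.data$drug != "DMSO")

  # replicate-mean viability per sample x condition x drug x concentration
  mean_v <- treated %>%
    group_by(.data$sample_id, .data$condition, .data$drug,
             .data$concentration_nM) %>%
    summarise(v = mean(.data$normalized_viability, na.rm = TRUE),
              .groups = "drop")

  wide <- mean_v %>%
    filter(.data$concentration_nM %in% integrate_at) %>%
    tidyr::pivot_wider(names_from = "concentration_nM", values_from = "v",
                       names_prefix = "c_")
  c1 <- paste0("c_", integrate_at[1]); c2 <- paste0("c_", integrate_at[2])
  for (cc in c(c1, c2)) if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  ir <- integrated_response(wide[[c1]], wide[[c2]])
  wide$integrated_response <- ir$integrated_response
  wide$integration_flag <- ir$flag

  flag_v <- mean_v %>%
    filter(.data$concentration_nM == flag_at) %>%
    select("sample_id", "condition", "drug", v_flag = "v") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "v_flag",
                       names_prefix = "v_")
  if (all(c("v_2D", "v_3D") %in% names(flag_v))) {
    flag_v$decreased_sensitivity_3d <-
      decreased_sensitivity_flag(flag_v$v_3D, flag_v$v_2D, delta = delta)
  } else {
    flag_v$decreased_sensitivity_3d <- NA
  }

  summary <- wide %>%
    group_by(.data$condition, .data$drug) %>%
    mutate(percentile_rank = percentile_rank(.data$integrated_response)) %>%
    ungroup() %>%
    left_join(select(flag_v, "sample_id", "drug",
                     "decreased_sensitivity_3d"),
              by = c("sample_id", "drug"))

  paired <- wide %>%
    select("sample_id", "drug", "condition", "integrated_response") %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "integrated_response") %>%
    group_by(.data$drug) %>%
    dplyr::group_modify(function(df, key) {
      if (all(c("2D", "3D") %in% names(df))) {
        paired_condition_test(df[["3D"]], df[["2D"]])
      } else {
        tibble(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
               mean_log_ratio = NA_real_, direction = "none",
               n_pairs = 0L, flag = "missing_condition")
      }
    }) %>%
    ungroup()

  structure(
    list(summary = summary, paired_tests = paired,
         integrate_at = integrate_at, flag_at = flag_at, delta = delta),
    class = "drp_summary"
  )
}

#' @export
print.drp_summary <- function(x, ...) {
  cat(sprintf("<drp_summary> %d record(s), integrated over %s nM, flag at %g nM (>%g pts)\n",
              nrow(x$summary), paste(x$integrate_at, collapse = " + "),
              x$flag_at, x$delta))
  print(x$paired_tests)
  invisible(x)
}

#' @export
tidy.drp_summary <- function(x, ...) {
  x$summary
}

#' @export
glance.drp_summary <- function(x, ...) {
  x$paired_tests %>%
    mutate(flagged_fraction = vapply(.data$drug, function(dr) {
      s <- x$summary %>%
        filter(.data$drug == dr, .data$condition == "3D")
      mean(s$decreased_sensitivity_3d, na.rm = TRUE)
    }, numeric(1)))
}
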