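# Dye-dilution proliferation analysis: generation estimation and the
# trimodal non- / slow- / high-cycling classification.

#' Estimate division generations from dye intensity
#'
#' Under exact dye halving per division, `g = log2(i0 / i)`, clipped below at
#' zero (a cell cannot have divided a negative number of times).
#'
#' @param i Measured dye intensities (> 0).
#' @param i0 Generation-0 reference intensity (> 0), typically the median of
#'   an undivided (timepoint-0) sample.
#' @return Generations (float, >= 0), same length as `i`.
#' @examples
#' generations_from_intensity(c(1000, 125), 1000)  # 0 3
#' @export
generations_from_intensity <- function(i, i0) {
  assert_scalar_num(i0, "i0", lower = 0, strict = TRUE)
  if (any(!is.finite(i)) || any(i <= 0)) {
    abort("intensities must be finite and > 0")
  }
  pmax(log2(i0 / i), 0)
}

#' Trimodal cycling classification from dye intensities
#'
#' Classifies cells into non-cycling (high dye intensity), slow-cycling
#' (intermediate) and high-cycling (low) populations against a timepoint-0
#' reference sample, in log-intensity space:
#' * the non-cycling gate is anchored at the `t0_quantile` (default 2.5th)
#'   percentile of the T0 distribution -- cells above it have not measurably
#'   diluted dye;
#' * the remaining cells split slow vs high at `g_cut` generations below the
#'   T0 median: intensity below `median(t0) / 2^g_cut` is high-cycling.
#'
#' `g_cut` must place the slow/high cut strictly below the non-cycling
#' anchor. The classification is invariant to rescaling all intensities by a
#' common positive factor. The default `g_cut = 3` is an assay convention,
#' not a measured value; for mixtures generated with known division rates the
#' cut should sit between the expected generation counts of the slow and
#' high classes.
#'
#' @param intensities Test-sample dye intensities (> 0).
#' @param t0_intensities Timepoint-0 reference intensities (> 0, non-empty).
#' @param g_cut Generation cut separating slow from high cycling.
#' @param t0_quantile Quantile of the T0 distribution anchoring the
#'   non-cycling gate.
#' @return Object of class `cycle_classification`: list with `fractions`
#'   (named, sums to 1), `labels` (factor per cell), `thresholds`
#'   (log2-intensity cuts) and `n`. Empty test input yields NA fractions with
#'   a warning.
#' @export
classify_cycling <- function(intensities, t0_intensities, g_cut = 3,
                             t0_quantile = 0.025) {
  if (!length(t0_intensities)) abort("T0 reference sample must be non-empty")
  if (any(t0_intensities <= 0) || any(intensities <= 0, na.rm = TRUE)) {
    abort("intensities must be > 0 (gate out non-positive events upstream)")
  }
  assert_scalar_num(g_cut, "g_cut", lower = 0, strict = TRUE)

  l_t0 <- log2(t0_intensities)
  anchor <- unname(quantile(l_t0, t0_quantile))
  low_cut <- unname(median(l_t0)) - g_cut
  if (low_cut >= anchor) {
    abort("`g_cut` too small: slow/high cut must lie below the T0 anchor")
  }

  if (!length(intensities)) {
    warn("empty test sample: fractions undefined")
    return(structure(
      list(fractions = c(non_cycling = NA_real_, slow_cycling = NA_real_,
                         high_cycling = NA_real_),
           labels = factor(character(0),
                           levels = c("non_cycling", "slow_cycling",
                                      "high_cycling")),
           thresholds = c(non_cycling_log2 = anchor, high_cycling_log2 = low_cut),
           n = 0L),
      class = "cycle_classification"
    ))
  }

  li <- log2(intensities)
  cls <- ifelse(li > anchor, "non_cycling",
                ifelse(li < low_cut, "high_cycling", "slow_cycling"))
  labels <- factor(cls, levels = c("non_cycling", "slow_cycling", "high_cycling"))
  fr <- as.numeric(table(labels)) / length(labels)
  structure(
    list(
      fractions = setNames(fr, levels(labels)),
      labels = labels,
      thresholds = c(non_cycling_log2 = anchor, high_cycling_log2 = low_cut),
      n = length(labels)
    ),
    class = "cycle_classification"
  )
}

#' @export
print.cycle_classification <- function(x, ...) {
  cat("<cycle_classification>\n")
  cat(sprintf("  n = %d | non %.1f%% | slow %.1f%% | high %.1f%%\n",
              x$n, 100 * x$fractions[1], 100 * x$fractions[2],
              100 * x$fractions[3]))
  invisible(x)
}

#' @export
tidy.cycle_classification <- function(x, ...) {
  tibble(cycle_class = names(x$fractions), fraction = unname(x$fractions))
}

#' @export
glance.cycle_classification <- function(x, ...) {
  tibble(n = x$n,
         non_cycling_log2 = unname(x$thresholds["non_cycling_log2"]),
         high_cycling_log2 = unname(x$thresholds["high_cycling_log2"]))
}

#' Per-sample class-presence comparison between 3D and 2D cultures
#'
#' Flags, per sample and condition, whether each cycling class exceeds a
#' minimum fraction, and whether all three classes are simultaneously
#' present (the heterogeneity readout distinguishing the 3D niche from flat
#' culture).
#'
#' @param fractions_3d,fractions_2d Tibbles with `sample_id`, `non_cycling`,
#'   `slow_cycling`, `high_cycling`; samples must match one-to-one.
#' @param min_fraction Presence threshold (default 0.05).
#' @return Tibble `sample_id`, `condition`, per-class presence flags and
#'   `all_classes_present`.
#' @export
compare_2d_3d_cycling <- function(fractions_3d, fractions_2d,
                                  min_fraction = 0.05) {
  cols <- c("sample_id", "non_cycling", "slow_cycling", "high_cycling")
  assert_cols(fractions_3d, cols, "fractions_3d")
  assert_cols(fractions_2d, cols, "fractions_2d")
  if (!setequal(fractions_3d$sample_id, fractions_2d$sample_id) ||
      nrow(fractions_3d) != nrow(fractions_2d)) {
    abort("unmatched samples between conditions")
  }
  presence <- function(df, cond) {
    df %>%
      mutate(
        condition = cond,
        non_present = .data$non_cycling > min_fraction,
        slow_present = .data$slow_cycling > min_fraction,
        high_present = .data$high_cycling > min_fraction,
        all_classes_present = .data$non_present & .data$slow_present &
          .data$high_present
      ) %>%
      select("sample_id", "condition", "non_present", "slow_present",
             "high_present", "all_classes_present")
  }
  bind_rows(presence(fractions_3d, "3D"), presence(fractions_2d, "2D")) %>%
    arrange(.data$sample_id, .data$condition)
}
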