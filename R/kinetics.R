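# Timelapse frame linking and motility kinetics.

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between successive frames: a
#' detection in frame t and one in frame t+1 are linked iff each is the
#' other's nearest neighbour and they are at most `max_link_um` apart.
#' Mutual-NN pairs are one-to-one, so each detection joins at most one
#' track; unlinked detections start new tracks. No gap closing or
#' merge/split handling.
#'
#' @param detections Tibble with `t_min`, `x_um`, `y_um`, `z_um` (and
#'   optionally `cell_id`, carried through as `source_id`).
#' @param max_link_um Maximum link distance in micrometres.
#' @return Track tibble `track_id`, `t_min`, `x_um`, `y_um`, `z_um`,
#'   `source_id`, ordered by track and time.
#' @export
link_tracks <- function(detections, max_link_um) {
  assert_cols(detections, c("t_min", "x_um", "y_um", "z_um"), "detections")
  assert_scalar_num(max_link_um, "max_link_um", lower = 0, strict = TRUE)
  tps <- unique(detections$t_min)
  if (is.unsorted(tps)) abort("frames must be supplied in time order")
  if (length(tps) < 2) abort("need at least 2 frames to link")

  det <- detections
  det$source_id <- if ("cell_id" %in% names(det)) det$cell_id else NA_integer_
  frames <- lapply(tps, function(t) det[det$t_min == t, , drop = FALSE])

  next_track <- 0L
  new_ids <- function(n) {
    ids <- next_track + seq_len(n)
    next_track <<- next_track + n
    ids
  }
  frames[[1]]$track_id <- new_ids(nrow(frames[[1]]))

  for (f in seq_len(length(frames) - 1L)) {
    A <- frames[[f]]; B <- frames[[f + 1L]]
    B$track_id <- NA_integer_
    if (nrow(A) > 0 && nrow(B) > 0) {
      am <- as.matrix(A[, c("x_um", "y_um", "z_um")])
      bm <- as.matrix(B[, c("x_um", "y_um", "z_um")])
      fwd <- FNN::get.knnx(bm, am, k = 1)   # A's nearest in B
      bwd <- FNN::get.knnx(am, bm, k = 1)   # B's nearest in A
      j <- fwd$nn.index[, 1]
      mutual <- bwd$nn.index[j, 1] == seq_len(nrow(A)) &
        fwd$nn.dist[, 1] <= max_link_um
      B$track_id[j[mutual]] <- A$track_id[mutual]
    }
    unlinked <- is.na(B$track_id)
    if (any(unlinked)) B$track_id[unlinked] <- new_ids(sum(unlinked))
    frames[[f + 1L]] <- B
  }
  bind_rows(frames) %>%
    select("track_id", "t_min", "x_um", "y_um", "z_um", "source_id") %>%
    arrange(.data$track_id, .data$t_min)
}

#' Per-timepoint step size and speed along tracks
#'
#' At each interior timepoint (both temporal neighbours present), with
#' neighbour distances `d_minus = |p_i - p_(i-1)|` and
#' `d_plus = |p_(i+1) - p_i|`:
#' step size `= d_minus + d_plus` (micrometres) and speed
#' `= (d_minus + d_plus) / (t_(i+1) - t_(i-1))` (micrometres/minute, a
#' central difference). Kinetics are computed in the XY plane by default;
#' endpoints and tracks shorter than 3 observations get `NA` kinetics, not
#' an error.
#'
#' @param tracks Track tibble (`track_id`, `t_min`, `x_um`, `y_um`, `z_um`).
#' @param dims `"xy"` (default, matching in-plane motility readouts) or
#'   `"xyz"`.
#' @return Input tibble plus `step_size_um` and `speed_um_per_min`.
#' @examples
#' tr <- tibble::tibble(track_id = 1, t_min = c(0, 5, 10),
#'                      x_um = c(0, 5, 10), y_um = 0, z_um = 0)
#' compute_kinetics(tr)$speed_um_per_min  # NA 1 NA
#' @export
compute_kinetics <- function(tracks, dims = c("xy", "xyz")) {
  assert_cols(tracks, c("track_id", "t_min", "x_um", "y_um", "z_um"), "tracks")
  dims <- match.arg(dims)
  tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$t_min, .by_group = TRUE) %>%
    mutate(
      .dx = .data$x_um - dplyr::lag(.data$x_um),
      .dy = .data$y_um - dplyr::lag(.data$y_um),
      .dz = if (dims == "xyz") .data$z_um - dplyr::lag(.data$z_um) else 0,
      .d_minus = sqrt(.data$.dx^2 + .data$.dy^2 + .data$.dz^2),
      .d_plus = dplyr::lead(.data$.d_minus),
      step_size_um = .data$.d_minus + .data$.d_plus,
      speed_um_per_min = .data$step_size_um /
        (dplyr::lead(.data$t_min) - dplyr::lag(.data$t_min))
    ) %>%
    ungroup() %>%
    select(-dplyr::starts_with("."))
}

#' Per-track displacement over an initial time window
#'
#' Net start-to-end XY distance over the window `[t_start, t_start + W]`
#' (default W = 360 min, i.e. the first 6 h), using the last observation at
#' or before the window end; cumulative XY path length over the same window
#' is reported alongside.
#'
#' @param tracks Track tibble.
#' @param window_min Window length in minutes.
#' @param dims `"xy"` (default) or `"xyz"`.
#' @return Tibble `track_id`, `n_obs`, `t_start_min`, `t_end_min`,
#'   `displacement_um` (net), `path_length_um`.
#' @export
track_displacement <- function(tracks, window_min = 360, dims = c("xy", "xyz")) {
  assert_cols(tracks, c("track_id", "t_min", "x_um", "y_um", "z_um"), "tracks")
  dims <- match.arg(dims)
  assert_scalar_num(window_min, "window_min", lower = 0, strict = TRUE)
  tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$t_min, .by_group = TRUE) %>%
    filter(.data$t_min <= min(.data$t_min) + window_min) %>%
    summarise(
      n_obs = n(),
      t_start_min = min(.data$t_min),
      t_end_min = max(.data$t_min),
      displacement_um = sqrt(
        (dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
          (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2 +
          if (dims == "xyz") {
            (dplyr::last(.data$z_um) - dplyr::first(.data$z_um))^2
          } else 0
      ),
      path_length_um = sum(sqrt(
        diff(.data$x_um)^2 + diff(.data$y_um)^2 +
          if (dims == "xyz") diff(.data$z_um)^2 else 0
      )),
      .groups = "drop"
    )
}

#' Two-sample Kolmogorov-Smirnov comparison of motility distributions
#'
#' Wrapper around the standard two-sample KS test; the statistic is the
#' supremum of the two empirical CDF differences.
#'
#' @param a,b Numeric samples (speeds, displacements, distances...).
#' @return One-row tibble `statistic`, `p_value`, `n_a`, `n_b`, `flag`
#'   (`"small_sample"` when either n < 2, with `NA` results).
#' @export
compare_distributions <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    warn("need n >= 2 in both samples for a KS comparison")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n_a = length(a), n_b = length(b), flag = "small_sample"))
  }
  kt <- suppressWarnings(ks.test(a, b))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(a), n_b = length(b), flag = NA_character_)
}
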