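# Independent oracles, kept free of the code paths they check.

# O(n^2) nearest-neighbour distances, plain R.
brute_min_distances <- function(query, target, exclude_same_id = TRUE) {
  sapply(seq_len(nrow(query)), function(i) {
    dx <- target$x_um - query$x_um[i]
    dy <- target$y_um - query$y_um[i]
    dz <- target$z_um - query$z_um[i]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    if (exclude_same_id) d[target$cell_id == query$cell_id[i]] <- Inf
    min(d)
  })
}

# All-pairs minimum distance between two point sets (matrices).
brute_set_distance <- function(a, b) {
  dmin <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sqrt(colSums((t(b) - a[i, ])^2))
    dmin <- min(dmin, min(d))
  }
  dmin
}

# Supremum of ECDF differences (two-sample KS statistic), direct.
brute_ks_statistic <- function(a, b) {
  x <- sort(unique(c(a, b)))
  Fa <- vapply(x, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(x, function(v) mean(b <= v), numeric(1))
  max(abs(Fa - Fb))
}

# Percentile rank by direct sort-and-count with mean tie sharing.
brute_percentile_rank <- function(values) {
  n <- length(values)
  sapply(values, function(v) {
    below <- sum(values < v)
    ties <- sum(values == v) - 1
    100 * (below + ties / 2) / (n - 1)
  })
}

# Step/speed formula transcribed term by term on one track.
brute_kinetics <- function(t, x, y) {
  n <- length(t)
  step <- speed <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    d_minus <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
    d_plus <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    step[i] <- d_minus + d_plus
    speed[i] <- (d_minus + d_plus) / (t[i + 1] - t[i - 1])
  }
  list(step_size = step, speed = speed)
}

random_cells <- function(n, extent = c(200, 200, 100), ids = seq_len(n)) {
  tibble::tibble(
    cell_id = ids,
    x_um = stats::runif(n, 0, extent[1]),
    y_um = stats::runif(n, 0, extent[2]),
    z_um = stats::runif(n, 0, extent[3])
  )
}

# Small well-spread cell field for rendering tests: rejection-samples
# positions at pairwise distance >= min_sep, away from the volume border.
spread_cells <- function(n, extent, min_sep, margin = 12, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    p <- c(runif(1, margin, extent[1] - margin),
           runif(1, margin, extent[2] - margin),
           runif(1, margin, extent[3] - margin))
    if (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - p)^2))) >= min_sep) {
      pts <- rbind(pts, p)
    }
  }
  tibble::tibble(cell_id = seq_len(n), x_um = pts[, 1], y_um = pts[, 2],
                 z_um = pts[, 3])
}
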