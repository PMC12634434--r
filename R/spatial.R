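# Proximity, aggregation, z-distribution and migration-depth statistics.

#' Minimum centroid-to-centroid distances to a target population
#'
#' For each query cell, the Euclidean 3D distance (micrometres) to the
#' nearest target cell, via a kd-tree but contractually equal to exhaustive
#' search. When a query cell also appears in the target set (same
#' `cell_id`), the identity match is excluded and the nearest *other* target
#' is used, so self-distances are never 0.
#'
#' @param query,target Tibbles with `cell_id`, `x_um`, `y_um`, `z_um`
#'   (one well, one timepoint).
#' @return Tibble `cell_id`, `distance_um`, `neighbor_id`, `flag`
#'   (`NA` flag when defined; `"empty_target"` / `"no_other_target"` rows
#'   carry `NA` distances rather than sentinels).
#' @examples
#' q <- tibble::tibble(cell_id = 1, x_um = 0, y_um = 0, z_um = 0)
#' t <- tibble::tibble(cell_id = 2, x_um = 3, y_um = 4, z_um = 0)
#' min_centroid_distances(q, t)$distance_um  # 5
#' @export
min_centroid_distances <- function(query, target) {
  assert_cols(query, c("cell_id", "x_um", "y_um", "z_um"), "query")
  assert_cols(target, c("cell_id", "x_um", "y_um", "z_um"), "target")
  if (nrow(query) == 0) {
    return(tibble(cell_id = integer(0), distance_um = numeric(0),
                  neighbor_id = integer(0), flag = character(0)))
  }
  if (nrow(target) == 0) {
    warn("empty target population: distances undefined")
    return(tibble(cell_id = query$cell_id, distance_um = NA_real_,
                  neighbor_id = NA_integer_, flag = "empty_target"))
  }
  qm <- as.matrix(query[, c("x_um", "y_um", "z_um")])
  tm <- as.matrix(target[, c("x_um", "y_um", "z_um")])
  k <- min(2L, nrow(target))
  nn <- FNN::get.knnx(tm, qm, k = k)

  d1 <- nn$nn.dist[, 1]
  id1 <- target$cell_id[nn$nn.index[, 1]]
  self_hit <- query$cell_id == id1
  dist_um <- d1
  nbr <- id1
  flag <- rep(NA_character_, nrow(query))
  if (any(self_hit)) {
    if (k >= 2) {
      dist_um[self_hit] <- nn$nn.dist[self_hit, 2]
      nbr[self_hit] <- target$cell_id[nn$nn.index[self_hit, 2]]
    } else {
      dist_um[self_hit] <- NA_real_
      nbr[self_hit] <- NA_integer_
      flag[self_hit] <- "no_other_target"
    }
  }
  tibble(cell_id = query$cell_id, distance_um = dist_um,
         neighbor_id = nbr, flag = flag)
}

#' Per-cell distance records to each neighbour class
#'
#' Convenience wrapper building the standard per-ALL-cell record: minimum
#' distance to the nearest other ALL cell (`d_all`), nearest MSC (`d_msc`)
#' and nearest endothelial cell (`d_ec`), centroid mode.
#'
#' @param cells One-timepoint observation tibble with `cell_id`, `cell_type`,
#'   `x_um`, `y_um`, `z_um`.
#' @param query_type Cell type the records are computed for (default ALL).
#' @return Tibble `cell_id`, `d_all`, `d_msc`, `d_ec`, `mode`.
#' @export
distance_records <- function(cells, query_type = "ALL") {
  assert_cols(cells, c("cell_id", "cell_type", "x_um", "y_um", "z_um"), "cells")
  q <- filter(cells, .data$cell_type == query_type)
  one <- function(type) {
    tgt <- filter(cells, .data$cell_type == type)
    if (nrow(tgt) == 0) return(rep(NA_real_, nrow(q)))
    min_centroid_distances(q, tgt)$distance_um
  }
  tibble(
    cell_id = q$cell_id,
    d_all = one("ALL"),
    d_msc = one("MSC"),
    d_ec = one("EC"),
    mode = "centroid"
  )
}

# Exposed-face centers of every object in a label volume: for each surface
# voxel (>= 1 background or different-label 6-neighbour), the centers of its
# exposed faces, at voxel center +/- d/2 along the exposed axis.
border_points <- function(lab) {
  L <- lab$labels
  d <- dim(L)
  vs <- lab$voxel_size
  pts <- list()
  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L),
                 c(0L, 0L, 1L), c(0L, 0L, -1L))
  pos <- which(L > 0L)
  if (!length(pos)) {
    return(tibble(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                  z_um = numeric(0)))
  }
  coord <- arrayInd(pos, d)
  ids <- L[pos]
  for (s in shifts) {
    nb_coord <- sweep(coord, 2, s, "+")
    inside <- nb_coord[, 1] >= 1 & nb_coord[, 1] <= d[1] &
      nb_coord[, 2] >= 1 & nb_coord[, 2] <= d[2] &
      nb_coord[, 3] >= 1 & nb_coord[, 3] <= d[3]
    nb_lab <- integer(length(pos))
    if (any(inside)) {
      lin <- (nb_coord[inside, 3] - 1L) * d[1] * d[2] +
        (nb_coord[inside, 2] - 1L) * d[1] + nb_coord[inside, 1]
      nb_lab[inside] <- L[lin]
    }
    exposed <- nb_lab != ids
    if (any(exposed)) {
      center <- sweep(coord[exposed, , drop = FALSE] - 0.5, 2, vs, "*")
      face <- center + matrix(s * vs / 2, sum(exposed), 3, byrow = TRUE)
      pts[[length(pts) + 1L]] <- tibble(
        label = ids[exposed], x_um = face[, 1], y_um = face[, 2],
        z_um = face[, 3]
      )
    }
  }
  bind_rows(pts)
}

#' Minimum border-to-border distances between two labelled volumes
#'
#' For each object in the query volume, the minimum Euclidean distance
#' between its border and the border of the nearest target object, in
#' micrometres. Borders are represented by exposed-face centers (the centers
#' of voxel faces adjoining background under 6-connectivity), so touching
#' objects score 0 and two unit voxels 10 um apart (1 um voxels) score 9 um.
#' Objects whose voxels overlap a target object score 0 exactly.
#'
#' @param query_lab,target_lab [label_volume()]s of identical shape and voxel
#'   size.
#' @return Tibble `label`, `distance_um`, `flag`.
#' @export
min_border_distances <- function(query_lab, target_lab) {
  stopifnot(inherits(query_lab, "label_volume"),
            inherits(target_lab, "label_volume"))
  if (!identical(dim(query_lab$labels), dim(target_lab$labels)) ||
      !isTRUE(all.equal(as.numeric(query_lab$voxel_size),
                        as.numeric(target_lab$voxel_size)))) {
    abort("query and target volumes must be aligned (same shape and voxel size)")
  }
  q_ids <- sort(setdiff(unique(as.vector(query_lab$labels)), 0L))
  if (!length(q_ids)) {
    return(tibble(label = integer(0), distance_um = numeric(0),
                  flag = character(0)))
  }
  tp <- border_points(target_lab)
  if (nrow(tp) == 0) {
    warn("empty target labels: border distances undefined")
    return(tibble(label = q_ids, distance_um = NA_real_, flag = "empty_target"))
  }
  qp <- border_points(query_lab)
  nn <- FNN::get.knnx(as.matrix(tp[, c("x_um", "y_um", "z_um")]),
                      as.matrix(qp[, c("x_um", "y_um", "z_um")]), k = 1)
  per_label <- tibble(label = qp$label, d = nn$nn.dist[, 1]) %>%
    group_by(.data$label) %>%
    summarise(distance_um = min(.data$d), .groups = "drop")

  # voxel-overlap with any target object => contact, distance 0
  overlap <- query_lab$labels > 0L & target_lab$labels > 0L
  if (any(overlap)) {
    hit <- unique(query_lab$labels[overlap])
    per_label$distance_um[per_label$label %in% hit] <- 0
  }
  tibble(label = q_ids) %>%
    left_join(per_label, by = "label") %>%
    mutate(flag = NA_character_)
}

#' Fraction of cells within a proximity threshold
#'
#' Fraction of distances strictly below the threshold (the "< 10 um"
#' convention of immediate cell-cell proximity).
#'
#' @param distances Numeric distances in micrometres.
#' @param threshold_um Threshold, default 10 um.
#' @param na_rm Drop undefined (NA) distances before computing.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) for empty input.
#' @export
proximity_fraction <- function(distances, threshold_um = 10, na_rm = TRUE) {
  assert_scalar_num(threshold_um, "threshold_um", lower = 0, strict = TRUE)
  if (na_rm) distances <- distances[!is.na(distances)]
  if (!length(distances)) {
    warn("no distances: proximity fraction undefined")
    return(NA_real_)
  }
  mean(distances < threshold_um)
}

#' Histogram with bins centered at multiples of the bin width
#'
#' Bin k is centered at `k * w` (k = 0, 1, 2, ...) and spans the half-open
#' interval `[k*w - w/2, k*w + w/2)`; counts conserve the sample size.
#'
#' @param distances Non-negative values (micrometres).
#' @param bin_center_width Bin width `w` (> 0); the convention used for
#'   cell-cell distance plots is `w = 5`, for motility plots `w = 2`.
#' @return Tibble `bin_center`, `count`, including interior zero-count bins.
#' @export
distance_histogram <- function(distances, bin_center_width) {
  assert_scalar_num(bin_center_width, "bin_center_width", lower = 0,
                    strict = TRUE)
  if (any(is.na(distances))) abort("NA distances are not allowed here")
  if (any(distances < 0)) abort("negative distances violate the contract")
  if (!length(distances)) {
    return(tibble(bin_center = numeric(0), count = integer(0)))
  }
  w <- bin_center_width
  k <- floor(distances / w + 0.5)
  tab <- table(factor(k, levels = 0:max(k)))
  tibble(bin_center = as.numeric(names(tab)) * w,
         count = as.integer(tab))
}

#' Depth-distribution profile of a timelapse
#'
#' Normalizes each timepoint's depths by its median (per-timepoint median of
#' normalized z is 0 by construction) and summarizes vertical migration: the
#' shift in raw median depth from the first to the last timepoint
#' (`delta_median_um`, positive = net downward) and the raw depth standard
#' deviation at the first and last timepoints.
#'
#' @param cells Observation tibble with `t_min` and `z_um` (>= 2 timepoints);
#'   typically pre-filtered to one cell type.
#' @return Object of class `z_profile`: list with `normalized` (tibble
#'   `t_min`, `z_norm_um`), `delta_median_um`, `sd_t0_um`, `sd_tend_um`,
#'   `t0_min`, `tend_min`.
#' @export
z_profile <- function(cells) {
  assert_cols(cells, c("t_min", "z_um"), "cells")
  cells <- filter(cells, !is.na(.data$z_um))
  tps <- sort(unique(cells$t_min))
  if (length(tps) < 2) abort("z_profile needs at least 2 timepoints")
  norm <- cells %>%
    group_by(.data$t_min) %>%
    mutate(z_norm_um = .data$z_um - median(.data$z_um)) %>%
    ungroup() %>%
    select("t_min", "z_norm_um")
  z0 <- cells$z_um[cells$t_min == tps[1]]
  zE <- cells$z_um[cells$t_min == tps[length(tps)]]
  structure(
    list(
      normalized = norm,
      delta_median_um = median(zE) - median(z0),
      sd_t0_um = sd(z0),
      sd_tend_um = sd(zE),
      t0_min = tps[1],
      tend_min = tps[length(tps)]
    ),
    class = "z_profile"
  )
}

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf(
    "<z_profile> t %g..%g min | delta median %.2f um | SD %.2f -> %.2f um\n",
    x$t0_min, x$tend_min, x$delta_median_um, x$sd_t0_um, x$sd_tend_um))
  invisible(x)
}

#' Migration depth percentages relative to the shallowest leukemic cell
#'
#' The reference depth is that of the "highest" (shallowest) cell of the
#' reference type; every cell's migration percentage is its depth below that
#' reference, as a percentage of the gel depth. The reference cell scores 0%.
#'
#' @param cells One-timepoint tibble with `cell_type` and `z_um`.
#' @param gel_depth_um Gel depth (denominator), micrometres.
#' @param reference_type Cell type defining the reference (default `"ALL"`).
#' @return Input tibble with a `migration_pct` column; the reference depth is
#'   attached as attribute `z_ref_um`.
#' @export
migration_percent <- function(cells, gel_depth_um, reference_type = "ALL") {
  assert_cols(cells, c("cell_type", "z_um"), "cells")
  assert_scalar_num(gel_depth_um, "gel_depth_um", lower = 0, strict = TRUE)
  ref <- cells$z_um[cells$cell_type == reference_type]
  if (!length(ref)) abort(paste0("no ", reference_type, " cells to anchor the reference"))
  z_ref <- min(ref)
  out <- mutate(cells, migration_pct = 100 * (.data$z_um - z_ref) / gel_depth_um)
  attr(out, "z_ref_um") <- z_ref
  out
}

#' Fraction of leukemic cells in direct contact with the network
#'
#' A cell counts as in contact when its migration percentage reaches the
#' network's depth percentage minus a tolerance band.
#'
#' @param all_percents Migration percentages of the ALL cells.
#' @param network_percent Network depth percentage (default 40, the settling
#'   depth of the vasculature-like structures).
#' @param band Tolerance band in percentage points (default 10).
#' @return Fraction in `[0, 1]`; `NA` with a warning on empty input.
#' @export
network_contact_fraction <- function(all_percents, network_percent = 40,
                                     band = 10) {
  if (network_percent < 0 || network_percent > 100) {
    abort("`network_percent` must lie in [0, 100]")
  }
  assert_scalar_num(band, "band", lower = 0, strict = TRUE)
  all_percents <- all_percents[!is.na(all_percents)]
  if (!length(all_percents)) {
    warn("no migration percentages: contact fraction undefined")
    return(NA_real_)
  }
  mean(all_percents >= network_percent - band)
}
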