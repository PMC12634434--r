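# Segmentation analogues of the commercial "find image region" /
# "find nuclei" building blocks, plus morphometry and centroid extraction.

#' Threshold-based region segmentation of a channel
#'
#' Reference analogue of intensity-threshold region finding: voxels above the
#' threshold are foreground, connected components (26-connectivity in 3D) are
#' labelled, and components below the minimum volume are dropped. In
#' `"local"` mode the threshold is a fraction of a local background estimate
#' (a wide Gaussian blur of the image, scale `local_sigma_um`); in
#' `"absolute"` mode it is in intensity units. Thresholds are
#' fluorophore-dependent and therefore always explicit, never defaulted.
#'
#' @param stack An [image_stack()].
#' @param threshold_mode `"absolute"` or `"local"`.
#' @param threshold Intensity (absolute mode) or fraction of the local
#'   background estimate (local mode).
#' @param min_volume Minimum object size in voxels (default 2).
#' @param local_sigma_um Background estimation scale for local mode.
#' @return A [label_volume()] with labels 1..K; an all-zero stack yields an
#'   empty labelling, not an error.
#' @export
segment_region <- function(stack, threshold_mode = c("absolute", "local"),
                           threshold, min_volume = 2, local_sigma_um = 50) {
  stopifnot(inherits(stack, "image_stack"))
  threshold_mode <- match.arg(threshold_mode)
  if (missing(threshold)) abort("`threshold` is required (fluorophore-dependent)")
  assert_scalar_num(threshold, "threshold", lower = 0)

  img <- stack$voxels
  mask <- if (threshold_mode == "absolute") {
    img >= threshold
  } else {
    bg <- cpp_gaussian_blur(as.numeric(img), dim(img),
                            local_sigma_um / stack$voxel_size)
    img >= threshold * array(bg, dim = dim(img))
  }
  lab <- cpp_label_components(as.logical(mask), dim(img))
  lab <- filter_small_labels(lab, min_volume)
  dim(lab) <- dim(img)
  label_volume(lab, stack$voxel_size, channel = stack$channel)
}

# Drop labels below min_volume and relabel contiguously 1..K.
filter_small_labels <- function(lab, min_volume) {
  if (!any(lab > 0)) return(as.integer(lab))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_volume)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- integer(length(lab))
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  out
}

#' Spot-like 3D nucleus segmentation of leukemic cells
#'
#' Reference analogue of spot/nucleus finding for roughly spherical dim
#' objects in anisotropic z-stacks:
#' anisotropy-aware Gaussian smoothing (sd = `smooth_sigma_um` per axis,
#' converted to voxels by the voxel size), local-maxima seeding with a
#' minimum separation of `expected_radius_um` (brighter maxima win), a
#' seeded watershed on the inverted smoothed intensity restricted to the
#' foreground mask, and a size filter. Two seeds closer than the minimum
#' separation merge into one object by construction.
#'
#' @param stack An [image_stack()].
#' @param expected_radius_um Expected cell radius in micrometres (> 0).
#' @param threshold Foreground threshold on the smoothed image (intensity
#'   units); required, fluorophore-dependent.
#' @param smooth_sigma_um Smoothing scale; default `expected_radius_um / 2`.
#' @param min_volume Minimum object size in voxels.
#' @return List with `labels` (a [label_volume()]) and `centroids` (tibble of
#'   per-object centroids in micrometres, from [extract_positions()]).
#' @export
segment_nuclei <- function(stack, expected_radius_um, threshold,
                           smooth_sigma_um = expected_radius_um / 2,
                           min_volume = 2) {
  stopifnot(inherits(stack, "image_stack"))
  assert_scalar_num(expected_radius_um, "expected_radius_um", lower = 0,
                    strict = TRUE)
  if (missing(threshold)) abort("`threshold` is required (fluorophore-dependent)")

  img <- stack$voxels
  d <- dim(img)
  vs <- stack$voxel_size
  smooth <- array(cpp_gaussian_blur(as.numeric(img), d, smooth_sigma_um / vs),
                  dim = d)

  if (!any(smooth > threshold)) {
    empty <- label_volume(array(0L, dim = d), vs, channel = stack$channel)
    return(list(labels = empty, centroids = empty_positions(stack$channel)))
  }

  peaks <- cpp_local_maxima(as.numeric(smooth), d, threshold)
  if (!length(peaks)) {
    empty <- label_volume(array(0L, dim = d), vs, channel = stack$channel)
    return(list(labels = empty, centroids = empty_positions(stack$channel)))
  }
  # quantized images produce plateau maxima: collapse 26-connected plateaus
  # to a single representative voxel each
  if (length(peaks) > 1) {
    pk_mask <- array(FALSE, dim = d)
    pk_mask[peaks] <- TRUE
    pk_lab <- cpp_label_components(as.logical(pk_mask), d)[peaks]
    keep <- !duplicated(pk_lab)
    peaks <- peaks[keep]
  }
  coord <- arrayInd(peaks, d)
  pos_um <- sweep((coord - 0.5), 2, vs, "*")
  ord <- order(smooth[peaks], decreasing = TRUE)

  # greedy non-maximum suppression at the minimum separation
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted)) {
      accepted <- i
      next
    }
    dmin <- min(sqrt(rowSums(
      (pos_um[accepted, , drop = FALSE] -
         matrix(pos_um[i, ], length(accepted), 3, byrow = TRUE))^2
    )))
    if (dmin >= expected_radius_um) accepted <- c(accepted, i)
  }

  seeds <- array(0L, dim = d)
  seeds[peaks[accepted]] <- seq_along(accepted)
  mask <- smooth > threshold
  lab <- cpp_watershed(as.numeric(-smooth), as.integer(seeds),
                       as.logical(mask), d)
  lab <- filter_small_labels(lab, min_volume)
  dim(lab) <- d
  volume <- label_volume(lab, vs, channel = stack$channel)
  list(labels = volume, centroids = extract_positions(volume))
}

empty_positions <- function(channel) {
  tibble(cell_id = integer(0), cell_type = character(0),
         x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
         n_voxels = integer(0))
}

#' Volume and surface-area morphometry of a labelled volume
#'
#' Per-label volume is voxel count times the physical voxel volume
#' (`dx*dy*dz`); surface area counts exposed voxel faces (a face whose
#' 6-neighbour is a different label, background, or outside the volume),
#' weighted by the physical face area. This is a voxel-surface definition,
#' not a marching-cubes mesh area.
#'
#' @param lab A [label_volume()].
#' @return List with `total_volume_um3`, `total_surface_um2` and `per_label`
#'   (tibble `label`, `n_voxels`, `volume_um3`, `surface_um2`). Zero labels
#'   give zero totals and an empty table.
#' @export
measure_volume_surface <- function(lab) {
  stopifnot(inherits(lab, "label_volume"))
  L <- lab$labels
  vs <- lab$voxel_size
  K <- max(L)
  if (K == 0) {
    return(list(
      total_volume_um3 = 0, total_surface_um2 = 0,
      per_label = tibble(label = integer(0), n_voxels = integer(0),
                         volume_um3 = numeric(0), surface_um2 = numeric(0))
    ))
  }
  n_vox <- tabulate(L, nbins = K)
  face_area <- c(vs["dy"] * vs["dz"], vs["dx"] * vs["dz"], vs["dx"] * vs["dy"])

  # exposed-face counts per label per axis via shifted comparisons
  d <- dim(L)
  exposed <- matrix(0, nrow = K, ncol = 3)
  for (ax in 1:3) {
    n_ax <- d[ax]
    idx <- function(shift) {
      # neighbour label along `ax` at offset `shift`, 0 outside the volume
      nb <- array(0L, dim = d)
      src <- lapply(d, seq_len)
      dst <- src
      if (shift == 1L) {
        dst[[ax]] <- seq_len(n_ax - 1L); src[[ax]] <- 2:n_ax
      } else {
        dst[[ax]] <- 2:n_ax; src[[ax]] <- seq_len(n_ax - 1L)
      }
      if (n_ax > 1L) {
        nb <- do.call(`[<-`, c(list(nb), dst, list(do.call(`[`, c(list(L), src)))))
      }
      nb
    }
    for (shift in c(1L, -1L)) {
      nb <- idx(shift)
      hit <- L > 0L & nb != L
      if (any(hit)) {
        counts <- tabulate(L[hit], nbins = K)
        exposed[, ax] <- exposed[, ax] + counts
      }
    }
  }
  surf <- as.numeric(exposed %*% face_area)
  vol <- n_vox * prod(vs)
  per_label <- tibble(label = seq_len(K), n_voxels = n_vox,
                      volume_um3 = vol, surface_um2 = surf) %>%
    filter(.data$n_voxels > 0)
  list(
    total_volume_um3 = sum(per_label$volume_um3),
    total_surface_um2 = sum(per_label$surface_um2),
    per_label = per_label
  )
}

#' Extract per-object centroid positions from a label volume
#'
#' Geometric (intensity-independent) centroids in micrometres: the mean of
#' labelled voxel centers, with voxel centers at `(i + 0.5) * d` per axis
#' under 0-based voxel indexing.
#'
#' @param lab A [label_volume()].
#' @return Tibble `cell_id`, `cell_type`, `x_um`, `y_um`, `z_um`, `n_voxels`.
#' @export
extract_positions <- function(lab) {
  stopifnot(inherits(lab, "label_volume"))
  L <- lab$labels
  if (!any(L > 0)) return(empty_positions(lab$channel))
  vs <- lab$voxel_size
  pos <- which(L > 0L)
  ids <- L[pos]
  coord <- arrayInd(pos, dim(L))
  centers <- sweep(coord - 0.5, 2, vs, "*")
  agg <- rowsum(centers, group = ids)
  n <- as.integer(rowsum(rep(1, length(ids)), group = ids))
  tibble(
    cell_id = as.integer(rownames(agg)),
    cell_type = lab$channel,
    x_um = unname(agg[, 1] / n),
    y_um = unname(agg[, 2] / n),
    z_um = unname(agg[, 3] / n),
    n_voxels = unname(n)
  )
}
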