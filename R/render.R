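# Voxel renderers: turn simulated cells and network geometry into image
# stacks so the segmentation stages can be exercised (and ground-truthed)
# without microscopy data.

default_stack_dims <- function(extent_um, voxel_size) {
  pmax(1L, as.integer(ceiling(extent_um / voxel_size)))
}

#' Render point-like cells into a 3D image stack
#'
#' Each cell becomes an anisotropy-aware Gaussian spot (sd = `radius_um / 2`
#' per axis, in micrometres) of peak `amplitude`, on a dark background with
#' additive Gaussian read noise `amplitude / snr` (clipped at zero). Voxel
#' centers sit at `(i + 0.5) * d` per axis (0-based voxel indexing), matching
#' the centroid convention of [extract_positions()].
#'
#' @param cells Tibble with `x_um`, `y_um`, `z_um` (one timepoint).
#' @param extent_um Physical extent `(x, y, z)` of the rendered volume in
#'   micrometres.
#' @param voxel_size `(dx, dy, dz)` in micrometres; anisotropic by default.
#' @param radius_um Apparent cell radius.
#' @param amplitude Peak intensity.
#' @param snr Peak signal-to-noise ratio; `Inf` renders noiselessly.
#' @param channel Channel label carried into the stack.
#' @param seed Seed for the noise draw.
#' @return An [image_stack()].
#' @export
render_cells <- function(cells, extent_um, voxel_size = c(2, 2, 8),
                         radius_um = 5, amplitude = 1000, snr = 10,
                         channel = "ALL", seed = 1L) {
  assert_cols(cells, c("x_um", "y_um", "z_um"), "cells")
  dims <- default_stack_dims(extent_um, voxel_size)
  img <- array(0, dim = dims)
  sig <- rep(radius_um / 2, 3)
  half <- ceiling(3 * sig / voxel_size)
  centers <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size[a])
  for (r in seq_len(nrow(cells))) {
    p <- c(cells$x_um[r], cells$y_um[r], cells$z_um[r])
    iv <- floor(p / voxel_size)
    rng <- lapply(1:3, function(a) {
      lo <- max(1L, iv[a] + 1L - half[a]); hi <- min(dims[a], iv[a] + 1L + half[a])
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) next
    gx <- exp(-0.5 * ((centers[[1]][rng[[1]]] - p[1]) / sig[1])^2)
    gy <- exp(-0.5 * ((centers[[2]][rng[[2]]] - p[2]) / sig[2])^2)
    gz <- exp(-0.5 * ((centers[[3]][rng[[3]]] - p[3]) / sig[3])^2)
    spot <- amplitude * outer(outer(gx, gy), gz)
    dim(spot) <- c(length(gx), length(gy), length(gz))
    img[rng[[1]], rng[[2]], rng[[3]]] <-
      img[rng[[1]], rng[[2]], rng[[3]]] + spot
  }
  if (is.finite(snr) && snr > 0) {
    img <- with_stage_seed(seed, "render", {
      pmax(img + array(rnorm(length(img), 0, amplitude / snr), dim = dims), 0)
    })
  }
  image_stack(img, voxel_size, channel = channel)
}

#' Render a tubular network geometry into a stack and ground-truth mask
#'
#' Voxels whose centers lie within `radius_um` of any centerline polyline are
#' tube voxels. The intensity image is the mask at `amplitude` with Gaussian
#' noise `amplitude / snr`.
#'
#' @param geometry Output of [generate_network_geometry()] (or any tibble
#'   with `segment_id`, `x_um`, `y_um`, `z_um`, `radius_um`).
#' @param extent_um Physical extent `(x, y, z)` of the rendered volume.
#' @param voxel_size `(dx, dy, dz)` micrometres.
#' @param amplitude Peak intensity.
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param channel Channel label.
#' @param seed Noise seed.
#' @return List with `stack` (an [image_stack()]) and `mask` (logical 3D
#'   array of true tube voxels).
#' @export
render_network <- function(geometry, extent_um, voxel_size = c(2, 2, 8),
                           amplitude = 1000, snr = 10, channel = "EC",
                           seed = 1L) {
  assert_cols(geometry, c("segment_id", "x_um", "y_um", "z_um", "radius_um"),
              "geometry")
  dims <- default_stack_dims(extent_um, voxel_size)
  centers <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size[a])
  mask <- array(FALSE, dim = dims)

  segs <- split(geometry, geometry$segment_id)
  for (seg in segs) {
    pts <- as.matrix(seg[, c("x_um", "y_um", "z_um")])
    r <- seg$radius_um[1]
    for (e in seq_len(nrow(pts) - 1L)) {
      a <- pts[e, ]; b <- pts[e + 1L, ]
      lo <- pmin(a, b) - r; hi <- pmax(a, b) + r
      rng <- lapply(1:3, function(ax) {
        which(centers[[ax]] >= lo[ax] & centers[[ax]] <= hi[ax])
      })
      if (any(lengths(rng) == 0)) next
      cx <- centers[[1]][rng[[1]]]; cy <- centers[[2]][rng[[2]]]
      cz <- centers[[3]][rng[[3]]]
      grid <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
      ab <- b - a
      len2 <- sum(ab^2)
      tpar <- if (len2 > 0) {
        pmin(pmax((sweep(grid, 2, a) %*% ab) / len2, 0), 1)
      } else {
        matrix(0, nrow(grid), 1)
      }
      proj <- sweep(tpar %*% t(ab), 2, a, "+")
      d2 <- rowSums((grid - proj)^2)
      inside <- d2 <= r^2
      if (any(inside)) {
        sub <- array(FALSE, dim = lengths(rng))
        sub[inside] <- TRUE
        mask[rng[[1]], rng[[2]], rng[[3]]] <-
          mask[rng[[1]], rng[[2]], rng[[3]]] | sub
      }
    }
  }

  img <- array(0, dim = dims)
  img[mask] <- amplitude
  if (is.finite(snr) && snr > 0) {
    img <- with_stage_seed(seed, "render", {
      pmax(img + array(rnorm(length(img), 0, amplitude / snr), dim = dims), 0)
    })
  }
  list(stack = image_stack(img, voxel_size, channel = channel), mask = mask)
}
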