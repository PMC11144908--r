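# First-order, shape and discretization primitives of the radiomics
# extractor. Feature definitions follow the IBSI reference; degenerate ROIs
# get documented fallback values rather than NaN.

#' Discretize a volume inside a mask with a fixed bin width
#'
#' `level(v) = floor((v - min_masked) / bin_width) + 1`; the masked maximum
#' falls in level `floor((max - min)/bin_width) + 1`.
#'
#' @param volume a [setmag_volume()] or 3D array
#' @param mask binary 3D mask (same shape)
#' @param bin_width positive bin width in intensity units
#' @return object of class `discretized_roi`: `levels` (integer array, NA
#'   outside the mask), `n_levels`, `bin_width`, `mask`
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  arr <- if (inherits(volume, "setmag_volume")) volume$intensity else volume
  if (!any(mask)) stop("mask is empty")
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- min(arr[mask])
  lev <- array(NA_integer_, dim(arr))
  lev[mask] <- as.integer(floor((arr[mask] - lo) / bin_width)) + 1L
  structure(list(levels = lev, n_levels = max(lev[mask]),
                 bin_width = bin_width, mask = mask),
            class = "discretized_roi")
}

# Crop a levels array to the bounding box of its non-NA cells.
crop_levels <- function(lev) {
  nz <- which(!is.na(lev), arr.ind = TRUE)
  lev[min(nz[, 1L]):max(nz[, 1L]),
      min(nz[, 2L]):max(nz[, 2L]),
      min(nz[, 3L]):max(nz[, 3L]), drop = FALSE]
}

firstorder_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

#' First-order intensity statistics (18 features)
#'
#' @param values numeric vector of ROI intensities
#' @param bin_width bin width for the histogram-based entropy/uniformity
#' @param voxel_volume physical voxel volume in mm^3 (for total energy)
#' @return named numeric vector of the 18 first-order features
#' @export
first_order_features <- function(values, bin_width = 25, voxel_volume = 1) {
  if (length(values) == 0L) stop("empty ROI")
  n <- length(values)
  m <- mean(values)
  v <- mean((values - m)^2)
  q <- unname(stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  inr <- values[values >= q[1L] & values <= q[5L]]
  lev <- floor((values - min(values)) / bin_width) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  skew <- if (v > 0) mean((values - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((values - m)^4) / v^2 else 0
  out <- c(
    sum(values^2),
    voxel_volume * sum(values^2),
    -sum(p * log2(p)),
    min(values),
    q[1L],
    q[5L],
    max(values),
    m,
    q[3L],
    q[4L] - q[2L],
    max(values) - min(values),
    mean(abs(values - m)),
    if (length(inr)) mean(abs(inr - mean(inr))) else 0,
    sqrt(mean(values^2)),
    skew,
    kurt,
    v,
    sum(p^2))
  stats::setNames(out, paste0("firstorder_", firstorder_names))
}

shape_names <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
  "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")

#' 3D shape features of a binary mask (14 features)
#'
#' Volumes are voxel-counting volumes and the surface area is the total
#' area of exposed voxel faces (the package's voxel-based convention; the
#' two volume entries coincide under it). Diameters are maximal pairwise
#' distances between surface-voxel centres: in 3D, per axial slice, per
#' column plane, and per row plane. Axis lengths derive from the principal
#' components of the physical voxel-centre coordinates
#' (\eqn{4\sqrt{\lambda}}).
#'
#' @param mask binary 3D array
#' @param spacing voxel spacing in mm
#' @return named numeric vector of the 14 shape features
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (!any(mask)) stop("mask is empty")
  d <- dim(mask)
  n <- sum(mask)
  vox_vol <- prod(spacing)
  vol <- n * vox_vol

  # exposed faces per axis
  area <- 0
  for (axis in 1:3) {
    face_area <- prod(spacing[-axis])
    nn <- d[axis]
    up <- pmin(seq_len(nn) + 1L, nn)
    dn <- pmax(seq_len(nn) - 1L, 1L)
    get_ax <- function(i) {
      if (axis == 1L) mask[i, , , drop = FALSE]
      else if (axis == 2L) mask[, i, , drop = FALSE]
      else mask[, , i, drop = FALSE]
    }
    nb_hi <- get_ax(up); nb_hi[slice.index(mask, axis) == nn] <- FALSE
    nb_lo <- get_ax(dn); nb_lo[slice.index(mask, axis) == 1L] <- FALSE
    area <- area + face_area * (sum(mask & !nb_hi) + sum(mask & !nb_lo))
  }

  # surface voxels: mask voxels with at least one exposed 6-face
  interior <- mask
  for (axis in 1:3) {
    nn <- d[axis]
    up <- pmin(seq_len(nn) + 1L, nn)
    dn <- pmax(seq_len(nn) - 1L, 1L)
    if (axis == 1L) {
      hi <- mask[up, , , drop = FALSE]; lo <- mask[dn, , , drop = FALSE]
      hi[nn, , ] <- FALSE; lo[1L, , ] <- FALSE
    } else if (axis == 2L) {
      hi <- mask[, up, , drop = FALSE]; lo <- mask[, dn, , drop = FALSE]
      hi[, nn, ] <- FALSE; lo[, 1L, ] <- FALSE
    } else {
      hi <- mask[, , up, drop = FALSE]; lo <- mask[, , dn, drop = FALSE]
      hi[, , nn] <- FALSE; lo[, , 1L] <- FALSE
    }
    interior <- interior & hi & lo
  }
  surf <- mask & !interior
  sc <- which(surf, arr.ind = TRUE)
  pc <- sweep(sc, 2L, spacing, "*")

  max_pair <- function(xy) {
    if (nrow(xy) < 2L) return(0)
    max(stats::dist(xy))
  }
  d3 <- max_pair(pc)
  by_plane <- function(plane_axis, keep_axes) {
    vals <- unique(sc[, plane_axis])
    m <- 0
    for (vv in vals) {
      sel <- sc[, plane_axis] == vv
      m <- max(m, max_pair(pc[sel, keep_axes, drop = FALSE]))
    }
    m
  }
  d_slice <- by_plane(3L, c(1L, 2L))
  d_col <- by_plane(2L, c(1L, 3L))
  d_row <- by_plane(1L, c(2L, 3L))

  coords <- which(mask, arr.ind = TRUE)
  phys <- sweep(coords, 2L, spacing, "*")
  cen <- colMeans(phys)
  cv <- crossprod(sweep(phys, 2L, cen, "-")) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1L] > 0) sqrt(ev[2L] / ev[1L]) else 1
  flat <- if (ev[1L] > 0) sqrt(ev[3L] / ev[1L]) else 1

  out <- c(vol, vol, area, area / vol,
           (36 * pi * vol^2)^(1 / 3) / area,
           d3, d_slice, d_col, d_row,
           axes[1L], axes[2L], axes[3L], elong, flat)
  stats::setNames(out, paste0("shape_", shape_names))
}
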