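#' Construct a setMag volume object
#'
#' @param intensity 3D array of finite, non-negative intensities
#' @param voxel_spacing length-3 voxel spacing in mm
#' @return object of class `setmag_volume`
#' @export
setmag_volume <- function(intensity, voxel_spacing = c(1, 1, 1)) {
  if (length(dim(intensity)) != 3L) stop("intensity must be a 3D array")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
  structure(list(intensity = intensity,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "setmag_volume")
}

#' Reconstruct the short-echo-time magnitude (setMag) volume
#'
#' Combines the magnitude images of the three shortest echo times by
#' voxelwise arithmetic mean. The short echoes carry minimal T2*-weighting
#' and maximal T1-weighting, making the combination sensitive to
#' neuromelanin in the SNpc.
#'
#' @param series an [echo_series()]
#' @return a [setmag_volume()] with the series' voxel spacing
#' @export
reconstruct_setmag <- function(series) {
  if (!inherits(series, "echo_series")) stop("series must be an echo_series")
  if (length(series$volumes) < 3L) stop("at least 3 echoes are required")
  ord <- order(series$echo_times)[1:3]
  v <- (series$volumes[[ord[1L]]] + series$volumes[[ord[2L]]] +
          series$volumes[[ord[3L]]]) / 3
  setmag_volume(v, series$voxel_spacing)
}

#' Resample a volume to a target voxel spacing (nearest neighbour)
#'
#' The output grid covers the physical extent of the input; each output
#' voxel takes the value of the input voxel whose centre is nearest. The
#' default target is the 0.5 x 0.5 x 1 mm grid used for feature extraction.
#'
#' @param volume a [setmag_volume()] (or a bare 3D array, spacing 1 mm)
#' @param target_spacing length-3 target spacing in mm
#' @return resampled [setmag_volume()]
#' @export
resample_volume <- function(volume, target_spacing = c(0.5, 0.5, 1)) {
  if (is.array(volume)) volume <- setmag_volume(volume)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  sp_in <- volume$voxel_spacing
  d_in <- dim(volume$intensity)
  if (isTRUE(all.equal(sp_in, as.numeric(target_spacing)))) return(volume)
  d_out <- pmax(1L, as.integer(ceiling(d_in * sp_in / target_spacing)))
  idx <- lapply(1:3, function(ax) {
    centre <- (seq_len(d_out[ax]) - 0.5) * target_spacing[ax]
    j <- round(centre / sp_in[ax] - 0.5) + 1L
    pmin(pmax(j, 1L), d_in[ax])
  })
  out <- volume$intensity[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  setmag_volume(out, target_spacing)
}

#' Resample a binary mask on the same grid rule as [resample_volume()]
#' @param mask binary 3D array
#' @param spacing current spacing (mm)
#' @param target_spacing target spacing (mm)
#' @return resampled logical array
#' @export
resample_mask <- function(mask, spacing = c(1, 1, 1),
                          target_spacing = c(0.5, 0.5, 1)) {
  v <- resample_volume(setmag_volume(mask * 1, spacing), target_spacing)
  v$intensity > 0.5
}

#' Grayscale inversion of a 2D patch
#'
#' `out = max(patch) - patch`; broadens the dark end of the histogram so the
#' hypointense disease signal becomes bright.
#'
#' @param patch 2D numeric matrix
#' @return inverted matrix
#' @export
invert_gray <- function(patch) {
  if (length(patch) == 0L) stop("patch must be nonempty")
  max(patch) - patch
}

#' Global histogram equalization of a 2D patch
#'
#' The patch is binned to `n_levels` gray levels over its own range and
#' mapped through the normalized cumulative histogram
#' \eqn{h(v) = round((cdf(v) - cdf_{min}) / (n - cdf_{min}) (L-1))}.
#' Rank order of pixel values is preserved (ties allowed). A constant patch
#' is returned unchanged.
#'
#' @param patch 2D numeric matrix
#' @param n_levels number of gray levels (default 256)
#' @return equalized matrix with integer levels in `[0, n_levels - 1]`
#' @export
equalize_hist <- function(patch, n_levels = 256L) {
  if (length(patch) == 0L) stop("patch must be nonempty")
  rng <- range(patch)
  if (rng[1L] == rng[2L]) return(patch)
  lev <- pmin(floor((patch - rng[1L]) / (rng[2L] - rng[1L]) * n_levels),
              n_levels - 1L)
  h <- tabulate(lev + 1L, nbins = n_levels)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(patch)
  map <- if (n > cdf_min) {
    round((cdf - cdf_min) / (n - cdf_min) * (n_levels - 1L))
  } else {
    rep(0, n_levels)
  }
  matrix(map[lev + 1L], nrow = nrow(patch))
}

#' Min-max intensity normalization to [0, 1]
#'
#' @param volume a [setmag_volume()] or 3D array
#' @return normalized volume of the same class as the input
#' @export
normalize_intensity <- function(volume) {
  arr <- if (inherits(volume, "setmag_volume")) volume$intensity else volume
  rng <- range(arr)
  if (rng[1L] == rng[2L]) stop("cannot normalize a constant volume")
  out <- (arr - rng[1L]) / (rng[2L] - rng[1L])
  if (inherits(volume, "setmag_volume")) {
    setmag_volume(out, volume$voxel_spacing)
  } else {
    out
  }
}
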