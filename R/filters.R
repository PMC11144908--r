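# Image transformations applied before texture extraction: one-level 3D
# stationary Haar wavelet (8 sub-bands), Laplacian-of-Gaussian at a list of
# sigmas (mm), and the four intensity maps (square, squareroot, logarithm,
# exponential) plus the gradient-magnitude image. Intensity maps use the
# range-preserving scalings standard in IBSI-style toolkits.

# Periodic 1D Haar pair applied along one axis of a 3D array (undecimated).
swt_haar_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  nxt <- c(2:n, 1L)  # periodic neighbour
  if (axis == 1L) b <- a[nxt, , , drop = FALSE]
  else if (axis == 2L) b <- a[, nxt, , drop = FALSE]
  else b <- a[, , nxt, drop = FALSE]
  list(L = (a + b) / sqrt(2), H = (a - b) / sqrt(2))
}

# All 8 LLL..HHH sub-bands of the one-level 3D stationary Haar transform.
wavelet_subbands <- function(arr) {
  ax1 <- swt_haar_axis(arr, 1L)
  out <- list()
  for (n1 in c("L", "H")) {
    ax2 <- swt_haar_axis(ax1[[n1]], 2L)
    for (n2 in c("L", "H")) {
      ax3 <- swt_haar_axis(ax2[[n2]], 3L)
      for (n3 in c("L", "H")) {
        out[[paste0("wavelet-", n1, n2, n3)]] <- ax3[[n3]]
      }
    }
  }
  out
}

# 1D Gaussian convolution along one axis with nearest-edge padding,
# implemented as weighted shifted-array accumulation.
gauss_axis <- function(a, sigma_vox, axis) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  for (i in seq_along(k)) {
    off <- i - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[i] * (if (axis == 1L) a[idx, , , drop = FALSE]
                         else if (axis == 2L) a[, idx, , drop = FALSE]
                         else a[, , idx, drop = FALSE])
  }
  out
}

# Discrete Laplacian with spacing-aware second differences (nearest edges).
laplacian3d <- function(a, spacing) {
  out <- array(0, dim(a))
  for (axis in 1:3) {
    n <- dim(a)[axis]
    up <- pmin(seq_len(n) + 1L, n)
    dn <- pmax(seq_len(n) - 1L, 1L)
    if (axis == 1L) diff2 <- a[up, , , drop = FALSE] + a[dn, , , drop = FALSE] - 2 * a
    else if (axis == 2L) diff2 <- a[, up, , drop = FALSE] + a[, dn, , drop = FALSE] - 2 * a
    else diff2 <- a[, , up, drop = FALSE] + a[, , dn, drop = FALSE] - 2 * a
    out <- out + diff2 / spacing[axis]^2
  }
  out
}

# Gradient magnitude with central differences scaled by spacing.
gradient_magnitude <- function(a, spacing) {
  g2 <- array(0, dim(a))
  for (axis in 1:3) {
    n <- dim(a)[axis]
    up <- pmin(seq_len(n) + 1L, n)
    dn <- pmax(seq_len(n) - 1L, 1L)
    if (axis == 1L) g <- (a[up, , , drop = FALSE] - a[dn, , , drop = FALSE])
    else if (axis == 2L) g <- (a[, up, , drop = FALSE] - a[, dn, , drop = FALSE])
    else g <- (a[, , up, drop = FALSE] - a[, , dn, drop = FALSE])
    g2 <- g2 + (g / (2 * spacing[axis]))^2
  }
  sqrt(g2)
}

#' Apply a named filter transformation to a volume
#'
#' @param volume a [setmag_volume()]
#' @param kind one of `"wavelet"`, `"log"`, `"square"`, `"squareroot"`,
#'   `"logarithm"`, `"exponential"`, `"gradient"`
#' @param sigmas LoG sigmas in mm (only for `kind = "log"`); the default 5
#'   values together with the 8 wavelet sub-bands and the 5 single-image
#'   filters give the 18 filtered image types of the default configuration
#' @return named list of filtered volumes (arrays), one entry per derived
#'   image type
#' @export
filter_image <- function(volume, kind, sigmas = 1:5) {
  kind <- match.arg(kind, c("wavelet", "log", "square", "squareroot",
                            "logarithm", "exponential", "gradient"))
  arr <- volume$intensity
  sp <- volume$voxel_spacing
  amax <- max(abs(arr))
  if (kind == "wavelet") {
    return(wavelet_subbands(arr))
  }
  if (kind == "log") {
    out <- list()
    for (s in sigmas) {
      sm <- arr
      for (axis in 1:3) sm <- gauss_axis(sm, s / sp[axis], axis)
      out[[sprintf("log-sigma-%g-mm", s)]] <- -s^2 * laplacian3d(sm, sp)
    }
    return(out)
  }
  if (kind == "gradient") {
    return(list(gradient = gradient_magnitude(arr, sp)))
  }
  if (amax == 0) return(stats::setNames(list(arr), kind))
  out <- switch(kind,
    square = (arr / sqrt(amax))^2,
    squareroot = sign(arr) * sqrt(abs(arr) * amax),
    logarithm = sign(arr) * log(abs(arr) + 1) * amax / log(amax + 1),
    exponential = exp(arr * log(amax) / amax))
  stats::setNames(list(out), kind)
}

#' All filtered image types of the default extraction configuration
#'
#' @param volume a [setmag_volume()]
#' @param log_sigmas LoG sigma list in mm
#' @return named list of 18 arrays: 8 wavelet sub-bands, `length(log_sigmas)`
#'   LoG images, square, squareroot, logarithm, exponential, gradient
#' @export
all_filtered_images <- function(volume, log_sigmas = 1:5) {
  c(filter_image(volume, "wavelet"),
    filter_image(volume, "log", sigmas = log_sigmas),
    filter_image(volume, "square"),
    filter_image(volume, "squareroot"),
    filter_image(volume, "logarithm"),
    filter_image(volume, "exponential"),
    filter_image(volume, "gradient"))
}
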