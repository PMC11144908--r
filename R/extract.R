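#' Default radiomics extraction configuration
#'
#' @param bin_width fixed discretization bin width (intensity units)
#' @param log_sigmas LoG sigmas in mm
#' @param target_spacing extraction grid in mm
#' @return list of configuration values
#' @export
extraction_config <- function(bin_width = 25, log_sigmas = 1:5,
                              target_spacing = c(0.5, 0.5, 1)) {
  list(bin_width = bin_width, log_sigmas = log_sigmas,
       target_spacing = target_spacing)
}

texture_block <- function(lev_arr, bin_width) {
  roi <- lev_arr  # cropped levels array, NA outside mask
  c(glcm_features(roi), glrlm_features(roi), glszm_features(roi),
    gldm_features(roi), ngtdm_features(roi))
}

image_feature_block <- function(arr, mask, bin_width, voxel_volume) {
  vals <- arr[mask]
  lev <- array(NA_real_, dim(arr))
  lev[mask] <- floor((vals - min(vals)) / bin_width) + 1
  lev <- crop_levels(lev)
  c(first_order_features(vals, bin_width = bin_width,
                         voxel_volume = voxel_volume),
    texture_block(lev, bin_width))
}

#' Extract the full radiomics feature row for one case
#'
#' Computes 107 features on the original image (18 first-order, 14 shape,
#' 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) and 93 features (all
#' families except shape) on each of the 18 filtered image types (8 wavelet
#' sub-bands, 5 LoG sigmas, square, squareroot, logarithm, exponential,
#' gradient), for 107 + 18 x 93 = 1781 named features in a stable order.
#'
#' @param volume a (resampled) [setmag_volume()]
#' @param mask binary 3D mask on the same grid
#' @param config an [extraction_config()]
#' @param case_id identifier attached as an attribute
#' @return named numeric vector of 1781 features
#' @export
extract_all <- function(volume, mask, config = extraction_config(),
                        case_id = NULL) {
  if (!any(mask)) stop("mask is empty")
  if (!identical(dim(volume$intensity), dim(mask))) {
    stop("volume and mask must share one grid")
  }
  sp <- volume$voxel_spacing
  vv <- prod(sp)
  bw <- config$bin_width

  orig <- c(
    first_order_features(volume$intensity[mask], bin_width = bw,
                         voxel_volume = vv),
    shape_features(mask, sp),
    texture_block(crop_levels(discretize(volume, mask, bw)$levels), bw))
  names(orig) <- paste0("original_", names(orig))

  filtered <- all_filtered_images(volume, log_sigmas = config$log_sigmas)
  blocks <- lapply(names(filtered), function(nm) {
    fb <- image_feature_block(filtered[[nm]], mask, bw, vv)
    names(fb) <- paste0(nm, "_", names(fb))
    fb
  })
  out <- c(orig, unlist(blocks))
  if (!is.null(case_id)) attr(out, "case_id") <- case_id
  out
}

#' Extract the feature table of a cohort
#'
#' Reconstructs setMag, resamples volume and mask to the extraction grid,
#' rescales intensities to an 8-bit-like range (0-255) so the fixed bin
#' width yields a non-degenerate discretization, and extracts the 1781
#' features per case.
#'
#' @param cases list of `synthetic_case` objects
#' @param config an [extraction_config()]
#' @param rater which mask to use (`"rater1"` uses `snpc_mask`, `"rater2"`
#'   the second-rater mask)
#' @param verbose print progress
#' @return data.frame: case_id, label, then 1781 feature columns
#' @export
extract_cohort <- function(cases, config = extraction_config(),
                           rater = c("rater1", "rater2"), verbose = FALSE) {
  rater <- match.arg(rater)
  rows <- lapply(cases, function(cs) {
    vol <- reconstruct_setmag(cs$echoes)
    vol$intensity <- normalize_intensity(vol$intensity) * 255
    volr <- resample_volume(vol, config$target_spacing)
    msk <- if (rater == "rater1") cs$snpc_mask else cs$rater2_mask
    mskr <- resample_mask(msk, cs$echoes$voxel_spacing, config$target_spacing)
    if (verbose) message("extracting ", cs$case_id)
    extract_all(volr, mskr, config, case_id = cs$case_id)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
             label = vapply(cases, `[[`, "", "label"),
             tab, check.names = FALSE)
}

#' Fit a per-feature standardizer (zero mean, unit variance)
#'
#' @param X numeric matrix or data.frame of training rows only
#' @return list with per-feature `mean` and `sd` (class `feature_scaler`)
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  structure(list(mean = mu, sd = sd), class = "feature_scaler")
}

#' Apply a fitted standardizer
#'
#' Constant features (sd = 0 in the training rows) map to 0.
#'
#' @param scaler a [fit_scaler()] result
#' @param X matrix/data.frame with the same columns
#' @return standardized matrix
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  sd <- ifelse(scaler$sd > 0, scaler$sd, 1)
  out <- sweep(sweep(X, 2L, scaler$mean, "-"), 2L, sd, "/")
  out[, scaler$sd == 0] <- 0
  out
}
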