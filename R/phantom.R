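#' Parameters for the synthetic midbrain phantom
#'
#' Defines the geometry and signal model of a simplified axial midbrain
#' phantom: a bright midbrain ellipsoid on a dark background, bilateral
#' hyperintense SNpc crescents spanning exactly four contiguous axial
#' slices, and a dorsolateral "swallow-tail" hyperintensity inside each
#' crescent. Disease (PD) cases attenuate the swallow-tail intensity uplift
#' and shrink the crescent in-plane area. Multi-echo magnitude images follow
#' a mono-exponential T2* decay \eqn{S(TE) = S_0 e^{-TE/T_2^*}} with
#' tissue-specific \eqn{T_2^*}, so the shortest echoes are brightest;
#' optional Rician noise is added per echo.
#'
#' @param volume_shape integer length-3: voxels along (row, column, slice).
#' @param echo_times numeric, strictly increasing echo times in ms (>= 3).
#' @param voxel_spacing numeric length-3 spacing in mm.
#' @param midbrain_center,midbrain_axes ellipsoid centre / radii in voxels.
#' @param snpc_slice_start first of the 4 contiguous mask-bearing slices.
#' @param snpc_offset length-2 (row, column) offset of each crescent centre
#'   from the midbrain centre; the column offset is mirrored left/right.
#' @param snpc_axes in-plane (row, column) radii of each crescent.
#' @param swallowtail_offset,swallowtail_radius placement of the dorsolateral
#'   swallow-tail disc relative to the crescent centre.
#' @param swallowtail_contrast_hc intensity uplift (signal units on S0) of the
#'   swallow-tail in healthy controls.
#' @param swallowtail_attenuation_pd multiplicative attenuation of the uplift
#'   in PD, in [0, 1].
#' @param snpc_area_shrink_pd multiplicative in-plane area factor for the PD
#'   crescent, in (0, 1].
#' @param noise_sigma Rician noise sigma in signal units.
#' @param s0,t2star named S0 / T2* (ms) values per tissue class
#'   (background, midbrain, snpc, swallowtail).
#' @param tissue_intensity_cv,uplift_cv,center_jitter per-case biological
#'   variability: coefficient of variation of tissue S0 and of the uplift, and
#'   the maximal integer in-plane jitter of the midbrain centre.
#' @return an object of class `phantom_params`
#' @export
phantom_params <- function(volume_shape = c(64L, 64L, 12L),
                           echo_times = c(5, 10, 15, 20, 25, 30),
                           voxel_spacing = c(1, 1, 1),
                           midbrain_center = c(32, 32, 6),
                           midbrain_axes = c(20, 16, 4.5),
                           snpc_slice_start = 5L,
                           snpc_offset = c(6, 9),
                           snpc_axes = c(3.5, 6.5),
                           swallowtail_offset = c(1.5, 3.5),
                           swallowtail_radius = 2.2,
                           swallowtail_contrast_hc = 0.5,
                           swallowtail_attenuation_pd = 0.5,
                           snpc_area_shrink_pd = 0.8,
                           noise_sigma = 0.02,
                           s0 = c(background = 0.05, midbrain = 1.15,
                                  snpc = 1.45),
                           t2star = c(background = 100, midbrain = 45,
                                      snpc = 30, swallowtail = 35),
                           tissue_intensity_cv = 0.03,
                           uplift_cv = 0.06,
                           center_jitter = 2L) {
  p <- list(volume_shape = as.integer(volume_shape),
            echo_times = as.numeric(echo_times),
            voxel_spacing = as.numeric(voxel_spacing),
            midbrain_center = as.numeric(midbrain_center),
            midbrain_axes = as.numeric(midbrain_axes),
            snpc_slice_start = as.integer(snpc_slice_start),
            snpc_offset = as.numeric(snpc_offset),
            snpc_axes = as.numeric(snpc_axes),
            swallowtail_offset = as.numeric(swallowtail_offset),
            swallowtail_radius = as.numeric(swallowtail_radius),
            swallowtail_contrast_hc = swallowtail_contrast_hc,
            swallowtail_attenuation_pd = swallowtail_attenuation_pd,
            snpc_area_shrink_pd = snpc_area_shrink_pd,
            noise_sigma = noise_sigma,
            s0 = s0, t2star = t2star,
            tissue_intensity_cv = tissue_intensity_cv,
            uplift_cv = uplift_cv,
            center_jitter = as.integer(center_jitter))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (length(p$volume_shape) != 3L || any(p$volume_shape < 8L)) {
    stop("volume_shape must be 3 dimensions of at least 8 voxels")
  }
  if (length(p$echo_times) < 3L) stop("at least 3 echo times are required")
  if (any(diff(p$echo_times) <= 0)) stop("echo_times must be strictly increasing")
  if (p$swallowtail_attenuation_pd < 0 || p$swallowtail_attenuation_pd > 1) {
    stop("swallowtail_attenuation_pd must lie in [0, 1]")
  }
  if (p$snpc_area_shrink_pd <= 0 || p$snpc_area_shrink_pd > 1) {
    stop("snpc_area_shrink_pd must lie in (0, 1]")
  }
  if (p$noise_sigma < 0) stop("noise_sigma must be non-negative")
  jit <- p$center_jitter
  # every rendered structure (with jitter head-room) must fit in the volume
  lo_r <- p$midbrain_center[1] - p$midbrain_axes[1] - jit
  hi_r <- p$midbrain_center[1] + p$midbrain_axes[1] + jit
  lo_c <- p$midbrain_center[2] - p$midbrain_axes[2] - jit
  hi_c <- p$midbrain_center[2] + p$midbrain_axes[2] + jit
  tail_c <- p$midbrain_center[2] + p$snpc_offset[2] + p$swallowtail_offset[2] +
    p$swallowtail_radius + jit
  tail_r <- p$midbrain_center[1] + p$snpc_offset[1] + p$snpc_axes[1] + jit
  if (lo_r < 1 || lo_c < 1 || hi_r > p$volume_shape[1] ||
      hi_c > p$volume_shape[2] || tail_c > p$volume_shape[2] ||
      tail_r > p$volume_shape[1]) {
    stop("phantom geometry does not fit inside volume_shape")
  }
  zs <- p$snpc_slice_start
  if (zs < 1L || zs + 3L > p$volume_shape[3]) {
    stop("the 4 SNpc slices do not fit inside volume_shape")
  }
  invisible(p)
}

#' Construct a multi-echo magnitude series
#'
#' @param volumes list of 3D arrays (one per echo, identical shape)
#' @param echo_times echo times in ms
#' @param voxel_spacing voxel spacing in mm
#' @return object of class `echo_series`
#' @export
echo_series <- function(volumes, echo_times, voxel_spacing = c(1, 1, 1)) {
  if (length(volumes) < 3L) stop("an echo series needs at least 3 echoes")
  if (length(volumes) != length(echo_times)) {
    stop("one echo time per volume is required")
  }
  d <- dim(volumes[[1L]])
  for (v in volumes) {
    if (!identical(dim(v), d)) stop("all echo volumes must share one shape")
  }
  structure(list(volumes = volumes, echo_times = as.numeric(echo_times),
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "echo_series")
}

# In-plane ellipse indicator on the (row, col) grid of one slice.
ellipse_mask2d <- function(nr, nc, cr, cc, ar, ac) {
  r <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - cr) / ar)^2 + ((cl - cc) / ac)^2 <= 1
}

#' Generate one synthetic case
#'
#' Renders the phantom for one subject with per-case biological variability
#' (centre jitter, tissue-intensity and uplift multipliers), simulates the
#' multi-echo magnitude series under the T2* decay model, and derives the
#' SNpc mask, a second-rater mask (boundary jitter), the swallow-tail
#' sub-region mask and the per-slice true brainstem boxes.
#'
#' @param params a [phantom_params()] object
#' @param label `"HC"` or `"PD"`
#' @param seed integer seed; output is a pure function of (params, label, seed)
#' @param case_id identifier string
#' @return object of class `synthetic_case` with fields `case_id`, `echoes`,
#'   `snpc_mask`, `rater2_mask`, `swallowtail_mask`, `label`, `true_boxes`
#' @export
generate_case <- function(params, label = c("HC", "PD"), seed = 1L,
                          case_id = sprintf("case_%06d", as.integer(seed))) {
  label <- match.arg(label)
  validate_phantom_params(params)
  with_seed(seed, {
    d <- params$volume_shape
    jit <- if (params$center_jitter > 0) {
      sample(seq(-params$center_jitter, params$center_jitter), 2L, replace = TRUE)
    } else c(0L, 0L)
    cen <- params$midbrain_center + c(jit, 0)
    tf <- stats::rnorm(3L, 1, params$tissue_intensity_cv)  # bg, midbrain, snpc
    tf <- pmax(tf, 0.5)
    uplift <- params$swallowtail_contrast_hc *
      max(stats::rnorm(1L, 1, params$uplift_cv), 0.2)
    if (label == "PD") uplift <- uplift * params$swallowtail_attenuation_pd
    ax_scale <- if (label == "PD") sqrt(params$snpc_area_shrink_pd) else 1

    nr <- d[1L]; nc <- d[2L]; nz <- d[3L]
    s0 <- array(params$s0[["background"]] * tf[1L], dim = d)
    t2 <- array(params$t2star[["background"]], dim = d)

    # midbrain ellipsoid
    r <- array(rep(seq_len(nr), times = nc * nz), dim = d)
    cl <- array(rep(rep(seq_len(nc), each = nr), times = nz), dim = d)
    zz <- array(rep(seq_len(nz), each = nr * nc), dim = d)
    mb <- ((r - cen[1L]) / params$midbrain_axes[1L])^2 +
      ((cl - cen[2L]) / params$midbrain_axes[2L])^2 +
      ((zz - cen[3L]) / params$midbrain_axes[3L])^2 <= 1
    s0[mb] <- params$s0[["midbrain"]] * tf[2L]
    t2[mb] <- params$t2star[["midbrain"]]

    slices <- params$snpc_slice_start + 0:3
    mask <- array(FALSE, dim = d)
    tail_mask <- array(FALSE, dim = d)
    for (z in slices) {
      for (side in c(-1, 1)) {
        ccr <- cen[1L] + params$snpc_offset[1L]
        ccc <- cen[2L] + side * params$snpc_offset[2L]
        cres <- ellipse_mask2d(nr, nc, ccr, ccc,
                               params$snpc_axes[1L] * ax_scale,
                               params$snpc_axes[2L] * ax_scale)
        tcr <- ccr + params$swallowtail_offset[1L]
        tcc <- ccc + side * params$swallowtail_offset[2L]
        tl <- ellipse_mask2d(nr, nc, tcr, tcc,
                             params$swallowtail_radius,
                             params$swallowtail_radius) & cres
        mask[, , z] <- mask[, , z] | cres
        tail_mask[, , z] <- tail_mask[, , z] | tl
      }
    }
    s0[mask] <- params$s0[["snpc"]] * tf[3L]
    t2[mask] <- params$t2star[["snpc"]]
    s0[tail_mask] <- s0[tail_mask] + uplift
    t2[tail_mask] <- params$t2star[["swallowtail"]]

    vols <- lapply(params$echo_times, function(te) {
      s <- s0 * exp(-te / t2)
      if (params$noise_sigma > 0) {
        n1 <- array(stats::rnorm(length(s), 0, params$noise_sigma), dim = d)
        n2 <- array(stats::rnorm(length(s), 0, params$noise_sigma), dim = d)
        s <- sqrt((s + n1)^2 + n2^2)
      }
      s
    })
    boxes <- data.frame(slice = slices,
                        center_row = round(cen[1L]),
                        center_col = round(cen[2L]),
                        height = 40L, width = 40L)
    r2 <- perturb_mask(mask, seed = derive_seed(seed, 1L, stream = 3L))
    structure(list(case_id = case_id,
                   echoes = echo_series(vols, params$echo_times,
                                        params$voxel_spacing),
                   snpc_mask = mask,
                   rater2_mask = r2,
                   swallowtail_mask = tail_mask,
                   label = label,
                   true_boxes = boxes),
              class = "synthetic_case")
  })
}

#' Generate a synthetic cohort
#'
#' @param n_hc,n_pd number of healthy-control / PD cases (>= 0)
#' @param params a [phantom_params()] object
#' @param seed master seed; per-case seeds are derived deterministically
#' @return list of [generate_case()] results (HC cases first)
#' @export
generate_cohort <- function(n_hc, n_pd, params = phantom_params(), seed = 1L) {
  if (n_hc < 0 || n_pd < 0) stop("cohort sizes must be non-negative")
  n <- n_hc + n_pd
  if (n == 0L) return(list())
  labels <- c(rep("HC", n_hc), rep("PD", n_pd))
  lapply(seq_len(n), function(i) {
    generate_case(params, labels[i], seed = derive_seed(seed, i),
                  case_id = sprintf("case_%03d", i))
  })
}

#' Jitter a segmentation mask to emulate a second rater
#'
#' Random boundary flips per axial slice: each erodable in-mask boundary
#' voxel and each dilatable out-of-mask boundary voxel (4-neighbourhood in
#' plane) is flipped independently with probability `flip_prob`. At the
#' default amplitude the Dice similarity with the input lands in the range
#' typical of two expert raters.
#'
#' @param mask binary 3D array
#' @param seed integer seed
#' @param flip_prob boundary flip probability; 0 returns the mask unchanged
#' @return jittered binary mask of the same shape
#' @export
perturb_mask <- function(mask, seed = 1L, flip_prob = 0.2) {
  if (sum(mask) == 0L) stop("cannot perturb an empty mask")
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must lie in [0, 1]")
  if (flip_prob == 0) return(mask)
  with_seed(seed, {
    out <- mask
    d <- dim(mask)
    for (z in seq_len(d[3L])) {
      sl <- mask[, , z]
      if (!any(sl)) next
      nb <- matrix(0L, d[1L], d[2L])
      nb[-1, ] <- nb[-1, ] + sl[-d[1L], ]
      nb[-d[1L], ] <- nb[-d[1L], ] + sl[-1, ]
      nb[, -1] <- nb[, -1] + sl[, -d[2L]]
      nb[, -d[2L]] <- nb[, -d[2L]] + sl[, -1]
      inner_bd <- which(sl & nb < 4L)          # erodable
      outer_bd <- which(!sl & nb > 0L)         # dilatable
      er <- inner_bd[stats::runif(length(inner_bd)) < flip_prob]
      di <- outer_bd[stats::runif(length(outer_bd)) < flip_prob]
      sl[er] <- FALSE
      sl[di] <- TRUE
      out[, , z] <- sl
    }
    out
  })
}

#' Write a cohort to disk
#'
#' Writes per-case NIfTI volumes (echoes as a 4D image, both rater masks), a
#' cohort manifest CSV (case_id, label, file paths) and a flat key=value
#' config file describing the generator.
#'
#' @param cases list of `synthetic_case` objects
#' @param dir output directory (created if missing)
#' @param params the [phantom_params()] used (recorded in the config file)
#' @return path of the manifest CSV, invisibly
#' @export
write_cohort <- function(cases, dir, params = phantom_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    d <- dim(cs$echoes$volumes[[1L]])
    arr <- array(unlist(cs$echoes$volumes), dim = c(d, length(cs$echoes$volumes)))
    f_e <- file.path(dir, paste0(cs$case_id, "_echoes.nii.gz"))
    f_m <- file.path(dir, paste0(cs$case_id, "_mask.nii.gz"))
    f_r <- file.path(dir, paste0(cs$case_id, "_mask_rater2.nii.gz"))
    sp <- cs$echoes$voxel_spacing
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(sp, 1)), f_e)
    RNifti::writeNifti(RNifti::asNifti(cs$snpc_mask * 1L, pixdim = sp), f_m)
    RNifti::writeNifti(RNifti::asNifti(cs$rater2_mask * 1L, pixdim = sp), f_r)
    data.frame(case_id = cs$case_id, label = cs$label, echoes = f_e,
               mask = f_m, rater2_mask = f_r)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  cfg <- file.path(dir, "generator_config.txt")
  flat <- unlist(lapply(params, function(x) paste(x, collapse = ",")))
  writeLines(paste0(names(flat), "=", flat), cfg)
  invisible(mf)
}
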