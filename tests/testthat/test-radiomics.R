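test_that("discretization follows the fixed-bin-width formula", {
  vals <- c(0, 24.9, 25, 50)
  vol <- array(vals, c(4, 1, 1))
  msk <- array(TRUE, c(4, 1, 1))
  dr <- discretize(vol, msk, 25)
  expect_identical(as.vector(dr$levels), c(1L, 1L, 2L, 3L))
  expect_identical(dr$n_levels, 3L)
  cst <- discretize(array(7, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 25)
  expect_true(all(cst$levels == 1L))
  expect_error(discretize(vol, array(FALSE, c(4, 1, 1)), 25), "empty")
  # level count tracks ceil((max-min)/bw) up to the bin-edge case
  set.seed(8)
  for (i in 1:10) {
    v <- array(runif(27, 0, 100), c(3, 3, 3))
    m <- array(TRUE, c(3, 3, 3))
    bw <- runif(1, 5, 30)
    nl <- discretize(v, m, bw)$n_levels
    span <- max(v) - min(v)
    expect_true(nl == ceiling(span / bw) || nl == ceiling(span / bw) + 1)
  }
})

test_that("first-order features match hand arithmetic", {
  f <- first_order_features(c(2, 2, 2))
  expect_equal(unname(f["firstorder_Mean"]), 2)
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["firstorder_Uniformity"]), 1)
  g <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(g["firstorder_Mean"]), 2.5)
  expect_equal(unname(g["firstorder_Range"]), 3)
  expect_equal(unname(g["firstorder_Median"]), 2.5)
  expect_equal(unname(first_order_features(c(1, 2, 2, 3))["firstorder_Skewness"]), 0)
  # closed forms on integer ROIs
  set.seed(9)
  for (i in 1:5) {
    v <- sample(1:50, 20, replace = TRUE)
    fo <- first_order_features(v)
    expect_equal(unname(fo["firstorder_Mean"]), sum(v) / 20, tolerance = 1e-10)
    expect_equal(unname(fo["firstorder_Variance"]),
                 sum((v - mean(v))^2) / 20, tolerance = 1e-10)
    expect_equal(unname(fo["firstorder_Energy"]), sum(v^2), tolerance = 1e-10)
  }
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("shape features satisfy analytic cuboid and sphericity bounds", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  f1 <- shape_features(one, c(1, 1, 1))
  expect_equal(unname(f1["shape_VoxelVolume"]), 1)
  expect_equal(unname(f1["shape_SurfaceArea"]), 6)
  expect_equal(unname(f1["shape_Maximum3DDiameter"]), 0)
  # doubling the spacing: volume x8, surface x4 on a cuboid
  cub <- array(FALSE, c(6, 6, 6)); cub[2:4, 2:5, 2:3] <- TRUE
  a <- shape_features(cub, c(1, 1, 1))
  b <- shape_features(cub, c(2, 2, 2))
  expect_equal(unname(b["shape_VoxelVolume"]), 8 * unname(a["shape_VoxelVolume"]))
  expect_equal(unname(b["shape_SurfaceArea"]), 4 * unname(a["shape_SurfaceArea"]))
  # voxel-count volume of the 3x4x2 cuboid
  expect_equal(unname(a["shape_VoxelVolume"]), 24)
  expect_equal(unname(a["shape_SurfaceArea"]), 2 * (12 + 8 + 6))
  set.seed(10)
  for (i in 1:8) {
    m <- array(runif(125) < 0.4, c(5, 5, 5))
    if (!any(m)) next
    s <- shape_features(m, c(1, 1, 1))
    expect_lte(unname(s["shape_Sphericity"]), 1 + 1e-12)
    expect_gte(unname(s["shape_Elongation"]), 0)
    expect_lte(unname(s["shape_Flatness"]), 1 + 1e-12)
  }
  expect_error(shape_features(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("filter bank honours its algebraic identities", {
  cst <- setmag_volume(array(4, c(6, 6, 4)))
  sq <- filter_image(cst, "square")[[1]]
  expect_equal(unique(as.vector(sq)), 4)
  gr <- filter_image(cst, "gradient")[[1]]
  expect_true(all(gr == 0))
  set.seed(11)
  v <- setmag_volume(array(runif(6 * 6 * 4), c(6, 6, 4)))
  wb <- filter_image(v, "wavelet")
  expect_length(wb, 8L)
  expect_setequal(names(wb), paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                                  "HLL", "HLH", "HHL", "HHH")))
  for (w in wb) expect_identical(dim(w), dim(v$intensity))
  lg <- filter_image(v, "log", sigmas = c(1, 2))
  expect_length(lg, 2L)
  expect_named(lg, c("log-sigma-1-mm", "log-sigma-2-mm"))
  expect_error(filter_image(v, "fourier"))
})

test_that("GLCM matches the 4-voxel hand oracle and degenerate conventions", {
  # levels [1,1,2,2] along one line: sym counts (1,1):2,(1,2):2,(2,2):2
  lev <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  roi <- structure(list(levels = lev, n_levels = 2L, bin_width = 1,
                        mask = array(TRUE, c(4, 1, 1))),
                   class = "discretized_roi")
  f <- glcm_features(roi)
  expect_equal(unname(f["glcm_JointEnergy"]), 2 * (1 / 3)^2 + 2 * (1 / 6)^2)
  expect_equal(unname(f["glcm_MaximumProbability"]), 1 / 3)
  expect_equal(unname(f["glcm_Contrast"]), 1 / 3)
  cst <- structure(list(levels = array(1L, c(3, 3, 1)), n_levels = 1L,
                        bin_width = 1, mask = array(TRUE, c(3, 3, 1))),
                   class = "discretized_roi")
  fc <- glcm_features(cst)
  expect_equal(unname(fc["glcm_Contrast"]), 0)
  expect_equal(unname(fc["glcm_MaximumProbability"]), 1)
  expect_equal(unname(fc["glcm_Correlation"]), 1)  # degenerate fallback
})

test_that("level-shift invariance holds where expected", {
  lev <- random_small_roi(21, n_levels = 3)
  shifted <- lev + 3L
  f1 <- glcm_features(lev)
  f2 <- glcm_features(shifted)
  expect_equal(f1[["glcm_Contrast"]], f2[["glcm_Contrast"]], tolerance = 1e-12)
  expect_equal(f1[["glcm_Idm"]], f2[["glcm_Idm"]], tolerance = 1e-12)
})

test_that("GLRLM matches the hand run-table on a single direction", {
  lev <- array(c(1L, 1L, 1L, 2L), c(4, 1, 1))
  R <- nmhybrid:::glrlm_matrix_one(lev, 2L, c(1, 0, 0))
  expect_equal(R[1, 3], 1)  # level 1, run of 3
  expect_equal(R[2, 1], 1)  # level 2, run of 1
  expect_equal(sum(R), 2)
  lre <- nmhybrid:::glrlm_features_one(R, 4L)[2]
  expect_equal(lre, (1 * 9 + 1 * 1) / 2)  # long-run emphasis
})

test_that("GLSZM and NGTDM handle constant ROIs per convention", {
  cst <- structure(list(levels = array(1L, c(2, 2, 2)), n_levels = 1L,
                        bin_width = 1, mask = array(TRUE, c(2, 2, 2))),
                   class = "discretized_roi")
  z <- glszm_features(cst)
  expect_equal(unname(z["glszm_ZonePercentage"]), 1 / 8)  # one zone of 8
  expect_equal(unname(z["glszm_ZoneEntropy"]), 0)
  expect_equal(unname(z["glszm_LargeAreaEmphasis"]), 64)
  n <- ngtdm_features(cst)
  expect_equal(unname(n["ngtdm_Coarseness"]), 1e6)
})

test_that("all five texture families match the brute-force oracle", {
  for (seed in c(101, 202, 303, 404)) {
    lev <- random_small_roi(seed, dims = c(3, 3, 3), n_levels = 4)
    expect_lt(max(abs(glcm_features(lev) - oracle_glcm(lev))), 1e-8)
    expect_lt(max(abs(glrlm_features(lev) - oracle_glrlm(lev))), 1e-8)
    expect_lt(max(abs(glszm_features(lev) - oracle_glszm(lev))), 1e-8)
    expect_lt(max(abs(gldm_features(lev) - oracle_gldm(lev))), 1e-8)
    expect_lt(max(abs(ngtdm_features(lev) - oracle_ngtdm(lev))), 1e-8)
  }
})

test_that("full extraction yields 1781 stably-ordered features", {
  co <- test_cohort()
  cs <- co$cases[[1]]
  vol <- reconstruct_setmag(cs$echoes)
  vol$intensity <- normalize_intensity(vol$intensity) * 255
  volr <- resample_volume(vol, c(0.5, 0.5, 1))
  mskr <- resample_mask(cs$snpc_mask)
  row1 <- extract_all(volr, mskr)
  expect_length(row1, 1781L)
  expect_true(all(is.finite(row1)))
  nm <- names(row1)
  expect_identical(anyDuplicated(nm), 0L)
  # shape features only under the original image
  shp <- grepl("_shape_", nm)
  expect_identical(sum(shp), 14L)
  expect_true(all(startsWith(nm[shp], "original_")))
  expect_identical(sum(startsWith(nm, "original_")), 107L)
  # 18 filtered types x 93 features
  types <- unique(sub("_(firstorder|shape|glcm|glrlm|glszm|gldm|ngtdm)_.*", "", nm))
  expect_length(types, 19L)
  for (ty in setdiff(types, "original")) {
    expect_identical(sum(startsWith(nm, paste0(ty, "_"))), 93L)
  }
  # determinism
  row2 <- extract_all(volr, mskr)
  expect_identical(row1, row2)
  expect_error(extract_all(volr, array(FALSE, dim(mskr))), "empty")
})
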