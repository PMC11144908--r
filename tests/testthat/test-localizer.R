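test_that("iou matches hand-computed areas and its invariants", {
  b <- function(cr, cc) brainstem_box(3, cr, cc)
  expect_equal(iou(b(50, 50), b(50, 50)), 1)
  expect_equal(iou(b(10, 10), b(100, 100)), 0)
  expect_equal(iou(b(50, 50), b(50, 70)), 1 / 3)  # 20-column offset
  expect_error(iou(brainstem_box(1, 5, 5), brainstem_box(2, 5, 5)),
               "different slices")
  set.seed(7)
  for (i in 1:20) {
    a <- b(runif(1, 0, 100), runif(1, 0, 100))
    c2 <- b(runif(1, 0, 100), runif(1, 0, 100))
    v <- iou(a, c2)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, iou(c2, a))
  }
})

test_that("heuristic detection finds a bright blob and is deterministic", {
  vol <- array(0, c(96, 96, 3))
  vol[50, 60, 2] <- 10
  vol[20, 20, 2] <- 0.01  # faint background speck below Otsu
  bx <- heuristic_detect(setmag_volume(vol), 2)
  expect_equal(bx$center_row, 50)
  expect_equal(bx$center_col, 60)
  bx2 <- heuristic_detect(setmag_volume(vol), 2)
  expect_identical(bx, bx2)
  expect_error(heuristic_detect(setmag_volume(array(0, c(8, 8, 2))), 1),
               "zero")
})

test_that("heuristic centre lies on the midline of a symmetric phantom", {
  cs <- generate_case(phantom_params(noise_sigma = 0, center_jitter = 0L),
                      "HC", seed = 1)
  vol <- reconstruct_setmag(cs$echoes)
  bx <- heuristic_detect(vol, 6)
  expect_equal(bx$center_col, 32.5, tolerance = 0.05)
})

test_that("patch stacks are 40x40x4, clamped, and preprocessed", {
  co <- test_cohort()
  st <- co$stacks[[1]]
  expect_identical(dim(st$patches), c(40L, 40L, 4L))
  expect_true(all(is.finite(st$patches)))
  expect_length(st$source_boxes, 4L)
  # blob near a corner: crop stays fully inside the slice
  vol <- array(0, c(64, 64, 6))
  vol[3, 3, 2:5] <- 10
  stc <- detect_brainstem(setmag_volume(vol), 2:5)
  for (bx in stc$source_boxes) {
    expect_gte(bx$center_row - 19.5, 1)
    expect_lte(bx$center_row + 19.5, 64)
    expect_gte(bx$center_col - 19.5, 1)
  }
  expect_error(detect_brainstem(setmag_volume(vol), c(1, 2, 3, 99)),
               "out of range")
  expect_error(detect_brainstem(setmag_volume(vol), 1:3), "4 slice")
})

test_that("detection is invariant to an additive intensity shift", {
  cs <- generate_case(phantom_params(), "PD", seed = 8)
  vol <- reconstruct_setmag(cs$echoes)
  zs <- select_slices(cs$snpc_mask, dim(vol$intensity)[3])
  a <- detect_brainstem(vol, zs)
  shifted <- setmag_volume(vol$intensity + 17.3, vol$voxel_spacing)
  b <- detect_brainstem(shifted, zs)
  expect_equal(a$patches, b$patches)
})

test_that("trained centre regressor localizes held-out slices", {
  co <- test_cohort()
  train_ids <- 1:20
  test_ids <- 21:27
  det <- train_detector(co$cases[train_ids], seed = 6)
  # loss goes down overall (plateaus allowed)
  el <- det$epoch_loss
  expect_lt(mean(tail(el, 5)), mean(head(el, 5)))
  expect_lt(el[length(el)], el[1])
  # determinism
  det2 <- train_detector(co$cases[train_ids], seed = 6)
  expect_identical(det$net$layers, det2$net$layers)
  # held-out IoU with true boxes
  ious <- c()
  for (i in test_ids) {
    cs <- co$cases[[i]]
    vol <- normalize_intensity(reconstruct_setmag(cs$echoes))
    for (bi in seq_len(nrow(cs$true_boxes))) {
      bx <- cs$true_boxes[bi, ]
      pred <- predict_box(det, vol$intensity[, , bx$slice], bx$slice)
      truth <- brainstem_box(bx$slice, bx$center_row, bx$center_col)
      ious <- c(ious, iou(pred, truth))
    }
  }
  expect_gte(length(ious), 20L)
  expect_gte(mean(ious), 0.7)
  expect_error(train_detector(list()), "empty")
  expect_error(train_detector(co$cases[1:3]), "10 cases")
})

test_that("crops around the trained centre contain the SNpc", {
  co <- test_cohort()
  det <- train_detector(co$cases[1:20], seed = 6)
  cs <- co$cases[[25]]
  vol <- reconstruct_setmag(cs$echoes)
  zs <- select_slices(cs$snpc_mask, dim(vol$intensity)[3])
  st <- detect_brainstem(vol, zs, model = det)
  overlap <- 0; total <- 0
  for (i in seq_along(zs)) {
    bx <- st$source_boxes[[i]]
    rows <- (bx$center_row - 19.5):(bx$center_row + 19.5)
    cols <- (bx$center_col - 19.5):(bx$center_col + 19.5)
    m <- cs$snpc_mask[, , zs[i]]
    total <- total + sum(m)
    overlap <- overlap + sum(m[rows, cols])
  }
  expect_gte(overlap / total, 0.95)
})
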