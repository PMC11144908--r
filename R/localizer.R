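#' Axis-aligned brainstem bounding box
#'
#' @param slice_index axial slice the box lives on
#' @param center_row,center_col box centre in voxels
#' @param height,width box size in voxels (the pipeline uses 40 x 40)
#' @return object of class `brainstem_box`
#' @export
brainstem_box <- function(slice_index, center_row, center_col,
                          height = 40L, width = 40L) {
  structure(list(slice_index = as.integer(slice_index),
                 center_row = center_row, center_col = center_col,
                 height = height, width = width),
            class = "brainstem_box")
}

#' Intersection-over-union of two boxes on the same slice
#'
#' @param a,b [brainstem_box()] objects on the same slice
#' @return IoU in [0, 1]
#' @export
iou <- function(a, b) {
  if (a$slice_index != b$slice_index) {
    stop("boxes lie on different slices")
  }
  ov <- function(c1, s1, c2, s2) {
    max(0, min(c1 + s1 / 2, c2 + s2 / 2) - max(c1 - s1 / 2, c2 - s2 / 2))
  }
  inter <- ov(a$center_row, a$height, b$center_row, b$height) *
    ov(a$center_col, a$width, b$center_col, b$width)
  union <- a$height * a$width + b$height * b$width - inter
  inter / union
}

# Otsu threshold on a 256-bin histogram.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (rng[1L] == rng[2L]) return(rng[1L])
  nb <- 256L
  lev <- pmin(floor((v - rng[1L]) / (rng[2L] - rng[1L]) * nb), nb - 1L)
  h <- tabulate(lev + 1L, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nb) - 1L))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1L] + k / nb * (rng[2L] - rng[1L])
}

#' Heuristic brainstem detection on one axial slice
#'
#' Thresholds the slice with Otsu's method and returns a 40 x 40 box centred
#' on the intensity centroid of the upper half (smaller row indices) of the
#' foreground. Used as the model-free fallback of [detect_brainstem()].
#'
#' @param volume a [setmag_volume()] or 3D array
#' @param slice_index axial slice index
#' @return a [brainstem_box()]
#' @export
heuristic_detect <- function(volume, slice_index) {
  arr <- if (inherits(volume, "setmag_volume")) volume$intensity else volume
  sl <- arr[, , slice_index]
  if (all(sl == 0)) stop("slice is entirely zero")
  thr <- otsu_threshold(as.vector(sl))
  fg <- sl > thr
  if (!any(fg)) fg <- sl >= max(sl)
  rows <- row(sl)[fg]; cols <- col(sl)[fg]; w <- sl[fg]
  mid <- (min(rows) + max(rows)) / 2
  keep <- rows <= mid
  if (!any(keep)) keep <- rep(TRUE, length(rows))
  cr <- sum(rows[keep] * w[keep]) / sum(w[keep])
  cc <- sum(cols[keep] * w[keep]) / sum(w[keep])
  brainstem_box(slice_index, cr, cc)
}

# Clamp a 40x40 crop window fully inside an (nr, nc) slice; returns row/col
# index vectors.
clamp_window <- function(center_row, center_col, nr, nc, size = 40L) {
  r0 <- round(center_row) - size %/% 2L + 1L
  c0 <- round(center_col) - size %/% 2L + 1L
  r0 <- min(max(r0, 1L), nr - size + 1L)
  c0 <- min(max(c0, 1L), nc - size + 1L)
  list(rows = r0:(r0 + size - 1L), cols = c0:(c0 + size - 1L))
}

# 2x average-pool downsample of a matrix (odd trailing row/col dropped).
downsample2 <- function(m) {
  nr <- nrow(m) - nrow(m) %% 2L
  nc <- ncol(m) - ncol(m) %% 2L
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1L, nr, 2L), seq(1L, nc, 2L)] + m[seq(2L, nr, 2L), seq(1L, nc, 2L)] +
     m[seq(1L, nr, 2L), seq(2L, nc, 2L)] + m[seq(2L, nr, 2L), seq(2L, nc, 2L)]) / 4
}

standardize_patch <- function(p) {
  s <- stats::sd(p)
  if (s == 0) p - mean(p) else (p - mean(p)) / s
}

# Assemble the (ds x ds x 1 x B) input batch for the centre regressor.
detector_input <- function(slices_list) {
  ds <- lapply(slices_list, function(sl) standardize_patch(downsample2(sl)))
  d <- dim(ds[[1L]])
  array(unlist(ds), dim = c(d[1L], d[2L], 1L, length(ds)))
}

#' Train the convolutional brainstem-centre regressor
#'
#' A small three-convolution-block regressor maps a 2x-downsampled,
#' standardized axial slice to the normalized (row, col) brainstem centre.
#' Replaces a heavyweight object detector while preserving the pipeline
#' contract (40 x 40 crops around the predicted centre).
#'
#' @param cases list of `synthetic_case` objects (>= 10) with true boxes
#' @param seed training seed (initialization, shuffling)
#' @param epochs,lr,batch_size optimizer settings (Adam)
#' @return object of class `detector_model` with the fitted network and the
#'   per-epoch mean training loss
#' @export
train_detector <- function(cases, seed = 1L, epochs = 40L, lr = 2e-3,
                           batch_size = 16L) {
  if (length(cases) == 0L) stop("empty training set")
  if (length(cases) < 10L) stop("at least 10 cases are required")
  slices_list <- list()
  targets <- list()
  dims <- NULL
  for (cs in cases) {
    vol <- normalize_intensity(reconstruct_setmag(cs$echoes))
    dims <- dim(vol$intensity)
    for (bi in seq_len(nrow(cs$true_boxes))) {
      bx <- cs$true_boxes[bi, ]
      slices_list[[length(slices_list) + 1L]] <- vol$intensity[, , bx$slice]
      targets[[length(targets) + 1L]] <-
        c(bx$center_row / dims[1L], bx$center_col / dims[2L])
    }
  }
  X <- detector_input(slices_list)
  Y <- do.call(rbind, targets)
  in_shape <- c(dim(X)[1L], dim(X)[2L], 1L)
  specs <- list(list(type = "conv", k = 5L, n = 4L), list(type = "relu"),
                list(type = "pool"),
                list(type = "conv", k = 3L, n = 8L), list(type = "relu"),
                list(type = "pool"),
                list(type = "flatten"),
                list(type = "fc", n = 32L), list(type = "relu"),
                list(type = "fc", n = 2L))
  model <- nn_new(specs, in_shape, seed = derive_seed(seed, 1L))
  state <- nn_adam_init(model)
  n <- dim(X)[4L]
  epoch_loss <- numeric(epochs)
  t <- 0L
  with_seed(derive_seed(seed, 2L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1L, n)]
        xb <- X[, , , ids, drop = FALSE]
        fw <- nn_forward(model, xb)
        lo <- mse_loss(fw$out, Y[ids, , drop = FALSE])
        bw <- nn_backward(model, fw$caches, lo$dpred)
        t <- t + 1L
        upd <- nn_adam_step(model, bw$grads, state, lr = lr, t = t)
        model <- upd$model; state <- upd$state
        losses <- c(losses, lo$loss)
      }
      epoch_loss[ep] <- mean(losses)
    }
  })
  structure(list(net = model, slice_dims = dims, seed = seed,
                 epoch_loss = epoch_loss),
            class = "detector_model")
}

#' Predict the brainstem box on one slice with a trained detector
#' @param model a [train_detector()] result
#' @param slice 2D slice matrix (same grid as training volumes)
#' @param slice_index slice index recorded in the box
#' @return a [brainstem_box()]
#' @export
predict_box <- function(model, slice, slice_index) {
  X <- detector_input(list(slice))
  out <- nn_forward(model$net, X, keep_cache = FALSE)$out
  brainstem_box(slice_index,
                out[1L, 1L] * nrow(slice),
                out[1L, 2L] * ncol(slice))
}

#' Extract the preprocessed 40 x 40 x 4 patch stack of a case
#'
#' Normalizes the volume, predicts (or heuristically finds) the brainstem
#' centre on each requested slice, crops a clamped 40 x 40 window, and
#' applies grayscale inversion followed by histogram equalization to each
#' patch.
#'
#' @param volume a [setmag_volume()]
#' @param slices exactly 4 axial slice indices
#' @param model optional `detector_model`; when NULL the heuristic detector
#'   is used
#' @param case_id identifier carried into the stack
#' @return object of class `patch_stack`: `patches` is a 40 x 40 x 4 array
#'   (axial slices along the third axis), `source_boxes` the predicted boxes
#' @export
detect_brainstem <- function(volume, slices, model = NULL,
                             case_id = "case") {
  if (length(slices) != 4L) stop("exactly 4 slice indices are required")
  d <- dim(volume$intensity)
  if (any(slices < 1L) || any(slices > d[3L])) {
    stop("slice index out of range")
  }
  vol <- normalize_intensity(volume)
  patches <- array(0, c(40L, 40L, 4L))
  boxes <- vector("list", 4L)
  for (i in seq_along(slices)) {
    z <- slices[i]
    bx <- if (is.null(model)) {
      heuristic_detect(vol, z)
    } else {
      predict_box(model, vol$intensity[, , z], z)
    }
    win <- clamp_window(bx$center_row, bx$center_col, d[1L], d[2L])
    patch <- vol$intensity[win$rows, win$cols, z]
    patch <- equalize_hist(invert_gray(patch))
    patches[, , i] <- patch
    boxes[[i]] <- brainstem_box(z, mean(win$rows), mean(win$cols))
  }
  structure(list(case_id = case_id, patches = patches, source_boxes = boxes),
            class = "patch_stack")
}

#' Choose the 4 axial slices to feed the CNN
#'
#' Uses the 4 mask-bearing slices when a mask is available, otherwise the 4
#' central axial slices.
#'
#' @param mask optional binary 3D mask
#' @param n_slices total number of axial slices
#' @return integer vector of 4 slice indices
#' @export
select_slices <- function(mask = NULL, n_slices) {
  if (!is.null(mask)) {
    zs <- which(apply(mask, 3L, any))
    if (length(zs) == 4L) return(zs)
  }
  mid <- n_slices %/% 2L
  (mid - 1L):(mid + 2L)
}
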