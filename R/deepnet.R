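# Modified LeNet on 40x40 brainstem patches: shape chain
# 40 -> conv5(6) 36 -> pool 18 -> conv5(16) 14 -> pool 7 -> flatten 784
# -> fc 200 (feature layer) -> fc 2 -> softmax.

lenet_specs <- function() {
  list(list(type = "conv", k = 5L, n = 6L), list(type = "relu"),
       list(type = "pool"),
       list(type = "conv", k = 5L, n = 16L), list(type = "relu"),
       list(type = "pool"),
       list(type = "flatten"),
       list(type = "fc", n = 200L), list(type = "relu"),
       list(type = "fc", n = 2L))
}
LENET_FEATURE_LAYER <- 9L  # activations after the 200-unit layer + ReLU

#' Geometric augmentation of a 40 x 40 patch
#'
#' Returns the original plus `n_copies` randomly scaled (U(0.95, 1.05)) and
#' rotated (U(-5, 5) degrees) copies, tripling the training data at the
#' default. Bilinear interpolation about the patch centre with edge
#' clamping keeps the output at 40 x 40.
#'
#' @param patch 2D matrix
#' @param seed integer seed
#' @param n_copies number of augmented copies (default 2)
#' @return list of `n_copies + 1` patches (the first is the original)
#' @export
augment <- function(patch, seed = 1L, n_copies = 2L) {
  with_seed(seed, {
    out <- list(patch)
    for (i in seq_len(n_copies)) {
      s <- stats::runif(1L, 0.95, 1.05)
      th <- stats::runif(1L, -5, 5) * pi / 180
      out[[i + 1L]] <- affine_patch(patch, s, th)
    }
    out
  })
}

#' Apply a scale + rotation about the patch centre (bilinear)
#' @param patch 2D matrix
#' @param scale isotropic scale factor
#' @param angle rotation angle in radians
#' @return transformed patch of the same size
#' @export
affine_patch <- function(patch, scale = 1, angle = 0) {
  nr <- nrow(patch); nc <- ncol(patch)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  gi <- matrix(seq_len(nr), nr, nc) - cr
  gj <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # inverse map: rotate by -angle, scale by 1/scale
  si <- (cos(angle) * gi + sin(angle) * gj) / scale + cr
  sj <- (-sin(angle) * gi + cos(angle) * gj) / scale + cc
  i0 <- pmin(pmax(floor(si), 1L), nr); i1 <- pmin(i0 + 1L, nr)
  j0 <- pmin(pmax(floor(sj), 1L), nc); j1 <- pmin(j0 + 1L, nc)
  fi <- pmin(pmax(si - i0, 0), 1); fj <- pmin(pmax(sj - j0, 0), 1)
  at <- function(ii, jj) matrix(patch[cbind(as.vector(ii), as.vector(jj))], nr, nc)
  (1 - fi) * (1 - fj) * at(i0, j0) + fi * (1 - fj) * at(i1, j0) +
    (1 - fi) * fj * at(i0, j1) + fi * fj * at(i1, j1)
}

# Patches (list of 40x40) -> standardized network batch (40,40,1,B).
patch_batch <- function(patches) {
  ps <- lapply(patches, standardize_patch)
  array(unlist(ps), dim = c(dim(ps[[1L]]), 1L, length(ps)))
}

# One SGD/Adam training run; X (40,40,1,N), y integer classes.
train_net <- function(X, y, epochs, lr, batch_size, seed,
                      valX = NULL, valy = NULL, specs = lenet_specs()) {
  in_shape <- dim(X)[1:3]
  model <- nn_new(specs, in_shape, seed = derive_seed(seed, 1L))
  state <- nn_adam_init(model)
  n <- dim(X)[4L]
  t <- 0L
  val_acc <- numeric(0)
  loss_hist <- numeric(0)
  best <- list(acc = -Inf, model = model, epoch = 0L)
  with_seed(derive_seed(seed, 2L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1L, n)]
        fw <- nn_forward(model, X[, , , ids, drop = FALSE])
        lo <- softmax_xent(fw$out, y[ids])
        bw <- nn_backward(model, fw$caches, lo$dlogits)
        t <- t + 1L
        upd <- nn_adam_step(model, bw$grads, state, lr = lr, t = t)
        model <- upd$model; state <- upd$state
        losses <- c(losses, lo$loss)
      }
      loss_hist[ep] <- mean(losses)
      if (!is.null(valX)) {
        pv <- nn_forward(model, valX, keep_cache = FALSE)$out
        acc <- mean(max.col(pv) == valy)
        val_acc[ep] <- acc
        if (acc > best$acc) best <- list(acc = acc, model = model, epoch = ep)
      }
    }
  })
  if (is.null(valX)) best <- list(acc = NA_real_, model = model, epoch = epochs)
  list(model = model, best = best, val_acc = val_acc, loss = loss_hist)
}

#' Train the modified LeNet with case-level cross-validation
#'
#' Splits cases (not images) into `n_folds` folds, trains one network per
#' fold with augmented training patches (validation patches are never
#' augmented), records per-epoch validation accuracy and the best
#' checkpoint, then refits on all cases for the best epoch count (default)
#' or returns the best single-fold checkpoint.
#'
#' @param stacks list of [detect_brainstem()] patch stacks
#' @param labels case labels ("HC"/"PD"), one per stack
#' @param n_folds folds (default 5)
#' @param seed master seed
#' @param epochs maximal epochs per fold
#' @param lr,batch_size Adam settings
#' @param augment_training triple the training patches by random
#'   scale/rotation copies
#' @param refit refit on all cases after CV (default TRUE)
#' @return object of class `lenet_bundle`
#' @export
train_cnn <- function(stacks, labels, n_folds = 5L, seed = 1L, epochs = 15L,
                      lr = 1e-3, batch_size = 32L, augment_training = TRUE,
                      refit = TRUE) {
  n_cases <- length(stacks)
  if (n_cases < n_folds) stop("fewer cases than folds")
  if (length(labels) != n_cases) stop("one label per stack is required")
  classes <- c("HC", "PD")
  yc <- match(labels, classes)
  if (anyNA(yc)) stop("labels must be HC or PD")
  folds <- with_seed(derive_seed(seed, 10L), {
    sample(rep(seq_len(n_folds), length.out = n_cases))
  })

  case_patches <- function(ids, do_augment) {
    ps <- list(); ys <- c()
    for (ci in ids) {
      for (k in 1:4) {
        p <- stacks[[ci]]$patches[, , k]
        if (do_augment) {
          aug <- augment(p, seed = derive_seed(seed, ci * 7L + k))
          ps <- c(ps, aug)
          ys <- c(ys, rep(yc[ci], length(aug)))
        } else {
          ps <- c(ps, list(p))
          ys <- c(ys, yc[ci])
        }
      }
    }
    list(X = patch_batch(ps), y = ys)
  }

  val_acc <- matrix(NA_real_, n_folds, epochs)
  fold_best <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- case_patches(which(folds != f), augment_training)
    va <- case_patches(which(folds == f), FALSE)
    run <- train_net(tr$X, tr$y, epochs, lr, batch_size,
                     seed = derive_seed(seed, 100L + f),
                     valX = va$X, valy = va$y)
    val_acc[f, seq_along(run$val_acc)] <- run$val_acc
    fold_best[[f]] <- run$best
  }
  mean_acc <- colMeans(val_acc)
  best_epoch <- which.max(mean_acc)

  final <- if (refit) {
    allp <- case_patches(seq_len(n_cases), augment_training)
    train_net(allp$X, allp$y, best_epoch, lr, batch_size,
              seed = derive_seed(seed, 999L))$model
  } else {
    fold_best[[which.max(vapply(fold_best, `[[`, 0, "acc"))]]$model
  }
  structure(list(net = final, classes = classes, folds = folds,
                 val_acc = val_acc, best_epoch = best_epoch,
                 seed = seed, feature_layer = LENET_FEATURE_LAYER),
            class = "lenet_bundle")
}

check_bundle <- function(model) {
  if (!inherits(model, "lenet_bundle")) stop("model is not a trained bundle")
}

#' Deep features of a patch stack (4 x 200)
#'
#' Activations of the 200-unit feature layer for each of the 4 patches, in
#' slice order.
#'
#' @param model a [train_cnn()] bundle
#' @param stack a `patch_stack`
#' @return 4 x 200 numeric matrix
#' @export
extract_deep_features <- function(model, stack) {
  check_bundle(model)
  X <- patch_batch(lapply(1:4, function(k) stack$patches[, , k]))
  act <- nn_activations(model$net, X, model$feature_layer)
  colnames_out <- sprintf("deep_%03d", 1:200)
  out <- act  # (B x 200)
  dimnames(out) <- list(NULL, colnames_out)
  out
}

#' Probability that a single patch is PD
#'
#' @param model a [train_cnn()] bundle
#' @param patch 40 x 40 matrix
#' @return softmax probability of the PD class
#' @export
predict_image <- function(model, patch) {
  check_bundle(model)
  if (!identical(dim(patch), c(40L, 40L))) stop("patch must be 40 x 40")
  X <- patch_batch(list(patch))
  logits <- nn_forward(model$net, X, keep_cache = FALSE)$out
  softmax(logits)[1L, 2L]
}

#' Image-level PD probabilities for a whole stack
#' @param model a [train_cnn()] bundle
#' @param stack a `patch_stack`
#' @return numeric vector of 4 probabilities
#' @export
predict_stack <- function(model, stack) {
  check_bundle(model)
  X <- patch_batch(lapply(1:4, function(k) stack$patches[, , k]))
  softmax(nn_forward(model$net, X, keep_cache = FALSE)$out)[, 2L]
}

# Gradient of one class logit wrt the standardized network input.
net_input_grad <- function(net, xstd, class_index) {
  fw <- nn_forward(net, xstd)
  dlog <- matrix(0, 1L, 2L)
  dlog[1L, class_index] <- 1
  nn_backward(net, fw$caches, dlog)$dx
}

#' Gradient saliency map of a patch
#'
#' Absolute gradient of the predicted class' logit with respect to the
#' standardized input patch: non-negative, same shape as the input.
#'
#' @param model a [train_cnn()] bundle
#' @param patch 40 x 40 matrix
#' @return 40 x 40 non-negative matrix
#' @export
saliency_map <- function(model, patch) {
  check_bundle(model)
  if (!identical(dim(patch), c(40L, 40L))) stop("patch must be 40 x 40")
  X <- patch_batch(list(patch))
  logits <- nn_forward(model$net, X, keep_cache = FALSE)$out
  cls <- which.max(logits[1L, ])
  g <- net_input_grad(model$net, X, cls)
  abs(g[, , 1L, 1L])
}

#' Save / load a trained bundle
#'
#' Weights go to an RDS file, with a JSON sidecar recording architecture,
#' seed, folds and validation metrics.
#'
#' @param model a `lenet_bundle`
#' @param path output path (without extension)
#' @return `path`, invisibly
#' @export
save_model_bundle <- function(model, path) {
  check_bundle(model)
  saveRDS(model, paste0(path, ".rds"))
  side <- list(architecture = "lenet-6-16-200-2", seed = model$seed,
               folds = model$folds, best_epoch = model$best_epoch,
               val_acc = model$val_acc)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  readRDS(paste0(path, ".rds"))
}
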