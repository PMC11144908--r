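zero_bundle <- function() {
  net <- nmhybrid:::nn_new(nmhybrid:::lenet_specs(), c(40L, 40L, 1L), seed = 1)
  for (li in seq_along(net$layers)) {
    if (!is.null(net$layers[[li]]$W)) {
      net$layers[[li]]$W[] <- 0
      net$layers[[li]]$b[] <- 0
    }
  }
  structure(list(net = net, classes = c("HC", "PD"), folds = integer(0),
                 val_acc = matrix(0, 1, 1), best_epoch = 1L, seed = 1L,
                 feature_layer = nmhybrid:::LENET_FEATURE_LAYER),
            class = "lenet_bundle")
}

test_that("augmentation triples the data deterministically", {
  set.seed(18)
  p <- matrix(runif(1600), 40, 40)
  a <- augment(p, seed = 3)
  expect_length(a, 3L)
  expect_identical(a[[1]], p)
  b <- augment(p, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a[[2]], p))
  # identity transform reproduces the patch exactly
  expect_equal(affine_patch(p, scale = 1, angle = 0), p)
})

test_that("the LeNet shape chain 40-36-18-14-7-784-200-2 holds", {
  net <- nmhybrid:::nn_new(nmhybrid:::lenet_specs(), c(40L, 40L, 1L), seed = 2)
  x <- array(rnorm(1600), c(40, 40, 1, 1))
  fw <- nmhybrid:::nn_forward(net, x)
  expect_identical(net$output_dim, 2L)
  expect_identical(dim(fw$out), c(1L, 2L))
  feats <- nmhybrid:::nn_activations(net, x, nmhybrid:::LENET_FEATURE_LAYER)
  expect_identical(dim(feats), c(1L, 200L))
  shapes <- list()
  cur <- x
  for (li in seq_along(net$layers)) {
    cur <- nmhybrid:::nn_activations(net, x, li)
    shapes[[li]] <- dim(cur)
  }
  expect_identical(shapes[[1]][1:3], c(36L, 36L, 6L))
  expect_identical(shapes[[3]][1:3], c(18L, 18L, 6L))
  expect_identical(shapes[[4]][1:3], c(14L, 14L, 16L))
  expect_identical(shapes[[6]][1:3], c(7L, 7L, 16L))
  expect_identical(shapes[[7]][2], 784L)
})

test_that("softmax head is normalized, symmetric at zero, and monotone", {
  sm <- nmhybrid:::softmax
  set.seed(19)
  L <- matrix(rnorm(20), 10, 2)
  P <- sm(L)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-6)
  zb <- zero_bundle()
  p <- matrix(runif(1600), 40, 40)
  expect_equal(predict_image(zb, p), 0.5)
  # increasing the PD logit increases the PD probability
  base <- sm(matrix(c(0.3, 0.1), 1))[1, 2]
  up <- sm(matrix(c(0.3, 0.6), 1))[1, 2]
  expect_gt(up, base)
  expect_error(predict_image(zb, matrix(0, 20, 20)), "40 x 40")
})

test_that("deep feature extraction returns deterministic 4 x 200 rows", {
  zb <- zero_bundle()
  co <- test_cohort()
  st <- co$stacks[[3]]
  f <- extract_deep_features(zb, st)
  expect_identical(dim(f), c(4L, 200L))
  f2 <- extract_deep_features(zb, st)
  expect_identical(f, f2)
  # identical patches give identical rows
  st2 <- st
  for (k in 2:4) st2$patches[, , k] <- st2$patches[, , 1]
  g <- extract_deep_features(zb, st2)
  expect_equal(g[1, ], g[2, ])
  expect_equal(g[1, ], g[4, ])
  expect_error(extract_deep_features(list(), st), "bundle")
})

test_that("training respects case-level folds and a fixed seed", {
  co <- test_cohort()
  tc <- test_cnn()
  b <- tc$bundle
  expect_length(b$folds, length(tc$split$train))
  expect_identical(sort(unique(b$folds)), 1:3)
  expect_identical(b$best_epoch, which.max(colMeans(b$val_acc)))
  expect_error(train_cnn(co$stacks[1:3], co$labels[1:3], n_folds = 5),
               "fewer cases")
  # small-run determinism of the optimizer
  X <- nmhybrid:::patch_batch(lapply(1:8, function(k) co$stacks[[k]]$patches[, , 1]))
  y <- rep(1:2, 4)
  r1 <- nmhybrid:::train_net(X, y, epochs = 2, lr = 1e-3, batch_size = 4,
                             seed = 7)
  r2 <- nmhybrid:::train_net(X, y, epochs = 2, lr = 1e-3, batch_size = 4,
                             seed = 7)
  expect_identical(r1$loss, r2$loss)
  expect_identical(r1$model$layers, r2$model$layers)
})

test_that("saliency is non-negative and matches finite differences", {
  tc <- test_cnn()
  co <- test_cohort()
  patch <- co$stacks[[1]]$patches[, , 2]
  sal <- saliency_map(tc$bundle, patch)
  expect_identical(dim(sal), c(40L, 40L))
  expect_true(all(sal >= 0))
  # finite-difference check of the predicted-class logit gradient
  net <- tc$bundle$net
  X <- nmhybrid:::patch_batch(list(patch))
  logits <- nmhybrid:::nn_forward(net, X, keep_cache = FALSE)$out
  cls <- which.max(logits[1, ])
  g <- nmhybrid:::net_input_grad(net, X, cls)
  eps <- 1e-4
  set.seed(20)
  for (t in 1:10) {
    i <- sample(40, 1); j <- sample(40, 1)
    Xp <- X; Xp[i, j, 1, 1] <- Xp[i, j, 1, 1] + eps
    Xm <- X; Xm[i, j, 1, 1] <- Xm[i, j, 1, 1] - eps
    fd <- (nmhybrid:::nn_forward(net, Xp, FALSE)$out[1, cls] -
             nmhybrid:::nn_forward(net, Xm, FALSE)$out[1, cls]) / (2 * eps)
    an <- g[i, j, 1, 1]
    expect_equal(an, fd, tolerance = 1e-4 * max(abs(fd), 1e-6))
  }
})

test_that("model bundles round-trip through disk", {
  tc <- test_cnn()
  co <- test_cohort()
  path <- file.path(withr::local_tempdir(), "cnn")
  save_model_bundle(tc$bundle, path)
  expect_true(file.exists(paste0(path, ".rds")))
  expect_true(file.exists(paste0(path, ".json")))
  reloaded <- load_model_bundle(path)
  p <- co$stacks[[2]]$patches[, , 1]
  expect_identical(predict_image(reloaded, p), predict_image(tc$bundle, p))
})
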