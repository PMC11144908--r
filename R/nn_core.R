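# Minimal CNN engine: valid 2D convolution via im2col, 2x2 max-pooling,
# ReLU, fully-connected layers, softmax / MSE heads, manual backprop and
# Adam. Batches are arrays of shape (H, W, C, B); fully-connected
# activations are (B x D) matrices. Gradients are exact (verified against
# finite differences in the test suite).

conv_im2col_idx <- function(H, W, C, k) {
  outH <- H - k + 1L
  outW <- W - k + 1L
  base_i <- rep(seq_len(outH), times = outW)
  base_j <- rep(seq_len(outW), each = outH)
  pos <- base_i + (base_j - 1L) * H
  ki <- rep(seq_len(k), times = k * C)
  kj <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  off <- (ki - 1L) + (kj - 1L) * H + (cc - 1L) * H * W
  list(idx = outer(pos, off, "+"), outH = outH, outW = outW)
}

#' Build a small CNN
#'
#' @param layer_specs list of layer descriptors: `list(type = "conv", k, n)`,
#'   `list(type = "relu")`, `list(type = "pool")`, `list(type = "flatten")`,
#'   `list(type = "fc", n)`
#' @param input_shape c(H, W, C)
#' @param seed weight-initialization seed (He-scaled normal)
#' @return model object of class `nn_model`
#' @keywords internal
nn_new <- function(layer_specs, input_shape, seed = 1L) {
  with_seed(seed, {
    shape <- input_shape  # c(H, W, C) or scalar D after flatten
    layers <- vector("list", length(layer_specs))
    for (li in seq_along(layer_specs)) {
      sp <- layer_specs[[li]]
      if (sp$type == "conv") {
        H <- shape[1L]; W <- shape[2L]; C <- shape[3L]
        im <- conv_im2col_idx(H, W, C, sp$k)
        fan_in <- sp$k * sp$k * C
        layers[[li]] <- list(
          type = "conv", k = sp$k, n = sp$n, in_shape = shape, im = im,
          W = matrix(stats::rnorm(fan_in * sp$n, 0, sqrt(2 / fan_in)),
                     fan_in, sp$n),
          b = numeric(sp$n))
        shape <- c(im$outH, im$outW, sp$n)
      } else if (sp$type == "relu") {
        layers[[li]] <- list(type = "relu")
      } else if (sp$type == "pool") {
        stopifnot(shape[1L] %% 2L == 0L, shape[2L] %% 2L == 0L)
        layers[[li]] <- list(type = "pool", in_shape = shape)
        shape <- c(shape[1L] %/% 2L, shape[2L] %/% 2L, shape[3L])
      } else if (sp$type == "flatten") {
        layers[[li]] <- list(type = "flatten", in_shape = shape)
        shape <- prod(shape)
      } else if (sp$type == "fc") {
        D <- shape[1L]
        layers[[li]] <- list(
          type = "fc", n = sp$n,
          W = matrix(stats::rnorm(D * sp$n, 0, sqrt(2 / D)), D, sp$n),
          b = numeric(sp$n))
        shape <- sp$n
      } else {
        stop("unknown layer type: ", sp$type)
      }
    }
    structure(list(layers = layers, input_shape = input_shape,
                   output_dim = shape),
              class = "nn_model")
  })
}

nn_forward <- function(model, x, keep_cache = TRUE) {
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      d <- dim(x); B <- d[4L]
      P <- nrow(ly$im$idx); Q <- ncol(ly$im$idx)
      HWC <- prod(ly$in_shape)
      xv <- as.vector(x)
      Xc <- matrix(0, P * B, Q)
      for (b in seq_len(B)) {
        Xc[((b - 1L) * P + 1L):(b * P), ] <- xv[ly$im$idx + (b - 1L) * HWC]
      }
      Y <- Xc %*% ly$W
      Y <- sweep(Y, 2L, ly$b, "+")
      out <- aperm(array(Y, c(P, B, ly$n)), c(1L, 3L, 2L))
      dim(out) <- c(ly$im$outH, ly$im$outW, ly$n, B)
      if (keep_cache) caches[[li]] <- list(Xc = Xc, B = B)
      x <- out
    } else if (ly$type == "relu") {
      if (keep_cache) caches[[li]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (ly$type == "pool") {
      d <- dim(x)
      ro <- seq(1L, d[1L], by = 2L); co <- seq(1L, d[2L], by = 2L)
      a11 <- x[ro, co, , , drop = FALSE]
      a21 <- x[ro + 1L, co, , , drop = FALSE]
      a12 <- x[ro, co + 1L, , , drop = FALSE]
      a22 <- x[ro + 1L, co + 1L, , , drop = FALSE]
      out <- pmax(a11, a21, a12, a22)
      if (keep_cache) {
        p1 <- a11 == out
        p2 <- (a21 == out) & !p1
        p3 <- (a12 == out) & !(p1 | p2)
        p4 <- !(p1 | p2 | p3)
        caches[[li]] <- list(p = list(p1, p2, p3, p4), in_dim = d)
      }
      x <- out
    } else if (ly$type == "flatten") {
      d <- dim(x); B <- d[4L]
      if (keep_cache) caches[[li]] <- list(in_dim = d)
      x <- t(matrix(x, prod(d[1:3]), B))
    } else if (ly$type == "fc") {
      if (keep_cache) caches[[li]] <- list(X = x)
      x <- sweep(x %*% ly$W, 2L, ly$b, "+")
    }
  }
  list(out = x, caches = caches)
}

# Returns per-layer gradients and the gradient wrt the input batch.
nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    ca <- caches[[li]]
    if (ly$type == "conv") {
      B <- ca$B
      P <- nrow(ly$im$idx)
      dY <- matrix(aperm(array(dout, c(P, ly$n, B)), c(1L, 3L, 2L)),
                   P * B, ly$n)
      grads[[li]] <- list(W = crossprod(ca$Xc, dY), b = colSums(dY))
      dXc <- dY %*% t(ly$W)
      HWC <- prod(ly$in_shape)
      dxv <- numeric(HWC * B)
      for (b in seq_len(B)) {
        offb <- (b - 1L) * HWC
        rows <- ((b - 1L) * P + 1L):(b * P)
        for (q in seq_len(ncol(ly$im$idx))) {
          tgt <- ly$im$idx[, q] + offb
          dxv[tgt] <- dxv[tgt] + dXc[rows, q]
        }
      }
      dout <- array(dxv, c(ly$in_shape, B))
    } else if (ly$type == "relu") {
      dout <- dout * ca$mask
    } else if (ly$type == "pool") {
      d <- ca$in_dim
      dx <- array(0, d)
      ro <- seq(1L, d[1L], by = 2L); co <- seq(1L, d[2L], by = 2L)
      sub <- array(0, dim(ca$p[[1L]]))
      sub[ca$p[[1L]]] <- dout[ca$p[[1L]]]
      dx[ro, co, , ] <- sub
      sub <- array(0, dim(sub)); sub[ca$p[[2L]]] <- dout[ca$p[[2L]]]
      dx[ro + 1L, co, , ] <- sub
      sub <- array(0, dim(sub)); sub[ca$p[[3L]]] <- dout[ca$p[[3L]]]
      dx[ro, co + 1L, , ] <- sub
      sub <- array(0, dim(sub)); sub[ca$p[[4L]]] <- dout[ca$p[[4L]]]
      dx[ro + 1L, co + 1L, , ] <- sub
      dout <- dx
    } else if (ly$type == "flatten") {
      dout <- array(t(dout), ca$in_dim)
    } else if (ly$type == "fc") {
      grads[[li]] <- list(W = crossprod(ca$X, dout), b = colSums(dout))
      dout <- dout %*% t(ly$W)
    }
  }
  list(grads = grads, dx = dout)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss and gradient; y is an integer class vector (1-based).
softmax_xent <- function(logits, y) {
  p <- softmax(logits)
  B <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(B), y)] + eps))
  dlog <- p
  dlog[cbind(seq_len(B), y)] <- dlog[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dlog / B)
}

mse_loss <- function(pred, target) {
  B <- nrow(pred)
  diff <- pred - target
  list(loss = mean(diff^2), dpred = 2 * diff / (B * ncol(pred)))
}

nn_adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (!is.null(ly$W)) {
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    } else NULL
  })
}

nn_adam_step <- function(model, grads, state, lr = 1e-3, t = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    st <- state[[li]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    mWh <- st$mW / (1 - beta1^t); vWh <- st$vW / (1 - beta2^t)
    mbh <- st$mb / (1 - beta1^t); vbh <- st$vb / (1 - beta2^t)
    model$layers[[li]]$W <- model$layers[[li]]$W - lr * mWh / (sqrt(vWh) + eps)
    model$layers[[li]]$b <- model$layers[[li]]$b - lr * mbh / (sqrt(vbh) + eps)
    state[[li]] <- st
  }
  list(model = model, state = state)
}

# Activations of an intermediate layer (1-based index into model$layers).
nn_activations <- function(model, x, layer_index) {
  for (li in seq_len(layer_index)) {
    ly <- model$layers[[li]]
    x <- nn_forward(structure(list(layers = list(ly)), class = "nn_model"),
                    x, keep_cache = FALSE)$out
  }
  x
}
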