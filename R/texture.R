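# Texture-feature families on discretized ROIs: GLCM and GLRLM averaged
# over the 13 unique 3D directions at distance 1, GLSZM/GLDM/NGTDM with
# 26-connectivity (GLDM dependence tolerance alpha = 0). Formulas follow
# the IBSI definitions with the documented degenerate-case fallbacks.

glcm_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")

glrlm_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

glszm_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

gldm_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

ngtdm_names <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength")

roi_levels <- function(roi) {
  if (inherits(roi, "discretized_roi")) {
    crop_levels(roi$levels)
  } else {
    roi  # already a levels array (possibly with NAs)
  }
}

# Symmetric normalized co-occurrence matrix for one offset; NULL when no
# valid pair exists.
glcm_matrix_one <- function(lev, Ng, dx, dy, dz) {
  b <- shift3d(lev, dx, dy, dz, fill = NA_real_)
  sel <- !is.na(lev) & !is.na(b)
  if (!any(sel)) return(NULL)
  counts <- tabulate((lev[sel] - 1L) * Ng + b[sel], nbins = Ng * Ng)
  P <- matrix(counts, Ng, Ng, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

glcm_features_one <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(i[, 1L] * px)
  sig2 <- sum((i[, 1L] - mu)^2 * px)
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1L))
  k_dif <- 0:(Ng - 1L)
  p_dif <- vapply(k_dif, function(k) sum(P[abs(i - j) == k]), numeric(1L))
  eps <- 1e-16
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  da <- sum(k_dif * p_dif)
  hxy <- ent(P)
  pxpy <- outer(px, px)
  hxy1 <- -sum(P * log2(pxpy + eps))
  hxy2 <- ent_safe <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hx <- ent(px)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  inv_var <- {
    sel <- i != j
    sum(P[sel] / (i[sel] - j[sel])^2)
  }
  mcc <- if (Ng < 2L || sig2 == 0) 1 else {
    nzr <- px > 0
    Q <- diag(1 / px[nzr], nrow = sum(nzr)) %*% P[nzr, nzr, drop = FALSE] %*%
      diag(1 / px[nzr], nrow = sum(nzr)) %*% t(P[nzr, nzr, drop = FALSE])
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(lam) < 2L) 1 else sqrt(max(min(lam[2L], 1), 0))
  }
  c(sum(i * j * P),
    mu,
    sum((i + j - 2 * mu)^4 * P),
    sum((i + j - 2 * mu)^3 * P),
    sum((i + j - 2 * mu)^2 * P),
    sum((i - j)^2 * P),
    corr,
    da,
    ent(p_dif),
    sum((k_dif - da)^2 * p_dif),
    sum(P^2),
    hxy,
    imc1,
    imc2,
    sum(P / (1 + (i - j)^2)),
    sum(P / (1 + ((i - j) / Ng)^2)),
    sum(P / (1 + abs(i - j))),
    sum(P / (1 + abs(i - j) / Ng)),
    inv_var,
    max(P),
    sum(k_sum * p_sum),
    ent(p_sum),
    sum((i - mu)^2 * P),
    mcc)
}

#' Gray-level co-occurrence features (24, averaged over 13 directions)
#' @param roi a [discretize()] result
#' @return named numeric vector of the 24 GLCM features
#' @export
glcm_features <- function(roi) {
  lev <- roi_levels(roi)
  if (sum(!is.na(lev)) < 2L) stop("GLCM needs at least 2 ROI voxels")
  Ng <- max(lev, na.rm = TRUE)
  offs <- offsets13()
  feats <- list()
  for (o in seq_len(nrow(offs))) {
    P <- glcm_matrix_one(lev, Ng, offs[o, 1L], offs[o, 2L], offs[o, 3L])
    if (!is.null(P)) feats[[length(feats) + 1L]] <- glcm_features_one(P)
  }
  stats::setNames(colMeans(do.call(rbind, feats)),
                  paste0("glcm_", glcm_names))
}

# Run-length matrix (Ng x max_len) for one direction.
glrlm_matrix_one <- function(lev, Ng, d) {
  coords <- which(!is.na(lev), arr.ind = TRUE)
  v <- lev[coords]
  t_proj <- as.vector(coords %*% d)
  dd <- sum(d^2)
  # line id: invariant along the direction, integer-valued
  lid <- coords * dd - outer(t_proj, as.vector(d))
  B <- 4 * max(dim(lev)) * 3 + 10
  key <- (lid[, 1L] + B) + (lid[, 2L] + B) * (2 * B + 1) +
    (lid[, 3L] + B) * (2 * B + 1)^2
  ord <- order(key, t_proj)
  kv <- key[ord]; tv <- t_proj[ord]; vv <- v[ord]
  n <- length(vv)
  newrun <- c(TRUE, kv[-1L] != kv[-n] | vv[-1L] != vv[-n] |
                tv[-1L] != tv[-n] + dd)
  run_id <- cumsum(newrun)
  len <- tabulate(run_id)
  run_lev <- vv[newrun]
  maxlen <- max(len)
  counts <- tabulate((run_lev - 1L) * maxlen + len, nbins = Ng * maxlen)
  matrix(counts, Ng, maxlen, byrow = TRUE)
}

glrlm_features_one <- function(R, Np) {
  Ng <- nrow(R); L <- ncol(R)
  Nr <- sum(R)
  i <- matrix(seq_len(Ng), Ng, L)
  l <- matrix(seq_len(L), Ng, L, byrow = TRUE)
  p <- R / Nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  pe <- p[p > 0]
  c(sum(R / l^2) / Nr,
    sum(R * l^2) / Nr,
    sum(rowSums(R)^2) / Nr,
    sum(rowSums(R)^2) / Nr^2,
    sum(colSums(R)^2) / Nr,
    sum(colSums(R)^2) / Nr^2,
    Nr / Np,
    sum((i - mu_i)^2 * p),
    sum((l - mu_l)^2 * p),
    -sum(pe * log2(pe)),
    sum(p / i^2),
    sum(p * i^2),
    sum(p / (i^2 * l^2)),
    sum(p * i^2 / l^2),
    sum(p * l^2 / i^2),
    sum(p * i^2 * l^2))
}

#' Gray-level run-length features (16, averaged over 13 directions)
#' @param roi a [discretize()] result
#' @return named numeric vector of the 16 GLRLM features
#' @export
glrlm_features <- function(roi) {
  lev <- roi_levels(roi)
  Np <- sum(!is.na(lev))
  if (Np < 1L) stop("empty ROI")
  Ng <- max(lev, na.rm = TRUE)
  offs <- offsets13()
  feats <- vapply(seq_len(nrow(offs)), function(o) {
    R <- glrlm_matrix_one(lev, Ng, offs[o, ])
    glrlm_features_one(R, Np)
  }, numeric(16L))
  stats::setNames(rowMeans(feats), paste0("glrlm_", glrlm_names))
}

# 26-connected zone labelling by iterative minimum-label propagation.
label_zones <- function(lev) {
  d <- dim(lev)
  lab <- array(NA_real_, d)
  sel <- !is.na(lev)
  lab[sel] <- seq_len(prod(d))[sel]
  offs <- offsets26()
  repeat {
    changed <- FALSE
    for (o in seq_len(nrow(offs))) {
      shl <- shift3d(lab, offs[o, 1L], offs[o, 2L], offs[o, 3L])
      shv <- shift3d(lev, offs[o, 1L], offs[o, 2L], offs[o, 3L])
      upd <- sel & !is.na(shl) & shv == lev & shl < lab
      upd[is.na(upd)] <- FALSE
      if (any(upd)) {
        lab[upd] <- shl[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Gray-level size-zone features (16, 26-connected zones)
#' @param roi a [discretize()] result
#' @return named numeric vector of the 16 GLSZM features
#' @export
glszm_features <- function(roi) {
  lev <- roi_levels(roi)
  Np <- sum(!is.na(lev))
  if (Np < 1L) stop("empty ROI")
  Ng <- max(lev, na.rm = TRUE)
  lab <- label_zones(lev)
  zl <- lab[!is.na(lab)]
  sizes <- table(zl)
  zone_size <- as.integer(sizes)
  zone_level <- lev[match(as.numeric(names(sizes)), lab)]
  maxs <- max(zone_size)
  counts <- tabulate((zone_level - 1L) * maxs + zone_size, nbins = Ng * maxs)
  S <- matrix(counts, Ng, maxs, byrow = TRUE)
  Nz <- sum(S)
  i <- matrix(seq_len(Ng), Ng, maxs)
  s <- matrix(seq_len(maxs), Ng, maxs, byrow = TRUE)
  p <- S / Nz
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  pe <- p[p > 0]
  out <- c(sum(S / s^2) / Nz,
           sum(S * s^2) / Nz,
           sum(rowSums(S)^2) / Nz,
           sum(rowSums(S)^2) / Nz^2,
           sum(colSums(S)^2) / Nz,
           sum(colSums(S)^2) / Nz^2,
           Nz / Np,
           sum((i - mu_i)^2 * p),
           sum((s - mu_s)^2 * p),
           -sum(pe * log2(pe)),
           sum(p / i^2),
           sum(p * i^2),
           sum(p / (i^2 * s^2)),
           sum(p * i^2 / s^2),
           sum(p * s^2 / i^2),
           sum(p * i^2 * s^2))
  stats::setNames(out, paste0("glszm_", glszm_names))
}

#' Gray-level dependence features (14; alpha = 0, 26-connectivity)
#' @param roi a [discretize()] result
#' @return named numeric vector of the 14 GLDM features
#' @export
gldm_features <- function(roi) {
  lev <- roi_levels(roi)
  Np <- sum(!is.na(lev))
  if (Np < 1L) stop("empty ROI")
  Ng <- max(lev, na.rm = TRUE)
  dep <- array(0L, dim(lev))
  offs <- offsets26()
  for (o in seq_len(nrow(offs))) {
    shv <- shift3d(lev, offs[o, 1L], offs[o, 2L], offs[o, 3L])
    eqn <- !is.na(shv) & shv == lev
    eqn[is.na(eqn)] <- FALSE
    dep <- dep + eqn
  }
  sel <- !is.na(lev)
  j <- dep[sel] + 1L  # dependence size (neighbours + centre)
  iv <- lev[sel]
  maxj <- max(j)
  counts <- tabulate((iv - 1L) * maxj + j, nbins = Ng * maxj)
  D <- matrix(counts, Ng, maxj, byrow = TRUE)
  Nz <- sum(D)
  i <- matrix(seq_len(Ng), Ng, maxj)
  jj <- matrix(seq_len(maxj), Ng, maxj, byrow = TRUE)
  p <- D / Nz
  mu_i <- sum(i * p); mu_j <- sum(jj * p)
  pe <- p[p > 0]
  out <- c(sum(D / jj^2) / Nz,
           sum(D * jj^2) / Nz,
           sum(rowSums(D)^2) / Nz,
           sum(colSums(D)^2) / Nz,
           sum(colSums(D)^2) / Nz^2,
           sum((i - mu_i)^2 * p),
           sum((jj - mu_j)^2 * p),
           -sum(pe * log2(pe)),
           sum(p / i^2),
           sum(p * i^2),
           sum(p / (i^2 * jj^2)),
           sum(p * i^2 / jj^2),
           sum(p * jj^2 / i^2),
           sum(p * i^2 * jj^2))
  stats::setNames(out, paste0("gldm_", gldm_names))
}

#' Neighbouring gray-tone difference features (5; 26-connectivity)
#' @param roi a [discretize()] result
#' @return named numeric vector of the 5 NGTDM features
#' @export
ngtdm_features <- function(roi) {
  lev <- roi_levels(roi)
  Np <- sum(!is.na(lev))
  if (Np < 1L) stop("empty ROI")
  Ng <- max(lev, na.rm = TRUE)
  nb_sum <- array(0, dim(lev))
  nb_cnt <- array(0L, dim(lev))
  offs <- offsets26()
  for (o in seq_len(nrow(offs))) {
    shv <- shift3d(lev, offs[o, 1L], offs[o, 2L], offs[o, 3L])
    has <- !is.na(shv)
    shv[!has] <- 0
    nb_sum <- nb_sum + shv
    nb_cnt <- nb_cnt + has
  }
  sel <- !is.na(lev) & nb_cnt > 0L
  Nv <- sum(sel)
  abar <- nb_sum[sel] / nb_cnt[sel]
  iv <- lev[sel]
  n_i <- tabulate(iv, nbins = Ng)
  s_i <- vapply(seq_len(Ng), function(g) sum(abs(g - abar[iv == g])),
                numeric(1L))
  p_i <- n_i / Nv
  nz <- p_i > 0
  Ngp <- sum(nz)
  gl <- seq_len(Ng)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1L) {
    (sum(outer(p_i[nz], p_i[nz]) * outer(gl[nz], gl[nz], "-")^2) /
       (Ngp * (Ngp - 1L))) * sum(s_i) / Nv
  } else 0
  busy_den <- sum(abs(outer(gl[nz] * p_i[nz], gl[nz] * p_i[nz], "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  pi_nz <- p_i[nz]; si_nz <- s_i[nz]; gl_nz <- gl[nz]
  complexity <- sum(abs(outer(gl_nz, gl_nz, "-")) *
                      (outer(pi_nz * si_nz, pi_nz * si_nz, "+")) /
                      outer(pi_nz, pi_nz, "+")) / Nv
  strength_num <- sum(outer(pi_nz, pi_nz, "+") * outer(gl_nz, gl_nz, "-")^2)
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength),
                  paste0("ngtdm_", ngtdm_names))
}
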