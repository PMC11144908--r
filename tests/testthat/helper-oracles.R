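# Brute-force oracles, written independently of the package implementation:
# plain nested loops that enumerate voxel pairs, runs, zones, dependencies
# and neighbourhood differences directly, then apply the textbook formulas
# in scalar form.

oracle_offsets13 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      out[[length(out) + 1L]] <- c(dx, dy, dz)
    }
  }
  out
}

oracle_offsets26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (!(dx == 0 && dy == 0 && dz == 0)) out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

in_bounds <- function(p, d) all(p >= 1L) && all(p <= d)

# --- GLCM ------------------------------------------------------------------

oracle_glcm_matrix <- function(lev, off) {
  d <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  P <- matrix(0, Ng, Ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k])) next
    q <- c(i, j, k) + off
    if (!in_bounds(q, d)) next
    if (is.na(lev[q[1], q[2], q[3]])) next
    a <- lev[i, j, k]; b <- lev[q[1], q[2], q[3]]
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  px <- rowSums(P)
  mu <- 0; for (i in 1:Ng) mu <- mu + i * px[i]
  sig2 <- 0; for (i in 1:Ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  f <- c(Autocorrelation = 0, JointAverage = mu, ClusterProminence = 0,
         ClusterShade = 0, ClusterTendency = 0, Contrast = 0,
         Correlation = 0, DifferenceAverage = 0, DifferenceEntropy = 0,
         DifferenceVariance = 0, JointEnergy = 0, JointEntropy = 0,
         Imc1 = 0, Imc2 = 0, Idm = 0, Idmn = 0, Id = 0, Idn = 0,
         InverseVariance = 0, MaximumProbability = max(P), SumAverage = 0,
         SumEntropy = 0, SumSquares = 0, MCC = 0)
  pdiff <- rep(0, Ng); psum <- rep(0, 2 * Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * p
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - 2 * mu)^4 * p
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - 2 * mu)^3 * p
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - 2 * mu)^2 * p
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * p
    f["JointEnergy"] <- f["JointEnergy"] + p^2
    if (p > 0) f["JointEntropy"] <- f["JointEntropy"] - p * log2(p)
    f["Idm"] <- f["Idm"] + p / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + p / (1 + ((i - j) / Ng)^2)
    f["Id"] <- f["Id"] + p / (1 + abs(i - j))
    f["Idn"] <- f["Idn"] + p / (1 + abs(i - j) / Ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + p / (i - j)^2
    f["SumSquares"] <- f["SumSquares"] + (i - mu)^2 * p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    psum[i + j] <- psum[i + j] + p
  }
  da <- 0; for (k in 0:(Ng - 1)) da <- da + k * pdiff[k + 1]
  f["DifferenceAverage"] <- da
  for (k in 0:(Ng - 1)) {
    if (pdiff[k + 1] > 0) {
      f["DifferenceEntropy"] <- f["DifferenceEntropy"] -
        pdiff[k + 1] * log2(pdiff[k + 1])
    }
    f["DifferenceVariance"] <- f["DifferenceVariance"] +
      (k - da)^2 * pdiff[k + 1]
  }
  for (k in 2:(2 * Ng)) {
    f["SumAverage"] <- f["SumAverage"] + k * psum[k]
    if (psum[k] > 0) f["SumEntropy"] <- f["SumEntropy"] - psum[k] * log2(psum[k])
  }
  f["Correlation"] <- if (sig2 > 0) (f[["Autocorrelation"]] - mu^2) / sig2 else 1
  hx <- 0
  for (i in 1:Ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    pp <- px[i] * px[j]
    if (pp > 0) {
      hxy1 <- hxy1 - P[i, j] * log2(pp)
      hxy2 <- hxy2 - pp * log2(pp)
    }
  }
  f["Imc1"] <- if (hx > 0) (f[["JointEntropy"]] - hxy1) / hx else 0
  f["Imc2"] <- if (hxy2 >= f[["JointEntropy"]]) {
    sqrt(1 - exp(-2 * (hxy2 - f[["JointEntropy"]])))
  } else 0
  f["MCC"] <- if (Ng < 2 || sig2 == 0) 1 else {
    nz <- which(px > 0)
    Q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      s <- 0
      for (k in nz) s <- s + P[nz[a], k] * P[nz[b], k] / (px[nz[a]] * px[k])
      Q[a, b] <- s
    }
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(lam) < 2) 1 else sqrt(max(min(lam[2], 1), 0))
  }
  f
}

oracle_glcm <- function(lev) {
  feats <- NULL
  for (off in oracle_offsets13()) {
    P <- oracle_glcm_matrix(lev, off)
    if (is.null(P)) next
    feats <- rbind(feats, oracle_glcm_features(P))
  }
  colMeans(feats)
}

# --- GLRLM -----------------------------------------------------------------

oracle_glrlm_runs <- function(lev, off) {
  d <- dim(lev)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c(i, j, k)
    if (is.na(lev[i, j, k])) next
    prev <- p - off
    # start of a run only if the previous cell is absent or different
    if (in_bounds(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == lev[i, j, k]) next
    len <- 1L
    q <- p + off
    while (in_bounds(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
           lev[q[1], q[2], q[3]] == lev[i, j, k]) {
      len <- len + 1L
      q <- q + off
    }
    runs[[length(runs) + 1L]] <- c(lev[i, j, k], len)
  }
  runs
}

oracle_run_matrix <- function(runs, Ng) {
  maxl <- max(vapply(runs, `[`, 0, 2))
  R <- matrix(0, Ng, maxl)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_sz_features <- function(M, Np, prefix) {
  # shared formula block for run-length / size-zone style matrices
  Ng <- nrow(M); L <- ncol(M)
  Ns <- sum(M)
  p <- M / Ns
  mu_i <- 0; mu_l <- 0
  for (i in 1:Ng) for (l in 1:L) {
    mu_i <- mu_i + i * p[i, l]; mu_l <- mu_l + l * p[i, l]
  }
  acc <- function(fun) {
    s <- 0
    for (i in 1:Ng) for (l in 1:L) s <- s + fun(i, l, M[i, l], p[i, l])
    s
  }
  ent <- 0
  for (i in 1:Ng) for (l in 1:L) if (p[i, l] > 0) ent <- ent - p[i, l] * log2(p[i, l])
  gsum <- rowSums(M); lsum <- colSums(M)
  out <- c(
    acc(function(i, l, m, q) m / l^2) / Ns,
    acc(function(i, l, m, q) m * l^2) / Ns,
    sum(gsum^2) / Ns,
    sum(gsum^2) / Ns^2,
    sum(lsum^2) / Ns,
    sum(lsum^2) / Ns^2,
    Ns / Np,
    acc(function(i, l, m, q) (i - mu_i)^2 * q),
    acc(function(i, l, m, q) (l - mu_l)^2 * q),
    ent,
    acc(function(i, l, m, q) q / i^2),
    acc(function(i, l, m, q) q * i^2),
    acc(function(i, l, m, q) q / (i^2 * l^2)),
    acc(function(i, l, m, q) q * i^2 / l^2),
    acc(function(i, l, m, q) q * l^2 / i^2),
    acc(function(i, l, m, q) q * i^2 * l^2))
  out
}

oracle_glrlm <- function(lev) {
  Ng <- max(lev, na.rm = TRUE)
  Np <- sum(!is.na(lev))
  feats <- NULL
  for (off in oracle_offsets13()) {
    R <- oracle_run_matrix(oracle_glrlm_runs(lev, off), Ng)
    feats <- rbind(feats, oracle_sz_features(R, Np, "glrlm"))
  }
  colMeans(feats)
}

# --- GLSZM -----------------------------------------------------------------

oracle_zones <- function(lev) {
  d <- dim(lev)
  visited <- array(FALSE, d)
  zones <- list()
  offs <- oracle_offsets26()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k]) || visited[i, j, k]) next
    g <- lev[i, j, k]
    queue <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      size <- size + 1L
      for (off in offs) {
        q <- p + off
        if (in_bounds(q, d) && !visited[q[1], q[2], q[3]] &&
            !is.na(lev[q[1], q[2], q[3]]) && lev[q[1], q[2], q[3]] == g) {
          visited[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  zones
}

oracle_glszm <- function(lev) {
  Ng <- max(lev, na.rm = TRUE)
  Np <- sum(!is.na(lev))
  S <- oracle_run_matrix(oracle_zones(lev), Ng)
  oracle_sz_features(S, Np, "glszm")
}

# --- GLDM ------------------------------------------------------------------

oracle_gldm <- function(lev) {
  d <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  offs <- oracle_offsets26()
  deps <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k])) next
    cnt <- 0L
    for (off in offs) {
      q <- c(i, j, k) + off
      if (in_bounds(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
          lev[q[1], q[2], q[3]] == lev[i, j, k]) cnt <- cnt + 1L
    }
    deps[[length(deps) + 1L]] <- c(lev[i, j, k], cnt + 1L)
  }
  D <- oracle_run_matrix(deps, Ng)
  Nz <- sum(D)
  Ngr <- nrow(D); Nd <- ncol(D)
  p <- D / Nz
  mu_i <- 0; mu_j <- 0
  for (i in 1:Ngr) for (j in 1:Nd) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  acc <- function(fun) {
    s <- 0
    for (i in 1:Ngr) for (j in 1:Nd) s <- s + fun(i, j, D[i, j], p[i, j])
    s
  }
  ent <- 0
  for (i in 1:Ngr) for (j in 1:Nd) if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  c(acc(function(i, j, m, q) m / j^2) / Nz,
    acc(function(i, j, m, q) m * j^2) / Nz,
    sum(rowSums(D)^2) / Nz,
    sum(colSums(D)^2) / Nz,
    sum(colSums(D)^2) / Nz^2,
    acc(function(i, j, m, q) (i - mu_i)^2 * q),
    acc(function(i, j, m, q) (j - mu_j)^2 * q),
    ent,
    acc(function(i, j, m, q) q / i^2),
    acc(function(i, j, m, q) q * i^2),
    acc(function(i, j, m, q) q / (i^2 * j^2)),
    acc(function(i, j, m, q) q * i^2 / j^2),
    acc(function(i, j, m, q) q * j^2 / i^2),
    acc(function(i, j, m, q) q * i^2 * j^2))
}

# --- NGTDM -----------------------------------------------------------------

oracle_ngtdm <- function(lev) {
  d <- dim(lev)
  Ng <- max(lev, na.rm = TRUE)
  offs <- oracle_offsets26()
  n_i <- rep(0, Ng); s_i <- rep(0, Ng)
  Nv <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k])) next
    nb <- c()
    for (off in offs) {
      q <- c(i, j, k) + off
      if (in_bounds(q, d) && !is.na(lev[q[1], q[2], q[3]])) {
        nb <- c(nb, lev[q[1], q[2], q[3]])
      }
    }
    if (length(nb) == 0L) next
    Nv <- Nv + 1L
    g <- lev[i, j, k]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  p_i <- n_i / Nv
  nz <- which(p_i > 0)
  Ngp <- length(nz)
  coarse <- 0
  for (i in nz) coarse <- coarse + p_i[i] * s_i[i]
  coarseness <- if (coarse > 0) 1 / coarse else 1e6
  contrast <- 0
  if (Ngp > 1) {
    for (i in nz) for (j in nz) contrast <- contrast + p_i[i] * p_i[j] * (i - j)^2
    contrast <- contrast / (Ngp * (Ngp - 1)) * sum(s_i) / Nv
  }
  busy_den <- 0
  for (i in nz) for (j in nz) busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
  busyness <- if (busy_den > 0) coarse / busy_den else 0
  complexity <- 0
  for (i in nz) for (j in nz) {
    complexity <- complexity + abs(i - j) *
      (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
  }
  complexity <- complexity / Nv
  strength <- 0
  for (i in nz) for (j in nz) strength <- strength + (p_i[i] + p_i[j]) * (i - j)^2
  strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  c(coarseness, contrast, busyness, complexity, strength)
}

# Random small levels array (<= 30 voxels) for oracle comparisons.
random_small_roi <- function(seed, dims = c(3, 3, 3), n_levels = 4,
                             p_mask = 0.8) {
  set.seed(seed)
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  keep <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(keep)) keep[1, 1, 1] <- TRUE
  lev[!keep] <- NA
  lev
}

# Independent ICC(2,1) oracle via the base-R two-way ANOVA table.
oracle_icc21 <- function(r1, r2) {
  n <- length(r1)
  df <- data.frame(y = c(r1, r2),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# Exhaustive pairwise AUC oracle (ties count 1/2).
oracle_auc_pairs <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# 2D 26(8)-connected component count on one slice (flood fill).
count_components_2d <- function(sl) {
  d <- dim(sl)
  visited <- matrix(FALSE, d[1], d[2])
  ncomp <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!sl[i, j] || visited[i, j]) next
    ncomp <- ncomp + 1L
    queue <- list(c(i, j)); visited[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dx in -1:1) for (dy in -1:1) {
        q <- p + c(dx, dy)
        if (all(q >= 1) && q[1] <= d[1] && q[2] <= d[2] &&
            sl[q[1], q[2]] && !visited[q[1], q[2]]) {
          visited[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  ncomp
}
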