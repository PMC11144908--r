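# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG, evaluates `expr`, and restores the previous RNG state so
#' package functions are deterministic without clobbering the caller's stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(master, index, stream = 0L) {
  ((as.numeric(master) %% 1e6) * 1009 + index * 101 + stream * 7919) %% 2147483647
}

# Cheap FNV-1a style checksum of an R object (for run manifests).
object_checksum <- function(x) {
  raw <- serialize(x, connection = NULL, version = 3L)
  v <- as.integer(raw)
  h <- 2166136261
  # fold in 4k-byte strides to keep the loop short on big objects
  stride <- max(1L, length(v) %/% 4096L)
  idx <- seq(1L, length(v), by = stride)
  for (b in v[idx]) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Shift a 3D array by (dx, dy, dz), filling vacated cells with `fill`.
shift3d <- function(a, dx, dy, dz, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, dim = d)
  lo <- pmax(1L, 1L - c(dx, dy, dz))
  hi <- pmin(d, d - c(dx, dy, dz))
  if (any(lo > hi)) return(out)
  src1 <- lo[1L]:hi[1L]; src2 <- lo[2L]:hi[2L]; src3 <- lo[3L]:hi[3L]
  out[src1 + dx, src2 + dy, src3 + dz] <- a[src1, src2, src3, drop = FALSE]
  out
}

# The 13 unique direction offsets on a 3D lattice (half of the 26-neighbourhood).
offsets13 <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, , drop = FALSE])
}

# All 26 neighbour offsets.
offsets26 <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
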