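# Internal numeric helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so library calls never perturb user code.
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# O(n) centered sliding-window minimum via the block prefix/suffix cummin
# decomposition. `w` is forced odd; out-of-range positions count as +Inf.
.runningMin <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w < 1L) stop("window must be >= 1")
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(Inf, h), x, rep(Inf, h))
  m <- length(xp)
  nb <- ceiling(m / w)
  xp <- c(xp, rep(Inf, nb * w - m))
  mat <- matrix(xp, nrow = w)
  pre <- as.vector(apply(mat, 2L, cummin))
  suf <- as.vector(apply(mat[w:1L, , drop = FALSE], 2L, cummin)[w:1L, ,
                                                                drop = FALSE])
  i <- seq_len(n)
  pmin(suf[i], pre[i + w - 1L])
}

# Centered moving average with shortened (partial-mean) edge windows, so the
# total signal is approximately conserved.
.movingAverage <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Daubechies-4 orthonormal filter pair.
.d4Filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  list(h = h, g = g)
}

# One periodic analysis step: x (even length) -> approximation + detail.
.dwtStep <- function(x, h, g) {
  n <- length(x)
  k <- seq(1L, n, by = 2L)
  a <- numeric(n / 2L)
  d <- numeric(n / 2L)
  for (m in seq_along(h)) {
    xi <- x[((k + m - 2L) %% n) + 1L]
    a <- a + h[m] * xi
    d <- d + g[m] * xi
  }
  list(a = a, d = d)
}

# One periodic synthesis step (transpose of .dwtStep; orthonormal filters give
# perfect reconstruction).
.idwtStep <- function(a, d, h, g) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  k <- seq(1L, n, by = 2L)
  for (m in seq_along(h)) {
    pos <- ((k + m - 2L) %% n) + 1L
    x[pos] <- x[pos] + h[m] * a + g[m] * d
  }
  x
}

# Discrete wavelet soft-threshold denoiser (D4, periodic on a symmetric
# padding to the next power of two). The threshold is the universal threshold
# sigma * sqrt(2 log n) with sigma estimated from the median absolute
# finest-level detail coefficient; a noise-free smooth signal therefore passes
# through essentially unchanged.
.waveletDenoise <- function(x, levels = 6L) {
  n <- length(x)
  n2 <- 2L^ceiling(log2(n))
  if (n2 > n) {
    pad <- rev(x)[seq_len(n2 - n)]
    xp <- c(x, pad)
  } else xp <- x
  f <- .d4Filters()
  levels <- min(as.integer(levels), as.integer(log2(n2)) - 2L)
  a <- xp
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- .dwtStep(a, f$h, f$g)
    a <- st$a
    details[[l]] <- st$d
  }
  sigma <- stats::median(abs(details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n2))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in seq_len(levels)) details[[l]] <- soft(details[[l]])
  for (l in rev(seq_len(levels))) {
    a <- .idwtStep(a, details[[l]], f$h, f$g)
  }
  a[seq_len(n)]
}

# Largest principal angle (radians) between the column spans of A and B.
.subspaceAngleInternal <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  s <- pmin(pmax(s, -1), 1)
  acos(min(s))
}

#' Largest principal angle between two subspaces
#'
#' Computes the largest principal angle (in radians) between the column
#' spans of two matrices with the same number of rows, via orthonormalization
#' and the SVD of the cross-product. Useful for judging how well an estimated
#' factor loading matrix recovers a known subspace.
#'
#' @param A,B numeric matrices with equal row counts.
#' @return angle in radians, in \code{[0, pi/2]}.
#' @examples
#' subspaceAngle(diag(3)[, 1:2], diag(3)[, 1:2])  # 0
#' @export
subspaceAngle <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  .subspaceAngleInternal(as.matrix(A), as.matrix(B))
}
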