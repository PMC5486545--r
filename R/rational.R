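# Exact linear algebra over the rationals and GF(2).
#
# Rational matrices are carried as a pair of double matrices (num, den) with
# den > 0 and gcd(|num|, den) = 1 entrywise. Doubles represent integers
# exactly up to 2^53; the matrices handled here are small (character tables),
# and an overflow guard aborts rather than silently rounding.

gcd2 <- function(a, b) {
  # a, b >= 0
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  a / gcd2(a, b) * b
}

rat_check <- function(num, den) {
  if (any(abs(num) > 2^52) || any(den > 2^52))
    stop("exact arithmetic overflow: entries too large for exact elimination")
}

# normalize num/den vectors: den > 0, reduced
rat_reduce <- function(num, den) {
  neg <- den < 0
  num[neg] <- -num[neg]; den[neg] <- -den[neg]
  g <- mapply(gcd2, abs(num), den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

# Reduced row echelon form of an integer matrix, exact over Q.
# Column-pivoted with first-row tie-breaking; pivots normalized to 1.
rref_rational <- function(A) {
  n <- nrow(A); m <- ncol(A)
  N <- A; D <- matrix(1, n, m)
  pivots <- integer(0)
  prow <- 1L
  for (col in seq_len(m)) {
    if (prow > n) break
    hit <- which(N[prow:n, col] != 0)
    if (!length(hit)) next
    r <- prow + hit[1L] - 1L
    if (r != prow) {
      tmp <- N[prow, ]; N[prow, ] <- N[r, ]; N[r, ] <- tmp
      tmp <- D[prow, ]; D[prow, ] <- D[r, ]; D[r, ] <- tmp
    }
    # scale pivot row so the pivot becomes 1
    pn <- N[prow, col]; pd <- D[prow, col]
    rr <- rat_reduce(N[prow, ] * pd, D[prow, ] * pn)
    N[prow, ] <- rr$num; D[prow, ] <- rr$den
    rat_check(N[prow, ], D[prow, ])
    # eliminate the column everywhere else
    for (r2 in seq_len(n)) {
      if (r2 == prow || N[r2, col] == 0) next
      fn <- N[r2, col]; fd <- D[r2, col]
      # row r2 <- row r2 - (fn/fd) * row prow
      num <- N[r2, ] * fd * D[prow, ] - fn * N[prow, ] * D[r2, ]
      den <- D[r2, ] * fd * D[prow, ]
      rat_check(num, den)
      rr <- rat_reduce(num, den)
      N[r2, ] <- rr$num; D[r2, ] <- rr$den
    }
    pivots <- c(pivots, col)
    prow <- prow + 1L
  }
  list(num = N, den = D, pivots = pivots)
}

# Row echelon reduction over GF(2); returns reduced rows and pivot columns.
rref_gf2 <- function(A) {
  A <- A %% 2
  n <- nrow(A); m <- ncol(A)
  pivots <- integer(0)
  prow <- 1L
  for (col in seq_len(m)) {
    if (prow > n) break
    hit <- which(A[prow:n, col] == 1)
    if (!length(hit)) next
    r <- prow + hit[1L] - 1L
    if (r != prow) { tmp <- A[prow, ]; A[prow, ] <- A[r, ]; A[r, ] <- tmp }
    for (r2 in seq_len(n)) {
      if (r2 != prow && A[r2, col] == 1)
        A[r2, ] <- (A[r2, ] + A[prow, ]) %% 2
    }
    pivots <- c(pivots, col)
    prow <- prow + 1L
  }
  list(mat = A, pivots = pivots)
}

# Exact equality check A %*% (Bnum/Bden) == C, in rational arithmetic.
rational_product_equals <- function(A, Bnum, Bden, C) {
  r <- nrow(Bnum); m <- ncol(Bnum)
  for (j in seq_len(m)) {
    L <- Reduce(lcm2, Bden[, j], accumulate = FALSE)
    scaled <- Bnum[, j] * (L / Bden[, j])          # integer-valued
    lhs <- as.vector(A %*% scaled)
    rhs <- C[, j] * L
    rat_check(lhs, abs(rhs) + 1)
    if (!all(lhs == rhs)) return(FALSE)
  }
  TRUE
}
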