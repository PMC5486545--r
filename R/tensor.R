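# Tensor rank of feature-frequency tensors.
#
# Higher-order joint frequency tensors carry dependencies that the pairwise
# table misses; their CP (sum of outer products of vectors) rank measures
# those dependencies. Exact tensor rank is NP-hard in general, so only two
# honest regimes are offered: a provably exact answer for very small tensors
# (exact_small), and an ALS-based upper bound for everything else.

# mode-k unfolding, remaining modes in increasing order, first one fastest
unfold <- function(T, mode) {
  d <- dim(T)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(T, perm), nrow = d[mode])
}

# column-wise Khatri-Rao product; rows of B vary fastest
khatri_rao <- function(A, B) {
  r <- ncol(A)
  stopifnot(ncol(B) == r)
  out <- matrix(0, nrow(A) * nrow(B), r)
  for (c in seq_len(r)) out[, c] <- kronecker(A[, c], B[, c])
  out
}

num_rank <- function(X, tol = 1e-8) {
  if (all(X == 0)) return(0L)
  d <- svd(X, nu = 0, nv = 0)$d
  sum(d > tol * d[1L])
}

# T has rank <= 1 iff every mode unfolding has matrix rank <= 1
is_rank_one <- function(T, field = "real") {
  rk <- function(X) {
    if (field == "gf2") length(rref_gf2(X)$pivots) else num_rank(X)
  }
  all(vapply(seq_along(dim(T)), function(k) rk(unfold(T, k)), 0L) <= 1L)
}

#' CP decomposition by alternating least squares
#'
#' Fits a rank-\code{r} sum of outer products to an order-d tensor by
#' cyclically solving the linear least-squares problem for each factor
#' matrix. The fit residual is an upper-bound diagnostic only: ALS can stall
#' in local minima, and for tensors whose border rank is below their rank
#' the residual can creep toward zero with diverging factors without a
#' rank-\code{r} representation existing.
#'
#' @param T numeric array (order >= 2).
#' @param r target number of rank-1 terms.
#' @param n_iter,conv_tol iteration cap and relative-fit convergence
#'   threshold.
#' @param n_starts random restarts; the best fit is kept.
#' @param seed RNG seed for the restarts (restored afterwards).
#' @return list with \code{factors} (one matrix per mode, columns are the
#'   rank-1 components), \code{residual} (relative Frobenius residual) and
#'   \code{iterations}.
#' @export
cp_als <- function(T, r, n_iter = 250L, conv_tol = 1e-12, n_starts = 3L,
                   seed = 1L) {
  d <- dim(T)
  nm <- length(d)
  stopifnot(nm >= 2L, r >= 1L)
  normT <- sqrt(sum(T^2))
  if (normT == 0)
    return(list(factors = lapply(d, function(dk) matrix(0, dk, r)),
                residual = 0, iterations = 0L))
  unfolds <- lapply(seq_len(nm), function(k) unfold(T, k))

  one_run <- function() {
    A <- lapply(d, function(dk) matrix(stats::rnorm(dk * r), dk, r))
    prev <- Inf
    for (it in seq_len(n_iter)) {
      for (k in seq_len(nm)) {
        others <- setdiff(seq_len(nm), k)
        Z <- Reduce(khatri_rao, rev(A[others]))   # decreasing mode order
        W <- Reduce(`*`, lapply(A[others], crossprod))
        A[[k]] <- unfolds[[k]] %*% Z %*% solve(W + diag(1e-12, r))
      }
      res <- sqrt(sum((unfolds[[1L]] - A[[1L]] %*%
                         t(Reduce(khatri_rao, rev(A[-1L]))))^2)) / normT
      if (abs(prev - res) < conv_tol) break
      prev <- res
    }
    list(factors = A, residual = res, iterations = it)
  }

  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      run <- one_run()
      if (is.null(best) || run$residual < best$residual) best <- run
      if (best$residual < conv_tol) break
    }
    best
  })
}

# exhaustive GF(2) rank: smallest k <= max_rank such that T is the XOR of k
# distinct non-zero rank-1 tensors over GF(2)
gf2_tensor_rank <- function(T, max_rank) {
  d <- dim(T)
  if (prod(d) > 16L)
    stop("exact_small cap exceeded (total entries > 16); ",
         "use mode = \"als_upper_bound\"")
  # all non-zero 0/1 vectors per mode
  vecs <- lapply(d, function(dk) {
    g <- as.matrix(expand.grid(rep(list(0:1), dk)))
    g[rowSums(g) > 0, , drop = FALSE]
  })
  idx_grid <- as.matrix(expand.grid(lapply(vecs, function(v) seq_len(nrow(v)))))
  cands <- t(apply(idx_grid, 1L, function(ix) {
    as.vector(Reduce(outer,   # column-major: first mode fastest, as in as.vector
                     lapply(seq_along(d), function(k) vecs[[k]][ix[k], ])))
  }))
  cands <- unique(cands)
  keys <- apply(cands, 1L, paste, collapse = "")
  target <- as.vector(T) %% 2
  tkey <- paste(target, collapse = "")

  if (tkey %in% keys) return(1L)
  N <- nrow(cands)
  for (k in 2:max_rank) {
    # enumerate increasing (k-1)-subsets, close with a hash lookup
    combos <- utils::combn(N, k - 1L)
    if (ncol(combos) > 5e5)
      stop("exact_small search space too large for max_rank = ", max_rank,
           "; use mode = \"als_upper_bound\"")
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      rem <- (target + colSums(cands[sel, , drop = FALSE])) %% 2
      hit <- match(paste(rem, collapse = ""), keys)
      if (!is.na(hit) && hit > max(sel)) return(k)
    }
  }
  NA_integer_  # > max_rank
}

# exact real rank of a 2x2x2 tensor via the slice-pencil criterion:
# with slices A, B and an invertible combination C1, the tensor has rank
# <= 2 iff C2 C1^{-1} is diagonalizable with real eigenvalues; otherwise 3.
pencil_rank_222 <- function(T, tol = 1e-10) {
  A <- T[1L, , ]; B <- T[2L, , ]
  trials <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1), c(1, 2), c(2, 1))
  C1 <- NULL; w <- NULL
  for (tr in trials) {
    C <- tr[1L] * A + tr[2L] * B
    if (abs(det(C)) > tol * max(1, sum(C^2))) { C1 <- C; w <- tr; break }
  }
  if (is.null(C1))
    stop("internal error: singular pencil not reduced before pencil test")  # nocov
  w2 <- c(-w[2L], w[1L])                     # independent companion combo
  C2 <- w2[1L] * A + w2[2L] * B
  M <- C2 %*% solve(C1)
  ev <- eigen(M, only.values = TRUE)$values
  if (any(abs(Im(ev)) > tol * max(1, max(abs(ev))))) return(3L)
  ev <- Re(ev)
  if (abs(ev[1L] - ev[2L]) > tol * max(1, max(abs(ev)))) return(2L)
  # repeated eigenvalue: rank 2 iff M is (that multiple of) the identity
  if (sum((M - ev[1L] * diag(2))^2) <= tol * max(1, sum(M^2))) 2L else 3L
}

#' Tensor rank (exact for small tensors, ALS upper bound otherwise)
#'
#' Computes the CP rank of an order-d tensor, i.e. the minimal number of
#' rank-1 (outer-product) terms summing to it. Two modes:
#' \describe{
#'   \item{\code{exact_small}}{a provably correct answer, available for:
#'     order-2 tensors (matrix rank); tensors of rank <= 1 at any size
#'     (all unfoldings rank <= 1); GF(2) tensors with at most 16 entries,
#'     by exhaustive search over sums of distinct non-zero rank-1 GF(2)
#'     tensors up to \code{max_rank}; real order-3 tensors that reduce to a
#'     matrix (some unfolding of rank 1) or are 2x2x2, where the exact
#'     slice-pencil eigenvalue criterion applies. Anything else errors,
#'     directing to the ALS mode — exhaustive search over an infinite field
#'     cannot certify a rank.}
#'   \item{\code{als_upper_bound}}{the smallest r <= \code{max_rank} whose
#'     CP-ALS fit has relative residual below \code{fit_tol}. This is an
#'     upper bound on the rank only: a near-zero residual at rank r does
#'     not preclude the true rank exceeding r when the border rank is
#'     smaller (the fit can approach the tensor with diverging factors).}
#' }
#'
#' @param T numeric array, order >= 2.
#' @param mode \code{"exact_small"} or \code{"als_upper_bound"}.
#' @param max_rank search cap (default 4).
#' @param field \code{"real"} or \code{"gf2"} (exact_small only).
#' @param fit_tol relative-residual acceptance threshold for ALS.
#' @param seed RNG seed for ALS restarts.
#' @return list with \code{rank} (integer, or \code{NA} when the search is
#'   exhausted, meaning "> max_rank"), \code{bound} (\code{"exact"} or
#'   \code{"upper"}), and for ALS the \code{decomposition} and
#'   \code{residual}.
#' @examples
#' p <- c(0.2, 0.8)
#' tensor_rank(outer(outer(p, p), p))$rank            # 1
#' w <- array(c(1, 0, 0, 1, 0, 0, 1, 0), dim = c(2, 2, 2))
#' tensor_rank(w)$rank                                # 3 over the reals
#' @export
tensor_rank <- function(T, mode = c("exact_small", "als_upper_bound"),
                        max_rank = 4L, field = c("real", "gf2"),
                        fit_tol = 1e-6, seed = 1L) {
  mode <- match.arg(mode)
  field <- match.arg(field)
  T <- as.array(T)
  if (length(dim(T)) < 2L) stop("tensor order must be at least 2")
  if (field == "gf2" && !all(T %in% c(0, 1)))
    stop("field \"gf2\" requires 0/1 entries")

  if (all(T == 0)) return(list(rank = 0L, bound = "exact"))
  if (is_rank_one(T, field)) return(list(rank = 1L, bound = "exact"))

  if (length(dim(T)) == 2L) {
    r <- if (field == "gf2") length(rref_gf2(T)$pivots) else num_rank(T)
    return(list(rank = r, bound = "exact"))
  }

  if (mode == "exact_small") {
    if (field == "gf2")
      return(list(rank = gf2_tensor_rank(T, max_rank), bound = "exact"))
    # real: try reduction through a rank-1 unfolding
    d <- dim(T)
    for (k in seq_along(d)) {
      X <- unfold(T, k)
      if (num_rank(X) == 1L) {
        sv <- svd(X, nu = 1, nv = 1)
        M <- matrix(sv$d[1L] * sv$v[, 1L], nrow = d[setdiff(seq_along(d), k)][1L])
        return(list(rank = num_rank(M), bound = "exact"))
      }
    }
    if (length(d) == 3L && all(d == 2L))
      return(list(rank = pencil_rank_222(T), bound = "exact"))
    stop("exact_small supports rank <= 1 (any size), order-2, GF(2) tensors ",
         "with <= 16 entries, and real 2x2x2 tensors; ",
         "use mode = \"als_upper_bound\" for this tensor")
  }

  # ALS upper bound
  for (r in seq_len(max_rank)) {
    fit <- cp_als(T, r, seed = seed)
    if (fit$residual < fit_tol)
      return(list(rank = r, bound = "upper", decomposition = fit$factors,
                  residual = fit$residual))
  }
  list(rank = NA_integer_, bound = "upper",
       residual = fit$residual, note = paste0("> max_rank (", max_rank, ")"))
}
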