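#' Rank of a character matrix
#'
#' The minimal number r of outer-product terms a^nu (x) b^nu whose sum
#' reproduces the carrier-feature matrix C. Each b^nu is an independent
#' feature combination (a character cluster) and a^nu the corresponding
#' carrier factors, so the rank counts how many independent character
#' clusters the table contains: a maximal-rank table is cladistic-like
#' (every carrier contributes fresh information), a low-rank one is dominated
#' by a few correlated syndromes.
#'
#' For exact fields (\code{"integer"}, \code{"gf2"}) the rank is computed by
#' exact Gaussian elimination (over the rationals, resp. modulo 2). For
#' \code{"real"} matrices it is the count of singular values exceeding
#' \code{tol} times the largest one.
#'
#' @param M a \code{\link{character_matrix}} (or plain matrix, coerced with
#'   field \code{"real"}). Must have no missing entries; resolve those first,
#'   e.g. with \code{\link{complete_features}}.
#' @param tol relative singular-value threshold, used only for the real
#'   field. Default \code{1e-8}.
#' @return a non-negative integer.
#' @examples
#' matrix_rank(character_matrix(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))))  # 3
#' matrix_rank(character_matrix(rbind(c(1, 2, 5), c(2, 4, 10))))             # 1
#' @export
matrix_rank <- function(M, tol = 1e-8) {
  M <- as_character_matrix(M)
  assert_complete(M, "matrix_rank")
  V <- M$values
  if (all(V == 0)) return(0L)
  switch(M$field,
    real = {
      d <- svd(V, nu = 0, nv = 0)$d
      sum(d > tol * d[1L])
    },
    integer = length(rref_rational(V)$pivots),
    gf2 = length(rref_gf2(V)$pivots))
}

#' Minimal rank decomposition of a character matrix
#'
#' Computes an explicit representation C = sum_nu a^nu (x) b^nu with
#' r = \code{\link{matrix_rank}} terms. The representation is not unique;
#' it is canonicalized so results are reproducible:
#' \itemize{
#'   \item exact fields: column-pivoted Gauss-Jordan elimination. The a^nu
#'     are the pivot columns of C itself and the b^nu the non-zero rows of
#'     the reduced row echelon form, so each b^nu has leading coefficient 1.
#'     Reconstruction is verified exactly (rational arithmetic / modulo 2).
#'   \item real field: SVD factors, a^nu = sigma_nu u_nu, b^nu = v_nu, in
#'     descending sigma order.
#' }
#'
#' @inheritParams matrix_rank
#' @return an object of class \code{rank_decomposition}: list with
#'   \code{terms} (list of \code{list(a, b)}), \code{a_mat} (n x r),
#'   \code{b_mat} (r x m), \code{rank}, \code{reconstruction_error}
#'   (Frobenius; exactly 0 for exact fields), \code{field}.
#' @examples
#' d <- rank_decompose(character_matrix(rbind(c(1, 2, 5), c(2, 4, 10)),
#'                                      field = "integer"))
#' d$terms[[1]]$a  # (1, 2)
#' d$terms[[1]]$b  # (1, 2, 5)
#' @export
rank_decompose <- function(M, tol = 1e-8) {
  M <- as_character_matrix(M)
  assert_complete(M, "rank_decompose")
  V <- M$values
  n <- nrow(V); m <- ncol(V)

  if (all(V == 0)) {
    return(new_rank_decomposition(
      a_mat = matrix(0, n, 0), b_mat = matrix(0, 0, m),
      error = 0, M = M))
  }

  if (M$field == "real") {
    sv <- svd(V)
    r <- sum(sv$d > tol * sv$d[1L])
    a_mat <- sv$u[, seq_len(r), drop = FALSE] %*%
      diag(sv$d[seq_len(r)], r, r)
    b_mat <- t(sv$v[, seq_len(r), drop = FALSE])
    err <- if (r < length(sv$d)) sqrt(sum(sv$d[-seq_len(r)]^2)) else 0
    return(new_rank_decomposition(a_mat, b_mat, err, M))
  }

  if (M$field == "gf2") {
    rr <- rref_gf2(V)
    r <- length(rr$pivots)
    a_mat <- V[, rr$pivots, drop = FALSE] %% 2
    b_mat <- rr$mat[seq_len(r), , drop = FALSE]
    if (!all((a_mat %*% b_mat) %% 2 == V %% 2))
      stop("internal error: GF(2) factorization failed")  # nocov
    return(new_rank_decomposition(a_mat, b_mat, 0, M))
  }

  # integer field: exact over Q
  rr <- rref_rational(V)
  r <- length(rr$pivots)
  a_mat <- V[, rr$pivots, drop = FALSE]
  b_num <- rr$num[seq_len(r), , drop = FALSE]
  b_den <- rr$den[seq_len(r), , drop = FALSE]
  if (!rational_product_equals(a_mat, b_num, b_den, V))
    stop("internal error: rational factorization failed")  # nocov
  d <- new_rank_decomposition(a_mat, b_num / b_den, 0, M)
  d$b_num <- b_num
  d$b_den <- b_den
  d
}

new_rank_decomposition <- function(a_mat, b_mat, error, M) {
  r <- ncol(a_mat)
  terms <- lapply(seq_len(r), function(nu)
    list(a = stats::setNames(a_mat[, nu], M$carrier_ids),
         b = stats::setNames(b_mat[nu, ], M$feature_ids)))
  structure(
    list(terms = terms, a_mat = a_mat, b_mat = b_mat, rank = r,
         reconstruction_error = error, field = M$field,
         carrier_ids = M$carrier_ids, feature_ids = M$feature_ids),
    class = "rank_decomposition")
}

#' @export
print.rank_decomposition <- function(x, ...) {
  cat(sprintf("rank decomposition: rank %d, field %s, reconstruction error %g\n",
              x$rank, x$field, x$reconstruction_error))
  for (nu in seq_along(x$terms)) {
    cat(sprintf("  term %d: a = (%s), b = (%s)\n", nu,
                paste(signif(x$terms[[nu]]$a, 4), collapse = ", "),
                paste(signif(x$terms[[nu]]$b, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Reconstruct the matrix from a rank decomposition
#'
#' @param d a \code{rank_decomposition}.
#' @return the numeric matrix sum of outer products (reduced mod 2 for the
#'   GF(2) field).
#' @export
reconstruct <- function(d) {
  stopifnot(inherits(d, "rank_decomposition"))
  out <- d$a_mat %*% d$b_mat
  if (d$field == "gf2") out <- out %% 2
  dimnames(out) <- list(d$carrier_ids, d$feature_ids)
  out
}

#' Numerical rank within a measurement-error bound (epsilon-rank)
#'
#' Minimal rank over all matrices C' with ||C - C'|| < eps in Frobenius norm
#' (strict inequality): by the Eckart-Young theorem this is the smallest k
#' such that the tail singular-value energy sum_{i>k} sigma_i^2 is strictly
#' below eps^2. A tail energy exactly at the boundary keeps the higher rank.
#'
#' This is the noise-robust form of the character-cluster count: measured
#' matrices typically have full rank, and eps encodes the measurement error
#' within which lower-rank structure is accepted.
#'
#' @param M a real-field \code{\link{character_matrix}} without missing
#'   entries.
#' @param eps positive error bound.
#' @param norm only \code{"frobenius"} is supported.
#' @return a non-negative integer.
#' @export
epsilon_rank <- function(M, eps, norm = "frobenius") {
  M <- as_character_matrix(M)
  norm <- match.arg(norm, "frobenius")
  if (M$field != "real")
    stop("epsilon_rank is defined for the real field; use matrix_rank for ",
         "exact fields")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("eps must be a positive scalar")
  assert_complete(M, "epsilon_rank")
  d <- svd(M$values, nu = 0, nv = 0)$d
  tail_energy <- rev(cumsum(rev(d^2)))       # tail_energy[k] = sum_{i>=k} d_i^2
  for (k in 0:length(d)) {
    te <- if (k >= length(d)) 0 else tail_energy[k + 1L]
    if (te < eps^2) return(k)
  }
  length(d)  # nocov (loop always returns)
}

#' Character clusters of a carrier-feature matrix
#'
#' A character cluster is an independent feature combination b^nu of a
#' minimal-rank representation of the matrix; the features with non-zero
#' loading in b^nu are the characters representing the cluster (any one of
#' them distinguishes the same carriers, the others being correlated with
#' it). With \code{eps > 0} (real field only) the minimal rank is taken over
#' all matrices within Frobenius distance eps, i.e. clusters of the
#' epsilon-rank truncation.
#'
#' @inheritParams matrix_rank
#' @param eps non-negative error bound; 0 selects the exact definition.
#' @return list of \code{character_cluster} objects (one per decomposition
#'   term), ordered by decreasing carrier-factor norm. Each has
#'   \code{feature_combination} (b^nu), \code{carrier_factors} (a^nu) and
#'   \code{representative_features} (ids with non-zero loading for exact
#'   fields, dominant-magnitude loading for the real field).
#' @examples
#' m24 <- character_matrix(
#'   cbind(teeth = c(1, 1, 1, 2, 2, 2), feet = c(1, 1, 1, 2, 2, 2),
#'         fur = c(1, 2, 3, 1, 2, 3), color = c(1, 2, 3, 1, 2, 3)),
#'   field = "integer")
#' lapply(character_clusters(m24), `[[`, "representative_features")
#' @export
character_clusters <- function(M, eps = 0, tol = 1e-8) {
  M <- as_character_matrix(M)
  if (eps < 0) stop("eps must be non-negative")
  if (eps > 0 && M$field != "real")
    stop("eps > 0 requires the real field; exact fields use eps = 0")

  if (eps == 0) {
    d <- rank_decompose(M, tol = tol)
  } else {
    assert_complete(M, "character_clusters")
    r <- epsilon_rank(M, eps)
    sv <- svd(M$values)
    a_mat <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r, r)
    b_mat <- t(sv$v[, seq_len(r), drop = FALSE])
    err <- sqrt(max(0, sum(sv$d^2) - sum(sv$d[seq_len(r)]^2)))
    d <- new_rank_decomposition(a_mat, b_mat, err, M)
  }

  clusters <- lapply(d$terms, function(tm) {
    b <- tm$b
    rep_feats <- if (M$field == "real") {
      names(b)[abs(b) > 1e-8 * max(abs(b))]
    } else {
      names(b)[b != 0]
    }
    structure(list(feature_combination = b,
                   carrier_factors = tm$a,
                   representative_features = rep_feats),
              class = "character_cluster")
  })
  norms <- vapply(clusters, function(cl) sqrt(sum(cl$carrier_factors^2)), 0)
  clusters[order(-norms)]
}

#' @export
print.character_cluster <- function(x, ...) {
  cat("character cluster on {",
      paste(x$representative_features, collapse = ", "), "}\n")
  invisible(x)
}
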