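#' Carrier co-occurrence matrix
#'
#' The normalized Gram matrix P with entries
#' \deqn{p_{ij} = (1/Z) \sum_k c_{ik} c_{jk}, \qquad Z = \sum_{r,s,t} c_{rt} c_{st},}
#' i.e. P = C C'/Z with Z the sum of all entries of C C' (equivalently the
#' sum of squared column sums). P is symmetric and its entries sum to 1.
#' Its key property is that rank(P) = rank(C) over the reals, so the number
#' of independent character clusters can be read off the carrier
#' co-occurrence structure alone.
#'
#' @param M a \code{\link{character_matrix}} without missing entries.
#' @return a \code{frequency_model} with the \code{cooccurrence} field (an
#'   n x n matrix over carriers) and the normalizer \code{Z}.
#' @examples
#' m8 <- character_matrix(rbind(c(1, 2, 5), c(2, 4, 10)), field = "integer")
#' cooccurrence_matrix(m8)$cooccurrence  # [[1/9, 2/9], [2/9, 4/9]]
#' @export
cooccurrence_matrix <- function(M) {
  M <- as_character_matrix(M)
  assert_complete(M, "cooccurrence_matrix")
  V <- M$values
  G <- V %*% t(V)
  Z <- sum(G)
  if (Z == 0) stop("degenerate matrix: all co-occurrence mass is zero")
  P <- G / Z
  dimnames(P) <- list(M$carrier_ids, M$carrier_ids)
  new_frequency_model(cooccurrence = P, Z = Z)
}

new_frequency_model <- function(convention = NULL, marginals = NULL,
                                pairwise = NULL, joint_tensors = NULL,
                                cooccurrence = NULL, Z = NULL,
                                feature_ids = NULL, n_carriers = NULL) {
  structure(list(convention = convention, marginals = marginals,
                 pairwise = pairwise, joint_tensors = joint_tensors,
                 cooccurrence = cooccurrence, Z = Z,
                 feature_ids = feature_ids, n_carriers = n_carriers),
            class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat("frequency model")
  if (!is.null(x$convention)) cat(" (convention: ", x$convention, ")", sep = "")
  cat("\n")
  if (!is.null(x$marginals)) {
    cat("marginals:\n"); print(x$marginals)
  }
  if (!is.null(x$cooccurrence)) {
    cat("carrier co-occurrence matrix (Z = ", x$Z, "):\n", sep = "")
    print(x$cooccurrence)
  }
  invisible(x)
}

#' Feature occurrence frequencies and joint tensors
#'
#' For a presence/absence (GF(2)) matrix, builds marginal frequencies p_j,
#' the symmetric pairwise table p_jk, and optionally higher-order joint
#' tensors p_{j1...js}, under one of three normalization conventions:
#' \describe{
#'   \item{\code{carrier_fraction} (default)}{p_{j1...js} is the fraction of
#'     carriers possessing all of the features j1...js. This is the
#'     convention under which every worked example of the underlying
#'     construction comes out as printed (e.g. a feature present in all
#'     carriers has p_j = 1).}
#'   \item{\code{total_normalized}}{counts are normalized by their grand
#'     total per order, so each tensor sums to 1; marginals are
#'     r_j / sum_l r_l with r_j the occurrence count of feature j.}
#'   \item{\code{distributional}}{the order-s tensor is the distribution of
#'     an ordered s-tuple of feature occurrences drawn from a single
#'     carrier: p_{j1...js} = sum_i prod_t c_{i j_t} / sum_i R_i^s, with R_i
#'     the number of features carrier i possesses. Under this convention the
#'     row sums of the pairwise table equal the marginals (which are defined
#'     as those row sums), the property the symmetric-joint-table view
#'     requires.}
#' }
#' The conventions genuinely disagree (carrier_fraction tensors do not sum
#' to 1; total_normalized marginals are not per-carrier fractions); which
#' one is "the" relative frequency is a modelling choice, so all three are
#' available and every report records the one used.
#'
#' @param M a GF(2) \code{\link{character_matrix}} without missing entries.
#' @param convention one of \code{"carrier_fraction"},
#'   \code{"total_normalized"}, \code{"distributional"}.
#' @param max_order highest tensor order s to populate (1 <= s <= m).
#' @return a \code{frequency_model} with \code{marginals}, \code{pairwise}
#'   and \code{joint_tensors[[s]]} for s = 1..max_order.
#' @examples
#' m19 <- character_matrix(rbind(c(1, 0, 0, 1), c(0, 1, 1, 0)), field = "gf2")
#' f <- feature_frequencies(m19)
#' f$marginals            # all 0.5
#' f$pairwise[1, 4]       # 0.5, != p1 * p4 = 0.25
#' @export
feature_frequencies <- function(M,
                                convention = c("carrier_fraction",
                                               "total_normalized",
                                               "distributional"),
                                max_order = 2L) {
  M <- as_character_matrix(M)
  convention <- match.arg(convention)
  if (M$field != "gf2")
    stop("feature_frequencies requires binary presence/absence data ",
         "(field \"gf2\")")
  assert_complete(M, "feature_frequencies")
  V <- M$values
  n <- nrow(V); m <- ncol(V)
  if (max_order < 1L || max_order > m)
    stop("max_order must be between 1 and the number of features")
  if (max_order > 1L && m^max_order > 1e6)
    stop("joint tensor too large (m^s > 1e6); lower max_order")

  # count tensor of order s: entry (j1..js) = number of carriers with all
  counts <- function(s) {
    acc <- NULL
    for (i in seq_len(n)) {
      o <- Reduce(outer, rep(list(V[i, ]), s))
      acc <- if (is.null(acc)) o else acc + o
    }
    if (s == 1L) acc <- stats::setNames(as.vector(acc), M$feature_ids)
    acc
  }

  r_j <- colSums(V)
  R_i <- rowSums(V)
  joint <- vector("list", max_order)
  for (s in seq_len(max_order)) {
    cs <- counts(s)
    joint[[s]] <- switch(convention,
      carrier_fraction = cs / n,
      total_normalized = if (sum(cs) == 0) cs else cs / sum(cs),
      distributional   = if (sum(R_i^s) == 0) cs else cs / sum(R_i^s))
  }

  marginals <- switch(convention,
    carrier_fraction = stats::setNames(r_j / n, M$feature_ids),
    total_normalized = stats::setNames(
      if (sum(r_j) == 0) r_j else r_j / sum(r_j), M$feature_ids),
    distributional = {
      pw <- if (max_order >= 2L) joint[[2L]] else counts(2L) / max(1, sum(R_i^2))
      stats::setNames(rowSums(pw), M$feature_ids)
    })

  pairwise <- if (max_order >= 2L) joint[[2L]] else {
    cs <- counts(2L)
    switch(convention,
      carrier_fraction = cs / n,
      total_normalized = if (sum(cs) == 0) cs else cs / sum(cs),
      distributional   = if (sum(R_i^2) == 0) cs else cs / sum(R_i^2))
  }
  dimnames(pairwise) <- list(M$feature_ids, M$feature_ids)

  new_frequency_model(convention = convention, marginals = marginals,
                      pairwise = pairwise, joint_tensors = joint,
                      feature_ids = M$feature_ids, n_carriers = n)
}

#' Test independence of feature frequencies
#'
#' The feature frequencies are independent at order s when the order-s joint
#' tensor factorizes as the s-fold outer product of the marginal vector,
#' p_{j1...js} = p_{j1} ... p_{js}. Dependencies between features (features
#' that always co-occur) break this factorization; conversely a table of
#' carriers with perfectly correlated feature combinations has independent
#' frequencies.
#'
#' For presence/absence data the cells with repeated indices are degenerate
#' (c^2 = c forces p_jj = p_j), so by default only tuples of pairwise
#' distinct features are compared; \code{include_repeats = TRUE} compares
#' every cell.
#'
#' @param F a \code{frequency_model} from \code{\link{feature_frequencies}}.
#' @param order tensor order s to test; the model must contain it.
#' @param tol entrywise tolerance for the factorization.
#' @param include_repeats compare cells with repeated feature indices too.
#' @return list with \code{independent} (logical), \code{max_deviation}
#'   (max |p_{j1...js} - p_{j1}...p_{js}| over compared cells) and
#'   \code{worst} (indices of the maximal deviation, or NULL).
#' @export
independence_test <- function(F, order = 2L, tol = 1e-12,
                              include_repeats = FALSE) {
  stopifnot(inherits(F, "frequency_model"))
  if (is.null(F$joint_tensors) || length(F$joint_tensors) < order ||
      is.null(F$joint_tensors[[order]]))
    stop("frequency model has no joint tensor of order ", order,
         "; recompute with max_order >= ", order)
  p <- F$marginals
  joint <- F$joint_tensors[[order]]
  prod_tensor <- if (order == 1L) p else Reduce(outer, rep(list(p), order))
  dev <- abs(joint - prod_tensor)

  if (!include_repeats && order >= 2L) {
    m <- length(p)
    grid <- as.matrix(expand.grid(rep(list(seq_len(m)), order)))
    distinct <- apply(grid, 1L, function(ix) !anyDuplicated(ix))
    mask <- array(FALSE, dim = rep(m, order))
    mask[grid[distinct, , drop = FALSE]] <- TRUE
    dev[!mask] <- NA_real_
  }

  if (all(is.na(dev))) {
    return(list(independent = TRUE, max_deviation = 0, worst = NULL))
  }
  mx <- max(dev, na.rm = TRUE)
  worst <- which(dev == mx, arr.ind = TRUE)
  if (is.matrix(worst)) worst <- worst[1L, ]
  list(independent = mx <= tol, max_deviation = mx,
       worst = stats::setNames(F$feature_ids[worst],
                               paste0("j", seq_along(worst))))
}

#' Joint vs product frequency for one feature pair
#'
#' Convenience report for a single pair (j, k): the joint frequency p_jk,
#' the product p_j p_k, and their difference.
#'
#' @param F a \code{frequency_model}.
#' @param j,k feature ids or indices.
#' @export
feature_pair <- function(F, j, k) {
  stopifnot(inherits(F, "frequency_model"), !is.null(F$pairwise))
  ix <- function(x) if (is.character(x)) match(x, F$feature_ids) else as.integer(x)
  j <- ix(j); k <- ix(k)
  if (is.na(j) || is.na(k)) stop("unknown feature id")
  joint <- F$pairwise[j, k]
  prod <- F$marginals[j] * F$marginals[k]
  list(features = F$feature_ids[c(j, k)], joint = unname(joint),
       product = unname(prod), deviation = unname(abs(joint - prod)))
}
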