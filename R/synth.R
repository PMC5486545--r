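#' Generate a cladistic staircase matrix
#'
#' The textbook cladistic character table for a pectinate (fully ladderized)
#' phylogeny: carrier i possesses features 1..i, so the last species carries
#' every character investigated, feature i is the synapomorphy of the clade
#' {species i, ..., species n}, and feature n is an apomorphy of the last
#' species alone. The matrix is lower-triangular and has maximal rank n.
#'
#' @param n number of species (and characters), n >= 1.
#' @return a GF(2) \code{\link{character_matrix}} with ids
#'   \code{species_1..n} / \code{char_1..n}.
#' @export
gen_cladistic <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  n <- as.integer(n)
  V <- matrix(0, n, n)
  V[lower.tri(V, diag = TRUE)] <- 1
  character_matrix(V, field = "gf2",
                   carrier_ids = paste0("species_", seq_len(n)),
                   feature_ids = paste0("char_", seq_len(n)))
}

#' Generate a functional character matrix with planted clusters
#'
#' Builds a table as the overlay of character clusters: the features are
#' partitioned into clusters, each cluster has its own set of states, and
#' all features within a cluster carry the same state label for a given
#' carrier (perfect functional correlation; e.g. one cluster driven by
#' feeding type, another by climate). With \code{complete = TRUE} the
#' carriers are the full factorial of cluster states (the first cluster
#' varying slowest), which makes the canonical-labeled rank equal the
#' number of clusters; with \code{complete = FALSE}, \code{n_carriers}
#' state combinations are drawn at random under \code{seed}.
#'
#' @param clusters list of cluster specs, each a list with \code{features}
#'   (character vector of feature ids) and \code{states} (number of states,
#'   >= 1). Feature sets must be disjoint.
#' @param complete full factorial design (default) or sampled carriers.
#' @param n_carriers number of carriers when \code{complete = FALSE}.
#' @param seed RNG seed, required when sampling.
#' @return an integer-field \code{\link{character_matrix}}.
#' @examples
#' # the feeding-type x climate example: 6 carriers, rank 2
#' m <- gen_functional(list(list(features = c("teeth", "feet"), states = 2),
#'                          list(features = c("fur", "color"), states = 3)))
#' matrix_rank(m)
#' @export
gen_functional <- function(clusters, complete = TRUE, n_carriers = NULL,
                           seed = NULL) {
  if (!length(clusters)) stop("at least one cluster is required")
  feats <- lapply(clusters, function(cl) as.character(cl$features))
  states <- vapply(clusters, function(cl) as.integer(cl$states), 0L)
  if (any(states < 1L)) stop("each cluster needs >= 1 states")
  all_feats <- unlist(feats)
  if (anyDuplicated(all_feats))
    stop("cluster feature sets must be disjoint; duplicated: ",
         paste(unique(all_feats[duplicated(all_feats)]), collapse = ", "))

  k <- length(clusters)
  if (complete) {
    # full factorial, first cluster slowest
    grid <- expand.grid(rev(lapply(states, seq_len)), KEEP.OUT.ATTRS = FALSE)
    grid <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
  } else {
    if (is.null(n_carriers) || is.null(seed))
      stop("sampled designs need n_carriers and seed")
    grid <- with_seed(seed, {
      vapply(states, function(s) sample.int(s, n_carriers, replace = TRUE),
             integer(n_carriers))
    })
    grid <- matrix(grid, nrow = n_carriers)
  }
  V <- matrix(0L, nrow(grid), length(all_feats))
  col <- 0L
  for (ci in seq_len(k)) for (f in feats[[ci]]) {
    col <- col + 1L
    V[, col] <- grid[, ci]
  }
  character_matrix(V, field = "integer",
                   carrier_ids = paste0("carrier_", seq_len(nrow(V))),
                   feature_ids = all_feats)
}

#' Add seeded noise to a character matrix
#'
#' Measurement error makes empirical character tables full-rank; this
#' generator emulates that with the minimal standard noise models: i.i.d.
#' Gaussian perturbation of each entry (real field) or independent bit
#' flips (GF(2)). Deterministic for a given seed; the model and magnitude
#' actually applied are recorded in attribute \code{"noise"}.
#'
#' @param M a complete \code{\link{character_matrix}}.
#' @param model \code{"gaussian_sd"} (real field only) or
#'   \code{"flip_rate"} (GF(2) only).
#' @param magnitude standard deviation, resp. per-entry flip probability.
#' @param seed RNG seed.
#' @return the perturbed \code{character_matrix}.
#' @export
gen_noisy <- function(M, model = c("gaussian_sd", "flip_rate"), magnitude,
                      seed) {
  M <- as_character_matrix(M)
  model <- match.arg(model)
  assert_complete(M, "gen_noisy")
  if (magnitude < 0) stop("magnitude must be non-negative")
  V <- M$values
  applied <- list(model = model, magnitude = magnitude, seed = seed)
  if (magnitude > 0) {
    if (model == "gaussian_sd") {
      if (M$field != "real")
        stop("gaussian_sd noise requires the real field")
      V <- V + with_seed(seed, matrix(stats::rnorm(length(V), sd = magnitude),
                                      nrow(V), ncol(V)))
    } else {
      if (M$field != "gf2")
        stop("flip_rate noise requires the gf2 field")
      flips <- with_seed(seed, matrix(stats::runif(length(V)) < magnitude,
                                      nrow(V), ncol(V)))
      V[flips] <- 1 - V[flips]
      applied$n_flipped <- sum(flips)
    }
  }
  out <- character_matrix(V, field = M$field, carrier_ids = M$carrier_ids,
                          feature_ids = M$feature_ids)
  attr(out, "noise") <- applied
  out
}

#' Generate a random constrained feature space
#'
#' A seeded feature space with the two behaviors every presheaf fixture
#' needs: some partial section with at least two extensions (apomorphies
#' exist) and some section with none (a forbidden feature combination).
#' Fibers are \code{v1..v_size}; the admissible set is a random sample of
#' \code{n_admissible} distinct global sections. Requiring
#' \code{2 <= n_admissible < prod(fiber sizes)} guarantees both behaviors:
#' two distinct admissible sections restricted to their agreement domain
#' have >= 2 extensions, and any non-admissible global section has 0.
#'
#' @param n_features number of features (>= 1).
#' @param fiber_sizes fiber size per feature (recycled to length
#'   \code{n_features}).
#' @param n_admissible number of admissible global sections.
#' @param seed RNG seed.
#' @return a constrained \code{\link{feature_space}}.
#' @export
gen_space <- function(n_features, fiber_sizes, n_admissible, seed) {
  n_features <- as.integer(n_features)
  if (n_features < 1L) stop("n_features must be >= 1")
  fiber_sizes <- rep_len(as.integer(fiber_sizes), n_features)
  if (any(fiber_sizes < 1L)) stop("fiber sizes must be >= 1")
  total <- prod(fiber_sizes)
  if (n_admissible < 2L || n_admissible >= total)
    stop("cannot guarantee both an unextendable section and apomorphies: ",
         "need 2 <= n_admissible < ", total,
         " (the number of global sections)")
  base <- paste0("f", seq_len(n_features))
  fibers <- stats::setNames(
    lapply(fiber_sizes, function(s) paste0("v", seq_len(s))), base)
  picks <- with_seed(seed, sort(sample.int(total, n_admissible)))
  decode <- function(ix) {        # mixed-radix, first feature fastest
    ix <- ix - 1L
    vals <- character(n_features)
    for (j in seq_len(n_features)) {
      vals[j] <- fibers[[j]][(ix %% fiber_sizes[j]) + 1L]
      ix <- ix %/% fiber_sizes[j]
    }
    stats::setNames(vals, base)
  }
  feature_space(base, fibers, lapply(picks, decode))
}
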