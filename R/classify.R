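#' Test whether a binary character matrix is cladistic
#'
#' A binary character table is compatible with a rooted binary-branching
#' phylogeny (state 0 ancestral) exactly when the support sets of its
#' features — the sets of carriers possessing each character — form a
#' laminar family: any two supports are nested or disjoint. This is the
#' classical perfect-phylogeny compatibility criterion; the textbook
#' staircase matrix (each species possessing the characters of its
#' ancestors plus one new synapomorphy) is the extreme case.
#'
#' When the matrix is cladistic, carrier and feature permutations exhibiting
#' the staircase are reported (features by decreasing support size, carriers
#' sorted so every clade is contiguous), along with each feature's clade:
#' the carriers sharing it. A single-carrier support is an apomorphy, a
#' larger one a synapomorphy of its clade.
#'
#' @param M a GF(2) \code{\link{character_matrix}} without missing entries.
#' @return a \code{cladistic_report}: list with \code{is_cladistic},
#'   \code{carrier_order}, \code{feature_order} (ids; NULL when not
#'   cladistic), \code{synapomorphies} (feature id -> carrier ids),
#'   \code{violations} (data frame of feature pairs breaking laminarity).
#' @export
is_cladistic <- function(M) {
  M <- as_character_matrix(M)
  if (M$field != "gf2")
    stop("is_cladistic requires binary presence/absence data (field \"gf2\")")
  assert_complete(M, "is_cladistic")
  V <- M$values
  m <- ncol(V)
  supports <- lapply(seq_len(m), function(j) which(V[, j] == 1))

  viol <- list()
  if (m >= 2L) for (j in seq_len(m - 1L)) for (k in (j + 1L):m) {
    a <- supports[[j]]; b <- supports[[k]]
    inter <- intersect(a, b)
    if (length(inter) && !setequal(inter, a) && !setequal(inter, b))
      viol[[length(viol) + 1L]] <-
        data.frame(feature_1 = M$feature_ids[j], feature_2 = M$feature_ids[k])
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(feature_1 = character(0), feature_2 = character(0))
  syn <- stats::setNames(lapply(supports, function(s) M$carrier_ids[s]),
                         M$feature_ids)

  if (nrow(violations) > 0L) {
    return(structure(list(is_cladistic = FALSE, carrier_order = NULL,
                          feature_order = NULL, synapomorphies = syn,
                          violations = violations),
                     class = "cladistic_report"))
  }
  # feature order: decreasing support size, stable in input order
  ford <- order(-lengths(supports), seq_len(m))
  # carrier order: ascending lexicographic on the ordered membership vector;
  # laminarity makes every support contiguous, and the pure staircase comes
  # out exactly in its printed form
  keys <- apply(V[, ford, drop = FALSE], 1L, paste, collapse = "")
  cord <- order(keys, seq_len(nrow(V)))
  structure(list(is_cladistic = TRUE,
                 carrier_order = M$carrier_ids[cord],
                 feature_order = M$feature_ids[ford],
                 synapomorphies = syn,
                 violations = violations),
            class = "cladistic_report")
}

#' @export
print.cladistic_report <- function(x, ...) {
  cat("cladistic:", x$is_cladistic, "\n")
  if (x$is_cladistic) {
    cat("feature order:", paste(x$feature_order, collapse = ", "), "\n")
    cat("carrier order:", paste(x$carrier_order, collapse = ", "), "\n")
  } else {
    cat("laminarity violations:\n"); print(x$violations)
  }
  invisible(x)
}

#' Newick tree implied by a cladistic matrix
#'
#' When the feature supports form a laminar family they generate a rooted
#' tree whose internal nodes are the clades supported by synapomorphies;
#' this writes that tree as a Newick string (leaf labels = carrier ids).
#'
#' @param M a GF(2) \code{\link{character_matrix}} that passes
#'   \code{\link{is_cladistic}} (or a \code{cladistic_report} is computed
#'   internally).
#' @return a Newick string, terminated by ";".
#' @export
cladistic_newick <- function(M) {
  M <- as_character_matrix(M)
  rep <- is_cladistic(M)
  if (!rep$is_cladistic)
    stop("matrix is not cladistic; no tree is implied")
  all_ids <- M$carrier_ids
  clades <- unique(Filter(function(s) length(s) > 0,
                          lapply(rep$synapomorphies, sort)))
  clades <- clades[order(-lengths(clades))]
  sanitize <- function(x) gsub("[ ,();:]", "_", x)
  build <- function(ids, pool) {
    # maximal proper sub-clades of ids among pool
    subs <- Filter(function(s) length(s) < length(ids) && all(s %in% ids), pool)
    chosen <- list()
    covered <- character(0)
    for (s in subs[order(-lengths(subs))]) {
      if (!any(s %in% covered)) { chosen <- c(chosen, list(s)); covered <- c(covered, s) }
    }
    singles <- setdiff(ids, covered)
    parts <- c(vapply(chosen, function(s) build(s, pool), ""),
               sanitize(singles))
    if (length(parts) == 1L) parts else paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(sort(all_ids), clades), ";")
}

#' Functional character clusters by induced carrier partition
#'
#' In a functionally structured table, the state labels are arbitrary
#' ("mere labels"): what two perfectly correlated characters share is not
#' their numbers but the way they partition the carriers (all carnivores
#' alike, all herbivores alike, ...). Features are therefore grouped by
#' equality of the carrier partition each one induces — an exact,
#' label-free criterion that is invariant under any per-feature relabeling
#' of states. For comparison with the algebraic picture, each feature is
#' also recoded with canonical integer labels 1, 2, ... (in order of first
#' appearance of each block) and the real rank of the recoded matrix is
#' reported: on a full-factorial functional design with k clusters this
#' rank equals k.
#'
#' @param M an integer-coded categorical \code{\link{character_matrix}}
#'   without missing entries.
#' @return a \code{functional_clustering}: list with \code{clusters}
#'   (partition of feature ids), \code{carrier_partitions} (one partition
#'   of carrier ids per cluster, as a list of blocks),
#'   \code{numeric_rank_after_labeling}, and \code{relabeled} (the
#'   canonical integer matrix).
#' @export
functional_clusters <- function(M) {
  M <- as_character_matrix(M)
  assert_complete(M, "functional_clusters")
  V <- M$values
  m <- ncol(V)
  codes <- vapply(seq_len(m), function(j) {
    v <- V[, j]
    match(v, unique(v))      # canonical labels by first appearance
  }, integer(nrow(V)))
  codes <- matrix(codes, nrow = nrow(V))
  sig <- apply(codes, 2L, paste, collapse = ",")
  groups <- split(seq_len(m), factor(sig, levels = unique(sig)))
  clusters <- lapply(groups, function(ix) M$feature_ids[ix])
  partitions <- lapply(groups, function(ix) {
    cj <- codes[, ix[1L]]
    lapply(seq_len(max(cj)), function(b) M$carrier_ids[cj == b])
  })
  names(clusters) <- names(partitions) <- paste0("cluster_", seq_along(groups))
  relabeled <- character_matrix(codes, field = "integer",
                                carrier_ids = M$carrier_ids,
                                feature_ids = M$feature_ids)
  structure(list(clusters = clusters,
                 carrier_partitions = partitions,
                 numeric_rank_after_labeling = matrix_rank(relabeled),
                 relabeled = relabeled),
            class = "functional_clustering")
}

#' @export
print.functional_clustering <- function(x, ...) {
  cat(sprintf("functional clustering: %d cluster(s), rank after labeling %d\n",
              length(x$clusters), x$numeric_rank_after_labeling))
  for (i in seq_along(x$clusters))
    cat("  ", names(x$clusters)[i], ": {",
        paste(x$clusters[[i]], collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Rank signature: cladistic-like vs functional-like
#'
#' A quick verdict from the rank alone: a cladistic table, where each
#' carrier adds fresh synapomorphic information, has maximal rank
#' min(n, m); a functional one, dominated by a few correlated character
#' syndromes, has rank well below it. The verdict thresholds are a
#' reporting convention (configurable), not a theorem.
#'
#' @inheritParams matrix_rank
#' @param functional_ratio rank/min-dimension ratio at or below which the
#'   verdict is "functional-like" (default 0.5).
#' @return list with \code{rank}, \code{min_dim}, \code{ratio},
#'   \code{verdict} ("cladistic-like", "functional-like" or "mixed") and
#'   \code{degenerate} (TRUE for the zero matrix).
#' @export
rank_signature <- function(M, tol = 1e-8, functional_ratio = 0.5) {
  M <- as_character_matrix(M)
  r <- matrix_rank(M, tol = tol)
  md <- min(dim(M$values))
  ratio <- r / md
  verdict <- if (r == md) "cladistic-like"
  else if (ratio <= functional_ratio) "functional-like"
  else "mixed"
  list(rank = r, min_dim = md, ratio = ratio, verdict = verdict,
       degenerate = r == 0L)
}
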