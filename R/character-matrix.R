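#' Carrier-by-feature character matrix
#'
#' The basic data container: an \code{n x m} table of character-state values
#' \code{c_ij}, where rows are carriers (species or higher taxa) and columns
#' are features (characters). Values live in one of three coefficient fields:
#' \describe{
#'   \item{\code{"real"}}{measurements; rank and decompositions are computed
#'     numerically via the SVD.}
#'   \item{\code{"integer"}}{counts or categorical codes; rank and
#'     decompositions are computed exactly over the rationals.}
#'   \item{\code{"gf2"}}{presence/absence (0/1); arithmetic is modulo 2.}
#' }
#' Missing entries are encoded as \code{NA} and tracked in a logical mask;
#' they model carriers that do not possess a feature at all (e.g. wing length
#' for a wingless organism) and turn the carrier's row into a partial section
#' (see \code{\link{sections_from_matrix}}).
#'
#' @param values numeric matrix (or object coercible to one); \code{NA} marks
#'   a missing entry.
#' @param field coefficient field tag: \code{"real"}, \code{"integer"} or
#'   \code{"gf2"}. Defaults to \code{"real"}; when all non-missing entries are
#'   0/1 a message suggests \code{"gf2"}, since ranks differ between fields.
#' @param carrier_ids,feature_ids optional row/column identifiers; default to
#'   existing dimnames or \code{carrier_1..n} / \code{feature_1..m}.
#' @return an object of class \code{character_matrix}.
#' @examples
#' m <- character_matrix(rbind(c(1, 2, 5), c(2, 4, 10)), field = "integer")
#' matrix_rank(m)
#' @export
character_matrix <- function(values, field = NULL, carrier_ids = NULL,
                             feature_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("character matrix must have at least one carrier and one feature")

  if (is.null(carrier_ids)) carrier_ids <- rownames(values)
  if (is.null(carrier_ids)) carrier_ids <- paste0("carrier_", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(ncol(values)))
  carrier_ids <- as.character(carrier_ids)
  feature_ids <- as.character(feature_ids)
  if (length(carrier_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(carrier_ids)) stop("duplicate carrier ids: ",
    paste(unique(carrier_ids[duplicated(carrier_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids: ",
    paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))

  obs <- values[!is.na(values)]
  if (is.null(field)) {
    field <- "real"
    if (length(obs) && all(obs %in% c(0, 1)))
      message("all values are 0/1; consider field = \"gf2\" ",
              "(rank differs between fields)")
  }
  field <- match.arg(field, c("real", "integer", "gf2"))
  if (field == "gf2" && length(obs) && !all(obs %in% c(0, 1)))
    stop("field \"gf2\" requires all non-missing entries in {0, 1}")
  if (field == "integer" && length(obs) && any(obs != round(obs)))
    stop("field \"integer\" requires whole-number entries")

  dimnames(values) <- list(carrier_ids, feature_ids)
  structure(
    list(values = values,
         carrier_ids = carrier_ids,
         feature_ids = feature_ids,
         field = field,
         missing = is.na(values)),
    class = "character_matrix")
}

#' Coerce to a character matrix
#'
#' @param x a \code{character_matrix} (returned unchanged) or a plain matrix.
#' @param field coefficient field used when coercing a plain matrix.
#' @export
as_character_matrix <- function(x, field = NULL) {
  if (inherits(x, "character_matrix")) return(x)
  character_matrix(x, field = field)
}

#' @export
as.matrix.character_matrix <- function(x, ...) x$values

#' @export
dim.character_matrix <- function(x) dim(x$values)

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character matrix: %d carriers x %d features, field = %s",
              nrow(x$values), ncol(x$values), x$field))
  nmiss <- sum(x$missing)
  if (nmiss > 0) cat(sprintf(", %d missing", nmiss))
  cat("\n")
  print(x$values)
  invisible(x)
}

# Error if M has missing entries, naming the offending cells.
assert_complete <- function(M, op = "this operation") {
  if (any(M$missing)) {
    idx <- which(M$missing, arr.ind = TRUE)
    cells <- apply(idx, 1L, function(rc)
      paste0(M$carrier_ids[rc[1L]], "/", M$feature_ids[rc[2L]]))
    stop(op, " requires a complete matrix; missing entries at: ",
         paste(utils::head(cells, 10L), collapse = ", "),
         if (length(cells) > 10L) sprintf(" (and %d more)", length(cells) - 10L))
  }
  invisible(M)
}

#' Restrict to the complete feature columns
#'
#' The rank machinery refuses matrices with missing entries (imputing states
#' silently would fabricate characters). This helper drops every feature
#' column containing a missing value and reports which ones were removed,
#' giving the maximal complete column subset.
#'
#' @param M a \code{character_matrix}.
#' @return a complete \code{character_matrix}; attribute \code{"dropped"}
#'   holds the removed feature ids.
#' @export
complete_features <- function(M) {
  M <- as_character_matrix(M)
  bad <- apply(M$missing, 2L, any)
  if (all(bad)) stop("no complete feature columns remain")
  if (any(bad))
    message("dropping incomplete features: ",
            paste(M$feature_ids[bad], collapse = ", "))
  out <- character_matrix(M$values[, !bad, drop = FALSE], field = M$field,
                          carrier_ids = M$carrier_ids,
                          feature_ids = M$feature_ids[!bad])
  attr(out, "dropped") <- M$feature_ids[bad]
  out
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
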