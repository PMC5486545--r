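#' Feature space: base of features with finite fibers of values
#'
#' The geometric picture of a character table: the base B is the set of
#' features under consideration, and the fiber F_j over feature j is the
#' finite set of values that feature can take. A taxon is a (partial)
#' section over this space (see \code{\link{section}}); which global
#' sections are biologically realizable is recorded in an optional
#' constraint set — the admissible sections — standing for structural,
#' functional, developmental or environmental constraints.
#'
#' Fiber values are stored as character strings; numeric values are
#' converted. Constraints are an explicit finite enumeration of admissible
#' global sections (predicate-style constraints are out of scope).
#'
#' @param base character vector of feature ids (unique).
#' @param fibers named list, one non-empty vector of values per feature.
#' @param constraints optional list of admissible global sections, each a
#'   named vector (or \code{section}) covering the full base with values in
#'   the corresponding fibers; duplicates are rejected.
#' @return an object of class \code{feature_space}.
#' @export
feature_space <- function(base, fibers, constraints = NULL) {
  base <- as.character(base)
  if (anyDuplicated(base)) stop("duplicate feature ids in base")
  if (!all(base %in% names(fibers)))
    stop("fibers missing for: ",
         paste(setdiff(base, names(fibers)), collapse = ", "))
  fibers <- lapply(fibers[base], function(f) {
    f <- unique(as.character(f))
    if (!length(f)) stop("empty fiber")
    f
  })
  space <- structure(list(base = base, fibers = fibers, constraints = NULL),
                     class = "feature_space")
  if (!is.null(constraints)) {
    constraints <- lapply(constraints, as_assignment)
    keys <- vapply(constraints, function(s) section_key(s, base), "")
    if (anyDuplicated(keys)) stop("duplicate admissible sections")
    for (s in constraints) validate_assignment(s, space, global = TRUE)
    space$constraints <- constraints
  }
  space
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("feature space: %d features (%s)\n", length(x$base),
              paste(x$base, collapse = ", ")))
  for (j in x$base)
    cat("  ", j, ": {", paste(x$fibers[[j]], collapse = ", "), "}\n", sep = "")
  if (!is.null(x$constraints))
    cat(sprintf("  %d admissible global sections\n", length(x$constraints)))
  invisible(x)
}

as_assignment <- function(s) {
  if (inherits(s, "section")) return(s$assignment)
  v <- unlist(s)
  stats::setNames(as.character(v), names(v))
}

validate_assignment <- function(a, space, global = FALSE) {
  dom <- names(a)
  if (length(a) && (is.null(dom) || anyDuplicated(dom)))
    stop("assignment needs unique names")
  unknown <- setdiff(dom, space$base)
  if (length(unknown)) stop("unknown feature ids: ",
                            paste(unknown, collapse = ", "))
  if (global && !setequal(dom, space$base))
    stop("constraint sections must be global (cover the full base)")
  for (j in dom)
    if (!a[[j]] %in% space$fibers[[j]])
      stop("value \"", a[[j]], "\" not in fiber of feature \"", j, "\"")
  invisible(a)
}

section_key <- function(a, base) {
  dom <- intersect(base, names(a))
  paste(paste0(dom, "=", a[dom]), collapse = ";")
}

#' Partial section: a taxon as an assignment of feature values
#'
#' A section assigns to each feature j in its domain (a subset of the base)
#' a value s(j) in the fiber F_j. A global section (domain = full base)
#' models a fully specified species; a proper partial section models a
#' higher taxon, whose undetermined features are exactly those on which its
#' member species differ.
#'
#' @param assignment named vector: names are feature ids, values fiber
#'   values.
#' @param label identifier (e.g. taxon name).
#' @param space optional \code{feature_space} to validate against.
#' @return an object of class \code{section}.
#' @export
section <- function(assignment, label = NULL, space = NULL) {
  a <- as_assignment(assignment)
  if (length(a) && (is.null(names(a)) || any(names(a) == "")))
    stop("assignment must be fully named by feature ids")
  if (!is.null(space)) validate_assignment(a, space)
  structure(list(label = label, assignment = a), class = "section")
}

#' @export
print.section <- function(x, ...) {
  lbl <- if (is.null(x$label)) "section" else paste0("section \"", x$label, "\"")
  if (!length(x$assignment)) cat(lbl, ": empty domain\n", sep = "")
  else cat(lbl, ": ", paste(paste0(names(x$assignment), "=", x$assignment),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
format.section <- function(x, ...) section_key(x$assignment, names(x$assignment))

section_domain <- function(s) names(s$assignment)

sections_equal <- function(s, t) {
  identical(sort(section_domain(s)), sort(section_domain(t))) &&
    all(s$assignment[sort(section_domain(s))] ==
          t$assignment[sort(section_domain(s))])
}

#' Restrict a section to a smaller base
#'
#' Passing to a higher taxon: values outside \code{subbase} become
#' undetermined, values inside are kept unchanged. Restriction to the empty
#' subbase gives the empty section (the top taxon).
#'
#' @param s a \code{section}.
#' @param subbase feature ids to keep.
#' @param space optional \code{feature_space}; when given, \code{subbase}
#'   must consist of known feature ids.
#' @return the restricted \code{section}.
#' @export
restrict <- function(s, subbase, space = NULL) {
  stopifnot(inherits(s, "section"))
  subbase <- as.character(subbase)
  if (!is.null(space)) {
    unknown <- setdiff(subbase, space$base)
    if (length(unknown)) stop("unknown feature ids: ",
                              paste(unknown, collapse = ", "))
  }
  keep <- intersect(section_domain(s), subbase)
  section(s$assignment[keep], label = s$label)
}

#' Extensions of a partial section to global sections
#'
#' Passing to more specific taxa: all global sections agreeing with \code{s}
#' on its domain. With constraints present these are the admissible
#' sections compatible with \code{s}, in admissible-list order; without
#' constraints, all combinatorial completions, in lexicographic fiber order
#' (first missing feature varies slowest). An empty result signals a
#' partial section that cannot be completed at all — a feature-value
#' combination forbidden by the constraints.
#'
#' @param s a \code{section} valid in \code{space}.
#' @param space a \code{feature_space}.
#' @return list of global \code{section}s.
#' @export
extensions <- function(s, space) {
  stopifnot(inherits(s, "section"), inherits(space, "feature_space"))
  validate_assignment(s$assignment, space)
  dom <- section_domain(s)

  if (!is.null(space$constraints)) {
    hits <- Filter(function(g) all(g[dom] == s$assignment[dom]),
                   space$constraints)
    return(lapply(hits, function(g)
      section(g[space$base], label = s$label)))
  }

  free <- setdiff(space$base, dom)
  if (!length(free)) return(list(section(s$assignment[space$base], label = s$label)))
  # lexicographic: first free feature slowest -> build reversed, then reorder
  grid <- expand.grid(rev(space$fibers[free]), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(free)), drop = FALSE]
  names(grid) <- free
  lapply(seq_len(nrow(grid)), function(i) {
    a <- c(s$assignment, unlist(lapply(grid[i, , drop = FALSE], as.character)))
    section(stats::setNames(a[space$base], space$base), label = s$label)
  })
}

#' Apomorphy candidates of a partial section
#'
#' For each feature outside the domain of \code{s}, the set of values
#' attained across the extensions of \code{s}. Features attaining two or
#' more values are the apomorphy-bearing ones: their values distinguish the
#' sister taxa refining \code{s}. When \code{s} has at most one extension
#' there is nothing to distinguish and the map is empty.
#'
#' @inheritParams extensions
#' @return named list feature id -> character vector of attained values.
#' @export
apomorphies <- function(s, space) {
  exts <- extensions(s, space)
  if (length(exts) <= 1L) return(stats::setNames(list(), character(0)))
  free <- setdiff(space$base, section_domain(s))
  out <- lapply(free, function(j)
    sort(unique(vapply(exts, function(t) t$assignment[[j]], ""))))
  stats::setNames(out, free)
}

#' Innovations: enlarge a fiber or add a feature
#'
#' Two of the elementary innovation types in the geometric picture:
#' \describe{
#'   \item{\code{extend_fiber}}{the fiber of an existing feature gains new
#'     values (payload: \code{list(feature =, values =)}). Existing sections
#'     and constraints remain valid; previously unextendable sections may
#'     gain extensions once admissible sections using the new values are
#'     added.}
#'   \item{\code{add_feature}}{a fresh feature with its own fiber is added
#'     (payload: \code{list(feature =, fiber =, default =)}). Existing
#'     admissible sections are no longer global; if \code{default} (a value
#'     in the new fiber) is supplied each is completed with it, otherwise
#'     the constraint set is dropped with a warning — silently broadcasting
#'     old constraints over arbitrary new values is refused.}
#' }
#'
#' @param space a \code{feature_space}.
#' @param kind \code{"extend_fiber"} or \code{"add_feature"}.
#' @param payload see above.
#' @return the new \code{feature_space}.
#' @export
innovate <- function(space, kind = c("extend_fiber", "add_feature"), payload) {
  stopifnot(inherits(space, "feature_space"))
  kind <- match.arg(kind)
  if (kind == "extend_fiber") {
    j <- as.character(payload$feature)
    vals <- as.character(payload$values)
    if (!j %in% space$base) stop("unknown feature: ", j)
    if (!length(vals)) stop("no new values supplied")
    if (any(vals %in% space$fibers[[j]]))
      stop("values already in fiber: ",
           paste(intersect(vals, space$fibers[[j]]), collapse = ", "))
    fibers <- space$fibers
    fibers[[j]] <- c(fibers[[j]], vals)
    return(feature_space(space$base, fibers, space$constraints))
  }
  # add_feature
  j <- as.character(payload$feature)
  fib <- as.character(payload$fiber)
  if (j %in% space$base) stop("feature already exists: ", j)
  if (!length(fib)) stop("new feature needs a non-empty fiber")
  base <- c(space$base, j)
  fibers <- c(space$fibers, stats::setNames(list(fib), j))
  constraints <- space$constraints
  if (!is.null(constraints)) {
    if (!is.null(payload$default)) {
      default <- as.character(payload$default)
      if (!default %in% fib) stop("default value not in the new fiber")
      constraints <- lapply(constraints, function(g)
        c(g, stats::setNames(default, j)))
    } else {
      warning("add_feature without a default: dropping the constraint set ",
              "(admissible sections must be re-specified over the new base)")
      constraints <- NULL
    }
  }
  feature_space(base, fibers, constraints)
}

#' Amalgamation: combine two features into one
#'
#' The innovation in which two existing structures with their own functions
#' are identified into a single new feature serving a new function — the
#' canonical example being feathers (thermoregulation) plus extended
#' forelimbs (climbing) combining into a wing (flight). The combination is
#' specified by a partial \code{value_map} from pairs of old fiber values to
#' new fiber values; the new fiber is exactly the image of the map, and
#' value pairs outside its domain have no counterpart in the new space.
#'
#' Sections are transported by the returned \code{transport} function: a
#' section defined on both features with a mapped value pair gains the new
#' feature with the mapped value; a section whose pair is unmapped, or which
#' is defined on only one of the two features, loses those features (the
#' loss is recorded in attribute \code{"lost_features"}). Admissible
#' sections that would lose the feature are removed from the constraint set
#' (with a warning naming how many).
#'
#' @param space a \code{feature_space}.
#' @param j1,j2 distinct feature ids to amalgamate.
#' @param j_new fresh id for the combined feature.
#' @param value_map data frame with columns \code{v1}, \code{v2}, \code{to}.
#' @return list with the new \code{space} and the \code{transport} function.
#' @examples
#' sp <- feature_space(c("feathers", "forelimb"),
#'                     list(feathers = c("absent", "present"),
#'                          forelimb = c("short", "extended")))
#' am <- amalgamate(sp, "feathers", "forelimb", "flight_apparatus",
#'                  data.frame(v1 = "present", v2 = "extended", to = "wing"))
#' am$transport(section(c(feathers = "present", forelimb = "extended")))
#' @export
amalgamate <- function(space, j1, j2, j_new, value_map) {
  stopifnot(inherits(space, "feature_space"))
  j1 <- as.character(j1); j2 <- as.character(j2); j_new <- as.character(j_new)
  if (j1 == j2) stop("j1 and j2 must differ")
  for (j in c(j1, j2)) if (!j %in% space$base) stop("unknown feature: ", j)
  if (j_new %in% setdiff(space$base, c(j1, j2)))
    stop("j_new must be fresh: ", j_new)
  value_map <- as.data.frame(lapply(value_map, as.character),
                             stringsAsFactors = FALSE)
  if (!all(c("v1", "v2", "to") %in% names(value_map)) || nrow(value_map) == 0)
    stop("value_map must be a non-empty data frame with columns v1, v2, to")
  if (!all(value_map$v1 %in% space$fibers[[j1]]) ||
      !all(value_map$v2 %in% space$fibers[[j2]]))
    stop("value_map refers to values outside the fibers of ", j1, "/", j2)
  mkey <- paste(value_map$v1, value_map$v2, sep = "\r")
  if (anyDuplicated(mkey)) stop("value_map assigns a pair twice")

  keep <- setdiff(space$base, c(j1, j2))
  base <- c(keep, j_new)
  fibers <- c(space$fibers[keep],
              stats::setNames(list(unique(value_map$to)), j_new))

  transport <- function(s) {
    stopifnot(inherits(s, "section"))
    a <- s$assignment
    dom <- names(a)
    lost <- character(0)
    new_val <- NULL
    if (all(c(j1, j2) %in% dom)) {
      hit <- match(paste(a[[j1]], a[[j2]], sep = "\r"), mkey)
      if (!is.na(hit)) new_val <- value_map$to[hit]
      else lost <- c(j1, j2)
    } else lost <- intersect(c(j1, j2), dom)
    a <- a[setdiff(dom, c(j1, j2))]
    if (!is.null(new_val)) a <- c(a, stats::setNames(new_val, j_new))
    out <- section(a, label = s$label)
    attr(out, "lost_features") <- lost
    out
  }

  constraints <- NULL
  if (!is.null(space$constraints)) {
    moved <- lapply(space$constraints, function(g)
      transport(section(g)))
    ok <- vapply(moved, function(t) j_new %in% section_domain(t), TRUE)
    if (any(!ok))
      warning(sum(!ok), " admissible section(s) dropped: value pair outside ",
              "the amalgamation map")
    constraints <- lapply(moved[ok], function(t) t$assignment[base])
    if (!length(constraints)) constraints <- NULL
  }

  list(space = feature_space(base, fibers, constraints),
       transport = transport)
}

#' Sections of a character matrix
#'
#' The bridge from the algebraic to the geometric picture: base = features,
#' fiber F_j = values observed in column j, and one section per carrier with
#' s_i(j) = c_ij on the features where carrier i has a value (missing
#' entries make the section partial).
#'
#' @param M a \code{\link{character_matrix}}; missing entries allowed.
#' @return list with \code{space} (a \code{feature_space}) and
#'   \code{sections} (one per carrier).
#' @export
sections_from_matrix <- function(M) {
  M <- as_character_matrix(M)
  fibers <- lapply(seq_along(M$feature_ids), function(j) {
    v <- M$values[, j]
    sort(unique(as.character(v[!is.na(v)])))
  })
  names(fibers) <- M$feature_ids
  if (any(!lengths(fibers)))
    stop("feature(s) with no observed values: ",
         paste(M$feature_ids[!lengths(fibers)], collapse = ", "))
  space <- feature_space(M$feature_ids, fibers)
  sections <- lapply(seq_along(M$carrier_ids), function(i) {
    ok <- !M$missing[i, ]
    section(stats::setNames(as.character(M$values[i, ok]), M$feature_ids[ok]),
            label = M$carrier_ids[i])
  })
  list(space = space, sections = sections)
}
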