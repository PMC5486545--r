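#' Group action on the fibers of a feature space
#'
#' A finite transformation group G acting fiberwise: each group element g
#' induces, on each fiber F_j, a bijection x -> g(x), and composition in
#' the group must match composition of the maps, (g o h)(x) = g(h(x)).
#' Scalings, relabelings, reflections and other pattern transformations are
#' modelled this way; the orbits of sections under G are the gestalts (see
#' \code{\link{orbit_classes}}).
#'
#' The action may differ between fibers, and may be trivial on some of
#' them: a feature omitted from an element's map list is fixed pointwise.
#'
#' @param elements character vector of group-element ids.
#' @param identity the id of the identity element.
#' @param compose composition table: matrix with dimnames
#'   \code{(elements, elements)}; entry \code{[g, h]} is the id of g o h.
#' @param action nested list \code{action[[g]][[feature]]}: a named
#'   character vector mapping each fiber value to its image.
#' @return an object of class \code{group_action}. The group axioms are NOT
#'   checked here; \code{\link{verify_action}} does that and reports every
#'   violation as data.
#' @export
group_action <- function(elements, identity, compose, action) {
  elements <- as.character(elements)
  if (anyDuplicated(elements)) stop("duplicate group-element ids")
  if (!identity %in% elements) stop("identity must be one of the elements")
  compose <- as.matrix(compose)
  if (!all(dim(compose) == length(elements)))
    stop("compose table must be square over the elements")
  dimnames(compose) <- list(elements, elements)
  structure(list(elements = elements, identity = identity,
                 compose = compose, action = action),
            class = "group_action")
}

act_value <- function(G, g, j, x) {
  maps <- G$action[[g]]
  if (is.null(maps) || is.null(maps[[j]])) return(x)   # trivial on this fiber
  m <- maps[[j]]
  if (!x %in% names(m)) return(NA_character_)
  unname(m[[x]])
}

#' Apply a group element to a section
#'
#' Acts fiberwise: (g s)(j) = g(s(j)) on every feature in the domain of s.
#'
#' @param G a \code{group_action}; \code{g} an element id; \code{s} a
#'   \code{section}.
#' @export
apply_action <- function(G, g, s) {
  stopifnot(inherits(G, "group_action"), inherits(s, "section"))
  if (!g %in% G$elements) stop("unknown group element: ", g)
  a <- s$assignment
  for (j in names(a)) {
    v <- act_value(G, g, j, a[[j]])
    if (is.na(v)) stop("element ", g, " has no image for value \"", a[[j]],
                       "\" on feature ", j)
    a[[j]] <- v
  }
  section(a, label = s$label)
}

#' Verify the group-action axioms
#'
#' Checks, exhaustively over the finite data, that (i) the composition
#' table is a group (closure, identity, inverses, associativity), (ii) each
#' element acts on each fiber by a bijection, (iii) the identity acts
#' trivially, and (iv) compatibility: (g o h)(x) = g(h(x)) for all g, h and
#' every x in every fiber. Violations are returned as data, not raised as
#' errors — a biological "almost-group" (e.g. a translation acting on a
#' finite chain of serial homologues such as the vertebral column, which
#' falls off the end instead of wrapping) is a meaningful finding, and its
#' boundary failures are exactly what this report lists.
#'
#' @param G a \code{group_action}.
#' @param space a \code{feature_space} the action is checked against.
#' @return list with \code{valid} (logical) and \code{violations} (data
#'   frame with columns \code{type, g, h, feature, value, detail}).
#' @export
verify_action <- function(G, space) {
  stopifnot(inherits(G, "group_action"), inherits(space, "feature_space"))
  v <- list()
  bad <- function(type, g = NA, h = NA, feature = NA, value = NA, detail = "")
    v[[length(v) + 1L]] <<- data.frame(type = type, g = g, h = h,
                                       feature = feature, value = value,
                                       detail = detail)
  els <- G$elements
  # table axioms
  if (!all(G$compose %in% els)) bad("closure", detail = "table entry not an element")
  for (g in els) {
    if (!identical(unname(G$compose[G$identity, g]), g))
      bad("identity", g = G$identity, h = g, detail = "e o g != g")
    if (!identical(unname(G$compose[g, G$identity]), g))
      bad("identity", g = g, h = G$identity, detail = "g o e != g")
    if (!any(G$compose[g, ] == G$identity))
      bad("inverse", g = g, detail = "no right inverse")
  }
  for (g in els) for (h in els) for (k in els) {
    lhs <- G$compose[G$compose[g, h], k]
    rhs <- G$compose[g, G$compose[h, k]]
    if (!identical(lhs, rhs))
      bad("associativity", g = g, h = h, detail = paste0("(gh)k=", lhs,
                                                         " g(hk)=", rhs))
  }
  # fiberwise bijections + identity triviality
  for (g in els) for (j in space$base) {
    fib <- space$fibers[[j]]
    img <- vapply(fib, function(x) {
      y <- act_value(G, g, j, x)
      if (is.na(y)) NA_character_ else y
    }, "")
    if (anyNA(img)) {
      for (x in fib[is.na(img)])
        bad("not_total", g = g, feature = j, value = x,
            detail = "no image for fiber value")
      next
    }
    if (!all(img %in% fib))
      for (x in fib[!img %in% fib])
        bad("off_fiber", g = g, feature = j, value = x,
            detail = paste0("image ", img[[x]], " outside fiber"))
    if (anyDuplicated(img))
      for (x in fib[duplicated(img) | duplicated(img, fromLast = TRUE)])
        bad("not_bijective", g = g, feature = j, value = x,
            detail = paste0("value ", x, " collides at image ", img[[x]]))
    if (g == G$identity && !all(img == fib))
      for (x in fib[img != fib])
        bad("identity_moves", g = g, feature = j, value = x,
            detail = "identity does not fix fiber value")
  }
  # compatibility (g o h)(x) = g(h(x))
  for (g in els) for (h in els) for (j in space$base) {
    gh <- G$compose[g, h]
    for (x in space$fibers[[j]]) {
      lhs <- act_value(G, gh, j, x)
      hx <- act_value(G, h, j, x)
      rhs <- if (is.na(hx)) NA_character_ else act_value(G, g, j, hx)
      if (!identical(lhs, rhs))
        bad("composition", g = g, h = h, feature = j, value = x,
            detail = paste0("(g o h)(x)=", lhs, " but g(h(x))=", rhs))
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(0), g = character(0), h = character(0),
               feature = character(0), value = character(0),
               detail = character(0))
  list(valid = nrow(violations) == 0L, violations = violations)
}

#' Gestalt classes: orbits of sections under a group action
#'
#' A gestalt is what a collection of patterns that can be transformed into
#' each other have in common: formally, an orbit of sections under the
#' transformation group. Two sections are equivalent when their domains
#' coincide and some group element maps one to the other fiberwise. The
#' result is a partition of the input; each class's representative is its
#' lexicographically smallest member.
#'
#' @param sections list of \code{section}s over \code{space}.
#' @param G a \code{group_action}; must pass \code{\link{verify_action}}.
#' @param space the shared \code{feature_space}.
#' @return list of classes; each class is a list with \code{representative}
#'   and \code{members} (indices into \code{sections}).
#' @export
orbit_classes <- function(sections, G, space) {
  chk <- verify_action(G, space)
  if (!chk$valid)
    stop("group action violates the axioms (",
         nrow(chk$violations), " violations); see verify_action()")
  n <- length(sections)
  keys <- vapply(sections, function(s) section_key(s$assignment, space$base), "")
  equivalent <- function(s, t) {
    if (!setequal(section_domain(s), section_domain(t))) return(FALSE)
    for (g in G$elements)
      if (sections_equal(apply_action(G, g, s), t)) return(TRUE)
    FALSE
  }
  class_of <- integer(n)
  nclass <- 0L
  for (i in order(keys)) {           # lexicographic representatives
    assigned <- FALSE
    for (cl in seq_len(nclass)) {
      rep_ix <- which(class_of == cl)[1L]
      if (equivalent(sections[[rep_ix]], sections[[i]])) {
        class_of[i] <- cl; assigned <- TRUE; break
      }
    }
    if (!assigned) { nclass <- nclass + 1L; class_of[i] <- nclass }
  }
  lapply(seq_len(nclass), function(cl) {
    members <- which(class_of == cl)
    members <- members[order(keys[members])]
    list(representative = sections[[members[1L]]], members = members)
  })
}

#' Example actions: cyclic relabeling, identity, finite-chain translation
#'
#' Three ready-made actions for a given space:
#' \itemize{
#'   \item \code{cyclic_shift_action}: the cyclic group C_L (L = least
#'     common multiple of the fiber sizes) acting by cyclic shift of each
#'     fiber's value list — a pure relabeling symmetry; satisfies all
#'     axioms.
#'   \item \code{identity_action}: the trivial group; every fiber fixed.
#'   \item \code{chain_translation_action}: "shift by one" on each ordered
#'     fiber, clamping at the last value — the serial-homology situation of
#'     a translation acting on a finite chain (e.g. vertebrae). This is
#'     deliberately NOT a group action: the clamp makes the map
#'     non-bijective and breaks compatibility at the boundary, and
#'     \code{\link{verify_action}} lists exactly those boundary violations.
#' }
#'
#' @param space a \code{feature_space}.
#' @return a \code{group_action}.
#' @export
cyclic_shift_action <- function(space) {
  sizes <- lengths(space$fibers)
  L <- Reduce(lcm2, sizes)
  els <- paste0("g", seq_len(L) - 1L)
  compose <- outer(seq_len(L) - 1L, seq_len(L) - 1L,
                   function(a, b) els[((a + b) %% L) + 1L])
  action <- lapply(seq_len(L) - 1L, function(k) {
    maps <- lapply(space$base, function(j) {
      fib <- space$fibers[[j]]
      f <- length(fib)
      stats::setNames(fib[((seq_len(f) - 1L + k) %% f) + 1L], fib)
    })
    stats::setNames(maps, space$base)
  })
  names(action) <- els
  group_action(els, "g0", compose, action)
}

#' @rdname cyclic_shift_action
#' @export
identity_action <- function(space) {
  group_action("e", "e", matrix("e", 1, 1),
               list(e = stats::setNames(
                 lapply(space$base, function(j)
                   stats::setNames(space$fibers[[j]], space$fibers[[j]])),
                 space$base)))
}

#' @rdname cyclic_shift_action
#' @export
chain_translation_action <- function(space) {
  els <- c("e", "t")
  compose <- matrix(c("e", "t", "t", "t"), 2, 2, byrow = TRUE)  # forced closure
  shift_clamp <- function(fib) {
    f <- length(fib)
    stats::setNames(fib[pmin(seq_len(f) + 1L, f)], fib)
  }
  action <- list(
    e = stats::setNames(lapply(space$base, function(j)
      stats::setNames(space$fibers[[j]], space$fibers[[j]])), space$base),
    t = stats::setNames(lapply(space$base, function(j)
      shift_clamp(space$fibers[[j]])), space$base))
  group_action(els, "e", compose, action)
}
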