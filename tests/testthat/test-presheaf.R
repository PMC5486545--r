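test_that("restriction keeps values and models the taxon hierarchy", {
  sp <- binary_space(3)
  g <- section(c(f1 = "1", f2 = "0", f3 = "1"))
  expect_true(sec_eq(restrict(g, c("f1", "f2", "f3")), g))
  expect_length(restrict(g, character(0))$assignment, 0L)
  r <- restrict(g, c("f2", "f3"))
  expect_identical(unname(r$assignment["f2"]), "0")
  expect_error(restrict(g, "nope", sp), "unknown feature")
})

test_that("unconstrained extensions enumerate completions in fiber order", {
  sp <- binary_space(3)
  s <- section(c(f2 = "1"))
  exts <- extensions(s, sp)
  expect_length(exts, 4L)   # product of free fiber sizes
  # lexicographic: f1 varies slowest, f3 fastest
  keys <- vapply(exts, function(t)
    paste(t$assignment[c("f1", "f3")], collapse = ""), "")
  expect_identical(keys, c("00", "01", "10", "11"))
  # a global section has exactly itself as extension
  g <- exts[[1]]
  expect_length(extensions(g, sp), 1L)
})

test_that("constrained extensions filter the admissible set", {
  adm <- list(c(f1 = "1", f2 = "0", f3 = "0"),
              c(f1 = "1", f2 = "0", f3 = "1"),
              c(f1 = "1", f2 = "1", f3 = "0"),
              c(f1 = "0", f2 = "0", f3 = "0"))
  sp <- binary_space(3, adm)
  expect_length(extensions(section(c(f1 = "1")), sp), 3L)
  expect_length(extensions(section(c(f1 = "0", f2 = "1")), sp), 0L)
  # admissible-list order is preserved
  exts <- extensions(section(c(f1 = "1")), sp)
  expect_identical(unname(exts[[1]]$assignment[sp$base]), c("1", "0", "0"))
})

test_that("the shipped demo space exhibits both extension behaviors", {
  path <- system.file("extdata", "extensions_demo.json",
                      package = "morphorank")
  demo <- read_space_json(path)
  labels <- vapply(demo$sections, `[[`, "", "label")
  three <- demo$sections[[match("three_extensions", labels)]]
  none <- demo$sections[[match("unextendable", labels)]]
  expect_length(extensions(three, demo$space), 3L)
  expect_length(extensions(none, demo$space), 0L)
})

test_that("restrict/extend round-trip holds exhaustively on small spaces", {
  specs <- list(list(m = 2, f = 3, k = 4), list(m = 3, f = 2, k = 3),
                list(m = 4, f = 2, k = 6), list(m = 4, f = 3, k = 10))
  for (spec in specs) {
    for (seed in 1:3) {
      sp <- gen_space(spec$m, spec$f, spec$k, seed = seed)
      for (s in all_partial_sections(sp)) {
        for (t in extensions(s, sp)) {
          expect_true(sec_eq(restrict(t, names(s$assignment)), s))
        }
      }
    }
    # and on the unconstrained space of the same shape
    spu <- gen_space(spec$m, spec$f, spec$k, seed = 1)
    spu$constraints <- NULL
    for (s in all_partial_sections(spu)) {
      exts <- extensions(s, spu)
      free <- setdiff(spu$base, names(s$assignment))
      expect_length(exts, prod(lengths(spu$fibers[free])))
      for (t in exts)
        expect_true(sec_eq(restrict(t, names(s$assignment)), s))
    }
  }
})

test_that("restriction is monotone: coarser taxa have more extensions", {
  for (seed in 1:5) {
    sp <- gen_space(3, c(2, 3, 2), 5, seed = seed)
    for (s in all_partial_sections(sp)) {
      exts <- extensions(s, sp)
      dom <- names(s$assignment)
      if (length(dom) == 0) next
      sub <- restrict(s, dom[-1])
      # every extension of s also extends the restricted (higher) taxon
      keys_s <- vapply(exts, function(t) format(t), "")
      keys_sub <- vapply(extensions(sub, sp), function(t) format(t), "")
      expect_true(all(keys_s %in% keys_sub))
    }
  }
})

test_that("enlarging the admissible set never removes extensions", {
  sp_small <- gen_space(3, 2, 3, seed = 2)
  extra <- setdiff(
    vapply(extensions(section(character(0)),
                      unconstrained_like(sp_small)), format, ""),
    vapply(sp_small$constraints, function(a) format(section(a)), ""))
  # add one more admissible section
  add <- strsplit(strsplit(extra[1], ";")[[1]], "=")
  new_sec <- stats::setNames(vapply(add, `[`, "", 2), vapply(add, `[`, "", 1))
  sp_big <- feature_space(sp_small$base, sp_small$fibers,
                          c(sp_small$constraints, list(new_sec)))
  for (s in all_partial_sections(sp_small)) {
    expect_gte(length(extensions(s, sp_big)), length(extensions(s, sp_small)))
  }
})

test_that("apomorphies are the features distinguishing sister extensions", {
  adm <- list(c(f1 = "1", f2 = "0", f3 = "0"),
              c(f1 = "1", f2 = "0", f3 = "1"))
  sp <- binary_space(3, adm)
  apo <- apomorphies(section(c(f1 = "1")), sp)
  # f2 is shared (no apomorphy there), f3 distinguishes the two species
  expect_identical(apo$f2, "0")
  expect_identical(apo$f3, c("0", "1"))
  # single extension -> empty map
  expect_length(apomorphies(section(c(f1 = "1", f3 = "1")), sp), 0L)
  # unconstrained space: an undefined binary feature attains its full fiber
  spu <- binary_space(2)
  apo_u <- apomorphies(section(c(f1 = "0")), spu)
  expect_identical(apo_u$f2, c("0", "1"))
})

test_that("fiber extension can make an unextendable section extendable", {
  adm <- list(c(f1 = "0", f2 = "0"))
  sp <- feature_space(c("f1", "f2"),
                      list(f1 = c("0", "1"), f2 = c("0", "1")), adm)
  stuck <- section(c(f1 = "1"))
  expect_length(extensions(stuck, sp), 0L)
  sp2 <- innovate(sp, "extend_fiber", list(feature = "f2", values = "2"))
  # existing admissible sections survive the innovation
  expect_length(sp2$constraints, 1L)
  sp3 <- feature_space(sp2$base, sp2$fibers,
                       c(sp2$constraints, list(c(f1 = "1", f2 = "2"))))
  expect_length(extensions(stuck, sp3), 1L)
  expect_error(innovate(sp, "extend_fiber", list(feature = "f2", values = "0")),
               "already in fiber")
})

test_that("adding a feature completes or drops the constraint set", {
  adm <- list(c(f1 = "0"), c(f1 = "1"))
  sp <- feature_space("f1", list(f1 = c("0", "1")), adm)
  # singleton default: forced completion, extension counts unchanged
  sp2 <- innovate(sp, "add_feature",
                  list(feature = "f2", fiber = "x", default = "x"))
  expect_length(sp2$constraints, 2L)
  expect_length(extensions(section(c(f1 = "0")), sp2), 1L)
  # no default: refuse to broadcast, drop with a warning
  expect_warning(
    sp3 <- innovate(sp, "add_feature", list(feature = "f2", fiber = c("x", "y"))),
    "dropping the constraint set")
  expect_null(sp3$constraints)
  expect_error(innovate(sp, "add_feature", list(feature = "f1", fiber = "x")),
               "already exists")
})

test_that("amalgamation combines feathers and forelimbs into a wing", {
  sp <- feature_space(c("feathers", "forelimb", "size"),
                      list(feathers = c("absent", "present"),
                           forelimb = c("short", "extended"),
                           size = c("small", "large")))
  am <- amalgamate(sp, "feathers", "forelimb", "flight_apparatus",
                   data.frame(v1 = "present", v2 = "extended", to = "wing"))
  expect_setequal(am$space$base, c("size", "flight_apparatus"))
  expect_identical(am$space$fibers$flight_apparatus, "wing")
  flyer <- am$transport(section(c(feathers = "present", forelimb = "extended",
                                  size = "small")))
  expect_identical(unname(flyer$assignment["flight_apparatus"]), "wing")
  walker <- am$transport(section(c(feathers = "absent", forelimb = "short",
                                   size = "large")))
  expect_false("flight_apparatus" %in% names(walker$assignment))
  expect_setequal(attr(walker, "lost_features"), c("feathers", "forelimb"))
})

test_that("a total injective value map transports sections bijectively", {
  sp <- feature_space(c("a", "b"), list(a = c("0", "1"), b = c("0", "1")))
  vm <- expand.grid(v1 = c("0", "1"), v2 = c("0", "1"),
                    stringsAsFactors = FALSE)
  vm$to <- paste0(vm$v1, vm$v2)
  am <- amalgamate(sp, "a", "b", "ab", vm)
  globals <- extensions(section(character(0)), sp)
  images <- vapply(globals, function(s) format(am$transport(s)), "")
  expect_identical(anyDuplicated(images), 0L)
  expect_length(unique(images), 4L)
})

test_that("amalgamating commutes with restriction to untouched features", {
  sp <- feature_space(c("a", "b", "c"),
                      list(a = c("0", "1"), b = c("0", "1"), c = c("0", "1")))
  vm <- data.frame(v1 = c("0", "1"), v2 = c("0", "1"), to = c("p", "q"))
  am <- amalgamate(sp, "a", "b", "ab", vm)
  for (s in all_partial_sections(sp)) {
    lhs <- restrict(am$transport(s), "c")
    rhs <- am$transport(restrict(s, "c"))
    expect_true(sec_eq(lhs, rhs))
  }
})

test_that("sections_from_matrix converts rows to (partial) sections", {
  sm19 <- sections_from_matrix(complementary_rows_matrix())
  expect_length(sm19$sections, 2L)
  expect_true(all(vapply(sm19$sections, function(s)
    length(s$assignment) == 4L, TRUE)))
  expect_false(sec_eq(sm19$sections[[1]], sm19$sections[[2]]))
  sm18 <- sections_from_matrix(duplicated_rows_matrix())
  expect_true(sec_eq(sm18$sections[[1]], sm18$sections[[2]]))
  # a missing entry makes a partial section
  V <- rbind(c(1, NA, 0), c(0, 1, 1))
  M <- character_matrix(V, field = "gf2")
  sm <- sections_from_matrix(M)
  expect_length(sm$sections[[1]]$assignment, 2L)
  expect_length(sm$sections[[2]]$assignment, 3L)
})
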