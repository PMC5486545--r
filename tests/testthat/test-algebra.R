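test_that("rank of the printed example matrices matches each field", {
  expect_identical(matrix_rank(perm3_matrix()), 3L)
  expect_identical(matrix_rank(corr_rank1_matrix()), 1L)
  expect_identical(matrix_rank(corr_rank1_matrix(field = "real")), 1L)
  expect_identical(matrix_rank(ladder5_matrix()), 5L)
  expect_identical(matrix_rank(uniform_labels_matrix()), 1L)
  expect_identical(matrix_rank(overlay_matrix()), 2L)
  zero <- character_matrix(matrix(0, 3, 4), field = "integer")
  expect_identical(matrix_rank(zero), 0L)
})

test_that("exact ranks agree with the numeric rank on integer matrices", {
  set.seed(11)
  for (i in 1:50) {
    M <- random_palette_matrix(sample(2:6, 1), sample(2:6, 1), "integer")
    Mr <- character_matrix(M$values, field = "real")
    expect_identical(matrix_rank(M), matrix_rank(Mr))
  }
})

test_that("GF(2) rank can be strictly below the real rank of a 0/1 matrix", {
  # circulant of (1,1,0): rows sum to zero mod 2
  V <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  gf2 <- character_matrix(V, field = "gf2")
  real <- character_matrix(V, field = "real")
  expect_identical(matrix_rank(gf2), 2L)
  expect_identical(matrix_rank(real), 3L)
  # and generally real rank >= GF(2) rank on 0/1 matrices
  set.seed(5)
  for (i in 1:40) {
    M <- random_palette_matrix(sample(2:6, 1), sample(2:6, 1), "gf2")
    expect_gte(matrix_rank(character_matrix(M$values, field = "real")),
               matrix_rank(M))
  }
})

test_that("rank operations refuse missing entries and name the cells", {
  V <- rbind(c(1, NA), c(0, 1))
  M <- character_matrix(V, field = "gf2",
                        carrier_ids = c("sp1", "sp2"),
                        feature_ids = c("chA", "chB"))
  expect_error(matrix_rank(M), "sp1/chB")
  expect_error(rank_decompose(M), "missing")
  expect_error(cooccurrence_matrix(M), "missing")
  kept <- suppressMessages(complete_features(M))
  expect_identical(kept$feature_ids, "chA")
  expect_identical(attr(kept, "dropped"), "chB")
})

test_that("non-binary entries are rejected under gf2", {
  expect_error(character_matrix(rbind(c(0, 2)), field = "gf2"), "\\{0, 1\\}")
})

test_that("decomposition of the rank-1 example is the printed outer product", {
  d <- rank_decompose(corr_rank1_matrix())
  expect_identical(d$rank, 1L)
  expect_equal(unname(d$terms[[1]]$a), c(1, 2))
  expect_equal(unname(d$terms[[1]]$b), c(1, 2, 5))
  expect_identical(d$reconstruction_error, 0)
  expect_equal(reconstruct(d), corr_rank1_matrix()$values, ignore_attr = TRUE)
})

test_that("the two-cluster example decomposes into its printed terms", {
  d <- rank_decompose(overlay_matrix())
  expect_identical(d$rank, 2L)
  a_list <- lapply(d$terms, function(t) unname(t$a))
  b_list <- lapply(d$terms, function(t) unname(t$b))
  has_vec <- function(lst, v)
    any(vapply(lst, function(x) isTRUE(all.equal(x, v)), TRUE))
  expect_true(has_vec(a_list, c(1, 1, 1, 2, 2, 2)))
  expect_true(has_vec(a_list, c(1, 2, 3, 1, 2, 3)))
  expect_true(has_vec(b_list, c(1, 1, 0, 0)))
  expect_true(has_vec(b_list, c(0, 0, 1, 1)))
  expect_equal(reconstruct(d), overlay_matrix()$values, ignore_attr = TRUE)
})

test_that("identity decomposes into exactly n exact terms", {
  I <- character_matrix(diag(2), field = "integer")
  d <- rank_decompose(I)
  expect_identical(d$rank, 2L)
  expect_equal(reconstruct(d), diag(2), ignore_attr = TRUE)
})

test_that("exact decompositions reconstruct entrywise; rank <= min(n, m)", {
  set.seed(23)
  for (field in c("integer", "gf2")) {
    for (i in 1:40) {
      M <- random_palette_matrix(sample(1:6, 1), sample(1:6, 1), field)
      d <- rank_decompose(M)
      expect_lte(d$rank, min(dim(M$values)))
      rec <- reconstruct(d)
      expect_equal(rec, if (field == "gf2") M$values %% 2 else M$values,
                   ignore_attr = TRUE, tolerance = 1e-12)
      expect_identical(d$reconstruction_error, 0)
      if (d$rank > 0) {
        # minimality witness: both factor sets linearly independent
        expect_identical(qr(d$a_mat)$rank, d$rank)
        expect_identical(qr(t(d$b_mat))$rank, d$rank)
      }
    }
  }
})

test_that("real decompositions meet the tolerance contract", {
  set.seed(31)
  for (i in 1:20) {
    M <- random_palette_matrix(sample(2:6, 1), sample(2:6, 1), "real")
    d <- rank_decompose(M)
    expect_lte(d$reconstruction_error, 1e-8 * sqrt(sum(M$values^2)) + 1e-12)
    expect_equal(reconstruct(d), M$values, ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
})

test_that("epsilon-rank follows the Eckart-Young tail-energy rule", {
  # perturbed rank-1 matrix recovers rank 1 within a generous error bound
  pert <- corr_rank1_matrix(field = "real")
  Mp <- character_matrix(pert$values + 1e-6, field = "real")
  expect_identical(matrix_rank(Mp), 2L)   # noise makes it full rank
  expect_identical(epsilon_rank(Mp, 1e-3), 1L)
  # eps below the smallest tail energy reproduces the exact rank
  M <- perm3_matrix()
  expect_identical(epsilon_rank(M, 1e-12), matrix_rank(M))
  # eps above the total norm allows the zero matrix
  expect_identical(epsilon_rank(M, 10), 0L)
  # strictness: tail energy exactly at the bound keeps the higher rank
  D <- character_matrix(diag(c(2, 1)), field = "real")
  expect_identical(epsilon_rank(D, 1), 2L)    # tail = 1 is not < 1
  expect_identical(epsilon_rank(D, 1 + 1e-9), 1L)
  expect_error(epsilon_rank(D, -1), "positive")
  expect_error(epsilon_rank(corr_rank1_matrix(), 0.1), "exact fields")
})

test_that("epsilon-rank agrees with a brute-force truncation oracle", {
  set.seed(47)
  for (i in 1:100) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    M <- random_palette_matrix(n, m, "real")
    eps <- stats::runif(1, 0.05, 3)
    # oracle: smallest k whose best rank-k truncation is strictly within eps,
    # measured by reconstructing the truncation and taking the residual norm
    sv <- svd(M$values)
    oracle <- NA_integer_
    for (k in 0:min(n, m)) {
      approx_k <- if (k == 0) 0 * M$values else
        sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k, k) %*%
        t(sv$v[, 1:k, drop = FALSE])
      if (sqrt(sum((M$values - approx_k)^2)) < eps) { oracle <- k; break }
    }
    expect_identical(epsilon_rank(M, eps), oracle)
  }
})

test_that("character clusters match the printed cluster structure", {
  # fully correlated example: one cluster covering all features
  cl8 <- character_clusters(corr_rank1_matrix())
  expect_length(cl8, 1L)
  expect_setequal(cl8[[1]]$representative_features,
                  corr_rank1_matrix()$feature_ids)
  # two overlaid clusters: feeding on {teeth, feet}, climate on {fur, color}
  cl24 <- character_clusters(overlay_matrix())
  expect_length(cl24, 2L)
  reps <- lapply(cl24, `[[`, "representative_features")
  expect_true(any(vapply(reps, setequal, TRUE, y = c("teeth", "feet"))))
  expect_true(any(vapply(reps, setequal, TRUE, y = c("fur", "color"))))
  # clusters come ordered by decreasing carrier-factor norm
  norms <- vapply(cl24, function(x) sqrt(sum(x$carrier_factors^2)), 0)
  expect_true(all(diff(norms) <= 0))
  # identity: n singleton clusters
  cln <- character_clusters(character_matrix(diag(3), field = "integer"))
  expect_length(cln, 3L)
  expect_true(all(lengths(lapply(cln, `[[`, "representative_features")) == 1L))
  expect_error(character_clusters(corr_rank1_matrix(), eps = 0.1), "real field")
})

test_that("co-occurrence matrix matches the hand computation and Lemma", {
  P <- cooccurrence_matrix(corr_rank1_matrix())
  expect_equal(P$cooccurrence,
               rbind(c(1, 2), c(2, 4)) / 9, ignore_attr = TRUE)
  expect_identical(P$Z, 270)
  expect_equal(sum(P$cooccurrence), 1)
  expect_identical(matrix_rank(character_matrix(P$cooccurrence)), 1L)
  # 1x1 non-zero normalizes to 1
  expect_equal(cooccurrence_matrix(character_matrix(matrix(3)))$cooccurrence,
               matrix(1), ignore_attr = TRUE)
  expect_error(cooccurrence_matrix(character_matrix(matrix(0, 2, 2))),
               "degenerate")
  # Z = 0 can happen with non-zero real entries (columns summing to zero)
  expect_error(
    cooccurrence_matrix(character_matrix(rbind(1, -1), field = "real")),
    "degenerate")
})

test_that("co-occurrence is symmetric and rank-preserving on random input", {
  set.seed(61)
  for (field in c("gf2", "integer", "real")) {
    for (i in 1:60) {
      M <- random_palette_matrix(sample(2:6, 1), sample(2:6, 1), field)
      G <- M$values %*% t(M$values)
      if (sum(G) == 0) next
      P <- cooccurrence_matrix(M)
      expect_equal(P$cooccurrence, t(P$cooccurrence))
      # the frequency matrix lives over the rationals: compare real ranks
      expect_identical(
        matrix_rank(character_matrix(P$cooccurrence, field = "real")),
        matrix_rank(character_matrix(M$values, field = "real")))
    }
  }
})
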