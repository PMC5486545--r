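# Worked-example matrices from the package documentation, built in code.

perm3_matrix <- function()
  character_matrix(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)), field = "real")

corr_rank1_matrix <- function(field = "integer")
  character_matrix(rbind(c(1, 2, 5), c(2, 4, 10)), field = field)

duplicated_rows_matrix <- function()
  character_matrix(rbind(c(1, 0, 0, 1), c(1, 0, 0, 1)), field = "gf2")

complementary_rows_matrix <- function()
  character_matrix(rbind(c(1, 0, 0, 1), c(0, 1, 1, 0)), field = "gf2")

# 5x5 cladistic staircase: species i possesses characters 1..i
ladder5_matrix <- function() gen_cladistic(5)

uniform_labels_matrix <- function()
  character_matrix(rbind(c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3)),
                   field = "integer")

# feeding type (2 states) x climate (3 states), full factorial
overlay_matrix <- function()
  character_matrix(cbind(teeth = c(1, 1, 1, 2, 2, 2),
                         feet  = c(1, 1, 1, 2, 2, 2),
                         fur   = c(1, 2, 3, 1, 2, 3),
                         color = c(1, 2, 3, 1, 2, 3)),
                   field = "integer")

# random matrix with entries from a palette, by field tag
random_palette_matrix <- function(n, m, field) {
  vals <- switch(field,
    gf2     = sample(c(0, 1), n * m, replace = TRUE),
    integer = sample(-2:3, n * m, replace = TRUE),
    real    = round(stats::runif(n * m, -2, 2), 3))
  character_matrix(matrix(vals, n, m), field = field)
}

# tiny binary feature space over m features
binary_space <- function(m, constraints = NULL) {
  base <- paste0("f", seq_len(m))
  feature_space(base,
                stats::setNames(rep(list(c("0", "1")), m), base),
                constraints)
}

# all partial sections of a space (each feature: undefined or a fiber value)
all_partial_sections <- function(space) {
  opts <- lapply(space$base, function(j) c(NA_character_, space$fibers[[j]]))
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  names(grid) <- space$base
  lapply(seq_len(nrow(grid)), function(i) {
    row <- unlist(grid[i, , drop = FALSE])
    section(row[!is.na(row)])
  })
}

# equality of two sections (domain and values)
sec_eq <- function(s, t) {
  ds <- sort(names(s$assignment)); dt <- sort(names(t$assignment))
  identical(ds, dt) && all(s$assignment[ds] == t$assignment[ds])
}

# the unconstrained space with the same base and fibers
unconstrained_like <- function(space) feature_space(space$base, space$fibers)

# evaluate expr under a seed, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}
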