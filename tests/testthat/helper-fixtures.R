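# Shared helpers: small random objects built in code at test time.

# random symmetric nonnegative matrix with zero diagonal (not ultrametric)
random_distance_matrix <- function(n, labels = sprintf("sp%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 10)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# ultrametric divergence matrix drawn from a random Yule tree
random_ultrametric_matrix <- function(n, crown = 50, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  divergence_from_tree(simulate_yule_tree(n, crown, seed = seed))
}

# the three-point violation of a matrix (duplicated small oracle: direct
# brute force over triples, independent of the package internals)
brute_three_point <- function(m) {
  n <- nrow(m)
  worst <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    v <- sort(c(m[i, j], m[i, k], m[j, k]), decreasing = TRUE)
    worst <- max(worst, v[1] - v[2])
  }
  worst
}

write_species_file <- function(species, path = tempfile(fileext = ".txt")) {
  writeLines(species, path)
  path
}
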