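#' Mantel permutation test between two distance matrices
#'
#' Correlates a divergence-time matrix with a second symmetric distance
#' matrix (e.g. pairwise genetic distance) over their upper triangles, and
#' assesses significance by simultaneously permuting the rows and columns
#' of the second matrix. The p-value uses the plus-one rule
#' (observed statistic counted among the permutations), so it is never 0.
#' The default test is two-sided on |r|; the matrices must share labels and
#' label order.
#'
#' @param x Divergence-time matrix (square, symmetric, zero diagonal,
#'   labelled).
#' @param y Second distance matrix, same labels and order as `x`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed; results are reproducible given the
#'   seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Object of class `mantel_result`: list with `r`, `p_value`,
#'   `n_perm`, `seed`, `alternative`.
#' @export
mantel_test <- function(x, y, n_perm = 999, seed = NULL,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_matrix_pair(x, y)
  if (nrow(x) < 4) stop("Mantel test needs at least 4 labels")
  if (n_perm < 1) stop("n_perm must be >= 1")
  ut <- upper.tri(x)
  xv <- x[ut]
  yv <- y[ut]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in a distance triangle: Mantel r undefined")
  r_obs <- stats::cor(xv, yv)
  n <- nrow(x)
  run <- function() {
    r_perm <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      yp <- y[p, p]
      r_perm[k] <- stats::cor(xv, yp[ut])
    }
    r_perm
  }
  r_perm <- if (is.null(seed)) run() else with_seed(seed, run())
  exceed <- switch(alternative,
                   two.sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12),
                   greater = sum(r_perm >= r_obs - 1e-12),
                   less = sum(r_perm <= r_obs + 1e-12))
  structure(list(r = r_obs, p_value = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%s permutations)\n",
              x$alternative, x$r, x$p_value,
              if (is.finite(x$n_perm)) format(x$n_perm) else "all"))
  invisible(x)
}

check_matrix_pair <- function(x, y) {
  validate_divergence_matrix(x)
  if (!is.matrix(y) || !is.numeric(y)) stop("second matrix must be numeric")
  if (!identical(dim(x), dim(y))) stop("matrix dimensions differ")
  if (!identical(rownames(x), rownames(y)) ||
      !identical(colnames(x), colnames(y)))
    stop("matrix labels differ or are ordered differently")
  if (any(y < 0)) stop("second matrix must be nonnegative")
  if (max(abs(y - t(y))) > 1e-8) stop("second matrix is not symmetric")
  invisible(TRUE)
}

#' Exact Mantel test by full permutation enumeration
#'
#' Enumerates every label permutation of the second matrix (so only
#' feasible for up to 7 labels, 5040 permutations) and reports the exact
#' p-value: the fraction of permutations, identity included, whose
#' statistic is at least as extreme as the observed one. Serves as the
#' exact reference for [mantel_test()].
#'
#' @inheritParams mantel_test
#' @return Object of class `mantel_result` (`n_perm` is the number of
#'   enumerated permutations).
#' @export
mantel_exact <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_matrix_pair(x, y)
  n <- nrow(x)
  if (n < 4) stop("Mantel test needs at least 4 labels")
  if (n > 7) stop("too many labels for exact enumeration (max 7); use mantel_test()")
  ut <- upper.tri(x)
  xv <- x[ut]
  yv <- y[ut]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in a distance triangle: Mantel r undefined")
  r_obs <- stats::cor(xv, yv)
  perms <- e1071::permutations(n)
  r_all <- apply(perms, 1L, function(p) {
    yp <- y[p, p]
    stats::cor(xv, yp[ut])
  })
  exceed <- switch(alternative,
                   two.sided = sum(abs(r_all) >= abs(r_obs) - 1e-12),
                   greater = sum(r_all >= r_obs - 1e-12),
                   less = sum(r_all <= r_obs + 1e-12))
  structure(list(r = r_obs, p_value = exceed / nrow(perms),
                 n_perm = nrow(perms), seed = NULL,
                 alternative = alternative),
            class = "mantel_result")
}

#' Mantel correlogram over divergence-time classes
#'
#' Splits the pairwise divergence times into distance classes and, for each
#' class, runs a Mantel test between the second matrix and the 0/1
#' indicator of the pair's time falling in that class (same permutation
#' scheme as [mantel_test()]). Classes holding fewer than 3 pairs are
#' flagged untestable and get no statistic.
#'
#' @inheritParams mantel_test
#' @param breaks Strictly increasing numeric class bounds covering
#'   `(0, max(x)]`; when `NULL`, equal-width classes by Sturges' rule on
#'   the pair count.
#' @return Data frame of class `mantel_correlogram`: `lower_mya`,
#'   `upper_mya`, `r`, `p_value`, `n_pairs`, `testable`.
#' @export
correlogram <- function(x, y, breaks = NULL, n_perm = 999, seed = NULL) {
  check_matrix_pair(x, y)
  ut <- upper.tri(x)
  xv <- x[ut]
  if (is.null(breaks)) {
    k <- max(1L, ceiling(log2(length(xv))) + 1L)
    breaks <- seq(0, max(xv), length.out = k + 1L)
  }
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  if (breaks[1] > 0 || breaks[length(breaks)] < max(xv))
    stop("breaks must cover (0, max divergence time]")
  n_class <- length(breaks) - 1L
  out <- data.frame(lower_mya = breaks[-length(breaks)],
                    upper_mya = breaks[-1], r = NA_real_,
                    p_value = NA_real_, n_pairs = NA_integer_,
                    testable = FALSE)
  for (c_idx in seq_len(n_class)) {
    lo <- out$lower_mya[c_idx]; hi <- out$upper_mya[c_idx]
    inside <- if (c_idx == 1L) xv >= lo & xv <= hi else xv > lo & xv <= hi
    out$n_pairs[c_idx] <- sum(inside)
    if (sum(inside) < 3) next
    ind <- x * 0
    ind[ut] <- as.numeric(inside)
    ind[lower.tri(ind)] <- t(ind)[lower.tri(ind)]
    res <- mantel_test(ind, y, n_perm = n_perm, seed = seed)
    out$r[c_idx] <- res$r
    out$p_value[c_idx] <- res$p_value
    out$testable[c_idx] <- TRUE
  }
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}

#' Read / write a square labelled matrix as CSV
#'
#' The CSV carries the labels as both header row and first column.
#'
#' @param m Square labelled numeric matrix.
#' @param path CSV path.
#' @return `read_matrix_csv`: the matrix; `write_matrix_csv`: `path`,
#'   invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read matrix: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix CSV is not square")
  storage.mode(m) <- "double"
  dimnames(m) <- list(normalize_name(rownames(m)), normalize_name(colnames(m)))
  m
}

#' Write a correlogram result table as CSV
#'
#' @param cg A [correlogram()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_correlogram_csv <- function(cg, path) {
  utils::write.csv(as.data.frame(cg), path, row.names = FALSE, na = "")
  invisible(path)
}
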