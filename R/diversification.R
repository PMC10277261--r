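#' Extinction ratio
#'
#' The extinction ratio (epsilon) is the extinction rate mu divided by the
#' speciation rate lambda. The extinction-corrected crown-age rate estimator
#' is only defined for epsilon in [0, 1), so `mu >= lam` is rejected.
#'
#' @param mu Extinction rate (per MY, >= 0).
#' @param lam Speciation rate (per MY, > 0).
#' @return epsilon = mu / lam, in [0, 1).
#' @examples
#' extinction_ratio(0.5, 1.0)
#' @export
extinction_ratio <- function(mu, lam) {
  if (!is.numeric(mu) || !is.numeric(lam)) stop("rates must be numeric")
  if (any(lam <= 0)) stop("speciation rate lambda must be positive")
  if (any(mu < 0)) stop("extinction rate mu must be nonnegative")
  if (any(mu >= lam))
    stop("mu must be smaller than lambda: the crown-age estimator with ",
         "extinction requires extinction ratio epsilon = mu/lambda in [0, 1)")
  mu / lam
}

new_rate_result <- function(r, method, n, delta_t, epsilon = 0) {
  structure(list(r = r, method = method, n = n, delta_t = delta_t,
                 epsilon = epsilon),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("Net diversification rate r = %.2f per MY\n", x$r))
  cat(sprintf("  method: %s (n = %d, crown age = %g MY%s)\n",
              x$method, x$n, x$delta_t,
              if (x$method == "CROWN_WITH_EXTINCTION")
                sprintf(", epsilon = %g", x$epsilon) else ""))
  invisible(x)
}

check_clade_args <- function(n, delta_t) {
  if (length(n) != 1 || is.na(n) || n != round(n) || n < 2)
    stop("n must be a single integer >= 2 (extant species count)")
  if (length(delta_t) != 1 || is.na(delta_t) || delta_t <= 0)
    stop("delta_t must be a single positive crown age in MY")
}

#' Crown-age net diversification rate (no extinction)
#'
#' The Magallon-Sanderson crown-age estimator with zero relative extinction:
#' r = (ln n - ln 2) / delta_t, with n the total number of extant species in
#' the clade and delta_t its crown age in MY. The logarithm is natural.
#'
#' @param n Extant species count (>= 2).
#' @param delta_t Crown age in MY (> 0).
#' @return A `rate_result` with fields `r` (per MY) and `method`.
#' @examples
#' rate_crown(12, 4.73)  # r ~ 0.38
#' rate_crown(11, 9.0)   # r ~ 0.19
#' @export
rate_crown <- function(n, delta_t) {
  check_clade_args(n, delta_t)
  r <- (log(n) - log(2)) / delta_t
  new_rate_result(r, "CROWN_NO_EXTINCTION", as.integer(n), delta_t)
}

#' Crown-age net diversification rate with extinction
#'
#' The Magallon-Sanderson crown-age estimator under a relative extinction
#' ratio epsilon = mu/lambda in [0, 1):
#' \deqn{r = \frac{1}{\Delta t}\left(\log\!\Big(\frac{n(1-\varepsilon^2)}{2}
#'   + 2\varepsilon + \frac{1-\varepsilon}{2}
#'   \sqrt{n\,(n\varepsilon^2 - 8\varepsilon + 2n\varepsilon + n)}\Big)
#'   - \log 2\right)}
#' with natural logarithms. At epsilon = 0 this reduces algebraically to
#' [rate_crown()].
#'
#' @inheritParams rate_crown
#' @param epsilon Extinction ratio in [0, 1).
#' @return A `rate_result`.
#' @examples
#' rate_crown_extinction(12, 4.73, 0.5)
#' @export
rate_crown_extinction <- function(n, delta_t, epsilon) {
  check_clade_args(n, delta_t)
  if (length(epsilon) != 1 || is.na(epsilon) || epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)")
  radicand <- n * (n * epsilon^2 - 8 * epsilon + 2 * n * epsilon + n)
  if (radicand < 0)
    stop("internal error: negative radicand in crown-age estimator")
  inner <- n * (1 - epsilon^2) / 2 + 2 * epsilon +
    (1 - epsilon) / 2 * sqrt(radicand)
  r <- (log(inner) - log(2)) / delta_t
  new_rate_result(r, "CROWN_WITH_EXTINCTION", as.integer(n), delta_t, epsilon)
}

#' Diversification rate from a time tree
#'
#' Takes the crown age from an ultrametric time tree and the species count
#' from its tip count (or from `n_total`, when the tree undersamples the
#' clade's known richness), then dispatches to [rate_crown()] when
#' `epsilon = 0` or [rate_crown_extinction()] otherwise.
#'
#' @param tree Ultrametric `phylo` tree, branch lengths in MY.
#' @param n_total Optional known extant richness (>= tip count).
#' @param epsilon Extinction ratio in [0, 1); default 0.
#' @param tol Ultrametricity tolerance (MY).
#' @return A `rate_result`.
#' @export
rate_from_clade <- function(tree, n_total = NULL, epsilon = 0, tol = 0.01) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("need a tree with at least 2 tips")
  delta_t <- crown_age(tree, tol)
  n <- length(tree$tip.label)
  if (!is.null(n_total)) {
    if (n_total < n)
      stop("n_total cannot be smaller than the number of tips in the tree")
    n <- n_total
  }
  if (epsilon == 0) rate_crown(n, delta_t)
  else rate_crown_extinction(n, delta_t, epsilon)
}
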