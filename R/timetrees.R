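#' Parse / write time trees in Newick format
#'
#' `parse_newick` reads a Newick string with branch lengths (MY) into an
#' `ape` `phylo` object and checks structural requirements for a time tree:
#' at least two tips, unique tip labels, branch lengths present. Underscores
#' in labels are read back as spaces. `write_newick` is the inverse;
#' `parse_newick(write_newick(tree))` reproduces the tree.
#'
#' @param text Newick string (trailing semicolon optional on input).
#' @param tree A `phylo` tree.
#' @param digits Significant digits for branch lengths on output.
#' @return `parse_newick`: a `phylo`; `write_newick`: a Newick string.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  # locate structural defects ape reports unhelpfully
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("Newick parse error at character %d: unmatched ')'", i))
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error at character %d: %d unclosed '('",
                 length(chars), depth))
  if (!endsWith(text, ";")) text <- paste0(text, ";")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: unreadable tree text")
  if (length(tree$tip.label) < 2L) stop("a time tree needs at least 2 tips")
  tree$tip.label <- normalize_name(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("time tree must carry branch lengths (MY)")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- gsub(" ", "_", tree$tip.label)
  ape::write.tree(tree, digits = digits)
}

#' Read / write a Newick file
#' @param path File path.
#' @inheritParams parse_newick
#' @return `read_newick_file`: a `phylo`; `write_newick_file`: `path`,
#'   invisibly.
#' @export
read_newick_file <- function(path) {
  if (!file.exists(path)) stop("cannot read tree file: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname read_newick_file
#' @export
write_newick_file <- function(tree, path) {
  writeLines(write_newick(tree), path)
  invisible(path)
}

tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_along(tree$tip.label)]
}

#' Test whether a time tree is ultrametric
#'
#' A time tree is ultrametric when all root-to-tip path lengths agree; the
#' check is on the absolute spread (max depth minus min depth).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tol Maximum allowed depth spread in MY. The default 0.01 reflects
#'   the 0.1-MY precision of retrieved divergence times.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 0.01) {
  stopifnot(inherits(tree, "phylo"))
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol
}

assert_ultrametric <- function(tree, tol = 0.01) {
  if (!is_ultrametric_tree(tree, tol))
    stop(sprintf("tree is not ultrametric: root-to-tip depth spread %.4g MY exceeds tol %g",
                 max(tip_depths(tree)) - min(tip_depths(tree)), tol))
  invisible(tree)
}

#' Extract the pairwise divergence-time matrix from an ultrametric tree
#'
#' Entry (i, j) is the age of the most recent common ancestor of tips i and
#' j in MY — half the cophenetic (total path) distance on an ultrametric
#' tree. The diagonal is 0 and the maximum entry is the crown age.
#'
#' @param tree Ultrametric `phylo` tree, branch lengths in MY.
#' @param tol Ultrametricity tolerance passed to [is_ultrametric_tree()].
#' @return Symmetric numeric matrix labelled by tip names.
#' @export
divergence_from_tree <- function(tree, tol = 0.01) {
  assert_ultrametric(tree, tol)
  m <- ape::cophenetic.phylo(tree) / 2
  labs <- tree$tip.label
  m <- m[labs, labs]
  dimnames(m) <- list(normalize_name(labs), normalize_name(labs))
  diag(m) <- 0
  m[lower.tri(m)] <- t(m)[lower.tri(m)]  # exact symmetry
  m
}

# Worst three-point-condition violation in a divergence matrix: for every
# triple the two largest pairwise values must agree. Returns the violation
# magnitude and the worst triple.
three_point_violation <- function(m) {
  n <- nrow(m)
  worst <- 0
  worst_triple <- NULL
  if (n < 3) return(list(violation = 0, triple = NULL))
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    v <- sort(c(m[i, j], m[i, k], m[j, k]), decreasing = TRUE)
    gap <- v[1] - v[2]
    if (gap > worst) {
      worst <- gap
      worst_triple <- rownames(m)[c(i, j, k)]
    }
  }
  list(violation = worst, triple = worst_triple)
}

#' Reconstruct an ultrametric tree from a divergence matrix
#'
#' Average-linkage (UPGMA) agglomeration over MRCA ages: the height of each
#' merge is the size-weighted mean divergence between the merged clusters,
#' so node heights are MRCA ages in MY. For an exactly ultrametric input the
#' reconstruction is exact: `divergence_from_tree(tree_from_matrix(m))`
#' returns `m`. The input must satisfy the three-point condition (for every
#' triple of taxa the two largest pairwise times agree) within `tol`. Ties
#' are broken by merging the lexicographically smallest label pair first.
#'
#' @param m Square symmetric divergence matrix, zero diagonal, labelled.
#' @param tol Allowed three-point violation in MY.
#' @return Ultrametric `phylo` tree (internal nodes unlabelled).
#' @export
tree_from_matrix <- function(m, tol = 0.01) {
  validate_divergence_matrix(m)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 taxa to build a tree")
  tp <- three_point_violation(m)
  if (tp$violation > tol)
    stop(sprintf(
      "matrix is not ultrametric: three-point condition violated by %.4g MY for triple (%s)",
      tp$violation, paste(tp$triple, collapse = ", ")))
  labs <- rownames(m)
  d <- m
  # cluster bookkeeping: each active cluster carries a Newick fragment, a
  # size, its merge height, and a representative label (lexicographically
  # smallest member) used for deterministic tie-breaks; the tree is grown
  # as Newick text and parsed at the end, with branch lengths printed at
  # %.17g so double precision survives the round trip
  active <- seq_len(n)               # indices into d
  frag <- gsub(" ", "_", labs)
  size <- rep(1L, n)
  height <- rep(0, n)
  rep_lab <- labs
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    # find minimal pair; deterministic lexicographic tie-break
    best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dij <- d[active[i], active[j]]
      lab_pair <- sort(c(rep_lab[i], rep_lab[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (lab_pair[1] < best$lab[1] ||
            (lab_pair[1] == best$lab[1] && lab_pair[2] < best$lab[2])))) {
        best <- list(i = i, j = j, d = dij, lab = lab_pair)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d
    merged <- sprintf("(%s:%.17g,%s:%.17g)",
                      frag[i], h - height[i], frag[j], h - height[j])
    # UPGMA update: size-weighted average distance to the merged cluster
    ai <- active[i]; aj <- active[j]
    wi <- size[i]; wj <- size[j]
    others <- active[-c(i, j)]
    if (length(others)) {
      newd <- (wi * d[ai, others] + wj * d[aj, others]) / (wi + wj)
      d[ai, others] <- newd
      d[others, ai] <- newd
    }
    # cluster j dies, i becomes the merged cluster
    frag[i] <- merged
    size[i] <- wi + wj
    height[i] <- h
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- active[-j]
    frag <- frag[-j]; size <- size[-j]
    height <- height[-j]; rep_lab <- rep_lab[-j]
  }
  parse_newick(paste0(frag[1], ";"))
}

#' Crown age of an ultrametric tree
#'
#' The age of the deepest split among the tree's tips (root height), equal
#' to the maximum pairwise divergence time in the tree.
#'
#' @inheritParams divergence_from_tree
#' @return Crown age in MY.
#' @export
crown_age <- function(tree, tol = 0.01) {
  assert_ultrametric(tree, tol)
  max(tip_depths(tree))
}

#' ASCII preview of a tree topology
#'
#' Deterministic text rendering of the branching order with labelled tips,
#' one line per tip plus connector lines.
#'
#' @param tree A `phylo` tree.
#' @return Character scalar (multi-line); also printed when called
#'   interactively via `cat`.
#' @export
ascii_preview <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  render <- function(node, prefix, is_last) {
    head <- if (nzchar(prefix) || !is_last) {
      paste0(prefix, if (is_last) "`-- " else "+-- ")
    } else "+-- "
    if (node <= n) return(paste0(head, tree$tip.label[node]))
    ch <- kids[[as.character(node)]]
    sub_prefix <- paste0(prefix, if (is_last) "    " else "|   ")
    lines <- c(paste0(head, "+"))
    for (idx in seq_along(ch))
      lines <- c(lines, render(ch[idx], sub_prefix, idx == length(ch)))
    lines
  }
  ch <- kids[[as.character(root)]]
  lines <- "*"
  for (idx in seq_along(ch))
    lines <- c(lines, render(ch[idx], "", idx == length(ch)))
  paste(lines, collapse = "\n")
}
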