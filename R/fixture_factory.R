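#' Common-name aliases for the packaged example species
#'
#' The packaged four-species example table is keyed by scientific binomials;
#' the corresponding English common names are accepted anywhere a species
#' name is looked up against the fixture backend.
#'
#' @return Named character vector mapping common name to binomial.
#' @export
species_aliases <- function() {
  c("Lazuli bunting"       = "Passerina amoena",
    "Malachite kingfisher" = "Corythornis cristatus",
    "Amethyst sunbird"     = "Chalcomitra amethystine",
    "Emerald cuckoo"       = "Chrysococcyx cupreus")
}

#' Resolve a common-name alias to its binomial
#'
#' @param name Species name (common or scientific), normalized or not.
#' @return The canonical binomial when `name` is a known common name,
#'   otherwise `name` unchanged (normalized).
#' @export
resolve_species_alias <- function(name) {
  name <- normalize_name(name)
  al <- species_aliases()
  hit <- match(name, names(al))
  ifelse(is.na(hit), name, unname(al[hit]))
}

#' The packaged four-species example table
#'
#' Returns the 16-row FULL pairwise table for the four-bird example set
#' (Lazuli bunting, Malachite kingfisher, Amethyst sunbird, Emerald cuckoo):
#' zero diagonal; off-diagonal median times 70.0, 27.6 and 80.0 MY with their
#' confidence intervals (64.5-80.0, 25.4-38.1, 73.7-97.3) and study counts
#' (16, 5, 3). Taxa are keyed by binomial; common names resolve through
#' [resolve_species_alias()].
#'
#' @return A [pairwise_table()] in FULL mode.
#' @export
table1_fixture <- function() {
  sp <- unname(species_aliases())  # amoena, cristatus, amethystine, cupreus
  vals <- list(
    list("Passerina amoena", "Corythornis cristatus", 70.0, 64.5, 80.0, 16),
    list("Passerina amoena", "Chalcomitra amethystine", 27.6, 25.4, 38.1, 5),
    list("Passerina amoena", "Chrysococcyx cupreus", 80.0, 73.7, 97.3, 3),
    list("Corythornis cristatus", "Chalcomitra amethystine", 70.0, 64.5, 80.0, 16),
    list("Corythornis cristatus", "Chrysococcyx cupreus", 80.0, 73.7, 97.3, 3),
    list("Chalcomitra amethystine", "Chrysococcyx cupreus", 80.0, 73.7, 97.3, 3))
  up <- do.call(rbind, lapply(vals, function(v)
    data.frame(taxon_a = v[[1]], taxon_b = v[[2]], time_mya = v[[3]],
               ci_low_mya = v[[4]], ci_high_mya = v[[5]], n_studies = v[[6]],
               stringsAsFactors = FALSE)))
  full <- expand.grid(b = sp, a = sp, stringsAsFactors = FALSE)[, c("a", "b")]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = " | ")
  hit <- match(key(full$a, full$b), key(up$taxon_a, up$taxon_b))
  rows <- data.frame(
    taxon_a = full$a, taxon_b = full$b,
    time_mya = ifelse(full$a == full$b, 0, up$time_mya[hit]),
    ci_low_mya = ifelse(full$a == full$b, NA_real_, up$ci_low_mya[hit]),
    ci_high_mya = ifelse(full$a == full$b, NA_real_, up$ci_high_mya[hit]),
    n_studies = ifelse(full$a == full$b, NA_real_, up$n_studies[hit]),
    stringsAsFactors = FALSE)
  pairwise_table(rows, species = sp, mode = "FULL")
}

#' Look up one pair in a pairwise table
#'
#' Accepts common-name aliases for the packaged example species.
#'
#' @param table A [pairwise_table()].
#' @param a,b Species names.
#' @return The matching row (one-row data frame), or `NULL` when absent.
#' @export
lookup_pair <- function(table, a, b) {
  a <- resolve_species_alias(a); b <- resolve_species_alias(b)
  hit <- which((table$taxon_a == a & table$taxon_b == b) |
                 (table$taxon_a == b & table$taxon_b == a))
  if (!length(hit)) return(NULL)
  as.data.frame(table)[hit[1], , drop = FALSE]
}

# Runs `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a pure-birth (Yule) time tree with a fixed crown age
#'
#' Simulates a pure-birth tree conditioned on the number of tips, then
#' rescales all branch lengths so the crown (root) age equals
#' `crown_age_mya` exactly. The output is ultrametric by construction and
#' deterministic for a fixed seed.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param crown_age_mya Target crown age in MY (> 0).
#' @param seed Integer RNG seed.
#' @param tip_labels Optional character vector of tip labels (length
#'   `n_tips`); defaults to `t1..tn`.
#' @return An ultrametric `phylo` tree with branch lengths in MY.
#' @export
simulate_yule_tree <- function(n_tips, crown_age_mya, seed, tip_labels = NULL) {
  stopifnot(n_tips >= 2, crown_age_mya > 0)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (crown_age_mya / depth)
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_tips)
    tree$tip.label <- gsub(" ", "_", normalize_name(tip_labels))
  }
  tree
}

#' Inject controlled corruption into a pairwise table
#'
#' Blanks the divergence time of named pairs (both orderings in a FULL
#' table) and/or shifts the reverse-ordering value of one pair to create a
#' detectable asymmetry. Used to exercise the validation workflow.
#'
#' @param table A [pairwise_table()].
#' @param drop List of 2-element character vectors naming pairs whose time
#'   becomes missing.
#' @param skew Optional list with elements `pair` (2-element character
#'   vector) and `delta` (MY): the (b, a) row's time is shifted by `delta`.
#' @return The corrupted [pairwise_table()].
#' @export
corrupt_table <- function(table, drop = list(), skew = NULL) {
  find_rows <- function(a, b, ordered = FALSE) {
    a <- resolve_species_alias(a); b <- resolve_species_alias(b)
    if (ordered)
      hit <- which(table$taxon_a == a & table$taxon_b == b)
    else
      hit <- which((table$taxon_a == a & table$taxon_b == b) |
                     (table$taxon_a == b & table$taxon_b == a))
    if (!length(hit)) stop(sprintf("pair (%s, %s) not present in table", a, b))
    hit
  }
  for (pr in drop)
    table$time_mya[find_rows(pr[1], pr[2])] <- NA_real_
  if (!is.null(skew)) {
    hit <- find_rows(skew$pair[2], skew$pair[1], ordered = TRUE)
    table$time_mya[hit] <- table$time_mya[hit] + skew$delta
  }
  table
}
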