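#' Normalize a species name
#'
#' Canonicalises a raw species-name string: underscores become spaces,
#' runs of internal whitespace collapse to a single space, and leading or
#' trailing whitespace is stripped. Case is preserved.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_name("Passerina_amoena ")
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw)) stop("species names must be character")
  out <- gsub("_", " ", raw)
  out <- gsub("[[:space:]]+", " ", out)
  out <- trimws(out)
  if (any(!nzchar(out) | is.na(out)))
    stop("unusable species entry: empty name after normalization")
  out
}

#' Read a species list from a text file
#'
#' One binomial per line; blank lines are ignored, names are normalized
#' with [normalize_name()], and duplicates are dropped (keeping the first
#' occurrence) with a warning. Input order is preserved.
#'
#' @param path Path to a plain-text species list.
#' @return Character vector of normalized species names.
#' @export
read_species_list <- function(path) {
  if (!file.exists(path)) stop("cannot read species list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no usable species names in ", path)
  nm <- normalize_name(lines)
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    warning("dropping duplicate species (keeping first occurrence): ",
            paste(dup, collapse = ", "))
    nm <- nm[!duplicated(nm)]
  }
  nm
}

#' Construct a pairwise divergence-time table
#'
#' A `pairwise_table` is the long-format ("vectorized") representation of a
#' divergence-time matrix: one row per taxon pair with the divergence time in
#' millions of years (MY), optional confidence-interval bounds and study
#' counts. Two layouts exist: `"FULL"` holds all n^2 ordered pairs including
#' self-pairs (time 0); `"UNORDERED"` holds each of the n(n-1)/2 distinct
#' unordered pairs once.
#'
#' @param rows Data frame with columns `taxon_a`, `taxon_b`, `time_mya` and
#'   optionally `ci_low_mya`, `ci_high_mya`, `n_studies`. `NA` in `time_mya`
#'   marks a missing (unretrieved) value.
#' @param species Optional character vector fixing the species order;
#'   defaults to first-appearance order in `rows`.
#' @param mode `"FULL"` or `"UNORDERED"`.
#' @return An object of class `pairwise_table` (a data frame with `species`
#'   and `mode` attributes).
#' @export
pairwise_table <- function(rows, species = NULL, mode = c("FULL", "UNORDERED")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(rows))
  need <- c("taxon_a", "taxon_b", "time_mya")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("rows lack mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in c("ci_low_mya", "ci_high_mya", "n_studies"))
    if (is.null(rows[[col]])) rows[[col]] <- rep(NA_real_, nrow(rows))
  rows <- rows[, c("taxon_a", "taxon_b", "time_mya",
                   "ci_low_mya", "ci_high_mya", "n_studies")]
  rows$taxon_a <- normalize_name(rows$taxon_a)
  rows$taxon_b <- normalize_name(rows$taxon_b)
  rows$time_mya <- as.numeric(rows$time_mya)
  rows$ci_low_mya <- as.numeric(rows$ci_low_mya)
  rows$ci_high_mya <- as.numeric(rows$ci_high_mya)
  rows$n_studies <- as.numeric(rows$n_studies)
  if (is.null(species))
    species <- unique(c(rbind(rows$taxon_a, rows$taxon_b)))
  else
    species <- normalize_name(species)
  structure(rows, species = species, mode = mode,
            class = c("pairwise_table", "data.frame"))
}

#' @export
as.data.frame.pairwise_table <- function(x, ...) {
  attributes(x) <- list(names = names(unclass(x)),
                        row.names = .row_names_info(x, type = 0L),
                        class = "data.frame")
  x
}

#' @export
print.pairwise_table <- function(x, ...) {
  cat(sprintf("Pairwise divergence table: %d species, %d rows (%s mode)\n",
              length(attr(x, "species")), nrow(x), attr(x, "mode")))
  print.data.frame(utils::head(as.data.frame(x), 12), row.names = FALSE)
  if (nrow(x) > 12) cat("... ", nrow(x) - 12, " more rows\n", sep = "")
  invisible(x)
}

table_species <- function(table) attr(table, "species")
table_mode <- function(table) attr(table, "mode")

validate_pairwise_table <- function(table) {
  sp <- table_species(table)
  mode <- table_mode(table)
  n <- length(sp)
  if (anyDuplicated(sp)) stop("duplicate species in table")
  key <- paste(table$taxon_a, table$taxon_b, sep = " | ")
  if (anyDuplicated(key))
    stop("duplicate (taxon_a, taxon_b) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (mode == "FULL" && nrow(table) != n * n)
    stop(sprintf("FULL table over %d species must have %d rows, found %d",
                 n, n * n, nrow(table)))
  if (mode == "UNORDERED" && nrow(table) != n * (n - 1) / 2)
    stop(sprintf("UNORDERED table over %d species must have %d rows, found %d",
                 n, n * (n - 1) / 2, nrow(table)))
  self <- table$taxon_a == table$taxon_b
  bad_self <- self & !is.na(table$time_mya) & table$time_mya != 0
  if (any(bad_self))
    stop("self-pairs must have divergence time 0: ",
         paste(table$taxon_a[bad_self], collapse = ", "))
  has_ci <- !is.na(table$ci_low_mya) & !is.na(table$ci_high_mya)
  if (any(has_ci & table$ci_low_mya > table$ci_high_mya))
    stop("CI lower bound exceeds upper bound")
  invisible(table)
}

#' Convert a pairwise table to a square divergence matrix
#'
#' Builds the symmetric n x n matrix of divergence times (MY, zero diagonal)
#' from a `pairwise_table`. Every unordered pair of the table's species must
#' carry a non-missing time. When a FULL table supplies both orderings of a
#' pair, they must agree within `tol`; the value with `taxon_a` earlier in
#' species order is stored.
#'
#' @param table A [pairwise_table()].
#' @param tol Tolerance (MY) for agreement between the two orderings of a
#'   pair. Defaults to 0.05 since retrieved times carry one decimal.
#' @return Numeric matrix with species labels as dimnames.
#' @export
table_to_matrix <- function(table, tol = 0.05) {
  validate_pairwise_table(table)
  sp <- table_species(table)
  n <- length(sp)
  m <- matrix(NA_real_, n, n, dimnames = list(sp, sp))
  diag(m) <- 0
  ia <- match(table$taxon_a, sp)
  ib <- match(table$taxon_b, sp)
  if (anyNA(ia) || anyNA(ib)) stop("table row names a taxon absent from the species list")
  for (k in seq_len(nrow(table))) {
    i <- ia[k]; j <- ib[k]
    if (i == j) next
    t <- table$time_mya[k]
    if (is.na(t)) next
    lo <- min(i, j); hi <- max(i, j)
    prev <- m[lo, hi]
    if (!is.na(prev)) {
      if (abs(prev - t) > tol)
        stop(sprintf(
          "conflicting divergence times for pair (%s, %s): %g vs %g (tol %g)",
          sp[lo], sp[hi], prev, t, tol))
      if (i == lo) m[lo, hi] <- t  # the a-before-b ordering wins
    } else {
      m[lo, hi] <- t
    }
  }
  absent <- which(upper.tri(m) & is.na(m), arr.ind = TRUE)
  if (nrow(absent) > 0) {
    pairs <- apply(absent, 1L, function(idx)
      sprintf("(%s, %s)", sp[idx[1]], sp[idx[2]]))
    stop("missing divergence time for pair(s): ", paste(pairs, collapse = ", "))
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

validate_divergence_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) stop("divergence matrix must be numeric")
  if (nrow(m) != ncol(m)) stop("divergence matrix must be square")
  labs <- rownames(m)
  if (is.null(labs) || anyDuplicated(labs)) stop("matrix needs unique row/col labels")
  if (!identical(labs, colnames(m))) stop("row and column labels differ")
  if (any(m < 0)) stop("divergence times must be nonnegative")
  if (any(diag(m) != 0)) stop("divergence matrix diagonal must be exactly 0")
  if (max(abs(m - t(m))) > tol) stop("divergence matrix is not symmetric")
  invisible(m)
}

#' Flatten a divergence matrix into a pairwise table
#'
#' Inverse of [table_to_matrix()]. `"FULL"` emits all n^2 ordered pairs in
#' row-major label order, self-pairs at time 0; `"UNORDERED"` emits the
#' n(n-1)/2 pairs with `taxon_a` preceding `taxon_b` in label order.
#'
#' @param m Square symmetric divergence matrix with labels.
#' @param mode `"FULL"` or `"UNORDERED"`.
#' @return A [pairwise_table()].
#' @export
matrix_to_table <- function(m, mode = c("FULL", "UNORDERED")) {
  mode <- match.arg(mode)
  validate_divergence_matrix(m)
  labs <- rownames(m)
  n <- length(labs)
  if (mode == "FULL") {
    idx <- expand.grid(j = seq_len(n), i = seq_len(n))[, c("i", "j")]
  } else {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    idx <- data.frame(i = idx[, 1], j = idx[, 2])
    idx <- idx[order(idx$i, idx$j), , drop = FALSE]
  }
  rows <- data.frame(
    taxon_a = labs[idx$i], taxon_b = labs[idx$j],
    time_mya = m[cbind(idx$i, idx$j)],
    stringsAsFactors = FALSE)
  pairwise_table(rows, species = labs, mode = mode)
}

#' Find missing divergence values in a pairwise table
#'
#' Reports every row whose time is missing plus every unordered pair of the
#' table's species list absent from the table altogether. An empty result
#' means the table is complete and [table_to_matrix()] will succeed.
#'
#' @param table A [pairwise_table()].
#' @return Data frame with columns `taxon_a`, `taxon_b` (possibly 0 rows).
#' @export
find_missing <- function(table) {
  sp <- table_species(table)
  n <- length(sp)
  canon <- function(a, b) {
    ia <- match(a, sp); ib <- match(b, sp)
    swap <- ia > ib
    data.frame(taxon_a = ifelse(swap, b, a), taxon_b = ifelse(swap, a, b),
               stringsAsFactors = FALSE)
  }
  out <- canon(character(), character())
  blank <- !is.na(match(table$taxon_a, sp)) & is.na(table$time_mya) &
    table$taxon_a != table$taxon_b
  if (any(blank))
    out <- rbind(out, canon(table$taxon_a[blank], table$taxon_b[blank]))
  if (n >= 2) {
    all_pairs <- t(utils::combn(sp, 2L))
    have <- unique(rbind(
      canon(table$taxon_a[table$taxon_a != table$taxon_b],
            table$taxon_b[table$taxon_a != table$taxon_b]),
      make.row.names = FALSE))
    key_all <- paste(all_pairs[, 1], all_pairs[, 2], sep = " | ")
    key_have <- paste(have$taxon_a, have$taxon_b, sep = " | ")
    absent <- !(key_all %in% key_have)
    if (any(absent))
      out <- rbind(out, data.frame(taxon_a = all_pairs[absent, 1],
                                   taxon_b = all_pairs[absent, 2],
                                   stringsAsFactors = FALSE))
  }
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Write / read a pairwise table as CSV
#'
#' The on-disk form is the three-column vectorized matrix: mandatory columns
#' `"Taxa 1"`, `"Taxa 2"`, `"Divergence time"`, optional `"CI_low"`,
#' `"CI_high"`, `"Studies"`. Missing times are empty fields; the strings
#' `"NA"`, `"n. a"` and `"n.a"` are accepted on read (mapped to 0 for
#' self-pair times, missing otherwise). Times are plain decimals in MY.
#'
#' @param table A [pairwise_table()].
#' @param path Output / input CSV path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   returns a [pairwise_table()].
#' @export
write_table_csv <- function(table, path) {
  validate_pairwise_table(table)
  df <- data.frame(
    `Taxa 1` = table$taxon_a, `Taxa 2` = table$taxon_b,
    `Divergence time` = table$time_mya,
    CI_low = table$ci_low_mya, CI_high = table$ci_high_mya,
    Studies = table$n_studies, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("Taxa 1", "Taxa 2", "Divergence time"))
    if (is.null(df[[col]]))
      stop("CSV is missing mandatory column \"", col, "\"")
  na_tokens <- c("", "NA", "n. a", "n.a", "n. a.")
  parse_num <- function(x, what) {
    x <- trimws(x)
    out <- rep(NA_real_, length(x))
    keep <- !(x %in% na_tokens)
    val <- suppressWarnings(as.numeric(x[keep]))
    if (anyNA(val)) {
      bad <- which(keep)[is.na(val)]
      stop(sprintf("non-numeric %s at data row %d: \"%s\"",
                   what, bad[1], x[bad[1]]))
    }
    out[keep] <- val
    out
  }
  a <- normalize_name(df[["Taxa 1"]])
  b <- normalize_name(df[["Taxa 2"]])
  tm <- parse_num(df[["Divergence time"]], "divergence time")
  tm[a == b & is.na(tm)] <- 0  # diagonal "n. a" means zero self-divergence
  rows <- data.frame(taxon_a = a, taxon_b = b, time_mya = tm,
                     stringsAsFactors = FALSE)
  if (!is.null(df[["CI_low"]])) rows$ci_low_mya <- parse_num(df[["CI_low"]], "CI_low")
  if (!is.null(df[["CI_high"]])) rows$ci_high_mya <- parse_num(df[["CI_high"]], "CI_high")
  if (!is.null(df[["Studies"]])) rows$n_studies <- parse_num(df[["Studies"]], "Studies")
  sp <- unique(c(rbind(rows$taxon_a, rows$taxon_b)))
  n <- length(sp)
  mode <- if (nrow(rows) == n * n) "FULL" else "UNORDERED"
  pairwise_table(rows, species = sp, mode = mode)
}
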