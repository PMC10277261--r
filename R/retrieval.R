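#' Backend contract for divergence-time retrieval
#'
#' A backend is any object (class `divtime_backend`) implementing the
#' retrieval generics [check_availability()], [get_divergence()],
#' [batch_divergence()], [repair_missing()], [get_timetree()] and
#' [get_timeline()], subject to two invariants: `get_divergence(a, b)` and
#' `get_divergence(b, a)` report the same time, and a self-query on a known
#' species reports time 0.
#'
#' The package ships one complete implementation, the offline
#' [fixture_backend()], which serves the packaged four-species example
#' table, the thrush/fairywren example pair (35 MY) and two synthetic genus
#' time trees. A client for the live TimeTree web resource is a second
#' conforming implementation a user may supply (same generics, an
#' `id` field, polite rate limiting); no network transport is included
#' here, and [live_backend()] only documents that contract.
#'
#' Failed lookups are value-level outcomes, not exceptions: an unresolved
#' pair carries a missing time plus a substitution record (columns
#' `requested`, `resolved`, `note`) so batch runs always complete.
#'
#' @name backend-contract
NULL

substitution_record <- function(requested, resolved = NA_character_, note = "") {
  data.frame(requested = requested, resolved = resolved, note = note,
             stringsAsFactors = FALSE)
}

no_substitutions <- function() {
  substitution_record(character(), character(), character())
}

#' Offline fixture retrieval backend
#'
#' An in-memory backend serving packaged example data: the four-species
#' pairwise table (zero diagonal; 70.0 / 27.6 / 80.0 MY medians with CIs and
#' study counts), the Swainson's thrush x Superb fairywren pair at 35 MY,
#' and two synthetic ultrametric genus trees (12 Catharus-like tips, crown
#' 4.73 MY; 11 Malurus-like tips, crown 9.0 MY). Divergence times between
#' two tips of the same fixture tree are read off the tree.
#'
#' @return An object of class `c("fixture_backend", "divtime_backend")`.
#' @export
fixture_backend <- function() {
  t1 <- table1_fixture()
  pairs <- as.data.frame(t1)[t1$taxon_a != t1$taxon_b, , drop = FALSE]
  keep <- match(pairs$taxon_a, table_species(t1)) <
    match(pairs$taxon_b, table_species(t1))
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- rbind(pairs, data.frame(
    taxon_a = "Catharus ustulatus", taxon_b = "Malurus cyaneus",
    time_mya = 35, ci_low_mya = NA_real_, ci_high_mya = NA_real_,
    n_studies = NA_real_, stringsAsFactors = FALSE))
  trees <- list()
  for (genus in c("Catharus", "Malurus")) {
    f <- system.file("extdata",
                     sprintf("genus_%s_synthetic.nwk", tolower(genus)),
                     package = "divtime")
    if (nzchar(f)) trees[[genus]] <- read_newick_file(f)
  }
  structure(list(id = "fixture", pairs = pairs, trees = trees),
            class = c("fixture_backend", "divtime_backend"))
}

#' Live TimeTree backend (contract only)
#'
#' Placeholder documenting the second backend of the
#' \link[=backend-contract]{backend contract}: a client submitting queries
#' to the TimeTree web resource. A conforming implementation must provide
#' the same generics as [fixture_backend()], wait at least 1 s between
#' requests and retry transient failures (3 attempts, exponential backoff).
#' No network transport ships with this package, so calling this function
#' is an error.
#'
#' @export
live_backend <- function() {
  stop("no live web transport ships with this package; ",
       "implement the backend generics (see ?`backend-contract`) ",
       "against the live resource, or use fixture_backend()")
}

# every species the fixture backend knows at species rank
fixture_species <- function(backend) {
  unique(c(backend$pairs$taxon_a, backend$pairs$taxon_b,
           unlist(lapply(backend$trees, function(tr) tr$tip.label),
                  use.names = FALSE)))
}

#' Check data availability for a species
#'
#' @param backend A backend (see \link[=backend-contract]{backend-contract}).
#' @param species One species name (common-name aliases accepted).
#' @return One-row data frame with columns `species`, `available`.
#' @export
check_availability <- function(backend, species) UseMethod("check_availability")

#' @export
check_availability.fixture_backend <- function(backend, species) {
  sp <- resolve_species_alias(species)
  data.frame(species = normalize_name(species),
             available = sp %in% fixture_species(backend),
             stringsAsFactors = FALSE)
}

#' Check data availability for a species list
#'
#' One record per input name, input order preserved. When `out` is given, a
#' CSV with columns `"Species"`, `"Availability"` (strings `"Available"` /
#' `"Not Available"`) is written.
#'
#' @inheritParams check_availability
#' @param species Character vector of species names (non-empty).
#' @param out Optional CSV output path.
#' @return Data frame with columns `species`, `available`.
#' @export
check_availability_list <- function(backend, species, out = NULL) {
  if (length(species) == 0) stop("empty species list")
  res <- do.call(rbind, lapply(species, function(s) {
    tryCatch(check_availability(backend, s),
             error = function(e) data.frame(
               species = normalize_name(s), available = FALSE,
               stringsAsFactors = FALSE))
  }))
  if (!is.null(out)) {
    utils::write.csv(
      data.frame(Species = res$species,
                 Availability = ifelse(res$available, "Available", "Not Available"),
                 check.names = FALSE),
      out, row.names = FALSE)
  }
  res
}

#' Divergence time for one species pair
#'
#' Symmetric in its arguments; a self-query on a known species reports 0.
#' When either species is unknown to the backend the result is an
#' "unresolved pair": the time is `NA` and a substitution record (attribute
#' `"substitution"`) names the species that failed, so batch callers can
#' keep going.
#'
#' @inheritParams check_availability
#' @param a,b Species names (common-name aliases accepted).
#' @return One-row data frame (`taxon_a`, `taxon_b`, `time_mya`,
#'   `ci_low_mya`, `ci_high_mya`, `n_studies`) with a `"substitution"`
#'   attribute holding a 0-row or 1+-row substitution table.
#' @export
get_divergence <- function(backend, a, b) UseMethod("get_divergence")

#' @export
get_divergence.fixture_backend <- function(backend, a, b) {
  a_raw <- normalize_name(a); b_raw <- normalize_name(b)
  a <- resolve_species_alias(a_raw); b <- resolve_species_alias(b_raw)
  known <- c(a, b) %in% fixture_species(backend)
  result <- function(time, lo = NA_real_, hi = NA_real_, ns = NA_real_,
                     subs = no_substitutions()) {
    out <- data.frame(taxon_a = a_raw, taxon_b = b_raw, time_mya = time,
                      ci_low_mya = lo, ci_high_mya = hi, n_studies = ns,
                      stringsAsFactors = FALSE)
    attr(out, "substitution") <- subs
    out
  }
  if (!all(known)) {
    bad <- unique(c(a, b)[!known])
    return(result(NA_real_, subs = do.call(rbind, lapply(bad, function(s)
      substitution_record(s, NA_character_, "species not in backend")))))
  }
  if (a == b) return(result(0))
  p <- backend$pairs
  hit <- which((p$taxon_a == a & p$taxon_b == b) |
                 (p$taxon_a == b & p$taxon_b == a))
  if (length(hit)) {
    k <- hit[1]
    return(result(p$time_mya[k], p$ci_low_mya[k], p$ci_high_mya[k],
                  p$n_studies[k]))
  }
  for (tr in backend$trees) {
    if (all(c(a, b) %in% tr$tip.label)) {
      m <- divergence_from_tree(tr)
      return(result(m[a, b]))
    }
  }
  result(NA_real_,
         subs = substitution_record(paste(a, "x", b), NA_character_,
                                    "no shared record for this pair"))
}

#' Batch divergence-time retrieval over a species list
#'
#' Iterates over the pair set implied by `mode` (`"FULL"`: all ordered
#' pairs including self-pairs, outer loop on `taxon_a` in input order;
#' `"UNORDERED"`: each distinct pair once) and queries the backend for each.
#' Unresolved pairs get a missing time and a substitution record; the run
#' never aborts on a single failure.
#'
#' @inheritParams check_availability_list
#' @param mode `"FULL"` or `"UNORDERED"`.
#' @return A [pairwise_table()] with attribute `"substitutions"` (data frame
#'   of substitution records, 0 rows when everything resolved).
#' @export
batch_divergence <- function(backend, species, mode = c("FULL", "UNORDERED")) {
  mode <- match.arg(mode)
  species <- normalize_name(species)
  species <- species[!duplicated(species)]
  if (length(species) < 2) stop("need at least 2 species for batch retrieval")
  resolved <- resolve_species_alias(species)
  avail <- check_availability_list(backend, species)
  if (!any(avail$available)) stop("none of the requested species is known to the backend")
  n <- length(species)
  if (mode == "FULL") {
    idx <- expand.grid(j = seq_len(n), i = seq_len(n))[, c("i", "j")]
  } else {
    idx <- as.data.frame(t(utils::combn(seq_len(n), 2L)))
    names(idx) <- c("i", "j")
  }
  subs <- no_substitutions()
  rows <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    res <- get_divergence(backend, species[idx$i[k]], species[idx$j[k]])
    s <- attr(res, "substitution")
    if (nrow(s)) subs <- rbind(subs, s)
    rows[[k]] <- as.data.frame(res)
  }
  tab <- pairwise_table(do.call(rbind, rows), species = species, mode = mode)
  attr(tab, "substitutions") <- unique(subs)
  tab
}

#' Re-query and repair missing values in a pairwise table
#'
#' Every pair whose time is missing is re-queried against the backend;
#' resolved values (time, CI, study count) are filled in place. Pairs that
#' still fail remain missing and are listed in the returned table's
#' `"unrepaired"` attribute. A table with no missing values is returned
#' unchanged.
#'
#' @inheritParams check_availability
#' @param table A [pairwise_table()].
#' @return The repaired [pairwise_table()].
#' @export
repair_missing <- function(backend, table) {
  miss <- which(is.na(table$time_mya))
  unrepaired <- find_missing(table)[0, ]
  for (k in miss) {
    res <- get_divergence(backend, table$taxon_a[k], table$taxon_b[k])
    if (!is.na(res$time_mya)) {
      table$time_mya[k] <- res$time_mya
      table$ci_low_mya[k] <- res$ci_low_mya
      table$ci_high_mya[k] <- res$ci_high_mya
      table$n_studies[k] <- res$n_studies
    } else {
      unrepaired <- rbind(unrepaired,
                          data.frame(taxon_a = table$taxon_a[k],
                                     taxon_b = table$taxon_b[k],
                                     stringsAsFactors = FALSE))
    }
  }
  attr(table, "unrepaired") <- unique(unrepaired)
  table
}

#' Retrieve a time tree for a taxon or species list
#'
#' A single taxon query (e.g. a genus name) returns that group's packaged
#' tree. A list of species is resolved pair by pair: the divergence matrix
#' over the resolvable species is assembled through [batch_divergence()]
#' and turned into an ultrametric tree with [tree_from_matrix()]. Species
#' that cannot be resolved are dropped and reported in the substitution
#' table.
#'
#' @inheritParams check_availability
#' @param query One taxon name, or a character vector of >= 2 species.
#' @return List with elements `newick` (tree text, branch lengths in MY)
#'   and `substitutions` (data frame).
#' @export
get_timetree <- function(backend, query) UseMethod("get_timetree")

#' @export
get_timetree.fixture_backend <- function(backend, query) {
  query <- normalize_name(query)
  if (length(query) == 1L) {
    if (query %in% names(backend$trees))
      return(list(newick = write_newick(backend$trees[[query]]),
                  substitutions = no_substitutions()))
    stop("cannot resolve taxon query to at least 2 tips: ", query)
  }
  query <- query[!duplicated(query)]
  avail <- check_availability_list(backend, query)
  subs <- no_substitutions()
  if (any(!avail$available))
    subs <- do.call(rbind, lapply(query[!avail$available], function(s)
      substitution_record(s, NA_character_, "dropped: species not in backend")))
  keep <- query[avail$available]
  if (length(keep) < 2)
    stop("cannot resolve the species list to at least 2 tips")
  tab <- batch_divergence(backend, keep, mode = "UNORDERED")
  m <- table_to_matrix(tab)
  tree <- tree_from_matrix(m)
  list(newick = write_newick(tree), substitutions = unique(rbind(
    subs, attr(tab, "substitutions"))))
}

#' Retrieve an evolutionary timeline image for a species
#'
#' Writes a JPEG timeline for one species. The fixture backend generates a
#' placeholder panel — a labelled geological-style time axis carrying the
#' species name and the backend's divergence records for it — standing in
#' for the richer artwork a live resource would return.
#'
#' @inheritParams check_availability
#' @param out Output JPEG path.
#' @return `out`, invisibly.
#' @export
get_timeline <- function(backend, species, out) UseMethod("get_timeline")

#' @export
get_timeline.fixture_backend <- function(backend, species, out) {
  av <- check_availability(backend, species)
  if (!av$available) stop("species not available: ", species)
  sp <- resolve_species_alias(species)
  p <- backend$pairs
  hit <- p[p$taxon_a == sp | p$taxon_b == sp, , drop = FALSE]
  depth <- max(100, hit$time_mya * 1.2, na.rm = TRUE)
  grDevices::jpeg(out, width = 480, height = 640, quality = 90)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(depth, 0), xaxt = "n",
                 xlab = "", ylab = "MYA",
                 main = paste("Evolutionary timeline:", av$species))
  graphics::abline(h = pretty(c(0, depth)), col = "grey80")
  if (nrow(hit)) {
    other <- ifelse(hit$taxon_a == sp, hit$taxon_b, hit$taxon_a)
    graphics::segments(0.5, depth, 0.5, 0, lwd = 2)
    graphics::points(rep(0.5, nrow(hit)), hit$time_mya, pch = 19)
    graphics::text(0.55, hit$time_mya, sprintf("%s (%.1f MYA)", other, hit$time_mya),
                   adj = 0, cex = 0.7)
  }
  invisible(out)
}
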