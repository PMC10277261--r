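#!/usr/bin/env Rscript
# Regenerates the packaged plain-text fixtures under inst/extdata/ from the
# package's own generators, with fixed seeds. Run from the repository root
# with the package installed or loaded via pkgload.

if (requireNamespace("pkgload", quietly = TRUE) && file.exists("DESCRIPTION")) {
  pkgload::load_all(".", quiet = TRUE)
} else {
  library(divtime)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

# Four-species example table (FULL vectorized form)
write_table_csv(table1_fixture(), "inst/extdata/table1.csv")

# Synthetic genus trees: real binomials on simulated Yule topologies with
# the crown ages used in the worked examples (4.73 MY / 9.0 MY)
catharus <- c(
  "Catharus aurantiirostris", "Catharus bicknelli", "Catharus dryas",
  "Catharus frantzii", "Catharus fuscater", "Catharus fuscescens",
  "Catharus gracilirostris", "Catharus guttatus", "Catharus mexicanus",
  "Catharus minimus", "Catharus occidentalis", "Catharus ustulatus")
malurus <- c(
  "Malurus alboscapulatus", "Malurus amabilis", "Malurus coronatus",
  "Malurus cyaneus", "Malurus elegans", "Malurus grayi",
  "Malurus lamberti", "Malurus leucopterus", "Malurus melanocephalus",
  "Malurus pulcherrimus", "Malurus splendens")

write_newick_file(
  simulate_yule_tree(12, 4.73, seed = 101, tip_labels = catharus),
  "inst/extdata/genus_catharus_synthetic.nwk")
write_newick_file(
  simulate_yule_tree(11, 9.0, seed = 202, tip_labels = malurus),
  "inst/extdata/genus_malurus_synthetic.nwk")

cat("fixtures written to inst/extdata/\n")
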