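test_that("species names are normalized and bad input rejected", {
  expect_identical(normalize_name("Passerina_amoena "), "Passerina amoena")
  expect_identical(normalize_name("Passerina amoena"), "Passerina amoena")
  expect_identical(normalize_name("  Malurus   cyaneus"), "Malurus cyaneus")
  expect_error(normalize_name(""), "empty")
  expect_error(normalize_name("   "), "empty")
})

test_that("species lists read in order, skip blanks, deduplicate with warning", {
  f <- write_species_file(c("Passerina amoena", "", "Corythornis_cristatus",
                            "Chalcomitra amethystine", "Chrysococcyx cupreus"))
  sp <- read_species_list(f)
  expect_length(sp, 4)
  expect_identical(sp[2], "Corythornis cristatus")

  f2 <- write_species_file(c("Passerina amoena", "Passerina amoena"))
  expect_warning(sp2 <- read_species_list(f2), "duplicate")
  expect_identical(sp2, "Passerina amoena")

  expect_error(read_species_list(write_species_file(character())), "no usable")
  expect_error(read_species_list(file.path(tempdir(), "nope.txt")), "cannot read")
})

test_that("the four-species example table converts to the expected matrix", {
  m <- table_to_matrix(table1_fixture())
  expect_identical(dim(m), c(4L, 4L))
  expect_identical(diag(m), setNames(rep(0, 4), rownames(m)))
  expect_identical(m, t(m))
  expect_setequal(m[upper.tri(m)], c(70.0, 27.6, 80.0))
  expect_equal(m["Passerina amoena", "Chalcomitra amethystine"], 27.6)
  expect_equal(m["Passerina amoena", "Corythornis cristatus"], 70.0)
  expect_equal(m["Chalcomitra amethystine", "Chrysococcyx cupreus"], 80.0)
})

test_that("degenerate and conflicting tables are handled", {
  one <- pairwise_table(data.frame(taxon_a = "A sp", taxon_b = "A sp",
                                   time_mya = 0), mode = "FULL")
  m1 <- table_to_matrix(one)
  expect_identical(dim(m1), c(1L, 1L))
  expect_identical(unname(m1[1, 1]), 0)

  skewed <- pairwise_table(data.frame(
    taxon_a = c("A sp", "B sp", "A sp", "B sp"),
    taxon_b = c("A sp", "A sp", "B sp", "B sp"),
    time_mya = c(0, 71.0, 70.0, 0)), species = c("A sp", "B sp"),
    mode = "FULL")
  expect_error(table_to_matrix(skewed, tol = 0.5), "conflicting")
  # generous tolerance accepts, keeping the a-before-b value
  expect_equal(table_to_matrix(skewed, tol = 2)["A sp", "B sp"], 70.0)

  incomplete <- pairwise_table(data.frame(
    taxon_a = c("A sp", "A sp"), taxon_b = c("B sp", "C sp"),
    time_mya = c(1, 2)), species = c("A sp", "B sp", "C sp"),
    mode = "UNORDERED")
  expect_error(table_to_matrix(incomplete), "UNORDERED table")
})

test_that("matrix_to_table emits both layouts and inverts table_to_matrix", {
  m <- table_to_matrix(table1_fixture())
  full <- matrix_to_table(m, "FULL")
  expect_equal(nrow(full), 16)
  expect_equal(sum(full$taxon_a == full$taxon_b), 4)
  expect_true(all(full$time_mya[full$taxon_a == full$taxon_b] == 0))
  expect_identical(table_to_matrix(full), m)

  un <- matrix_to_table(m, "UNORDERED")
  expect_equal(nrow(un), 6)
  expect_identical(table_to_matrix(un), m)

  two <- matrix(c(0, 35, 35, 0), 2, dimnames = list(c("A sp", "B sp"),
                                                    c("A sp", "B sp")))
  row <- matrix_to_table(two, "UNORDERED")
  expect_equal(nrow(row), 1)
  expect_equal(row$time_mya, 35)

  single <- matrix(0, 1, 1, dimnames = list("A sp", "A sp"))
  expect_equal(nrow(matrix_to_table(single, "UNORDERED")), 0)
})

test_that("round trips hold for random matrices in both layouts", {
  set.seed(404)
  for (rep in 1:10) {
    n <- sample(2:20, 1)
    m <- random_ultrametric_matrix(n)
    for (mode in c("FULL", "UNORDERED")) {
      tab <- matrix_to_table(m, mode)
      expect_equal(nrow(tab), if (mode == "FULL") n^2 else n * (n - 1) / 2)
      expect_identical(table_to_matrix(tab), m)
    }
  }
})

test_that("find_missing reports blanked and absent pairs, empty when complete", {
  t1 <- table1_fixture()
  expect_equal(nrow(find_missing(t1)), 0)

  blanked <- corrupt_table(t1, drop = list(c("Lazuli bunting", "Emerald cuckoo")))
  miss <- find_missing(blanked)
  expect_equal(nrow(miss), 1)
  expect_setequal(unlist(miss), c("Passerina amoena", "Chrysococcyx cupreus"))

  partial <- pairwise_table(data.frame(
    taxon_a = c("A sp", "A sp"), taxon_b = c("B sp", "C sp"),
    time_mya = c(1, 2)), species = c("A sp", "B sp", "C sp"),
    mode = "UNORDERED")
  gap <- find_missing(partial)
  expect_equal(nrow(gap), 1)
  expect_identical(gap$taxon_a, "B sp")
  expect_identical(gap$taxon_b, "C sp")
})

test_that("CSV write/read is the identity, keeps missing values and CI columns", {
  t1 <- table1_fixture()
  f <- tempfile(fileext = ".csv")
  write_table_csv(t1, f)
  back <- read_table_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(t1))
  expect_identical(table_mode <- attr(back, "mode"), "FULL")

  holed <- corrupt_table(t1, drop = list(c("Lazuli bunting", "Emerald cuckoo")))
  write_table_csv(holed, f)
  raw <- read.csv(f, colClasses = "character", check.names = FALSE)
  expect_true(any(raw[["Divergence time"]] == ""))
  back2 <- read_table_csv(f)
  expect_equal(as.data.frame(back2), as.data.frame(holed))
})

test_that("CSV reader flags format problems precisely", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("\"Taxa 1\",\"Divergence time\"", "\"A sp\",1"), f)
  expect_error(read_table_csv(f), "Taxa 2")
  writeLines(c("\"Taxa 1\",\"Taxa 2\",\"Divergence time\"",
               "\"A sp\",\"B sp\",fast"), f)
  expect_error(read_table_csv(f), "row 1")
  # diagonal "n. a" tokens read as 0 self-divergence
  writeLines(c("\"Taxa 1\",\"Taxa 2\",\"Divergence time\"",
               "\"A sp\",\"A sp\",n. a",
               "\"A sp\",\"B sp\",5",
               "\"B sp\",\"A sp\",5",
               "\"B sp\",\"B sp\",n. a"), f)
  tab <- read_table_csv(f)
  expect_equal(tab$time_mya[tab$taxon_a == tab$taxon_b], c(0, 0))
})
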