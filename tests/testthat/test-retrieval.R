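backend <- fixture_backend()

test_that("availability checks match the fixture holdings", {
  expect_true(check_availability(backend, "Passerina amoena")$available)
  expect_true(check_availability(backend, "Catharus ustulatus")$available)
  expect_true(check_availability(backend, "Lazuli bunting")$available)
  expect_false(check_availability(backend, "Tyrannosaurus rex")$available)
})

test_that("availability over a list preserves order and writes the CSV form", {
  sp <- c("Passerina amoena", "Corythornis cristatus",
          "Chalcomitra amethystine", "Chrysococcyx cupreus")
  out <- tempfile(fileext = ".csv")
  av <- check_availability_list(backend, sp, out = out)
  expect_identical(av$species, sp)
  expect_true(all(av$available))
  csv <- read.csv(out, check.names = FALSE)
  expect_identical(names(csv), c("Species", "Availability"))
  expect_identical(unique(csv$Availability), "Available")

  av2 <- check_availability_list(backend, c(sp[1:3], "Dodo ineptus"))
  expect_identical(av2$available, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(check_availability_list(backend, character()), "empty")
})

test_that("pair queries are symmetric, zero on self, and carry CI metadata", {
  r <- get_divergence(backend, "Catharus ustulatus", "Malurus cyaneus")
  expect_equal(r$time_mya, 35)
  r_rev <- get_divergence(backend, "Malurus cyaneus", "Catharus ustulatus")
  expect_equal(r_rev$time_mya, r$time_mya)

  r2 <- get_divergence(backend, "Passerina amoena", "Chalcomitra amethystine")
  expect_equal(r2$time_mya, 27.6)
  expect_equal(r2$ci_low_mya, 25.4)
  expect_equal(r2$ci_high_mya, 38.1)
  expect_equal(r2$n_studies, 5)

  expect_equal(get_divergence(backend, "Passerina amoena",
                              "Passerina amoena")$time_mya, 0)
})

test_that("unknown species yield a substitution record, not an exception", {
  r <- get_divergence(backend, "Passerina amoena", "Dodo ineptus")
  expect_true(is.na(r$time_mya))
  sub <- attr(r, "substitution")
  expect_equal(nrow(sub), 1)
  expect_identical(sub$requested, "Dodo ineptus")
  expect_true(is.na(sub$resolved))
})

test_that("backend symmetry holds across all fixture species", {
  sp <- c("Passerina amoena", "Corythornis cristatus",
          "Chalcomitra amethystine", "Chrysococcyx cupreus",
          "Catharus ustulatus", "Catharus guttatus", "Malurus cyaneus")
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    a <- get_divergence(backend, sp[i], sp[j])$time_mya
    b <- get_divergence(backend, sp[j], sp[i])$time_mya
    expect_equal(a, b)
  }
})

test_that("batch retrieval reproduces the example table and its matrix", {
  sp <- c("Passerina amoena", "Corythornis cristatus",
          "Chalcomitra amethystine", "Chrysococcyx cupreus")
  tab <- batch_divergence(backend, sp, mode = "FULL")
  expect_equal(nrow(tab), 16)
  expect_equal(as.data.frame(tab), as.data.frame(table1_fixture()))
  m <- table_to_matrix(tab)
  expect_identical(m, t(m))
  expect_identical(unname(diag(m)), rep(0, 4))

  two <- batch_divergence(backend, sp[1:2], mode = "FULL")
  expect_equal(nrow(two), 4)
})

test_that("a batch containing an unknown species completes with missing rows", {
  sp <- c("Passerina amoena", "Corythornis cristatus",
          "Chalcomitra amethystine", "Dodo ineptus")
  tab <- batch_divergence(backend, sp, mode = "FULL")
  expect_equal(nrow(tab), 16)
  # every ordered pair touching the unknown species is unresolved
  touches <- tab$taxon_a == "Dodo ineptus" | tab$taxon_b == "Dodo ineptus"
  expect_identical(is.na(tab$time_mya), touches)
  expect_equal(sum(is.na(tab$time_mya)), 7)
  expect_true("Dodo ineptus" %in% attr(tab, "substitutions")$requested)
  expect_error(batch_divergence(backend, c("Dodo ineptus", "Raphus cucullatus")),
               "none of the requested species")
})

test_that("repair_missing restores blanked values bit-exactly", {
  t1 <- table1_fixture()
  holed <- corrupt_table(t1, drop = list(c("Lazuli bunting", "Emerald cuckoo")))
  fixed <- repair_missing(backend, holed)
  expect_identical(fixed$time_mya,
                   t1$time_mya)
  expect_equal(as.data.frame(fixed), as.data.frame(t1))
  expect_equal(nrow(attr(fixed, "unrepaired")), 0)

  # complete table is a no-op
  same <- repair_missing(backend, t1)
  expect_equal(as.data.frame(same), as.data.frame(t1))

  # a pair with an unknown species stays missing and is reported
  odd <- pairwise_table(data.frame(
    taxon_a = c("Passerina amoena", "Dodo ineptus"),
    taxon_b = c("Dodo ineptus", "Passerina amoena"),
    time_mya = NA_real_),
    species = c("Passerina amoena", "Dodo ineptus"), mode = "UNORDERED")
  attr(odd, "mode") <- "UNORDERED"
  still <- repair_missing(backend, odd)
  expect_true(all(is.na(still$time_mya)))
  expect_gt(nrow(attr(still, "unrepaired")), 0)
})

test_that("time trees come back as ultrametric Newick with MY branch lengths", {
  cat_tree <- parse_newick(get_timetree(backend, "Catharus")$newick)
  expect_length(cat_tree$tip.label, 12)
  expect_true(is_ultrametric_tree(cat_tree, tol = 1e-6))

  mal_tree <- parse_newick(get_timetree(backend, "Malurus")$newick)
  expect_length(mal_tree$tip.label, 11)
  expect_true(is_ultrametric_tree(mal_tree, tol = 1e-6))

  pair <- get_timetree(backend, c("Catharus ustulatus", "Malurus cyaneus"))
  ptree <- parse_newick(pair$newick)
  expect_length(ptree$tip.label, 2)
  expect_equal(crown_age(ptree), 35)

  expect_error(get_timetree(backend, "Unknownus"), "at least 2 tips")
  dropped <- get_timetree(backend, c("Catharus ustulatus", "Malurus cyaneus",
                                     "Dodo ineptus"))
  expect_length(parse_newick(dropped$newick)$tip.label, 2)
  expect_true("Dodo ineptus" %in% dropped$substitutions$requested)
})

test_that("availability is consistent with pair resolution", {
  sp <- c("Passerina amoena", "Corythornis cristatus", "Catharus ustulatus",
          "Catharus guttatus", "Malurus cyaneus", "Malurus splendens")
  av <- check_availability_list(backend, sp)
  expect_true(all(av$available))
  for (i in 1:(length(sp) - 1)) for (j in (i + 1):length(sp)) {
    r <- get_divergence(backend, sp[i], sp[j])
    # two Available species never produce an unresolved *species*; a pair
    # spanning two disjoint fixture sources may still lack a shared record
    sub <- attr(r, "substitution")
    if (nrow(sub)) expect_false(any(sub$requested %in% sp))
  }
})

test_that("timeline retrieval writes a JPEG for available species only", {
  out <- tempfile(fileext = ".jpg")
  get_timeline(backend, "Passerina amoena", out)
  expect_true(file.exists(out))
  expect_gt(file.size(out), 1000)
  expect_error(get_timeline(backend, "Dodo ineptus", tempfile()), "not available")
})
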