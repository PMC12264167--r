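test_that("record validation issues the right verdicts", {
  expect_identical(validate_records(
    mutation_table("P", 2L, "K", "R"), c(P = "MKT")), "VALID")
  expect_identical(validate_records(
    mutation_table("P", 5L, "K", "R"), c(P = "MKT")), "INVALID_POSITION")
  expect_identical(validate_records(
    mutation_table("P", 2L, "R", "K"), c(P = "MKT")), "INVALID_WT")
  expect_error(mutation_table("P", 2L, "k", "R"), "residue letter")
  expect_error(mutation_table("P", 2L, "K", "K"), "must differ")
})

test_that("toy fixture verdicts match the hand-computed set exactly", {
  fx <- fixture_toy_records()
  expect_identical(validate_records(fx$records, fx$sequences),
                   fx$expected_verdicts)
  kept <- drop_invalid_records(fx$records, fx$sequences, quiet = TRUE)
  expect_equal(nrow(kept), 8L)
})

test_that("source filter keeps exactly the multi-source records, in order", {
  fx <- fixture_toy_records()
  valid <- drop_invalid_records(fx$records, fx$sequences, quiet = TRUE)
  out <- filter_min_sources(valid)
  # survivor set documented in the fixture: r1, r4, r7(VALID rows only), r9
  expect_equal(nrow(out), 4L)
  expect_true(all(vapply(strsplit(out$sources, ";"), length, 1L) >= 2L))
  # singletons dropped, multi-source kept
  one <- mutation_table("P", 1L, "M", "V", sources = "ClinVar")
  two <- mutation_table("P", 1L, "M", "V", sources = "ClinVar;COSMIC")
  expect_equal(nrow(filter_min_sources(one)), 0L)
  expect_equal(nrow(filter_min_sources(two)), 1L)
  bad <- one; bad$sources <- "NotADatabase"
  expect_error(filter_min_sources(bad), "unknown source")
})

test_that("source filter is idempotent and order-preserving", {
  fx <- fixture_toy_records()
  once <- filter_min_sources(fx$records)
  twice <- filter_min_sources(once)
  expect_identical(once, twice)
  # original relative order retained
  keys <- paste(fx$records$protein_id, fx$records$position)
  expect_false(is.unsorted(match(paste(once$protein_id, once$position), keys)))
})

test_that("topology grouping is the fixed five-to-three mapping", {
  expect_identical(map_topology("H"), "transmembrane")
  expect_identical(map_topology("B"), "transmembrane")
  expect_identical(map_topology("i"), "cytoplasmic")
  expect_identical(map_topology("o"), "extracellular")
  expect_identical(map_topology("S"), "extracellular")
  expect_error(map_topology("x"), "unknown topology")
  # total on the five codes and surjective onto the three classes
  classes <- map_topology(topology_codes())
  expect_setequal(unique(classes),
                  c("transmembrane", "cytoplasmic", "extracellular"))
})

test_that("pathogenicity dataset keeps only labelled records", {
  recs <- mutation_table("P", c(1L, 2L, 3L, 4L, 5L), c("M", "K", "T", "A", "Y"),
                         c("V", "R", "S", "G", "F"),
                         patho_label = c(1L, 1L, 1L, 0L, 0L))
  ds <- build_patho_dataset(recs)
  expect_identical(ds$patho_label, c(1L, 1L, 1L, 0L, 0L))
  recs2 <- recs; recs2$patho_label[3] <- NA_integer_
  expect_message(out <- build_patho_dataset(recs2), "excluding 1")
  expect_equal(nrow(out), 4L)
  expect_warning(build_patho_dataset(recs[0, ]), "empty")
})

test_that("disease dataset is pathogenic-only with 15-dim multi-hot labels", {
  recs <- mutation_table("P", c(1L, 2L, 3L), c("M", "K", "T"),
                         c("V", "R", "S"),
                         patho_label = c(1L, 0L, 1L),
                         disease_labels = c("NSD;MD", "", "CDM"))
  ds <- build_disease_dataset(recs)
  expect_equal(nrow(ds$records), 2L)
  expect_equal(dim(ds$labels), c(2L, 15L))
  expect_equal(sum(ds$labels[1, ]), 2L)          # multi-label record
  expect_equal(which(ds$labels[1, ] == 1L),
               match(c("NSD", "MD"), disease_codes()), ignore_attr = TRUE)
  expect_equal(sum(ds$labels[2, ]), 1L)
  expect_error(disease_label_matrix("XYZ"), "unknown disease")
  expect_error(mutation_table("P", 1L, "M", "V", patho_label = 0L,
                              disease_labels = "NSD"),
               "pathogenic")
})
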