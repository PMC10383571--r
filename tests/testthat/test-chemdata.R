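test_that("parsing canonicalizes equivalent encodings to one identity key", {
  a <- parse_structure("C1CCNCC1")
  b <- parse_structure("N1CCCCC1")
  expect_identical(a$canonical_key, b$canonical_key)
  expect_identical(parse_structure("CC")$canonical_key, parse_structure("CC")$canonical_key)
  expect_gte(a$n_atoms, 1L)
  # idempotence: reparse the canonical form
  expect_identical(parse_structure(a$canonical_key)$canonical_key, a$canonical_key)
})

test_that("malformed and chemically invalid strings are rejected with the text reported", {
  expect_error(parse_structure("C("), "C\\(")
  expect_error(parse_structure(""), "empty|non-empty")
  expect_error(parse_structure("C1CC"), "ring")
  expect_error(parse_structure("CC(C)(C)(C)C"), "valence|invalid")
})

test_that("salts reduce to the largest fragment and graph fields are chemically sound", {
  m <- parse_structure("CCO.Cl")
  expect_identical(m$canonical_key, parse_structure("CCO")$canonical_key)
  expect_equal(m$n_atoms, 3L)
  pip <- parse_structure("C1CCNCC1")
  expect_equal(pip$n_h, c(2L, 2L, 2L, 1L, 2L, 2L))
  expect_true(all(pip$in_ring))
  expect_false(any(parse_structure("CCO")$in_ring))
  expect_equal(parse_structure("C")$n_h, 4L)
})

test_that("curation filters remove offending records and audit counts removals in order", {
  rec <- passing_records(6)
  rec$mass_da[2] <- 1200
  rec$activity_comment[3] <- "declared INACTIVE at 10uM"
  rec$relation[4] <- ">"
  rec$confidence_score[5] <- 8L
  rec$potency_value[6] <- 50
  res <- apply_curation_filters(rec)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(unname(res$audit[c("comment", "mass", "relation", "confidence", "potency")]),
               c(1L, 1L, 1L, 1L, 1L))

  # comment blocklist removes regardless of the other fields
  rec2 <- passing_records(1)
  rec2$activity_comment <- "inconclusive"
  expect_equal(nrow(apply_curation_filters(rec2)$kept), 0L)

  # all passing records pass through with a zero audit
  res3 <- apply_curation_filters(passing_records(3))
  expect_equal(nrow(res3$kept), 3L)
  expect_true(all(res3$audit == 0L))

  # missing fields land in the malformed bucket
  rec4 <- passing_records(2)
  rec4$potency_value[1] <- NA
  res4 <- apply_curation_filters(rec4)
  expect_equal(unname(res4$audit["malformed"]), 1L)
  expect_equal(nrow(res4$kept), 1L)

  # configurable direction follows the opposite reading
  rec5 <- passing_records(2)
  rec5$potency_value <- c(1, 50)
  res5 <- apply_curation_filters(rec5, potency_direction = "gt")
  expect_equal(res5$kept$potency_value, 50)
})

test_that("filter composability: the kept set is order-independent", {
  set.seed(7)
  rec <- passing_records(40)
  rec$mass_da <- sample(c(300, 1500), 40, TRUE)
  rec$potency_value <- sample(c(1, 100), 40, TRUE)
  rec$relation <- sample(c("=", ">"), 40, TRUE)
  rec$confidence_score <- sample(c(9L, 5L), 40, TRUE)
  rec$activity_comment <- sample(c("", "inactive"), 40, TRUE)
  kept <- apply_curation_filters(rec)$kept
  # independent conjunction of the predicates, no sequencing
  manual <- rec[rec$mass_da < 1000 & rec$potency_value <= 10 & rec$relation == "=" &
                  rec$confidence_score == 9L & !grepl("inactive", rec$activity_comment), ]
  expect_equal(rownames(kept), rownames(manual))
})

test_that("undersampling balances to the minimum class and never touches it", {
  ds <- multiclass_dataset(
    smiles = c(paste0("C", strrep("C", 1:6)), "CCO", "CCN", "CCCO", "c1ccccc1", "CCS"),
    label = c(rep("DT", 6), "ST_A", "ST_A", "ST_B", "ST_B", "R"),
    canonicalize = FALSE
  )
  b <- balance_by_undersampling(ds, seed = 3)
  expect_true(all(attr(b, "class_counts") == 1L))
  expect_true("CCS" %in% b$smiles)  # minimum class untouched
  # determinism and fixed point
  b2 <- balance_by_undersampling(ds, seed = 3)
  expect_identical(b$smiles, b2$smiles)
  expect_identical(balance_by_undersampling(b, seed = 9)$smiles, b$smiles)
  # empty class errors by name
  ds0 <- ds[ds$label != "R", ]
  class(ds0) <- c("shapcf_dataset", "data.frame")
  expect_error(balance_by_undersampling(ds0, 1), "R")
})

test_that("compound files round-trip through the smi and csv readers", {
  ds <- multiclass_dataset(c("CCO", "c1ccccc1"), c("DT", "R"), c("a", "b"))
  smi <- tempfile(fileext = ".smi")
  csv <- tempfile(fileext = ".csv")
  write_compounds(ds, smi)
  write_compounds(ds, csv)
  r1 <- read_compounds(smi, labels = c("DT", "R"))
  r2 <- read_compounds(csv)
  expect_equal(r1$smiles, ds$smiles)
  expect_equal(r2$label, ds$label)
  expect_equal(r2$id, ds$id)
})
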