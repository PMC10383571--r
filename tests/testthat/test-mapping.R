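# A fingerprint/explanation pair with hand-set attributions over a molecule,
# for exercising the apportionment rule directly.
make_expl <- function(fp, phi_by_bit, classes = class_labels()) {
  phi <- matrix(0, length(classes), fp$n_bits, dimnames = list(classes, NULL))
  for (b in names(phi_by_bit)) phi[, as.integer(b)] <- phi_by_bit[[b]]
  probs <- setNames(rowSums(phi) + 0.25, classes)
  structure(list(phi = phi, base = setNames(rep(0.25, length(classes)), classes),
                 foreground_bits = fp$on_bits, probs = probs, background_size = 1L),
            class = "shapcf_shap")
}

env_row <- function(center, radius, env_hash, atoms) {
  df <- data.frame(center = center, radius = radius, env_hash = env_hash)
  df$atoms <- list(as.integer(atoms))
  df
}

test_that("atom attribution follows the assignment and collision apportionment rules", {
  mol <- parse_structure("CCO")
  # single environment {1,2} on bit 4 with phi 0.3
  fp <- structure(list(n_bits = 16L, on_bits = 4L,
                       provenance = list(`4` = env_row(1L, 1L, 3L, c(1, 2)))),
                  class = "shapcf_fp")
  am <- atom_attributions(mol, fp, make_expl(fp, list(`4` = 0.3)), "DT")
  expect_equal(am$raw, c(0.3, 0.3, 0))
  # two non-colliding environments accumulate on the shared atom
  fp2 <- structure(list(n_bits = 16L, on_bits = c(4L, 9L),
                        provenance = list(`4` = env_row(1L, 1L, 3L, c(1, 2)),
                                          `9` = env_row(2L, 1L, 8L, c(2, 3)))),
                   class = "shapcf_fp")
  am2 <- atom_attributions(mol, fp2, make_expl(fp2, list(`4` = 0.3, `9` = -0.1)), "DT")
  expect_equal(am2$raw, c(0.3, 0.2, -0.1))
  # collision: both environments on one bit each receive half before assignment
  prov3 <- rbind(env_row(1L, 0L, 3L, 1), env_row(3L, 0L, 19L, 3))
  fp3 <- structure(list(n_bits = 16L, on_bits = 4L, provenance = list(`4` = prov3)),
                   class = "shapcf_fp")
  am3 <- atom_attributions(mol, fp3, make_expl(fp3, list(`4` = 0.4)), "DT")
  expect_equal(am3$raw, c(0.2, 0, 0.2))
  # a set bit without provenance marks a corrupt fingerprint
  fp_bad <- structure(list(n_bits = 16L, on_bits = 4L, provenance = list()),
                      class = "shapcf_fp")
  expect_error(atom_attributions(mol, fp_bad, make_expl(fp_bad, list(`4` = 0.1)), "DT"),
               "corrupt")
})

test_that("the conservation identity holds on attribution maps from real explanations", {
  set.seed(17)
  mol <- parse_structure("CC(=O)Nc1ccc(O)cc1")
  fp <- fingerprint(mol, n_bits = 256L)
  model <- random_ensemble(256L, 3L, 4L)
  bg <- matrix(rbinom(256 * 8, 1, 0.1), 8, 256)
  expl <- interventional_shap(model, fp_dense(fp), bg)
  expl$foreground_bits <- fp$on_bits
  am <- atom_attributions(mol, fp, expl, "ST_B")
  expected <- 0
  for (b in fp$on_bits) {
    prov <- fp$provenance[[as.character(b)]]
    expected <- expected + expl$phi["ST_B", b] *
      sum(vapply(prov$atoms, length, integer(1))) / nrow(prov)
  }
  expect_lt(abs(sum(am$raw) - expected), 1e-12)
  # locality: atoms outside every set-bit environment stay exactly zero
  covered <- sort(unique(unlist(lapply(fp$provenance, function(p) unlist(p$atoms)))))
  expect_true(all(am$raw[setdiff(seq_len(mol$n_atoms), covered)] == 0))
})

test_that("normalization scales symmetrically into [-1, 1] preserving signs and zeros", {
  mol <- parse_structure("CCO")
  map <- structure(list(molecule = mol, target_class = "DT",
                        raw = c(0.3, -0.6, 0), normalized = NULL, prob = 0.5),
                   class = "shapcf_atommap")
  nm <- normalize_attributions(map)
  expect_equal(nm$normalized, c(0.5, -1, 0))
  map$raw <- c(0, 0, 0)
  expect_equal(normalize_attributions(map)$normalized, c(0, 0, 0))
  set.seed(4)
  map$raw <- rnorm(3)
  expect_equal(sign(normalize_attributions(map)$normalized), sign(map$raw))
})

test_that("depictions render deterministically with the diverging color contract", {
  mol <- parse_structure("CC(=O)Nc1ccc(O)cc1")
  map <- structure(list(molecule = mol, target_class = "DT",
                        raw = seq(0.1, 1, length.out = mol$n_atoms),
                        normalized = NULL, prob = 0.42),
                   class = "shapcf_atommap")
  map <- normalize_attributions(map)
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  render_depiction(map, f1)
  render_depiction(map, f2)
  expect_identical(readLines(f1), readLines(f2))
  svg <- paste(readLines(f1), collapse = "\n")
  # all-positive map: red-channel highlights only, no blue-dominated fill
  fills <- regmatches(svg, gregexpr('fill="#[0-9A-F]{6}"', svg))[[1]]
  expect_gt(length(fills), 0)
  expect_true(all(startsWith(fills, 'fill="#FF')))
  expect_true(grepl("P\\(DT\\) = 0.42", svg))
  # zero map: no highlight circles at all
  map0 <- normalize_attributions(structure(
    list(molecule = mol, target_class = "DT", raw = rep(0, mol$n_atoms),
         normalized = NULL, prob = 0.1), class = "shapcf_atommap"))
  f3 <- tempfile(fileext = ".svg")
  render_depiction(map0, f3)
  expect_false(grepl("circle", paste(readLines(f3), collapse = "")))
  expect_error(render_depiction(map, "/nonexistent-dir/x.svg"), "cannot write")
})

test_that("substructure enrichment tables report per-pattern fractions and differences", {
  set_a <- c("C1CCNCC1", "CC1CCNCC1")          # all contain piperidine
  set_b <- c("c1ccccc1", "CCO")
  tab <- compare_substructure_enrichment(set_a, set_b,
                                         c(pip = "C1CCNCC1", ben = "c1ccccc1"))
  expect_equal(tab$fraction_a, c(1, 0))
  expect_equal(tab$fraction_b, c(0, 0.5))
  expect_equal(tab$difference, c(1, -0.5))
  same <- compare_substructure_enrichment(set_a, set_a, c(p = "C1CCNCC1"))
  expect_equal(same$difference, 0)
  expect_error(compare_substructure_enrichment(set_a, set_b, c(bad = "][")), "SMARTS")
  expect_error(compare_substructure_enrichment(character(), set_b, "C"), "non-empty")
})
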