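test_that("brute-force Shapley satisfies the single-player and additivity axioms", {
  # single player: phi = v({1}) - v({})
  v1 <- function(S) if (1 %in% S) 3.5 else 1.25
  expect_equal(brute_force_shapley(v1, 1L), 2.25)
  # additive game: phi_i = w_i
  w <- c(0.3, -1.2, 2.0, 0.7)
  vadd <- function(S) sum(w[S])
  expect_equal(brute_force_shapley(vadd, 4L), w, tolerance = 1e-12)
  expect_error(brute_force_shapley(vadd, 17L), "too large")
})

test_that("brute-force Shapley matches a permutation-average computation on a fixed 3-player game", {
  tab <- c(`""` = 0, `"1"` = 2, `"2"` = 3, `"3"` = 1, `"12"` = 7, `"13"` = 2,
           `"23"` = 5, `"123"` = 10)
  key <- function(S) paste0('"', paste(sort(S), collapse = ""), '"')
  v <- function(S) unname(tab[key(S)])
  phi <- brute_force_shapley(v, 3L)
  # independent oracle: average marginal contributions over all 3! orderings
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  phi_perm <- numeric(3)
  for (p in perms) {
    pre <- integer()
    for (i in p) {
      phi_perm[i] <- phi_perm[i] + (v(c(pre, i)) - v(pre)) / length(perms)
      pre <- c(pre, i)
    }
  }
  expect_equal(phi, phi_perm, tolerance = 1e-12)
  # efficiency
  expect_equal(sum(phi), v(1:3) - v(integer()), tolerance = 1e-12)
})

test_that("a single-split stump attributes the leaf difference to its bit", {
  model <- make_model(list(make_stump(7L, c(0.8, 0.2, 0, 0), c(0.1, 0.3, 0.4, 0.2))), 8L)
  x <- rep(0, 8); x[7] <- 1
  z <- matrix(0, 1, 8)
  expl <- interventional_shap(model, x, z)
  expect_equal(unname(expl$phi[, 7]), c(0.1 - 0.8, 0.3 - 0.2, 0.4 - 0, 0.2 - 0))
  expect_true(all(expl$phi[, -7] == 0))
  # no contrast: background equal to the foreground zeroes everything
  expl0 <- interventional_shap(model, x, matrix(x, 1))
  expect_true(all(expl0$phi == 0))
  expect_equal(unname(expl0$base), unname(expl0$probs))
  expect_error(interventional_shap(model, x, matrix(0, 0, 8)), "empty")
})

test_that("tree attributions equal brute-force Shapley values on random ensembles", {
  set.seed(101)
  maxdev <- 0
  for (case in 1:40) {
    M <- 8L
    model <- random_ensemble(M, sample(1:5, 1), sample(1:4, 1))
    x <- rbinom(M, 1, 0.5)
    bg <- matrix(rbinom(M * sample(1:16, 1), 1, 0.5), ncol = M)
    expl <- interventional_shap(model, x, bg)
    for (cl in 1:4) {
      phi_bf <- brute_force_shapley(ensemble_game(model, x, bg, cl), M)
      maxdev <- max(maxdev, max(abs(phi_bf - expl$phi[cl, ])))
    }
  }
  expect_lt(maxdev, 1e-10)
})

test_that("local accuracy and class additivity hold on every explanation", {
  set.seed(33)
  for (case in 1:20) {
    model <- random_ensemble(10L, 4L, 4L)
    x <- rbinom(10, 1, 0.5)
    bg <- matrix(rbinom(10 * 12, 1, 0.4), 12, 10)
    expl <- interventional_shap(model, x, bg)
    expect_lt(max(abs(expl$base + rowSums(expl$phi) - expl$probs)), 1e-8)
    expect_equal(sum(expl$base) + sum(expl$phi), 1, tolerance = 1e-8)
  }
})

test_that("symmetric bits receive identical attributions and dummies get zero", {
  # two trees using bit 1 and bit 2 in exactly exchangeable roles
  leafL <- c(0.6, 0.2, 0.1, 0.1); leafR <- c(0.1, 0.1, 0.2, 0.6)
  model <- make_model(list(make_stump(1L, leafL, leafR), make_stump(2L, leafL, leafR)), 5L)
  x <- c(1, 1, 0, 1, 0)
  set.seed(5)
  bg <- matrix(rbinom(5 * 8, 1, 0.5), 8, 5)
  bg[, 2] <- bg[, 1]  # background symmetric in the two bits as well
  expl <- interventional_shap(model, x, bg)
  expect_equal(expl$phi[, 1], expl$phi[, 2], tolerance = 1e-12)
  # bits never tested by any tree are exact dummies
  expect_true(all(expl$phi[, 3:5] == 0))
})

test_that("attributions with a pooled background equal the mean over single-sample backgrounds", {
  set.seed(55)
  model <- random_ensemble(8L, 3L, 3L)
  x <- rbinom(8, 1, 0.5)
  bg <- matrix(rbinom(8 * 6, 1, 0.5), 6, 8)
  pooled <- interventional_shap(model, x, bg)
  singles <- lapply(seq_len(nrow(bg)), function(i) {
    interventional_shap(model, x, bg[i, , drop = FALSE])$phi
  })
  expect_equal(pooled$phi, Reduce(`+`, singles) / length(singles), tolerance = 1e-12)
})

test_that("present/absent partition splits by foreground bit value and preserves additivity", {
  model <- make_model(list(make_stump(3L, c(0.7, 0.1, 0.1, 0.1), c(0.2, 0.2, 0.3, 0.3)),
                           make_stump(9L, c(0.5, 0.3, 0.1, 0.1), c(0.1, 0.5, 0.2, 0.2))), 10L)
  x <- rep(0, 10); x[3] <- 1       # bit 3 present, bit 9 absent
  set.seed(8)
  bg <- matrix(rbinom(10 * 10, 1, 0.5), 10, 10)
  expl <- interventional_shap(model, x, bg)
  pa <- partition_present_absent(expl)
  for (k in seq_len(nrow(pa))) {
    cl <- pa$class[k]
    expect_equal(pa$present_sum[k], unname(expl$phi[cl, 3]))
    expect_equal(pa$absent_sum[k], sum(expl$phi[cl, -3]))
    expect_equal(pa$present_sum[k] + pa$absent_sum[k] + pa$base[k], pa$prob[k],
                 tolerance = 1e-8)
  }
  # all-zero foreground: nothing is present
  expl0 <- interventional_shap(model, rep(0, 10), bg)
  expect_true(all(partition_present_absent(expl0)$present_sum == 0))
})

test_that("cumulative summaries use only correctly predicted compounds and flag empty cells", {
  # model predicts DT iff bit 1, ST_A iff bit 2 (constructed stumps)
  model <- make_model(list(make_stump(1L, c(0, 0.4, 0.3, 0.3), c(1, 0, 0, 0)),
                           make_stump(2L, c(0.1, 0, 0.45, 0.45), c(0, 1, 0, 0))), 4L)
  mk <- function(bits) structure(list(n_bits = 4L, on_bits = as.integer(bits),
                                      provenance = list()), class = "shapcf_fp")
  fps <- list(mk(1L), mk(2L), mk(integer()))
  y <- c("DT", "ST_A", "DT")  # third compound cannot be predicted DT
  bg <- diag(4)[, ]
  cs <- cumulative_shap(model, fps, y, bg)
  expect_equal(cs$n_compounds[cs$class == "DT"], 1L)
  expect_equal(cs$n_compounds[cs$class == "ST_A"], 1L)
  expect_true(cs$empty[cs$class == "ST_B"])
  expect_true(is.na(cs$present[cs$class == "ST_B"]))
  # the contributing DT cell equals that compound's own partition
  expl <- interventional_shap(model, fps[[1]], bg)
  pa <- partition_present_absent(expl)
  expect_equal(cs$present[cs$class == "DT"], pa$present_sum[pa$class == "DT"])
})
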