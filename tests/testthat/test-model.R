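# Shared toy problem: four classes determined by two indicator bits.
toy_data <- function(n = 240, p = 30, seed = 11) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  y <- ifelse(X[, 1] == 1 & X[, 2] == 1, "DT",
              ifelse(X[, 1] == 1, "ST_A", ifelse(X[, 2] == 1, "ST_B", "R")))
  list(X = X, y = y)
}

test_that("stratified splits preserve class proportions and are seed-deterministic", {
  y <- rep(class_labels(), each = 100)
  sp <- stratified_split(y, 0.7, seed = 5)
  expect_length(sp$train, 280L)
  expect_length(sp$test, 120L)
  for (cl in class_labels()) expect_equal(sum(y[sp$train] == cl), 70L)
  expect_identical(sp, stratified_split(y, 0.7, seed = 5))
  expect_false(identical(sp$train, stratified_split(y, 0.7, seed = 6)$train))
  expect_error(stratified_split(y, 1.0), "between 0 and 1")
  expect_error(stratified_split(c("DT", rep("R", 5)), 0.7), "fewer than 2")
  # rounding stays within one compound of the exact fraction
  y2 <- c(rep("DT", 13), rep("ST_A", 7), rep("ST_B", 29), rep("R", 5))
  sp2 <- stratified_split(y2, 0.7, 1)
  for (cl in class_labels()) {
    expect_lte(abs(sum(y2[sp2$train] == cl) - round(sum(y2 == cl) * 0.7)), 1)
  }
})

test_that("training is deterministic, separable data is memorized, and leaves are distributions", {
  d <- toy_data()
  params <- list(n_trees = 25L, min_samples_leaf = 1L, min_samples_split = 2L)
  m1 <- train_model(d$X, d$y, params, seed = 4)
  m2 <- train_model(d$X, d$y, params, seed = 4)
  expect_equal(predict_probabilities(m1, d$X), predict_probabilities(m2, d$X))
  expect_equal(mean(assign_class(predict_probabilities(m1, d$X)) == d$y), 1.0)
  for (tree in m1$trees) {
    lp <- tree$leafp[tree$terminal, , drop = FALSE]
    expect_true(all(lp >= 0))
    expect_equal(rowSums(lp), rep(1, nrow(lp)), tolerance = 1e-9)
  }
  expect_error(train_model(d$X, rep("DT", nrow(d$X)), params), "single class")
})

test_that("prediction averages leaf vectors and validates dimensions", {
  m1 <- make_model(list(make_stump(1L, c(0.9, 0.1, 0, 0), c(0, 0, 0, 1))), 4L)
  x0 <- c(0, 1, 1, 0); x1 <- c(1, 1, 1, 0)
  expect_equal(drop(predict_probabilities(m1, x0)), c(DT = 0.9, ST_A = 0.1, ST_B = 0, R = 0))
  m2 <- make_model(list(make_stump(1L, c(1, 0, 0, 0), c(1, 0, 0, 0)),
                        make_stump(2L, c(0, 1, 0, 0), c(0, 1, 0, 0))), 4L)
  expect_equal(unname(drop(predict_probabilities(m2, x1))), c(0.5, 0.5, 0, 0))
  expect_error(predict_probabilities(m1, c(1, 0)), "features")
  set.seed(2)
  pr <- predict_probabilities(m2, matrix(rbinom(40, 1, 0.5), 10, 4))
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, 10))
})

test_that("class assignment is argmax with ties to the smallest class code", {
  expect_equal(assign_class(c(0.37, 0.33, 0.20, 0.10)), "DT")
  expect_equal(assign_class(c(0.25, 0.25, 0.25, 0.25)), "DT")
  expect_equal(assign_class(c(0, 0, 0, 1)), "R")
  expect_equal(assign_class(rbind(c(0.1, 0.5, 0.2, 0.2), c(0.2, 0.2, 0.3, 0.3))),
               c("ST_A", "ST_B"))
})

test_that("metric formulas reproduce their printed values and recounts", {
  # perfect classifier
  perf <- compute_metrics(rep(class_labels(), 10), rep(class_labels(), 10))
  expect_true(all(abs(perf$macro - 1) < 1e-12))
  expect_true(all(perf$per_class$MCC == 1))
  # fixed tallies through a constructed label set
  tal <- shapcf:::.metrics_from_tally(c(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(unname(tal$values["MCC"]), 0)
  tal2 <- shapcf:::.metrics_from_tally(c(TP = 40, FP = 10, TN = 40, FN = 10))
  expect_equal(unname(tal2$values["MCC"]), 0.6)
  expect_equal(unname(tal2$values["BA"]), 0.8)
  expect_error(compute_metrics(c("DT"), c("DT", "R")), "lengths")
})

test_that("metrics agree with a naive confusion recount on random label vectors", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    pred <- sample(class_labels(), n, TRUE)
    truth <- sample(class_labels(), n, TRUE)
    got <- compute_metrics(pred, truth)
    for (cl in class_labels()) {
      tp <- sum(pred == cl & truth == cl); fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl); tn <- n - tp - fp - fn
      row <- got$per_class[got$per_class$class == cl, ]
      expect_equal(row$TP + row$FP + row$TN + row$FN, n)
      if (tp + fp > 0) expect_equal(row$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(row$recall, tp / (tp + fn))
      den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
      if (den > 0) expect_equal(row$MCC, (tp * tn - fp * fn) / den)
    }
  }
})

test_that("tuning returns the exhaustive argmax with the lexicographic tie-break", {
  d <- toy_data(n = 160, p = 20, seed = 3)
  grid <- hyperparameter_grid(n_trees = c(25L, 50L), min_samples_leaf = c(1L, 5L),
                              min_samples_split = c(2L, 5L))
  tu <- tune_hyperparameters(d$X, d$y, grid, seed = 2)
  # independent re-scoring of every grid point
  sp <- stratified_split(d$y, 0.7, seed = 2)
  rescore <- vapply(seq_len(nrow(grid)), function(i) {
    m <- train_model(d$X[sp$train, ], d$y[sp$train], as.list(grid[i, ]), seed = 2)
    pred <- assign_class(predict_probabilities(m, d$X[sp$test, ]))
    unname(compute_metrics(pred, d$y[sp$test])$macro["BA"])
  }, numeric(1))
  expect_equal(tu$scores, rescore)
  best <- which.max(rescore)  # first maximum = lexicographic winner
  expect_equal(tu$params, as.list(grid[best, ]))
  # single-row grid short-circuits to that row
  g1 <- hyperparameter_grid(n_trees = 25L, min_samples_leaf = 1L, min_samples_split = 2L)
  expect_equal(tune_hyperparameters(d$X, d$y, g1, seed = 1)$params, as.list(g1[1, ]))
  expect_error(tune_hyperparameters(d$X, d$y, g1[0, ], seed = 1), "empty")
})

test_that("trials are reproducible and summarized per metric", {
  d <- toy_data(n = 160, p = 20, seed = 9)
  g <- hyperparameter_grid(n_trees = 25L, min_samples_leaf = 1L, min_samples_split = 2L)
  t1 <- run_trials(d$X, d$y, n_trials = 2, base_seed = 7, grid = g)
  t2 <- run_trials(d$X, d$y, n_trials = 2, base_seed = 7, grid = g)
  expect_equal(t1$metric_table, t2$metric_table)
  expect_equal(nrow(t1$metric_table), 2L)
  single <- run_trials(d$X, d$y, n_trials = 1, base_seed = 7, grid = g)
  expect_equal(single$summary$median[single$summary$metric == "BA"],
               single$metric_table$BA[1])
})

test_that("the JSON tree dump restores a model with identical predictions", {
  d <- toy_data(n = 120, p = 15, seed = 13)
  m <- train_model(d$X, d$y, list(n_trees = 10L, min_samples_leaf = 1L, min_samples_split = 2L), seed = 1)
  path <- tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_equal(predict_probabilities(m2, d$X), predict_probabilities(m, d$X))
  expect_equal(m2$class_order, m$class_order)
})
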