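# Multiclass random-forest training on binary fingerprints. Forests are fit
# with ranger and immediately exported to a plain node-table representation
# (split feature, threshold, children, per-class leaf probability vectors).
# All predictions in the package are computed by traversing the exported
# trees, so model output and tree-based Shapley attributions are consistent
# by construction.

#' The full hyperparameter grid of the training protocol
#'
#' Cartesian product of the minimum samples per leaf (1, 2, 5, 10), the
#' minimum samples required to split a node (2, 3, 5, 10) and the number of
#' trees (25, 50, 100, 200, 400): 80 combinations. Rows are ordered
#' lexicographically by (n_trees, min_samples_leaf, min_samples_split) so the
#' first best-scoring row is the deterministic tie-break winner.
#'
#' @param min_samples_leaf,min_samples_split,n_trees Optional reduced value
#'   sets for smaller searches.
#' @return Data.frame with one row per combination.
#' @export
hyperparameter_grid <- function(min_samples_leaf = c(1L, 2L, 5L, 10L),
                                min_samples_split = c(2L, 3L, 5L, 10L),
                                n_trees = c(25L, 50L, 100L, 200L, 400L)) {
  g <- expand.grid(
    min_samples_split = as.integer(min_samples_split),
    min_samples_leaf = as.integer(min_samples_leaf),
    n_trees = as.integer(n_trees),
    KEEP.OUT.ATTRS = FALSE
  )
  g <- g[order(g$n_trees, g$min_samples_leaf, g$min_samples_split), c("n_trees", "min_samples_leaf", "min_samples_split")]
  rownames(g) <- NULL
  g
}

#' Stratified train/test split
#'
#' Each class is split independently at `train_fraction` (train count
#' `round(n_c * fraction)`, always leaving at least one compound on each
#' side), so per-class proportions in the training partition match the whole
#' set within rounding.
#'
#' @param labels Character vector of class labels.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train`, `test` (integer index vectors), `seed` and
#'   `train_fraction`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  cls <- unique(labels)
  cnt <- table(labels)
  if (any(cnt < 2L)) stop("class with fewer than 2 members: ", names(cnt)[cnt < 2][1])
  train <- with_seed(seed, {
    out <- integer()
    for (cl in sort(cls)) {
      idx <- which(labels == cl)
      k <- round(length(idx) * train_fraction)
      k <- min(max(k, 1L), length(idx) - 1L)
      out <- c(out, sample(idx, k))
    }
    out
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train),
       seed = as.integer(seed), train_fraction = train_fraction)
}

# ranger backend --------------------------------------------------------------

.ranger_defaults <- function(p) {
  list(mtry = floor(sqrt(p)), sample_fraction = 1, replace = TRUE,
       split_rule = "gini", respect_unordered_factors = FALSE)
}

#' Train a multiclass random-forest model
#'
#' Fits a probability forest with ranger (per-leaf class frequencies of the
#' in-bag samples) and exports every tree into a backend-independent node
#' table. Remaining hyperparameters stay at conventional random-forest
#' defaults (`mtry = floor(sqrt(p))`, bootstrap sampling with replacement),
#' recorded in the model manifest.
#'
#' @param X Binary feature matrix (rows = compounds, columns = fingerprint bits).
#' @param y Character vector of class labels.
#' @param params One row of [hyperparameter_grid()] (or a list with elements
#'   `n_trees`, `min_samples_leaf`, `min_samples_split`).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `shapcf_model`: list with `trees` (node tables), `class_order`,
#'   `params`, `seed`, `n_features` and `manifest`.
#' @export
train_model <- function(X, y, params = list(n_trees = 100L, min_samples_leaf = 1L, min_samples_split = 2L),
                        seed = 1L) {
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  class_order <- class_labels()[class_labels() %in% unique(y)]
  if (length(class_order) < length(unique(y))) {
    class_order <- sort(unique(y))  # labels outside the standard four
  }
  yf <- factor(y, levels = class_order)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  defaults <- .ranger_defaults(ncol(X))
  rf <- ranger::ranger(
    x = X, y = yf, probability = TRUE,
    num.trees = as.integer(params$n_trees),
    min.node.size = as.integer(params$min_samples_split),
    min.bucket = as.integer(params$min_samples_leaf),
    mtry = defaults$mtry, replace = defaults$replace,
    sample.fraction = defaults$sample_fraction,
    seed = as.integer(seed), num.threads = 1L
  )
  trees <- lapply(seq_len(rf$num.trees), function(t) .export_tree(rf, t, class_order))
  model <- structure(
    list(
      trees = trees, class_order = class_order,
      params = list(n_trees = as.integer(params$n_trees),
                    min_samples_leaf = as.integer(params$min_samples_leaf),
                    min_samples_split = as.integer(params$min_samples_split)),
      seed = as.integer(seed), n_features = ncol(X),
      manifest = c(defaults, backend = paste0("ranger ", utils::packageVersion("ranger")))
    ),
    class = "shapcf_model"
  )
  attr(model, "shap_cache") <- new.env(parent = emptyenv())
  model
}

.export_tree <- function(rf, t, class_order) {
  ti <- ranger::treeInfo(rf, t)
  pred_cols <- paste0("pred.", class_order)
  if (!all(pred_cols %in% colnames(ti))) {
    pred_cols <- grep("^pred", colnames(ti), value = TRUE)  # fallback naming
  }
  leafp <- as.matrix(ti[, pred_cols, drop = FALSE])
  colnames(leafp) <- class_order
  list(
    left = ti$leftChild + 1L,
    right = ti$rightChild + 1L,
    feature = ti$splitvarID + 1L,
    threshold = ti$splitval,
    terminal = ti$terminal,
    leafp = leafp
  )
}

#' @export
print.shapcf_model <- function(x, ...) {
  cat("<shapcf_model> ", length(x$trees), " trees, ", x$n_features, " features, classes: ",
      paste(x$class_order, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# Traversal -------------------------------------------------------------------

.predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  if (length(tree$terminal) == 1L) return(tree$leafp[node, , drop = FALSE])
  repeat {
    open <- which(!tree$terminal[node])
    if (!length(open)) break
    nd <- node[open]
    goleft <- X[cbind(open, tree$feature[nd])] <= tree$threshold[nd]
    node[open] <- ifelse(goleft, tree$left[nd], tree$right[nd])
  }
  tree$leafp[node, , drop = FALSE]
}

#' Predict class probabilities
#'
#' The ensemble output is the unweighted mean of the per-tree leaf class
#' vectors reached by the input; rows sum to one.
#'
#' @param model A `shapcf_model`.
#' @param X A feature matrix, a single 0/1 vector, or a `shapcf_fp`.
#' @return Matrix of class probabilities (rows = inputs, columns in
#'   `model$class_order`).
#' @export
predict_probabilities <- function(model, X) {
  if (inherits(X, "shapcf_fp")) X <- matrix(fp_dense(X), nrow = 1)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$n_features) {
    stop("input has ", ncol(X), " features; model expects ", model$n_features)
  }
  acc <- matrix(0, nrow(X), length(model$class_order))
  for (tree in model$trees) acc <- acc + .predict_tree(tree, X)
  out <- acc / length(model$trees)
  colnames(out) <- model$class_order
  out
}

#' Hard class assignment from probabilities
#'
#' Argmax over classes; exact ties go to the smallest class code (`DT` first).
#'
#' @param probs Probability matrix or vector in class-code order.
#' @return Character vector of class labels.
#' @export
assign_class <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  cls <- colnames(probs)
  if (is.null(cls)) cls <- class_labels()[seq_len(ncol(probs))]
  cls[apply(probs, 1, which.max)]
}

# Metrics ---------------------------------------------------------------------

.class_tally <- function(predictions, truths, cl) {
  tp <- sum(predictions == cl & truths == cl)
  fp <- sum(predictions == cl & truths != cl)
  fn <- sum(predictions != cl & truths == cl)
  tn <- sum(predictions != cl & truths != cl)
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

.metrics_from_tally <- function(tly) {
  tp <- unname(tly["TP"]); fp <- unname(tly["FP"])
  tn <- unname(tly["TN"]); fn <- unname(tly["FN"])
  safe <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  tpr <- safe(tp, tp + fn); tnr <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp); rec <- tpr
  f1 <- safe(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) c(0, TRUE) else c((tp * tn - fp * fn) / mcc_den, FALSE)
  list(
    values = c(BA = (tpr[1] + tnr[1]) / 2, precision = prec[1], recall = rec[1],
               F1 = f1[1], MCC = mcc[1]),
    degenerate = any(c(tpr[2], tnr[2], prec[2], f1[2], mcc[2]) == 1)
  )
}

#' Multiclass performance metrics
#'
#' Computes balanced accuracy, precision, recall, F1 and the Matthews
#' correlation coefficient from one-vs-rest confusion tallies for each class:
#' `BA = (TPR + TNR) / 2`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `F1 = 2 TP / (2 TP + FP + FN)` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Macro values
#' are unweighted means over the classes. Ratios with zero denominators are
#' reported as 0 and flagged.
#'
#' @param predictions,truths Equal-length character vectors of class labels.
#' @param classes Class set to evaluate (defaults to [class_labels()]).
#' @return List with `per_class` (data.frame: class, TP, FP, TN, FN, metrics,
#'   degenerate flag) and `macro` (named numeric vector).
#' @export
compute_metrics <- function(predictions, truths, classes = class_labels()) {
  if (length(predictions) != length(truths)) stop("prediction/truth lengths differ")
  if (length(predictions) == 0L) stop("empty prediction vector")
  rows <- lapply(classes, function(cl) {
    tly <- .class_tally(predictions, truths, cl)
    m <- .metrics_from_tally(tly)
    data.frame(class = cl, t(tly), t(m$values), degenerate = m$degenerate,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  macro <- colMeans(per_class[, c("BA", "precision", "recall", "F1", "MCC")])
  list(per_class = per_class, macro = macro)
}

# Tuning ----------------------------------------------------------------------

#' Select hyperparameters on an inner validation split
#'
#' The training partition is split again 70/30 (stratified); every grid row is
#' trained on the inner-training part and scored by macro balanced accuracy on
#' the inner-validation part. The first row attaining the maximum score wins,
#' which by the grid's ordering prefers fewer trees, then smaller leaves, then
#' smaller split sizes.
#'
#' @param X,y Training features and labels.
#' @param grid Data.frame of candidate hyperparameters (see
#'   [hyperparameter_grid()]).
#' @param seed Integer seed for the inner split and the candidate fits.
#' @param inner_fraction Inner training fraction (default 0.7).
#' @return List with `params` (winning row as a list), `scores` (macro BA per
#'   grid row) and `inner_split`.
#' @export
tune_hyperparameters <- function(X, y, grid = hyperparameter_grid(), seed = 1L,
                                 inner_fraction = 0.7) {
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  split <- stratified_split(y, inner_fraction, seed)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- train_model(X[split$train, , drop = FALSE], y[split$train],
                     as.list(grid[i, ]), seed = seed)
    pred <- assign_class(predict_probabilities(m, X[split$test, , drop = FALSE]))
    scores[i] <- compute_metrics(pred, y[split$test])$macro["BA"]
  }
  best <- which.max(scores)
  list(params = as.list(grid[best, ]), scores = scores, inner_split = split)
}

# Trials ----------------------------------------------------------------------

#' Run independent prediction trials
#'
#' Trial `t` uses seed `base_seed + t`: the compounds are split 70/30
#' (stratified), hyperparameters are selected on the training partition (see
#' [tune_hyperparameters()]), the final model is trained on the entire
#' training partition, and the test partition is scored.
#'
#' @param X,y Features and labels of the (balanced) dataset.
#' @param n_trials Number of trials (default 10).
#' @param base_seed Base seed.
#' @param grid Hyperparameter grid; a single-row grid skips the inner search.
#' @param train_fraction Outer training fraction.
#' @return A `shapcf_trials` list: per-trial `split`, `params`, `model`,
#'   `metrics`, plus `summary` (median and quartiles of every macro metric
#'   over trials) and `metric_table` (tidy per-trial macro metrics).
#' @export
run_trials <- function(X, y, n_trials = 10L, base_seed = 0L,
                       grid = hyperparameter_grid(), train_fraction = 0.7) {
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    seed <- as.integer(base_seed) + t
    split <- stratified_split(y, train_fraction, seed)
    Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
    params <- if (nrow(grid) == 1L) as.list(grid[1, ]) else {
      tune_hyperparameters(Xtr, ytr, grid, seed)$params
    }
    model <- train_model(Xtr, ytr, params, seed = seed)
    pred <- assign_class(predict_probabilities(model, X[split$test, , drop = FALSE]))
    metrics <- compute_metrics(pred, y[split$test])
    trials[[t]] <- list(trial = t, seed = seed, split = split, params = params,
                        model = model, metrics = metrics)
  }
  metric_table <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial = tr$trial, t(tr$metrics$macro))
  }))
  summ <- do.call(rbind, lapply(c("BA", "precision", "recall", "F1", "MCC"), function(mname) {
    v <- metric_table[[mname]]
    data.frame(metric = mname, median = median(v),
               q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)))
  }))
  structure(list(trials = trials, metric_table = metric_table, summary = summ,
                 base_seed = as.integer(base_seed)),
            class = "shapcf_trials")
}

#' @export
print.shapcf_trials <- function(x, ...) {
  cat("<shapcf_trials> ", length(x$trials), " trials\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Serialization ---------------------------------------------------------------

#' Serialize a model to a self-describing JSON tree dump
#'
#' The dump holds, per tree, the node table (children, split feature,
#' threshold, terminal flag, per-class leaf probability vectors) so any
#' consumer can traverse the trees without the training backend.
#'
#' @param model A `shapcf_model`.
#' @param path Output file.
#' @return `path`, invisibly. `model_from_json()` returns the restored model.
#' @export
model_to_json <- function(model, path) {
  payload <- list(
    class_order = model$class_order, params = model$params, seed = model$seed,
    n_features = model$n_features,
    trees = lapply(model$trees, function(tr) {
      list(left = tr$left, right = tr$right, feature = tr$feature,
           threshold = tr$threshold, terminal = tr$terminal,
           leafp = unname(tr$leafp))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  cls <- as.character(unlist(p$class_order))
  trees <- lapply(p$trees, function(tr) {
    leafp <- do.call(rbind, lapply(tr$leafp, num))
    colnames(leafp) <- cls
    list(left = as.integer(num(tr$left)), right = as.integer(num(tr$right)),
         feature = as.integer(num(tr$feature)), threshold = num(tr$threshold),
         terminal = vapply(tr$terminal, isTRUE, logical(1)), leafp = leafp)
  })
  p$class_order <- cls
  model <- structure(
    list(trees = trees, class_order = p$class_order, params = p$params,
         seed = p$seed, n_features = p$n_features, manifest = list(restored = TRUE)),
    class = "shapcf_model"
  )
  attr(model, "shap_cache") <- new.env(parent = emptyenv())
  model
}
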