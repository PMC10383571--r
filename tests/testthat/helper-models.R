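# Shared test helpers: hand-built tree models in the package's exported node
# format, random tree-ensemble generators, and small molecule fixtures.

# A model made of explicit node tables (used to test traversal and Shapley
# attribution against hand-computed values and brute-force enumeration).
make_model <- function(trees, n_features, classes = class_labels()) {
  trees <- lapply(trees, function(tr) {
    colnames(tr$leafp) <- classes
    tr
  })
  structure(
    list(trees = trees, class_order = classes, params = list(), seed = 0L,
         n_features = n_features, manifest = list()),
    class = "shapcf_model"
  )
}

# A single-split stump on `feature`, returning `left`/`right` leaf vectors.
make_stump <- function(feature, left, right) {
  leafp <- rbind(rep(NA_real_, length(left)), left, right)
  dimnames(leafp) <- NULL
  list(
    left = c(2L, NA, NA), right = c(3L, NA, NA),
    feature = c(feature, NA, NA), threshold = c(0.5, NA, NA),
    terminal = c(FALSE, TRUE, TRUE),
    leafp = leafp
  )
}

# Random binary tree with splits on features 1..n_feat, thresholds 0.5 and
# random class-probability leaves.
random_tree <- function(n_feat, depth) {
  nodes <- list()
  build <- function(d) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()
    if (d == 0L || stats::runif(1) < 0.3) {
      p <- stats::runif(4); p <- p / sum(p)
      nodes[[id]] <<- list(terminal = TRUE, leafp = p, feature = NA_integer_,
                           threshold = NA_real_, left = NA_integer_, right = NA_integer_)
    } else {
      f <- sample.int(n_feat, 1L)
      l <- build(d - 1L); r <- build(d - 1L)
      nodes[[id]] <<- list(terminal = FALSE, feature = as.integer(f), threshold = 0.5,
                           left = l, right = r, leafp = rep(NA_real_, 4))
    }
    id
  }
  build(depth)
  list(
    left = vapply(nodes, function(n) as.integer(n$left), integer(1)),
    right = vapply(nodes, function(n) as.integer(n$right), integer(1)),
    feature = vapply(nodes, function(n) as.integer(n$feature), integer(1)),
    threshold = vapply(nodes, function(n) as.numeric(n$threshold), numeric(1)),
    terminal = vapply(nodes, function(n) n$terminal, logical(1)),
    leafp = do.call(rbind, lapply(nodes, function(n) n$leafp))
  )
}

random_ensemble <- function(n_feat, n_trees, depth) {
  make_model(lapply(seq_len(n_trees), function(i) random_tree(n_feat, depth)), n_feat)
}

# The interventional ensemble game: v(S) = mean over trees and background
# rows of the class-`cl` output on hybrids taking bits in S from `x`.
ensemble_game <- function(model, x, bg, cl) {
  function(S) {
    hyb <- bg
    if (length(S)) hyb[, S] <- matrix(x[S], nrow(bg), length(S), byrow = TRUE)
    mean(predict_probabilities(model, hyb)[, cl])
  }
}

# Small molecule fixtures (built fresh per call; parsing is cheap).
fixture_mols <- function() {
  list(
    ethanol = parse_structure("CCO"),
    piperidine = parse_structure("C1CCNCC1"),
    benzene = parse_structure("c1ccccc1"),
    paracetamol = parse_structure("CC(=O)Nc1ccc(O)cc1")
  )
}

# Activity-record table where every row passes the default curation filters.
passing_records <- function(n = 3L) {
  data.frame(
    potency_value = rep(1, n), potency_type = rep("Ki", n), relation = rep("=", n),
    mass_da = rep(350, n), confidence_score = rep(9L, n),
    activity_comment = rep("", n), stringsAsFactors = FALSE
  )
}
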