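# Exact interventional Shapley attributions for tree ensembles over binary
# fingerprint bits.
#
# For one tree T and one background sample z, the coalition game of a
# foreground x is v(S) = T(hybrid(S)), where the hybrid takes the bits in S
# from x and every other bit from z. Each leaf contributes through its path
# constraints: a path bit that x satisfies but z violates must be IN the
# coalition for the leaf to be reached (set I, |I| = a), a bit that z
# satisfies but x violates must be OUT (set O, |O| = b), a bit both satisfy
# never blocks the leaf, and a bit both violate makes the leaf unreachable.
# The Shapley value of such a conjunction game has a closed form that does
# not depend on the total number of players:
#   i in I:  phi_i = +leaf_value * (a-1)! b! / (a+b)!
#   i in O:  phi_i = -leaf_value * a! (b-1)! / (a+b)!
# Summing leaf contributions, then averaging over background samples and
# trees (Shapley linearity), yields exact attributions whose total satisfies
# local accuracy: base + sum(phi) = model output for x.

# Closed-form weight tables up to path length `nmax`.
.shap_weight_tables <- function(nmax) {
  win <- matrix(0, nmax + 1L, nmax + 1L)   # [a+1, b+1]
  wout <- matrix(0, nmax + 1L, nmax + 1L)
  for (a in 1:nmax) {
    for (b in 0:(nmax - a)) {
      w <- exp(lgamma(a) + lgamma(b + 1) - lgamma(a + b + 1))
      win[a + 1L, b + 1L] <- w
      wout[b + 1L, a + 1L] <- w  # symmetric role swap: a! (b-1)! / (a+b)!
    }
  }
  list(win = win, wout = wout)
}

# Extract, per tree, the reachable leaves and their binarized path
# constraints. Feature domains are {0, 1}; a split "x <= t" keeps 0 (and 1 if
# t >= 1) on the left. Constraints that admit both values are dropped;
# contradictory constraints prune the leaf.
.tree_leaf_paths <- function(tree) {
  leaves <- list()
  walk <- function(node, feats, reqs) {
    if (tree$terminal[node]) {
      leaves[[length(leaves) + 1L]] <<- list(feats = feats, reqs = reqs,
                                             leafp = tree$leafp[node, ])
      return(invisible())
    }
    f <- tree$feature[node]; thr <- tree$threshold[node]
    left_vals <- c(0, 1)[c(0 <= thr, 1 <= thr)]
    for (side in c("L", "R")) {
      vals <- if (side == "L") left_vals else setdiff(c(0, 1), left_vals)
      child <- if (side == "L") tree$left[node] else tree$right[node]
      if (length(vals) == 0L) next  # side unreachable for binary inputs
      j <- match(f, feats)
      if (length(vals) == 2L) {          # vacuous split for binary inputs
        walk(child, feats, reqs)
      } else if (is.na(j)) {
        walk(child, c(feats, f), c(reqs, vals))
      } else if (reqs[j] == vals) {      # repeated consistent constraint
        walk(child, feats, reqs)
      }                                  # else contradictory: prune
    }
  }
  walk(1L, integer(), numeric())
  leaves
}

# Precompute the per-tree structures used by interventional_shap(). Stored as
# flat index vectors so the per-foreground work is pure matrix algebra.
.shap_prepare <- function(model) {
  lapply(model$trees, function(tree) {
    leaves <- .tree_leaf_paths(tree)
    if (!length(leaves)) return(NULL)
    feats <- unlist(lapply(leaves, `[[`, "feats"))
    tested <- sort(unique(feats))
    pathlen <- vapply(leaves, function(l) length(l$feats), integer(1))
    list(
      tested = tested,
      rows = rep(seq_along(leaves), pathlen),
      cols = match(feats, tested),
      reqs = unlist(lapply(leaves, `[[`, "reqs")),
      leafp = do.call(rbind, lapply(leaves, `[[`, "leafp")),
      n_leaves = length(leaves),
      max_path = max(pathlen, 0L)
    )
  })
}

.get_shap_cache <- function(model) {
  env <- attr(model, "shap_cache")
  if (is.null(env)) return(.shap_prepare(model))
  if (is.null(env$paths)) env$paths <- .shap_prepare(model)
  env$paths
}

#' Exact interventional Shapley attributions for a tree-ensemble prediction
#'
#' Computes, for every class and fingerprint bit, the exact Shapley value of
#' the interventional coalition game in which out-of-coalition bits are
#' replaced by values from background samples (by default the model's full
#' training partition). The per-class base value is the mean model probability
#' over the background set, and local accuracy holds exactly:
#' `base_c + sum(phi[c, ]) = p_c(foreground)`.
#'
#' @param model A `shapcf_model`.
#' @param foreground A `shapcf_fp` or 0/1 vector of length `model$n_features`.
#' @param background Matrix of background fingerprints (rows = samples), a
#'   list of `shapcf_fp`, or a single fingerprint.
#' @return A `shapcf_shap`: list with `phi` (class x bit matrix), `base`
#'   (per-class vector), `foreground_bits` (set bit indices), `probs` (model
#'   output for the foreground) and `background_size`.
#' @export
interventional_shap <- function(model, foreground, background) {
  fg_bits <- NULL
  if (inherits(foreground, "shapcf_fp")) {
    fg_bits <- foreground$on_bits
    foreground <- fp_dense(foreground)
  }
  if (inherits(background, "shapcf_fp")) background <- list(background)
  if (is.list(background) && !is.matrix(background)) {
    background <- fingerprint_matrix(background)
  }
  if (is.null(dim(background))) background <- matrix(background, nrow = 1)
  if (nrow(background) == 0L) stop("background set is empty")
  if (length(foreground) != model$n_features || ncol(background) != model$n_features) {
    stop("feature dimensions of foreground/background do not match the model")
  }
  if (is.null(fg_bits)) fg_bits <- which(foreground == 1)

  C <- length(model$class_order)
  nB <- nrow(background)
  phi <- matrix(0, C, model$n_features, dimnames = list(model$class_order, NULL))
  paths <- .get_shap_cache(model)
  maxp <- max(c(1L, vapply(paths, function(p) if (is.null(p)) 0L else p$max_path, integer(1))))
  wt <- .shap_weight_tables(maxp)

  for (p in paths) {
    if (is.null(p) || length(p$tested) == 0L) next
    m <- length(p$tested); L <- p$n_leaves
    xv <- foreground[p$tested]
    xmatch <- xv[p$cols] == p$reqs
    req1 <- p$reqs == 1
    A1 <- A0 <- B1 <- B0 <- matrix(0, L, m)
    idx <- cbind(p$rows, p$cols)
    A1[idx[xmatch & req1, , drop = FALSE]] <- 1
    A0[idx[xmatch & !req1, , drop = FALSE]] <- 1
    B1[idx[!xmatch & req1, , drop = FALSE]] <- 1
    B0[idx[!xmatch & !req1, , drop = FALSE]] <- 1

    Z <- background[, p$tested, drop = FALSE]
    Zc <- 1 - Z
    a_cnt <- tcrossprod(Zc, A1) + tcrossprod(Z, A0)     # nB x L
    b_cnt <- tcrossprod(Z, B1) + tcrossprod(Zc, B0)
    dead <- (tcrossprod(Zc, B1) + tcrossprod(Z, B0)) > 0
    ab_idx <- cbind(as.vector(a_cnt) + 1L, as.vector(b_cnt) + 1L)
    Wi <- matrix(wt$win[ab_idx], nB, L)
    Wo <- matrix(wt$wout[ab_idx], nB, L)
    Wi[dead] <- 0; Wo[dead] <- 0

    for (c in seq_len(C)) {
      lc <- p$leafp[, c]
      inn <- colSums((Wi %*% (A1 * lc)) * Zc + (Wi %*% (A0 * lc)) * Z)
      out <- colSums((Wo %*% (B1 * lc)) * Z + (Wo %*% (B0 * lc)) * Zc)
      phi[c, p$tested] <- phi[c, p$tested] + (inn - out)
    }
  }
  phi <- phi / (length(model$trees) * nB)
  base <- colMeans(predict_probabilities(model, background))
  probs <- drop(predict_probabilities(model, matrix(foreground, nrow = 1)))
  structure(
    list(phi = phi, base = base, foreground_bits = as.integer(fg_bits),
         probs = probs, background_size = nB),
    class = "shapcf_shap"
  )
}

#' @export
print.shapcf_shap <- function(x, ...) {
  cat("<shapcf_shap> background n=", x$background_size, "\n", sep = "")
  s <- partition_present_absent(x)
  print(s)
  invisible(x)
}

#' Brute-force Shapley values of an arbitrary coalition game
#'
#' Direct evaluation of
#' `phi_i = sum_S |S|! (M-|S|-1)! / M! * (v(S + i) - v(S))` over all subsets,
#' used as the independent oracle for the tree algorithm.
#'
#' @param value_function Function taking an integer vector of player indices
#'   (a coalition, possibly empty) and returning a numeric value.
#' @param M Number of players (at most 16; beyond that, use
#'   [interventional_shap()]).
#' @return Numeric vector of M Shapley values.
#' @export
brute_force_shapley <- function(value_function, M) {
  if (M > 16L) stop("M too large for enumeration; use interventional_shap() for tree models")
  if (M < 1L) stop("M must be at least 1")
  n_sub <- 2^M
  vals <- numeric(n_sub)
  sizes <- integer(n_sub)
  members <- vector("list", n_sub)
  for (s in 0:(n_sub - 1)) {
    mem <- which(bitwAnd(s, 2^(0:(M - 1))) > 0)
    members[[s + 1]] <- mem
    sizes[s + 1] <- length(mem)
    vals[s + 1] <- value_function(mem)
  }
  w <- factorial(0:(M - 1)) * factorial(M - 1 - (0:(M - 1))) / factorial(M)
  phi <- numeric(M)
  for (s in 0:(n_sub - 1)) {
    for (i in seq_len(M)) {
      if (bitwAnd(s, 2^(i - 1)) == 0) {
        phi[i] <- phi[i] + w[sizes[s + 1] + 1] * (vals[bitwOr(s, 2^(i - 1)) + 1] - vals[s + 1])
      }
    }
  }
  phi
}

#' Split attributions into present- and absent-feature sums
#'
#' @param expl A `shapcf_shap`.
#' @return Data.frame with one row per class: `present_sum` (attribution mass
#'   on bits set in the foreground), `absent_sum` (mass on unset bits), `base`
#'   and `prob`; `present_sum + absent_sum + base = prob` per class.
#' @export
partition_present_absent <- function(expl) {
  present <- expl$foreground_bits
  classes <- rownames(expl$phi)
  ps <- if (length(present)) rowSums(expl$phi[, present, drop = FALSE]) else numeric(nrow(expl$phi))
  as_ <- rowSums(expl$phi) - ps
  data.frame(class = classes, present_sum = unname(ps), absent_sum = unname(as_),
             base = unname(expl$base), prob = unname(expl$probs),
             stringsAsFactors = FALSE)
}

#' Cumulative per-class attribution summary over a test set
#'
#' Restricted to correctly predicted compounds: for each one, the present- and
#' absent-feature attribution sums are taken for its true (= predicted) class,
#' then aggregated per class across compounds. The default aggregate is the
#' mean; `aggregate = "sum"` gives the summed variant (identical up to the
#' per-class compound count).
#'
#' @param model A `shapcf_model`.
#' @param fps_test List of test-set `shapcf_fp`.
#' @param y_test True labels of the test set.
#' @param background Background fingerprint matrix (training partition).
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Data.frame with one row per class: `present`, `absent`,
#'   `n_compounds` and `empty` (TRUE when no compound of the class was
#'   correctly predicted; its cells are NA, not zero).
#' @export
cumulative_shap <- function(model, fps_test, y_test, background,
                            aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  X <- fingerprint_matrix(fps_test)
  pred <- assign_class(predict_probabilities(model, X))
  correct <- which(pred == y_test)
  acc <- list()
  for (i in correct) {
    expl <- interventional_shap(model, fps_test[[i]], background)
    pa <- partition_present_absent(expl)
    row <- pa[pa$class == y_test[i], ]
    acc[[length(acc) + 1L]] <- data.frame(class = y_test[i],
                                          present = row$present_sum,
                                          absent = row$absent_sum)
  }
  acc <- if (length(acc)) do.call(rbind, acc) else data.frame(class = character(), present = numeric(), absent = numeric())
  out <- do.call(rbind, lapply(class_labels(), function(cl) {
    sub <- acc[acc$class == cl, ]
    if (nrow(sub) == 0L) {
      data.frame(class = cl, present = NA_real_, absent = NA_real_,
                 n_compounds = 0L, empty = TRUE)
    } else {
      f <- if (aggregate == "mean") mean else sum
      data.frame(class = cl, present = f(sub$present), absent = f(sub$absent),
                 n_compounds = nrow(sub), empty = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}
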