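# Counterfactual search: populate narrow chemical space around a base
# compound with structural analogues, predict them with the multiclass
# model, and qualify candidates whose predicted class flips to the target
# class (dual-target by default). Two pluggable generation strategies are
# built in: random SMILES token edits with validity filtering, and
# substituent transformations drawn from a fragment library.

#' Default substituent library for analogue generation
#'
#' Substituents frequently observed in active compounds: halogens, methyl,
#' methoxy, amide, phenyl, benzyl, piperidinyl, piperazinyl, morpholinyl,
#' azetidinyl and sulfonamide. Fragments attach through their first atom and
#' use ring-closure digits 5+ so they can be spliced into any base SMILES.
#'
#' @return Named character vector of substituent SMILES.
#' @export
default_fragment_library <- function() {
  c(
    fluoro = "F", chloro = "Cl", bromo = "Br", methyl = "C", methoxy = "OC",
    amide = "C(=O)N", phenyl = "c5ccccc5", benzyl = "Cc5ccccc5",
    piperidinyl = "N5CCCCC5", piperazinyl = "N5CCNCC5",
    morpholinyl = "N5CCOCC5", azetidinyl = "N5CCC5",
    sulfonamide = "S(=O)(=O)N"
  )
}

# Insertion point after an atom token: skip trailing ring-closure digits so
# "c1(F)..." style branches stay syntactically valid.
.insertion_point <- function(smiles, token_end) {
  pos <- token_end
  chars <- strsplit(smiles, "")[[1]]
  while (pos < length(chars)) {
    nxt <- chars[pos + 1L]
    if (grepl("[0-9%]", nxt)) pos <- pos + 1L else break
  }
  pos
}

# Batch validity filter: full sanitizing parse, drop failures, the base
# itself and canonical-key duplicates; preserves first-seen order.
.validate_candidates <- function(smiles, base_key) {
  smiles <- unique(smiles[nzchar(smiles)])
  if (!length(smiles)) return(character())
  mols <- parse_structures(smiles, on_error = "drop")
  parsed <- !vapply(mols, is.null, logical(1))
  keys <- rep(NA_character_, length(smiles))
  keys[parsed] <- vapply(mols[parsed], `[[`, character(1), "canonical_key")
  keep <- parsed & keys != base_key & !duplicated(keys)
  smiles[keep]
}

#' Analogues by random SMILES token edits
#'
#' Applies `k` point edits (substitute, insert or delete an atom token, `k`
#' drawn from `mutations_range`) to the base compound's SMILES and keeps the
#' edited strings that decode to valid molecules. Aromatic tokens are
#' substituted within the aromatic subset and aliphatic tokens within the
#' aliphatic subset. Results are deduplicated by canonical key, exclude the
#' base itself, and are deterministic for a fixed seed.
#'
#' @param base A `shapcf_mol`.
#' @param n_candidates Number of analogues requested (the attempt budget is
#'   capped, so fewer may be returned for very constrained bases).
#' @param mutations_range Integer vector of edit counts to draw from.
#' @param seed Integer seed.
#' @return Character vector of analogue SMILES.
#' @export
mutate_string_analogues <- function(base, n_candidates, mutations_range = 1:2, seed = 0L) {
  if (n_candidates < 1L) return(character())
  rt <- .ob_canonical(base$smiles)
  if (is.na(rt) || rt != base$canonical_key) stop("base SMILES does not round-trip")
  aromatic <- c("c", "n", "o", "s")
  aliphatic <- c("C", "N", "O", "S", "F", "Cl", "Br")
  out <- character()
  batch <- 0L
  with_seed(seed, {
    while (length(out) < n_candidates && batch < 12L) {
      batch <- batch + 1L
      raw <- character(max(200L, n_candidates))
      for (i in seq_along(raw)) {
        smi <- base$smiles
        k <- sample(rep(mutations_range, 2L), 1L)
        for (e in seq_len(k)) {
          toks <- .tokenize_atoms(smi)
          if (nrow(toks) < 2L) break
          j <- sample.int(nrow(toks), 1L)
          op <- sample(c("sub", "ins", "del"), 1L)
          if (op == "sub") {
            pool <- if (toks$token[j] %in% aromatic) aromatic else aliphatic
            pool <- setdiff(pool, toks$token[j])
            smi <- paste0(substr(smi, 1, toks$start[j] - 1L), sample(pool, 1L),
                          substr(smi, toks$end[j] + 1L, nchar(smi)))
          } else if (op == "ins") {
            ip <- .insertion_point(smi, toks$end[j])
            smi <- paste0(substr(smi, 1, ip), sample(c("C", "N", "O"), 1L),
                          substr(smi, ip + 1L, nchar(smi)))
          } else {
            if (toks$token[j] %in% aromatic) next  # ring atoms: skip deletion
            tail_start <- toks$end[j] + 1L
            if (tail_start <= nchar(smi) && grepl("^[0-9%]", substr(smi, tail_start, tail_start))) next
            smi <- paste0(substr(smi, 1, toks$start[j] - 1L),
                          substr(smi, tail_start, nchar(smi)))
          }
        }
        raw[i] <- smi
      }
      out <- c(out, .validate_candidates(raw, base$canonical_key))
      out <- out[!duplicated(out)]
    }
  })
  head(out, n_candidates)
}

#' Analogues by substituent transformations
#'
#' Three edit families around the base compound: attach a library substituent
#' at a substitutable atom (H-bearing and not a ring junction), replace a
#' terminal substituent (an acyclic parenthesised branch) with a library
#' substituent, and delete such a branch. All candidates are sanitized,
#' deduplicated and deterministic for a fixed seed; a base without any
#' substitutable site yields an empty set with a warning.
#'
#' @param base A `shapcf_mol`.
#' @param fragment_library Character vector of substituent SMILES (ring
#'   digits 5+); defaults to [default_fragment_library()].
#' @param seed Integer seed (used only to subsample down to `max_candidates`).
#' @param ops Edit families to enable.
#' @param max_candidates Optional cap on the returned set.
#' @return Character vector of analogue SMILES.
#' @export
transform_analogues <- function(base, fragment_library = default_fragment_library(),
                                seed = 0L, ops = c("attach", "replace", "delete"),
                                max_candidates = Inf) {
  if (length(fragment_library) == 0L) stop("fragment library is empty")
  smi <- base$smiles
  toks <- .tokenize_atoms(smi)
  cand <- character()

  ring_bond_count <- integer(base$n_atoms)
  if (nrow(base$bonds)) {
    g <- igraph::graph_from_edgelist(cbind(base$bonds$from, base$bonds$to), directed = FALSE)
    if (igraph::vcount(g) < base$n_atoms) g <- igraph::add_vertices(g, base$n_atoms - igraph::vcount(g))
    br <- as.integer(igraph::bridges(g))
    ring_edges <- setdiff(seq_len(nrow(base$bonds)), br)
    tab <- tabulate(c(base$bonds$from[ring_edges], base$bonds$to[ring_edges]), nbins = base$n_atoms)
    ring_bond_count <- tab
  }
  substitutable <- which(base$n_h >= 1L & ring_bond_count <= 2L)

  if ("attach" %in% ops) {
    for (a in substitutable) {
      ip <- .insertion_point(smi, toks$end[a])
      for (frag in fragment_library) {
        cand <- c(cand, paste0(substr(smi, 1, ip), "(", frag, ")",
                               substr(smi, ip + 1L, nchar(smi))))
      }
    }
  }

  if (any(c("replace", "delete") %in% ops)) {
    branches <- .acyclic_branches(smi)
    for (b in branches) {
      if ("delete" %in% ops) {
        cand <- c(cand, paste0(substr(smi, 1, b[1] - 1L), substr(smi, b[2] + 1L, nchar(smi))))
      }
      if ("replace" %in% ops) {
        for (frag in fragment_library) {
          cand <- c(cand, paste0(substr(smi, 1, b[1]), frag, substr(smi, b[2], nchar(smi))))
        }
      }
    }
  }

  out <- .validate_candidates(cand, base$canonical_key)
  if (!length(out)) {
    warning("no substitutable site or valid edit for base ", base$canonical_key)
    return(character())
  }
  if (length(out) > max_candidates) {
    out <- with_seed(seed, sort(sample(out, max_candidates)))
  }
  out
}

# Parenthesised acyclic branches "(...)" containing atoms but no ring-closure
# digits: start/end character positions (of the parentheses) in the SMILES.
.acyclic_branches <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  res <- list()
  depth <- 0L
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      start <- stack[length(stack)]
      stack <- stack[-length(stack)]
      inner <- substr(smiles, start + 1L, i - 1L)
      if (!grepl("[0-9%()]", inner) && nrow(.tokenize_atoms(inner)) >= 1L) {
        res[[length(res) + 1L]] <- c(start, i)
      }
    }
  }
  res
}

#' Find counterfactual analogues that flip a prediction to a target class
#'
#' Every candidate is fingerprinted and predicted; a candidate qualifies as a
#' counterfactual when its highest-probability class equals `target_class`.
#' All candidates are returned with their class probabilities, qualification
#' flag and Tanimoto similarity to the base; the qualified subset sorts by
#' descending similarity, then descending target-class probability, then
#' canonical key.
#'
#' @param model A `shapcf_model`.
#' @param base A `shapcf_mol`, correctly predicted as a class other than
#'   `target_class` (counterfactual search is ill-posed otherwise).
#' @param target_class Class the prediction should flip to (default `DT`).
#' @param candidates Character vector of candidate SMILES (from the
#'   generators) or list of `shapcf_mol`.
#' @param n_bits,max_radius Fingerprint parameters (must match the model).
#' @param generator_tag Free-text tag recorded per candidate.
#' @return A `shapcf_cfset`: data.frame with columns `base_id`,
#'   `candidate_smiles`, `canonical_key`, one probability column per class,
#'   `predicted`, `qualified`, `similarity`, `generator_tag`.
#' @export
find_counterfactuals <- function(model, base, target_class = "DT", candidates,
                                 n_bits = 4096L, max_radius = 2L,
                                 generator_tag = "custom") {
  base_fp <- fingerprint(base, n_bits, max_radius)
  base_probs <- predict_probabilities(model, base_fp)
  base_pred <- assign_class(base_probs)
  if (base_pred == target_class) {
    stop("base compound is already predicted as ", target_class,
         "; not a counterfactual setting")
  }
  if (length(candidates) == 0L) {
    return(.empty_cfset(model, base, base_probs, target_class))
  }
  mols <- if (is.character(candidates)) {
    parsed <- parse_structures(candidates, on_error = "drop")
    parsed[!vapply(parsed, is.null, logical(1))]
  } else candidates
  if (length(mols) == 0L) return(.empty_cfset(model, base, base_probs, target_class))
  fps <- lapply(mols, fingerprint, n_bits = n_bits, max_radius = max_radius)
  X <- fingerprint_matrix(fps)
  probs <- predict_probabilities(model, X)
  pred <- assign_class(probs)
  sim <- vapply(fps, tanimoto, numeric(1), b = base_fp)
  tab <- data.frame(
    base_id = if (is.na(base$source_id)) base$canonical_key else base$source_id,
    candidate_smiles = vapply(mols, `[[`, character(1), "smiles"),
    canonical_key = vapply(mols, `[[`, character(1), "canonical_key"),
    stringsAsFactors = FALSE
  )
  colnames(probs) <- paste0("p_", colnames(probs))
  tab <- cbind(tab, probs)
  tab$predicted <- pred
  tab$qualified <- pred == target_class
  tab$similarity <- sim
  tab$generator_tag <- rep_len(generator_tag, nrow(tab))
  qcol <- paste0("p_", target_class)
  ord <- order(!tab$qualified, -tab$similarity, -tab[[qcol]], tab$canonical_key)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "base_probs") <- drop(base_probs)
  attr(tab, "target_class") <- target_class
  class(tab) <- c("shapcf_cfset", "data.frame")
  tab
}

.empty_cfset <- function(model, base, base_probs, target_class) {
  tab <- data.frame(
    base_id = character(), candidate_smiles = character(), canonical_key = character(),
    stringsAsFactors = FALSE
  )
  for (cl in model$class_order) tab[[paste0("p_", cl)]] <- numeric()
  tab$predicted <- character(); tab$qualified <- logical()
  tab$similarity <- numeric(); tab$generator_tag <- character()
  attr(tab, "base_probs") <- drop(base_probs)
  attr(tab, "target_class") <- target_class
  class(tab) <- c("shapcf_cfset", "data.frame")
  tab
}

#' @export
print.shapcf_cfset <- function(x, ...) {
  cat("<shapcf_cfset> ", nrow(x), " candidates, ", sum(x$qualified),
      " qualified counterfactuals (target ", attr(x, "target_class"), ")\n", sep = "")
  invisible(x)
}
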