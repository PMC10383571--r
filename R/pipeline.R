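# End-to-end orchestration: dataset -> balanced classes -> prediction trials
# (split / tune / train / evaluate) -> Shapley attributions on correct test
# predictions -> cumulative per-class summaries -> counterfactual search from
# correctly predicted single-target bases -> attributions and atom maps for
# base/counterfactual pairs -> substructure enrichment tables. Every stage
# writes deterministic CSV/JSON artifacts; re-running an identical
# configuration reproduces them byte for byte.

#' Build a pipeline configuration
#'
#' @param benchmark A [benchmark_spec()] to generate the input dataset, or
#'   NULL when `input` is given.
#' @param input Path to a compound file readable by [read_compounds()]
#'   (ignored when `benchmark` is set).
#' @param out_dir Output directory for all artifacts.
#' @param n_bits,max_radius Fingerprint parameters.
#' @param grid Hyperparameter grid for tuning (single-row grids skip the
#'   inner search).
#' @param n_trials,base_seed Trial protocol.
#' @param background_size Background subsample size for Shapley attributions
#'   (NULL = the full training partition).
#' @param shap_per_trial Maximum number of correctly predicted test compounds
#'   explained per trial (NULL = all).
#' @param cf_target Target class of the counterfactual search.
#' @param cf_n_bases Number of correctly predicted single-target base
#'   compounds to expand (0 disables the counterfactual stage).
#' @param cf_budget Candidate budget per base compound and strategy.
#' @param cf_fragments Fragment library for the substituent-transform
#'   strategy; `"auto"` uses [default_fragment_library()] plus, for benchmark
#'   runs, the substituents recurrent in the active training classes (the
#'   planted motifs).
#' @param enrichment_patterns Named SMARTS vector for the enrichment table;
#'   `"auto"` uses the benchmark motif patterns plus piperidine/piperazine.
#' @param n_depictions Number of base/counterfactual pairs rendered as SVG.
#' @return A `shapcf_config` list.
#' @export
pipeline_config <- function(benchmark = benchmark_spec(n_per_class = 50),
                            input = NULL,
                            out_dir = "shapcf_run",
                            n_bits = 4096L, max_radius = 2L,
                            grid = hyperparameter_grid(),
                            n_trials = 10L, base_seed = 0L,
                            background_size = 50L,
                            shap_per_trial = NULL,
                            cf_target = "DT",
                            cf_n_bases = 10L,
                            cf_budget = 1000L,
                            cf_fragments = "auto",
                            enrichment_patterns = "auto",
                            n_depictions = 2L) {
  cfg <- list(
    benchmark = benchmark, input = input, out_dir = out_dir,
    n_bits = as.integer(n_bits), max_radius = as.integer(max_radius),
    grid = grid, n_trials = as.integer(n_trials), base_seed = as.integer(base_seed),
    background_size = if (is.null(background_size)) NULL else as.integer(background_size),
    shap_per_trial = if (is.null(shap_per_trial)) NULL else as.integer(shap_per_trial),
    cf_target = cf_target, cf_n_bases = as.integer(cf_n_bases),
    cf_budget = as.integer(cf_budget), cf_fragments = cf_fragments,
    enrichment_patterns = enrichment_patterns,
    n_depictions = as.integer(n_depictions)
  )
  class(cfg) <- "shapcf_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# Deterministic per-base seed derived from the canonical key, so adding or
# removing base compounds never reshuffles the candidates of the others.
.base_seed_hash <- function(key, base_seed) {
  h <- .poly_hash_matrix(matrix(utf8ToInt(key), nrow = 1))
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

.write_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full explanation workflow
#'
#' Executes the configured stages and writes the artifact families under
#' `config$out_dir`: `manifest.json`, `dataset.csv`, `metrics.csv` (+
#' `metrics_summary.csv`), `cumulative_shap.csv`, `cf_records.csv` (+
#' `cf_qualified.smi`), `atom_attributions.csv`, `enrichment.csv`,
#' `depictions/*.svg` and `report.md`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `shapcf_bundle` list with the in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "shapcf_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$out_dir, "PARTIAL")
  writeLines("run in progress or aborted; artifacts may be incomplete", marker)
  on.exit(if (file.exists(marker)) invisible(NULL), add = TRUE)

  # --- dataset ---------------------------------------------------------------
  ds <- .stage("dataset", {
    if (!is.null(config$benchmark)) generate_benchmark(config$benchmark)
    else read_compounds(config$input)
  })
  ds <- .stage("balance", balance_by_undersampling(ds, config$base_seed))
  spec <- attr(ds, "spec")
  .write_csv(as.data.frame(ds), file.path(config$out_dir, "dataset.csv"))

  mols <- .stage("parse", parse_structures(ds$smiles, ds$label, ds$id))
  fps <- .stage("fingerprint", lapply(mols, fingerprint, n_bits = config$n_bits,
                                      max_radius = config$max_radius))
  X <- fingerprint_matrix(fps)

  # --- trials ----------------------------------------------------------------
  trials <- .stage("trials", run_trials(X, ds$label, config$n_trials,
                                        config$base_seed, config$grid))
  per_trial <- do.call(rbind, lapply(trials$trials, function(tr) {
    cbind(trial = tr$trial, tr$metrics$per_class)
  }))
  .write_csv(per_trial, file.path(config$out_dir, "metrics.csv"))
  .write_csv(trials$summary, file.path(config$out_dir, "metrics_summary.csv"))

  # --- cumulative attributions ----------------------------------------------
  cumulative <- .stage("cumulative_shap", {
    rows <- list()
    for (tr in trials$trials) {
      bg <- .background_for(tr, X, config)
      te <- tr$split$test
      n_take <- if (is.null(config$shap_per_trial)) length(te) else config$shap_per_trial
      cs <- cumulative_shap(tr$model, fps[te][seq_len(min(n_take, length(te)))],
                            ds$label[te][seq_len(min(n_take, length(te)))], bg)
      rows[[tr$trial]] <- cbind(trial = tr$trial, cs)
    }
    do.call(rbind, rows)
  })
  .write_csv(cumulative, file.path(config$out_dir, "cumulative_shap.csv"))

  # --- counterfactual search -------------------------------------------------
  cf_tab <- atom_tab <- enrich <- NULL
  pairs <- list()
  if (config$cf_n_bases > 0L) {
    trial1 <- trials$trials[[1]]
    model <- trial1$model
    bg <- .background_for(trial1, X, config)
    te <- trial1$split$test
    pred <- assign_class(predict_probabilities(model, X[te, , drop = FALSE]))
    st_classes <- setdiff(class_labels(), c(config$cf_target, "R"))
    base_pool <- te[pred == ds$label[te] & ds$label[te] %in% st_classes]
    base_idx <- head(base_pool, config$cf_n_bases)
    frags <- .resolve_fragments(config, spec)

    cf_tab <- .stage("counterfactuals", {
      all_cf <- list()
      for (i in base_idx) {
        base <- mols[[i]]
        bseed <- .base_seed_hash(base$canonical_key, config$base_seed)
        c_t <- transform_analogues(base, frags, seed = bseed,
                                   max_candidates = config$cf_budget)
        c_m <- mutate_string_analogues(base, max(0L, config$cf_budget - length(c_t)),
                                       seed = bseed)
        tags <- c(rep("transform", length(c_t)), rep("mutate", length(c_m)))
        cand <- c(c_t, c_m)
        dup <- duplicated(cand)
        cf <- find_counterfactuals(model, base, config$cf_target, cand[!dup],
                                   n_bits = config$n_bits, max_radius = config$max_radius,
                                   generator_tag = "mixed")
        cf$generator_tag <- tags[!dup][match(cf$candidate_smiles, cand[!dup])]
        all_cf[[length(all_cf) + 1L]] <- cf
      }
      do.call(rbind, lapply(all_cf, as.data.frame))
    })
    .write_csv(cf_tab, file.path(config$out_dir, "cf_records.csv"))
    qual <- cf_tab[cf_tab$qualified, , drop = FALSE]
    writeLines(paste(qual$candidate_smiles, qual$base_id), file.path(config$out_dir, "cf_qualified.smi"))

    # --- attributions and depictions for base / counterfactual pairs --------
    atom_rows <- list()
    n_pairs <- 0L
    for (i in base_idx) {
      if (n_pairs >= config$n_depictions) break
      base <- mols[[i]]
      bid <- if (is.na(base$source_id)) base$canonical_key else base$source_id
      q <- cf_tab[cf_tab$base_id == bid & cf_tab$qualified, , drop = FALSE]
      if (nrow(q) == 0L) next
      n_pairs <- n_pairs + 1L
      cf_mol <- parse_structure(q$candidate_smiles[1],
                                source_ids = paste0(bid, "_cf"))
      for (entry in list(list(mol = base, tag = "base"), list(mol = cf_mol, tag = "cf"))) {
        fpx <- fingerprint(entry$mol, config$n_bits, config$max_radius)
        expl <- interventional_shap(model, fpx, bg)
        am <- atom_attributions(entry$mol, fpx, expl, config$cf_target)
        atom_rows[[length(atom_rows) + 1L]] <- data.frame(
          compound_id = paste0(bid, "_", entry$tag), atom = seq_along(am$raw),
          element = entry$mol$elements, raw = am$raw, normalized = am$normalized,
          stringsAsFactors = FALSE
        )
        dir.create(file.path(config$out_dir, "depictions"), showWarnings = FALSE)
        render_depiction(am, file.path(config$out_dir, "depictions",
                                       paste0(bid, "_", entry$tag, ".svg")))
        pairs[[length(pairs) + 1L]] <- list(id = paste0(bid, "_", entry$tag),
                                            prob = am$prob, tag = entry$tag, base_id = bid)
      }
    }
    atom_tab <- if (length(atom_rows)) do.call(rbind, atom_rows) else
      data.frame(compound_id = character(), atom = integer(), element = character(),
                 raw = numeric(), normalized = numeric())
    .write_csv(atom_tab, file.path(config$out_dir, "atom_attributions.csv"))

    # --- enrichment ----------------------------------------------------------
    patterns <- .resolve_patterns(config, spec)
    enrich <- .stage("enrichment", {
      dt_set <- ds$smiles[ds$label == config$cf_target]
      st_set <- ds$smiles[ds$label %in% st_classes]
      tab1 <- cbind(comparison = "DT_vs_ST_dataset",
                    compare_substructure_enrichment(dt_set, st_set, patterns))
      if (nrow(qual) > 0L && any(!cf_tab$qualified)) {
        tab2 <- cbind(comparison = "qualifiedCF_vs_unqualified",
                      compare_substructure_enrichment(qual$candidate_smiles,
                                                      cf_tab$candidate_smiles[!cf_tab$qualified],
                                                      patterns))
        rbind(tab1, tab2)
      } else tab1
    })
    .write_csv(enrich, file.path(config$out_dir, "enrichment.csv"))
  }

  # --- manifest and report ---------------------------------------------------
  manifest <- list(
    config = .serializable_config(config),
    seeds = list(base_seed = config$base_seed,
                 trial_seeds = vapply(trials$trials, `[[`, integer(1), "seed")),
    chosen_params = lapply(trials$trials, `[[`, "params"),
    forest_defaults = trials$trials[[1]]$model$manifest,
    versions = list(
      r = paste(R.version$major, R.version$minor, sep = "."),
      shapcf = as.character(utils::packageVersion("shapcf"))
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  bundle <- structure(
    list(config = config, dataset = ds, trials = trials, cumulative = cumulative,
         cf_records = cf_tab, atom_attributions = atom_tab, enrichment = enrich,
         pairs = pairs, out_dir = config$out_dir),
    class = "shapcf_bundle"
  )
  writeLines(make_report(bundle), file.path(config$out_dir, "report.md"))
  file.remove(marker)
  invisible(bundle)
}

.background_for <- function(trial, X, config) {
  tr_idx <- trial$split$train
  if (!is.null(config$background_size) && config$background_size < length(tr_idx)) {
    tr_idx <- with_seed(trial$seed, sort(sample(tr_idx, config$background_size)))
  }
  X[tr_idx, , drop = FALSE]
}

.resolve_fragments <- function(config, spec) {
  if (!identical(config$cf_fragments, "auto")) return(config$cf_fragments)
  lib <- default_fragment_library()
  if (!is.null(spec)) lib <- c(lib, motif_a = spec$motif_a, motif_b = spec$motif_b)
  lib
}

.resolve_patterns <- function(config, spec) {
  if (!identical(config$enrichment_patterns, "auto")) return(config$enrichment_patterns)
  pats <- c(piperidine = "C1CCNCC1", piperazine = "C1CNCCN1")
  if (!is.null(spec)) pats <- c(motif_a = spec$motif_a_smarts, motif_b = spec$motif_b_smarts, pats)
  pats
}

.serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$grid <- as.data.frame(cfg$grid)
  if (!is.null(cfg$benchmark)) cfg$benchmark <- unclass(cfg$benchmark)
  cfg
}

#' Render a human-readable summary of a pipeline run
#'
#' Markdown with the per-trial metric distributions, the cumulative
#' present/absent attribution table, the base/counterfactual gallery with
#' target-class probabilities, and the substructure enrichment table.
#'
#' @param bundle A `shapcf_bundle` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
make_report <- function(bundle) {
  fmt_tab <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
    c(paste("|", paste(colnames(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  out <- c("# Multiclass activity-prediction explanation report", "")
  cc <- attr(bundle$dataset, "class_counts")
  out <- c(out, paste0("Dataset: ", nrow(bundle$dataset), " compounds (",
                       paste(names(cc), cc, sep = "=", collapse = ", "), ")"), "")
  out <- c(out, "## Prediction performance over trials", "", fmt_tab(bundle$trials$summary), "")
  out <- c(out, "## Cumulative present/absent attributions (correct test predictions)", "",
           fmt_tab(bundle$cumulative), "")
  out <- c(out, "## Base / counterfactual gallery", "")
  if (length(bundle$pairs) == 0L) {
    out <- c(out, "no qualified counterfactuals", "")
  } else {
    for (p in bundle$pairs) {
      out <- c(out, sprintf("- %s (%s): P(%s) = %.3f [depictions/%s.svg]",
                            p$id, p$tag, bundle$config$cf_target, p$prob, p$id))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$cf_records)) {
    out <- c(out, sprintf("Counterfactual search: %d candidates over %d base compounds, %d qualified.",
                          nrow(bundle$cf_records), length(unique(bundle$cf_records$base_id)),
                          sum(bundle$cf_records$qualified)), "")
  }
  if (!is.null(bundle$enrichment)) {
    out <- c(out, "## Substructure enrichment", "", fmt_tab(bundle$enrichment), "")
  }
  out
}

#' @export
print.shapcf_bundle <- function(x, ...) {
  cat("<shapcf_bundle> artifacts in ", x$out_dir, "\n", sep = "")
  invisible(x)
}
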