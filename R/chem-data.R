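# Dataset containers, compound curation filters and file readers/writers.

#' Build a labeled multiclass dataset
#'
#' @param smiles Character vector of SMILES.
#' @param label Character vector of class labels (see [class_labels()]).
#' @param id Optional identifiers; defaults to `cpd_1`, `cpd_2`, ...
#' @param canonicalize Compute canonical keys via OpenBabel (default TRUE).
#' @return A `shapcf_dataset`: a data.frame with columns `id`, `smiles`,
#'   `canonical_key`, `label`, carrying per-class counts in
#'   `attr(, "class_counts")`.
#' @export
multiclass_dataset <- function(smiles, label, id = NULL, canonicalize = TRUE) {
  if (length(smiles) != length(label)) stop("smiles and label lengths differ")
  if (anyNA(label) || !all(label %in% class_labels())) {
    stop("every entry must carry a label in {", paste(class_labels(), collapse = ", "), "}")
  }
  if (is.null(id)) id <- paste0("cpd_", seq_along(smiles))
  keys <- if (canonicalize) .ob_canonical(smiles) else smiles
  ds <- data.frame(
    id = as.character(id), smiles = as.character(smiles),
    canonical_key = keys, label = as.character(label),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("shapcf_dataset", "data.frame")
  attr(ds, "class_counts") <- .count_classes(ds$label)
  ds
}

.count_classes <- function(labels) {
  cnt <- table(factor(labels, levels = class_labels()))
  setNames(as.integer(cnt), names(cnt))
}

#' @export
print.shapcf_dataset <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat("<shapcf_dataset> ", nrow(x), " compounds (",
      paste(names(cc), cc, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Curation --------------------------------------------------------------------

#' Default activity-comment blocklist
#'
#' Case-insensitive substrings that mark records as unusable for modeling
#' active compounds.
#' @return Character vector of blocked comment phrases.
#' @export
default_comment_blocklist <- function() {
  c("inactive", "not active", "inconclusive", "potential transcription error")
}

#' Filter compound activity records for model-ready actives
#'
#' Applies the record-level curation filters in sequence: activity comment not
#' on the blocklist, molecular mass below `max_mass_da`, standard potency type
#' (Ki, Kd or IC50), exact standard relation, full target confidence and the
#' potency criterion. The potency filter keeps compounds *active at*
#' `potency_cutoff_um` or better (`potency_value <= cutoff`) by default, since
#' the modeled single- and dual-target classes consist of active compounds;
#' set `potency_direction = "gt"` for the opposite reading.
#'
#' @param records A data.frame with columns `potency_value` (micromolar),
#'   `potency_type`, `relation`, `mass_da`, `confidence_score`,
#'   `activity_comment`, plus any identifier columns, one row per record.
#' @param max_mass_da Upper mass bound in Dalton (exclusive).
#' @param potency_cutoff_um Potency cutoff in micromolar.
#' @param required_confidence Required target confidence score.
#' @param blocked_comments Blocklist of comment substrings (case-insensitive).
#' @param relation_required Required standard relation.
#' @param potency_direction `"le"` keeps `potency_value <= cutoff` (default);
#'   `"gt"` keeps `potency_value > cutoff`.
#' @return List with `kept` (the surviving rows) and `audit` (named integer
#'   vector of removal counts per filter, applied in the listed order, plus a
#'   `malformed` bucket for rows with missing required fields).
#' @export
apply_curation_filters <- function(records,
                                   max_mass_da = 1000,
                                   potency_cutoff_um = 10,
                                   required_confidence = 9L,
                                   blocked_comments = default_comment_blocklist(),
                                   relation_required = "=",
                                   potency_direction = c("le", "gt")) {
  potency_direction <- match.arg(potency_direction)
  need <- c("potency_value", "potency_type", "relation", "mass_da",
            "confidence_score", "activity_comment")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  audit <- c(malformed = 0L, comment = 0L, mass = 0L, potency_type = 0L,
             relation = 0L, confidence = 0L, potency = 0L)
  ok <- rep(TRUE, nrow(records))

  malformed <- Reduce(`|`, lapply(records[need], is.na))
  audit["malformed"] <- sum(malformed)
  ok <- ok & !malformed

  comment_bad <- rep(FALSE, nrow(records))
  for (phrase in blocked_comments) {
    comment_bad <- comment_bad | grepl(phrase, records$activity_comment,
                                       ignore.case = TRUE, fixed = FALSE)
  }
  audit["comment"] <- sum(ok & comment_bad)
  ok <- ok & !comment_bad

  f <- !(records$mass_da < max_mass_da)
  audit["mass"] <- sum(ok & f); ok <- ok & !f

  f <- !(records$potency_type %in% c("Ki", "Kd", "IC50"))
  audit["potency_type"] <- sum(ok & f, na.rm = TRUE); ok <- ok & !f

  f <- !(records$relation == relation_required)
  audit["relation"] <- sum(ok & f, na.rm = TRUE); ok <- ok & !f

  f <- !(records$confidence_score == required_confidence)
  audit["confidence"] <- sum(ok & f, na.rm = TRUE); ok <- ok & !f

  f <- if (potency_direction == "le") {
    !(records$potency_value <= potency_cutoff_um)
  } else {
    !(records$potency_value > potency_cutoff_um)
  }
  audit["potency"] <- sum(ok & f, na.rm = TRUE); ok <- ok & !f

  ok[is.na(ok)] <- FALSE
  list(kept = records[ok, , drop = FALSE], audit = audit)
}

#' Balance a dataset by undersampling majority classes
#'
#' Every class is reduced to the minimum class count by uniform random
#' removal; the minimum-count class is left untouched. Deterministic for a
#' fixed seed.
#'
#' @param dataset A `shapcf_dataset`.
#' @param seed Integer seed.
#' @return A balanced `shapcf_dataset`.
#' @export
balance_by_undersampling <- function(dataset, seed) {
  cc <- .count_classes(dataset$label)
  if (any(cc == 0L)) stop("class has no members: ", paste(names(cc)[cc == 0L], collapse = ", "))
  n_min <- min(cc)
  keep <- with_seed(seed, {
    out <- integer()
    for (cl in class_labels()) {
      idx <- which(dataset$label == cl)
      if (length(idx) > n_min) idx <- sample(idx, n_min)
      out <- c(out, idx)
    }
    out
  })
  keep <- sort(keep)
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shapcf_dataset", "data.frame")
  attr(out, "class_counts") <- .count_classes(out$label)
  attr(out, "ground_truth") <- attr(dataset, "ground_truth")[keep]
  attr(out, "spec") <- attr(dataset, "spec")
  out
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed` and restores
#' the caller's RNG state afterwards, so seeded package code never perturbs
#' user sessions. All randomized steps in the package route through this
#' scope, which is what makes run manifests sufficient to replay a run.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Readers / writers -----------------------------------------------------------

#' Read and write compound sets
#'
#' `read_compounds()` accepts `.smi` files (one SMILES plus optional
#' whitespace-separated id per line), CSV files with columns
#' `smiles,label[,id]` and SDF files. `write_compounds()` mirrors the `.smi`
#' and CSV formats.
#'
#' @param path File path; format inferred from the extension.
#' @param labels Optional labels when the format does not carry any.
#' @return A `shapcf_dataset`.
#' @export
read_compounds <- function(path, labels = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(tab)) stop("CSV must have a 'smiles' column")
    lab <- if ("label" %in% names(tab)) tab$label else rep_len(labels, nrow(tab))
    id <- if ("id" %in% names(tab)) tab$id else NULL
    return(multiclass_dataset(tab$smiles, lab, id))
  }
  if (ext %in% c("smi", "txt")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(parts, `[[`, character(1), 1)
    id <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1))
    if (anyNA(id)) id <- NULL
    return(multiclass_dataset(smiles, rep_len(labels, length(smiles)), id))
  }
  if (ext == "sdf") {
    sdfs <- ChemmineR::read.SDFset(path)
    smiles <- as.character(ChemmineR::sdf2smiles(sdfs))
    return(multiclass_dataset(smiles, rep_len(labels, length(smiles)), ChemmineR::sdfid(sdfs)))
  }
  stop("unsupported compound file format: .", ext)
}

#' @rdname read_compounds
#' @param dataset A `shapcf_dataset`.
#' @export
write_compounds <- function(dataset, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.csv(as.data.frame(dataset)[, c("smiles", "label", "id")], path, row.names = FALSE)
  } else if (ext == "smi") {
    writeLines(paste(dataset$smiles, dataset$id), path)
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}
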