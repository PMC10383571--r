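#' @importFrom stats median quantile setNames
#' @importFrom utils head read.csv write.csv
NULL

# Class labels ----------------------------------------------------------------

#' Class labels of the four-class activity prediction task
#'
#' The task distinguishes dual-target compounds (`DT`), single-target
#' compounds for each target of the pair (`ST_A`, `ST_B`) and randomly
#' selected, presumed inactive compounds (`R`). The integer codes `0:3`
#' follow this fixed order; ties in predicted class probabilities are
#' always broken towards the smallest code.
#'
#' @return Character vector of the four labels in code order.
#' @export
class_labels <- function() c("DT", "ST_A", "ST_B", "R")

#' Convert between class labels and integer codes
#'
#' @param x Character vector of labels or integer vector of codes `0:3`.
#' @return `class_code()` returns integer codes; `class_label()` returns labels.
#' @export
class_code <- function(x) {
  i <- match(as.character(x), class_labels())
  if (anyNA(i)) stop("unknown class label: ", paste(setdiff(x, class_labels()), collapse = ", "))
  i - 1L
}

#' @rdname class_code
#' @export
class_label <- function(x) {
  x <- as.integer(x)
  if (any(x < 0L | x > 3L)) stop("class codes must be in 0..3")
  class_labels()[x + 1L]
}

# SMILES tokenization ---------------------------------------------------------

# Atom tokens: bracket atoms or the organic subset (two-letter halogens first).
.atom_token_re <- "\\[[^]\\[]+\\]|Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s"

# Positions of atom tokens in a SMILES string, in reading order (which is the
# order OpenBabel assigns atom indices when parsing the same string).
.tokenize_atoms <- function(smiles) {
  m <- gregexpr(.atom_token_re, smiles)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer(), token = character()))
  data.frame(
    start = as.integer(m),
    end = as.integer(m) + attr(m, "match.length") - 1L,
    token = regmatches(smiles, gregexpr(.atom_token_re, smiles))[[1]],
    stringsAsFactors = FALSE
  )
}

# Light syntactic validation. OpenBabel silently repairs some malformed
# strings (e.g. "C(" parses as methane), so unbalanced parentheses, brackets
# and unpaired ring-closure digits are rejected here before conversion.
.check_smiles_syntax <- function(text) {
  if (!nzchar(text)) return("empty SMILES")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return("unbalanced parentheses")
  }
  if (depth != 0L) return("unbalanced parentheses")
  nob <- gsub("\\[[^]\\[]*\\]", "A", text)
  if (grepl("\\[|\\]", nob)) return("unbalanced brackets")
  ring <- gsub("%[0-9]{2}", "", nob)
  digits <- strsplit(gsub("[^0-9]", "", ring), "")[[1]]
  two <- regmatches(nob, gregexpr("%[0-9]{2}", nob))[[1]]
  cnt <- table(c(digits, two))
  if (any(cnt %% 2L != 0L)) return("unpaired ring-closure digit")
  if (nrow(.tokenize_atoms(text)) == 0L) return("no atoms")
  NULL
}

# OpenBabel conversion --------------------------------------------------------

# Batch canonicalization. Returns a character vector aligned with `smiles`;
# entries that fail conversion are NA.
.ob_canonical <- function(smiles) {
  if (length(smiles) == 0L) return(character())
  input <- paste0(smiles, " id", seq_along(smiles), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(input, "\n")),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  res <- rep(NA_character_, length(smiles))
  if (length(lines) == 0L) return(res)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2L) next
    idx <- suppressWarnings(as.integer(sub("^id", "", trimws(p[2]))))
    if (!is.na(idx) && nzchar(trimws(p[1]))) res[idx] <- trimws(p[1])
  }
  res
}

# MDL old-style charge codes (atom block field) -> formal charge.
.mdl_charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# Allowed valences for implicit hydrogen assignment (organic subset rules).
.valence_table <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L
)

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

# Molecule construction -------------------------------------------------------

# Build the graph fields of a molecule from a ChemmineR SDF object whose atom
# order matches the source SMILES.
.mol_from_sdf <- function(sdf, smiles, canonical_key, label = NA_character_,
                          source_id = NA_character_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(n) || n < 1L) stop("structure has no heavy atoms: ", smiles)
  elements <- sub("_.*$", "", rownames(ab))
  charge <- .mdl_charge(if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0L, n))
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- data.frame(
      from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  }
  degree <- tabulate(c(bonds$from, bonds$to), nbins = n)
  bondsum <- rep(0L, n)
  if (nrow(bonds)) {
    bs <- tapply(c(bonds$order, bonds$order), c(bonds$from, bonds$to), sum)
    bondsum[as.integer(names(bs))] <- as.integer(bs)
  }
  nH <- integer(n)
  for (i in seq_len(n)) {
    allowed <- .valence_table[[elements[i]]]
    if (is.null(allowed)) { nH[i] <- 0L; next }
    target <- allowed[allowed + charge[i] >= bondsum[i]]
    if (length(target) == 0L) {
      if (charge[i] == 0L) stop("valence of ", elements[i], " exceeded in: ", smiles)
      nH[i] <- 0L
    } else {
      nH[i] <- min(target) + charge[i] - bondsum[i]
    }
  }
  in_ring <- rep(FALSE, n)
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(cbind(bonds$from, bonds$to), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    in_ring[unique(c(bonds$from[ring_edges], bonds$to[ring_edges]))] <- TRUE
  }
  structure(
    list(
      smiles = smiles, canonical_key = canonical_key,
      n_atoms = n, elements = elements, charge = charge, degree = degree,
      n_h = nH, in_ring = in_ring, bonds = bonds,
      label = label, source_id = source_id
    ),
    class = "shapcf_mol"
  )
}

#' Parse SMILES strings into annotated molecules
#'
#' Structures are sanitized with OpenBabel: the canonical SMILES serves as the
#' identity key, so any two encodings of the same structure compare equal.
#' Multi-fragment inputs (salts) are reduced to the largest fragment by heavy
#' atom count before parsing, and stereochemistry plays no role downstream.
#' The heavy-atom indices of the returned graph follow the reading order of
#' the (salt-stripped) input SMILES.
#'
#' @param texts Character vector of SMILES strings.
#' @param labels Optional class labels (see [class_labels()]), recycled.
#' @param source_ids Optional free-text identifiers, recycled.
#' @param strip_salt Keep only the largest disconnected fragment (default TRUE).
#' @param on_error `"stop"` (default) rejects the whole call on the first
#'   invalid structure; `"drop"` replaces invalid entries with `NULL` (used
#'   when screening large machine-generated candidate sets).
#' @return For `parse_structures()`, a list of `shapcf_mol` objects with
#'   fields `smiles`, `canonical_key`, `elements`, `charge`, `degree`, `n_h`,
#'   `in_ring`, `bonds`, `label` and `source_id`. `parse_structure()` returns
#'   a single molecule.
#' @examples
#' m <- parse_structure("C1CCNCC1")
#' m$canonical_key == parse_structure("N1CCCCC1")$canonical_key
#' @export
parse_structures <- function(texts, labels = NA_character_, source_ids = NA_character_,
                             strip_salt = TRUE, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  if (length(texts) == 0L) return(list())
  labels <- rep_len(as.character(labels), length(texts))
  source_ids <- rep_len(as.character(source_ids), length(texts))
  texts <- trimws(texts)
  fail <- function(i, why) {
    if (on_error == "stop") stop("invalid SMILES '", texts[i], "': ", why)
    FALSE
  }
  ok <- rep(TRUE, length(texts))
  for (i in seq_along(texts)) {
    err <- .check_smiles_syntax(texts[i])
    if (!is.null(err)) ok[i] <- fail(i, err)
  }
  work <- rep(NA_character_, length(texts))
  work[ok] <- vapply(texts[ok], .largest_fragment, character(1), strip = strip_salt, USE.NAMES = FALSE)
  keys <- rep(NA_character_, length(texts))
  keys[ok] <- .ob_canonical(work[ok])
  for (i in which(ok & is.na(keys))) ok[i] <- fail(i, "conversion failed")
  single <- rep(FALSE, length(texts))
  single[ok] <- vapply(work[ok], function(s) nrow(.tokenize_atoms(s)) == 1L, logical(1), USE.NAMES = FALSE)
  out <- vector("list", length(texts))
  multi_idx <- which(ok & !single)
  if (length(multi_idx)) {
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(setNames(work[multi_idx], paste0("m", multi_idx))))
    ids <- match(paste0("m", multi_idx), ChemmineR::sdfid(sdfs))
    valid <- suppressWarnings(ChemmineR::validSDF(sdfs))
    for (k in seq_along(multi_idx)) {
      i <- multi_idx[k]
      if (is.na(ids[k]) || !valid[ids[k]]) {
        ok[i] <- fail(i, "structure rejected")
        next
      }
      mol <- tryCatch(.mol_from_sdf(sdfs[[ids[k]]], work[i], keys[i], labels[i], source_ids[i]),
                      error = function(e) NULL)
      if (is.null(mol)) ok[i] <- fail(i, "chemically invalid structure") else out[[i]] <- mol
    }
  }
  for (i in which(ok & single)) {
    out[[i]] <- .mol_single_atom(work[i], keys[i], labels[i], source_ids[i])
  }
  out
}

# ChemmineR cannot represent a bond-free ctab, so one-atom molecules are
# assembled straight from their token.
.mol_single_atom <- function(smiles, canonical_key, label, source_id) {
  tok <- .tokenize_atoms(smiles)$token[1]
  charge <- 0L
  nH <- NA_integer_
  if (startsWith(tok, "[")) {
    body <- gsub("\\[|\\]", "", tok)
    charge <- sum(gregexpr("\\+", body)[[1]] > 0) - sum(gregexpr("-", body)[[1]] > 0)
    nchg <- regmatches(body, regexpr("[+-][0-9]+", body))
    if (length(nchg)) charge <- as.integer(nchg)
    hm <- regmatches(body, regexpr("H[0-9]*", body))
    nH <- if (length(hm)) {
      d <- sub("H", "", hm)
      if (nzchar(d)) as.integer(d) else 1L
    } else 0L
    element <- regmatches(body, regexpr("[A-Z][a-z]?", body))
  } else {
    element <- toupper(tok)
  }
  if (is.na(nH)) {
    allowed <- .valence_table[[element]]
    nH <- if (is.null(allowed)) 0L else max(0L, min(allowed) + charge)
  }
  structure(
    list(
      smiles = smiles, canonical_key = canonical_key, n_atoms = 1L,
      elements = element, charge = as.integer(charge), degree = 0L,
      n_h = as.integer(nH), in_ring = FALSE,
      bonds = data.frame(from = integer(), to = integer(), order = integer()),
      label = label, source_id = source_id
    ),
    class = "shapcf_mol"
  )
}

#' @rdname parse_structures
#' @param text A single SMILES string.
#' @export
parse_structure <- function(text, labels = NA_character_, source_ids = NA_character_,
                            strip_salt = TRUE) {
  if (length(text) != 1L) stop("parse_structure() expects a single string")
  parse_structures(text, labels, source_ids, strip_salt)[[1]]
}

.largest_fragment <- function(smiles, strip = TRUE) {
  if (!strip || !grepl(".", smiles, fixed = TRUE)) return(smiles)
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  sizes <- vapply(parts, function(p) nrow(.tokenize_atoms(p)), integer(1))
  parts[which.max(sizes)]
}

#' @export
print.shapcf_mol <- function(x, ...) {
  cat("<shapcf_mol> ", x$canonical_key, "\n", sep = "")
  cat("  atoms: ", x$n_atoms, "  bonds: ", nrow(x$bonds),
      "  label: ", ifelse(is.na(x$label), "-", x$label),
      "  id: ", ifelse(is.na(x$source_id), "-", x$source_id), "\n", sep = "")
  invisible(x)
}

# SMARTS matching -------------------------------------------------------------

# Match a SMARTS pattern against SMILES strings using OpenBabel.
# Returns a list (one element per molecule) of integer-vector matches,
# each vector holding the 1-based atom indices of one unique match.
.smarts_match <- function(smiles, pattern) {
  OB <- getNamespace("ChemmineOB")
  sp <- OB$OBSmartsPattern__SWIG_0()
  on.exit(OB$delete_OBSmartsPattern(sp), add = TRUE)
  if (!OB$OBSmartsPattern_Init(sp, pattern)) stop("invalid SMARTS pattern: ", pattern)
  input <- paste0(paste(smiles, collapse = "\n"), "\n")
  ChemmineOB::forEachMol("SMILES", input, function(mol) {
    OB$OBSmartsPattern_Match(sp, mol)
    OB$OBSmartsPattern_GetUMapList(sp)
  })
}

#' Count molecules containing a substructure
#'
#' @param mols List of `shapcf_mol` objects (or character SMILES).
#' @param pattern A SMARTS pattern.
#' @return Logical vector: does each molecule contain at least one match?
#' @export
has_substructure <- function(mols, pattern) {
  smiles <- if (is.character(mols)) mols else vapply(mols, `[[`, character(1), "smiles")
  if (length(smiles) == 0L) stop("no molecules supplied")
  vapply(.smarts_match(smiles, pattern), function(m) length(m) > 0L, logical(1))
}
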