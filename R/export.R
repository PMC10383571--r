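# Plain-text export helpers for fingerprints and explanations.

#' Export fingerprints as dense CSV rows or bit-index JSON
#'
#' @param fps List of `shapcf_fp`.
#' @param path Output file; `.csv` writes dense 0/1 rows (one per
#'   fingerprint), `.json` writes per-fingerprint set-bit index lists.
#' @param ids Optional identifiers (defaults to `fp_1`, ...).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("fp_", seq_along(fps))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    X <- fingerprint_matrix(fps)
    df <- data.frame(id = ids, X, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    payload <- lapply(seq_along(fps), function(i) {
      list(id = ids[i], n_bits = fps[[i]]$n_bits, on_bits = fps[[i]]$on_bits)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported fingerprint export format: .", ext)
  }
  invisible(path)
}

#' Export a fingerprint's bit-to-environment provenance as JSON
#'
#' @param fp A `shapcf_fp`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(fp, path) {
  payload <- lapply(names(fp$provenance), function(b) {
    prov <- fp$provenance[[b]]
    list(bit = as.integer(b), environments = lapply(seq_len(nrow(prov)), function(k) {
      list(center = prov$center[k], radius = prov$radius[k],
           atoms = prov$atoms[[k]])
    }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tidy table of the non-zero attributions of an explanation
#'
#' @param expl A `shapcf_shap`.
#' @param compound_id Identifier recorded in the table.
#' @return Data.frame with columns `compound_id`, `class`, `bit`, `present`,
#'   `phi` (rows with `phi == 0` are omitted).
#' @export
shap_to_table <- function(expl, compound_id = "compound") {
  rows <- list()
  for (cl in rownames(expl$phi)) {
    nz <- which(expl$phi[cl, ] != 0)
    if (!length(nz)) next
    rows[[cl]] <- data.frame(
      compound_id = compound_id, class = cl, bit = nz,
      present = nz %in% expl$foreground_bits,
      phi = unname(expl$phi[cl, nz]), stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(compound_id = character(), class = character(),
                      bit = integer(), present = logical(), phi = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
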