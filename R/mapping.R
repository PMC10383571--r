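# Projection of per-bit Shapley attributions onto atoms through fingerprint
# provenance, and color-coded 2D depictions. Only features PRESENT in a
# compound are mapped: absent features have no atoms to receive their
# attribution (those contributions remain visible in the cumulative
# summaries). When several environments collide on one bit, the bit's
# attribution is split equally among them before each environment passes its
# share to every one of its atoms; an atom participating in several
# environments accumulates the sum.

#' Project per-bit attributions onto atoms
#'
#' For each set bit `b` with attribution `phi`, every environment in
#' `provenance[b]` receives `phi / n_colliding` and assigns that share in
#' full to each of its atoms. Atom values are the sums over all assignments.
#' The conservation identity
#' `sum(raw) = sum_b phi_b * sum_env |atoms(env)| / |prov(b)|`
#' holds exactly and is checked on every call.
#'
#' @param mol The `shapcf_mol` the fingerprint came from.
#' @param fp Its `shapcf_fp`.
#' @param expl A `shapcf_shap` for the same fingerprint and model.
#' @param target_class Class whose attributions are mapped (default `DT`).
#' @return A `shapcf_atommap`: list with `molecule`, `target_class`, `raw`
#'   and `normalized` per-atom vectors and `prob` (model probability of the
#'   target class).
#' @export
atom_attributions <- function(mol, fp, expl, target_class = "DT") {
  if (!target_class %in% rownames(expl$phi)) stop("unknown target class: ", target_class)
  if (!identical(sort(fp$on_bits), sort(expl$foreground_bits))) {
    stop("fingerprint and explanation disagree on the set bits")
  }
  phi <- expl$phi[target_class, ]
  raw <- numeric(mol$n_atoms)
  expected <- 0
  for (b in fp$on_bits) {
    prov <- fp$provenance[[as.character(b)]]
    if (is.null(prov) || nrow(prov) == 0L) stop("corrupt fingerprint: set bit ", b, " lacks provenance")
    share <- phi[b] / nrow(prov)
    for (k in seq_len(nrow(prov))) {
      atoms <- prov$atoms[[k]]
      if (any(atoms > mol$n_atoms)) stop("provenance refers to atoms outside the molecule")
      raw[atoms] <- raw[atoms] + share
      expected <- expected + share * length(atoms)
    }
  }
  if (abs(sum(raw) - expected) > 1e-12) {
    stop("attribution conservation violated by ", abs(sum(raw) - expected))
  }
  out <- structure(
    list(molecule = mol, target_class = target_class, raw = raw,
         normalized = NULL, prob = unname(expl$probs[target_class])),
    class = "shapcf_atommap"
  )
  normalize_attributions(out)
}

#' Normalize an atom attribution map for depiction
#'
#' Symmetric max-abs scaling into `[-1, 1]`; an all-zero map stays zero and
#' signs are preserved.
#'
#' @param map A `shapcf_atommap`.
#' @return The map with its `normalized` field populated.
#' @export
normalize_attributions <- function(map) {
  m <- max(abs(map$raw))
  map$normalized <- if (m > 0) map$raw / m else rep(0, length(map$raw))
  map
}

#' @export
print.shapcf_atommap <- function(x, ...) {
  cat("<shapcf_atommap> ", x$molecule$canonical_key, " class ", x$target_class,
      " P=", sprintf("%.3f", x$prob), "\n", sep = "")
  invisible(x)
}

# Diverging blue-white-red color for a normalized value in [-1, 1].
.diverging_color <- function(v) {
  v <- max(-1, min(1, v))
  if (v >= 0) {
    sprintf("#FF%02X%02X", round(255 * (1 - v)), round(255 * (1 - v)))
  } else {
    sprintf("#%02X%02XFF", round(255 * (1 + v)), round(255 * (1 + v)))
  }
}

# 2D coordinates for depiction, computed with OpenBabel's layout generator;
# atom order matches the molecule's stored SMILES.
.layout_2d <- function(mol) {
  sdf_txt <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(mol$smiles, " m\n"),
    options = data.frame(names = "gen2D", args = "")
  )
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  if (is.na(n) || n != mol$n_atoms) stop("2D layout atom count mismatch")
  xy <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    ln <- lines[4 + i]
    xy[i, 1] <- as.numeric(substr(ln, 1, 10))
    xy[i, 2] <- as.numeric(substr(ln, 11, 20))
  }
  xy
}

#' Render an attribution map as an SVG depiction
#'
#' Atoms are shaded on a diverging blue-white-red scale (red supports the
#' target class, blue opposes it) over a 2D layout, annotated with the
#' model's probability of the target class. Output is plain deterministic
#' SVG text.
#'
#' @param map A `shapcf_atommap` (normalized).
#' @param out_path Output `.svg` path.
#' @param width,height Canvas size in pixels.
#' @param title Optional title line; defaults to `P(<class>) = <prob>`.
#' @return `out_path`, invisibly.
#' @export
render_depiction <- function(map, out_path, width = 360, height = 360, title = NULL) {
  mol <- map$molecule
  xy <- .layout_2d(mol)
  pad <- 40
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1e-6)
  sc <- (min(width, height) - 2 * pad) / span
  px <- pad + (xy[, 1] - rngx[1]) * sc + (width - 2 * pad - (rngx[2] - rngx[1]) * sc) / 2
  py <- height - pad - (xy[, 2] - rngy[1]) * sc - (height - 2 * pad - (rngy[2] - rngy[1]) * sc) / 2
  if (is.null(title)) title <- sprintf("P(%s) = %.2f", map$target_class, map$prob)

  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect width="%d" height="%d" fill="white"/>', width, height)
  )
  # atom highlights under the skeleton
  for (i in seq_len(mol$n_atoms)) {
    v <- map$normalized[i]
    if (v != 0) {
      out <- c(out, sprintf('<circle cx="%.2f" cy="%.2f" r="11" fill="%s" fill-opacity="0.85"/>',
                            px[i], py[i], .diverging_color(v)))
    }
  }
  bonds <- mol$bonds
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]
    seg <- sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" stroke-width="1.4"/>',
                   px[i], py[i], px[j], py[j])
    out <- c(out, seg)
    if (bonds$order[k] >= 2) {
      dx <- py[j] - py[i]; dy <- px[i] - px[j]
      nrm <- sqrt(dx^2 + dy^2); if (nrm < 1e-9) nrm <- 1
      ox <- 2.5 * dx / nrm; oy <- 2.5 * dy / nrm
      out <- c(out, sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" stroke-width="1.1"/>',
                            px[i] + ox, py[i] + oy, px[j] + ox, py[j] + oy))
    }
  }
  for (i in seq_len(mol$n_atoms)) {
    if (mol$elements[i] != "C") {
      out <- c(out, sprintf('<text x="%.2f" y="%.2f" font-size="11" font-family="sans-serif" text-anchor="middle" dy="4">%s</text>',
                            px[i], py[i], mol$elements[i]))
    }
  }
  out <- c(out, sprintf('<text x="%d" y="%d" font-size="13" font-family="sans-serif" text-anchor="middle">%s</text>',
                        as.integer(width / 2), height - 12, title),
           "</svg>")
  con <- tryCatch(suppressWarnings(file(out_path, "w")),
                  error = function(e) stop("cannot write depiction to ", out_path))
  on.exit(close(con), add = TRUE)
  writeLines(out, con)
  invisible(out_path)
}

#' Compare substructure frequencies between two compound sets
#'
#' For every SMARTS pattern, the fraction of molecules containing it is
#' computed in both sets together with the difference, quantifying whether
#' moieties highlighted by attribution or counterfactual analysis are
#' enriched in a reference class.
#'
#' @param set_a,set_b Non-empty lists of `shapcf_mol` (or SMILES vectors).
#' @param patterns Character vector of SMARTS patterns (names are kept).
#' @return Data.frame with `pattern`, `fraction_a`, `fraction_b`, `difference`.
#' @export
compare_substructure_enrichment <- function(set_a, set_b, patterns) {
  if (length(set_a) == 0L || length(set_b) == 0L) stop("both compound sets must be non-empty")
  rows <- lapply(seq_along(patterns), function(i) {
    p <- patterns[i]
    fa <- substructure_fraction(set_a, p)
    fb <- substructure_fraction(set_b, p)
    data.frame(
      pattern = if (!is.null(names(patterns)) && nzchar(names(patterns)[i])) names(patterns)[i] else p,
      smarts = unname(p), fraction_a = fa, fraction_b = fb, difference = fa - fb,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
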