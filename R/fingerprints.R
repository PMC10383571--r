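# Atom-environment (extended-connectivity) fingerprints with full bit->atom
# provenance. Environments are circular substructures of bond radius 0..2
# (bond diameter 4) around each heavy atom; their hashes are folded into a
# fixed-length binary fingerprint, and every bit remembers which environments
# set it so that per-bit attributions can later be projected onto atoms.

# Polynomial rolling hash over non-negative integer sequences, modulo a prime
# small enough that every product stays exactly representable in doubles.
.hash_prime <- 67108859   # largest prime < 2^26
.hash_base <- 1000003

.poly_hash_matrix <- function(m) {
  # m: numeric matrix, one sequence per row; returns one hash per row
  h <- rep(17, nrow(m))
  for (j in seq_len(ncol(m))) {
    h <- (h * .hash_base + m[, j]) %% .hash_prime
  }
  h
}

# Initial atom identifiers from connectivity invariants: element, heavy-atom
# degree, formal charge, implicit hydrogen count, ring membership.
.atom_init_ids <- function(mol) {
  z <- .atomic_numbers[mol$elements]
  z[is.na(z)] <- 99
  m <- cbind(z, mol$degree, mol$charge + 10L, mol$n_h, as.integer(mol$in_ring))
  .poly_hash_matrix(m)
}

#' Enumerate atom-environment features of a molecule
#'
#' One candidate feature exists per heavy atom and bond radius `0..max_radius`.
#' Identifiers are built iteratively: each round hashes an atom's previous
#' identifier together with the sorted (bond order, neighbour identifier)
#' pairs, so that identical chemical environments receive identical hashes
#' regardless of atom numbering. A feature is dropped when growing the radius
#' adds neither atoms nor bonds (the environment is already exhausted), and
#' duplicated environments within one molecule are kept once (set semantics).
#'
#' @param mol A `shapcf_mol`.
#' @param max_radius Maximum bond radius (bond diameter is twice this; the
#'   default 2 gives the diameter-4 feature set).
#' @return A data.frame with columns `center`, `radius`, `env_hash` and a
#'   list-column `atoms` holding the atom indices within the radius.
#' @export
enumerate_environments <- function(mol, max_radius = 2L) {
  stopifnot(inherits(mol, "shapcf_mol"), max_radius >= 0L)
  n <- mol$n_atoms
  bonds <- mol$bonds
  # neighbour lists with bond orders
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- list(idx = integer(), ord = integer())
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      f <- bonds$from[k]; t <- bonds$to[k]; o <- bonds$order[k]
      nbr[[f]]$idx <- c(nbr[[f]]$idx, t); nbr[[f]]$ord <- c(nbr[[f]]$ord, o)
      nbr[[t]]$idx <- c(nbr[[t]]$idx, f); nbr[[t]]$ord <- c(nbr[[t]]$ord, o)
    }
  }
  # shortest bond distances (BFS from every atom; molecules are small)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(a) nbr[[a]]$idx)))
      nxt <- nxt[dist[s, nxt] == Inf]
      if (length(nxt)) dist[s, nxt] <- d
      frontier <- nxt
    }
  }
  edge_within <- function(center, r) {
    if (!nrow(bonds)) return(0L)
    inside <- dist[center, ] <= r
    sum(inside[bonds$from] & inside[bonds$to])
  }

  ids <- .atom_init_ids(mol)
  rows <- list()
  prev_atoms <- as.list(seq_len(n))
  prev_edges <- rep(0L, n)
  for (a in seq_len(n)) {
    rows[[length(rows) + 1L]] <- list(center = a, radius = 0L, env_hash = ids[a],
                                      atoms = a)
  }
  r <- 0L
  while (r < max_radius) {
    r <- r + 1L
    new_ids <- numeric(n)
    for (a in seq_len(n)) {
      pairs <- cbind(nbr[[a]]$ord, ids[nbr[[a]]$idx])
      if (nrow(pairs)) pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      vec <- c(r, ids[a], as.numeric(t(pairs)))
      new_ids[a] <- .poly_hash_matrix(matrix(vec, nrow = 1))
    }
    for (a in seq_len(n)) {
      atoms <- which(dist[a, ] <= r)
      edges <- edge_within(a, r)
      if (length(atoms) == length(prev_atoms[[a]]) && edges == prev_edges[a]) {
        prev_atoms[[a]] <- atoms; prev_edges[a] <- edges
        next  # environment exhausted: no growth at this radius
      }
      rows[[length(rows) + 1L]] <- list(center = a, radius = r, env_hash = new_ids[a],
                                        atoms = atoms)
      prev_atoms[[a]] <- atoms; prev_edges[a] <- edges
    }
    ids <- new_ids
  }
  feats <- data.frame(
    center = vapply(rows, `[[`, numeric(1), "center"),
    radius = vapply(rows, `[[`, numeric(1), "radius"),
    env_hash = vapply(rows, `[[`, numeric(1), "env_hash")
  )
  feats$atoms <- lapply(rows, function(x) as.integer(x$atoms))
  # set semantics: deduplicate by env_hash, keeping the first occurrence in
  # (radius, center) order
  feats <- feats[order(feats$radius, feats$center), ]
  feats <- feats[!duplicated(feats$env_hash), ]
  rownames(feats) <- NULL
  feats
}

#' Fold enumerated environments into a fixed-length binary fingerprint
#'
#' Bit index is `env_hash mod n_bits` (reported 1-based). When distinct
#' environments collide on one bit, the bit is set once and the provenance
#' list keeps every colliding environment; downstream atom mapping splits the
#' bit's attribution equally among them.
#'
#' @param features Output of [enumerate_environments()].
#' @param n_bits Fingerprint length (default 4096).
#' @return A `shapcf_fp` with fields `n_bits`, `on_bits` (sorted set bit
#'   indices) and `provenance` (list keyed by bit index as character, each a
#'   data.frame of colliding environments with list-column `atoms`).
#' @export
fold_to_fingerprint <- function(features, n_bits = 4096L) {
  if (n_bits <= 0L) stop("n_bits must be positive")
  if (nrow(features) == 0L) {
    return(structure(list(n_bits = as.integer(n_bits), on_bits = integer(),
                          provenance = list()), class = "shapcf_fp"))
  }
  bit <- as.integer(features$env_hash %% n_bits) + 1L
  prov <- split(features, bit)
  structure(
    list(n_bits = as.integer(n_bits), on_bits = sort(unique(bit)), provenance = prov),
    class = "shapcf_fp"
  )
}

#' Fingerprint a molecule
#'
#' Convenience wrapper: [enumerate_environments()] followed by
#' [fold_to_fingerprint()].
#' @inheritParams enumerate_environments
#' @inheritParams fold_to_fingerprint
#' @return A `shapcf_fp`.
#' @export
fingerprint <- function(mol, n_bits = 4096L, max_radius = 2L) {
  fold_to_fingerprint(enumerate_environments(mol, max_radius), n_bits)
}

#' @export
print.shapcf_fp <- function(x, ...) {
  cat("<shapcf_fp> ", length(x$on_bits), "/", x$n_bits, " bits set\n", sep = "")
  invisible(x)
}

#' Dense 0/1 vector form of a fingerprint
#' @param fp A `shapcf_fp`.
#' @return Numeric vector of length `n_bits`.
#' @export
fp_dense <- function(fp) {
  v <- numeric(fp$n_bits)
  v[fp$on_bits] <- 1
  v
}

#' Stack fingerprints into a dense 0/1 matrix
#' @param fps List of `shapcf_fp` objects with equal `n_bits`.
#' @return Numeric matrix, one row per fingerprint.
#' @export
fingerprint_matrix <- function(fps) {
  if (length(fps) == 0L) stop("no fingerprints supplied")
  nb <- unique(vapply(fps, `[[`, integer(1), "n_bits"))
  if (length(nb) != 1L) stop("fingerprints differ in length")
  X <- matrix(0, nrow = length(fps), ncol = nb)
  for (i in seq_along(fps)) X[i, fps[[i]]$on_bits] <- 1
  colnames(X) <- paste0("b", seq_len(nb))
  X
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of the set bits; two all-zero fingerprints are
#' defined as identical (similarity 1).
#' @param a,b `shapcf_fp` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (a$n_bits != b$n_bits) stop("fingerprint lengths differ")
  u <- length(union(a$on_bits, b$on_bits))
  if (u == 0L) return(1.0)
  length(intersect(a$on_bits, b$on_bits)) / u
}

#' Fraction of molecules containing a substructure
#'
#' @param mols Non-empty list of `shapcf_mol` objects (or SMILES strings).
#' @param pattern A SMARTS pattern.
#' @return Fraction in `[0, 1]` of molecules with at least one match.
#' @export
substructure_fraction <- function(mols, pattern) {
  if (length(mols) == 0L) stop("no molecules supplied")
  mean(has_substructure(mols, pattern))
}
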