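# Atom-pair fingerprints: hashed (atom type, atom type, topological
# distance) triples over heavy atoms. Atom type = (element, heavy-neighbor
# count, aromatic flag); distances capped at 30 bonds.

AP_DIST_CAP <- 30L

# integer atom-type code, stable across sessions
atom_type_codes <- function(mol) {
  el_idx <- match(mol$atoms$element,
                  c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I"))
  el_idx[is.na(el_idx)] <- 11L
  deg <- pmin(atom_degree(mol), 9L)
  el_idx * 100L + deg * 10L + as.integer(mol$atoms$aromatic)
}

#' Atom-pair fingerprint
#'
#' @param mol a molecule with at least 2 heavy atoms; a single-heavy-atom
#'   molecule yields an empty fingerprint with a warning.
#' @return object of class `fingerprint`: sorted integer vector of hashed keys
#' @export
atom_pair_fingerprint <- function(mol) {
  n <- n_atoms(mol)
  if (n < 2L) {
    warning("single-heavy-atom molecule: empty fingerprint")
    return(structure(integer(0), class = "fingerprint"))
  }
  types <- atom_type_codes(mol)
  D <- topo_distances(mol, cap = AP_DIST_CAP)
  keys <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- D[i, j]
      if (d > AP_DIST_CAP) next  # disconnected pair beyond cap
      t1 <- min(types[i], types[j]); t2 <- max(types[i], types[j])
      keys <- c(keys, hash_mix(c(t1, t2, d)))
    }
  }
  structure(sort(unique(keys)), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d keys>\n", length(x)))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' |A intersect B| / |A union B|. Both-empty input is undefined and raises
#' an error rather than returning 0.
#'
#' @param a,b fingerprints (integer key sets)
#' @return similarity in [0, 1]
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (!length(a) && !length(b))
    abort2("Tanimoto undefined for two empty fingerprints", "cavigrow_domain_error")
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Fold a fingerprint into a fixed-length count vector
#'
#' Deterministic modular folding; used by descriptor-space providers.
#' @param fp fingerprint
#' @param nbits vector length
#' @return numeric vector of length nbits
#' @export
fold_fingerprint <- function(fp, nbits = 64L) {
  v <- numeric(nbits)
  if (length(fp)) {
    idx <- (as.integer(fp) %% nbits) + 1L
    tab <- table(idx)
    v[as.integer(names(tab))] <- as.numeric(tab)
  }
  v
}
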