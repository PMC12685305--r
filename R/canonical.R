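# Canonical atom ranking by Morgan-style iterative refinement with
# deterministic tie-breaking, and the canonical line-notation built on it.

#' Canonical atom ranks
#'
#' Initial invariant: (element, heavy degree, formal charge, implicit H,
#' aromatic flag, ring membership). Ranks are refined by the sorted
#' multiset of (neighbor rank, bond order) codes until the partition is
#' stable; remaining ties are broken by promoting one member of the
#' lowest tied class (an automorphism orbit after refinement) and
#' re-refining until all ranks are distinct.
#'
#' @param mol a molecule
#' @return integer vector: rank 1..n per atom (1 = canonical root)
#' @export
canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 1L) return(1L)
  adj <- adjacency(mol)
  b <- mol$bonds
  bkey <- paste(b$i, b$j)
  ord_of <- function(i, j) b$order[match(paste(min(i, j), max(i, j)), bkey)]
  deg <- atom_degree(mol)
  hc <- implicit_hydrogens(mol)
  ri <- ring_info(mol)

  init <- sprintf("%2s|%02d|%+03d|%02d|%d|%d",
                  mol$atoms$element, deg, mol$atoms$charge, hc,
                  as.integer(mol$atoms$aromatic), as.integer(ri$atom_in_ring))
  rank <- match(init, sort(unique(init)))

  refine <- function(rank) {
    repeat {
      nbcode <- vapply(seq_len(n), function(k) {
        if (!length(adj[[k]])) return("")
        codes <- vapply(adj[[k]], function(u)
          sprintf("%04d:%03.1f", rank[u], ord_of(k, u)), character(1))
        paste(sort(codes), collapse = ";")
      }, character(1))
      newkey <- sprintf("%04d|%s", rank, nbcode)
      newrank <- match(newkey, sort(unique(newkey)))
      if (length(unique(newrank)) == length(unique(rank))) return(newrank)
      rank <- newrank
    }
  }

  rank <- refine(rank)
  while (anyDuplicated(rank)) {
    dup_vals <- unique(rank[duplicated(rank)])
    cls <- min(dup_vals)
    members <- which(rank == cls)
    # members form one refined class (orbit); promote one and re-refine
    promote <- members[1]
    rank <- rank * 2L
    rank[promote] <- rank[promote] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

#' Canonical line-notation (SMILES) for a molecule
#'
#' Deterministic: isomorphic heavy-atom graphs map to the same string.
#' Invalid (valence-violating) molecules are rejected with the index of
#' the offending atom.
#'
#' @param mol a molecule
#' @return canonical SMILES string
#' @export
canonicalize <- function(mol) {
  validate_molecule(mol)
  write_smiles(mol, ranks = canonical_ranks(mol))
}
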