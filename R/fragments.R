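# Fragment library handling and deterministic 3D embedding of molecular
# graphs. The shipped library (inst/extdata/fragments.tsv) holds 177
# fragments assembled from common ring systems, linkers and terminal
# groups, each with free-valence attachment points.

#' Path of the shipped default fragment library
#' @export
default_fragment_library <- function() {
  system.file("extdata", "fragments.tsv", package = "cavigrow")
}

#' Load a fragment library
#'
#' Each TSV row: id, smiles, attachments (comma-separated 1-based atom
#' indices), class in {donor, acceptor, hydrophobe, aromatic, linker}.
#' Fragments that fail to parse, violate valence or have no free-valence
#' attachment point are skipped with a warning.
#'
#' @param path library TSV (default: the shipped 177-fragment library)
#' @return list of fragments: list(id, mol, attachments, class)
#' @export
load_fragment_library <- function(path = default_fragment_library()) {
  if (!file.exists(path) || file.size(path) == 0L)
    abort2("fragment library file missing or empty", "cavigrow_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) abort2("fragment library has no entries", "cavigrow_io_error")
  out <- list()
  nskip <- 0L
  for (k in seq_len(nrow(df))) {
    mol <- tryCatch(parse_smiles(df$smiles[k], id = df$id[k]),
                    error = function(e) NULL)
    if (is.null(mol)) { nskip <- nskip + 1L; next }
    h <- implicit_hydrogens(mol)
    att <- suppressWarnings(
      as.integer(strsplit(as.character(df$attachments[k]), ",")[[1]]))
    att <- att[!is.na(att) & att >= 1L & att <= n_atoms(mol) & h[att] > 0L]
    if (!length(att)) att <- which(h > 0L)
    if (!length(att)) { nskip <- nskip + 1L; next }
    out[[length(out) + 1L]] <- list(id = df$id[k], mol = mol,
                                    attachments = att, class = df$class[k])
  }
  if (nskip > 0L)
    warning(sprintf("skipped %d invalid fragment(s) (parse/valence/attachment)",
                    nskip))
  if (!length(out)) abort2("no usable fragments in library", "cavigrow_io_error")
  out
}

#' Deterministic 3D embedding of a molecular graph
#'
#' Lightweight distance-geometry refinement: a jittered BFS layout is
#' relaxed under bond-length springs (1.50 angstrom single, 1.40
#' aromatic), 1-3 angle spacers (2.45 angstrom) and a soft nonbonded
#' repulsion floor (2.8 angstrom for pairs >= 3 bonds apart). The seed is
#' derived from the canonical form, so an identical molecule always
#' embeds identically regardless of atom order. Geometry is coarse by
#' design: it feeds a 0.5-angstrom grid fitness, not an energy model.
#'
#' @param mol a molecule
#' @param iters refinement iterations (default 120)
#' @return the molecule with `coords` set
#' @export
embed_molecule <- function(mol, iters = 120L) {
  n <- n_atoms(mol)
  seed <- hash_mix(utf8ToInt(canonicalize(mol)))
  b <- mol$bonds
  if (n == 1L) { mol$coords <- matrix(0, 1, 3); return(mol) }
  D <- topo_distances(mol, cap = 6L)
  r0 <- ifelse(b$order == 1.5, 1.40, 1.50)
  # 1-3 pairs
  pairs13 <- which(D == 2L & upper.tri(D), arr.ind = TRUE)
  pairsNB <- which(D >= 3L & upper.tri(D), arr.ind = TRUE)
  x <- with_seed(seed, {
    init <- matrix(stats::rnorm(n * 3, sd = 0.5), n, 3)
    # BFS layering along x to pre-stretch chains
    comp_layer <- topo_distances(mol, cap = 50L)[1, ]
    init[, 1] <- init[, 1] + comp_layer * 1.2
    init
  })
  step <- 0.12
  for (it in seq_len(iters)) {
    g <- matrix(0, n, 3)
    # bond springs
    d <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
    len <- sqrt(rowSums(d^2)); len[len < 1e-6] <- 1e-6
    f <- (len - r0) / len
    gi <- d * f
    for (k in seq_len(nrow(b))) {
      g[b$i[k], ] <- g[b$i[k], ] + gi[k, ]
      g[b$j[k], ] <- g[b$j[k], ] - gi[k, ]
    }
    # 1-3 spacers (attract/repel to 2.45)
    if (nrow(pairs13)) {
      d <- x[pairs13[, 1], , drop = FALSE] - x[pairs13[, 2], , drop = FALSE]
      len <- sqrt(rowSums(d^2)); len[len < 1e-6] <- 1e-6
      f <- 0.5 * (len - 2.45) / len
      gi <- d * f
      for (k in seq_len(nrow(pairs13))) {
        g[pairs13[k, 1], ] <- g[pairs13[k, 1], ] + gi[k, ]
        g[pairs13[k, 2], ] <- g[pairs13[k, 2], ] - gi[k, ]
      }
    }
    # nonbonded floor
    if (nrow(pairsNB)) {
      d <- x[pairsNB[, 1], , drop = FALSE] - x[pairsNB[, 2], , drop = FALSE]
      len <- sqrt(rowSums(d^2)); len[len < 1e-6] <- 1e-6
      viol <- len < 2.8
      if (any(viol)) {
        f <- numeric(length(len))
        f[viol] <- 0.5 * (len[viol] - 2.8) / len[viol]
        gi <- d * f
        for (k in which(viol)) {
          g[pairsNB[k, 1], ] <- g[pairsNB[k, 1], ] + gi[k, ]
          g[pairsNB[k, 2], ] <- g[pairsNB[k, 2], ] - gi[k, ]
        }
      }
    }
    x <- x - step * g
  }
  mol$coords <- sweep(x, 2, colMeans(x))
  mol
}

#' Bond-geometry strain of an embedded molecule
#'
#' Mean absolute deviation of bond lengths from their targets (angstrom);
#' the strain term of the growth fitness.
#' @param mol embedded molecule
#' @export
bond_strain <- function(mol) {
  if (is.null(mol$coords) || !nrow(mol$bonds)) return(0)
  b <- mol$bonds
  d <- mol$coords[b$i, , drop = FALSE] - mol$coords[b$j, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  r0 <- ifelse(b$order == 1.5, 1.40, 1.50)
  mean(abs(len - r0))
}

# --- graph surgery used by the GA -----------------------------------------

# join two molecules with a single bond between atom ai of a and atom bi of b
join_molecules <- function(a, ai, b, bi) {
  na <- n_atoms(a)
  atoms <- rbind(a$atoms, b$atoms)
  bonds_b <- b$bonds
  if (nrow(bonds_b)) {
    bonds_b$i <- bonds_b$i + na; bonds_b$j <- bonds_b$j + na
  }
  bonds <- rbind(a$bonds, bonds_b,
                 data.frame(i = ai, j = bi + na, order = 1))
  molecule(atoms, bonds, id = a$id, validate = FALSE)
}

# add a single bond inside one molecule (LINK closing a ring)
bridge_atoms <- function(mol, ai, bi) {
  bonds <- rbind(mol$bonds, data.frame(i = min(ai, bi), j = max(ai, bi),
                                       order = 1))
  molecule(mol$atoms, bonds, id = mol$id, validate = FALSE)
}

# split at an acyclic bond; returns the two sides as molecules plus the
# cut-atom index within each side (NULL if the bond is in a ring)
split_at_bond <- function(mol, bond_idx) {
  b <- mol$bonds[bond_idx, ]
  keep <- mol$bonds[-bond_idx, , drop = FALSE]
  tmp <- molecule(mol$atoms, keep, validate = FALSE)
  comp <- mol_components(tmp)
  if (comp[b$i] == comp[b$j]) return(NULL)
  side <- function(root_atom) {
    members <- which(comp == comp[root_atom])
    remap <- match(seq_len(n_atoms(mol)), members)
    bk <- keep[comp[keep$i] == comp[root_atom], , drop = FALSE]
    bk$i <- remap[bk$i]; bk$j <- remap[bk$j]
    list(mol = molecule(mol$atoms[members, , drop = FALSE], bk,
                        validate = FALSE),
         cut = remap[root_atom])
  }
  list(a = side(b$i), b = side(b$j))
}

# atoms with at least one free valence (implicit H), safe to bond to
attachable_atoms <- function(mol) {
  h <- tryCatch(implicit_hydrogens(mol), error = function(e) NULL)
  if (is.null(h)) return(integer(0))
  which(h > 0L)
}

# TRUE if the molecule passes valence validation
valence_ok <- function(mol) {
  isTRUE(tryCatch(validate_molecule(mol), error = function(e) FALSE))
}
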