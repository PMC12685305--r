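# Fixed 24-descriptor physicochemical panel, cosine similarity and PCA
# projection. The panel is a documented, deterministic subset of the
# usual 2D physicochemical space (masses, counts, topology, crude logP
# and TPSA estimates); descriptor failures are imputed with the panel
# median of the batch and flagged.

DESCRIPTOR_NAMES <- c(
  "MW", "nHeavy", "nBonds", "nRings", "nAromRings", "nAromAtoms",
  "nC", "nN", "nO", "nS", "nHal", "nHBD", "nHBA", "nRot",
  "TPSA", "cLogP", "frCsp3", "meanDegree", "maxDegree", "Wiener",
  "totalCharge", "nHetero", "frBranched", "frRingAtoms"
)

# crude Crippen-style atomic logP contributions (heavy atoms; implicit H
# folded into the carbon terms)
LOGP_CONTRIB <- c(C = 0.36, N = -0.60, O = -0.55, S = 0.25, P = -0.30,
                  F = 0.22, Cl = 0.65, Br = 0.85, I = 1.05, B = 0.10)

# crude TPSA contributions by (element, has H) class
tpsa_contrib <- function(el, h, arom) {
  if (el == "N") {
    if (arom) return(if (h > 0) 15.79 else 12.89)
    return(if (h > 0) 12.03 + 9.0 * min(h - 1, 1) else 3.24)
  }
  if (el == "O") return(if (h > 0) 20.23 else 9.23)
  if (el == "S") return(if (h > 0) 38.80 else 25.30)
  if (el == "P") return(13.59)
  0
}

#' Physicochemical descriptor vector (fixed 24-descriptor panel)
#'
#' Deterministic panel: molecular weight, atom/bond/ring counts, aromatic
#' content, element counts, H-bond donors/acceptors, rotatable bonds,
#' TPSA and logP estimates, sp3 fraction, degree statistics, Wiener
#' index, charge, heteroatom count, branching and ring-atom fractions.
#'
#' @param mol a molecule
#' @return object of class `descriptor_vector`: named numeric vector of
#'   length 24 with attribute `imputed` naming any imputed entries
#' @export
descriptor_vector <- function(mol) {
  vals <- tryCatch(compute_descriptors(mol), error = function(e) NULL)
  if (is.null(vals)) {
    vals <- stats::setNames(rep(NA_real_, length(DESCRIPTOR_NAMES)),
                            DESCRIPTOR_NAMES)
  }
  imputed <- names(vals)[!is.finite(vals)]
  if (length(imputed)) {
    med <- stats::median(vals[is.finite(vals)])
    if (!is.finite(med)) med <- 0
    vals[!is.finite(vals)] <- med
  }
  structure(vals, class = "descriptor_vector", imputed = imputed)
}

compute_descriptors <- function(mol) {
  el <- mol$atoms$element
  n <- n_atoms(mol)
  h <- implicit_hydrogens(mol)
  deg <- atom_degree(mol)
  ri <- ring_info(mol)
  rings <- find_rings(mol)
  arom_rings <- sum(vapply(rings, function(r) all(mol$atoms$aromatic[r]),
                           logical(1)))
  b <- mol$bonds
  # rotatable: acyclic single bonds between non-terminal heavy atoms
  nrot <- 0L
  if (nrow(b)) {
    rot <- b$order == 1 & !ri$bond_in_ring & deg[b$i] > 1L & deg[b$j] > 1L
    nrot <- sum(rot)
  }
  hbd <- sum(el %in% c("N", "O") & h > 0L)
  hba <- sum(el %in% c("N", "O"))
  tpsa <- sum(vapply(seq_len(n), function(k)
    tpsa_contrib(el[k], h[k], mol$atoms$aromatic[k]), numeric(1)))
  clogp <- sum(LOGP_CONTRIB[el], na.rm = TRUE) + 0.12 * sum(h[el == "C"])
  csp3 <- sum(el == "C" & !mol$atoms$aromatic &
                vapply(seq_len(n), function(k) {
                  if (el[k] != "C") return(FALSE)
                  kb <- b[b$i == k | b$j == k, , drop = FALSE]
                  all(kb$order == 1)
                }, logical(1)))
  D <- topo_distances(mol, cap = 60L)
  Dfin <- D[upper.tri(D)]
  wiener <- sum(Dfin[Dfin <= 60L])
  c(MW = mol_weight(mol),
    nHeavy = n,
    nBonds = nrow(b),
    nRings = ri$cycle_rank,
    nAromRings = arom_rings,
    nAromAtoms = sum(mol$atoms$aromatic),
    nC = sum(el == "C"),
    nN = sum(el == "N"),
    nO = sum(el == "O"),
    nS = sum(el == "S"),
    nHal = sum(el %in% c("F", "Cl", "Br", "I")),
    nHBD = hbd,
    nHBA = hba,
    nRot = nrot,
    TPSA = tpsa,
    cLogP = clogp,
    frCsp3 = if (sum(el == "C")) csp3 / sum(el == "C") else 0,
    meanDegree = mean(deg),
    maxDegree = max(deg),
    Wiener = wiener,
    totalCharge = sum(mol$atoms$charge),
    nHetero = sum(!(el %in% c("C"))),
    frBranched = mean(deg >= 3L),
    frRingAtoms = mean(ri$atom_in_ring))
}

#' Cosine similarity of two numeric vectors
#'
#' @param a,b equal-length numeric vectors with nonzero norm
#' @return dot(a, b) / (||a|| ||b||), in [-1, 1]
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    abort2("cosine similarity requires equal-length vectors", "cavigrow_domain_error")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    abort2("cosine similarity undefined for zero-norm vector", "cavigrow_domain_error")
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' PCA projection of a samples x features matrix
#'
#' Mean-centered principal component scores via [stats::prcomp].
#'
#' @param x numeric matrix (rows = samples)
#' @param k number of components
#' @return list(scores = samples x k matrix, explained = variance fractions)
#' @export
pca_project <- function(x, k) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort2("PCA requires >= 2 samples", "cavigrow_domain_error")
  if (k > min(nrow(x), ncol(x)))
    abort2("k exceeds min(samples, features)", "cavigrow_domain_error")
  sdev_cols <- apply(x, 2, stats::sd)
  if (all(sdev_cols == 0))
    abort2("all features constant: PCA undefined", "cavigrow_domain_error")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)])
}
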