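# Interface-conservation analytics: pairwise cavity-region RMSD
# normalized by whole-protein RMSD across a structure family, and
# physicochemical similarity between per-structure ligand sets.

#' Pairwise normalized cavity RMSD matrix
#'
#' For each structure pair, shared C-alpha atoms (matched by chain +
#' residue number) are superposed twice: once on the whole protein and
#' once on the cavity residue set; normalized RMSD = cavity / whole.
#' A whole-protein RMSD below 0.01 angstrom means the pair is a rigid
#' copy, and the normalized entry is defined as 0 (logged). Pairs
#' sharing fewer than 3 atoms in either set are marked missing and
#' excluded from the summaries.
#'
#' @param structures list of structure3d (>= 2)
#' @param cavity_residues data.frame(chain, resno) of cavity residues, or
#'   an integer vector of residue numbers (chain-agnostic)
#' @param atom_name atom matched per residue (default "CA"; use e.g.
#'   "CB" or another name for an all-atom variant per atom type)
#' @return object of class `conservation_result`: list(ids, cavity_rmsd,
#'   whole_rmsd, normalized, summary)
#' @export
interface_rmsd_matrix <- function(structures, cavity_residues,
                                  atom_name = "CA") {
  ns <- length(structures)
  if (ns < 2L) abort2("need at least two structures", "cavigrow_domain_error")
  if (!is.data.frame(cavity_residues))
    cavity_residues <- data.frame(chain = "A", resno = cavity_residues)
  ids <- vapply(structures, `[[`, character(1), "id")
  Mcav <- matrix(NA_real_, ns, ns, dimnames = list(ids, ids))
  Mwhole <- Mcav; Mnorm <- Mcav
  diag(Mcav) <- 0; diag(Mwhole) <- 0; diag(Mnorm) <- 0
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      whole <- paired_coords(structures[[i]], structures[[j]], atom_name)
      cavp <- paired_coords(structures[[i]], structures[[j]], atom_name,
                            residues = cavity_residues)
      if (nrow(whole$x1) < 3L || nrow(cavp$x1) < 3L) next
      rw <- kabsch_superpose(whole$x1, whole$x2)$rmsd
      rc <- kabsch_superpose(cavp$x1, cavp$x2)$rmsd
      Mwhole[i, j] <- Mwhole[j, i] <- rw
      Mcav[i, j] <- Mcav[j, i] <- rc
      Mnorm[i, j] <- Mnorm[j, i] <- if (rw < 0.01) 0 else rc / rw
    }
  }
  ut <- upper.tri(Mnorm)
  summary <- list(
    mean_normalized = mean(Mnorm[ut], na.rm = TRUE),
    median_normalized = stats::median(Mnorm[ut], na.rm = TRUE),
    mean_cavity = mean(Mcav[ut], na.rm = TRUE),
    median_cavity = stats::median(Mcav[ut], na.rm = TRUE),
    n_missing_pairs = sum(is.na(Mnorm[ut])))
  structure(list(ids = ids, cavity_rmsd = Mcav, whole_rmsd = Mwhole,
                 normalized = Mnorm, summary = summary),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf(
    "<conservation_result: %d structures; normalized RMSD mean %.3f, median %.3f>\n",
    length(x$ids), x$summary$mean_normalized, x$summary$median_normalized))
  invisible(x)
}

#' Pairwise cosine similarity between per-structure ligand sets
#'
#' Each ligand set is reduced to its mean descriptor vector; the output
#' is the symmetric cosine matrix with unit diagonal. Sets whose
#' descriptors fail entirely are excluded with a warning.
#'
#' @param ligand_sets named list: one list of molecules per structure
#' @return symmetric cosine similarity matrix
#' @export
ligandset_similarity <- function(ligand_sets) {
  if (!length(ligand_sets)) abort2("no ligand sets", "cavigrow_domain_error")
  means <- list()
  for (nm in names(ligand_sets)) {
    vs <- lapply(ligand_sets[[nm]], function(m)
      tryCatch(as.numeric(descriptor_vector(m)), error = function(e) NULL))
    vs <- vs[!vapply(vs, is.null, logical(1))]
    if (!length(vs)) {
      warning(sprintf("descriptor failure for entire set '%s'; excluded", nm))
      next
    }
    means[[nm]] <- colMeans(do.call(rbind, vs))
  }
  ns <- length(means)
  M <- matrix(1, ns, ns, dimnames = list(names(means), names(means)))
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      M[i, j] <- M[j, i] <- cosine_similarity(means[[i]], means[[j]])
    }
  }
  M
}
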