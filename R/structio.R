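# Protein structure I/O and superposition. PDB parsing is backed by
# bio3d; on top of it: first-altloc selection, water removal, element
# inference from atom names where the element columns are absent, and
# Bondi van der Waals radii.

# Bondi radii (angstrom); 1.7 default for anything else
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
VDW_DEFAULT <- 1.7

#' Read a protein structure from a PDB file
#'
#' ATOM and HETATM records are parsed (first MODEL only); for alternate
#' locations the first is kept; waters (HOH/WAT) are dropped by default.
#' The element is taken from PDB columns 77-78 when present, otherwise
#' inferred from the atom name. Van der Waals radii from the Bondi table
#' (1.7 angstrom for unknown elements).
#'
#' @param path PDB file path
#' @param keep_waters keep HOH/WAT residues (default FALSE)
#' @param keep_hydrogens keep hydrogen atoms (default FALSE; the cavity
#'   grid works on heavy atoms)
#' @return object of class `structure3d`: list with `atoms` data.frame
#'   (serial, name, element, resname, resno, chain, x, y, z, vdw) and `id`
#' @export
read_pdb <- function(path, keep_waters = FALSE, keep_hydrogens = FALSE) {
  if (!file.exists(path)) abort2(paste("no such file:", path), "cavigrow_io_error")
  invisible(utils::capture.output(
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                            verbose = FALSE))))
  a <- pdb$atom
  if (!nrow(a)) abort2("no ATOM records in PDB file", "cavigrow_io_error")
  # first altloc: keep blank or the first label encountered per atom site
  alt <- a$alt
  alt[is.na(alt)] <- ""
  keep <- alt == "" | !duplicated(paste(a$chain, a$resno, a$resid, a$elety))
  a <- a[keep, , drop = FALSE]
  if (!keep_waters) a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  el <- a$elesy
  el[is.na(el) | el == ""] <- NA
  miss <- is.na(el)
  if (any(miss)) el[miss] <- infer_element(a$elety[miss])
  el <- normalize_element(el)
  if (!keep_hydrogens) {
    hmask <- el == "H"
    a <- a[!hmask, , drop = FALSE]; el <- el[!hmask]
  }
  if (!nrow(a)) abort2("no atoms left after filtering", "cavigrow_io_error")
  vdw <- VDW_RADII[el]
  vdw[is.na(vdw)] <- VDW_DEFAULT
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = el,
    resname = a$resid, resno = a$resno, chain = a$chain,
    x = a$x, y = a$y, z = a$z, vdw = as.numeric(vdw),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    abort2("non-finite coordinates in PDB file", "cavigrow_io_error")
  structure(list(atoms = atoms, id = sub("\\.pdb$", "", basename(path))),
            class = "structure3d")
}

infer_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE"),
               two, substr(gsub("[0-9']", "", nm), 1, 1))
  el
}

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d %s: %d atoms, %d residues, chains %s>\n",
              x$id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param s a structure3d
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Write a structure (or pseudo-atom table) as a PDB file
#'
#' Fixed-column PDB writer used for fixture structures and cavity grid
#' point dumps.
#'
#' @param s structure3d
#' @param path output path
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    a$serial %% 100000L, substr(a$name, 1, 4), substr(a$resname, 1, 3),
    substr(a$chain, 1, 1), a$resno %% 10000L, a$x, a$y, a$z,
    toupper(substr(a$element, 1, 2)))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Rigidly transform a structure
#' @param s structure3d
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector (angstrom)
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `mobile` onto `fixed` via SVD
#' of the cross-covariance, with the determinant sign correction that
#' guarantees a proper rotation.
#'
#' @param fixed,mobile N x 3 coordinate matrices, N >= 3
#' @return object of class `superposition`: list(rotation, translation,
#'   rmsd); `rotation %*% mobile_i + translation` approximates fixed_i
#' @export
kabsch_superpose <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (nrow(fixed) != nrow(mobile) || ncol(fixed) != 3L || ncol(mobile) != 3L)
    abort2("superposition needs equal-size N x 3 matrices", "cavigrow_domain_error")
  n <- nrow(fixed)
  if (n < 3L) abort2("superposition needs at least 3 points", "cavigrow_domain_error")
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(fixed, 2, cf); B <- sweep(mobile, 2, cm)
  # degenerate (collinear) point sets have rank-deficient covariance
  H <- t(B) %*% A
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
    abort2("degenerate (collinear) point set", "cavigrow_domain_error")
  d <- sign(det(sv$v %*% t(sv$u)))
  Dm <- diag(c(1, 1, d))
  R <- sv$v %*% Dm %*% t(sv$u)
  t_vec <- cf - as.numeric(R %*% cm)
  moved <- mobile %*% t(R)
  moved <- sweep(moved, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f A>\n", x$rmsd))
  invisible(x)
}

#' Paired C-alpha (or named-atom) coordinates for two structures
#'
#' Residue matching by (chain, residue number, atom name) intersection.
#' @param s1,s2 structure3d objects
#' @param atom_name atom to match on (default "CA")
#' @param residues optional data.frame(chain, resno) restricting the match
#' @return list(x1, x2) of paired coordinate matrices
#' @export
paired_coords <- function(s1, s2, atom_name = "CA", residues = NULL) {
  pick <- function(s) {
    a <- s$atoms[s$atoms$name == atom_name, , drop = FALSE]
    if (!is.null(residues)) {
      keymask <- paste(a$chain, a$resno) %in% paste(residues$chain, residues$resno)
      a <- a[keymask, , drop = FALSE]
    }
    a[!duplicated(paste(a$chain, a$resno)), , drop = FALSE]
  }
  a1 <- pick(s1); a2 <- pick(s2)
  key1 <- paste(a1$chain, a1$resno); key2 <- paste(a2$chain, a2$resno)
  shared <- intersect(key1, key2)
  i1 <- match(shared, key1); i2 <- match(shared, key2)
  list(x1 = as.matrix(a1[i1, c("x", "y", "z")]),
       x2 = as.matrix(a2[i2, c("x", "y", "z")]),
       keys = shared)
}
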