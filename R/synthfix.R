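# Deterministic synthetic-fixture generators: toy pocket structures with
# known ground truth, planted binding-energy mixtures, separable scaffold
# families for classifier training, ROC label/score sets, and perturbed
# structure families for conservation analysis. Every fixture is a pure
# function of (parameters, seed).

# quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Toy pocket structure with known ground truth
#'
#' A spherical shell of pseudo-atoms (two layers, ~2 angstrom lattice)
#' with a circular mouth opening along +z. The enclosed ball is the
#' planted cavity; its centroid, approximate interior radius and volume
#' are returned as ground truth. Lining pharmacophores are planted by
#' assigning residue names of the requested classes to shell atoms.
#'
#' @param radius shell radius in angstrom (>= 4)
#' @param mouth mouth width (chord) in angstrom; 0 = sealed pocket
#' @param pharmacophores character vector from
#'   {"donor","acceptor","hydrophobe","charged"} cycled over lining atoms
#' @param seed integer seed
#' @param center pocket center (default origin)
#' @param two_pockets if TRUE, a second identical pocket is added 6*radius
#'   away along x and both ground-truth descriptors are returned
#' @return list(structure, truth) where truth is a list of per-pocket
#'   descriptors (centroid, inner_radius, volume)
#' @export
make_pocket <- function(radius = 6, mouth = 4,
                        pharmacophores = c("hydrophobe", "donor", "acceptor"),
                        seed = 1L, center = c(0, 0, 0), two_pockets = FALSE) {
  if (radius < 4) abort2("pocket radius must be >= 4 angstrom", "cavigrow_domain_error")
  if (mouth >= 2 * radius)
    abort2("mouth width >= shell diameter: no enclosure", "cavigrow_domain_error")
  res_pool <- list(
    donor = c("SER", "THR", "LYS"),
    acceptor = c("ASP", "GLU"),
    hydrophobe = c("LEU", "VAL", "PHE"),
    charged = c("ARG", "ASP"))
  unknown <- setdiff(pharmacophores, names(res_pool))
  if (length(unknown))
    abort2(paste("unknown pharmacophore class:", unknown[1]), "cavigrow_domain_error")

  build_shell <- function(ctr, serial0, chain) {
    pts <- list()
    for (r in c(radius, radius + 1.9)) {
      n <- max(40L, round(4 * pi * r^2 / 4.0))  # ~2 A lattice
      u <- fibonacci_sphere(n) * r
      if (mouth > 0) {
        cos_cap <- sqrt(pmax(0, 1 - (mouth / (2 * r))^2))
        keep <- u[, 3] / r < cos_cap
        u <- u[keep, , drop = FALSE]
      }
      pts[[length(pts) + 1L]] <- u
    }
    u <- do.call(rbind, pts)
    u <- sweep(u, 2, ctr, "+")
    m <- nrow(u)
    classes <- rep(pharmacophores, length.out = m)
    resnames <- vapply(seq_len(m), function(k) {
      pool <- res_pool[[classes[k]]]
      pool[(k - 1L) %% length(pool) + 1L]
    }, character(1))
    data.frame(serial = serial0 + seq_len(m), name = "CA", element = "C",
               resname = resnames, resno = seq_len(m), chain = chain,
               x = u[, 1], y = u[, 2], z = u[, 3],
               vdw = VDW_RADII[["C"]], stringsAsFactors = FALSE)
  }

  atoms <- build_shell(center, 0L, "A")
  truth <- list(list(centroid = center,
                     inner_radius = radius - VDW_RADII[["C"]] - 1.0,
                     volume = 4 / 3 * pi * (radius - VDW_RADII[["C"]] - 1.0)^3))
  if (two_pockets) {
    c2 <- center + c(6 * radius, 0, 0)
    atoms2 <- build_shell(c2, nrow(atoms), "B")
    atoms <- rbind(atoms, atoms2)
    truth[[2]] <- list(centroid = c2,
                       inner_radius = truth[[1]]$inner_radius,
                       volume = truth[[1]]$volume)
  }
  list(structure = structure(list(atoms = atoms, id = "toy_pocket"),
                             class = "structure3d"),
       truth = truth)
}

# deterministic drug-like SMILES from an integer code and a family
# template; family "aromatic": benzene/pyridine cores + amine chains;
# family "aliphatic": branched alkyl/ether chains
fixture_smiles <- function(i, family) {
  digits <- integer(0)
  v <- i
  repeat {
    digits <- c(digits, v %% 3L)
    v <- v %/% 3L
    if (v == 0L) break
  }
  if (family == "aromatic") {
    core <- c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1")[(i %% 3L) + 1L]
    chain <- paste(c("C", "CN", "CC")[digits + 1L], collapse = "")
    paste0("N", chain, "C", sub("c1", "c1", core))  # amine tail + core
  } else {
    head <- c("CC(C)", "CCC", "CC(C)(C)")[(i %% 3L) + 1L]
    chain <- paste(c("C", "CO", "CC")[digits + 1L], collapse = "")
    paste0(head, chain, "O")
  }
}

#' Planted binding-energy mixture
#'
#' Two scaffold families with Gaussian binding energies: binders at
#' `mu_binder`, non-binders at `mu_nonbinder` (kcal/mol, more negative =
#' stronger). Truth labels are retained so segregation recovery can be
#' scored.
#'
#' @param n total number of ligands
#' @param mu_binder,mu_nonbinder component means (mu_binder < mu_nonbinder)
#' @param sigma common standard deviation (> 0)
#' @param binder_fraction fraction of true binders (default 0.5)
#' @param seed integer seed
#' @return list(mols, energies, labels) with labels "binder"/"nonbinder"
#' @export
make_energy_set <- function(n = 500, mu_binder = -9, mu_nonbinder = -5,
                            sigma = 0.5, binder_fraction = 0.5, seed = 1L) {
  if (sigma <= 0) abort2("sigma must be positive", "cavigrow_domain_error")
  if (mu_binder >= mu_nonbinder)
    abort2("mu_binder must be more negative than mu_nonbinder",
           "cavigrow_domain_error")
  nb <- round(n * binder_fraction)
  labels <- c(rep("binder", nb), rep("nonbinder", n - nb))
  energies <- with_seed(derive_seed(seed, "energy_set"), {
    e <- numeric(n)
    e[labels == "binder"] <- stats::rnorm(nb, mu_binder, sigma)
    e[labels == "nonbinder"] <- stats::rnorm(n - nb, mu_nonbinder, sigma)
    e
  })
  mols <- lapply(seq_len(n), function(k) {
    fam <- if (labels[k] == "binder") "aromatic" else "aliphatic"
    m <- parse_smiles(fixture_smiles(k, fam), id = sprintf("lig%04d", k))
    m
  })
  list(mols = mols, energies = energies, labels = labels)
}

#' Separable two-scaffold labeled molecule set
#'
#' Class 1 draws from an aromatic amine family, class 0 from an aliphatic
#' ether family. `divergence` in [0, 1] controls the fingerprint overlap:
#' each molecule draws from its own family with probability
#' (1 + divergence) / 2, otherwise from the other, so divergence 0 gives
#' identical class distributions and divergence 1 fully separable ones.
#'
#' @param n_per_class molecules per class (>= 20)
#' @param divergence scaffold divergence in [0, 1]
#' @param seed integer seed
#' @return list(mols, labels) with labels in {0, 1}
#' @export
make_separable_classes <- function(n_per_class = 100, divergence = 1.0,
                                   seed = 1L) {
  if (n_per_class < 20) abort2("need >= 20 molecules per class", "cavigrow_domain_error")
  if (divergence < 0 || divergence > 1)
    abort2("divergence must lie in [0, 1]", "cavigrow_domain_error")
  n <- 2L * n_per_class
  labels <- rep(c(1L, 0L), each = n_per_class)
  own <- with_seed(derive_seed(seed, "separable"),
                   stats::runif(n) < (1 + divergence) / 2)
  # both classes use the same molecule-code range so at divergence 0 the
  # class distributions are identical (no size confound between classes)
  code <- ((seq_len(n) - 1L) %% n_per_class) + 1L
  mols <- lapply(seq_len(n), function(k) {
    fam_own <- if (labels[k] == 1L) "aromatic" else "aliphatic"
    fam_other <- if (labels[k] == 1L) "aliphatic" else "aromatic"
    fam <- if (own[k]) fam_own else fam_other
    parse_smiles(fixture_smiles(code[k], fam), id = sprintf("m%04d", k))
  })
  list(mols = mols, labels = labels)
}

#' Random label/score ROC fixture
#'
#' Scores for positives drawn at `shift` above negatives (standard normal
#' noise), giving a tunable but non-degenerate ROC.
#'
#' @param n total size
#' @param shift mean score separation
#' @param seed integer seed
#' @return list(labels, scores)
#' @export
make_roc_set <- function(n = 50, shift = 1.0, seed = 1L) {
  with_seed(derive_seed(seed, "roc_set"), {
    labels <- stats::rbinom(n, 1L, 0.5)
    if (all(labels == labels[1])) labels[1] <- 1L - labels[1]
    scores <- stats::rnorm(n) + shift * labels
    list(labels = labels, scores = scores)
  })
}

#' Family of perturbed structures for conservation analysis
#'
#' A base pseudo-protein C-alpha trace (smooth random walk) plus copies
#' under random rigid motion, whole-chain Gaussian noise `noise_global`
#' and extra perturbation `noise_cavity` applied to the designated cavity
#' residues.
#'
#' @param n_structures number of structures (>= 2)
#' @param n_res residues in the chain
#' @param cavity_resno residue numbers forming the "cavity" set
#' @param noise_global whole-chain coordinate noise sd (angstrom)
#' @param noise_cavity additional cavity-residue noise sd (angstrom)
#' @param seed integer seed
#' @return list(structures = list of structure3d, cavity_resno)
#' @export
make_structure_family <- function(n_structures = 3, n_res = 40,
                                  cavity_resno = 10:18,
                                  noise_global = 0.2, noise_cavity = 1.0,
                                  seed = 1L) {
  with_seed(derive_seed(seed, "structure_family"), {
    # smooth self-avoiding-ish walk
    steps <- matrix(stats::rnorm(3 * (n_res - 1), sd = 1), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 3.8
    # smooth directions to avoid collapse
    for (k in 2:nrow(steps)) steps[k, ] <- 0.6 * steps[k - 1, ] + 0.4 * steps[k, ]
    base <- apply(rbind(c(0, 0, 0), steps), 2, cumsum)
    structures <- lapply(seq_len(n_structures), function(si) {
      xyz <- base
      if (si > 1L) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_global),
                            ncol = 3)
        cmask <- seq_len(n_res) %in% cavity_resno
        xyz[cmask, ] <- xyz[cmask, ] +
          matrix(stats::rnorm(sum(cmask) * 3, sd = noise_cavity), ncol = 3)
        # random rigid motion
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ang <- stats::runif(1, 0, pi)
        R <- rotation_about_axis(ax, ang)
        xyz <- xyz %*% t(R)
        xyz <- sweep(xyz, 2, stats::rnorm(3, sd = 10), "+")
      }
      atoms <- data.frame(serial = seq_len(n_res), name = "CA",
                          element = "C", resname = "ALA",
                          resno = seq_len(n_res), chain = "A",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          vdw = VDW_RADII[["C"]], stringsAsFactors = FALSE)
      structure(list(atoms = atoms, id = sprintf("fam%02d", si)),
                class = "structure3d")
    })
    list(structures = structures, cavity_resno = cavity_resno)
  })
}

#' Rotation matrix about an axis (Rodrigues)
#' @param axis unit 3-vector
#' @param angle radians
#' @export
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
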