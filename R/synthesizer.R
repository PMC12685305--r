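# Fragment genetic algorithm growing ligands inside a selected cavity.
# Molecules evolve as heavy-atom graphs (GROW: attach a fragment at a
# free valence; LINK: bridge two sites through a linker fragment;
# crossover: exchange subtrees at acyclic bonds; deletion: drop a
# terminal moiety), are embedded deterministically, posed rigidly in the
# cavity over an orientation sample, and scored by cavity fill,
# pharmacophore matching, clashes and strain. Unique canonical forms are
# collected until the target count.

#' Genetic-algorithm configuration for ligand growth
#'
#' Defaults: population 64, up to 200 generations, crossover 0.6,
#' mutation 0.3, elitism 4, GROW/LINK split 0.8/0.2, 500 unique target
#' ligands, 10-40 heavy atoms, 30 pose orientations.
#'
#' @param population_size GA population
#' @param generations generation cap
#' @param crossover_rate probability an offspring comes from crossover
#' @param mutation_rate probability a parent copy is mutated
#' @param target_count unique ligands to collect (default 500)
#' @param seed integer seed for the GA stream
#' @param elitism top individuals carried over unchanged
#' @param grow_prob probability a mutation is GROW rather than LINK
#' @param size_min,size_max heavy-atom bounds for collected ligands
#' @param orientations rigid orientations sampled when posing
#' @param weights fitness weights c(fill, pharm, clash, strain)
#' @return list of class `ga_config`
#' @export
ga_config <- function(population_size = 64L, generations = 200L,
                      crossover_rate = 0.6, mutation_rate = 0.3,
                      target_count = 500L, seed = 42L, elitism = 4L,
                      grow_prob = 0.8, size_min = 10L, size_max = 40L,
                      orientations = 30L,
                      weights = c(fill = 1.0, pharm = 1.0,
                                  clash = 1.0, strain = 0.25)) {
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            target_count >= 1L, population_size >= 4L)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 target_count = as.integer(target_count),
                 seed = as.integer(seed), elitism = as.integer(elitism),
                 grow_prob = grow_prob, size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 orientations = as.integer(orientations),
                 weights = weights),
            class = "ga_config")
}

# pharmacophore class per ligand atom
ligand_pharmacophores <- function(mol) {
  h <- implicit_hydrogens(mol)
  el <- mol$atoms$element
  cls <- rep("hydrophobe", n_atoms(mol))
  cls[mol$atoms$aromatic] <- "aromatic"
  cls[el %in% c("N", "O") & h > 0L] <- "donor"
  cls[el %in% c("N", "O") & h == 0L] <- "acceptor"
  cls
}

# cavity-side pharmacophore feature points from lining residues
cavity_features <- function(cavity, structure) {
  lr <- cavity$lining_residues
  a <- structure$atoms
  keymask <- paste(a$chain, a$resno) %in% paste(lr$chain, lr$resno)
  la <- a[keymask, , drop = FALSE]
  cls <- rep(NA_character_, nrow(la))
  cls[la$resname %in% RES_HYDROPHOBIC] <- "hydrophobe"
  cls[la$resname %in% RES_DONOR] <- "donor"
  cls[la$resname %in% RES_ACCEPTOR] <- "acceptor"
  cls[la$resname %in% RES_CHARGED] <- "charged"
  ok <- !is.na(cls)
  list(xyz = as.matrix(la[ok, c("x", "y", "z")]), class = cls[ok])
}

# pharmacophore matching contact distance (angstrom): lining atom
# centers sit behind the probe-inflated occupied shell, so the closest
# heavy-atom approach is ~vdW+vdW+probe = 4.4 A; one lattice layer of
# slack on top of that counts as contact
PHARM_CONTACT <- 5.5

# complementary cavity classes for a ligand pharmacophore class
complementary <- list(
  donor = c("acceptor", "charged"),
  acceptor = c("donor", "charged"),
  hydrophobe = "hydrophobe",
  aromatic = "hydrophobe")

#' Fitness of a posed ligand in a cavity
#'
#' w_fill * (fraction of cavity points within 2 angstrom of a ligand
#' atom) + w_pharm * (matched ligand pharmacophores / total ligand
#' pharmacophores) - w_clash * (atoms on occupied grid points) -
#' w_strain * bond-geometry strain.
#'
#' @param xyz posed ligand coordinates (n x 3)
#' @param mol the ligand graph
#' @param cavity_xyz cavity point coordinates (possibly subsampled)
#' @param features cavity pharmacophore features from `cavity_features`
#' @param grid the cavity_grid (clash lookup)
#' @param weights fitness weights c(fill, pharm, clash, strain)
#' @return list(score, fill, pharm, clash, strain)
#' @export
grow_fitness <- function(xyz, mol, cavity_xyz, features, grid,
                         weights = c(fill = 1, pharm = 1,
                                     clash = 1, strain = 0.25)) {
  covered <- logical(nrow(cavity_xyz))
  for (k in seq_len(nrow(xyz))) {
    d2 <- (cavity_xyz[, 1] - xyz[k, 1])^2 + (cavity_xyz[, 2] - xyz[k, 2])^2 +
      (cavity_xyz[, 3] - xyz[k, 3])^2
    covered <- covered | d2 <= 4
  }
  fill <- mean(covered)
  lig_cls <- ligand_pharmacophores(mol)
  matched <- 0L
  if (nrow(features$xyz)) {
    for (k in seq_along(lig_cls)) {
      comp <- complementary[[lig_cls[k]]]
      fm <- features$class %in% comp
      if (!any(fm)) next
      d2 <- (features$xyz[fm, 1] - xyz[k, 1])^2 +
        (features$xyz[fm, 2] - xyz[k, 2])^2 +
        (features$xyz[fm, 3] - xyz[k, 3])^2
      if (min(d2) <= PHARM_CONTACT^2) matched <- matched + 1L
    }
  }
  pharm <- if (length(lig_cls)) matched / length(lig_cls) else 0
  clash <- clash_count(grid, xyz)
  tmp <- mol; tmp$coords <- xyz
  strain <- bond_strain(tmp)
  score <- weights[["fill"]] * fill + weights[["pharm"]] * pharm -
    weights[["clash"]] * clash - weights[["strain"]] * strain
  list(score = score, fill = fill, pharm = pharm,
       clash = clash, strain = strain)
}

#' Number of atoms sitting on occupied grid points
#' @param grid a cavity_grid
#' @param xyz atom coordinates
#' @export
clash_count <- function(grid, xyz) {
  sub <- round(sweep(xyz, 2, grid$origin) / grid$spacing)
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  inb <- sub[, 1] >= 0 & sub[, 1] < nx & sub[, 2] >= 0 & sub[, 2] < ny &
    sub[, 3] >= 0 & sub[, 3] < nz
  if (!any(inb)) return(0L)
  lin <- sub[inb, 1] + nx * (sub[inb, 2] + ny * sub[inb, 3]) + 1L
  sum(grid$labels[lin] == 1L)
}

# fraction of atoms within `tol` of some cavity point
containment_fraction <- function(xyz, cavity_xyz, tol = 2.5) {
  inside <- vapply(seq_len(nrow(xyz)), function(k) {
    d2 <- (cavity_xyz[, 1] - xyz[k, 1])^2 + (cavity_xyz[, 2] - xyz[k, 2])^2 +
      (cavity_xyz[, 3] - xyz[k, 3])^2
    min(d2) <= tol^2
  }, logical(1))
  mean(inside)
}

# rigid orientation sample: fibonacci axes x 3 angles
orientation_sample <- function(n) {
  naxes <- max(1L, ceiling(n / 3))
  axes <- fibonacci_sphere(naxes)
  rots <- list()
  for (a in seq_len(naxes)) {
    for (ang in c(0, 2 * pi / 3, 4 * pi / 3)) {
      if (length(rots) >= n) break
      rots[[length(rots) + 1L]] <- rotation_about_axis(axes[a, ], ang)
    }
  }
  rots
}

# pose a molecule: best-scoring rigid placement; clash repair by small
# translations if needed
pose_molecule <- function(mol, cavity, grid, features, rots, weights,
                          cavity_sub) {
  emb <- embed_molecule(mol)
  base <- emb$coords
  ctr <- cavity$centroid
  best <- NULL
  for (R in rots) {
    xyz <- base %*% t(R)
    xyz <- sweep(xyz, 2, ctr, "+")
    fit <- grow_fitness(xyz, mol, cavity_sub, features, grid, weights)
    if (is.null(best) || fit$score > best$fit$score)
      best <- list(xyz = xyz, fit = fit)
  }
  if (best$fit$clash > 0L) {
    for (dxyz in list(c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0),
                      c(0, -0.5, 0), c(0, 0, 0.5), c(0, 0, -0.5),
                      c(0, 0, 1), c(0, 0, -1))) {
      xyz <- sweep(best$xyz, 2, dxyz, "+")
      fit <- grow_fitness(xyz, mol, cavity_sub, features, grid, weights)
      if (fit$clash < best$fit$clash ||
          (fit$clash == best$fit$clash && fit$score > best$fit$score))
        best <- list(xyz = xyz, fit = fit)
      if (best$fit$clash == 0L) break
    }
  }
  best
}

# GROW: attach a random library fragment at a random free valence
op_grow <- function(mol, library) {
  att <- attachable_atoms(mol)
  if (!length(att)) return(NULL)
  fr <- library[[sample.int(length(library), 1L)]]
  fa <- fr$attachments[sample.int(length(fr$attachments), 1L)]
  out <- join_molecules(mol, att[sample.int(length(att), 1L)], fr$mol, fa)
  if (valence_ok(out)) out else NULL
}

# LINK: bridge two distant free valences through a linker fragment
op_link <- function(mol, library) {
  att <- attachable_atoms(mol)
  if (length(att) < 2L) return(NULL)
  D <- topo_distances(mol, cap = 30L)
  pairs <- which(D[att, att, drop = FALSE] >= 4L &
                   upper.tri(D[att, att, drop = FALSE]), arr.ind = TRUE)
  if (!nrow(pairs)) return(NULL)
  p <- pairs[sample.int(nrow(pairs), 1L), ]
  a <- att[p[1]]; b <- att[p[2]]
  linkers <- Filter(function(f) length(f$attachments) >= 2L, library)
  if (!length(linkers)) return(NULL)
  fr <- linkers[[sample.int(length(linkers), 1L)]]
  na <- n_atoms(mol)
  out <- join_molecules(mol, a, fr$mol, fr$attachments[1])
  att2 <- fr$attachments[2] + na
  h <- tryCatch(implicit_hydrogens(out), error = function(e) NULL)
  if (is.null(h) || h[att2] < 1L || h[b] < 1L) return(NULL)
  out <- bridge_atoms(out, b, att2)
  if (valence_ok(out)) out else NULL
}

# deletion: drop a small terminal moiety
op_delete <- function(mol, max_leaf = 6L) {
  b <- mol$bonds
  cand <- which(b$order == 1)
  for (bi in sample(cand)) {
    sp <- split_at_bond(mol, bi)
    if (is.null(sp)) next
    sa <- n_atoms(sp$a$mol); sb <- n_atoms(sp$b$mol)
    if (min(sa, sb) > max_leaf) next
    keep <- if (sa >= sb) sp$a$mol else sp$b$mol
    if (n_atoms(keep) >= 2L && valence_ok(keep)) return(keep)
  }
  NULL
}

# crossover: exchange subtrees at acyclic single bonds
op_crossover <- function(m1, m2) {
  c1 <- which(m1$bonds$order == 1)
  c2 <- which(m2$bonds$order == 1)
  if (!length(c1) || !length(c2)) return(NULL)
  for (try in 1:6) {
    s1 <- split_at_bond(m1, c1[sample.int(length(c1), 1L)])
    s2 <- split_at_bond(m2, c2[sample.int(length(c2), 1L)])
    if (is.null(s1) || is.null(s2)) next
    out <- join_molecules(s1$a$mol, s1$a$cut, s2$b$mol, s2$b$cut)
    if (valence_ok(out)) return(out)
  }
  NULL
}

#' Grow ligands inside a cavity with the fragment genetic algorithm
#'
#' Runs seed placement, iterative GROW/LINK extension, fitness-ranked
#' selection with elitism, crossover and mutation, collecting ligands
#' that are clash-free, cavity-contained (>= 80% of heavy atoms within
#' 2.5 angstrom of a cavity point) and within the heavy-atom size bounds,
#' until `config$target_count` pairwise-distinct canonical forms are
#' found or the generation cap is hit (shortfall raises a warning and is
#' flagged in the result attributes).
#'
#' @param cavity a cavity from [detect_cavities]
#' @param structure the structure3d
#' @param grid the cavity_grid
#' @param library fragment library (default: shipped library)
#' @param config a [ga_config]
#' @return list of grown ligands: list(mol (posed coords), canonical,
#'   fitness, fill, pharm, provenance); attribute `shortfall` TRUE if the
#'   target was not reached
#' @export
grow_ligands <- function(cavity, structure, grid,
                         library = load_fragment_library(),
                         config = ga_config()) {
  if (!length(library)) abort2("empty fragment library", "cavigrow_domain_error")
  weights <- config$weights
  rots <- orientation_sample(config$orientations)
  features <- cavity_features(cavity, structure)
  # subsample cavity points for fitness speed; full set kept for checks
  cav_xyz <- cavity$xyz
  sub_idx <- unique(round(seq(1, nrow(cav_xyz),
                              length.out = min(200, nrow(cav_xyz)))))
  cavity_sub <- cav_xyz[sub_idx, , drop = FALSE]

  collected <- list()
  collected_keys <- character(0)
  pose_cache <- new.env(parent = emptyenv())

  evaluate <- function(mol) {
    key <- canonicalize(mol)
    if (!is.null(pose_cache[[key]])) return(pose_cache[[key]])
    p <- pose_molecule(mol, cavity, grid, features, rots, weights, cavity_sub)
    res <- list(key = key, pose = p)
    pose_cache[[key]] <- res
    res
  }

  with_seed(derive_seed(config$seed, "ga"), {
    # seed population
    pop <- lapply(seq_len(config$population_size), function(k) {
      fr <- library[[sample.int(length(library), 1L)]]
      list(mol = fr$mol, prov = fr$id, score = NA_real_)
    })
    gen <- 0L
    while (gen < config$generations &&
           length(collected) < config$target_count) {
      gen <- gen + 1L
      for (k in seq_along(pop)) {
        ev <- evaluate(pop[[k]]$mol)
        pop[[k]]$score <- ev$pose$fit$score
      }
      # selection before collection: only the fitter half of the
      # generation contributes to the output, so cavity pharmacophores
      # steer the collected chemistry, not just the parent pool
      scores <- vapply(pop, `[[`, numeric(1), "score")
      bar <- stats::quantile(scores, 0.7, names = FALSE)
      for (k in seq_along(pop)) {
        if (scores[k] < bar) next
        ev <- evaluate(pop[[k]]$mol)
        nat <- n_atoms(pop[[k]]$mol)
        if (nat >= config$size_min && nat <= config$size_max &&
            ev$pose$fit$clash == 0L &&
            containment_fraction(ev$pose$xyz, cav_xyz) >= 0.8 &&
            !(ev$key %in% collected_keys)) {
          m <- pop[[k]]$mol
          m$coords <- ev$pose$xyz
          m$id <- sprintf("LIG%04d", length(collected) + 1L)
          collected[[length(collected) + 1L]] <- list(
            mol = m, canonical = ev$key, fitness = ev$pose$fit$score,
            fill = ev$pose$fit$fill, pharm = ev$pose$fit$pharm,
            provenance = pop[[k]]$prov)
          collected_keys <- c(collected_keys, ev$key)
          if (length(collected) >= config$target_count) break
        }
      }
      if (length(collected) >= config$target_count) break
      # selection: rank by score
      ord <- order(vapply(pop, `[[`, numeric(1), "score"), decreasing = TRUE)
      pop <- pop[ord]
      elite <- pop[seq_len(min(config$elitism, length(pop)))]
      parents <- pop[seq_len(max(2L, floor(length(pop) / 3)))]
      offspring <- list()
      while (length(offspring) < config$population_size - length(elite)) {
        r <- stats::runif(1)
        child <- NULL
        p1 <- parents[[sample.int(length(parents), 1L)]]
        if (r < config$crossover_rate && length(parents) >= 2L) {
          p2 <- parents[[sample.int(length(parents), 1L)]]
          child <- op_crossover(p1$mol, p2$mol)
          prov <- paste0(p1$prov, "x")
        }
        if (is.null(child)) {
          # mutation path: GROW / LINK / occasional delete
          u <- stats::runif(1)
          if (u < config$mutation_rate) {
            child <- op_delete(p1$mol)
            prov <- paste0(p1$prov, "-")
          }
          if (is.null(child)) {
            if (stats::runif(1) < config$grow_prob) {
              child <- op_grow(p1$mol, library)
              prov <- paste0(p1$prov, "+")
            } else {
              child <- op_link(p1$mol, library)
              prov <- paste0(p1$prov, "%")
            }
          }
        }
        if (is.null(child)) { child <- p1$mol; prov <- p1$prov }
        if (n_atoms(child) > config$size_max + 8L) {
          shr <- op_delete(child, max_leaf = 10L)
          if (!is.null(shr)) child <- shr
        }
        offspring[[length(offspring) + 1L]] <-
          list(mol = child, prov = prov, score = NA_real_)
      }
      pop <- c(elite, offspring)
    }
  })
  shortfall <- length(collected) < config$target_count
  if (shortfall)
    warning(sprintf(
      "ligand growth shortfall: %d of %d unique ligands after %d generations",
      length(collected), config$target_count, config$generations))
  structure(collected, shortfall = shortfall)
}

#' Table view of grown ligands
#' @param ligands result of [grow_ligands]
#' @return data.frame(id, canonical, n_atoms, fitness, fill, pharm)
#' @export
ligand_table <- function(ligands) {
  data.frame(
    id = vapply(ligands, function(l) l$mol$id, character(1)),
    canonical = vapply(ligands, `[[`, character(1), "canonical"),
    n_atoms = vapply(ligands, function(l) n_atoms(l$mol), integer(1)),
    fitness = vapply(ligands, `[[`, numeric(1), "fitness"),
    fill = vapply(ligands, `[[`, numeric(1), "fill"),
    pharm = vapply(ligands, `[[`, numeric(1), "pharm"),
    stringsAsFactors = FALSE)
}
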