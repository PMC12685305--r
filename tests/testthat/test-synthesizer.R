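# Fragment library, embedding, fitness and the growth GA.

test_that("the shipped fragment library loads 177 usable fragments", {
  lib <- fx_library()
  expect_length(lib, 177L)
  expect_true(all(vapply(lib, function(f) length(f$attachments) >= 1L,
                         logical(1))))
  expect_true(all(vapply(lib, function(f)
    all(implicit_hydrogens(f$mol)[f$attachments] > 0L), logical(1))))
})

test_that("malformed library entries are skipped; empty libraries error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles\tattachments\tclass",
               "F1\tCCO\t1\tlinker",
               "F2\tnot_a_smiles((\t1\tlinker",
               "F3\tc1ccccc1\t1\taromatic",
               "F4\tC1CC1\t1\thydrophobe",
               "F5\tCCN\t2\tdonor"), f)
  expect_warning(lib <- load_fragment_library(f), "skipped 1")
  expect_length(lib, 4L)
  fe <- tempfile(fileext = ".tsv")
  file.create(fe)
  expect_error(load_fragment_library(fe), "missing or empty")
})

test_that("embedding is deterministic, compact and low-strain", {
  m1 <- embed_molecule(parse_smiles("CC(=O)Nc1ccccc1"))
  m2 <- embed_molecule(parse_smiles("O=C(C)Nc1ccccc1"))  # same molecule
  expect_lt(bond_strain(m1), 0.15)
  # canonical-seeded: identical geometry regardless of input atom order
  d1 <- sort(as.numeric(dist(m1$coords)))
  d2 <- sort(as.numeric(dist(m2$coords)))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("fitness terms respond to geometry as specified", {
  p8 <- fx_pocket8()
  feats <- cavigrow:::cavity_features(p8$cavity, p8$pk$structure)
  w <- ga_config()$weights
  mol <- embed_molecule(parse_smiles("CCO"))
  # ligand far outside the cavity: no fill
  far <- sweep(mol$coords, 2, p8$cavity$centroid + c(60, 60, 60), "+")
  fit_far <- grow_fitness(far, mol, p8$cavity$xyz, feats, p8$grid, w)
  expect_equal(fit_far$fill, 0)
  # ligand centered in the cavity: positive fill, no clash
  ctr <- sweep(mol$coords, 2, p8$cavity$centroid, "+")
  fit_ctr <- grow_fitness(ctr, mol, p8$cavity$xyz, feats, p8$grid, w)
  expect_gt(fit_ctr$fill, 0)
  expect_equal(fit_ctr$clash, 0L)
  # atom inside the occupied shell: clash penalty
  wall <- p8$pk$structure$atoms[1, ]
  clashed <- rbind(ctr[-1, , drop = FALSE],
                   c(wall$x, wall$y, wall$z))
  fit_cl <- grow_fitness(clashed, mol, p8$cavity$xyz, feats, p8$grid, w)
  expect_gt(fit_cl$clash, 0L)
  expect_lt(fit_cl$score, fit_ctr$score)
})

test_that("a donor posed at a planted acceptor site gets full pharm credit", {
  p8 <- fx_pocket8()
  feats <- cavigrow:::cavity_features(p8$cavity, p8$pk$structure)
  acc <- which(feats$class == "acceptor")[1]
  # hydroxyl donor probe posed in contact range of the acceptor feature,
  # pulled toward the pocket center
  site <- feats$xyz[acc, ]
  ctr <- p8$cavity$centroid
  dirv <- (ctr - site) / sqrt(sum((ctr - site)^2))
  mol <- parse_smiles("O")
  xyz <- matrix(site + 4.6 * dirv, 1, 3)
  mol$coords <- xyz
  expect_identical(cavigrow:::ligand_pharmacophores(mol), "donor")
  fit <- grow_fitness(xyz, mol, p8$cavity$xyz, feats, p8$grid,
                      ga_config()$weights)
  expect_equal(fit$pharm, 1.0)   # the single planted-donor match
  # moved out of contact range the credit disappears
  far <- matrix(ctr + c(0, 0, 0), 1, 3)
  d_far <- min(sqrt(rowSums(sweep(feats$xyz[feats$class %in%
                                              c("acceptor", "charged"), ,
                                            drop = FALSE], 2, far[1, ])^2)))
  if (d_far > cavigrow:::PHARM_CONTACT) {
    fit2 <- grow_fitness(far, mol, p8$cavity$xyz, feats, p8$grid,
                         ga_config()$weights)
    expect_equal(fit2$pharm, 0)
  }
})

test_that("growth reaches the target with unique, valid, contained ligands", {
  ligs <- fx_ligands()
  expect_length(ligs, 20L)
  expect_false(isTRUE(attr(ligs, "shortfall")))
  tab <- ligand_table(ligs)
  expect_length(unique(tab$canonical), 20L)
  expect_true(all(tab$n_atoms >= 10L & tab$n_atoms <= 40L))
  p8 <- fx_pocket8()
  prot <- coords(p8$pk$structure)
  for (lg in ligs) {
    xyz <- lg$mol$coords
    # independent clash oracle: distance to every protein atom must
    # exceed the occupied radius minus grid discretization slack
    dmin <- min(vapply(seq_len(nrow(xyz)), function(k)
      min(sqrt((prot[, 1] - xyz[k, 1])^2 + (prot[, 2] - xyz[k, 2])^2 +
                 (prot[, 3] - xyz[k, 3])^2)), numeric(1)))
    expect_gt(dmin, 2.7 - sqrt(3) * p8$grid$spacing / 2 - 1e-9)
    # containment: >= 80% of atoms near the cavity point set
    expect_gte(cavigrow:::containment_fraction(xyz, p8$cavity$xyz), 0.8)
    # valence validity survived the graph surgery
    expect_true(cavigrow:::valence_ok(lg$mol))
  }
})

test_that("growth is bit-reproducible under a fixed seed", {
  p8 <- fx_pocket8()
  cfg <- ga_config(target_count = 8L, population_size = 24L,
                   generations = 30L, seed = 5L)
  l1 <- suppressWarnings(grow_ligands(p8$cavity, p8$pk$structure, p8$grid,
                                      fx_library(), cfg))
  l2 <- suppressWarnings(grow_ligands(p8$cavity, p8$pk$structure, p8$grid,
                                      fx_library(), cfg))
  expect_identical(vapply(l1, `[[`, character(1), "canonical"),
                   vapply(l2, `[[`, character(1), "canonical"))
  expect_equal(vapply(l1, `[[`, numeric(1), "fitness"),
               vapply(l2, `[[`, numeric(1), "fitness"))
})

test_that("an unreachable target reports an explicit shortfall", {
  p8 <- fx_pocket8()
  cfg <- ga_config(target_count = 400L, population_size = 16L,
                   generations = 2L, seed = 5L)
  expect_warning(out <- grow_ligands(p8$cavity, p8$pk$structure, p8$grid,
                                     fx_library(), cfg),
                 "shortfall")
  expect_true(attr(out, "shortfall"))
  expect_lt(length(out), 400L)
})

test_that("ligands from pharmacophorically distinct cavities separate in PCA", {
  lib <- fx_library()
  mk <- function(ph) {
    pk <- make_pocket(radius = 8, mouth = 5, pharmacophores = ph, seed = 1)
    g <- build_grid(pk$structure, spacing = 0.5)
    list(pk = pk, g = g, cv = detect_cavities(g, pk$structure)[[1]])
  }
  A <- mk("hydrophobe")
  B <- mk(c("donor", "acceptor", "charged"))
  cfg <- ga_config(target_count = 20L, population_size = 32L,
                   generations = 60L, seed = 11L)
  ligA <- suppressWarnings(grow_ligands(A$cv, A$pk$structure, A$g, lib, cfg))
  ligB <- suppressWarnings(grow_ligands(B$cv, B$pk$structure, B$g, lib, cfg))
  fps <- lapply(c(lapply(ligA, `[[`, "mol"), lapply(ligB, `[[`, "mol")),
                atom_pair_fingerprint)
  keys <- sort(unique(unlist(fps)))
  X <- t(vapply(fps, function(f) as.numeric(keys %in% f),
                numeric(length(keys))))
  lab <- rep(1:2, c(length(ligA), length(ligB)))
  S <- pca_project(X, 2)$scores
  expect_gt(mean_silhouette(S, lab), 0)
})
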