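# Grid construction, burial, cavity detection and druggability scoring.

single_atom_structure <- function() {
  structure(list(atoms = data.frame(
    serial = 1L, name = "CA", element = "C", resname = "ALA", resno = 1L,
    chain = "A", x = 0, y = 0, z = 0, vdw = 1.7, stringsAsFactors = FALSE),
    id = "one"), class = "structure3d")
}

test_that("grid occupancy follows the probe-inflated radius", {
  s <- single_atom_structure()
  g <- build_grid(s, spacing = 0.5, probe = 1.0)
  idx <- seq_along(g$labels)
  xyz <- cavigrow:::grid_points_xyz(g, idx)
  r <- sqrt(rowSums(xyz^2))
  occ <- g$labels == 1L
  expect_true(all(occ[r <= 2.7 - 1e-9]))       # within vdW + probe
  expect_true(all(!occ[r > 2.7 + 1e-9]))
  # far-from-atom points are vacant, and surface forms a one-layer shell
  surf <- g$labels == 2L
  expect_true(all(r[surf] > 2.7))
  expect_true(all(r[surf] <= 2.7 + sqrt(3) * g$spacing + 1e-9))
  expect_true(all(g$labels[r > 2.7 + sqrt(3) * 0.5 + 1e-9] == 0L))
})

test_that("grid guards its domain", {
  s <- single_atom_structure()
  expect_error(build_grid(s, spacing = 0), "positive")
  expect_error(build_grid(s, spacing = 0.1, max_points = 1000),
               "coarser spacing")
})

test_that("a planted pocket is recovered with centroid and volume", {
  p8 <- fx_pocket8()
  expect_length(p8$cavities, 1L)
  cv <- p8$cavity
  truth <- p8$pk$truth[[1]]
  d <- sqrt(rowSums(sweep(cv$xyz, 2, truth$centroid)^2))
  expect_lt(min(d), 1.0)                       # centroid inside the cavity
  expect_lt(abs(cv$volume - truth$volume) / truth$volume, 0.25)
  # cavity points are never occupied
  expect_true(all(p8$grid$labels[cv$points] != 1L))
})

test_that("a solid slab yields no cavities", {
  xy <- expand.grid(x = seq(0, 16, by = 2), y = seq(0, 16, by = 2))
  atoms <- data.frame(serial = seq_len(nrow(xy)), name = "CA",
                      element = "C", resname = "LEU",
                      resno = seq_len(nrow(xy)), chain = "A",
                      x = xy$x, y = xy$y, z = 0, vdw = 1.7,
                      stringsAsFactors = FALSE)
  slab <- structure(list(atoms = atoms, id = "slab"), class = "structure3d")
  g <- build_grid(slab, spacing = 0.75)
  expect_length(detect_cavities(g, slab), 0L)
})

test_that("two planted pockets give two disjoint cavities", {
  pk <- make_pocket(radius = 6, mouth = 4, seed = 3, two_pockets = TRUE)
  g <- build_grid(pk$structure, spacing = 0.75)
  cavs <- detect_cavities(g, pk$structure)
  expect_length(cavs, 2L)
  expect_length(intersect(cavs[[1]]$points, cavs[[2]]$points), 0L)
  # each contains one of the planted centroids
  ctrs <- lapply(pk$truth, `[[`, "centroid")
  hit <- vapply(cavs, function(cv) {
    which.min(vapply(ctrs, function(ct)
      min(rowSums(sweep(cv$xyz, 2, ct)^2)), numeric(1)))
  }, integer(1))
  expect_setequal(hit, c(1L, 2L))
})

test_that("druggability follows its documented formula and monotonicity", {
  lin_hydro <- data.frame(chain = "A", resno = 1:10,
                          resname = rep("LEU", 10))
  lin_mixed <- data.frame(chain = "A", resno = 1:12,
                          resname = rep(c("LEU", "SER", "ASP", "ARG"), 3))
  # fully exposed minimal patch scores low
  expect_lte(druggability(volume = 50, burial_fraction = 0,
                          lining = data.frame(chain = character(),
                                              resno = integer(),
                                              resname = character())),
             0.25)
  # deep enclosed hydrophobic pocket scores high
  expect_gte(druggability(volume = 500, burial_fraction = 0.95,
                          lining = lin_mixed), 0.7)
  # monotone in burial with everything else fixed
  expect_gte(druggability(400, 0.6, lin_hydro),
             druggability(400, 0.3, lin_hydro))
  # direct formula check
  s <- druggability(250, 0.5, lin_hydro)
  expect_equal(s, 0.25 * 0.5 + 0.30 * 0.5 + 0.30 * 1.0 + 0.15 * 0,
               tolerance = 1e-12)
  expect_gte(s, 0); expect_lte(s, 1)
})

test_that("cavity selection honors critical residues and tie rules", {
  cav <- function(name, score, resnos) {
    structure(list(points = 1:10, xyz = matrix(0, 1, 3),
                   centroid = c(0, 0, 0),
                   lining_residues = data.frame(chain = "A", resno = resnos,
                                                resname = "LEU"),
                   volume = 100, burial_fraction = 0.6,
                   druggability_score = score, location_tag = "NA",
                   name = name), class = "cavity")
  }
  c1 <- cav("NA1", 0.9, 1:5); c2 <- cav("NA2", 0.4, 10:12)
  expect_identical(select_cavity(list(c1, c2), c(10, 11))$name, "NA2")
  expect_identical(select_cavity(list(c1, c2))$name, "NA1")
  # equal overlap -> higher score wins
  c3 <- cav("NA3", 0.5, c(10, 20)); c4 <- cav("NA4", 0.8, c(10, 30))
  expect_identical(select_cavity(list(c3, c4), c(10))$name, "NA4")
  err <- tryCatch(select_cavity(list(c1, c2), c(999)), error = identity)
  expect_s3_class(err, "cavigrow_selection_error")
  expect_match(conditionMessage(err), "best candidates")
})

test_that("detection is invariant under a lattice-compatible rigid motion", {
  pk <- make_pocket(radius = 6, mouth = 4, seed = 4)
  g1 <- build_grid(pk$structure, spacing = 0.75)
  c1 <- detect_cavities(g1, pk$structure)
  moved <- transform_structure(pk$structure,
                               rotation_about_axis(c(0, 0, 1), pi / 2),
                               c(7.3, -2.1, 4.9))
  g2 <- build_grid(moved, spacing = 0.75)
  c2 <- detect_cavities(g2, moved)
  expect_length(c2, length(c1))
  lining1 <- sort(c1[[1]]$lining_residues$resno)
  lining2 <- sort(c2[[1]]$lining_residues$resno)
  expect_identical(lining1, lining2)
})

test_that("halving the spacing changes the detected volume < 15%", {
  pk <- make_pocket(radius = 7, mouth = 4, seed = 5)
  g_coarse <- build_grid(pk$structure, spacing = 1.0)
  g_fine <- build_grid(pk$structure, spacing = 0.5)
  v_coarse <- detect_cavities(g_coarse, pk$structure)[[1]]$volume
  v_fine <- detect_cavities(g_fine, pk$structure)[[1]]$volume
  expect_lt(abs(v_fine - v_coarse) / v_fine, 0.15)
})

test_that("membrane slab drives EC/IC/TM naming", {
  pk <- make_pocket(radius = 6, mouth = 4, seed = 6)
  g <- build_grid(pk$structure, spacing = 0.75)
  up <- detect_cavities(g, pk$structure, membrane = c(-20, -10))
  expect_match(up[[1]]$name, "^EC")
  dn <- detect_cavities(g, pk$structure, membrane = c(10, 20))
  expect_match(dn[[1]]$name, "^IC")
  mid <- detect_cavities(g, pk$structure, membrane = c(-15, 15))
  expect_match(mid[[1]]$name, "^TM")
  none <- detect_cavities(g, pk$structure)
  expect_match(none[[1]]$name, "^NA")
})
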