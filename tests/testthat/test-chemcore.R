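# Molecule representation, canonical identity, fingerprints, descriptors
# and the shared similarity math.

test_that("canonicalization gives a single identity per graph", {
  expect_identical(canonicalize(parse_smiles("C")), "C")
  expect_identical(canonicalize(parse_smiles("CCO")),
                   canonicalize(parse_smiles("OCC")))
  # 50 random atom-order permutations collapse to one canonical string
  mol <- parse_smiles("CC(=O)Nc1ccc(O)cc1")  # paracetamol-like fixture
  set.seed(42)
  cans <- vapply(1:50, function(k) {
    canonicalize(permute_molecule(mol, sample(n_atoms(mol))))
  }, character(1))
  expect_length(unique(cans), 1L)
  expect_identical(unique(cans), canonicalize(mol))
})

test_that("canonicalization is idempotent over a structure panel", {
  panel <- c("CCO", "c1ccccc1", "c1ccc2ccccc2c1", "CC(C)CC(=O)NC",
             "C1CCNCC1", "c1cc[nH]c1", "C1CNCCN1S(=O)(=O)C",
             "[NH3+]CC([O-])=O", "FC(F)(F)c1ccccc1C#N", "O=C1CCCCC1")
  for (smi in panel) {
    can1 <- canonicalize(parse_smiles(smi))
    can2 <- canonicalize(parse_smiles(can1))
    expect_identical(can2, can1)
  }
})

test_that("valence violations are rejected with the atom index", {
  err <- tryCatch(parse_smiles("C(C)(C)(C)(C)C"), error = identity)
  expect_s3_class(err, "cavigrow_valence_error")
  expect_match(conditionMessage(err), "atom [0-9]+")
})

test_that("atom-pair fingerprints hash typed pairs, order-independently", {
  # ethane: a single (C,C,1) pair
  expect_length(atom_pair_fingerprint(parse_smiles("CC")), 1L)
  # propane: enumeration oracle over all C(3,2) pairs with BFS distances
  propane <- parse_smiles("CCC")
  expect_identical(as.integer(atom_pair_fingerprint(propane)),
                   oracle_fingerprint(propane))
  # single heavy atom: warning + empty sentinel
  expect_warning(fp0 <- atom_pair_fingerprint(parse_smiles("C")),
                 "empty fingerprint")
  expect_length(fp0, 0L)
})

test_that("fingerprints are invariant under atom reordering", {
  skip_if_not_installed("igraph")
  panel <- c("CC(=O)Nc1ccccc1", "C1CCNCC1CO", "c1ccc2ccccc2c1",
             "CCOC(=O)CN", "FC(F)(F)c1ccncc1", "CC(C)(C)OC(=O)NCCS",
             "O=S(=O)(N)c1ccccc1", "C1CNCCN1", "CCCCC(N)=O", "c1cnco1")
  set.seed(7)
  for (smi in panel) {
    mol <- parse_smiles(smi)
    ref <- atom_pair_fingerprint(mol)
    expect_identical(as.integer(ref), oracle_fingerprint(mol))
    for (r in 1:10) {
      pm <- permute_molecule(mol, sample(n_atoms(mol)))
      expect_identical(atom_pair_fingerprint(pm), ref)
    }
  }
})

test_that("tanimoto matches set arithmetic and its contract", {
  expect_equal(tanimoto(c(1L, 5L, 9L), c(1L, 5L, 9L)), 1.0)
  expect_equal(tanimoto(c(1L, 2L), c(3L, 4L)), 0.0)
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_error(tanimoto(integer(0), integer(0)), "empty")
  set.seed(3)
  for (r in 1:25) {
    a <- sample.int(100, 12); b <- sample.int(100, 15)
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
  }
})

test_that("descriptor panel is fixed-length, deterministic and sane", {
  d <- descriptor_vector(parse_smiles("O"))
  expect_length(d, 24L)
  expect_identical(names(d), cavigrow:::DESCRIPTOR_NAMES)
  expect_equal(d[["MW"]], 18.02, tolerance = 1e-3)
  benz <- descriptor_vector(parse_smiles("c1ccccc1"))
  expect_equal(benz[["nAromRings"]], 1)
  expect_equal(benz[["nAromAtoms"]], 6)
  # independent recomputation of the count-type descriptors
  panel <- c("CCO", "CC(=O)NC", "c1ccncc1", "C1CCCCC1O", "CCCOCC",
             "NCCc1ccccc1", "CC(C)C(=O)O", "Clc1ccccc1", "CCSCC", "CCNCC")
  for (smi in panel) {
    mol <- parse_smiles(smi)
    d <- descriptor_vector(mol)
    el <- mol$atoms$element
    expect_equal(d[["nHeavy"]], length(el))
    expect_equal(d[["nC"]], sum(el == "C"))
    expect_equal(d[["nN"]], sum(el == "N"))
    expect_equal(d[["nO"]], sum(el == "O"))
    expect_equal(d[["nBonds"]], nrow(mol$bonds))
    h <- implicit_hydrogens(mol)
    expect_equal(d[["nHBD"]], sum(el %in% c("N", "O") & h > 0))
    expect_equal(d[["nHBA"]], sum(el %in% c("N", "O")))
    # MW from first principles
    mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, Cl = 35.453)
    expect_equal(d[["MW"]], sum(mass[el]) + sum(h) * 1.008, tolerance = 1e-6)
  }
})

test_that("cosine similarity follows the closed form", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 0.7071, tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal-length")
  set.seed(5)
  for (r in 1:25) {
    a <- rnorm(6); b <- rnorm(6)
    cs <- cosine_similarity(a, b)
    expect_identical(cs, cosine_similarity(b, a))
    expect_gte(cs, -1); expect_lte(cs, 1)
  }
})

test_that("PCA projection matches the eigendecomposition oracle", {
  # collinear points: one component explains everything
  line <- cbind(1:6, 2 * (1:6))
  p <- pca_project(line, 1)
  expect_equal(p$explained[1], 1.0)
  # k = rank: fractions sum to 1
  set.seed(8)
  X <- matrix(rnorm(15), 5, 3)
  p3 <- pca_project(X, 3)
  expect_equal(sum(p3$explained), 1.0)
  expect_true(all(diff(p3$explained) <= 1e-12))
  # scores match a direct eigensolve of the covariance (up to sign)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(stats::cov(Xc))
  scores_oracle <- Xc %*% ev$vectors
  for (k in 1:3) {
    expect_equal(abs(p3$scores[, k]), abs(scores_oracle[, k]),
                 tolerance = 1e-8)
  }
  expect_error(pca_project(matrix(1, 4, 2), 1), "constant")
  expect_error(pca_project(X, 4), "exceeds")
})

test_that("SMILES file round trip preserves identity and ids", {
  mols <- lapply(c("CCO", "c1ccccc1", "CC(=O)N"), parse_smiles)
  for (k in seq_along(mols)) mols[[k]]$id <- paste0("M", k)
  f <- tmp_smiles(mols)
  back <- read_smiles_file(f)
  expect_length(back, 3L)
  expect_identical(vapply(back, function(m) m$id, character(1)),
                   c("M1", "M2", "M3"))
  expect_identical(vapply(back, canonicalize, character(1)),
                   vapply(mols, canonicalize, character(1)))
  # unparsable minority is skipped with a warning; majority failure errors
  f2 <- tempfile(fileext = ".smi")
  writeLines(c("CCO ok", "not_a_smiles((", "CCN ok2"), f2)
  expect_warning(got <- read_smiles_file(f2), "could not be parsed")
  expect_length(got, 2L)
  f3 <- tempfile(fileext = ".smi")
  writeLines(c("xxx((", "yyy(("), f3)
  expect_error(suppressWarnings(read_smiles_file(f3)), "unparsable")
})
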