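# Shared fixtures and independent oracles. Expensive fixtures are built
# lazily once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# toy pocket (radius 8, mouth 5) + grid + detected cavity
fx_pocket8 <- function() fx_get("pocket8", function() {
  pk <- make_pocket(radius = 8, mouth = 5, seed = 1)
  grid <- build_grid(pk$structure, spacing = 0.5)
  cavs <- detect_cavities(grid, pk$structure)
  list(pk = pk, grid = grid, cavities = cavs, cavity = cavs[[1]])
})

fx_library <- function() fx_get("library", function() load_fragment_library())

# small grown ligand set on the toy pocket (target 20, seed 11)
fx_ligands <- function() fx_get("ligands", function() {
  p8 <- fx_pocket8()
  cfg <- ga_config(target_count = 20L, population_size = 32L,
                   generations = 60L, seed = 11L)
  suppressWarnings(grow_ligands(p8$cavity, p8$pk$structure, p8$grid,
                                fx_library(), cfg))
})

# random atom permutation of a molecule (graph relabeling)
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  b$i <- inv[b$i]; b$j <- inv[b$j]
  coords <- if (!is.null(mol$coords)) mol$coords[perm, , drop = FALSE]
  molecule(atoms, b, coords = coords, id = mol$id)
}

# independent atom-pair fingerprint oracle: igraph BFS distances,
# explicitly enumerated types, same published hashing contract
oracle_fingerprint <- function(mol) {
  requireNamespace("igraph", quietly = TRUE)
  n <- n_atoms(mol)
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  D <- igraph::distances(g)
  deg <- igraph::degree(g)
  el_idx <- match(mol$atoms$element,
                  c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I"))
  el_idx[is.na(el_idx)] <- 11L
  types <- el_idx * 100L + pmin(deg, 9L) * 10L + as.integer(mol$atoms$aromatic)
  keys <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- D[i, j]
    if (!is.finite(d) || d > 30) next
    t1 <- min(types[i], types[j]); t2 <- max(types[i], types[j])
    h <- 5381
    for (v in c(t1, t2, d)) h <- (h * 33 + (v %% 2147483647)) %% 2147483647
    keys <- c(keys, as.integer(h))
  }
  sort(unique(keys))
}

# mean silhouette over a 2-class labeling in a score space
mean_silhouette <- function(S, lab) {
  d <- as.matrix(dist(S))
  n <- nrow(S)
  s <- numeric(n)
  for (i in seq_len(n)) {
    a <- mean(d[i, lab == lab[i] & seq_len(n) != i])
    b <- mean(d[i, lab != lab[i]])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force KS oracle: evaluate |F1 - F2| at every pooled point
oracle_ks <- function(x, y) {
  pts <- c(x, y)
  m <- 0
  for (p in pts) {
    m <- max(m, abs(mean(x <= p) - mean(y <= p)))
  }
  m
}

# pairwise-ordering (Mann-Whitney) AUC oracle
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# dense power-iteration PageRank oracle on an explicit weight matrix
# (rows = all nodes), teleport vector given
oracle_pagerank <- function(W, teleport, d = 0.85, tol = 1e-12,
                            max_iter = 1e5) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  rs <- rowSums(W)
  for (i in seq_len(n)) P[i, ] <- if (rs[i] > 0) W[i, ] / rs[i] else teleport
  pr <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    pr2 <- (1 - d) * teleport + d * as.numeric(pr %*% P)
    if (sum(abs(pr2 - pr)) < tol) return(pr2)
    pr <- pr2
  }
  pr
}

# exhaustive threshold-selection oracle
oracle_threshold <- function(labels, scores, method) {
  cuts <- sort(unique(c(min(scores) - 1e-9, scores)))
  best <- -Inf; best_cut <- cuts[1]
  for (ct in cuts) {
    pos <- scores > ct
    sens <- sum(pos & labels == 1) / sum(labels == 1)
    spec <- sum(!pos & labels == 0) / sum(labels == 0)
    crit <- if (method == "gmeans") sqrt(sens * spec) else sens + spec - 1
    if (crit > best + 1e-12) { best <- crit; best_cut <- ct }
  }
  list(threshold = best_cut, criterion = best)
}

# coarse-to-fine rotation-grid RMSD oracle (brute force over rotations,
# centroids aligned)
oracle_rmsd <- function(fixed, mobile) {
  A <- sweep(fixed, 2, colMeans(fixed))
  B <- sweep(mobile, 2, colMeans(mobile))
  rmsd_of <- function(R) sqrt(mean(rowSums((B %*% t(R) - A)^2)))
  best <- Inf; best_ang <- c(0, 0, 0)
  span <- pi; steps <- 12
  ctr <- c(0, 0, 0)
  for (level in 1:4) {
    angs <- lapply(1:3, function(k)
      seq(ctr[k] - span, ctr[k] + span, length.out = steps))
    for (a1 in angs[[1]]) for (a2 in angs[[2]]) for (a3 in angs[[3]]) {
      R <- rotation_about_axis(c(0, 0, 1), a3) %*%
        rotation_about_axis(c(0, 1, 0), a2) %*%
        rotation_about_axis(c(1, 0, 0), a1)
      r <- rmsd_of(R)
      if (r < best) { best <- r; best_ang <- c(a1, a2, a3) }
    }
    ctr <- best_ang
    span <- span / 5
  }
  best
}

# write a temporary SMILES file for a molecule list
tmp_smiles <- function(mols) {
  f <- tempfile(fileext = ".smi")
  write_smiles_file(mols, f)
  f
}
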