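# Binding-energy authentication: score ligands through a pluggable
# docking backend, partition into High-/Low-Affinity Binders at an
# energy threshold (default -7 kcal/mol, inclusive on the HAB side),
# check the class split with two-sample distribution tests over the
# ECDFs (Kolmogorov-Smirnov, Anderson-Darling, Epps-Singleton), and
# balance classes with property-matched decoys when needed.

#' Built-in surrogate docking backend
#'
#' A pose-free additive binding-energy estimate used for testing and
#' offline runs: -0.35 per matched pharmacophore pair, -0.06 per heavy
#' atom inside the cavity envelope (within 2.5 angstrom of a cavity
#' point), +0.8 per clash with the occupied grid, plus seeded Gaussian
#' noise (sd `sigma`). It is a transparent toy energy model with the
#' right qualitative shape, not a physics engine.
#'
#' @param cavity a cavity
#' @param structure the structure3d
#' @param grid the cavity_grid
#' @param sigma noise standard deviation in kcal/mol (default 0.3)
#' @param seed integer seed for the noise stream
#' @return backend object of class `docking_backend`
#' @export
surrogate_backend <- function(cavity, structure, grid, sigma = 0.3,
                              seed = 42L) {
  structure(list(type = "surrogate", cavity = cavity,
                 structure = structure, grid = grid,
                 features = cavity_features(cavity, structure),
                 sigma = sigma, seed = as.integer(seed)),
            class = "docking_backend")
}

#' External docking program adapter
#'
#' Contract only: receptor prepared once per cavity, search box = cavity
#' bounding box + 4 angstrom pad, exhaustiveness and seed passed through.
#' Scoring errors if the executable is absent; the adapter is never
#' exercised by the test suite.
#'
#' @param exe path to the docking executable
#' @param receptor receptor file prepared for the backend
#' @param cavity a cavity (defines the search box)
#' @param exhaustiveness search effort passed through
#' @param seed seed passed through
#' @export
external_backend <- function(exe, receptor, cavity, exhaustiveness = 8L,
                             seed = 42L) {
  structure(list(type = "external", exe = exe, receptor = receptor,
                 cavity = cavity, box = external_box(cavity),
                 exhaustiveness = exhaustiveness, seed = as.integer(seed)),
            class = "docking_backend")
}

external_box <- function(cavity, pad = 4) {
  lo <- apply(cavity$xyz, 2, min) - pad
  hi <- apply(cavity$xyz, 2, max) + pad
  list(center = (lo + hi) / 2, size = hi - lo)
}

#' Score ligands with a docking backend
#'
#' One binding energy (kcal/mol, more negative = stronger) per ligand.
#' Ligands the backend fails on are excluded with a warning.
#'
#' @param ligands list of grown ligands (posed molecules) or molecules
#'   with coordinates
#' @param backend a `docking_backend`
#' @return data.frame(id, energy, backend)
#' @export
score_ligands <- function(ligands, backend) {
  if (backend$type == "external") {
    if (!file.exists(backend$exe %||% ""))
      abort2(sprintf(
        "external docking adapter: executable not found at '%s'",
        backend$exe), "cavigrow_backend_error")
    abort2("external docking adapter is a contract shim in this build",
           "cavigrow_backend_error")
  }
  cav_xyz <- backend$cavity$xyz
  rows <- vector("list", length(ligands))
  noise <- with_seed(derive_seed(backend$seed, "surrogate"), {
    if (backend$sigma > 0) stats::rnorm(length(ligands), 0, backend$sigma)
    else numeric(length(ligands))
  })
  for (k in seq_along(ligands)) {
    lg <- ligands[[k]]
    mol <- if (!is.null(lg$mol)) lg$mol else lg
    if (is.null(mol$coords)) {
      warning(sprintf("ligand %d has no coordinates; excluded", k))
      next
    }
    e <- surrogate_energy(mol, backend) + noise[k]
    rows[[k]] <- data.frame(id = if (nzchar(mol$id)) mol$id else sprintf("L%04d", k),
                            energy = e, backend = "surrogate",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out))
    abort2("backend produced no energies", "cavigrow_backend_error")
  rownames(out) <- NULL
  out
}

#' Deterministic part of the surrogate energy
#' @keywords internal
surrogate_energy <- function(mol, backend) {
  xyz <- mol$coords
  cav_xyz <- backend$cavity$xyz
  lig_cls <- ligand_pharmacophores(mol)
  matched <- 0L
  feats <- backend$features
  if (nrow(feats$xyz)) {
    for (k in seq_along(lig_cls)) {
      comp <- complementary[[lig_cls[k]]]
      fm <- feats$class %in% comp
      if (!any(fm)) next
      d2 <- (feats$xyz[fm, 1] - xyz[k, 1])^2 +
        (feats$xyz[fm, 2] - xyz[k, 2])^2 + (feats$xyz[fm, 3] - xyz[k, 3])^2
      if (min(d2) <= PHARM_CONTACT^2) matched <- matched + 1L
    }
  }
  inside <- round(containment_fraction(xyz, cav_xyz) * nrow(xyz))
  clash <- clash_count(backend$grid, xyz)
  -0.35 * matched - 0.06 * inside + 0.8 * clash
}

#' Segregate docking results into HABs and LABs
#'
#' Inclusive rule: energy <= threshold is a High-Affinity Binder. The
#' partition is complete and disjoint. A class-balance ratio outside
#' [1/3, 3] (or an empty class) sets the imbalance flag, which signals
#' the decoy path downstream.
#'
#' @param results data.frame(id, energy) from [score_ligands]
#' @param threshold energy cutoff in kcal/mol (default -7)
#' @return object of class `labeled_set`: list(habs, labs, threshold,
#'   balance_ratio, imbalance)
#' @export
segregate <- function(results, threshold = -7.0) {
  if (nrow(results) < 2L)
    abort2("need at least two docking results", "cavigrow_domain_error")
  is_hab <- results$energy <= threshold
  habs <- results[is_hab, , drop = FALSE]
  labs <- results[!is_hab, , drop = FALSE]
  ratio <- if (nrow(labs) == 0L) Inf else nrow(habs) / nrow(labs)
  imbalance <- nrow(habs) == 0L || nrow(labs) == 0L ||
    ratio < 1 / 3 || ratio > 3
  structure(list(habs = habs, labs = labs, threshold = threshold,
                 balance_ratio = ratio, imbalance = imbalance),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("<labeled_set: %d HAB / %d LAB at %.1f kcal/mol%s>\n",
              nrow(x$habs), nrow(x$labs), x$threshold,
              if (x$imbalance) " [imbalanced]" else ""))
  invisible(x)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous non-decreasing step function with F(max) = 1
#' (wraps [stats::ecdf]).
#' @param values numeric vector (non-empty)
#' @return a step function
#' @export
energy_ecdf <- function(values) {
  if (!length(values)) abort2("ECDF of an empty sample", "cavigrow_domain_error")
  stats::ecdf(values)
}

#' Two-sample distribution comparison (KS / AD / ES)
#'
#' KS: D = sup|F1 - F2| computed exactly over the pooled points, p-value
#' from the asymptotic two-sided Kolmogorov distribution. AD: two-sample
#' Anderson-Darling, midrank (tie-aware) statistic with the standard
#' normalization and critical-value interpolation of the significance
#' scale (p clipped to [0.001, 0.25]). ES: Epps-Singleton empirical
#' characteristic function test at t = (0.4, 0.8) scaled by the pooled
#' semi-interquartile range, asymptotic chi-squared p-value with the
#' usual small-sample correction below n = 25.
#'
#' @param x,y numeric samples (each >= 5 observations)
#' @param test one of "ks", "ad", "es"
#' @return list(test, statistic, p_value)
#' @export
compare_distributions <- function(x, y, test = c("ks", "ad", "es")) {
  test <- match.arg(test)
  if (length(x) < 5L || length(y) < 5L)
    abort2(sprintf("the %s test here requires >= 5 observations per sample",
                   toupper(test)), "cavigrow_domain_error")
  res <- switch(test,
                ks = ks_two_sample(x, y),
                ad = ad_two_sample(x, y),
                es = es_two_sample(x, y))
  res$test <- switch(test, ks = "KS", ad = "AndersonDarling",
                     es = "EppsSingleton")
  res
}

#' Exact two-sample KS statistic from the pooled sort
#' @param x,y numeric samples
#' @return list(statistic, p_value)
#' @export
ks_two_sample <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  Fx <- vapply(pool, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(pool, function(v) mean(y <= v), numeric(1))
  D <- max(abs(Fx - Fy))
  p <- suppressWarnings(stats::ks.test(x, y)$p.value)
  list(statistic = D, p_value = p)
}

#' Two-sample Anderson-Darling test (midrank variant)
#' @param x,y numeric samples
#' @return list(statistic (standardized), p_value, a2akn)
#' @export
ad_two_sample <- function(x, y) {
  samples <- list(x, y)
  k <- 2L
  Z <- sort(c(x, y))
  N <- length(Z)
  Zstar <- unique(Z)
  if (length(Zstar) < 2L)
    abort2("need more than one distinct observation", "cavigrow_domain_error")
  n <- lengths(samples)
  left <- findInterval(Zstar, Z, left.open = TRUE)      # count Z < z
  right <- findInterval(Zstar, Z)                       # count Z <= z
  lj <- right - left
  Bj <- left + lj / 2
  A2akN <- 0
  for (i in seq_len(k)) {
    s <- sort(samples[[i]])
    sr <- findInterval(Zstar, s)
    sl <- findInterval(Zstar, s, left.open = TRUE)
    Mij <- sr - (sr - sl) / 2
    inner <- lj / N * (N * Mij - Bj * n[i])^2 / (Bj * (N - Bj) - N * lj / 4)
    A2akN <- A2akN + sum(inner) / n[i]
  }
  A2akN <- A2akN * (N - 1) / N
  # normalization (Scholz & Stephens variance)
  H <- sum(1 / n)
  hs_cs <- cumsum(1 / ((N - 1):2))
  h <- hs_cs[length(hs_cs)] + 1
  g <- sum(hs_cs / (2:(N - 1)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigmasq <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
  m <- k - 1
  A2 <- (A2akN - m) / sqrt(sigmasq)
  # critical-value interpolation on the significance scale
  b0 <- c(0.675, 1.281, 1.645, 1.96, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.25, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  critical <- b0 + b1 / sqrt(m) + b2 / m
  sig <- c(0.25, 0.1, 0.05, 0.025, 0.01, 0.005, 0.001)
  p <- if (A2 < min(critical)) {
    max(sig)
  } else if (A2 > max(critical)) {
    min(sig)
  } else {
    pf <- stats::lm(log(sig) ~ stats::poly(critical, 2, raw = TRUE))
    exp(stats::predict(pf, data.frame(critical = A2)))
  }
  list(statistic = A2, p_value = as.numeric(p), a2akn = A2akN)
}

#' Two-sample Epps-Singleton test
#' @param x,y numeric samples (>= 5 each)
#' @param t characteristic-function evaluation points (default 0.4, 0.8)
#' @return list(statistic, p_value)
#' @export
es_two_sample <- function(x, y, t = c(0.4, 0.8)) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  sigma <- stats::IQR(c(x, y), type = 7) / 2
  if (sigma == 0) abort2("zero pooled IQR: ES test undefined", "cavigrow_domain_error")
  ts <- t / sigma
  gfun <- function(v) {
    rbind(cos(ts[1] * v), cos(ts[2] * v), sin(ts[1] * v), sin(ts[2] * v))
  }
  gx <- gfun(x); gy <- gfun(y)
  cov_x <- stats::cov(t(gx)) * (nx - 1) / nx
  cov_y <- stats::cov(t(gy)) * (ny - 1) / ny
  est_cov <- (n / nx) * cov_x + (n / ny) * cov_y
  sv <- svd(est_cov)
  pos <- sv$d > max(sv$d) * 1e-12
  r <- sum(pos)
  inv <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], r) %*%
    t(sv$u[, pos, drop = FALSE])
  gdiff <- rowMeans(gx) - rowMeans(gy)
  w <- n * as.numeric(t(gdiff) %*% inv %*% gdiff)
  if (max(nx, ny) < 25)
    w <- w / (1 + n^(-0.45) + 10.1 * (nx^(-1.7) + ny^(-1.7)))
  p <- stats::pchisq(w, df = r, lower.tail = FALSE)
  list(statistic = w, p_value = p)
}

#' Authenticate a HAB/LAB split
#'
#' Runs the chosen distribution test on the two energy samples. With the
#' default gate the pipeline warns and proceeds when the test does not
#' reach `alpha`; with `gate = "stop"` it errors.
#'
#' @param labeled a labeled_set from [segregate]
#' @param test "ks", "ad" or "es"
#' @param alpha significance level (default 0.05)
#' @param gate "warn" (default) or "stop"
#' @return the test result (list(test, statistic, p_value, significant))
#' @export
authenticate_split <- function(labeled, test = "ks", alpha = 0.05,
                               gate = c("warn", "stop")) {
  gate <- match.arg(gate)
  res <- compare_distributions(labeled$habs$energy, labeled$labs$energy, test)
  res$significant <- res$p_value < alpha
  if (!res$significant) {
    msg <- sprintf(
      "HAB/LAB energy distributions not separated (%s p = %.3g >= %.2g)",
      res$test, res$p_value, alpha)
    if (gate == "stop") abort2(msg, "cavigrow_gate_error") else warning(msg)
  }
  res
}

#' Generate property-matched topological decoys from HABs
#'
#' Fragment-recombination decoys: HAB scaffolds are cut at acyclic bonds
#' and re-joined across molecules, then accepted only if property-matched
#' to some HAB (molecular weight within +/- 25, cLogP within +/- 1, HBD
#' and HBA within +/- 1) and topologically dissimilar to every HAB
#' (atom-pair Tanimoto < 0.4). Seeded and deterministic.
#'
#' @param hab_mols list of HAB molecules
#' @param n decoys wanted
#' @param seed integer seed
#' @param max_attempts budget (default 400 * n)
#' @return list of decoy molecules; shortfall raises a warning and is
#'   flagged in attribute `shortfall`
#' @export
generate_decoys <- function(hab_mols, n, seed = 42L, max_attempts = 400L * n) {
  if (!length(hab_mols)) abort2("need at least one HAB", "cavigrow_domain_error")
  hab_fps <- lapply(hab_mols, atom_pair_fingerprint)
  hab_desc <- lapply(hab_mols, descriptor_vector)
  hab_keys <- vapply(hab_mols, canonicalize, character(1))
  decoys <- list(); keys <- character(0)
  with_seed(derive_seed(seed, "decoys"), {
    attempts <- 0L
    while (length(decoys) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      m1 <- hab_mols[[sample.int(length(hab_mols), 1L)]]
      m2 <- hab_mols[[sample.int(length(hab_mols), 1L)]]
      cand <- op_crossover(m1, m2)
      if (is.null(cand)) next
      # attachment permutation: occasionally shuffle a terminal group
      if (stats::runif(1) < 0.5) {
        alt <- op_delete(cand)
        if (!is.null(alt) && n_atoms(alt) >= 6L) cand <- alt
      }
      key <- tryCatch(canonicalize(cand), error = function(e) NULL)
      if (is.null(key) || key %in% keys || key %in% hab_keys) next
      fp <- suppressWarnings(atom_pair_fingerprint(cand))
      if (!length(fp)) next
      tmax <- max(vapply(hab_fps, function(h)
        if (length(h)) tanimoto(fp, h) else 0, numeric(1)))
      if (tmax >= 0.4) next
      d <- descriptor_vector(cand)
      matched <- any(vapply(hab_desc, function(hd) {
        abs(d[["MW"]] - hd[["MW"]]) <= 25 &&
          abs(d[["cLogP"]] - hd[["cLogP"]]) <= 1 &&
          abs(d[["nHBD"]] - hd[["nHBD"]]) <= 1 &&
          abs(d[["nHBA"]] - hd[["nHBA"]]) <= 1
      }, logical(1)))
      if (!matched) next
      cand$id <- sprintf("DECOY%04d", length(decoys) + 1L)
      decoys[[length(decoys) + 1L]] <- cand
      keys <- c(keys, key)
    }
  })
  shortfall <- length(decoys) < n
  if (shortfall)
    warning(sprintf("decoy shortfall: %d of %d within the attempt budget",
                    length(decoys), n))
  structure(decoys, shortfall = shortfall)
}

#' Validate a user-supplied negative set
#'
#' Parses, canonicalizes and deduplicates a SMILES file against the HABs
#' (overlapping records are dropped with a warning). More than 50%
#' unparsable records is an error.
#'
#' @param path SMILES file
#' @param hab_mols list of HAB molecules (for deduplication)
#' @return list of negative molecules
#' @export
accept_user_negatives <- function(path, hab_mols = list()) {
  mols <- read_smiles_file(path)
  keys <- vapply(mols, canonicalize, character(1))
  dup_internal <- duplicated(keys)
  mols <- mols[!dup_internal]; keys <- keys[!dup_internal]
  hab_keys <- vapply(hab_mols, canonicalize, character(1))
  overlap <- keys %in% hab_keys
  if (any(overlap))
    warning(sprintf("%d negative(s) identical to a HAB dropped", sum(overlap)))
  mols[!overlap]
}
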