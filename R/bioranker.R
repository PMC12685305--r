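# Post-prediction compound prioritization: ROC-based probability
# threshold selection (G-means, Youden's J), positive-set selection, and
# personalized PageRank over cosine-similarity bipartite graphs built in
# bioactivity descriptor spaces (Chemistry, Targets, Networks, Cells,
# Clinics), with sequential multi-level screening.

#' Choose a probability threshold by G-means or Youden's J
#'
#' Every distinct score is evaluated as a cut (positive call: score >
#' cut). G-means maximizes sqrt(sensitivity * specificity); Youden's J
#' maximizes sensitivity + specificity - 1. Ties go to the lower (more
#' inclusive) threshold.
#'
#' @param labels 0/1 vector (both classes present)
#' @param scores numeric scores
#' @param method "gmeans", "youden" or "fixed"
#' @param fixed cutoff used when method = "fixed" (default 0.5)
#' @return list(method, threshold, sensitivity, specificity, criterion)
#' @export
choose_threshold <- function(labels, scores, method = c("gmeans", "youden",
                                                        "fixed"),
                             fixed = 0.5) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    abort2("threshold selection needs both classes", "cavigrow_domain_error")
  eval_cut <- function(cut) {
    pos <- scores > cut
    sens <- sum(pos & labels == 1L) / sum(labels == 1L)
    spec <- sum(!pos & labels == 0L) / sum(labels == 0L)
    c(sens = sens, spec = spec)
  }
  if (method == "fixed") {
    ss <- eval_cut(fixed)
    return(list(method = method, threshold = fixed,
                sensitivity = ss[["sens"]], specificity = ss[["spec"]],
                criterion = NA_real_))
  }
  # candidate cuts: just below min (all positive) plus every distinct score
  cuts <- sort(unique(c(min(scores) - 1e-9, scores)))
  crit <- vapply(cuts, function(ct) {
    ss <- eval_cut(ct)
    if (method == "gmeans") sqrt(ss[["sens"]] * ss[["spec"]])
    else ss[["sens"]] + ss[["spec"]] - 1
  }, numeric(1))
  best <- which(crit >= max(crit) - 1e-12)[1]   # lowest threshold among ties
  ss <- eval_cut(cuts[best])
  list(method = method, threshold = cuts[best],
       sensitivity = ss[["sens"]], specificity = ss[["spec"]],
       criterion = crit[best])
}

#' Select positive compounds by probability cutoff
#'
#' Strictly greater than the cutoff (default 0.5). An empty result warns
#' but is not an error.
#'
#' @param predictions data.frame(id, probability)
#' @param cutoff probability cutoff or a result of [choose_threshold]
#' @return the positive subset of `predictions`
#' @export
select_positives <- function(predictions, cutoff = 0.5) {
  if (is.list(cutoff) && !is.null(cutoff$threshold)) cutoff <- cutoff$threshold
  pos <- predictions[predictions$probability > cutoff, , drop = FALSE]
  if (!nrow(pos)) warning("no compounds above the probability cutoff")
  rownames(pos) <- NULL
  pos
}

# --- bioactivity descriptor spaces ----------------------------------------

#' Built-in bioactivity descriptor-space providers
#'
#' Each provider is a deterministic function molecule -> fixed-length
#' real vector. Chemistry is the physicochemical descriptor panel; the
#' Targets, Networks, Cells and Clinics spaces are documented
#' deterministic projections of the folded atom-pair fingerprint through
#' seeded random bases — stand-ins for learned bioactivity embeddings,
#' not claims of equivalence.
#'
#' @param names spaces wanted (default all five)
#' @return named list of provider functions
#' @export
bioactivity_spaces <- function(names = c("Chemistry", "Targets", "Networks",
                                         "Cells", "Clinics")) {
  mk_proj <- function(space, dim_out = 32L, nbits = 64L) {
    Wp <- with_seed(derive_seed(1L, paste0("space-", space)),
                    matrix(stats::rnorm(nbits * dim_out), nbits, dim_out))
    function(mol) {
      fp <- suppressWarnings(atom_pair_fingerprint(mol))
      v <- fold_fingerprint(fp, nbits)
      as.numeric(tanh(v %*% Wp))
    }
  }
  providers <- list(
    Chemistry = function(mol) as.numeric(descriptor_vector(mol)),
    Targets = mk_proj("Targets"),
    Networks = mk_proj("Networks"),
    Cells = mk_proj("Cells"),
    Clinics = mk_proj("Clinics"))
  unknown <- setdiff(names, names(providers))
  if (length(unknown))
    abort2(paste("unknown bioactivity space:", unknown[1]),
           "cavigrow_domain_error")
  providers[names]
}

#' Personalized PageRank ranking of positives against HABs in one space
#'
#' Positives and HABs are projected into the space; a bipartite weighted
#' graph links each positive to each HAB with weight max(cosine, 0).
#' Personalized PageRank with teleport mass restricted to the HAB nodes
#' is iterated to L1 convergence < 1e-10; the positives' stationary mass
#' is renormalized to sum 1.
#'
#' @param positives list of molecules (screened compounds called positive)
#' @param habs list of HAB molecules
#' @param provider a provider function from [bioactivity_spaces]
#' @param damping damping factor d (default 0.85)
#' @param max_iter iteration cap (default 1e4)
#' @return data.frame(id, score, rank) for the positives
#' @export
project_and_rank <- function(positives, habs, provider, damping = 0.85,
                             max_iter = 1e4) {
  if (!length(positives) || !length(habs))
    abort2("need at least one positive and one HAB", "cavigrow_domain_error")
  vp <- lapply(positives, provider)
  vh <- lapply(habs, provider)
  np <- length(vp); nh <- length(vh)
  W <- matrix(0, np, nh)
  for (i in seq_len(np)) for (j in seq_len(nh)) {
    cs <- tryCatch(cosine_similarity(vp[[i]], vh[[j]]), error = function(e) 0)
    W[i, j] <- max(cs, 0)
  }
  if (all(W == 0))
    abort2("all similarity weights are zero in this space",
           "cavigrow_domain_error")
  # full (np+nh) transition matrix, rows normalized; dangling rows teleport
  n <- np + nh
  A <- matrix(0, n, n)
  A[seq_len(np), np + seq_len(nh)] <- W
  A[np + seq_len(nh), seq_len(np)] <- t(W)
  rs <- rowSums(A)
  teleport <- c(rep(0, np), rep(1 / nh, nh))
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, ] <- if (rs[i] > 0) A[i, ] / rs[i] else teleport
  }
  pr <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    pr_new <- (1 - damping) * teleport + damping * as.numeric(pr %*% P)
    if (sum(abs(pr_new - pr)) < 1e-10) { pr <- pr_new; break }
    pr <- pr_new
    if (it == max_iter)
      abort2("PageRank did not converge within the iteration cap",
             "cavigrow_numeric_error")
  }
  mass <- pr[seq_len(np)]
  score <- mass / sum(mass)
  ids <- vapply(positives, function(m) {
    if (nzchar(m$id)) m$id else canonicalize(m)
  }, character(1))
  out <- data.frame(id = ids, score = score, stringsAsFactors = FALSE)
  out$rank <- rank(-out$score, ties.method = "first")
  out[order(out$rank), ]
}

#' Sequential multi-level screening across bioactivity spaces
#'
#' Ranks within each space in order, keeps the top ceiling(q * n)
#' survivors, and passes them on; the final order is the last space's
#' ranking. The audit trail records at which level each compound was
#' dropped.
#'
#' @param positives list of molecules
#' @param habs list of HAB molecules
#' @param spaces named list of providers (ordered), e.g. from
#'   [bioactivity_spaces]
#' @param keep_fraction q in (0, 1] kept per level (default 0.5)
#' @param damping PageRank damping (default 0.85)
#' @return list(final = data.frame(id, score, rank), trail = data.frame
#'   (id, dropped_at_level) for all inputs, per_space = per-space rank
#'   tables)
#' @export
multi_level_screen <- function(positives, habs, spaces,
                               keep_fraction = 0.5, damping = 0.85) {
  if (!length(spaces)) abort2("need at least one space", "cavigrow_domain_error")
  if (keep_fraction <= 0 || keep_fraction > 1)
    abort2("keep fraction must lie in (0, 1]", "cavigrow_domain_error")
  ids_all <- vapply(positives, function(m) {
    if (nzchar(m$id)) m$id else canonicalize(m)
  }, character(1))
  dropped <- stats::setNames(rep(NA_character_, length(positives)), ids_all)
  survivors <- positives
  per_space <- list()
  final <- NULL
  for (lev in seq_along(spaces)) {
    sp_name <- names(spaces)[lev] %||% paste0("space", lev)
    if (!length(survivors)) {
      warning(sprintf("no survivors entering level %s", sp_name))
      return(structure(list(final = final,
                            trail = data.frame(id = ids_all,
                                               dropped_at_level = dropped,
                                               stringsAsFactors = FALSE),
                            per_space = per_space),
                       incomplete = TRUE))
    }
    rk <- project_and_rank(survivors, habs, spaces[[lev]], damping = damping)
    per_space[[sp_name]] <- rk
    n_keep <- ceiling(keep_fraction * nrow(rk))
    keep_ids <- rk$id[rk$rank <= n_keep]
    cut_ids <- rk$id[rk$rank > n_keep]
    dropped[cut_ids] <- sp_name
    surv_ids <- vapply(survivors, function(m) {
      if (nzchar(m$id)) m$id else canonicalize(m)
    }, character(1))
    survivors <- survivors[surv_ids %in% keep_ids]
    final <- rk[rk$id %in% keep_ids, , drop = FALSE]
    final$rank <- rank(-final$score, ties.method = "first")
  }
  list(final = final[order(final$rank), ],
       trail = data.frame(id = ids_all, dropped_at_level = dropped,
                          stringsAsFactors = FALSE),
       per_space = per_space)
}

#' Direct-SMILES screening path
#'
#' Ranks a user-supplied compound list against HABs without any
#' probability filter (multi-level screening over the given spaces).
#'
#' @param smiles_path SMILES file of query compounds
#' @param habs list of HAB molecules
#' @param spaces providers (default all five built-ins)
#' @param keep_fraction q per level (default 0.5)
#' @return as [multi_level_screen]
#' @export
screen_smiles <- function(smiles_path, habs, spaces = bioactivity_spaces(),
                          keep_fraction = 0.5) {
  mols <- read_smiles_file(smiles_path)
  multi_level_screen(mols, habs, spaces, keep_fraction = keep_fraction)
}
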