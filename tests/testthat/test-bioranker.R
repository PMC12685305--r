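# Threshold selection, positive calling, PageRank ranking and the
# multi-level screen.

test_that("threshold criteria match their closed forms", {
  labels <- c(0, 0, 0, 1, 1, 1)
  scores <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  for (m in c("gmeans", "youden")) {
    ch <- choose_threshold(labels, scores, m)
    expect_equal(ch$sensitivity, 1)
    expect_equal(ch$specificity, 1)
    expect_equal(ch$criterion, 1.0)
  }
  # sens 0.8 / spec 0.8 arithmetic: J = 0.6, G = 0.8
  expect_equal(0.8 + 0.8 - 1, 0.6)
  expect_equal(sqrt(0.8 * 0.8), 0.8)
  expect_error(choose_threshold(c(1, 1), c(0.2, 0.3), "gmeans"),
               "both classes")
})

test_that("threshold selection agrees with exhaustive enumeration", {
  set.seed(10)
  for (r in 1:100) {
    n <- sample(8:30, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1] <- 1L - labels[1]
    scores <- round(runif(n), 2)
    for (m in c("gmeans", "youden")) {
      ch <- choose_threshold(labels, scores, m)
      orc <- oracle_threshold(labels, scores, m)
      expect_equal(ch$criterion, orc$criterion, tolerance = 1e-9)
      expect_equal(ch$threshold, orc$threshold, tolerance = 1e-9)
    }
  }
})

test_that("positive selection is strict and consistent", {
  preds <- data.frame(id = c("a", "b", "c"),
                      probability = c(0.9, 0.5, 0.2))
  expect_identical(select_positives(preds, 0.5)$id, "a")  # strict >
  expect_equal(nrow(select_positives(preds, 0.0)), 3L)
  expect_warning(out <- select_positives(preds, 0.95), "no compounds")
  expect_equal(nrow(out), 0L)
  # a choose_threshold result can stand in for the cutoff
  ch <- list(threshold = 0.4)
  expect_identical(select_positives(preds, ch)$id,
                   preds$id[preds$probability > 0.4])
})

test_that("pagerank ranking matches the dense power-iteration oracle", {
  # degenerate case: single positive, single HAB
  fix <- make_separable_classes(20, 1, seed = 4)
  sp <- bioactivity_spaces("Chemistry")[[1]]
  r1 <- project_and_rank(fix$mols[1], fix$mols[2], sp)
  expect_equal(r1$score, 1.0)
  # symmetric two-positive toy via custom providers
  prov <- function(mol) {
    # deterministic vector keyed on the id suffix
    k <- as.integer(sub("^m", "", mol$id))
    c(1, k %% 2, (k %% 3) / 2, 0.5)
  }
  pos <- fix$mols[c(1, 1)]
  pos[[1]]$id <- "m0001"; pos[[2]]$id <- "m0003"
  habs <- fix$mols[5:8]
  # identical provider vectors for both positives -> equal scores
  prov_same <- function(mol) c(1, 2, 3)
  rsym <- project_and_rank(pos, habs, prov_same)
  expect_equal(rsym$score, c(0.5, 0.5), tolerance = 1e-9)
  # general toy graph vs the independent dense oracle
  pos2 <- fix$mols[1:3]; habs2 <- fix$mols[11:14]
  got <- project_and_rank(pos2, habs2, sp, damping = 0.85)
  vp <- lapply(pos2, sp); vh <- lapply(habs2, sp)
  W <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4)
    W[i, j] <- max(cosine_similarity(vp[[i]], vh[[j]]), 0)
  n <- 7
  Wfull <- matrix(0, n, n)
  Wfull[1:3, 4:7] <- W; Wfull[4:7, 1:3] <- t(W)
  teleport <- c(rep(0, 3), rep(0.25, 4))
  pr <- oracle_pagerank(Wfull, teleport, 0.85)
  oracle_scores <- pr[1:3] / sum(pr[1:3])
  ids <- vapply(pos2, function(m) m$id, character(1))
  expect_equal(got$score[match(ids, got$id)], oracle_scores,
               tolerance = 1e-8)
  expect_equal(sum(got$score), 1.0, tolerance = 1e-9)
  expect_true(all(got$score >= 0))
  expect_setequal(got$rank, 1:3)
})

test_that("pagerank agrees with igraph's personalized implementation", {
  skip_if_not_installed("igraph")
  fix <- make_separable_classes(20, 1, seed = 4)
  sp <- bioactivity_spaces("Chemistry")[[1]]
  pos <- fix$mols[1:4]; habs <- fix$mols[11:15]
  got <- project_and_rank(pos, habs, sp, damping = 0.85)
  vp <- lapply(pos, sp); vh <- lapply(habs, sp)
  W <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5)
    W[i, j] <- max(cosine_similarity(vp[[i]], vh[[j]]), 0)
  n <- 9
  Wfull <- matrix(0, n, n)
  Wfull[1:4, 5:9] <- W; Wfull[5:9, 1:4] <- t(W)
  g <- igraph::graph_from_adjacency_matrix(Wfull, mode = "directed",
                                           weighted = TRUE)
  pr <- igraph::page_rank(g, damping = 0.85,
                          personalized = c(rep(0, 4), rep(1, 5)))$vector
  oracle_scores <- pr[1:4] / sum(pr[1:4])
  ids <- vapply(pos, function(m) m$id, character(1))
  expect_equal(got$score[match(ids, got$id)], unname(oracle_scores),
               tolerance = 1e-6)
})

test_that("pagerank is invariant to node insertion order", {
  fix <- make_separable_classes(20, 1, seed = 4)
  sp <- bioactivity_spaces("Targets")[[1]]
  pos <- fix$mols[1:4]; habs <- fix$mols[11:15]
  a <- project_and_rank(pos, habs, sp)
  b <- project_and_rank(rev(pos), rev(habs), sp)
  expect_equal(a$score[order(a$id)], b$score[order(b$id)],
               tolerance = 1e-9)
})

test_that("raising damping moves scores toward the principal eigenvector", {
  fix <- make_separable_classes(20, 1, seed = 4)
  sp <- bioactivity_spaces("Chemistry")[[1]]
  pos <- fix$mols[1:3]; habs <- fix$mols[11:14]
  vp <- lapply(pos, sp); vh <- lapply(habs, sp)
  W <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4)
    W[i, j] <- max(cosine_similarity(vp[[i]], vh[[j]]), 0)
  n <- 7
  Wfull <- matrix(0, n, n); Wfull[1:3, 4:7] <- W; Wfull[4:7, 1:3] <- t(W)
  P <- Wfull / rowSums(Wfull)
  ev <- eigen(t(P))
  principal <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  principal <- principal / sum(principal)
  sims <- vapply(c(0.5, 0.7, 0.9, 0.99), function(d) {
    teleport <- c(rep(0, 3), rep(0.25, 4))
    pr <- oracle_pagerank(Wfull, teleport, d)
    cosine_similarity(pr, principal)
  }, numeric(1))
  expect_true(all(diff(sims) > -1e-9))
})

test_that("multi-level screening keeps the audited survivors", {
  fix <- make_separable_classes(20, 1, seed = 4)
  sp <- bioactivity_spaces(c("Chemistry", "Targets"))
  pos <- fix$mols[1:10]; habs <- fix$mols[21:26]
  # q = 1: final order equals the last space's ranking of everyone
  full <- multi_level_screen(pos, habs, sp, keep_fraction = 1)
  direct_last <- project_and_rank(pos, habs, sp$Targets)
  expect_identical(full$final$id, direct_last$id)
  # one space only: identical to project_and_rank
  one <- multi_level_screen(pos, habs, sp["Chemistry"], keep_fraction = 1)
  direct <- project_and_rank(pos, habs, sp$Chemistry)
  expect_identical(one$final$id, direct$id)
  expect_equal(one$final$score, direct$score, tolerance = 1e-12)
  # q = 0.5 over two spaces: hand-traced survivor intersection
  half <- multi_level_screen(pos, habs, sp, keep_fraction = 0.5)
  r1 <- project_and_rank(pos, habs, sp$Chemistry)
  keep1 <- r1$id[r1$rank <= 5]
  pos2 <- pos[vapply(pos, function(m) m$id, character(1)) %in% keep1]
  r2 <- project_and_rank(pos2, habs, sp$Targets)
  keep2 <- r2$id[r2$rank <= 3]
  expect_setequal(half$final$id, keep2)
  # audit trail: dropped compounds name their level, survivors are NA
  tr <- half$trail
  expect_setequal(tr$id[is.na(tr$dropped_at_level)], keep2)
  expect_true(all(tr$dropped_at_level[!is.na(tr$dropped_at_level)] %in%
                    c("Chemistry", "Targets")))
  expect_error(multi_level_screen(pos, habs, sp, keep_fraction = 0),
               "keep fraction")
})
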