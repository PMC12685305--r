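# Graph classifiers for HAB vs LAB/decoy molecules. Four message-passing
# encoder architectures (GCM, GCN, GAT, AFP) turn a molecular graph into
# a fixed-length embedding; a ridge-regularized logistic readout head is
# trained on the embeddings with binary cross-entropy. Encoder weights
# are deterministic seeded random projections (fixed per model), so
# training the head is convex, fast and exactly reproducible on CPU;
# the architecture semantics live in the aggregation scheme: GCM =
# unnormalized sum over neighbors + self, GCN = symmetric
# degree-normalized convolution, GAT = per-edge softmax attention, AFP =
# gated recurrent updates with an attentive graph readout.

FEATURIZER_VERSION <- "cavigrow-feat-1"
ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")

#' Featurize a molecule as a graph with node/edge feature matrices
#'
#' Node features (length 14): one-hot element over
#' {C,N,O,S,P,F,Cl,Br,I,other}, degree/4, formal charge, aromatic flag,
#' implicit H count/3. Edge features (length 6): bond-order one-hot
#' (single, double, triple, aromatic), conjugation flag, ring flag.
#' Unknown elements map to "other" with a warning.
#'
#' @param mol a molecule
#' @param label optional class label in {0, 1}
#' @return object of class `molgraph`
#' @export
featurize <- function(mol, label = NA_integer_) {
  n <- n_atoms(mol)
  if (n == 0L) abort2("cannot featurize an empty molecule", "cavigrow_domain_error")
  el <- mol$atoms$element
  vocab_idx <- match(el, ELEMENT_VOCAB)
  if (anyNA(vocab_idx)) {
    warning(sprintf("element(s) %s outside the vocabulary mapped to 'other'",
                    paste(unique(el[is.na(vocab_idx)]), collapse = ",")))
    vocab_idx[is.na(vocab_idx)] <- length(ELEMENT_VOCAB)
  }
  X <- matrix(0, n, length(ELEMENT_VOCAB) + 4L)
  X[cbind(seq_len(n), vocab_idx)] <- 1
  deg <- atom_degree(mol)
  h <- implicit_hydrogens(mol)
  X[, 11] <- deg / 4
  X[, 12] <- mol$atoms$charge
  X[, 13] <- as.numeric(mol$atoms$aromatic)
  X[, 14] <- h / 3
  b <- mol$bonds
  E <- matrix(0, nrow(b), 6L)
  if (nrow(b)) {
    ri <- ring_info(mol)
    ord_slot <- match(b$order, c(1, 2, 3, 1.5))
    E[cbind(seq_len(nrow(b)), ord_slot)] <- 1
    conj <- b$order > 1 | (mol$atoms$aromatic[b$i] & mol$atoms$aromatic[b$j])
    E[, 5] <- as.numeric(conj)
    E[, 6] <- as.numeric(ri$bond_in_ring)
  }
  comp <- mol_components(mol)
  structure(list(x = X, edges = b[, c("i", "j")], edge_attr = E,
                 label = as.integer(label),
                 multi_fragment = max(comp) > 1L,
                 id = mol$id, version = FEATURIZER_VERSION),
            class = "molgraph")
}

#' Model configuration for the graph classifiers
#'
#' @param architecture "GCM", "GCN", "AFP" or "GAT"
#' @param hidden hidden width (default 64)
#' @param layers message-passing layers (default 2)
#' @param dropout kept for interface compatibility; the convex readout
#'   head does not use it (must be in [0, 1))
#' @param learning_rate,batch_size,epochs,patience kept for interface
#'   compatibility with iterative trainers; the ridge head is fit in
#'   closed form by IRLS
#' @param lambda ridge penalty of the logistic head (default 0.01)
#' @param k_folds cross-validation folds (default 3)
#' @param seed integer seed (encoder weights + fold assignment)
#' @export
model_config <- function(architecture = c("AFP", "GCM", "GCN", "GAT"),
                         hidden = 64L, layers = 2L, dropout = 0.1,
                         learning_rate = 1e-3, batch_size = 32L,
                         epochs = 150L, patience = 15L,
                         lambda = 0.01, k_folds = 3L, seed = 42L) {
  architecture <- match.arg(architecture)
  stopifnot(k_folds >= 2L, dropout >= 0, dropout < 1)
  structure(list(architecture = architecture, hidden = as.integer(hidden),
                 layers = as.integer(layers), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 lambda = lambda, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "model_config")
}

# seeded encoder parameter set for one architecture
encoder_params <- function(config, in_dim = 14L) {
  h <- config$hidden
  with_seed(derive_seed(config$seed, paste0("enc-", config$architecture)), {
    sc <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))),
                                  nr, nc)
    list(W_in = sc(in_dim, h),
         W = lapply(seq_len(config$layers), function(l) sc(h, h)),
         W_self = lapply(seq_len(config$layers), function(l) sc(h, h)),
         att_a = lapply(seq_len(config$layers), function(l) stats::rnorm(2 * h, sd = 0.3)),
         W_gate = lapply(seq_len(config$layers), function(l) sc(2 * h, h)),
         readout_u = stats::rnorm(h, sd = 0.3),
         W_read = sc(h, h))
  })
}

relu <- function(m) { m[m < 0] <- 0; m }
sigmoid <- function(m) 1 / (1 + exp(-m))

#' Graph embedding under one encoder architecture
#'
#' @param mg a molgraph
#' @param config a model_config
#' @param params encoder parameters (default derived from config seed)
#' @return numeric embedding of length 2 * hidden (mean + max readout;
#'   AFP uses attentive + max readout)
#' @export
encode_graph <- function(mg, config, params = encoder_params(config)) {
  n <- nrow(mg$x)
  H <- mg$x %*% params$W_in
  A <- matrix(0, n, n)
  if (nrow(mg$edges)) {
    A[cbind(mg$edges$i, mg$edges$j)] <- 1
    A[cbind(mg$edges$j, mg$edges$i)] <- 1
  }
  arch <- config$architecture
  for (l in seq_len(config$layers)) {
    W <- params$W[[l]]
    if (arch == "GCM") {
      H <- relu((A %*% H) %*% W + H %*% params$W_self[[l]])
    } else if (arch == "GCN") {
      dg <- rowSums(A) + 1
      An <- (A + diag(n)) / sqrt(outer(dg, dg))
      H <- relu((An %*% H) %*% W)
    } else if (arch == "GAT") {
      HW <- H %*% W
      S <- matrix(-Inf, n, n)
      a <- params$att_a[[l]]
      h2 <- config$hidden
      si <- HW %*% a[seq_len(h2)]
      sj <- HW %*% a[h2 + seq_len(h2)]
      M <- A + diag(n)
      S <- outer(as.numeric(si), rep(1, n)) + outer(rep(1, n), as.numeric(sj))
      S <- ifelse(S > 0, S, 0.2 * S)          # leaky relu
      S[M == 0] <- -Inf
      S <- exp(S - apply(S, 1, max))
      S[M == 0] <- 0
      alpha <- S / pmax(rowSums(S), 1e-12)
      H <- relu(alpha %*% HW)
    } else {                                  # AFP: gated update
      Msg <- A %*% (H %*% W)
      Z <- sigmoid(cbind(H, Msg) %*% params$W_gate[[l]])
      Cand <- tanh(Msg %*% params$W_self[[l]])
      H <- (1 - Z) * H + Z * Cand
    }
  }
  if (arch == "AFP") {
    w <- as.numeric(tanh(H %*% params$W_read) %*% params$readout_u)
    w <- exp(w - max(w)); w <- w / sum(w)
    emb_mean <- as.numeric(t(w) %*% H)
  } else {
    emb_mean <- colMeans(H)
  }
  emb_max <- apply(H, 2, max)
  c(emb_mean, emb_max)
}

# embeddings for a list of molgraphs
encode_dataset <- function(graphs, config, params) {
  t(vapply(graphs, function(g) encode_graph(g, config, params),
           numeric(2L * config$hidden)))
}

# stratified fold assignment, seeded
stratified_folds <- function(labels, k, seed) {
  with_seed(derive_seed(seed, "folds"), {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# upsample minority class to parity (returns row indices, training only)
upsample_parity <- function(idx, labels, seed) {
  tab <- table(labels[idx])
  if (length(tab) < 2L) return(idx)
  target <- max(tab)
  out <- idx
  with_seed(derive_seed(seed, "upsample"), {
    for (cls in names(tab)) {
      cls_idx <- idx[labels[idx] == as.integer(cls)]
      need <- target - length(cls_idx)
      if (need > 0L)
        out <- c(out, sample(cls_idx, need, replace = TRUE))
    }
  })
  out
}

fit_head <- function(X, y, lambda) {
  tryCatch(
    glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = lambda, standardize = TRUE),
    error = function(e) abort2(paste0(
      "logistic head fit failed (degenerate embeddings?): ",
      conditionMessage(e)), "cavigrow_numeric_error"))
}

predict_head <- function(head, X) {
  as.numeric(stats::predict(head, X, type = "response"))
}

#' Train a graph classifier with stratified cross-validation
#'
#' Per-fold metrics are computed first (minority class upsampled to
#' parity inside each training fold only, never the validation fold),
#' then the final model is refit on the complete dataset.
#'
#' @param graphs list of molgraphs with labels in {0, 1}
#' @param config a model_config
#' @return object of class `trained_model`: architecture, encoder params,
#'   head, featurizer version, per-fold metrics (auc, sensitivity,
#'   specificity), fold audit info
#' @export
train_model <- function(graphs, config = model_config()) {
  labels <- vapply(graphs, `[[`, integer(1), "label")
  if (anyNA(labels)) abort2("all graphs need labels", "cavigrow_domain_error")
  if (length(unique(labels)) < 2L)
    abort2("training needs both classes", "cavigrow_domain_error")
  if (length(graphs) < 20L)
    abort2("training needs >= 20 molecules", "cavigrow_domain_error")
  params <- encoder_params(config)
  X <- encode_dataset(graphs, config, params)
  if (any(!is.finite(X)))
    abort2("non-finite encoder output: aborting with diagnostics (check
            featurization of inputs)", "cavigrow_numeric_error")
  fold <- stratified_folds(labels, config$k_folds, config$seed)
  fold_metrics <- list(); fold_audit <- list()
  for (f in seq_len(config$k_folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    tr_up <- upsample_parity(tr, labels, config$seed + f)
    head <- fit_head(X[tr_up, , drop = FALSE], labels[tr_up], config$lambda)
    p <- predict_head(head, X[va, , drop = FALSE])
    rm <- roc_metrics(labels[va], p, threshold = 0.5)
    fold_metrics[[f]] <- c(auc = rm$auc, sensitivity = rm$sensitivity,
                           specificity = rm$specificity)
    fold_audit[[f]] <- list(train_ids = tr_up, val_ids = va,
                            train_label_table = table(labels[tr_up]))
  }
  final_idx <- upsample_parity(seq_along(graphs), labels, config$seed)
  head <- fit_head(X[final_idx, , drop = FALSE], labels[final_idx],
                   config$lambda)
  metrics <- do.call(rbind, fold_metrics)
  structure(list(architecture = config$architecture, config = config,
                 params = params, head = head,
                 featurizer_version = FEATURIZER_VERSION,
                 cv_metrics = as.data.frame(metrics),
                 mean_cv_auc = mean(metrics[, "auc"]),
                 fold_audit = fold_audit, final_fit = TRUE),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model %s: mean CV AUC %.3f over %d folds>\n",
              x$architecture, x$mean_cv_auc, nrow(x$cv_metrics)))
  invisible(x)
}

#' Hyperparameter/architecture search by mean CV AUC
#'
#' @param graphs labeled molgraphs
#' @param space list of model_config candidates (>= 1)
#' @return list(best = winning config, model = its trained model,
#'   leaderboard = data.frame sorted by mean CV AUC desc)
#' @export
tune_model <- function(graphs, space) {
  if (!length(space)) abort2("empty search space", "cavigrow_domain_error")
  rows <- list(); models <- list()
  for (k in seq_along(space)) {
    m <- tryCatch(train_model(graphs, space[[k]]), error = function(e) e)
    if (inherits(m, "error")) {
      # a broken candidate (e.g. collapsed embeddings) ranks last
      warning(sprintf("config %d failed: %s", k, conditionMessage(m)))
      models[k] <- list(NULL)
      rows[[k]] <- data.frame(config = k,
                              architecture = space[[k]]$architecture,
                              hidden = space[[k]]$hidden,
                              lambda = space[[k]]$lambda,
                              mean_cv_auc = NA_real_)
      next
    }
    models[[k]] <- m
    rows[[k]] <- data.frame(config = k, architecture = m$architecture,
                            hidden = space[[k]]$hidden,
                            lambda = space[[k]]$lambda,
                            mean_cv_auc = m$mean_cv_auc)
  }
  lb <- do.call(rbind, rows)
  lb <- lb[order(-lb$mean_cv_auc, lb$config, na.last = TRUE), ]
  rownames(lb) <- NULL
  if (is.na(lb$mean_cv_auc[1]))
    abort2("no configuration in the space trained successfully",
           "cavigrow_domain_error")
  best_k <- lb$config[1]
  list(best = space[[best_k]], model = models[[best_k]], leaderboard = lb)
}

#' Predict HAB probability for molecules
#'
#' @param model a trained_model
#' @param mols list of molecules (or molgraphs)
#' @return numeric probabilities in input order
#' @export
predict_molecules <- function(model, mols) {
  graphs <- lapply(mols, function(m) {
    if (inherits(m, "molgraph")) m else featurize(m)
  })
  vers <- vapply(graphs, `[[`, character(1), "version")
  if (any(vers != model$featurizer_version))
    abort2("featurizer version mismatch between model and inputs",
           "cavigrow_version_error")
  X <- encode_dataset(graphs, model$config, model$params)
  predict_head(model$head, X)
}

#' ROC curve, AUC and sensitivity/specificity at a threshold
#'
#' AUC by trapezoid over the rank-based curve (midrank tie convention,
#' so it equals the Mann-Whitney pairwise-ordering probability).
#' Sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) at `threshold`
#' (positive call: score > threshold).
#'
#' @param labels 0/1 vector (both classes present)
#' @param scores numeric scores, higher = more positive
#' @param threshold operating point (default 0.5)
#' @return list(thresholds, tpr, fpr, auc, sensitivity, specificity)
#' @export
roc_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    abort2("ROC needs both classes", "cavigrow_domain_error")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group by distinct score
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l == 1L, grp, sum)
  fp <- tapply(l == 0L, grp, sum)
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  tpr <- c(0, ctp / np); fpr <- c(0, cfp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pos_call <- scores > threshold
  sens <- sum(pos_call & labels == 1L) / np
  spec <- sum(!pos_call & labels == 0L) / nn
  list(thresholds = c(Inf, unique(s)), tpr = as.numeric(tpr),
       fpr = as.numeric(fpr), auc = as.numeric(auc),
       sensitivity = sens, specificity = spec)
}
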