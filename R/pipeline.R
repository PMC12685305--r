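# End-to-end orchestration: cavity detection -> ligand growth ->
# energy authentication -> classifier training -> screening -> ranking,
# with per-stage artifacts, a checksum manifest, and file-level resume.

PIPELINE_FIELDS <- c(
  "pdb", "outdir", "seed", "spacing", "probe", "min_volume", "membrane",
  "critical_residues", "target_count", "population_size", "generations",
  "threshold", "test", "architecture", "k_folds", "query_smiles",
  "cutoff_method", "cutoff", "spaces", "keep_fraction", "sigma")

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline]. Unknown keys in `...`
#' are rejected by name. The defaults are the pipeline's study
#' conditions: 0.5 angstrom grid, -7 kcal/mol energy threshold, 500
#' target ligands, threefold CV, 0.5 probability cutoff.
#'
#' @param pdb input protein structure (PDB path)
#' @param outdir run directory for artifacts
#' @param seed global seed; per-stage streams are derived from it
#' @param ... overrides for any documented field (spacing, probe,
#'   min_volume, membrane, critical_residues, target_count,
#'   population_size, generations, threshold, test, architecture,
#'   k_folds, query_smiles, cutoff_method, cutoff, spaces,
#'   keep_fraction, sigma)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(pdb, outdir, seed = 42L, ...) {
  cfg <- list(pdb = pdb, outdir = outdir, seed = as.integer(seed),
              spacing = 0.5, probe = 1.0, min_volume = 50,
              membrane = NULL, critical_residues = NULL,
              target_count = 500L, population_size = 64L,
              generations = 200L, threshold = -7.0, test = "ks",
              architecture = "AFP", k_folds = 3L, query_smiles = NULL,
              cutoff_method = "fixed", cutoff = 0.5,
              spaces = c("Chemistry", "Targets", "Networks",
                         "Cells", "Clinics"),
              keep_fraction = 0.5, sigma = 0.3)
  extra <- list(...)
  unknown <- setdiff(names(extra), PIPELINE_FIELDS)
  if (length(unknown))
    abort2(paste("unknown configuration key:",
                 paste(unknown, collapse = ", ")), "cavigrow_config_error")
  cfg[names(extra)] <- extra
  structure(cfg, class = "pipeline_config")
}

stage_files <- function(outdir) {
  list(cavity = file.path(outdir, c("cavities.tsv", "cavity.json")),
       synth = file.path(outdir, "ligands.smi"),
       auth = file.path(outdir, "labeled.tsv"),
       gen = file.path(outdir, "cv_metrics.tsv"),
       rank = file.path(outdir, c("predictions.tsv", "ranking.tsv")))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes cavity detection, ligand growth, authentication, training
#' and (when `query_smiles` is configured) screening plus ranking.
#' Artifacts land in `config$outdir`; `manifest.json` records the seed,
#' stage parameters and md5 checksums of every artifact. Stages whose
#' artifacts already exist are skipped (resume), so deleting a stage's
#' files re-runs that stage only. A stage failure halts with the stage
#' name; earlier artifacts are preserved.
#'
#' @param config a [pipeline_config]
#' @param force re-run all stages even if artifacts exist
#' @return invisible list with in-memory stage results and the manifest
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sf <- stage_files(config$outdir)
  done <- function(stage) all(file.exists(sf[[stage]]))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort2(sprintf("pipeline halted at stage '%s': %s", stage,
                     conditionMessage(e)), "cavigrow_stage_error")
    })
  }
  results <- list()

  # -- cavity ---------------------------------------------------------------
  structure3d <- run_stage("cavity", read_pdb(config$pdb))
  grid <- run_stage("cavity", build_grid(structure3d, spacing = config$spacing,
                                         probe = config$probe))
  cavities <- run_stage("cavity",
                        detect_cavities(grid, structure3d,
                                        min_volume = config$min_volume,
                                        membrane = config$membrane))
  if (!length(cavities))
    abort2("pipeline halted at stage 'cavity': no cavities detected",
           "cavigrow_stage_error")
  cavity <- run_stage("cavity", select_cavity(cavities,
                                              config$critical_residues))
  if (force || !done("cavity")) {
    write_tsv(cavity_table(cavities), sf$cavity[1])
    write_cavity_json(cavity, grid, sf$cavity[2])
  }
  results$cavity <- cavity

  # -- synthesizer ----------------------------------------------------------
  if (force || !done("synth")) {
    ga <- ga_config(target_count = config$target_count,
                    population_size = config$population_size,
                    generations = config$generations,
                    seed = derive_seed(config$seed, "synth"))
    ligands <- run_stage("synth",
                         grow_ligands(cavity, structure3d, grid,
                                      config = ga))
    write_smiles_file(lapply(ligands, `[[`, "mol"), sf$synth)
    results$ligands <- ligands
  } else {
    mols <- read_smiles_file(sf$synth)
    results$ligands <- lapply(mols, function(m)
      list(mol = embed_and_pose_cached(m, cavity), canonical = canonicalize(m)))
  }

  # -- authenticator --------------------------------------------------------
  if (force || !done("auth")) {
    backend <- surrogate_backend(cavity, structure3d, grid,
                                 sigma = config$sigma,
                                 seed = derive_seed(config$seed, "auth"))
    energies <- run_stage("auth", score_ligands(results$ligands, backend))
    labeled <- run_stage("auth", segregate(energies, config$threshold))
    mols_by_id <- stats::setNames(lapply(results$ligands, `[[`, "mol"),
                                  vapply(results$ligands,
                                         function(l) l$mol$id, character(1)))
    lab_df <- rbind(
      data.frame(id = labeled$habs$id, energy = labeled$habs$energy,
                 label = "HAB", stringsAsFactors = FALSE),
      data.frame(id = labeled$labs$id, energy = labeled$labs$energy,
                 label = "LAB", stringsAsFactors = FALSE))
    lab_df$canonical <- vapply(mols_by_id[lab_df$id], canonicalize,
                               character(1))
    write_tsv(lab_df[, c("id", "canonical", "energy", "label")], sf$auth)
  } else {
    # resume: the authenticated energies are the artifact of record
    lab_df <- utils::read.delim(sf$auth, stringsAsFactors = FALSE)
    labeled <- run_stage("auth",
                         segregate(lab_df[, c("id", "energy")],
                                   config$threshold))
    mols_by_id <- stats::setNames(
      lapply(seq_len(nrow(lab_df)), function(k) {
        m <- parse_smiles(lab_df$canonical[k], id = lab_df$id[k])
        m
      }), lab_df$id)
  }
  results$split_test <- run_stage("auth",
                                  tryCatch(authenticate_split(labeled,
                                                              config$test),
                                           error = function(e) NULL))
  neg_mols <- mols_by_id[labeled$labs$id]
  if (labeled$imbalance && nrow(labeled$habs) > nrow(labeled$labs)) {
    need <- nrow(labeled$habs) - nrow(labeled$labs)
    dec <- run_stage("auth",
                     suppressWarnings(
                       generate_decoys(mols_by_id[labeled$habs$id], need,
                                       seed = derive_seed(config$seed,
                                                          "decoys"))))
    neg_mols <- c(neg_mols, dec)
  }
  hab_mols <- mols_by_id[labeled$habs$id]
  results$labeled <- labeled

  # -- generator ------------------------------------------------------------
  graphs <- c(lapply(hab_mols, featurize, label = 1L),
              lapply(neg_mols, featurize, label = 0L))
  model <- run_stage("gen",
                     train_model(graphs,
                                 model_config(config$architecture,
                                              k_folds = config$k_folds,
                                              seed = derive_seed(config$seed,
                                                                 "gen"))))
  if (force || !done("gen")) write_tsv(model$cv_metrics, sf$gen)
  results$model <- model

  # -- bioranker ------------------------------------------------------------
  if (!is.null(config$query_smiles)) {
    query <- read_smiles_file(config$query_smiles)
    probs <- run_stage("rank", predict_molecules(model, query))
    preds <- data.frame(
      id = vapply(query, function(m) m$id, character(1)),
      probability = probs, stringsAsFactors = FALSE)
    blank <- !nzchar(preds$id)
    preds$id[blank] <- sprintf("Q%03d", which(blank))
    for (k in which(blank)) query[[k]]$id <- preds$id[k]
    positives <- select_positives(preds, config$cutoff)
    if (nrow(positives)) {
      pos_mols <- query[match(positives$id, preds$id)]
      spaces <- bioactivity_spaces(config$spaces)
      screen <- run_stage("rank",
                          multi_level_screen(pos_mols, hab_mols, spaces,
                                             config$keep_fraction))
      if (force || !done("rank")) {
        write_tsv(preds, sf$rank[1])
        write_tsv(merge(screen$final, screen$trail, by = "id",
                        all.y = FALSE), sf$rank[2])
      }
      results$screen <- screen
    }
    results$predictions <- preds
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    checksums = as.list(tools::md5sum(list.files(config$outdir,
                                                 full.names = TRUE,
                                                 pattern = "\\.(tsv|smi|json)$"))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# resume helper: a ligand read back from file needs coordinates again
embed_and_pose_cached <- function(mol, cavity) {
  m <- embed_molecule(mol)
  m$coords <- sweep(m$coords, 2, cavity$centroid, "+")
  m
}

#' Benchmark a trained model on external actives/decoys
#'
#' Reads user-supplied active and decoy SMILES files (never downloaded),
#' predicts with the model and reports AUC, sensitivity and specificity.
#'
#' @param actives_path,decoys_path SMILES files
#' @param model a trained_model
#' @param cutoff probability cutoff for sensitivity/specificity
#' @return list(auc, sensitivity, specificity, n_actives, n_decoys)
#' @export
benchmark_external <- function(actives_path, decoys_path, model,
                               cutoff = 0.5) {
  for (p in c(actives_path, decoys_path)) {
    if (!file.exists(p))
      abort2(sprintf(
        "benchmark needs external data; file not found: %s", p),
        "cavigrow_io_error")
  }
  actives <- read_smiles_file(actives_path)
  decoys <- read_smiles_file(decoys_path)
  if (!length(actives) || !length(decoys))
    abort2("empty actives or decoys file", "cavigrow_io_error")
  mols <- c(actives, decoys)
  labels <- c(rep(1L, length(actives)), rep(0L, length(decoys)))
  probs <- predict_molecules(model, mols)
  rm <- roc_metrics(labels, probs, threshold = cutoff)
  list(auc = rm$auc, sensitivity = rm$sensitivity,
       specificity = rm$specificity,
       n_actives = length(actives), n_decoys = length(decoys))
}
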