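#' Full-run configuration
#'
#' A run either simulates a synthetic panel (`panel` set) or ingests real
#' prediction/label tables (`predictions_path`/`labels_path` set) — exactly
#' one of the two. All downstream randomness (panel, split, weight init,
#' shuffling) derives from `seed` through named substreams.
#'
#' @param panel a [panel_config()], or NULL when ingesting tables.
#' @param predictions_path,labels_path paths to a prediction table and a
#'   labels table (TSV: protein_id, position, wt_aa, rsa, aa_class), or NULL
#'   when simulating.
#' @param n_proteins proteins to simulate (ignored when ingesting).
#' @param test_fraction fraction of proteins held out for evaluation.
#' @param clusters optional [parse_cluster_file()] table for homology-aware
#'   splitting.
#' @param train a [train_config()]; its seed is overridden from `seed`.
#' @param class_map amino-acid class map.
#' @param rsa_bin_width,confidence_bin_width histogram bin widths.
#' @param out_dir output directory for report tables and the manifest.
#' @param seed global integer seed.
#' @param verbose emit per-stage log lines.
#' @return object of class `run_config`.
#' @export
run_config <- function(panel = NULL, predictions_path = NULL,
                       labels_path = NULL, n_proteins = 60L,
                       test_fraction = 0.25, clusters = NULL,
                       train = train_config(), class_map = aa_class_map(),
                       rsa_bin_width = 0.05, confidence_bin_width = 0.05,
                       out_dir = NULL, seed = 1L, verbose = FALSE) {
  has_panel <- !is.null(panel)
  has_tables <- !is.null(predictions_path) || !is.null(labels_path)
  if (has_panel && has_tables)
    stop_resstack("resstack_config_error",
                  "set either a simulation panel or real table paths, not both")
  if (!has_panel && !has_tables) panel <- default_panel_config()
  if (has_tables && (is.null(predictions_path) || is.null(labels_path)))
    stop_resstack("resstack_config_error",
                  "real-data runs need both predictions_path and labels_path")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_resstack("resstack_config_error", "test_fraction must be in (0,1)")
  structure(list(panel = panel, predictions_path = predictions_path,
                 labels_path = labels_path, n_proteins = as.integer(n_proteins),
                 test_fraction = test_fraction, clusters = clusters,
                 train = train, class_map = class_map,
                 rsa_bin_width = rsa_bin_width,
                 confidence_bin_width = confidence_bin_width,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Homology-aware train/test split
#'
#' Splits by protein, never by site. When a cluster table is given, all
#' proteins sharing a cluster land on the same side; a cluster too large for
#' the test side is assigned to training (with a warning if it fits neither
#' side's nominal capacity). Deterministic given `seed`.
#'
#' @param proteins character vector of protein ids.
#' @param test_fraction target fraction of proteins in the test side.
#' @param clusters optional [parse_cluster_file()] table.
#' @param seed integer seed.
#' @return list with `train` and `test` (disjoint character vectors covering
#'   `proteins`).
#' @export
split_train_test <- function(proteins, test_fraction, clusters = NULL,
                             seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_resstack("resstack_config_error", "test_fraction must be in (0,1)")
  proteins <- unique(proteins)
  n <- length(proteins)
  if (is.null(clusters)) {
    group_of <- seq_len(n)
  } else {
    norm_members <- norm_pdb_id(names(clusters$member_index))
    ords <- vapply(norm_pdb_id(proteins), function(id) {
      hit <- clusters$member_index[norm_members %in% id]
      if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
    }, integer(1))
    group_of <- ifelse(is.na(ords), -seq_len(n), ords)  # singletons
  }
  groups <- split(proteins, group_of)
  target <- max(1L, round(n * test_fraction))
  test <- character(0)
  with_stream(hash_seed(seed, "split"), {
    for (g in groups[sample.int(length(groups))]) {
      if (length(test) >= target) break
      if (length(test) + length(g) <= target) {
        test <- c(test, g)
      } else if (length(g) > target && length(g) > n - target) {
        warning(sprintf("cluster of %d protein(s) exceeds both sides' capacity; assigned to training",
                        length(g)), call. = FALSE)
      }
    }
  })
  list(train = setdiff(proteins, test), test = test)
}

pipeline_log <- function(cfg, stage, fmt, ...) {
  if (cfg$verbose)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# infer structure/sequence types from panel profiles or id prefixes
infer_model_types <- function(cfg, model_ids) {
  if (!is.null(cfg$panel)) {
    types <- vapply(cfg$panel$profiles, function(p) p$model_type,
                    character(1))
    return(types)
  }
  guess <- ifelse(grepl("^struct", model_ids), "structure",
           ifelse(grepl("^seq", model_ids), "sequence", NA_character_))
  stats::setNames(guess, model_ids)
}

#' Run the full comparison-and-stacking pipeline
#'
#' Stages, in order: simulate (or ingest) the four-model prediction corpus;
#' split proteins into train/test (homology-aware if clusters are given);
#' train the stacking network on the training sites; predict the combined
#' model and the two naive baselines on the held-out sites; evaluate
#' everything (per-protein accuracy, class accuracy, accuracy correlations,
#' agreement taxonomy, confidence-RSA histograms). When `cfg$out_dir` is set,
#' report tables, the trained model, and a manifest (config hash, seed,
#' versions, counts, train/test ids) are written there; reruns with an
#' identical config reproduce identical bytes.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list: `report` (evaluation tables), `params` (trained
#'   combiner), `loss_trace`, `split`, `pset`, `labels`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  if (!is.null(cfg$panel)) {
    pipeline_log(cfg, "simulate", "panel of %d proteins, seed %d",
                 cfg$n_proteins, cfg$seed)
    sim <- simulate_panel(cfg$panel, cfg$n_proteins,
                          seed = hash_seed(cfg$seed, "panel"),
                          class_map = cfg$class_map)
    pset <- sim$pset; labels <- sim$labels
  } else {
    pipeline_log(cfg, "ingest", "%s + %s", cfg$predictions_path,
                 cfg$labels_path)
    pset <- read_prediction_table(cfg$predictions_path)
    labels <- read_labels_table(cfg$labels_path)
  }
  model_ids <- pset_models(pset)
  model_types <- infer_model_types(cfg, model_ids)

  split <- split_train_test(unique(labels$protein_id), cfg$test_fraction,
                            cfg$clusters, seed = cfg$seed)
  if (length(intersect(split$train, split$test)) > 0)
    stop_resstack("resstack_internal_error", "train/test overlap")
  pipeline_log(cfg, "split", "%d train / %d test proteins",
               length(split$train), length(split$test))

  train_labels <- labels[labels$protein_id %in% split$train]
  test_labels <- labels[labels$protein_id %in% split$test]
  train_pset <- as_prediction_set(pset[pset$protein_id %in% split$train])
  test_pset <- as_prediction_set(pset[pset$protein_id %in% split$test])

  tcfg <- cfg$train
  tcfg$seed <- hash_seed(cfg$seed, "train")
  pipeline_log(cfg, "train", "%d sites, %d epochs", nrow(train_labels),
               tcfg$epochs)
  fit <- train_combiner(train_pset, train_labels, tcfg)

  combined <- predict_combined(fit$params, test_pset)
  bases <- baseline_psets(test_pset, fit$params$model_order)
  all_pset <- as_prediction_set(data.table::rbindlist(
    list(test_pset, combined, bases$average, bases$max_vote)))
  pipeline_log(cfg, "predict", "combined + baselines on %d test sites",
               nrow(test_labels))

  report <- evaluate_models(all_pset, test_labels, model_types = model_types,
                            class_map = cfg$class_map,
                            rsa_bin_width = cfg$rsa_bin_width,
                            confidence_bin_width = cfg$confidence_bin_width)
  manifest <- list(
    package_version = as.character(utils::packageVersion("resstack")),
    r_version = R.version.string,
    seed = cfg$seed, config_hash = hash_seed(config_signature(cfg)),
    n_proteins = length(unique(labels$protein_id)),
    n_sites = nrow(labels), n_train = length(split$train),
    n_test = length(split$test),
    train_test_overlap = length(intersect(split$train, split$test)),
    train_ids = sort(split$train), test_ids = sort(split$test),
    epochs = tcfg$epochs, final_loss = fit$loss_trace[length(fit$loss_trace)],
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out <- list(report = report, params = fit$params,
              loss_trace = fit$loss_trace, split = split, pset = pset,
              labels = labels, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_report(out, cfg)
  invisible(out)
}

# stable textual signature of a run config (for the manifest hash)
config_signature <- function(cfg) {
  paste(utils::capture.output(utils::str(
    cfg[setdiff(names(cfg), c("out_dir", "verbose"))], digits.d = 15)),
    collapse = "\n")
}

#' Evaluate a set of models against labels
#'
#' Computes the full report: per-protein accuracies, mean accuracy per
#' model, pooled class accuracies, pairwise Pearson correlations of
#' per-protein accuracies, the agreement-category table (when the combined
#' model and exactly four typed individual models are present), and one
#' confidence-vs-RSA histogram per model (when labels carry RSA).
#'
#' @param pset a [prediction_set()].
#' @param labels site table.
#' @param model_types named type vector for the individual models (for the
#'   agreement table); NA types skip that table.
#' @param combined_id id of the combined model in `pset`.
#' @param class_map,rsa_bin_width,confidence_bin_width see [run_config()].
#' @return list of report tables.
#' @export
evaluate_models <- function(pset, labels, model_types = NULL,
                            combined_id = "combined",
                            class_map = aa_class_map(), rsa_bin_width = 0.05,
                            confidence_bin_width = 0.05) {
  models <- pset_models(pset)
  pp <- per_protein_accuracy(pset, labels)
  acc_mat <- as.matrix(data.table::dcast(
    pp, protein_id ~ model_id, value.var = "accuracy"),
    rownames = "protein_id")
  per_class <- data.table::rbindlist(lapply(models, function(m)
    class_accuracy(pset, labels, m, class_map)))
  corr <- suppressWarnings(accuracy_correlation_matrix(acc_mat))
  indiv <- setdiff(models, c(combined_id, "ensemble_average", "ensemble_max"))
  agreement <- NULL
  if (combined_id %in% models && length(indiv) == 4 &&
      !is.null(model_types) && all(indiv %in% names(model_types)) &&
      !anyNA(model_types[indiv])) {
    sub <- as_prediction_set(pset[pset$model_id %in% c(indiv, combined_id)])
    agreement <- agreement_summary(sub, labels, model_types[indiv],
                                   combined_id)
  }
  hist_tab <- NULL
  if ("rsa" %in% names(labels)) {
    ct <- correctness_table(pset, labels)
    hist_tab <- data.table::rbindlist(lapply(models, function(m) {
      h <- rsa_confidence_histogram(ct[ct$model_id == m]$rsa,
                                    ct[ct$model_id == m]$confidence,
                                    rsa_bin_width, confidence_bin_width)
      h[, model_id := m]
      h
    }))
  }
  list(mean_accuracy = colMeans(acc_mat)[models], per_protein = pp,
       per_class = per_class, correlation = corr, agreement = agreement,
       rsa_confidence = hist_tab)
}

write_tsv_det <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
}

write_report <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rp <- out$report
  f <- function(name) file.path(cfg$out_dir, name)
  write_tsv_det(rp$per_protein, f("per_protein_accuracy.tsv"))
  write_tsv_det(rp$per_class, f("class_accuracy.tsv"))
  write_tsv_det(data.table::as.data.table(rp$correlation$r,
                                          keep.rownames = "model_id"),
                f("correlation_r.tsv"))
  write_tsv_det(data.table::as.data.table(rp$correlation$p,
                                          keep.rownames = "model_id"),
                f("correlation_p.tsv"))
  if (!is.null(rp$agreement))
    write_tsv_det(rp$agreement, f("agreement.tsv"))
  if (!is.null(rp$rsa_confidence))
    write_tsv_det(rp$rsa_confidence, f("rsa_confidence_histogram.tsv"))
  write_tsv_det(data.table(epoch = seq_along(out$loss_trace),
                           loss = out$loss_trace), f("loss_trace.tsv"))
  save_combiner(out$params, f("combined_model.json"), train_cfg = cfg$train)
  jsonlite::write_json(out$manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Read / write a labels table
#'
#' TSV with columns `protein_id`, `position`, `wt_aa` and optionally `rsa`,
#' `aa_class`, `burial`.
#'
#' @param path file path.
#' @param labels a labels data.table (for the writer).
#' @return the labels data.table.
#' @export
read_labels_table <- function(path) {
  if (!file.exists(path))
    stop_resstack("resstack_io_error", "file not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("protein_id", "position", "wt_aa")
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0)
    stop_resstack("resstack_format_error",
                  "labels table is missing column(s): %s",
                  paste(missing, collapse = ", "))
  dt[, `:=`(protein_id = as.character(protein_id),
            position = as.integer(position))]
  dt
}

#' @rdname read_labels_table
#' @export
write_labels_table <- function(labels, path) {
  write_tsv_det(as.data.table(labels), path)
  invisible(path)
}
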