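#' Top prediction of a probability vector
#'
#' The predicted amino acid is the one assigned the highest of the 20
#' probabilities; the model's confidence is that probability. Ties are broken
#' in [aa_alphabet()] order.
#'
#' @param v numeric vector of 20 probabilities in alphabet order.
#' @return list with `aa` and `confidence`.
#' @export
#' @examples
#' top_prediction(rep(0.05, 20))  # tie -> "A"
top_prediction <- function(v) {
  if (length(v) != 20 || any(!is.finite(v)))
    stop_resstack("resstack_value_error",
                  "need a finite probability vector of length 20")
  i <- which.max(v)
  list(aa = aa_alphabet()[i], confidence = v[i])
}

# vectorized argmax over a site x 20 matrix; first (= alphabetical) winner
top_predictions <- function(probs) {
  idx <- max.col(probs, ties.method = "first")
  list(aa = aa_alphabet()[idx],
       confidence = probs[cbind(seq_len(nrow(probs)), idx)])
}

# join predictions to labels; one row per (model, site) with correctness.
# Sites whose wildtype is outside the canonical alphabet (e.g. X) are
# excluded from all evaluation, with a message.
correctness_table <- function(pset, labels) {
  labels <- as.data.table(labels)
  bad <- !(labels$wt_aa %in% aa_alphabet())
  if (any(bad)) {
    message(sprintf("excluding %d site(s) with non-canonical wildtype",
                    sum(bad)))
    labels <- labels[!bad]
  }
  tp <- top_predictions(pset_prob_matrix(pset))
  pred <- data.table(protein_id = pset$protein_id, position = pset$position,
                     model_id = pset$model_id, top_aa = tp$aa,
                     confidence = tp$confidence)
  keep <- intersect(c("protein_id", "position", "wt_aa", "rsa", "aa_class",
                      "burial"), names(labels))
  out <- merge(pred, labels[, keep, with = FALSE],
               by = c("protein_id", "position"))
  out[, correct := top_aa == wt_aa]
  out
}

#' Per-protein prediction accuracy
#'
#' Accuracy is the fraction of a protein's sites at which the model's top
#' prediction equals the wildtype (masked) amino acid.
#'
#' @param pset a [prediction_set()].
#' @param labels site table with `protein_id`, `position`, `wt_aa`.
#' @param model_id,protein_id for [protein_accuracy()], the single model and
#'   protein to score.
#' @return [per_protein_accuracy()]: data.table with one row per
#'   (model, protein): `accuracy`, `n_correct`, `n_sites`.
#'   [protein_accuracy()]: list with `accuracy`, `n_correct`, `n_sites`
#'   (accuracy `NA` with a warning if no site is evaluable).
#' @export
per_protein_accuracy <- function(pset, labels) {
  ct <- correctness_table(pset, labels)
  ct[, list(accuracy = mean(correct), n_correct = sum(correct),
            n_sites = .N),
     by = c("model_id", "protein_id")]
}

#' @rdname per_protein_accuracy
#' @export
protein_accuracy <- function(pset, labels, model_id, protein_id) {
  sel_model <- model_id; sel_prot <- protein_id
  sub <- pset[pset$model_id == sel_model & pset$protein_id == sel_prot]
  labels <- as.data.table(labels)
  labels <- labels[labels$protein_id == sel_prot]
  if (nrow(sub) == 0 || nrow(labels) == 0 ||
      !any(labels$wt_aa %in% aa_alphabet())) {
    warning(sprintf("no evaluable sites for (%s, %s)", sel_model, sel_prot),
            call. = FALSE)
    return(list(accuracy = NA_real_, n_correct = 0L, n_sites = 0L))
  }
  ct <- correctness_table(as_prediction_set(sub), labels)
  list(accuracy = mean(ct$correct), n_correct = sum(ct$correct),
       n_sites = nrow(ct))
}

#' Pooled per-class accuracy
#'
#' Pools sites across all proteins and reports the fraction correct within
#' each amino-acid class. Classes with zero sites get `NA` accuracy.
#'
#' @inheritParams per_protein_accuracy
#' @param model_id model to score.
#' @param class_map amino-acid class map (default [aa_class_map()]).
#' @return data.table: `model_id`, `class`, `accuracy`, `n_correct`,
#'   `n_sites`.
#' @export
class_accuracy <- function(pset, labels, model_id, class_map = aa_class_map()) {
  class_map <- check_class_map(class_map)
  sel <- model_id
  sub <- as_prediction_set(pset[pset$model_id == sel])
  ct <- correctness_table(sub, labels)
  ct[, cls := unname(class_map[wt_aa])]
  agg <- ct[, list(accuracy = mean(correct), n_correct = sum(correct),
                   n_sites = .N), by = "cls"]
  out <- merge(data.table(cls = aa_class_labels()), agg, by = "cls",
               all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, n_correct = 0L)]
  out[, model_id := sel]
  data.table::setnames(out, "cls", "class")
  out[, c("model_id", "class", "accuracy", "n_correct", "n_sites"),
      with = FALSE][match(aa_class_labels(), class)]
}

#' Pearson correlation between two models' per-protein accuracies
#'
#' Standard product-moment r with a two-sided t-distribution p-value.
#'
#' @param acc_a,acc_b numeric vectors of per-protein accuracies over the same
#'   proteins, in the same order.
#' @return list with `r` and `p` (both `NA`, with a warning, if either
#'   vector is constant).
#' @export
accuracy_correlation <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    stop_resstack("resstack_input_error",
                  "accuracy vectors must cover the same proteins")
  if (length(acc_a) < 3)
    stop_resstack("resstack_input_error",
                  "need at least 3 proteins for a correlation")
  if (stats::sd(acc_a) == 0 || stats::sd(acc_b) == 0) {
    warning("correlation undefined for constant accuracy vector",
            call. = FALSE)
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(acc_a, acc_b, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# pairwise r/p matrices over the columns of a protein x model accuracy matrix
accuracy_correlation_matrix <- function(acc_mat) {
  models <- colnames(acc_mat)
  k <- length(models)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(models, models))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    rp <- tryCatch(
      suppressWarnings(accuracy_correlation(acc_mat[, i], acc_mat[, j])),
      resstack_input_error = function(e) list(r = NA_real_, p = NA_real_))
    if (is.na(rp$r))
      warning(sprintf("correlation (%s, %s) undefined", models[i], models[j]),
              call. = FALSE)
    r[i, j] <- r[j, i] <- rp$r
    p[i, j] <- p[j, i] <- rp$p
  }
  list(r = r, p = p)
}

agreement_labels <- function() {
  c("ALL", "SEQUENCE_ONLY", "STRUCTURE_ONLY", "MIXED", "NONE")
}

#' Classify a site's model agreement
#'
#' A site is classified by which of the four individual models' top
#' predictions match the combined model's top prediction: all four `ALL`,
#' none `NONE`, a nonempty subset of the sequence pair `SEQUENCE_ONLY`, of
#' the structure pair `STRUCTURE_ONLY`, and any mix of types `MIXED`. The
#' exact agreeing subset is returned alongside the label so finer groupings
#' can be derived by relabeling.
#'
#' @param individual_tops named character vector: the four models' top amino
#'   acids.
#' @param combined_top the combined model's top amino acid.
#' @param model_types named character vector mapping each model id to
#'   `"structure"` or `"sequence"`.
#' @return list with `label` and `agreeing_models`.
#' @export
classify_agreement <- function(individual_tops, combined_top, model_types) {
  ids <- names(individual_tops)
  if (length(ids) != 4 || !all(ids %in% names(model_types)))
    stop_resstack("resstack_config_error",
                  "need four model tops with known model types")
  types <- model_types[ids]
  if (!all(types %in% c("structure", "sequence")))
    stop_resstack("resstack_config_error", "unknown model type: %s",
                  paste(setdiff(types, c("structure", "sequence")),
                        collapse = ", "))
  agree <- ids[individual_tops == combined_top]
  list(label = agreement_label_for(agree, ids, types),
       agreeing_models = agree)
}

agreement_label_for <- function(agree, ids, types) {
  if (length(agree) == 4) return("ALL")
  if (length(agree) == 0) return("NONE")
  at <- types[match(agree, ids)]
  if (all(at == "sequence")) return("SEQUENCE_ONLY")
  if (all(at == "structure")) return("STRUCTURE_ONLY")
  "MIXED"
}

#' Agreement-category summary
#'
#' For every site, classifies the agreement between the combined model and
#' the four individual models ([classify_agreement()]), then reports per
#' category the combined model's accuracy against the wildtype, the
#' proportion of sites, and the count. Proportions sum to 1.
#'
#' @param pset a [prediction_set()] containing the four individual models and
#'   the combined model.
#' @param labels site table.
#' @param model_types named character vector typing the four individual
#'   models.
#' @param combined_id model id of the combined model (default "combined").
#' @return data.table: `category`, `accuracy`, `proportion`, `n_sites`.
#' @export
agreement_summary <- function(pset, labels, model_types,
                              combined_id = "combined") {
  models <- pset_models(pset)
  indiv <- setdiff(models, combined_id)
  if (!combined_id %in% models || length(indiv) != 4)
    stop_resstack("resstack_input_error",
                  "need the combined model plus exactly 4 individual models")
  ct <- correctness_table(pset, labels)
  wide <- data.table::dcast(ct, protein_id + position + wt_aa ~ model_id,
                            value.var = "top_aa")
  wide <- wide[stats::complete.cases(wide)]
  types <- model_types[indiv]
  seq_ids <- indiv[types == "sequence"]
  str_ids <- indiv[types == "structure"]
  comb <- wide[[combined_id]]
  n_agree <- function(ids) rowSums(matrix(
    vapply(ids, function(m) wide[[m]] == comb, logical(nrow(wide))),
    nrow = nrow(wide)))
  seq_n <- n_agree(seq_ids)
  str_n <- n_agree(str_ids)
  label <- ifelse(seq_n + str_n == 4, "ALL",
           ifelse(seq_n + str_n == 0, "NONE",
           ifelse(str_n == 0, "SEQUENCE_ONLY",
           ifelse(seq_n == 0, "STRUCTURE_ONLY", "MIXED"))))
  res <- data.table(category = label, correct = comb == wide$wt_aa)
  agg <- res[, list(accuracy = mean(correct), n_sites = .N), by = "category"]
  agg[, proportion := n_sites / sum(n_sites)]
  out <- merge(data.table(category = agreement_labels()), agg,
               by = "category", all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, proportion = 0)]
  out[match(agreement_labels(), category),
      c("category", "accuracy", "proportion", "n_sites"), with = FALSE]
}

#' 2D histogram of confidence versus relative solvent accessibility
#'
#' Bins sites into a half-open (RSA, confidence) grid (last bin closed) and
#' labels each populated cell with the count band used to color such plots:
#' 1-25, 26-50, 51-75 or >75 sites per cell.
#'
#' @param rsa,confidence numeric vectors, one value per site; sites with
#'   missing RSA are skipped (with a message giving the count).
#' @param rsa_bin_width,confidence_bin_width bin widths (default 0.05).
#' @return data.table: `rsa_lo`, `rsa_hi`, `conf_lo`, `conf_hi`, `count`,
#'   `band`; only populated cells are listed, and counts sum to the number
#'   of evaluable sites.
#' @export
rsa_confidence_histogram <- function(rsa, confidence, rsa_bin_width = 0.05,
                                     confidence_bin_width = 0.05) {
  stopifnot(length(rsa) == length(confidence))
  drop <- is.na(rsa)
  if (any(drop)) {
    message(sprintf("skipping %d site(s) without RSA", sum(drop)))
    rsa <- rsa[!drop]; confidence <- confidence[!drop]
  }
  # half-open [lo, hi) bins; for confidence the natural domain top is 1, and
  # the last bin is closed there so confidence exactly 1 is not orphaned
  bin <- function(x, w, domain_top = NULL) {
    idx <- pmax(0L, floor(x / w + 1e-9))  # guard fp edges like 0.95/0.05
    if (!is.null(domain_top)) {
      top_bin <- ceiling(domain_top / w) - 1L
      idx <- pmin(idx, top_bin)
    }
    idx
  }
  i_rsa <- bin(rsa, rsa_bin_width)
  i_conf <- bin(confidence, confidence_bin_width, domain_top = 1)
  dt <- data.table(i_rsa = i_rsa, i_conf = i_conf)
  agg <- dt[, list(count = .N), by = c("i_rsa", "i_conf")]
  agg[, `:=`(rsa_lo = i_rsa * rsa_bin_width,
             rsa_hi = (i_rsa + 1) * rsa_bin_width,
             conf_lo = i_conf * confidence_bin_width,
             conf_hi = (i_conf + 1) * confidence_bin_width)]
  agg[, band := cut(count, breaks = c(0, 25, 50, 75, Inf),
                    labels = c("1-25", "26-50", "51-75", ">75"))]
  data.table::setorder(agg, i_rsa, i_conf)
  agg[, c("rsa_lo", "rsa_hi", "conf_lo", "conf_hi", "count", "band"),
      with = FALSE]
}
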