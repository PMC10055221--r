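#' Define a simulated predictor's skill profile
#'
#' A skill profile describes one simulated masked-residue predictor: its
#' probability of calling the wildtype amino acid correctly as a function of
#' amino-acid class and burial state, the Beta distributions its top-rank
#' confidence is drawn from (one for correct calls, one for wrong calls), and
#' a per-class kernel over decoy amino acids used when it is wrong.
#'
#' @param model_id identifier string.
#' @param model_type `"structure"` or `"sequence"`; models of the same type
#'   share correlated correctness latents in [simulate_panel()].
#' @param skill 6 x 2 numeric matrix in `[0, 1]`; rows named by
#'   [aa_class_labels()], columns `buried`, `exposed`.
#' @param confidence_when_correct,confidence_when_wrong length-2 numeric
#'   `(alpha, beta)` Beta parameters for the top-probability draw. The
#'   defaults overlap substantially (means 0.70 and 0.59, with the correct
#'   distribution stochastically larger): real predictors are overconfident
#'   when wrong, and a wide separation here would make naive probability
#'   averaging trivially near-perfect, the opposite of how such panels
#'   behave.
#' @param decoy_kernel 6 x 20 matrix (rows: class of the true amino acid,
#'   columns: [aa_alphabet()]), each row a distribution over decoys; the true
#'   amino acid's entry is zeroed and the row renormalized at sampling time.
#'   Default: same-class decoys weighted 3x over other amino acids.
#' @return object of class `skill_profile`.
#' @export
skill_profile <- function(model_id, model_type, skill,
                          confidence_when_correct = c(7, 3),
                          confidence_when_wrong = c(5, 3.5),
                          decoy_kernel = default_decoy_kernel()) {
  if (!model_type %in% c("structure", "sequence"))
    stop_resstack("resstack_config_error",
                  "model_type must be 'structure' or 'sequence'")
  skill <- as.matrix(skill)
  if (!all(aa_class_labels() %in% rownames(skill)) ||
      !all(c("buried", "exposed") %in% colnames(skill)))
    stop_resstack("resstack_config_error",
                  "skill matrix needs rows %s and columns buried/exposed",
                  paste(aa_class_labels(), collapse = ","))
  skill <- skill[aa_class_labels(), c("buried", "exposed")]
  if (any(!is.finite(skill)) || any(skill < 0) || any(skill > 1))
    stop_resstack("resstack_config_error", "skill entries must lie in [0,1]")
  for (p in list(confidence_when_correct, confidence_when_wrong))
    if (length(p) != 2 || any(!is.finite(p)) || any(p <= 0))
      stop_resstack("resstack_config_error",
                    "confidence Beta parameters must be positive")
  decoy_kernel <- as.matrix(decoy_kernel)[aa_class_labels(), aa_alphabet()]
  if (any(decoy_kernel < 0) ||
      any(abs(rowSums(decoy_kernel) - 1) > 1e-9))
    stop_resstack("resstack_config_error",
                  "decoy kernel rows must be distributions")
  structure(list(model_id = model_id, model_type = model_type, skill = skill,
                 confidence_when_correct = confidence_when_correct,
                 confidence_when_wrong = confidence_when_wrong,
                 decoy_kernel = decoy_kernel),
            class = "skill_profile")
}

#' @rdname skill_profile
#' @export
default_decoy_kernel <- function() {
  cmap <- aa_class_map()
  k <- matrix(1, nrow = 6, ncol = 20,
              dimnames = list(aa_class_labels(), aa_alphabet()))
  for (cl in aa_class_labels()) k[cl, cmap == cl] <- 3
  k / rowSums(k)
}

#' Flat class-independent skill matrix
#'
#' Convenience constructor for [skill_profile()]: the same correct-call
#' probability for every amino-acid class, optionally different between
#' buried and exposed sites.
#'
#' @param buried,exposed correct-call probabilities in `[0, 1]`.
#' @return 6 x 2 matrix suitable for `skill_profile(skill = ...)`.
#' @export
uniform_skill <- function(buried, exposed = buried) {
  matrix(c(rep(buried, 6), rep(exposed, 6)), ncol = 2,
         dimnames = list(aa_class_labels(), c("buried", "exposed")))
}

# archetype class x burial skill shapes: structure models are strong on
# buried hydrophobics and G/P, sequence models on polar/charged surface sites
base_skill_structure <- function() {
  rbind(aliphatic = c(0.85, 0.55), aromatic = c(0.75, 0.55),
        polar = c(0.52, 0.42), positive = c(0.48, 0.42),
        negative = c(0.48, 0.42), unique = c(0.85, 0.70)) |>
    (\(m) { colnames(m) <- c("buried", "exposed"); m })()
}

base_skill_sequence <- function() {
  rbind(aliphatic = c(0.64, 0.54), aromatic = c(0.64, 0.58),
        polar = c(0.65, 0.62), positive = c(0.70, 0.66),
        negative = c(0.70, 0.66), unique = c(0.60, 0.55)) |>
    (\(m) { colnames(m) <- c("buried", "exposed"); m })()
}

#' Configure a synthetic predictor panel
#'
#' Bundles four [skill_profile()]s (two structure-type, two sequence-type)
#' with the site-generation model: a two-component Beta mixture for relative
#' solvent accessibility (RSA), a burial threshold splitting sites into
#' buried/exposed, per-burial amino-acid composition, and the within-type
#' latent-sharing weights that induce correlated correctness between models
#' of the same type.
#'
#' @param profiles list of four skill profiles, two per model type.
#' @param rho_within_type named numeric, latent-sharing weight in `[0,1]` for
#'   `structure` and `sequence` pairs (0 = independent, 1 = comonotone).
#' @param burial_threshold RSA below this is "buried" (default 0.2).
#' @param rsa_mixture list with `weights`, `shape1`, `shape2` and optional
#'   `point` (per-component point mass overriding the Beta draw).
#' @param composition 20 x 2 matrix of amino-acid frequencies, columns
#'   `buried` and `exposed`, each summing to 1.
#' @param protein_length_range integer `(min, max)` protein lengths.
#' @return object of class `panel_config`.
#' @seealso [default_panel_config()] for the calibrated defaults.
#' @export
panel_config <- function(profiles,
                         rho_within_type = c(structure = 0.85, sequence = 0.6),
                         burial_threshold = 0.2,
                         rsa_mixture = default_rsa_mixture(),
                         composition = default_composition(),
                         protein_length_range = c(80L, 250L)) {
  types <- vapply(profiles, function(p) p$model_type, character(1))
  ids <- vapply(profiles, function(p) p$model_id, character(1))
  if (length(profiles) != 4 || sum(types == "structure") != 2 ||
      sum(types == "sequence") != 2 || anyDuplicated(ids) > 0)
    stop_resstack("resstack_config_error",
                  "panel needs 4 uniquely named profiles, 2 per model type")
  if (!all(c("structure", "sequence") %in% names(rho_within_type)) ||
      any(rho_within_type < 0) || any(rho_within_type > 1))
    stop_resstack("resstack_config_error",
                  "rho_within_type needs structure/sequence entries in [0,1]")
  w <- rsa_mixture$weights
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
    stop_resstack("resstack_config_error", "invalid RSA mixture weights")
  rsa_mixture$weights <- w / sum(w)
  rsa_mixture$point <- rsa_mixture$point %||% rep(NA_real_, length(w))
  composition <- as.matrix(composition)[aa_alphabet(), c("buried", "exposed")]
  if (any(composition < 0) || any(abs(colSums(composition) - 1) > 1e-9))
    stop_resstack("resstack_config_error",
                  "composition columns must sum to 1")
  names(profiles) <- ids
  structure(list(profiles = profiles,
                 rho_within_type = rho_within_type[c("structure", "sequence")],
                 burial_threshold = burial_threshold,
                 rsa_mixture = rsa_mixture, composition = composition,
                 protein_length_range = as.integer(protein_length_range)),
            class = "panel_config")
}

#' @rdname panel_config
#' @export
default_rsa_mixture <- function() {
  list(weights = c(0.45, 0.55), shape1 = c(0.6, 2.5), shape2 = c(8, 3.5),
       point = c(NA_real_, NA_real_))
}

#' @rdname panel_config
#' @export
default_composition <- function() {
  w_bur <- c(A = 9, C = 2.5, D = 2, E = 2, F = 6, G = 8, H = 1.5, I = 8,
             K = 1.5, L = 12, M = 3.5, N = 2, P = 3, Q = 1.5, R = 2, S = 4,
             T = 4, V = 9, W = 2.5, Y = 4)
  w_exp <- c(A = 6, C = 0.8, D = 8, E = 9, F = 2, G = 7, H = 3, I = 3,
             K = 8, L = 5, M = 1.5, N = 6, P = 6, Q = 5.5, R = 7, S = 8,
             T = 7, V = 4, W = 0.8, Y = 3)
  cbind(buried = w_bur[aa_alphabet()] / sum(w_bur),
        exposed = w_exp[aa_alphabet()] / sum(w_exp))
}

#' Calibrated default panel
#'
#' Four simulated predictors whose expected mean per-protein accuracies are
#' calibrated (analytically, via the blended-latent threshold CDF) to land
#' near 0.61, 0.64, 0.65 and 0.68 for `seq_a`, `struct_a`, `struct_b` and
#' `seq_b` respectively, with the structure pair strongly correlated
#' (rho 0.85) and the sequence pair moderately correlated (rho 0.6).
#' Structure-type profiles are strongest on buried aliphatic/unique sites,
#' sequence-type profiles on polar and charged sites. Confidence profiles
#' are deliberately heterogeneous — the sequence pair outputs sharp,
#' near-one-hot distributions, the structure pair diffuse ones — mirroring
#' the calibration differences real predictor panels show; this is what
#' makes naive probability averaging collapse toward the sharpest model
#' instead of improving on it.
#'
#' @return a [panel_config()].
#' @export
default_panel_config <- function() {
  clamp01 <- function(m) pmin(pmax(m, 0.02), 0.98)
  panel_config(profiles = list(
    skill_profile("seq_a", "sequence",
                  clamp01(base_skill_sequence() - 0.058309),
                  confidence_when_correct = c(12, 2),
                  confidence_when_wrong = c(9, 3)),
    skill_profile("seq_b", "sequence",
                  clamp01(base_skill_sequence() - 0.015169),
                  confidence_when_correct = c(16, 1.5),
                  confidence_when_wrong = c(12, 2.5)),
    skill_profile("struct_a", "structure",
                  clamp01(base_skill_structure() + 0.005279),
                  confidence_when_correct = c(6, 3),
                  confidence_when_wrong = c(4, 4)),
    skill_profile("struct_b", "structure",
                  clamp01(base_skill_structure() + 0.013940),
                  confidence_when_correct = c(8, 3),
                  confidence_when_wrong = c(5, 3.5))))
}

#' Complementary-skill variant of the default panel
#'
#' The default panel with every skill matrix replaced by a flat
#' class-independent pattern: structure-type models get `skill_buried` on
#' buried sites and `skill_exposed` on exposed ones, sequence-type models
#' the reverse. With the defaults (0.9/0.3) each model's overall accuracy is
#' about 0.6 while a context-aware combination has enough information to
#' exceed 0.8 — the cleanest setting in which stacking must dominate both
#' individual models and naive ensembles.
#'
#' @param skill_buried,skill_exposed structure-type skill on buried and
#'   exposed sites (sequence-type swaps them).
#' @return a [panel_config()].
#' @export
complementary_panel_config <- function(skill_buried = 0.9,
                                       skill_exposed = 0.3) {
  cfg <- default_panel_config()
  for (id in names(cfg$profiles)) {
    ty <- cfg$profiles[[id]]$model_type
    cfg$profiles[[id]]$skill <- if (ty == "structure")
      uniform_skill(skill_buried, skill_exposed)
    else uniform_skill(skill_exposed, skill_buried)
  }
  cfg
}

sample_rsa <- function(mix, n) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  r <- numeric(n)
  for (k in seq_along(mix$weights)) {
    idx <- comp == k
    if (!any(idx)) next
    if (is.finite(mix$point[k])) {
      r[idx] <- mix$point[k]
    } else {
      if (mix$shape1[k] <= 0 || mix$shape2[k] <= 0)
        stop_resstack("resstack_config_error",
                      "RSA mixture component %d has nonpositive shape", k)
      r[idx] <- stats::rbeta(sum(idx), mix$shape1[k], mix$shape2[k])
    }
  }
  r
}

#' Generate one synthetic protein
#'
#' Draws per-site RSA from the configured Beta mixture, assigns burial by
#' threshold, then draws each wildtype amino acid from the per-burial
#' composition. The returned site table carries everything downstream
#' evaluation needs (wildtype, RSA, class, burial).
#'
#' @param config a [panel_config()].
#' @param protein_id id string for the generated protein.
#' @param length number of residues; must lie in
#'   `config$protein_length_range`.
#' @param seed integer RNG seed for this protein's label stream.
#' @param class_map amino-acid class map (default [aa_class_map()]).
#' @return list with `sequence` (string) and `sites` (data.table:
#'   protein_id, position, wt_aa, rsa, aa_class, burial).
#' @export
generate_protein <- function(config, protein_id, length, seed,
                             class_map = aa_class_map()) {
  rng <- config$protein_length_range
  if (length < rng[1] || length > rng[2])
    stop_resstack("resstack_config_error",
                  "length %d outside configured range [%d, %d]",
                  length, rng[1], rng[2])
  class_map <- check_class_map(class_map)
  with_stream(seed, {
    rsa <- sample_rsa(config$rsa_mixture, length)
    burial <- ifelse(rsa < config$burial_threshold, "buried", "exposed")
    wt <- character(length)
    for (b in c("buried", "exposed")) {
      idx <- burial == b
      if (any(idx))
        wt[idx] <- sample(aa_alphabet(), sum(idx), replace = TRUE,
                          prob = config$composition[, b])
    }
    list(sequence = paste0(wt, collapse = ""),
         sites = data.table(protein_id = protein_id,
                            position = seq_len(length), wt_aa = wt,
                            rsa = rsa, aa_class = unname(class_map[wt]),
                            burial = burial))
  })
}

#' Simulate one predictor over a set of sites
#'
#' Correctness at each site is decided by thresholding a blended latent
#' `v = rho * u + (1 - rho) * w` against the profile's skill for the site's
#' (class, burial) cell, where `u` is the shared per-type latent and `w` a
#' fresh uniform draw. A correct call puts a Beta-drawn top probability on
#' the wildtype amino acid; a wrong call puts it on a decoy drawn from the
#' profile's class-conditional decoy kernel. The remaining mass is spread
#' uniformly over the other 19 amino acids. Top probabilities are floored at
#' 0.1 so the intended top entry is always the argmax. Note that for
#' `0 < rho < 1` the blend `v` is not uniform, so the realized accuracy is
#' the blend CDF evaluated at the skill value, slightly compressing extreme
#' skills toward the middle; the shipped defaults are calibrated through that
#' CDF.
#'
#' @param sites site table from [generate_protein()] (needs wt_aa, aa_class,
#'   rsa columns).
#' @param profile a [skill_profile()].
#' @param shared_latents numeric vector of per-site shared uniforms (one per
#'   site), or NULL to draw fresh ones (equivalent to rho = 0).
#' @param shared_decoy_latents optional second shared uniform vector driving
#'   decoy choice through the same blend, so that two models of a type that
#'   are wrong together also tend to pick the same wrong amino acid (same-
#'   type predictors make correlated mistakes; without this, cross-model
#'   agreement would be a near-infallible correctness signal and naive
#'   probability averaging would be close to unbeatable, unlike real
#'   panels). NULL draws private uniforms.
#' @param rho latent-sharing weight in `[0, 1]`.
#' @param seed integer seed for this model's private stream.
#' @param burial_threshold RSA cutoff (default 0.2).
#' @return numeric matrix, one row per site, 20 columns in [aa_alphabet()]
#'   order; every row a probability distribution.
#' @export
simulate_predictor <- function(sites, profile, shared_latents = NULL,
                               shared_decoy_latents = NULL, rho = 0,
                               seed = 1L, burial_threshold = 0.2) {
  n <- nrow(sites)
  burial <- if ("burial" %in% names(sites)) sites$burial
            else ifelse(sites$rsa < burial_threshold, "buried", "exposed")
  cells <- cbind(match(sites$aa_class, rownames(profile$skill)),
                 match(burial, colnames(profile$skill)))
  if (anyNA(cells))
    stop_resstack("resstack_config_error",
                  "skill matrix missing a (class, burial) cell used by sites")
  p_skill <- profile$skill[cells]
  with_stream(seed, {
    w <- stats::runif(n)
    u <- if (is.null(shared_latents)) stats::runif(n) else shared_latents
    if (length(u) != n)
      stop_resstack("resstack_config_error",
                    "shared_latents must have one draw per site")
    v <- rho * u + (1 - rho) * w
    correct <- v < p_skill
    conf_c <- stats::rbeta(n, profile$confidence_when_correct[1],
                           profile$confidence_when_correct[2])
    conf_w <- stats::rbeta(n, profile$confidence_when_wrong[1],
                           profile$confidence_when_wrong[2])
    w_decoy <- stats::runif(n)
    u_decoy <- if (is.null(shared_decoy_latents)) w_decoy
               else rho * shared_decoy_latents + (1 - rho) * w_decoy
    conf <- pmax(ifelse(correct, conf_c, conf_w), 0.1)
    wt_idx <- match(sites$wt_aa, aa_alphabet())
    top_idx <- wt_idx
    for (i in which(!correct)) {
      kern <- profile$decoy_kernel[sites$aa_class[i], ]
      kern[wt_idx[i]] <- 0
      kern <- cumsum(kern / sum(kern))
      top_idx[i] <- min(findInterval(u_decoy[i], kern) + 1L, 20L)
    }
    probs <- matrix((1 - conf) / 19, nrow = n, ncol = 20)
    probs[cbind(seq_len(n), top_idx)] <- conf
    colnames(probs) <- aa_alphabet()
    probs
  })
}

#' Simulate a full four-predictor panel
#'
#' Generates `n_proteins` labeled proteins and the four predictors' 20-way
#' probability outputs at every site. Models of the same type share per-site
#' correctness latents with weight `rho_within_type` for their type; there is
#' no latent sharing across types. All randomness derives deterministically
#' from `seed` through named substreams — one per (model, protein), one per
#' (type, protein) for the shared latents, and one per protein for labels —
#' so identical seeds give bitwise-identical output and adding a model never
#' perturbs the others.
#'
#' @param config a [panel_config()].
#' @param n_proteins number of proteins to generate.
#' @param seed integer master seed.
#' @param class_map amino-acid class map.
#' @return list with `pset` (a [prediction_set()] over the four models) and
#'   `labels` (row-bound site tables from [generate_protein()]).
#' @export
simulate_panel <- function(config, n_proteins, seed = 1L,
                           class_map = aa_class_map()) {
  if (!is_count(n_proteins))
    stop_resstack("resstack_config_error", "n_proteins must be >= 1")
  rng <- config$protein_length_range
  lengths <- with_stream(hash_seed(seed, "lengths"),
                         rng[1] - 1L + sample.int(rng[2] - rng[1] + 1L,
                                                  n_proteins, replace = TRUE))
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  label_list <- vector("list", n_proteins)
  pred_list <- vector("list", n_proteins)
  for (p in seq_len(n_proteins)) {
    gp <- generate_protein(config, ids[p], lengths[p],
                           seed = hash_seed(seed, "labels", ids[p]),
                           class_map = class_map)
    label_list[[p]] <- gp$sites
    latents <- lapply(
      c(structure = "structure", sequence = "sequence"),
      function(ty) list(
        coin = with_stream(hash_seed(seed, "latent", ty, ids[p]),
                           stats::runif(lengths[p])),
        decoy = with_stream(hash_seed(seed, "latent_decoy", ty, ids[p]),
                            stats::runif(lengths[p]))))
    per_model <- lapply(config$profiles, function(prof) {
      probs <- simulate_predictor(
        gp$sites, prof,
        shared_latents = latents[[prof$model_type]]$coin,
        shared_decoy_latents = latents[[prof$model_type]]$decoy,
        rho = config$rho_within_type[[prof$model_type]],
        seed = hash_seed(seed, "model", prof$model_id, ids[p]),
        burial_threshold = config$burial_threshold)
      prediction_set(gp$sites$protein_id, gp$sites$position,
                     prof$model_id, probs)
    })
    pred_list[[p]] <- data.table::rbindlist(per_model)
  }
  list(pset = as_prediction_set(data.table::rbindlist(pred_list)),
       labels = data.table::rbindlist(label_list))
}

#' Summarize a simulated panel
#'
#' Calibration readout: mean per-protein accuracy per model, the pairwise
#' Pearson correlation matrix of per-protein accuracies, and pooled per-class
#' accuracies. Correlations that are undefined (constant accuracy vectors,
#' or fewer than 3 proteins) are reported as `NA` with a warning.
#'
#' @param pset a [prediction_set()].
#' @param labels matching site table.
#' @param class_map amino-acid class map.
#' @return list with `mean_accuracy`, `per_protein`, `correlation` (list of
#'   matrices `r`, `p`), `per_class`.
#' @export
panel_summary <- function(pset, labels, class_map = aa_class_map()) {
  models <- pset_models(pset)
  pp <- per_protein_accuracy(pset, labels)
  acc_mat <- as.matrix(data.table::dcast(
    pp, protein_id ~ model_id, value.var = "accuracy"), rownames = "protein_id")
  mean_acc <- colMeans(acc_mat)[models]
  corr <- accuracy_correlation_matrix(acc_mat)
  per_class <- data.table::rbindlist(lapply(models, function(m)
    class_accuracy(pset, labels, m, class_map)))
  list(mean_accuracy = mean_acc, per_protein = pp, correlation = corr,
       per_class = per_class)
}
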