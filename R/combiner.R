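#' Training configuration for the stacking network
#'
#' The stacking network is trained with Adam on categorical cross-entropy at
#' a fixed learning rate for a fixed number of epochs; there is no validation
#' split or early stopping. Loss and optimizer are fixed; only the scalars
#' below are tunable.
#'
#' @param learning_rate fixed Adam step size (default 1e-4).
#' @param epochs number of passes over the training sites (default 150).
#' @param batch_size minibatch size (default 128); batches are drawn from a
#'   global per-epoch shuffle of all sites across proteins.
#' @param seed integer seed driving weight initialization and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 150L,
                         batch_size = 128L, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_resstack("resstack_config_error", "learning_rate must be > 0")
  if (!is_count(epochs) || !is_count(batch_size))
    stop_resstack("resstack_config_error",
                  "epochs and batch_size must be integers >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = "categorical_crossentropy",
                 optimizer = list(name = "adam", beta1 = 0.9, beta2 = 0.999,
                                  eps = 1e-8)),
            class = "train_config")
}

combiner_dims <- function() c(80L, 120L, 60L, 20L)

new_combiner_params <- function(W1, b1, W2, b2, W3, b3, model_order) {
  d <- combiner_dims()
  shapes_ok <- all(dim(W1) == d[1:2]) && length(b1) == d[2] &&
    all(dim(W2) == d[2:3]) && length(b2) == d[3] &&
    all(dim(W3) == d[3:4]) && length(b3) == d[4]
  if (!shapes_ok)
    stop_resstack("resstack_shape_error",
                  "combiner weights must have shapes 80x120/120x60/60x20")
  if (length(model_order) != 4 || anyDuplicated(model_order) > 0)
    stop_resstack("resstack_config_error",
                  "model_order must list exactly 4 distinct model ids")
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
                 W3 = W3, b3 = as.numeric(b3),
                 model_order = as.character(model_order),
                 alphabet = aa_alphabet()),
            class = "combiner_params")
}

#' @export
print.combiner_params <- function(x, ...) {
  cat(sprintf("<combiner_params> 80-120-60-20, model order: %s\n",
              paste(x$model_order, collapse = " ")))
  invisible(x)
}

# He-style uniform init, all draws from one seeded stream
init_combiner_params <- function(model_order, seed) {
  d <- combiner_dims()
  with_stream(seed, {
    mats <- lapply(1:3, function(k) {
      lim <- sqrt(6 / d[k])
      matrix(stats::runif(d[k] * d[k + 1], -lim, lim), d[k], d[k + 1])
    })
    new_combiner_params(mats[[1]], numeric(d[2]), mats[[2]], numeric(d[3]),
                        mats[[3]], numeric(d[4]), model_order)
  })
}

#' Concatenate four model outputs into the stacking input
#'
#' Builds the 80-component input vector by concatenating the four models'
#' 20-way probability vectors in `model_order`: components `20k ... 20k+19`
#' hold the k-th model's vector.
#'
#' @param site_vectors named list of four 20-vectors, one per model id.
#' @param model_order character vector of exactly the four expected ids.
#' @return numeric vector of length 80.
#' @export
concat_inputs <- function(site_vectors, model_order) {
  extra <- setdiff(names(site_vectors), model_order)
  miss <- setdiff(model_order, names(site_vectors))
  if (length(extra) > 0 || length(miss) > 0)
    stop_resstack("resstack_input_error",
                  "model ids do not match model_order (missing: %s; extra: %s)",
                  paste(miss, collapse = ","), paste(extra, collapse = ","))
  unlist(site_vectors[model_order], use.names = FALSE)
}

relu <- function(x) (x + abs(x)) / 2

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# batched forward pass; x is n x 80
forward_matrix <- function(params, x) {
  h1 <- relu(x %*% params$W1 + rep(params$b1, each = nrow(x)))
  h2 <- relu(h1 %*% params$W2 + rep(params$b2, each = nrow(x)))
  softmax_rows(h2 %*% params$W3 + rep(params$b3, each = nrow(x)))
}

#' Forward pass of the stacking network
#'
#' `y = softmax(W3 relu(W2 relu(W1 x + b1) + b2) + b3)`: two hidden relu
#' layers of 120 and 60 nodes and a 20-way softmax output.
#'
#' @param params a `combiner_params` object.
#' @param x numeric vector of length 80 (see [concat_inputs()]).
#' @return probability vector of length 20 in [aa_alphabet()] order.
#' @export
forward <- function(params, x) {
  if (length(x) != 80 || any(!is.finite(x)))
    stop_resstack("resstack_shape_error", "input must be a finite 80-vector")
  drop(forward_matrix(params, matrix(x, nrow = 1)))
}

# cross-entropy loss and analytic gradients for a batch.
# X: n x 80, Yidx: integer targets in 1..20
combiner_loss_grad <- function(params, X, Yidx) {
  n <- nrow(X)
  z1 <- X %*% params$W1 + rep(params$b1, each = n); h1 <- relu(z1)
  z2 <- h1 %*% params$W2 + rep(params$b2, each = n); h2 <- relu(z2)
  z3 <- h2 %*% params$W3 + rep(params$b3, each = n)
  p <- softmax_rows(z3)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), Yidx)], 1e-12)))
  d3 <- p
  d3[cbind(seq_len(n), Yidx)] <- d3[cbind(seq_len(n), Yidx)] - 1
  d3 <- d3 / n
  dh2 <- d3 %*% t(params$W3)
  d2 <- dh2 * (h2 > 0)
  dh1 <- d2 %*% t(params$W2)
  d1 <- dh1 * (h1 > 0)
  list(loss = loss,
       grads = list(W1 = crossprod(X, d1), b1 = colSums(d1),
                    W2 = crossprod(h1, d2), b2 = colSums(d2),
                    W3 = crossprod(h2, d3), b3 = colSums(d3)))
}

#' Train the stacking network
#'
#' One training example per site: the input is the four models'
#' probabilities concatenated in `model_order` (alphabetical by model id)
#' and the target is the one-hot wildtype amino acid. Trains for exactly
#' `cfg$epochs` epochs of Adam minibatch steps on categorical cross-entropy;
#' fully deterministic given `cfg$seed` (initialization and per-epoch
#' shuffles both derive from it).
#'
#' @param pset a [prediction_set()] with exactly four models covering every
#'   label site.
#' @param labels site table with `protein_id`, `position`, `wt_aa`; sites
#'   with non-canonical wildtype are excluded.
#' @param cfg a [train_config()].
#' @return list with `params` (a `combiner_params`) and `loss_trace`
#'   (mean per-epoch training loss, length `cfg$epochs`).
#' @export
train_combiner <- function(pset, labels, cfg = train_config()) {
  xy <- build_training_matrix(pset, labels)
  n <- nrow(xy$X)
  if (n == 0)
    stop_resstack("resstack_input_error", "no training sites")
  params <- init_combiner_params(xy$model_order, cfg$seed)
  opt <- cfg$optimizer
  state <- list(m = lapply(params[1:6], function(p) p * 0),
                v = lapply(params[1:6], function(p) p * 0), t = 0)
  loss_trace <- numeric(cfg$epochs)
  with_stream(hash_seed(cfg$seed, "shuffle"), {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- idx[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
        lg <- combiner_loss_grad(params, xy$X[rows, , drop = FALSE],
                                 xy$Yidx[rows])
        if (!is.finite(lg$loss))
          stop_resstack("resstack_divergence_error",
                        "non-finite training loss at epoch %d", epoch)
        batch_losses[bi] <- lg$loss
        state$t <- state$t + 1
        bc1 <- 1 - opt$beta1^state$t
        bc2 <- 1 - opt$beta2^state$t
        for (nm in names(lg$grads)) {
          g <- lg$grads[[nm]]
          state$m[[nm]] <- opt$beta1 * state$m[[nm]] + (1 - opt$beta1) * g
          state$v[[nm]] <- opt$beta2 * state$v[[nm]] + (1 - opt$beta2) * g^2
          params[[nm]] <- params[[nm]] - cfg$learning_rate *
            (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + opt$eps)
        }
      }
      loss_trace[epoch] <- mean(batch_losses)
    }
  })
  list(params = params, loss_trace = loss_trace)
}

# align pset rows with labels and build the n x 80 input / target index
build_training_matrix <- function(pset, labels) {
  model_order <- pset_models(pset)
  if (length(model_order) != 4)
    stop_resstack("resstack_input_error",
                  "need exactly 4 models, got: %s",
                  paste(model_order, collapse = ", "))
  labels <- as.data.table(labels)
  labels <- labels[labels$wt_aa %in% aa_alphabet()]
  key <- labels[, c("protein_id", "position", "wt_aa")]
  blocks <- lapply(model_order, function(m) {
    sub <- pset[pset$model_id == m]
    mg <- merge(key, sub, by = c("protein_id", "position"), sort = TRUE)
    if (nrow(mg) < nrow(key))
      stop_resstack("resstack_input_error",
                    "model %s is missing %d label site(s)", m,
                    nrow(key) - nrow(mg))
    mg
  })
  X <- do.call(cbind, lapply(blocks, function(b)
    as.matrix(b[, prob_cols(), with = FALSE])))
  list(X = X, Yidx = match(blocks[[1]]$wt_aa, aa_alphabet()),
       model_order = model_order,
       sites = blocks[[1]][, c("protein_id", "position"), with = FALSE])
}

#' Predict with a trained stacking network
#'
#' Concatenates each site's four input-model vectors in the stored
#' `model_order` and applies [forward()]; emits a prediction set with the
#' single model id `"combined"`.
#'
#' @param params a trained `combiner_params`.
#' @param pset a [prediction_set()] containing (at least) the four
#'   `model_order` models, complete over their common sites.
#' @param model_id output model id (default `"combined"`).
#' @return a [prediction_set()].
#' @export
predict_combined <- function(params, pset, model_id = "combined") {
  sub <- as_prediction_set(pset[pset$model_id %in% params$model_order])
  if (length(pset_models(sub)) != 4)
    stop_resstack("resstack_input_error",
                  "prediction set lacks the combiner's input models (%s)",
                  paste(params$model_order, collapse = ", "))
  blocks <- lapply(params$model_order, function(m) {
    b <- sub[sub$model_id == m]
    data.table::setorder(b, protein_id, position)
    b
  })
  ref <- blocks[[1]][, c("protein_id", "position"), with = FALSE]
  for (b in blocks[-1])
    if (!identical(ref, b[, c("protein_id", "position"), with = FALSE]))
      stop_resstack("resstack_input_error",
                    "input models do not cover identical sites")
  X <- do.call(cbind, lapply(blocks, function(b)
    as.matrix(b[, prob_cols(), with = FALSE])))
  prediction_set(ref$protein_id, ref$position, model_id,
                 forward_matrix(params, X))
}

#' Naive ensemble baselines
#'
#' `ensemble_average()` is the componentwise mean of the four probability
#' vectors. `ensemble_max()` predicts the amino acid attaining the single
#' highest probability across all 80 entries, with that probability as
#' confidence; ties break by alphabet order, then by position in
#' `site_vectors`. Neither baseline has trainable parameters.
#'
#' @param site_vectors list of four 20-way probability vectors.
#' @return `ensemble_average()`: a 20-vector. `ensemble_max()`: list with
#'   `aa` and `confidence`.
#' @export
ensemble_average <- function(site_vectors) {
  if (length(site_vectors) != 4)
    stop_resstack("resstack_input_error", "need exactly 4 model vectors")
  colMeans(do.call(rbind, site_vectors))
}

#' @rdname ensemble_average
#' @export
ensemble_max <- function(site_vectors) {
  if (length(site_vectors) != 4)
    stop_resstack("resstack_input_error", "need exactly 4 model vectors")
  m <- do.call(rbind, site_vectors)  # 4 x 20
  best_p <- apply(m, 2, max)
  aa_i <- which.max(best_p)  # alphabet-order tie break across amino acids
  list(aa = aa_alphabet()[aa_i], confidence = best_p[aa_i])
}

# matrix versions of the baselines over aligned per-model blocks
baseline_psets <- function(pset, model_order) {
  blocks <- lapply(model_order, function(m) {
    b <- pset[pset$model_id == m]
    data.table::setorder(b, protein_id, position)
    as.matrix(b[, prob_cols(), with = FALSE])
  })
  ref <- pset[pset$model_id == model_order[1]]
  data.table::setorder(ref, protein_id, position)
  avg <- Reduce(`+`, blocks) / length(blocks)
  pmax_mat <- Reduce(pmax, blocks)
  top <- max.col(pmax_mat, ties.method = "first")
  conf <- pmax_mat[cbind(seq_along(top), top)]
  vote <- matrix((1 - conf) / 19, nrow = length(top), ncol = 20)
  vote[cbind(seq_along(top), top)] <- conf
  list(average = prediction_set(ref$protein_id, ref$position,
                                "ensemble_average", avg),
       max_vote = prediction_set(ref$protein_id, ref$position,
                                 "ensemble_max", vote))
}

#' Save / load stacking-network parameters
#'
#' The model file is a self-describing JSON archive holding layer shapes,
#' weights at full double precision, the input `model_order`, the amino-acid
#' alphabet, and an optional training-config echo. Round trips are exact to
#' well below 1e-12 per weight.
#'
#' @param params a `combiner_params`.
#' @param path file path.
#' @param train_cfg optional [train_config()] stored for provenance.
#' @return `load_combiner()` returns the restored `combiner_params`.
#' @export
save_combiner <- function(params, path, train_cfg = NULL) {
  payload <- list(
    format = "resstack_combiner", version = 1L,
    shapes = lapply(params[c("W1", "W2", "W3")], dim),
    model_order = params$model_order, alphabet = params$alphabet,
    weights = list(W1 = as.numeric(params$W1), b1 = params$b1,
                   W2 = as.numeric(params$W2), b2 = params$b2,
                   W3 = as.numeric(params$W3), b3 = params$b3),
    train_config = if (!is.null(train_cfg)) unclass(train_cfg))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_combiner
#' @export
load_combiner <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop_resstack("resstack_corrupt_model",
                                      "cannot parse model file: %s",
                                      conditionMessage(e)))
  d <- combiner_dims()
  exp_shapes <- list(W1 = d[1:2], W2 = d[2:3], W3 = d[3:4])
  w <- payload$weights
  for (nm in names(exp_shapes)) {
    sh <- payload$shapes[[nm]]
    if (is.null(sh) || !identical(as.integer(sh), exp_shapes[[nm]]) ||
        length(w[[nm]]) != prod(exp_shapes[[nm]]))
      stop_resstack("resstack_corrupt_model",
                    "model file has wrong shape for %s", nm)
  }
  if (!identical(as.character(payload$alphabet), aa_alphabet()))
    stop_resstack("resstack_corrupt_model", "model file alphabet mismatch")
  new_combiner_params(matrix(w$W1, d[1], d[2]), w$b1,
                      matrix(w$W2, d[2], d[3]), w$b2,
                      matrix(w$W3, d[3], d[4]), w$b3,
                      payload$model_order)
}
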