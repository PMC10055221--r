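zero_params <- function(order = paste0("m", 1:4)) {
  resstack:::new_combiner_params(
    matrix(0, 80, 120), numeric(120), matrix(0, 120, 60), numeric(60),
    matrix(0, 60, 20), numeric(20), order)
}

test_that("concat_inputs concatenates blockwise in model order", {
  vecs <- list(m1 = uniform_vec(), m2 = uniform_vec(), m3 = uniform_vec(),
               m4 = uniform_vec())
  expect_equal(concat_inputs(vecs, names(vecs)), rep(0.05, 80))

  vecs$m2 <- spike_vec("W", 0.8)
  x <- concat_inputs(vecs, c("m2", "m1", "m3", "m4"))
  expect_equal(x[1:20], spike_vec("W", 0.8))
  expect_equal(x[21:40], uniform_vec())

  expect_error(concat_inputs(vecs[1:3], names(vecs)),
               class = "resstack_input_error")
})

test_that("forward matches softmax identities and a hand-computed reduction", {
  p <- zero_params()
  expect_equal(forward(p, runif(80)), rep(1 / 20, 20))

  # softmax shift invariance via the output bias
  set.seed(1)
  p2 <- resstack:::init_combiner_params(paste0("m", 1:4), seed = 5)
  x <- runif(80)
  y1 <- forward(p2, x)
  p2$b3 <- p2$b3 + 3.7
  expect_equal(forward(p2, x), y1, tolerance = 1e-12)

  # scalar chain embedded in the full network: x -> w1 -> relu -> w2 ->
  # relu -> two logits; everything else stays zero
  w1 <- 0.8; w2 <- -1.3; w3 <- c(0.5, -0.2)
  p3 <- zero_params()
  p3$W1[1, 1] <- w1; p3$W2[1, 1] <- w2; p3$W3[1, 1:2] <- w3
  for (x1 in c(0.3, -0.6)) {
    xv <- c(x1, numeric(79))
    h <- max(w2 * max(w1 * x1, 0), 0)
    logits <- c(w3 * h, numeric(18))
    manual <- exp(logits) / sum(exp(logits))
    expect_equal(forward(p3, xv), manual, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(9)
  params <- resstack:::init_combiner_params(paste0("m", 1:4), seed = 7)
  X <- matrix(runif(20 * 80), 20, 80)
  X <- X / rowSums(X) * 4  # roughly probability-scaled inputs
  Y <- sample(20, 20, replace = TRUE)
  lg <- resstack:::combiner_loss_grad(params, X, Y)
  h <- 1e-6
  for (k in 1:10) {
    nm <- sample(c("W1", "b1", "W2", "b2", "W3", "b3"), 1)
    i <- sample(length(params[[nm]]), 1)
    up <- params; up[[nm]][i] <- up[[nm]][i] + h
    dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
    num <- (resstack:::combiner_loss_grad(up, X, Y)$loss -
              resstack:::combiner_loss_grad(dn, X, Y)$loss) / (2 * h)
    ana <- lg$grads[[nm]][i]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

# dataset where model m1 is a perfect oracle and the rest are uniform
oracle_panel <- function(n_prot, len, seed) {
  cfg <- default_panel_config()
  labels <- data.table::rbindlist(lapply(seq_len(n_prot), function(p)
    generate_protein(cfg, sprintf("op%03d", p), len,
                     seed = resstack:::hash_seed(seed, p))$sites))
  n <- nrow(labels)
  probs <- do.call(rbind, lapply(labels$wt_aa, spike_vec, p = 1))
  pset <- prediction_set(
    protein_id = rep(labels$protein_id, 4),
    position = rep(labels$position, 4),
    model_id = rep(paste0("m", 1:4), each = n),
    probs = rbind(probs, matrix(0.05, 3 * n, 20)))
  list(pset = pset, labels = labels)
}

test_that("training recovers an oracle input model and is deterministic", {
  op <- oracle_panel(16, 120L, seed = 3)
  cfg <- train_config(seed = 11)
  fit <- train_combiner(op$pset, op$labels, cfg)
  expect_length(fit$loss_trace, 150)
  # independent oracle: argmax of block m1 solves the task exactly, so a
  # competent learner must get essentially everything right in-sample
  pred <- predict_combined(fit$params, op$pset)
  tp <- resstack:::top_predictions(resstack:::pset_prob_matrix(pred))
  expect_gte(mean(tp$aa == op$labels$wt_aa), 0.99)
  pp <- per_protein_accuracy(pred, op$labels)
  expect_gte(min(pp$accuracy), 0.99)

  # identical seeds give identical loss traces; different seeds do not
  small <- oracle_panel(4, 80L, seed = 5)
  t1 <- train_combiner(small$pset, small$labels,
                       train_config(epochs = 5, seed = 2))
  t2 <- train_combiner(small$pset, small$labels,
                       train_config(epochs = 5, seed = 2))
  expect_identical(t1$loss_trace, t2$loss_trace)
  expect_identical(t1$params, t2$params)
  t3 <- train_combiner(small$pset, small$labels,
                       train_config(epochs = 5, seed = 3))
  expect_false(identical(t1$loss_trace, t3$loss_trace))
})

test_that("training fits a constant target and always descends", {
  # all sites share one wildtype: reachable through the output bias alone
  n <- 400L
  labels <- toy_labels(rep("L", n))
  pset <- prediction_set(rep("p1", 4 * n), rep(seq_len(n), 4),
                         rep(paste0("m", 1:4), each = n),
                         matrix(0.05, 4 * n, 20))
  fit <- train_combiner(pset, labels, train_config(epochs = 60, seed = 1))
  pred <- predict_combined(fit$params, pset)
  tp <- resstack:::top_predictions(resstack:::pset_prob_matrix(pred))
  expect_true(all(tp$aa == "L"))

  # descent check on a small random dataset at the default configuration
  cfg <- flat_panel(0.6, protein_length_range = c(100L, 100L))
  sim <- simulate_panel(cfg, 10, seed = 13)
  fit2 <- train_combiner(sim$pset, sim$labels, train_config(seed = 4))
  expect_lt(fit2$loss_trace[150], fit2$loss_trace[1])

  expect_error(train_combiner(pset, labels[0], train_config()),
               class = "resstack_input_error")
})

test_that("predict_combined validates inputs and survives serialization", {
  op <- oracle_panel(2, 90L, seed = 9)
  pred <- predict_combined(zero_params(), op$pset)
  expect_true(all(abs(resstack:::pset_prob_matrix(pred) - 0.05) < 1e-12))
  expect_identical(pset_models(pred), "combined")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_table(pred, path)
  back <- read_prediction_table(path)
  expect_lt(max(abs(resstack:::pset_prob_matrix(back) -
                      resstack:::pset_prob_matrix(pred))), 1e-9)

  missing <- op$pset[op$pset$model_id != "m1"]
  expect_error(predict_combined(zero_params(), missing),
               class = "resstack_input_error")
})

test_that("naive ensemble baselines follow their closed forms", {
  v <- spike_vec("L", 0.9)
  expect_equal(ensemble_average(list(v, v, v, v)), v)
  avg <- ensemble_average(list(spike_vec("A", 1), uniform_vec(),
                               uniform_vec(), uniform_vec()))
  expect_equal(unname(avg[1]), (1 + 3 * 0.05) / 4)
  expect_equal(unname(avg[2]), (0 + 3 * 0.05) / 4)
  vecs <- list(spike_vec("C", 0.4), spike_vec("W", 0.31), uniform_vec(),
               spike_vec("Y", 0.22))
  expect_equal(ensemble_average(vecs), ensemble_average(rev(vecs)))
  expect_error(ensemble_average(vecs[1:3]), class = "resstack_input_error")

  em <- ensemble_max(list(spike_vec("L", 0.9), uniform_vec(), uniform_vec(),
                          uniform_vec()))
  expect_identical(em$aa, "L")
  expect_equal(em$confidence, 0.9)
  # all-uniform tie resolves to the first amino acid in the alphabet
  tie <- ensemble_max(rep(list(uniform_vec()), 4))
  expect_identical(tie$aa, "A")
  expect_identical(ensemble_max(vecs), ensemble_max(rev(vecs)))
})

test_that("combiner parameters round-trip through the model file", {
  params <- resstack:::init_combiner_params(c("b", "a", "d", "c"), seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  save_combiner(params, path, train_cfg = train_config())
  back <- load_combiner(path)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3"))
    expect_lt(max(abs(back[[nm]] - params[[nm]])), 1e-12)
  expect_identical(back$model_order, c("b", "a", "d", "c"))
  expect_identical(back$alphabet, aa_alphabet())

  # tampering with shape metadata is caught
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$shapes$W2 <- c(120, 61)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  expect_error(load_combiner(path), class = "resstack_corrupt_model")
})

test_that("the combiner recovers a perfect model from noise on held-out data", {
  op <- oracle_panel(30, 100L, seed = 21)
  ids <- unique(op$labels$protein_id)
  sp <- split_train_test(ids, 0.25, seed = 21)
  tr <- op$labels[op$labels$protein_id %in% sp$train]
  te <- op$labels[op$labels$protein_id %in% sp$test]
  trp <- resstack:::as_prediction_set(
    op$pset[op$pset$protein_id %in% sp$train])
  tep <- resstack:::as_prediction_set(
    op$pset[op$pset$protein_id %in% sp$test])
  fit <- train_combiner(trp, tr, train_config(seed = 6))
  pred <- predict_combined(fit$params, tep)
  acc <- per_protein_accuracy(pred, te)
  expect_gte(sum(acc$n_correct) / sum(acc$n_sites), 0.95)
})
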