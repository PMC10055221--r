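test_that("top_prediction follows the argmax-with-alphabet-ties contract", {
  expect_identical(top_prediction(uniform_vec()), list(aa = "A",
                                                       confidence = 0.05))
  expect_identical(top_prediction(spike_vec("W", 0.7))$aa, "W")
  expect_equal(top_prediction(spike_vec("W", 0.7))$confidence, 0.7)
  tie <- numeric(20); tie[match(c("C", "Y"), aa_alphabet())] <- 0.5
  expect_identical(top_prediction(tie), list(aa = "C", confidence = 0.5))
  expect_error(top_prediction(c(NA, numeric(19))),
               class = "resstack_value_error")
})

test_that("protein accuracy is an exact fraction and matches a recount", {
  pset <- toy_pset(list(m1 = c("A", "C", "D", "E")))
  labels <- toy_labels(c("A", "C", "D", "W"))
  pa <- protein_accuracy(pset, labels, "m1", "p1")
  expect_equal(pa$accuracy, 0.75)
  expect_identical(pa$n_correct, 3L)
  expect_identical(pa$n_sites, 4L)
  expect_equal(protein_accuracy(toy_pset(list(m1 = c("A", "C"))),
                                toy_labels(c("A", "C")), "m1", "p1")$accuracy,
               1)
  expect_warning(pa0 <- protein_accuracy(pset, labels, "m1", "nope"),
                 "no evaluable sites")
  expect_true(is.na(pa0$accuracy))

  # brute-force recount over 50 random synthetic proteins
  sim <- simulate_panel(flat_panel(0.6, protein_length_range = c(40L, 70L)),
                        50, seed = 12)
  pp <- per_protein_accuracy(sim$pset, sim$labels)
  probs <- resstack:::pset_prob_matrix(sim$pset)
  for (k in sample(nrow(pp), 25)) {
    rows <- which(sim$pset$model_id == pp$model_id[k] &
                    sim$pset$protein_id == pp$protein_id[k])
    hits <- 0L
    for (r in rows) {
      top <- aa_alphabet()[which.max(probs[r, ])]
      wt <- sim$labels[sim$labels$protein_id == pp$protein_id[k] &
                         sim$labels$position == sim$pset$position[r]]$wt_aa
      hits <- hits + (top == wt)
    }
    expect_equal(pp$accuracy[k], hits / length(rows))
  }
})

test_that("class accuracy pools sites and respects the class map", {
  pset <- toy_pset(list(m1 = c("A", "G", "P", "S")))
  labels <- toy_labels(c("A", "G", "P", "S"))
  ca <- class_accuracy(pset, labels, "m1")
  expect_true(all(ca$accuracy[ca$n_sites > 0] == 1))
  expect_true(is.na(ca$accuracy[ca$class == "aromatic"]))

  # correct only on G and P: unique class 1, other populated classes 0
  pset2 <- toy_pset(list(m1 = c("C", "G", "P", "T")))
  labels2 <- toy_labels(c("A", "G", "P", "S"))
  ca2 <- class_accuracy(pset2, labels2, "m1")
  expect_equal(ca2$accuracy[ca2$class == "unique"], 1)
  expect_equal(ca2$accuracy[ca2$class == "aliphatic"], 0)
  expect_equal(ca2$accuracy[ca2$class == "polar"], 0)

  # pooled accuracy equals the site-count-weighted mean over proteins
  sim <- simulate_panel(flat_panel(0.55, protein_length_range = c(30L, 60L)),
                        12, seed = 3)
  ca3 <- class_accuracy(sim$pset, sim$labels, "seq_a")
  ct <- resstack:::correctness_table(
    resstack:::as_prediction_set(sim$pset[sim$pset$model_id == "seq_a"]),
    sim$labels)
  byprot <- ct[, list(acc = mean(correct), n = .N),
               by = c("protein_id", "aa_class")]
  for (cl in aa_class_labels()) {
    sub <- byprot[byprot$aa_class == cl]
    if (nrow(sub) == 0) next
    expect_equal(ca3$accuracy[ca3$class == cl],
                 sum(sub$acc * sub$n) / sum(sub$n))
  }

  expect_error(class_accuracy(pset, labels, "m1",
                              class_map = c(A = "aliphatic")),
               class = "resstack_config_error")
})

test_that("accuracy correlation equals its closed form", {
  a <- c(0.2, 0.4, 0.6)
  expect_equal(accuracy_correlation(a, a)$r, 1)
  expect_equal(accuracy_correlation(a, 1 - a)$r, -1)

  b <- c(0.3, 0.3, 0.9)
  got <- accuracy_correlation(a, b)
  # from-definition oracle: covariance over the product of sd's
  r_def <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_def, tolerance = 1e-12)
  # two-sided p through the t transform
  tstat <- r_def * sqrt((3 - 2) / (1 - r_def^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tstat), df = 1), tolerance = 1e-12)

  # oracle equivalence on random vectors
  set.seed(77)
  for (k in 1:10) {
    x <- runif(20); y <- runif(20)
    r_def <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(accuracy_correlation(x, y)$r, r_def, tolerance = 1e-10)
  }

  expect_warning(rc <- accuracy_correlation(rep(0.5, 5), runif(5)),
                 "constant")
  expect_true(is.na(rc$r))
  expect_error(accuracy_correlation(c(1, 2), c(3, 4)),
               class = "resstack_input_error")
  expect_error(accuracy_correlation(1:4 / 4, 1:3 / 3),
               class = "resstack_input_error")
})

test_that("agreement classification is total and exclusive over all subsets", {
  types <- c(s1 = "structure", s2 = "structure", l1 = "sequence",
             l2 = "sequence")
  ids <- names(types)
  for (mask in 0:15) {
    agree <- ids[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
    tops <- stats::setNames(ifelse(ids %in% agree, "A", "C"), ids)
    got <- classify_agreement(tops, "A", types)
    expect_setequal(got$agreeing_models, agree)
    expected <- if (length(agree) == 4) "ALL"
    else if (length(agree) == 0) "NONE"
    else if (all(agree %in% c("l1", "l2"))) "SEQUENCE_ONLY"
    else if (all(agree %in% c("s1", "s2"))) "STRUCTURE_ONLY"
    else "MIXED"
    expect_identical(got$label, expected)
  }
  expect_error(classify_agreement(stats::setNames(rep("A", 4), ids), "A",
                                  c(s1 = "structure")),
               class = "resstack_config_error")
})

test_that("agreement_summary tallies categories against a hand count", {
  types <- c(s1 = "structure", s2 = "structure", l1 = "sequence",
             l2 = "sequence")
  # identical oracle panel: everything lands in ALL with accuracy 1
  wt <- c("A", "C", "D", "E", "F")
  pset <- toy_pset(list(s1 = wt, s2 = wt, l1 = wt, l2 = wt, combined = wt))
  summ <- agreement_summary(pset, toy_labels(wt), types)
  expect_equal(summ$proportion[summ$category == "ALL"], 1)
  expect_equal(summ$accuracy[summ$category == "ALL"], 1)
  expect_equal(sum(summ$proportion), 1)

  # 10-site toy with hand-assigned tops
  wt <- rep("A", 10)
  comb <- c("A", "A", "A", "A", "C", "C", "A", "A", "A", "D")
  s1 <- c("A", "A", "C", "A", "C", "D", "A", "C", "C", "A")
  s2 <- c("A", "A", "C", "A", "C", "C", "A", "C", "C", "A")
  l1 <- c("A", "C", "A", "A", "C", "C", "C", "A", "C", "A")
  l2 <- c("A", "C", "A", "C", "D", "C", "C", "A", "C", "A")
  # hand tally: site 1 ALL; 2 STRUCTURE_ONLY; 3 SEQUENCE_ONLY; 4 MIXED
  # (s1,s2,l1); 5 MIXED (s1,s2,l1); 6 MIXED (s2,l1,l2); 7 STRUCTURE_ONLY;
  # 8 SEQUENCE_ONLY; 9 NONE; 10 NONE
  pset <- toy_pset(list(s1 = s1, s2 = s2, l1 = l1, l2 = l2,
                        combined = comb))
  summ <- agreement_summary(pset, toy_labels(wt), types)
  counts <- stats::setNames(summ$n_sites, summ$category)
  expect_identical(unname(counts[agreement_labels()]), c(1L, 2L, 2L, 3L, 2L))
  # combined is correct at sites 1-4, 7-9 -> per-category accuracies
  expect_equal(summ$accuracy[summ$category == "ALL"], 1)
  expect_equal(summ$accuracy[summ$category == "MIXED"], 1 / 3)
  expect_equal(summ$accuracy[summ$category == "NONE"], 1 / 2)
  expect_equal(sum(summ$proportion), 1)
})

test_that("rsa/confidence histogram conserves counts and labels bands", {
  h <- rsa_confidence_histogram(rep(0.05, 10), rep(0.95, 10))
  expect_identical(nrow(h), 1L)
  expect_identical(h$count, 10L)
  expect_identical(as.character(h$band), "1-25")
  expect_equal(h$rsa_lo, 0.05)  # half-open bins: 0.05 starts its own bin
  expect_equal(h$conf_lo, 0.95)

  set.seed(5)
  rsa <- runif(500, 0, 1.1)
  conf <- runif(500)
  h2 <- rsa_confidence_histogram(rsa, conf)
  expect_identical(sum(h2$count), 500L)

  h3 <- rsa_confidence_histogram(c(rep(0.12, 80), 0.9), rep(0.5, 81))
  expect_identical(as.character(h3$band[h3$count == 80]), ">75")

  # confidence exactly 1 falls in the closed last bin
  h4 <- rsa_confidence_histogram(0.1, 1)
  expect_equal(h4$conf_lo, 0.95)

  expect_message(rsa_confidence_histogram(c(0.1, NA), c(0.5, 0.5)),
                 "skipping 1")
})

test_that("accuracy rises with confidence when the generator says it should", {
  cfg <- flat_panel(0.5, protein_length_range = c(200L, 200L))
  sites <- sites_only(cfg, 20000L, seed = 55)
  prof <- skill_profile("m", "sequence", uniform_skill(0.5))
  pr <- simulate_predictor(sites, prof, seed = 66)
  tp <- resstack:::top_predictions(pr)
  dec <- cut(tp$confidence,
             breaks = stats::quantile(tp$confidence, 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  acc_by_dec <- tapply(tp$aa == sites$wt_aa, dec, mean)
  expect_true(all(diff(acc_by_dec) > -0.02))  # nondecreasing up to noise
  expect_gt(acc_by_dec[10], acc_by_dec[1])
})
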