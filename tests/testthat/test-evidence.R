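# Stage 2: coverage screening, binned likelihood ratios, naive Bayes
# composition, cutoff selection, and the integration cross-validation.

make_gold_small <- function(seed = 2) {
  w <- make_world(40, 0, 5, c(4, 8), seed = seed)
  make_gold_standard(w)
}

test_that("coverage is the fraction of gold pairs with a score", {
  gold <- make_gold_small()
  pairs <- rbind(gold$positives, gold$negatives)

  full <- simulate_evidence(gold, pairs, evidence_spec("full", coverage = 1),
                            seed = 1)
  expect_equal(compute_coverage(full, gold), 1)

  none <- simulate_evidence(gold, pairs, evidence_spec("none", coverage = 0),
                            seed = 1)
  expect_equal(compute_coverage(none, gold), 0)

  # constructed fixture at the 20% inclusion boundary: 30 of 150 gold pairs
  g150 <- fabricated_gold(75, 75)
  p150 <- rbind(g150$positives, g150$negatives)
  ev30 <- evidence_table(cbind(p150[1:30, ], score = 1), name = "part")
  expect_equal(compute_coverage(ev30, g150), 0.2)

  empty_gold <- gold_standard(gold$positives[0, ], gold$negatives[0, ])
  expect_error(compute_coverage(full, empty_gold),
               class = "mitofln_undefined_metric")
})

test_that("pairwise independence screening uses PCC on common gold pairs", {
  gold <- fabricated_gold(5000, 5000)
  pairs <- rbind(gold$positives, gold$negatives)
  sp <- evidence_spec("e", coverage = 1)
  e1 <- simulate_evidence(gold, pairs, sp, seed = 1)
  e2 <- simulate_evidence(gold, pairs, sp, seed = 2)

  # an evidence against itself and against its negation
  neg <- evidence_table(
    data.frame(gene_a = e1$gene_a, gene_b = e1$gene_b, score = -e1$score),
    name = "neg")
  m <- pairwise_independence(list(a = e1, self = e1, neg = neg), gold)
  expect_equal(m["a", "self"], 1)
  expect_equal(m["a", "neg"], -1)

  # independently simulated noise evidences are uncorrelated
  flat <- evidence_spec("flat",
                        list(family = "normal", mean = 0, sd = 1),
                        list(family = "normal", mean = 0, sd = 1))
  f1 <- simulate_evidence(gold, pairs, flat, seed = 11)
  f2 <- simulate_evidence(gold, pairs, flat, seed = 12)
  m2 <- pairwise_independence(list(f1 = f1, f2 = f2), gold)
  expect_lt(abs(m2["f1", "f2"]), 0.1)

  # fewer than 3 common observations is not assessable
  tiny <- evidence_table(cbind(pairs[1:2, ], score = c(1, 2)), name = "tiny")
  m3 <- pairwise_independence(list(t = tiny, f = f1), gold)
  expect_true(is.na(m3["t", "f"]))
})

test_that("bin likelihood ratios are the smoothed count ratios", {
  # categorical fixture: category A holds 10/100 positives and 5/100
  # negatives, so its unsmoothed LR is exactly 2
  n <- 100
  a <- sprintf("p%03d", 1:n); b <- sprintf("q%03d", 1:n)
  pos <- data.frame(gene_a = a, gene_b = b)
  neg <- data.frame(gene_a = sprintf("r%03d", 1:n), gene_b = sprintf("s%03d", 1:n))
  gold <- gold_standard(pos, neg)
  score <- c(rep(1, 10), rep(0, 90),   # positives: 10 in category "1"
             rep(1, 5), rep(0, 95))    # negatives: 5 in category "1"
  ev <- evidence_table(cbind(rbind(pos, neg), score = score), name = "cat")
  m <- fit_binned_likelihood(ev, gold, pseudocount = 0, type = "categorical")
  expect_equal(m$lr[m$levels == 1], 2.0)
  expect_equal(m$lr[m$levels == 0], (90 / 100) / (95 / 100))

  # pre-smoothing rates each sum to one
  expect_equal(sum(m$pos_counts) , 100)
  expect_equal(sum(m$pos_counts / sum(m$pos_counts)), 1)
  expect_equal(sum(m$neg_counts / sum(m$neg_counts)), 1)
})

test_that("pseudocount keeps every bin LR finite and positive", {
  gold <- make_gold_small(3)
  sep <- evidence_spec("sep", list(family = "normal", mean = 4, sd = 0.5),
                       list(family = "normal", mean = -4, sd = 0.5))
  ev <- simulate_evidence(gold, NULL, sep, seed = 1)
  m <- fit_binned_likelihood(ev, gold, n_bins = 5, pseudocount = 1)
  expect_true(all(is.finite(m$lr)))
  expect_true(all(m$lr > 0))
  # fully separated classes still give at least one bin with LR > 1
  expect_gt(max(m$lr), 1)
})

test_that("identical class distributions drive every bin LR to 1", {
  gold <- fabricated_gold(50000, 50000)
  flat <- evidence_spec("flat",
                        list(family = "normal", mean = 0, sd = 1),
                        list(family = "normal", mean = 0, sd = 1))
  ev <- simulate_evidence(gold, NULL, flat, seed = 21)
  m <- fit_binned_likelihood(ev, gold, n_bins = 5)
  expect_true(all(abs(m$lr - 1) < 0.1))
})

test_that("estimated bin LRs recover the analytic class-probability ratios", {
  gold <- fabricated_gold(50000, 50000)
  posd <- list(family = "normal", mean = 1, sd = 1)
  negd <- list(family = "normal", mean = 0, sd = 1)
  ev <- simulate_evidence(gold, NULL, evidence_spec("n", posd, negd), seed = 31)
  m <- fit_binned_likelihood(ev, gold, n_bins = 5)
  b <- as.data.frame(m)
  analytic <- (pnorm(b$upper, 1, 1) - pnorm(b$lower, 1, 1)) /
              (pnorm(b$upper, 0, 1) - pnorm(b$lower, 0, 1))
  expect_true(all(abs(m$lr / analytic - 1) < 0.1))
})

test_that("evidence without gold overlap is not fittable", {
  gold <- make_gold_small(4)
  far <- evidence_table(data.frame(gene_a = "zz1", gene_b = "zz2", score = 1),
                        name = "far")
  expect_error(fit_binned_likelihood(far, gold),
               class = "mitofln_not_fittable")
})

test_that("composite LR obeys the naive Bayes identities", {
  gold <- make_gold_small(5)
  specs <- informative_specs()
  evs <- simulate_evidences(gold, specs, seed = 7)
  models <- lapply(evs, fit_binned_likelihood, gold = gold)
  pairs <- rbind(gold$positives, gold$negatives)
  comp <- composite_lr(pairs, models, evs, prior_odds = 0.25)

  # posterior odds = prior odds x composite LR, exactly, for any prior
  expect_equal(comp$posterior_odds, 0.25 * comp$lr)
  # log form and product form agree to 12 significant digits
  key <- function(a, b) paste(a, b, sep = "\t")
  prod_oracle <- setNames(rep(1, nrow(pairs)),
                          key(pairs$gene_a, pairs$gene_b))
  for (i in seq_along(evs)) {
    lr_i <- predict(models[[i]], evs[[i]]$score)
    k <- key(evs[[i]]$gene_a, evs[[i]]$gene_b)
    hit <- k %in% names(prod_oracle)
    prod_oracle[k[hit]] <- prod_oracle[k[hit]] * lr_i[hit]
  }
  expect_equal(comp$lr, unname(prod_oracle[key(comp$gene_a, comp$gene_b)]),
               tolerance = 1e-12)

  # invariance to evidence ordering
  comp_rev <- composite_lr(pairs, rev(models), rev(evs), prior_odds = 0.25)
  ord <- order(comp$gene_a, comp$gene_b)
  ord_rev <- order(comp_rev$gene_a, comp_rev$gene_b)
  expect_equal(comp$lr[ord], comp_rev$lr[ord_rev], tolerance = 1e-12)

  # an evidence whose every bin LR is 1 is a no-op
  unit <- models[[1]]
  unit$lr[] <- 1
  comp_unit <- composite_lr(pairs, c(models, list(unit)),
                            c(evs, list(evs[[1]])), prior_odds = 0.25)
  expect_equal(comp_unit$lr[order(comp_unit$gene_a, comp_unit$gene_b)],
               comp$lr[ord], tolerance = 1e-12)

  # a pair covered by no evidence carries LR exactly 1
  lone <- composite_lr(data.frame(gene_a = "zz8", gene_b = "zz9"),
                       models, evs)
  expect_equal(lone$lr, 1)
  expect_equal(lone$n_evidence, 0L)
})

test_that("the TP/FP curve is monotone and hits 50% precision at ratio 1", {
  gold <- make_gold_small(6)
  evs <- simulate_evidences(gold, informative_specs(), seed = 8)
  models <- lapply(evs, fit_binned_likelihood, gold = gold)
  comp <- composite_lr(rbind(gold$positives, gold$negatives), models, evs)
  curve <- tp_fp_curve(comp, gold)

  expect_equal(curve$sensitivity[1], 1)           # cutoff below all scores
  expect_true(all(diff(curve$tp) <= 0))
  expect_true(all(diff(curve$fp) <= 0))
  expect_true(all(diff(curve$sensitivity) <= 0))

  # wherever TP/FP = 1, precision TP/(TP+FP) is exactly 50%
  at1 <- which(curve$ratio == 1)
  if (length(at1)) {
    expect_equal(curve$tp[at1] / (curve$tp[at1] + curve$fp[at1]),
                 rep(0.5, length(at1)))
  }
})

test_that("cutoff selection takes the smallest cutoff reaching the target", {
  curve <- data.frame(cutoff = c(1, 2, 3, 4), tp = c(40, 30, 24, 10),
                      fp = c(50, 30, 20, 5))
  curve$ratio <- curve$tp / curve$fp
  curve$sensitivity <- curve$tp / 40
  # ratio crosses 1 between cutoffs 2 and 3 -> the >= rule returns 3
  expect_equal(select_cutoff(curve, target_ratio = 1.1), 3)
  expect_equal(select_cutoff(curve, target_ratio = 0), 1)
  expect_error(select_cutoff(curve, target_ratio = 10),
               class = "mitofln_not_attainable")
})

test_that("the selected cutoff achieves at least 50% held-out precision", {
  w <- make_world(60, 0, 8, c(5, 10), seed = 9)
  gold <- make_gold_standard(w)
  # strongly separated class-conditional scores: Normal(2,1) vs Normal(0,1)
  strong <- lapply(sprintf("s%d", 1:3), function(nm) {
    evidence_spec(nm, list(family = "normal", mean = 2, sd = 1),
                  list(family = "normal", mean = 0, sd = 1))
  })
  names(strong) <- sprintf("s%d", 1:3)
  evs <- simulate_evidences(gold, strong, seed = 9)
  all_pairs <- rbind(gold$positives, gold$negatives)
  labels <- rep(c(TRUE, FALSE), c(nrow(gold$positives), nrow(gold$negatives)))
  set.seed(10)
  fold <- sample(rep_len(1:5, nrow(all_pairs)))
  prec <- numeric(5)
  for (f in 1:5) {
    tr <- gold_standard(gold$positives[fold[labels] != f, ],
                        gold$negatives[fold[!labels] != f, ])
    models <- lapply(evs, fit_binned_likelihood, gold = tr)
    comp_tr <- composite_lr(all_pairs[fold != f, ], models, evs)
    cut <- select_cutoff(tp_fp_curve(comp_tr, tr))
    comp_te <- composite_lr(all_pairs[fold == f, ], models, evs)
    called <- comp_te$lr >= cut
    key <- paste(comp_te$gene_a, comp_te$gene_b, sep = "\t")
    truth <- key %in% paste(gold$positives$gene_a, gold$positives$gene_b,
                            sep = "\t")
    prec[f] <- sum(called & truth) / sum(called)
  }
  expect_gte(mean(prec), 0.5)
})

test_that("network construction respects the cutoff and drops isolated genes", {
  gold <- make_gold_small(11)
  evs <- simulate_evidences(gold, informative_specs(), seed = 11)
  models <- lapply(evs, fit_binned_likelihood, gold = gold)
  comp <- composite_lr(rbind(gold$positives, gold$negatives), models, evs)
  genes <- unique(c(comp$gene_a, comp$gene_b))

  g_empty <- build_fln(genes, comp, cutoff = max(comp$lr) + 1)
  expect_equal(length(g_empty$nodes), 0L)

  g_all <- build_fln(genes, comp, cutoff = NULL)
  expect_equal(nrow(g_all$edges), nrow(comp))
  expect_lte(length(g_all$nodes), length(genes))

  g_cut <- build_fln(genes, comp, cutoff = 2)
  expect_true(all(g_cut$edges$weight >= 2))
  expect_setequal(c(g_cut$nodes, g_cut$isolated), genes)
})

test_that("trapezoidal AUC agrees with pROC on tied and untied scores", {
  set.seed(17)
  labels <- rep(c(TRUE, FALSE), each = 150)
  scores <- c(rnorm(150, 1), rnorm(150))          # untied
  tied <- round(scores, 1)                         # heavy ties
  for (sc in list(scores, tied)) {
    ours <- mitofln:::roc_auc(sc, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("five-fold integration CV ranks models sensibly", {
  gold <- make_gold_small(12)
  evs <- simulate_evidences(gold, informative_specs(), seed = 12)
  cv <- crossvalidate_integration_5fold(evs, gold, seed = 1)
  expect_named(cv$auc, c("coexpr", "domain", "ppi", "integrated",
                         "integrated_genome-scale",
                         "integrated_mitochondria-specific"),
               ignore.order = TRUE)
  expect_gte(cv$auc[["integrated"]],
             max(cv$auc[c("coexpr", "domain", "ppi")]) - 0.02)

  # chance-level evidence scores at AUC ~ 0.5
  gold_big <- fabricated_gold(2000, 2000)
  flat <- evidence_spec("flat",
                        list(family = "normal", mean = 0, sd = 1),
                        list(family = "normal", mean = 0, sd = 1))
  evf <- list(flat = simulate_evidence(gold_big, NULL, flat, seed = 5))
  cvf <- crossvalidate_integration_5fold(evf, gold_big, seed = 2)
  expect_lt(abs(cvf$auc[["flat"]] - 0.5), 0.05)
  expect_lt(abs(cvf$auc[["integrated"]] - 0.5), 0.05)

  # perfectly separated supports give AUC 1
  gold_s <- fabricated_gold(100, 100)
  ps <- rbind(gold_s$positives, gold_s$negatives)
  perfect <- evidence_table(
    cbind(ps, score = rep(c(10, -10), each = 100)), name = "perfect")
  cvp <- crossvalidate_integration_5fold(list(perfect = perfect), gold_s,
                                         seed = 3)
  expect_equal(cvp$auc[["perfect"]], 1)
})
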