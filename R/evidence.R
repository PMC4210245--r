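# Stage 2: naive Bayes likelihood-ratio integration of heterogeneous
# pairwise evidence against the gold standard, composite-LR cutoff
# selection, and construction of the weighted functional linkage network.
#
# For one evidence E with score falling in bin b, the likelihood ratio is
# LR_b = P(b | linked) / P(b | unlinked), estimated from binned counts of
# gold positive and negative pairs with Laplace smoothing. Under conditional
# independence the composite LR of a pair is the product of its per-evidence
# bin LRs, and posterior odds = prior odds x composite LR.

gold_keys <- function(gold) {
  list(pos = pair_key(gold$positives$gene_a, gold$positives$gene_b),
       neg = pair_key(gold$negatives$gene_a, gold$negatives$gene_b))
}

#' Coverage of an evidence on the gold standard
#'
#' Fraction of gold-standard pairs (GSP plus GSN) for which the evidence has
#' a score. Evidences below a coverage threshold (0.20 by convention) are
#' typically excluded from the integrated model.
#'
#' @param ev an [evidence_table].
#' @param gold a [gold_standard].
#' @return fraction in `[0, 1]`.
#' @export
compute_coverage <- function(ev, gold) {
  gk <- gold_keys(gold)
  n_gold <- length(gk$pos) + length(gk$neg)
  if (n_gold == 0L) stop_undefined_metric("coverage undefined: empty gold standard")
  ek <- pair_key(ev$gene_a, ev$gene_b)
  sum(c(gk$pos, gk$neg) %in% ek) / n_gold
}

#' Pairwise Pearson correlation between evidences on the gold standard
#'
#' Screens for statistical dependence between evidence sources: for each
#' pair of evidences, the Pearson correlation of their scores on gold pairs
#' covered by both. Pairs with fewer than 3 common observations are not
#' assessable and reported as `NA`.
#'
#' @param evs named list of [evidence_table] objects (>= 2).
#' @param gold a [gold_standard].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_independence <- function(evs, gold) {
  if (length(evs) < 2L) stop_invalid_input("need at least 2 evidences")
  gk <- gold_keys(gold)
  all_gold <- c(gk$pos, gk$neg)
  scored <- lapply(evs, function(ev) {
    k <- pair_key(ev$gene_a, ev$gene_b)
    keep <- k %in% all_gold
    stats::setNames(ev$score[keep], k[keep])
  })
  nm <- names(evs) %||% vapply(evs, attr, "", "evidence_name")
  n <- length(evs)
  m <- diag(1, n)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      common <- intersect(names(scored[[i]]), names(scored[[j]]))
      m[i, j] <- m[j, i] <- if (length(common) < 3L) NA_real_ else {
        suppressWarnings(stats::cor(scored[[i]][common], scored[[j]][common]))
      }
    }
  }
  m
}

#' Fit a binned likelihood-ratio model for one evidence
#'
#' Scores observed on gold pairs are divided into bins — equal-frequency
#' (quantile) bins for continuous scores, or the score's distinct values
#' for categorical evidence — and each bin's likelihood ratio is estimated
#' with Laplace smoothing:
#' `LR_b = ((pos_b + c) / (pos_tot + B c)) / ((neg_b + c) / (neg_tot + B c))`
#' with `B` bins and pseudocount `c`.
#'
#' @param ev an [evidence_table].
#' @param gold a [gold_standard]; the evidence must cover at least one
#'   positive and one negative gold pair.
#' @param n_bins number of quantile bins (default 5).
#' @param pseudocount Laplace smoothing constant (default 1; with
#'   `pseudocount > 0` every bin LR is finite and positive).
#' @param type `"quantile"` for continuous scores or `"categorical"` to use
#'   distinct score values as bins.
#' @return object of class `binned_lr`: bin `breaks` (or `levels`),
#'   `pos_counts`, `neg_counts`, `lr`, and the evidence name.
#' @export
fit_binned_likelihood <- function(ev, gold, n_bins = 5, pseudocount = 1,
                                  type = c("quantile", "categorical")) {
  type <- match.arg(type)
  if (pseudocount < 0) stop_invalid_parameter("`pseudocount` must be >= 0")
  if (n_bins < 1) stop_invalid_parameter("`n_bins` must be >= 1")
  gk <- gold_keys(gold)
  ek <- pair_key(ev$gene_a, ev$gene_b)
  pos_scores <- ev$score[ek %in% gk$pos]
  neg_scores <- ev$score[ek %in% gk$neg]
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop_not_fittable(sprintf(
      "evidence '%s' covers %d positive and %d negative gold pairs; need >= 1 of each",
      attr(ev, "evidence_name"), length(pos_scores), length(neg_scores)))
  }
  all_scores <- c(pos_scores, neg_scores)
  # scores with at most n_bins distinct values (binary/categorical
  # evidences) use the values themselves as bins
  if (type == "quantile" && length(unique(all_scores)) <= n_bins) {
    type <- "categorical"
  }

  if (type == "categorical") {
    levels <- sort(unique(all_scores))
    bin_of <- function(x) match(x, levels)
    pos_bin <- bin_of(pos_scores)
    neg_bin <- bin_of(neg_scores)
    B <- length(levels)
    breaks <- NULL
  } else {
    qs <- stats::quantile(all_scores, probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE, type = 7)
    breaks <- unique(qs)
    if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1)  # constant scores
    # open-ended outer bins so unseen scores clamp into the end bins
    cut_breaks <- c(-Inf, breaks[-c(1L, length(breaks))], Inf)
    B <- length(cut_breaks) - 1L
    bin_of <- function(x) findInterval(x, cut_breaks, rightmost.closed = TRUE,
                                       left.open = TRUE)
    pos_bin <- bin_of(pos_scores)
    neg_bin <- bin_of(neg_scores)
    levels <- NULL
  }
  pos_counts <- tabulate(pos_bin, nbins = B)
  neg_counts <- tabulate(neg_bin, nbins = B)
  c0 <- pseudocount
  lr <- ((pos_counts + c0) / (length(pos_scores) + B * c0)) /
        ((neg_counts + c0) / (length(neg_scores) + B * c0))
  structure(
    list(evidence = attr(ev, "evidence_name"),
         scale_tag = attr(ev, "scale_tag") %||% "genome-scale",
         type = type, breaks = breaks, levels = levels,
         pos_counts = pos_counts, neg_counts = neg_counts,
         lr = lr, pseudocount = pseudocount,
         bin_of = bin_of),
    class = "binned_lr"
  )
}

#' @export
print.binned_lr <- function(x, ...) {
  cat(sprintf("Binned LR model for evidence '%s' (%s, %d bins)\n",
              x$evidence, x$type, length(x$lr)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.binned_lr <- function(x, ...) {
  if (x$type == "categorical") {
    data.frame(bin = seq_along(x$lr), level = x$levels,
               pos_count = x$pos_counts, neg_count = x$neg_counts, lr = x$lr)
  } else {
    lo <- c(-Inf, x$breaks[-c(1L, length(x$breaks))])
    hi <- c(x$breaks[-c(1L, length(x$breaks))], Inf)
    if (length(x$lr) == 1L) { lo <- -Inf; hi <- Inf }
    data.frame(bin = seq_along(x$lr), lower = lo, upper = hi,
               pos_count = x$pos_counts, neg_count = x$neg_counts, lr = x$lr)
  }
}

#' Per-score likelihood ratios from a fitted binned model
#'
#' Maps scores to their bin's likelihood ratio. Continuous scores outside
#' the fitted range fall into the corresponding end bin; categorical values
#' never seen during fitting contribute the neutral LR 1.
#'
#' @param object a [fit_binned_likelihood()] model.
#' @param scores numeric scores.
#' @param ... unused.
#' @export
predict.binned_lr <- function(object, scores, ...) {
  b <- object$bin_of(scores)
  out <- rep(1, length(scores))
  ok <- !is.na(b) & b >= 1L & b <= length(object$lr)
  out[ok] <- object$lr[b[ok]]
  out
}

#' Composite likelihood ratios under naive Bayes
#'
#' For each pair in the universe, the composite LR is the product of the bin
#' LRs of every evidence that covers the pair; evidence missing for a pair
#' contributes the neutral factor 1, so pairs covered by no evidence carry
#' LR exactly 1. Accumulation is done in the log domain.
#'
#' @param pairs data.frame of the candidate pair universe (`gene_a`,
#'   `gene_b`); defaults to the union of pairs scored by any evidence.
#' @param models list of [fit_binned_likelihood()] models, parallel to `evs`.
#' @param evs list of [evidence_table] objects.
#' @param prior_odds prior odds of functional linkage (default 1, so
#'   posterior odds equal the composite LR).
#' @return data.frame of class `composite_lr` with columns `gene_a`,
#'   `gene_b`, `lr`, `log_lr`, `n_evidence`, `posterior_odds`; attribute
#'   `"prior_odds"`.
#' @export
composite_lr <- function(pairs = NULL, models, evs, prior_odds = 1) {
  stopifnot(length(models) == length(evs))
  if (prior_odds <= 0) stop_invalid_parameter("`prior_odds` must be > 0")
  if (is.null(pairs)) {
    pairs <- unique(do.call(rbind, lapply(evs, function(ev) {
      data.frame(gene_a = ev$gene_a, gene_b = ev$gene_b)
    })))
  }
  pairs <- unique(canonicalize_pairs(pairs[, 1:2]))
  keys <- pair_key(pairs$gene_a, pairs$gene_b)
  log_lr <- rep(0, nrow(pairs))
  n_ev <- integer(nrow(pairs))
  for (i in seq_along(evs)) {
    ev <- evs[[i]]
    if (nrow(ev) == 0L) next
    hit <- match(pair_key(ev$gene_a, ev$gene_b), keys)
    ok <- !is.na(hit)
    if (!any(ok)) next
    lr_i <- predict(models[[i]], ev$score[ok])
    log_lr[hit[ok]] <- log_lr[hit[ok]] + log(lr_i)
    n_ev[hit[ok]] <- n_ev[hit[ok]] + 1L
  }
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    lr = exp(log_lr), log_lr = log_lr, n_evidence = n_ev)
  out$posterior_odds <- prior_odds * out$lr
  attr(out, "prior_odds") <- prior_odds
  class(out) <- c("composite_lr", "data.frame")
  out
}

# Composite LR of the gold pairs (pairs absent from `comp` carry LR 1,
# the missing-evidence contract).
gold_scores <- function(comp, gold) {
  keys <- pair_key(comp$gene_a, comp$gene_b)
  gk <- gold_keys(gold)
  score_of <- function(k) {
    hit <- match(k, keys)
    ifelse(is.na(hit), 1, comp$lr[hit])
  }
  list(pos = score_of(gk$pos), neg = score_of(gk$neg))
}

#' True/false positive curve over composite-LR cutoffs
#'
#' At each cutoff, `TP` is the number of gold positives with composite LR at
#' or above the cutoff and `FP` the corresponding count of gold negatives;
#' `ratio = TP/FP` is the precision-style accuracy measure used to select
#' the network cutoff (at `TP/FP = 1` precision is 50%), and sensitivity is
#' `TP / (TP + FN)`. Both TP and FP are non-increasing in the cutoff.
#'
#' @param comp a [composite_lr()] table.
#' @param gold a [gold_standard].
#' @param cutoffs ordered cutoff values; defaults to the sorted distinct
#'   gold-pair scores.
#' @return data.frame `(cutoff, tp, fp, ratio, sensitivity)`; `ratio` is
#'   `Inf` where `FP = 0` and `TP > 0`, `NaN` where both are 0.
#' @export
tp_fp_curve <- function(comp, gold, cutoffs = NULL) {
  gs <- gold_scores(comp, gold)
  if (is.null(cutoffs)) cutoffs <- sort(unique(c(gs$pos, gs$neg)))
  cutoffs <- sort(cutoffs)
  tp <- vapply(cutoffs, function(cc) sum(gs$pos >= cc), 0L)
  fp <- vapply(cutoffs, function(cc) sum(gs$neg >= cc), 0L)
  data.frame(cutoff = cutoffs, tp = tp, fp = fp, ratio = tp / fp,
             sensitivity = tp / length(gs$pos))
}

#' Select the composite-LR cutoff reaching a target TP/FP ratio
#'
#' Returns the smallest evaluated cutoff whose TP/FP ratio is at or above
#' `target_ratio` (default 1, the 50%-precision point). A cutoff where
#' `FP = 0` and `TP > 0` has infinite ratio and qualifies.
#'
#' @param curve a [tp_fp_curve()] result.
#' @param target_ratio required TP/FP ratio (default 1).
#' @return the selected cutoff value.
#' @export
select_cutoff <- function(curve, target_ratio = 1) {
  if (nrow(curve) == 0L) stop_invalid_input("empty curve")
  ok <- !is.nan(curve$ratio) & curve$ratio >= target_ratio
  if (!any(ok)) {
    stop_not_attainable(sprintf("no evaluated cutoff reaches TP/FP >= %g",
                                target_ratio))
  }
  min(curve$cutoff[ok])
}

#' Build the weighted functional linkage network
#'
#' Keeps every scored pair among `genes` whose composite LR is at or above
#' `cutoff` (all scored pairs when `cutoff` is `NULL`), with the composite
#' LR as edge weight. Genes incident to no retained edge are dropped from
#' the node set and recorded in the network's isolated-gene registry.
#'
#' @param genes character vector of eligible genes (e.g. the
#'   high-confidence inventory).
#' @param comp a [composite_lr()] table.
#' @param cutoff LR threshold, or `NULL` for the unfiltered network.
#' @return an [fln] object.
#' @export
build_fln <- function(genes, comp, cutoff = NULL) {
  genes <- unique(as.character(genes))
  keep <- comp$gene_a %in% genes & comp$gene_b %in% genes
  if (!is.null(cutoff)) keep <- keep & comp$lr >= cutoff
  edges <- data.frame(gene_a = comp$gene_a[keep], gene_b = comp$gene_b[keep],
                      weight = comp$lr[keep])
  g <- fln(edges, metadata = list(cutoff = cutoff))
  g$isolated <- sort(setdiff(genes, g$nodes))
  g
}

# Trapezoidal ROC/AUC over score thresholds (descending); ties share a
# threshold so tied scores produce a single ROC point.
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) {
    stop_undefined_metric("ROC undefined: need both classes")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels), 0L) / np
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels), 0L) / nn
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Five-fold cross-validated evaluation of evidence integration
#'
#' Stratified five-fold cross-validation on the gold standard: binned LR
#' models are fitted per evidence on four folds and held-out gold pairs are
#' scored by each single evidence, by the full integrated model, and
#' (optionally) by integrated subsets grouped by evidence scale
#' (genome-scale vs mitochondria-specific). Pooled held-out scores yield one
#' ROC curve and trapezoidal AUC per model.
#'
#' @param evs named list of [evidence_table] objects.
#' @param gold a [gold_standard] with >= 5 pairs per class.
#' @param n_bins,pseudocount passed to [fit_binned_likelihood()].
#' @param seed integer seed for the fold partition.
#' @param by_scale also evaluate integrated models restricted to each
#'   `scale_tag` group (default TRUE when tags differ).
#' @return list with `auc` (named vector), `roc` (named list of ROC point
#'   data.frames), and `scores` (pooled held-out scores per model).
#' @export
crossvalidate_integration_5fold <- function(evs, gold, n_bins = 5,
                                            pseudocount = 1, seed = 1,
                                            by_scale = NULL) {
  n_folds <- 5L
  if (nrow(gold$positives) < n_folds || nrow(gold$negatives) < n_folds) {
    stop_invalid_input("gold standard too small for 5 folds per class")
  }
  if (is.null(names(evs)) || any(!nzchar(names(evs)))) {
    names(evs) <- vapply(evs, attr, "", "evidence_name")
  }
  tags <- vapply(evs, function(e) attr(e, "scale_tag") %||% "genome-scale", "")
  if (is.null(by_scale)) by_scale <- length(unique(tags)) > 1L

  all_pairs <- rbind(gold$positives, gold$negatives)
  labels <- rep(c(TRUE, FALSE),
                c(nrow(gold$positives), nrow(gold$negatives)))
  fold <- stratified_folds(labels, n_folds, seed)

  model_names <- c(names(evs), "integrated",
                   if (by_scale) paste0("integrated_", unique(tags)))
  pooled <- stats::setNames(
    rep(list(numeric(nrow(all_pairs))), length(model_names)), model_names)

  for (f in seq_len(n_folds)) {
    test <- fold == f
    train_gold <- gold_standard(gold$positives[fold[labels] != f, , drop = FALSE],
                                gold$negatives[fold[!labels] != f, , drop = FALSE])
    models <- lapply(evs, fit_binned_likelihood, gold = train_gold,
                     n_bins = n_bins, pseudocount = pseudocount)
    test_pairs <- all_pairs[test, , drop = FALSE]
    per_ev <- lapply(seq_along(evs), function(i) {
      comp <- composite_lr(test_pairs, models[i], evs[i])
      comp$lr
    })
    for (i in seq_along(evs)) pooled[[names(evs)[i]]][test] <- per_ev[[i]]
    log_all <- Reduce(`+`, lapply(per_ev, log))
    pooled[["integrated"]][test] <- exp(log_all)
    if (by_scale) {
      for (tg in unique(tags)) {
        sel <- which(tags == tg)
        pooled[[paste0("integrated_", tg)]][test] <-
          exp(Reduce(`+`, lapply(per_ev[sel], log)))
      }
    }
  }

  rocs <- lapply(pooled, roc_auc, labels = labels)
  list(auc = vapply(rocs, `[[`, 0, "auc"),
       roc = lapply(rocs, `[[`, "points"),
       scores = pooled, labels = labels)
}
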