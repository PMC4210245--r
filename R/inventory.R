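# Stage 1: classify proteins as mitochondrial from the detection matrix,
# estimate sensitivity/FDR by stratified 10-fold cross-validation, and
# assemble the confidence-tiered inventory.

#' Confusion counts
#'
#' @param TP,FP,FN,TN non-negative counts.
#' @return named integer vector of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(is.na(v)) || any(v < 0)) {
    stop_invalid_input("confusion counts must be non-negative")
  }
  structure(v, class = "confusion_counts")
}

#' Sensitivity and false discovery rate
#'
#' `sensitivity = TP / (TP + FN)`; `fdr = FP / (FP + TP)`. A zero
#' denominator raises a classed `mitofln_undefined_metric` error rather than
#' silently returning 0.
#'
#' @param counts a [confusion_counts] object or named vector with `TP`,
#'   `FP`, `FN`, `TN`.
#' @return a fraction in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  if (tp + fn == 0) stop_undefined_metric("sensitivity undefined: TP + FN = 0")
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
fdr <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  if (tp + fp == 0) stop_undefined_metric("FDR undefined: TP + FP = 0")
  fp / (fp + tp)
}

# Stratified fold assignment: within each class, a seeded shuffle followed
# by round-robin assignment, so every fold holds both classes whenever each
# class has at least n_folds members.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Stratified 10-fold cross-validation of the boosted classifier
#'
#' Partitions the labeled genes (gold standard positives and negatives) into
#' stratified folds, trains [adaboost_stumps()] on nine folds and tests on
#' the held-out fold, and aggregates the confusion counts over all folds.
#'
#' @param x binary detection matrix restricted to labeled genes.
#' @param y binary labels (1 = gold positive).
#' @param rounds boosting rounds.
#' @param seed integer seed controlling the fold partition.
#' @param n_folds number of folds (default 10).
#' @return list with `confusion` ([confusion_counts] aggregated over folds),
#'   `per_fold` (data.frame of per-fold counts), `sensitivity`, `fdr`, and
#'   `folds` (the fold id per gene).
#' @export
crossvalidate_10fold <- function(x, y, rounds = 50, seed = 1, n_folds = 10) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_invalid_input("one label per row required")
  tab <- table(y)
  if (length(tab) < 2L) stop_invalid_input("both classes required")
  if (min(tab) < n_folds) {
    stop_invalid_input(sprintf(
      "each class needs at least %d labeled genes for %d-fold CV",
      n_folds, n_folds))
  }
  fold <- stratified_folds(y, n_folds, seed)
  per_fold <- lapply(seq_len(n_folds), function(f) {
    test <- fold == f
    model <- adaboost_stumps(x[!test, , drop = FALSE], y[!test], rounds)
    pred <- predict(model, x[test, , drop = FALSE])
    data.frame(fold = f,
               TP = sum(pred == 1 & y[test] == 1),
               FP = sum(pred == 1 & y[test] == 0),
               FN = sum(pred == 0 & y[test] == 1),
               TN = sum(pred == 0 & y[test] == 0))
  })
  per_fold <- do.call(rbind, per_fold)
  cc <- confusion_counts(sum(per_fold$TP), sum(per_fold$FP),
                         sum(per_fold$FN), sum(per_fold$TN))
  list(confusion = cc, per_fold = per_fold,
       sensitivity = sensitivity(cc), fdr = fdr(cc), folds = fold)
}

#' Assemble the confidence-tiered protein inventory
#'
#' The voting policy: a gene is high-confidence if the classifier predicted
#' it positive or it belongs to the curated gold standard positive set
#' (classifier false negatives on the GSP are restored manually);
#' of the remaining genes, a gene is middle-confidence if it appears in the
#' reference compendium or was detected in more than `vote_threshold`
#' experiments (strictly more, so the default 5 means >= 6 detections);
#' everything else is low-confidence.
#'
#' @param predicted_positive character vector of genes the classifier called
#'   positive.
#' @param gsp character vector of curated gold standard positive genes.
#' @param reference_members character vector of reference-compendium genes
#'   (MitoP2/MitoCarta analogue).
#' @param detections binary matrix with gene rownames; its rownames define
#'   the gene universe.
#' @param vote_threshold detection-count threshold for the middle tier
#'   (strict `>`; default 5).
#' @return data.frame of class `inventory_tiers` with columns `gene`,
#'   `tier` (`high`/`middle`/`low`), `detection_count`, `predicted`,
#'   `in_gsp`, `in_reference`; tier counts in attribute `"counts"`.
#' @export
assemble_inventory <- function(predicted_positive, gsp, reference_members,
                               detections, vote_threshold = 5) {
  validate_detections(detections)
  genes <- rownames(detections)
  for (set in list(predicted_positive, gsp, reference_members)) {
    if (!all(set %in% genes)) {
      stop_invalid_input("all gene sets must lie within the detection matrix universe")
    }
  }
  dc <- rowSums(detections)
  predicted <- genes %in% predicted_positive
  in_gsp <- genes %in% gsp
  in_ref <- genes %in% reference_members
  tier <- ifelse(predicted | in_gsp, "high",
                 ifelse(in_ref | dc > vote_threshold, "middle", "low"))
  out <- data.frame(gene = genes, tier = tier,
                    detection_count = as.integer(dc),
                    predicted = predicted, in_gsp = in_gsp,
                    in_reference = in_ref)
  attr(out, "counts") <- table(factor(tier, levels = c("high", "middle", "low")))
  class(out) <- c("inventory_tiers", "data.frame")
  out
}

#' @export
print.inventory_tiers <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Inventory: %d genes — %d high, %d middle, %d low confidence\n",
              nrow(x), cnt[["high"]], cnt[["middle"]], cnt[["low"]]))
  invisible(x)
}

#' Write inventory tiers and CV metrics to TSV
#'
#' @param inv an [assemble_inventory()] result.
#' @param path output path.
#' @export
write_inventory <- function(inv, path) {
  utils::write.table(as.data.frame(inv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
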