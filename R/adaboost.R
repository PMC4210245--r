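# AdaBoost.M1 over one-feature decision stumps on binary features.
#
# The feature space is a 0/1 detection matrix, so each weak learner is fully
# described by a feature index and the feature value that votes positive
# (feature index 0 denotes the degenerate constant stump, the ensemble's
# intercept).
# With weights summing to one, the stump predicting positive on x_j == 1 and
# the stump predicting positive on x_j == 0 have complementary weighted
# errors, so one pass over features evaluates all stumps. Ties between
# stumps are broken toward the lowest feature index (and toward the
# value-1 polarity within a feature), which together with the absence of
# any sampling makes training deterministic given the input order.

best_stump <- function(x, y, w) {
  # err1[j]: weighted error of "positive iff x_j == 1"
  pos <- x == 1L
  err1 <- colSums(w * (pos != y))
  err0 <- 1 - err1                      # complement stump, weights sum to 1
  use0 <- err0 < err1                   # strict: ties prefer value-1 polarity
  err <- ifelse(use0, err0, err1)
  j <- which.min(err)                   # which.min takes the first minimum
  # the degenerate stump whose split is uninformative predicts a constant
  # class; it supplies the intercept of the ensemble vote and is taken only
  # when strictly better than every single-feature stump
  errc1 <- sum(w * (1L != y))           # always-positive
  errc0 <- 1 - errc1                    # always-negative
  if (min(errc1, errc0) < err[[j]]) {
    return(list(feature = 0L, value = if (errc0 < errc1) 0L else 1L,
                error = min(errc1, errc0)))
  }
  list(feature = j, value = if (use0[j]) 0L else 1L, error = err[[j]])
}

stump_predict <- function(feature, value, x) {
  if (feature == 0L) rep(value, nrow(x)) else as.integer(x[, feature] == value)
}

#' Train an AdaBoost.M1 classifier of decision stumps
#'
#' Boosted one-feature decision stumps over a binary feature matrix, the
#' classifier used to call mitochondrial proteins from multi-experiment
#' detection profiles. Rounds stop early when a weak learner achieves zero
#' weighted error (the remaining rounds could not change the prediction) or
#' when no stump beats chance (weighted error >= 0.5).
#'
#' @param x binary matrix, observations x features.
#' @param y binary labels (0/1 or logical), one per row of `x`; both classes
#'   must be present.
#' @param rounds maximum number of boosting rounds (>= 1).
#' @return object of class `adaboost_stumps`: data.frame `stumps` with
#'   columns `feature`, `value`, `alpha`, `error`, plus the feature names.
#' @examples
#' x <- rbind(matrix(1L, 5, 3), matrix(0L, 5, 3))
#' m <- adaboost_stumps(x, rep(c(1, 0), each = 5), rounds = 5)
#' predict(m, x)
#' @export
adaboost_stumps <- function(x, y, rounds = 50) {
  x <- as.matrix(x)
  if (!all(x %in% c(0L, 1L))) stop_invalid_input("features must be binary 0/1")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_invalid_input("one label per row required")
  if (length(unique(y)) < 2L) {
    stop_invalid_input("training labels contain a single class")
  }
  if (rounds < 1) stop_invalid_parameter("`rounds` must be >= 1")

  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- vector("list", rounds)
  for (t in seq_len(rounds)) {
    s <- best_stump(x, y, w)
    if (s$error >= 0.5) break          # no weak learner beats chance
    eps <- max(s$error, 1e-10)         # cap the vote of a perfect stump
    alpha <- log((1 - eps) / eps)
    stumps[[t]] <- data.frame(feature = s$feature, value = s$value,
                              alpha = alpha, error = s$error)
    if (s$error == 0) break
    pred <- stump_predict(s$feature, s$value, x)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  stumps <- do.call(rbind, stumps[!vapply(stumps, is.null, NA)])
  if (is.null(stumps)) {
    stop_invalid_input("no stump performed better than chance on round 1")
  }
  structure(list(stumps = stumps, features = colnames(x), n_train = n),
            class = "adaboost_stumps")
}

#' @export
print.adaboost_stumps <- function(x, ...) {
  cat(sprintf("AdaBoost.M1 stump ensemble: %d weak learners over %d features\n",
              nrow(x$stumps), length(x$features %||% integer())))
  invisible(x)
}

#' Predict with a boosted stump ensemble
#'
#' The ensemble margin is `sum_t alpha_t (2 h_t(x) - 1)`; the predicted
#' class is positive when the margin is strictly positive (a zero margin
#' votes negative, deterministically).
#'
#' @param object an [adaboost_stumps] model.
#' @param newdata binary feature matrix.
#' @param type `"class"` for 0/1 predictions or `"score"` for the margin.
#' @param ... unused.
#' @export
predict.adaboost_stumps <- function(object, newdata,
                                    type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  margin <- rep(0, nrow(x))
  for (i in seq_len(nrow(object$stumps))) {
    h <- stump_predict(object$stumps$feature[i], object$stumps$value[i], x)
    margin <- margin + object$stumps$alpha[i] * (2 * h - 1)
  }
  if (type == "score") margin else as.integer(margin > 0)
}
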