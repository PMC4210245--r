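# Stage 3: rank candidate disease genes on the weighted network by
# propagating signal from seed genes. Four algorithms: average adjacency
# ranking (AAR), PageRank with priors (PRP), K-step Markov (KSM), and heat
# kernel diffusion ranking (HKDR).
#
# Orientation convention: with A the symmetric weighted adjacency and
# W = D^-1 A the row-stochastic transition matrix, probability mass placed
# on seeds propagates by the transpose, p <- t(W) p, so mass flows from
# seeds outward along transition probabilities. Zero-degree nodes are
# excluded from normalization, keep score 0, and are flagged.

#' Transition model of a weighted network
#'
#' Sparse symmetric adjacency `A` (`a_ij = w_ij`), weighted degrees
#' `D`, and the row-stochastic transition matrix `W = D^-1 A` of a random
#' walk on the network. Rows of `W` sum to 1 for every node with positive
#' degree; zero-degree nodes (possible only via the isolated-gene registry)
#' are flagged. The Laplacian-like operator used by heat diffusion is
#' `L = I - W`.
#'
#' @param g an [fln] object.
#' @param include_isolated also carry the isolated-gene registry as
#'   zero-degree nodes (default TRUE so rankings cover the full inventory).
#' @return object of class `transition_model`: `nodes`, sparse `A`, `W`,
#'   `degree`, `zero_degree` (logical).
#' @export
transition_model <- function(g, include_isolated = TRUE) {
  stopifnot(inherits(g, "fln"))
  nodes <- g$nodes
  if (include_isolated) nodes <- sort(c(nodes, g$isolated))
  n <- length(nodes)
  i <- match(g$edges$gene_a, nodes)
  j <- match(g$edges$gene_b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(g$edges$weight, 2L),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  deg <- Matrix::rowSums(A)
  zero <- deg == 0
  inv_deg <- ifelse(zero, 0, 1 / deg)
  W <- Matrix::Diagonal(n, inv_deg) %*% A
  structure(list(nodes = nodes, A = A, W = W,
                 degree = deg, zero_degree = zero),
            class = "transition_model")
}

as_transition <- function(g) {
  if (inherits(g, "transition_model")) g else transition_model(g)
}

# Resolve a seed set against the network nodes: must be non-empty after
# intersection; seeds absent from the network are dropped with a warning.
resolve_seeds <- function(tm, seeds) {
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, tm$nodes)
  if (length(missing)) {
    warning(sprintf("%d seed gene(s) absent from the network were dropped",
                    length(missing)))
  }
  seeds <- intersect(seeds, tm$nodes)
  if (length(seeds) == 0L) stop_invalid_input("no seed gene is in the network")
  sort(seeds)
}

seed_vector <- function(tm, seeds) {
  p <- stats::setNames(numeric(length(tm$nodes)), tm$nodes)
  p[seeds] <- 1 / length(seeds)
  p
}

ranking_result <- function(algorithm, params, scores, seeds, extras = list()) {
  stopifnot(all(is.finite(scores)))
  structure(list(algorithm = algorithm, params = params,
                 scores = scores, seeds = seeds, extras = extras),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  pstr <- paste(sprintf("%s=%s", names(x$params), unlist(x$params)),
                collapse = ", ")
  cat(sprintf("%s ranking (%s): %d genes scored, %d seeds\n",
              toupper(x$algorithm), pstr, length(x$scores), length(x$seeds)))
  print(utils::head(rank_candidates(x), 5))
  invisible(x)
}

#' Average adjacency ranking (AAR)
#'
#' Repeatedly samples `m` of the seed genes; in each iteration every gene
#' outside the sampled subset accrues the sum of its linkage weights to the
#' sampled seeds. The final score of gene `i` is its accumulated sum divided
#' by `n_i`, the number of iterations in which `i` was eligible (not
#' sampled). With `m` equal to the full seed count the score is exactly the
#' summed adjacency to all seeds.
#'
#' @param g an [fln] or [transition_model].
#' @param seeds character vector of seed genes (subset of the nodes).
#' @param m subset size per iteration, `1 <= m <= |seeds|` (default all
#'   seeds).
#' @param iterations number of resampling iterations (default 100).
#' @param seed integer RNG seed.
#' @return a `ranking_result`.
#' @export
aar <- function(g, seeds, m = NULL, iterations = 100, seed = 1) {
  tm <- as_transition(g)
  seeds <- resolve_seeds(tm, seeds)
  m <- m %||% length(seeds)
  if (m < 1 || m > length(seeds)) {
    stop_invalid_parameter("`m` must satisfy 1 <= m <= |seeds|")
  }
  if (iterations < 1) stop_invalid_parameter("`iterations` must be >= 1")
  n <- length(tm$nodes)
  acc <- stats::setNames(numeric(n), tm$nodes)
  n_elig <- stats::setNames(numeric(n), tm$nodes)
  if (m == length(seeds)) {
    contrib <- Matrix::rowSums(tm$A[, seeds, drop = FALSE])
    elig <- !(tm$nodes %in% seeds)
    acc[elig] <- contrib[elig]
    n_elig[elig] <- 1
  } else {
    with_seed(seed, {
      for (it in seq_len(iterations)) {
        s <- sample(seeds, m)
        contrib <- Matrix::rowSums(tm$A[, s, drop = FALSE])
        elig <- !(tm$nodes %in% s)
        acc[elig] <- acc[elig] + contrib[elig]
        n_elig[elig] <- n_elig[elig] + 1
      }
    })
  }
  scores <- ifelse(n_elig > 0, acc / pmax(n_elig, 1), 0)
  names(scores) <- tm$nodes
  ranking_result("aar", list(m = m, iterations = iterations), scores, seeds,
                 extras = list(eligible_iterations = n_elig))
}

#' PageRank with priors (PRP)
#'
#' Random walk with restart: at every step the walker jumps back to a seed
#' (chosen uniformly) with probability `beta`, otherwise follows the
#' transition probabilities. The stationary distribution
#' `pi = beta p + (1 - beta) t(W) pi` is found by power iteration; scores
#' sum to 1 over nodes with positive degree.
#'
#' @param g an [fln] or [transition_model].
#' @param seeds character vector of seed genes.
#' @param beta back-probability in `[0, 1]`; `beta = 1` returns the prior.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap; non-convergence raises a classed error
#'   carrying the residual.
#' @return a `ranking_result`.
#' @export
prp <- function(g, seeds, beta = 0.3, tol = 1e-10, max_iter = 10000) {
  tm <- as_transition(g)
  seeds <- resolve_seeds(tm, seeds)
  if (beta < 0 || beta > 1) stop_invalid_parameter("`beta` must be in [0, 1]")
  p <- seed_vector(tm, seeds)
  if (beta == 1) {
    return(ranking_result("prp", list(beta = beta), p, seeds))
  }
  Wt <- Matrix::t(tm$W)
  pi_v <- p
  for (it in seq_len(max_iter)) {
    nxt <- beta * p + (1 - beta) * as.numeric(Wt %*% pi_v)
    s <- sum(nxt)
    if (s > 0) nxt <- nxt / s          # re-inject mass lost at dangling nodes
    resid <- sum(abs(nxt - pi_v))
    pi_v <- nxt
    if (resid < tol) {
      names(pi_v) <- tm$nodes
      return(ranking_result("prp", list(beta = beta), pi_v, seeds,
                            extras = list(iterations = it, residual = resid)))
    }
  }
  stop_convergence_failure(
    sprintf("PageRank with priors did not converge in %d iterations (residual %.3g)",
            max_iter, resid),
    residual = resid)
}

#' K-step Markov ranking (KSM)
#'
#' Cumulative visit probability over exactly `K` random-walk steps starting
#' from the uniform seed distribution: `score = sum_{k=1..K} t(W)^k p_R`.
#' When every reached node has positive degree each step's vector sums to 1,
#' so the scores total `K`.
#'
#' @param g an [fln] or [transition_model].
#' @param seeds character vector of seed genes.
#' @param K number of steps (>= 1; default 6).
#' @return a `ranking_result`.
#' @export
ksm <- function(g, seeds, K = 6) {
  tm <- as_transition(g)
  seeds <- resolve_seeds(tm, seeds)
  if (K < 1) stop_invalid_parameter("`K` must be >= 1")
  Wt <- Matrix::t(tm$W)
  v <- seed_vector(tm, seeds)
  total <- numeric(length(v))
  for (k in seq_len(K)) {
    v <- as.numeric(Wt %*% v)
    total <- total + v
  }
  names(total) <- tm$nodes
  ranking_result("ksm", list(K = K), total, seeds)
}

#' Heat kernel diffusion ranking (HKDR)
#'
#' Discrete approximation of heat diffusion of the seed signal over the
#' network: with `L = I - W` and diffusion rate `alpha`, the ranking is
#' `p = (I - (alpha / N) t(L))^N p_0`, which converges to
#' `exp(-alpha t(L)) p_0` as the iteration count `N` grows. `alpha = 0`
#' returns the seed vector unchanged. Mass is conserved when every node has
#' positive degree.
#'
#' @param g an [fln] or [transition_model].
#' @param seeds character vector of seed genes.
#' @param alpha diffusion rate, >= 0 (default 1).
#' @param n_iter number of iterations `N` (>= 1; default 5).
#' @return a `ranking_result`.
#' @export
hkdr <- function(g, seeds, alpha = 1, n_iter = 5) {
  tm <- as_transition(g)
  seeds <- resolve_seeds(tm, seeds)
  if (alpha < 0) stop_invalid_parameter("`alpha` must be >= 0")
  if (n_iter < 1) stop_invalid_parameter("`n_iter` must be >= 1")
  Wt <- Matrix::t(tm$W)
  a <- alpha / n_iter
  p <- seed_vector(tm, seeds)
  for (k in seq_len(n_iter)) {
    # (I - a t(L)) p = (1 - a) p + a t(W) p
    p <- (1 - a) * p + a * as.numeric(Wt %*% p)
  }
  names(p) <- tm$nodes
  ranking_result("hkdr", list(alpha = alpha, n_iter = n_iter), p, seeds)
}

#' Rank candidate genes from propagation scores
#'
#' Orders genes by descending score with ties broken by ascending gene
#' identifier; seed genes are excluded (unless `exclude_seeds = FALSE`, in
#' which case they are kept and flagged). Optional confidence bands split
#' the candidates into three levels by score tertiles.
#'
#' @param result a `ranking_result`.
#' @param exclude_seeds drop seed genes from the candidate list (default
#'   TRUE).
#' @param bands add a `band` column (`top`/`middle`/`bottom` score
#'   tertiles).
#' @return data.frame `(rank, gene, score, is_seed)`.
#' @export
rank_candidates <- function(result, exclude_seeds = TRUE, bands = FALSE) {
  stopifnot(inherits(result, "ranking_result"))
  df <- data.frame(gene = names(result$scores),
                   score = as.numeric(result$scores),
                   is_seed = names(result$scores) %in% result$seeds)
  if (exclude_seeds) df <- df[!df$is_seed, , drop = FALSE]
  df <- df[order(-df$score, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  if (bands && nrow(df) > 0L) {
    q <- stats::quantile(df$score, c(1 / 3, 2 / 3), names = FALSE)
    df$band <- ifelse(df$score > q[2L], "top",
                      ifelse(df$score > q[1L], "middle", "bottom"))
  }
  rownames(df) <- NULL
  df[, c("rank", "gene", "score", "is_seed",
         if (bands) "band")]
}

#' Write a ranking to TSV
#'
#' @param result a `ranking_result`.
#' @param path output path.
#' @param ... passed to [rank_candidates()].
#' @export
write_ranking <- function(result, path, ...) {
  utils::write.table(rank_candidates(result, ...), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
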