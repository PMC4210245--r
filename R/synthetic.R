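# Synthetic-data module: generates every input the pipeline consumes with
# known ground truth — a gene universe with true mitochondrial membership,
# pathway/complex annotations (from which the gold standard derives),
# class-conditional pairwise evidence scores, multi-experiment detection
# matrices, and disease modules planted in a weighted network.
#
# Every generator is a pure function of its arguments and a single integer
# seed; RNG state is scoped so repeated calls with the same seed reproduce
# the output exactly and calls never perturb the caller's RNG.

#' Generate a synthetic gene universe with pathway annotations
#'
#' Creates `n_mito` genuinely mitochondrial and `n_nonmito` non-mitochondrial
#' genes, then samples `n_pathways` pathway/complex memberships, each drawn
#' without replacement from the mitochondrial genes with size uniform on
#' `pathway_size_range`. Genes may belong to several pathways; only
#' mitochondrial genes are ever annotated, mirroring organelle-restricted
#' pathway curation.
#'
#' @param n_mito number of true mitochondrial genes (>= 1).
#' @param n_nonmito number of contaminant / non-mitochondrial genes (>= 0).
#' @param n_pathways number of pathways to sample (>= 1).
#' @param pathway_size_range integer interval `c(min, max)` of pathway sizes;
#'   sizes must be >= 2 and at most `n_mito`.
#' @param seed integer seed.
#' @return object of class `synthetic_world`: `proteins` (character ids),
#'   `true_mito` (named logical), `pathways` (named list of member vectors),
#'   `disease_modules` (named list, empty until planted), `rng_seed`.
#' @examples
#' w <- make_world(50, 20, n_pathways = 5, pathway_size_range = c(4, 8), seed = 1)
#' @export
make_world <- function(n_mito, n_nonmito, n_pathways,
                       pathway_size_range = c(5, 15), seed = 1) {
  if (length(n_mito) != 1L || n_mito < 1) {
    stop_invalid_parameter("`n_mito` must be >= 1")
  }
  if (length(n_nonmito) != 1L || n_nonmito < 0) {
    stop_invalid_parameter("`n_nonmito` must be >= 0")
  }
  if (length(n_pathways) != 1L || n_pathways < 1) {
    stop_invalid_parameter("`n_pathways` must be >= 1")
  }
  pathway_size_range <- as.integer(round(pathway_size_range))
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1L] < 2L ||
      pathway_size_range[1L] > pathway_size_range[2L]) {
    stop_invalid_parameter("`pathway_size_range` must be an interval with min >= 2")
  }
  if (pathway_size_range[2L] > n_mito) {
    stop_invalid_parameter("pathway size cannot exceed `n_mito`")
  }
  n_total <- n_mito + n_nonmito
  width <- max(4L, nchar(as.character(n_total)))
  proteins <- sprintf("G%0*d", width, seq_len(n_total))
  true_mito <- stats::setNames(seq_len(n_total) <= n_mito, proteins)
  mito_ids <- proteins[true_mito]

  size_choices <- seq(pathway_size_range[1L], pathway_size_range[2L])
  pathways <- with_seed(seed, {
    sizes <- size_choices[sample.int(length(size_choices), n_pathways,
                                     replace = TRUE)]
    lapply(sizes, function(s) sort(sample(mito_ids, s, replace = FALSE)))
  })
  names(pathways) <- sprintf("P%02d", seq_len(n_pathways))

  structure(
    list(proteins = proteins, true_mito = true_mito, pathways = pathways,
         disease_modules = list(), rng_seed = as.integer(seed)),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d genes (%d mitochondrial), %d pathways, %d disease modules (seed %d)\n",
              length(x$proteins), sum(x$true_mito), length(x$pathways),
              length(x$disease_modules), x$rng_seed))
  invisible(x)
}

#' Gold standard pair sets
#'
#' Container for gold standard positive (GSP) and negative (GSN) unordered
#' gene pairs. Pairs are stored in canonical sorted-identifier order;
#' self-pairs are rejected and the two sets must be disjoint.
#'
#' @param positives,negatives data.frames with columns `gene_a`, `gene_b`.
#' @return object of class `gold_standard`.
#' @export
gold_standard <- function(positives, negatives) {
  empty <- data.frame(gene_a = character(), gene_b = character())
  positives <- if (nrow(positives)) canonicalize_pairs(positives[, 1:2]) else empty
  negatives <- if (nrow(negatives)) canonicalize_pairs(negatives[, 1:2]) else empty
  for (df in list(positives, negatives)) {
    if (any(df$gene_a == df$gene_b)) stop_invalid_input("self-pairs not allowed")
  }
  pk <- pair_key(positives$gene_a, positives$gene_b)
  nk <- pair_key(negatives$gene_a, negatives$gene_b)
  if (anyDuplicated(pk) || anyDuplicated(nk)) {
    stop_invalid_input("duplicate pairs within a gold-standard set")
  }
  if (length(intersect(pk, nk))) {
    stop_invalid_input("positive and negative pair sets must be disjoint")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("Gold standard: %d positive pairs (GSP), %d negative pairs (GSN)\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

#' Derive the gold standard from pathway co-membership
#'
#' Positives are unordered pairs of genes co-occurring in at least one
#' pathway/complex; negatives are pairs where both genes carry at least one
#' annotation but share none. Unannotated genes contribute no pairs.
#'
#' @param world a [make_world()] object with at least one pathway.
#' @return a [gold_standard] object.
#' @examples
#' w <- make_world(30, 10, n_pathways = 3, pathway_size_range = c(3, 6), seed = 2)
#' make_gold_standard(w)
#' @export
make_gold_standard <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  if (length(world$pathways) < 1L) {
    stop_invalid_input("world has no pathways to derive a gold standard from")
  }
  annotated <- sort(unique(unlist(world$pathways)))
  n <- length(annotated)
  if (n < 2L) {
    return(gold_standard(data.frame(gene_a = character(), gene_b = character()),
                         data.frame(gene_a = character(), gene_b = character())))
  }
  # membership matrix genes x pathways; shared-term counts via crossproduct
  M <- vapply(world$pathways, function(p) annotated %in% p,
              logical(n))
  if (is.null(dim(M))) M <- matrix(M, nrow = n)
  S <- tcrossprod(M * 1)          # S[i,j] = number of shared pathways
  idx <- which(upper.tri(S), arr.ind = TRUE)
  shared <- S[upper.tri(S)]
  pos <- idx[shared > 0, , drop = FALSE]
  neg <- idx[shared == 0, , drop = FALSE]
  gold_standard(
    data.frame(gene_a = annotated[pos[, 1L]], gene_b = annotated[pos[, 2L]]),
    data.frame(gene_a = annotated[neg[, 1L]], gene_b = annotated[neg[, 2L]])
  )
}

# ---- evidence -------------------------------------------------------------

# Supported class-conditional score distribution families.
validate_distribution <- function(d) {
  if (!is.list(d) || is.null(d$family)) {
    stop_invalid_parameter("distribution must be list(family=, ...)")
  }
  switch(d$family,
    normal = {
      if (is.null(d$mean) || is.null(d$sd) || d$sd <= 0) {
        stop_invalid_parameter("normal distribution needs mean and sd > 0")
      }
    },
    beta = {
      if (is.null(d$shape1) || is.null(d$shape2) ||
          d$shape1 <= 0 || d$shape2 <= 0) {
        stop_invalid_parameter("beta distribution needs shape1, shape2 > 0")
      }
    },
    stop_invalid_parameter(sprintf("unsupported distribution family '%s'",
                                   d$family))
  )
  d
}

draw_scores <- function(d, n) {
  switch(d$family,
         normal = stats::rnorm(n, d$mean, d$sd),
         beta = stats::rbeta(n, d$shape1, d$shape2))
}

density_at <- function(d, x) {
  switch(d$family,
         normal = stats::dnorm(x, d$mean, d$sd),
         beta = stats::dbeta(x, d$shape1, d$shape2))
}

# P(score in (lo, hi]) under distribution d; used as the analytic per-bin
# probability when checking likelihood-ratio recovery.
prob_interval <- function(d, lo, hi) {
  cdf <- switch(d$family,
                normal = function(q) stats::pnorm(q, d$mean, d$sd),
                beta = function(q) stats::pbeta(q, d$shape1, d$shape2))
  cdf(hi) - cdf(lo)
}

#' Specify a synthetic pairwise evidence source
#'
#' Describes one heterogeneous evidence dataset (co-expression correlation,
#' interaction score, semantic similarity, ...) by its class-conditional
#' score distributions: functionally linked pairs draw from
#' `positive_distribution`, unlinked pairs from `negative_distribution`.
#' `coverage` is the fraction of the pair universe for which a score exists
#' at all; missingness is applied uniformly at random, independent of class.
#'
#' @param name evidence name.
#' @param positive_distribution,negative_distribution `list(family = "normal",
#'   mean=, sd=)` or `list(family = "beta", shape1=, shape2=)`; both must use
#'   the same family so they share a common support.
#' @param coverage fraction in `[0, 1]`.
#' @param scale_tag `"genome-scale"` or `"mitochondria-specific"`, used to
#'   group evidences in scale-restricted integration.
#' @return object of class `evidence_spec`.
#' @export
evidence_spec <- function(name,
                          positive_distribution = list(family = "normal", mean = 1, sd = 1),
                          negative_distribution = list(family = "normal", mean = 0, sd = 1),
                          coverage = 1,
                          scale_tag = c("genome-scale", "mitochondria-specific")) {
  scale_tag <- match.arg(scale_tag)
  validate_distribution(positive_distribution)
  validate_distribution(negative_distribution)
  if (!identical(positive_distribution$family, negative_distribution$family)) {
    stop_invalid_parameter("positive and negative distributions must share a family (common support)")
  }
  if (length(coverage) != 1L || is.na(coverage) || coverage < 0 || coverage > 1) {
    stop_invalid_parameter("`coverage` must be in [0, 1]")
  }
  structure(list(name = as.character(name),
                 positive_distribution = positive_distribution,
                 negative_distribution = negative_distribution,
                 coverage = coverage, scale_tag = scale_tag),
            class = "evidence_spec")
}

#' Evidence score table
#'
#' Sparse mapping from unordered gene pairs to scores for one evidence
#' source; at most one score per pair.
#'
#' @param df data.frame with columns `gene_a`, `gene_b`, `score`.
#' @param name evidence name.
#' @param scale_tag optional scale annotation.
#' @return data.frame of class `evidence_table` (canonical pair order) with
#'   attributes `evidence_name` and `scale_tag`.
#' @export
evidence_table <- function(df, name, scale_tag = "genome-scale") {
  if (nrow(df) == 0L) {
    df <- data.frame(gene_a = character(), gene_b = character(),
                     score = numeric())
  } else {
    df <- canonicalize_pairs(df[, c("gene_a", "gene_b", "score")])
    if (any(df$gene_a == df$gene_b)) stop_invalid_input("self-pairs not allowed")
    if (anyDuplicated(pair_key(df$gene_a, df$gene_b))) {
      stop_invalid_input("at most one score per pair per evidence")
    }
  }
  structure(df, class = c("evidence_table", "data.frame"),
            evidence_name = as.character(name),
            scale_tag = scale_tag)
}

#' Simulate evidence scores over a pair universe
#'
#' Covers `floor(coverage * n_pairs)` pairs selected uniformly at random;
#' each covered pair draws its score from the positive distribution if it is
#' a gold positive (or listed in `extra_positives`, e.g. planted linkages),
#' otherwise from the negative distribution.
#'
#' @param gold a [gold_standard] object (its positives define the linked
#'   class).
#' @param all_pairs data.frame of the pair universe (`gene_a`, `gene_b`);
#'   defaults to the union of gold positives and negatives.
#' @param spec an [evidence_spec].
#' @param seed integer seed.
#' @param extra_positives optional data.frame of additional pairs to treat
#'   as linked.
#' @return an [evidence_table].
#' @export
simulate_evidence <- function(gold, all_pairs = NULL, spec, seed,
                              extra_positives = NULL) {
  stopifnot(inherits(gold, "gold_standard"), inherits(spec, "evidence_spec"))
  if (is.null(all_pairs)) {
    all_pairs <- rbind(gold$positives, gold$negatives)
  }
  all_pairs <- canonicalize_pairs(all_pairs[, 1:2])
  n_cov <- floor(spec$coverage * nrow(all_pairs))
  if (n_cov == 0L) {
    return(evidence_table(data.frame(gene_a = character(), gene_b = character(),
                                     score = numeric()),
                          name = spec$name, scale_tag = spec$scale_tag))
  }
  pos_keys <- pair_key(gold$positives$gene_a, gold$positives$gene_b)
  if (!is.null(extra_positives) && nrow(extra_positives)) {
    ep <- canonicalize_pairs(extra_positives[, 1:2])
    pos_keys <- union(pos_keys, pair_key(ep$gene_a, ep$gene_b))
  }
  with_seed(seed, {
    covered <- all_pairs[sort(sample.int(nrow(all_pairs), n_cov)), ]
    is_pos <- pair_key(covered$gene_a, covered$gene_b) %in% pos_keys
    score <- numeric(n_cov)
    score[is_pos] <- draw_scores(spec$positive_distribution, sum(is_pos))
    score[!is_pos] <- draw_scores(spec$negative_distribution, sum(!is_pos))
    covered$score <- score
    evidence_table(covered, name = spec$name, scale_tag = spec$scale_tag)
  })
}

# ---- detections -----------------------------------------------------------

validate_detections <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop_invalid_input("detection matrix needs gene rownames and dataset colnames")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_invalid_input("duplicate gene or dataset identifiers")
  }
  if (!all(m %in% c(0L, 1L))) stop_invalid_input("detection values must be 0/1")
  invisible(m)
}

#' Simulate a binary detection matrix
#'
#' Emulates a collection of mitochondrial purification proteomics
#' experiments: each gene is detected in each dataset independently with a
#' class-specific Bernoulli probability — high for genuine mitochondrial
#' proteins, low for contaminants that co-purify sporadically.
#'
#' @param world a [make_world()] object.
#' @param n_datasets number of simulated experiments.
#' @param p_detect_mito detection probability for true mitochondrial genes.
#' @param p_detect_contaminant detection probability for other genes.
#' @param seed integer seed.
#' @return integer 0/1 matrix, genes x datasets.
#' @export
simulate_detections <- function(world, n_datasets, p_detect_mito,
                                p_detect_contaminant, seed) {
  stopifnot(inherits(world, "synthetic_world"))
  for (p in c(p_detect_mito, p_detect_contaminant)) {
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop_invalid_parameter("detection probabilities must be in [0, 1]")
    }
  }
  if (n_datasets < 1) stop_invalid_parameter("`n_datasets` must be >= 1")
  n <- length(world$proteins)
  p_gene <- ifelse(world$true_mito, p_detect_mito, p_detect_contaminant)
  m <- with_seed(seed, {
    matrix(stats::rbinom(n * n_datasets, 1L, rep(p_gene, times = n_datasets)),
           nrow = n, ncol = n_datasets)
  })
  storage.mode(m) <- "integer"
  dimnames(m) <- list(world$proteins, sprintf("DS%02d", seq_len(n_datasets)))
  m
}

# ---- disease modules ------------------------------------------------------

#' Plant disease gene modules in a weighted network
#'
#' Samples `n_diseases` disjoint gene modules from the network's nodes and
#' strengthens each module's internal cohesion: existing internal edges have
#' their weights multiplied by `boost`; when `boost > 1`, internal edges
#' absent from the network are created at the network's median edge weight
#' (times `boost`). `boost = 1` leaves the network exactly unchanged.
#'
#' @param g an [fln] object.
#' @param n_diseases number of modules.
#' @param module_size genes per module (`n_diseases * module_size` must not
#'   exceed the node count).
#' @param boost weight multiplier, >= 1.
#' @param seed integer seed.
#' @return list with `fln` (modified network) and `modules` (named list of
#'   gene sets, `D01`, `D02`, ...).
#' @export
plant_disease_modules <- function(g, n_diseases, module_size, boost, seed) {
  stopifnot(inherits(g, "fln"))
  if (boost < 1) stop_invalid_parameter("`boost` must be >= 1")
  if (module_size < 2) stop_invalid_parameter("`module_size` must be >= 2")
  n_nodes <- length(g$nodes)
  if (module_size > n_nodes) {
    stop_invalid_parameter("`module_size` exceeds the node count")
  }
  if (n_diseases * module_size > n_nodes) {
    stop_invalid_parameter("disjoint modules need n_diseases * module_size <= node count")
  }
  modules <- with_seed(seed, {
    picked <- sample(g$nodes, n_diseases * module_size, replace = FALSE)
    split(picked, rep(seq_len(n_diseases), each = module_size))
  })
  modules <- lapply(modules, sort)
  names(modules) <- sprintf("D%02d", seq_len(n_diseases))

  if (boost == 1) {
    return(list(fln = g, modules = modules))
  }
  edges <- g$edges
  baseline <- stats::median(edges$weight)
  keys <- pair_key(edges$gene_a, edges$gene_b)
  for (mod in modules) {
    idx <- utils::combn(mod, 2L)
    mk <- pair_key(idx[1L, ], idx[2L, ])
    hit <- match(mk, keys)
    present <- !is.na(hit)
    edges$weight[hit[present]] <- edges$weight[hit[present]] * boost
    if (any(!present)) {
      add <- data.frame(gene_a = idx[1L, !present], gene_b = idx[2L, !present],
                        weight = baseline * boost)
      edges <- rbind(edges, canonicalize_pairs(add))
      keys <- c(keys, mk[!present])
    }
  }
  list(fln = fln(edges, isolated = g$isolated, metadata = g$metadata),
       modules = modules)
}
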