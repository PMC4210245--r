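# Shared fixtures, built in code at test time.

# Small weighted graph used across prioritization tests:
#   a-b (2), b-c (1), c-d (3), a-d (1), b-d (0.5)
toy_fln <- function() {
  fln(data.frame(
    gene_a = c("a", "b", "c", "a", "b"),
    gene_b = c("b", "c", "d", "d", "d"),
    weight = c(2, 1, 3, 1, 0.5)
  ))
}

# Random simple weighted graph on n nodes with ~n_edges edges (deduplicated).
random_fln <- function(n_nodes, n_edges, seed = 1, max_weight = 5) {
  genes <- sprintf("n%02d", seq_len(n_nodes))
  set.seed(seed)
  a <- sample(genes, 4 * n_edges, replace = TRUE)
  b <- sample(genes, 4 * n_edges, replace = TRUE)
  keep <- a != b
  df <- data.frame(gene_a = pmin(a, b)[keep], gene_b = pmax(a, b)[keep])
  df <- unique(df)[seq_len(n_edges), ]
  df$weight <- stats::runif(nrow(df), 0.1, max_weight)
  fln(df)
}

# Brute-force gold standard: double loop over all protein pairs, the
# independent oracle for make_gold_standard.
gold_bruteforce <- function(world) {
  annotated <- sort(unique(unlist(world$pathways)))
  pos <- list(); neg <- list()
  terms_of <- function(g) names(world$pathways)[
    vapply(world$pathways, function(p) g %in% p, NA)]
  k <- 0L
  for (i in seq_along(annotated)) {
    for (j in seq_along(annotated)) {
      if (i >= j) next
      k <- k + 1L
      shared <- length(intersect(terms_of(annotated[i]), terms_of(annotated[j])))
      row <- data.frame(gene_a = annotated[i], gene_b = annotated[j])
      if (shared > 0) pos[[length(pos) + 1L]] <- row
      else neg[[length(neg) + 1L]] <- row
    }
  }
  empty <- data.frame(gene_a = character(), gene_b = character())
  list(positives = if (length(pos)) do.call(rbind, pos) else empty,
       negatives = if (length(neg)) do.call(rbind, neg) else empty)
}

# Standard three-evidence configuration used by integration tests: two
# genome-scale and one mitochondria-specific evidence, all informative.
informative_specs <- function() {
  list(
    coexpr = evidence_spec("coexpr",
                           list(family = "normal", mean = 1.2, sd = 1),
                           list(family = "normal", mean = 0, sd = 1),
                           coverage = 0.8),
    domain = evidence_spec("domain",
                           list(family = "beta", shape1 = 4, shape2 = 2),
                           list(family = "beta", shape1 = 2, shape2 = 4),
                           coverage = 0.6),
    ppi = evidence_spec("ppi",
                        list(family = "normal", mean = 1, sd = 1),
                        list(family = "normal", mean = 0, sd = 1),
                        coverage = 0.7, scale_tag = "mitochondria-specific")
  )
}

simulate_evidences <- function(gold, specs, seed) {
  pairs <- rbind(gold$positives, gold$negatives)
  evs <- lapply(seq_along(specs), function(i) {
    simulate_evidence(gold, pairs, specs[[i]], seed = seed * 100 + i)
  })
  names(evs) <- vapply(evs, attr, "", "evidence_name")
  evs
}

# Synthetic gold standard of the requested size built directly from
# fabricated pair identifiers (for large-sample likelihood-ratio checks
# where pathway-derived gold standards would be unwieldy).
fabricated_gold <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  a <- sprintf("a%06d", seq_len(n))
  b <- sprintf("b%06d", seq_len(n))
  gold_standard(
    data.frame(gene_a = a[seq_len(n_pos)], gene_b = b[seq_len(n_pos)]),
    data.frame(gene_a = a[n_pos + seq_len(n_neg)], gene_b = b[n_pos + seq_len(n_neg)])
  )
}

# Dense matrix pieces of a transition model, for oracle computations.
dense_tm <- function(g) {
  tm <- transition_model(g)
  list(nodes = tm$nodes, A = as.matrix(tm$A), W = as.matrix(tm$W),
       degree = as.numeric(tm$degree))
}
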