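# Core weighted-graph model: the functional linkage network (FLN) container,
# its summary statistics, and the pair-counting conventions.

#' Construct a weighted functional linkage network
#'
#' An FLN is an undirected simple graph over gene identifiers whose edge
#' weights are positive reals (composite likelihood ratios when built by
#' [build_fln()]). Self-loops and duplicate undirected edges are rejected;
#' edges are stored in canonical (lexicographically sorted identifier) order.
#' The node set consists of genes incident to at least one edge; genes known
#' to the analysis but isolated in the network can be carried along in the
#' `isolated` registry for reporting.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @param isolated optional character vector of isolated genes to register
#'   (not part of the node set used by graph statistics).
#' @param metadata optional list of construction provenance (cutoff used,
#'   evidence names, ...).
#' @return An object of class `fln` with fields `edges` (canonical
#'   data.frame), `nodes` (sorted incident genes), `isolated`, `metadata`.
#' @examples
#' g <- fln(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
#'                     weight = c(2, 3)))
#' graph_stats(g)
#' @export
fln <- function(edges, isolated = character(), metadata = list()) {
  if (!is.data.frame(edges)) stop_invalid_input("`edges` must be a data.frame")
  if (nrow(edges) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric())
  }
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(edges))) {
    stop_invalid_input("edge table needs columns gene_a, gene_b, weight")
  }
  edges <- canonicalize_pairs(edges[, need])
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$gene_a == edges$gene_b)) {
    stop_invalid_input("self-loops are not allowed in an FLN")
  }
  if (anyDuplicated(pair_key(edges$gene_a, edges$gene_b))) {
    stop_invalid_input("duplicate undirected edges are not allowed")
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop_invalid_input("edge weights must be finite and > 0")
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(
    list(edges = edges, nodes = nodes,
         isolated = sort(setdiff(as.character(isolated), nodes)),
         metadata = metadata),
    class = "fln"
  )
}

#' @export
print.fln <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf("Functional linkage network: %d nodes, %d edges\n",
              s$nodes, s$edges))
  cat(sprintf("  average neighbors %.3f, density %.3f\n",
              s$average_neighbors, s$density))
  if (length(x$isolated)) {
    cat(sprintf("  (+%d isolated genes registered)\n", length(x$isolated)))
  }
  invisible(x)
}

#' @export
summary.fln <- function(object, ...) {
  s <- graph_stats(object)
  s$weight_summary <- summary(object$edges$weight)
  s
}

#' Graph statistics of a weighted network
#'
#' Node and edge counts plus the two derived statistics used to describe
#' FLNs: average number of neighbors `2E/N` (0 for the empty graph) and
#' density `2E/(N(N-1))` (0 when `N < 2`).
#'
#' @param g an [fln] object.
#' @return list with `nodes`, `edges`, `average_neighbors`, `density`.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "fln"))
  n <- length(g$nodes)
  e <- nrow(g$edges)
  list(
    nodes = n,
    edges = e,
    average_neighbors = if (n > 0) 2 * e / n else 0,
    density = if (n >= 2) 2 * e / (n * (n - 1)) else 0
  )
}

#' Count candidate gene pairs under two conventions
#'
#' The combinatorial convention counts unordered pairs of distinct genes,
#' `n(n-1)/2`. The `paper` convention is `floor(n^2 / 2)`, the rounding that
#' some published inventories use when quoting the number of potential
#' pairwise linkages among `n` proteins; it exceeds the combinatorial count
#' by `floor(n/2)`.
#'
#' @param n non-negative gene count.
#' @param convention `"combinatorial"` (default) or `"paper"`.
#' @return pair count (numeric, exact for n well below 2^26).
#' @examples
#' pair_count(1124)            # 631126 unordered pairs
#' pair_count(1124, "paper")   # 631688
#' @export
pair_count <- function(n, convention = c("combinatorial", "paper")) {
  convention <- match.arg(convention)
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != floor(n)) {
    stop_invalid_parameter("`n` must be a single non-negative integer")
  }
  n <- as.numeric(n)
  switch(convention,
         combinatorial = n * (n - 1) / 2,
         paper = floor(n * n / 2))
}

#' Complete network over a gene set with uniform weights
#'
#' Utility used for benchmarking unfiltered ("no cutoff") networks, where
#' every pair of genes is linked.
#'
#' @param genes character vector of gene identifiers (or a single count, in
#'   which case identifiers `g1..gN` are generated).
#' @param weight common edge weight (default 1).
#' @return an [fln] object with `choose(N, 2)` edges.
#' @export
complete_fln <- function(genes, weight = 1) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("g%d", seq_len(genes))
  }
  genes <- sort(unique(as.character(genes)))
  n <- length(genes)
  if (n < 2) stop_invalid_parameter("need at least 2 genes")
  idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  fln(data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                 weight = weight))
}

# igraph view of an fln; used for GraphML I/O and as an independent
# cross-check in tests.
as_igraph <- function(g) {
  stopifnot(inherits(g, "fln"))
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = g$nodes)
  )
  igraph::E(ig)$weight <- g$edges$weight
  ig
}
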