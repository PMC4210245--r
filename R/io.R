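# Plain-text I/O: TSV edge lists, GraphML, GMT gene sets, and the pipeline's
# tabular interchange formats. All TSVs are tab-separated UTF-8 with a header.

#' Read a weighted edge list from TSV
#'
#' Expects the exact header `gene_a<TAB>gene_b<TAB>weight`. Rows are
#' canonicalized to sorted-identifier order; a file containing both (a,b)
#' and (b,a) is rejected as a duplicate edge. Malformed rows are reported
#' with their line number; non-positive weights are a validation error.
#'
#' @param path file path.
#' @return an [fln] object.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop_parse_error(sprintf("%s: empty file", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("gene_a", "gene_b", "weight"))) {
    stop_parse_error(sprintf(
      "%s: line 1: expected header 'gene_a\\tgene_b\\tweight'", path))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop_parse_error(sprintf("%s: line %d: expected 3 tab-separated fields",
                             path, bad[1L] + 1L))
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  w <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(w)) {
    stop_parse_error(sprintf("%s: line %d: non-numeric weight",
                             path, which(is.na(w))[1L] + 1L))
  }
  if (any(w <= 0)) {
    mf_stop(sprintf("%s: line %d: weight must be > 0",
                    path, which(w <= 0)[1L] + 1L),
            "mitofln_validation_error")
  }
  edges <- data.frame(gene_a = m[, 1L], gene_b = m[, 2L], weight = w)
  if (anyDuplicated(pair_key(edges$gene_a, edges$gene_b))) {
    mf_stop(sprintf("%s: duplicate undirected edge", path),
            "mitofln_validation_error")
  }
  fln(edges)
}

#' Write a weighted edge list to TSV
#'
#' Inverse of [read_edgelist()]: `read_edgelist(write_edgelist(g, p))`
#' reproduces `g` up to row order.
#'
#' @param g an [fln] object.
#' @param path output path.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "fln"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export / import GraphML
#'
#' GraphML per the standard schema with the edge weight carried as an edge
#' attribute named `weight`.
#'
#' @param g an [fln] object.
#' @param path file path.
#' @export
export_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  df <- igraph::as_data_frame(ig, what = "edges")
  fln(data.frame(gene_a = df$from, gene_b = df$to, weight = df$weight))
}

#' Read and write GMT gene sets
#'
#' GMT: one set per line, `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop_parse_error(sprintf("%s: line %d: GMT row needs name, description and >=1 member",
                             path, short[1L]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write gold-standard pair tables
#'
#' TSV with columns `gene_a`, `gene_b`, `label` where label is `pos` or
#' `neg`.
#'
#' @param path file path.
#' @return a [gold_standard] object.
#' @export
read_gold_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "label") %in% names(df))) {
    stop_parse_error(sprintf("%s: expected columns gene_a, gene_b, label", path))
  }
  if (!all(df$label %in% c("pos", "neg"))) {
    stop_parse_error(sprintf("%s: label must be 'pos' or 'neg'", path))
  }
  gold_standard(df[df$label == "pos", 1:2], df[df$label == "neg", 1:2])
}

#' @rdname read_gold_pairs
#' @param gold a [gold_standard] object.
#' @export
write_gold_pairs <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  df <- rbind(
    cbind(gold$positives, label = rep("pos", nrow(gold$positives))),
    cbind(gold$negatives, label = rep("neg", nrow(gold$negatives)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write evidence score tables
#'
#' TSV with columns `gene_a`, `gene_b`, `evidence_name`, `score`; one file
#' may hold several evidences. `read_evidence` returns a named list of
#' [evidence_table] objects.
#'
#' @param path file path.
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "evidence_name", "score")
  if (!all(need %in% names(df))) {
    stop_parse_error(sprintf("%s: expected columns %s", path,
                             paste(need, collapse = ", ")))
  }
  split_df <- split(df[, c("gene_a", "gene_b", "score")], df$evidence_name)
  lapply(stats::setNames(nm = names(split_df)), function(nm) {
    evidence_table(split_df[[nm]], name = nm)
  })
}

#' @rdname read_evidence
#' @param evs a single [evidence_table] or a list of them.
#' @export
write_evidence <- function(evs, path) {
  if (inherits(evs, "evidence_table")) evs <- list(evs)
  rows <- do.call(rbind, lapply(evs, function(ev) {
    data.frame(gene_a = ev$gene_a, gene_b = ev$gene_b,
               evidence_name = attr(ev, "evidence_name"), score = ev$score)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write binary detection matrices
#'
#' Genes-by-datasets 0/1 TSV; first column `gene` holds identifiers.
#'
#' @param path file path.
#' @export
read_detections <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene") {
    stop_parse_error(sprintf("%s: first column must be 'gene'", path))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  validate_detections(m)
  m
}

#' @rdname read_detections
#' @param m binary matrix with gene rownames and dataset colnames.
#' @export
write_detections <- function(m, path) {
  validate_detections(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the gene table of a synthetic world
#'
#' Columns: `gene`, `true_mito` (0/1), `pathways` (semicolon-joined ids).
#'
#' @param world a [make_world()] object.
#' @param path output path.
#' @export
write_gene_table <- function(world, path) {
  stopifnot(inherits(world, "synthetic_world"))
  pw <- vapply(world$proteins, function(g) {
    paste(names(world$pathways)[vapply(world$pathways, function(p) g %in% p, NA)],
          collapse = ";")
  }, "")
  df <- data.frame(gene = world$proteins,
                   true_mito = as.integer(world$true_mito),
                   pathways = pw)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
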