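# Internal helpers: classed error conditions, seeded RNG scope, pair keys.

mf_stop <- function(msg, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "mitofln_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

stop_invalid_parameter <- function(msg) mf_stop(msg, "mitofln_invalid_parameter")
stop_invalid_input <- function(msg) mf_stop(msg, "mitofln_invalid_input")
stop_undefined_metric <- function(msg) mf_stop(msg, "mitofln_undefined_metric")
stop_not_fittable <- function(msg) mf_stop(msg, "mitofln_not_fittable")
stop_not_attainable <- function(msg) mf_stop(msg, "mitofln_not_attainable")
stop_parse_error <- function(msg) mf_stop(msg, "mitofln_parse_error")
stop_convergence_failure <- function(msg, residual = NA_real_) {
  mf_stop(msg, "mitofln_convergence_failure", residual = residual)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
# All generators route their randomness through this so a single integer seed
# fully determines the output and no hidden global state leaks.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Canonical unordered-pair key: identifiers sorted lexicographically and
# joined by a tab (which cannot occur inside a TSV field).
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# Put a two-column pair frame in canonical (sorted-id) order and drop
# attributes; returns a data.frame with columns gene_a, gene_b (+ extras kept).
canonicalize_pairs <- function(df) {
  a <- as.character(df[[1L]])
  b <- as.character(df[[2L]])
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  out <- df
  out[[1L]] <- a
  out[[2L]] <- b
  names(out)[1:2] <- c("gene_a", "gene_b")
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
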