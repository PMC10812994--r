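#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= overlap)` where X is the overlap between
#' a random query of the observed size and the gene set, drawn without
#' replacement from the universe.
#'
#' @param query Character vector of query genes (deduplicated).
#' @param gene_set Character vector of set members.
#' @param universe Character vector of background genes; query and set are
#'   intersected with it.
#' @return List: `p`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`.
#' @export
hypergeometric_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("hypergeometric_test: empty universe")
  q <- unique(intersect(query, universe))
  s <- unique(intersect(gene_set, universe))
  k <- length(intersect(q, s))
  p <- if (k == 0L) 1 else
    stats::phyper(k - 1, length(s), N - length(s), length(q),
                  lower.tail = FALSE)
  list(p = p, overlap = k, set_size = length(s), query_size = length(q),
       universe_size = N)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving in the input.
#'
#' @param p_values Numeric vector of p-values.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list
#'
#' One hypergeometric test per gene set with at least `min_overlap`
#' overlapping genes; Benjamini-Hochberg adjustment within each category
#' (mirroring per-ontology reporting) or globally.
#'
#' @param query Character vector of query genes (deduplicated before
#'   testing).
#' @param collections Named list of gene sets (as from
#'   [read_gene_sets()]), or a list of such lists, one per category.
#' @param universe Background gene vector, typically the genes that
#'   survived preprocessing.
#' @param q_max Keep terms with q below this (default 1 = keep all;
#'   typical reporting uses 0.05).
#' @param min_overlap Minimum overlap to test a set (default 3).
#' @param by_category Adjust within category (default `TRUE`).
#' @return Data.frame sorted by q then p: `set`, `category`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `q`.
#' @export
run_enrichment <- function(query, collections, universe, q_max = 1,
                           min_overlap = 3L, by_category = TRUE) {
  if (!is.list(collections[[1]]) || is.character(collections[[1]])) {
    collections <- list(user = collections)
  }
  query <- unique(query)
  rows <- list()
  for (cat in names(collections)) {
    sets <- collections[[cat]]
    for (nm in names(sets)) {
      ht <- hypergeometric_test(query, sets[[nm]], universe)
      if (ht$overlap < min_overlap) next
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, category = cat, overlap = ht$overlap,
        set_size = ht$set_size, query_size = ht$query_size,
        universe_size = ht$universe_size, p = ht$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(set = character(0), category = character(0),
                      overlap = integer(0), set_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  if (by_category) {
    out$q <- NA_real_
    for (cat in unique(out$category)) {
      sel <- out$category == cat
      out$q[sel] <- bh_adjust(out$p[sel])
    }
  } else {
    out$q <- bh_adjust(out$p)
  }
  out <- out[out$q <= q_max, , drop = FALSE]
  out <- out[order(out$q, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
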