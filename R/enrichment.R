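# Category over-representation of significant proteins: fold enrichment,
# upper-tail hypergeometric test, BH FDR across categories, and the display
# filters used for pathway bar charts (fold > cutoff, q < FDR cutoff, top N
# by fold). The background universe should be the set of proteins with at
# least one quantified site (conditioning on detectability), not the whole
# proteome.

#' Fold enrichment
#'
#' `(k/n) / (m/N)`: the proportion of the significant list falling in a
#' category relative to the category's share of the background universe.
#'
#' @param k Hits (significant proteins in the category).
#' @param n Significant-list size.
#' @param m Category size (within the universe).
#' @param N Universe size.
#' @return Fold enrichment (>= 0).
#' @examples
#' fold_enrichment(3, 5, 5, 20)  # 2.4
#' @export
fold_enrichment <- function(k, n, m, N) {
  if (any(N <= 0) || any(n <= 0) || any(m <= 0)) {
    stop("n, m and N must be positive")
  }
  (k / n) / (m / N)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the number of category members among `n` draws without
#' replacement from a universe of `N` containing `m` category members — the
#' standard over-representation test.
#'
#' @inheritParams fold_enrichment
#' @return Upper-tail probability.
#' @examples
#' hypergeom_upper(3, 5, 5, 20)  # 1126/15504
#' @export
hypergeom_upper <- function(k, n, m, N) {
  if (any(N <= 0) || any(n <= 0) || any(m <= 0)) stop("n, m and N must be positive")
  if (any(n > N) || any(m > N)) stop("n and m cannot exceed N")
  if (any(k > pmin(n, m)) || any(k < 0)) {
    stop("impossible configuration: k must lie in [0, min(n, m)]")
  }
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Category over-representation analysis
#'
#' Tests each annotation category for over-representation of the significant
#' protein set against the background universe, adjusts across categories by
#' Benjamini-Hochberg, and applies the display filters: keep categories with
#' `q_bh < fdr_cut` and `fold_enrichment > min_fold`, sort by descending fold
#' (ties broken by ascending q, then category id), truncate to `top_n`.
#' Categories with fewer than 2 members in the universe are dropped before
#' testing. The unfiltered table is attached as attribute `"all"`.
#'
#' @param sig_proteins Character vector of significant protein ids (must be a
#'   subset of `universe`).
#' @param annotations Data frame with columns `category_id`, `protein_id`
#'   (long format) and optionally `category_name`.
#' @param universe Character vector of background protein ids.
#' @param top_n Keep at most this many categories (default 10).
#' @param min_fold Fold-enrichment display cutoff (default 5).
#' @param fdr_cut BH FDR display cutoff (default 0.05).
#' @return Data frame of `EnrichmentRow`s: `category_id`, `category_name`,
#'   `k`, `n`, `m`, `N`, `fold_enrichment`, `p`, `q_bh`.
#' @export
enrich <- function(sig_proteins, annotations, universe, top_n = 10L,
                   min_fold = 5, fdr_cut = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty background universe")
  sig_proteins <- unique(as.character(sig_proteins))
  if (length(setdiff(sig_proteins, universe))) {
    stop("significant proteins must be a subset of the universe")
  }
  ann <- as.data.frame(annotations)
  if (!all(c("category_id", "protein_id") %in% names(ann))) {
    stop("'annotations' needs columns category_id and protein_id")
  }
  if (!"category_name" %in% names(ann)) ann$category_name <- ann$category_id
  ann <- ann[ann$protein_id %in% universe, , drop = FALSE]

  empty <- data.frame(category_id = character(), category_name = character(),
                      k = integer(), n = integer(), m = integer(), N = integer(),
                      fold_enrichment = numeric(), p = numeric(), q_bh = numeric())
  if (!length(sig_proteins) || !nrow(ann)) {
    attr(empty, "all") <- empty
    return(empty)
  }

  members <- split(unique(ann[c("category_id", "protein_id")])$protein_id,
                   unique(ann[c("category_id", "protein_id")])$category_id)
  members <- members[lengths(members) >= 2L]   # singletons dropped
  if (!length(members)) { attr(empty, "all") <- empty; return(empty) }
  nm <- ann$category_name[match(names(members), ann$category_id)]

  N <- length(universe); n <- length(sig_proteins)
  rows <- data.frame(
    category_id = names(members),
    category_name = nm,
    k = vapply(members, function(mm) length(intersect(mm, sig_proteins)), integer(1)),
    n = n,
    m = lengths(members),
    N = N,
    row.names = NULL
  )
  rows$fold_enrichment <- fold_enrichment(rows$k, rows$n, rows$m, rows$N)
  rows$p <- hypergeom_upper(rows$k, rows$n, rows$m, rows$N)
  rows$q_bh <- bh_fdr(rows$p)
  rows <- rows[order(-rows$fold_enrichment, rows$q_bh, rows$category_id), , drop = FALSE]
  rownames(rows) <- NULL

  keep <- rows[rows$q_bh < fdr_cut & rows$fold_enrichment > min_fold, , drop = FALSE]
  keep <- utils::head(keep, top_n)
  rownames(keep) <- NULL
  attr(keep, "all") <- rows
  keep
}
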