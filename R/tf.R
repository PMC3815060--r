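# Transcription-factor module enrichment: hypergeometric
# over-representation of TF target sets in condition-dependent gene sets
# (from the factorial ANOVA) and in the gene sets significantly
# correlated or anti-correlated to each metabolite or lipid, with
# positively and negatively correlated sets tested separately.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) for X ~ hypergeometric(N, K, n):
#' drawing a query of size n from a universe of size N containing K target
#' genes, equal to the one-sided Fisher exact test on the 2x2 table.
#'
#' @param k observed overlap.
#' @param K target-set size.
#' @param n query-set size.
#' @param N universe size.
#' @return One-sided p-value in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' TF target-set enrichment over labeled query gene sets
#'
#' Tests every (TF target set, query set) combination with an observed
#' overlap of at least one gene for over-representation. Target sets are
#' intersected with the universe before testing; query sets must be
#' subsets of the universe. No multiple-testing correction is applied by
#' default (results are thresholded on the raw hypergeometric p, the
#' study's convention); set \code{bh = TRUE} for a BH-adjusted column and
#' thresholding.
#'
#' @param query_sets named list of gene-id vectors (e.g. per-factor ANOVA
#'   sets, or per-metabolite positively/negatively correlated sets).
#' @param tf_targets named list of TF target gene sets.
#' @param universe gene universe the counts refer to (explicit, never
#'   inferred).
#' @param alpha significance threshold (default 0.01).
#' @param bh apply Benjamini-Hochberg across all tested combinations.
#' @return Data frame: tf, query, k, K, n, N, p (and p_bh if requested),
#'   significant.
#' @export
tf_enrichment <- function(query_sets, tf_targets, universe, alpha = 0.01,
                          bh = FALSE) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  N <- length(universe)
  bad <- names(query_sets)[!vapply(query_sets,
                                   function(q) all(q %in% universe), NA)]
  if (length(bad)) stop("query sets outside the universe: ",
                        paste(bad, collapse = ", "))
  rows <- list()
  for (tf in names(tf_targets)) {
    targ <- intersect(tf_targets[[tf]], universe)
    if (length(targ) == 0) next
    for (q in names(query_sets)) {
      qs <- unique(query_sets[[q]])
      k <- length(intersect(targ, qs))
      if (k < 1) next
      rows[[paste(tf, q)]] <- data.frame(
        tf = tf, query = q, k = k, K = length(targ), n = length(qs), N = N,
        p = hypergeom_p(k, length(targ), length(qs), N),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(tf = character(0), query = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0))
  }
  if (bh && nrow(res) > 0) {
    res$p_bh <- bh_adjust(res$p)
    res$significant <- res$p_bh <= alpha
  } else if (nrow(res) > 0) {
    res$significant <- res$p <= alpha
  }
  rownames(res) <- NULL
  res
}

#' Signed correlated gene sets per metabolite
#'
#' Splits the significant correlation records of each target into its
#' positively and negatively correlated gene sets (labels
#' \code{"<target>/+"} and \code{"<target>/-"}), the query sets of the
#' TF-module analysis. A gene positively correlated to a target never
#' enters that target's negative set.
#'
#' @param records \code{\link{all_pairs}} records.
#' @return Named list of gene-id vectors (empty sets dropped).
#' @export
signed_query_sets <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  out <- list()
  for (tg in unique(sig$target)) {
    for (s in c("+", "-")) {
      g <- sig$gene[sig$target == tg & sig$sign == s]
      if (length(g)) out[[paste0(tg, "/", s)]] <- unique(g)
    }
  }
  out
}
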