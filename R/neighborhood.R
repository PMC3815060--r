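# The metabolic-network neighborhood correlation-bias test: for each
# metabolite or lipid, its Pearson correlations to neighbor-gene
# transcripts are compared with its correlations to all non-neighbor
# transcripts by a two-sided Mann-Whitney rank-sum test, with
# Benjamini-Hochberg control across the tested species.

#' Mann-Whitney U test (Wilcoxon rank-sum), two-sided
#'
#' Rank-sum test with midrank ties. The p-value is computed by exact
#' enumeration when the combined sample size is at most \code{exact_max}
#' and the data are tie-free, and otherwise by the normal approximation
#' with tie and continuity correction (the large-sample regime the
#' neighborhood test lives in, with hundreds of genes per group).
#'
#' @param a,b non-empty numeric vectors (the two groups).
#' @param exact_max combined-size cutoff for the exact distribution.
#' @return List with \code{U} (for \code{a} relative to \code{b}) and the
#'   two-sided \code{p}.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {       # no separation at all
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  use_exact <- (length(a) + length(b)) <= exact_max &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted p-values (monotone step-up, order-preserving).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Metabolite x gene correlation matrix
#'
#' Correlation of every target (row of \code{targets}) with every gene
#' transcript across the shared samples, oriented targets x genes -- the
#' input shape of \code{\link{neighborhood_test}} and
#' \code{\link{pathway_test}}.
#'
#' @param expr genes x samples matrix.
#' @param targets targets x samples matrix.
#' @return Numeric matrix, rows = targets, columns = genes.
#' @export
correlation_matrix <- function(expr, targets) {
  expr <- as.matrix(expr); targets <- as.matrix(targets)
  if (ncol(expr) != ncol(targets)) stop("sample count mismatch")
  stats::cor(t(targets), t(expr))
}

#' Neighborhood correlation-bias test
#'
#' For each metabolite (row of \code{cors}) with a non-empty gene
#' neighborhood, compares its correlation coefficients to neighbor genes
#' (order 1: genes of reactions touching it; order 2: genes within two
#' reaction steps) against its correlations to all remaining genes using
#' the two-sided Mann-Whitney test, then adjusts across all tested
#' metabolites by Benjamini-Hochberg. Metabolites missing from the
#' correlation matrix or with empty/degenerate neighborhoods are skipped
#' and listed in the \code{"skipped"} attribute.
#'
#' @param cors targets x genes correlation matrix
#'   (\code{\link{correlation_matrix}}), covering the gene universe of the
#'   map.
#' @param index \code{\link{neighborhoods}} result.
#' @param order 1 or 2: which neighborhood definition to test.
#' @return Data frame of class \code{"neighborhood_result"}: metabolite,
#'   order, U, p, p_bh, direction (sign of the median-rank shift,
#'   \code{"+"} = neighbors more positively correlated), n_linked.
#' @export
neighborhood_test <- function(cors, index, order = 2) {
  stopifnot(inherits(index, "neighborhood_index"), order %in% c(1, 2))
  nb_list <- if (order == 1) index$first else index$second
  genes <- colnames(cors)
  mets <- intersect(rownames(cors), names(nb_list))
  skipped <- setdiff(names(nb_list), rownames(cors))
  if (length(skipped)) {
    warning("metabolites absent from the correlation matrix: ",
            paste(skipped, collapse = ", "))
  }
  rows <- list()
  for (m in mets) {
    nb <- intersect(nb_list[[m]], genes)
    other <- setdiff(genes, nb)
    if (length(nb) == 0 || length(other) == 0) {
      skipped <- c(skipped, m)
      next
    }
    a <- cors[m, nb]; b <- cors[m, other]
    mw <- mann_whitney_u(a, b)
    rows[[m]] <- data.frame(
      metabolite = m, order = order, U = mw$U, p = mw$p,
      direction = if (stats::median(a) >= stats::median(b)) "+" else "-",
      n_linked = length(nb), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable metabolites")
  res$p_bh <- bh_adjust(res$p)
  o <- base::order(res$p_bh, res$p)
  res <- res[o, c("metabolite", "order", "U", "p",
                  "p_bh", "direction", "n_linked")]
  rownames(res) <- NULL
  attr(res, "skipped") <- unique(skipped)
  class(res) <- c("neighborhood_result", "data.frame")
  res
}

#' Report of neighborhood-significant metabolites and lipids
#'
#' Formats the neighborhood-test output in the study's summary-table
#' layout: species passing the BH threshold sorted by adjusted p, with the
#' neighbor-gene count (at the order tested), the count of genes
#' significantly correlated to the species (Bonferroni-adjusted
#' correlation p <= \code{cor_alpha}), and the overlap of those two gene
#' sets.
#'
#' @param results a \code{\link{neighborhood_test}} result.
#' @param records correlation records (\code{\link{all_pairs}}) from the
#'   same run.
#' @param index the neighborhood index used for the test.
#' @param bh_alpha BH threshold for inclusion (default 0.01).
#' @param cor_alpha Bonferroni threshold defining "significantly
#'   correlated" genes (default 0.01).
#' @return Data frame with columns \code{metabolite}, \code{p.BH},
#'   \code{n.MetMap.linked}, \code{n.PCC.sig}, \code{n.linkedANDsig};
#'   empty (with header) when nothing passes.
#' @export
table1_report <- function(results, records, index,
                          bh_alpha = 0.01, cor_alpha = 0.01) {
  stopifnot(inherits(results, "neighborhood_result"))
  keep <- results[results$p_bh <= bh_alpha, , drop = FALSE]
  nb_list <- if (all(keep$order == 1)) index$first else index$second
  out <- data.frame(metabolite = character(0), p.BH = numeric(0),
                    n.MetMap.linked = integer(0), n.PCC.sig = integer(0),
                    n.linkedANDsig = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(keep))) {
    m <- keep$metabolite[i]
    sig_genes <- records$gene[records$target == m & records$p_adj <= cor_alpha]
    linked <- nb_list[[m]]
    out[i, ] <- list(m, keep$p_bh[i], length(linked),
                     length(unique(sig_genes)),
                     length(intersect(linked, unique(sig_genes))))
  }
  out[order(out$p.BH), , drop = FALSE]
}
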