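# Exhaustive gene-expression vs metabolite/lipid Pearson correlation
# testing across all chemostats (replicates treated as independent
# samples, n = 24 in the full design), Bonferroni control within each pair
# class, condition-split opposing-correlation screening, and assembly of
# the significant-correlation network.

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around the product-moment formula for two
#' sample vectors. Constant vectors make the correlation undefined and are
#' rejected rather than returned as NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The correlation coefficient r in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  stats::cor(x, y)
}

#' Two-sided test for zero correlation
#'
#' p-value from t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of
#' freedom, the same test \code{stats::cor.test} performs with the
#' two-sided alternative. |r| = 1 returns p = 0 by convention.
#'
#' @param r correlation coefficient.
#' @param n number of paired samples (>= 3).
#' @return Two-sided p-value.
#' @export
cor_test_p <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0, {
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  })
  p
}

#' All gene-target correlation records for one pair class
#'
#' Computes the Pearson correlation of every gene (row of \code{expr})
#' with every target (row of \code{targets}) across the shared samples,
#' tests each for zero correlation (two-sided), and applies Bonferroni
#' adjustment with family size = number of retained pairs in this layer.
#' Pairs involving a constant or incomplete (NA-containing) feature are
#' dropped and listed in the \code{"dropped"} attribute, not imputed.
#'
#' @param expr genes x samples matrix (log2 expression).
#' @param targets targets x samples matrix (metabolites, lipids or
#'   lipid acyl-chain species, linear scale as measured).
#' @param alpha significance threshold on the adjusted p (default 0.001).
#' @param layer label recorded on each record (e.g. "metabolite").
#' @return Data frame of class \code{"correlation_records"}: gene, target,
#'   layer, r, n, p, p_adj, sign, significant.
#' @export
all_pairs <- function(expr, targets, alpha = 0.001, layer = "metabolite") {
  expr <- as.matrix(expr); targets <- as.matrix(targets)
  if (ncol(expr) != ncol(targets) ||
      (!is.null(colnames(expr)) && !is.null(colnames(targets)) &&
       !identical(colnames(expr), colnames(targets)))) {
    stop("expression and target matrices must share the sample set and order")
  }
  n <- ncol(expr)
  ok_e <- apply(expr, 1, function(v) !anyNA(v) && stats::sd(v) > 0)
  ok_t <- apply(targets, 1, function(v) !anyNA(v) && stats::sd(v) > 0)
  dropped <- c(rownames(expr)[!ok_e], rownames(targets)[!ok_t])
  expr <- expr[ok_e, , drop = FALSE]
  targets <- targets[ok_t, , drop = FALSE]
  R <- stats::cor(t(expr), t(targets))        # genes x targets
  rec <- data.frame(
    gene   = rep(rownames(R), times = ncol(R)),
    target = rep(colnames(R), each = nrow(R)),
    layer  = layer,
    r      = as.vector(R),
    n      = n,
    stringsAsFactors = FALSE
  )
  rec$p <- cor_test_p(rec$r, rec$n)
  fam <- nrow(rec)
  rec$p_adj <- pmin(rec$p * fam, 1)
  rec$sign <- ifelse(rec$r >= 0, "+", "-")
  rec$significant <- rec$p_adj <= alpha
  attr(rec, "family_size") <- fam
  attr(rec, "dropped") <- dropped
  class(rec) <- c("correlation_records", "data.frame")
  rec
}

#' Condition-split screen for opposing correlations
#'
#' Splits the samples in half by one design factor, runs the full
#' correlation analysis separately in each half, and reports pairs
#' significant in both halves, classified as \code{"opposing"} (opposite
#' correlation signs -- the pattern the split exists to find) or
#' \code{"agreeing"}.
#'
#' @param expr,targets matrices as in \code{\link{all_pairs}}.
#' @param design the factorial design of the samples.
#' @param factor one of "C", "O", "T".
#' @param alpha_half per-half threshold on the Bonferroni-adjusted p.
#' @return Data frame with one row per pair significant in both halves:
#'   r and adjusted p per half plus \code{relation}.
#' @export
split_half_opposing <- function(expr, targets, design, factor = "C",
                                alpha_half = 0.001) {
  assert_design(design)
  col <- switch(factor, C = "carbon", O = "oxygen", T = "temperature",
                stop("unknown factor '", factor, "' (use C, O or T)"))
  lv <- sort(unique(design[[col]]), decreasing = TRUE)  # first level first
  halves <- lapply(lv, function(l) design$sample[design[[col]] == l])
  if (any(vapply(halves, length, 0L) < 3)) stop("degenerate half: < 3 samples")
  res <- lapply(halves, function(s) {
    all_pairs(expr[, s, drop = FALSE], targets[, s, drop = FALSE],
              alpha = alpha_half)
  })
  a <- res[[1]]; b <- res[[2]]
  key <- paste(a$gene, a$target)
  stopifnot(identical(key, paste(b$gene, b$target)))
  both <- a$significant & b$significant
  out <- data.frame(gene = a$gene[both], target = a$target[both],
                    r_half1 = a$r[both], p_adj_half1 = a$p_adj[both],
                    r_half2 = b$r[both], p_adj_half2 = b$p_adj[both],
                    stringsAsFactors = FALSE)
  out$relation <- ifelse(sign(out$r_half1) != sign(out$r_half2),
                         "opposing", "agreeing")
  attr(out, "factor") <- factor
  attr(out, "levels") <- lv
  out
}

#' Assemble the significant-correlation network
#'
#' Keeps the significant correlation records whose endpoints pass the
#' requested ANOVA main-effect filter, splits edges into positive and
#' negative classes, and returns a network object ready for Cytoscape
#' export. The gene endpoint must be significant for the filter factor in
#' \code{anova_genes}; if \code{anova_targets} is supplied the target
#' endpoint is filtered the same way.
#'
#' @param records output of \code{\link{all_pairs}} (one or several layers
#'   row-bound together).
#' @param anova_genes \code{\link{fit_factorial}} result for the
#'   expression layer.
#' @param factor_filter main effect to filter on: "C", "O" or "T".
#' @param alpha ANOVA threshold on the adjusted p (default 0.001).
#' @param anova_targets optional ANOVA result for the target layer.
#' @return A \code{"correlation_network"}: node and edge data frames.
#' @export
assemble_network <- function(records, anova_genes, factor_filter = "O",
                             alpha = 0.001, anova_targets = NULL) {
  if (!factor_filter %in% c("C", "O", "T")) {
    stop("unknown factor '", factor_filter, "'")
  }
  keep_genes <- significant_features(anova_genes, alpha)[[factor_filter]]
  ed <- records[records$significant & records$gene %in% keep_genes, , drop = FALSE]
  if (!is.null(anova_targets)) {
    keep_t <- significant_features(anova_targets, alpha)[[factor_filter]]
    ed <- ed[ed$target %in% keep_t, , drop = FALSE]
  }
  nodes <- rbind(
    data.frame(id = unique(ed$gene),
               type = rep("gene", length(unique(ed$gene))),
               stringsAsFactors = FALSE),
    unique(data.frame(id = ed$target, type = ed$layer,
                      stringsAsFactors = FALSE))
  )
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = as.data.frame(ed),
                 factor_filter = factor_filter, alpha = alpha),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network (", x$factor_filter, "-filtered ): ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "+"), " positive, ",
      sum(x$edges$sign == "-"), " negative )\n", sep = "")
  invisible(x)
}
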