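# Per-feature factorial ANOVA: ordinary least squares on the +1/-1 coded
# two-level design, per-term F tests against the residual, and Bonferroni
# selection of condition-dependent features. Under balance the coded
# columns are orthogonal, so X'X = n I and every term has 1 df; the whole
# layer is fitted with two matrix products.

#' Fit the per-feature factorial linear model
#'
#' Each feature (row of \code{matrix}) is regressed on the +1/-1 coded
#' main effects C (carbon), O (oxygen), T (temperature), their pairwise
#' interactions and, by default, the three-way interaction. Every term has
#' one degree of freedom; its F statistic against the residual equals the
#' squared t statistic of its coefficient. Because coding is +1/-1, a
#' coefficient beta corresponds to a level difference of 2*beta.
#'
#' @param matrix numeric features x samples matrix whose columns match
#'   \code{design$sample} (log2 expression, or log2-transformed
#'   abundances if desired -- the model is scale-agnostic).
#' @param design a balanced \code{\link{make_design}} design.
#' @param include_three_way include the C:O:T term (default TRUE; with a
#'   single replicate this saturates the model and is rejected).
#' @return A \code{"factorial_anova"} object: coefficient, F, raw p and
#'   Bonferroni-adjusted p matrices (features x terms; family = number of
#'   features, applied within each term), plus the residual df.
#' @examples
#' d <- make_design(3)
#' rec <- simulate_reconstruction(20, 15, 25, seed = 1)
#' tr <- make_planted_truth(rec, expression_effects =
#'   matrix(2, 1, 1, dimnames = list("G001", "C")), noise_sd =
#'   c(expression = 0.2, abundance = 0.2), seed = 1)
#' om <- simulate_omics(d, rec, tr)
#' fit <- fit_factorial(om$expression, d)
#' fit$coefficients["G001", "C"]
#' @export
fit_factorial <- function(matrix, design, include_three_way = TRUE) {
  assert_design(design)
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != nrow(design)) stop("matrix/design sample count mismatch")
  if (!is.null(colnames(matrix)) && !identical(colnames(matrix), design$sample)) {
    if (!all(design$sample %in% colnames(matrix))) {
      stop("matrix columns do not match design samples")
    }
    matrix <- matrix[, design$sample, drop = FALSE]
  }
  X <- design_matrix(design, include_three_way)
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df < 1) {
    stop("no residual degrees of freedom: the '",
         colnames(X)[p], "' term saturates the model; ",
         "add replicates or drop the three-way term")
  }
  # orthogonal +/-1 columns: X'X = n I, so OLS is a single cross-product
  B <- matrix %*% X / n                         # features x terms
  R <- matrix - B %*% t(X)
  mse <- rowSums(R^2) / df
  se2 <- mse / n                                # Var(beta_j) under orthogonality
  Fstat <- sweep(B^2, 1, se2, "/")
  pval <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  m <- nrow(matrix)
  padj <- pmin(pval * m, 1)
  terms <- setdiff(colnames(X), "(Intercept)")
  structure(list(coefficients = B,
                 F = Fstat[, terms, drop = FALSE],
                 p = pval[, terms, drop = FALSE],
                 p_adj = padj[, terms, drop = FALSE],
                 df_residual = df,
                 n_features = m,
                 terms = terms),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat("Factorial ANOVA:", x$n_features, "features,",
      length(x$terms), "tested terms, residual df =", x$df_residual, "\n")
  cat("Features with Bonferroni p <= 0.001 per term:\n")
  print(colSums(x$p_adj <= 0.001))
  invisible(x)
}

#' Condition-dependent feature sets from a factorial ANOVA
#'
#' Selects, per model term, the features whose Bonferroni-adjusted p-value
#' passes \code{alpha} (family = number of features in the layer), and the
#' union over all terms -- the "affected by one or more factors" set used
#' as the headline differential count.
#'
#' @param result a \code{\link{fit_factorial}} result.
#' @param alpha significance threshold on the adjusted p (default 0.001).
#' @return Named list of feature-id vectors, one per term, plus
#'   \code{union}.
#' @export
significant_features <- function(result, alpha = 0.001) {
  stopifnot(inherits(result, "factorial_anova"), alpha > 0, alpha < 1)
  sets <- lapply(result$terms, function(tm) {
    rownames(result$p_adj)[result$p_adj[, tm] <= alpha]
  })
  names(sets) <- result$terms
  sets$union <- sort(unique(unlist(sets)))
  sets
}
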