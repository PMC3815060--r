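#' Balanced two-level three-factor chemostat design
#'
#' Constructs the balanced 2x2x2 factorial design used throughout the
#' package: carbon limitation (C = carbon-limited, N = nitrogen-limited),
#' oxygen availability (O = aerobic, A = anaerobic) and temperature
#' (T = 30 degrees, t = 15 degrees). With \code{replicates = r} the design
#' has \code{8 * r} samples; sample ids encode the condition code and
#' replicate number (e.g. \code{"COT-1"}). Conditions are laid out in the
#' fixed order COT, CAT, COt, CAt, NOT, NAT, NOt, NAt with replicates of a
#' condition contiguous, so the design is a pure function of
#' \code{replicates}.
#'
#' @param replicates number of chemostat replicates per condition
#'   (positive integer; the study design uses 3).
#' @return A data frame of class \code{"factorial_design"} with columns
#'   \code{sample}, \code{carbon}, \code{oxygen}, \code{temperature},
#'   \code{replicate} and \code{condition}.
#' @examples
#' d <- make_design(3)
#' nrow(d)            # 24 chemostats
#' table(d$condition) # each condition code 3 times
#' @export
make_design <- function(replicates) {
  if (length(replicates) != 1L || !is.finite(replicates) ||
      replicates < 1 || replicates != round(replicates)) {
    stop("'replicates' must be a single positive integer")
  }
  replicates <- as.integer(replicates)
  codes <- c("COT", "CAT", "COt", "CAt", "NOT", "NAT", "NOt", "NAt")
  cond <- rep(codes, each = replicates)
  rep_no <- rep(seq_len(replicates), times = 8L)
  d <- data.frame(
    sample      = paste0(cond, "-", rep_no),
    carbon      = substr(cond, 1L, 1L),
    oxygen      = substr(cond, 2L, 2L),
    temperature = substr(cond, 3L, 3L),
    replicate   = rep_no,
    condition   = cond,
    stringsAsFactors = FALSE
  )
  class(d) <- c("factorial_design", "data.frame")
  d
}

#' @export
print.factorial_design <- function(x, ...) {
  cat("Factorial 2x2x2 chemostat design:", nrow(x), "samples (",
      nrow(x) / 8L, "replicate(s) per condition )\n", sep = " ")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

# +1/-1 coding: first-listed level (C, O, T) is +1. Columns are the
# intercept, the three mains, the three pairwise products and (optionally)
# the three-way product; orthogonal under balance.
design_matrix <- function(design, include_three_way = TRUE) {
  xC <- ifelse(design$carbon == "C", 1, -1)
  xO <- ifelse(design$oxygen == "O", 1, -1)
  xT <- ifelse(design$temperature == "T", 1, -1)
  X <- cbind(
    `(Intercept)` = 1, C = xC, O = xO, T = xT,
    `C:O` = xC * xO, `C:T` = xC * xT, `O:T` = xO * xT
  )
  if (include_three_way) X <- cbind(X, `C:O:T` = xC * xO * xT)
  rownames(X) <- design$sample
  X
}

assert_design <- function(design) {
  if (!inherits(design, "factorial_design")) {
    stop("'design' must be created by make_design()")
  }
  tab <- table(design$condition)
  if (length(tab) != 8L || length(unique(tab)) != 1L) {
    stop("design is not balanced across the 8 factorial cells")
  }
  invisible(design)
}
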