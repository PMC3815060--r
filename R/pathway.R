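# Pathway-grouped correlation-bias test: are the correlations between a
# pathway's metabolites and the transcripts of the pathway's own enzymes
# shifted relative to all out-of-pathway metabolite-gene correlations?
# Pathway membership arrives as two parallel GMT files (gene members and
# metabolite members, matched by set name), keeping curated-database
# content out of the package.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated as name, description,
#' then member ids. Duplicate members within a set are counted once.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a \code{"description"}
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i,
                            ": need name, description and >= 1 member")
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors; an optional
#'   \code{"description"} attribute supplies the second column (default
#'   \code{"na"}).
#' @param path output path.
#' @return \code{path}, invisibly. Round-trips through
#'   \code{\link{read_gmt}}.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pair gene and metabolite GMT collections into pathway sets
#'
#' @param gene_sets,metabolite_sets named lists (from
#'   \code{\link{read_gmt}} or \code{\link{simulate_gene_sets}}); only set
#'   names present in both are kept.
#' @return List of pathway sets: each a list with \code{name},
#'   \code{genes}, \code{metabolites}.
#' @export
make_pathway_sets <- function(gene_sets, metabolite_sets) {
  common <- intersect(names(gene_sets), names(metabolite_sets))
  lapply(stats::setNames(common, common), function(nm) {
    list(name = nm, genes = gene_sets[[nm]],
         metabolites = metabolite_sets[[nm]])
  })
}

#' Pathway-grouped correlation-bias test
#'
#' For each pathway, group A holds every correlation r(m, g) with both the
#' metabolite m and the gene g in the pathway, and group B all remaining
#' entries of the correlation matrix; the two groups are compared by the
#' two-sided Mann-Whitney test and adjusted across pathways by
#' Benjamini-Hochberg. Pathways with no in-pathway pair, or spanning the
#' whole matrix (empty group B), are skipped and listed in the
#' \code{"skipped"} attribute.
#'
#' @param cors targets x genes correlation matrix.
#' @param pathways list from \code{\link{make_pathway_sets}}.
#' @return Data frame: pathway, U, p, p_bh, direction, n_in (in-pathway
#'   pair count).
#' @export
pathway_test <- function(cors, pathways) {
  rows <- list(); skipped <- character(0)
  for (pw in pathways) {
    mi <- intersect(pw$metabolites, rownames(cors))
    gi <- intersect(pw$genes, colnames(cors))
    inside <- matrix(FALSE, nrow(cors), ncol(cors),
                     dimnames = dimnames(cors))
    inside[mi, gi] <- TRUE
    a <- cors[inside]; b <- cors[!inside]
    if (length(a) == 0 || length(b) == 0) {
      skipped <- c(skipped, pw$name)
      next
    }
    mw <- mann_whitney_u(a, b)
    rows[[pw$name]] <- data.frame(
      pathway = pw$name, U = mw$U, p = mw$p,
      direction = if (stats::median(a) >= stats::median(b)) "+" else "-",
      n_in = length(a), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable pathways")
  res$p_bh <- bh_adjust(res$p)
  o <- base::order(res$p_bh, res$p)
  res <- res[o, c("pathway", "U", "p", "p_bh", "direction", "n_in")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
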