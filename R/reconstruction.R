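# Metabolic reconstruction handling: a documented TSV reaction dialect
# (reaction_id, equation, gene_association), projection to the
# metabolite-gene bipartite map, first/second-order gene neighborhoods,
# summary statistics, and the merged "visual map" topology in which linear
# reaction chains are collapsed.

new_reconstruction <- function(reactions, metabolites, genes) {
  structure(list(reactions = reactions,
                 metabolites = metabolites,
                 genes = genes),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("Metabolic reconstruction:", length(x$reactions), "reactions,",
      length(x$metabolites), "metabolites,", length(x$genes), "genes\n")
  invisible(x)
}

# "2 A + B -> C" / "A <=> B" -> list(stoich = signed named vector, reversible)
parse_equation <- function(eq, line = NA) {
  where <- if (is.na(line)) "" else paste0(" (line ", line, ")")
  rev <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev) "<=>" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2 || (!rev && grepl("<", eq, fixed = TRUE))) {
    stop("malformed equation", where, ": ", eq)
  }
  parse_side <- function(side, sgn) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0) stop("empty reaction side", where, ": ", eq)
    coefs <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        coefs[parts[2]] <- sgn * as.numeric(parts[1])
      } else if (length(parts) == 1) {
        coefs[parts[1]] <- sgn * 1
      } else {
        stop("malformed term '", tm, "'", where)
      }
    }
    coefs
  }
  stoich <- c(parse_side(sides[1], -1), parse_side(sides[2], 1))
  if (anyDuplicated(names(stoich))) {
    stop("metabolite repeated on both sides", where, ": ", eq)
  }
  if (any(stoich == 0)) stop("zero stoichiometric coefficient", where)
  list(stoich = stoich, reversible = rev)
}

# GPR boolean structure is discarded: any mentioned gene is associated.
flatten_gpr <- function(assoc) {
  if (is.na(assoc) || !nzchar(trimws(assoc))) return(character(0))
  toks <- regmatches(assoc, gregexpr("[A-Za-z0-9_.:-]+", assoc))[[1]]
  unique(toks[!tolower(toks) %in% c("and", "or")])
}

#' Read a metabolic reconstruction from a reaction table
#'
#' The native dialect is a TSV with header columns \code{reaction_id},
#' \code{equation} and \code{gene_association}. Equations use
#' \code{"2 A + B -> C"} for irreversible and \code{"A <=> B"} for
#' reversible reactions; the gene association is a boolean expression over
#' gene ids (\code{"g1 or (g2 and g3)"}) that is flattened to the set of
#' all mentioned genes.
#'
#' @param path path to the reaction TSV.
#' @return A \code{"reconstruction"} object: a list with \code{reactions}
#'   (each \code{id}, signed \code{stoich}, \code{reversible},
#'   \code{genes}), the metabolite id set and the gene id set.
#' @export
load_reconstruction <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("reaction_id", "equation", "gene_association")
  if (!all(need %in% names(tab))) {
    stop("reaction table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$reaction_id)) {
    dup <- tab$reaction_id[duplicated(tab$reaction_id)][1]
    stop("duplicate reaction id '", dup, "' (line ",
         which(tab$reaction_id == dup)[2] + 1L, ")")
  }
  reactions <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pe <- parse_equation(tab$equation[i], line = i + 1L)
    reactions[[i]] <- list(id = tab$reaction_id[i], stoich = pe$stoich,
                           reversible = pe$reversible,
                           genes = flatten_gpr(tab$gene_association[i]))
  }
  names(reactions) <- tab$reaction_id
  mets  <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoich)))))
  genes <- sort(unique(unlist(lapply(reactions, `[[`, "genes"))))
  new_reconstruction(reactions, mets, genes)
}

#' Write a reconstruction in the native reaction-table dialect
#'
#' @param recon a reconstruction.
#' @param path output TSV path.
#' @return \code{path}, invisibly. Round-trips through
#'   \code{\link{load_reconstruction}}.
#' @export
write_reconstruction <- function(recon, path) {
  fmt_side <- function(stoich) {
    paste(ifelse(abs(stoich) == 1, names(stoich),
                 paste(abs(stoich), names(stoich))), collapse = " + ")
  }
  rows <- vapply(recon$reactions, function(r) {
    lhs <- r$stoich[r$stoich < 0]
    rhs <- r$stoich[r$stoich > 0]
    eq <- paste(fmt_side(lhs), if (r$reversible) "<=>" else "->", fmt_side(rhs))
    paste(r$id, eq, paste(r$genes, collapse = " or "), sep = "\t")
  }, "")
  writeLines(c("reaction_id\tequation\tgene_association", rows), path)
  invisible(path)
}

#' Project a reconstruction to the metabolite-gene bipartite map
#'
#' A metabolite is connected to every gene encoding an enzyme that
#' catalyses a reaction consuming or producing it; reaction direction is
#' ignored. Currency metabolites (if any are named) are removed before any
#' edge is created. By default no metabolite is excluded, matching an
#' analysis in which cofactors such as NADPH remain testable nodes.
#'
#' @param recon a reconstruction.
#' @param currency_ids metabolite ids dropped before projection
#'   (subset of \code{recon$metabolites}; may be empty).
#' @return A \code{"bipartite_map"}: edge data frame
#'   (\code{metabolite}, \code{gene}), the retained metabolite and gene
#'   node sets, and the excluded ids.
#' @export
build_bipartite <- function(recon, currency_ids = character(0)) {
  stopifnot(inherits(recon, "reconstruction"))
  if (!all(currency_ids %in% recon$metabolites)) {
    stop("currency_ids must be a subset of the reconstruction's metabolites")
  }
  em <- character(0); eg <- character(0)
  for (r in recon$reactions) {
    mets <- setdiff(names(r$stoich), currency_ids)
    if (length(mets) == 0 || length(r$genes) == 0) next
    em <- c(em, rep(mets, each = length(r$genes)))
    eg <- c(eg, rep(r$genes, times = length(mets)))
  }
  edges <- unique(data.frame(metabolite = em, gene = eg,
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$metabolite, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 metabolites = setdiff(recon$metabolites, currency_ids),
                 genes = recon$genes,
                 currency_excluded = currency_ids),
            class = "bipartite_map")
}

#' @export
print.bipartite_map <- function(x, ...) {
  cat("Bipartite metabolite-gene map:", length(x$metabolites), "metabolites,",
      length(x$genes), "genes,", nrow(x$edges), "edges")
  if (length(x$currency_excluded)) {
    cat(" (", length(x$currency_excluded), "currency metabolites excluded )")
  }
  cat("\n")
  invisible(x)
}

#' First- and second-order gene neighborhoods of each metabolite
#'
#' First neighbors of a metabolite are the genes of reactions touching it
#' (after currency filtering). Second neighbors additionally include the
#' genes of reactions touching any non-currency metabolite that shares a
#' reaction with it, i.e. all genes within two reaction steps. Second
#' neighborhoods are always supersets of first neighborhoods. Metabolites
#' absent from the map get empty neighborhoods and are flagged in the
#' \code{"missing"} attribute.
#'
#' @param map bipartite map built from \code{recon}.
#' @param recon the reconstruction behind the map.
#' @return A \code{"neighborhood_index"}: list with named lists
#'   \code{first} and \code{second} of gene-id vectors.
#' @export
neighborhoods <- function(map, recon) {
  stopifnot(inherits(map, "bipartite_map"), inherits(recon, "reconstruction"))
  curr <- map$currency_excluded
  first <- split(map$edges$gene, map$edges$metabolite)
  mets <- map$metabolites
  empty <- setdiff(mets, names(first))
  first <- c(first, stats::setNames(rep(list(character(0)), length(empty)), empty))
  # metabolite co-occurrence within reactions (currency-filtered)
  adj <- stats::setNames(rep(list(character(0)), length(mets)), mets)
  for (r in recon$reactions) {
    rm <- setdiff(names(r$stoich), curr)
    for (m in rm) adj[[m]] <- unique(c(adj[[m]], setdiff(rm, m)))
  }
  second <- lapply(mets, function(m) {
    nb2 <- unique(c(first[[m]], unlist(first[adj[[m]]], use.names = FALSE)))
    sort(nb2)
  })
  names(second) <- mets
  first <- lapply(first, function(g) sort(unique(g)))
  structure(list(first = first[mets], second = second),
            class = "neighborhood_index",
            missing = empty)
}

#' Summary statistics of a bipartite map
#'
#' @param map a non-empty bipartite map.
#' @return List with metabolite, gene and edge counts and the median
#'   genes-per-metabolite and metabolites-per-gene degrees (degree-0 nodes
#'   included; even-count medians are the mean of the central pair).
#' @export
network_stats <- function(map) {
  stopifnot(inherits(map, "bipartite_map"))
  if (nrow(map$edges) == 0) stop("empty bipartite map")
  deg_m <- table(factor(map$edges$metabolite, levels = map$metabolites))
  deg_g <- table(factor(map$edges$gene, levels = map$genes))
  list(n_metabolites = length(map$metabolites),
       n_genes = length(map$genes),
       n_edges = nrow(map$edges),
       median_genes_per_metabolite = stats::median(as.numeric(deg_m)),
       median_metabolites_per_gene = stats::median(as.numeric(deg_g)))
}

#' Collapse linear reaction chains for the visual map
#'
#' Maximal chains of reactions linked through intermediates that occur in
#' exactly two reactions (and nowhere else) are merged into one reaction:
#' the intermediate cancels out of the combined stoichiometry, and the
#' merged reaction carries the union of member gene sets. This reproduces
#' the phospholipid methylation example in which
#' PE -> PMME -> PDME -> PC collapses to a single PE -> PC step annotated
#' with both CHO2 and OPI3. Reactions are merged only when the
#' intermediate is a product of one and a substrate of the other; networks
#' without such intermediates are returned unchanged.
#'
#' @param recon a reconstruction.
#' @return A reconstruction with collapsed chains; merged reaction ids are
#'   the member ids joined by \code{"+"}.
#' @export
merge_linear_pathways <- function(recon) {
  stopifnot(inherits(recon, "reconstruction"))
  reactions <- recon$reactions
  repeat {
    occ <- table(unlist(lapply(reactions, function(r) names(r$stoich))))
    cands <- names(occ)[occ == 2]
    merged <- FALSE
    for (m in cands) {
      idx <- which(vapply(reactions, function(r) m %in% names(r$stoich), NA))
      if (length(idx) != 2) next
      s1 <- reactions[[idx[1]]]$stoich
      s2 <- reactions[[idx[2]]]$stoich
      if (sign(s1[[m]]) == sign(s2[[m]])) next  # not a through-chain
      # orient so the intermediate is produced by r1 and consumed by r2
      if (s1[[m]] < 0) { idx <- rev(idx); tmp <- s1; s1 <- s2; s2 <- tmp }
      lam <- -s1[[m]] / s2[[m]]
      comb <- s1
      for (mm in names(s2)) {
        comb[mm] <- if (mm %in% names(comb)) comb[mm] + lam * s2[[mm]] else lam * s2[[mm]]
      }
      comb <- comb[abs(comb) > 1e-12]
      if (!any(comb < 0) || !any(comb > 0)) next  # degenerate cancellation
      r1 <- reactions[[idx[1]]]; r2 <- reactions[[idx[2]]]
      new <- list(id = paste(r1$id, r2$id, sep = "+"),
                  stoich = comb,
                  reversible = r1$reversible && r2$reversible,
                  genes = unique(c(r1$genes, r2$genes)))
      reactions <- reactions[-idx]
      reactions[[new$id]] <- new
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  mets  <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoich)))))
  genes <- sort(unique(unlist(lapply(reactions, `[[`, "genes"))))
  new_reconstruction(reactions, mets, genes)
}
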