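# Synthetic-data generator: factorial omics matrices with planted factor
# effects and planted gene-metabolite correlations, toy metabolic
# reconstructions with recorded ground-truth bipartite edges, and random
# gene-set collections. Everything is a pure function of its arguments
# including the seed, so downstream stages are testable without downloads.

TERMS <- c("(Intercept)", "C", "O", "T", "C:O", "C:T", "O:T", "C:O:T")

#' Simulate a toy metabolic reconstruction
#'
#' Generates a connected reaction network over \code{n_met} metabolites,
#' \code{n_gene} genes and \code{n_rxn} reactions. A spanning chain of
#' reactions M1 -> M2 -> ... is laid down first so the network is connected
#' by construction; remaining reactions draw 1-2 random substrates and
#' products. Each reaction carries 0-2 genes (every gene is used at least
#' once) and is reversible with probability \code{p_reversible}. The
#' metabolite-gene edges created along the way are recorded independently
#' of any later projection and attached as \code{attr(, "truth_edges")},
#' giving tests an oracle for the bipartite map.
#'
#' @param n_met number of metabolites (>= 2).
#' @param n_gene number of genes (>= 0).
#' @param n_rxn number of reactions (>= max(1, n_met - 1)).
#' @param seed integer seed; identical arguments give identical networks.
#' @param p_reversible probability a non-chain reaction is reversible.
#' @return A \code{"reconstruction"} object (see
#'   \code{\link{load_reconstruction}}) with a \code{"truth_edges"}
#'   attribute (data frame with columns \code{metabolite}, \code{gene}).
#' @examples
#' rec <- simulate_reconstruction(10, 8, 12, seed = 7)
#' rec
#' @export
simulate_reconstruction <- function(n_met, n_gene, n_rxn, seed,
                                    p_reversible = 0.1) {
  if (n_met < 2) stop("n_met must be >= 2: reactions need a substrate and a product")
  if (n_rxn < 1) stop("n_rxn must be >= 1")
  if (n_rxn < n_met - 1) {
    stop("n_rxn must be >= n_met - 1 so every metabolite can be wired in")
  }
  set.seed(as.integer(seed))
  mets  <- sprintf("M%03d", seq_len(n_met))
  genes <- if (n_gene > 0) sprintf("G%03d", seq_len(n_gene)) else character(0)

  reactions <- vector("list", n_rxn)
  edge_m <- character(0)
  edge_g <- character(0)
  record_edges <- function(stoich_names, rxn_genes) {
    if (length(rxn_genes) == 0) return()
    edge_m <<- c(edge_m, rep(stoich_names, each = length(rxn_genes)))
    edge_g <<- c(edge_g, rep(rxn_genes, times = length(stoich_names)))
  }
  draw_genes <- function() {
    if (length(genes) == 0) return(character(0))
    k <- sample(0:2, 1L, prob = c(0.15, 0.55, 0.30))
    if (k == 0) character(0) else sample(genes, min(k, length(genes)))
  }
  for (i in seq_len(n_rxn)) {
    if (i <= n_met - 1) {            # spanning chain
      stoich <- c(-1, 1)
      names(stoich) <- c(mets[i], mets[i + 1])
      rev <- FALSE
    } else {
      ns <- sample(1:2, 1L)
      np <- sample(1:2, 1L)
      picks <- sample(mets, ns + np)
      coefs <- sample(c(1, 1, 1, 2), ns + np, replace = TRUE)
      stoich <- c(-coefs[seq_len(ns)], coefs[ns + seq_len(np)])
      names(stoich) <- picks
      rev <- stats::runif(1) < p_reversible
    }
    g <- draw_genes()
    record_edges(names(stoich), g)
    reactions[[i]] <- list(id = sprintf("r%03d", i), stoich = stoich,
                           reversible = rev, genes = g)
  }
  # guarantee every gene appears on some reaction
  used <- unique(unlist(lapply(reactions, `[[`, "genes")))
  for (g in setdiff(genes, used)) {
    j <- sample.int(n_rxn, 1L)
    reactions[[j]]$genes <- c(reactions[[j]]$genes, g)
    record_edges(names(reactions[[j]]$stoich), g)
  }
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  rec <- new_reconstruction(reactions, metabolites = mets, genes = genes)
  truth <- unique(data.frame(metabolite = edge_m, gene = edge_g,
                             stringsAsFactors = FALSE))
  truth <- truth[order(truth$metabolite, truth$gene), , drop = FALSE]
  rownames(truth) <- NULL
  attr(rec, "truth_edges") <- truth
  rec
}

#' Planted ground truth for the omics simulator
#'
#' Bundles per-feature factorial effect coefficients, planted
#' gene-metabolite correlation links, and noise levels. Effect coefficients
#' use the same +1/-1 factor coding as the ANOVA stage, so a main-effect
#' coefficient beta implies a level difference of 2*beta (log2 units for
#' expression; for abundances a coefficient beta is a linear fold change of
#' 2^(2*beta) between the levels). Partial effect matrices are accepted:
#' rows are features, columns any subset of
#' \code{c("(Intercept)","C","O","T","C:O","C:T","O:T","C:O:T")}; missing
#' entries default to zero effects with baseline intercepts.
#'
#' @param recon reconstruction whose genes/metabolites the truth refers to.
#' @param expression_effects optional numeric matrix (gene rows).
#' @param abundance_effects optional numeric matrix (metabolite rows),
#'   log2 scale.
#' @param linked_pairs optional data frame with columns \code{metabolite},
#'   \code{gene}, \code{sign} (+1/-1): pairs tied through a shared latent
#'   condition response.
#' @param noise_sd named vector: Gaussian sd of log2 expression noise and
#'   of log2 abundance noise.
#' @param latent_sd sd of the shared per-condition latent used to induce
#'   planted correlations.
#' @param base_expression,base_abundance default intercepts (log2 GCRMA-like
#'   expression level; linear abundance).
#' @param seed integer seed consumed by \code{\link{simulate_omics}}.
#' @return A \code{"planted_truth"} object.
#' @export
make_planted_truth <- function(recon,
                               expression_effects = NULL,
                               abundance_effects = NULL,
                               linked_pairs = NULL,
                               noise_sd = c(expression = 0.25, abundance = 0.25),
                               latent_sd = 1,
                               base_expression = 8,
                               base_abundance = 100,
                               seed = 1) {
  stopifnot(inherits(recon, "reconstruction"))
  fill <- function(partial, features, intercept) {
    full <- matrix(0, length(features), length(TERMS),
                   dimnames = list(features, TERMS))
    full[, "(Intercept)"] <- intercept
    if (!is.null(partial)) {
      partial <- as.matrix(partial)
      bad <- setdiff(rownames(partial), features)
      if (length(bad)) stop("effect rows not in reconstruction: ",
                            paste(bad, collapse = ", "))
      badc <- setdiff(colnames(partial), TERMS)
      if (length(badc)) stop("unknown model terms: ", paste(badc, collapse = ", "))
      full[rownames(partial), colnames(partial)] <- partial
    }
    full
  }
  ee <- fill(expression_effects, recon$genes, base_expression)
  ae <- fill(abundance_effects, recon$metabolites, log2(base_abundance))
  if (!is.null(linked_pairs)) {
    linked_pairs <- as.data.frame(linked_pairs, stringsAsFactors = FALSE)
    stopifnot(all(c("metabolite", "gene", "sign") %in% names(linked_pairs)))
    if (!all(linked_pairs$sign %in% c(-1, 1))) {
      stop("linked pair signs must be +1 or -1")
    }
    if (!all(linked_pairs$metabolite %in% recon$metabolites) ||
        !all(linked_pairs$gene %in% recon$genes)) {
      stop("linked pairs reference ids absent from the reconstruction")
    }
  }
  structure(list(expression_effects = ee, abundance_effects = ae,
                 linked_pairs = linked_pairs,
                 noise_sd = noise_sd, latent_sd = latent_sd,
                 seed = as.integer(seed)),
            class = "planted_truth")
}

#' Link a metabolite to its neighborhood genes
#'
#' Convenience constructor of planted correlation links: every gene within
#' \code{order} reaction steps of \code{metabolite} is tied to it with the
#' given sign. \code{order = 1} plants a first-neighbor-correlated
#' metabolite; \code{order = 2} plants a species co-regulated with its
#' whole first-plus-second gene shell, the pattern the neighborhood
#' summary table describes. With \code{metabolite = NULL} the metabolite
#' with most first-neighbor genes is chosen.
#'
#' @param recon a reconstruction.
#' @param metabolite metabolite id, or NULL for the best-connected one.
#' @param sign +1 (correlated) or -1 (anti-correlated).
#' @param order neighborhood order of the planted links (1 or 2).
#' @return Data frame with columns metabolite, gene, sign, suitable for
#'   \code{\link{make_planted_truth}}.
#' @export
plant_neighborhood <- function(recon, metabolite = NULL, sign = 1, order = 1) {
  stopifnot(order %in% c(1, 2))
  map <- build_bipartite(recon)
  if (is.null(metabolite)) {
    deg <- table(map$edges$metabolite)
    metabolite <- names(deg)[which.max(deg)]
  }
  idx <- neighborhoods(map, recon)
  nb <- if (order == 1) idx$first[[metabolite]] else idx$second[[metabolite]]
  if (length(nb) == 0) stop("metabolite has no neighboring genes")
  data.frame(metabolite = metabolite, gene = nb, sign = sign,
             stringsAsFactors = FALSE)
}

#' Derive acyl-chain sub-species from lipid abundances
#'
#' Splits each designated lipid row of an abundance matrix into
#' per-acyl-chain sub-species (rows named \code{"<lipid>_C<chain>"}):
#' random chain proportions (fixed per lipid) times the parent abundance,
#' with multiplicative log-normal noise. Emulates biomass-normalised
#' lipid panels in which the same class is quantified per chain length,
#' giving the correlation stage a third, separately-tested pair class.
#'
#' @param abundances targets x samples matrix (linear scale).
#' @param lipid_ids rows to split.
#' @param chains acyl-chain labels, e.g. \code{c("100","160","181")}.
#' @param noise_sd sd of the per-cell log2 noise.
#' @param seed integer seed.
#' @return Sub-species x samples matrix.
#' @export
simulate_lipid_subspecies <- function(abundances, lipid_ids,
                                      chains = c("100", "160", "181"),
                                      noise_sd = 0.25, seed = 1) {
  stopifnot(all(lipid_ids %in% rownames(abundances)))
  set.seed(as.integer(seed))
  out <- list()
  for (l in lipid_ids) {
    w <- stats::runif(length(chains)); w <- w / sum(w)
    for (j in seq_along(chains)) {
      noise <- 2^stats::rnorm(ncol(abundances), 0, noise_sd)
      out[[paste0(l, "_C", chains[j])]] <- abundances[l, ] * w[j] * noise
    }
  }
  do.call(rbind, out)
}

#' Simulate expression and abundance matrices under a planted truth
#'
#' Gene expression is generated on the log2 scale as design effects plus a
#' shared latent condition response for planted links plus Gaussian noise.
#' Metabolite abundances are strictly positive: log-normal around their
#' design effects (log2 scale internally). Each planted link
#' (metabolite, gene, sign) shares a per-condition latent draw
#' N(0, latent_sd^2); the gene receives \code{sign} times the latent and
#' the metabolite the latent itself, so the realised Pearson correlation
#' across samples carries the planted sign with probability approaching 1
#' as noise shrinks. Fully reproducible from \code{truth$seed}.
#'
#' @param design a \code{\link{make_design}} design.
#' @param recon the companion reconstruction.
#' @param truth a \code{\link{make_planted_truth}} object.
#' @return List with matrices \code{expression} (genes x samples, log2)
#'   and \code{abundances} (metabolites x samples, linear positive).
#' @examples
#' rec <- simulate_reconstruction(10, 8, 12, seed = 7)
#' tr  <- make_planted_truth(rec, seed = 7)
#' om  <- simulate_omics(make_design(3), rec, tr)
#' dim(om$expression)
#' @export
simulate_omics <- function(design, recon, truth) {
  assert_design(design)
  stopifnot(inherits(recon, "reconstruction"), inherits(truth, "planted_truth"))
  set.seed(truth$seed)
  X <- design_matrix(design, include_three_way = TRUE)   # samples x 8
  expr <- truth$expression_effects %*% t(X)              # genes x samples
  la   <- truth$abundance_effects %*% t(X)               # log2 abundances
  if (ncol(expr) != nrow(design)) stop("design/sample dimension mismatch")

  lp <- truth$linked_pairs
  if (!is.null(lp) && nrow(lp) > 0) {
    conds <- unique(design$condition)
    for (m in unique(lp$metabolite)) {
      z_cond <- stats::rnorm(length(conds), 0, truth$latent_sd)
      names(z_cond) <- conds
      z <- z_cond[design$condition]
      la[m, ] <- la[m, ] + z
      rows <- lp[lp$metabolite == m, , drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        expr[rows$gene[j], ] <- expr[rows$gene[j], ] + rows$sign[j] * z
      }
    }
  }
  nsd <- truth$noise_sd
  expr <- expr + matrix(stats::rnorm(length(expr), 0, nsd[["expression"]]),
                        nrow(expr))
  la   <- la + matrix(stats::rnorm(length(la), 0, nsd[["abundance"]]),
                      nrow(la))
  dimnames(expr) <- list(recon$genes, design$sample)
  ab <- 2^la
  dimnames(ab) <- list(recon$metabolites, design$sample)
  list(expression = expr, abundances = ab)
}

#' Simulate gene-set collections (pathway or TF-target stand-ins)
#'
#' Draws \code{n_sets} random gene sets from a universe; optionally the
#' first set is constructed to overlap a designated gene list at a stated
#' rate (overlap 1 reproduces the list exactly), giving enrichment tests a
#' planted positive.
#'
#' @param genes gene-id universe (non-empty).
#' @param n_sets number of sets (>= 1).
#' @param planted optional designated gene list for the planted set.
#' @param overlap_rate fraction of \code{planted} included in the planted
#'   set; its size always equals \code{length(planted)}.
#' @param set_size_range inclusive size range for the random sets.
#' @param seed integer seed.
#' @return Named list of character vectors (GMT-writable).
#' @export
simulate_gene_sets <- function(genes, n_sets, planted = NULL,
                               overlap_rate = 1,
                               set_size_range = c(5, 30), seed = 1) {
  if (length(genes) == 0) stop("empty gene universe")
  if (n_sets < 1) stop("n_sets must be >= 1")
  set.seed(as.integer(seed))
  sizes <- pmin(sample(set_size_range[1]:set_size_range[2], n_sets,
                       replace = TRUE), length(genes))
  sets <- lapply(sizes, function(k) sort(sample(genes, k)))
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  if (!is.null(planted)) {
    if (!all(planted %in% genes)) stop("planted genes must lie in the universe")
    k <- round(overlap_rate * length(planted))
    inside <- if (k > 0) sample(planted, k) else character(0)
    pool <- setdiff(genes, planted)
    outside <- if (length(planted) - k > 0) {
      sample(pool, length(planted) - k)
    } else character(0)
    sets[[1]] <- sort(c(inside, outside))
    names(sets)[1] <- "PLANTED"
  }
  sets
}
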