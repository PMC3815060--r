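# Orchestration and reporting: descriptive summaries (PCA variance
# fractions, condition log2 ratios), Cytoscape-ready SIF/attribute
# export, and a deterministic end-to-end pipeline over the synthetic
# generator that writes every artifact plus a hashed manifest.

#' PCA variance fractions of an omics matrix
#'
#' Principal components are computed on samples-as-observations with
#' features centred and, by default, unit-scaled (measurement layers live
#' on very different scales); the returned fractions are non-increasing
#' and sum to one.
#'
#' @param matrix features x samples numeric matrix (>= 2 of each).
#' @param scale. standardise features before decomposition.
#' @return Numeric vector of per-component variance fractions.
#' @export
pca_variance_fractions <- function(matrix, scale. = TRUE) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2 || ncol(matrix) < 2) stop("need >= 2 features and samples")
  sds <- apply(matrix, 1, stats::sd)
  if (all(sds == 0)) stop("constant matrix: PCA undefined")
  if (scale. && any(sds == 0)) {
    matrix <- matrix[sds > 0, , drop = FALSE]   # constant features carry no variance
  }
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = scale.)
  pc$sdev^2 / sum(pc$sdev^2)
}

#' Per-feature condition log2 ratios for node colouring
#'
#' Log2 ratio of the first factor level over the second (e.g. O over A),
#' paired with the matching ANOVA term p-value. For log2-scale layers the
#' ratio is the difference of level means; for linear layers it is
#' log2(mean_first / mean_second), withheld (NA) when a level mean is not
#' positive.
#'
#' @param matrix features x samples matrix.
#' @param design the factorial design.
#' @param contrast "C", "O" or "T".
#' @param anova optional \code{\link{fit_factorial}} result supplying the
#'   p column.
#' @param log_scale is the matrix already on the log2 scale?
#' @return Data frame: feature, log2_ratio, p (NA without \code{anova}),
#'   flagged.
#' @export
condition_ratio_attributes <- function(matrix, design, contrast = "O",
                                       anova = NULL, log_scale = TRUE) {
  assert_design(design)
  col <- switch(contrast, C = "carbon", O = "oxygen", T = "temperature",
                stop("unknown contrast '", contrast, "'"))
  first <- substr(contrast, 1, 1)            # C, O, T are the first levels
  matrix <- as.matrix(matrix)[, design$sample, drop = FALSE]
  m1 <- rowMeans(matrix[, design[[col]] == first, drop = FALSE])
  m2 <- rowMeans(matrix[, design[[col]] != first, drop = FALSE])
  if (log_scale) {
    ratio <- m1 - m2
    flagged <- rep(FALSE, length(ratio))
  } else {
    flagged <- m1 <= 0 | m2 <= 0
    ratio <- rep(NA_real_, length(m1))
    ratio[!flagged] <- log2(m1[!flagged] / m2[!flagged])
  }
  p <- rep(NA_real_, nrow(matrix))
  if (!is.null(anova)) {
    idx <- match(rownames(matrix), rownames(anova$p))
    p <- anova$p[idx, contrast]
  }
  data.frame(feature = rownames(matrix), log2_ratio = unname(ratio),
             p = unname(p), flagged = flagged, stringsAsFactors = FALSE)
}

sif_edges <- function(x) {
  if (inherits(x, "correlation_network")) {
    type <- if (nrow(x$edges)) paste0("correlation", x$edges$sign) else character(0)
    data.frame(source = x$edges$gene, type = type,
               target = x$edges$target, stringsAsFactors = FALSE)
  } else if (inherits(x, "bipartite_map")) {
    data.frame(source = x$edges$metabolite, type = "metabolite-gene",
               target = x$edges$gene, stringsAsFactors = FALSE)
  } else if (inherits(x, "reconstruction")) {
    do.call(rbind, lapply(x$reactions, function(r) {
      rbind(
        if (length(r$genes)) data.frame(source = r$genes,
                                        type = "gene-reaction",
                                        target = r$id,
                                        stringsAsFactors = FALSE),
        data.frame(source = names(r$stoich), type = "metabolite-reaction",
                   target = r$id, stringsAsFactors = FALSE)
      )
    }))
  } else stop("no SIF representation for class ", class(x)[1])
}

#' Export a network and its attributes for Cytoscape
#'
#' Writes \code{<prefix>.sif} (source, interaction type, target) plus tab
#' separated node and edge attribute tables. Works for correlation
#' networks (edge types \code{correlation+}/\code{correlation-}),
#' bipartite maps and reconstructions (\code{gene-reaction},
#' \code{metabolite-reaction} edges). Attribute rows whose id does not
#' occur in the network are skipped with a warning.
#'
#' @param x the network object.
#' @param prefix output path prefix.
#' @param node_attributes optional data frame whose first column holds
#'   node ids.
#' @return Character vector of written paths, invisibly.
#' @export
export_cytoscape <- function(x, prefix, node_attributes = NULL) {
  ed <- sif_edges(x)
  sif <- paste0(prefix, ".sif")
  writeLines(if (nrow(ed)) paste(ed$source, ed$type, ed$target, sep = "\t")
             else character(0), sif)
  paths <- sif
  if (inherits(x, "correlation_network") && nrow(x$edges)) {
    ep <- paste0(prefix, "_edges.tsv")
    write_tsv(x$edges[, c("gene", "target", "r", "p_adj", "sign")], ep)
    paths <- c(paths, ep)
  }
  if (!is.null(node_attributes)) {
    ids <- unique(c(ed$source, ed$target))
    keep <- node_attributes[[1]] %in% ids
    if (any(!keep)) {
      warning(sum(!keep), " attribute row(s) with ids absent from the network skipped")
    }
    np <- paste0(prefix, "_nodes.tsv")
    write_tsv(node_attributes[keep, , drop = FALSE], np)
    paths <- c(paths, np)
  }
  invisible(paths)
}

#' Read a SIF file back as an edge table
#'
#' @param path SIF path.
#' @return Data frame with columns source, type, target.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(source = character(0), type = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(source = vapply(parts, `[`, "", 1),
             type   = vapply(parts, `[`, "", 2),
             target = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated parameter bundle for \code{\link{run_pipeline}}: generator
#' sizes, planted structure, the four significance thresholds and the
#' master seed every stochastic stage derives from.
#'
#' @param n_gene,n_met,n_rxn generator sizes (defaults keep the full
#'   pipeline in the seconds range).
#' @param replicates chemostats per condition.
#' @param planted plant ground truth (factor effects, one
#'   neighborhood-linked metabolite, one TF target set)?
#' @param n_affected number of genes given a planted carbon effect.
#' @param effect_size planted coefficient (log2, +1/-1 coding).
#' @param noise_sd generator noise (expression/abundance log2 sd).
#' @param anova_alpha,cor_alpha,bh_alpha,enrich_alpha stage thresholds.
#' @param n_gene_sets simulated TF target-set count.
#' @param seed master seed.
#' @return A \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(n_gene = 200, n_met = 30, n_rxn = 40,
                            replicates = 3, planted = TRUE,
                            n_affected = 20, effect_size = 2,
                            noise_sd = c(expression = 0.25, abundance = 0.25),
                            anova_alpha = 0.001, cor_alpha = 0.001,
                            bh_alpha = 0.01, enrich_alpha = 0.01,
                            n_gene_sets = 15, seed = 1) {
  cfg <- as.list(environment())
  th <- c(anova_alpha, cor_alpha, bh_alpha, enrich_alpha)
  if (any(th <= 0 | th >= 1)) stop("thresholds must lie in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Generates a design, reconstruction and omics matrices, then runs every
#' analysis stage -- factorial ANOVA on both layers, all-pairs correlation
#' testing, first- and second-order neighborhood bias tests with the
#' summary report, pathway-grouped tests, TF enrichment, PCA summaries and
#' condition-ratio attributes -- writing each artifact as TSV/SIF under
#' \code{outdir} together with a manifest listing every file with its MD5
#' hash and the parameters used. Identical configs produce byte-identical
#' statistical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list: \code{manifest} (file/md5 data frame),
#'   \code{summary} (headline counts), and the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("lipidnet_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  with(config, {
    design <- make_design(replicates)
    recon <- simulate_reconstruction(n_met, n_gene, n_rxn, seed = seed)
    say("simulate: n_gene=", n_gene, " n_met=", n_met, " n_rxn=", n_rxn,
        " replicates=", replicates, " seed=", seed, " planted=", planted)

    if (planted) {
      set.seed(seed + 1)
      affected <- sample(recon$genes, min(n_affected, n_gene))
      ee <- matrix(effect_size, length(affected), 1,
                   dimnames = list(affected, "C"))
      links <- plant_neighborhood(recon, order = 2)
      planted_tf <- links$gene
      truth <- make_planted_truth(recon, expression_effects = ee,
                                  linked_pairs = links, noise_sd = noise_sd,
                                  seed = seed + 2)
    } else {
      truth <- make_planted_truth(recon, noise_sd = noise_sd, seed = seed + 2)
      affected <- character(0); links <- NULL; planted_tf <- character(0)
    }
    om <- simulate_omics(design, recon, truth)

    write_tsv(as.data.frame(design), file.path(outdir, "design.tsv"))
    write_matrix <- function(m, f) {
      write_tsv(data.frame(feature = rownames(m), m, check.names = FALSE),
                file.path(outdir, f))
    }
    write_matrix(om$expression, "expression.tsv")
    write_matrix(om$abundances, "abundances.tsv")
    write_reconstruction(recon, file.path(outdir, "reconstruction.tsv"))

    fit_e <- fit_factorial(om$expression, design)
    fit_a <- fit_factorial(log2(om$abundances), design)
    say("anova: alpha=", anova_alpha, " union(expr)=",
        length(significant_features(fit_e, anova_alpha)$union))
    anova_tab <- data.frame(feature = rep(rownames(fit_e$p), length(fit_e$terms)),
                            term = rep(fit_e$terms, each = nrow(fit_e$p)),
                            estimate = as.vector(fit_e$coefficients[, fit_e$terms]),
                            F = as.vector(fit_e$F), p = as.vector(fit_e$p),
                            p_adj = as.vector(fit_e$p_adj))
    write_tsv(anova_tab, file.path(outdir, "anova_expression.tsv"))

    records <- all_pairs(om$expression, om$abundances, alpha = cor_alpha)
    n_lipid <- min(5, n_met)
    chains <- simulate_lipid_subspecies(om$abundances,
                                        utils::tail(recon$metabolites, n_lipid),
                                        seed = seed + 5)
    records_chain <- all_pairs(om$expression, chains, alpha = cor_alpha,
                               layer = "lipid-by-chain")
    say("correlate: pairs=", nrow(records), "+", nrow(records_chain),
        " significant=", sum(records$significant), "+",
        sum(records_chain$significant), " alpha=", cor_alpha)
    write_tsv(rbind(as.data.frame(records), as.data.frame(records_chain)),
              file.path(outdir, "correlations.tsv"))

    map <- build_bipartite(recon)
    idx <- neighborhoods(map, recon)
    cors <- correlation_matrix(om$expression, om$abundances)
    nb1 <- neighborhood_test(cors, idx, order = 1)
    nb2 <- neighborhood_test(cors, idx, order = 2)
    say("neighborhood: tested=", nrow(nb2), " significant(order2,BH<=",
        bh_alpha, ")=", sum(nb2$p_bh <= bh_alpha))
    write_tsv(nb1, file.path(outdir, "neighborhood_order1.tsv"))
    write_tsv(nb2, file.path(outdir, "neighborhood_order2.tsv"))
    write_tsv(table1_report(nb2, records, idx, bh_alpha = bh_alpha),
              file.path(outdir, "neighborhood_report.tsv"))

    gsets <- simulate_gene_sets(recon$genes, n_gene_sets,
                                planted = if (planted) planted_tf else NULL,
                                seed = seed + 3)
    set.seed(seed + 4)
    msets <- lapply(gsets, function(g) sample(recon$metabolites,
                                              min(5, n_met)))
    pw <- make_pathway_sets(gsets, msets)
    pw_res <- pathway_test(cors, pw)
    write_tsv(pw_res, file.path(outdir, "pathway_bias.tsv"))
    say("pathway: tested=", nrow(pw_res))

    queries <- c(significant_features(fit_e, anova_alpha)[c("C", "O", "T")],
                 signed_query_sets(records))
    queries <- queries[vapply(queries, length, 0L) > 0]
    enr <- tf_enrichment(queries, gsets, universe = recon$genes,
                         alpha = enrich_alpha)
    write_tsv(enr, file.path(outdir, "tf_enrichment.tsv"))
    say("tf-enrich: combinations=", nrow(enr), " significant=",
        if (nrow(enr)) sum(enr$significant) else 0L)

    pca <- list(expression = pca_variance_fractions(om$expression),
                abundances = pca_variance_fractions(om$abundances))
    write_tsv(data.frame(component = seq_along(pca$expression),
                         fraction = pca$expression),
              file.path(outdir, "pca_expression.tsv"))
    ratios <- condition_ratio_attributes(om$expression, design, "C",
                                         anova = fit_e)
    write_tsv(ratios, file.path(outdir, "ratios_expression_C.tsv"))

    net <- assemble_network(records, fit_e, factor_filter = "C",
                            alpha = anova_alpha)
    export_cytoscape(net, file.path(outdir, "correlation_network"))
    export_cytoscape(map, file.path(outdir, "bipartite_map"))
    vis <- merge_linear_pathways(recon)
    export_cytoscape(vis, file.path(outdir, "visual_map"))

    writeLines(log, file.path(outdir, "pipeline.log"))
    files <- sort(list.files(outdir, full.names = FALSE))
    files <- setdiff(files, "manifest.tsv")
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(outdir, files))),
      stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))

    invisible(list(
      manifest = manifest,
      outdir = outdir,
      summary = list(
        n_samples = nrow(design),
        anova_union = length(significant_features(fit_e, anova_alpha)$union),
        n_significant_correlations = sum(records$significant) +
          sum(records_chain$significant),
        n_neighborhood_significant = sum(nb2$p_bh <= bh_alpha),
        top_neighborhood = nb2$metabolite[1]),
      truth = list(affected = affected, links = links,
                   planted_tf = planted_tf),
      design = design, recon = recon, omics = om,
      anova = list(expression = fit_e, abundance = fit_a),
      records = records, records_chain = records_chain,
      map = map, index = idx,
      neighborhood = list(order1 = nb1, order2 = nb2),
      pathways = pw_res, enrichment = enr, pca = pca, network = net))
  })
}
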