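# Independent oracles used to freeze expected values: brute-force
# enumeration, permutation, and hand-rolled formulas kept deliberately
# separate from the package's code paths.

# Exact two-sided Mann-Whitney p by enumerating all C(n_a + n_b, n_a)
# assignments of the pooled ranks (tie-free data), with the standard
# doubled-tail convention.
mw_enum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Upper-tail hypergeometric by direct combinatorial summation.
hyper_sum_p <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Monte-Carlo permutation test for zero correlation.
perm_cor_p <- function(x, y, B = 1e4) {
  r_obs <- abs(cor(x, y))
  hits <- 0L
  for (i in seq_len(B)) {
    if (abs(cor(x, sample(y))) >= r_obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# Hand-computed BH step-up (cumulative minimum from the largest p).
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- cummin(p[o] * m / (m:1))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force LP oracle: enumerate candidate vertices of
# {S v = 0, lb <= v <= ub} by fixing each subset of n - rank(S) variables
# at a bound and solving for the rest; returns the best feasible
# objective.
lp_vertex_enum <- function(S, lb, ub, cc, tol = 1e-9) {
  n <- ncol(S)
  r <- qr(S)$rank
  nfree <- n - r
  best <- -Inf
  for (fixed in utils::combn(n, nfree, simplify = FALSE)) {
    basic <- setdiff(seq_len(n), fixed)
    grid <- expand.grid(rep(list(c(1, 2)), nfree))
    for (gi in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fixed] <- ifelse(unlist(grid[gi, ]) == 1, lb[fixed], ub[fixed])
      rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
      sol <- tryCatch(qr.solve(S[, basic, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v[basic] <- sol
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      best <- max(best, sum(cc * v))
    }
  }
  best
}

# Depth-limited breadth-first traversal over the reaction hypergraph:
# genes reachable from a metabolite within `depth` reaction steps,
# skipping currency metabolites.
bfs_neighbor_genes <- function(recon, m, depth = 2, currency = character(0)) {
  frontier <- setdiff(m, currency)
  genes <- character(0)
  seen <- frontier
  for (d in seq_len(depth)) {
    rxns <- Filter(function(r) any(names(r$stoich) %in% frontier),
                   recon$reactions)
    genes <- union(genes, unlist(lapply(rxns, `[[`, "genes")))
    nxt <- setdiff(unlist(lapply(rxns, function(r) names(r$stoich))),
                   c(seen, currency))
    seen <- union(seen, nxt)
    frontier <- nxt
  }
  sort(genes)
}

# Undirected metabolite reachability (metabolites sharing a reaction are
# adjacent); used to check that merging linear chains preserves
# connectivity between surviving metabolites.
reachable_sets <- function(recon) {
  mets <- recon$metabolites
  comp <- stats::setNames(seq_along(mets), mets)
  for (r in recon$reactions) {
    ms <- names(r$stoich)
    tgt <- min(comp[ms])
    comp[names(comp) %in% names(comp)[comp %in% comp[ms]]] <- tgt
  }
  split(names(comp), comp)
}

# Tiny in-code reconstruction: a 3-metabolite chain
# m1 -r1(g1)-> m2 -r2(g2)-> m3.
chain_recon <- function() {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tm1 -> m2\tg1",
               "r2\tm2 -> m3\tg2"), tf)
  load_reconstruction(tf)
}

toy_reactions_path <- function() {
  system.file("extdata", "toy_reactions.tsv", package = "lipidnet")
}
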