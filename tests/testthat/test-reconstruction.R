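test_that("equation parsing handles coefficients, reversibility and GPRs", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA + B -> C\tg1 or g2",
               "r2\t2 A <=> B\t"), tf)
  rec <- load_reconstruction(tf)
  expect_equal(rec$reactions$r1$stoich, c(A = -1, B = -1, C = 1))
  expect_setequal(rec$reactions$r1$genes, c("g1", "g2"))
  expect_false(rec$reactions$r1$reversible)
  expect_equal(rec$reactions$r2$stoich, c(A = -2, B = 1))
  expect_true(rec$reactions$r2$reversible)
  expect_length(rec$reactions$r2$genes, 0L)
})

test_that("malformed equations and duplicate ids are rejected with the line", {
  bad1 <- tempfile(); bad2 <- tempfile(); bad3 <- tempfile()
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA -> \tg1"), bad1)
  expect_error(load_reconstruction(bad1), "line 2")
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA <- B\tg1"), bad2)
  expect_error(load_reconstruction(bad2), "malformed")
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA -> B\tg1",
               "r1\tB -> C\tg2"), bad3)
  expect_error(load_reconstruction(bad3), "duplicate")
})

test_that("the bundled fixture parses to its hand-counted totals", {
  rec <- load_reconstruction(toy_reactions_path())
  expect_length(rec$reactions, 10L)
  expect_length(rec$metabolites, 11L)   # GLCxt..ETH plus ACLAC
  expect_length(rec$genes, 13L)
  expect_equal(sum(vapply(rec$reactions, `[[`, NA, "reversible")), 1L)
  expect_setequal(rec$reactions$r06$genes, c("TDH1", "TDH2", "TDH3"))
  expect_equal(rec$reactions$r10$stoich, c(PYR = -2, ACLAC = 1))
})

test_that("reconstructions round-trip through the TSV dialect", {
  rec <- load_reconstruction(toy_reactions_path())
  tf <- tempfile(fileext = ".tsv")
  write_reconstruction(rec, tf)
  rec2 <- load_reconstruction(tf)
  for (id in names(rec$reactions)) {
    expect_equal(rec2$reactions[[id]]$stoich, rec$reactions[[id]]$stoich)
    expect_setequal(rec2$reactions[[id]]$genes, rec$reactions[[id]]$genes)
  }
})

test_that("bipartite projection links metabolites to catalysing genes", {
  tf <- tempfile()
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA -> B\tg"), tf)
  rec <- load_reconstruction(tf)
  map <- build_bipartite(rec)
  expect_equal(map$edges,
               data.frame(metabolite = c("A", "B"), gene = c("g", "g")))
  withcur <- build_bipartite(rec, currency_ids = "B")
  expect_equal(withcur$edges,
               data.frame(metabolite = "A", gene = "g"))
  expect_error(build_bipartite(rec, currency_ids = "Z"), "subset")
})

test_that("projection is idempotent and monotone under added reactions", {
  rec <- simulate_reconstruction(15, 12, 20, seed = 8)
  m1 <- build_bipartite(rec)
  expect_identical(m1$edges, build_bipartite(rec)$edges)
  bigger <- rec
  bigger$reactions$rx <- list(id = "rx", stoich = c(M001 = -1, M015 = 1),
                              reversible = FALSE, genes = "G001")
  m2 <- build_bipartite(bigger)
  key1 <- paste(m1$edges$metabolite, m1$edges$gene)
  key2 <- paste(m2$edges$metabolite, m2$edges$gene)
  expect_true(all(key1 %in% key2))
})

test_that("first and second neighborhoods follow the chain example", {
  rec <- chain_recon()
  idx <- neighborhoods(build_bipartite(rec), rec)
  expect_equal(idx$first$m1, "g1")
  expect_setequal(idx$second$m1, c("g1", "g2"))
  expect_setequal(idx$first$m2, c("g1", "g2"))
  expect_setequal(idx$second$m2, c("g1", "g2"))
})

test_that("isolated metabolites get empty neighborhoods and a flag", {
  tf <- tempfile()
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA -> B\tg1",
               "r2\tC -> D\t"), tf)  # C, D touch no genes
  rec <- load_reconstruction(tf)
  idx <- neighborhoods(build_bipartite(rec), rec)
  expect_length(idx$first$C, 0L)
  expect_length(idx$second$C, 0L)
  expect_true(all(c("C", "D") %in% attr(idx, "missing")))
})

test_that("second neighborhoods equal a depth-2 BFS over the reaction hypergraph", {
  rec <- simulate_reconstruction(25, 20, 35, seed = 17)
  map <- build_bipartite(rec)
  idx <- neighborhoods(map, rec)
  for (m in sample(rec$metabolites, 8)) {
    expect_equal(idx$second[[m]], bfs_neighbor_genes(rec, m, depth = 2),
                 info = m)
    expect_equal(idx$first[[m]], bfs_neighbor_genes(rec, m, depth = 1),
                 info = m)
  }
  # global containment
  expect_true(all(mapply(function(f, s) all(f %in% s),
                         idx$first, idx$second)))
})

test_that("currency exclusion removes hub shortcuts from neighborhoods", {
  # A -r1(g1)- ATP and B -r2(g2)- ATP: without exclusion A reaches g2
  tf <- tempfile()
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA -> ATP\tg1",
               "r2\tATP -> B\tg2"), tf)
  rec <- load_reconstruction(tf)
  idx_all <- neighborhoods(build_bipartite(rec), rec)
  expect_setequal(idx_all$second$A, c("g1", "g2"))
  idx_cur <- neighborhoods(build_bipartite(rec, currency_ids = "ATP"), rec)
  expect_equal(idx_cur$second$A, "g1")
})

test_that("network statistics use the even-count median convention", {
  tf <- tempfile()
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tA -> X\tg1",
               "r2\tB -> X\tg1 or g2 or g3"), tf)
  rec <- load_reconstruction(tf)
  # A: g1 (1 gene); B: g1,g2,g3 (3) ; X: g1..g3 (3) -> median over {1,3,3}
  st <- network_stats(build_bipartite(rec))
  expect_equal(st$median_genes_per_metabolite, 3)
  two <- build_bipartite(rec, currency_ids = "X")
  expect_equal(network_stats(two)$median_genes_per_metabolite, 2) # {1,3}
  single <- load_reconstruction({
    tq <- tempfile()
    writeLines(c("reaction_id\tequation\tgene_association",
                 "r1\tA -> B\tg1"), tq); tq
  })
  ss <- network_stats(build_bipartite(single, currency_ids = "B"))
  expect_equal(unname(unlist(ss)), c(1, 1, 1, 1, 1))
  empty <- build_bipartite(single, currency_ids = c("A", "B"))
  expect_error(network_stats(empty), "empty")
})

test_that("linear methylation chains merge into one annotated reaction", {
  tf <- tempfile()
  writeLines(c("reaction_id\tequation\tgene_association",
               "r1\tPE + SAM -> PMME + SAH\tCHO2",
               "r2\tPMME + SAM -> PDME + SAH\tOPI3",
               "r3\tPDME + SAM -> PC + SAH\tOPI3"), tf)
  rec <- load_reconstruction(tf)
  merged <- merge_linear_pathways(rec)
  expect_length(merged$reactions, 1L)
  st <- merged$reactions[[1]]$stoich
  expect_equal(st[["PE"]], -1)
  expect_equal(st[["PC"]], 1)
  expect_equal(st[["SAM"]], -3)
  expect_equal(st[["SAH"]], 3)
  expect_false(any(c("PMME", "PDME") %in% names(st)))
  expect_setequal(merged$reactions[[1]]$genes, c("CHO2", "OPI3"))
})

test_that("merging is a fixed point without degree-2 intermediates", {
  rec <- load_reconstruction(toy_reactions_path())
  # the glycolytic chain collapses; re-merging changes nothing further
  m1 <- merge_linear_pathways(rec)
  m2 <- merge_linear_pathways(m1)
  expect_equal(length(m1$reactions), length(m2$reactions))
  expect_setequal(m1$genes, rec$genes)     # gene union preserved
})

test_that("merging preserves reachability between surviving metabolites", {
  rec <- simulate_reconstruction(20, 10, 24, seed = 33)
  merged <- merge_linear_pathways(rec)
  comp_before <- reachable_sets(rec)
  comp_after <- reachable_sets(merged)
  # every pair of surviving metabolites connected before stays connected
  surv <- merged$metabolites
  before_map <- rep(seq_along(comp_before),
                    vapply(comp_before, length, 0L))
  names(before_map) <- unlist(comp_before)
  after_map <- rep(seq_along(comp_after), vapply(comp_after, length, 0L))
  names(after_map) <- unlist(comp_after)
  for (i in seq_len(min(40, length(surv) - 1))) {
    a <- surv[i]; b <- surv[i + 1]
    if (before_map[a] == before_map[b]) {
      expect_equal(unname(after_map[a]), unname(after_map[b]),
                   info = paste(a, b))
    }
  }
})
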