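test_that("rank-sum test matches small-sample enumeration", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(8)
    mw <- mann_whitney_u(a, b)
    expect_equal(mw$p, mw_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("ties are handled by midranks and identical groups give p = 1", {
  mw <- mann_whitney_u(c(1, 1, 2), c(1, 2, 2))
  expect_true(mw$p <= 1 && mw$p > 0.5)
  same <- mann_whitney_u(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("U statistics for the two orientations sum to n_a * n_b", {
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(7); b <- rnorm(9)
    u1 <- mann_whitney_u(a, b)$U
    u2 <- mann_whitney_u(b, a)$U
    expect_equal(u1 + u2, 63)
  }
})

test_that("normal approximation approaches the exact p at moderate sizes", {
  set.seed(15)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(8, mean = 0.5)
    p_exact <- mann_whitney_u(a, b, exact_max = 20)$p
    p_norm <- mann_whitney_u(a, b, exact_max = 0)$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  p <- runif(40)
  expect_equal(bh_adjust(p), bh_hand(p), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("an extreme planted neighborhood has the smallest raw p", {
  genes <- sprintf("g%03d", 1:205)
  nb_genes <- genes[1:5]
  mets <- sprintf("m%02d", 1:10)
  set.seed(30)
  cors <- matrix(rnorm(10 * 205, sd = 0.1), 10, 205,
                 dimnames = list(mets, genes))
  cors["m01", nb_genes] <- 0.9
  idx <- structure(list(
    first = c(list(m01 = nb_genes),
              setNames(lapply(2:10, function(i) sample(genes, 5)),
                       mets[-1])),
    second = c(list(m01 = nb_genes),
               setNames(lapply(2:10, function(i) sample(genes, 12)),
                        mets[-1]))),
    class = "neighborhood_index")
  res <- neighborhood_test(cors, idx, order = 1)
  expect_equal(res$metabolite[1], "m01")
  expect_equal(min(res$p), res$p[res$metabolite == "m01"])
  expect_equal(res$direction[1], "+")
  expect_equal(res$n_linked[res$metabolite == "m01"], 5L)
})

test_that("permuting neighborhood labels calibrates raw p to uniformity", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:150)
  mets <- sprintf("m%02d", 1:60)
  cors <- matrix(rnorm(60 * 150, sd = 0.2), 60, 150,
                 dimnames = list(mets, genes))
  idx <- structure(list(
    first = setNames(lapply(mets, function(m) sample(genes, 15)), mets),
    second = setNames(lapply(mets, function(m) sample(genes, 40)), mets)),
    class = "neighborhood_index")
  res <- neighborhood_test(cors, idx, order = 2)
  ks <- suppressWarnings(ks.test(res$p, "punif"))  # midrank ties in discrete p
  expect_gt(ks$p.value, 0.01)
})

test_that("metabolites without usable neighborhoods are skipped, not crashed", {
  cors <- matrix(rnorm(2 * 10), 2, 10,
                 dimnames = list(c("m1", "m2"), paste0("g", 1:10)))
  idx <- structure(list(
    first = list(m1 = paste0("g", 1:3), m2 = character(0), m3 = "g1"),
    second = list(m1 = paste0("g", 1:5), m2 = character(0), m3 = "g1")),
    class = "neighborhood_index")
  expect_warning(res <- neighborhood_test(cors, idx, order = 1), "m3")
  expect_equal(res$metabolite, "m1")
  expect_true(all(c("m2", "m3") %in% attr(res, "skipped")))
})

test_that("the summary report counts linked, significant and overlap genes", {
  d <- make_design(3)
  rec <- simulate_reconstruction(20, 120, 28, seed = 19)
  links <- plant_neighborhood(rec, order = 2)
  truth <- make_planted_truth(rec, linked_pairs = links,
                              noise_sd = c(expression = 0.1, abundance = 0.1),
                              seed = 19)
  om <- simulate_omics(d, rec, truth)
  cors <- correlation_matrix(om$expression, om$abundances)
  map <- build_bipartite(rec)
  idx <- neighborhoods(map, rec)
  res <- neighborhood_test(cors, idx, order = 2)
  records <- all_pairs(om$expression, om$abundances, alpha = 0.001)
  rep2 <- table1_report(res, records, idx, bh_alpha = 0.01, cor_alpha = 0.01)
  expect_equal(names(rep2), c("metabolite", "p.BH", "n.MetMap.linked",
                              "n.PCC.sig", "n.linkedANDsig"))
  m <- links$metabolite[1]
  expect_true(m %in% rep2$metabolite)
  row <- rep2[rep2$metabolite == m, ]
  expect_equal(row$n.MetMap.linked, length(idx$second[[m]]))
  # every planted link should be recovered as significantly correlated
  expect_equal(row$n.linkedANDsig, nrow(links))
  expect_true(all(diff(rep2$p.BH) >= 0))
  # empty report keeps the header
  none <- res; none$p_bh <- 1
  empty <- table1_report(none, records, idx)
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), names(rep2))
})
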