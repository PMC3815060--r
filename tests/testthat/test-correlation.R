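test_that("pearson_r matches hand-computed coefficients", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 2:1), "3")
})

test_that("cor_test_p reproduces the t-based two-sided test", {
  expect_equal(cor_test_p(0, 10), 1)
  # r = 0.8, n = 4: t = 0.8 sqrt(2) / 0.6 on 2 df
  expect_equal(cor_test_p(0.8, 4),
               2 * pt(-0.8 * sqrt(2) / 0.6, df = 2), tolerance = 1e-12)
  expect_equal(cor_test_p(1, 5), 0)
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    ct <- cor.test(x, y, alternative = "two.sided")
    expect_equal(cor_test_p(cor(x, y), 12), ct$p.value, tolerance = 1e-12)
  }
})

test_that("t-based p agrees with a permutation oracle on small samples", {
  set.seed(42)
  for (n in c(6, 8)) {
    x <- rnorm(n)
    y <- x * 0.5 + rnorm(n)      # moderate association, p not extreme
    p_t <- cor_test_p(cor(x, y), n)
    p_perm <- perm_cor_p(x, y, B = 1e4)
    se <- sqrt(p_perm * (1 - p_perm) / 1e4)
    expect_lt(abs(p_t - p_perm), 3 * se + 0.02)
  }
})

test_that("all_pairs builds one Bonferroni-adjusted record per combination", {
  set.seed(9)
  d <- make_design(3)
  expr <- matrix(rnorm(10 * 24), 10, 24,
                 dimnames = list(sprintf("g%02d", 1:10), d$sample))
  targ <- matrix(2^rnorm(5 * 24), 5, 24,
                 dimnames = list(sprintf("m%02d", 1:5), d$sample))
  rec <- all_pairs(expr, targ, alpha = 0.001)
  expect_equal(nrow(rec), 50L)
  expect_equal(attr(rec, "family_size"), 50L)
  expect_equal(rec$p_adj, pmin(rec$p * 50, 1))
  expect_true(all(rec$p_adj >= rec$p))
  expect_equal(rec$sign, ifelse(rec$r >= 0, "+", "-"))
  # a perfectly correlated planted pair is significant at any practical alpha
  targ2 <- rbind(targ, mp = 2^expr["g01", ])
  rec2 <- all_pairs(expr, targ2)
  row <- rec2[rec2$gene == "g01" & rec2$target == "mp", ]
  expect_true(row$significant)
  expect_gt(row$r, 0.9)   # 2^x is monotone but curved, r just below 1
})

test_that("sample mismatch and degenerate features are handled", {
  expr <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  targ <- matrix(rnorm(8), 2, 4, dimnames = list(c("m1", "m2"), paste0("t", 1:4)))
  expect_error(all_pairs(expr, targ), "sample")
  colnames(targ) <- colnames(expr)
  expr["g2", ] <- 1   # constant: dropped, not imputed
  rec <- all_pairs(expr, targ)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "dropped"), "g2")
})

test_that("r is invariant under positive affine maps and flips under negation", {
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y))
  expect_equal(pearson_r(-x, y), -pearson_r(x, y))
})

test_that("split-half screening classifies opposing and agreeing pairs", {
  d <- make_design(3)
  set.seed(11)
  base <- rnorm(24)
  Cmask <- d$carbon == "C"
  target_op <- numeric(24)
  target_op[Cmask] <- base[Cmask] + rnorm(12, sd = 0.01)
  target_op[!Cmask] <- -base[!Cmask] + rnorm(12, sd = 0.01)
  target_ag <- base + rnorm(24, sd = 0.01)
  expr <- rbind(g1 = base)
  colnames(expr) <- d$sample
  targ <- rbind(mo = target_op - min(target_op) + 1,
                ma = target_ag)
  colnames(targ) <- d$sample
  out <- split_half_opposing(expr, targ, d, factor = "C", alpha_half = 0.01)
  expect_equal(out$relation[out$target == "mo"], "opposing")
  expect_equal(out$relation[out$target == "ma"], "agreeing")
})

test_that("null data yield no opposing pairs at a stringent threshold", {
  set.seed(13)
  d <- make_design(3)
  expr <- matrix(rnorm(30 * 24), 30, 24,
                 dimnames = list(sprintf("g%02d", 1:30), d$sample))
  targ <- matrix(rnorm(10 * 24), 10, 24,
                 dimnames = list(sprintf("m%02d", 1:10), d$sample))
  for (f in c("C", "O", "T")) {
    out <- split_half_opposing(expr, targ, d, factor = f, alpha_half = 0.001)
    expect_equal(sum(out$relation == "opposing"), 0L, info = f)
  }
})

test_that("network assembly applies the ANOVA endpoint filter", {
  set.seed(21)
  d <- make_design(3)
  X <- lipidnet:::design_matrix(d)
  expr <- matrix(rnorm(20 * 24, sd = 0.2), 20, 24,
                 dimnames = list(sprintf("g%02d", 1:20), d$sample))
  expr["g01", ] <- expr["g01", ] + 2 * X[, "C"]   # C-responsive
  targ <- rbind(m1 = 2^(expr["g01", ] + rnorm(24, sd = 0.05)),
                m2 = 2^(expr["g02", ] + rnorm(24, sd = 0.05)))
  colnames(targ) <- d$sample
  recs <- all_pairs(expr, targ)
  fit <- fit_factorial(expr, d)
  net <- assemble_network(recs, fit, factor_filter = "C", alpha = 0.001)
  expect_true("g01" %in% net$edges$gene)
  expect_false("g02" %in% net$edges$gene)  # correlated but not C-responsive
  empty <- assemble_network(recs[0, ], fit, "C")
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)
  expect_error(assemble_network(recs, fit, "Q"), "unknown factor")
})
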