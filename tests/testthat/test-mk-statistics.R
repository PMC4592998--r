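counts13 <- dmel_mt_mk_counts()
sets <- oxphos_gene_sets()

test_that("NI applies the all-cells pseudocount exactly when a cell is 0", {
  ni <- neutrality_index(c(5, 2, 11, 35))
  expect_equal(round(as.numeric(ni), 3), 7.955)
  expect_false(attr(ni, "pseudocount_applied"))

  ni0 <- neutrality_index(c(0, 16, 8, 101))
  expect_equal(round(as.numeric(ni0), 3), 0.667)
  expect_true(attr(ni0, "pseudocount_applied"))

  ni8 <- neutrality_index(c(1, 0, 2, 8))
  expect_equal(as.numeric(ni8), 6)

  # neutral expectation: equal ratios give NI = 1
  expect_equal(as.numeric(neutrality_index(c(3, 6, 5, 10))), 1)

  # scale equivariance on zero-free tables
  set.seed(51)
  for (r in 1:20) {
    cells <- sample(1:40, 4)
    expect_equal(as.numeric(neutrality_index(cells)),
                 as.numeric(neutrality_index(cells * 7)))
  }
})

test_that("Z* and plain Z follow their log10 definitions", {
  expect_equal(round(z_star(c(5, 2, 11, 35)), 3), -0.778)
  expect_equal(round(z_star(c(0, 16, 8, 101)), 3), 0.176)
  expect_equal(z_star(c(0, 0, 0, 0)), 0)

  expect_equal(round(z_plain(c(6, 2, 13, 43)), 3), -0.997)
  expect_equal(z_plain(c(5, 5, 7, 7)), 0)
  expect_true(is.na(z_plain(c(0, 5, 7, 7))))

  # Z = -log10(NI) exactly on zero-free tables
  set.seed(52)
  for (r in 1:20) {
    cells <- sample(1:50, 4)
    expect_equal(z_plain(cells),
                 -log10(as.numeric(neutrality_index(cells))),
                 tolerance = 1e-12)
  }
})

test_that("Fisher's exact MK test reproduces published p-values", {
  expect_equal(round(fisher_exact_mk(c(5, 2, 11, 35)), 3), 0.021)
  expect_equal(round(fisher_exact_mk(c(1, 0, 2, 8)), 3), 0.273)
  expect_equal(fisher_exact_mk(c(10, 10, 10, 10)), 1)
  # fractional counts are rounded half-away-from-zero before testing
  expect_equal(fisher_exact_mk(c(4.6, 9.5, 55.833, 107.167)),
               fisher_exact_mk(c(5, 10, 56, 107)))
})

test_that("NI_TG combines gene tables by synonymous-total weights", {
  cv <- counts13[counts13$gene %in% sets$`Complex V`, ]
  expect_equal(round(ni_tg(cv), 2), 9.64)
  expect_equal(round(ni_tg(counts13), 2), 1.67)

  # a single zero-free gene reduces to its own raw-count NI
  one <- data.frame(PN = 5, PS = 2, DN = 11, DS = 35)
  expect_equal(ni_tg(one), as.numeric(neutrality_index(one)))
  # identical copies leave the estimator unchanged
  expect_equal(ni_tg(one[rep(1, 6), ]), ni_tg(one))
  expect_error(ni_tg(data.frame(PN = numeric(), PS = numeric(),
                                DN = numeric(), DS = numeric())),
               "empty")
})

test_that("bootstrap intervals are seeded, degenerate and undefined as
           their inputs dictate", {
  ci_a <- ni_tg_bootstrap_ci(counts13, n_boot = 500, seed = 7)
  ci_b <- ni_tg_bootstrap_ci(counts13, n_boot = 500, seed = 7)
  expect_identical(ci_a, ci_b)

  one <- data.frame(PN = 5, PS = 2, DN = 11, DS = 35)
  ci_one <- ni_tg_bootstrap_ci(one, n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci_one), rep(ni_tg(one), 2))

  # Complex V: resamples drawing only the zero-denominator gene make the
  # interval undefined
  cv <- counts13[counts13$gene %in% sets$`Complex V`, ]
  ci_cv <- ni_tg_bootstrap_ci(cv, n_boot = 500, seed = 2)
  expect_true(anyNA(ci_cv))
  expect_gt(attr(ci_cv, "frac_undefined"), 0.1)

  # the 13-gene interval brackets the point estimate near (1.0, 2.9)
  ci13 <- ni_tg_bootstrap_ci(counts13, n_boot = 5000, seed = 3)
  expect_lt(ci13[1], ni_tg(counts13))
  expect_gt(ci13[2], ni_tg(counts13))
  expect_gt(ci13[1], 0.8)
  expect_lt(ci13[2], 3.3)
})

test_that("bootstrap interval coverage is near nominal on homogeneous
           gene sets", {
  lam <- c(PN = 10, PS = 10, DN = 20, DS = 40)
  set.seed(99)
  big <- data.frame(PN = rpois(2e5, lam[1]), PS = rpois(2e5, lam[2]),
                    DN = rpois(2e5, lam[3]), DS = rpois(2e5, lam[4]))
  truth <- ni_tg(big)
  set.seed(123)
  cover <- replicate(500, {
    g <- data.frame(PN = rpois(80, lam[1]), PS = rpois(80, lam[2]),
                    DN = rpois(80, lam[3]), DS = rpois(80, lam[4]))
    ci <- ni_tg_bootstrap_ci(g, n_boot = 400)
    !anyNA(ci) && ci[1] <= truth && truth <= ci[2]
  })
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("Woolf's homogeneity test matches its weighted chi-square form", {
  same <- data.frame(PN = c(10, 10), PS = c(10, 10), DN = c(10, 10),
                     DS = c(10, 10))
  w0 <- woolf_homogeneity(same)
  expect_equal(w0$chi2, 0)
  expect_equal(w0$p, 1)

  two <- data.frame(PN = c(10, 40), PS = c(10, 10), DN = c(10, 10),
                    DS = c(10, 40))
  # hand computation with the +0.5 correction
  lor <- c(log((10.5 * 10.5) / (10.5 * 10.5)),
           log((40.5 * 40.5) / (10.5 * 10.5)))
  wts <- c(1 / (4 / 10.5), 1 / (2 / 40.5 + 2 / 10.5))
  mu <- sum(wts * lor) / sum(wts)
  chi2 <- sum(wts * (lor - mu)^2)
  w2 <- woolf_homogeneity(two)
  expect_equal(w2$chi2, chi2, tolerance = 1e-12)
  expect_equal(w2$df, 1L)
  expect_equal(w2$p, pchisq(chi2, 1, lower.tail = FALSE))

  # the fly mitochondrial gene set is homogeneous
  expect_gt(woolf_homogeneity(counts13)$p, 0.05)
  expect_error(woolf_homogeneity(counts13[1, ]), "two tables")
})

test_that("gene-set summaries reproduce the printed set-level statistics", {
  ac <- summarize_gene_set(counts13, "All coding", n_boot = 300, seed = 1)
  expect_equal(round(ac$NI_summed, 2), 1.59)
  expect_equal(round(ac$per_gene$NI[["median"]], 2), 1.97)
  expect_equal(round(ac$per_gene$NI[["mean"]], 2), 3.57)
  expect_equal(round(ac$per_gene$NI[["sd"]], 2), 3.89)

  civ <- summarize_gene_set(counts13[counts13$gene %in% sets$`Complex IV`, ],
                            "Complex IV", n_boot = 300, seed = 1)
  expect_equal(round(civ$NI_summed, 2), 0.56)

  expect_error(summarize_gene_set(counts13[0, ]), "empty")
})

test_that("rank-sum comparison and effect sizes behave canonically", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  expect_equal(unname(rank_sum_compare(x, x)[["p"]]), 1, tolerance = 1e-9)
  a <- 1:10
  b <- 101:110
  expect_lt(rank_sum_compare(a, b)[["p"]], 0.001)
  expect_equal(unname(rank_sum_compare(1, 2)[["U"]]), 0)

  expect_equal(effect_size(2, 1.5, 2, 0.4), 0)
  expect_equal(effect_size(1, 1, 2, 1), 1)
  expect_equal(round(effect_size(5.2, 3.333, 2.0, 3.333), 2), 0.96)
})
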