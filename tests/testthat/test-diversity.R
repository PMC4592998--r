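test_that("segregating sites, pi and theta follow their definitions", {
  two <- rbind(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "A"))
  expect_equal(segregating_sites(two), 1L)
  expect_equal(nuc_pi(two), 1)
  expect_equal(nuc_pi(two, per_site = TRUE), 0.25)

  mono <- matrix("A", 5, 3, dimnames = list(letters[1:5], NULL))
  expect_equal(segregating_sites(mono), 0L)
  expect_equal(nuc_pi(mono), 0)

  # 19/19 split among n = 38: (n/(n-1)) * 2p(1-p)
  col <- matrix(c(rep("A", 19), rep("G", 19)), ncol = 1)
  expect_equal(nuc_pi(col), (38 / 37) * 0.5, tolerance = 1e-12)

  expect_equal(watterson_theta(0, 38), 0)
  expect_error(watterson_theta(3, 1), "n >= 2")
})

test_that("Tajima's D matches the published per-gene values", {
  expect_equal(round(watterson_theta(16, 38), 2), 3.81)
  expect_equal(round(watterson_theta(1, 38), 2), 0.24)
  expect_equal(round(tajimas_d(1.57, 16, 38), 2), -1.91)
  expect_true(is.na(tajimas_d(0, 0, 38)))
  # pi == theta_w gives exactly zero
  th <- watterson_theta(10, 20)
  expect_equal(tajimas_d(th, 10, 20), 0)
})

test_that("diversity statistics agree with the naive double-loop oracle", {
  set.seed(41)
  for (rep in 1:8) {
    mat <- random_base_matrix(10, 50, missing_rate = 0.05)
    expect_equal(segregating_sites(mat), oracle_S(mat))
    expect_equal(nuc_pi(mat), oracle_pi(mat), tolerance = 1e-10)
    S <- segregating_sites(mat)
    expect_equal(tajimas_d(nuc_pi(mat), S, nrow(mat)),
                 oracle_tajima_d(mat), tolerance = 1e-10)
  }
})

test_that("Fu and Li's D responds to the singleton load as expected", {
  expect_true(is.na(fu_li_d(matrix("A", 4, 6), rep("A", 6))))

  # every mutation a derived singleton on a different row: strongly negative
  sing <- matrix("A", 4, 6, dimnames = list(letters[1:4], NULL))
  for (j in 1:4) sing[j, j] <- "G"
  d_sing <- fu_li_d(sing, rep("A", 6))
  expect_lt(d_sing, 0)

  # shared derived alleles, no singletons: positive
  shared <- matrix("A", 4, 6, dimnames = list(letters[1:4], NULL))
  shared[1:2, 1] <- "G"; shared[3:4, 2] <- "G"; shared[1:2, 3] <- "G"
  expect_gt(fu_li_d(shared, rep("A", 6)), 0)

  expect_error(fu_li_d(sing, NULL), "outgroup")
})

test_that("SFS construction applies the outgroup-sharing omission rule", {
  col1 <- matrix(c(rep("A", 37), "G"), ncol = 1)
  s1 <- sfs(col1, "unfolded", outgroup_row = "A")
  expect_equal(unname(s1$counts[["1"]]), 1L)
  expect_equal(s1$omitted_sites, 0L)

  col2 <- matrix(c(rep("A", 20), rep("G", 18)), ncol = 1)
  s2 <- sfs(col2, "unfolded", outgroup_row = "C")
  expect_equal(sum(s2$counts), 0L)
  expect_equal(s2$omitted_sites, 1L)
  # the fold ignores polarity entirely
  s2f <- sfs(col2, "folded")
  expect_equal(unname(s2f$counts[["18"]]), 1L)

  # three ingroup alleles: skipped with a log entry in both modes
  col3 <- matrix(c(rep("A", 10), rep("G", 5), rep("T", 3)), ncol = 1)
  s3 <- sfs(col3, "folded")
  expect_equal(sum(s3$counts), 0L)
  expect_equal(s3$skipped_multiallelic, 1L)

  expect_error(sfs(col1, "unfolded"), "outgroup")
})

test_that("the unfolded spectrum refolds exactly to the folded spectrum", {
  set.seed(42)
  for (rep in 1:5) {
    X <- oracle_coalescent_matrix(12, 20)
    mat <- binary_to_bases(X)
    unf <- sfs(mat, "unfolded", outgroup_row = rep("A", ncol(mat)))
    fol <- sfs(mat, "folded")
    expect_identical(fold_sfs(unf)$counts, fol$counts)
  }
})

test_that("Fay and Wu's H matches its closed form and sign conventions", {
  # n = 4, one derived singleton: pi = 1/2, theta_H = 1/6, H = 1/3
  mat <- matrix("A", 4, 5, dimnames = list(letters[1:4], NULL))
  mat[1, 1] <- "G"
  h <- fay_wu_h(sfs(mat, "unfolded", outgroup_row = rep("A", 5)))
  expect_equal(h, 1 / 3, tolerance = 1e-12)

  empty <- sfs(matrix("A", 4, 3), "unfolded", outgroup_row = rep("A", 3))
  expect_equal(fay_wu_h(empty), 0)
  expect_error(fay_wu_h(sfs(mat, "folded")), "unfolded")

  # high-frequency derived alleles drive H negative
  hi <- matrix("G", 6, 4, dimnames = list(letters[1:6], NULL))
  hi[1, ] <- "A"
  expect_lt(fay_wu_h(sfs(hi, "unfolded", outgroup_row = rep("A", 4))), 0)
})

test_that("equilibrium simulations centre pi, theta_W and H correctly", {
  set.seed(43)
  reps <- 800
  n <- 12
  theta <- 4
  pis <- thetas <- hs <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- simulate_genealogy(n)
    X <- drop_poisson(tr, theta)
    mat <- binary_to_bases(X)
    pis[r] <- nuc_pi(mat)
    thetas[r] <- watterson_theta(segregating_sites(mat), n)
    hs[r] <- fay_wu_h(sfs(mat, "unfolded",
                          outgroup_row = rep("A", ncol(mat))))
  }
  # E[pi] = E[theta_W] = theta and E[H] = 0 under neutral equilibrium
  expect_equal(mean(pis), theta, tolerance = 0.1)
  expect_equal(mean(thetas), theta, tolerance = 0.1)
  se_h <- sd(hs) / sqrt(reps)
  expect_lt(abs(mean(hs)), 4 * se_h + 0.05)
})

test_that("per-gene class summaries recover planted mutation classes", {
  ds <- generate_dataset(sim_config(theta_syn = 5, theta_nonsyn = 0,
                                    n_codons = 150, seed = 55))
  gene <- extract_gene(ds$alignment, ds$annotation[1, ])
  div <- diversity_summary(gene)
  expect_equal(div$S[div$site_class == "nonsynonymous"], 0L)
  expect_equal(div$S[div$site_class == "synonymous"], ds$truth$P_S)
  expect_equal(div$S[div$site_class == "all"], ds$truth$P_S)
  # fractional site totals cover the whole gene
  expect_equal(sum(div$n_sites[div$site_class %in%
                                 c("synonymous", "nonsynonymous")]),
               3 * ncol(gene$codons), tolerance = 1e-8)
})
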