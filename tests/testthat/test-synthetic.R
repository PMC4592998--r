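test_that("class-restricted generation plants only the requested class", {
  ds <- generate_dataset(sim_config(theta_syn = 5, theta_nonsyn = 0,
                                    outgroup_divergence = c(syn = 0,
                                                            nonsyn = 0),
                                    n_codons = 120, seed = 81))
  expect_equal(ds$truth$P_N, 0L)
  gene <- extract_gene(ds$alignment, ds$annotation[1, ])
  tab <- build_mk_table(gene)
  expect_equal(tab$PN, 0)
  expect_equal(tab$DN + tab$DS, 0)
  expect_equal(tab$PS, ds$truth$P_S)
})

test_that("planted mutation numbers follow their Poisson means", {
  set.seed(82)
  theta <- 5
  reps <- 3000
  S <- numeric(reps)
  cfg <- sim_config(theta_syn = theta, theta_nonsyn = 0,
                    outgroup_divergence = c(syn = 0, nonsyn = 0),
                    n_codons = 120)
  for (r in seq_len(reps)) S[r] <- generate_dataset(cfg)$truth$P_S
  expect_equal(mean(S), theta * sum(1 / (1:37)), tolerance = 0.02)
})

test_that("generated data round-trip through the IO layer and respect the
           infinite-sites structure", {
  dir <- tempfile()
  ds <- generate_dataset(sim_config(n_codons = 100, missing_rate = 0.01,
                                    seed = 83), out_dir = dir)
  expect_true(all(file.exists(ds$paths)))
  back <- read_alignment(file.path(dir, "alignment.fasta"),
                         outgroup = "outgroup")
  expect_identical(back$mat, ds$alignment$mat)
  ann <- read_annotation(file.path(dir, "genes.tsv"))
  expect_equal(ann$gene, ds$annotation$gene)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$P_S, ds$truth$P_S)

  set.seed(84)
  for (r in 1:25) {
    d <- generate_dataset(sim_config(n_codons = 100))
    expect_equal(
      four_gamete_test(ingroup_matrix(d$alignment))$n_violating_pairs, 0L)
  }
})

test_that("total mutation bias turns every derived allele into A or T", {
  ds <- generate_dataset(sim_config(gc_to_at_bias = 1, ancestral_gc = 0.9,
                                    theta_syn = 4, theta_nonsyn = 4,
                                    n_codons = 200, seed = 85))
  expect_gt(nrow(ds$truth$sites), 0)
  expect_true(all(ds$truth$sites$to %in% c("A", "T")))
  expect_true(all(ds$truth$sites$from %in% c("G", "C")))
})

test_that("a mutation load larger than the gene raises a generation error", {
  expect_error(
    generate_dataset(sim_config(theta_syn = 500, n_codons = 10,
                                seed = 86)),
    "generation error")
})

test_that("missing-data masking feeds the less-inclusive filter", {
  ds <- generate_dataset(sim_config(missing_rate = 0.002, n_codons = 120,
                                    seed = 87))
  expect_gt(sum(is.na(ds$alignment$mat)), 0)
  gene <- extract_gene(ds$alignment, ds$annotation[1, ])
  less <- build_mk_table(gene, method = "less_inclusive")
  more <- build_mk_table(gene, method = "more_inclusive")
  expect_s3_class(less, "mk_table")
  # dropping codons with missing data can only reduce polymorphism counts
  expect_lte(less$PN + less$PS, more$PN + more$PS)
})

test_that("parameter recovery reports calibrated Watterson estimates", {
  set.seed(88)
  cfg <- sim_config(theta_syn = 5, theta_nonsyn = 0,
                    outgroup_divergence = c(syn = 3, nonsyn = 1),
                    n_codons = 120)
  datasets <- lapply(1:40, function(i) generate_dataset(cfg))
  rec <- recover_parameters(datasets)
  expect_equal(nrow(rec$estimates), 40L)
  expect_true(all(rec$estimates$theta_nonsyn_hat == 0))
  expect_equal(unname(rec$rmse[["theta_nonsyn"]]), 0)
  expect_lt(abs(unname(rec$bias[["theta_syn"]])), 1.5)
})

test_that("the partial-sweep genealogy concentrates the sample as asked", {
  set.seed(89)
  tr <- polydiv:::sweep_genealogy(38, 0.95, 2, burst = 0.05)
  expect_equal(tr$n, 38L)
  swept <- attr(tr, "swept_tips")
  expect_equal(length(swept), 36L)
  # the swept cluster has fully coalesced by the burst time: some internal
  # node subtends exactly the swept tips
  has_cluster <- any(vapply(tr$tips, function(tp) {
    setequal(tp, swept)
  }, logical(1)))
  expect_true(has_cluster)
})
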