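code5 <- genetic_code(5)
code1 <- genetic_code(1)

test_that("pathway enumeration reproduces hand-worked mitochondrial cases", {
  # TTT -> GTA: via GTT (Phe->Val nonsyn, Val->Val syn) or via TTA
  # (Phe->Leu, Leu->Val, both nonsyn): average 0.5 syn / 1.5 nonsyn
  ps <- enumerate_pathways("TTT", "GTA", code5)
  expect_equal(ps$k, 2L)
  expect_equal(nrow(ps$paths), 2L)
  expect_setequal(paste(ps$paths$n_syn, ps$paths$n_nonsyn),
                  c("1 1", "0 2"))
  expect_equal(ps$syn, 0.5)
  expect_equal(ps$nonsyn, 1.5)

  expect_equal(enumerate_pathways("AAA", "AAA", code5)$k, 0L)
  expect_equal(enumerate_pathways("AAA", "AAA", code5)$syn, 0)

  # GTA -> ATG: both orderings give one synonymous + one nonsynonymous step
  ps2 <- enumerate_pathways("GTA", "ATG", code5)
  expect_equal(ps2$paths$n_syn, c(1, 1))
  expect_equal(ps2$paths$n_nonsyn, c(1, 1))
})

test_that("pathway averages match the brute-force oracle on random pairs", {
  set.seed(31)
  codons <- names(code5)
  for (code in list(code1, code5)) {
    ocode <- oracle_code(attr(code, "table_id"))
    for (rep in seq_len(150)) {
      pair <- sample(codons, 2)
      ps <- enumerate_pathways(pair[1], pair[2], code)
      expected <- suppressWarnings(
        oracle_pathway_average(pair[1], pair[2], ocode))
      got <- suppressWarnings(
        enumerate_pathways(pair[1], pair[2], code))
      expect_equal(c(syn = got$syn, nonsyn = got$nonsyn), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("per-codon site counts follow the fractional-site definition", {
  expect_equal(count_site_classes("TTT", code5),
               c(syn = 1 / 3, nonsyn = 8 / 3))
  # ATG is Met under both codes, but ATA is Met only in the mito code
  expect_equal(count_site_classes("ATG", code5),
               c(syn = 1 / 3, nonsyn = 8 / 3))
  expect_equal(count_site_classes("ATG", code1), c(syn = 0, nonsyn = 3))
  # third position of a four-fold family is fully synonymous
  expect_gte(count_site_classes("GGG", code1)[["syn"]], 1)
  expect_error(count_site_classes("TAA", code1), "stop")
})

test_that("codon columns classify into the four MK cells as specified", {
  # Lys/Lys polymorphism, outgroup matches the major allele
  contrib <- classify_codon_column(c(rep("AAA", 37), "AAG"), "AAA", code5)
  expect_equal(contrib$class, "PS")
  expect_equal(contrib$weight, 1)

  # fixed Leu/Leu difference to the outgroup
  contrib2 <- classify_codon_column(rep("TTA", 10), "TTG", code5)
  expect_equal(contrib2$class, "DS")
  expect_equal(contrib2$weight, 1)

  # two-step divergence: averaged vs minimal-nonsynonymous counting
  more <- classify_codon_column(rep("TTT", 10), "GTA", code5,
                                method = "more_inclusive")
  expect_equal(sum(more$weight[more$class == "DS"]), 0.5)
  expect_equal(sum(more$weight[more$class == "DN"]), 1.5)
  less <- classify_codon_column(rep("TTT", 10), "GTA", code5,
                                method = "less_inclusive")
  expect_equal(sum(less$weight[less$class == "DS"]), 1)
  expect_equal(sum(less$weight[less$class == "DN"]), 1)

  # polymorphic site where the outgroup allele is present in the ingroup
  # contributes polymorphism only; absent allele adds a fixed difference too
  shared <- classify_codon_column(c(rep("AAA", 5), rep("AAG", 5)), "AAG",
                                  code5)
  expect_equal(sum(shared$weight[startsWith(shared$class, "D")]), 0)
  absent <- classify_codon_column(c(rep("TTA", 5), rep("TTG", 5)), "TTC",
                                  code5)
  expect_equal(sum(absent$weight[startsWith(absent$class, "P")]), 1)
  expect_equal(sum(absent$weight[startsWith(absent$class, "D")]), 1)

  # all-missing column is skipped with a reason
  skipped <- classify_codon_column(c(NA_character_, NA_character_), "AAA",
                                   code5)
  expect_equal(nrow(skipped), 0L)
  expect_match(attr(skipped, "skipped"), "min_ingroup")
})

test_that("gene-level MK tables sum column contributions", {
  # two-codon toy gene: one synonymous polymorphism + one synonymous
  # fixed difference
  codons <- cbind(c(rep("AAA", 37), "AAG"), rep("TTA", 38))
  rownames(codons) <- sprintf("s%02d", 1:38)
  codons <- rbind(codons, out = c("AAA", "TTG"))
  gene <- structure(list(gene = "toy", codons = codons,
                         ingroup = sprintf("s%02d", 1:38),
                         outgroup = "out", code = code5),
                    class = "gene_alignment")
  tab <- build_mk_table(gene)
  expect_equal(c(tab$PN, tab$PS, tab$DN, tab$DS), c(0, 1, 0, 1))

  # invariant gene gives the all-zero table
  inv <- matrix("ATT", 11, 4,
                dimnames = list(c(sprintf("s%d", 1:10), "out"), NULL))
  gene_inv <- structure(list(gene = "inv", codons = inv,
                             ingroup = sprintf("s%d", 1:10),
                             outgroup = "out", code = code5),
                        class = "gene_alignment")
  tab0 <- build_mk_table(gene_inv)
  expect_equal(c(tab0$PN, tab0$PS, tab0$DN, tab0$DS), c(0, 0, 0, 0))
})

test_that("synthetic planted MK counts are recovered exactly", {
  for (seed in c(101, 102, 103)) {
    ds <- generate_dataset(sim_config(n_codons = 150, seed = seed))
    gene <- extract_gene(ds$alignment, ds$annotation[1, ])
    tab <- build_mk_table(gene)
    expect_equal(tab$PN, ds$truth$P_N)
    expect_equal(tab$PS, ds$truth$P_S)
    expect_equal(tab$DN, ds$truth$D_N)
    expect_equal(tab$DS, ds$truth$D_S)
  }
})

test_that("less-inclusive divergence never exceeds more-inclusive D_N and
           steps sum to the number of differing positions", {
  set.seed(33)
  codons <- names(code5)[code5 != "*"]
  for (rep in seq_len(60)) {
    pair <- sample(codons, 2)
    ps <- suppressWarnings(enumerate_pathways(pair[1], pair[2], code5))
    mn <- polydiv:::min_nonsyn_path(ps)
    expect_lte(mn[["nonsyn"]], ps$nonsyn + 1e-12)
    expect_equal(ps$syn + ps$nonsyn, ps$k)
    expect_equal(unname(mn[["syn"]] + mn[["nonsyn"]]), ps$k)
  }
})

test_that("polymorphism counts agree between methods without missing data", {
  set.seed(34)
  ds <- generate_dataset(sim_config(n_codons = 120, seed = 77))
  gene <- extract_gene(ds$alignment, ds$annotation[1, ])
  more <- build_mk_table(gene, method = "more_inclusive")
  less <- build_mk_table(gene, method = "less_inclusive")
  expect_equal(more$PN, less$PN)
  expect_equal(more$PS, less$PS)
})

test_that("dual-outgroup polarization follows the agreement rule", {
  mk_gene <- function(ing, og1, og2) {
    codons <- rbind(matrix(ing, length(ing), 1), og1, og2)
    rownames(codons) <- c(sprintf("s%d", seq_along(ing)), "og1", "og2")
    structure(list(gene = "g", codons = codons,
                   ingroup = sprintf("s%d", seq_along(ing)),
                   outgroup = c("og1", "og2"), code = code5),
              class = "gene_alignment")
  }
  # ingroup fixed AAA (Lys), both outgroups GAA: one divergence
  tab <- polarize_with_two_outgroups(mk_gene(rep("AAA", 6), "GAA", "GAA"))
  expect_equal(tab$DN + tab$DS, 1)
  # discordant outgroups: excluded from divergence
  tab2 <- polarize_with_two_outgroups(mk_gene(rep("AAA", 6), "GAA", "AAA"))
  expect_equal(tab2$DN + tab2$DS, 0)
  # ingroup polymorphic {AAA, GAA}, both outgroups GAA: polymorphism only
  tab3 <- polarize_with_two_outgroups(
    mk_gene(c(rep("AAA", 4), rep("GAA", 2)), "GAA", "GAA"))
  expect_equal(tab3$DN + tab3$DS, 0)
  expect_equal(tab3$PN + tab3$PS, 1)
  # a single outgroup row is not enough
  g1 <- mk_gene(rep("AAA", 6), "GAA", "GAA")
  g1$outgroup <- "og1"
  expect_error(polarize_with_two_outgroups(g1), "two outgroup")
})

test_that("site totals sum to three per codon away from stop neighbours", {
  sums <- vapply(c("TTT", "GGG", "ATG", "CCC", "GAT"), function(cd) {
    sum(count_site_classes(cd, code5))
  }, numeric(1))
  expect_equal(unname(sums), rep(3, 5))
})
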