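# End-to-end orchestration: alignment -> per-gene diversity and MK tables
# -> gene-set statistics -> recombination and neutrality tests.

#' Run the full polymorphism/divergence analysis
#'
#' Orchestrates the pipeline on an aligned population sample: per-gene
#' diversity summaries split by site class, per-gene MK tables and summary
#' statistics, gene-set summaries (summed counts, NI_TG with bootstrap CI,
#' Woolf homogeneity), the LD and four-gamete recombination report, and the
#' synonymous-vs-nonsynonymous Tajima's D heterogeneity test. Overlapping
#' gene annotations are analysed independently: a site inside two genes
#' contributes to both genes' tables.
#'
#' @param aln A \code{pop_alignment} (or FASTA path, read with
#'   \code{outgroup}).
#' @param annotation A \code{gene_annotation} table (or TSV path).
#' @param gene_sets Named list of gene-name vectors (default: one set,
#'   "all", containing every annotated gene).
#' @param method MK counting method, \code{"more_inclusive"} (default) or
#'   \code{"less_inclusive"}.
#' @param outgroup Outgroup label(s); defaults to the alignment's outgroup
#'   set. Two labels with \code{polarize = TRUE} use dual-outgroup
#'   polarized divergence.
#' @param polarize Use two outgroups to polarize divergence (default
#'   FALSE).
#' @param drop_sequences Sequences removed before less-inclusive counting.
#' @param maf_cutoffs Minor-allele-frequency cutoffs for the LD report
#'   (default 0, 0.05, 0.1).
#' @param n_boot Bootstrap resamples for NI_TG intervals.
#' @param n_reps Replicates for the coalescent null machinery.
#' @param n_perm Permutations for LD-distance correlation p-values.
#' @param seed Seed recorded in the manifest and used for every stochastic
#'   step.
#' @param out_dir Optional output directory for TSV reports.
#' @return List of class \code{polydiv_run} with elements
#'   \code{diversity}, \code{mk_genes}, \code{gene_sets}, \code{ld},
#'   \code{four_gamete}, \code{heterogeneity}, \code{manifest}.
#' @export
run_pipeline <- function(aln, annotation, gene_sets = NULL,
                         method = c("more_inclusive", "less_inclusive"),
                         outgroup = NULL, polarize = FALSE,
                         drop_sequences = character(),
                         maf_cutoffs = c(0, 0.05, 0.1),
                         n_boot = 5000, n_reps = 10000, n_perm = 1000,
                         seed = NULL, out_dir = NULL) {
  method <- match.arg(method)
  if (is.character(aln) && length(aln) == 1L) {
    aln <- read_alignment(aln, outgroup = outgroup %||% character())
  }
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.null(outgroup)) outgroup <- aln$outgroup
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_sets)) gene_sets <- list(all = annotation$gene)
  missing_genes <- setdiff(unlist(gene_sets), annotation$gene)
  if (length(missing_genes)) {
    stop("gene set member(s) absent from annotation: ",
         paste(missing_genes, collapse = ", "))
  }
  # stable order regardless of input FASTA row order
  ord <- order(match(aln$ids, c(sort(aln$ingroup), sort(aln$outgroup))))
  aln <- pop_alignment(aln$mat[aln$ids[ord], , drop = FALSE],
                       outgroup = aln$outgroup)

  diversity <- list()
  mk <- list()
  skipped <- 0L
  for (g in seq_len(nrow(annotation))) {
    gene <- extract_gene(aln, annotation[g, ])
    diversity[[g]] <- diversity_summary(gene, outgroup = outgroup[1L])
    tab <- if (polarize) {
      polarize_with_two_outgroups(gene, outgroups = outgroup[1:2],
                                  method = method)
    } else {
      build_mk_table(gene, method = method, outgroup = outgroup[1L],
                     drop_sequences = drop_sequences)
    }
    skipped <- skipped + nrow(attr(tab, "skipped") %||%
                                data.frame())
    mk[[g]] <- tab
  }
  diversity <- do.call(rbind, diversity)
  mk_counts <- do.call(rbind, lapply(mk, as.data.frame))
  mk_genes <- mk_statistics(mk_counts)

  sets <- lapply(names(gene_sets), function(nm) {
    summarize_gene_set(mk_counts[mk_counts$gene %in% gene_sets[[nm]], ,
                                 drop = FALSE],
                       set_name = nm, n_boot = n_boot, seed = seed)
  })
  names(sets) <- names(gene_sets)

  ing <- ingroup_matrix(aln)
  ld <- lapply(maf_cutoffs, function(m) {
    pairs <- pairwise_ld(ing, maf_cutoff = m)
    cors <- if (nrow(pairs) >= 3L) {
      rbind(
        data.frame(measure = "d_prime_abs",
                   t(ld_distance_correlation(pairs, "d_prime_abs",
                                             n_perm = n_perm,
                                             seed = seed))),
        data.frame(measure = "r2",
                   t(ld_distance_correlation(pairs, "r2", n_perm = n_perm,
                                             seed = seed))))
    } else NULL
    list(maf_cutoff = m, pairs = pairs, correlations = cors)
  })
  names(ld) <- paste0("maf_", maf_cutoffs)
  fgt <- four_gamete_test(ing)

  # heterogeneity of Tajima's D between site classes, across all genes
  syn <- diversity[diversity$site_class == "synonymous", ]
  nonsyn <- diversity[diversity$site_class == "nonsynonymous", ]
  het <- NULL
  S_syn <- sum(syn$S); S_nonsyn <- sum(nonsyn$S)
  if (S_syn >= 1L && S_nonsyn >= 1L) {
    # observed per-class D pooled over the annotated coding region
    n_ing <- length(aln$ingroup)
    d_syn <- tajimas_d(sum(syn$pi), S_syn, n_ing)
    d_nonsyn <- tajimas_d(sum(nonsyn$pi), S_nonsyn, n_ing)
    het <- list(
      S_syn = S_syn, S_nonsyn = S_nonsyn,
      d_syn = d_syn, d_nonsyn = d_nonsyn,
      delta = d_nonsyn - d_syn,
      p = unname(heterogeneity_test(n_ing, S_syn, S_nonsyn,
                                    d_nonsyn - d_syn,
                                    n_reps = n_reps, seed = seed)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("polydiv")),
    r_version = R.version.string,
    seed = seed, method = method, polarize = polarize,
    n_ingroup = length(aln$ingroup), outgroup = outgroup,
    n_genes = nrow(annotation), skipped_columns = skipped,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  res <- structure(
    list(diversity = diversity, mk_genes = mk_genes, gene_sets = sets,
         ld = ld, four_gamete = fgt, heterogeneity = het,
         manifest = manifest),
    class = "polydiv_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(res$diversity, file.path(out_dir, "diversity.tsv"))
  write_results_table(res$mk_genes, file.path(out_dir, "mk_genes.tsv"))
  sets <- do.call(rbind, lapply(res$gene_sets, function(s) {
    data.frame(set = s$set_name, n_genes = length(s$genes),
               PN = s$summed$PN, PS = s$summed$PS, DN = s$summed$DN,
               DS = s$summed$DS, NI = s$NI_summed, Z = s$Z_summed,
               NI_TG = s$NI_TG, NI_TG_low = s$NI_TG_CI[1L],
               NI_TG_high = s$NI_TG_CI[2L], p_fet = s$p_fet,
               woolf_p = if (is.null(s$woolf)) NA else s$woolf$p)
  }))
  write_results_table(sets, file.path(out_dir, "gene_sets.tsv"))
  for (nm in names(res$ld)) {
    write_results_table(res$ld[[nm]]$pairs,
                        file.path(out_dir, paste0("ld_", nm, ".tsv")))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.polydiv_run <- function(x, ...) {
  cat("polydiv run:", x$manifest$n_genes, "gene(s),",
      x$manifest$n_ingroup, "ingroup sequences, method",
      x$manifest$method, "\n")
  cat("  four-gamete violating pairs:",
      x$four_gamete$n_violating_pairs, "\n")
  if (!is.null(x$heterogeneity)) {
    cat("  syn/nonsyn Tajima's D heterogeneity: delta =",
        format(x$heterogeneity$delta, digits = 3), ", p =",
        format(x$heterogeneity$p, digits = 3), "\n")
  }
  cat("  gene sets:", paste(names(x$gene_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Table-style MK reports from a pre-tabulated count file
#'
#' Stats-only entry point for data supplied as gene-level MK counts (the
#' form in which published polymorphism/divergence tables circulate):
#' produces the per-gene statistics table (NI, Z*, Fisher p) and the
#' gene-set summaries (summed-count NI/Z, NI_TG with bootstrap CI, Woolf
#' homogeneity).
#'
#' @param counts Path to a TSV with columns \code{gene, PN, PS, DN, DS}, or
#'   an equivalent data frame.
#' @param gene_sets Named list of gene-name vectors; default: one set
#'   ("All") with every gene.
#' @param n_boot Bootstrap resamples for NI_TG intervals.
#' @param seed Optional seed for the bootstrap.
#' @return List with \code{genes} (an \code{mk_statistics} data frame) and
#'   \code{sets} (list of \code{gene_set_summary}).
#' @export
mk_from_counts <- function(counts, gene_sets = NULL, n_boot = 5000,
                           seed = NULL) {
  if (is.character(counts)) counts <- read_mk_counts(counts)
  counts <- as_mk_counts(counts)
  if (!nrow(counts)) stop("empty MK count table")
  if (is.null(gene_sets)) gene_sets <- list(All = counts$gene)
  missing_genes <- setdiff(unlist(gene_sets), counts$gene)
  if (length(missing_genes)) {
    stop("gene set member(s) absent from counts: ",
         paste(missing_genes, collapse = ", "))
  }
  sets <- lapply(names(gene_sets), function(nm) {
    summarize_gene_set(counts[counts$gene %in% gene_sets[[nm]], ,
                              drop = FALSE],
                       set_name = nm, n_boot = n_boot, seed = seed)
  })
  names(sets) <- names(gene_sets)
  list(genes = mk_statistics(counts), sets = sets)
}
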