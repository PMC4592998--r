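# Synthetic-data generator: codon-structured population alignments with an
# outgroup, drawn on a single genealogy (equilibrium or partial-sweep), with
# exact truth records for every planted mutation.

.codon_change_cache <- new.env(parent = emptyenv())

# per-codon table of the nine single-base changes with their class and
# whether they create a stop; memoised per genetic code
codon_change_table <- function(code) {
  key <- attr(code, "table_id")
  if (!is.null(.codon_change_cache[[key]])) {
    return(.codon_change_cache[[key]])
  }
  out <- list()
  for (cd in names(code)) {
    if (code[cd] == "*") {
      out[[cd]] <- NULL
      next
    }
    b <- strsplit(cd, "")[[1L]]
    rows <- list()
    for (pos in 1:3) {
      for (alt in setdiff(.BASES, b[pos])) {
        mut <- b
        mut[pos] <- alt
        mcd <- paste0(mut, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, from = b[pos], to = alt,
          class = if (identical(unname(code[cd]), unname(code[mcd])))
            "syn" else "nonsyn",
          to_stop = unname(code[mcd]) == "*")
      }
    }
    out[[cd]] <- do.call(rbind, rows)
  }
  .codon_change_cache[[key]] <- out
  out
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions of a single-population sample of a
#' nonrecombining mitochondrial protein-coding gene: 38 haploid ingroup
#' sequences, one outgroup at moderate divergence, AT-rich codon
#' composition, and a partial-sweep scenario available for the haplotype
#' structure of a recent cytoplasmic sweep (one dominant recent haplotype
#' cluster plus a couple of deeply divergent lineages).
#'
#' @param n_ingroup Number of ingroup haploid sequences (default 38).
#' @param n_codons Gene length in codons (default 300, a mid-sized
#'   mitochondrial gene).
#' @param genetic_code_id Translation table (default 5, invertebrate
#'   mitochondrial).
#' @param theta_syn,theta_nonsyn Population mutation rates per class, count
#'   units per gene (defaults 5 and 2).
#' @param outgroup_divergence Expected substitutions per class on the
#'   outgroup branch, named \code{c(syn =, nonsyn =)} (default 20 and 8).
#' @param scenario \code{"equilibrium"} or \code{"partial_sweep"}.
#' @param sweep_fraction Proportion of the sample inside the swept cluster
#'   (default 0.95).
#' @param n_divergent_lineages Deeply divergent lineages attached near the
#'   root (default 2).
#' @param sweep_burst_time Coalescent time by which the swept cluster has
#'   fully coalesced (default 0.05).
#' @param missing_rate Per-cell probability of masking an ingroup base
#'   (default 0).
#' @param gc_to_at_bias Probability that a mutation is constrained to change
#'   G or C into A or T (default 0).
#' @param ancestral_gc Per-base G+C weight of the ancestral sequence
#'   (default 0.3, AT-rich as in insect mtDNA).
#' @param seed Optional integer seed.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_ingroup = 38, n_codons = 300, genetic_code_id = 5,
                       theta_syn = 5, theta_nonsyn = 2,
                       outgroup_divergence = c(syn = 20, nonsyn = 8),
                       scenario = c("equilibrium", "partial_sweep"),
                       sweep_fraction = 0.95, n_divergent_lineages = 2,
                       sweep_burst_time = 0.05,
                       missing_rate = 0, gc_to_at_bias = 0,
                       ancestral_gc = 0.3, seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(names(outgroup_divergence))) {
    names(outgroup_divergence) <- c("syn", "nonsyn")
  }
  stopifnot(n_ingroup >= 2, n_codons >= 1,
            theta_syn >= 0, theta_nonsyn >= 0,
            all(outgroup_divergence >= 0),
            sweep_fraction > 0, sweep_fraction <= 1,
            n_divergent_lineages >= 0,
            missing_rate >= 0, missing_rate <= 1,
            gc_to_at_bias >= 0, gc_to_at_bias <= 1,
            ancestral_gc >= 0, ancestral_gc <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# constrained genealogy for a partial cytoplasmic sweep: a cluster of m tips
# coalesces in a star-like burst near the present, any intermediate tips
# join the swept lineage at shallow times, and the divergent lineages
# coalesce near the root
sweep_genealogy <- function(n, sweep_fraction, n_divergent, burst = 0.05) {
  m <- max(2L, min(round(sweep_fraction * n), n))
  d <- min(n_divergent, n - m)
  g <- n - m - d
  swept <- seq_len(m)
  inter <- if (g > 0) m + seq_len(g) else integer(0)
  diverg <- if (d > 0) m + g + seq_len(d) else integer(0)

  times <- numeric(0); ea <- integer(0); eb <- integer(0)
  nxt <- n
  # phase 1: burst coalescence of the swept cluster
  t_burst <- sort(runif(m - 1L, 0, burst))
  active <- swept
  for (i in seq_len(m - 1L)) {
    pair <- sample(length(active), 2L)
    nxt <- nxt + 1L
    times <- c(times, t_burst[i])
    ea <- c(ea, active[pair[1L]]); eb <- c(eb, active[pair[2L]])
    active <- c(active[-pair], nxt)
  }
  main <- active[length(active)]
  # phase 2: intermediate lineages join the swept lineage at shallow times
  if (g > 0) {
    t_int <- sort(runif(g, burst, 0.6))
    for (i in seq_len(g)) {
      nxt <- nxt + 1L
      times <- c(times, t_int[i])
      ea <- c(ea, main); eb <- c(eb, inter[i])
      main <- nxt
    }
  }
  # phase 3: deep standard coalescent among main + divergent lineages
  if (d > 0) {
    active <- c(main, diverg)
    t <- 1
    while (length(active) > 1L) {
      k <- length(active)
      t <- t + rexp(1L, k * (k - 1) / 2)
      pair <- sample(k, 2L)
      nxt <- nxt + 1L
      times <- c(times, t)
      ea <- c(ea, active[pair[1L]]); eb <- c(eb, active[pair[2L]])
      active <- c(active[-pair], nxt)
    }
  }
  tree <- build_genealogy(n, data.frame(time = times, a = ea, b = eb))
  attr(tree, "swept_tips") <- swept
  tree
}

# pick (codon index, change row) for one mutation from the unused codon
# pool; honours the class and, when biased, the G/C -> A/T constraint
draw_mutation_site <- function(pool, anc_codons, changes, class, biased) {
  pick <- function(require_bias) {
    for (idx in seq_along(pool)) {
      cj <- pool[idx]
      tab <- changes[[anc_codons[cj]]]
      if (is.null(tab)) next
      ok <- tab$class == class & !tab$to_stop
      if (require_bias) {
        ok <- ok & tab$from %in% c("G", "C") & tab$to %in% c("A", "T")
      }
      if (any(ok)) {
        row <- tab[which(ok)[sample.int(sum(ok), 1L)], ]
        return(list(codon = cj, row = row, pool_idx = idx))
      }
    }
    NULL
  }
  hit <- pick(biased)
  if (is.null(hit) && biased) hit <- pick(FALSE)
  if (is.null(hit)) {
    stop("generation error: no codon in the pool admits a ", class,
         " change; increase n_codons or lower the mutation rates")
  }
  hit
}

#' Generate a synthetic population dataset with known truth
#'
#' Draws one genealogy (neutral equilibrium coalescent, or the constrained
#' partial-sweep genealogy), builds an AT/GC-weighted ancestral codon
#' sequence, and plants mutations: ingroup polymorphisms are dropped on
#' branches with probability proportional to branch length, outgroup
#' substitutions on the outgroup branch. Synonymous mutations are placed
#' only at positions where the change is synonymous on the current
#' background (and conversely for nonsynonymous), changes creating stop
#' codons are avoided, and every mutation occupies its own codon (infinite
#' sites across codons), which keeps the truth record exact. Mutation
#' numbers are Poisson: ingroup classes with mean theta/2 times the total
#' tree length, outgroup classes with mean \code{outgroup_divergence}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{alignment.fasta}, \code{genes.tsv} and \code{truth.json} there.
#' @return List of class \code{sim_dataset} with elements
#'   \code{alignment} (a \code{pop_alignment}), \code{annotation}
#'   (single-gene annotation table), \code{truth} (planted counts, per-site
#'   records, the genealogy and the config).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  code <- genetic_code(cfg$genetic_code_id)
  changes <- codon_change_table(code)
  n <- cfg$n_ingroup

  tree <- if (cfg$scenario == "partial_sweep") {
    sweep_genealogy(n, cfg$sweep_fraction, cfg$n_divergent_lineages,
                    cfg$sweep_burst_time)
  } else {
    simulate_genealogy(n)
  }
  L <- tree_length(tree)

  n_mut <- c(P_syn = rpois(1L, cfg$theta_syn / 2 * L),
             P_nonsyn = rpois(1L, cfg$theta_nonsyn / 2 * L),
             D_syn = rpois(1L, cfg$outgroup_divergence[["syn"]]),
             D_nonsyn = rpois(1L, cfg$outgroup_divergence[["nonsyn"]]))
  if (sum(n_mut) > cfg$n_codons) {
    stop("generation error: ", sum(n_mut), " mutations exceed ",
         cfg$n_codons, " codons; increase n_codons")
  }

  # ancestral sequence: non-stop codons weighted by per-base GC content
  codon_names <- names(code)[code != "*"]
  gc_w <- vapply(strsplit(codon_names, ""), function(b) {
    prod(ifelse(b %in% c("G", "C"), cfg$ancestral_gc / 2,
                (1 - cfg$ancestral_gc) / 2))
  }, numeric(1))
  anc_codons <- sample(codon_names, cfg$n_codons, replace = TRUE,
                       prob = gc_w)

  # codon matrix: n ingroup rows + 1 outgroup row, all ancestral to start
  cmat <- matrix(rep(anc_codons, each = n + 1L), n + 1L, cfg$n_codons)
  pool <- sample.int(cfg$n_codons)
  sites <- list()
  classes <- c(P_syn = "syn", P_nonsyn = "nonsyn",
               D_syn = "syn", D_nonsyn = "nonsyn")
  for (kind in names(n_mut)) {
    for (s in seq_len(n_mut[[kind]])) {
      biased <- runif(1L) < cfg$gc_to_at_bias
      hit <- draw_mutation_site(pool, anc_codons, changes,
                                classes[[kind]], biased)
      pool <- pool[-hit$pool_idx]
      cj <- hit$codon
      mut_codon <- strsplit(anc_codons[cj], "")[[1L]]
      mut_codon[hit$row$pos] <- hit$row$to
      mut_codon <- paste0(mut_codon, collapse = "")
      if (startsWith(kind, "P")) {
        branch <- sample(length(tree$blen), 1L, prob = tree$blen)
        carriers <- tree$tips[[branch]]
        cmat[carriers, cj] <- mut_codon
        derived_count <- length(carriers)
      } else {
        cmat[n + 1L, cj] <- mut_codon
        branch <- NA_integer_
        derived_count <- NA_integer_
      }
      sites[[length(sites) + 1L]] <- data.frame(
        codon = cj, pos = hit$row$pos,
        column = 3L * (cj - 1L) + hit$row$pos,
        from = hit$row$from, to = hit$row$to,
        class = classes[[kind]],
        type = if (startsWith(kind, "P")) "polymorphism" else "divergence",
        branch = branch, derived_count = derived_count)
    }
  }
  site_df <- if (length(sites)) do.call(rbind, sites) else
    data.frame(codon = integer(), pos = integer(), column = integer(),
               from = character(), to = character(), class = character(),
               type = character(), branch = integer(),
               derived_count = integer())

  # expand codons to bases
  base_mat <- matrix(NA_character_, n + 1L, 3L * cfg$n_codons)
  split_codons <- strsplit(as.vector(cmat), "")
  for (j in seq_len(cfg$n_codons)) {
    idx <- (j - 1L) * (n + 1L) + seq_len(n + 1L)
    base_mat[, (3L * j - 2L):(3L * j)] <- do.call(rbind, split_codons[idx])
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(n * ncol(base_mat)) < cfg$missing_rate, n)
    base_mat[seq_len(n), ][mask] <- NA_character_
  }
  rownames(base_mat) <- c(sprintf("seq%02d", seq_len(n)), "outgroup")
  aln <- pop_alignment(base_mat, outgroup = "outgroup")

  ann <- as_gene_annotation(data.frame(
    gene = "gene1", start = 1L, end = 3L * cfg$n_codons, strand = "+",
    frame = 0L, code = cfg$genetic_code_id, stringsAsFactors = FALSE))

  truth <- list(
    P_N = unname(n_mut[["P_nonsyn"]]), P_S = unname(n_mut[["P_syn"]]),
    D_N = unname(n_mut[["D_nonsyn"]]), D_S = unname(n_mut[["D_syn"]]),
    sites = site_df,
    swept_tips = attr(tree, "swept_tips"),
    tree = tree, config = cfg)

  out <- structure(list(alignment = aln, annotation = ann, truth = truth),
                   class = "sim_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_alignment(aln, file.path(out_dir, "alignment.fasta"))
    write.table(ann, file.path(out_dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tr <- truth[c("P_N", "P_S", "D_N", "D_S")]
    tr$sites <- truth$sites
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$paths <- file.path(out_dir,
                           c("alignment.fasta", "genes.tsv", "truth.json"))
  }
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset (", x$truth$config$scenario, "): ",
      length(x$alignment$ingroup), " ingroup + 1 outgroup, ",
      ncol(x$alignment$mat), " bp; planted P_N=", x$truth$P_N,
      " P_S=", x$truth$P_S, " D_N=", x$truth$D_N, " D_S=", x$truth$D_S,
      "\n", sep = "")
  invisible(x)
}

#' Recover generator parameters from synthetic replicates
#'
#' Runs each dataset through the analysis path (gene extraction, site
#' classification, Watterson's theta per class) and summarises the bias and
#' RMSE of the estimates against the generating values.
#'
#' @param datasets List of \code{sim_dataset} objects generated under one
#'   equilibrium configuration.
#' @return List with \code{estimates} (per-replicate data frame),
#'   \code{truth}, \code{bias} and \code{rmse} (named by class).
#' @export
recover_parameters <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  cfg <- datasets[[1L]]$truth$config
  est <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    gene <- extract_gene(ds$alignment, ds$annotation[1L, ])
    div <- diversity_summary(gene)
    data.frame(
      rep = i,
      theta_syn_hat = div$theta_w[div$site_class == "synonymous"],
      theta_nonsyn_hat = div$theta_w[div$site_class == "nonsynonymous"])
  }))
  truth <- c(theta_syn = cfg$theta_syn, theta_nonsyn = cfg$theta_nonsyn)
  bias <- c(theta_syn = mean(est$theta_syn_hat) - cfg$theta_syn,
            theta_nonsyn = mean(est$theta_nonsyn_hat) - cfg$theta_nonsyn)
  rmse <- c(theta_syn = sqrt(mean((est$theta_syn_hat - cfg$theta_syn)^2)),
            theta_nonsyn =
              sqrt(mean((est$theta_nonsyn_hat - cfg$theta_nonsyn)^2)))
  list(estimates = est, truth = truth, bias = bias, rmse = rmse)
}
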