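# Neutrality-index statistics computed from MK contingency tables.

as_mk_counts <- function(x) {
  if (is.numeric(x) && length(x) == 4L) {
    x <- as.data.frame(as.list(setNames(x, c("PN", "PS", "DN", "DS"))))
  }
  stopifnot(all(c("PN", "PS", "DN", "DS") %in% names(x)))
  if (any(x$PN < 0 | x$PS < 0 | x$DN < 0 | x$DS < 0)) {
    stop("MK counts must be non-negative")
  }
  x
}

#' Neutrality index of an MK table
#'
#' NI = (P_N/P_S) / (D_N/D_S) = (D_S P_N)/(D_N P_S). Whenever any of the
#' four cells is zero, a count of 1 is added to \emph{all} four cells before
#' the ratio is taken, so NI is always defined and positive.
#'
#' @param counts MK counts: numeric \code{c(PN, PS, DN, DS)} or a data frame
#'   with those columns (vectorized over rows).
#' @return Numeric vector of NI values, with logical attribute
#'   \code{pseudocount_applied} marking rows where the zero-cell rule fired.
#' @examples
#' neutrality_index(c(5, 2, 11, 35))  # 7.955
#' neutrality_index(c(0, 16, 8, 101)) # pseudocount path, 0.667
#' @export
neutrality_index <- function(counts) {
  x <- as_mk_counts(counts)
  pseudo <- x$PN == 0 | x$PS == 0 | x$DN == 0 | x$DS == 0
  a <- x$PN + pseudo; b <- x$PS + pseudo
  c_ <- x$DN + pseudo; d <- x$DS + pseudo
  ni <- (d * a) / (c_ * b)
  attr(ni, "pseudocount_applied") <- pseudo
  ni
}

#' Z* statistic of an MK table
#'
#' Z* = log10(((D_N + 1)(P_S + 1)) / ((D_S + 1)(P_N + 1))). The +1 in every
#' cell is part of the definition, so Z* is always finite; negative values
#' indicate an excess of (weakly deleterious) nonsynonymous polymorphism,
#' positive values an excess of nonsynonymous divergence.
#'
#' @inheritParams neutrality_index
#' @return Numeric vector.
#' @examples
#' z_star(c(5, 2, 11, 35)) # -0.778
#' @export
z_star <- function(counts) {
  x <- as_mk_counts(counts)
  log10(((x$DN + 1) * (x$PS + 1)) / ((x$DS + 1) * (x$PN + 1)))
}

#' Plain Z statistic (no pseudocounts)
#'
#' Z = log10((D_N P_S)/(D_S P_N)) on the raw counts; equals -log10(NI)
#' exactly when no cell is zero. Returns NA (undefined) when any cell is
#' zero. Used for summed counts across gene sets, which rarely contain
#' zeros.
#'
#' @inheritParams neutrality_index
#' @return Numeric vector, NA where undefined.
#' @export
z_plain <- function(counts) {
  x <- as_mk_counts(counts)
  z <- log10((x$DN * x$PS) / (x$DS * x$PN))
  z[x$PN == 0 | x$PS == 0 | x$DN == 0 | x$DS == 0] <- NA_real_
  z
}

round_half_up <- function(x) floor(x + 0.5)

#' Fisher's exact test of an MK table
#'
#' Two-sided exact test of the 2x2 table (point-probability method: the
#' p-value sums all tables whose probability does not exceed that of the
#' observed table). Fractional counts, which arise from pathway averaging,
#' are rounded half-away-from-zero before testing; NI/Z/Z* elsewhere use the
#' unrounded values.
#'
#' @inheritParams neutrality_index
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_exact_mk(c(5, 2, 11, 35)) # 0.021
#' @export
fisher_exact_mk <- function(counts) {
  x <- as_mk_counts(counts)
  vapply(seq_len(nrow(x)), function(i) {
    m <- matrix(round_half_up(c(x$PN[i], x$DN[i], x$PS[i], x$DS[i])), 2L)
    stats::fisher.test(m)$p.value
  }, numeric(1))
}

#' Combined neutrality index across genes (NI_TG)
#'
#' The unbiased combined estimator
#' \deqn{NI_{TG} = \frac{\sum_i D_{Si} P_{Ni}/(P_{Si}+D_{Si})}
#'                      {\sum_i P_{Si} D_{Ni}/(P_{Si}+D_{Si})}}
#' computed over gene-level tables with raw counts (no pseudocounts). Genes
#' with \eqn{P_{Si} + D_{Si} = 0} contribute nothing; the estimator is NA
#' (undefined) when the denominator sum is zero.
#'
#' @param counts Data frame of gene-level MK counts.
#' @return Single numeric value, NA when undefined.
#' @export
ni_tg <- function(counts) {
  x <- as_mk_counts(counts)
  if (!nrow(x)) stop("empty table list")
  w <- x$PS + x$DS
  keep <- w > 0
  num <- sum((x$DS * x$PN / w)[keep])
  den <- sum((x$PS * x$DN / w)[keep])
  if (den == 0) return(NA_real_)
  num / den
}

#' Bootstrap confidence interval for NI_TG
#'
#' Percentile interval from resampling genes with replacement. A resample
#' for which the estimator is undefined (zero denominator) makes the whole
#' interval undefined once the fraction of such resamples exceeds
#' \code{max_undefined} (default 0: any undefined resample voids the
#' interval, matching the behaviour of combined-estimator software on gene
#' sets containing zero-denominator genes).
#'
#' @param counts Data frame of gene-level MK counts.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Optional integer seed; identical seeds give identical
#'   intervals.
#' @param conf Confidence level (default 0.95).
#' @param max_undefined Tolerated fraction of undefined resamples.
#' @return Numeric \code{c(low, high)}, or \code{c(NA, NA)} when undefined;
#'   attribute \code{frac_undefined} reports the undefined fraction.
#' @export
ni_tg_bootstrap_ci <- function(counts, n_boot = 5000, seed = NULL,
                               conf = 0.95, max_undefined = 0) {
  x <- as_mk_counts(counts)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  # resampling genes = resampling their per-gene estimator terms
  w <- x$PS + x$DS
  numt <- ifelse(w > 0, x$DS * x$PN / w, 0)
  dent <- ifelse(w > 0, x$PS * x$DN / w, 0)
  est <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    den <- sum(dent[idx])
    if (den == 0) NA_real_ else sum(numt[idx]) / den
  }, numeric(1))
  frac_undef <- mean(is.na(est))
  if (frac_undef > max_undefined) {
    out <- c(low = NA_real_, high = NA_real_)
  } else {
    qs <- quantile(est[!is.na(est)], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE)
    out <- c(low = qs[1L], high = qs[2L])
  }
  attr(out, "frac_undefined") <- frac_undef
  out
}

#' Woolf's test of homogeneity of MK odds ratios
#'
#' Tests whether the gene-level MK odds ratios are homogeneous. Each table
#' gets the Haldane-Anscombe +0.5 correction in every cell; with corrected
#' cells (a, b, c, d) = (P_N, P_S, D_N, D_S), gene weights are
#' \eqn{w_i = (1/a + 1/b + 1/c + 1/d)^{-1}} and
#' \eqn{\chi^2 = \sum_i w_i (\ln OR_i - \overline{\ln OR})^2}, with the
#' weighted mean log odds ratio and df = number of tables - 1.
#'
#' @param counts Data frame of gene-level MK counts (>= 2 rows).
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
woolf_homogeneity <- function(counts) {
  x <- as_mk_counts(counts)
  if (nrow(x) < 2L) stop("Woolf's test needs at least two tables")
  a <- x$PN + 0.5; b <- x$PS + 0.5; c_ <- x$DN + 0.5; d <- x$DS + 0.5
  lor <- log((a * d) / (b * c_))
  w <- 1 / (1 / a + 1 / b + 1 / c_ + 1 / d)
  mu <- sum(w * lor) / sum(w)
  chi2 <- sum(w * (lor - mu)^2)
  df <- nrow(x) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Per-gene MK summary statistics
#'
#' Adds NI (with the zero-cell pseudocount rule), Z*, plain Z, the two-sided
#' Fisher exact p-value and a pseudocount flag to a table of gene-level MK
#' counts.
#'
#' @param counts Data frame with columns \code{gene, PN, PS, DN, DS}.
#' @return Data frame of class \code{mk_statistics}.
#' @export
mk_statistics <- function(counts) {
  x <- as_mk_counts(counts)
  ni <- neutrality_index(x)
  out <- data.frame(
    gene = if ("gene" %in% names(x)) x$gene else seq_len(nrow(x)),
    PN = x$PN, PS = x$PS, DN = x$DN, DS = x$DS,
    NI = as.numeric(ni),
    Zstar = z_star(x),
    Z = z_plain(x),
    p_fet = fisher_exact_mk(x),
    pseudocount_applied = attr(ni, "pseudocount_applied"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mk_statistics", "data.frame")
  out
}

#' Summarise a gene set's MK tables
#'
#' Computes the summed-count statistics (raw sums, no pseudocount: NI, Z and
#' Fisher's exact test of the summed table), the combined estimator NI_TG
#' with its gene-bootstrap confidence interval, Woolf's homogeneity test,
#' and the median/mean/SD of the per-gene NI and Z* distributions.
#'
#' @param counts Data frame of gene-level MK counts for the member genes.
#' @param set_name Label for the set.
#' @param n_boot Bootstrap resamples for the NI_TG interval.
#' @param seed Optional seed for the bootstrap.
#' @return List of class \code{gene_set_summary}.
#' @export
summarize_gene_set <- function(counts, set_name = "gene set",
                               n_boot = 5000, seed = NULL) {
  x <- as_mk_counts(counts)
  if (!nrow(x)) stop("empty gene set")
  summed <- data.frame(PN = sum(x$PN), PS = sum(x$PS),
                       DN = sum(x$DN), DS = sum(x$DS))
  ni_raw <- with(summed, if (PN > 0 && PS > 0 && DN > 0 && DS > 0) {
    (DS * PN) / (DN * PS)
  } else NA_real_)
  per_ni <- as.numeric(neutrality_index(x))
  per_zs <- z_star(x)
  ci <- ni_tg_bootstrap_ci(x, n_boot = n_boot, seed = seed)
  out <- list(
    set_name = set_name,
    genes = if ("gene" %in% names(x)) x$gene else seq_len(nrow(x)),
    summed = summed,
    NI_summed = ni_raw,
    Z_summed = z_plain(summed),
    p_fet = fisher_exact_mk(summed),
    NI_TG = ni_tg(x),
    NI_TG_CI = ci,
    woolf = if (nrow(x) >= 2L) woolf_homogeneity(x) else NULL,
    per_gene = list(
      NI = c(median = median(per_ni), mean = mean(per_ni), sd = sd(per_ni)),
      Zstar = c(median = median(per_zs), mean = mean(per_zs),
                sd = sd(per_zs))
    )
  )
  class(out) <- "gene_set_summary"
  out
}

#' @export
print.gene_set_summary <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undef", formatC(v, format = "g",
                                                       digits = 4))
  cat(x$set_name, " (", length(x$genes), " gene",
      if (length(x$genes) > 1) "s", ")\n", sep = "")
  cat("  summed counts: PN=", x$summed$PN, " PS=", x$summed$PS,
      " DN=", x$summed$DN, " DS=", x$summed$DS, "\n", sep = "")
  cat("  NI (summed) =", fmt(x$NI_summed),
      "  Z =", fmt(x$Z_summed),
      "  P_FET =", fmt(x$p_fet), "\n")
  ci <- x$NI_TG_CI
  cat("  NI_TG =", fmt(x$NI_TG),
      if (anyNA(ci)) "(CI undef)" else
        paste0("(", fmt(ci[1]), ", ", fmt(ci[2]), ")"), "\n")
  if (!is.null(x$woolf)) {
    cat("  Woolf homogeneity: chi2 =", fmt(x$woolf$chi2), "df =", x$woolf$df,
        "p =", fmt(x$woolf$p), "\n")
  }
  cat("  per-gene NI median/mean/sd:",
      paste(fmt(x$per_gene$NI), collapse = " / "), "\n")
  invisible(x)
}

#' Mann-Whitney rank-sum comparison of two statistic distributions
#'
#' Exact U test for small samples without ties, normal approximation with
#' continuity and tie correction otherwise (the standard behaviour of
#' \code{\link[stats]{wilcox.test}}).
#'
#' @param values_a,values_b Numeric vectors (e.g. per-gene NI for two
#'   genomes).
#' @return Named numeric \code{c(U = , p = )}.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  c(U = unname(wt$statistic), p = wt$p.value)
}

#' Effect size between two statistic distributions
#'
#' Absolute difference in means divided by the root mean square of the two
#' standard deviations.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group means and SDs.
#' @return Single numeric effect size.
#' @export
effect_size <- function(mean_a, sd_a, mean_b, sd_b) {
  abs(mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Bonferroni correction helper
#'
#' @param p Vector of p-values.
#' @param n Number of tests (default \code{length(p)}).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, n = length(p)) {
  pmin(1, p * n)
}
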