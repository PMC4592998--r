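# Sequence-diversity and site-frequency-spectrum statistics.
# Columns are nucleotide alignment columns (ingroup rows); missing data are
# NA cells and every statistic uses the per-column non-missing sample size
# where a frequency is needed, while normalising constants that depend on
# the sample size use the full ingroup n.

harmonic <- function(n) sum(1 / seq_len(n))
harmonic2 <- function(n) sum(1 / seq_len(n)^2)

column_counts <- function(col) {
  table(col[!is.na(col)])
}

#' Number of segregating sites
#'
#' Counts alignment columns with at least two distinct non-missing bases.
#'
#' @param mat Character matrix of ingroup sequences (rows) by sites
#'   (columns), entries A/C/G/T or NA.
#' @return Integer count.
#' @export
segregating_sites <- function(mat) {
  sum(apply(mat, 2L, function(col) {
    length(unique(col[!is.na(col)])) >= 2L
  }))
}

pi_column <- function(col) {
  tab <- column_counts(col)
  nc <- sum(tab)
  if (nc < 2L) return(0)
  p <- tab / nc
  (1 - sum(p^2)) * nc / (nc - 1)
}

#' Nucleotide diversity (expected heterozygosity)
#'
#' Per column, the unbiased expected heterozygosity
#' \eqn{2\sum_{a<b} p_a p_b \cdot n_c/(n_c - 1)} using the non-missing
#' sample size \eqn{n_c} of that column, summed over columns. Reported in
#' count units by default (expected pairwise differences across the region),
#' or per site.
#'
#' @param mat Site matrix as in \code{\link{segregating_sites}}.
#' @param per_site Divide by the number of sites (default FALSE).
#' @param n_sites Number of sites for the per-site divisor; defaults to
#'   \code{ncol(mat)} and may be fractional for codon site classes.
#' @return Numeric value.
#' @export
nuc_pi <- function(mat, per_site = FALSE, n_sites = ncol(mat)) {
  val <- sum(apply(mat, 2L, pi_column))
  if (per_site) val / n_sites else val
}

#' Watterson's theta
#'
#' \eqn{\theta_W = S / a_{n-1}} with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i},
#' in the same count units as S.
#'
#' @param S Number of segregating sites.
#' @param n Sample size (number of sequences), >= 2.
#' @return Numeric value.
#' @examples
#' watterson_theta(16, 38) # 3.81
#' @export
watterson_theta <- function(S, n) {
  if (n < 2L) stop("Watterson's theta requires n >= 2")
  S / harmonic(n - 1L)
}

tajima_constants <- function(n) {
  a1 <- harmonic(n - 1L); a2 <- harmonic2(n - 1L)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' \eqn{D = (\pi - \theta_W)/\sqrt{e_1 S + e_2 S(S-1)}} with the 1989
#' normalising constants computed from the full sample size n. Undefined
#' (NA) when S = 0.
#'
#' @param pi Nucleotide diversity in count units.
#' @param S Number of segregating sites.
#' @param n Sample size used for the constants.
#' @return Numeric value, NA when S = 0.
#' @examples
#' tajimas_d(1.57, 16, 38) # -1.91
#' @export
tajimas_d <- function(pi, S, n) {
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

fu_li_constants <- function(n) {
  an <- harmonic(n - 1L); bn <- harmonic2(n - 1L)
  cn <- if (n > 2L) 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  vd <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  ud <- an - 1 - vd
  # starred (unpolarized) variant constants
  an1 <- an + 1 / n
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vds <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uds <- n / (n - 1) * (an - n / (n - 1)) - vds
  list(an = an, ud = ud, vd = vd, uds = uds, vds = vds)
}

#' Fu and Li's D (outgroup-polarized)
#'
#' Contrasts the total number of segregating mutations with the number of
#' derived singletons (mutations on external branches of the genealogy):
#' \eqn{D = (S - a_n \eta_e)/\sqrt{u_D S + v_D S^2}}. Derived states are
#' assigned from the outgroup base; sites at which the outgroup carries
#' neither ingroup allele (or is missing) still count toward S but cannot
#' contribute singletons. Undefined when S = 0.
#'
#' @param mat Ingroup site matrix.
#' @param outgroup_row Character vector of outgroup bases, one per column.
#' @return Numeric value, NA when S = 0.
#' @export
fu_li_d <- function(mat, outgroup_row) {
  if (is.null(outgroup_row)) stop("polarized Fu & Li's D needs an outgroup")
  stopifnot(length(outgroup_row) == ncol(mat))
  n <- nrow(mat)
  S <- 0L
  eta_e <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- column_counts(mat[, j])
    if (length(tab) < 2L) next
    S <- S + 1L
    o <- outgroup_row[j]
    if (is.na(o) || !o %in% names(tab)) next
    derived <- tab[names(tab) != o]
    eta_e <- eta_e + sum(derived == 1L)
  }
  if (S == 0L) return(NA_real_)
  k <- fu_li_constants(n)
  (S - k$an * eta_e) / sqrt(k$ud * S + k$vd * S^2)
}

#' Fu and Li's D* (unpolarized)
#'
#' Outgroup-free variant using the number of singletons (alleles observed in
#' exactly one sequence) in place of derived singletons.
#'
#' @param mat Ingroup site matrix.
#' @return Numeric value, NA when S = 0.
#' @export
fu_li_d_star <- function(mat) {
  n <- nrow(mat)
  S <- 0L
  eta_s <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- column_counts(mat[, j])
    if (length(tab) < 2L) next
    S <- S + 1L
    eta_s <- eta_s + sum(tab == 1L)
  }
  if (S == 0L) return(NA_real_)
  k <- fu_li_constants(n)
  (n / (n - 1) * S - k$an * eta_s) / sqrt(k$uds * S + k$vds * S^2)
}

#' Site-frequency spectrum
#'
#' Folded mode bins the minor-allele count of each biallelic segregating
#' site; unfolded mode bins the derived-allele count, where the derived
#' allele is the ingroup allele not matching the outgroup base. A site is
#' omitted from the unfolded spectrum (and counted in \code{omitted_sites})
#' when the outgroup base matches neither ingroup allele or is missing.
#' Sites with more than two ingroup alleles are skipped in both modes and
#' counted in \code{skipped_multiallelic}.
#'
#' @param mat Ingroup site matrix.
#' @param mode \code{"folded"} or \code{"unfolded"}.
#' @param outgroup_row Outgroup bases (required for unfolded mode).
#' @return Object of class \code{sfs}: list with \code{n}, \code{counts}
#'   (named vector over frequency classes 1..floor(n/2) folded,
#'   1..n-1 unfolded), \code{polarized}, \code{omitted_sites},
#'   \code{skipped_multiallelic}.
#' @export
sfs <- function(mat, mode = c("folded", "unfolded"), outgroup_row = NULL) {
  mode <- match.arg(mode)
  n <- nrow(mat)
  if (mode == "unfolded" && is.null(outgroup_row)) {
    stop("unfolded SFS requires an outgroup")
  }
  n_class <- if (mode == "folded") n %/% 2L else n - 1L
  counts <- setNames(integer(n_class), seq_len(n_class))
  omitted <- 0L
  multi <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- column_counts(mat[, j])
    if (length(tab) < 2L) next
    if (length(tab) > 2L) {
      multi <- multi + 1L
      next
    }
    if (mode == "folded") {
      cls <- min(tab)
      counts[cls] <- counts[cls] + 1L
    } else {
      o <- outgroup_row[j]
      if (is.na(o) || !o %in% names(tab)) {
        omitted <- omitted + 1L
        next
      }
      cls <- unname(tab[names(tab) != o])
      counts[cls] <- counts[cls] + 1L
    }
  }
  structure(list(n = n, counts = counts, polarized = mode == "unfolded",
                 omitted_sites = omitted, skipped_multiallelic = multi),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(if (x$polarized) "unfolded" else "folded",
      "SFS, n =", x$n, ",", sum(x$counts), "sites")
  if (x$polarized) cat(" (", x$omitted_sites, "omitted )")
  cat("\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' @export
plot.sfs <- function(x, ...) {
  graphics::barplot(x$counts,
                    xlab = if (x$polarized) "derived-allele count"
                           else "minor-allele count",
                    ylab = "number of sites", ...)
  invisible(x)
}

#' Refold an unfolded SFS
#'
#' Merges derived-count classes i and n - i into minor-allele classes.
#'
#' @param x Unfolded \code{sfs} object.
#' @return Folded \code{sfs} object.
#' @export
fold_sfs <- function(x) {
  stopifnot(inherits(x, "sfs"), x$polarized)
  n <- x$n
  n_class <- n %/% 2L
  counts <- setNames(integer(n_class), seq_len(n_class))
  for (i in seq_len(n - 1L)) {
    cls <- min(i, n - i)
    counts[cls] <- counts[cls] + x$counts[[i]]
  }
  structure(list(n = n, counts = counts, polarized = FALSE,
                 omitted_sites = x$omitted_sites,
                 skipped_multiallelic = x$skipped_multiallelic),
            class = "sfs")
}

#' Fay and Wu's H
#'
#' \eqn{H = \pi - \theta_H} with
#' \eqn{\theta_H = \sum_i S_i \cdot 2 i^2 / (n(n-1))} over derived-allele
#' counts i; negative values indicate an excess of high-frequency derived
#' alleles. Requires a polarized (unfolded) spectrum.
#'
#' @param unfolded_sfs An unfolded \code{sfs} object.
#' @return Numeric value (0 for an empty spectrum).
#' @export
fay_wu_h <- function(unfolded_sfs) {
  x <- unfolded_sfs
  if (!inherits(x, "sfs") || !x$polarized) {
    stop("fay_wu_h requires an unfolded (polarized) SFS")
  }
  n <- x$n
  i <- as.integer(names(x$counts))
  pi <- sum(x$counts * 2 * i * (n - i)) / (n * (n - 1))
  theta_h <- sum(x$counts * 2 * i^2) / (n * (n - 1))
  pi - theta_h
}
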