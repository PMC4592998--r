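# Pairwise linkage disequilibrium, LD-distance correlation tests, and the
# four-gamete test for haploid alignments.

# biallelic-site bookkeeping: returns, for each usable site, a 0/1/NA coded
# column (1 = lexicographically first allele) plus its position and minor
# allele frequency
biallelic_sites <- function(mat, positions = seq_len(ncol(mat))) {
  keep <- integer(0)
  multi <- 0L
  cols <- list()
  maf <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    tab <- column_counts(mat[, j])
    if (length(tab) < 2L) next
    if (length(tab) > 2L) {
      multi <- multi + 1L
      next
    }
    alleles <- sort(names(tab))
    x <- rep(NA_integer_, nrow(mat))
    ok <- !is.na(mat[, j])
    x[ok] <- as.integer(mat[ok, j] == alleles[1L])
    keep <- c(keep, j)
    cols[[length(cols) + 1L]] <- x
    maf <- c(maf, min(tab) / sum(tab))
  }
  list(X = if (length(cols)) do.call(cbind, cols) else
         matrix(integer(), nrow(mat), 0L),
       positions = positions[keep], maf = maf, multiallelic = multi)
}

#' Pairwise linkage disequilibrium
#'
#' For every pair of biallelic sites passing the minor-allele-frequency
#' cutoff, computes |D'| and r-squared on the sequences non-missing at both
#' sites: \eqn{D = p_{AB} - p_A p_B}; \eqn{D' = D / D_{max}} with
#' \eqn{D_{max} = \min(p_A(1-p_B), (1-p_A)p_B)} when D > 0 and
#' \eqn{\min(p_A p_B, (1-p_A)(1-p_B))} otherwise;
#' \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))}. Sites with more than two
#' alleles are excluded; pairs monomorphic after missing-data restriction
#' are dropped.
#'
#' @param mat Ingroup site matrix (A/C/G/T/NA), or a 0/1/NA matrix of
#'   haplotypes.
#' @param maf_cutoff Minimum minor-allele frequency for a site to enter
#'   (default 0: all biallelic sites).
#' @param positions Physical positions of the columns (default column
#'   index).
#' @param circular Use circular distances \eqn{\min(d, L - d)}.
#' @param total_length Sequence length L for circular distances.
#' @return Data frame of class \code{ld_pairs} with columns
#'   \code{site_i, site_j, distance, d_prime_abs, r2, n_informative,
#'   four_gametes}; attributes record the positions and distance convention.
#' @export
pairwise_ld <- function(mat, maf_cutoff = 0,
                        positions = seq_len(ncol(mat)),
                        circular = FALSE, total_length = max(positions)) {
  if (is.numeric(mat)) {
    X <- mat
    keep <- which(apply(X, 2L, function(x) {
      v <- x[!is.na(x)]
      length(unique(v)) == 2L
    }))
    X <- X[, keep, drop = FALSE]
    positions <- positions[keep]
    maf <- apply(X, 2L, function(x) {
      m <- mean(x, na.rm = TRUE)
      min(m, 1 - m)
    })
  } else {
    bs <- biallelic_sites(mat, positions)
    X <- bs$X
    positions <- bs$positions
    maf <- bs$maf
  }
  sel <- maf >= maf_cutoff
  X <- X[, sel, drop = FALSE]
  positions <- positions[sel]
  S <- ncol(X)
  empty <- data.frame(site_i = integer(), site_j = integer(),
                      distance = numeric(), d_prime_abs = numeric(),
                      r2 = numeric(), n_informative = integer(),
                      four_gametes = logical())
  if (S < 2L) return(structure(empty, class = c("ld_pairs", "data.frame")))

  M1 <- X == 1L & !is.na(X)
  M0 <- X == 0L & !is.na(X)
  n11 <- crossprod(M1)
  n10 <- crossprod(M1, M0)
  n01 <- crossprod(M0, M1)
  n00 <- crossprod(M0)
  n_inf <- n11 + n10 + n01 + n00

  up <- which(upper.tri(n_inf), arr.ind = TRUE)
  i <- up[, 1L]; j <- up[, 2L]
  ninf <- n_inf[up]
  pA <- (n11[up] + n10[up]) / ninf
  pB <- (n11[up] + n01[up]) / ninf
  pAB <- n11[up] / ninf
  D <- pAB - pA * pB
  dmax <- ifelse(D > 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  dprime <- ifelse(D == 0, 0, abs(D / dmax))
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  d <- abs(positions[j] - positions[i])
  if (circular) d <- pmin(d, total_length - d)
  out <- data.frame(
    site_i = positions[i], site_j = positions[j], distance = d,
    d_prime_abs = dprime, r2 = r2, n_informative = as.integer(ninf),
    four_gametes = n11[up] > 0 & n10[up] > 0 & n01[up] > 0 & n00[up] > 0)
  # drop pairs monomorphic after pairwise missing-data restriction
  out <- out[!is.na(out$r2) & ninf >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ld_pairs", "data.frame"),
            positions = positions, circular = circular,
            total_length = total_length)
}

#' Correlation between LD and distance, with permutation p-value
#'
#' Spearman correlation between an LD measure and the pairwise distance,
#' with a one-sided (negative-direction) permutation p-value obtained by
#' permuting the site positions and recomputing all pairwise distances per
#' permutation, which respects the non-independence of site pairs. A
#' significantly negative correlation is the classic signature of
#' recombination eroding LD with distance.
#'
#' @param pairs An \code{ld_pairs} data frame from
#'   \code{\link{pairwise_ld}}.
#' @param measure \code{"d_prime_abs"} or \code{"r2"}.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed; results are deterministic given the seed.
#' @return Named numeric \code{c(rho = , p_one_sided = )}.
#' @export
ld_distance_correlation <- function(pairs,
                                    measure = c("d_prime_abs", "r2"),
                                    n_perm = 1000, seed = NULL) {
  measure <- match.arg(measure)
  if (nrow(pairs) < 3L) stop("need at least 3 site pairs")
  if (!is.null(seed)) set.seed(seed)
  y <- pairs[[measure]]
  if (length(unique(y)) == 1L) {
    return(c(rho = 0, p_one_sided = 1))
  }
  positions <- attr(pairs, "positions")
  circular <- isTRUE(attr(pairs, "circular"))
  total_length <- attr(pairs, "total_length")
  idx_i <- match(pairs$site_i, positions)
  idx_j <- match(pairs$site_j, positions)
  dist_for <- function(pos) {
    d <- abs(pos[idx_j] - pos[idx_i])
    if (circular) d <- pmin(d, total_length - d)
    d
  }
  rho_obs <- cor(y, dist_for(positions), method = "spearman")
  hits <- 0L
  for (b in seq_len(n_perm)) {
    rho_b <- cor(y, dist_for(sample(positions)), method = "spearman")
    if (rho_b <= rho_obs) hits <- hits + 1L
  }
  c(rho = rho_obs, p_one_sided = (1 + hits) / (n_perm + 1))
}

#' Four-gamete test
#'
#' Counts pairs of biallelic sites at which all four haplotypes occur among
#' the sequences non-missing at both sites. Under no recombination and no
#' recurrent mutation (a single genealogy with infinite sites), no pair can
#' show all four gametes.
#'
#' @param mat Site matrix as in \code{\link{pairwise_ld}}.
#' @return List with \code{n_violating_pairs} and \code{pairs} (data frame
#'   of the violating site pairs).
#' @export
four_gamete_test <- function(mat) {
  pairs <- pairwise_ld(mat, maf_cutoff = 0)
  viol <- pairs[pairs$four_gametes, c("site_i", "site_j"), drop = FALSE]
  rownames(viol) <- NULL
  list(n_violating_pairs = nrow(viol), pairs = viol)
}
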