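# Neutral Kingman coalescent simulation (no recombination) and
# Monte-Carlo null distributions for site-frequency statistics.

# fold a list of coalescence events into the genealogy node arrays;
# events: data.frame(time, a, b) in increasing time, a/b = node ids of the
# merging lineages. Tips are 1..n, internal nodes n+1..2n-1 in event order.
build_genealogy <- function(n, events) {
  m <- 2L * n - 1L
  parent <- rep(NA_integer_, m)
  blen <- numeric(m)
  birth <- numeric(m)        # time each node (lineage) starts
  tips <- vector("list", m)
  tips[seq_len(n)] <- as.list(seq_len(n))
  for (e in seq_len(nrow(events))) {
    node <- n + e
    for (child in c(events$a[e], events$b[e])) {
      parent[child] <- node
      blen[child] <- events$time[e] - birth[child]
    }
    birth[node] <- events$time[e]
    tips[[node]] <- c(tips[[events$a[e]]], tips[[events$b[e]]])
  }
  structure(list(n = n, parent = parent, blen = blen,
                 n_desc = lengths(tips), tips = tips),
            class = "genealogy")
}

#' Simulate a neutral coalescent genealogy
#'
#' Standard Kingman coalescent for n haploid lineages: with k lineages the
#' waiting time to the next coalescence is exponential with rate
#' k(k-1)/2 (time in units of 2N generations) and a uniformly chosen pair
#' merges.
#'
#' @param n Number of tips (>= 2).
#' @return A \code{genealogy}: list with \code{n}, \code{parent},
#'   \code{blen} (branch length above each node; 0 at the root),
#'   \code{n_desc} (tips subtended) and \code{tips} (tip sets per node).
#'   Nodes 1..n are tips, node 2n-1 the root.
#' @export
simulate_genealogy <- function(n) {
  stopifnot(n >= 2L)
  active <- seq_len(n)
  times <- numeric(n - 1L)
  a <- b <- integer(n - 1L)
  t <- 0
  nxt <- n
  for (e in seq_len(n - 1L)) {
    k <- length(active)
    t <- t + rexp(1L, k * (k - 1) / 2)
    pair <- sample(k, 2L)
    times[e] <- t
    a[e] <- active[pair[1L]]
    b[e] <- active[pair[2L]]
    nxt <- nxt + 1L
    active <- c(active[-pair], nxt)
  }
  build_genealogy(n, data.frame(time = times, a = a, b = b))
}

#' Total branch length of a genealogy
#'
#' @param tree A \code{genealogy}.
#' @return Sum of all branch lengths, in coalescent units.
#' @export
tree_length <- function(tree) sum(tree$blen)

#' Drop a fixed number of mutations on a genealogy
#'
#' Places exactly S infinite-sites mutations on branches with probability
#' proportional to branch length and returns the resulting haplotype
#' matrix.
#'
#' @param tree A \code{genealogy}.
#' @param S Number of mutations (>= 0).
#' @return n x S binary matrix (1 = derived); also attribute
#'   \code{branches}: the branch (node id) carrying each mutation.
#' @export
drop_fixed_s <- function(tree, S) {
  n <- tree$n
  out <- matrix(0L, n, S)
  if (S == 0L) return(out)
  branches <- sample(length(tree$blen), S, replace = TRUE,
                     prob = tree$blen)
  for (s in seq_len(S)) {
    out[tree$tips[[branches[s]]], s] <- 1L
  }
  attr(out, "branches") <- branches
  out
}

#' Drop mutations at a fixed population rate
#'
#' Free-S companion of \code{\link{drop_fixed_s}}: the number of mutations
#' is Poisson with mean theta/2 times the total tree length, so
#' \eqn{E[S] = \theta a_{n-1}}.
#'
#' @param tree A \code{genealogy}.
#' @param theta Population mutation rate (count units).
#' @return As \code{\link{drop_fixed_s}}.
#' @export
drop_poisson <- function(tree, theta) {
  drop_fixed_s(tree, rpois(1L, theta / 2 * tree_length(tree)))
}

#' Monte-Carlo p-value of a site-frequency statistic
#'
#' Compares an observed statistic with its null distribution over
#' genealogies simulated with no recombination, conditioned on the observed
#' number of segregating sites S (mutations are dropped after the tree is
#' drawn). For the polarized statistics the derived state of each simulated
#' mutation is known by construction, so no outgroup is simulated. The
#' p-value uses the (r + 1)/(m + 1) convention; lower tail:
#' p = (1 + #\{sim <= observed\})/(n_reps + 1), upper tail mirrored,
#' two-tailed doubled and capped at 1.
#'
#' @param stat_name One of \code{"tajima_d"}, \code{"fu_li_d"},
#'   \code{"fay_wu_h"}.
#' @param observed Observed value of the statistic.
#' @param n Sample size.
#' @param S Observed number of segregating sites (>= 1).
#' @param n_reps Number of simulated genealogies (default 10000).
#' @param tail \code{"lower"} (default; the deleterious/sweep direction for
#'   all three statistics), \code{"upper"} or \code{"two"}.
#' @param seed Optional seed; runs are reproducible given (seed, n_reps).
#' @return Named numeric \code{c(p = )} with attribute \code{null_mean}.
#' @export
stat_null_pvalue <- function(stat_name = c("tajima_d", "fu_li_d",
                                           "fay_wu_h"),
                             observed, n, S, n_reps = 10000,
                             tail = c("lower", "upper", "two"),
                             seed = NULL) {
  stat_name <- match.arg(stat_name)
  tail <- match.arg(tail)
  if (S < 1L) stop("null distributions are conditioned on S >= 1")
  if (!is.null(seed)) set.seed(seed)
  sims <- cpp_null_stats(n, S, n_reps)[, stat_name]
  p_low <- (1 + sum(sims <= observed)) / (n_reps + 1)
  p_up <- (1 + sum(sims >= observed)) / (n_reps + 1)
  p <- switch(tail,
              lower = p_low,
              upper = p_up,
              two = min(1, 2 * min(p_low, p_up)))
  out <- c(p = p)
  attr(out, "null_mean") <- mean(sims)
  out
}

#' Heterogeneity test for Tajima's D between mutation classes
#'
#' Tests whether the frequency-spectrum skew differs between synonymous and
#' nonsynonymous polymorphisms. Per replicate one genealogy is simulated
#' with no recombination, S_syn + S_nonsyn mutations are dropped on it, and
#' the class labels are assigned at random; the simulated difference in
#' Tajima's D between the classes is compared with the observed difference.
#' Setting \code{shared_genealogy = FALSE} instead simulates each class on
#' its own genealogy.
#'
#' @param n Sample size.
#' @param S_syn,S_nonsyn Segregating sites per class (both >= 1).
#' @param observed_delta_d Observed D_nonsyn - D_syn.
#' @param n_reps Number of replicates (default 10000).
#' @param sided \code{"two"} (default; |delta| comparison) or
#'   \code{"lower"}.
#' @param shared_genealogy Drop both classes on one genealogy per replicate
#'   (default TRUE).
#' @param seed Optional seed.
#' @return Named numeric \code{c(p = )} with attribute \code{delta_null}
#'   (the simulated differences).
#' @export
heterogeneity_test <- function(n, S_syn, S_nonsyn, observed_delta_d,
                               n_reps = 10000,
                               sided = c("two", "lower"),
                               shared_genealogy = TRUE, seed = NULL) {
  sided <- match.arg(sided)
  if (S_syn < 1L || S_nonsyn < 1L) {
    stop("heterogeneity test needs S >= 1 in both classes")
  }
  if (!is.null(seed)) set.seed(seed)
  delta <- cpp_delta_tajima(n, S_syn, S_nonsyn, n_reps, shared_genealogy)
  p <- if (sided == "two") {
    (1 + sum(abs(delta) >= abs(observed_delta_d))) / (n_reps + 1)
  } else {
    (1 + sum(delta <= observed_delta_d)) / (n_reps + 1)
  }
  out <- c(p = p)
  attr(out, "delta_null") <- delta
  out
}
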