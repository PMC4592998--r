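#' Enumerate mutational pathways between two codons
#'
#' For codons differing at k positions (k = 0..3) there are k! orderings of
#' the single-base steps. Each step is classified as synonymous or
#' nonsynonymous by comparing the translations of the codon before and after
#' the step. Pathways that pass through a stop codon at an intermediate step
#' are flagged; by default they are excluded from the averaged counts unless
#' every pathway hits a stop, in which case all pathways are retained with a
#' warning.
#'
#' @param codon_from,codon_to Fully resolved codons (3-letter strings).
#' @param code Genetic code from \code{\link{genetic_code}}.
#' @return A \code{pathway_set}: list with \code{k}, and a data frame
#'   \code{paths} with one row per pathway (columns \code{order} -- the
#'   position sequence as a string, \code{n_syn}, \code{n_nonsyn},
#'   \code{through_stop}), plus \code{syn}/\code{nonsyn}: the more-inclusive
#'   averages over usable pathways.
#' @examples
#' code5 <- genetic_code(5)
#' enumerate_pathways("TTT", "GTA", code5) # average 0.5 syn, 1.5 nonsyn
#' @export
enumerate_pathways <- function(codon_from, codon_to, code) {
  f <- strsplit(codon_from, "")[[1L]]
  t <- strsplit(codon_to, "")[[1L]]
  stopifnot(length(f) == 3L, length(t) == 3L)
  diff_pos <- which(f != t)
  k <- length(diff_pos)
  if (k == 0L) {
    ps <- list(k = 0L,
               paths = data.frame(order = character(), n_syn = numeric(),
                                  n_nonsyn = numeric(),
                                  through_stop = logical()),
               syn = 0, nonsyn = 0, all_through_stop = FALSE)
    class(ps) <- "pathway_set"
    return(ps)
  }
  orders <- permutations(diff_pos)
  n_syn <- n_nonsyn <- numeric(nrow(orders))
  through_stop <- logical(nrow(orders))
  for (r in seq_len(nrow(orders))) {
    cur <- f
    for (pos in orders[r, ]) {
      prev_aa <- code[paste0(cur, collapse = "")]
      cur[pos] <- t[pos]
      codon <- paste0(cur, collapse = "")
      aa <- code[codon]
      if (aa == "*" && !identical(codon, codon_to)) through_stop[r] <- TRUE
      if (identical(unname(aa), unname(prev_aa))) {
        n_syn[r] <- n_syn[r] + 1
      } else {
        n_nonsyn[r] <- n_nonsyn[r] + 1
      }
    }
  }
  usable <- !through_stop
  all_stop <- !any(usable)
  if (all_stop) {
    warning("all pathways ", codon_from, "->", codon_to,
            " traverse a stop codon; averaging over all of them")
    usable <- rep(TRUE, length(usable))
  }
  ps <- list(
    k = k,
    paths = data.frame(
      order = apply(orders, 1L, paste, collapse = ","),
      n_syn = n_syn, n_nonsyn = n_nonsyn, through_stop = through_stop),
    syn = mean(n_syn[usable]),
    nonsyn = mean(n_nonsyn[usable]),
    all_through_stop = all_stop
  )
  class(ps) <- "pathway_set"
  ps
}

#' @export
print.pathway_set <- function(x, ...) {
  cat("pathway_set: k =", x$k, "(", nrow(x$paths), "pathways ),",
      "average syn =", format(x$syn), "nonsyn =", format(x$nonsyn), "\n")
  invisible(x)
}

# all orderings of a short vector (k <= 3), rows in lexicographic order of
# the position sequence -- the deterministic tie-break order used by the
# minimal-nonsynonymous pathway choice
permutations <- function(v) {
  k <- length(v)
  if (k == 1L) return(matrix(v, 1L))
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(v[i], permutations(v[-i]))
  }))
  out[order(apply(out, 1L, paste, collapse = ",")), , drop = FALSE]
}

# pathway (syn, nonsyn) pair under the minimal-nonsynonymous rule:
# smallest n_nonsyn, ties broken toward the lexicographically first position
# order (rows of `paths` are already in that order)
min_nonsyn_path <- function(ps) {
  if (ps$k == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- ps$paths
  usable <- !paths$through_stop
  if (!any(usable)) usable <- rep(TRUE, nrow(paths))
  paths <- paths[usable, , drop = FALSE]
  best <- which(paths$n_nonsyn == min(paths$n_nonsyn))[1L]
  c(syn = paths$n_syn[best], nonsyn = paths$n_nonsyn[best])
}

#' Count synonymous and nonsynonymous sites of a codon
#'
#' For each of the nine single-base changes, the synonymous fraction at a
#' position is the number of synonymous changes divided by the number of
#' changes not creating a stop codon; changes to stop codons are excluded
#' from both numerator and denominator. Site counts are the sums of these
#' fractions over the three positions, so \code{syn + nonsyn = 3} whenever
#' every position retains at least one non-stop change.
#'
#' @param codon Fully resolved non-stop codon.
#' @param code Genetic code.
#' @return Named numeric vector \code{c(syn = , nonsyn = )}.
#' @examples
#' count_site_classes("TTT", genetic_code(5)) # 1/3 synonymous sites
#' @export
count_site_classes <- function(codon, code) {
  if (is_stop_codon(codon, code)) {
    stop("undefined-site error: stop codon ", codon)
  }
  b <- strsplit(codon, "")[[1L]]
  aa0 <- code[codon]
  syn <- nonsyn <- 0
  for (pos in 1:3) {
    n_syn <- n_tot <- 0L
    for (alt in setdiff(.BASES, b[pos])) {
      mut <- b
      mut[pos] <- alt
      aa <- code[paste0(mut, collapse = "")]
      if (aa == "*") next
      n_tot <- n_tot + 1L
      if (identical(unname(aa), unname(aa0))) n_syn <- n_syn + 1L
    }
    if (n_tot > 0L) {
      syn <- syn + n_syn / n_tot
      nonsyn <- nonsyn + (n_tot - n_syn) / n_tot
    }
  }
  c(syn = syn, nonsyn = nonsyn)
}
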