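# Per-gene diversity summaries split by synonymous / nonsynonymous site
# class, mirroring the per-gene polymorphism tables of mitochondrial
# population studies.

.site_class_cache <- new.env(parent = emptyenv())

# 64 x 2 matrix of (syn, nonsyn) site counts per codon, memoised per code
site_class_table <- function(code) {
  key <- attr(code, "table_id")
  if (is.null(key)) key <- paste(code, collapse = "")
  if (!is.null(.site_class_cache[[key]])) return(.site_class_cache[[key]])
  codons <- names(code)
  out <- matrix(0, 64L, 2L, dimnames = list(codons, c("syn", "nonsyn")))
  for (cd in codons) {
    if (code[cd] == "*") next
    out[cd, ] <- count_site_classes(cd, code)
  }
  .site_class_cache[[key]] <- out
  out
}

# rebuild the nucleotide matrix of a gene from its codon matrix
# (codon-missing entries expand to three NA bases)
gene_base_matrix <- function(gene, rows) {
  codons <- gene$codons[rows, , drop = FALSE]
  n <- nrow(codons)
  L <- 3L * ncol(codons)
  mat <- matrix(NA_character_, n, L, dimnames = list(rows, NULL))
  for (j in seq_len(ncol(codons))) {
    ok <- !is.na(codons[, j])
    if (any(ok)) {
      mat[ok, (3L * j - 2L):(3L * j)] <-
        do.call(rbind, strsplit(codons[ok, j], ""))
    }
  }
  mat
}

# classify every variable nucleotide site of a gene as synonymous or
# nonsynonymous against the majority codon background; returns the ingroup
# base matrix, the outgroup base row, and a per-variable-site table
classify_gene_sites <- function(gene, outgroup = NULL) {
  ing <- gene_base_matrix(gene, gene$ingroup)
  og <- NULL
  if (!is.null(outgroup) || length(gene$outgroup)) {
    if (is.null(outgroup)) outgroup <- gene$outgroup[1L]
    og <- gene_base_matrix(gene, outgroup)[1L, ]
  }
  code <- gene$code
  n_codons <- ncol(gene$codons)
  sites <- data.frame(column = integer(), codon = integer(),
                      pos = integer(), class = character())
  for (cj in seq_len(n_codons)) {
    cols <- (3L * cj - 2L):(3L * cj)
    sub <- ing[, cols, drop = FALSE]
    var_pos <- which(vapply(1:3, function(p) {
      length(unique(sub[!is.na(sub[, p]), p])) >= 2L
    }, logical(1)))
    if (!length(var_pos)) next
    # majority codon background over fully observed ingroup codons
    obs <- gene$codons[gene$ingroup, cj]
    obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    tab <- table(obs)
    majority <- strsplit(names(tab)[which.max(tab)], "")[[1L]]
    for (p in var_pos) {
      btab <- table(sub[!is.na(sub[, p]), p])
      alts <- setdiff(names(btab), majority[p])
      if (!length(alts)) next
      # class of the most frequent non-majority allele (ties lexicographic:
      # table() sorts names and which.max takes the first maximum)
      alt <- alts[which.max(btab[alts])]
      mut <- majority
      mut[p] <- alt
      same <- identical(unname(code[paste0(majority, collapse = "")]),
                        unname(code[paste0(mut, collapse = "")]))
      sites <- rbind(sites, data.frame(
        column = cols[p], codon = cj, pos = p,
        class = if (same) "synonymous" else "nonsynonymous"))
    }
  }
  list(ingroup = ing, outgroup_row = og, sites = sites)
}

#' Per-gene diversity summary by site class
#'
#' Computes, for the synonymous, nonsynonymous and combined site classes of
#' one gene: the (fractional) number of sites, S, nucleotide diversity pi
#' and Watterson's theta in count units, Tajima's D, and -- when an outgroup
#' is available -- Fu and Li's polarized D and Fay and Wu's H. Variable
#' sites are assigned to a class against the majority codon background;
#' site totals sum the per-codon synonymous/nonsynonymous site fractions of
#' the ingroup majority codons. Normalising constants use the full ingroup
#' sample size.
#'
#' @param gene A \code{gene_alignment}.
#' @param outgroup Outgroup label for polarized statistics (default: the
#'   first outgroup row when one exists; the polarized columns are NA for
#'   genes without an outgroup).
#' @return Data frame with one row per site class
#'   (\code{synonymous}, \code{nonsynonymous}, \code{all}).
#' @export
diversity_summary <- function(gene, outgroup = NULL) {
  cls <- classify_gene_sites(gene, outgroup)
  ing <- cls$ingroup
  n <- nrow(ing)
  sct <- site_class_table(gene$code)

  # fractional site totals from ingroup majority codons
  n_syn_sites <- 0
  n_nonsyn_sites <- 0
  for (cj in seq_len(ncol(gene$codons))) {
    obs <- gene$codons[gene$ingroup, cj]
    obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    tab <- table(obs)
    major <- names(tab)[which.max(tab)]
    if (gene$code[major] == "*") next
    n_syn_sites <- n_syn_sites + sct[major, "syn"]
    n_nonsyn_sites <- n_nonsyn_sites + sct[major, "nonsyn"]
  }

  one_class <- function(class_name, columns, n_sites) {
    sub <- ing[, columns, drop = FALSE]
    S <- segregating_sites(sub)
    pi <- nuc_pi(sub)
    row <- data.frame(
      gene = gene$gene, site_class = class_name, n_sites = n_sites,
      S = S, pi = pi,
      theta_w = watterson_theta(S, n),
      tajima_d = tajimas_d(pi, S, n),
      fu_li_d = NA_real_, fay_wu_h = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(cls$outgroup_row)) {
      og <- cls$outgroup_row[columns]
      row$fu_li_d <- fu_li_d(sub, og)
      row$fay_wu_h <- if (S > 0) {
        fay_wu_h(sfs(sub, "unfolded", og))
      } else 0
    }
    row
  }

  syn_cols <- cls$sites$column[cls$sites$class == "synonymous"]
  nonsyn_cols <- cls$sites$column[cls$sites$class == "nonsynonymous"]
  rbind(
    one_class("synonymous", syn_cols, n_syn_sites),
    one_class("nonsynonymous", nonsyn_cols, n_nonsyn_sites),
    one_class("all", seq_len(ncol(ing)), n_syn_sites + n_nonsyn_sites)
  )
}

#' Site-frequency spectrum of one gene, by site class
#'
#' @param gene A \code{gene_alignment}.
#' @param site_class \code{"synonymous"}, \code{"nonsynonymous"} or
#'   \code{"all"}.
#' @param mode \code{"folded"} or \code{"unfolded"}.
#' @param outgroup Outgroup label used for classification/polarization.
#' @return An \code{sfs} object.
#' @export
gene_sfs <- function(gene, site_class = c("all", "synonymous",
                                          "nonsynonymous"),
                     mode = c("folded", "unfolded"), outgroup = NULL) {
  site_class <- match.arg(site_class)
  mode <- match.arg(mode)
  cls <- classify_gene_sites(gene, outgroup)
  columns <- if (site_class == "all") {
    seq_len(ncol(cls$ingroup))
  } else {
    cls$sites$column[cls$sites$class == site_class]
  }
  sfs(cls$ingroup[, columns, drop = FALSE], mode,
      if (mode == "unfolded") cls$outgroup_row[columns])
}
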