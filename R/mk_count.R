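# Codon-column classification into polymorphism / fixed-difference
# contributions, and gene-level McDonald-Kreitman tables.

#' Classify one codon column into MK contributions
#'
#' Applies the counting rules for a single codon column of an ingroup sample
#' plus one outgroup codon:
#' \enumerate{
#'   \item Positions variable among ingroup codons contribute polymorphisms.
#'     With exactly two ingroup codon states, steps are classified by
#'     averaging over all mutational pathways between the two states
#'     (fractional counts when pathways disagree). With three or more states,
#'     each variable nucleotide position contributes one count per
#'     non-majority allele, classified against the majority codon background
#'     (ties broken lexicographically).
#'   \item Positions at which all ingroup sequences share one base that
#'     differs from the outgroup contribute fixed differences, classified by
#'     enumerating pathways between the ingroup consensus codon and the
#'     outgroup codon: averaged under \code{more_inclusive}, or using the
#'     pathway minimising the nonsynonymous count under
#'     \code{less_inclusive}.
#'   \item A position that is polymorphic in the ingroup and differs from the
#'     outgroup contributes a polymorphism only when the outgroup allele is
#'     present in the ingroup; when it is not, the position contributes both
#'     a polymorphism and a fixed difference.
#' }
#'
#' @param ingroup_codons Character vector of ingroup codons (NA = missing).
#' @param outgroup_codon Single outgroup codon, NA if missing, or a length-3
#'   character vector of per-position outgroup bases (NA where the outgroup
#'   state is unavailable, e.g. discordant dual outgroups).
#' @param code Genetic code.
#' @param method \code{"more_inclusive"} or \code{"less_inclusive"}
#'   (divergence pathway choice; polymorphism counting is identical).
#' @param min_ingroup Minimum non-missing ingroup codons required (default 2:
#'   a frequency needs at least two observations).
#' @return Data frame with columns \code{class} (one of PS, PN, DS, DN) and
#'   \code{weight}; zero rows when the column contributes nothing. Attribute
#'   \code{skipped} carries a reason string when the column was not counted.
#' @export
classify_codon_column <- function(ingroup_codons, outgroup_codon = NA,
                                  code,
                                  method = c("more_inclusive",
                                             "less_inclusive"),
                                  min_ingroup = 2L) {
  method <- match.arg(method)
  empty <- data.frame(class = character(), weight = numeric())
  obs <- ingroup_codons[!is.na(ingroup_codons)]
  if (length(obs) < min_ingroup) {
    attr(empty, "skipped") <- "fewer than min_ingroup non-missing codons"
    return(empty)
  }
  if (length(outgroup_codon) == 3L) {
    out_bases <- outgroup_codon
  } else if (length(outgroup_codon) == 1L && !is.na(outgroup_codon)) {
    out_bases <- strsplit(outgroup_codon, "")[[1L]]
  } else {
    out_bases <- rep(NA_character_, 3L)
  }

  bmat <- do.call(rbind, strsplit(obs, ""))
  allele_sets <- lapply(1:3, function(p) {
    tab <- table(bmat[, p])
    sort(names(tab))
  })
  majority <- vapply(1:3, function(p) {
    tab <- table(bmat[, p])           # table() sorts names, which.max takes
    names(tab)[which.max(tab)]        # the first max -> lexicographic tie-break
  }, character(1))
  poly_pos <- which(lengths(allele_sets) > 1L)

  out <- empty
  add <- function(cls, w) {
    if (w > 0) out <<- rbind(out, data.frame(class = cls, weight = w))
  }

  # --- polymorphism ---
  states <- sort(unique(obs))
  if (length(states) == 2L) {
    ps <- enumerate_pathways(states[1L], states[2L], code)
    add("PS", ps$syn)
    add("PN", ps$nonsyn)
  } else if (length(states) > 2L) {
    for (p in poly_pos) {
      for (alt in setdiff(allele_sets[[p]], majority[p])) {
        bg <- majority
        bg[p] <- alt
        from <- paste0(majority, collapse = "")
        to <- paste0(bg, collapse = "")
        same <- identical(unname(code[from]), unname(code[to]))
        add(if (same) "PS" else "PN", 1)
      }
    }
  }

  # --- fixed differences ---
  div_pos <- integer(0)
  for (p in 1:3) {
    o <- out_bases[p]
    if (is.na(o)) next
    if (p %in% poly_pos) {
      if (!o %in% allele_sets[[p]]) div_pos <- c(div_pos, p)
    } else if (o != majority[p]) {
      div_pos <- c(div_pos, p)
    }
  }
  if (length(div_pos)) {
    target <- majority
    target[div_pos] <- out_bases[div_pos]
    ps <- enumerate_pathways(paste0(majority, collapse = ""),
                             paste0(target, collapse = ""), code)
    if (method == "more_inclusive") {
      add("DS", ps$syn)
      add("DN", ps$nonsyn)
    } else {
      mn <- min_nonsyn_path(ps)
      add("DS", mn[["syn"]])
      add("DN", mn[["nonsyn"]])
    }
  }
  out
}

#' Build a gene-level MK table
#'
#' Sums \code{\link{classify_codon_column}} over the codon columns of one
#' gene. Under \code{more_inclusive}, columns with partial missing data are
#' kept and classified over the non-missing sequences; under
#' \code{less_inclusive}, any column with missing data (ingroup or outgroup)
#' is dropped, and designated high-missing sequences can be removed before
#' counting via \code{drop_sequences}.
#'
#' @param gene A \code{gene_alignment} from \code{\link{extract_gene}}.
#' @param method Counting method (see
#'   \code{\link{classify_codon_column}}).
#' @param outgroup Label or index of the outgroup sequence to use for
#'   divergence (default: the first outgroup row).
#' @param drop_sequences Labels of ingroup sequences to remove before
#'   counting (less-inclusive style).
#' @param min_ingroup Passed through to the column classifier.
#' @return One-row data frame of class \code{mk_table} with columns
#'   \code{gene, PN, PS, DN, DS, method, outgroup}; attribute
#'   \code{skipped} is a data frame logging skipped columns.
#' @export
build_mk_table <- function(gene,
                           method = c("more_inclusive", "less_inclusive"),
                           outgroup = NULL, drop_sequences = character(),
                           min_ingroup = 2L) {
  method <- match.arg(method)
  if (is.null(outgroup)) {
    if (!length(gene$outgroup)) stop("gene has no outgroup sequence")
    outgroup <- gene$outgroup[1L]
  }
  if (is.numeric(outgroup)) outgroup <- gene$outgroup[outgroup]
  ing_ids <- setdiff(gene$ingroup, drop_sequences)
  ing <- gene$codons[ing_ids, , drop = FALSE]
  og <- gene$codons[outgroup, ]
  keep <- seq_len(ncol(ing))
  if (method == "less_inclusive") {
    keep <- which(colSums(is.na(ing)) == 0L & !is.na(og))
  }
  if (!length(keep)) stop("empty-table error: no codon columns pass the ",
                          method, " missing-data rule")
  tot <- c(PS = 0, PN = 0, DS = 0, DN = 0)
  skipped <- data.frame(column = integer(), reason = character())
  for (j in keep) {
    contrib <- classify_codon_column(ing[, j], og[j], gene$code,
                                     method = method,
                                     min_ingroup = min_ingroup)
    reason <- attr(contrib, "skipped")
    if (!is.null(reason)) {
      skipped <- rbind(skipped, data.frame(column = j, reason = reason))
    }
    if (nrow(contrib)) {
      agg <- tapply(contrib$weight, contrib$class, sum)
      tot[names(agg)] <- tot[names(agg)] + agg
    }
  }
  out <- data.frame(gene = gene$gene,
                    PN = unname(tot["PN"]), PS = unname(tot["PS"]),
                    DN = unname(tot["DN"]), DS = unname(tot["DS"]),
                    method = method, outgroup = outgroup,
                    stringsAsFactors = FALSE)
  class(out) <- c("mk_table", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' MK table with divergence polarized by two outgroups
#'
#' Fixed differences are counted only at positions where the two outgroup
#' sequences agree with each other and differ from the (fixed) ingroup
#' state, so substitutions are assigned to the ingroup branch; positions
#' with discordant outgroups are excluded from divergence. Polymorphism
#' counting and the outgroup-allele-sharing rule are unchanged, applied with
#' the agreed outgroup state.
#'
#' @param gene A \code{gene_alignment} carrying at least two outgroup rows.
#' @param outgroups Labels of the two outgroup sequences (default: the first
#'   two outgroup rows).
#' @param method Divergence pathway choice, as in
#'   \code{\link{build_mk_table}}.
#' @param min_ingroup Passed through to the column classifier.
#' @return One-row \code{mk_table} with \code{outgroup} set to the joined
#'   labels and logical column \code{polarized = TRUE}.
#' @export
polarize_with_two_outgroups <- function(gene, outgroups = NULL,
                                        method = c("more_inclusive",
                                                   "less_inclusive"),
                                        min_ingroup = 2L) {
  method <- match.arg(method)
  if (is.null(outgroups)) outgroups <- gene$outgroup[1:2]
  if (length(outgroups) < 2L || anyNA(outgroups) ||
      !all(outgroups %in% rownames(gene$codons))) {
    stop("two outgroup sequences are required for polarized counting")
  }
  ing <- gene$codons[gene$ingroup, , drop = FALSE]
  og1 <- gene$codons[outgroups[1L], ]
  og2 <- gene$codons[outgroups[2L], ]
  tot <- c(PS = 0, PN = 0, DS = 0, DN = 0)
  for (j in seq_len(ncol(ing))) {
    b1 <- if (is.na(og1[j])) rep(NA_character_, 3) else
      strsplit(og1[j], "")[[1L]]
    b2 <- if (is.na(og2[j])) rep(NA_character_, 3) else
      strsplit(og2[j], "")[[1L]]
    agreed <- ifelse(!is.na(b1) & !is.na(b2) & b1 == b2, b1, NA_character_)
    contrib <- classify_codon_column(ing[, j], agreed, gene$code,
                                     method = method,
                                     min_ingroup = min_ingroup)
    if (nrow(contrib)) {
      agg <- tapply(contrib$weight, contrib$class, sum)
      tot[names(agg)] <- tot[names(agg)] + agg
    }
  }
  out <- data.frame(gene = gene$gene,
                    PN = unname(tot["PN"]), PS = unname(tot["PS"]),
                    DN = unname(tot["DN"]), DS = unname(tot["DS"]),
                    method = method,
                    outgroup = paste(outgroups, collapse = "+"),
                    polarized = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("mk_table", "data.frame")
  out
}

#' Read a pre-tabulated MK count table
#'
#' @param path TSV with columns \code{gene, PN, PS, DN, DS} (extra columns
#'   are kept). Fractional counts are permitted: pathway averaging over
#'   codons with multiple substitutions produces them.
#' @return Data frame of class \code{mk_table}.
#' @export
read_mk_counts <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "PN", "PS", "DN", "DS")
  if (!all(needed %in% names(x))) {
    stop("MK count table must have columns: ", paste(needed, collapse = ","))
  }
  if (any(x$PN < 0 | x$PS < 0 | x$DN < 0 | x$DS < 0)) {
    stop("MK counts must be non-negative")
  }
  class(x) <- c("mk_table", "data.frame")
  x
}

#' Packaged MK counts for the 13 fly mitochondrial protein-coding genes
#'
#' Gene-level counts of nonsynonymous/synonymous polymorphism and divergence
#' for the 13 mitochondrial protein-coding genes of a North American
#' \emph{D. melanogaster} population sample (n = 38) against
#' \emph{D. yakuba}, counted with the more-inclusive pathway-averaging
#' method. Fractional divergence counts arise from pathway averaging.
#'
#' @return \code{mk_table} data frame with 13 rows.
#' @export
dmel_mt_mk_counts <- function() {
  read_mk_counts(system.file("extdata", "dmel_mt_mk_counts.tsv",
                             package = "polydiv", mustWork = TRUE))
}

#' OXPHOS-complex gene sets for the fly mitochondrial genome
#'
#' @return Named list of gene-name vectors: Complex I (seven ND loci),
#'   Complex III (Cytochrome B), Complex IV (three CO loci), Complex V (two
#'   overlapping ATPase loci), and "All coding" (all 13).
#' @export
oxphos_gene_sets <- function() {
  list(
    `Complex I` = c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6"),
    `Complex III` = "Cyt-b",
    `Complex IV` = c("COI", "COII", "COIII"),
    `Complex V` = c("ATPase6", "ATPase8"),
    `All coding` = c("ATPase6", "ATPase8", "COI", "COII", "COIII", "Cyt-b",
                     "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6")
  )
}
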