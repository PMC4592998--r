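#' Read a gene annotation table
#'
#' Annotation files are tab-separated with header
#' \code{gene,start,end,strand,frame,code}; coordinates are 1-based inclusive
#' alignment columns (GenBank convention). \code{frame} is the number of
#' leading bases to trim before the first complete codon (0-2) and
#' \code{code} the genetic-code table id (1, 2 or 5).
#'
#' @param path TSV annotation file.
#' @return Data frame of class \code{gene_annotation} with one row per gene.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "start", "end", "strand", "frame", "code")
  if (!all(needed %in% names(ann))) {
    stop("annotation header must contain: ", paste(needed, collapse = ","))
  }
  ann <- ann[, needed]
  as_gene_annotation(ann)
}

#' Validate a gene annotation data frame
#'
#' @param ann Data frame with columns gene, start, end, strand, frame, code.
#' @return The validated data frame, classed \code{gene_annotation}.
#' @export
as_gene_annotation <- function(ann) {
  ann$strand <- as.character(ann$strand)
  # tolerate the typographic minus occasionally found in annotation exports
  ann$strand[ann$strand == "−"] <- "-"
  if (anyDuplicated(ann$gene)) {
    stop("duplicated gene name(s): ",
         paste(unique(ann$gene[duplicated(ann$gene)]), collapse = ", "))
  }
  if (any(ann$start > ann$end)) {
    stop("coordinate error: start > end for gene(s) ",
         paste(ann$gene[ann$start > ann$end], collapse = ", "))
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(ann$strand, c("+", "-"))), collapse = ", "))
  }
  if (!all(ann$frame %in% 0:2)) stop("frame must be 0, 1 or 2")
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Extract one annotated gene as a codon alignment
#'
#' Slices the annotated interval out of the whole alignment, orients it to the
#' coding strand (reverse-complementing minus-strand genes), trims the frame
#' offset and any trailing partial codon, and splits the remainder into codon
#' columns. A codon containing any missing base is flagged missing (NA) for
#' that sequence only. Internal stop codons among observed codons are
#' permitted but reported with a warning, as real mitochondrial annotations
#' with incomplete stop codons produce them.
#'
#' @param aln A \code{pop_alignment}.
#' @param ann One row of a \code{gene_annotation} (or list with the same
#'   fields).
#' @param code Genetic code from \code{\link{genetic_code}}; defaults to the
#'   annotation's \code{code} field.
#' @return A \code{gene_alignment}: list with \code{gene}, \code{codons}
#'   (n x n_codons character matrix of triplets, NA = codon missing),
#'   \code{ingroup}, \code{outgroup}, \code{code}, and \code{positions}
#'   (alignment column of each codon's first coding-strand base).
#' @export
extract_gene <- function(aln, ann, code = NULL) {
  ann <- as.list(ann)
  if (is.null(code)) code <- genetic_code(ann$code)
  if (ann$end > ncol(aln$mat)) {
    stop("annotation end (", ann$end, ") exceeds alignment length for gene ",
         ann$gene)
  }
  sub <- aln$mat[, ann$start:ann$end, drop = FALSE]
  if (identical(ann$strand, "-")) sub <- reverse_complement_rows(sub)
  off <- ann$frame
  if (off > 0) sub <- sub[, -(seq_len(off)), drop = FALSE]
  n_codons <- ncol(sub) %/% 3L
  if (n_codons < 1L) stop("empty-gene error: region shorter than one codon")
  sub <- sub[, seq_len(3L * n_codons), drop = FALSE]
  codons <- matrix(NA_character_, nrow(sub), n_codons,
                   dimnames = list(rownames(sub), NULL))
  for (j in seq_len(n_codons)) {
    trip <- sub[, (3L * j - 2L):(3L * j), drop = FALSE]
    ok <- !apply(is.na(trip), 1L, any)
    codons[ok, j] <- paste0(trip[ok, 1L], trip[ok, 2L], trip[ok, 3L])
  }
  obs <- codons[!is.na(codons)]
  n_stop <- sum(code[obs] == "*")
  if (n_stop > 0) {
    warning(n_stop, " internal stop codon occurrence(s) in gene ", ann$gene)
  }
  structure(
    list(gene = ann$gene, codons = codons,
         ingroup = intersect(rownames(codons), aln$ingroup),
         outgroup = intersect(rownames(codons), aln$outgroup),
         code = code,
         positions = ann$start + if (identical(ann$strand, "-")) {
           integer(0)
         } else {
           off + 3L * (seq_len(n_codons) - 1L)
         }),
    class = "gene_alignment"
  )
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("gene_alignment '", x$gene, "': ", length(x$ingroup), " ingroup + ",
      length(x$outgroup), " outgroup, ", ncol(x$codons), " codons\n",
      sep = "")
  invisible(x)
}

#' Write a results table as TSV
#'
#' Deterministic column order (as supplied); numeric columns are printed at a
#' fixed precision so written tables are stable across platforms.
#'
#' @param records Data frame of results.
#' @param path Output path.
#' @param digits Decimal places for numeric columns (default 3, the precision
#'   used for per-gene statistics tables).
#' @return \code{path}, invisibly.
#' @export
write_results_table <- function(records, path, digits = 3) {
  out <- as.data.frame(records)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], format = "f", digits = digits))
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
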