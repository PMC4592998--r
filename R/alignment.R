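#' Read an aligned population sample from FASTA
#'
#' Reads a multiple-sequence alignment of ingroup haplotypes plus one or two
#' outgroup sequences. All records must have identical length. Any character
#' other than A, C, G or T (case-insensitive) -- gaps, N, ? and IUPAC
#' ambiguity codes -- is collapsed to a single missing state, stored as
#' \code{NA}: downstream analyses filter missing data rather than interpret
#' ambiguity.
#'
#' @param path FASTA file of aligned sequences.
#' @param outgroup Character vector of record labels to treat as outgroup
#'   sequences (may be empty for purely unpolarized analyses).
#' @return A \code{pop_alignment}: list with \code{ids}, \code{mat}
#'   (n x L character matrix over A/C/G/T/NA, rownames = ids),
#'   \code{ingroup}, \code{outgroup}.
#' @export
read_alignment <- function(path, outgroup = character()) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence labels in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L) {
    stop("alignment error: records have unequal lengths (",
         paste(unique(w), collapse = ", "), ")")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- ids
  mat[!mat %in% .BASES] <- NA_character_
  pop_alignment(mat, outgroup = outgroup)
}

#' Construct a population alignment from a character matrix
#'
#' @param mat Character matrix (rows = sequences, named) with entries in
#'   A/C/G/T or NA for missing.
#' @param outgroup Labels of outgroup rows; must be present in rownames.
#' @return A \code{pop_alignment} object.
#' @export
pop_alignment <- function(mat, outgroup = character()) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  bad <- !is.na(mat) & !mat %in% .BASES
  if (any(bad)) stop("matrix cells must be A/C/G/T or NA")
  ids <- rownames(mat)
  missing_og <- setdiff(outgroup, ids)
  if (length(missing_og)) {
    stop("outgroup label(s) not found in alignment: ",
         paste(missing_og, collapse = ", "))
  }
  structure(
    list(ids = ids, mat = mat,
         ingroup = setdiff(ids, outgroup),
         outgroup = outgroup),
    class = "pop_alignment"
  )
}

#' @export
print.pop_alignment <- function(x, ...) {
  cat("pop_alignment: ", length(x$ingroup), " ingroup + ",
      length(x$outgroup), " outgroup sequence(s), ",
      ncol(x$mat), " columns, ",
      sum(is.na(x$mat)), " missing cells\n", sep = "")
  invisible(x)
}

#' Write a population alignment to FASTA
#'
#' Missing cells are written as \code{N}; reading the file back with
#' \code{\link{read_alignment}} reproduces the object exactly.
#'
#' @param aln A \code{pop_alignment}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  mat <- aln$mat
  mat[is.na(mat)] <- "N"
  seqs <- Biostrings::BStringSet(apply(mat, 1L, paste0, collapse = ""))
  names(seqs) <- aln$ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Ingroup site matrix of a population alignment
#'
#' @param aln A \code{pop_alignment}.
#' @return Character matrix restricted to the ingroup rows.
#' @export
ingroup_matrix <- function(aln) {
  aln$mat[aln$ingroup, , drop = FALSE]
}

outgroup_row <- function(aln, which = 1L) {
  if (length(aln$outgroup) < which) stop("no outgroup sequence available")
  aln$mat[aln$outgroup[which], ]
}
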