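#' Genetic code tables
#'
#' Returns a genetic code as a named character vector mapping all 64 codons to
#' one-letter amino acids, with stop codons mapped to \code{"*"}. Codes are
#' taken from the NCBI translation tables via \pkg{Biostrings}. The three
#' tables used for mitochondrial and nuclear protein-coding genes are:
#' \describe{
#'   \item{1}{standard nuclear code}
#'   \item{2}{vertebrate mitochondrial (human mtDNA)}
#'   \item{5}{invertebrate mitochondrial (\emph{Drosophila} mtDNA)}
#' }
#'
#' @param table_id Translation-table identifier (integer or character);
#'   one of 1, 2, 5 or any id known to
#'   \code{\link[Biostrings]{getGeneticCode}}.
#' @return Named character vector of length 64 (names are codons over ACGT),
#'   with attribute \code{table_id}.
#' @examples
#' code <- genetic_code(5)
#' code[["ATA"]] # Met under the invertebrate mitochondrial code
#' @export
genetic_code <- function(table_id = 1) {
  id <- as.character(table_id)
  tab <- Biostrings::getGeneticCode(id)
  tab <- tab[order(names(tab))]
  stopifnot(length(tab) == 64L)
  attr(tab, "table_id") <- id
  tab
}

translate_codon <- function(codon, code) {
  unname(code[codon])
}

is_stop_codon <- function(codon, code) {
  !is.na(codon) & code[codon] == "*"
}

reverse_complement_rows <- function(mat) {
  out <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  out[] <- .COMPLEMENT[out]
  out
}
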