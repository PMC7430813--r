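# Standard genetic code, with stop codons rendered "&" in protein views.
# Built once at load from Biostrings::GENETIC_CODE so the table is never
# hand-copied.

STOP_SYMBOL <- "&"

.genetic_code <- local({
  gc <- Biostrings::GENETIC_CODE
  gc[gc == "*"] <- STOP_SYMBOL
  gc
})

#' All 64 codons in the standard genetic code
#' @return Character vector of 64 codons named by the amino acid (one-letter,
#'   stop = `"&"`) they encode.
#' @export
genetic_code_table <- function() .genetic_code

SENSE_CODONS <- names(.genetic_code)[.genetic_code != STOP_SYMBOL]
STOP_CODONS <- names(.genetic_code)[.genetic_code == STOP_SYMBOL]

# codon -> number of codons in its synonymous family (stop counted as a family)
.family_size <- table(.genetic_code)[.genetic_code]
names(.family_size) <- names(.genetic_code)

#' Synonymous family of a codon
#'
#' @param codon A codon string, e.g. `"TTA"`.
#' @return Character vector of all codons encoding the same amino acid.
#' @export
synonymous_family <- function(codon) {
  aa <- .genetic_code[[toupper(codon)]]
  names(.genetic_code)[.genetic_code == aa]
}

#' Translate a coding sequence
#'
#' One-letter amino acids, stop codons rendered `"&"`. The sequence length
#' must be a multiple of 3 and contain only unambiguous bases.
#'
#' @param cds DNA string over \{A,C,G,T\}.
#' @return Protein string, one symbol per codon.
#' @examples
#' translate_cds("ATGTGA") # "M&"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    abort(sprintf("CDS length %d is not a positive multiple of 3", n))
  }
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  bad <- grep("[^ACGT]", codons)
  if (length(bad)) {
    abort(sprintf(
      "ambiguous or invalid base in codon %d ('%s')", bad[1L], codons[bad[1L]]
    ))
  }
  paste(.genetic_code[codons], collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}
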