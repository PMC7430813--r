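# Codon alignment container: a codon-cell matrix (rows = records, columns =
# aligned codon positions), a protein-level view with stops rendered "&", and
# a reference-coordinate map used to anchor site classifications.

#' Construct a codon alignment
#'
#' @param codon_matrix Character matrix of codon cells; each cell a 3-letter
#'   codon or the gap cell `"---"`. Row names are record ids.
#' @param reference_id Record whose coordinates anchor `reference_map`
#'   (default: first row).
#' @return An object of class `cgap_codon_alignment` with components
#'   `ids`, `codons`, `protein` (single-letter view, stop `"&"`, gap `"-"`),
#'   and `reference_map` (per column, the 1-based amino-acid position in the
#'   reference record, `NA` at reference-gapped columns).
#' @export
codon_alignment <- function(codon_matrix, reference_id = rownames(codon_matrix)[1L]) {
  stopifnot(is.matrix(codon_matrix), !is.null(rownames(codon_matrix)))
  ids <- rownames(codon_matrix)
  if (!reference_id %in% ids) {
    abort(sprintf("reference record '%s' is not in the alignment", reference_id))
  }
  cells <- unique(as.vector(codon_matrix))
  bad <- cells[!(cells == "---" | cells %in% names(.genetic_code))]
  if (length(bad)) {
    abort(sprintf("invalid codon cell '%s' (not a codon or '---')", bad[1L]))
  }
  prot <- matrix("-", nrow(codon_matrix), ncol(codon_matrix),
                 dimnames = dimnames(codon_matrix))
  nongap <- codon_matrix != "---"
  prot[nongap] <- unname(.genetic_code[codon_matrix[nongap]])
  ref_row <- codon_matrix[reference_id, ]
  reference_map <- rep(NA_integer_, ncol(codon_matrix))
  reference_map[ref_row != "---"] <- seq_len(sum(ref_row != "---"))
  structure(
    list(ids = ids, codons = codon_matrix, protein = prot,
         reference_id = reference_id, reference_map = reference_map),
    class = "cgap_codon_alignment"
  )
}

#' @export
print.cgap_codon_alignment <- function(x, ...) {
  cat(sprintf("<codon alignment: %d sequences x %d codon columns; reference %s>\n",
              length(x$ids), ncol(x$codons), x$reference_id))
  invisible(x)
}

#' Nucleotide-level view of a codon alignment
#'
#' Expands each codon cell into three nucleotide columns (gap cell to
#' `"-","-","-"`), the view on which pairwise identities, distances and
#' bootstrap column resampling operate.
#'
#' @param aln A `cgap_codon_alignment`.
#' @return Character matrix, `length(ids)` rows, `3 * ncol(codons)` columns.
#' @export
as_nucleotide_matrix <- function(aln) {
  cod <- aln$codons
  out <- matrix("-", nrow(cod), 3L * ncol(cod), dimnames = list(rownames(cod), NULL))
  for (j in seq_len(ncol(cod))) {
    cells <- cod[, j]
    out[, (3L * j - 2L):(3L * j)] <-
      matrix(unlist(strsplit(cells, "", fixed = TRUE), use.names = FALSE),
             ncol = 3L, byrow = TRUE)
  }
  out
}

#' De-gap one alignment row back to its CDS
#' @param aln A `cgap_codon_alignment`.
#' @param id Record id.
#' @return The unaligned CDS string.
#' @export
degap_row <- function(aln, id) {
  row <- aln$codons[id, ]
  paste(row[row != "---"], collapse = "")
}

#' Check de-gap faithfulness of an alignment against a record set
#'
#' Asserts the core alignment invariant: removing gaps from each row
#' reproduces that record's CDS exactly.
#'
#' @param aln A `cgap_codon_alignment`.
#' @param records A `cgap_records` tibble containing every aligned id.
#' @return `TRUE`, invisibly; aborts naming the first mismatching record.
#' @export
assert_degap_faithful <- function(aln, records) {
  for (id in aln$ids) {
    cds <- records$cds[match(id, records$id)]
    if (is.na(cds)) abort(sprintf("record %s missing from record set", id))
    if (!identical(degap_row(aln, id), cds)) {
      abort(sprintf("row %s does not de-gap to its CDS", id))
    }
  }
  invisible(TRUE)
}
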