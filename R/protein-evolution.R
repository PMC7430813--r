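# Tests of protein molecular evolution: relative synonymous codon usage
# (R = Counts / Expected counts, expected = equal usage within each
# synonymous family), not-preferable codons (R <= threshold), reference-
# anchored invariant/forward/compensatory site classification, and
# alignment landmark extraction (common cysteines, exon-intron boundary
# sites, N-glycosylation sequons).

#' Relative synonymous codon usage
#'
#' Tabulates codon counts over the dataset and computes, for every codon,
#' `R = count / expected` where the expected count is the codon's
#' synonymous-family total divided by the family size (equal usage). Codons
#' of single-codon families (ATG, TGG) have `R = 1` by construction; stop
#' codons are tabulated (reported as amino acid `&`) but never classified
#' not-preferable. Codons with `R <= threshold` in families of two or more
#' form the not-preferable set.
#'
#' @param x A `cgap_records` tibble (codons counted from the CDSs) or a
#'   `cgap_codon_alignment` (non-gap cells counted).
#' @param threshold Not-preferable threshold on `R` (default 0.7).
#' @param complete_only For record input, drop putative records first
#'   (default `TRUE`).
#' @return Object of class `cgap_rscu`: list with `table` (tibble: `codon`,
#'   `amino_acid`, `family_size`, `count`, `expected`, `R`,
#'   `not_preferable`), `not_preferable` (codon set) and `threshold`.
#' @export
codon_usage <- function(x, threshold = 0.7, complete_only = TRUE) {
  codons <- if (inherits(x, "cgap_codon_alignment")) {
    cells <- as.vector(x$codons)
    cells[cells != "---"]
  } else {
    recs <- if (complete_only) x[x$status != "putative", ] else x
    unlist(lapply(recs$cds, split_codons), use.names = FALSE)
  }
  counts <- table(factor(codons, levels = names(.genetic_code)))
  tab <- tibble(
    codon = names(.genetic_code),
    amino_acid = unname(.genetic_code),
    family_size = as.integer(unname(.family_size)),
    count = as.integer(counts)
  )
  fam <- dplyr::summarise(dplyr::group_by(tab, .data$amino_acid),
                          family_total = sum(.data$count), .groups = "drop")
  tab <- dplyr::left_join(tab, fam, by = "amino_acid")
  tab$expected <- tab$family_total / tab$family_size
  tab$R <- ifelse(tab$family_total > 0, tab$count / tab$expected, NA_real_)
  tab$not_preferable <- !is.na(tab$R) & tab$R <= threshold &
    tab$family_size >= 2L & tab$amino_acid != STOP_SYMBOL
  tab$family_total <- NULL
  structure(
    list(table = tab,
         not_preferable = tab$codon[tab$not_preferable],
         threshold = threshold),
    class = "cgap_rscu"
  )
}

#' @export
print.cgap_rscu <- function(x, ...) {
  cat(sprintf("<RSCU over %d codons: %d not-preferable codons at R <= %g>\n",
              sum(x$table$count), length(x$not_preferable), x$threshold))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cgap_rscu <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.cgap_rscu <- function(x, ...) {
  sense <- x$table[x$table$amino_acid != STOP_SYMBOL, ]
  tibble(n_codons = sum(x$table$count),
         n_sense_codons = sum(sense$count),
         n_not_preferable = length(x$not_preferable),
         threshold = x$threshold)
}

#' RSCU bar chart by synonymous family
#' @param object A `cgap_rscu`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cgap_rscu <- function(object, ...) {
  df <- object$table[!is.na(object$table$R), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$R,
                                   fill = .data$not_preferable)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::facet_wrap(~amino_acid, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = sprintf("R <= %g", object$threshold)) +
    ggplot2::labs(y = "R = counts / expected counts", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Classify reference-anchored amino-acid sites
#'
#' Labels every reference amino-acid position as `invariant` (exactly one
#' amino acid observed across all rows at that alignment column, gapped
#' rows excluded), `forward` (variant, and no aligned codon in the
#' not-preferable set) or `compensatory` (variant, with at least one
#' not-preferable codon). Columns where the reference row is gapped carry
#' no reference coordinate and are skipped (logged).
#'
#' @param aln A `cgap_codon_alignment`.
#' @param rscu A `cgap_rscu` computed from the same dataset (or any codon
#'   set supplying the not-preferable codons).
#' @param reference_id Reference record id; defaults to the alignment's.
#' @return Object of class `cgap_sites`: tibble with `ref_pos`, `column`,
#'   `label`, `n_amino_acids`, `amino_acids`, `has_not_preferable`.
#' @export
classify_sites <- function(aln, rscu, reference_id = aln$reference_id) {
  if (!reference_id %in% aln$ids) {
    abort(sprintf("reference record '%s' is not in the alignment", reference_id))
  }
  if (reference_id != aln$reference_id) {
    aln <- codon_alignment(aln$codons, reference_id = reference_id)
  }
  np <- rscu$not_preferable
  cols <- which(!is.na(aln$reference_map))
  skipped <- ncol(aln$codons) - length(cols)
  if (skipped > 0L) {
    inform(sprintf("%d reference-gapped column(s) skipped", skipped))
  }
  out <- lapply(cols, function(j) {
    cod <- aln$codons[, j]
    keep <- cod != "---"
    aas <- unique(aln$protein[keep, j])
    invariant <- length(aas) == 1L
    has_np <- any(cod[keep] %in% np)
    tibble(
      ref_pos = aln$reference_map[j], column = j,
      label = if (invariant) "invariant" else if (has_np) "compensatory" else "forward",
      n_amino_acids = length(aas),
      amino_acids = paste(sort(aas), collapse = ""),
      has_not_preferable = has_np
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("cgap_sites", class(out))
  out
}

#' Summary counts of site classes
#' @param x A `cgap_sites` table.
#' @param ... Unused.
#' @return One-row tibble with `n_sites`, `n_invariant`, `n_forward`,
#'   `n_compensatory`.
#' @exportS3Method generics::glance
glance.cgap_sites <- function(x, ...) {
  tibble(n_sites = nrow(x),
         n_invariant = sum(x$label == "invariant"),
         n_forward = sum(x$label == "forward"),
         n_compensatory = sum(x$label == "compensatory"))
}

#' Site-class map along the reference
#' @param object A `cgap_sites` table.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cgap_sites <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ref_pos, y = 1,
                                       fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(invariant = "#5e3c99",
                                          forward = "#e66101",
                                          compensatory = "grey70")) +
    ggplot2::labs(x = "reference amino-acid position", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

# per-member map: amino-acid index -> alignment column
row_columns <- function(aln, id) which(aln$codons[id, ] != "---")

# exon-intron boundary amino-acid positions of one record; a codon split by
# an intron belongs to the upstream exon's boundary position
splice_boundary_positions <- function(record_exons) {
  lens <- record_exons$end - record_exons$start
  cum <- cumsum(lens)
  if (length(cum) < 2L) return(integer())
  as.integer(ceiling(cum[-length(cum)] / 3))
}

sequon_starts <- function(protein) {
  p <- strsplit(protein, "")[[1L]]
  n <- length(p)
  if (n < 3L) return(integer())
  which(p[1:(n - 2L)] == "N" & p[2:(n - 1L)] != "P" &
          p[3:n] %in% c("S", "T"))
}

#' Extract common landmarks from a cluster alignment
#'
#' Landmarks common to every member of an aligned cluster: alignment
#' columns where all members carry a cysteine; columns hosting an
#' exon-intron boundary at the homologous position in every member (a
#' 5-coding-exon gene has 4 boundary positions); and columns where every
#' member starts an N-glycosylation sequon N-X-\[S/T\] with X != P.
#'
#' @param aln A `cgap_codon_alignment` of the cluster's members.
#' @param records A `cgap_records` tibble supplying exon models.
#' @return Tibble with `type` (`cysteine`, `splice_site`, `nglyc`),
#'   `column`, and `ref_pos` (reference coordinate, `NA` if the reference
#'   is gapped there).
#' @export
extract_landmarks <- function(aln, records) {
  ids <- aln$ids
  n <- length(ids)
  # common cysteines: every member C at the column
  cys_cols <- which(colSums(aln$protein == "C") == n)
  # common splice sites
  boundary_cols <- lapply(ids, function(id) {
    ex <- records$exons[[match(id, records$id)]]
    if (is.null(ex)) abort(sprintf("record %s missing from record set", id))
    pos <- splice_boundary_positions(ex)
    row_columns(aln, id)[pos]
  })
  splice_cols <- if (n > 0 && all(lengths(boundary_cols) > 0)) {
    Reduce(intersect, boundary_cols)
  } else integer()
  # common N-glycosylation sequon starts
  sequon_cols <- lapply(ids, function(id) {
    prot <- paste(aln$protein[id, aln$codons[id, ] != "---"], collapse = "")
    row_columns(aln, id)[sequon_starts(prot)]
  })
  nglyc_cols <- Reduce(intersect, sequon_cols)
  res <- dplyr::bind_rows(
    tibble(type = "cysteine", column = as.integer(cys_cols)),
    tibble(type = "splice_site", column = as.integer(splice_cols)),
    tibble(type = "nglyc", column = as.integer(nglyc_cols))
  )
  if (!nrow(res)) {
    return(tibble(type = character(), column = integer(), ref_pos = integer()))
  }
  res$ref_pos <- aln$reference_map[res$column]
  dplyr::arrange(res, .data$type, .data$column)
}
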