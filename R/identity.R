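# Pairwise nucleotide sequence identities (pairwise deletion), the summary
# statistics a-bar / a-bar_ad / a_max / a_min, and identity-pattern
# classification.

#' Pairwise nucleotide identity under pairwise deletion
#'
#' Fraction of matching nucleotide columns between two alignment rows,
#' excluding (per pair) every column gapped in either row. `NA` when no
#' columns are comparable.
#'
#' @param aln A `cgap_codon_alignment` (or a character matrix of nucleotide
#'   columns with `-` gaps).
#' @param i,j Row ids or indices.
#' @return Identity fraction in \[0, 1\], or `NA`.
#' @export
pairwise_identity <- function(aln, i, j) {
  m <- if (inherits(aln, "cgap_codon_alignment")) as_nucleotide_matrix(aln) else aln
  a <- m[i, ]; b <- m[j, ]
  keep <- a != "-" & b != "-"
  if (!any(keep)) return(NA_real_)
  mean(a[keep] == b[keep])
}

#' All-pairs identity matrix
#'
#' @param aln A `cgap_codon_alignment` or nucleotide character matrix.
#' @param subset Optional ids/indices restricting the rows.
#' @return Symmetric matrix of pairwise identities with unit diagonal.
#' @export
identity_matrix <- function(aln, subset = NULL) {
  m <- if (inherits(aln, "cgap_codon_alignment")) as_nucleotide_matrix(aln) else aln
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  n <- nrow(m)
  ng <- m != "-"
  A <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    keep <- ng[i, ] & ng[j, ]
    A[i, j] <- A[j, i] <-
      if (any(keep)) mean(m[i, keep] == m[j, keep]) else NA_real_
  }
  A
}

#' Identity pattern statistics
#'
#' Average pairwise nucleotide sequence identity (a-bar), its average
#' absolute deviation (a-bar_ad), and the largest/smallest pairwise
#' identities (a_max, a_min) over all unordered pairs in the subset.
#' Pairs with no comparable columns are excluded from the statistics.
#'
#' @inheritParams identity_matrix
#' @return Object of class `cgap_identity_stats`: a list with the four
#'   statistics, `n_pairs`, and the pairwise `matrix`.
#' @export
identity_stats <- function(aln, subset = NULL) {
  A <- identity_matrix(aln, subset)
  if (nrow(A) < 2L) abort("need at least 2 sequences")
  vals <- A[lower.tri(A)]
  vals <- vals[!is.na(vals)]
  a_bar <- mean(vals)
  structure(
    list(a_bar = a_bar,
         a_bar_ad = mean(abs(vals - a_bar)),
         a_max = max(vals), a_min = min(vals),
         n_pairs = length(vals), matrix = A),
    class = "cgap_identity_stats"
  )
}

#' @export
print.cgap_identity_stats <- function(x, ...) {
  cat(sprintf(
    "<identity stats over %d pairs: a-bar=%.3f (a_max=%.3f, a_min=%.3f, a-bar_ad=%.3f)>\n",
    x$n_pairs, x$a_bar, x$a_max, x$a_min, x$a_bar_ad))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cgap_identity_stats <- function(x, ...) {
  tibble(a_bar = x$a_bar, a_bar_ad = x$a_bar_ad,
         a_max = x$a_max, a_min = x$a_min, n_pairs = x$n_pairs)
}

#' @exportS3Method generics::tidy
tidy.cgap_identity_stats <- function(x, ...) {
  A <- x$matrix
  idx <- which(lower.tri(A), arr.ind = TRUE)
  tibble(id1 = rownames(A)[idx[, 1L]], id2 = colnames(A)[idx[, 2L]],
         identity = A[idx])
}

#' Classify an identity value into a pattern category
#'
#' Bins a pairwise (or group-average) nucleotide identity into the pattern
#' categories `very_close`, `close`, `typical`, `distant`, `very_distant`.
#' The default bin boundaries are package configuration choices (no
#' published boundaries exist for the categories); supply your own bins via
#' the config. Higher identity never maps to a more distant category.
#'
#' @param identity Numeric vector of identities in \[0, 1\].
#' @param level `"orthologue"` (within-cluster) or `"homologue"` (between
#'   clusters); recorded in the output, the binning is the same.
#' @param bins Named decreasing thresholds (category applies at or above its
#'   value); anything below the last threshold is `very_distant`.
#' @return Tibble with `identity`, `category` (ordered factor) and `level`.
#' @export
classify_pattern <- function(identity, level = c("orthologue", "homologue"),
                             bins = protocol_config()$identity_pattern_bins) {
  level <- match.arg(level)
  stopifnot(all(identity >= 0 & identity <= 1, na.rm = TRUE),
            !is.unsorted(rev(bins)))
  cats <- c(names(bins), "very_distant")
  idx <- vapply(identity, function(a) {
    if (is.na(a)) return(NA_integer_)
    hit <- which(a >= bins)
    if (length(hit)) hit[1L] else length(bins) + 1L
  }, integer(1))
  tibble(identity = identity,
         category = factor(cats[idx], levels = rev(cats), ordered = TRUE),
         level = level)
}

#' Identity heatmap of an alignment
#'
#' @param object A `cgap_identity_stats`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cgap_identity_stats <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id1, y = .data$id2,
                                   fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "identity") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("pairwise identity (a-bar = %.3f)", object$a_bar)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
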