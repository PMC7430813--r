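# Core record types. All user-facing containers are tibbles so results chain
# with the pipe; sequence payloads are plain character columns and exon models
# are list-columns of tibbles. Internal coordinates are 0-based half-open;
# GFF3 (1-based closed) only at the file boundary.

#' Construct a coding-sequence record table
#'
#' One row per potential coding sequence. `exons` is a list-column: for each
#' record a tibble with columns `contig_id`, `start`, `end` (0-based
#' half-open on the contig), `strand` (`"+"`/`"-"`), rows ordered 5'→3' in
#' transcript order.
#'
#' @param id Character vector of unique accession-like ids.
#' @param taxon Species names.
#' @param cds CDS nucleotide strings over \{A,C,G,T\}; length a positive
#'   multiple of 3.
#' @param exons List of exon-model tibbles (one per record). Defaults to a
#'   single-exon model spanning the CDS on a contig named after the record.
#' @param cluster_label,supercluster_label Gene-cluster labels, `NA` when
#'   unknown (classification stages may fill them).
#' @param status One of `"potential"`, `"complete"`, `"putative"`.
#' @param validate Check record invariants (default `TRUE`).
#' @return A tibble of class `cgap_records`.
#' @export
cds_records <- function(id, taxon, cds,
                        exons = NULL,
                        cluster_label = NA_character_,
                        supercluster_label = NA_character_,
                        status = "potential",
                        validate = TRUE) {
  cds <- toupper(cds)
  if (is.null(exons)) {
    exons <- purrr::map2(id, cds, function(i, s) {
      tibble(contig_id = i, start = 0L, end = nchar(s), strand = "+")
    })
  }
  out <- tibble(
    id = as.character(id),
    taxon = as.character(taxon),
    cluster_label = rep_len(as.character(cluster_label), length(id)),
    supercluster_label = rep_len(as.character(supercluster_label), length(id)),
    status = rep_len(status, length(id)),
    cds = cds,
    exons = exons
  )
  class(out) <- c("cgap_records", class(out))
  if (validate) validate_records(out)
  out
}

#' Validate coding-sequence record invariants
#'
#' Checks that ids are unique, each CDS length is a positive multiple of 3,
#' exon span lengths sum to the CDS length, spans within a contig do not
#' overlap, and statuses are known. Aborts on first violation.
#'
#' @param records A `cgap_records` tibble.
#' @return `records`, invisibly.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id)) {
    abort(sprintf("duplicate record id: %s",
                  records$id[duplicated(records$id)][1L]))
  }
  ok_status <- c("potential", "complete", "putative")
  bad <- setdiff(unique(records$status), ok_status)
  if (length(bad)) abort(sprintf("unknown status '%s'", bad[1L]))
  for (k in seq_len(nrow(records))) {
    id <- records$id[k]
    n <- nchar(records$cds[k])
    if (n == 0L || n %% 3L != 0L) {
      abort(sprintf("record %s: CDS length %d is not a positive multiple of 3",
                    id, n))
    }
    if (grepl("[^ACGT]", records$cds[k])) {
      abort(sprintf("record %s: CDS contains non-ACGT characters", id))
    }
    ex <- records$exons[[k]]
    if (nrow(ex) < 1L) abort(sprintf("record %s: no exons", id))
    if (any(ex$end <= ex$start)) {
      abort(sprintf("record %s: empty or inverted exon span", id))
    }
    if (sum(ex$end - ex$start) != n) {
      abort(sprintf(
        "record %s: exon spans sum to %d but CDS length is %d",
        id, sum(ex$end - ex$start), n
      ))
    }
    for (ctg in unique(ex$contig_id)) {
      spans <- dplyr::arrange(ex[ex$contig_id == ctg, ], .data$start)
      if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)])) {
        abort(sprintf("record %s: overlapping exon spans on %s", id, ctg))
      }
    }
  }
  invisible(records)
}

#' Construct coverage tracks
#'
#' Per-nucleotide trace-coverage integers over each record's CDS span.
#'
#' @param record_id Character vector of record ids.
#' @param coverage List of non-negative integer vectors, one per record, each
#'   the same length as the record's CDS.
#' @return A tibble with columns `record_id` and list-column `coverage`.
#' @export
coverage_tracks <- function(record_id, coverage) {
  if (!is.list(coverage)) coverage <- list(coverage)
  bad <- which(vapply(coverage, function(x) any(x < 0), logical(1)))
  if (length(bad)) {
    abort(sprintf("negative coverage for record %s", record_id[bad[1L]]))
  }
  tibble(record_id = as.character(record_id),
         coverage = purrr::map(coverage, as.integer))
}

#' Construct genomic contigs
#'
#' @param id,taxon,sequence,role Vectors; `role` is `"base"` or `"target"`,
#'   `sequence` over \{A,C,G,T,N\}.
#' @return A tibble with one row per contig.
#' @export
genomic_contigs <- function(id, taxon, sequence, role = "target") {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) == 0L)) abort("empty contig sequence")
  if (any(grepl("[^ACGTN]", sequence))) {
    abort("contig sequence outside alphabet {A,C,G,T,N}")
  }
  if (!all(role %in% c("base", "target"))) abort("role must be base or target")
  tibble(id = as.character(id), taxon = as.character(taxon),
         sequence = sequence, role = rep_len(role, length(id)))
}

#' Protocol configuration
#'
#' Houses the tunable constants of the protocol: taxon-tiered contiguity
#' cutoffs, the RSCU not-preferable threshold, bootstrap constants, and the
#' identity-pattern bins.
#'
#' @param contiguity_cutoffs Data frame with columns `group` (regex matched
#'   against the taxon name), `identity` (fraction in (0,1]) and `window_bp`.
#'   Defaults to the empirically tiered table (see [default_cutoff_table()]).
#' @param contiguity_fallback Two-element list `(identity, window_bp)` applied
#'   when no group matches; default `0.70 / 100`.
#' @param rscu_threshold Codons with usage ratio `R <=` this are
#'   not-preferable; default `0.7`.
#' @param bootstrap_replicates Default bootstrap replicate count (`1000`).
#' @param bootstrap_collapse Support percentage below which internal branches
#'   are collapsed (`50`).
#' @param identity_pattern_bins Named decreasing thresholds mapping pairwise
#'   identity to pattern categories. Defaults are package choices, not
#'   published boundaries; override freely.
#' @param min_depth Minimum per-base trace coverage for the reliability test
#'   (default `1`).
#' @param min_overlap Minimum exon/conserved-segment overlap in bp (`1`).
#' @param random_seed Default seed for stochastic steps.
#' @return A list of class `cgap_config`.
#' @export
protocol_config <- function(contiguity_cutoffs = default_cutoff_table(),
                            contiguity_fallback = list(identity = 0.70,
                                                       window_bp = 100L),
                            rscu_threshold = 0.7,
                            bootstrap_replicates = 1000L,
                            bootstrap_collapse = 50,
                            identity_pattern_bins = c(
                              very_close = 0.85, close = 0.75,
                              typical = 0.60, distant = 0.45
                            ),
                            min_depth = 1L,
                            min_overlap = 1L,
                            random_seed = 1L) {
  stopifnot(
    all(contiguity_cutoffs$identity > 0), all(contiguity_cutoffs$identity <= 1),
    all(contiguity_cutoffs$window_bp >= 1),
    rscu_threshold > 0, rscu_threshold < 1,
    bootstrap_replicates >= 1,
    !is.unsorted(rev(identity_pattern_bins))
  )
  structure(
    list(
      contiguity_cutoffs = contiguity_cutoffs,
      contiguity_fallback = contiguity_fallback,
      rscu_threshold = rscu_threshold,
      bootstrap_replicates = as.integer(bootstrap_replicates),
      bootstrap_collapse = bootstrap_collapse,
      identity_pattern_bins = identity_pattern_bins,
      min_depth = as.integer(min_depth),
      min_overlap = as.integer(min_overlap),
      random_seed = as.integer(random_seed)
    ),
    class = "cgap_config"
  )
}

#' Default taxon-tiered contiguity cutoff table
#'
#' Empirically tiered windowed-identity cutoffs for detecting common genomic
#' sequence regions in pairwise alignments against a human base sequence:
#' 95%/100 bp for chimpanzee and gorilla, 90% for orangutan and gibbon, 85%
#' for macaques and baboons, 80% for marmoset, 75% for tarsier and the
#' strepsirrhines, 65% for rodents, and 70% in other pairwise alignments
#' (the fallback tier, held in the config rather than this table).
#'
#' @return Tibble with columns `group`, `identity`, `window_bp`.
#' @export
default_cutoff_table <- function() {
  tibble(
    group = c(
      "Pan |Pan$|troglodytes|Gorilla",
      "Pongo|abelii|Nomascus|leucogenys",
      "Macaca|mulatta|Papio|hamadryas",
      "Callithrix|jacchus",
      "Tarsius|syrichta|Microcebus|murinus|Otolemur|garnettii",
      "Rodentia|Mus |Mus$|musculus|Rattus|norvegicus|Cavia|porcellus|Spermophilus"
    ),
    identity = c(0.95, 0.90, 0.85, 0.80, 0.75, 0.65),
    window_bp = 100L
  )
}

#' @export
print.cgap_config <- function(x, ...) {
  cat("<cgap protocol configuration>\n")
  cat(sprintf("  RSCU not-preferable threshold : R <= %g\n", x$rscu_threshold))
  cat(sprintf("  bootstrap                     : %d replicates, collapse < %g%%\n",
              x$bootstrap_replicates, x$bootstrap_collapse))
  cat(sprintf("  reliability min depth         : %d\n", x$min_depth))
  cat(sprintf("  contiguity tiers              : %d + fallback %g/%d bp\n",
              nrow(x$contiguity_cutoffs), x$contiguity_fallback$identity,
              x$contiguity_fallback$window_bp))
  cat("  identity-pattern bins         : ",
      paste(sprintf("%s>=%g", names(x$identity_pattern_bins),
                    x$identity_pattern_bins), collapse = ", "),
      ", else very_distant\n", sep = "")
  invisible(x)
}
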