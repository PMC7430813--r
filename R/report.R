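# Aggregates stage outputs into the protocol-style deliverables: a cluster
# membership table with exon-count constancy flags, identity patterns within
# and between clusters, and a per-record annotation table.

#' Build the annotation report
#'
#' Joins the per-stage outputs on record id; any stage row referencing an
#' unknown record id is an error. Clusters whose members disagree in
#' coding-exon count are flagged as potential differential
#' expansion/misassembly. Identity patterns are computed from the codon
#' alignment when one is supplied.
#'
#' @param records A `cgap_records` tibble with `cluster_label` and
#'   `supercluster_label` filled (e.g. via [assign_clusters()]).
#' @param reliability Optional verdict table from [classify_reliability()].
#' @param contiguity Optional verdict table from [test_contiguity()] rows.
#' @param aln Optional `cgap_codon_alignment` over the complete records.
#' @param config A [protocol_config()] (identity-pattern bins).
#' @return Object of class `cgap_report`: list with `clusters`,
#'   `superclusters`, `records` tibbles and a `summary` character vector.
#' @export
build_report <- function(records, reliability = NULL, contiguity = NULL,
                         aln = NULL, config = protocol_config()) {
  if (nrow(records) == 0L) {
    return(structure(list(
      clusters = tibble(), superclusters = tibble(), records = tibble(),
      summary = "empty record set"), class = "cgap_report"))
  }
  for (stage in list(reliability = reliability, contiguity = contiguity)) {
    if (!is.null(stage) && nrow(stage)) {
      unknown <- setdiff(stage$record_id, records$id)
      if (length(unknown)) {
        abort(sprintf("stage output references unknown record id %s", unknown[1L]))
      }
    }
  }
  per_rec <- tibble(
    record_id = records$id, taxon = records$taxon,
    cluster = records$cluster_label, supercluster = records$supercluster_label,
    status = records$status,
    n_exons = vapply(records$exons, nrow, integer(1)),
    n_codons = nchar(records$cds) %/% 3L
  )
  if (!is.null(reliability)) {
    per_rec <- dplyr::left_join(
      per_rec, reliability[, c("record_id", "n_uncovered")], by = "record_id")
  }
  if (!is.null(contiguity)) {
    per_rec <- dplyr::left_join(
      per_rec, contiguity[, c("record_id", "verdict", "defect_hint")],
      by = "record_id")
  }
  idm <- if (!is.null(aln)) identity_matrix(aln) else NULL
  pair_mean <- function(ids1, ids2 = ids1) {
    if (is.null(idm)) return(NA_real_)
    ids1 <- intersect(ids1, rownames(idm)); ids2 <- intersect(ids2, rownames(idm))
    if (!length(ids1) || !length(ids2)) return(NA_real_)
    sub <- idm[ids1, ids2, drop = FALSE]
    if (identical(ids1, ids2)) {
      if (length(ids1) < 2L) return(NA_real_)
      mean(sub[lower.tri(sub)], na.rm = TRUE)
    } else {
      mean(sub, na.rm = TRUE)
    }
  }
  complete <- per_rec[per_rec$status != "putative", ]
  clusters <- dplyr::group_by(complete, .data$cluster, .data$supercluster)
  clusters <- dplyr::summarise(
    clusters,
    n_members = dplyr::n(),
    exon_count = .data$n_exons[1L],
    exon_count_constant = dplyr::n_distinct(.data$n_exons) == 1L,
    .groups = "drop"
  )
  clusters$within_identity <- vapply(clusters$cluster, function(cl) {
    pair_mean(complete$record_id[complete$cluster == cl])
  }, double(1))
  clusters$within_pattern <- as.character(
    classify_pattern(clusters$within_identity, "orthologue",
                     config$identity_pattern_bins)$category)
  supers <- dplyr::group_by(clusters, .data$supercluster)
  supers <- dplyr::summarise(
    supers,
    n_clusters = dplyr::n(),
    clusters = paste(.data$cluster, collapse = ","),
    n_members = sum(.data$n_members),
    .groups = "drop"
  )
  supers$between_identity <- vapply(supers$supercluster, function(sc) {
    cls <- clusters$cluster[clusters$supercluster == sc]
    if (length(cls) < 2L) return(NA_real_)
    vals <- c()
    for (a in seq_along(cls)) for (b in seq_len(a - 1L)) {
      vals <- c(vals, pair_mean(
        complete$record_id[complete$cluster == cls[a]],
        complete$record_id[complete$cluster == cls[b]]))
    }
    mean(vals, na.rm = TRUE)
  }, double(1))
  supers$between_pattern <- as.character(
    classify_pattern(supers$between_identity, "homologue",
                     config$identity_pattern_bins)$category)
  flagged <- clusters$cluster[!clusters$exon_count_constant]
  summary <- c(
    sprintf("%d records (%d complete, %d putative)",
            nrow(per_rec), sum(per_rec$status == "complete"),
            sum(per_rec$status == "putative")),
    sprintf("%d major gene clusters in %d superclusters",
            nrow(clusters), nrow(supers)),
    sprintf("%d coding exons among complete records",
            sum(complete$n_exons)),
    if (length(flagged)) {
      sprintf("exon count NOT constant in: %s (potential differential expansion/misassembly)",
              paste(flagged, collapse = ", "))
    } else "coding exon numbers constant within all major gene clusters"
  )
  structure(
    list(clusters = clusters, superclusters = supers, records = per_rec,
         summary = summary),
    class = "cgap_report"
  )
}

#' @export
print.cgap_report <- function(x, ...) {
  cat("<annotation report>\n")
  for (line in x$summary) cat(" ", line, "\n")
  invisible(x)
}

#' Write a report's tables and summary to a directory
#' @param report A `cgap_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(report$records, file.path(dir, "records.tsv"))
  write_table(report$clusters, file.path(dir, "clusters.tsv"))
  write_table(report$superclusters, file.path(dir, "superclusters.tsv"))
  writeLines(c("# Annotation report", "", paste("-", report$summary)),
             file.path(dir, "summary.md"))
  invisible(dir)
}
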