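# Test of reliability: a potential coding sequence is "complete" when trace
# coverage is available for every CDS nucleotide, otherwise "putative" and
# excluded from all downstream analyses.

#' Classify coding sequences by trace-coverage reliability
#'
#' For each record, a verdict of `"complete"` (every CDS position covered by
#' at least `min_depth` traces) or `"putative"` (at least one uncovered
#' position). The verdict is monotone in coverage: adding coverage can never
#' turn a complete record putative.
#'
#' @param records A `cgap_records` tibble.
#' @param tracks A coverage tibble from [coverage_tracks()]; every record
#'   needs a track of exactly its CDS length.
#' @param min_depth Minimum per-base depth counting as covered (default 1).
#' @return Tibble with columns `record_id`, `status`
#'   (`complete`/`putative`), `n_uncovered`, and list-column
#'   `uncovered_positions` (0-based CDS positions).
#' @export
classify_reliability <- function(records, tracks, min_depth = 1L) {
  idx <- match(records$id, tracks$record_id)
  if (anyNA(idx)) {
    abort(sprintf("no coverage track for record %s",
                  records$id[which(is.na(idx))[1L]]))
  }
  out <- purrr::map2(records$id, idx, function(id, i) {
    cov <- tracks$coverage[[i]]
    n <- nchar(records$cds[match(id, records$id)])
    if (length(cov) != n) {
      abort(sprintf("record %s: coverage length %d != CDS length %d",
                    id, length(cov), n))
    }
    unc <- which(cov < min_depth) - 1L
    tibble(record_id = id,
           status = if (length(unc)) "putative" else "complete",
           n_uncovered = length(unc),
           uncovered_positions = list(unc))
  })
  dplyr::bind_rows(out)
}

#' Apply reliability verdicts to a record set
#'
#' Writes each verdict's status into the record table so downstream stages
#' can drop putative records.
#'
#' @param records A `cgap_records` tibble.
#' @param verdicts Output of [classify_reliability()].
#' @return The record tibble with `status` updated.
#' @export
apply_reliability <- function(records, verdicts) {
  idx <- match(records$id, verdicts$record_id)
  records$status <- ifelse(is.na(idx), records$status, verdicts$status[idx])
  records
}

#' Summarize reliability verdicts
#'
#' @param verdicts Output of [classify_reliability()].
#' @return One-row tibble with `n_potential`, `n_complete`, `n_putative`
#'   (`n_potential = n_complete + n_putative`).
#' @export
summarize_reliability <- function(verdicts) {
  tibble(
    n_potential = nrow(verdicts),
    n_complete = sum(verdicts$status == "complete"),
    n_putative = sum(verdicts$status == "putative")
  )
}
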