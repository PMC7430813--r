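# Test of contiguity: pairwise genomic alignment of the base-taxon contig
# against orthologous contigs, detection of common (conserved) regions under
# taxon-tiered windowed-identity cutoffs, and verification that coding exons
# appear in the expected number, order and relative orientation. The aligner
# is a seed-and-chain design: exact k-mer anchors on both strands, collapsed
# along diagonals, chained into orientation-homogeneous co-linear blocks,
# with inter-anchor gaps closed by global alignment. Only the windowed
# identity over the resulting pairwise alignment feeds the test.

#' Contiguity cutoff tier for a taxon
#'
#' Resolves the taxon (or group) to its windowed-identity detection cutoff;
#' unmatched taxa receive the fallback tier (default 70% over 100 bp).
#'
#' @param taxon Species or group name, e.g. `"Pan troglodytes"`.
#' @param config A [protocol_config()].
#' @return List with `identity` (fraction) and `window_bp`.
#' @export
cutoff_for <- function(taxon, config = protocol_config()) {
  tab <- config$contiguity_cutoffs
  for (i in seq_len(nrow(tab))) {
    if (grepl(tab$group[i], taxon)) {
      return(list(identity = tab$identity[i], window_bp = as.integer(tab$window_bp[i])))
    }
  }
  list(identity = config$contiguity_fallback$identity,
       window_bp = as.integer(config$contiguity_fallback$window_bp))
}

seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  substring(x, 1:(n - k + 1L), k:n)
}

# exact k-mer anchors of base vs target (one strand), collapsed along
# diagonals into maximal exact runs; coordinates 0-based half-open
collapse_anchors <- function(bpos, tpos, k) {
  if (!length(bpos)) {
    return(tibble(bstart = integer(), bend = integer(),
                  tstart = integer(), tend = integer()))
  }
  diag <- tpos - bpos
  ord <- order(diag, bpos)
  bpos <- bpos[ord]; tpos <- tpos[ord]; diag <- diag[ord]
  new_run <- c(TRUE, diff(diag) != 0L | diff(bpos) > k)
  grp <- cumsum(new_run)
  tibble(
    bstart = as.integer(tapply(bpos, grp, min)) - 1L,
    bend = as.integer(tapply(bpos, grp, max)) + k - 1L,
    tstart = as.integer(tapply(tpos, grp, min)) - 1L,
    tend = as.integer(tapply(tpos, grp, max)) + k - 1L
  )
}

# weighted co-linear chaining (best chain peeled off repeatedly)
chain_segments <- function(seg, max_gap, max_indel) {
  blocks <- list()
  seg <- dplyr::arrange(seg, .data$bstart, .data$tstart)
  alive <- rep(TRUE, nrow(seg))
  while (any(alive)) {
    idx <- which(alive)
    s <- seg[idx, ]
    n <- nrow(s)
    len <- s$bend - s$bstart
    score <- len
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        bgap <- s$bstart[i] - s$bend[j]
        tgap <- s$tstart[i] - s$tend[j]
        if (bgap >= -5L && tgap >= -5L && bgap <= max_gap && tgap <= max_gap &&
            abs(bgap - tgap) <= max_indel) {
          cand <- score[j] + len[i]
          if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
        }
      }
    }
    best <- which.max(score)
    chain <- integer()
    at <- best
    while (at != 0L) { chain <- c(at, chain); at <- prev[at] }
    blocks[[length(blocks) + 1L]] <- s[chain, ]
    alive[idx[chain]] <- FALSE
  }
  blocks
}

nw_fill <- function(a, b) {
  # simple DNA global alignment for inter-anchor gaps
  if (nchar(a) == 0L && nchar(b) == 0L) return(list(a = "", b = ""))
  if (nchar(a) == 0L) return(list(a = strrep("-", nchar(b)), b = b))
  if (nchar(b) == 0L) return(list(a = a, b = strrep("-", nchar(a))))
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  S <- outer(av, bv, function(x, y) ifelse(x == y & x != "N" & y != "N", 1, -1))
  res <- nw_dp(S, 2, 0.5)
  pair <- path_to_pair(res$path, av, bv, "-")
  list(a = paste(pair$a, collapse = ""), b = paste(pair$b, collapse = ""))
}

build_block <- function(s, base, tgt_oriented, nt, orientation, max_fill) {
  # s: chained exact segments in working (possibly reverse-complemented)
  # target coordinates; returns one alignment block
  a_parts <- character(); b_parts <- character()
  pb <- s$bstart[1L]; pt <- s$tstart[1L]
  for (i in seq_len(nrow(s))) {
    bs <- s$bstart[i]; ts <- s$tstart[i]
    # trim overlap with what is already emitted
    trim <- max(pb - bs, pt - ts, 0L)
    bs <- bs + trim; ts <- ts + trim
    be <- s$bend[i]; te <- s$tend[i]
    if (be <= pb || te <= pt) next
    if (bs > pb || ts > pt) {
      ga <- substr(base, pb + 1L, bs)
      gb <- substr(tgt_oriented, pt + 1L, ts)
      if (nchar(ga) > max_fill || nchar(gb) > max_fill) {
        # should not happen given chaining max_gap; align as full gaps
        a_parts <- c(a_parts, ga, strrep("-", nchar(gb)))
        b_parts <- c(b_parts, strrep("-", nchar(ga)), gb)
      } else {
        fill <- nw_fill(ga, gb)
        a_parts <- c(a_parts, fill$a); b_parts <- c(b_parts, fill$b)
      }
    }
    a_parts <- c(a_parts, substr(base, bs + 1L, be))
    b_parts <- c(b_parts, substr(tgt_oriented, ts + 1L, te))
    pb <- be; pt <- te
  }
  a_aln <- paste(a_parts, collapse = "")
  b_aln <- paste(b_parts, collapse = "")
  wstart <- s$tstart[1L]; wend <- max(s$tend)
  if (orientation == "reverse") {
    t0 <- nt - wend; t1 <- nt - wstart
  } else {
    t0 <- wstart; t1 <- wend
  }
  tibble(
    base_start = s$bstart[1L], base_end = max(s$bend),
    target_start = as.integer(t0), target_end = as.integer(t1),
    orientation = orientation,
    base_aln = a_aln, target_aln = b_aln
  )
}

#' Pairwise genomic alignment as a chain of co-linear blocks
#'
#' Seeds exact `k`-mer anchors on both strands of the target, collapses them
#' along diagonals, chains them into co-linear blocks (maximum anchored
#' length, deterministic), and closes inter-anchor gaps with global
#' alignment. A rearranged or inverted region surfaces as its own
#' orientation-homogeneous block rather than being forced into one chain.
#'
#' @param base,target Contig sequences (strings) or one-row contig tibbles.
#' @param k Anchor k-mer size (default 12).
#' @param max_gap Maximum unanchored stretch chained through (default 400 bp).
#' @param max_indel Maximum base/target gap-length difference within a chain
#'   link (default 100 bp).
#' @param min_block Minimum anchored length for a reported block (default 30).
#' @return Tibble of blocks: base/target coordinates (0-based half-open,
#'   target coordinates always on the forward strand), `orientation`
#'   (`forward`/`reverse`), and the two aligned strings (reverse blocks are
#'   aligned in reverse-complemented target space). Zero rows when no anchors
#'   are found.
#' @export
pairwise_genomic_align <- function(base, target, k = 12L, max_gap = 400L,
                                   max_indel = 100L, min_block = 30L) {
  if (is.data.frame(base)) base <- base$sequence[1L]
  if (is.data.frame(target)) target <- target$sequence[1L]
  base <- toupper(base); target <- toupper(target)
  if (nchar(base) == 0L || nchar(target) == 0L) abort("empty contig")
  nt <- nchar(target)
  bk <- seq_kmers(base, k)
  empty <- tibble(base_start = integer(), base_end = integer(),
                  target_start = integer(), target_end = integer(),
                  orientation = character(),
                  base_aln = character(), target_aln = character())
  out <- list()
  for (orientation in c("forward", "reverse")) {
    tseq <- if (orientation == "forward") target else reverse_complement(target)
    tk <- seq_kmers(tseq, k)
    pos_by_kmer <- split(seq_along(tk), tk)
    hit <- bk %in% names(pos_by_kmer)
    if (!any(hit)) next
    bpos <- integer(); tpos <- integer()
    for (i in which(hit)) {
      tp <- pos_by_kmer[[bk[i]]]
      bpos <- c(bpos, rep.int(i, length(tp)))
      tpos <- c(tpos, tp)
    }
    seg <- collapse_anchors(bpos, tpos, k)
    blocks <- chain_segments(seg, max_gap, max_indel)
    for (s in blocks) {
      if (sum(s$bend - s$bstart) < min_block) next
      out[[length(out) + 1L]] <-
        build_block(s, base, tseq, nt, orientation, max_fill = 2L * max_gap)
    }
  }
  if (!length(out)) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$base_start)
}

#' Detect common (conserved) genomic regions in an alignment chain
#'
#' Within each block, marks the maximal runs of alignment columns in which
#' every full window of `window_bp` columns has nucleotide identity at or
#' above `identity` (window step 1; a column gapped in either row counts as
#' a mismatch). Runs shorter than one window cannot be reported.
#'
#' @param chain Output of [pairwise_genomic_align()].
#' @param identity,window_bp Cutoff tier, e.g. from [cutoff_for()].
#' @return Tibble of segments with base/target coordinates (0-based
#'   half-open), `orientation` and `mean_identity`.
#' @export
detect_conserved_regions <- function(chain, identity, window_bp = 100L) {
  out <- list()
  for (b in seq_len(nrow(chain))) {
    a <- strsplit(chain$base_aln[b], "")[[1L]]
    t <- strsplit(chain$target_aln[b], "")[[1L]]
    L <- length(a)
    if (L < window_bp) next
    m <- as.integer(a == t & a != "-" & t != "-")
    cs <- c(0L, cumsum(m))
    starts <- 1:(L - window_bp + 1L)
    wid <- cs[starts + window_bp] - cs[starts]
    pass <- wid >= identity * window_bp - 1e-9
    if (!any(pass)) next
    covered <- logical(L)
    for (s in starts[pass]) covered[s:(s + window_bp - 1L)] <- TRUE
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    begins <- ends - runs$lengths + 1L
    base_off <- cumsum(a != "-") # columns -> base offset within block
    tgt_off <- cumsum(t != "-")
    for (r in which(runs$values)) {
      c0 <- begins[r]; c1 <- ends[r]
      bs <- chain$base_start[b] + (if (c0 == 1L) 0L else base_off[c0 - 1L])
      be <- chain$base_start[b] + base_off[c1]
      # target offsets are in block working orientation
      ts_w <- (if (c0 == 1L) 0L else tgt_off[c0 - 1L])
      te_w <- tgt_off[c1]
      if (chain$orientation[b] == "reverse") {
        wlen <- chain$target_end[b] - chain$target_start[b]
        ts <- chain$target_start[b] + (wlen - te_w)
        te <- chain$target_start[b] + (wlen - ts_w)
      } else {
        ts <- chain$target_start[b] + ts_w
        te <- chain$target_start[b] + te_w
      }
      out[[length(out) + 1L]] <- tibble(
        base_start = as.integer(bs), base_end = as.integer(be),
        target_start = as.integer(ts), target_end = as.integer(te),
        orientation = chain$orientation[b],
        mean_identity = (cs[c1 + 1L] - cs[c0]) / (c1 - c0 + 1L)
      )
    }
  }
  if (!length(out)) {
    return(tibble(base_start = integer(), base_end = integer(),
                  target_start = integer(), target_end = integer(),
                  orientation = character(), mean_identity = double()))
  }
  segs <- dplyr::arrange(dplyr::bind_rows(out), .data$base_start)
  # merge segments that touch on the base (possible across block boundaries)
  merged <- segs[1L, ]
  for (i in seq_len(nrow(segs))[-1L]) {
    last <- nrow(merged)
    if (segs$base_start[i] <= merged$base_end[last] &&
        segs$orientation[i] == merged$orientation[last]) {
      merged$base_end[last] <- max(merged$base_end[last], segs$base_end[i])
      merged$target_start[last] <- min(merged$target_start[last], segs$target_start[i])
      merged$target_end[last] <- max(merged$target_end[last], segs$target_end[i])
      merged$mean_identity[last] <- max(merged$mean_identity[last], segs$mean_identity[i])
    } else {
      merged <- dplyr::bind_rows(merged, segs[i, ])
    }
  }
  merged
}

#' Contiguity verdict for one gene model
#'
#' For every coding exon of the base gene model, the exon is conserved in a
#' target taxon when it overlaps (by at least `config$min_overlap` bp) a
#' conserved segment detected at that taxon's cutoff tier. The gene is
#' `consistent` when the number of conserved exons equals the expected exon
#' count, all supporting segments agree in orientation, and the exons'
#' target positions follow the base physical order; anything else is a
#' `misassembly`, with a `defect_hint` when the pattern matches a known
#' defect signature.
#'
#' @param record One-row slice of a `cgap_records` tibble (the base gene).
#' @param chains Named list, taxon -> alignment chain of the base contig
#'   against that taxon's orthologous contig.
#' @param config A [protocol_config()].
#' @param expected_exons Expected coding-exon count (defaults to the number
#'   of exons in the model; pass the family's known count to catch losses).
#' @param min_targets How many target taxa must confirm an exon (default 1).
#' @return One-row tibble: `record_id`, `expected_exons`, `conserved_exons`,
#'   `orientations_consistent`, `order_consistent`, `verdict`, `defect_hint`.
#' @export
test_contiguity <- function(record, chains, config = protocol_config(),
                            expected_exons = NULL, min_targets = 1L) {
  ex <- record$exons[[1L]]
  expected <- as.integer(expected_exons %||% nrow(ex))
  n_ex <- nrow(ex)
  support <- matrix(0L, n_ex, length(chains)) # overlap bp
  orient <- matrix(NA_character_, n_ex, length(chains))
  tmid <- matrix(NA_real_, n_ex, length(chains))
  for (ti in seq_along(chains)) {
    cut <- cutoff_for(names(chains)[ti], config)
    segs <- detect_conserved_regions(chains[[ti]], cut$identity, cut$window_bp)
    if (!nrow(segs)) next
    for (e in seq_len(n_ex)) {
      ov <- pmin(segs$base_end, ex$end[e]) - pmax(segs$base_start, ex$start[e])
      best <- which(ov >= config$min_overlap)
      if (length(best)) {
        best <- best[which.max(ov[best])]
        support[e, ti] <- ov[best]
        orient[e, ti] <- segs$orientation[best]
        tmid[e, ti] <- (segs$target_start[best] + segs$target_end[best]) / 2
      }
    }
  }
  conserved <- rowSums(support >= config$min_overlap) >= min_targets
  n_conserved <- sum(conserved)
  # orientation consistency: within each target, all supported exons must
  # share one orientation
  orientations_consistent <- TRUE
  for (ti in seq_along(chains)) {
    o <- orient[, ti]
    o <- o[!is.na(o)]
    if (length(unique(o)) > 1L) orientations_consistent <- FALSE
  }
  # order consistency: in base physical order, target positions monotone
  order_consistent <- TRUE
  phys <- order(ex$start)
  for (ti in seq_along(chains)) {
    tm <- tmid[phys, ti]
    tm <- tm[!is.na(tm)]
    if (length(tm) >= 2L && is.unsorted(tm) && is.unsorted(rev(tm))) {
      order_consistent <- FALSE
    }
  }
  verdict <- if (n_conserved == expected && orientations_consistent &&
                 order_consistent) "consistent" else "misassembly"
  hint <- NA_character_
  if (verdict == "misassembly") {
    hint <- if (!orientations_consistent) "inversion"
            else if (!order_consistent) "reorder"
            else "missing_exon"
  }
  tibble(
    record_id = record$id[1L], expected_exons = expected,
    conserved_exons = n_conserved,
    orientations_consistent = orientations_consistent,
    order_consistent = order_consistent,
    verdict = verdict, defect_hint = hint
  )
}

#' Run the contiguity test for a base gene against orthologous contigs
#'
#' Convenience wrapper: aligns the base record's contig against each target
#' contig and evaluates [test_contiguity()].
#'
#' @param record One-row `cgap_records` slice (base gene).
#' @param base_contig Sequence (string or one-row contig tibble) of the
#'   contig carrying the record's exons.
#' @param target_contigs Contig tibble (columns `taxon`, `sequence`) of
#'   orthologous genomic sequences.
#' @inheritParams test_contiguity
#' @return One-row verdict tibble (see [test_contiguity()]).
#' @export
run_contiguity <- function(record, base_contig, target_contigs,
                           config = protocol_config(),
                           expected_exons = NULL, min_targets = 1L) {
  chains <- lapply(seq_len(nrow(target_contigs)), function(i) {
    pairwise_genomic_align(base_contig, target_contigs$sequence[i])
  })
  names(chains) <- target_contigs$taxon
  test_contiguity(record, chains, config,
                  expected_exons = expected_exons, min_targets = min_targets)
}
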