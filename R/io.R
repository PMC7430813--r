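# Readers and writers for the on-disk formats: FASTA + GFF3 (gene models),
# EMBL flat files (best-effort CDS join() reader), coverage tracks
# (bedGraph or long TSV), alignments (FASTA), trees (Newick), tables (TSV).
# GFF3 is 1-based closed on disk, 0-based half-open in memory.

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a coding-sequence dataset from FASTA + GFF3
#'
#' Assembles one record per gene model from CDS features. Features sharing a
#' `Parent` (or, failing that, `ID`) attribute form one model; minus-strand
#' models are reverse-complemented into the spliced CDS. Optional attributes
#' `taxon`, `cluster` and `supercluster` populate record metadata. Records
#' whose spliced CDS length is not a multiple of 3 are rejected with a logged
#' reason; a CDS feature naming a contig absent from the FASTA is an error.
#'
#' @param fasta Path to contig FASTA.
#' @param gff3 Path to GFF3 with CDS features.
#' @return A `cgap_records` tibble.
#' @export
read_dataset <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (!length(gr)) abort("no CDS features in GFF3")
  meta <- as.data.frame(gr)
  key <- rep(NA_character_, nrow(meta))
  if ("Parent" %in% names(meta)) {
    p <- vapply(meta$Parent, function(x) if (length(x)) as.character(x)[1L] else NA_character_,
                character(1))
    key <- ifelse(is.na(key), p, key)
  }
  if ("ID" %in% names(meta)) key <- ifelse(is.na(key), as.character(meta$ID), key)
  if (anyNA(key)) abort("CDS feature without Parent or ID attribute")

  grab <- function(col, rows) {
    if (col %in% names(meta)) as.character(meta[[col]][rows])[1L] else NA_character_
  }
  records <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    contig <- as.character(meta$seqnames[rows])
    if (!all(contig %in% names(seqs))) {
      abort(sprintf("record %s: contig '%s' missing from FASTA",
                    k, setdiff(contig, names(seqs))[1L]))
    }
    strand <- as.character(meta$strand[rows])[1L]
    # to 0-based half-open
    start0 <- meta$start[rows] - 1L
    end0 <- meta$end[rows]
    ord <- order(start0)
    if (strand == "-") ord <- rev(ord)
    rows <- rows[ord]; contig <- contig[ord]
    start0 <- start0[ord]; end0 <- end0[ord]
    pieces <- vapply(seq_along(rows), function(i) {
      as.character(Biostrings::subseq(seqs[[contig[i]]], start0[i] + 1L, end0[i]))
    }, character(1))
    if (strand == "-") pieces <- reverse_complement(pieces)
    cds <- toupper(paste(pieces, collapse = ""))
    if (nchar(cds) %% 3L != 0L || nchar(cds) == 0L) {
      inform(sprintf("[reject] %s: rule=cds_length_multiple_of_3 length=%d",
                     k, nchar(cds)))
      next
    }
    records[[k]] <- tibble(
      id = k,
      taxon = grab("taxon", rows) %||% NA_character_,
      cluster_label = grab("cluster", rows),
      supercluster_label = grab("supercluster", rows),
      status = "potential",
      cds = cds,
      exons = list(tibble(contig_id = contig, start = as.integer(start0),
                          end = as.integer(end0), strand = strand))
    )
  }
  if (!length(records)) abort("no valid records in dataset")
  out <- dplyr::bind_rows(records)
  class(out) <- c("cgap_records", class(out))
  validate_records(out)
}

#' Write a record set as FASTA + GFF3
#'
#' Inverse of [read_dataset()] for records carrying contig sequences: writes
#' the supplied contigs and a GFF3 of CDS features (1-based closed
#' coordinates) with `taxon`/`cluster`/`supercluster` attributes.
#'
#' @param records A `cgap_records` tibble.
#' @param contigs Contig tibble from [genomic_contigs()] covering every exon.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(records, contigs, fasta, gff3) {
  seqs <- Biostrings::DNAStringSet(setNames(contigs$sequence, contigs$id))
  Biostrings::writeXStringSet(seqs, fasta)
  lines <- c("##gff-version 3")
  for (k in seq_len(nrow(records))) {
    ex <- records$exons[[k]]
    attr_extra <- ""
    if (!is.na(records$taxon[k])) {
      attr_extra <- paste0(attr_extra, ";taxon=", records$taxon[k])
    }
    if (!is.na(records$cluster_label[k])) {
      attr_extra <- paste0(attr_extra, ";cluster=", records$cluster_label[k])
    }
    if (!is.na(records$supercluster_label[k])) {
      attr_extra <- paste0(attr_extra, ";supercluster=", records$supercluster_label[k])
    }
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        ex$contig_id[i], "cgap", "CDS",
        ex$start[i] + 1L, ex$end[i], ".", ex$strand[i], "0",
        paste0("ID=", records$id[k], ".cds", i, ";Parent=", records$id[k], attr_extra),
        sep = "\t"
      ))
    }
  }
  writeLines(lines, gff3)
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read CDS records from an EMBL flat file
#'
#' Best-effort reader for standard EMBL entries: one record per `CDS` feature
#' (plain span, `join(...)`, or `complement(join(...))`), sequence taken from
#' the entry's `SQ` block, taxon from the `OS` line. Coordinates are EMBL
#' 1-based closed, converted internally to 0-based half-open.
#'
#' @param path Path to an EMBL flat file (possibly multi-entry).
#' @return A `cgap_records` tibble.
#' @export
read_embl_cds <- function(path) {
  txt <- readLines(path)
  breaks <- c(0L, which(txt == "//"))
  records <- list()
  for (e in seq_len(length(breaks) - 1L)) {
    entry <- txt[(breaks[e] + 1L):(breaks[e + 1L] - 1L)]
    id_line <- grep("^ID ", entry, value = TRUE)
    acc <- if (length(id_line)) sub("^ID\\s+([^;\\s]+).*$", "\\1", id_line[1L]) else sprintf("entry%d", e)
    os_line <- grep("^OS ", entry, value = TRUE)
    taxon <- if (length(os_line)) trimws(sub("^OS\\s+", "", os_line[1L])) else NA_character_
    sq_at <- grep("^SQ ", entry)
    if (!length(sq_at)) abort(sprintf("entry %s: no SQ sequence block", acc))
    seq_lines <- entry[(sq_at[1L] + 1L):length(entry)]
    seq <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
    ft <- grep("^FT ", entry, value = TRUE)
    cds_at <- grep("^FT   CDS ", ft)
    if (!length(cds_at)) next
    # location may continue over lines until a qualifier (FT ... /xxx) starts
    for (ci in seq_along(cds_at)) {
      i <- cds_at[ci]
      loc <- sub("^FT\\s+CDS\\s+", "", ft[i])
      j <- i + 1L
      while (j <= length(ft) && !grepl("^FT\\s+/", ft[j]) &&
             !grepl("^FT   [A-Za-z]", ft[j])) {
        loc <- paste0(loc, trimws(sub("^FT\\s+", "", ft[j])))
        j <- j + 1L
      }
      comp <- grepl("complement", loc)
      spans <- stringr::str_match_all(loc, "(\\d+)\\.\\.(\\d+)")[[1L]]
      if (!nrow(spans)) next
      start0 <- as.integer(spans[, 2L]) - 1L
      end0 <- as.integer(spans[, 3L])
      pieces <- substring(seq, start0 + 1L, end0)
      cds <- if (comp) paste(rev(reverse_complement(pieces)), collapse = "")
             else paste(pieces, collapse = "")
      rid <- if (length(cds_at) > 1L) sprintf("%s.%d", acc, ci) else acc
      if (nchar(cds) %% 3L != 0L || nchar(cds) == 0L) {
        inform(sprintf("[reject] %s: rule=cds_length_multiple_of_3 length=%d",
                       rid, nchar(cds)))
        next
      }
      ord <- order(start0)
      if (comp) ord <- rev(ord)
      records[[rid]] <- tibble(
        id = rid, taxon = taxon,
        cluster_label = NA_character_, supercluster_label = NA_character_,
        status = "potential", cds = cds,
        exons = list(tibble(contig_id = acc, start = start0[ord], end = end0[ord],
                            strand = if (comp) "-" else "+"))
      )
    }
  }
  if (!length(records)) abort("no CDS records parsed from EMBL file")
  out <- dplyr::bind_rows(records)
  class(out) <- c("cgap_records", class(out))
  validate_records(out)
}

#' Read/write coverage tracks
#'
#' The TSV layout is long format with columns `record_id`, `pos` (0-based CDS
#' position) and `depth`; bedGraph input (`chrom start end value`, 0-based
#' half-open, chrom = record id) is also accepted by [read_coverage()] and
#' expanded per base.
#'
#' @param tracks Coverage tibble from [coverage_tracks()].
#' @param path File path.
#' @return [read_coverage()] returns a coverage tibble; [write_coverage()]
#'   returns the path invisibly.
#' @export
write_coverage <- function(tracks, path) {
  long <- tidyr::unnest(
    dplyr::mutate(tracks, pos = purrr::map(.data$coverage, ~ seq_along(.x) - 1L)),
    c("pos", "coverage")
  )
  out <- long[, c("record_id", "pos", "coverage")]
  names(out)[3L] <- "depth"
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  first <- readLines(path, n = 1L)
  nfield <- length(strsplit(first, "\t")[[1L]])
  if (nfield == 4L) {
    df <- readr::read_tsv(path, col_names = c("record_id", "start", "end", "depth"),
                          show_col_types = FALSE)
    df <- tidyr::uncount(df, weights = .data$end - .data$start, .id = "off")
    df$pos <- df$start + df$off - 1L
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    names(df) <- c("record_id", "pos", "depth")
    if (is.character(df$pos)) { # header-less file
      df <- readr::read_tsv(path, col_names = c("record_id", "pos", "depth"),
                            show_col_types = FALSE)
    }
  }
  df <- dplyr::arrange(df, .data$record_id, .data$pos)
  out <- dplyr::summarise(dplyr::group_by(df, .data$record_id),
                          coverage = list(as.integer(.data$depth)),
                          .groups = "drop")
  coverage_tracks(out$record_id, out$coverage)
}

#' Write an alignment to FASTA
#'
#' @param aln A `cgap_codon_alignment`.
#' @param path Output path.
#' @param view `"codon"` (nucleotide rows with `---` gaps) or `"protein"`
#'   (single-letter rows, stop codons as `&`).
#' @return The path, invisibly.
#' @export
write_alignment <- function(aln, path, view = c("codon", "protein")) {
  view <- match.arg(view)
  rows <- if (view == "codon") {
    apply(aln$codons, 1L, paste, collapse = "")
  } else {
    apply(aln$protein, 1L, paste, collapse = "")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(rows), path)
  invisible(path)
}

#' Import an externally curated codon alignment
#'
#' Reads a FASTA nucleotide alignment (codon-aligned, gaps in multiples of
#' 3) and validates it against a record set: every row must de-gap exactly to
#' its record's CDS. This is the route for manually corrected alignments.
#'
#' @param path FASTA alignment path.
#' @param records A `cgap_records` tibble with matching ids, or `NULL` to
#'   skip de-gap validation.
#' @param reference_id Reference record id (default first row).
#' @return A `cgap_codon_alignment`.
#' @export
accept_external_alignment <- function(path, records = NULL, reference_id = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  rows <- toupper(as.character(seqs))
  wid <- unique(nchar(rows))
  if (length(wid) != 1L) abort("alignment rows differ in length")
  if (wid %% 3L != 0L) abort("alignment width is not a multiple of 3")
  ncol <- wid %/% 3L
  cells <- t(vapply(rows, function(r) {
    substring(r, seq(1L, wid, 3L), seq(3L, wid, 3L))
  }, character(ncol)))
  if (any(!(cells == "---" | cells %in% names(.genetic_code)))) {
    abort("alignment contains frame-breaking gaps or invalid codons")
  }
  rownames(cells) <- names(seqs)
  aln <- codon_alignment(cells, reference_id = reference_id %||% names(seqs)[1L])
  if (!is.null(records)) assert_degap_faithful(aln, records)
  aln
}

#' Write a tree to Newick / a results table to TSV
#'
#' Thin wrappers kept for a uniform I/O surface; empty tables are written as
#' a header-only file.
#'
#' @param tree An `ape::phylo` tree.
#' @param x A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_tree
#' @export
write_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
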