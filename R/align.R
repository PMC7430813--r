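# Codon-aware multiple alignment: complete coding sequences are translated,
# aligned at the amino-acid level by a progressive profile aligner (k-mer
# guide distances, UPGMA guide tree, profile-profile Needleman-Wunsch with
# affine gaps), and the nucleotide alignment is threaded back codon-wise.
# The aligner is deliberately interchangeable behind the codon-alignment
# contract: curated alignments enter through accept_external_alignment().

PROTEIN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                      "F","P","S","T","W","Y","V", STOP_SYMBOL)

# Substitution matrix over the 21-symbol alphabet; stop ("&") takes the
# terminator row/column of the source matrix.
protein_score_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- env[[name]]
  key <- ifelse(PROTEIN_ALPHABET == STOP_SYMBOL, "*", PROTEIN_ALPHABET)
  out <- m[key, key]
  dimnames(out) <- list(PROTEIN_ALPHABET, PROTEIN_ALPHABET)
  out
}

path_to_pair <- function(path, a_items, b_items, gap) {
  n <- length(path)
  arow <- rep(gap, n); brow <- rep(gap, n)
  ia <- 0L; ib <- 0L
  for (k in seq_len(n)) {
    mv <- path[k]
    if (mv == 1L) { ia <- ia + 1L; ib <- ib + 1L
      arow[k] <- a_items[ia]; brow[k] <- b_items[ib] }
    else if (mv == 2L) { ia <- ia + 1L; arow[k] <- a_items[ia] }
    else { ib <- ib + 1L; brow[k] <- b_items[ib] }
  }
  list(a = arow, b = brow)
}

#' Global protein alignment score (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment score of two protein strings; a gap of length
#' `k` costs `gap_open + gap_extend * (k - 1)`. Exposed mainly for
#' transparency of the aligner's scoring core.
#'
#' @param a,b Protein strings.
#' @param matrix Substitution matrix name from Biostrings (e.g. `"BLOSUM62"`,
#'   `"BLOSUM50"`).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `score` and the two aligned strings.
#' @export
pairwise_protein_align <- function(a, b, matrix = "BLOSUM62",
                                   gap_open = 10, gap_extend = 0.5) {
  smat <- protein_score_matrix(matrix)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  S <- smat[av, bv, drop = FALSE]
  res <- nw_dp(S, gap_open, gap_extend)
  pair <- path_to_pair(res$path, av, bv, "-")
  list(score = res$score,
       a = paste(pair$a, collapse = ""), b = paste(pair$b, collapse = ""))
}

kmer_counts <- function(x, k = 3L) {
  n <- nchar(x)
  if (n < k) return(table(character()))
  table(substring(x, 1:(n - k + 1L), k:n))
}

kmer_distance_matrix <- function(proteins, k = 3L) {
  n <- length(proteins)
  counts <- lapply(proteins, kmer_counts, k = k)
  D <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    ci <- counts[[i]]; cj <- counts[[j]]
    common <- intersect(names(ci), names(cj))
    shared <- sum(pmin(ci[common], cj[common]))
    denom <- min(sum(ci), sum(cj))
    d <- 1 - if (denom > 0) shared / denom else 0
    D[i, j] <- D[j, i] <- d
  }
  D
}

profile_of <- function(mat) {
  # rows x columns character matrix -> columns x 21 frequency matrix
  # (gap fraction excluded; gaps score zero against anything)
  L <- ncol(mat)
  P <- matrix(0, L, length(PROTEIN_ALPHABET),
              dimnames = list(NULL, PROTEIN_ALPHABET))
  nr <- nrow(mat)
  for (a in PROTEIN_ALPHABET) P[, a] <- colSums(mat == a) / nr
  P
}

merge_profiles <- function(m1, m2, smat, gap_open, gap_extend) {
  S <- profile_of(m1) %*% smat %*% t(profile_of(m2))
  res <- nw_dp(S, gap_open, gap_extend)
  path <- res$path
  n <- length(path)
  out <- matrix("-", nrow(m1) + nrow(m2), n,
                dimnames = list(c(rownames(m1), rownames(m2)), NULL))
  i <- 0L; j <- 0L
  for (k in seq_len(n)) {
    mv <- path[k]
    if (mv != 3L) { i <- i + 1L; out[seq_len(nrow(m1)), k] <- m1[, i] }
    if (mv != 2L) { j <- j + 1L; out[nrow(m1) + seq_len(nrow(m2)), k] <- m2[, j] }
  }
  out
}

#' Progressive multiple protein alignment
#'
#' Aligns two or more proteins progressively: pairwise 3-mer distances build
#' a UPGMA guide tree, and profiles are merged along it with a
#' profile-profile Needleman-Wunsch (affine gaps; dynamic-programming ties
#' broken diagonal > up > left, so the result is deterministic).
#'
#' @param proteins Named character vector of protein strings (stops as `&`).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties (defaults 10 / 0.5).
#' @return Character matrix of aligned single-letter rows, rownames = ids.
#' @export
align_proteins <- function(proteins, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (length(proteins) < 2L) abort("need at least 2 sequences to align")
  if (any(nchar(proteins) == 0L)) abort("empty protein sequence")
  if (is.null(names(proteins))) names(proteins) <- paste0("seq", seq_along(proteins))
  smat <- protein_score_matrix(matrix)
  mats <- lapply(names(proteins), function(id) {
    matrix(strsplit(proteins[[id]], "")[[1L]], nrow = 1L,
           dimnames = list(id, NULL))
  })
  names(mats) <- names(proteins)
  if (length(proteins) == 2L) {
    return(merge_profiles(mats[[1L]], mats[[2L]], smat, gap_open, gap_extend))
  }
  D <- kmer_distance_matrix(proteins)
  hc <- hclust(as.dist(D), method = "average") # UPGMA
  nodes <- vector("list", nrow(hc$merge))
  leaf <- function(i) mats[[hc$labels[-i]]]
  for (s in seq_len(nrow(hc$merge))) {
    l <- hc$merge[s, 1L]; r <- hc$merge[s, 2L]
    m1 <- if (l < 0) leaf(l) else nodes[[l]]
    m2 <- if (r < 0) leaf(r) else nodes[[r]]
    nodes[[s]] <- merge_profiles(m1, m2, smat, gap_open, gap_extend)
  }
  out <- nodes[[length(nodes)]]
  out[names(proteins), , drop = FALSE]
}

#' Thread a codon alignment from a protein alignment
#'
#' Expands each aligned amino acid back to its source codon; protein gaps
#' become the `---` codon cell. Each protein row must be exactly the
#' translation of its record's CDS.
#'
#' @param protein_msa Character matrix from [align_proteins()] (rownames are
#'   record ids).
#' @param records A `cgap_records` tibble supplying each id's CDS.
#' @param reference_id Reference for the coordinate map (default first row).
#' @return A `cgap_codon_alignment`.
#' @export
thread_codons <- function(protein_msa, records, reference_id = rownames(protein_msa)[1L]) {
  ids <- rownames(protein_msa)
  cod <- matrix("---", length(ids), ncol(protein_msa), dimnames = list(ids, NULL))
  for (id in ids) {
    cds <- records$cds[match(id, records$id)]
    if (is.na(cds)) abort(sprintf("record %s missing from record set", id))
    codons <- split_codons(cds)
    row <- protein_msa[id, ]
    nongap <- which(row != "-")
    if (length(nongap) != length(codons)) {
      abort(sprintf("record %s: protein row does not match CDS codon count", id))
    }
    if (!identical(paste(row[nongap], collapse = ""), translate_cds(cds))) {
      abort(sprintf("record %s: protein row is not the translation of its CDS", id))
    }
    cod[id, nongap] <- codons
  }
  codon_alignment(cod, reference_id = reference_id)
}

#' Translate, align and thread a record set in one step
#'
#' The codon-aware alignment stage of the protocol: translates every record
#' (all must be reliability-complete if `complete_only = TRUE`), aligns the
#' proteins progressively and threads the codon alignment.
#'
#' @param records A `cgap_records` tibble.
#' @param reference_id Reference record id (default first record).
#' @param complete_only Drop records whose `status` is `"putative"` before
#'   aligning (default `TRUE`); putative sequences are excluded from all
#'   analyses.
#' @param ... Passed to [align_proteins()].
#' @return A `cgap_codon_alignment`.
#' @export
align_records <- function(records, reference_id = NULL, complete_only = TRUE, ...) {
  if (complete_only) records <- records[records$status != "putative", ]
  if (nrow(records) < 2L) abort("need at least 2 (non-putative) records")
  prot <- setNames(vapply(records$cds, translate_cds, character(1)), records$id)
  msa <- align_proteins(prot, ...)
  aln <- thread_codons(msa, records,
                       reference_id = reference_id %||% records$id[1L])
  assert_degap_faithful(aln, records)
  aln
}

#' Sum-of-pairs score of a protein alignment
#'
#' Scores every row pair on its pairwise projection (columns gapped in both
#' rows dropped) with the same substitution matrix and affine gap costs as
#' the aligner; used to compare alignments of the same sequences.
#'
#' @param protein_msa Character matrix of aligned rows.
#' @inheritParams align_proteins
#' @return Total sum-of-pairs score.
#' @export
alignment_sp_score <- function(protein_msa, matrix = "BLOSUM62",
                               gap_open = 10, gap_extend = 0.5) {
  smat <- protein_score_matrix(matrix)
  n <- nrow(protein_msa)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    a <- protein_msa[i, ]; b <- protein_msa[j, ]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    both <- a != "-" & b != "-"
    total <- total + sum(smat[cbind(a[both], b[both])])
    for (row in list(a, b)) {
      gap <- row == "-"
      if (any(gap)) {
        runs <- rle(gap)
        glen <- runs$lengths[runs$values]
        total <- total - sum(gap_open + gap_extend * (glen - 1))
      }
    }
  }
  total
}
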