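# Gene-family simulator with a machine-readable truth record. Emulates the
# statistical structure the protocol assumes: a hierarchy of superclusters,
# major gene clusters and per-species orthologues; CDS with 3 or 5 coding
# exons embedded in contigs; codon usage biased against a designed rare
# set; invariant amino-acid sites; per-base trace coverage with optional
# zero-coverage holes; and injectable exon misassemblies.

# Default designed rare codon set: the larger-family (>= 3 synonymous
# alternatives... i.e. family size >= 3) members typically under-used in
# mammalian coding sequence.
DEFAULT_RARE_CODONS <- c("TTA", "CTT", "CTA", "ATA", "GTT", "GTA",
                         "TCA", "TCG", "CCG", "ACG", "GCG",
                         "CGT", "CGA", "GGT")

# 10-taxon eutherian-like panel; ultrametric, root-to-tip depth 1, so the
# within-cluster divergence scale is the species-tree depth in
# substitutions/site.
DEFAULT_SPECIES_TREE <- paste0(
  "((((((Homo_sapiens:0.02,Pan_troglodytes:0.02):0.06,Pongo_abelii:0.08):0.07,",
  "Macaca_mulatta:0.15):0.1,Callithrix_jacchus:0.25):0.25,",
  "Microcebus_murinus:0.5):0.5,((Mus_musculus:0.35,Rattus_norvegicus:0.35):0.45,",
  "(Bos_taurus:0.55,Canis_lupus_familiaris:0.55):0.25):0.2);"
)

#' Gene-family simulation design
#'
#' Defines the study conditions for a simulated family. Divergence scales
#' must be strictly ordered `within_cluster < between_cluster <
#' between_supercluster` (expected substitution proposals per site for,
#' respectively, the species-tree depth inside a cluster, the split between
#' clusters of one supercluster, and the split between superclusters).
#'
#' @param n_superclusters,clusters_per_supercluster Family shape (defaults 2 x 2).
#' @param taxa Species names; default a 10-taxon eutherian-like panel whose
#'   names hit the tiered contiguity cutoffs.
#' @param exons_per_cluster Coding-exon counts, recycled over clusters
#'   (default alternating 3 and 5).
#' @param protein_length_range Reference protein length range in amino
#'   acids, stop excluded (default 200--260).
#' @param within_cluster,between_cluster,between_supercluster Divergence
#'   scales (defaults 0.05 / 0.25 / 0.5).
#' @param invariant_fraction Fraction of amino-acid positions designed
#'   invariant (default 0.3).
#' @param rare_codon_set Designed under-used codons; every member must have
#'   a synonymous family of at least 3 codons.
#' @param rare_codon_bias Multiplier `< 1` on the acceptance of substitutions
#'   creating a rare codon, and on the rare codons' weight when the ancestral
#'   sequence is drawn (default 0.15).
#' @param nonsyn_acceptance Acceptance probability of amino-acid-changing
#'   proposals at non-invariant sites (default 0.5; purifying selection).
#' @param kappa Transition/transversion proposal bias (default 2).
#' @param intron_length_range,spacer_length_range Intron and flanking spacer
#'   lengths in bp (defaults 150--300 and 200--400).
#' @param mean_depth,hole_probability Coverage simulation defaults (10 and 0).
#' @param species_tree Newick string; branch lengths are multiplied by
#'   `within_cluster`.
#' @return A list of class `cgap_design`.
#' @export
family_design <- function(n_superclusters = 2L,
                          clusters_per_supercluster = 2L,
                          taxa = NULL,
                          exons_per_cluster = c(3L, 5L),
                          protein_length_range = c(200L, 260L),
                          within_cluster = 0.05,
                          between_cluster = 0.25,
                          between_supercluster = 0.5,
                          invariant_fraction = 0.3,
                          rare_codon_set = DEFAULT_RARE_CODONS,
                          rare_codon_bias = 0.15,
                          nonsyn_acceptance = 0.5,
                          kappa = 2,
                          intron_length_range = c(150L, 300L),
                          spacer_length_range = c(200L, 400L),
                          mean_depth = 10,
                          hole_probability = 0,
                          species_tree = DEFAULT_SPECIES_TREE) {
  tree <- ape::read.tree(text = species_tree)
  if (is.null(taxa)) taxa <- tree$tip.label
  taxa <- gsub("[ ]+", "_", taxa) # tree labels use underscores
  if (!all(taxa %in% tree$tip.label)) abort("taxa must be tips of species_tree")
  if (!(within_cluster < between_cluster &&
        between_cluster < between_supercluster)) {
    abort("divergence scales must satisfy within < between-cluster < between-supercluster")
  }
  if (invariant_fraction < 0 || invariant_fraction > 1) {
    abort("invariant_fraction must be in [0, 1]")
  }
  bad <- rare_codon_set[.family_size[rare_codon_set] < 3L |
                          .genetic_code[rare_codon_set] == STOP_SYMBOL]
  if (length(bad)) {
    abort(sprintf("rare codon %s lacks >=2 synonymous alternatives", bad[1L]))
  }
  if (rare_codon_bias <= 0 || rare_codon_bias >= 1) {
    abort("rare_codon_bias must be in (0, 1)")
  }
  structure(
    list(n_superclusters = as.integer(n_superclusters),
         clusters_per_supercluster = as.integer(clusters_per_supercluster),
         taxa = taxa,
         exons_per_cluster = as.integer(exons_per_cluster),
         protein_length_range = as.integer(protein_length_range),
         within_cluster = within_cluster,
         between_cluster = between_cluster,
         between_supercluster = between_supercluster,
         invariant_fraction = invariant_fraction,
         rare_codon_set = rare_codon_set,
         rare_codon_bias = rare_codon_bias,
         nonsyn_acceptance = nonsyn_acceptance,
         kappa = kappa,
         intron_length_range = as.integer(intron_length_range),
         spacer_length_range = as.integer(spacer_length_range),
         mean_depth = mean_depth,
         hole_probability = hole_probability,
         species_tree = species_tree),
    class = "cgap_design"
  )
}

random_dna <- function(n) {
  paste(sample(NUC, n, replace = TRUE), collapse = "")
}

# ancestral codon sequence: ATG start, biased synonymous choice, terminal stop
draw_root_codons <- function(n_aa, design) {
  aas <- sample(setdiff(unique(unname(.genetic_code)), STOP_SYMBOL),
                n_aa - 1L, replace = TRUE)
  codons <- vapply(aas, function(a) {
    fam <- names(.genetic_code)[.genetic_code == a]
    w <- ifelse(fam %in% design$rare_codon_set, design$rare_codon_bias, 1)
    sample(fam, 1L, prob = w)
  }, character(1))
  c("ATG", unname(codons), sample(STOP_CODONS, 1L))
}

# one substitution proposal at nucleotide site `pos` of the codon vector
propose_base <- function(cur, kappa) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  others <- setdiff(NUC, c(cur, transitions[[cur]]))
  sample(c(transitions[[cur]], others), 1L,
         prob = c(kappa, 1, 1) / (kappa + 2))
}

# evolve a codon vector along one branch of expected length b proposals/site
evolve_codons <- function(codons, b, design, invariant_pos) {
  n_nt <- 3L * length(codons)
  n_events <- rpois(1L, b * n_nt)
  if (n_events == 0L) return(codons)
  sites <- sample.int(n_nt, n_events, replace = TRUE)
  stop_idx <- length(codons)
  for (s in sites) {
    ci <- (s - 1L) %/% 3L + 1L
    off <- (s - 1L) %% 3L + 1L
    old_codon <- codons[ci]
    old_base <- substr(old_codon, off, off)
    new_base <- propose_base(old_base, design$kappa)
    new_codon <- old_codon
    substr(new_codon, off, off) <- new_base
    old_aa <- .genetic_code[[old_codon]]
    new_aa <- .genetic_code[[new_codon]]
    if (ci == stop_idx) {
      if (new_aa != STOP_SYMBOL) next # terminal stop stays a stop
    } else {
      if (new_aa == STOP_SYMBOL) next # no internal stops
      if (old_aa != new_aa) {
        if (ci %in% invariant_pos) next
        if (runif(1L) > design$nonsyn_acceptance) next
      }
    }
    if (new_codon %in% design$rare_codon_set &&
        runif(1L) > design$rare_codon_bias) next
    codons[ci] <- new_codon
  }
  codons
}

evolve_along_tree <- function(root_codons, tree, scale, design, invariant_pos) {
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- root_codons
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    seqs[[edges[e, 2L]]] <- evolve_codons(seqs[[edges[e, 1L]]],
                                          lens[e] * scale, design, invariant_pos)
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

# split a CDS length into exon lengths (deterministic given the RNG state)
split_exons <- function(cds_len, n_exons) {
  if (n_exons == 1L) return(cds_len)
  base_len <- cds_len %/% n_exons
  jitter <- round(runif(n_exons - 1L, -0.1, 0.1) * base_len)
  lens <- rep(base_len, n_exons)
  lens[seq_len(n_exons - 1L)] <- lens[seq_len(n_exons - 1L)] + jitter
  lens[n_exons] <- cds_len - sum(lens[-n_exons])
  stopifnot(all(lens >= 60L))
  as.integer(lens)
}

#' Simulate a gene family
#'
#' Draws one ancestral codon sequence per family, evolves it to supercluster
#' and cluster ancestors and then along the species tree (scaled to the
#' within-cluster divergence), under a transition-biased nucleotide proposal
#' process that forbids internal stops and amino-acid changes at the designed
#' invariant positions, down-weights substitutions creating rare codons, and
#' thins amino-acid changes by the purifying acceptance. Each orthologue's
#' CDS is split into the cluster's exon count and embedded in a contig with
#' random intron/intergenic spacers; coverage tracks carry optional injected
#' zero-coverage holes. Deterministic for a fixed `(design, seed)`.
#'
#' @param design A [family_design()].
#' @param seed Integer seed.
#' @return List of class `cgap_sim` with `records` (a `cgap_records`
#'   tibble), `contigs`, `tracks`, and `truth` (species tree, cluster
#'   membership, designed invariant positions, rare codon set, injected
#'   coverage holes, misassembly slots all `"none"`).
#' @export
simulate_family <- function(design = family_design(), seed = 1L) {
  set.seed(seed)
  tree <- ape::read.tree(text = design$species_tree)
  tree <- ape::keep.tip(tree, design$taxa)
  n_aa <- sample(seq(design$protein_length_range[1L],
                     design$protein_length_range[2L]), 1L)
  n_codon <- n_aa + 1L # terminal stop
  invariant_pos <- sort(unique(c(
    1L, sample(2:n_aa, max(0L, round(design$invariant_fraction * n_aa) - 1L))
  )))
  root <- draw_root_codons(n_aa, design) # n_codon codons incl. terminal stop
  rec_rows <- list(); ctg_rows <- list(); trk_rows <- list()
  membership <- list(); holes <- list()
  n_clusters_total <- design$n_superclusters * design$clusters_per_supercluster
  exon_counts <- rep_len(design$exons_per_cluster, n_clusters_total)
  cl_i <- 0L
  for (s in seq_len(design$n_superclusters)) {
    sc_label <- sprintf("SC%d", s)
    sc_root <- evolve_codons(root, design$between_supercluster / 2,
                             design, invariant_pos)
    for (cc in seq_len(design$clusters_per_supercluster)) {
      cl_i <- cl_i + 1L
      cl_label <- sprintf("CL%d.%d", s, cc)
      cl_root <- evolve_codons(sc_root, design$between_cluster / 2,
                               design, invariant_pos)
      tips <- evolve_along_tree(cl_root, tree, design$within_cluster,
                                design, invariant_pos)
      n_ex <- exon_counts[cl_i]
      exon_lens <- split_exons(3L * n_codon, n_ex)
      for (tx in design$taxa) {
        cds <- paste(tips[[tx]], collapse = "")
        rid <- sprintf("%s_%s", cl_label, gsub("[^A-Za-z0-9]+", "_", tx))
        ctg_id <- paste0("ctg_", rid)
        spacers <- round(runif(2L, design$spacer_length_range[1L],
                               design$spacer_length_range[2L]))
        introns <- if (n_ex > 1L) {
          round(runif(n_ex - 1L, design$intron_length_range[1L],
                      design$intron_length_range[2L]))
        } else integer()
        pieces <- character(); pos <- 0L
        starts <- integer(n_ex); ends <- integer(n_ex)
        pieces <- c(pieces, random_dna(spacers[1L])); pos <- spacers[1L]
        off <- 0L
        for (e in seq_len(n_ex)) {
          starts[e] <- pos
          exon_seq <- substr(cds, off + 1L, off + exon_lens[e])
          pieces <- c(pieces, exon_seq)
          pos <- pos + exon_lens[e]; ends[e] <- pos
          off <- off + exon_lens[e]
          if (e < n_ex) {
            pieces <- c(pieces, random_dna(introns[e]))
            pos <- pos + introns[e]
          }
        }
        pieces <- c(pieces, random_dna(spacers[2L]))
        contig <- paste(pieces, collapse = "")
        cov <- 1L + rpois(nchar(cds), design$mean_depth - 1)
        hole_pos <- integer()
        if (design$hole_probability > 0 &&
            runif(1L) < design$hole_probability) {
          hlen <- sample(1:20, 1L)
          h0 <- sample.int(nchar(cds) - hlen + 1L, 1L)
          hole_pos <- (h0 - 1L):(h0 + hlen - 2L) # 0-based
          cov[hole_pos + 1L] <- 0L
        }
        rec_rows[[rid]] <- tibble(
          id = rid, taxon = tx, cluster_label = cl_label,
          supercluster_label = sc_label, status = "potential", cds = cds,
          exons = list(tibble(contig_id = ctg_id, start = starts,
                              end = ends, strand = "+"))
        )
        ctg_rows[[ctg_id]] <- tibble(
          id = ctg_id, taxon = tx, sequence = contig,
          role = if (tx == design$taxa[1L]) "base" else "target"
        )
        trk_rows[[rid]] <- tibble(record_id = rid, coverage = list(cov))
        membership[[rid]] <- tibble(record_id = rid, supercluster = sc_label,
                                    cluster = cl_label)
        if (length(hole_pos)) holes[[rid]] <- hole_pos
      }
    }
  }
  records <- dplyr::bind_rows(rec_rows)
  class(records) <- c("cgap_records", class(records))
  validate_records(records)
  truth <- list(
    species_tree = ape::write.tree(tree),
    cluster_membership = dplyr::bind_rows(membership),
    invariant_site_positions = invariant_pos,
    rare_codon_set = design$rare_codon_set,
    misassembly_injections = setNames(rep("none", nrow(records)), records$id),
    coverage_holes = holes,
    n_codon = n_codon
  )
  structure(
    list(records = records, contigs = dplyr::bind_rows(ctg_rows),
         tracks = dplyr::bind_rows(trk_rows), truth = truth,
         design = design, seed = seed),
    class = "cgap_sim"
  )
}

#' @export
print.cgap_sim <- function(x, ...) {
  cat(sprintf("<simulated family: %d records, %d contigs, seed %d>\n",
              nrow(x$records), nrow(x$contigs), x$seed))
  invisible(x)
}

#' Inject a coding-exon misassembly into a contig
#'
#' Creates the defect classes the contiguity test must detect: `inversion`
#' reverse-complements one exon in place; `exon_loss` deletes one exon span
#' (the annotated model loses that exon and downstream coordinates shift);
#' `reorder` exchanges the genomic positions of two exons (the model keeps
#' transcript order, so physical order no longer matches); `none` returns
#' the input unchanged.
#'
#' @param contig Contig sequence string.
#' @param exon_model Exon tibble (`start`, `end`, 0-based half-open, in
#'   transcript order on the forward strand).
#' @param defect One of `"inversion"`, `"exon_loss"`, `"reorder"`, `"none"`.
#' @param exon Index of the exon to mutate (default 2); for `reorder`, the
#'   exon exchanged with `exon2`.
#' @param exon2 Second exon for `reorder` (default `exon + 1`).
#' @return List with `sequence` (mutated contig) and `exons` (the annotated
#'   model after the defect).
#' @export
inject_misassembly <- function(contig, exon_model, defect, exon = 2L,
                               exon2 = exon + 1L) {
  defect <- match.arg(defect, c("inversion", "exon_loss", "reorder", "none"))
  if (defect == "none") return(list(sequence = contig, exons = exon_model))
  n_ex <- nrow(exon_model)
  if (defect == "reorder" && n_ex < 2L) abort("reorder needs >= 2 exons")
  if (exon > n_ex || (defect == "reorder" && exon2 > n_ex)) {
    abort("exon index out of range")
  }
  s <- exon_model$start[exon]; e <- exon_model$end[exon]
  if (defect == "inversion") {
    inv <- reverse_complement(substr(contig, s + 1L, e))
    seq <- paste0(substr(contig, 1L, s), inv,
                  substr(contig, e + 1L, nchar(contig)))
    return(list(sequence = seq, exons = exon_model))
  }
  if (defect == "exon_loss") {
    seq <- paste0(substr(contig, 1L, s), substr(contig, e + 1L, nchar(contig)))
    len <- e - s
    ex <- exon_model[-exon, ]
    shift <- ex$start >= e
    ex$start[shift] <- ex$start[shift] - len
    ex$end[shift] <- ex$end[shift] - len
    return(list(sequence = seq, exons = ex))
  }
  # reorder: exchange the genomic contents of exon and exon2
  i <- min(exon, exon2); j <- max(exon, exon2)
  si <- exon_model$start[i]; ei <- exon_model$end[i]
  sj <- exon_model$start[j]; ej <- exon_model$end[j]
  blk_i <- substr(contig, si + 1L, ei)
  blk_j <- substr(contig, sj + 1L, ej)
  seq <- paste0(substr(contig, 1L, si), blk_j,
                substr(contig, ei + 1L, sj), blk_i,
                substr(contig, ej + 1L, nchar(contig)))
  delta <- nchar(blk_j) - nchar(blk_i)
  ex <- exon_model
  # transcript exon i's content now ends where exon j ended; exon j's
  # content sits at exon i's old start
  ex$start[i] <- sj + delta; ex$end[i] <- ej
  ex$start[j] <- si; ex$end[j] <- si + nchar(blk_j)
  # middle exons shift by delta
  if (j - i > 1L) {
    mid <- (i + 1L):(j - 1L)
    ex$start[mid] <- ex$start[mid] + delta
    ex$end[mid] <- ex$end[mid] + delta
  }
  list(sequence = seq, exons = ex)
}

#' Simulate a coverage track
#'
#' Per-base depths are `1 + Poisson(mean_depth - 1)` so every position is
#' covered unless a hole is injected; with probability `hole_probability`
#' one contiguous run of 1--20 positions is zeroed.
#'
#' @param cds_length CDS length in nucleotides.
#' @param mean_depth Mean depth (> 0).
#' @param hole_probability Probability of injecting one zero-coverage run.
#' @param seed Integer seed.
#' @return List with `coverage` (integer vector) and `hole_positions`
#'   (0-based, possibly empty).
#' @export
simulate_coverage <- function(cds_length, mean_depth = 10,
                              hole_probability = 0, seed = 1L) {
  if (mean_depth <= 0) abort("mean_depth must be > 0")
  set.seed(seed)
  cov <- 1L + rpois(cds_length, max(mean_depth - 1, 0))
  hole_pos <- integer()
  if (hole_probability > 0 && runif(1L) < hole_probability) {
    hlen <- sample(1:20, 1L)
    h0 <- sample.int(cds_length - hlen + 1L, 1L)
    hole_pos <- (h0 - 1L):(h0 + hlen - 2L)
    cov[hole_pos + 1L] <- 0L
  }
  list(coverage = cov, hole_positions = hole_pos)
}

#' Write a simulated family to disk
#'
#' Writes contig FASTA, gene-model GFF3, a coverage TSV and `truth.json`
#' into a directory; the FASTA/GFF3 pair round-trips through
#' [read_dataset()].
#'
#' @param sim A `cgap_sim`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(sim$records, sim$contigs,
                file.path(dir, "contigs.fasta"), file.path(dir, "models.gff3"))
  write_coverage(sim$tracks, file.path(dir, "coverage.tsv"))
  truth <- sim$truth
  truth$cluster_membership <- as.list(setNames(
    purrr::map2(truth$cluster_membership$supercluster,
                truth$cluster_membership$cluster, c),
    truth$cluster_membership$record_id
  ))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
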