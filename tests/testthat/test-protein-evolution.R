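test_that("uniform synonymous usage gives R = 1 everywhere, no not-preferable", {
  # one copy of each sense codon: every family is perfectly uniform
  rec <- cds_records("u1", "t", paste(SENSE_CODONS <- cgap:::SENSE_CODONS,
                                      collapse = ""))
  ru <- codon_usage(rec, complete_only = FALSE)
  sense <- ru$table[ru$table$amino_acid != "&", ]
  expect_true(all(sense$R == 1))
  expect_length(ru$not_preferable, 0L)
})

test_that("R = count / (family total / family size), threshold at 0.7", {
  # counts TTT:3, TTC:1 -> family total 4, expected 2 each
  cells <- matrix(c("TTT", "TTT", "TTT", "TTC"), nrow = 2,
                  dimnames = list(c("a", "b"), NULL))
  ru <- codon_usage(codon_alignment(cells))
  tab <- ru$table
  expect_equal(tab$R[tab$codon == "TTT"], 1.5)
  expect_equal(tab$R[tab$codon == "TTC"], 0.5)
  expect_true("TTC" %in% ru$not_preferable)
  expect_false("TTT" %in% ru$not_preferable)
})

test_that("RSCU family means equal 1 and stops are never not-preferable", {
  for (seed in c(2, 9)) {
    sim <- simulate_family(test_design(), seed = seed)
    ru <- codon_usage(sim$records, complete_only = FALSE)
    tab <- ru$table[!is.na(ru$table$R), ]
    fam_means <- tapply(tab$R, tab$amino_acid, mean)
    expect_equal(as.numeric(fam_means), rep(1, length(fam_means)))
    # single-codon families are pinned at R = 1
    expect_equal(tab$R[tab$codon %in% c("ATG", "TGG")], c(1, 1))
    expect_false(any(cgap:::STOP_CODONS %in% ru$not_preferable))
    expect_true(all(tab$R >= 0))
    # per-family expected counts sum to observed counts
    sums <- dplyr::summarise(dplyr::group_by(ru$table, amino_acid),
                             ok = sum(expected) == sum(count))
    expect_true(all(sums$ok))
  }
})

test_that("site classes follow the invariant/forward/compensatory definitions", {
  # Leu pool 9 CTG : 1 TTA -> R(TTA) = 1 / (10/6) = 0.6 <= 0.7
  np_source <- codon_alignment(matrix(c(rep("CTG", 9), "TTA"), 2,
                                      dimnames = list(c("x", "y"), NULL)))
  ru <- codon_usage(np_source)
  expect_true("TTA" %in% ru$not_preferable)
  expect_false("CTG" %in% ru$not_preferable)
  # column 1 invariant M; column 2 variant K/R all preferable; column 3
  # variant (Leu/Val) including the not-preferable Leu codon TTA
  aln <- toy_codon_alignment(c(r1 = "ATGAAACTG", r2 = "ATGAGAGTG",
                               r3 = "ATGAAATTA"))
  sites <- classify_sites(aln, ru)
  expect_equal(sites$label, c("invariant", "forward", "compensatory"))
  expect_equal(sites$ref_pos, 1:3)
  # every reference site receives exactly one label
  expect_equal(nrow(sites), 3L)
  expect_true(all(sites$label %in% c("invariant", "forward", "compensatory")))
})

test_that("gapped rows are excluded per site (near-universal invariants)", {
  # one member lacks the initiator column; the site stays invariant across
  # the members that do align there
  cells <- matrix(c("ATG", "ATG", "---", "AAA", "AAA", "AAA"), nrow = 3,
                  dimnames = list(c("a", "b", "c"), NULL))
  aln <- codon_alignment(cells, reference_id = "a")
  ru <- codon_usage(aln)
  sites <- classify_sites(aln, ru)
  expect_equal(sites$label[sites$ref_pos == 1], "invariant")
})

test_that("raising the threshold never shrinks the not-preferable set", {
  sim <- simulate_family(test_design(), seed = 12)
  np_sets <- lapply(c(0.5, 0.7, 0.9), function(th) {
    codon_usage(sim$records, threshold = th, complete_only = FALSE)$not_preferable
  })
  expect_true(all(np_sets[[1]] %in% np_sets[[2]]))
  expect_true(all(np_sets[[2]] %in% np_sets[[3]]))
})

test_that("designed invariant sites are recovered from simulated families", {
  for (seed in 1:5) {
    sim <- simulate_family(test_design(), seed = seed)
    aln <- align_records(sim$records, complete_only = FALSE)
    ru <- codon_usage(sim$records, complete_only = FALSE)
    sites <- classify_sites(aln, ru)
    truth <- sim$truth$invariant_site_positions
    labs <- sites$label[match(truth, sites$ref_pos)]
    expect_true(all(labs == "invariant"),
                label = sprintf("seed %d: designed invariant sites invariant", seed))
  }
})

test_that("landmarks: common cysteines, splice boundaries, sequons", {
  # identical proteins containing one NGS sequon and one cysteine;
  # 2 exons -> 1 boundary position
  cds <- paste0("ATG", "TGC", "AAT", "GGC", "AGC", "TAA") # M C N G S &
  rec <- cds_records(c("a", "b"), "t", c(cds, cds),
                     exons = list(
                       tibble::tibble(contig_id = "c1", start = 0L, end = 9L,
                                      strand = "+"),
                       tibble::tibble(contig_id = "c2", start = 0L, end = 9L,
                                      strand = "+")
                     ), validate = FALSE)
  # fix exon models to cover the full 18 bp in two exons of 9
  rec$exons <- list(
    tibble::tibble(contig_id = "c1", start = c(0L, 100L), end = c(9L, 109L),
                   strand = "+"),
    tibble::tibble(contig_id = "c2", start = c(0L, 100L), end = c(9L, 109L),
                   strand = "+")
  )
  aln <- align_records(rec, complete_only = FALSE)
  lm <- extract_landmarks(aln, rec)
  expect_equal(lm$ref_pos[lm$type == "cysteine"], 2L)
  expect_equal(lm$ref_pos[lm$type == "nglyc"], 3L) # N-G-S sequon start
  expect_equal(lm$ref_pos[lm$type == "splice_site"], 3L) # 9 bp -> codon 3
})

test_that("a 5-exon cluster has 4 common splice-site positions", {
  sim <- simulate_family(
    family_design(taxa = c("Homo sapiens", "Pan troglodytes", "Mus musculus"),
                  n_superclusters = 1, clusters_per_supercluster = 1,
                  exons_per_cluster = 5L),
    seed = 14)
  recs <- sim$records
  aln <- align_records(recs, complete_only = FALSE)
  lm <- extract_landmarks(aln, recs)
  expect_equal(sum(lm$type == "splice_site"), 4L)
})

test_that("one divergent member removes a column from common cysteines", {
  cds_c <- paste0("ATG", "TGC", "TAA") # M C &
  cds_s <- paste0("ATG", "AGC", "TAA") # M S &
  rec <- cds_records(c("a", "b", "c"), "t", c(cds_c, cds_c, cds_s))
  aln <- align_records(rec, complete_only = FALSE)
  lm <- extract_landmarks(aln, rec)
  expect_false(2L %in% lm$ref_pos[lm$type == "cysteine"])
})
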