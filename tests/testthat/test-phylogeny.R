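test_that("pairwise identity uses pairwise deletion", {
  m <- rbind(a = c("A", "T", "G", "-", "-", "-"),
             b = c("A", "T", "G", "C", "C", "C"))
  expect_equal(pairwise_identity(m, "a", "b"), 1.0)
  m2 <- rbind(a = rep("-", 3), b = c("A", "C", "G"))
  expect_true(is.na(pairwise_identity(m2, "a", "b")))
  aln <- toy_codon_alignment(c(x = "ATGAAA", y = "ATGAAA"))
  expect_equal(pairwise_identity(aln, "x", "y"), 1.0)
})

test_that("identity statistics match hand arithmetic on 3-sequence fixtures", {
  # identities: (s1,s2)=1, (s1,s3)=0.5, (s2,s3)=0.5
  # a-bar = 2/3; deviations = 1/3, 1/6, 1/6 -> a-bar_ad = 2/9
  m <- rbind(s1 = c("A", "A", "C", "C"),
             s2 = c("A", "A", "C", "C"),
             s3 = c("A", "A", "G", "G"))
  st <- identity_stats(m)
  expect_equal(st$a_bar, 2 / 3)
  expect_equal(st$a_bar_ad, 2 / 9)
  expect_equal(st$a_max, 1)
  expect_equal(st$a_min, 0.5)
  expect_equal(st$n_pairs, 3L)
  # two identical sequences: degenerate extreme
  st2 <- identity_stats(rbind(a = c("A", "C"), b = c("A", "C")))
  expect_equal(unlist(st2[c("a_bar", "a_bar_ad", "a_max", "a_min")]),
               c(a_bar = 1, a_bar_ad = 0, a_max = 1, a_min = 1))
  # invariant ordering on arbitrary inputs
  sim <- simulate_family(test_design(), seed = 3)
  st3 <- identity_stats(align_records(sim$records, complete_only = FALSE))
  expect_true(st3$a_min <= st3$a_bar && st3$a_bar <= st3$a_max)
  expect_gte(st3$a_bar_ad, 0)
  expect_true(isSymmetric(st3$matrix))
  expect_true(all(diag(st3$matrix) == 1))
})

test_that("pattern classification is monotone over the identity sweep", {
  expect_equal(as.character(classify_pattern(1.0)$category), "very_close")
  expect_equal(as.character(classify_pattern(0.0)$category), "very_distant")
  sweep <- classify_pattern(seq(0, 1, by = 0.01))$category
  expect_false(is.unsorted(sweep)) # ordered factor: never more distant as identity rises
  # bins are configuration, not constants
  custom <- classify_pattern(0.5, bins = c(very_close = 0.4, close = 0.3,
                                           typical = 0.2, distant = 0.1))
  expect_equal(as.character(custom$category), "very_close")
})

test_that("TN93 distances: zero for identical sequences, moment match for a pair", {
  aln <- toy_codon_alignment(c(a = "ATGAAACCCTGA", b = "ATGAAACCCTGA"))
  D <- mcl_distances(aln)$distances
  expect_equal(D["a", "b"], 0)
  # with exactly two sequences the composite-likelihood estimate reduces to
  # the per-pair TN93 estimate (exactly identified model)
  jc <- jc_pair(2000, 0.15, seed = 11)
  d_joint <- mcl_distances(jc$matrix)$distances[1, 2]
  d_closed <- mcl_distances(jc$matrix, method = "closed_form")$distances[1, 2]
  expect_equal(d_joint, d_closed, tolerance = 1e-3)
  # and both agree with the independent implementation in ape
  d_ape <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(jc$matrix)),
                                   model = "TN93",
                                   pairwise.deletion = TRUE))[1, 2]
  expect_equal(d_closed, d_ape, tolerance = 0.01)
})

test_that("saturated pairs are reported missing, not fabricated", {
  m <- rbind(a = rep(c("A", "C", "G", "T"), 25),
             b = rep(c("C", "A", "T", "G"), 25)) # 0% identity
  expect_warning(D <- mcl_distances(m, method = "closed_form")$distances,
                 "saturated")
  expect_true(is.na(D["a", "b"]))
})

test_that("distance estimator bias shrinks with alignment length", {
  errs <- vapply(c(300L, 3000L), function(L) {
    e <- vapply(1:8, function(s) {
      jc <- jc_pair(L, 0.2, seed = 100 + s)
      mcl_distances(jc$matrix, method = "closed_form")$distances[1, 2] - 0.2
    }, double(1))
    abs(mean(e))
  }, double(1))
  expect_lt(errs[2], errs[1] + 0.01)
  expect_lt(errs[2], 0.02)
})

test_that("OLS branch lengths reproduce an additive tree exactly", {
  D <- additive_matrix()
  tr <- ape::unroot(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);"))
  f <- ols_branch_lengths(tr, D)
  expect_equal(f$total, 11)
  # cophenetic distances of the fitted tree reproduce D exactly
  expect_equal(ape::cophenetic.phylo(f$tree)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
})

test_that("minimum-evolution search recovers the 4-taxon additive topology", {
  D <- additive_matrix()
  # exhaustive oracle over the three unrooted topologies
  tops <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  totals <- vapply(tops, function(tp) {
    ols_branch_lengths(ape::unroot(ape::read.tree(text = tp)), D)$total
  }, double(1))
  expect_equal(unname(which.min(totals)), 1L)
  fit <- me_tree(D, n_bootstrap = 0)
  expect_equal(fit$ols_length, min(totals))
  expect_equal(as.numeric(ape::dist.topo(
    ape::unroot(fit$tree),
    ape::unroot(ape::read.tree(text = tops[1])))), 0)
})

test_that("accepted CNI swaps never increase the OLS total length", {
  sim <- simulate_family(test_design(), seed = 33)
  aln <- align_records(sim$records, complete_only = FALSE)
  D <- mcl_distances(aln, method = "closed_form")$distances
  nj_total <- ols_branch_lengths(ape::nj(as.dist(D)), D)$total
  fit <- me_tree(D, n_bootstrap = 0)
  expect_lte(fit$ols_length, nj_total + 1e-12)
})

test_that("bootstrap of identical sequences collapses to a star tree", {
  rows <- setNames(rep("ATGAAACCCGGGTTTTGA", 5), paste0("s", 1:5))
  aln <- toy_codon_alignment(as.list(rows))
  ph <- suppressWarnings(me_tree(aln, n_bootstrap = 20, seed = 2))
  collapsed <- ph$collapsed_tree
  # no internal structure survives the 50% support filter
  expect_equal(collapsed$Nnode, 1L)
})

test_that("bootstrap supports are stable across seeds on a fixture", {
  sim <- simulate_family(test_design(), seed = 41)
  recs <- sim$records[sim$records$cluster_label %in% c("CL1.1", "CL2.1"), ]
  aln <- align_records(recs, complete_only = FALSE)
  s1 <- me_tree(aln, n_bootstrap = 1000, seed = 1)$supports
  s2 <- me_tree(aln, n_bootstrap = 1000, seed = 99)$supports
  expect_equal(length(s1), length(s2))
  expect_true(all(abs(s1 - s2) <= 5))
})

test_that("cluster assignment recovers the simulated partition", {
  sim <- simulate_family(test_design(), seed = 42)
  aln <- align_records(sim$records, complete_only = FALSE)
  ph <- me_tree(aln, n_bootstrap = 100, seed = 5)
  asg <- assign_clusters(ph, sim$records)
  truth <- sim$truth$cluster_membership
  # partition equality up to label names
  part <- function(ids, labels) {
    unname(lapply(split(ids, labels), sort)[order(vapply(split(ids, labels),
                                                         min, character(1)))])
  }
  expect_identical(part(asg$record_id, asg$cluster),
                   part(truth$record_id, truth$cluster))
  expect_identical(part(asg$record_id, asg$supercluster),
                   part(truth$record_id, truth$supercluster))
  expect_true(all(asg$monophyletic))
  # lettering is supercluster-number + letter
  expect_true(all(grepl("^[0-9]+[A-Z]$", asg$cluster)))
})

test_that("a single cluster maps to supercluster 1, cluster 1A", {
  sim <- simulate_family(
    family_design(taxa = c("Homo sapiens", "Pan troglodytes", "Macaca mulatta",
                           "Mus musculus"),
                  n_superclusters = 1, clusters_per_supercluster = 1),
    seed = 2)
  aln <- align_records(sim$records, complete_only = FALSE)
  ph <- me_tree(aln, n_bootstrap = 50, seed = 3)
  asg <- assign_clusters(ph, sim$records)
  expect_true(all(asg$supercluster == "1"))
  expect_true(all(asg$cluster == "1A"))
})
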