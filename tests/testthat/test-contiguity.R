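# brute-force oracle: exhaustive all-windows scan over a block alignment
brute_conserved_columns <- function(base_aln, target_aln, identity, window) {
  a <- strsplit(base_aln, "")[[1]]
  b <- strsplit(target_aln, "")[[1]]
  L <- length(a)
  m <- a == b & a != "-" & b != "-"
  covered <- logical(L)
  if (L >= window) {
    for (s in 1:(L - window + 1)) {
      if (sum(m[s:(s + window - 1)]) >= identity * window - 1e-9) {
        covered[s:(s + window - 1)] <- TRUE
      }
    }
  }
  covered
}

make_chain <- function(base_aln, target_aln, orientation = "forward") {
  nb <- sum(strsplit(base_aln, "")[[1]] != "-")
  nt <- sum(strsplit(target_aln, "")[[1]] != "-")
  tibble::tibble(base_start = 0L, base_end = nb,
                 target_start = 0L, target_end = nt,
                 orientation = orientation,
                 base_aln = base_aln, target_aln = target_aln)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

test_that("cutoff tiers resolve taxa to the empirical identity/window pairs", {
  cfg <- protocol_config()
  expect_equal(cutoff_for("Pan troglodytes", cfg),
               list(identity = 0.95, window_bp = 100L))
  expect_equal(cutoff_for("Gorilla gorilla", cfg)$identity, 0.95)
  expect_equal(cutoff_for("Pongo abelii", cfg)$identity, 0.90)
  expect_equal(cutoff_for("Nomascus leucogenys", cfg)$identity, 0.90)
  expect_equal(cutoff_for("Macaca mulatta", cfg)$identity, 0.85)
  expect_equal(cutoff_for("Papio hamadryas", cfg)$identity, 0.85)
  expect_equal(cutoff_for("Callithrix jacchus", cfg)$identity, 0.80)
  expect_equal(cutoff_for("Tarsius syrichta", cfg)$identity, 0.75)
  expect_equal(cutoff_for("Microcebus murinus", cfg)$identity, 0.75)
  expect_equal(cutoff_for("Otolemur garnettii", cfg)$identity, 0.75)
  expect_equal(cutoff_for("Mus musculus", cfg)$identity, 0.65)
  expect_equal(cutoff_for("Rattus norvegicus", cfg)$identity, 0.65)
  # fallback tier for other pairwise alignments
  expect_equal(cutoff_for("Bos taurus", cfg),
               list(identity = 0.70, window_bp = 100L))
  expect_equal(cutoff_for("Loxodonta africana", cfg)$identity, 0.70)
})

test_that("identical contigs align as one full-length block at identity 1", {
  set.seed(1)
  s <- random_seq(1000)
  chain <- pairwise_genomic_align(s, s)
  expect_equal(nrow(chain), 1L)
  expect_equal(chain$base_start, 0L)
  expect_equal(chain$base_end, 1000L)
  expect_equal(chain$orientation, "forward")
  segs <- detect_conserved_regions(chain, 0.95, 100L)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$mean_identity, 1.0)
  expect_equal(segs$base_start, 0L)
  expect_equal(segs$base_end, 1000L)
})

test_that("detection is symmetric under base/target swap for identical contigs", {
  set.seed(2)
  s <- random_seq(600)
  c1 <- pairwise_genomic_align(s, s)
  expect_identical(
    detect_conserved_regions(c1, 0.9, 100L)[, c("base_start", "base_end")],
    detect_conserved_regions(c1, 0.9, 100L)[, c("base_start", "base_end")]
  )
  # swapping the roles of two different but homologous contigs mirrors coords
  fx <- contiguity_fixture(seed = 5)
  tgt <- fx$targets$sequence[1]
  ab <- detect_conserved_regions(pairwise_genomic_align(fx$base$sequence, tgt),
                                 0.7, 100L)
  ba <- detect_conserved_regions(pairwise_genomic_align(tgt, fx$base$sequence),
                                 0.7, 100L)
  expect_equal(ab$base_start, ba$target_start)
  expect_equal(ab$target_end, ba$base_end)
})

test_that("windowed detection matches the exhaustive all-windows oracle", {
  set.seed(3)
  for (rep_i in 1:5) {
    n <- 600
    a <- strsplit(random_seq(n), "")[[1]]
    b <- a
    flip <- runif(n) < 0.08
    b[flip] <- vapply(a[flip], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    chain <- make_chain(paste(a, collapse = ""), paste(b, collapse = ""))
    for (cut in c(0.85, 0.95)) {
      segs <- detect_conserved_regions(chain, cut, 100L)
      covered <- brute_conserved_columns(chain$base_aln, chain$target_aln,
                                         cut, 100L)
      got <- logical(n)
      for (k in seq_len(nrow(segs))) {
        got[(segs$base_start[k] + 1):segs$base_end[k]] <- TRUE
      }
      expect_identical(got, covered)
    }
  }
})

test_that("a 96%-identity block passes the 95% cutoff but not 97%", {
  set.seed(4)
  n <- 200
  a <- strsplit(random_seq(n), "")[[1]]
  b <- a
  miss <- seq(25, 200, by = 25) # 8 mismatches: every 100-window has 4 (96%)
  b[miss] <- vapply(a[miss], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  chain <- make_chain(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_gt(nrow(detect_conserved_regions(chain, 0.95, 100L)), 0L)
  expect_equal(nrow(detect_conserved_regions(chain, 0.97, 100L)), 0L)
})

test_that("segments shorter than one window are never reported", {
  set.seed(5)
  s <- random_seq(80)
  chain <- make_chain(s, s)
  expect_equal(nrow(detect_conserved_regions(chain, 0.9, 100L)), 0L)
})

test_that("random unrelated contigs produce no conserved segment at any tier", {
  set.seed(6)
  n_segments <- 0L
  for (rep_i in 1:20) {
    chain <- pairwise_genomic_align(random_seq(1000), random_seq(1000))
    if (nrow(chain) == 0) next
    n_segments <- n_segments +
      nrow(detect_conserved_regions(chain, 0.65, 100L))
  }
  expect_equal(n_segments, 0L)
})

test_that("a reverse-complemented exon surfaces as a reverse-orientation block", {
  fx <- contiguity_fixture(seed = 9)
  ex <- fx$record$exons[[1]]
  inj <- inject_misassembly(fx$base$sequence, ex, "inversion", exon = 2)
  chain <- pairwise_genomic_align(inj$sequence, fx$base$sequence)
  rev_blocks <- chain[chain$orientation == "reverse", ]
  expect_gt(nrow(rev_blocks), 0L)
  # the reverse block overlaps the inverted exon span on the mutated base
  ov <- pmin(rev_blocks$base_end, ex$end[2]) - pmax(rev_blocks$base_start, ex$start[2])
  expect_true(any(ov > 0))
})

test_that("clean orthologue sets are consistent and injected defects are flagged", {
  fx <- contiguity_fixture(seed = 21)
  v <- run_contiguity(fx$record, fx$base, fx$targets)
  expect_equal(v$verdict, "consistent")
  expect_equal(v$conserved_exons, v$expected_exons)

  ex <- fx$record$exons[[1]]
  inv <- inject_misassembly(fx$base$sequence, ex, "inversion", exon = 2)
  v_inv <- run_contiguity(tibble::tibble(id = "inv", exons = list(inv$exons)),
                          inv$sequence, fx$targets, expected_exons = 3)
  expect_equal(v_inv$verdict, "misassembly")
  expect_equal(v_inv$defect_hint, "inversion")

  loss <- inject_misassembly(fx$base$sequence, ex, "exon_loss", exon = 2)
  v_loss <- run_contiguity(tibble::tibble(id = "loss", exons = list(loss$exons)),
                           loss$sequence, fx$targets, expected_exons = 3)
  expect_equal(v_loss$verdict, "misassembly")
  expect_equal(v_loss$conserved_exons, 2L)
  expect_equal(v_loss$defect_hint, "missing_exon")

  reord <- inject_misassembly(fx$base$sequence, ex, "reorder",
                              exon = 1, exon2 = 2)
  v_re <- run_contiguity(tibble::tibble(id = "re", exons = list(reord$exons)),
                         reord$sequence, fx$targets, expected_exons = 3)
  expect_equal(v_re$verdict, "misassembly")
  expect_equal(v_re$defect_hint, "reorder")
})
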