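test_that("record invariants are enforced", {
  expect_error(cds_records("r1", "Homo sapiens", "ATGA"), "multiple of 3")
  expect_error(cds_records(c("a", "a"), "t", c("ATGTAA", "ATGTAA")), "duplicate")
  bad_exons <- list(tibble::tibble(contig_id = "c", start = 0L, end = 3L,
                                   strand = "+"))
  expect_error(cds_records("r1", "t", "ATGTAA", exons = bad_exons),
               "exon spans sum")
  ok <- cds_records("r1", "t", "ATGTAA")
  expect_s3_class(ok, "cgap_records")
  expect_equal(nrow(ok$exons[[1]]), 1L)
})

test_that("single-exon plus-strand toy gene reads back identically", {
  td <- tempfile(); dir.create(td)
  fa <- file.path(td, "c.fa"); gff <- file.path(td, "m.gff3")
  writeLines(c(">ctg1", "AAATGGGTTAACC"), fa)
  writeLines(c("##gff-version 3",
               paste("ctg1", "t", "CDS", 3, 11, ".", "+", "0",
                     "ID=g1.c1;Parent=g1;taxon=Homo sapiens", sep = "\t")),
             gff)
  rec <- read_dataset(fa, gff)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$cds, "ATGGGTTAA")
  expect_equal(nchar(rec$cds), 9L)
  expect_equal(rec$taxon, "Homo sapiens")
})

test_that("two-exon minus-strand gene is reverse-complemented in transcript order", {
  # hand-derived: exons (1-based closed) 4..9 = TGACAT and 13..18 = CCCAAA on
  # the minus strand; transcript = revcomp(CCCAAA) + revcomp(TGACAT)
  td <- tempfile(); dir.create(td)
  fa <- file.path(td, "c.fa"); gff <- file.path(td, "m.gff3")
  writeLines(c(">ctgM", "TTTTGACATGGGCCCAAA"), fa)
  writeLines(c("##gff-version 3",
               paste("ctgM", "t", "CDS", 4, 9, ".", "-", "0",
                     "ID=g1.c1;Parent=g1", sep = "\t"),
               paste("ctgM", "t", "CDS", 13, 18, ".", "-", "0",
                     "ID=g1.c2;Parent=g1", sep = "\t")), gff)
  rec <- read_dataset(fa, gff)
  expect_equal(rec$cds, "TTTGGGATGTCA")
  expect_equal(rec$exons[[1]]$strand, c("-", "-"))
  # transcript order: downstream genomic exon first on the minus strand
  expect_equal(rec$exons[[1]]$start, c(12L, 3L))
})

test_that("EMBL join() features give the same record as GFF3+FASTA", {
  td <- tempfile(); dir.create(td)
  seqline <- "TTTTGACATGGGCCCAAA"
  fa <- file.path(td, "c.fa"); gff <- file.path(td, "m.gff3")
  writeLines(c(">ctgE", seqline), fa)
  writeLines(c("##gff-version 3",
               paste("ctgE", "t", "CDS", 4, 9, ".", "+", "0",
                     "ID=g1.c1;Parent=g1", sep = "\t"),
               paste("ctgE", "t", "CDS", 13, 18, ".", "+", "0",
                     "ID=g1.c2;Parent=g1", sep = "\t")), gff)
  from_gff <- read_dataset(fa, gff)
  embl <- file.path(td, "e.embl")
  writeLines(c(
    "ID   ctgE; SV 1; linear; genomic DNA; STD; MAM; 18 BP.",
    "OS   Homo sapiens",
    "FT   CDS             join(4..9,13..18)",
    "FT                   /gene=\"toy\"",
    "SQ   Sequence 18 BP;",
    paste0("     ", tolower(seqline), "        18"),
    "//"
  ), embl)
  from_embl <- read_embl_cds(embl)
  expect_equal(from_embl$cds, from_gff$cds)
  expect_equal(from_embl$exons[[1]]$start, from_gff$exons[[1]]$start)
  expect_equal(from_embl$exons[[1]]$end, from_gff$exons[[1]]$end)
  expect_equal(from_embl$taxon, "Homo sapiens")
})

test_that("EMBL complement(join()) matches the minus-strand GFF3 reading", {
  td <- tempfile(); dir.create(td)
  embl <- file.path(td, "e.embl")
  writeLines(c(
    "ID   ctgM; SV 1; linear; genomic DNA; STD; MAM; 18 BP.",
    "OS   Mus musculus",
    "FT   CDS             complement(join(4..9,13..18))",
    "SQ   Sequence 18 BP;",
    "     ttttgacatgggcccaaa    18",
    "//"
  ), embl)
  rec <- read_embl_cds(embl)
  expect_equal(rec$cds, "TTTGGGATGTCA")
})

test_that("reader rejects frame-breaking records but keeps valid ones", {
  td <- tempfile(); dir.create(td)
  fa <- file.path(td, "c.fa"); gff <- file.path(td, "m.gff3")
  writeLines(c(">ctg1", "AAATGGGTTAACCGG"), fa)
  writeLines(c("##gff-version 3",
               paste("ctg1", "t", "CDS", 3, 11, ".", "+", "0",
                     "ID=ok.c1;Parent=ok", sep = "\t"),
               paste("ctg1", "t", "CDS", 3, 12, ".", "+", "0",
                     "ID=bad.c1;Parent=bad", sep = "\t")), gff)
  expect_message(rec <- read_dataset(fa, gff), "reject.*bad")
  expect_equal(rec$id, "ok")
})

test_that("dataset, coverage, alignment and tree writers round-trip", {
  td <- tempfile(); dir.create(td)
  sim <- simulate_family(test_design(), seed = 4)
  write_dataset(sim$records, sim$contigs,
                file.path(td, "c.fa"), file.path(td, "m.gff3"))
  back <- read_dataset(file.path(td, "c.fa"), file.path(td, "m.gff3"))
  back <- back[match(sim$records$id, back$id), ]
  expect_identical(back$cds, sim$records$cds)
  expect_identical(back$cluster_label, sim$records$cluster_label)

  write_coverage(sim$tracks, file.path(td, "cov.tsv"))
  tr <- read_coverage(file.path(td, "cov.tsv"))
  tr <- tr[match(sim$tracks$record_id, tr$record_id), ]
  expect_identical(tr$coverage, sim$tracks$coverage)

  aln <- align_records(sim$records, complete_only = FALSE)
  write_alignment(aln, file.path(td, "aln.fa"))
  aln2 <- accept_external_alignment(file.path(td, "aln.fa"), sim$records)
  expect_identical(aln2$codons, aln$codons)

  tree <- ape::rtree(3)
  write_tree(tree, file.path(td, "t.nwk"))
  tree2 <- ape::read.tree(file.path(td, "t.nwk"))
  expect_setequal(tree2$tip.label, tree$tip.label)
})

test_that("stop codons appear as '&' in the protein view on disk", {
  aln <- toy_codon_alignment(c(a = "ATGTGA", b = "ATGTAA"))
  td <- tempfile(); dir.create(td)
  write_alignment(aln, file.path(td, "p.fa"), view = "protein")
  lines <- readLines(file.path(td, "p.fa"))
  expect_true(any(grepl("&", lines)))
  expect_equal(lines[2], "M&")
})

test_that("empty results write a header-only table", {
  td <- tempfile(); dir.create(td)
  write_table(tibble::tibble(record_id = character(), verdict = character()),
              file.path(td, "empty.tsv"))
  lines <- readLines(file.path(td, "empty.tsv"))
  expect_equal(lines, "record_id\tverdict")
})

test_that("cutoff configuration rejects invalid fractions", {
  expect_error(protocol_config(rscu_threshold = 1.2))
  tab <- default_cutoff_table(); tab$identity[1] <- 1.5
  expect_error(protocol_config(contiguity_cutoffs = tab))
})
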