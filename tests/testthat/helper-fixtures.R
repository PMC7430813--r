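# Shared fixture builders; everything is generated in code.

# small design used throughout: 4 informative taxa, modest protein size
test_design <- function(...) {
  family_design(
    taxa = c("Homo sapiens", "Pan troglodytes", "Macaca mulatta",
             "Mus musculus"),
    ...
  )
}

# compact single-cluster design for contiguity runs
contiguity_design <- function(...) {
  family_design(
    taxa = c("Homo sapiens", "Pan troglodytes", "Mus musculus"),
    n_superclusters = 1L, clusters_per_supercluster = 1L,
    exons_per_cluster = 3L, protein_length_range = c(150L, 180L),
    ...
  )
}

# base record + its contig + target contigs for one simulated cluster
contiguity_fixture <- function(seed) {
  sim <- simulate_family(contiguity_design(), seed = seed)
  base_rec <- sim$records[sim$records$taxon == "Homo_sapiens", ]
  base_ctg <- sim$contigs[sim$contigs$id == base_rec$exons[[1]]$contig_id[1], ]
  targets <- sim$contigs[sim$contigs$taxon != "Homo_sapiens", ]
  list(sim = sim, record = base_rec, base = base_ctg, targets = targets)
}

# hand-built codon alignment from rows of codon strings
toy_codon_alignment <- function(rows, reference_id = names(rows)[1]) {
  ncol <- nchar(rows[[1]]) / 3
  cells <- t(vapply(rows, function(r) {
    substring(r, seq(1, nchar(r), 3), seq(3, nchar(r), 3))
  }, character(ncol)))
  rownames(cells) <- names(rows)
  codon_alignment(cells, reference_id = reference_id)
}

# sequence pair diverged under Jukes-Cantor at true distance d
jc_pair <- function(L, d, seed) {
  set.seed(seed)
  nuc <- c("A", "C", "G", "T")
  a <- sample(nuc, L, replace = TRUE)
  p <- 3 / 4 * (1 - exp(-4 * d / 3))
  b <- a
  flip <- runif(L) < p
  b[flip] <- vapply(a[flip], function(x) sample(setdiff(nuc, x), 1), character(1))
  m <- rbind(a, b)
  rownames(m) <- c("s1", "s2")
  list(matrix = m, p_used = p)
}

# analytic standard error of the JC distance estimate
jc_se <- function(L, d) {
  p <- 3 / 4 * (1 - exp(-4 * d / 3))
  sqrt(p * (1 - p) / L) / (1 - 4 * p / 3)
}

# distances from the tree ((A:1,B:2):1,(C:3,D:4))
additive_matrix <- function() {
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

`%||%` <- function(x, y) if (is.null(x)) y else x
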