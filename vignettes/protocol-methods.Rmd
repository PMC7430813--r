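---
title: "Methods: a comparative genomic analysis protocol for eutherian gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a comparative genomic analysis protocol for eutherian gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgap)
```

`cgap` implements, as a reusable and tested pipeline, the comparative
genomic analysis protocol used to annotate and classify eutherian multigene
families such as the fibroblast growth factors: a reliability test on trace
coverage, a contiguity test on orthologous genomic sequence, codon-aware
multiple alignment, minimum-evolution phylogenetics with pairwise-identity
pattern statistics, and codon-usage-based tests of protein molecular
evolution. This vignette is the package's account of the underlying
methods, the tunable parameters, and the design choices that were genuinely
open.

## The record model

A *potential coding sequence* is a CDS annotated on a genomic contig: an
ordered exon model (0-based half-open internally; GFF3's 1-based closed
convention only at the file boundary), a spliced CDS whose length must be a
multiple of 3, a taxon, and optional cluster labels. Minus-strand models
are reverse-complemented into transcript orientation at read time. Records
whose spliced CDS breaks the reading frame are rejected with a logged
reason; they are never silently truncated.

## Test of reliability

A potential coding sequence is **complete** when per-nucleotide trace
coverage is available for every CDS position, otherwise **putative** and
excluded from all downstream analyses. The published criterion is
qualitative ("coverage available for every nucleotide"), so the depth
threshold is configurable (`min_depth`, default 1 read per base — one
consensus trace suffices; whether multiple independent traces were required
is unstated in the source protocol, and the weaker reading is the default).
The verdict is monotone: adding coverage can never demote a complete
record.

## Test of contiguity

The contiguity test asks whether a gene's coding exons appear in the
expected number, order and relative orientation in orthologous genomic
sequence; failures indicate assembly errors (exon inversion, loss, or
rearrangement). Pairwise genomic alignments are produced by a
seed-and-chain aligner: exact k-mer anchors (default `k = 12`) on both
strands, collapsed along diagonals into maximal exact runs, chained into
co-linear blocks (maximum anchored length, links limited to `max_gap = 400`
bp and `max_indel = 100` bp), with inter-anchor gaps closed by global
alignment. A rearranged or inverted region surfaces as its own
orientation-homogeneous block rather than being forced into one chain. The
aligner is interchangeable: the only contract downstream is the
windowed-identity profile of the pairwise alignment.

*Common genomic sequence regions* are maximal runs of alignment columns in
which **every** window of `window_bp` columns reaches the identity cutoff
(window step 1, the conservative reading of "along 100 bp"; a column
gapped in either row counts as a mismatch). The cutoffs are tiered by
target taxon, following the empirically determined detection tiers against
a human base sequence: 95%/100 bp (chimpanzee, gorilla), 90% (orangutan,
gibbon), 85% (macaque, baboon), 80% (marmoset), 75% (tarsier,
strepsirrhines), 65% (rodents) and 70% elsewhere. Transposable elements
are not masked. An exon is *conserved* when it overlaps a conserved
segment by at least `min_overlap` (default 1 bp) in at least `min_targets`
(default 1) target taxa; the published protocol does not state how many
taxa must confirm an exon, so the permissive default is used and both
knobs are configuration. The verdict is `consistent` exactly when
conserved exons equal the expected count, orientations agree, and target
positions follow the base physical order; the defect hint names the
matching failure signature.

## Codon-aware alignment

Complete coding sequences are translated (standard code; stop codons are
rendered `&`, following the convention of the source alignments) and
aligned at the protein level; the nucleotide alignment is threaded back
codon-wise, so every aligned cell is a codon or the `---` gap cell and
every row de-gaps exactly to its CDS — an invariant asserted on every
alignment the package builds. The bundled aligner is progressive: 3-mer
profile distances, a UPGMA guide tree, and profile–profile
Needleman–Wunsch with BLOSUM62 and affine gaps (open 10, extend 0.5), ties
broken diagonal > up > left for determinism. Published alignments of this
kind typically carry manual corrections that no aligner reproduces; the
import path (`accept_external_alignment()`) therefore accepts curated
alignments and validates them against the record set, and the aligner
itself is exchangeable behind the codon-alignment contract.

## Identity patterns and phylogeny

Pairwise nucleotide identities use pairwise deletion (per pair, only
columns gapped in that pair are dropped). `identity_stats()` reports the
average pairwise identity (a-bar), its average absolute deviation
(a-bar_ad), and the extremes (a_max, a_min). Identity *patterns*
(very close, close, typical, distant, very distant) are bin labels; the
published protocol names the categories but prints no boundaries, so the
defaults (0.85/0.75/0.60/0.45) are package configuration choices, exposed
in `protocol_config()` and never treated as published values.

Distances are Tamura–Nei (TN93) with base frequencies pooled over the
alignment and the two transition/transversion rate ratios estimated
jointly across all pairs by maximizing the composite (summed over pairs)
log-likelihood, with each pair's distance profiled out numerically — the
composite-likelihood flavour of TN93 popularized by large-scale
neighbor-joining work. With exactly two sequences this reduces to the
per-pair TN93 estimate. Saturated pairs yield missing distances and a
warning, never a fabricated number. Bootstrap replicates reuse the
point-estimate rate ratios and the closed-form TN93 distance; this keeps
replicates consistent with the point estimate at a fraction of the cost,
and is a package design choice.

The tree criterion is minimum evolution: a neighbor-joining starting tree
refined by close-neighbor-interchange, accepting any swap that lowers the
ordinary-least-squares total branch length (first improvement in a
deterministic traversal). Bootstrap resamples nucleotide columns (not
codons), matching the common default for nucleotide alignments; supports
below the collapse threshold (default 50%, after the conventional 1000
replicates — smaller replicate counts are used in examples and tests for
speed) are contracted, as are zero-length internal branches, which carry
no signal regardless of their bootstrap count. Major gene clusters are the
known labels checked for monophyly (via unrooted bipartitions, so the
check does not depend on root placement); superclusters are the subtrees
hanging off the midpoint root of the collapsed tree. Supercluster
numbering is by size then traversal order, and member clusters are
lettered `A`, `B`, … by post-order appearance — the published lettering
rule is unstated, so determinism is the requirement the package meets.

## Tests of protein molecular evolution

Relative synonymous codon usage is `R = counts / expected counts`, with
the expected count of a codon equal to its amino-acid family total divided
by the family size. Family means of `R` are exactly 1 whenever the family
is observed; single-codon families (ATG, TGG) are pinned at `R = 1` and
can never be not-preferable. Codons with `R <= 0.7` (configurable) are
**not-preferable**; stop codons are tabulated (shown as `&`) but never
classified. Reference-anchored site classes follow the source
definitions: a reference position is **invariant** when exactly one amino
acid is observed across all rows of its column, **forward** when variant
with no aligned not-preferable codon, and **compensatory** when variant
with at least one. Whether codons of all rows or only non-reference rows
enter the forward/compensatory decision is not stated in the source; this
package evaluates all rows. Columns where a member is gapped are
classified over the non-gapped rows — which is what lets a site remain
invariant when one record lacks, say, the initiator methionine — and
reference-gapped columns are skipped with a log message.

Landmarks per cluster are: common cysteines (every member has `C` at the
column), common exon–intron boundary sites (the boundary position is the
codon index containing the exon's last full or partial codon — a codon
split by an intron belongs to the upstream exon — so a 5-exon gene has 4
boundary positions), and common N-glycosylation sequons (N-X-[S/T],
X ≠ P, canonical rule rather than an external predictor; the scanning
function is pluggable).

## The synthetic-data generator

Every stage is verified against simulated families with a machine-readable
truth record. The generator emulates exactly the structure the analyses
assume: a hierarchy of superclusters → major gene clusters → per-species
orthologues on a fixed 10-taxon eutherian-like species tree (ultrametric,
depth 1, so the within-cluster divergence scale is in expected
substitution proposals per site); codon usage biased against a designed
rare-codon set; designed invariant amino-acid positions; 3- or 5-exon
models embedded in contigs with i.i.d.-random introns and spacers;
coverage tracks with injectable zero-coverage holes; and injectable exon
misassemblies (inversion, loss, reorder) applied to the base-taxon contig,
the assembly under test.

The substitution process proposes per-site nucleotide mutations with a
transition bias (`kappa = 2`), rejects internal stops and amino-acid
changes at invariant positions, thins amino-acid changes by a purifying
acceptance (default 0.5), and down-weights any proposal creating a rare
codon by `rare_codon_bias` (default 0.15) — the simplest process that
creates both the codon-usage signal and the invariant columns the tests
must recover. Because acceptance thins proposals, realized divergences sit
below the nominal scales; only their strict ordering (within-cluster <
between-cluster < between-supercluster, defaults 0.05 / 0.25 / 0.5)
matters to the recovery tests. The designed rare set is the subset of
commonly under-used mammalian codons whose synonymous families have at
least three members, a constraint of the truth model (two-codon families
cannot be biased without the partner codon's ratio saturating the design).
Coverage is drawn as `1 + Poisson(mean_depth - 1)` so that the only
zero-coverage positions are the injected holes and hole recovery is exact
rather than statistical. The generator produces no indels — real gene
families have them; what passing tests show is that the statistics,
classifications and recoveries are correct on alignable data, not that the
aligner resolves hard indel placement — and no splice-site realism, since
the contiguity test only consumes identity windows.

A note on degenerate designs: the divergence scales must be strictly
ordered, so "all scales zero" is not a valid design; the identical-
orthologue limiting case is exercised by setting the within-cluster scale
to zero while keeping the others positive.

## Numerical choices and problem sizes

Dynamic-programming ties prefer diagonal > up > left; CNI accepts the
first improving swap in a deterministic traversal; OLS branch lengths come
from a least-squares fit to the tree's path matrix (negative estimates are
kept in the criterion, as is conventional for OLS minimum evolution);
saturated distances and zero-coverage records are reported as missing or
putative, never imputed. All randomness flows from a single integer seed;
identical (design, seed) pairs give byte-identical outputs.

The bundled examples, tests and the acceptance script run at deliberately
modest problem sizes chosen as representative rather than exhaustive: 4-
or 10-taxon panels, 2 x 2 cluster families (16–40 records), proteins of
150–260 amino acids, 100-replicate bootstraps (1000 where seed-stability
itself is the property under test), 20 clean orthologue sets plus paired
injections for the contiguity error rates, and 1200-bp pairs for distance
calibration at a true distance of 0.2.

## Known limitations

The aligner is not ClustalW and the distances are not bit-for-bit those of
any particular MEGA release; both stand behind contracts (the codon
alignment invariants; the TN93 composite-likelihood definition) that the
tests pin down. Reproducing the published dataset-level numbers (record
counts, the 20-codon not-preferable set, the printed identity statistics)
requires the deposited third-party records and trace-archive coverage,
which this package deliberately does not fetch: it consumes files, it does
not query services. On synthetic data the corresponding quantities are
recomputed end to end by `scripts/acceptance.R`.
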