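---
title: "RGeneAtlas: models, thresholds and design of the comparative R-gene pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RGeneAtlas methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

RGeneAtlas compares the NBS-LRR (R-gene) complements of several plant
genomes: it identifies candidates from motifs and homology, separates intact
genes from pseudogenes, groups genes into lineages and loci, tests each
locus's presence, absence or translocation in the other genomes, detects
sequence-exchange (gene conversion) tracts, and summarises family sizes.
This vignette explains the underlying models, why each threshold has the
value it does, the numerical choices, and what the synthetic-data validation
does and does not establish.

## Identification model

NBS-LRR proteins are recognised through the conserved NB-ARC motif chain:
kinase-1a/P-loop (`GGVGKTT` and variants), kinase-2 (`VLDDVW`), NBS-VI
(`FLDIACF`), HD/GLPL (`CKGLPL`) and NBS-IX (`FLHIACF`). `scanMotifs()`
matches degenerate amino-acid patterns (`[..]` alternatives, `.`/`X`
wildcards) allowing one mismatch per motif by default; a gene is NBS-LRR
when P-loop, kinase-2 and GLPL occur in that order, TIR-subclass when an
N-terminal TIR signature precedes the P-loop, and LRR-RLK when a kinase
catalytic motif co-occurs with at least three LRR repeats and no NB-ARC
chain. This is a deliberately self-contained substitute for a profile-HMM
screen: it needs no model downloads, its behaviour is fully deterministic,
and the motifs are exactly those the field's degenerate primers target. A
user with HMMER available can intersect or union its hits with
`identifyCandidates()` output; the downstream stages only need the candidate
table.

Pseudogenes no longer encode the full motif chain, so identification has a
second pass: `findHomologs()` recruits any gene whose CDS aligns locally to
a verified candidate at ≥ 70 % identity over ≥ 150 bp. The identity value is
the one the field uses for R-gene homologue screens; the 150 bp floor
replaces a database e-value cutoff (e-values depend on database size and so
are not reproducible in a self-contained tool). Recruitment iterates to a
fixed point, with newly recruited genes acting as baits.

All pairwise alignment in the package uses one fixed scoring scheme
(match +1, mismatch −1, gap open −2, extend −1), a reproducible surrogate
for BLASTN defaults. Genome-scale searches (`bestHits()`) are seeded by
shared 12-mers, BLAST-style: only subjects sharing at least three words are
aligned, ranked by word count, and for equal-length pairs whose ungapped
identity is already ≥ 85 % the ungapped comparison is used directly — at
that similarity an optimal gapped alignment cannot change identity
materially. These short-cuts are what keep three-genome comparisons on a
laptop-scale budget.

## Pseudogene calling

A clade's reference is its longest motif-complete member that is also a
true open reading frame (in-frame length, no internal stop) — mirroring the
rule that full-length homologues with an ORF in one clade share a gene
structure. Against that reference, a gene is:

* **partial** when the best local alignment covers < 70 % of the modeled
  CDS. The threshold is tunable; 70 % reads "large deletions" strictly
  enough that diverged but complete genes never trip it.
* **frameshift** when the alignment demands indels whose net length is not
  a multiple of 3. Two numerical details matter here. First, indel calls
  use stiffer gap costs (open 5, extend 2) than homology search: at ~10 %
  within-clade divergence the cheap-gap scheme starts inserting spurious
  compensating 1-bp gap pairs into perfectly intact genes. Second, the
  criterion is the *net* frame offset, so a compensating insertion/deletion
  pair (net 0) — an alignment artefact, not a lesion — is not called.
* **nonsense** when an in-frame stop occurs before the final 5 % of the
  modeled CDS; stops at or near the native position are not lesions.

A clade with no ORF reference yields `unassessable` verdicts rather than
guesses.

## Lineages, subfamilies, loci

Trees are neighbor-joining (`ape::nj`) from p-distances (proteins) or
Kimura two-parameter distances (`d = −½·ln((1−2P−Q)·√(1−2Q))`), computed on
the conserved P-loop → GLPL region — the one region alignable across
subfamilies. Supports come from 100 column-resample replicates; each node is
labelled with the percentage of replicate trees containing its bipartition
(trivial splits count as 100). Because NJ trees are unrooted and no outgroup
is assumed, trees are midpoint-rooted before clade extraction. A *lineage*
(clade) is a maximal monophyletic group with support > 80 whose maximum
within-clade pairwise distance is ≤ 0.3; taxa in no qualifying clade become
singletons, so clades always partition the taxa. The cutoff's alternative
reading — minimum distance *between* clades > 0.3 — is available as
`cutoff_semantics = "between"`; within-clade max is the default because it
makes clade membership a property of the clade alone.

*Subfamilies* are single-linkage clusters at ≥ 70 % nucleotide identity.
Identity is measured over the best local alignment (minimum overlap 150 bp),
not a global alignment: family tables count pseudogenes too, and a
half-length truncated gene shares its sequence with its relatives even
though its global identity to them is arithmetically capped near 50 %.
Global identity would exile every partial gene into its own subfamily and
inflate subfamily counts.

*Loci* are the transitive closure of "separated by at most 8 non-R genes"
over gene ordinals; a single R-gene is a single-copy locus, two or more are
a cluster.

## Orthology, synteny and presence/absence

Orthologs are bidirectional best hits with an HSP longer than 500 bp and
identity above 80 % (both strict inequalities, as the thresholds are
phrased). A locus's syntenic region in another genome is found from up to
10 flanking genes on each side of its first member: if at least 14 of their
best hits co-occur in one 20-gene window on one target chromosome, that
window is the syntenic interval (at chromosome ends the requirement scales
as ⌈0.7 × flank count⌉, keeping the 14/20 stringency). Two details:

* R-genes are excluded from the flank set *and* from the target-side gene
  ranking. A deleted or translocated cluster must not erode its own
  anchoring context, and a target genome's own R-cluster would otherwise
  consume window ordinals and dilute the count.
* The interval is reported in base pairs; status tests use bp overlap.

Status per (locus, target genome): **present** if any member's ortholog
lies in the interval; **translocated** if orthologs exist only outside it;
**absent-deleted** if the interval exists but holds no ortholog;
**gap/unassessable** if no interval is found. These are computed for every
ordered genome pair, and the integrated map anchors every locus of every
genome onto the anchor genome (merging orthologous loci, placing
anchor-absent loci by their syntenic interval, and reporting the
unanchorable remainder). Translocation is direction-agnostic: a locus moved
in the query genome is seen as translocated relative to every retained
copy, and the data alone cannot say which side moved.

## Sequence-exchange detection

Gene conversion between homologues leaves unusually long runs of agreement
at polymorphic sites. The detector works on the polymorphic columns of an
alignment (≥ 3 sequences; columns with > 20 % gaps dropped): for each pair,
candidate fragments are the maximal runs of consecutive polymorphic sites
with *no mismatch*, bounded by disagreements or profile ends; a run covering
the whole profile is uninformative and discarded. The fragment score is the
run length in polymorphic sites; the reported tract is the bp span from the
run's first to last polymorphic column.

Significance is experiment-wise: polymorphic columns are shuffled jointly
across all rows, and the null distribution of the *maximum* pairwise
fragment statistic over all pairs is accumulated; `p = (1 + exceedances) /
(n_perm + 1)`. Because the site-count statistic is integer-valued and
lumpy, ties are broken by the physical bp span of the run (lexicographic
comparison) in the permutation ranking — this keeps the null distribution
nearly continuous and the test calibrated, which the test suite verifies
directly: on 500 null alignments of i.i.d. columns the rejection rate at
α = 0.05 sits inside the binomial confidence band. Exact equality with any
external conversion-detection program's output is not promised; the
implementation honours the zero-mismatch fragment definition and replaces
asymptotic corrections with permutation.

## Family statistics

`pearsonR()` and `twoSampleT()` wrap the standard product-moment
correlation and Welch's unequal-variance t-test (a pooled-variance switch
exists; Welch is the default because per-subfamily count variances differ
strongly between small and large genomes). `cladeSharingStats()` reports
the percentage of family-specific clades *truncated* to one decimal —
23 specific of 39 clades is 58.97 %, reported as 58.9 — matching the
convention of never printing more precision than intended.
`familySummary()` computes mean genes per subfamily as total / subfamily
count and can carry an externally supplied per-subfamily mean alongside it
(published per-subfamily averages are sometimes computed on a different
gene subset than the printed totals, so the two are reported side by side
rather than reconciled).

## The synthetic-genome generator

`simulateGenomes()` builds one ancestral genome — background genes, an
LRR-RLK family, and R-gene lineages of mean copy number 4 occupying one or
two clustered loci — and evolves each species from it star-wise. Defaults
(3 species, 4 chromosomes × 60 background genes, 12 lineages, 4 % per-branch
substitution, lineage loss 0.15/species, locus deletion 0.10, translocation
0.05, pseudogene probability 0.45 with a 0.4/0.3/0.3
frameshift/nonsense/partial mix, three conversion tracts of 300–1200 bp in
the largest lineage, 12 LRR-RLKs) emulate a small R-gene complement: a few
dozen R-genes per genome, roughly half pseudogenized, frequent lineage
loss, rare translocation, one conversion-active ("Type I") lineage. The
tract-length floor of 300 bp is the planted-power condition for the
zero-mismatch detector at desk scale; observed tracts in real data extend
below that, where the detector has little power.

Deliberate simplifications, and what they mean for the tests:

* **No indels in intact genes.** Lineage ancestors derive from one master
  scaffold by heavy substitution (within-lineage identity ~90 %,
  between-lineage well below the 70 % subfamily threshold), motif codons
  protected, stop codons reverted. Homologous simulated genes are therefore
  directly comparable column-by-column, and the pipeline needs no multiple
  aligner. Passing tests show the *logic* of every stage is right; they do
  not exercise alignment quality on indel-rich real data, where an external
  aligner (e.g. MAFFT) should produce the input alignments.
* **Conversion tracts are planted in-frame** (codon-aligned bounds) so
  chimeras stay open reading frames; real conversion tracts have arbitrary
  bounds.
* **The conversion lineage is exempt from loss and lesions**, mirroring its
  role as a diverse, conversion-active lineage and guaranteeing the planted
  tracts remain observable.
* **The LRR-RLK family size is coupled phenomenologically** to the retained
  R-gene fraction, so the simulated family sizes co-vary positively; the
  generator makes no mechanistic claim about why real genomes show that
  correlation.
* **No intergenic sequence**: genes are laid out with fixed 200 bp spacers;
  coordinates are consistent but not base-accurate models of real genomes.
* Background genes are random ORFs kept motif-free by rejection sampling,
  so identification sensitivity/specificity on simulations is clean by
  construction — those tests validate the scanner's rules, not its
  performance on borderline real proteins.

Every stochastic choice flows from one integer seed; simulation output and
the whole pipeline report are byte-identical across re-runs.

## Problem sizes and runtime

The shipped tests and the acceptance script run on one CPU in minutes: the
default simulation (~290 genes × 3 genomes) drives the full pipeline in
about two minutes; calibration uses 500 null alignments of 6 × 240 columns
with 200 permutations each; the neighbor-joining exactness check uses 50
random additive matrices with up to 12 taxa. Larger simulations scale
roughly linearly in gene count for identification and loci, and
quadratically within gene families for clustering and conversion scanning.

## Known limitations

* No built-in multiple sequence alignment; unequal-length protein regions
  skip the tree stage with a log note rather than guessing an alignment.
* Best-hit search is heuristic (word seeding, top-5 candidate cap,
  ungapped fast path); pathological inputs — e.g. genes whose only
  similarity is a short perfect repeat — could in principle evade seeding.
* Orthology is sequence-only BBH; a translocated locus whose copies are
  also heavily truncated can lose its bidirectional best hit and be called
  absent rather than translocated — the same ambiguity the underlying
  comparison faces on real genomes.
* The conversion detector reports pairwise fragments; deduplication by
  identical tract is provided, but fragment counts between different tools
  are not directly comparable.
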