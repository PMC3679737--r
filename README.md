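# RGeneAtlas

Comparative annotation and evolutionary analysis of plant disease-resistance
(NBS-LRR) gene families, for genome biologists studying why R-gene copy
number varies so strongly between plant genomes.

Plant genomes differ more than tenfold in their complement of NBS-LRR
resistance genes, and the forces behind a *small* complement — loss of whole
gene lineages versus lack of duplication within surviving lineages — can only
be separated by comparing several genomes at once. RGeneAtlas implements
that comparison as a reusable pipeline:

* **Identification** — degenerate-motif scanning for the conserved NB-ARC
  motifs (kinase-1a/P-loop `GGVGKTT`, kinase-2 `VLDDVW`, NBS-VI `FLDIACF`,
  HD/GLPL `CKGLPL`, NBS-IX `FLHIACF`), TIR/non-TIR subclassing, LRR-RLK
  detection, and recruitment of pseudogenized homologues by local alignment
  (≥ 70 % nucleotide identity). In-silico PCR with the degenerate primer
  panel (240–700 bp products) and 99.5 %-identity fragment deduplication.
* **Gene models & pseudogenes** — clade reference structures (full-length
  homologues with an ORF share exon count, intron positions and phases);
  each gene is called intact or pseudogene with a lesion type:
  partial (aligned coverage < 70 % of the modeled CDS), frameshift
  (net indel ≢ 0 mod 3), or nonsense (in-frame stop before the final 5 %).
* **Phylogeny** — p-distance (protein) and Kimura two-parameter
  (`d = −½·ln((1−2P−Q)·√(1−2Q))`) neighbor-joining trees with 100-replicate
  bootstrap; lineages are maximal clades with support > 80 and within-clade
  distance ≤ 0.3, built from the conserved P-loop → GLPL region.
* **Loci & cross-genome comparison** — R-genes separated by ≤ 8 non-R genes
  form one locus; orthologs are bidirectional best hits with HSP > 500 bp at
  > 80 % identity; a locus's syntenic region in another genome needs ≥ 14 of
  20 flanking-gene best hits in one 20-gene window, yielding
  present / absent-deleted / translocated / unassessable calls and an
  integrated cross-genome locus map.
* **Sequence exchange (Type I chimeras)** — a zero-mismatch fragment
  statistic over polymorphic sites with experiment-wise permutation
  p-values, reporting conversion tracts in bp and a chimera painting.
* **Family statistics** — 70 %-identity subfamilies, per-species family
  tables, clade sharing across plant families, Pearson correlation of
  NBS-LRR vs LRR-RLK family sizes, Welch t-tests on per-subfamily counts.
* **Synthetic genomes with ground truth** — `simulateGenomes()` plants
  orthologous gene orders, R-gene lineages, lineage losses, locus deletions,
  translocations, frameshift/nonsense/partial lesions, conversion tracts and
  a co-varying LRR-RLK family, and records every event in a machine-readable
  truth set, so every stage above is testable end-to-end without downloads.

## Worked example

```r
library(RGeneAtlas)

run <- runPipeline(pipelineConfig(
  simulation = simulationConfig(seed = 1L),  # 3 genomes, 12 R lineages
  seed = 3L, out_dir = "atlas_report"))
run$summary
#>   species genes r_genes rlk_genes pseudogenes loci
#> 1    sp01   282      33         8           9   12
#> 2    sp02   279      30         8          10    9
#> 3    sp03   285      36         9           9   11

evaluateAgainstTruth(run)[c("pseudogene_sensitivity",
                            "pseudogene_specificity", "pa_accuracy")]
#> $pseudogene_sensitivity
#> [1] 1
#> $pseudogene_specificity
#> [1] 1
#> $pa_accuracy
#> [1] 1
```

The summary counts per genome the annotated genes, identified R-genes
(motif-complete plus homology-recruited) and LRR-RLKs, pseudogene calls and
R-gene loci; `evaluateAgainstTruth()` scores the calls against the planted
events. `atlas_report/` holds one TSV per stage (candidates, subfamilies,
pseudogenes, clades, loci, orthologs, PA calls, integrated map, conversion
events, family summary), the Newick tree, a `stats.json` blob and a run
manifest; re-running the same configuration reproduces the files
byte-for-byte.

Single statistics work standalone, e.g. the family-size correlation across
cucumber, melon, watermelon, soybean and poplar:

```r
pearsonR(c(70, 75, 55, 450, 552), c(189, 169, 184, 501, 447))
#> [1] 0.9619706   # rounds to 0.96
```

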