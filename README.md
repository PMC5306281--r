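# pangest

Pan-genome and pan-transcriptome analysis of same-species sequence sets,
for plant (and other eukaryote) genomics groups working from per-accession
CDS collections or de novo assembled transcriptomes rather than finished
reference genomes.

The pan-genome of a species is the union of the sequences found across all
of its individuals; clusters present in every accession form the **core**
genome, the rest are **accessory** (soft-core, shell, cloud, by
*occupancy* — the number of accessions represented in a cluster).
`pangest` reconstructs this structure from one FASTA file per accession:

- **Alignment evidence** — parses standard 12-column tabular hits, or
  computes its own with a built-in seed-and-extend aligner; HSPs of a
  sequence pair are merged by interval union, with coverage
  `100 · covered / min(Lq, Ls)` (over the longest sequence for full-length
  cDNA pairs), so split genes, truncated transcripts and retained introns
  still reach a fair coverage value.
- **Clustering** — redundant isoforms (overlap ≥ 40 bp, identity ≥ 95%)
  are collapsed; in-paralogs detected; families built either with
  bidirectional best hits seeded from a reference accession (BDBH) or with
  OrthoMCL-style Markov clustering (expansion/inflation iterations on the
  symmetrized, accession-pair-normalized weight matrix).
- **Summaries** — pan-genome matrices with core/soft-core/shell/cloud
  classes; average nucleotide identity (ANI) matrices over co-clustered
  sequences, with complete/average-linkage dendrograms; pan/core/soft-core
  growth curves over random accession orderings with exponential-saturation
  fits `κ·e^(−n/τ) + Ω`; Nei–Gojobori (NG86) dN/dS with Jukes–Cantor
  correction on single-copy clusters (occupancy ≥ 4, cluster ω > 1.5
  excluded); Robinson–Foulds and branch-score tree distances; Fisher/FDR
  protein-domain enrichment with once-per-cluster counting; consensus CDS
  inference from ORF + protein-homology evidence; expression (TPM)
  summaries by occupancy class with notched box statistics
  (median ± 1.58·IQR/√n).
- **Synthetic data** — `generate_pangenome()` builds multi-accession gene
  families with programmed occupancy classes, divergence, isoforms,
  fragments, split genes, retained introns and class-ordered expression,
  plus a ground-truth table, so every analysis above is testable offline.

## Worked example

```r
library(pangest)

sp  <- generate_pangenome(synth_config(seed = 1))   # 6 accessions, 100 families
sp$seqs
#> accession_set: 6 accessions, 521 sequences

res <- cluster_sequences(sp$seqs)                   # aligner -> graph -> OMCL
res$graph
#> similarity_graph: 521 nodes, 2620 directed edges (identity >= 95%, coverage >= 50%)
length(res$clusters)
#> [1] 100

pm <- build_pangenome_matrix(res$clusters, sp$seqs)
table(classify_occupancy(pm))
#> cloud  core shell
#>    20    50    30

compute_ani(res$clusters, res$graph, sp$seqs, filter = "core")
#> ani_matrix: 6 accessions, mean off-diagonal ANI 98.998%

truth_recovery(res$clusters, sp$truth)[c("n_recovered", "occupancy_agreement")]
#> $n_recovered [1] 100      $occupancy_agreement [1] 1

curves <- simulate_composition(sp$seqs, graph = res$graph,
                               permutations = 20, seed = 2)
growth_summary(curves)
#>  n_genomes permutations n_saturation coverage_target novel_per_genome
#>          6           20            6            0.99         1.023509
#>  core_asymptote pan_final_mean pan_final_sd core_final_mean
#>        50.67561          104.9     1.165287           51.75
```

Reading: all 100 programmed families are recovered exactly as clusters and
fall into their programmed occupancy classes; the core ANI of 99.0% is the
programmed 1% pairwise divergence; the growth fit reports a mean final pan
size of 104.9 non-redundant sequences (split-gene pieces add a few columns
beyond the 100 families) with ~1 novel sequence per added genome at
saturation, and the core asymptote Ω ≈ 50.7 matches the 50 programmed core
families.

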