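---
title: "Methods: clustering same-species sequence sets into a pan-genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering same-species sequence sets into a pan-genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangest)
```

# Scope

`pangest` reconstructs a gene-based pan-genome from per-accession nucleotide
sequence sets of a *single species*: annotated CDS from whole-genome
assemblies, or de novo assembled transcripts. Sequences are compared by
local alignment, merged into per-pair similarity evidence, clustered into
gene families, and summarized as pan-genome matrices, occupancy classes,
ANI matrices and dendrograms, growth curves, dN/dS estimates, and domain
enrichment tables. A synthetic generator provides ground-truth data so the
whole pipeline is testable without downloads.

# Alignment evidence and coverage

## The built-in aligner

Real runs of the original workflow consume all-vs-all hits from an external
nucleotide search tool in the common 12-column tabular format, and
`parse_tabular_hits()` accepts exactly that. For self-contained operation,
`local_align()`/`compute_all_hits()` provide a native aligner: exact k-mer
seeds (default `k = 12`) select candidate diagonals on both strands; each
diagonal is scanned for maximal ungapped scoring segments (match `+1`,
mismatch `-2`; N counts as mismatch), with a recursive-Kadane extraction
and an identity-refinement split at deep score dips. A segment qualifies as
an HSP when it is at least `min_hsp_len = 30` bp long at
`min_hsp_identity = 90` percent identity.

The aligner is deliberately **ungapped per diagonal**. Indels, retained
introns and split genes then surface as *multiple* HSPs on shifted
diagonals — precisely the situation the downstream coverage merge is
designed for. The cost is that small isolated indels inside an otherwise
contiguous alignment produce two HSPs instead of one gapped HSP; coverage
and identity summaries are unaffected because they operate on the merged
interval union. Intra-species comparisons at the default 95% identity
cut-off are dominated by substitutions, where this design is exact.

Because no search-statistics theory is attached to the raw segment score,
the E-value is a length-scaled surrogate, `Lq * Ls * 2^(-score)`. It decays
monotonically in score, which is the only property the best-hit logic and
the edge weighting consume.

## Merging HSPs into coverage

`merge_hsps()` keeps the majority strand (by summed score), projects the
retained HSPs onto query intervals, and counts the interval union once.
Coverage is `100 * covered / min(Lq, Ls)` by default — assembled
transcripts are frequently truncated, so the shortest sequence is the
fair denominator — and `100 * covered / max(Lq, Ls)` when both sequences
are declared full-length cDNAs. Merged identity is the
alignment-length-weighted mean of HSP identities; an unweighted mean would
let short fragments dominate. Both thresholds applied to the merged values
(identity >= 95, coverage >= 50 by default) are inclusive.

# Graph construction and clustering

Nodes are sequences; a directed edge q -> s exists when the merged hit
passes both thresholds; its weight is `min(300, -log10(evalue))`, with
E-value 0 mapped to 300. A per-(node, target accession) best-hit index
(bitscore, then E-value, then lexicographic id) makes all tie-breaking
deterministic.

**Isoform collapse.** Within one accession, sequences whose merged overlap
is at least 40 bp at >= 95% identity and passing coverage are redundancy
groups (transitive closure); the longest member represents the group, and
dropped isoforms are reattached to their representative's final cluster.
Collapse runs before in-paralog detection and clustering; the original's
ordering of these steps is not documented, and collapsing first keeps the
best-hit structure clean.

**In-paralogs** are same-accession reciprocal best hits whose mutual score
is at least as good as either member's best cross-accession hit.

**BDBH** seeds one candidate cluster per non-redundant reference sequence
and adds, per other accession, the bidirectional best hit of the seed,
then attaches in-paralogs. Genes absent from the reference are never
clustered — the documented, intentional blind spot of this fast algorithm.

**OMCL-style Markov clustering.** Directed weights are symmetrized as the
mean of the two directions with a missing direction contributing zero:
truncated transcripts often produce one-sided coverage, and demanding
strict reciprocity would discard them (a flag restores strictness).
Weights are then normalized per accession pair by that pair's mean edge
weight (the OrthoMCL convention; without it closely related accessions
dominate the attractor structure), self-loops are set to the maximum
incident weight, and standard MCL iterations run per connected component:
column-normalize, square (expansion), elementwise power `inflation = 1.5`
(the OrthoMCL default; the original names the algorithm but no inflation
value), prune entries below `1e-5`, renormalize, until the maximum entry
change falls below `1e-6` or 100 iterations (warning and current partition
on non-convergence). Clusters are the connected components of the
converged nonzero structure; every node, including singletons, is emitted.

# Pan-genome matrices and occupancy classes

The pan-genome matrix counts sequences per accession and cluster
(isoforms counted with their representative by default). With N
accessions, occupancy classes are: **core** = occupancy N; **soft-core** =
occupancy at least `round(0.95 * N)` but below N (at the default fraction
this is exactly "core minus one accession" for N of 16 or 19, and the band
merges into core for small N such as 4 — the rounding, rather than a
ceiling, is what makes those identities hold); **cloud** = occupancy at
most 2; **shell** = the remainder.

# ANI

For each accession pair, ANI averages the merged per-pair identities of
co-clustered sequences, optionally restricted to core or single-copy
clusters. Merged per-pair hits are used rather than raw HSPs so fragmented
alignments are not double-counted; whether the original averages raw or
merged alignments is ambiguous, and a flag (`include_isoforms`) exposes
the adjacent choice of counting collapsed isoforms. Accession pairs never
co-clustered yield NA and block dendrogram construction rather than being
silently imputed. Dendrograms use complete linkage on either
`100 - ANI` directly or Euclidean distances among ANI columns (the heatmap
convention).

# Growth simulation and saturation fits

`simulate_composition()` permutes accession order (default 20
permutations) and grows a sequence pool: an incoming sequence is *novel*
unless some pool sequence matches it at identity >= 70 and shortest-mode
coverage >= 50 — thresholds loose enough that retained/unprocessed introns
still match. Matching is sequence-level, not cluster-level, so the
simulated core can differ slightly from the cluster-based core count; both
are reported. core(n) counts pool sequences matched in all n accessions
seen so far; soft_core(n) relaxes that to `ceil(0.95 n)`.

`fit_growth()` fits `kappa * exp(-n/tau) + omega` by Levenberg-Marquardt
least squares on all permutation points (not means), with multi-start
initialization (`omega0` from the last values, `tau0` in {1, N/3}) because
exponential fits are initialization-sensitive. The pan curve is fitted on
per-step novel-gene counts for n >= 2 — pan(1) is a library size, not a
decay observation — and reconstructed by cumulative summation; `omega` is
then the asymptotic number of novel genes per added genome. A constant
curve degenerates gracefully to `kappa = 0, omega = constant`.

# dN/dS

Single-copy clusters with occupancy >= 4 (below that the summary is
meaningless) are codon-aligned: peptides are aligned progressively
(center-star over affine-gap pairwise alignments, BLOSUM62, gap open 10 /
extend 0.5) and back-translated, so gaps always occupy whole codons.

Pairwise dN/dS uses the Nei–Gojobori (1986) counting method with
Jukes–Cantor correction. Site counts are averaged over the two codons;
changes that would create a stop codon are counted as nonsynonymous, so
`S + N = 3 *` codons for every pair — a deliberate, testable invariant.
Multiple-hit codons average over all minimal mutational pathways,
excluding pathways through stops; codons with no stop-free pathway are
dropped entirely. Gap- or N-containing codons are skipped pairwise rather
than column-wise, maximizing usable codons per pair. `omega = dN/dS` is
undefined (NA, never infinite) when `dS = 0`, and undefined pairs are
excluded from cluster means rather than capped. Cluster means above 1.5
are flagged as likely misalignments and excluded from downstream
summaries; below 1 is classified purifying, above 1 positive.

NG86 was chosen over maximum-likelihood or transition/transversion-aware
counting because it is fully specified, fast, and verifiable against an
exhaustive enumeration oracle; *rankings* of omega across occupancy
classes, not absolute values, are the quantity of interest here.

Notched box statistics use type-7 quantiles and the standard notch
`median ± 1.58 * IQR / sqrt(n)`; two groups are called different when
their notches do not overlap.

# Tree distances

Robinson–Foulds (symmetric) distance counts non-trivial bipartitions
present in exactly one unrooted tree. The branch score sums squared
branch-length differences over the union of all bipartitions including
terminal branches (absent split = length 0); because the cited
implementations disagree on whether the squared sum or its root is "the"
branch score, both are reported. `prune_to_common()` restricts two trees
to shared leaves, suppressing degree-2 nodes with lengths summed.

# Consensus CDS and annotation

`find_orfs()` scans all six frames and reports maximal ORFs with 5'/3'
completeness flags. `consensus_cds()` reconciles the best ORF with the
best frame-resolved protein-homology region: same frame and overlapping
spans are assembled into the union (evidence `both`); frame or strand
disagreement defers to homology (`homology`); otherwise the single
available evidence wins, or the transcript is labeled non-coding. The
published description of the original's rule table is a summary, so this
three-row reconstruction is pinned by tests rather than claimed to be a
byte-exact port. Output CDS are always a codon multiple and truncated at
any internal stop.

Retained introns are flagged when a reference intron aligns with an HSP
*strictly* longer than 100 nt at >= 98% identity. Domain enrichment
builds per-domain 2x2 tables with each domain counted at most once per
cluster (isoform bias), tests them with Fisher's exact test (one-sided
enrichment by default; the two-sided and depletion alternatives are
exposed), and adjusts with Benjamini–Hochberg. Cluster expression is the
mean TPM of members with data; members without data are missing, not
zero, unless explicitly requested otherwise.

# The synthetic generator

`generate_pangenome()` emulates the statistical structure the pipeline is
designed for, with exact ground truth. Defaults — chosen once as the
package's study conditions — are 6 accessions and 100 gene families
(50 core / 30 shell with uniform occupancy 3..N-1 / 20 cloud with
occupancy 1–2), ancestral CDS of 300–2400 bp (uniform over codon counts,
start/stop codons, no internal stop), 1% expected *pairwise* divergence
(each copy mutated at half that rate from the ancestor, so downstream ANI
is centred on `100 * (1 - divergence)`), 20% degraded copies (8%
truncated fragments retaining 60% of the sequence, 4% split genes cut at
40–60%, 8% retained introns of 150–400 random bases inserted at a codon
boundary), 10% extra truncated isoforms, and log-normal TPM with
class-ordered meanlog (core 4 > shell 3 > cloud 1, sdlog 1). Mutation is
codon-aware (no internal stops; synonymous-only and nonsynonymous-biased
modes exist for dN/dS fixtures). Everything is deterministic under the
configured seed.

What the generator does **not** emulate: sequencing error, chimeric
assemblies, alternative splicing beyond simple truncation, base
composition bias, gene families with cross-family homology (each family
is an independent random CDS), and transcript abundance–dependent
assembly quality. Passing tests on this fixture therefore demonstrate the
correctness of the algorithms under controlled conditions, not
performance on real transcriptome assemblies.

# Problem sizes and runtime choices

The default validation fixture (6 accessions, ~520–540 sequences,
~1000–3000 all-vs-all candidate pairs) clusters in a few seconds; growth
simulations reuse the clustering graph's merged pairs, and the dN/dS
summary runs on the few dozen single-copy clusters with occupancy >= 4.
These sizes were chosen so that the full test suite and the acceptance
script each complete in minutes on one CPU while still exercising every
degeneracy class (fragments, splits, retained introns, isoforms) at
realistic rates.

# Known limitations

- The built-in aligner is for fixture-scale data; for large real datasets
  precomputed tabular hits from a dedicated search tool are the intended
  input path.
- Ungapped HSPs split alignments at small indels; downstream coverage is
  unaffected, but HSP counts are not comparable with gapped aligners.
- The novelty match in growth simulations is greedy and sequence-level;
  non-transitive match chains can make the final pan size weakly
  order-dependent (a property inherent to the procedure, visible in the
  permutation spread).
- NG86 underestimates dS when transition/transversion bias is strong;
  class comparisons are robust to this, absolute omega values less so.
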