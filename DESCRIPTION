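Package: pangest
Title: Pan-Genome and Pan-Transcriptome Clustering of Same-Species Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters nucleotide sequences from multiple accessions of one
    species into gene families and derives pan-genome summaries. Local
    alignments (computed natively or parsed from 12-column tabular hit
    files) are merged into per-pair coverage and identity statistics,
    turned into a similarity graph, and clustered with bidirectional best
    hits or Markov clustering. Downstream analyses include pan-genome
    matrices with core/soft-core/shell/cloud occupancy classes, average
    nucleotide identity matrices and dendrograms, pan-genome growth
    simulations with exponential-saturation fits, Nei-Gojobori (1986)
    dN/dS estimates on codon alignments, Robinson-Foulds and branch-score
    tree distances, protein-domain enrichment tests, consensus CDS
    inference from transcripts, and a synthetic pan-genome generator with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    igraph,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
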