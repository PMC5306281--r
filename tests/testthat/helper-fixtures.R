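# Shared fixtures. The default synthetic pan-genome and its clustering are
# computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    sp <- generate_pangenome(synth_config(seed = 42L))
    hits <- compute_all_hits(sp$seqs)
    res <- cluster_sequences(sp$seqs, hsps = hits)
    pm <- build_pangenome_matrix(res$clusters, sp$seqs)
    .fixture_cache$default <- list(sp = sp, hits = hits, res = res, pm = pm)
  }
  .fixture_cache$default
}

# a small abstract similarity graph + matching accession set, for
# clustering tests that need exact control over edges
abstract_graph <- function(nodes, edges, min_identity = 95, min_coverage = 50) {
  # nodes: data.frame(seq_id, accession, length); edges: data.frame(q_id,
  # s_id, weight[, total_bitscore, best_evalue, identity, coverage])
  n_e <- nrow(edges)
  if (is.null(edges$total_bitscore)) edges$total_bitscore <- edges$weight
  if (is.null(edges$best_evalue)) edges$best_evalue <- 10^(-edges$weight)
  if (is.null(edges$identity)) edges$identity <- rep(99, n_e)
  if (is.null(edges$coverage)) edges$coverage <- rep(100, n_e)
  edges$acc_q <- nodes$accession[match(edges$q_id, nodes$seq_id)]
  edges$acc_s <- nodes$accession[match(edges$s_id, nodes$seq_id)]
  edges$pass <- rep(TRUE, n_e)
  seq_list <- split(
    setNames(vapply(nodes$length, function(L) random_dna(L), ""), nodes$seq_id),
    nodes$accession)
  seqs <- accession_set(seq_list[unique(nodes$accession)])
  graph <- structure(
    list(nodes = seqs$records, pairs = edges, edges = edges,
         best_hit = pangest:::best_hit_index(edges),
         min_identity = min_identity, min_coverage = min_coverage,
         accessions = seqs$accessions),
    class = "similarity_graph")
  list(graph = graph, seqs = seqs)
}

# symmetric edge table (both directions with equal weight)
both_dirs <- function(q, s, w) {
  data.frame(q_id = c(q, s), s_id = c(s, q), weight = c(w, w),
             stringsAsFactors = FALSE)
}

cluster_member_sets <- function(clusters) {
  lapply(clusters, function(cl) sort(c(cl$members, cl$isoforms)))
}

digest_file <- function(f) unname(tools::md5sum(f))

translate_peptide <- function(nt) {
  suppressWarnings(as.character(Biostrings::translate(Biostrings::DNAString(nt))))
}

write_fasta_file <- function(seqs, path, gz = FALSE) {
  lines <- unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]])))
  if (gz) {
    con <- gzfile(path, "w")
    writeLines(lines, con)
    close(con)
  } else {
    writeLines(lines, path)
  }
  path
}
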