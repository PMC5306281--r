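# Similarity graph: nodes are sequences, directed edges are merged pairwise
# hits passing the identity/coverage thresholds, plus a per-(node, target
# accession) best-hit index used by BDBH and in-paralog detection.

utils::globalVariables(c("idx", "i.idx", "N", "q_id", "s_id", "bitscore",
                         "evalue", "pass", "acc_q", "acc_s", "weight", ".",
                         "pct_identity", "aln_len"))

#' Build a similarity graph from HSPs
#'
#' HSPs are grouped per ordered (query, subject) pair and merged with
#' [merge_hsps()]; a directed edge q -> s exists iff the merged hit passes
#' `identity >= min_identity` and `coverage >= min_coverage` (both
#' inclusive). Coverage mode is `longest` iff *both* ids are declared
#' full-length, `shortest` otherwise. Edge weight is
#' `min(300, -log10(evalue))` with E-value 0 mapped to 300. Self hits are
#' excluded. The default identity cut-off of 95% matches the convention for
#' calling paralogous/isoform sequences within one species.
#'
#' @param hsps HSP data.frame (both directions when available).
#' @param seqs `accession_set`.
#' @param min_identity percent identity threshold (inclusive), default 95.
#' @param min_coverage percent coverage threshold (inclusive), default 50.
#' @param full_length_ids ids of full-length cDNAs (coverage over the
#'   longest sequence when two of them are compared).
#' @return `similarity_graph` object: list with `nodes` (data.frame),
#'   `pairs` (all merged hits with a `pass` flag), `edges` (passing hits
#'   with weights), `best_hit` (per node and target accession), and the
#'   thresholds used.
#' @export
build_similarity_graph <- function(hsps, seqs, min_identity = 95,
                                   min_coverage = 50,
                                   full_length_ids = character(0)) {
  nodes <- seqs$records
  if (nrow(hsps) > 0L) {
    hsps <- hsps[hsps$q_id != hsps$s_id, , drop = FALSE]
  }
  if (nrow(hsps) == 0L) {
    pairs <- data.frame(q_id = character(0), s_id = character(0),
                        Lq = integer(0), Ls = integer(0), covered = integer(0),
                        coverage = numeric(0), identity = numeric(0),
                        best_evalue = numeric(0), total_bitscore = numeric(0),
                        strand = character(0), n_hsps = integer(0),
                        pass = logical(0))
  } else {
    dt <- data.table::as.data.table(hsps)
    lens <- setNames(nodes$length, nodes$seq_id)
    full <- setNames(nodes$seq_id %in% full_length_ids, nodes$seq_id)
    merged <- dt[, {
      q <- .BY[[1L]]
      s <- .BY[[2L]]
      mode <- if (full[[q]] && full[[s]]) "longest" else "shortest"
      merge_hsps_core(.SD, Lq = lens[[q]], Ls = lens[[s]], mode = mode)
    }, by = c("q_id", "s_id")]
    pairs <- as.data.frame(merged)
    pairs$pass <- pairs$identity >= min_identity & pairs$coverage >= min_coverage
  }
  edges <- pairs[pairs$pass, , drop = FALSE]
  if (nrow(edges) > 0L) {
    w <- -log10(edges$best_evalue)
    w[!is.finite(w)] <- 300
    edges$weight <- pmin(300, pmax(0, w))
    edges$acc_s <- seq_accession(seqs, edges$s_id)
    edges$acc_q <- seq_accession(seqs, edges$q_id)
  } else {
    edges$weight <- numeric(0)
    edges$acc_s <- character(0)
    edges$acc_q <- character(0)
  }
  rownames(edges) <- NULL
  g <- structure(
    list(nodes = nodes, pairs = pairs, edges = edges,
         best_hit = best_hit_index(edges),
         min_identity = min_identity, min_coverage = min_coverage,
         accessions = seqs$accessions),
    class = "similarity_graph"
  )
  g
}

# per (source node, target accession): edge with highest bitscore,
# tie -> lower evalue, tie -> lexicographic target id
best_hit_index <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(q_id = character(0), acc_s = character(0),
                      s_id = character(0), total_bitscore = numeric(0),
                      best_evalue = numeric(0), weight = numeric(0)))
  }
  e <- edges[order(edges$q_id, edges$acc_s, -edges$total_bitscore,
                   edges$best_evalue, edges$s_id), , drop = FALSE]
  first <- !duplicated(e[, c("q_id", "acc_s")])
  out <- e[first, c("q_id", "acc_s", "s_id", "total_bitscore", "best_evalue",
                    "weight"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# best hit of `id` within accession `acc`; NULL if none
best_hit_of <- function(graph, id, acc) {
  bh <- graph$best_hit
  row <- bh[bh$q_id == id & bh$acc_s == acc, , drop = FALSE]
  if (nrow(row) == 0L) NULL else row
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf(
    "similarity_graph: %d nodes, %d directed edges (identity >= %.4g%%, coverage >= %.4g%%)\n",
    nrow(x$nodes), nrow(x$edges), x$min_identity, x$min_coverage))
  invisible(x)
}
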