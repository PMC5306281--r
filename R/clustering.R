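# Sequence clustering: redundant-isoform collapse, in-paralog detection,
# bidirectional best hit (BDBH) clustering seeded from a reference
# accession, and Markov clustering of the similarity graph (OMCL-style).

# simple union-find
uf_new <- function(ids) {
  env <- new.env(parent = emptyenv())
  env$parent <- setNames(ids, ids)
  env
}
uf_find <- function(uf, x) {
  while (uf$parent[[x]] != x) {
    uf$parent[[x]] <- uf$parent[[uf$parent[[x]]]]
    x <- uf$parent[[x]]
  }
  x
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a)
  rb <- uf_find(uf, b)
  if (ra != rb) uf$parent[[rb]] <- ra
  invisible(NULL)
}

#' Collapse redundant isoforms within each accession
#'
#' Within one accession only, sequence x is redundant to a longer sequence y
#' when their merged hit has a union overlap of at least `min_overlap` bp
#' (default 40, the classic assembly-redundancy cut-off), identity >=
#' `min_identity`, and shortest-mode coverage >= the graph's coverage
#' threshold. Redundancy groups are transitive closures; the longest member
#' (ties broken lexicographically) represents its group. Dropped sequences
#' are excluded from clustering but reattached to their representative's
#' cluster as isoforms.
#'
#' @param graph `similarity_graph` built from `seqs`.
#' @param seqs `accession_set`.
#' @param min_overlap minimum union overlap in bp (inclusive), default 40.
#' @param min_identity minimum percent identity (inclusive), default 95.
#' @return `redundancy_map`: list with `representative` (named character,
#'   identity for non-redundant ids) and `dropped` (character).
#' @export
collapse_isoforms <- function(graph, seqs, min_overlap = 40L, min_identity = 95) {
  ids <- seqs$records$seq_id
  uf <- uf_new(ids)
  p <- graph$pairs
  if (nrow(p) > 0L) {
    same_acc <- seq_accession(seqs, p$q_id) == seq_accession(seqs, p$s_id)
    hit <- same_acc & p$covered >= min_overlap & p$identity >= min_identity &
      p$coverage >= graph$min_coverage
    sel <- p[hit, , drop = FALSE]
    for (r in seq_len(nrow(sel))) uf_union(uf, sel$q_id[r], sel$s_id[r])
  }
  roots <- vapply(ids, function(x) uf_find(uf, x), "")
  lens <- setNames(seqs$records$length, ids)
  rep_map <- setNames(ids, ids)
  for (grp in split(ids, roots)) {
    if (length(grp) < 2L) next
    rep_id <- grp[order(-lens[grp], grp)][1L]
    rep_map[grp] <- rep_id
  }
  structure(
    list(representative = rep_map,
         dropped = names(rep_map)[rep_map != names(rep_map)]),
    class = "redundancy_map"
  )
}

# filter edges/best-hit index of a graph to a set of retained nodes
graph_restrict <- function(graph, keep_ids) {
  e <- graph$edges
  e <- e[e$q_id %in% keep_ids & e$s_id %in% keep_ids, , drop = FALSE]
  list(edges = e, best_hit = best_hit_index(e))
}

#' Detect in-paralogs (same-accession reciprocal best hits)
#'
#' In-paralogs are sequences whose best hit lies in their own accession:
#' x and y (same accession) are in-paralogs when each is the other's best
#' within-accession hit and their mutual bitscore is at least as good as the
#' best cross-accession hit of either. The returned mapping is symmetric.
#'
#' @param graph `similarity_graph` (best-hit index populated).
#' @param exclude ids to ignore (e.g. collapsed isoforms).
#' @return named list: seq_id -> character vector of in-paralog ids (empty
#'   sets omitted).
#' @export
detect_inparalogs <- function(graph, exclude = character(0)) {
  bh <- graph$best_hit
  if (length(exclude) > 0L) {
    sub <- graph_restrict(graph, setdiff(graph$nodes$seq_id, exclude))
    bh <- sub$best_hit
  }
  if (nrow(bh) == 0L) return(list())
  acc_of <- setNames(graph$nodes$accession, graph$nodes$seq_id)
  own <- bh[bh$acc_s == acc_of[bh$q_id], , drop = FALSE]
  if (nrow(own) == 0L) return(list())
  cross <- bh[bh$acc_s != acc_of[bh$q_id], , drop = FALSE]
  best_cross <- if (nrow(cross) > 0L) {
    tapply(cross$total_bitscore, cross$q_id, max)
  } else {
    setNames(numeric(0), character(0))
  }
  cross_score <- function(id) {
    v <- best_cross[id]
    if (is.na(v)) -Inf else v
  }
  own_best <- setNames(own$s_id, own$q_id)
  pairs <- list()
  for (i in seq_len(nrow(own))) {
    x <- own$q_id[i]
    y <- own$s_id[i]
    if (x >= y) next  # handle each unordered pair once
    if (is.na(own_best[y]) || own_best[y] != x) next
    w <- own$total_bitscore[i]
    if (w >= cross_score(x) && w >= cross_score(y)) {
      pairs[[length(pairs) + 1L]] <- c(x, y)
    }
  }
  out <- list()
  for (p in pairs) {
    out[[p[1L]]] <- sort(unique(c(out[[p[1L]]], p[2L])))
    out[[p[2L]]] <- sort(unique(c(out[[p[2L]]], p[1L])))
  }
  out
}

make_cluster <- function(members, seqs, isoforms = character(0), id = NA_character_) {
  acc <- seq_accession(seqs, members)
  per_acc <- table(factor(acc, levels = seqs$accessions))
  per_acc <- setNames(as.integer(per_acc), names(per_acc))
  per_acc <- per_acc[per_acc > 0L]
  structure(
    list(cluster_id = id, members = sort(members),
         isoforms = sort(isoforms),
         per_accession = per_acc,
         occupancy = length(per_acc),
         single_copy = all(per_acc <= 1L)),
    class = "cluster"
  )
}

# deterministic ids: sort by descending occupancy, then size, then first member
finalize_clusters <- function(raw_members, seqs, redundancy = NULL,
                              inparalogs = NULL) {
  clusters <- lapply(unname(raw_members), function(m) make_cluster(m, seqs))
  first <- vapply(clusters, function(cl) cl$members[1L], "")
  occ <- vapply(clusters, `[[`, 0L, "occupancy")
  size <- vapply(clusters, function(cl) length(cl$members), 0L)
  ord <- order(-occ, -size, first)
  clusters <- clusters[ord]
  if (!is.null(redundancy) && length(redundancy$dropped) > 0L) {
    rep_of <- redundancy$representative
    member_cluster <- unlist(lapply(seq_along(clusters), function(i) {
      setNames(rep(i, length(clusters[[i]]$members)), clusters[[i]]$members)
    }))
    for (d in redundancy$dropped) {
      tgt <- member_cluster[rep_of[[d]]]
      if (!is.na(tgt)) {
        clusters[[tgt]]$isoforms <- sort(c(clusters[[tgt]]$isoforms, d))
      }
    }
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$cluster_id <- sprintf("C%05d", i)
  }
  clusters
}

#' @export
print.cluster <- function(x, ...) {
  cat(sprintf("cluster %s: %d members, occupancy %d%s\n",
              x$cluster_id, length(x$members), x$occupancy,
              if (length(x$isoforms) > 0L)
                sprintf(" (+%d isoforms)", length(x$isoforms)) else ""))
  invisible(x)
}

#' Bidirectional-best-hit clustering seeded from a reference accession
#'
#' Each non-redundant sequence of the reference accession seeds one
#' candidate cluster. For every other accession (input order) the sequence
#' forming a bidirectional best hit with the seed is added, provided its
#' edges pass the graph thresholds. In-paralogs of every added member are
#' then attached. Genes absent from the reference are never clustered.
#'
#' @param graph `similarity_graph`.
#' @param reference reference accession id.
#' @param seqs `accession_set`.
#' @param redundancy optional `redundancy_map` from [collapse_isoforms()].
#' @param min_occupancy drop clusters below this occupancy (0 = keep all).
#' @return list of `cluster` objects.
#' @export
cluster_bdbh <- function(graph, reference, seqs, redundancy = NULL,
                         min_occupancy = 0L) {
  if (!reference %in% graph$accessions) {
    stopf("unknown reference accession '%s'", reference)
  }
  dropped <- if (is.null(redundancy)) character(0) else redundancy$dropped
  keep <- setdiff(graph$nodes$seq_id, dropped)
  sub <- graph_restrict(graph, keep)
  bh <- sub$best_hit
  acc_of <- setNames(graph$nodes$accession, graph$nodes$seq_id)
  seeds <- graph$nodes$seq_id[graph$nodes$accession == reference &
                                graph$nodes$seq_id %in% keep]
  assigned <- setNames(rep(NA_character_, length(keep)), keep)
  members <- setNames(lapply(seeds, function(s) s), seeds)
  for (acc in setdiff(graph$accessions, reference)) {
    for (s in seeds) {
      cand <- bh[bh$q_id == s & bh$acc_s == acc, , drop = FALSE]
      if (nrow(cand) == 0L) next
      cid <- cand$s_id[1L]
      back <- bh[bh$q_id == cid & bh$acc_s == reference, , drop = FALSE]
      if (nrow(back) == 0L || back$s_id[1L] != s) next
      if (!is.na(assigned[[cid]])) next
      assigned[[cid]] <- s
      members[[s]] <- c(members[[s]], cid)
    }
  }
  # attach in-paralogs of every added member (unclustered sequences only;
  # conflicts resolved by strongest link, then seed id)
  inpar <- detect_inparalogs(graph, exclude = dropped)
  if (length(inpar) > 0L) {
    wt <- setNames(sub$edges$total_bitscore,
                   paste(sub$edges$q_id, sub$edges$s_id))
    for (s in seeds) assigned[members[[s]]] <- s
    claims <- list()
    for (x in names(inpar)) {
      if (is.na(assigned[x])) next
      for (y in inpar[[x]]) {
        if (!y %in% keep || !is.na(assigned[y])) next
        w <- wt[paste(x, y)]
        claims[[y]] <- rbind(claims[[y]],
                             data.frame(seed = assigned[[x]],
                                        w = ifelse(is.na(w), 0, w),
                                        stringsAsFactors = FALSE))
      }
    }
    for (y in names(claims)) {
      cl <- claims[[y]][order(-claims[[y]]$w, claims[[y]]$seed), , drop = FALSE]
      s <- cl$seed[1L]
      members[[s]] <- c(members[[s]], y)
      assigned[y] <- s
    }
  }
  clusters <- finalize_clusters(unname(members), seqs, redundancy = redundancy)
  if (min_occupancy > 0L) {
    clusters <- Filter(function(cl) cl$occupancy >= min_occupancy, clusters)
  }
  clusters
}

# --- Markov clustering -----------------------------------------------------

# one dense MCL run on a symmetric non-negative weight matrix
run_mcl <- function(W, inflation, max_iter, prune_below, tol) {
  n <- nrow(W)
  diag(W) <- apply(W, 2, max)  # self-loops = max incident weight
  M <- sweep(W, 2, pmax(colSums(W), .Machine$double.eps), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                       # expansion
    M <- M^inflation                   # inflation
    M[M < prune_below] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warnf("Markov clustering did not converge after %d iterations; using current partition", max_iter)
  }
  # clusters = connected components of the converged nonzero structure
  A <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  igraph::components(g)$membership
}

#' Markov clustering of the similarity graph (OMCL-style)
#'
#' Directed edge weights are symmetrized (mean of both directions, with a
#' missing direction contributing 0, so that one-sided hits from truncated
#' transcripts are retained), then normalized per accession pair by the mean
#' weight of that pair's edges (the OrthoMCL convention, preventing closely
#' related accessions from dominating). Markov clustering is run per
#' connected component: column-normalize, then iterate expansion (matrix
#' square), inflation (elementwise power + column renormalization) and
#' pruning until convergence. With no cluster-size restriction every node,
#' including singletons, is emitted as a cluster.
#'
#' @param graph `similarity_graph`.
#' @param seqs `accession_set`.
#' @param inflation MCL inflation parameter, default 1.5.
#' @param max_iter iteration cap, default 100 (warning + current partition
#'   on non-convergence).
#' @param prune_below entries below this are zeroed each iteration.
#' @param tol convergence tolerance on the max entry change.
#' @param redundancy optional `redundancy_map`; dropped isoforms are
#'   excluded from clustering and reattached to their representative.
#' @param normalize_pairs disable the accession-pair weight normalization
#'   by setting FALSE.
#' @param min_occupancy drop clusters below this occupancy (0 = keep all).
#' @return list of `cluster` objects forming a partition of the
#'   non-redundant nodes.
#' @export
cluster_omcl <- function(graph, seqs, inflation = 1.5, max_iter = 100L,
                         prune_below = 1e-5, tol = 1e-6, redundancy = NULL,
                         normalize_pairs = TRUE, min_occupancy = 0L) {
  dropped <- if (is.null(redundancy)) character(0) else redundancy$dropped
  ids <- setdiff(graph$nodes$seq_id, dropped)
  if (length(ids) == 0L) stopf("cluster_omcl: empty graph")
  e <- graph$edges
  e <- e[e$q_id %in% ids & e$s_id %in% ids, , drop = FALSE]
  # symmetrize: mean of the two directions, absent direction = 0
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (nrow(e) > 0L) {
    dt <- data.table::data.table(k = key(e$q_id, e$s_id), weight = e$weight)
    sym <- dt[, list(weight = sum(weight) / 2), by = "k"]
    uv <- do.call(rbind, strsplit(sym$k, "\r", fixed = TRUE))
    edges <- data.frame(u = uv[, 1L], v = uv[, 2L], weight = sym$weight,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(u = character(0), v = character(0), weight = numeric(0))
  }
  if (normalize_pairs && nrow(edges) > 0L) {
    acc_of <- setNames(graph$nodes$accession, graph$nodes$seq_id)
    pair_key <- key(acc_of[edges$u], acc_of[edges$v])
    mean_w <- tapply(edges$weight, pair_key, mean)
    edges$weight <- edges$weight / as.numeric(mean_w[pair_key])
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  raw <- list()
  for (cc in split(names(comp), comp)) {
    if (length(cc) == 1L) {
      raw[[length(raw) + 1L]] <- cc
      next
    }
    sub <- edges[edges$u %in% cc & edges$v %in% cc, , drop = FALSE]
    W <- matrix(0, length(cc), length(cc), dimnames = list(cc, cc))
    W[cbind(sub$u, sub$v)] <- sub$weight
    W[cbind(sub$v, sub$u)] <- sub$weight
    membership <- run_mcl(W, inflation, max_iter, prune_below, tol)
    raw <- c(raw, split(cc, membership))
  }
  clusters <- finalize_clusters(raw, seqs, redundancy = redundancy)
  if (min_occupancy > 0L) {
    clusters <- Filter(function(cl) cl$occupancy >= min_occupancy, clusters)
  }
  clusters
}

#' One-call clustering pipeline
#'
#' Convenience wrapper: compute (or accept) all-vs-all hits, build the
#' similarity graph, collapse isoforms, and cluster with OMCL or BDBH.
#'
#' @param seqs `accession_set` (at least 2 accessions).
#' @param hsps optional precomputed HSP data.frame (e.g. from
#'   [parse_tabular_hits()]); computed with [compute_all_hits()] otherwise.
#' @param algorithm `"omcl"` (default) or `"bdbh"`.
#' @param reference reference accession (required for BDBH).
#' @param min_identity,min_coverage graph thresholds (defaults 95 / 50).
#' @param isoform_overlap redundancy overlap cut-off in bp (default 40).
#' @param inflation MCL inflation (default 1.5).
#' @param min_occupancy cluster occupancy filter (0 = none).
#' @param full_length_ids ids treated as full-length cDNAs.
#' @return list with `clusters`, `graph`, `redundancy`, `hsps`.
#' @export
cluster_sequences <- function(seqs, hsps = NULL,
                              algorithm = c("omcl", "bdbh"),
                              reference = NULL,
                              min_identity = 95, min_coverage = 50,
                              isoform_overlap = 40L, inflation = 1.5,
                              min_occupancy = 0L,
                              full_length_ids = character(0)) {
  algorithm <- match.arg(algorithm)
  if (length(seqs$accessions) < 2L) stopf("need at least 2 accessions")
  if (is.null(hsps)) hsps <- compute_all_hits(seqs)
  graph <- build_similarity_graph(hsps, seqs, min_identity = min_identity,
                                  min_coverage = min_coverage,
                                  full_length_ids = full_length_ids)
  redundancy <- collapse_isoforms(graph, seqs, min_overlap = isoform_overlap,
                                  min_identity = min_identity)
  clusters <- if (algorithm == "omcl") {
    cluster_omcl(graph, seqs, inflation = inflation, redundancy = redundancy,
                 min_occupancy = min_occupancy)
  } else {
    if (is.null(reference)) stopf("BDBH requires a reference accession")
    cluster_bdbh(graph, reference, seqs, redundancy = redundancy,
                 min_occupancy = min_occupancy)
  }
  list(clusters = clusters, graph = graph, redundancy = redundancy, hsps = hsps)
}
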