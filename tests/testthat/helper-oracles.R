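# Independent oracles used by the property-style tests. These are written
# from the definitions, not from the package implementation, and stay
# deliberately naive.

# per-position coverage counter: number of distinct query positions covered
# by any interval
oracle_union_positions <- function(q_start, q_end, Lq) {
  hit <- logical(Lq)
  for (i in seq_along(q_start)) {
    hit[q_start[i]:q_end[i]] <- TRUE
  }
  sum(hit)
}

# best ungapped local segment between two sequences (exhaustive over all
# diagonals and all segment ends), used to sanity-check the seeded aligner
oracle_best_ungapped <- function(a, b, match = 1, mismatch = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- list(score = 0)
  for (d in (-(length(bv) - 1)):(length(av) - 1)) {
    i0 <- max(1, 1 + d)
    i1 <- min(length(av), length(bv) + d)
    if (i1 < i0) next
    run <- 0
    run_start <- i0
    for (i in i0:i1) {
      sc <- if (av[i] == bv[i - d]) match else mismatch
      if (run <= 0) {
        run <- sc
        run_start <- i
      } else {
        run <- run + sc
      }
      if (run > best$score) {
        best <- list(score = run, q_start = run_start, q_end = i, diag = d)
      }
    }
  }
  best
}

# straightforward dense Markov clustering, coded independently of the
# package (no component decomposition, no igraph)
oracle_mcl <- function(W, inflation = 1.5, max_iter = 200, prune = 1e-5,
                       tol = 1e-6) {
  n <- nrow(W)
  for (i in seq_len(n)) W[i, i] <- max(W[, i])
  M <- W
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    old <- M
    M <- M %*% M
    M <- M^inflation
    M[M < prune] <- 0
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s > 0) M[, j] <- M[, j] / s
    }
    if (max(abs(M - old)) < tol) break
  }
  A <- (M > 0) | t(M > 0)
  # connected components by repeated BFS
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# exhaustive NG86 pathway counts between two codons: enumerate orders of
# the differing positions recursively
oracle_codon_paths <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  diff <- which(substring(c1, 1:3, 1:3) != substring(c2, 1:3, 1:3))
  paths <- list()
  walk <- function(cur, remaining, syn, nonsyn) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(syn = syn, nonsyn = nonsyn)
      return()
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (nxt %in% stops) next
      if (code[[cur]] == code[[nxt]]) {
        walk(nxt, setdiff(remaining, pos), syn + 1, nonsyn)
      } else {
        walk(nxt, setdiff(remaining, pos), syn, nonsyn + 1)
      }
    }
  }
  walk(c1, diff, 0, 0)
  if (length(paths) == 0) return(NULL)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "syn"]), nd = mean(m[, "nonsyn"]), n_paths = nrow(m))
}

# NG86 synonymous sites of one codon from first principles (stops count as
# nonsynonymous targets)
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (!(alt %in% stops) && code[[alt]] == code[[codon]]) syn <- syn + 1 / 3
    }
  }
  syn
}

# splits of a tree by brute force: delete each edge and collect the leaf
# set of the component not containing the alphabetically first tip
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    g <- igraph::graph_from_edgelist(
      matrix(as.character(tree$edge[-e, , drop = FALSE]), ncol = 2), directed = FALSE)
    miss <- setdiff(as.character(unique(as.vector(tree$edge))), igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(miss), name = miss)
    comp <- igraph::components(g)$membership
    child <- as.character(tree$edge[e, 2])
    side_nodes <- names(comp)[comp == comp[child]]
    side <- tips[as.integer(side_nodes[as.integer(side_nodes) <= length(tips)])]
    if (ref %in% side) side <- setdiff(tips, side)
    len <- if (is.null(tree$edge.length)) 0 else tree$edge.length[e]
    key <- paste(sort(side), collapse = "|")
    out[[key]] <- (out[[key]] %||% 0) + len
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hypergeometric tail probabilities by explicit summation over tables with
# fixed margins
oracle_fisher_p <- function(k_exp, n_exp, k_ctl, n_ctl,
                            alternative = "greater") {
  m <- k_exp + k_ctl            # total "with domain"
  total <- n_exp + n_ctl
  lo <- max(0, m - n_ctl)
  hi <- min(m, n_exp)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(total - m, n_exp - x) / choose(total, n_exp)
  }, 0)
  names(probs) <- lo:hi
  p_obs <- probs[as.character(k_exp)]
  switch(alternative,
         greater = sum(probs[as.integer(names(probs)) >= k_exp]),
         less = sum(probs[as.integer(names(probs)) <= k_exp]),
         two.sided = sum(probs[probs <= p_obs + 1e-7]))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# random CDS helper for codon fixtures
random_cds_fixture <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, TRUE), collapse = ""), "TAA")
}
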