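# Fixtures here use abstract similarity graphs with hand-set weights so
# that best-hit orderings are fully controlled.

test_that("exact duplicates within an accession collapse to the longer sequence", {
  set.seed(201)
  a <- random_dna(600)
  seqs <- accession_set(list(A = c(long = a, short = substr(a, 1, 400)),
                             B = c(b1 = random_dna(500))))
  g <- build_similarity_graph(compute_all_hits(seqs), seqs)
  rmap <- collapse_isoforms(g, seqs)
  expect_equal(rmap$dropped, "short")
  expect_equal(unname(rmap$representative["short"]), "long")
  expect_equal(unname(rmap$representative["long"]), "long")
})

test_that("a 39 bp overlap stays below the isoform cut-off; 40 bp collapses", {
  set.seed(202)
  core <- random_dna(39)
  filler1 <- random_dna(300)
  filler2 <- random_dna(300)
  seqs39 <- accession_set(list(A = c(x = paste0(filler1, core),
                                     y = paste0(core, filler2))))
  g39 <- build_similarity_graph(
    compute_all_hits(seqs39, min_hsp_len = 20L), seqs39,
    min_coverage = 10)
  rmap39 <- collapse_isoforms(g39, seqs39)
  expect_length(rmap39$dropped, 0L)
  core40 <- random_dna(40)
  seqs40 <- accession_set(list(A = c(x = paste0(filler1, core40),
                                     y = paste0(core40, filler2))))
  g40 <- build_similarity_graph(
    compute_all_hits(seqs40, min_hsp_len = 20L), seqs40,
    min_coverage = 10)
  rmap40 <- collapse_isoforms(g40, seqs40)
  expect_equal(sort(rmap40$dropped), "y")  # ties on length break to "x"
})

test_that("redundancy chains close transitively onto the longest member", {
  set.seed(203)
  z <- random_dna(900)
  y <- substr(z, 1, 600)
  x <- substr(z, 1, 300)
  seqs <- accession_set(list(A = c(x = x, y = y, z = z)))
  g <- build_similarity_graph(compute_all_hits(seqs), seqs)
  rmap <- collapse_isoforms(g, seqs)
  expect_setequal(rmap$dropped, c("x", "y"))
  expect_equal(unname(rmap$representative[c("x", "y", "z")]),
               c("z", "z", "z"))
})

test_that("in-paralogs are same-accession reciprocal bests beating cross hits", {
  nodes <- data.frame(
    seq_id = c("a1", "a2", "b1"),
    accession = c("A", "A", "B"),
    length = 500L)
  # a1 and a2 hit each other strongly, both hit b1 weakly
  edges <- rbind(both_dirs("a1", "a2", 200),
                 both_dirs("a1", "b1", 50),
                 both_dirs("a2", "b1", 40))
  edges$total_bitscore <- edges$weight * 2
  fx <- abstract_graph(nodes, edges)
  ip <- detect_inparalogs(fx$graph)
  expect_equal(ip[["a1"]], "a2")
  expect_equal(ip[["a2"]], "a1")
  # reweight: a1's cross-accession hit now beats the same-accession hit
  edges2 <- rbind(both_dirs("a1", "a2", 50),
                  both_dirs("a1", "b1", 200),
                  both_dirs("a2", "b1", 40))
  edges2$total_bitscore <- edges2$weight * 2
  fx2 <- abstract_graph(nodes, edges2)
  expect_length(detect_inparalogs(fx2$graph), 0L)
  # an accession with a single sequence has no in-paralogs
  expect_false("b1" %in% names(ip))
})

test_that("BDBH seeds clusters from the reference and skips genes absent from it", {
  nodes <- data.frame(
    seq_id = c("r1", "b1", "c1", "b2", "c2"),
    accession = c("R", "B", "C", "B", "C"),
    length = 500L)
  # r1~b1~c1 reciprocal bests; b2~c2 form a family absent from R
  edges <- rbind(both_dirs("r1", "b1", 250),
                 both_dirs("r1", "c1", 240),
                 both_dirs("b1", "c1", 230),
                 both_dirs("b2", "c2", 260))
  edges$total_bitscore <- edges$weight
  fx <- abstract_graph(nodes, edges)
  clusters <- cluster_bdbh(fx$graph, "R", fx$seqs)
  expect_length(clusters, 1L)
  expect_setequal(clusters[[1]]$members, c("r1", "b1", "c1"))
  expect_equal(clusters[[1]]$occupancy, 3L)
  # every cluster contains a reference sequence; b2/c2 stay unclustered
  all_members <- unlist(lapply(clusters, `[[`, "members"))
  expect_false(any(c("b2", "c2") %in% all_members))
  expect_error(cluster_bdbh(fx$graph, "Z", fx$seqs), "unknown reference")
})

test_that("BDBH attaches in-paralog pairs to their representative's cluster", {
  nodes <- data.frame(
    seq_id = c("r1", "b1", "b2"),
    accession = c("R", "B", "B"),
    length = 500L)
  # b1-b2 are in-paralogs (strongest), b1 is the reciprocal best with r1
  edges <- rbind(both_dirs("b1", "b2", 300),
                 both_dirs("r1", "b1", 200),
                 both_dirs("r1", "b2", 100))
  edges$total_bitscore <- edges$weight
  fx <- abstract_graph(nodes, edges)
  clusters <- cluster_bdbh(fx$graph, "R", fx$seqs)
  expect_length(clusters, 1L)
  expect_setequal(clusters[[1]]$members, c("r1", "b1", "b2"))
  expect_equal(unname(clusters[[1]]$per_accession["B"]), 2L)
})

test_that("Markov clustering recovers clique components exactly", {
  nodes <- data.frame(seq_id = sprintf("n%02d", 1:6),
                      accession = rep(c("A", "B", "C"), 2),
                      length = 400L)
  clique <- function(ids, w) {
    do.call(rbind, lapply(utils::combn(ids, 2, simplify = FALSE),
                          function(p) both_dirs(p[1], p[2], w)))
  }
  edges <- rbind(clique(nodes$seq_id[1:3], 100), clique(nodes$seq_id[4:6], 100))
  fx <- abstract_graph(nodes, edges)
  for (infl in c(1.2, 1.5, 2, 4)) {
    cl <- cluster_omcl(fx$graph, fx$seqs, inflation = infl)
    expect_equal(sort(vapply(cluster_member_sets(cl), paste, "", collapse = ",")),
                 c("n01,n02,n03", "n04,n05,n06"))
  }
})

test_that("a single unconnected node is emitted as a singleton cluster", {
  nodes <- data.frame(seq_id = "lonely", accession = "A", length = 300L)
  edges <- data.frame(q_id = character(0), s_id = character(0),
                      weight = numeric(0))
  fx <- abstract_graph(nodes, edges)
  cl <- cluster_omcl(fx$graph, fx$seqs)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, "lonely")
  expect_equal(cl[[1]]$occupancy, 1L)
})

test_that("a weak bridge between two cliques splits at the bridge, matching an independent MCL", {
  ids <- sprintf("n%d", 1:8)
  nodes <- data.frame(seq_id = ids, accession = "A", length = 400L)
  clique_edges <- function(ids, w) {
    do.call(rbind, lapply(utils::combn(ids, 2, simplify = FALSE),
                          function(p) both_dirs(p[1], p[2], w)))
  }
  edges <- rbind(clique_edges(ids[1:4], 100), clique_edges(ids[5:8], 100),
                 both_dirs("n4", "n5", 10))
  fx <- abstract_graph(nodes, edges)
  cl <- cluster_omcl(fx$graph, fx$seqs, inflation = 1.5,
                     normalize_pairs = FALSE)
  got <- sort(vapply(cluster_member_sets(cl), paste, "", collapse = ","))
  expect_equal(got, c("n1,n2,n3,n4", "n5,n6,n7,n8"))
  # independent dense MCL on the same symmetrized matrix
  W <- matrix(0, 8, 8, dimnames = list(ids, ids))
  W[cbind(edges$q_id, edges$s_id)] <- edges$weight
  comp <- oracle_mcl(W, inflation = 1.5)
  expect_equal(comp[1:4], rep(comp[1], 4))
  expect_equal(comp[5:8], rep(comp[5], 4))
  expect_false(comp[1] == comp[5])
})

test_that("OMCL output partitions the non-redundant nodes", {
  fx <- default_fixture()
  members <- unlist(lapply(fx$res$clusters, `[[`, "members"))
  expect_false(any(duplicated(members)))
  nonredundant <- setdiff(fx$sp$seqs$records$seq_id, fx$res$redundancy$dropped)
  expect_setequal(members, nonredundant)
  # every dropped isoform is attached to exactly one cluster
  isoforms <- unlist(lapply(fx$res$clusters, `[[`, "isoforms"))
  expect_setequal(isoforms, fx$res$redundancy$dropped)
})

test_that("clustering is invariant to accession input order", {
  sp <- generate_pangenome(synth_config(n_accessions = 4L, n_core = 10L,
                                        n_shell = 5L, n_cloud = 5L, seed = 77L))
  res1 <- cluster_sequences(sp$seqs)
  perm <- rev(sp$seqs$accessions)
  seqs2 <- accession_set(lapply(
    setNames(perm, perm),
    function(a) {
      ids <- sp$seqs$records$seq_id[sp$seqs$records$accession == a]
      sp$seqs$seq[ids]
    }))
  res2 <- cluster_sequences(seqs2)
  sets1 <- sort(vapply(cluster_member_sets(res1$clusters), paste, "", collapse = ","))
  sets2 <- sort(vapply(cluster_member_sets(res2$clusters), paste, "", collapse = ","))
  expect_equal(sets1, sets2)
})
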