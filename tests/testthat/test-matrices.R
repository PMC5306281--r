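two_acc_fixture <- function() {
  seqs <- accession_set(list(A = c(a1 = random_dna(300), a2 = random_dna(300)),
                             B = c(b1 = random_dna(300))))
  clusters <- list(pangest:::make_cluster(c("a1", "b1"), seqs, id = "C1"),
                   pangest:::make_cluster("a2", seqs, id = "C2"))
  list(seqs = seqs, clusters = clusters)
}

test_that("the pan-genome matrix counts sequences per accession and cluster", {
  set.seed(301)
  fx <- two_acc_fixture()
  pm <- build_pangenome_matrix(fx$clusters, fx$seqs)
  expect_equal(unname(pm$counts), matrix(c(1L, 1L, 1L, 0L), 2),
               ignore_attr = TRUE)
  expect_equal(unname(pm$occupancy), c(2L, 1L))
  # in-paralogs raise the count but not the occupancy contribution
  seqs <- accession_set(list(A = c(a1 = random_dna(200), a2 = random_dna(200)),
                             B = c(b1 = random_dna(200))))
  cl <- list(pangest:::make_cluster(c("a1", "a2", "b1"), seqs, id = "C1"))
  pm2 <- build_pangenome_matrix(cl, seqs)
  expect_equal(unname(pm2$counts[, 1]), c(2L, 1L))
  expect_equal(unname(pm2$occupancy), 2L)
  # empty cluster list: 0-column matrix
  pm3 <- build_pangenome_matrix(list(), seqs)
  expect_equal(ncol(pm3$counts), 0L)
})

test_that("counts include isoforms when requested and conserve sequences", {
  fx <- default_fixture()
  pm_iso <- build_pangenome_matrix(fx$res$clusters, fx$sp$seqs)
  pm_no <- build_pangenome_matrix(fx$res$clusters, fx$sp$seqs,
                                  include_isoforms = FALSE)
  expect_equal(sum(pm_iso$counts), nrow(fx$sp$seqs$records))
  expect_equal(sum(pm_no$counts),
               nrow(fx$sp$seqs$records) - length(fx$res$redundancy$dropped))
})

fake_pm <- function(occupancies, n_accessions) {
  ids <- sprintf("C%03d", seq_along(occupancies))
  counts <- vapply(occupancies, function(o) {
    v <- integer(n_accessions)
    v[seq_len(o)] <- 1L
    v
  }, integer(n_accessions))
  dimnames(counts) <- list(sprintf("G%02d", seq_len(n_accessions)), ids)
  structure(list(counts = counts, accessions = rownames(counts),
                 cluster_ids = ids,
                 occupancy = setNames(colSums(counts > 0), ids)),
            class = "pangenome_matrix")
}

test_that("occupancy classes at N = 19 match the class definitions", {
  pm <- fake_pm(c(19, 18, 17, 3, 2, 1), 19)
  cls <- classify_occupancy(pm)
  expect_equal(unname(cls),
               c("core", "soft-core", "shell", "shell", "cloud", "cloud"))
})

test_that("occupancy classes at N = 16 put occupancy 3 in the shell", {
  pm <- fake_pm(c(16, 15, 3, 2), 16)
  cls <- classify_occupancy(pm)
  expect_equal(unname(cls), c("core", "soft-core", "shell", "cloud"))
})

test_that("at N = 4 the soft-core band collapses into core (ceil(3.8) = 4)", {
  pm <- fake_pm(c(4, 3, 2), 4)
  cls <- classify_occupancy(pm)
  expect_equal(unname(cls), c("core", "shell", "cloud"))
  expect_false("soft-core" %in% cls)
})

test_that("occupancy classes partition all clusters", {
  fx <- default_fixture()
  cls <- classify_occupancy(fx$pm)
  expect_equal(length(cls), length(fx$pm$cluster_ids))
  expect_equal(sum(table(cls)), length(fx$pm$cluster_ids))
})

test_that("ANI is the arithmetic mean of co-clustered pair identities", {
  seqs <- accession_set(list(A = c(a1 = random_dna(300), a2 = random_dna(300)),
                             B = c(b1 = random_dna(300), b2 = random_dna(300))))
  clusters <- list(pangest:::make_cluster(c("a1", "b1", "b2"), seqs, id = "C1"))
  mk_pair <- function(q, s, ident) data.frame(
    q_id = q, s_id = s, Lq = 300L, Ls = 300L, covered = 300L, coverage = 100,
    identity = ident, best_evalue = 1e-50, total_bitscore = 300,
    strand = "+", n_hsps = 1L, pass = TRUE,
    weight = 50, acc_q = substr(q, 1, 1), acc_s = substr(s, 1, 1))
  pairs <- rbind(mk_pair("a1", "b1", 99), mk_pair("b1", "a1", 99),
                 mk_pair("a1", "b2", 98), mk_pair("b2", "a1", 98))
  graph <- structure(list(nodes = seqs$records, pairs = pairs,
                          edges = pairs, best_hit = pangest:::best_hit_index(pairs),
                          min_identity = 95, min_coverage = 50,
                          accessions = seqs$accessions),
                     class = "similarity_graph")
  ani <- compute_ani(clusters, graph, seqs)
  expect_equal(ani$values["A", "B"], 98.5)
  expect_equal(ani$values["B", "A"], 98.5)
  expect_equal(diag(ani$values), c(A = 100, B = 100))
  expect_equal(ani$n_pairs["A", "B"], 2L)
})

test_that("synthetic ANI is symmetric, 100 on the diagonal, and tracks divergence", {
  fx <- default_fixture()
  ani <- compute_ani(fx$res$clusters, fx$res$graph, fx$sp$seqs)
  expect_true(all(abs(ani$values - t(ani$values)) < 1e-9))
  expect_equal(unname(diag(ani$values)), rep(100, 6))
  off <- ani$values[upper.tri(ani$values)]
  expect_true(all(abs(off - 99.0) <= 0.2))
})

test_that("permuting accession order permutes the ANI matrix consistently", {
  fx <- default_fixture()
  ani <- compute_ani(fx$res$clusters, fx$res$graph, fx$sp$seqs)
  perm <- rev(fx$sp$seqs$accessions)
  seqs2 <- accession_set(lapply(setNames(perm, perm), function(a) {
    ids <- fx$sp$seqs$records$seq_id[fx$sp$seqs$records$accession == a]
    fx$sp$seqs$seq[ids]
  }))
  ani2 <- compute_ani(fx$res$clusters, fx$res$graph, seqs2)
  expect_equal(ani2$values[perm, perm], ani$values[perm, perm])
})

test_that("the ANI dendrogram reflects forced topology and matches a naive oracle", {
  vals <- matrix(98, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  vals["A", "B"] <- vals["B", "A"] <- 99.9
  diag(vals) <- 100
  ani <- structure(list(values = vals, n_pairs = vals * 0 + 1,
                        accessions = c("A", "B", "C")), class = "ani_matrix")
  tr <- ani_dendrogram(ani, method = "distance_direct", linkage = "complete")
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  # 4-accession merge order against a hand-rolled complete-linkage pass
  set.seed(303)
  vals4 <- matrix(runif(16, 95, 98), 4)
  vals4 <- (vals4 + t(vals4)) / 2
  diag(vals4) <- 100
  dimnames(vals4) <- list(LETTERS[1:4], LETTERS[1:4])
  ani4 <- structure(list(values = vals4, n_pairs = vals4 * 0 + 1,
                         accessions = LETTERS[1:4]), class = "ani_matrix")
  tr4 <- ani_dendrogram(ani4, method = "distance_direct", linkage = "complete")
  d <- 100 - vals4
  # first oracle merge = closest pair; it must be a cherry in the tree
  pair <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]
  expect_true(ape::is.monophyletic(tr4, rownames(vals4)[pair]))
  # incomplete matrices are rejected
  vals_na <- vals
  vals_na["A", "C"] <- NA
  ani_na <- structure(list(values = vals_na, n_pairs = vals * 0,
                           accessions = c("A", "B", "C")), class = "ani_matrix")
  expect_error(ani_dendrogram(ani_na), "missing")
})

test_that("NR collapse merges redundant clusters and reports recall/precision", {
  set.seed(304)
  s1 <- random_dna(600)
  s2 <- random_dna(600)
  seqs <- accession_set(list(
    A = c(a1 = s1, a2 = s1, a3 = s2),
    B = c(b1 = random_dna(600))))
  clusters <- list(pangest:::make_cluster("a1", seqs, id = "C1"),
                   pangest:::make_cluster("a2", seqs, id = "C2"),
                   pangest:::make_cluster("a3", seqs, id = "C3"),
                   pangest:::make_cluster("b1", seqs, id = "C4"))
  pm <- build_pangenome_matrix(clusters, seqs)
  # identical representatives C1/C2 collapse into one NR column
  nr <- make_nr_matrix(pm, clusters, seqs)
  expect_equal(length(nr$nr_pm$cluster_ids), 3L)
  expect_equal(sum(nr$nr_pm$counts), sum(pm$counts))
  # NR collapse is idempotent
  nr_clusters <- lapply(nr$nr_pm$cluster_ids, function(id) {
    pangest:::make_cluster(
      clusters[[match(id, vapply(clusters, `[[`, "", "cluster_id"))]]$members,
      seqs, id = id)
  })
  nr2 <- make_nr_matrix(nr$nr_pm, nr_clusters, seqs)
  expect_equal(nr2$nr_pm$cluster_ids, nr$nr_pm$cluster_ids)
  # reference comparison: r1 matches the s1 cluster, r2 matches nothing
  report <- make_nr_matrix(pm, clusters, seqs,
                           reference_cds = c(r1 = s1, r2 = random_dna(600)))$report
  expect_equal(report$matched_references, 1L)
  expect_equal(report$recall, 0.5)
  expect_equal(report$matching_clusters, 1L)
  expect_equal(report$precision, 1 / 3)
  expect_equal(report$clusters_per_cds, 1)
})

test_that("fragmented clusters matching one reference raise the clusters/CDS ratio", {
  set.seed(305)
  ref <- random_dna(900)
  seqs <- accession_set(list(
    A = c(a1 = substr(ref, 1, 450), a2 = substr(ref, 451, 900))))
  clusters <- list(pangest:::make_cluster("a1", seqs, id = "C1"),
                   pangest:::make_cluster("a2", seqs, id = "C2"))
  pm <- build_pangenome_matrix(clusters, seqs)
  report <- make_nr_matrix(pm, clusters, seqs,
                           reference_cds = c(r1 = ref))$report
  expect_equal(report$matched_references, 1L)
  expect_equal(report$matching_clusters, 2L)
  expect_equal(report$clusters_per_cds, 2)
  expect_equal(report$recall, 1)
})

test_that("accessory extraction respects include, exclude, and occupancy floors", {
  counts <- rbind(
    R1 = c(1L, 0L, 0L),
    R2 = c(1L, 0L, 1L),
    S1 = c(1L, 1L, 0L),
    S2 = c(1L, 1L, 0L),
    S3 = c(0L, 1L, 0L))
  colnames(counts) <- c("C1", "C2", "C3")
  pm <- structure(list(counts = counts, accessions = rownames(counts),
                       cluster_ids = colnames(counts),
                       occupancy = setNames(colSums(counts > 0), colnames(counts))),
                  class = "pangenome_matrix")
  # C2 is carried by the S accessions only: accessory relative to R1/R2
  expect_equal(find_accessory(pm, include = "S1", exclude = c("R1", "R2")),
               "C2")
  # C1 is present in an excluded accession: filtered out
  expect_false("C1" %in% find_accessory(pm, include = "S1",
                                        exclude = c("R1", "R2")))
  # without exclusions both C1 (occ 4) and C2 (occ 3) qualify
  expect_equal(find_accessory(pm, include = c("S1", "S2"),
                              exclude = character(0), min_occupancy = 3L),
               c("C1", "C2"))
  # the occupancy floor drops C2 (occ 3) when raised to 4
  expect_equal(find_accessory(pm, include = c("S1", "S2"),
                              exclude = character(0), min_occupancy = 4L),
               "C1")
  expect_error(find_accessory(pm, include = "S1", exclude = "S1"), "overlap")
})
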