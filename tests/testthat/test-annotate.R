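test_that("ORF finding reports the start-to-stop span with completeness flags", {
  o <- find_orfs("AAAATGGCTTAAAAA", min_aa = 1L)
  hit <- o[o$peptide == "MA", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$frame, 1L)
  expect_equal(c(hit$start, hit$end), c(3L, 9L))
  expect_true(hit$complete5)
  expect_true(hit$complete3)
  # all-N input yields nothing
  expect_equal(nrow(find_orfs(strrep("N", 300), min_aa = 1L)), 0L)
})

test_that("reverse-strand ORFs carry negative frames and mirror the forward set", {
  set.seed(701)
  cds <- random_cds_fixture(60)
  fwd <- find_orfs(cds, min_aa = 50L)
  expect_gte(nrow(fwd), 1L)
  expect_equal(fwd$frame[1], 1L)
  rc <- find_orfs(revcomp(cds), min_aa = 50L)
  expect_equal(rc$peptide[1], fwd$peptide[1])
  expect_lt(rc$frame[1], 0L)
  # mirror property: candidate sets coincide up to strand sign
  expect_setequal(fwd$peptide, rc$peptide)
  # (end - start) is always a codon multiple
  expect_true(all((fwd$end - fwd$start) %% 3L == 0L))
})

test_that("consensus CDS assembles same-frame overlapping evidence into the union", {
  set.seed(702)
  # transcript with a clean ORF at 99..459 and no internal stops in frame
  cds <- random_cds_fixture(150)
  nt <- paste0(substr(random_cds_fixture(40), 4, 99), cds)  # 96 nt of context
  orfs <- find_orfs(nt, min_aa = 30L)
  best <- orfs[1, ]
  hom <- data.frame(start = best$start + 60L, end = best$end + 0L,
                    frame = best$frame, score = 500)
  cc <- consensus_cds(nt, orfs, hom)
  expect_equal(cc$evidence, "both")
  expect_equal(cc$start, best$start)
  expect_gte(cc$end, best$end)
  expect_equal(nchar(cc$cds_nt) %% 3L, 0L)
  expect_false(grepl("\\*", cc$peptide))
})

test_that("frame disagreement defers to homology; single or no evidence degrade gracefully", {
  set.seed(703)
  nt <- paste0("AA", random_cds_fixture(80))  # frame +3 ORF
  orfs <- find_orfs(nt, min_aa = 40L)
  # homology on a different frame wins
  hom <- data.frame(start = 0L, end = 60L, frame = 1L, score = 900)
  cc <- consensus_cds(nt, orfs, hom)
  expect_equal(cc$evidence, "homology")
  expect_equal(c(cc$start, cc$end), c(0L, 60L))
  # ORF-only fallback
  cc2 <- consensus_cds(nt, orfs, NULL)
  expect_equal(cc2$evidence, "orf")
  # no evidence at all: non-coding
  cc3 <- consensus_cds(nt, orfs[0, ], NULL)
  expect_equal(cc3$evidence, "none")
  expect_null(cc3$cds_nt)
  # inconsistent homology coordinates are an error
  bad <- data.frame(start = 1L, end = 60L, frame = 1L, score = 1)
  expect_error(consensus_cds(nt, orfs, bad), "inconsistent")
})

test_that("consensus output never contains internal stops and stays codon-aligned", {
  set.seed(704)
  for (rep in 1:10) {
    nt <- paste0(random_dna(sample(5:50, 1)), random_cds_fixture(sample(55:90, 1)),
                 random_dna(sample(5:50, 1)))
    orfs <- find_orfs(nt, min_aa = 30L)
    if (nrow(orfs) == 0L) next
    cc <- consensus_cds(nt, orfs, NULL)
    expect_equal(nchar(cc$cds_nt) %% 3L, 0L)
    expect_false(grepl("\\*", cc$peptide))
  }
})

test_that("retained-intron flags require > 100 nt and >= 98% identity", {
  set.seed(705)
  intron150 <- random_dna(150)
  intron100 <- random_dna(100)
  t1 <- paste0(random_dna(200), intron150, random_dna(200))     # verbatim 150 nt
  t2 <- paste0(random_dna(200), intron100, random_dna(200))     # exactly 100 nt
  i150_div <- mutate_sequence(intron150, 0.03)                  # ~97% identity
  t3 <- paste0(random_dna(200), i150_div, random_dna(200))
  transcripts <- c(with_intron = t1, exact100 = t2, diverged = t3)
  flags <- flag_retained_introns(transcripts,
                                 c(i1 = intron150, i2 = intron100),
                                 min_len = 100L, min_identity = 98)
  expect_true(flags[["with_intron"]])
  expect_false(flags[["exact100"]])   # "longer than 100" is strict
  expect_false(flags[["diverged"]])
  expect_error(flag_retained_introns(transcripts, character(0)), "empty intron")
})

test_that("Fisher enrichment p-values equal brute-force hypergeometric tails", {
  set.seed(706)
  for (rep in 1:100) {
    n_exp <- sample(5:40, 1)
    n_ctl <- sample(50:500, 1)
    k_exp <- sample(0:n_exp, 1)
    k_ctl <- sample(0:n_ctl, 1)
    alt <- sample(c("greater", "less", "two.sided"), 1)
    tab <- matrix(c(k_exp, n_exp - k_exp, k_ctl, n_ctl - k_ctl), 2)
    p_pkg <- fisher.test(tab, alternative = alt)$p.value
    p_ora <- oracle_fisher_p(k_exp, n_exp, k_ctl, n_ctl, alt)
    expect_equal(p_pkg, unname(p_ora), tolerance = 1e-7,
                 info = sprintf("%d/%d vs %d/%d (%s)", k_exp, n_exp, k_ctl, n_ctl, alt))
  }
})

test_that("a worked 2x2 case matches the upper-tail sum and BH is monotone", {
  res <- suppressWarnings(domain_enrichment(
    experiment_clusters = lapply(1:10, function(i) list(paste0("e", i))),
    control_clusters = lapply(1:1000, function(i) list(paste0("c", i))),
    domains = data.frame(
      seq_id = c(paste0("e", 1:8), paste0("c", 1:50)),
      domain_acc = "PF00001"),
    alternative = "greater"))  # disjoint sets on purpose: warning expected
  expect_equal(res$p_value,
               unname(oracle_fisher_p(8, 10, 50, 1000, "greater")),
               tolerance = 1e-9)
  # BH-adjusted values are monotone in p-value rank
  set.seed(707)
  doms <- data.frame(
    seq_id = paste0("s", 1:400),
    domain_acc = sample(paste0("PF", 1:12), 400, TRUE))
  ctl <- lapply(1:400, function(i) list(paste0("s", i)))
  res2 <- domain_enrichment(ctl[1:60], ctl, doms)
  o <- order(res2$p_value)
  expect_true(all(diff(res2$fdr[o]) >= -1e-12))
  expect_true(all(res2$fdr >= res2$p_value - 1e-12))
})

test_that("domains are counted once per cluster regardless of isoforms", {
  seqs <- accession_set(list(A = c(i1 = random_dna(100), i2 = random_dna(100),
                                   i3 = random_dna(100), z1 = random_dna(100))))
  cl_iso <- pangest:::make_cluster("i1", seqs, isoforms = c("i2", "i3"), id = "C1")
  cl_other <- pangest:::make_cluster("z1", seqs, id = "C2")
  doms <- data.frame(seq_id = c("i1", "i2", "i3"), domain_acc = "PF7")
  res <- domain_enrichment(list(cl_iso), list(cl_iso, cl_other), doms)
  expect_equal(res$k_exp, 1L)
  expect_equal(res$k_ctl, 1L)
  # a domain absent from the experiment is never called enriched
  doms2 <- rbind(doms, data.frame(seq_id = "z1", domain_acc = "PF9"))
  res2 <- domain_enrichment(list(cl_iso), list(cl_iso, cl_other), doms2)
  pf9 <- res2[res2$domain_acc == "PF9", ]
  expect_equal(pf9$k_exp, 0L)
  expect_gte(pf9$p_value, 0.5)
  expect_error(domain_enrichment(list(), list(cl_iso), doms), "empty experiment")
})

test_that("cluster expression is the mean member TPM, with missing data excluded", {
  seqs <- accession_set(list(A = c(a1 = random_dna(100), a2 = random_dna(100),
                                   b1 = random_dna(100), c1 = random_dna(100),
                                   d1 = random_dna(100), d2 = random_dna(100)),
                             B = c(e1 = random_dna(100)),
                             C = c(f1 = random_dna(100))))
  clusters <- list(
    pangest:::make_cluster(c("a1", "a2", "e1", "f1"), seqs, id = "C1"),
    pangest:::make_cluster(c("b1", "c1"), seqs, id = "C2"),
    pangest:::make_cluster(c("d1", "d2"), seqs, id = "C3"))
  pm <- build_pangenome_matrix(clusters, seqs)
  classes <- classify_occupancy(pm)
  tpm <- c(a1 = 10, a2 = 20, e1 = 10, f1 = 20, b1 = 7)
  res <- expression_by_class(clusters, pm, classes, tpm)
  expect_equal(unname(res$cluster_expression["C1"]), 15)
  expect_equal(unname(res$cluster_expression["C2"]), 7)   # c1 missing, not zero
  expect_true(is.na(res$cluster_expression["C3"]))
  expect_equal(res$n_no_data, 1L)
  res0 <- expression_by_class(clusters, pm, classes, tpm, na_as_zero = TRUE)
  expect_equal(unname(res0$cluster_expression["C2"]), 3.5)
  expect_error(expression_by_class(clusters, pm, classes, numeric(0)), "empty TPM")
})

test_that("programmed class-ordered expression yields separated notches", {
  fx <- default_fixture()
  classes <- classify_occupancy(fx$pm)
  tpm <- setNames(fx$sp$truth$tpm$tpm, fx$sp$truth$tpm$seq_id)
  res <- expression_by_class(fx$res$clusters, fx$pm, classes, tpm)
  core <- res$by_class[res$by_class$class == "core", ]
  cloud <- res$by_class[res$by_class$class == "cloud", ]
  expect_gt(core$median, cloud$median)
  expect_false(notches_overlap(core, cloud))
})
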