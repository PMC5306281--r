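# Transcript annotation: ORF finding, consensus CDS inference from ORF +
# protein-homology evidence, retained-intron flagging, protein-domain
# enrichment, and expression-by-occupancy summaries.

#' Find open reading frames in all six frames
#'
#' Reports all maximal ORFs of at least `min_aa` codons. Within each
#' stop-to-stop segment the ORF starts at the first start codon
#' (`complete5 = TRUE`); a segment touching the sequence edge without an
#' upstream stop is reported from the edge as 5'-truncated. `complete3`
#' marks the presence of a terminating stop codon (which is never part of
#' the reported span). Coordinates are 0-based half-open on the forward
#' strand; frames are +1..+3 and -1..-3. Candidates translating entirely
#' to X (e.g. all-N input) are dropped.
#'
#' @param nt transcript nucleotide string.
#' @param min_aa minimum peptide length in amino acids, default 50.
#' @return data.frame (sorted by peptide length, descending): frame,
#'   start, end, complete5, complete3, peptide.
#' @export
find_orfs <- function(nt, min_aa = 50L) {
  stopifnot(nchar(nt) > 0L)
  L <- nchar(nt)
  out <- list()
  for (dir in c(1L, -1L)) {
    w <- if (dir == 1L) nt else revcomp(nt)
    for (off in 0:2) {
      n_codons <- (nchar(w) - off) %/% 3L
      if (n_codons < 1L) next
      aa <- translate_nt(substr(w, off + 1L, off + 3L * n_codons))
      aavec <- strsplit(aa, "")[[1]]
      stops <- which(aavec == "*")
      seg_start <- c(1L, stops + 1L)
      seg_end <- c(stops - 1L, n_codons)
      for (s in seq_along(seg_start)) {
        i0 <- seg_start[s]
        i1 <- seg_end[s]
        if (i1 < i0) next
        atg <- which(aavec[i0:i1] == "M")
        if (length(atg) > 0L) {
          orf_i <- i0 + atg[1L] - 1L
          complete5 <- TRUE
        } else if (i0 == 1L) {
          orf_i <- i0  # 5'-truncated: runs off the sequence edge
          complete5 <- FALSE
        } else {
          next
        }
        len_aa <- i1 - orf_i + 1L
        if (len_aa < min_aa) next
        pep <- paste(aavec[orf_i:i1], collapse = "")
        if (grepl("^X+$", pep)) next
        ws <- off + (orf_i - 1L) * 3L       # 0-based on w
        we <- off + i1 * 3L
        if (dir == 1L) {
          start <- ws
          end <- we
        } else {
          start <- L - we
          end <- L - ws
        }
        out[[length(out) + 1L]] <- data.frame(
          frame = dir * (off + 1L), start = start, end = end,
          complete5 = complete5, complete3 = s <= length(stops),
          peptide = pep, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(frame = integer(0), start = integer(0), end = integer(0),
                      complete5 = logical(0), complete3 = logical(0),
                      peptide = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(-nchar(res$peptide), res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# is a (start, end, frame) span frame-consistent on a transcript of length L?
frame_consistent <- function(start, end, frame, L) {
  if (start < 0L || end > L || end <= start) return(FALSE)
  if (frame > 0L) start %% 3L == (frame - 1L) %% 3L
  else (L - end) %% 3L == (-frame - 1L) %% 3L
}

#' Consensus CDS from ORF and protein-homology evidence
#'
#' Combines the best ORF candidate with the best frame-resolved
#' protein-homology region on the transcript: when both agree in frame and
#' overlap, the union span is assembled into a larger CDS (tag `both`);
#' when they disagree in frame or strand, the homology span wins (tag
#' `homology`); with a single evidence source, that source is used (tags
#' `orf` / `homology`); with none, the transcript is labeled non-coding.
#' The emitted CDS always has length divisible by 3 and is truncated at
#' the first internal stop codon, if any.
#'
#' @param nt transcript nucleotide string.
#' @param orfs data.frame from [find_orfs()] (best = first row); may be
#'   empty.
#' @param homology_hits data.frame with columns `start`, `end` (0-based
#'   half-open, forward strand), `frame` and optionally `score`; may be
#'   empty or NULL.
#' @return list: `cds_nt`, `peptide`, `evidence` (`both` / `orf` /
#'   `homology` / `none`), `start`, `end`, `frame` (NA when non-coding).
#' @export
consensus_cds <- function(nt, orfs, homology_hits = NULL) {
  L <- nchar(nt)
  no_cds <- list(cds_nt = NULL, peptide = NULL, evidence = "none",
                 start = NA_integer_, end = NA_integer_, frame = NA_integer_)
  best_orf <- if (!is.null(orfs) && nrow(orfs) > 0L) orfs[1L, ] else NULL
  best_hom <- NULL
  if (!is.null(homology_hits) && nrow(homology_hits) > 0L) {
    h <- homology_hits
    if (is.null(h$score)) h$score <- h$end - h$start
    h <- h[order(-h$score, h$start), , drop = FALSE]
    best_hom <- h[1L, ]
    if (!frame_consistent(best_hom$start, best_hom$end, best_hom$frame, L)) {
      stopf("homology hit with coordinates inconsistent with its frame")
    }
  }
  if (is.null(best_orf) && is.null(best_hom)) return(no_cds)
  if (is.null(best_hom)) {
    span <- c(best_orf$start, best_orf$end, best_orf$frame)
    evidence <- "orf"
  } else if (is.null(best_orf)) {
    span <- c(best_hom$start, best_hom$end, best_hom$frame)
    evidence <- "homology"
  } else if (best_orf$frame == best_hom$frame &&
             best_orf$start < best_hom$end && best_hom$start < best_orf$end) {
    span <- c(min(best_orf$start, best_hom$start),
              max(best_orf$end, best_hom$end), best_orf$frame)
    evidence <- "both"
  } else {
    span <- c(best_hom$start, best_hom$end, best_hom$frame)
    evidence <- "homology"
  }
  start <- span[1L]
  end <- span[2L]
  frame <- span[3L]
  end <- start + ((end - start) %/% 3L) * 3L  # enforce codon multiple
  region <- substr(nt, start + 1L, end)
  if (frame < 0L) region <- revcomp(region)
  pep <- translate_nt(region)
  stop_at <- regexpr("*", pep, fixed = TRUE)
  if (stop_at > 0L && stop_at < nchar(pep)) {
    # internal stop: truncate the CDS just before it
    keep <- (stop_at - 1L) * 3L
    if (frame > 0L) end <- start + keep else start <- end - keep
    region <- substr(region, 1L, keep)
    pep <- substr(pep, 1L, stop_at - 1L)
  } else if (stop_at == nchar(pep) && stop_at > 0L) {
    pep <- substr(pep, 1L, nchar(pep) - 1L)
  }
  list(cds_nt = region, peptide = pep, evidence = evidence,
       start = start, end = end, frame = frame)
}

#' Flag transcripts carrying retained introns
#'
#' A transcript is flagged when some reference intron aligns to it with an
#' HSP strictly longer than `min_len` nucleotides (default 100) at
#' identity >= `min_identity` (default 98).
#'
#' @param transcripts `accession_set` (or named character vector).
#' @param introns named character vector of intron sequences, or a FASTA
#'   path.
#' @param min_len HSP length threshold, exclusive (default 100).
#' @param min_identity percent identity threshold, inclusive (default 98).
#' @return named logical vector, one flag per transcript.
#' @export
flag_retained_introns <- function(transcripts, introns, min_len = 100L,
                                  min_identity = 98) {
  seqs <- if (inherits(transcripts, "accession_set")) transcripts$seq else transcripts
  if (is.character(introns) && length(introns) == 1L && file.exists(introns)) {
    introns <- read_fasta_chr(introns, type = "DNA")
  }
  if (length(introns) == 0L) stopf("empty intron reference set")
  flags <- setNames(rep(FALSE, length(seqs)), names(seqs))
  for (t_id in names(seqs)) {
    for (intr in introns) {
      h <- local_align(intr, seqs[[t_id]], min_hsp_len = min_len,
                       min_hsp_identity = min_identity)
      if (nrow(h) > 0L &&
          any(h$aln_len > min_len & h$pct_identity >= min_identity)) {
        flags[t_id] <- TRUE
        break
      }
    }
  }
  flags
}

# cluster -> unique domain set, each domain counted at most once per
# cluster regardless of how many isoforms carry it
cluster_domain_sets <- function(clusters, domain_map) {
  lapply(clusters, function(cl) {
    members <- if (inherits(cl, "cluster")) c(cl$members, cl$isoforms)
               else unlist(cl, use.names = FALSE)
    unique(unlist(domain_map[members], use.names = FALSE))
  })
}

#' Protein-domain enrichment between cluster sets
#'
#' For each domain, builds the 2x2 table of clusters with/without the
#' domain in the experiment vs control sets (each domain counted at most
#' once per cluster, avoiding isoform bias) and applies Fisher's exact
#' test, with Benjamini-Hochberg FDR across all tested domains.
#'
#' @param experiment_clusters,control_clusters lists of `cluster` objects
#'   (or plain lists of member-id vectors). The experiment set is expected
#'   to be a subset of the control set (warning otherwise).
#' @param domains data.frame with columns `seq_id`, `domain_acc`, or a TSV
#'   path with those columns.
#' @param alternative `"greater"` (enrichment, default), `"less"`, or
#'   `"two.sided"`.
#' @return data.frame sorted by FDR: domain_acc, k_exp, n_exp, k_ctl,
#'   n_ctl, odds_ratio, p_value, fdr, direction.
#' @export
domain_enrichment <- function(experiment_clusters, control_clusters, domains,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(experiment_clusters) == 0L) stopf("empty experiment set")
  if (is.character(domains) && length(domains) == 1L) {
    domains <- read_tsv(domains)
  }
  stopifnot(all(c("seq_id", "domain_acc") %in% names(domains)))
  domain_map <- split(domains$domain_acc, domains$seq_id)
  exp_sets <- cluster_domain_sets(experiment_clusters, domain_map)
  ctl_sets <- cluster_domain_sets(control_clusters, domain_map)
  exp_ids <- vapply(experiment_clusters, function(cl)
    if (inherits(cl, "cluster")) cl$cluster_id else paste(sort(unlist(cl)), collapse = ","), "")
  ctl_ids <- vapply(control_clusters, function(cl)
    if (inherits(cl, "cluster")) cl$cluster_id else paste(sort(unlist(cl)), collapse = ","), "")
  if (!all(exp_ids %in% ctl_ids)) {
    warnf("experiment set is not a subset of the control set")
  }
  n_exp <- length(exp_sets)
  n_ctl <- length(ctl_sets)
  tested <- sort(unique(unlist(c(exp_sets, ctl_sets), use.names = FALSE)))
  if (length(tested) == 0L) stopf("no domains annotated in either set")
  rows <- lapply(tested, function(d) {
    k_exp <- sum(vapply(exp_sets, function(s) d %in% s, TRUE))
    k_ctl <- sum(vapply(ctl_sets, function(s) d %in% s, TRUE))
    tab <- matrix(c(k_exp, n_exp - k_exp, k_ctl, n_ctl - k_ctl), nrow = 2L)
    ft <- fisher.test(tab, alternative = alternative)
    data.frame(
      domain_acc = d, k_exp = k_exp, n_exp = n_exp,
      k_ctl = k_ctl, n_ctl = n_ctl,
      odds_ratio = unname(ft$estimate), p_value = ft$p.value,
      direction = if (k_exp / n_exp >= k_ctl / n_ctl) "enriched" else "depleted",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$fdr, res$p_value, res$domain_acc),
             c("domain_acc", "k_exp", "n_exp", "k_ctl", "n_ctl",
               "odds_ratio", "p_value", "fdr", "direction")]
  rownames(res) <- NULL
  res
}

#' Expression summaries per occupancy class
#'
#' The expression of a cluster is the mean TPM of its members with data
#' (members without a TPM value are treated as missing, not zero, unless
#' `na_as_zero`). Returns notched box statistics per occupancy level and
#' per occupancy class, plus the per-cluster expression values and a tally
#' of clusters with no expressed member.
#'
#' @param clusters list of `cluster` objects.
#' @param pm `pangenome_matrix` matching `clusters`.
#' @param classes per-cluster class labels from [classify_occupancy()].
#' @param tpm named numeric vector (seq_id -> TPM), or a TSV path / data
#'   frame with columns `seq_id`, `tpm`.
#' @param na_as_zero treat missing TPMs as 0 instead of missing.
#' @return list: `cluster_expression` (named numeric),
#'   `by_occupancy` (data.frame of [box_stats()] rows), `by_class`
#'   (likewise, one row per class), `n_no_data`.
#' @export
expression_by_class <- function(clusters, pm, classes, tpm,
                                na_as_zero = FALSE) {
  if (is.character(tpm) && length(tpm) == 1L) tpm <- read_tsv(tpm)
  if (is.data.frame(tpm)) {
    stopifnot(all(c("seq_id", "tpm") %in% names(tpm)))
    tpm <- setNames(tpm$tpm, tpm$seq_id)
  }
  if (length(tpm) == 0L) stopf("empty TPM table")
  expr <- vapply(clusters, function(cl) {
    members <- c(cl$members, cl$isoforms)
    v <- tpm[members]
    if (na_as_zero) v[is.na(v)] <- 0
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  names(expr) <- vapply(clusters, `[[`, "", "cluster_id")
  n_no_data <- sum(is.na(expr))
  has <- !is.na(expr)
  if (!any(has)) stopf("no cluster has an expressed member")
  by_occ <- stratify_by_occupancy(expr[has], pm$occupancy)
  cls <- classes[names(expr)[has]]
  by_class <- do.call(rbind, lapply(
    intersect(c("core", "soft-core", "shell", "cloud"), unique(cls)),
    function(cl_name) {
      cbind(data.frame(class = cl_name),
            box_stats(expr[has][cls == cl_name]))
    }))
  list(cluster_expression = expr, by_occupancy = by_occ,
       by_class = by_class, n_no_data = n_no_data)
}
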