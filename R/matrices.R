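# Pan-genome matrices (accessions x clusters), occupancy classes, ANI
# matrices and dendrograms, non-redundant matrices with reference
# recall/precision, and accessory-set extraction.

#' Build a pan-genome matrix from clusters
#'
#' A pan-genome matrix (PM) counts the number of sequences from each
#' accession present in each cluster; rows are accessions, columns are
#' clusters. Occupancy of a column is the number of accessions with a
#' nonzero count.
#'
#' @param clusters list of `cluster` objects.
#' @param seqs `accession_set` (provides the accession row order and
#'   resolves isoform accessions).
#' @param include_isoforms count collapsed isoforms in their
#'   representative's cluster (default TRUE).
#' @return `pangenome_matrix`: list with `counts` (integer matrix),
#'   `accessions`, `cluster_ids`, `occupancy`.
#' @export
build_pangenome_matrix <- function(clusters, seqs, include_isoforms = TRUE) {
  accs <- seqs$accessions
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  counts <- matrix(0L, nrow = length(accs), ncol = length(clusters),
                   dimnames = list(accs, ids))
  for (i in seq_along(clusters)) {
    members <- clusters[[i]]$members
    if (include_isoforms) members <- c(members, clusters[[i]]$isoforms)
    macc <- seq_accession(seqs, members)
    if (anyNA(macc)) stopf("cluster member with unknown accession: %s",
                           members[is.na(macc)][1L])
    tab <- table(factor(macc, levels = accs))
    counts[, i] <- as.integer(tab)
  }
  structure(
    list(counts = counts, accessions = accs, cluster_ids = ids,
         occupancy = setNames(colSums(counts > 0L), ids)),
    class = "pangenome_matrix"
  )
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat(sprintf("pangenome_matrix: %d accessions x %d clusters\n",
              length(x$accessions), length(x$cluster_ids)))
  invisible(x)
}

#' Write a pan-genome matrix as TSV
#'
#' Rows are accessions, columns cluster ids, cells integer counts.
#' @param pm `pangenome_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pangenome_matrix <- function(pm, path) {
  df <- data.frame(accession = pm$accessions, pm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Classify clusters into core / soft-core / shell / cloud occupancy classes
#'
#' With N accessions: `core` clusters have occupancy N; `soft-core`
#' clusters satisfy `round(soft_fraction * N) <= occupancy < N` (core
#' genes that may be absent from about one accession: at the default
#' fraction this is occupancy >= N-1 for N of 16 or 19, and the band
#' merges into core for small N such as 4); `cloud` clusters have
#' occupancy at most `cloud_max` (default 2); everything else is `shell`.
#' If the soft-core band dips to or below `cloud_max` the soft band wins,
#' with a warning.
#'
#' @param pm `pangenome_matrix` with at least 3 accessions.
#' @param soft_fraction soft-core fraction of N (default 0.95, which gives
#'   occupancy >= N-1 for N of 16 or 19).
#' @param cloud_max maximum occupancy of cloud clusters (default 2).
#' @return named character vector (per cluster id) with levels
#'   core/soft-core/shell/cloud.
#' @export
classify_occupancy <- function(pm, soft_fraction = 0.95, cloud_max = 2L) {
  n <- length(pm$accessions)
  if (n < 3L) stopf("occupancy classification needs at least 3 accessions")
  occ <- pm$occupancy
  soft_min <- floor(soft_fraction * n + 0.5)  # round half up
  if (soft_min <= cloud_max) {
    warnf("soft-core threshold (%d) overlaps the cloud band (<= %d); soft-core wins",
          soft_min, cloud_max)
  }
  cls <- ifelse(occ == n, "core",
         ifelse(occ >= soft_min, "soft-core",
         ifelse(occ <= cloud_max, "cloud", "shell")))
  setNames(cls, names(occ))
}

# which clusters pass an ANI/dN-dS style cluster filter
filter_clusters <- function(clusters, n_accessions,
                            filter = c("all", "core", "single_copy"),
                            min_occupancy = 0L) {
  filter <- match.arg(filter)
  keep <- vapply(clusters, function(cl) {
    if (filter == "core" && cl$occupancy < n_accessions) return(FALSE)
    if (filter == "single_copy" && !cl$single_copy) return(FALSE)
    cl$occupancy >= min_occupancy
  }, TRUE)
  clusters[keep]
}

#' Compute an average nucleotide identity (ANI) matrix
#'
#' For each pair of accessions (A, B), ANI is the mean merged-alignment
#' identity over all retained pairwise hits between A-sequences and
#' B-sequences that lie in the same cluster, restricted to clusters passing
#' the filter. Accession pairs never co-clustered get NA (reported; a
#' dendrogram cannot be built from an incomplete matrix). The diagonal
#' is 100.
#'
#' @param clusters list of `cluster` objects.
#' @param graph `similarity_graph` holding the merged pairwise hits.
#' @param seqs `accession_set`.
#' @param filter `"all"`, `"core"`, or `"single_copy"`.
#' @param min_occupancy additional occupancy floor (default 0).
#' @param include_isoforms also use alignments of collapsed isoforms
#'   (default FALSE: merged per-pair hits of non-redundant members only,
#'   avoiding double counting of fragmented alignments).
#' @return `ani_matrix`: list with `values` (percent matrix), `n_pairs`
#'   (alignment counts) and `accessions`.
#' @export
compute_ani <- function(clusters, graph, seqs,
                        filter = c("all", "core", "single_copy"),
                        min_occupancy = 0L, include_isoforms = FALSE) {
  filter <- match.arg(filter)
  accs <- seqs$accessions
  clusters <- filter_clusters(clusters, length(accs), filter, min_occupancy)
  if (length(clusters) == 0L) stopf("cluster filter left no clusters")
  acc_of <- setNames(seqs$records$accession, seqs$records$seq_id)
  p <- graph$pairs
  pk <- paste(pmin(p$q_id, p$s_id), pmax(p$q_id, p$s_id), sep = "\r")
  pid <- tapply(p$identity, pk, mean)  # mean of the two directions
  sums <- matrix(0, length(accs), length(accs), dimnames = list(accs, accs))
  cnts <- matrix(0L, length(accs), length(accs), dimnames = list(accs, accs))
  for (cl in clusters) {
    members <- cl$members
    if (include_isoforms) members <- c(members, cl$isoforms)
    if (length(members) < 2L) next
    cmb <- utils::combn(sort(members), 2L)
    keys <- paste(cmb[1L, ], cmb[2L, ], sep = "\r")
    idn <- pid[keys]
    ok <- !is.na(idn)
    if (!any(ok)) next
    a1 <- acc_of[cmb[1L, ok]]
    a2 <- acc_of[cmb[2L, ok]]
    cross <- a1 != a2
    if (!any(cross)) next
    for (j in which(cross)) {
      sums[a1[j], a2[j]] <- sums[a1[j], a2[j]] + idn[ok][j]
      sums[a2[j], a1[j]] <- sums[a2[j], a1[j]] + idn[ok][j]
      cnts[a1[j], a2[j]] <- cnts[a1[j], a2[j]] + 1L
      cnts[a2[j], a1[j]] <- cnts[a2[j], a1[j]] + 1L
    }
  }
  vals <- sums / cnts
  vals[cnts == 0L] <- NA_real_
  diag(vals) <- 100
  diag(cnts) <- 0L
  if (any(is.na(vals))) {
    warnf("%d accession pair(s) never co-clustered under this filter (NA in ANI matrix)",
          sum(is.na(vals[upper.tri(vals)])))
  }
  structure(list(values = vals, n_pairs = cnts, accessions = accs),
            class = "ani_matrix")
}

#' @export
print.ani_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("ani_matrix: %d accessions, mean off-diagonal ANI %.3f%%\n",
              length(x$accessions), mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Write an ANI matrix as a square TSV
#' @param ani `ani_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ani_matrix <- function(ani, path) {
  df <- data.frame(accession = ani$accessions, ani$values, check.names = FALSE)
  write_tsv(df, path)
}

#' Hierarchical-clustering dendrogram of an ANI matrix
#'
#' `distance_direct` uses d = 100 - ANI; `euclidean_columns` (the heatmap
#' convention: Euclidean distances among ANI columns) uses the distance
#' between ANI column vectors. Complete or average linkage.
#'
#' @param ani complete `ani_matrix` (no missing values).
#' @param method `"euclidean_columns"` (default) or `"distance_direct"`.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return `phylo` tree (ape) with branch lengths; write with
#'   [ape::write.tree()].
#' @export
ani_dendrogram <- function(ani, method = c("euclidean_columns", "distance_direct"),
                           linkage = c("complete", "average")) {
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  if (any(is.na(ani$values))) stopf("ANI matrix has missing values; cannot build dendrogram")
  d <- if (method == "distance_direct") {
    as.dist(100 - ani$values)
  } else {
    dist(t(ani$values), method = "euclidean")
  }
  hc <- hclust(d, method = linkage)
  ape::as.phylo(hc)
}

#' Collapse a pan-genome matrix to non-redundant clusters and compare to
#' reference CDS
#'
#' Step 1 collapses clusters whose representatives (longest member) align
#' at `>= min_identity` identity and `>= min_coverage` shortest-mode
#' coverage, greedily by descending representative length, so the most
#' complete model absorbs its fragments. Step 2 (optional) matches NR
#' clusters against a reference CDS set under the same thresholds and
#' reports recall (matched references / references), precision (matching
#' clusters / NR clusters), and the clusters-per-matched-reference ratio.
#'
#' @param pm `pangenome_matrix` for `clusters`.
#' @param clusters list of `cluster` objects.
#' @param seqs `accession_set`.
#' @param min_identity,min_coverage match thresholds (defaults 95 / 50).
#' @param reference_cds optional: named character vector of reference CDS
#'   nucleotide sequences, or a FASTA path.
#' @return list with `nr_pm` (`pangenome_matrix` of NR columns),
#'   `nr_members` (NR column -> absorbed cluster ids) and `report`
#'   (one-row data.frame; only when `reference_cds` given).
#' @export
make_nr_matrix <- function(pm, clusters, seqs, min_identity = 95,
                           min_coverage = 50, reference_cds = NULL) {
  stopifnot(length(clusters) == length(pm$cluster_ids))
  reps <- vapply(clusters, cluster_representative, "", seqs = seqs)
  rep_len <- seq_length(seqs, reps)
  ord <- order(-rep_len, reps)
  kept <- integer(0)  # indices of NR column leaders
  absorb <- integer(length(clusters))  # leader index per cluster
  matches_nr <- function(rep_id, leader_id) {
    pair_matches(seqs$seq[[rep_id]], seqs$seq[[leader_id]],
                 min_identity, min_coverage)
  }
  for (i in ord) {
    hit <- 0L
    for (jj in kept) {
      if (matches_nr(reps[i], reps[jj])) {
        hit <- jj
        break
      }
    }
    if (hit == 0L) {
      kept <- c(kept, i)
      absorb[i] <- i
    } else {
      absorb[i] <- hit
    }
  }
  nr_ids <- pm$cluster_ids[kept]
  counts <- matrix(0L, length(pm$accessions), length(kept),
                   dimnames = list(pm$accessions, nr_ids))
  for (i in seq_along(clusters)) {
    j <- match(absorb[i], kept)
    counts[, j] <- counts[, j] + pm$counts[, i]
  }
  nr_pm <- structure(
    list(counts = counts, accessions = pm$accessions, cluster_ids = nr_ids,
         occupancy = setNames(colSums(counts > 0L), nr_ids)),
    class = "pangenome_matrix"
  )
  nr_members <- split(pm$cluster_ids, pm$cluster_ids[match(absorb, seq_along(clusters))])
  out <- list(nr_pm = nr_pm, nr_members = nr_members)
  if (!is.null(reference_cds)) {
    if (is.character(reference_cds) && length(reference_cds) == 1L &&
        file.exists(reference_cds)) {
      reference_cds <- read_fasta_chr(reference_cds, type = "DNA")
    }
    if (length(reference_cds) == 0L) stopf("empty reference CDS set")
    ref_ids <- names(reference_cds)
    matched_ref <- setNames(rep(FALSE, length(ref_ids)), ref_ids)
    cluster_match <- setNames(rep(FALSE, length(kept)), nr_ids)
    for (j in seq_along(kept)) {
      rep_seq <- seqs$seq[[reps[kept[j]]]]
      for (r in ref_ids) {
        if (pair_matches(rep_seq, reference_cds[[r]], min_identity, min_coverage)) {
          matched_ref[r] <- TRUE
          cluster_match[j] <- TRUE
        }
      }
    }
    n_matched_ref <- sum(matched_ref)
    n_matching_clusters <- sum(cluster_match)
    out$report <- data.frame(
      nr_clusters = length(kept),
      references = length(ref_ids),
      matched_references = n_matched_ref,
      matching_clusters = n_matching_clusters,
      recall = n_matched_ref / length(ref_ids),
      precision = n_matching_clusters / length(kept),
      clusters_per_cds = if (n_matched_ref > 0L)
        n_matching_clusters / n_matched_ref else NA_real_,
      pan_size = length(kept)
    )
  }
  out
}

# does a pair of sequences match at the identity/coverage thresholds?
pair_matches <- function(a, b, min_identity, min_coverage,
                         min_hsp_identity = NULL) {
  if (is.null(min_hsp_identity)) {
    min_hsp_identity <- max(70, min_identity - 5)
  }
  h <- local_align(a, b, min_hsp_identity = min_hsp_identity)
  if (nrow(h) == 0L) return(FALSE)
  m <- merge_hsps(h, nchar(a), nchar(b), mode = "shortest")
  m$identity >= min_identity && m$coverage >= min_coverage
}

#' Extract accessory clusters present in some accessions and absent from
#' others
#'
#' Returns clusters with nonzero counts for every accession in `include`,
#' zero counts for every accession in `exclude`, and occupancy at least
#' `min_occupancy` (default 3, the floor below which transcript clusters
#' are dominated by artifacts).
#'
#' @param pm `pangenome_matrix`.
#' @param include accessions that must all carry the cluster.
#' @param exclude accessions that must all lack it (disjoint from
#'   `include`).
#' @param min_occupancy occupancy floor, default 3.
#' @return character vector of cluster ids.
#' @export
find_accessory <- function(pm, include, exclude = character(0),
                           min_occupancy = 3L) {
  if (length(intersect(include, exclude)) > 0L) {
    stopf("include and exclude sets overlap")
  }
  unknown <- setdiff(c(include, exclude), pm$accessions)
  if (length(unknown) > 0L) stopf("unknown accessions: %s", paste(unknown, collapse = ", "))
  ok <- rep(TRUE, length(pm$cluster_ids))
  for (a in include) ok <- ok & pm$counts[a, ] > 0L
  for (a in exclude) ok <- ok & pm$counts[a, ] == 0L
  ok <- ok & pm$occupancy >= min_occupancy
  pm$cluster_ids[ok]
}
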