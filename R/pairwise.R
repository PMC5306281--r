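# Local-alignment evidence: native fixture-scale aligner, 12-column tabular
# hit parsing, and merging of HSPs into per-pair coverage/identity summaries.
#
# HSPs are rows of a data.frame with the 12-column tabular-hit fields
# (1-based inclusive coordinates; minus strand encoded, as in BLAST output,
# by s_start > s_end) plus a derived `strand` column.

hsp_columns <- c("q_id", "s_id", "pct_identity", "aln_len", "mismatch",
                 "gapopen", "q_start", "q_end", "s_start", "s_end",
                 "evalue", "bitscore", "strand")

empty_hsps <- function() {
  data.frame(q_id = character(0), s_id = character(0),
             pct_identity = numeric(0), aln_len = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Parse 12-column tabular alignment hits
#'
#' Reads the standard tab-separated hit format (columns qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Strand is derived: `-` iff sstart > send. Self hits (qseqid == sseqid)
#' are retained but flagged in the `self` column.
#'
#' @param path file path (or connection) to the tabular hits.
#' @param seqs optional `accession_set`; when given, hits whose ids are not
#'   resolvable are skipped with a warning (or rejected when `strict`).
#' @param strict error on malformed lines / unknown ids instead of
#'   skipping them with a warning.
#' @return HSP data.frame.
#' @export
parse_tabular_hits <- function(path, seqs = NULL, strict = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_hsps())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 12L
  if (any(!ok)) {
    if (strict) stopf("malformed tabular hit line (expected 12 columns): '%s'",
                      lines[!ok][1L])
    warnf("skipped %d malformed tabular hit line(s)", sum(!ok))
    fields <- fields[ok]
  }
  if (length(fields) == 0L) return(empty_hsps())
  m <- do.call(rbind, fields)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  hsps <- data.frame(
    q_id = m[, 1L], s_id = m[, 2L],
    pct_identity = num(3L), aln_len = as.integer(num(4L)),
    mismatch = as.integer(num(5L)), gapopen = as.integer(num(6L)),
    q_start = as.integer(num(7L)), q_end = as.integer(num(8L)),
    s_start = as.integer(num(9L)), s_end = as.integer(num(10L)),
    evalue = num(11L), bitscore = num(12L),
    stringsAsFactors = FALSE
  )
  bad <- !stats::complete.cases(hsps[, 3:12]) | hsps$q_start > hsps$q_end |
    hsps$aln_len < 1L | hsps$pct_identity < 0 | hsps$pct_identity > 100
  if (any(bad)) {
    if (strict) stopf("non-numeric or invalid fields in tabular hits (line %d)",
                      which(bad)[1L])
    warnf("skipped %d invalid tabular hit line(s)", sum(bad))
    hsps <- hsps[!bad, , drop = FALSE]
  }
  if (!is.null(seqs)) {
    known <- hsps$q_id %in% seqs$records$seq_id & hsps$s_id %in% seqs$records$seq_id
    if (any(!known)) {
      if (strict) stopf("tabular hits reference unknown sequence ids")
      warnf("skipped %d hit(s) with unresolvable sequence ids", sum(!known))
      hsps <- hsps[known, , drop = FALSE]
    }
  }
  hsps$strand <- ifelse(hsps$s_start > hsps$s_end, "-", "+")
  hsps$self <- hsps$q_id == hsps$s_id
  rownames(hsps) <- NULL
  hsps
}

#' Write HSPs in 12-column tabular format
#'
#' @param hsps HSP data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tabular_hits <- function(hsps, path) {
  out <- hsps[, hsp_columns[1:12]]
  out$evalue <- formatC(out$evalue, format = "g", digits = 3)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- built-in aligner ------------------------------------------------------

RAW_N <- charToRaw("N")

# All maximal-scoring segments of a +/- score vector: recursive Kadane.
# Returns matrix with columns start, end.
max_scoring_segments <- function(score, min_score) {
  out <- list()
  recurse <- function(lo, hi) {
    if (hi < lo) return()
    p <- cumsum(score[lo:hi])
    prev_min <- cummin(c(0, p[-length(p)]))
    gain <- p - prev_min
    j <- which.max(gain)
    if (gain[j] < min_score) return()
    i <- if (prev_min[j] == 0) 1L else which(c(0, p[-length(p)]) == prev_min[j])[1L]
    out[[length(out) + 1L]] <<- c(lo + i - 1L, lo + j - 1L)
    recurse(lo, lo + i - 2L)
    recurse(lo + j, hi)
  }
  recurse(1L, length(score))
  if (length(out) == 0L) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, out)
}

# Split a segment failing the identity threshold at its deepest internal
# score dip; emit qualifying sub-segments as rows (start, end, matches).
refine_segment <- function(eq, start, end, match, mismatch,
                           min_len, min_ident) {
  len <- end - start + 1L
  if (len < min_len) return(NULL)
  matches <- sum(eq[start:end])
  if (100 * matches / len >= min_ident) {
    return(matrix(c(start, end, matches), nrow = 1L))
  }
  if (len < 2L * min_len) return(NULL)
  p <- cumsum(ifelse(eq[start:end], match, mismatch))
  cut <- which.min(p[seq_len(len - 1L)])
  rbind(
    refine_segment(eq, start, start + cut - 1L, match, mismatch, min_len, min_ident),
    refine_segment(eq, start + cut, end, match, mismatch, min_len, min_ident)
  )
}

seq_kmers <- function(nt, k) {
  n <- nchar(nt)
  if (n < k) return(character(0))
  substring(nt, 1:(n - k + 1L), k:n)
}

# scan given diagonals of one (query, subject-strand) combination; returns
# matrix with columns qs, qe, matches (1-based on the query)
scan_diagonals <- function(qraw, qN, sraw, sN, diags, min_hsp_len,
                           min_hsp_identity, match, mismatch, min_score) {
  Lq <- length(qraw)
  Ls <- length(sraw)
  res <- list()
  for (d in diags) {
    i0 <- max(1L, 1L + d)
    i1 <- min(Lq, Ls + d)
    if (i1 - i0 + 1L < min_hsp_len) next
    qi <- i0:i1
    si <- qi - d
    eq <- (qraw[qi] == sraw[si]) & !qN[qi] & !sN[si]
    segs <- max_scoring_segments(ifelse(eq, match, mismatch), min_score)
    for (r in seq_len(nrow(segs))) {
      ref <- refine_segment(eq, segs[r, 1L], segs[r, 2L], match, mismatch,
                            min_hsp_len, min_hsp_identity)
      if (!is.null(ref)) {
        res[[length(res) + 1L]] <- cbind(qi[ref[, 1L]], qi[ref[, 2L]], ref[, 3L])
      }
    }
  }
  if (length(res) == 0L) return(matrix(integer(0), ncol = 3L))
  do.call(rbind, res)
}

# assemble an HSP data.frame from scan_diagonals() output
hsps_from_segments <- function(seg, strand, a_id, b_id, Lq, Ls,
                               match, mismatch) {
  if (nrow(seg) == 0L) return(NULL)
  qs <- seg[, 1L]
  qe <- seg[, 2L]
  matches <- seg[, 3L]
  len <- qe - qs + 1L
  mm <- len - matches
  score <- matches * match + mm * mismatch
  ss <- qs - seg[, 4L]  # column 4 carries the diagonal
  se <- qe - seg[, 4L]
  if (strand == "-") {
    tmp <- Ls - ss + 1L
    se2 <- Ls - se + 1L
    ss <- tmp
    se <- se2
  }
  data.frame(
    q_id = a_id, s_id = b_id,
    pct_identity = 100 * matches / len,
    aln_len = as.integer(len), mismatch = as.integer(mm), gapopen = 0L,
    q_start = as.integer(qs), q_end = as.integer(qe),
    s_start = as.integer(ss), s_end = as.integer(se),
    evalue = as.numeric(Lq) * Ls * 2^(-score), bitscore = score,
    strand = strand, stringsAsFactors = FALSE
  )
}

min_segment_score <- function(min_hsp_len, min_hsp_identity, match, mismatch) {
  max(1, floor(min_hsp_len *
    (min_hsp_identity / 100 * match + (1 - min_hsp_identity / 100) * mismatch)))
}

# seed diagonals between two k-mer vectors (all occurrences)
seed_diagonals <- function(qkm, skm) {
  if (length(qkm) == 0L || length(skm) == 0L) return(integer(0))
  dq <- data.table::data.table(kmer = qkm, q = seq_along(qkm))
  ds <- data.table::data.table(kmer = skm, s = seq_along(skm))
  mg <- ds[dq, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(mg) == 0L) return(integer(0))
  unique(mg$q - mg$s)
}

#' Local alignment of two nucleotide sequences (built-in aligner)
#'
#' Seed-and-extend aligner used at fixture scale so that no external search
#' tool is required: exact k-mer seeds identify candidate diagonals on both
#' strands, and each diagonal is scanned for maximal ungapped high-scoring
#' segments (match/mismatch scored, N treated as mismatch). Insertions,
#' deletions, split genes and retained introns therefore surface as
#' *multiple* HSPs on shifted diagonals, which is exactly what the
#' downstream coverage merge expects.
#'
#' The reported `bitscore` is the raw segment score and the E-value is the
#' length-scaled surrogate `Lq * Ls * 2^(-score)` (Karlin-Altschul shape;
#' only its ordering is consumed by best-hit logic).
#'
#' @param a,b nucleotide strings.
#' @param a_id,b_id sequence ids used in the output HSPs.
#' @param min_hsp_len minimum HSP length (bp), default 30.
#' @param min_hsp_identity minimum HSP percent identity, default 90.
#' @param k seed k-mer size, default 12.
#' @param match,mismatch per-base scores, defaults +1 / -2.
#' @return HSP data.frame (possibly empty).
#' @export
local_align <- function(a, b, a_id = "query", b_id = "subject",
                        min_hsp_len = 30L, min_hsp_identity = 90,
                        k = 12L, match = 1, mismatch = -2) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  Lq <- nchar(a)
  Ls <- nchar(b)
  min_score <- min_segment_score(min_hsp_len, min_hsp_identity, match, mismatch)
  qraw <- charToRaw(a)
  qN <- qraw == RAW_N
  qkm <- seq_kmers(a, k)
  out <- list()
  for (strand in c("+", "-")) {
    bstr <- if (strand == "+") b else revcomp(b)
    sraw <- charToRaw(bstr)
    sN <- sraw == RAW_N
    diags <- seed_diagonals(qkm, seq_kmers(bstr, k))
    segs_d <- lapply(diags, function(d) {
      m <- scan_diagonals(qraw, qN, sraw, sN, d, min_hsp_len,
                          min_hsp_identity, match, mismatch, min_score)
      if (nrow(m) == 0L) NULL else cbind(m, d)
    })
    segs_d <- segs_d[!vapply(segs_d, is.null, TRUE)]
    if (length(segs_d) == 0L) next
    out[[strand]] <- hsps_from_segments(do.call(rbind, segs_d), strand,
                                        a_id, b_id, Lq, Ls, match, mismatch)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty_hsps())
  hsps <- do.call(rbind, out)
  hsps <- unique(hsps)
  hsps <- hsps[order(-hsps$bitscore, hsps$q_start), , drop = FALSE]
  rownames(hsps) <- NULL
  hsps
}

# total length of the union of 1-based inclusive intervals
interval_union_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  total <- 0L
  cur_s <- starts[1L]
  cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[i]
      cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Merge the HSPs of one sequence pair into a coverage/identity summary
#'
#' Implements the suite's coverage rule: HSPs on the majority strand (by
#' summed bitscore) are projected onto query intervals, overlaps are counted
#' once via the interval union, and coverage is 100 x covered /
#' min(Lq, Ls) (`shortest` mode, the default, chosen because assembled
#' transcripts are frequently truncated) or / max(Lq, Ls) (`longest` mode,
#' used when both sequences are full-length cDNAs). Identity is the
#' alignment-length-weighted mean over retained HSPs.
#'
#' @param hsps HSP data.frame for a single ordered pair.
#' @param Lq,Ls query and subject lengths (bp).
#' @param mode `"shortest"` or `"longest"`.
#' @return one-row data.frame: q_id, s_id, Lq, Ls, covered, coverage,
#'   identity, best_evalue, total_bitscore, strand, n_hsps.
#' @export
merge_hsps <- function(hsps, Lq, Ls, mode = c("shortest", "longest")) {
  mode <- match.arg(mode)
  if (nrow(hsps) == 0L) stopf("merge_hsps: empty HSP list")
  if (length(unique(hsps$q_id)) != 1L || length(unique(hsps$s_id)) != 1L) {
    stopf("merge_hsps: HSPs must share one (q_id, s_id) pair")
  }
  core <- merge_hsps_core(hsps, Lq, Ls, mode)
  cbind(data.frame(q_id = hsps$q_id[1L], s_id = hsps$s_id[1L],
                   stringsAsFactors = FALSE),
        as.data.frame(core, stringsAsFactors = FALSE))
}

# id-free merge kernel (also used for grouped merging in graph building)
merge_hsps_core <- function(hsps, Lq, Ls, mode) {
  stopifnot(Lq > 0L, Ls > 0L)
  strand_score <- tapply(hsps$bitscore, hsps$strand, sum)
  keep_strand <- names(strand_score)[which.max(strand_score)]
  h <- hsps[hsps$strand == keep_strand, , drop = FALSE]
  covered <- interval_union_length(h$q_start, h$q_end)
  denom <- if (mode == "shortest") min(Lq, Ls) else max(Lq, Ls)
  list(
    Lq = Lq, Ls = Ls, covered = covered,
    coverage = min(100, 100 * covered / denom),
    identity = sum(h$pct_identity * h$aln_len) / sum(h$aln_len),
    best_evalue = min(h$evalue),
    total_bitscore = sum(h$bitscore),
    strand = keep_strand, n_hsps = nrow(h)
  )
}

#' All-vs-all HSPs for an accession set (built-in aligner)
#'
#' One global k-mer index over all sequences (forward and
#' reverse-complement) yields, per sequence pair, the set of seeded
#' diagonals on each strand; each diagonal is then scanned for HSPs as in
#' [local_align()]. Both hit directions are emitted, mirroring an
#' all-vs-all run of an external search tool.
#'
#' @param seqs `accession_set`.
#' @param k seed size, default 12.
#' @inheritParams local_align
#' @param max_kmer_occurrence k-mers seen at more positions than this are
#'   dropped from seeding (repeat guard).
#' @param within_accession also align pairs from the same accession
#'   (required for isoform collapse and in-paralog detection); default TRUE.
#' @return HSP data.frame with both (q,s) and (s,q) directions.
#' @export
compute_all_hits <- function(seqs, k = 12L, min_hsp_len = 30L,
                             min_hsp_identity = 90, match = 1, mismatch = -2,
                             max_kmer_occurrence = 500L,
                             within_accession = TRUE) {
  ids <- seqs$records$seq_id
  n <- length(ids)
  if (n < 2L) return(empty_hsps())
  min_score <- min_segment_score(min_hsp_len, min_hsp_identity, match, mismatch)
  fwd <- unname(seqs$seq[ids])
  rev <- vapply(fwd, revcomp, "", USE.NAMES = FALSE)
  raw_f <- lapply(fwd, charToRaw)
  raw_r <- lapply(rev, charToRaw)
  nmask_f <- lapply(raw_f, function(r) r == RAW_N)
  nmask_r <- lapply(raw_r, function(r) r == RAW_N)
  km_f <- lapply(fwd, seq_kmers, k = k)
  km_r <- lapply(rev, seq_kmers, k = k)
  pos_tab <- data.table::data.table(
    kmer = c(unlist(km_f, use.names = FALSE), unlist(km_r, use.names = FALSE)),
    seq = c(rep(seq_len(n), lengths(km_f)), rep(seq_len(n), lengths(km_r))),
    pos = c(unlist(lapply(km_f, seq_along), use.names = FALSE),
            unlist(lapply(km_r, seq_along), use.names = FALSE)),
    strand = rep(c("+", "-"), c(sum(lengths(km_f)), sum(lengths(km_r))))
  )
  reps <- pos_tab[, .N, by = "kmer"]
  bad_kmers <- reps$kmer[reps$N > max_kmer_occurrence]
  if (length(bad_kmers) > 0L) pos_tab <- pos_tab[!pos_tab$kmer %in% bad_kmers]
  qtab <- pos_tab[pos_tab$strand == "+"]
  data.table::setnames(qtab, c("seq", "pos"), c("qseq", "qpos"))
  seeds <- pos_tab[qtab, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  seeds <- seeds[seeds$qseq < seeds$seq]
  if (nrow(seeds) == 0L) return(empty_hsps())
  if (!within_accession) {
    acc <- seqs$records$accession
    seeds <- seeds[acc[seeds$qseq] != acc[seeds$seq]]
    if (nrow(seeds) == 0L) return(empty_hsps())
  }
  seeds <- unique(data.table::data.table(
    qseq = seeds$qseq, sseq = seeds$seq, strand = seeds$strand,
    diag = seeds$qpos - seeds$pos))
  grp <- split(seq_len(nrow(seeds)),
               paste(seeds$qseq, seeds$sseq, seeds$strand))
  out <- vector("list", length(grp))
  gi <- 0L
  for (rows in grp) {
    gi <- gi + 1L
    i <- seeds$qseq[rows[1L]]
    j <- seeds$sseq[rows[1L]]
    strand <- seeds$strand[rows[1L]]
    diags <- seeds$diag[rows]
    sraw <- if (strand == "+") raw_f[[j]] else raw_r[[j]]
    sN <- if (strand == "+") nmask_f[[j]] else nmask_r[[j]]
    Lq <- length(raw_f[[i]])
    Ls <- length(sraw)
    seg <- matrix(integer(0), ncol = 4L)
    segs_d <- lapply(diags, function(d) {
      m <- scan_diagonals(raw_f[[i]], nmask_f[[i]], sraw, sN, d,
                          min_hsp_len, min_hsp_identity, match, mismatch,
                          min_score)
      if (nrow(m) == 0L) NULL else cbind(m, d)
    })
    segs_d <- segs_d[!vapply(segs_d, is.null, TRUE)]
    if (length(segs_d) == 0L) next
    seg <- do.call(rbind, segs_d)
    h <- hsps_from_segments(seg, strand, ids[i], ids[j], Lq, Ls,
                            match, mismatch)
    out[[gi]] <- rbind(h, mirror_hsps(h))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty_hsps())
  res <- do.call(rbind, out)
  res <- unique(res)
  rownames(res) <- NULL
  res
}

# swap query and subject roles of a set of HSPs
mirror_hsps <- function(hsps) {
  m <- hsps
  m$q_id <- hsps$s_id
  m$s_id <- hsps$q_id
  plus <- hsps$strand == "+"
  m$q_start <- ifelse(plus, hsps$s_start, hsps$s_end)
  m$q_end <- ifelse(plus, hsps$s_end, hsps$s_start)
  m$s_start <- ifelse(plus, hsps$q_start, hsps$q_end)
  m$s_end <- ifelse(plus, hsps$q_end, hsps$q_start)
  m
}
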