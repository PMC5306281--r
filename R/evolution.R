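# Codon-level conservation analysis: progressive codon alignments, the
# Nei-Gojobori (1986) counting method for dN/dS with Jukes-Cantor
# correction, cluster-level omega summaries, and notched box statistics.

GENETIC_CODE_TAB <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TAB)[GENETIC_CODE_TAB == "*"]
BASES <- c("A", "C", "G", "T")

# synonymous site count per sense codon: at each of the 3 positions, the
# fraction of the 3 possible single-base changes that preserve the amino
# acid. Changes creating a stop codon count as nonsynonymous, so that
# S + N = 3 for every codon.
codon_syn_sites <- local({
  codons <- names(GENETIC_CODE_TAB)
  s <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (cd %in% STOP_CODONS) {
      s[cd] <- NA_real_
      next
    }
    aa <- GENETIC_CODE_TAB[[cd]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- b
        if (!alt %in% STOP_CODONS && GENETIC_CODE_TAB[[alt]] == aa) {
          syn <- syn + 1 / 3
        }
      }
    }
    s[cd] <- syn
  }
  s
})

# memoized syn/nonsyn step counts between two sense codons, averaged over
# all minimal mutational pathways; pathways through stop codons excluded.
codon_path_env <- new.env(parent = emptyenv())

codon_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- codon_path_env[[key]]
  if (!is.null(hit)) return(hit)
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  res <- if (nd == 0L) {
    c(sd = 0, nd = 0, valid = 1)
  } else {
    perms <- if (nd == 1L) list(diff_pos) else
      apply(permutations_of(nd), 1L, function(ix) diff_pos[ix], simplify = FALSE)
    sd_tot <- 0
    nd_tot <- 0
    n_valid <- 0L
    for (path in perms) {
      cur <- c1
      sd_p <- 0
      nd_p <- 0
      ok <- TRUE
      for (pos in path) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (nxt %in% STOP_CODONS) {
          ok <- FALSE
          break
        }
        if (GENETIC_CODE_TAB[[cur]] == GENETIC_CODE_TAB[[nxt]]) {
          sd_p <- sd_p + 1
        } else {
          nd_p <- nd_p + 1
        }
        cur <- nxt
      }
      if (ok) {
        sd_tot <- sd_tot + sd_p
        nd_tot <- nd_tot + nd_p
        n_valid <- n_valid + 1L
      }
    }
    if (n_valid == 0L) c(sd = NA_real_, nd = NA_real_, valid = 0) else
      c(sd = sd_tot / n_valid, nd = nd_tot / n_valid, valid = n_valid)
  }
  codon_path_env[[key]] <- res
  res
}

# all permutations of seq_len(n) as rows (n <= 3 here)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # correction undefined
  -0.75 * log(1 - 4 * p / 3)
}

split_codons <- function(row) {
  n <- nchar(row)
  stopifnot(n %% 3L == 0L)
  substring(row, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Synonymous and nonsynonymous site counts are derived per codon from the
#' standard genetic code (averaged over the two sequences; changes creating
#' stop codons count as nonsynonymous, so S + N = 3 x codons used).
#' Multiple-hit codons are averaged over all minimal mutational pathways,
#' excluding pathways through stop codons; codons for which every pathway
#' is blocked are dropped entirely. Proportions are corrected with
#' Jukes-Cantor, d = -(3/4) ln(1 - (4/3) p). Codons containing gaps or N
#' in either row are skipped pairwise.
#'
#' @param row_a,row_b aligned codon rows (equal length, multiple of 3).
#' @return one-row data.frame: dN, dS, omega (NA when dS is 0 or
#'   undefined), n_codons_used, S_sites, N_sites, Sd, Nd, usable (FALSE
#'   when a Jukes-Cantor correction was undefined, p >= 3/4).
#' @export
pairwise_ng86 <- function(row_a, row_b) {
  stopifnot(nchar(row_a) == nchar(row_b))
  ca <- split_codons(toupper(row_a))
  cb <- split_codons(toupper(row_b))
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS)
  ca <- ca[clean]
  cb <- cb[clean]
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (i in seq_along(ca)) {
    pc <- codon_path_counts(ca[i], cb[i])
    if (pc[["valid"]] == 0) next  # all pathways blocked by stops
    s_i <- (codon_syn_sites[[ca[i]]] + codon_syn_sites[[cb[i]]]) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    Sd <- Sd + pc[["sd"]]
    Nd <- Nd + pc[["nd"]]
    used <- used + 1L
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  usable <- !(isTRUE(pS >= 0.75) || isTRUE(pN >= 0.75))
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  data.frame(dN = dN, dS = dS, omega = omega, n_codons_used = used,
             S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, usable = usable)
}

# --- codon alignment -------------------------------------------------------

# merge a master multiple alignment with a center/new-seq pairwise
# alignment on their shared center sequence ("once a gap, always a gap")
merge_center_alignment <- function(master, center_aln, new_aln, new_id) {
  A <- lapply(master, function(x) strsplit(x, "")[[1]])
  cA <- A[[1L]]  # center is row 1 by construction
  cB <- strsplit(center_aln, "")[[1]]
  nB <- strsplit(new_aln, "")[[1]]
  out <- lapply(seq_along(A), function(i) character(0))
  outN <- character(0)
  i <- 1L
  j <- 1L
  while (i <= length(cA) || j <= length(cB)) {
    a_gap <- i <= length(cA) && cA[i] == "-"
    b_gap <- j <= length(cB) && cB[j] == "-"
    if (i <= length(cA) && j <= length(cB) && !a_gap && !b_gap) {
      for (r in seq_along(A)) out[[r]] <- c(out[[r]], A[[r]][i])
      outN <- c(outN, nB[j])
      i <- i + 1L
      j <- j + 1L
    } else if (a_gap) {
      for (r in seq_along(A)) out[[r]] <- c(out[[r]], A[[r]][i])
      outN <- c(outN, "-")
      i <- i + 1L
    } else {  # b_gap (insertion in the new sequence)
      for (r in seq_along(A)) out[[r]] <- c(out[[r]], "-")
      outN <- c(outN, nB[j])
      j <- j + 1L
    }
  }
  res <- c(lapply(out, paste, collapse = ""), paste(outN, collapse = ""))
  names(res) <- c(names(master), new_id)
  res
}

#' Progressive codon alignment of a cluster's CDS members
#'
#' Peptides (translations of the CDS, terminal stop removed) are aligned
#' progressively: a center sequence (maximizing total pairwise alignment
#' score, computed with a standard substitution matrix and affine gaps) is
#' chosen and all other members are merged onto it with the
#' "once a gap, always a gap" rule. The peptide alignment is then
#' back-translated codon-wise; gap columns become gap codons (`---`).
#' Members with internal stop codons are excluded with a warning; CDS
#' lengths must be divisible by 3.
#'
#' @param cds named character vector of CDS nucleotide sequences (>= 2).
#' @param gap_opening,gap_extension affine gap penalties for the peptide
#'   alignment (defaults 10 / 0.5).
#' @return `codon_alignment`: named character vector of aligned codon rows
#'   (equal lengths, divisible by 3), with attribute `peptides` holding
#'   the aligned peptide rows.
#' @export
align_codons <- function(cds, gap_opening = 10, gap_extension = 0.5) {
  stopifnot(length(cds) >= 2L, !is.null(names(cds)))
  bad_len <- nchar(cds) %% 3L != 0L
  if (any(bad_len)) stopf("CDS length not divisible by 3: %s",
                          paste(names(cds)[bad_len], collapse = ", "))
  peps <- vapply(cds, translate_nt, "")
  # strip terminal stop (codon retained in neither peptide nor codon rows)
  term_stop <- substring(peps, nchar(peps)) == "*"
  peps[term_stop] <- substring(peps[term_stop], 1L, nchar(peps[term_stop]) - 1L)
  cds[term_stop] <- substring(cds[term_stop], 1L, nchar(cds[term_stop]) - 3L)
  internal_stop <- grepl("\\*", peps)
  if (any(internal_stop)) {
    warnf("excluded %d member(s) with internal stop codons: %s",
          sum(internal_stop), paste(names(cds)[internal_stop], collapse = ", "))
    cds <- cds[!internal_stop]
    peps <- peps[!internal_stop]
  }
  if (length(cds) < 2L) stopf("fewer than 2 usable members after exclusions")
  ids <- names(cds)
  aa <- Biostrings::AAStringSet(peps)
  n <- length(ids)
  # center = member maximizing summed pairwise score
  score_sum <- numeric(n)
  pw <- vector("list", n)
  for (i in seq_len(n)) pw[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- Biostrings::pairwiseAlignment(
        aa[[i]], aa[[j]], type = "global",
        substitutionMatrix = "BLOSUM62",
        gapOpening = gap_opening, gapExtension = gap_extension)
      sc <- Biostrings::score(al)
      score_sum[i] <- score_sum[i] + sc
      score_sum[j] <- score_sum[j] + sc
      pw[[i]][[j]] <- al
    }
  }
  center <- which.max(score_sum)
  master <- setNames(list(peps[[center]]), ids[center])
  for (j in setdiff(seq_len(n), center)) {
    al <- if (center < j) pw[[center]][[j]] else NULL
    if (is.null(al)) {
      al <- Biostrings::pairwiseAlignment(
        aa[[center]], aa[[j]], type = "global",
        substitutionMatrix = "BLOSUM62",
        gapOpening = gap_opening, gapExtension = gap_extension)
    }
    master <- merge_center_alignment(
      master,
      as.character(Biostrings::alignedPattern(al)),
      as.character(Biostrings::alignedSubject(al)),
      ids[j])
  }
  master <- unlist(master)
  # back-translate peptide rows to codon rows
  codon_rows <- vapply(names(master), function(id) {
    codons <- split_codons(cds[[id]])
    chars <- strsplit(master[[id]], "")[[1]]
    k <- 0L
    paste(vapply(chars, function(ch) {
      if (ch == "-") return("---")
      k <<- k + 1L
      codons[k]
    }, ""), collapse = "")
  }, "")
  structure(codon_rows, peptides = master, class = "codon_alignment")
}

#' Cluster-level dN/dS summary
#'
#' Computes NG86 omega for all member pairs of a codon alignment; the
#' cluster omega is the mean of the defined pairwise omegas (undefined
#' pairs, dS = 0, are excluded rather than capped). Clusters with mean
#' omega above `max_omega` (default 1.5) are flagged for exclusion as
#' likely misalignments; clusters below 1 are classified as purifying,
#' above 1 as positive.
#'
#' @param aln `codon_alignment` (intended for single-copy clusters with
#'   occupancy >= 4, the minimum for a meaningful summary).
#' @param max_omega exclusion threshold on the cluster mean, default 1.5.
#' @return one-row data.frame: omega (NA when no pair is defined), mean_dN,
#'   mean_dS, n_pairs, n_defined, excluded, classification.
#' @export
cluster_omega <- function(aln, max_omega = 1.5) {
  ids <- names(aln)
  stopifnot(length(ids) >= 2L)
  pairs <- utils::combn(seq_along(ids), 2L)
  est <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    pairwise_ng86(aln[[pairs[1L, k]]], aln[[pairs[2L, k]]])
  }))
  defined <- !is.na(est$omega)
  omega <- if (any(defined)) mean(est$omega[defined]) else NA_real_
  excluded <- isTRUE(omega > max_omega)
  classification <- if (is.na(omega)) NA_character_
    else if (excluded) "excluded"
    else if (omega < 1) "purifying"
    else if (omega > 1) "positive"
    else "neutral"
  data.frame(
    omega = omega,
    mean_dN = mean(est$dN, na.rm = TRUE),
    mean_dS = mean(est$dS, na.rm = TRUE),
    n_pairs = ncol(pairs),
    n_defined = sum(defined),
    excluded = excluded,
    classification = classification,
    stringsAsFactors = FALSE
  )
}

#' Notched box statistics
#'
#' Quartiles (type-7), IQR and the 95% notch around the median computed as
#' median +/- 1.58 IQR / sqrt(n). Two groups are declared significantly
#' different when their notches do not overlap.
#'
#' @param x numeric vector (NAs dropped).
#' @return one-row data.frame: n, median, q1, q3, iqr, notch_low,
#'   notch_high.
#' @export
box_stats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 1L)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3L] - q[1L]
  half <- 1.58 * iqr / sqrt(n)
  data.frame(n = n, median = q[2L], q1 = q[1L], q3 = q[3L], iqr = iqr,
             notch_low = q[2L] - half, notch_high = q[2L] + half)
}

#' Stratify per-cluster values by occupancy level
#'
#' @param values named numeric vector (cluster id -> value, e.g. omega or
#'   mean TPM).
#' @param occupancy named integer vector (cluster id -> occupancy).
#' @return data.frame with one [box_stats()] row per occupancy level.
#' @export
stratify_by_occupancy <- function(values, occupancy) {
  occ <- occupancy[names(values)]
  keep <- !is.na(values) & !is.na(occ)
  values <- values[keep]
  occ <- occ[keep]
  stopifnot(length(values) >= 1L)
  levels <- sort(unique(occ))
  do.call(rbind, lapply(levels, function(l) {
    cbind(data.frame(occupancy = l), box_stats(values[occ == l]))
  }))
}

#' Do the notches of two groups overlap?
#'
#' Non-overlapping notches are the criterion for calling two medians
#' significantly different at roughly the 95% level.
#'
#' @param a,b one-row data.frames from [box_stats()].
#' @return TRUE when the notch intervals overlap.
#' @export
notches_overlap <- function(a, b) {
  a$notch_low <= b$notch_high && b$notch_low <= a$notch_high
}
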