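# Synthetic multi-accession pan-genomes with ground truth: gene families
# with programmed occupancy classes, per-copy divergence, isoforms, and
# the common transcript degeneracies (fragments, split genes, retained
# introns), plus class-ordered expression values.

SENSE_CODONS <- names(GENETIC_CODE_TAB)[GENETIC_CODE_TAB != "*"]

#' Configuration for the synthetic pan-genome generator
#'
#' Defaults describe a compact but realistic fixture: 6 accessions, 100
#' gene families (50 core, 30 shell, 20 cloud), 1% expected pairwise
#' divergence between accession copies, 20% of copies degraded (8%
#' truncated fragments, 4% split genes, 8% retained introns), 10% extra
#' isoforms, and log-normal expression with class-ordered means
#' (core > shell > cloud).
#'
#' @param n_accessions number of accessions (>= 3).
#' @param n_core,n_shell,n_cloud family counts per occupancy class.
#' @param divergence expected pairwise substitution divergence between two
#'   accession copies of one family (each copy is mutated at
#'   `divergence/2` from the family ancestor).
#' @param gene_length_range CDS length range in bp (codon multiples).
#' @param isoform_rate probability of adding a redundant truncated isoform
#'   to a copy.
#' @param fragment_rate,split_rate,intron_retention_rate per-copy
#'   degradation probabilities (mutually exclusive outcomes).
#' @param fragment_fraction retained fraction for truncated fragments.
#' @param intron_length_range retained-intron insert length range (bp).
#' @param expression_meanlog named meanlog per class for the log-normal
#'   TPM law (core > shell > cloud).
#' @param expression_sdlog sdlog of the TPM law.
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return `synth_config` list.
#' @export
synth_config <- function(n_accessions = 6L, n_core = 50L, n_shell = 30L,
                         n_cloud = 20L, divergence = 0.01,
                         gene_length_range = c(300L, 2400L),
                         isoform_rate = 0.10, fragment_rate = 0.08,
                         split_rate = 0.04, intron_retention_rate = 0.08,
                         fragment_fraction = 0.6,
                         intron_length_range = c(150L, 400L),
                         expression_meanlog = c(core = 4, shell = 3, cloud = 1),
                         expression_sdlog = 1,
                         seed = 1L) {
  stopifnot(n_accessions >= 3L,
            divergence >= 0, divergence <= 1,
            all(c(isoform_rate, fragment_rate, split_rate,
                  intron_retention_rate) >= 0),
            fragment_rate + split_rate + intron_retention_rate <= 1,
            gene_length_range[1L] >= 150L,
            all(c("core", "shell", "cloud") %in% names(expression_meanlog)))
  if (n_shell > 0L && n_accessions - 1L < 3L) {
    stopf("shell occupancies need n_accessions >= 4")
  }
  structure(as.list(environment()), class = "synth_config")
}

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Mutate a nucleotide sequence at a given substitution rate
#'
#' Substitution-only mutation. In codon-aware modes (sequence length
#' divisible by 3) no internal stop is introduced and the first and last
#' codons are protected; `synonymous_only` never changes the peptide;
#' `nonsynonymous_biased` prefers amino-acid-changing substitutions.
#' Non-codon-length input falls back to unconstrained substitution.
#'
#' @param nt nucleotide string.
#' @param rate expected per-site substitution rate.
#' @param mode `"any"`, `"synonymous_only"`, or `"nonsynonymous_biased"`.
#' @param seed optional seed for a self-contained reproducible draw.
#' @return mutated nucleotide string.
#' @export
mutate_sequence <- function(nt, rate,
                            mode = c("any", "synonymous_only", "nonsynonymous_biased"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) return(with_seed(seed, mutate_sequence(nt, rate, mode)))
  if (rate <= 0) return(nt)
  L <- nchar(nt)
  codon_aware <- L %% 3L == 0L
  n_mut <- rbinom(1L, L, rate)
  if (n_mut == 0L) return(nt)
  sites <- sample.int(L, n_mut)
  chars <- strsplit(nt, "")[[1]]
  for (pos in sites) {
    alts <- sample(setdiff(BASES, chars[pos]))
    if (!codon_aware) {
      chars[pos] <- alts[1L]
      next
    }
    ci <- (pos - 1L) %/% 3L + 1L
    if (ci == 1L || ci == L %/% 3L) next  # protect start and stop codons
    codon <- paste(chars[(3L * ci - 2L):(3L * ci)], collapse = "")
    cpos <- (pos - 1L) %% 3L + 1L
    aa <- GENETIC_CODE_TAB[[codon]]
    pick <- NA_character_
    fallback <- NA_character_
    for (b in alts) {
      alt_codon <- codon
      substr(alt_codon, cpos, cpos) <- b
      if (alt_codon %in% STOP_CODONS) next
      alt_aa <- GENETIC_CODE_TAB[[alt_codon]]
      ok <- switch(mode,
                   any = TRUE,
                   synonymous_only = alt_aa == aa,
                   nonsynonymous_biased = alt_aa != aa)
      if (ok) {
        pick <- b
        break
      }
      if (mode == "nonsynonymous_biased" && is.na(fallback)) fallback <- b
    }
    if (is.na(pick) && mode == "nonsynonymous_biased") pick <- fallback
    if (!is.na(pick)) chars[pos] <- pick
  }
  paste(chars, collapse = "")
}

#' Degrade a sequence copy (fragment, split gene, or retained intron)
#'
#' `fragment` returns one contiguous subsequence covering
#' `params$fraction` of the input; `split` returns two non-overlapping
#' pieces covering the whole input (cut point uniform in 40-60% of the
#' length); `retained_intron` inserts a random non-coding sequence of a
#' configured length at an internal codon boundary.
#'
#' @param nt nucleotide string.
#' @param kind `"fragment"`, `"split"`, or `"retained_intron"`.
#' @param params list: `fraction` (fragment), `intron_length_range`
#'   (retained_intron).
#' @param seed optional seed for a self-contained reproducible draw.
#' @return list: `records` (character vector of 1 or 2 sequences) and
#'   `entry` (data.frame describing the event).
#' @export
degrade_copy <- function(nt, kind = c("fragment", "split", "retained_intron"),
                         params = list(), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) return(with_seed(seed, degrade_copy(nt, kind, params)))
  L <- nchar(nt)
  if (kind == "fragment") {
    frac <- params$fraction %||% 0.6
    len <- max(1L, round(frac * L))
    if (len > L) stopf("fragment longer than source")
    start <- sample.int(L - len + 1L, 1L)
    rec <- substr(nt, start, start + len - 1L)
    entry <- data.frame(kind = "fragment", start = start, length = len)
  } else if (kind == "split") {
    cut <- round(L * runif(1L, 0.4, 0.6))
    cut <- min(max(cut, 1L), L - 1L)
    rec <- c(substr(nt, 1L, cut), substr(nt, cut + 1L, L))
    entry <- data.frame(kind = "split", start = cut, length = L)
  } else {
    rng <- params$intron_length_range %||% c(150L, 400L)
    ilen <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
    intron <- paste(sample(BASES, ilen, replace = TRUE), collapse = "")
    n_codons <- L %/% 3L
    at <- 3L * sample(seq_len(max(n_codons - 1L, 1L)), 1L)
    rec <- paste0(substr(nt, 1L, at), intron, substr(nt, at + 1L, L))
    entry <- data.frame(kind = "retained_intron", start = at, length = ilen)
  }
  list(records = rec, entry = entry)
}

#' Generate a synthetic pan-genome with ground truth
#'
#' Each family gets an ancestral random CDS (start codon, sense codons, no
#' internal stop, terminal stop). Occupancy classes honor the configured
#' counts exactly: core families occupy all accessions, shell families a
#' uniform draw of 3..N-1, cloud families 1 or 2. Every carrying accession
#' receives a copy mutated at `divergence/2` from the ancestor, optionally
#' degraded (fragment / split / retained intron) and optionally
#' accompanied by a redundant truncated isoform. Expression (TPM) is drawn
#' log-normally with class-ordered means. Fully deterministic under
#' `cfg$seed`.
#'
#' @param cfg `synth_config`.
#' @return list: `seqs` (`accession_set`), `truth` (list with `families`,
#'   `members`, `tpm` data.frames).
#' @export
generate_pangenome <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    accs <- sprintf("ACC%02d", seq_len(cfg$n_accessions))
    n_fam <- cfg$n_core + cfg$n_shell + cfg$n_cloud
    fam_ids <- sprintf("F%03d", seq_len(n_fam))
    classes <- rep(c("core", "shell", "cloud"),
                   c(cfg$n_core, cfg$n_shell, cfg$n_cloud))
    occ <- integer(n_fam)
    occ[classes == "core"] <- cfg$n_accessions
    if (cfg$n_shell > 0L) {
      occ[classes == "shell"] <- sample(3:(cfg$n_accessions - 1L),
                                        cfg$n_shell, replace = TRUE)
    }
    if (cfg$n_cloud > 0L) {
      occ[classes == "cloud"] <- sample(1:2, cfg$n_cloud, replace = TRUE)
    }
    n_codon_rng <- floor(cfg$gene_length_range / 3L)
    seq_by_acc <- setNames(lapply(accs, function(a) character(0)), accs)
    members <- list()
    tpm_rows <- list()
    fam_tpm <- numeric(n_fam)
    for (f in seq_len(n_fam)) {
      anc <- random_cds(sample(n_codon_rng[1L]:n_codon_rng[2L], 1L))
      carriers <- sort(sample(accs, occ[f]))
      fam_tpm[f] <- rlnorm(1L, cfg$expression_meanlog[[classes[f]]],
                           cfg$expression_sdlog)
      for (a in carriers) {
        copy <- mutate_sequence(anc, cfg$divergence / 2, mode = "any")
        u <- runif(1L)
        kind <- if (u < cfg$fragment_rate) "fragment"
          else if (u < cfg$fragment_rate + cfg$split_rate) "split"
          else if (u < cfg$fragment_rate + cfg$split_rate +
                     cfg$intron_retention_rate) "retained_intron"
          else "intact"
        base_id <- paste0(fam_ids[f], "_", a)
        if (kind == "intact") {
          recs <- setNames(copy, base_id)
        } else {
          d <- degrade_copy(copy, kind,
                            params = list(fraction = cfg$fragment_fraction,
                                          intron_length_range = cfg$intron_length_range))
          recs <- if (length(d$records) == 2L) {
            setNames(d$records, paste0(base_id, c("_p1", "_p2")))
          } else {
            setNames(d$records, base_id)
          }
        }
        if (runif(1L) < cfg$isoform_rate) {
          iso <- degrade_copy(copy, "fragment",
                              params = list(fraction = runif(1L, 0.5, 0.8)))
          recs <- c(recs, setNames(iso$records, paste0(base_id, "_i1")))
        }
        seq_by_acc[[a]] <- c(seq_by_acc[[a]], recs)
        for (id in names(recs)) {
          members[[length(members) + 1L]] <- data.frame(
            family_id = fam_ids[f], seq_id = id, accession = a,
            kind = if (grepl("_i1$", id)) "isoform"
                   else if (grepl("_p[12]$", id)) "split" else kind,
            stringsAsFactors = FALSE)
          tpm_rows[[length(tpm_rows) + 1L]] <- data.frame(
            seq_id = id,
            tpm = fam_tpm[f] * exp(stats::rnorm(1L, 0, 0.25)),
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- list(
      families = data.frame(family_id = fam_ids, class = classes,
                            occupancy = occ, tpm = fam_tpm,
                            stringsAsFactors = FALSE),
      members = do.call(rbind, members),
      tpm = do.call(rbind, tpm_rows)
    )
    list(seqs = accession_set(seq_by_acc), truth = truth)
  })
}

#' Evaluate clustering output against synthetic ground truth
#'
#' A truth family is recovered *exactly* when some cluster's member set
#' (members plus attached isoforms) equals the family's full sequence set.
#' Occupancy agreement is measured per cluster: the cluster's occupancy is
#' compared with the truth occupancy of the family contributing most of
#' its members.
#'
#' @param clusters list of `cluster` objects.
#' @param truth truth list from [generate_pangenome()].
#' @return list: `n_families`, `n_recovered`, `recovery_rate`,
#'   `n_clusters`, `occupancy_agreement`.
#' @export
truth_recovery <- function(clusters, truth) {
  fam_sets <- lapply(split(truth$members$seq_id, truth$members$family_id), sort)
  cl_sets <- lapply(clusters, function(cl) sort(c(cl$members, cl$isoforms)))
  cl_keys <- vapply(cl_sets, paste, "", collapse = "\r")
  fam_keys <- vapply(fam_sets, paste, "", collapse = "\r")
  recovered <- fam_keys %in% cl_keys
  fam_of <- setNames(truth$members$family_id, truth$members$seq_id)
  fam_occ <- setNames(truth$families$occupancy, truth$families$family_id)
  agree <- vapply(clusters, function(cl) {
    fams <- fam_of[c(cl$members, cl$isoforms)]
    top <- names(sort(table(fams), decreasing = TRUE))[1L]
    cl$occupancy == fam_occ[[top]]
  }, TRUE)
  list(
    n_families = length(fam_sets),
    n_recovered = sum(recovered),
    recovery_rate = mean(recovered),
    n_clusters = length(clusters),
    occupancy_agreement = mean(agree)
  )
}
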