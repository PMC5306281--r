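# Reading per-accession FASTA sets and writing cluster artifacts.
#
# An accession_set is the package's central input container: one accession
# per nucleotide FASTA file (the accession id is the file stem), optionally
# paired with translated-peptide FASTA mates.

NT_EXTENSIONS <- c("fa", "fna", "fasta")
PEP_EXTENSIONS <- c("faa", "pep")

# strip .gz/.bz2 then one recognized extension; NA if not recognized
file_stem <- function(path, extensions) {
  base <- basename(path)
  base <- sub("\\.(gz|bz2)$", "", base)
  ext <- tolower(tools::file_ext(base))
  if (!ext %in% extensions) return(NA_character_)
  sub(paste0("\\.", ext, "$"), "", base)
}

# Decompress .gz/.bz2 to a temp file so Biostrings can read it; plain files
# are returned unchanged.
materialize_fasta <- function(path) {
  if (!grepl("\\.(gz|bz2)$", path)) return(path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else bzfile(path, "rb")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".fasta")
  out <- file(tmp, "wb")
  while (length(chunk <- readBin(con, "raw", n = 1048576L)) > 0L) {
    writeBin(chunk, out)
  }
  close(out)
  tmp
}

read_fasta_chr <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  real <- materialize_fasta(path)
  set <- tryCatch(
    if (type == "DNA") Biostrings::readBStringSet(real)
    else Biostrings::readAAStringSet(real),
    error = function(e) stopf("invalid FASTA file '%s': %s", path, conditionMessage(e))
  )
  if (length(set) == 0L) stopf("FASTA file '%s' contains no sequences", path)
  seqs <- toupper(as.character(set))
  # headers parsed to first whitespace
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(names(seqs) == "")) stopf("FASTA file '%s' has an empty sequence id", path)
  if (any(nchar(seqs) == 0L)) stopf("FASTA file '%s' has a zero-length sequence", path)
  seqs
}

#' Read per-accession sequence sets from a folder
#'
#' Reads every nucleotide FASTA file (optionally gzip- or bzip2-compressed)
#' in `folder`; each file becomes one accession named after the file stem.
#' If *every* nucleotide file has a translated-peptide mate (same stem,
#' `.faa`/`.pep` suffix) the set is flagged `has_peptides` and peptides are
#' attached; peptide pairing is all-or-nothing per run.
#'
#' Non-ACGT nucleotide characters other than N are mapped to N (a message
#' reports the count). Sequence ids colliding across accessions are
#' disambiguated by prefixing `<accession>|`.
#'
#' @param folder path containing FASTA files.
#' @param extensions recognized nucleotide extensions (without compression
#'   suffix). Default `c("fa", "fna", "fasta")`.
#' @return An object of class `accession_set`: a list with `accessions`
#'   (ordered character), `records` (data.frame `seq_id`, `accession`,
#'   `length`), `seq` (named character of nucleotide strings), `pep`
#'   (named character or NULL) and `has_peptides`.
#' @export
read_sequence_sets <- function(folder, extensions = NT_EXTENSIONS) {
  if (!dir.exists(folder)) stopf("folder '%s' does not exist", folder)
  files <- sort(list.files(folder, full.names = TRUE))
  stems <- vapply(files, file_stem, "", extensions = extensions)
  nt_files <- files[!is.na(stems)]
  if (length(nt_files) == 0L) stopf("no FASTA files with extensions %s in '%s'",
                                    paste(extensions, collapse = "/"), folder)
  pep_stems <- vapply(files, file_stem, "", extensions = PEP_EXTENSIONS)
  pep_files <- files[!is.na(pep_stems)]
  names(pep_files) <- pep_stems[!is.na(pep_stems)]

  accs <- unname(vapply(nt_files, file_stem, "", extensions = extensions))
  if (anyDuplicated(accs)) {
    stopf("duplicate accession stems: %s", paste(unique(accs[duplicated(accs)]), collapse = ", "))
  }
  per_acc <- lapply(nt_files, read_fasta_chr, type = "DNA")
  names(per_acc) <- accs

  # normalize alphabet
  n_bad <- 0L
  per_acc <- lapply(per_acc, function(s) {
    bad <- vapply(gregexpr("[^ACGTN]", s), function(m) if (m[1] == -1L) 0L else length(m), 0L)
    n_bad <<- n_bad + sum(bad)
    gsub("[^ACGTN]", "N", s)
  })
  if (n_bad > 0L) message(sprintf("mapped %d non-ACGTN characters to N", n_bad))

  has_pep <- length(pep_files) > 0L && all(accs %in% names(pep_files))
  peps <- NULL
  if (has_pep) {
    peps <- lapply(accs, function(a) {
      p <- read_fasta_chr(pep_files[[a]], type = "AA")
      missing <- setdiff(names(p), names(per_acc[[a]]))
      if (length(missing) > 0L) {
        stopf("peptide file for accession '%s' has ids not in its nucleotide mate: %s",
              a, paste(head(missing, 5L), collapse = ", "))
      }
      p
    })
    names(peps) <- accs
  }

  # resolve id collisions across accessions by prefixing accession
  all_ids <- unlist(lapply(per_acc, names), use.names = FALSE)
  dup_ids <- unique(all_ids[duplicated(all_ids)])
  if (length(dup_ids) > 0L) {
    for (a in accs) {
      hit <- names(per_acc[[a]]) %in% dup_ids
      if (any(hit)) {
        new <- paste0(a, "|", names(per_acc[[a]])[hit])
        if (!is.null(peps)) {
          phit <- names(peps[[a]]) %in% dup_ids
          names(peps[[a]])[phit] <- paste0(a, "|", names(peps[[a]])[phit])
        }
        names(per_acc[[a]])[hit] <- new
      }
    }
    all_ids <- unlist(lapply(per_acc, names), use.names = FALSE)
    if (anyDuplicated(all_ids)) {
      stopf("duplicate sequence ids remain after accession prefixing: %s",
            paste(head(unique(all_ids[duplicated(all_ids)]), 5L), collapse = ", "))
    }
    message(sprintf("prefixed %d duplicated ids with their accession", length(dup_ids)))
  }

  seq <- unlist(unname(per_acc))
  records <- data.frame(
    seq_id = unlist(lapply(per_acc, names), use.names = FALSE),
    accession = rep(accs, vapply(per_acc, length, 0L)),
    length = nchar(seq),
    stringsAsFactors = FALSE
  )
  pep <- if (!is.null(peps)) unlist(unname(peps)) else NULL
  structure(
    list(accessions = accs, records = records, seq = seq, pep = pep,
         has_peptides = has_pep),
    class = "accession_set"
  )
}

#' Construct an accession set from in-memory sequences
#'
#' Programmatic constructor used by the synthetic generator and by tests.
#'
#' @param seqs named list: accession -> named character vector of nucleotide
#'   strings.
#' @param peps optional named list with the same structure holding peptides.
#' @return `accession_set`, as from [read_sequence_sets()].
#' @export
accession_set <- function(seqs, peps = NULL) {
  stopifnot(is.list(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  accs <- names(seqs)
  seq <- unlist(unname(seqs))
  ids <- unlist(lapply(seqs, names), use.names = FALSE)
  if (is.null(ids) || anyDuplicated(ids)) stopf("sequence ids must be present and unique")
  names(seq) <- ids
  records <- data.frame(
    seq_id = ids,
    accession = rep(accs, vapply(seqs, length, 0L)),
    length = nchar(seq),
    stringsAsFactors = FALSE
  )
  pep <- if (!is.null(peps)) unlist(unname(peps)) else NULL
  structure(
    list(accessions = accs, records = records, seq = seq, pep = pep,
         has_peptides = !is.null(pep)),
    class = "accession_set"
  )
}

#' @export
print.accession_set <- function(x, ...) {
  cat(sprintf("accession_set: %d accessions, %d sequences%s\n",
              length(x$accessions), nrow(x$records),
              if (x$has_peptides) " (+peptides)" else ""))
  invisible(x)
}

seq_accession <- function(seqs, ids) {
  seqs$records$accession[match(ids, seqs$records$seq_id)]
}

seq_length <- function(seqs, ids) {
  seqs$records$length[match(ids, seqs$records$seq_id)]
}

#' Write per-accession FASTA files
#'
#' Inverse of [read_sequence_sets()]: one `<accession>.fna` per accession
#' (plus `<accession>.faa` when peptides are attached).
#'
#' @param seqs `accession_set`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sequence_sets <- function(seqs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (a in seqs$accessions) {
    ids <- seqs$records$seq_id[seqs$records$accession == a]
    path <- file.path(outdir, paste0(a, ".fna"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs$seq[ids]), path, width = 70L)
    paths <- c(paths, path)
    if (seqs$has_peptides) {
      pids <- intersect(ids, names(seqs$pep))
      if (length(pids) > 0L) {
        ppath <- file.path(outdir, paste0(a, ".faa"))
        Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs$pep[pids]), ppath, width = 70L)
        paths <- c(paths, ppath)
      }
    }
  }
  invisible(paths)
}

#' Write clusters as FASTA files plus a text index
#'
#' One FASTA per cluster (named `<cluster_id>_<representative>.fna`) and a
#' tab-delimited `cluster_list.tsv` index (cluster id, size, occupancy,
#' member ids). Ordering is deterministic: clusters by descending occupancy
#' then id; members by accession order then id.
#'
#' @param clusters list of `cluster` objects (see [cluster_omcl()]).
#' @param seqs `accession_set` resolving every member id.
#' @param outdir output directory.
#' @return invisibly, the index path.
#' @export
write_clusters <- function(clusters, seqs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dangling <- setdiff(unlist(lapply(clusters, `[[`, "members")), seqs$records$seq_id)
  if (length(dangling) > 0L) {
    stopf("cluster members not found in sequence set: %s",
          paste(head(dangling, 5L), collapse = ", "))
  }
  occ <- vapply(clusters, `[[`, 0L, "occupancy")
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  ord <- order(-occ, ids)
  clusters <- clusters[ord]
  rows <- lapply(clusters, function(cl) {
    members <- cl$members
    macc <- seq_accession(seqs, members)
    members <- members[order(match(macc, seqs$accessions), members)]
    rep_id <- cluster_representative(cl, seqs)
    fa <- file.path(outdir, paste0(cl$cluster_id, "_", gsub("[^A-Za-z0-9._|-]", "_", rep_id), ".fna"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs$seq[members]), fa, width = 70L)
    data.frame(cluster_id = cl$cluster_id, size = length(members),
               occupancy = cl$occupancy,
               members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  index <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), size = integer(0),
               occupancy = integer(0), members = character(0))
  path <- file.path(outdir, "cluster_list.tsv")
  write_tsv(index, path)
  invisible(path)
}

# longest member, ties broken lexicographically
cluster_representative <- function(cluster, seqs) {
  members <- cluster$members
  len <- seq_length(seqs, members)
  members[order(-len, members)][1L]
}

# all TSV outputs: tab-delimited, header row, '#' comments allowed on read
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}
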