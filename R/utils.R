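#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile p.adjust fisher.test setNames phyper
#'   cutree hclust as.dist dist runif rbinom rlnorm coef
#' @importFrom utils head tail write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table is used via :: only; declare awareness so its [ semantics apply
.datatable.aware <- TRUE

# Run code with a local, restorable RNG state so library functions never
# disturb the caller's random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

#' Reverse-complement a nucleotide string
#'
#' Operates on plain character strings, the package's internal sequence
#' representation.
#'
#' @param nt single nucleotide string (ACGTN).
#' @return reverse-complemented string.
#' @export
revcomp <- function(nt) {
  rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", nt))))
}

# translate a nucleotide string; returns AA string with "*" for stops
translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "X"
  )))
}
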