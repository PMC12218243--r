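POOLS <- c("SSU16S", "SSU18S")

#' Convert a phred+33 quality string to integer scores
#' @param qual character vector of phred+33 strings
#' @return list of integer vectors
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Convert integer quality scores to a phred+33 string
#' @param q integer vector of Phred scores in [0, 60]
#' @return single character string
#' @export
int_to_phred <- function(q) {
  stopifnot(all(q >= 0L), all(q <= 60L))
  rawToChar(as.raw(q + 33L))
}

# reverse a phred string
rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Reverse complement of plain ACGTN sequences
#' @param x character vector of nucleotide strings
#' @return character vector
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

# reverse complement of an IUPAC degenerate pattern
iupac_revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  rev_string(comp)
}

#' MD5 digest of sequence strings
#'
#' Content-hash feature ids in the QIIME2 style: the MD5 of the uppercase
#' sequence bytes. Identical sequences therefore receive identical ids in
#' every sample and run.
#' @param x character vector of sequences
#' @return character vector of 32-char hex digests
#' @export
md5_sequence <- function(x) {
  if (length(x) == 0L) return(character(0))
  dir <- tempfile("md5")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  paths <- file.path(dir, sprintf("s%06d", seq_along(x)))
  for (i in seq_along(x)) {
    con <- file(paths[i], "wb")
    writeBin(charToRaw(toupper(x[i])), con)
    close(con)
  }
  unname(tools::md5sum(paths))
}

# derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483587L
}
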