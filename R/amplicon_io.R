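#' Universal SSU primer pair
#'
#' Holds a forward/reverse primer pair written 5'->3' as ordered, using
#' IUPAC degeneracy codes. The package default is the three-domain
#' 515Y/926R pair, which amplifies the V4-V5 SSU region of bacteria,
#' archaea, eukaryotic nuclear 18S and plastid 16S in one reaction.
#'
#' @param forward,reverse IUPAC nucleotide strings, 5'->3'
#' @return an object of class `primer_pair`
#' @examples
#' primer_pair()  # 515Y/926R
#' @export
primer_pair <- function(forward = "GTGYCAGCMGCCGCGGTAA",
                        reverse = "CCGYCAATTYMTTTRAGTTT") {
  ok <- function(p) nchar(p) > 0L &&
    !grepl("[^ACGTRYSWKMBDHVN]", toupper(p))
  if (!ok(forward) || !ok(reverse))
    stop("primers must be nonempty IUPAC nucleotide strings")
  structure(list(forward = toupper(forward), reverse = toupper(reverse)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("primer_pair: fwd 5'-", x$forward, " rev 5'-", x$reverse, "\n", sep = "")
  invisible(x)
}

#' Match an IUPAC pattern against an equal-length window
#'
#' A window base mismatches when it is not in the allowed set of the
#' pattern's IUPAC code at that position; `N` in the window matches any
#' code.
#'
#' @param pattern IUPAC string
#' @param window plain nucleotide string, same length as `pattern`
#' @param max_mismatch allowed mismatch count
#' @return logical
#' @export
iupac_match <- function(pattern, window, max_mismatch = 0L) {
  if (nchar(pattern) != nchar(window))
    stop("pattern and window must have equal length")
  C_iupac_mismatches(toupper(pattern), toupper(window)) <= max_mismatch
}

#' Read paired FASTQ files into a read-pair table
#'
#' Reads two matched FASTQ files (plain or gzip) and returns one row per
#' pair. Record order is preserved; the two files must contain the same
#' number of records.
#'
#' @param fwd_path,rev_path FASTQ paths
#' @param sample_id sample label attached to every pair
#' @return `data.table` with columns read_id, fwd_seq, fwd_qual, rev_seq,
#'   rev_qual, sample_id (qualities as phred+33 strings)
#' @export
read_fastq_pairs <- function(fwd_path, rev_path, sample_id) {
  rd <- function(p) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ in ", p, ": ",
                               conditionMessage(e), call. = FALSE))
    x
  }
  fx <- rd(fwd_path)
  rx <- rd(rev_path)
  if (length(fx) != length(rx))
    stop(sprintf("mismatched record counts: %d in %s vs %d in %s",
                 length(fx), fwd_path, length(rx), rev_path), call. = FALSE)
  data.table::data.table(
    read_id = sub(" .*$", "", names(fx)),
    fwd_seq = as.character(fx),
    fwd_qual = as.character(S4Vectors::mcols(fx)$qualities),
    rev_seq = as.character(rx),
    rev_qual = as.character(S4Vectors::mcols(rx)$qualities),
    sample_id = sample_id)
}

#' Write a read-pair table back to paired FASTQ files
#'
#' Inverse of [read_fastq_pairs()]: ids, sequences, and qualities round-trip
#' byte-identically. Paths ending in `.gz` are gzip-compressed.
#'
#' @param pairs read-pair table
#' @param fwd_path,rev_path output FASTQ paths
#' @return invisibly, the two paths
#' @export
write_fastq_pairs <- function(pairs, fwd_path, rev_path) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path))
  }
  wr(pairs$fwd_seq, pairs$fwd_qual, pairs$read_id, fwd_path)
  wr(pairs$rev_seq, pairs$rev_qual, pairs$read_id, rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Read a sample manifest
#'
#' TSV with header `sample_id, fwd_path, rev_path, run_id`; `run_id` links
#' each sample to its sequencing-run chemistry record.
#'
#' @param path manifest TSV
#' @return `data.table`
#' @export
read_manifest <- function(path) {
  m <- data.table::fread(path, sep = "\t", colClasses = "character")
  need <- c("sample_id", "fwd_path", "rev_path", "run_id")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("manifest sample_ids must be unique")
  m
}

#' Locate and trim primers from read pairs
#'
#' Searches for the forward primer near the 5' end of the forward read and
#' the reverse primer near the 5' end of the reverse read, allowing a small
#' positional slack (demultiplexed reads start at or near the primer). Both
#' the primer and any preceding bases are removed, together with their
#' qualities. Pairs in which either primer is not found are rejected as a
#' whole, since downstream stages need both mates.
#'
#' @param pairs read-pair table from [read_fastq_pairs()]
#' @param primers a [primer_pair()]
#' @param max_mismatch allowed mismatches per primer (default 2)
#' @param slack extra leading bases searched beyond position 1 (default 5)
#' @return list with `pairs` (trimmed table) and `rejected_ids`
#' @export
trim_primers <- function(pairs, primers = primer_pair(), max_mismatch = 2L,
                         slack = 5L) {
  stopifnot(inherits(primers, "primer_pair"))
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, rejected_ids = character(0)))
  off_f <- C_iupac_find(pairs$fwd_seq, primers$forward, max_mismatch, slack)
  off_r <- C_iupac_find(pairs$rev_seq, primers$reverse, max_mismatch, slack)
  keep <- off_f >= 0L & off_r >= 0L
  out <- pairs[keep]
  cf <- off_f[keep] + nchar(primers$forward) + 1L
  cr <- off_r[keep] + nchar(primers$reverse) + 1L
  out[, `:=`(
    fwd_seq = substring(fwd_seq, cf),
    fwd_qual = substring(fwd_qual, cf),
    rev_seq = substring(rev_seq, cr),
    rev_qual = substring(rev_qual, cr))]
  list(pairs = out, rejected_ids = pairs$read_id[!keep])
}
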