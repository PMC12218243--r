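#' Dereplicate prepared sequences
#'
#' Collapses identical sequences to (sequence, abundance) records sorted by
#' abundance descending, ties broken by sequence lexicographically. The
#' deterministic order fixes the processing order of the greedy denoiser.
#'
#' @param seqs character vector of prepared sequences (one sample and pool)
#' @return `data.table` with columns sequence, abundance
#' @export
dereplicate <- function(seqs) {
  if (length(seqs) == 0L)
    return(data.table::data.table(sequence = character(0),
                                  abundance = integer(0)))
  tab <- table(seqs)
  d <- data.table::data.table(sequence = names(tab),
                              abundance = as.integer(tab))
  data.table::setorderv(d, c("abundance", "sequence"), order = c(-1L, 1L))
  d
}

#' Greedy abundance-skew denoising
#'
#' A defined, testable substitute for error-model denoisers: unique
#' sequences are processed in abundance order; a sequence joins the most
#' abundant already-accepted center within Hamming distance `max_dist`
#' whose abundance satisfies the UNOISE-style skew inequality
#' `abund(u) <= abund(c) / 2^(alpha * d + 1)`, and otherwise founds a new
#' center. Sequences of unequal length never merge.
#'
#' @param derep output of [dereplicate()] (already sorted)
#' @param alpha skew steepness (default 2)
#' @param max_dist maximum Hamming distance for merging (default 10)
#' @return `data.table` with sequence, abundance, center (the center
#'   sequence each unique sequence was assigned to)
#' @export
denoise_greedy <- function(derep, alpha = 2.0, max_dist = 10L) {
  if (nrow(derep) == 0L)
    return(data.table::data.table(sequence = character(0),
                                  abundance = integer(0),
                                  center = character(0)))
  idx <- C_greedy_denoise(derep$sequence, as.numeric(derep$abundance),
                          alpha, as.integer(max_dist))
  out <- data.table::copy(derep)
  out[, center := derep$sequence[idx]]
  out
}

#' Denoise one sample and pool into ASV counts
#'
#' Dereplicates, runs the greedy denoiser, and sums read counts per center
#' sequence. ASV ids are MD5 content hashes of the uppercase sequence, so
#' identical sequences get identical ids across samples and runs.
#'
#' @param prepared prepared-sequence table for one sample and pool
#' @param alpha,max_dist see [denoise_greedy()]
#' @return `data.table` with asv_id, sequence, count
#' @export
denoise_sample <- function(prepared, alpha = 2.0, max_dist = 10L) {
  dn <- denoise_greedy(dereplicate(prepared$sequence), alpha = alpha,
                       max_dist = max_dist)
  if (nrow(dn) == 0L)
    return(data.table::data.table(asv_id = character(0),
                                  sequence = character(0),
                                  count = integer(0)))
  agg <- dn[, .(count = sum(abundance)), by = .(sequence = center)]
  data.table::setorderv(agg, c("count", "sequence"), order = c(-1L, 1L))
  agg[, asv_id := md5_sequence(sequence)]
  agg[, .(asv_id, sequence, count)]
}

#' Assemble a raw ASV table from per-sample denoising results
#'
#' @param per_sample named list (by sample_id) of [denoise_sample()] outputs
#' @param pool `"SSU16S"` or `"SSU18S"`
#' @return object of class `raw_asv_table`: integer matrix `counts`
#'   (samples x ASVs), named character `seqs` (asv_id -> sequence), `pool`
#' @export
raw_asv_table <- function(per_sample, pool) {
  stopifnot(pool %in% POOLS)
  all_ids <- unique(unlist(lapply(per_sample, function(x) x$asv_id)))
  seqs <- character(0)
  counts <- matrix(0L, nrow = length(per_sample), ncol = length(all_ids),
                   dimnames = list(names(per_sample), all_ids))
  for (sid in names(per_sample)) {
    x <- per_sample[[sid]]
    if (nrow(x) == 0L) next
    counts[sid, x$asv_id] <- x$count
    seqs[x$asv_id] <- x$sequence
  }
  structure(list(counts = counts, seqs = seqs[all_ids], pool = pool),
            class = "raw_asv_table")
}

#' @export
print.raw_asv_table <- function(x, ...) {
  cat(sprintf("raw_asv_table (%s): %d samples x %d ASVs, %d reads\n",
              x$pool, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Flag and remove de novo bimeras
#'
#' An ASV is flagged as a bimera when two parent ASVs, each with at least
#' `min_fold` (default 2) times its study-wide abundance, exactly
#' reconstruct it as a prefix of one parent up to some breakpoint plus the
#' positional suffix of the other after it. Flagged ASVs and their counts
#' are removed from the table.
#'
#' @param table a [raw_asv_table()]
#' @param min_fold parent abundance fold requirement (default 2)
#' @return list with `table` (cleaned) and `flagged` (character asv_ids)
#' @export
remove_bimeras <- function(table, min_fold = 2.0) {
  stopifnot(inherits(table, "raw_asv_table"))
  if (ncol(table$counts) == 0L) return(list(table = table,
                                            flagged = character(0)))
  study <- colSums(table$counts)
  flags <- C_bimera_flags(unname(table$seqs), as.numeric(study), min_fold)
  flagged <- colnames(table$counts)[flags]
  keep <- !flags
  out <- structure(list(counts = table$counts[, keep, drop = FALSE],
                        seqs = table$seqs[keep], pool = table$pool),
                   class = "raw_asv_table")
  list(table = out, flagged = flagged)
}

#' Per-sample, per-pool denoising statistics
#'
#' `n_input` is the read count at pool entry (post-split, pre-MaxEE) so the
#' pass ratio absorbs quality filtering, denoising and chimera loss.
#'
#' @param sample_id,pool labels
#' @param n_input,n_filtered,n_denoised,n_nonchimeric read counts at the
#'   four accounting stages (must be non-increasing)
#' @return one-row `data.table` including `pass_ratio`
#' @export
denoise_stats <- function(sample_id, pool, n_input, n_filtered, n_denoised,
                          n_nonchimeric) {
  stopifnot(n_input >= n_filtered, n_filtered >= n_denoised,
            n_denoised >= n_nonchimeric, n_nonchimeric >= 0L)
  data.table::data.table(
    sample_id = sample_id, pool = pool, n_input = n_input,
    n_filtered = n_filtered, n_denoised = n_denoised,
    n_nonchimeric = n_nonchimeric,
    pass_ratio = if (n_input > 0L) n_nonchimeric / n_input else NA_real_)
}

#' Ratio of reads passing denoising and chimera removal
#'
#' Non-chimeric reads divided by the initial number of input reads; the
#' divisor of the corrected-abundance equation.
#'
#' @param stats one row of [denoise_stats()]
#' @return numeric pass ratio in [0, 1]
#' @export
compute_pass_ratio <- function(stats) {
  if (any(stats$n_input == 0L))
    stop("n_input is 0: sample unusable for this pool")
  stats$n_nonchimeric / stats$n_input
}
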