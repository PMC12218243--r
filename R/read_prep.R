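#' Expected number of sequencing errors in a read
#'
#' The MaxEE statistic: the sum over bases of the Phred error probability
#' `10^(-Q/10)`. An empty read has 0 expected errors.
#'
#' @param qual a phred+33 quality string, a character vector of them, or an
#'   integer vector of Phred scores
#' @return numeric vector of expected-error sums
#' @export
expected_errors <- function(qual) {
  if (is.numeric(qual)) {
    if (length(qual) == 0L) return(0)
    return(sum(10^(-qual / 10)))
  }
  C_expected_errors(qual)
}

#' Expected-error (MaxEE) filter for read pairs
#'
#' Applies optional fixed truncation to each mate, then fails the pair if
#' either mate's expected-error sum exceeds `max_ee`. A sum exactly equal
#' to `max_ee` passes ("errors higher than this" are discarded). Mates
#' shorter than their truncation length fail with the distinct status
#' `"too_short"`.
#'
#' @param pairs read-pair table
#' @param max_ee maximum expected errors per mate (default 2)
#' @param trunc_fwd,trunc_rev fixed truncation lengths, or NULL for none
#' @return list with `pairs` (truncated passing pairs) and `status`
#'   (character per input pair: "pass", "fail_ee", "too_short")
#' @export
filter_maxee <- function(pairs, max_ee = 2.0, trunc_fwd = NULL,
                         trunc_rev = NULL) {
  stopifnot(max_ee > 0)
  n <- nrow(pairs)
  status <- rep("pass", n)
  out <- data.table::copy(pairs)
  if (!is.null(trunc_fwd)) {
    short <- nchar(out$fwd_seq) < trunc_fwd
    status[short] <- "too_short"
    out[, `:=`(fwd_seq = substr(fwd_seq, 1L, trunc_fwd),
               fwd_qual = substr(fwd_qual, 1L, trunc_fwd))]
  }
  if (!is.null(trunc_rev)) {
    short <- nchar(out$rev_seq) < trunc_rev
    status[short] <- "too_short"
    out[, `:=`(rev_seq = substr(rev_seq, 1L, trunc_rev),
               rev_qual = substr(rev_qual, 1L, trunc_rev))]
  }
  if (n > 0L) {
    ee_f <- C_expected_errors(out$fwd_qual)
    ee_r <- C_expected_errors(out$rev_qual)
    fail <- (ee_f > max_ee | ee_r > max_ee) & status == "pass"
    status[fail] <- "fail_ee"
  }
  list(pairs = out[status == "pass"], status = status)
}

#' Overlap-merge 16S read pairs
#'
#' The standard treatment for the 16S pool, whose mates overlap at 2x250.
#' The reverse mate is reverse-complemented and the best ungapped overlap
#' of length at least `min_overlap` with mismatch fraction at most
#' `max_mismatch_frac` is chosen by maximal matching-base count (ties go to
#' the longest overlap). At agreeing positions the merged quality is the
#' capped sum of the two qualities; at disagreements the higher-quality
#' base wins with quality `|q1 - q2|`.
#'
#' @param pairs read-pair table assigned to the 16S pool
#' @param min_overlap minimum overlap length (default 20)
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.10)
#' @param qcap posterior quality cap (default 41)
#' @return list with `prepared` (sample_id, pool, sequence, qual for merged
#'   pairs) and `merged` (logical per input pair)
#' @export
merge_overlap <- function(pairs, min_overlap = 20L, max_mismatch_frac = 0.10,
                          qcap = 41L) {
  if (nrow(pairs) == 0L) {
    return(list(prepared = empty_prepared(), merged = logical(0)))
  }
  res <- C_merge_pairs(pairs$fwd_seq, pairs$fwd_qual,
                       revcomp(pairs$rev_seq), rev_string(pairs$rev_qual),
                       as.integer(min_overlap), max_mismatch_frac,
                       as.integer(qcap))
  ok <- res$merged
  prepared <- data.table::data.table(
    sample_id = pairs$sample_id[ok],
    pool = "SSU16S",
    sequence = res$seq[ok],
    qual = res$qual[ok])
  list(prepared = prepared, merged = ok)
}

empty_prepared <- function() {
  data.table::data.table(sample_id = character(0), pool = character(0),
                         sequence = character(0), qual = character(0))
}

#' Truncate-and-concatenate 18S read pairs
#'
#' The 18S amplicon is too long for the mates to overlap at 2x250, so each
#' pair is reduced to a fixed-geometry sequence: the forward mate truncated
#' to `trunc_fwd` (220) bases, an N spacer, and the reverse-complemented
#' reverse mate truncated to `trunc_rev` (180) bases. The universal trim
#' lengths make 18S ASVs directly comparable across sequencing runs. Pairs
#' with a mate shorter than its truncation length are rejected. Spacer
#' positions carry quality 0.
#'
#' @param pairs read-pair table assigned to the 18S pool
#' @param trunc_fwd,trunc_rev fixed truncation lengths (defaults 220/180)
#' @param spacer_len number of N bases joining the mates (default 10)
#' @return list with `prepared` and `kept` (logical per input pair)
#' @export
concat_18S <- function(pairs, trunc_fwd = 220L, trunc_rev = 180L,
                       spacer_len = 10L) {
  keep <- nchar(pairs$fwd_seq) >= trunc_fwd & nchar(pairs$rev_seq) >= trunc_rev
  kept <- pairs[keep]
  spacer <- strrep("N", spacer_len)
  spacer_q <- strrep("!", spacer_len)  # phred 0
  prepared <- if (nrow(kept) == 0L) empty_prepared() else
    data.table::data.table(
      sample_id = kept$sample_id,
      pool = "SSU18S",
      sequence = paste0(substr(kept$fwd_seq, 1L, trunc_fwd), spacer,
                        revcomp(substr(kept$rev_seq, 1L, trunc_rev))),
      qual = paste0(substr(kept$fwd_qual, 1L, trunc_fwd), spacer_q,
                    rev_string(substr(kept$rev_qual, 1L, trunc_rev))))
  list(prepared = prepared, kept = keep)
}

#' Pool-specific read preparation with accounting
#'
#' Runs the MaxEE filter followed by overlap merging (16S) or fixed-length
#' concatenation (18S) and reports read accounting for the prep report.
#' For the 18S pool, truncation to 220/180 is applied before the
#' expected-error computation.
#'
#' @param pairs read-pair table for one sample and pool
#' @param pool `"SSU16S"` or `"SSU18S"`
#' @param params list of preparation parameters; see [prep_params()]
#' @return list with `prepared` and a one-row `report`
#'   (sample_id, pool, n_input, n_maxee_fail, n_too_short, n_merge_fail,
#'   n_output)
#' @export
prep_pool <- function(pairs, pool, params = prep_params()) {
  stopifnot(pool %in% POOLS)
  sid <- if (nrow(pairs) > 0L) pairs$sample_id[1L] else NA_character_
  n_input <- nrow(pairs)
  if (pool == "SSU16S") {
    f <- filter_maxee(pairs, max_ee = params$max_ee)
    m <- merge_overlap(f$pairs, min_overlap = params$min_overlap,
                       max_mismatch_frac = params$max_mismatch_frac,
                       qcap = params$qcap)
    prepared <- m$prepared
    rep <- data.table::data.table(
      sample_id = sid, pool = pool, n_input = n_input,
      n_maxee_fail = sum(f$status == "fail_ee"),
      n_too_short = sum(f$status == "too_short"),
      n_merge_fail = sum(!m$merged),
      n_output = nrow(prepared))
  } else {
    f <- filter_maxee(pairs, max_ee = params$max_ee,
                      trunc_fwd = params$trunc_fwd,
                      trunc_rev = params$trunc_rev)
    cc <- concat_18S(f$pairs, trunc_fwd = params$trunc_fwd,
                     trunc_rev = params$trunc_rev,
                     spacer_len = params$spacer_len)
    prepared <- cc$prepared
    rep <- data.table::data.table(
      sample_id = sid, pool = pool, n_input = n_input,
      n_maxee_fail = sum(f$status == "fail_ee"),
      n_too_short = sum(f$status == "too_short"),
      n_merge_fail = 0L,
      n_output = nrow(prepared))
  }
  list(prepared = prepared, report = rep)
}

#' Default read-preparation parameters
#'
#' @param max_ee maximum expected errors per mate (default 2)
#' @param trunc_fwd,trunc_rev 18S truncation lengths (220/180)
#' @param spacer_len 18S N-spacer length (default 10)
#' @param min_overlap,max_mismatch_frac,qcap 16S merger settings
#' @return named list
#' @export
prep_params <- function(max_ee = 2.0, trunc_fwd = 220L, trunc_rev = 180L,
                        spacer_len = 10L, min_overlap = 20L,
                        max_mismatch_frac = 0.10, qcap = 41L) {
  list(max_ee = max_ee, trunc_fwd = trunc_fwd, trunc_rev = trunc_rev,
       spacer_len = spacer_len, min_overlap = min_overlap,
       max_mismatch_frac = max_mismatch_frac, qcap = qcap)
}
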