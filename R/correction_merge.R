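#' Bioanalyzer molar fractions of the 16S and 18S amplicon peaks
#'
#' The "expected" pre-sequencing composition: each pool's molar
#' concentration divided by the pooled total. Unit-invariant as long as
#' both concentrations share a unit.
#'
#' @param conc_16S,conc_18S molar concentrations (> 0, same unit)
#' @return named numeric `c(frac_16S_bio, frac_18S_bio)`
#' @export
bio_fractions <- function(conc_16S, conc_18S) {
  if (any(conc_16S <= 0) || any(conc_18S <= 0))
    stop("concentrations must be positive")
  tot <- conc_16S + conc_18S
  c(frac_16S_bio = conc_16S / tot, frac_18S_bio = conc_18S / tot)
}

#' Post-split sequence fractions of the 16S and 18S pools
#'
#' The realized composition after sequencing: each pool's read total after
#' the in silico 16S/18S split, divided by their sum.
#'
#' @param seqs_16S,seqs_18S post-split read totals for a sequencing run
#' @return named numeric `c(frac_16S_seq, frac_18S_seq)`
#' @export
seq_fractions <- function(seqs_16S, seqs_18S) {
  tot <- seqs_16S + seqs_18S
  if (any(tot <= 0)) stop("total read count must be positive")
  c(frac_16S_seq = seqs_16S / tot, frac_18S_seq = seqs_18S / tot)
}

#' Per-run correction factors for sequencing length bias
#'
#' Each pool's correction factor is its bioanalyzer molar fraction divided
#' by its post-split sequence fraction, computed from unrounded fractions
#' (the printed 2-dp factors are display values only). Factors above 1
#' re-inflate the pool the platform under-sampled (typically the longer
#' 18S fragments).
#'
#' @param chem one-row run-chemistry record (see [run_chemistry()]) or any
#'   list with conc_16S, conc_18S, seqs_16S, seqs_18S
#' @return named numeric `c(cf_16S, cf_18S)`
#' @export
correction_factors <- function(chem) {
  if (!is.null(chem$borrowed_from) && !is.na(chem$borrowed_from) &&
      nzchar(chem$borrowed_from))
    stop("run borrows its factors; resolve borrowed_from first")
  bio <- bio_fractions(chem$conc_16S, chem$conc_18S)
  sq <- seq_fractions(chem$seqs_16S, chem$seqs_18S)
  c(cf_16S = unname(bio[1L] / sq[1L]), cf_18S = unname(bio[2L] / sq[2L]))
}

#' Corrected read abundance
#'
#' Raw abundance times the pool's correction factor, divided by the
#' sample's pass ratio (the fraction of input reads surviving denoising
#' and chimera removal). Output is real-valued by design.
#'
#' @param raw raw read abundance
#' @param cf pool correction factor
#' @param pass_ratio per-sample, per-pool pass ratio in (0, 1]
#' @return numeric corrected abundance
#' @export
corrected_abundance <- function(raw, cf, pass_ratio) {
  if (any(pass_ratio <= 0))
    stop("pass_ratio must be positive; sample/pool unusable")
  raw * cf / pass_ratio
}

#' Build a run-chemistry table
#'
#' One row per sequencing run: molar concentrations of the 16S- and
#' 18S-length bioanalyzer peaks, post-split read totals, the derived
#' fractions and correction factors. Runs without a bioanalyzer trace name
#' another run in `borrowed_from` and inherit its correction factors (the
#' treatment used for runs whose libraries were prepared identically to a
#' traced run). Fractions and factors are carried unrounded; rounding is
#' for display only.
#'
#' @param run_id character vector of run labels
#' @param conc_16S,conc_18S molar concentrations (NA when borrowed)
#' @param seqs_16S,seqs_18S post-split read totals
#' @param borrowed_from donor run_id or NA
#' @param parse_ambiguous optional logical marker for rows whose source
#'   digits could not be parsed unambiguously
#' @return `data.table` of class `run_chemistry` with derived columns
#'   frac_16S_bio, frac_18S_bio, frac_16S_seq, frac_18S_seq, cf_16S, cf_18S
#' @export
run_chemistry <- function(run_id, conc_16S, conc_18S, seqs_16S, seqs_18S,
                          borrowed_from = NA_character_,
                          parse_ambiguous = FALSE) {
  d <- data.table::data.table(
    run_id = run_id, conc_16S = as.numeric(conc_16S),
    conc_18S = as.numeric(conc_18S),
    seqs_16S = as.numeric(seqs_16S), seqs_18S = as.numeric(seqs_18S),
    borrowed_from = borrowed_from, parse_ambiguous = parse_ambiguous)
  if (anyDuplicated(d$run_id)) stop("run_ids must be unique")
  d[, `:=`(frac_16S_bio = NA_real_, frac_18S_bio = NA_real_,
           frac_16S_seq = NA_real_, frac_18S_seq = NA_real_,
           cf_16S = NA_real_, cf_18S = NA_real_)]
  for (i in seq_len(nrow(d))) {
    sq <- seq_fractions(d$seqs_16S[i], d$seqs_18S[i])
    d[i, `:=`(frac_16S_seq = sq[1L], frac_18S_seq = sq[2L])]
    if (is.na(d$borrowed_from[i]) || !nzchar(d$borrowed_from[i])) {
      bio <- bio_fractions(d$conc_16S[i], d$conc_18S[i])
      d[i, `:=`(frac_16S_bio = bio[1L], frac_18S_bio = bio[2L],
                cf_16S = bio[1L] / sq[1L], cf_18S = bio[2L] / sq[2L])]
    }
  }
  # resolve borrowed factors after all native rows are computed
  for (i in which(!is.na(d$borrowed_from) & nzchar(d$borrowed_from))) {
    j <- match(d$borrowed_from[i], d$run_id)
    if (is.na(j) || is.na(d$cf_16S[j]))
      stop("unresolved borrowed_from for run ", d$run_id[i])
    d[i, `:=`(cf_16S = d$cf_16S[j], cf_18S = d$cf_18S[j])]
  }
  data.table::setattr(d, "class", c("run_chemistry", class(d)))
  d
}

#' Read / write run-chemistry TSV
#'
#' Columns mirror the per-run chemistry table: run_id, conc_16S, conc_18S,
#' seqs_16S, seqs_18S, borrowed_from (empty for native rows). Derived
#' columns are recomputed on read.
#' @param path TSV path
#' @return a [run_chemistry()] table
#' @export
read_chemistry <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  bf <- if ("borrowed_from" %in% names(d)) as.character(d$borrowed_from)
        else NA_character_
  bf[!nzchar(bf) | is.na(bf)] <- NA_character_
  run_chemistry(as.character(d$run_id), d$conc_16S, d$conc_18S,
                d$seqs_16S, d$seqs_18S, borrowed_from = bf)
}

#' @rdname read_chemistry
#' @param chem a [run_chemistry()] table
#' @export
write_chemistry <- function(chem, path) {
  out <- chem[, .(run_id, conc_16S, conc_18S, seqs_16S, seqs_18S,
                  borrowed_from)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Merge 16S and 18S ASV tables into one corrected three-domain table
#'
#' Samples whose combined raw post-denoise depth (16S + 18S) is strictly
#' below `min_depth` are dropped before any correction. Remaining counts
#' are corrected cell-wise by `raw * cf_pool / pass_ratio(sample, pool)`,
#' giving real-valued abundances, and the two pools' ASVs are placed in a
#' single table with pool tags.
#'
#' @param t16,t18 [raw_asv_table()]s for the two pools (post bimera
#'   removal); a pool may be NULL
#' @param chem [run_chemistry()] table covering every sample's run
#' @param stats rbind of [denoise_stats()] rows for each sample and pool
#' @param sample_runs named character vector mapping sample_id -> run_id
#' @param min_depth minimum combined raw depth (default 5000; samples at
#'   exactly `min_depth` are kept)
#' @return object of class `corrected_asv_table`: numeric matrix `counts`
#'   (samples x ASVs), `seqs`, `pool` (per ASV), and `provenance`
#'   (per sample/pool: run_id, cf, pass_ratio)
#' @export
merge_tables <- function(t16, t18, chem, stats, sample_runs,
                         min_depth = 5000L) {
  tabs <- list(SSU16S = t16, SSU18S = t18)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  samples <- unique(unlist(lapply(tabs, function(t) rownames(t$counts))))
  missing_run <- setdiff(samples, names(sample_runs))
  if (length(missing_run))
    stop("samples without run mapping: ", paste(missing_run, collapse = ", "))
  bad <- setdiff(unname(sample_runs[samples]), chem$run_id)
  if (length(bad))
    stop("missing chemistry for run(s): ", paste(unique(bad), collapse = ", "))
  # combined raw post-denoise depth per sample, before correction
  depth <- setNames(numeric(length(samples)), samples)
  for (t in tabs) {
    rs <- rowSums(t$counts)
    depth[names(rs)] <- depth[names(rs)] + rs
  }
  keep <- names(depth)[depth >= min_depth]
  asv_ids <- unlist(lapply(tabs, function(t) colnames(t$counts)),
                    use.names = FALSE)
  pool_tag <- unlist(lapply(tabs, function(t)
    rep(t$pool, ncol(t$counts))), use.names = FALSE)
  seqs <- unlist(unname(lapply(tabs, function(t) t$seqs)))
  names(pool_tag) <- asv_ids
  counts <- matrix(0, nrow = length(keep), ncol = length(asv_ids),
                   dimnames = list(keep, asv_ids))
  prov <- list()
  for (t in tabs) {
    pool <- t$pool
    cfcol <- if (pool == "SSU16S") "cf_16S" else "cf_18S"
    for (sid in intersect(rownames(t$counts), keep)) {
      run <- unname(sample_runs[sid])
      cf <- chem[[cfcol]][match(run, chem$run_id)]
      sel <- which(stats$sample_id == sid & stats$pool == pool)
      st <- stats[sel, ]
      if (nrow(st) != 1L)
        stop("missing denoise stats for sample ", sid, " pool ", pool)
      pr <- st$pass_ratio
      raw <- t$counts[sid, , drop = TRUE]
      if (any(raw > 0) && (is.na(pr) || pr <= 0))
        stop("nonpositive pass_ratio for sample ", sid, " pool ", pool)
      counts[sid, colnames(t$counts)] <-
        if (any(raw > 0)) corrected_abundance(raw, cf, pr) else 0
      prov[[length(prov) + 1L]] <- data.table::data.table(
        sample_id = sid, pool = pool, run_id = run, cf = cf,
        pass_ratio = pr)
    }
  }
  structure(list(counts = counts, seqs = seqs, pool = pool_tag,
                 provenance = data.table::rbindlist(prov),
                 dropped = setdiff(samples, keep)),
            class = "corrected_asv_table")
}

#' @export
print.corrected_asv_table <- function(x, ...) {
  cat(sprintf(
    "corrected_asv_table: %d samples x %d ASVs (%d x 16S, %d x 18S), %d dropped\n",
    nrow(x$counts), ncol(x$counts), sum(x$pool == "SSU16S"),
    sum(x$pool == "SSU18S"), length(x$dropped)))
  invisible(x)
}

#' Write a corrected ASV table as TSV triplets
#'
#' Long-format output (sample_id, asv_id, pool, abundance) plus a
#' provenance sidecar with the factor and pass ratio used per cell group.
#' @param x a `corrected_asv_table`
#' @param path output TSV; provenance written next to it as
#'   `<path>.provenance.tsv`
#' @export
write_corrected_table <- function(x, path) {
  idx <- which(x$counts != 0, arr.ind = TRUE)
  long <- data.table::data.table(
    sample_id = rownames(x$counts)[idx[, 1L]],
    asv_id = colnames(x$counts)[idx[, 2L]],
    pool = unname(x$pool[colnames(x$counts)[idx[, 2L]]]),
    abundance = x$counts[idx])
  data.table::setorderv(long, c("sample_id", "asv_id"))
  data.table::fwrite(long, path, sep = "\t")
  data.table::fwrite(x$provenance, paste0(path, ".provenance.tsv"),
                     sep = "\t")
  invisible(path)
}
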