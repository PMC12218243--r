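# Shared mock-community machinery for the test suite. Everything is built
# in code from the shipped pseudo-reference fixtures.

mock_ref16_path <- function()
  system.file("extdata", "mock_refs_16S.fasta", package = "ssufuse")
mock_ref18_path <- function()
  system.file("extdata", "mock_refs_18S.fasta", package = "ssufuse")

load_mock_refs <- function() {
  c(as.character(Biostrings::readDNAStringSet(mock_ref16_path())),
    as.character(Biostrings::readDNAStringSet(mock_ref18_path())))
}

# even members within each pool; molar 16S:18S = ratio16:(1-ratio16)
mock_members <- function(ratio16 = 2 / 3) {
  data.frame(
    ref_id = c(paste0("mock16S_", 1:5), paste0("mock18S_", 1:3)),
    pool = c(rep("SSU16S", 5), rep("SSU18S", 3)),
    molar_proportion = c(rep(ratio16 / 5, 5), rep((1 - ratio16) / 3, 3)))
}

.fixture_cache <- new.env(parent = emptyenv())

mock_split_index <- function() {
  if (is.null(.fixture_cache$index))
    .fixture_cache$index <- build_split_index(mock_ref16_path(),
                                              mock_ref18_path())
  .fixture_cache$index
}

# process one simulated sample through trim/split/prep/denoise; returns the
# intermediate pieces needed by correction-level tests
process_sample <- function(pairs, index = mock_split_index(),
                           params = prep_params(), alpha = 2, max_dist = 10) {
  tr <- trim_primers(pairs)
  dec <- split_pairs(tr$pairs, index)
  out <- list(split = dec,
              n16 = sum(dec$pool == "SSU16S"),
              n18 = sum(dec$pool == "SSU18S"))
  for (pool in c("SSU16S", "SSU18S")) {
    sel <- which(dec$pool == pool)
    pp <- prep_pool(tr$pairs[sel], pool, params)
    dn <- denoise_sample(pp$prepared, alpha = alpha, max_dist = max_dist)
    out[[pool]] <- list(prep = pp, asv = dn)
  }
  out
}

# full study: simulate + process n_samples, assemble corrected table
run_mock_study <- function(spec_base, n_samples = 1, seed = 1,
                           min_depth = 0, sample_props = NULL) {
  refs <- load_mock_refs()
  per16 <- list(); per18 <- list(); stats <- list()
  n16_tot <- 0; n18_tot <- 0
  conc <- c(0, 0)
  for (i in seq_len(n_samples)) {
    sid <- sprintf("s%02d", i)
    spec_i <- spec_base
    if (!is.null(sample_props)) {
      m <- data.table::copy(spec_base$members)
      m[, molar_proportion := sample_props[[i]]]
      spec_i$members <- m
    }
    spec_i$seed <- ssufuse:::derive_seed(seed, i)
    class(spec_i) <- "mock_spec"
    sim <- simulate_run(spec_i, refs, sample_id = sid)
    conc <- conc + emit_chemistry(spec_i) / n_samples
    pr <- process_sample(sim$pairs)
    per16[[sid]] <- pr$SSU16S$asv
    per18[[sid]] <- pr$SSU18S$asv
    n16_tot <- n16_tot + pr$n16
    n18_tot <- n18_tot + pr$n18
    stats[[paste0(sid, "_pre")]] <- list(sid = sid, n16 = pr$n16,
                                         n18 = pr$n18)
  }
  t16 <- raw_asv_table(per16, "SSU16S")
  t18 <- raw_asv_table(per18, "SSU18S")
  rb16 <- remove_bimeras(t16)
  rb18 <- remove_bimeras(t18)
  stat_rows <- list()
  for (i in seq_len(n_samples)) {
    sid <- sprintf("s%02d", i)
    pre <- stats[[paste0(sid, "_pre")]]
    nn16 <- if (ncol(rb16$table$counts)) sum(rb16$table$counts[sid, ]) else 0L
    nn18 <- if (ncol(rb18$table$counts)) sum(rb18$table$counts[sid, ]) else 0L
    stat_rows[[paste0(sid, "16")]] <-
      denoise_stats(sid, "SSU16S", pre$n16, sum(per16[[sid]]$count),
                    sum(per16[[sid]]$count), nn16)
    stat_rows[[paste0(sid, "18")]] <-
      denoise_stats(sid, "SSU18S", pre$n18, sum(per18[[sid]]$count),
                    sum(per18[[sid]]$count), nn18)
  }
  stats_dt <- data.table::rbindlist(stat_rows)
  chem <- run_chemistry("run1", conc[[1]], conc[[2]],
                        seqs_16S = n16_tot, seqs_18S = n18_tot)
  samples <- sprintf("s%02d", seq_len(n_samples))
  merged <- merge_tables(rb16$table, rb18$table, chem, stats_dt,
                         setNames(rep("run1", n_samples), samples),
                         min_depth = min_depth)
  list(merged = merged, chem = chem, stats = stats_dt,
       t16 = rb16$table, t18 = rb18$table,
       n16_tot = n16_tot, n18_tot = n18_tot)
}

# corrected 16S:18S read ratio of a merged table
pool_ratio <- function(merged) {
  p <- merged$pool[colnames(merged$counts)]
  sum(merged$counts[, p == "SSU16S", drop = FALSE]) /
    sum(merged$counts[, p == "SSU18S", drop = FALSE])
}

# toy read-pair table builder
make_pairs <- function(fwd, rev, qf = NULL, qr = NULL, sample_id = "t") {
  n <- length(fwd)
  if (is.null(qf)) qf <- vapply(nchar(fwd), function(l)
    strrep("I", l), character(1))
  if (is.null(qr)) qr <- vapply(nchar(rev), function(l)
    strrep("I", l), character(1))
  data.table::data.table(
    read_id = sprintf("r%03d", seq_len(n)), fwd_seq = fwd, fwd_qual = qf,
    rev_seq = rev, rev_qual = qr, sample_id = sample_id)
}
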