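#' Specify a synthetic mock community
#'
#' The stated world for simulation: a known molar mixture of 16S-type and
#' 18S-type reference amplicons, 2x250 read geometry (16S mates overlap,
#' 18S mates do not), per-base substitution error with a linear quality
#' decay, an optional chimera rate, and a single-parameter platform bias:
#' each 18S fragment is retained with probability `bias_18S` before
#' sequencing, emulating the under-sampling of longer fragments.
#'
#' @param members data.frame with columns ref_id, pool (`"SSU16S"` /
#'   `"SSU18S"`), molar_proportion (summing to 1)
#' @param n_read_pairs number of sequenced (post-bias) read pairs
#' @param read_len read length in bases (default 250)
#' @param bias_18S 18S retention probability beta in (0, 1]; 1 = unbiased
#' @param per_base_error substitution probability per base (default 0.001)
#' @param q_start,q_end linear quality decay endpoints (defaults 38, 25)
#' @param chimera_rate fraction of fragments replaced by two-parent
#'   splices (default 0)
#' @param seed RNG seed; all randomness derives from it
#' @return object of class `mock_spec`
#' @export
mock_spec <- function(members, n_read_pairs, read_len = 250L, bias_18S = 1.0,
                      per_base_error = 0.001, q_start = 38L, q_end = 25L,
                      chimera_rate = 0.0, seed = 1L) {
  members <- data.table::as.data.table(members)
  stopifnot(all(c("ref_id", "pool", "molar_proportion") %in% names(members)),
            all(members$pool %in% POOLS))
  if (abs(sum(members$molar_proportion) - 1) > 1e-9)
    stop("molar proportions must sum to 1")
  if (bias_18S <= 0 || bias_18S > 1) stop("bias_18S must be in (0, 1]")
  structure(list(members = members, n_read_pairs = as.integer(n_read_pairs),
                 read_len = as.integer(read_len), bias_18S = bias_18S,
                 per_base_error = per_base_error,
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 chimera_rate = chimera_rate, seed = as.integer(seed)),
            class = "mock_spec")
}

# mismatch count of an IUPAC pattern at every offset of seq
iupac_scan <- function(seq, pattern) {
  L <- nchar(seq) - nchar(pattern) + 1L
  if (L < 1L) return(integer(0))
  vapply(seq_len(L), function(i)
    C_iupac_mismatches(pattern, substr(seq, i, i + nchar(pattern) - 1L)),
    integer(1))
}

#' In silico PCR: extract the amplicon between two primer sites
#'
#' Locates the best (fewest-mismatch, leftmost on ties) forward-primer
#' site and the best reverse-primer site (matched as its reverse
#' complement on the forward strand, downstream of the forward site) and
#' returns the insert between them. Multiple equally good sites trigger a
#' warning and the leftmost is used. `NULL` if either site is absent.
#'
#' @param ref_seq near-full-length rRNA reference sequence
#' @param primers a [primer_pair()]
#' @param max_mismatch allowed mismatches per site (default 2)
#' @return insert string with attributes `fragment` (primer-inclusive
#'   amplicon) and `coords`, or NULL
#' @export
extract_amplicon <- function(ref_seq, primers = primer_pair(),
                             max_mismatch = 2L) {
  ref_seq <- toupper(ref_seq)
  pick <- function(mm, from = 1L) {
    if (length(mm) < from) return(NA_integer_)
    mm <- mm[from:length(mm)]
    best <- min(mm)
    if (best > max_mismatch) return(NA_integer_)
    hits <- which(mm == best)
    if (length(hits) > 1L)
      warning("multiple equally good primer sites; using leftmost")
    hits[1L] + from - 1L
  }
  fwd_at <- pick(iupac_scan(ref_seq, primers$forward))
  if (is.na(fwd_at)) return(NULL)
  fwd_end <- fwd_at + nchar(primers$forward) - 1L
  rc_rev <- iupac_revcomp(primers$reverse)
  rev_at <- pick(iupac_scan(ref_seq, rc_rev), from = fwd_end + 1L)
  if (is.na(rev_at)) return(NULL)
  rev_end <- rev_at + nchar(rc_rev) - 1L
  insert <- substr(ref_seq, fwd_end + 1L, rev_at - 1L)
  attr(insert, "fragment") <- substr(ref_seq, fwd_at, rev_end)
  attr(insert, "coords") <- c(fwd_start = fwd_at, rev_end = rev_end)
  insert
}

# linear quality decay string for a given read length
decay_qual <- function(len, read_len, q_start, q_end) {
  q <- round(seq(q_start, q_end, length.out = read_len))
  int_to_phred(q[seq_len(len)])
}

# inject substitution errors into reads at a fixed per-base rate
inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, rate)
  todo <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    pos <- sample.int(lens[i], nerr[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      cur <- chars[p]
      chars[p] <- sample(setdiff(bases, cur), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate one sequencing run of a mock community
#'
#' Fragments (primer-inclusive amplicons) are drawn per molar proportion;
#' each 18S draw is retained with probability `bias_18S`, and drawing
#' continues until `n_read_pairs` fragments are sequenced. A
#' `chimera_rate` fraction of sequenced fragments is replaced by a splice
#' of the fragment with a second same-pool member at a uniform interior
#' breakpoint. Reads are the first / last `read_len` bases of the fragment
#' (reverse read reverse-complemented) with per-base substitution errors
#' and linearly decaying qualities. Fully deterministic under the spec's
#' seed.
#'
#' @param spec a [mock_spec()]
#' @param refs named character vector (ref_id -> sequence) or FASTA path
#' @param primers a [primer_pair()]
#' @param sample_id sample label for the emitted reads
#' @return list with `pairs` (read-pair table), `truth` (read_id, member,
#'   pool, is_chimera), `n_drawn` (pre-bias draws per pool)
#' @export
simulate_run <- function(spec, refs, primers = primer_pair(),
                         sample_id = "mock1") {
  stopifnot(inherits(spec, "mock_spec"))
  if (length(refs) == 1L && file.exists(refs))
    refs <- as.character(Biostrings::readDNAStringSet(refs))
  mem <- spec$members
  absent <- setdiff(mem$ref_id, names(refs))
  if (length(absent))
    stop("members without a reference sequence: ",
         paste(absent, collapse = ", "))
  frags <- lapply(mem$ref_id, function(id) {
    amp <- extract_amplicon(refs[[id]], primers)
    if (is.null(amp))
      stop("member ", id, " yields no amplicon with the given primers")
    attr(amp, "fragment")
  })
  names(frags) <- mem$ref_id
  set.seed(spec$seed)
  n <- spec$n_read_pairs
  member_idx <- integer(0)
  n_drawn <- c(SSU16S = 0L, SSU18S = 0L)
  is18 <- mem$pool == "SSU18S"
  while (length(member_idx) < n) {
    need <- n - length(member_idx)
    m <- max(100L, ceiling(need * 1.3 /
      sum(mem$molar_proportion * ifelse(is18, spec$bias_18S, 1))))
    draw <- sample.int(nrow(mem), m, replace = TRUE,
                       prob = mem$molar_proportion)
    drawn18 <- is18[draw]
    tab <- tabulate(ifelse(drawn18, 2L, 1L), 2L)
    n_drawn <- n_drawn + tab
    keep <- !drawn18 | stats::runif(m) < spec$bias_18S
    member_idx <- c(member_idx, draw[keep])
  }
  member_idx <- member_idx[seq_len(n)]
  pool <- mem$pool[member_idx]
  frag_seq <- unlist(frags, use.names = FALSE)[member_idx]
  # chimeras: splice with a random other same-pool member
  is_chim <- stats::runif(n) < spec$chimera_rate
  for (i in which(is_chim)) {
    same <- which(mem$pool == pool[i] & seq_len(nrow(mem)) != member_idx[i])
    if (length(same) == 0L) { is_chim[i] <- FALSE; next }
    j <- same[sample.int(length(same), 1L)]
    a <- frag_seq[i]
    b <- frags[[j]]
    pmax_ <- min(nchar(a), nchar(b)) - 1L
    if (pmax_ < 2L) { is_chim[i] <- FALSE; next }
    p <- sample(seq.int(2L, pmax_), 1L)
    frag_seq[i] <- paste0(substr(a, 1L, p), substr(b, p + 1L, nchar(b)))
  }
  lens <- nchar(frag_seq)
  rl <- pmin(spec$read_len, lens)
  fwd <- substr(frag_seq, 1L, rl)
  rev <- revcomp(substr(frag_seq, lens - rl + 1L, lens))
  fwd <- inject_errors(fwd, spec$per_base_error)
  rev <- inject_errors(rev, spec$per_base_error)
  qual_cache <- new.env()
  qual_for <- function(len) {
    key <- as.character(len)
    if (is.null(qual_cache[[key]]))
      qual_cache[[key]] <- decay_qual(len, spec$read_len, spec$q_start,
                                      spec$q_end)
    qual_cache[[key]]
  }
  quals <- vapply(rl, qual_for, character(1))
  read_id <- sprintf("%s_r%07d", sample_id, seq_len(n))
  pairs <- data.table::data.table(
    read_id = read_id, fwd_seq = fwd, fwd_qual = quals,
    rev_seq = rev, rev_qual = quals, sample_id = sample_id)
  truth <- data.table::data.table(
    read_id = read_id, member = mem$ref_id[member_idx], pool = pool,
    is_chimera = is_chim)
  list(pairs = pairs, truth = truth, n_drawn = n_drawn)
}

#' Bioanalyzer-equivalent chemistry inputs for a mock run
#'
#' The true molar 16S and 18S totals of the specified community, scaled to
#' an arbitrary concentration unit: the "expected" pre-sequencing
#' composition that a bioanalyzer trace would report. A pool absent from
#' the community yields concentration 0, which is unusable for correction
#' factors (degenerate by construction).
#'
#' @param spec a [mock_spec()]
#' @param unit_scale multiplier into concentration units (default 1000)
#' @return named numeric `c(conc_16S, conc_18S)`
#' @export
emit_chemistry <- function(spec, unit_scale = 1000) {
  m16 <- sum(spec$members$molar_proportion[spec$members$pool == "SSU16S"])
  m18 <- sum(spec$members$molar_proportion[spec$members$pool == "SSU18S"])
  c(conc_16S = m16 * unit_scale, conc_18S = m18 * unit_scale)
}

#' Published per-run chemistry fixture
#'
#' The machine-readable per-sequencing-run chemistry table: molar
#' concentrations of the 16S and 18S bioanalyzer peaks and post-split read
#' totals for eight sequencing runs, from which the correction factors
#' derive. The FRAM/MOSAiC run has no bioanalyzer trace and borrows the
#' Southern Oceans factors. Two rows (I8/I9 and AMT19/AMT20/POTATOE) carry
#' digit runs that do not parse unambiguously in the typeset source; they
#' are included with `parse_ambiguous = TRUE` and excluded from exact
#' checks.
#'
#' @return a [run_chemistry()] table with 8 rows
#' @export
table1_fixture <- function() {
  run_chemistry(
    run_id = c("SOUTHERN_OCEANS", "GRADIENTS_1_2", "P16N_P16S",
               "GA03_GP13", "I8_I9", "GA02_GA10", "AMT19_AMT20_POTATOE",
               "FRAM_MOSAIC"),
    conc_16S = c(1340.0, 3292.0, 6162.1, 2052.0, 6162.1, 124014.1, 5969.3,
                 NA),
    conc_18S = c(335.1, 638.5, 2182.8, 434.0, 2185.2, 34444.1, 1361.0, NA),
    seqs_16S = c(295010733, 101174114, 42116230, 24433763, 40226353,
                 21661905, 12505672, 24349430),
    seqs_18S = c(34623340, 7014632, 3082200, 734205, 224586, 678869,
                 26122, 2035473),
    borrowed_from = c(rep(NA_character_, 7L), "SOUTHERN_OCEANS"),
    parse_ambiguous = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                        FALSE))
}
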