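# Independent brute-force oracles, deliberately written with different
# machinery than the package implementation.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

# all canonical k-mers of a set of sequences, via plain substring hashing
oracle_canonical_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      out <- c(out, if (km <= rc) km else rc)
    }
  }
  sort(unique(out))
}

# k-mer votes of one sequence against two exclusive sets (position counts)
oracle_votes <- function(seq, set16, set18, k) {
  v <- c(0L, 0L)
  n <- nchar(seq)
  if (n < k) return(v)
  for (i in seq_len(n - k + 1L)) {
    km <- substr(seq, i, i + k - 1L)
    if (grepl("[^ACGT]", km)) next
    rc <- oracle_revcomp(km)
    can <- if (km <= rc) km else rc
    if (can %in% set16) v[1L] <- v[1L] + 1L
    else if (can %in% set18) v[2L] <- v[2L] + 1L
  }
  v
}

oracle_ee <- function(q_ints) sum(10^(-q_ints / 10))

# exhaustive bimera search over all parent pairs and breakpoints
oracle_bimera <- function(seqs, abund, min_fold = 2) {
  n <- length(seqs)
  flags <- logical(n)
  for (i in seq_len(n)) {
    L <- nchar(seqs[i])
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == i || b == i) next
      if (nchar(seqs[a]) != L || nchar(seqs[b]) != L) next
      if (abund[a] < min_fold * abund[i] || abund[b] < min_fold * abund[i])
        next
      for (p in seq_len(L - 1L)) {
        cand <- paste0(substr(seqs[a], 1L, p), substr(seqs[b], p + 1L, L))
        if (cand == seqs[i]) { flags[i] <- TRUE; break }
      }
      if (flags[i]) break
    }
  }
  flags
}

# winding-number point-in-polygon (nonzero rule; equals even-odd for
# simple polygons)
oracle_winding <- function(lon, lat, poly) {
  wn <- 0L
  n <- nrow(poly)
  for (i in seq_len(n - 1L)) {
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    x2 <- poly[i + 1L, 1L]; y2 <- poly[i + 1L, 2L]
    if (y1 <= lat) {
      if (y2 > lat && (x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1) > 0)
        wn <- wn + 1L
    } else {
      if (y2 <= lat && (x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1) < 0)
        wn <- wn - 1L
    }
  }
  wn != 0L
}

# brute-force best ungapped overlap merge (sequence only)
oracle_merge <- function(fwd, rev_rc, min_overlap, max_mm_frac) {
  Lf <- nchar(fwd); Lr <- nchar(rev_rc)
  best <- NULL; best_match <- -1L; best_ov <- -1L
  for (ov in min_overlap:min(Lf, Lr)) {
    a <- substr(fwd, Lf - ov + 1L, Lf)
    b <- substr(rev_rc, 1L, ov)
    mm <- sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
    if (mm > max_mm_frac * ov) next
    if (ov - mm > best_match || (ov - mm == best_match && ov > best_ov)) {
      best_match <- ov - mm; best_ov <- ov
      best <- paste0(fwd, substr(rev_rc, ov + 1L, Lr))
    }
  }
  best
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
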