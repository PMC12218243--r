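test_that("expected_errors matches hand-computed sums", {
  expect_equal(expected_errors(rep(20L, 100)), 1.0)
  expect_equal(expected_errors(integer(0)), 0.0)
  expect_equal(expected_errors(c(10L, 20L, 30L, 40L)), 0.1111, tolerance = 1e-4)
  # string and integer forms agree
  expect_equal(expected_errors(int_to_phred(c(10L, 20L, 30L, 40L))),
               0.1111, tolerance = 1e-4)
})

test_that("filter_maxee boundary and failure semantics", {
  q20_100 <- strrep("5", 100)  # phred 20
  q10_100 <- strrep("+", 100)  # phred 10
  pr <- make_pairs("A", "A", q20_100, q20_100)
  pr$fwd_seq <- strrep("A", 100); pr$rev_seq <- strrep("A", 100)
  expect_equal(filter_maxee(pr, max_ee = 2)$status, "pass")
  bad <- data.table::copy(pr); bad$fwd_qual <- q10_100   # EE = 10
  expect_equal(filter_maxee(bad, max_ee = 2)$status, "fail_ee")
  # EE exactly equal to the threshold passes ("higher than" fails): use
  # the computed EE itself as the threshold so equality is exact
  exact <- data.table::copy(pr)
  exact$fwd_qual <- strrep(int_to_phred(20L), 200)       # EE ~ 2.0
  exact$fwd_seq <- strrep("A", 200)
  ee <- expected_errors(exact$fwd_qual)
  expect_equal(filter_maxee(exact, max_ee = ee)$status, "pass")
  expect_equal(filter_maxee(exact, max_ee = ee - 1e-9)$status, "fail_ee")
  # too-short under truncation is a distinct signal
  shrt <- make_pairs(strrep("A", 100), strrep("A", 300),
                     strrep("I", 100), strrep("I", 300))
  expect_equal(filter_maxee(shrt, trunc_fwd = 220, trunc_rev = 180)$status,
               "too_short")
})

test_that("maxEE decisions match the brute-force oracle on random reads", {
  set.seed(31)
  n <- 1000
  lens <- sample(50:250, n, replace = TRUE)
  quals <- vapply(lens, function(l)
    int_to_phred(sample(2:40, l, replace = TRUE)), character(1))
  pairs <- make_pairs(vapply(lens, function(l) strrep("A", l), character(1)),
                      strrep("A", 50), quals, strrep("I", 50))
  st <- filter_maxee(pairs, max_ee = 2)$status
  oracle <- vapply(quals, function(q)
    oracle_ee(ssufuse::phred_to_int(q)[[1]]) > 2, logical(1))
  expect_equal(unname(st == "fail_ee"), unname(oracle))
})

test_that("merge_overlap finds the best overlap (brute-force oracle)", {
  # 8-base true overlap between 10-mers
  pr <- make_pairs("ACGTACGTAC", revcomp("GTACGTACGT"))
  m <- merge_overlap(pr, min_overlap = 4)
  expect_true(m$merged)
  expect_equal(m$prepared$sequence, "ACGTACGTACGT")
  # identical full-length mates merge to the forward read
  pr2 <- make_pairs("ACGGTTCCAAGGTTCCAATT", revcomp("ACGGTTCCAAGGTTCCAATT"))
  m2 <- merge_overlap(pr2, min_overlap = 4)
  expect_equal(m2$prepared$sequence, "ACGGTTCCAAGGTTCCAATT")
  # zero admissible overlap rejects
  set.seed(41)
  pr3 <- make_pairs(random_seq(50), random_seq(50))
  expect_false(merge_overlap(pr3, min_overlap = 20)$merged)
  # random amplicons with known overlap geometry match the oracle
  for (rep in 1:20) {
    amp <- random_seq(sample(60:90, 1))
    L <- nchar(amp)
    rl <- sample(40:55, 1)
    fwd <- substr(amp, 1, min(rl, L))
    rev_rc <- substr(amp, max(1, L - rl + 1), L)
    m <- merge_overlap(make_pairs(fwd, revcomp(rev_rc)), min_overlap = 10)
    want <- oracle_merge(fwd, rev_rc, 10, 0.10)
    if (is.null(want)) {
      expect_false(m$merged)
    } else {
      expect_equal(m$prepared$sequence, want)
    }
  }
})

test_that("merged qualities follow the posterior rule", {
  # disagreement: higher-quality base wins with quality |q1-q2|
  fwd <- strrep("A", 20)
  rev_rc <- paste0(strrep("A", 19), "T")   # one mismatch, frac 0.05
  qf <- int_to_phred(c(rep(30L, 19), 10L))
  qr <- int_to_phred(c(rep(30L, 19), 25L))
  pr <- make_pairs(fwd, revcomp(rev_rc), qf, ssufuse:::rev_string(qr))
  m <- merge_overlap(pr, min_overlap = 10, qcap = 41)
  expect_equal(m$prepared$sequence, rev_rc)
  q <- ssufuse::phred_to_int(m$prepared$qual)[[1]]
  expect_equal(q[20], 15L)           # |25 - 10|
  expect_equal(q[1], 41L)            # 30 + 30 capped at 41
})

test_that("concat_18S builds the fixed-geometry sequence", {
  f <- random_seq(230); r <- random_seq(190)
  pr <- make_pairs(f, r, strrep("I", 230), strrep("5", 190))
  out <- concat_18S(pr, spacer_len = 10)
  expect_true(out$kept)
  expect_equal(nchar(out$prepared$sequence), 220 + 10 + 180)
  expect_equal(out$prepared$sequence,
               paste0(substr(f, 1, 220), strrep("N", 10),
                      revcomp(substr(r, 1, 180))))
  # spacer carries quality zero
  q <- ssufuse::phred_to_int(out$prepared$qual)[[1]]
  expect_equal(q[221:230], rep(0L, 10))
  # forward mate of 219 bases rejects
  pr2 <- make_pairs(random_seq(219), random_seq(190))
  expect_false(concat_18S(pr2)$kept)
  # differences beyond the truncation points are invisible
  f2 <- paste0(substr(f, 1, 220), random_seq(10))
  r2 <- paste0(substr(r, 1, 180), random_seq(10))
  out2 <- concat_18S(make_pairs(f2, r2, strrep("I", 230), strrep("5", 190)))
  expect_equal(out2$prepared$sequence, out$prepared$sequence)
})

test_that("error-free simulated pairs reconstruct their amplicons exactly", {
  spec <- mock_spec(mock_members(), n_read_pairs = 400, per_base_error = 0,
                    seed = 17)
  refs <- load_mock_refs()
  sim <- simulate_run(spec, refs)
  pr <- process_sample(sim$pairs)
  # every merged 16S sequence equals a true insert
  inserts16 <- vapply(paste0("mock16S_", 1:5), function(id)
    as.character(extract_amplicon(refs[[id]])), character(1))
  expect_true(all(pr$SSU16S$prep$prepared$sequence %in% inserts16))
  expect_setequal(unique(pr$SSU16S$prep$prepared$sequence), inserts16)
  # all 18S prepared sequences share one fixed length
  expect_equal(unique(nchar(pr$SSU18S$prep$prepared$sequence)), 410)
})
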