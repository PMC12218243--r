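test_that("bio and sequence fractions reproduce the published rows", {
  b <- bio_fractions(1340.0, 335.1)
  expect_equal(round(unname(b), 3), c(0.800, 0.200))
  expect_equal(unname(bio_fractions(7, 7)), c(0.5, 0.5))
  expect_equal(round(unname(bio_fractions(6162.1, 2182.8)), 3),
               c(0.738, 0.262))
  s <- seq_fractions(295010733, 34623340)
  expect_equal(round(unname(s), 3), c(0.895, 0.105))
  expect_equal(unname(seq_fractions(10, 0)), c(1.0, 0.0))
  expect_equal(round(unname(seq_fractions(101174114, 7014632)), 3),
               c(0.935, 0.065))
  expect_error(bio_fractions(-1, 5), "positive")
  expect_error(seq_fractions(0, 0), "positive")
})

test_that("correction factors come from unrounded fractions", {
  so <- correction_factors(list(conc_16S = 1340.0, conc_18S = 335.1,
                                seqs_16S = 295010733, seqs_18S = 34623340))
  expect_equal(round(unname(so), 2), c(0.89, 1.90))
  # frac_bio == frac_seq gives the identity factor
  id <- correction_factors(list(conc_16S = 3, conc_18S = 1,
                                seqs_16S = 300, seqs_18S = 100))
  expect_equal(unname(id), c(1, 1))
  ga <- correction_factors(list(conc_16S = 124014.1, conc_18S = 34444.1,
                                seqs_16S = 21661905, seqs_18S = 678869))
  expect_equal(round(unname(ga), 2), c(0.81, 7.15))
})

test_that("corrected abundance is raw * cf / pass_ratio", {
  expect_equal(corrected_abundance(100, 1.90, 0.5), 380.0)
  expect_equal(corrected_abundance(0, 5, 0.7), 0.0)
  expect_equal(corrected_abundance(137, 7.15, 0.914), 137 * 7.15 / 0.914,
               tolerance = 1e-12)
  expect_equal(corrected_abundance(137, 7.15, 0.914), 1071.72,
               tolerance = 1e-4)
  expect_error(corrected_abundance(10, 1, 0), "positive")
})

test_that("run_chemistry satisfies the algebraic invariants", {
  chem <- table1_fixture()
  native <- chem[is.na(chem$borrowed_from), ]
  # fractions sum to 1
  expect_equal(native$frac_16S_bio + native$frac_18S_bio,
               rep(1, nrow(native)), tolerance = 1e-9)
  expect_equal(chem$frac_16S_seq + chem$frac_18S_seq,
               rep(1, nrow(chem)), tolerance = 1e-9)
  # weighted identity cf16*f16seq + cf18*f18seq = 1 for native rows
  expect_equal(native$cf_16S * native$frac_16S_seq +
                 native$cf_18S * native$frac_18S_seq,
               rep(1, nrow(native)), tolerance = 1e-9)
  # borrowed run inherits the donor's factors
  fram <- chem[chem$run_id == "FRAM_MOSAIC", ]
  so <- chem[chem$run_id == "SOUTHERN_OCEANS", ]
  expect_equal(fram$cf_16S, so$cf_16S)
  expect_equal(fram$cf_18S, so$cf_18S)
  expect_error(run_chemistry("x", 1, 1, 10, 10, borrowed_from = "nope"),
               "unresolved")
})

test_that("correction factors are invariant to concentration units", {
  base <- list(conc_16S = 1340.0, conc_18S = 335.1,
               seqs_16S = 295010733, seqs_18S = 34623340)
  cf1 <- correction_factors(base)
  for (scale in c(1e-3, 1e3, 7.13)) {
    scaled <- base
    scaled$conc_16S <- base$conc_16S * scale
    scaled$conc_18S <- base$conc_18S * scale
    expect_equal(correction_factors(scaled), cf1, tolerance = 1e-12)
  }
})

test_that("chemistry TSV round-trips", {
  chem <- table1_fixture()
  path <- tempfile(fileext = ".tsv")
  write_chemistry(chem, path)
  back <- read_chemistry(path)
  expect_equal(back$cf_16S, chem$cf_16S, tolerance = 1e-12)
  expect_equal(back$run_id, chem$run_id)
})

toy_tables <- function(c16, c18) {
  t16 <- raw_asv_table(list(s1 = data.table::data.table(
    asv_id = "a16", sequence = "ACGTACGT", count = c16)), "SSU16S")
  t18 <- raw_asv_table(list(s1 = data.table::data.table(
    asv_id = "a18", sequence = "TTGGCCAA", count = c18)), "SSU18S")
  list(t16 = t16, t18 = t18)
}

toy_stats <- function(c16, c18, pr = 1.0) {
  rbind(denoise_stats("s1", "SSU16S", as.integer(c16 / pr), c16, c16, c16),
        denoise_stats("s1", "SSU18S", as.integer(c18 / pr), c18, c18, c18))
}

test_that("depth filter applies strictly below the threshold", {
  chem <- run_chemistry("r", 100, 100, 1000, 1000)
  tt <- toy_tables(4000L, 2000L)
  m <- merge_tables(tt$t16, tt$t18, chem, toy_stats(4000L, 2000L),
                    c(s1 = "r"), min_depth = 5000)
  expect_equal(rownames(m$counts), "s1")
  tt2 <- toy_tables(3000L, 1500L)
  m2 <- merge_tables(tt2$t16, tt2$t18, chem, toy_stats(3000L, 1500L),
                     c(s1 = "r"), min_depth = 5000)
  expect_equal(nrow(m2$counts), 0L)
  expect_equal(m2$dropped, "s1")
})

test_that("merged cells equal raw * cf / pass_ratio (spreadsheet oracle)", {
  # two samples, fixed factors 0.9 / 2.0, pass ratios 1
  chem <- run_chemistry("r", 9, 2, 900, 200)  # cf = (9/11)/(9/11) style
  expect_equal(unname(chem$cf_16S), 1)        # sanity: identity chem
  counts16 <- matrix(c(100L, 50L, 10L, 5L), 2, 2,
                     dimnames = list(c("s1", "s2"), c("x", "y")))
  t16 <- structure(list(counts = counts16,
                        seqs = c(x = "AAAA", y = "CCCC"), pool = "SSU16S"),
                   class = "raw_asv_table")
  counts18 <- matrix(c(20L, 40L), 2, 1,
                     dimnames = list(c("s1", "s2"), "z"))
  t18 <- structure(list(counts = counts18, seqs = c(z = "GGGG"),
                        pool = "SSU18S"), class = "raw_asv_table")
  # engineer chemistry with cf_16S = 0.9, cf_18S = 2.0:
  # pick concentrations matching those factors for the given seq fractions
  s16 <- sum(counts16); s18 <- sum(counts18)
  f16seq <- s16 / (s16 + s18)
  b16 <- 0.9 * f16seq                       # then cf16 = 0.9
  chem2 <- run_chemistry("r", b16, 1 - b16, s16, s18)
  expect_equal(unname(chem2$cf_16S), 0.9, tolerance = 1e-12)
  expect_equal(unname(chem2$cf_18S), (1 - b16) / (1 - f16seq),
               tolerance = 1e-12)
  stats <- rbind(
    denoise_stats("s1", "SSU16S", 110L, 110L, 110L, 110L),
    denoise_stats("s1", "SSU18S", 20L, 20L, 20L, 20L),
    denoise_stats("s2", "SSU16S", 55L, 55L, 55L, 55L),
    denoise_stats("s2", "SSU18S", 40L, 40L, 40L, 40L))
  m <- merge_tables(t16, t18, chem2, stats, c(s1 = "r", s2 = "r"),
                    min_depth = 0)
  cf18 <- unname(chem2$cf_18S)
  expect_equal(m$counts["s1", "x"], 100 * 0.9)
  expect_equal(m$counts["s2", "y"], 5 * 0.9)
  expect_equal(m$counts["s1", "z"], 20 * cf18)
  expect_equal(m$counts["s2", "z"], 40 * cf18)
  # corrected values may be non-integer and are stored as reals
  expect_true(is.double(m$counts))
  # missing chemistry is a hard error naming the run
  expect_error(merge_tables(t16, t18, chem2, stats, c(s1 = "other", s2 = "r"),
                            min_depth = 0), "other")
})

test_that("pass-ratio division is applied per sample and pool", {
  tt <- toy_tables(900L, 450L)
  chem <- run_chemistry("r", 2, 1, 900, 450)
  stats <- rbind(
    denoise_stats("s1", "SSU16S", 1000L, 950L, 950L, 900L),  # pr 0.9
    denoise_stats("s1", "SSU18S", 500L, 480L, 480L, 450L))   # pr 0.9
  m <- merge_tables(tt$t16, tt$t18, chem, stats, c(s1 = "r"), min_depth = 0)
  cf <- correction_factors(list(conc_16S = 2, conc_18S = 1,
                                seqs_16S = 900, seqs_18S = 450))
  expect_equal(m$counts["s1", "a16"], 900 * cf[["cf_16S"]] / 0.9)
  expect_equal(m$counts["s1", "a18"], 450 * cf[["cf_18S"]] / 0.9)
})
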