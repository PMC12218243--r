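ref3 <- function() {
  set.seed(61)
  reference_taxonomy(
    seqs = c(random_seq(120), random_seq(120), random_seq(120)),
    rank_paths = c("Bacteria;Proteobacteria;Alpha",
                   "Bacteria;Proteobacteria;Gamma",
                   "Archaea;Crenarchaeota;Nitroso"),
    scheme = "SILVA-like")
}

test_that("training requires at least two taxa and separable taxa classify", {
  expect_error(train_nb(reference_taxonomy("ACGTACGTACGT", "only;one",
                                           "SILVA-like")), "2 distinct")
  ref <- ref3()
  model <- train_nb(ref, k = 8)
  for (i in 1:3) {
    rec <- classify(ref$seqs[i], model, n_bootstrap = 50, seed = 3)
    expect_equal(paste(rec$ranks, collapse = ";"), ref$rank_paths[i])
    expect_equal(rec$confidence, rep(1, 3))
  }
})

test_that("posteriors match a brute-force Bayes oracle", {
  ref <- ref3()
  model <- train_nb(ref, k = 8, pseudocount = 0.5)
  set.seed(62)
  for (rep in 1:5) {
    q <- random_seq(60)
    codes <- ssufuse:::kmer_codes(q, 8)
    got <- ssufuse:::nb_posterior(model, codes)
    # oracle: direct product over query words of smoothed frequencies
    V <- 4^8
    logp <- vapply(unique(ref$rank_paths), function(tx) {
      train_codes <- unlist(lapply(ref$seqs[ref$rank_paths == tx],
                                   function(s) ssufuse:::kmer_codes(s, 8)))
      sum(vapply(codes, function(cd)
        log((sum(train_codes == cd) + 0.5) /
              (length(train_codes) + 0.5 * V)), numeric(1)))
    }, numeric(1))
    want <- exp(logp - max(logp)); want <- want / sum(want)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("duplicate sequence under two taxa splits the posterior", {
  set.seed(63)
  s <- random_seq(100)
  ref <- reference_taxonomy(c(s, s), c("A;x", "B;y"), "SILVA-like")
  model <- train_nb(ref, k = 8)
  post <- ssufuse:::nb_posterior(model, ssufuse:::kmer_codes(s, 8))
  expect_equal(unname(post), c(0.5, 0.5), tolerance = 1e-12)
  # bootstrap confidence cannot exceed the threshold: record is unassigned
  rec <- classify(s, model, n_bootstrap = 100, confidence = 0.7, seed = 1)
  expect_true(all(is.na(rec$ranks)))
})

test_that("classification handles degenerate queries and chimeras", {
  ref <- ref3()
  model <- train_nb(ref, k = 8)
  # all-N query has no valid words
  recN <- classify(strrep("N", 50), model)
  expect_true(all(is.na(recN$ranks)))
  expect_equal(recN$confidence, rep(0, 3))
  # a half/half chimera of two taxa sharing genus-level prefix truncates at
  # the deepest shared rank
  set.seed(64)
  shared <- random_seq(150)
  a <- paste0(shared, random_seq(150))
  b <- paste0(shared, random_seq(150))
  refc <- reference_taxonomy(
    c(a, b), c("Bacteria;Proteo;Alpha", "Bacteria;Proteo;Gamma"),
    "SILVA-like")
  mc <- train_nb(refc, k = 8)
  chim <- paste0(substr(a, 151, 300), substr(b, 151, 300))
  rec <- classify(chim, mc, n_bootstrap = 200, confidence = 0.7, seed = 9)
  expect_equal(rec$ranks[1:2], c("Bacteria", "Proteo"))
  expect_true(is.na(rec$ranks[3]))
  # deterministic under a fixed seed
  rec2 <- classify(chim, mc, n_bootstrap = 200, confidence = 0.7, seed = 9)
  expect_identical(rec, rec2)
})

test_that("the 18S spacer is excised before classification", {
  set.seed(65)
  a <- random_seq(200); b <- random_seq(200)
  ref <- reference_taxonomy(c(a, b), c("Euk;Alv;Dino", "Euk;Str;Diatom"),
                            "PR2-like")
  model <- train_nb(ref, k = 8)
  spaced <- paste0(substr(a, 1, 100), strrep("N", 10), substr(a, 101, 200))
  rec <- classify(spaced, model, seed = 2)
  expect_equal(rec$ranks, c("Euk", "Alv", "Dino"))
})

test_that("harmonize maps scheme levels onto the unified columns", {
  silva <- list(ranks = c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                          "Rhodobacterales", "Rhodobacteraceae",
                          "Sulfitobacter", "S. sp."),
                confidence = rep(1, 7), scheme = "SILVA-like")
  row <- harmonize(silva)
  expect_equal(unname(row["Domain"]), "Bacteria")
  expect_equal(unname(row["Phylum"]), "Proteobacteria")
  expect_true(is.na(row["Supergroup"]) && is.na(row["Division"]))
  pr2 <- list(ranks = c("Eukaryota", "TSAR", "Stramenopiles", "Bacillariophyta",
                        "Bacillariophyta_X", "Chaetocerotaceae", "Chaetoceros",
                        "C. sp."),
              confidence = rep(1, 8), scheme = "PR2-like")
  row2 <- harmonize(pr2)
  expect_equal(unname(row2["Supergroup"]), "TSAR")
  expect_true(is.na(row2["Phylum"]))
  expect_equal(unname(row2["Species"]), "C. sp.")
  pro <- list(ranks = "HLII", confidence = 1, scheme = "ProPortal-like")
  row3 <- harmonize(pro)
  expect_equal(unname(row3["Proportal_ASV_Ecotype"]), "HLII")
  expect_true(all(is.na(row3[1:9])))
  # truncation is prefix-closed through harmonize
  silva$ranks[4:7] <- NA
  row4 <- harmonize(silva)
  expect_true(is.na(row4["Order"]) && is.na(row4["Species"]))
  expect_equal(unname(row4["Class"]), "Alphaproteobacteria")
})

test_that("eco groups follow first-match-wins rules", {
  empty <- setNames(rep(NA_character_, 10), ssufuse:::UNIFIED_COLS)
  arch <- empty; arch["Domain"] <- "Archaea"
  expect_equal(assign_eco_group(arch, "SSU16S"), "Archaea")
  cyano <- empty; cyano["Domain"] <- "Bacteria"
  cyano["Class"] <- "Cyanobacteria"
  expect_equal(assign_eco_group(cyano, "SSU16S"), "Cyanobacteria")
  chloro <- cyano; chloro["Order"] <- "Chloroplast"
  expect_equal(assign_eco_group(chloro, "SSU16S"), "Chloroplast 16S")
  expect_equal(assign_eco_group(empty, "SSU16S"), "Other")
  expect_equal(assign_eco_group(empty, "SSU18S"), "Eukaryote 18S")
})

test_that("ecotype re-annotation resolves near matches", {
  set.seed(66)
  hlii <- random_seq(150); llv <- random_seq(150)
  ref <- reference_taxonomy(c(hlii, llv), c("HLII", "LLIV"),
                            "ProPortal-like")
  out <- ecotype_reannotate(c(asv1 = hlii), ref, seed = 4)
  expect_equal(unname(out["asv1"]), "HLII")
  # one mismatch from HLII still classifies as HLII
  v <- strsplit(hlii, "")[[1]]
  v[75] <- setdiff(c("A", "C", "G", "T"), v[75])[1]
  out2 <- ecotype_reannotate(c(q = paste(v, collapse = "")), ref, seed = 4)
  expect_equal(unname(out2["q"]), "HLII")
  expect_warning(
    out3 <- ecotype_reannotate(c(q = hlii), NULL), "empty")
  expect_true(is.na(out3["q"]))
})
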