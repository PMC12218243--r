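#' Reference taxonomy for naive Bayes classification
#'
#' Labeled reference sequences under one of three rank schemes:
#' `"SILVA-like"` (7 prokaryotic ranks), `"PR2-like"` (8 eukaryotic ranks)
#' or `"ProPortal-like"` (a single ecotype label).
#'
#' @param seqs character vector of reference sequences
#' @param rank_paths character vector of rank paths, levels separated by
#'   `";"`, one per sequence
#' @param scheme one of "SILVA-like", "PR2-like", "ProPortal-like"
#' @return object of class `reference_taxonomy`
#' @export
reference_taxonomy <- function(seqs, rank_paths, scheme) {
  scheme <- match.arg(scheme, c("SILVA-like", "PR2-like", "ProPortal-like"))
  stopifnot(length(seqs) == length(rank_paths), length(seqs) > 0L)
  depth <- lengths(strsplit(rank_paths, ";", fixed = TRUE))
  if (length(unique(depth)) != 1L)
    stop("rank paths must have consistent depth within a scheme")
  structure(list(seqs = toupper(seqs), rank_paths = rank_paths,
                 scheme = scheme), class = "reference_taxonomy")
}

# positional (forward strand) k-mer codes of a sequence, skipping windows
# with non-ACGT bases; base-4 codes with A<C<G<T
kmer_codes <- function(seq, k) {
  b <- utf8ToInt(toupper(seq))
  v <- integer(length(b))
  v[b == 67L] <- 1L   # C
  v[b == 71L] <- 2L   # G
  v[b == 84L] <- 3L   # T
  bad <- !(b %in% c(65L, 67L, 71L, 84L))
  n <- length(v) - k + 1L
  if (n < 1L) return(integer(0))
  code <- integer(n)
  for (j in seq_len(k)) code <- code * 4L + v[j:(j + n - 1L)]
  okpos <- !vapply(seq_len(n), function(i) any(bad[i:(i + k - 1L)]),
                   logical(1))
  code[okpos]
}

#' Train a naive Bayes k-mer classifier
#'
#' Multinomial naive Bayes over forward-strand k-mer counts with additive
#' (Laplace) smoothing over the full `4^k` vocabulary and uniform taxon
#' priors. Sequences sharing a rank path are pooled into one taxon.
#'
#' @param ref a [reference_taxonomy()]
#' @param k word size (default 8)
#' @param pseudocount additive smoothing mass (default 0.5)
#' @return object of class `nb_model`
#' @export
train_nb <- function(ref, k = 8L, pseudocount = 0.5) {
  stopifnot(inherits(ref, "reference_taxonomy"))
  taxa <- unique(ref$rank_paths)
  if (length(taxa) < 2L)
    stop("need at least 2 distinct rank paths to train")
  V <- 4^k
  counts <- lapply(taxa, function(tx) {
    codes <- unlist(lapply(ref$seqs[ref$rank_paths == tx], kmer_codes, k = k))
    tab <- table(codes)
    list(codes = as.integer(names(tab)), n = as.numeric(tab),
         total = length(codes))
  })
  structure(list(taxa = taxa, counts = counts, k = as.integer(k),
                 pseudocount = pseudocount, V = V, scheme = ref$scheme),
            class = "nb_model")
}

# log-likelihood of a bag of query k-mer codes under each taxon
nb_loglik <- function(model, codes) {
  tab <- table(codes)
  qcodes <- as.integer(names(tab))
  qn <- as.numeric(tab)
  vapply(model$counts, function(ct) {
    denom <- log(ct$total + model$pseudocount * model$V)
    hit <- match(qcodes, ct$codes)
    cnt <- ifelse(is.na(hit), 0, ct$n[hit])
    sum(qn * (log(cnt + model$pseudocount) - denom))
  }, numeric(1))
}

nb_posterior <- function(model, codes) {
  ll <- nb_loglik(model, codes)
  ll <- ll - max(ll)
  p <- exp(ll)
  p / sum(p)
}

#' Classify an ASV with bootstrap confidence
#'
#' The winning rank path is the maximum-posterior taxon over all query
#' k-mers; per-rank confidence is the fraction of bootstrap k-mer
#' subsamples (each of 1/8 of the query words, drawn with replacement)
#' whose winner agrees with the overall winner at that rank. Ranks below
#' the first rank falling under `confidence` are truncated with it, so
#' assignments are prefix-closed. For 18S ASVs the concatenation N-spacer
#' is excised before k-merization.
#'
#' @param sequence ASV sequence (may contain the N spacer)
#' @param model an [nb_model()][train_nb()]
#' @param n_bootstrap bootstrap replicates (default 100)
#' @param confidence per-rank retention threshold (default 0.7)
#' @param seed RNG seed for the bootstrap (classification is deterministic
#'   under a fixed seed)
#' @return list with `ranks` (character vector, NA below truncation),
#'   `confidence` (numeric per rank), `scheme`
#' @export
classify <- function(sequence, model, n_bootstrap = 100L, confidence = 0.7,
                     seed = 1L) {
  stopifnot(inherits(model, "nb_model"))
  seq2 <- gsub("N+", "", toupper(sequence))
  codes <- if (nchar(seq2) >= model$k) kmer_codes(seq2, model$k)
           else integer(0)
  depth <- length(strsplit(model$taxa[1L], ";", fixed = TRUE)[[1L]])
  if (length(codes) == 0L) {
    return(list(ranks = rep(NA_character_, depth),
                confidence = rep(0, depth), scheme = model$scheme))
  }
  win <- model$taxa[which.max(nb_posterior(model, codes))]
  win_ranks <- strsplit(win, ";", fixed = TRUE)[[1L]]
  m <- max(1L, ceiling(length(codes) / 8))
  agree <- matrix(FALSE, nrow = n_bootstrap, ncol = depth)
  set.seed(seed)
  for (b in seq_len(n_bootstrap)) {
    sub <- sample(codes, m, replace = TRUE)
    post <- nb_posterior(model, sub)
    # exact posterior ties (e.g. identical training sequences under two
    # taxa) are broken at random so confidence reflects the ambiguity
    top <- which(post >= max(post) - 1e-12)
    w <- model$taxa[top[sample.int(length(top), 1L)]]
    wr <- strsplit(w, ";", fixed = TRUE)[[1L]]
    agree[b, ] <- cumprod(wr == win_ranks) == 1
  }
  conf <- colMeans(agree)
  keep <- cumprod(conf >= confidence) == 1
  ranks <- ifelse(keep, win_ranks, NA_character_)
  list(ranks = ranks, confidence = conf, scheme = model$scheme)
}

UNIFIED_COLS <- c("Domain", "Supergroup", "Division", "Phylum", "Class",
                  "Order", "Family", "Genus", "Species",
                  "Proportal_ASV_Ecotype")

#' Harmonize a classification across reference schemes
#'
#' Maps scheme-specific rank levels onto the unified 10-column layout.
#' SILVA-like levels 1-7 fill Domain, Phylum, Class, Order, Family, Genus,
#' Species (Supergroup and Division do not exist in that scheme); PR2-like
#' levels 1-8 fill Domain, Supergroup, Division, Class, Order, Family,
#' Genus, Species (no Phylum); ProPortal-like fills only the ecotype
#' column. The mapping is lossless on the ranks a scheme possesses.
#'
#' @param record output of [classify()]
#' @return named character vector over the 10 unified columns (NA where a
#'   level does not exist or was truncated)
#' @export
harmonize <- function(record) {
  out <- setNames(rep(NA_character_, length(UNIFIED_COLS)), UNIFIED_COLS)
  r <- record$ranks
  if (record$scheme == "SILVA-like") {
    out[c("Domain", "Phylum", "Class", "Order", "Family", "Genus",
          "Species")] <- r[seq_len(7L)]
  } else if (record$scheme == "PR2-like") {
    out[c("Domain", "Supergroup", "Division", "Class", "Order", "Family",
          "Genus", "Species")] <- r[seq_len(8L)]
  } else if (record$scheme == "ProPortal-like") {
    out["Proportal_ASV_Ecotype"] <- r[1L]
  } else {
    stop("unknown scheme: ", record$scheme)
  }
  out
}

#' Default ecologically-relevant plankton group rules
#'
#' Ordered first-match-wins rules over the unified taxonomy columns plus
#' the pool tag, reproducing the standard prokaryote groups
#' (Alphaproteobacteria, Archaea, Bacteroidota, Cyanobacteria,
#' Gammaproteobacteria, Chloroplast 16S, Other Bacteria) and a catch-all
#' eukaryote 18S group. Ships as an editable TSV
#' (`system.file("extdata", "eco_groups.tsv", package = "ssufuse")`).
#'
#' @param path optional path to a rules TSV (columns: column, value, pool,
#'   label); default uses the shipped rules
#' @return `data.table` of rules
#' @export
eco_group_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "eco_groups.tsv", package = "ssufuse")
  data.table::fread(path, sep = "\t", colClasses = "character")
}

#' Assign an ecologically-relevant plankton group
#'
#' Applies ordered rules (first match wins) over a unified taxonomy row
#' and the ASV's pool tag; unmatched rows get `"Other"`.
#'
#' @param row named character vector from [harmonize()]
#' @param pool `"SSU16S"` or `"SSU18S"`
#' @param rules rules table from [eco_group_rules()]
#' @return single group label
#' @export
assign_eco_group <- function(row, pool, rules = eco_group_rules()) {
  for (i in seq_len(nrow(rules))) {
    rule_pool <- rules$pool[i]
    if (nzchar(rule_pool) && rule_pool != pool) next
    col <- rules$column[i]
    if (nzchar(col)) {
      val <- row[[col]]
      if (is.null(val) || is.na(val) || val != rules$value[i]) next
    }
    return(rules$label[i])
  }
  "Other"
}

#' Re-annotate cyanobacterial ASVs against an ecotype reference
#'
#' Runs a second [classify()] pass for the selected cyanobacterial ASVs
#' against a ProPortal-like reference, attaching a high-resolution ecotype
#' label; other ASVs are untouched.
#'
#' @param seqs named character vector (asv_id -> sequence) of the
#'   cyanobacterial subset
#' @param proportal_ref a ProPortal-like [reference_taxonomy()]
#' @param k,pseudocount,n_bootstrap,confidence,seed classifier settings
#' @return named character vector asv_id -> ecotype (NA if unresolved)
#' @export
ecotype_reannotate <- function(seqs, proportal_ref, k = 8L,
                               pseudocount = 0.5, n_bootstrap = 100L,
                               confidence = 0.7, seed = 1L) {
  if (length(seqs) == 0L) return(character(0))
  if (is.null(proportal_ref) || length(proportal_ref$seqs) == 0L) {
    warning("empty ecotype reference; skipping re-annotation")
    return(setNames(rep(NA_character_, length(seqs)), names(seqs)))
  }
  model <- train_nb(proportal_ref, k = k, pseudocount = pseudocount)
  out <- vapply(seq_along(seqs), function(i) {
    rec <- classify(seqs[[i]], model, n_bootstrap = n_bootstrap,
                    confidence = confidence,
                    seed = derive_seed(seed, i))
    rec$ranks[1L]
  }, character(1))
  setNames(out, names(seqs))
}

#' Classify all ASVs of a table and emit the unified taxonomy
#'
#' 16S ASVs are classified against the SILVA-like model, 18S ASVs against
#' the PR2-like model; cyanobacterial ASVs optionally get a ProPortal-like
#' ecotype. Output columns follow the unified layout plus
#' `Eco_relevant_plank_groups`.
#'
#' @param seqs named character vector asv_id -> sequence
#' @param pools named character vector asv_id -> pool
#' @param model16,model18 trained [nb_model][train_nb]s (either may be
#'   NULL to skip a pool)
#' @param proportal_ref optional ProPortal-like reference
#' @param rules eco-group rules
#' @param n_bootstrap,confidence,seed classifier settings
#' @return `data.table` with asv_id, the 10 unified columns, and
#'   `Eco_relevant_plank_groups`
#' @export
classify_table <- function(seqs, pools, model16, model18,
                           proportal_ref = NULL, rules = eco_group_rules(),
                           n_bootstrap = 100L, confidence = 0.7, seed = 1L) {
  rows <- lapply(seq_along(seqs), function(i) {
    pool <- pools[[names(seqs)[i]]]
    model <- if (pool == "SSU16S") model16 else model18
    if (is.null(model)) {
      row <- setNames(rep(NA_character_, length(UNIFIED_COLS)), UNIFIED_COLS)
    } else {
      rec <- classify(seqs[[i]], model, n_bootstrap = n_bootstrap,
                      confidence = confidence, seed = derive_seed(seed, i))
      row <- harmonize(rec)
    }
    c(asv_id = names(seqs)[i], row)
  })
  tax <- data.table::rbindlist(lapply(rows, function(r)
    as.list(r)))
  grp <- vapply(seq_len(nrow(tax)), function(i) {
    assign_eco_group(unlist(tax[i, -1L]), pools[[tax$asv_id[i]]], rules)
  }, character(1))
  tax[, Eco_relevant_plank_groups := grp]
  if (!is.null(proportal_ref)) {
    cyano <- which(!is.na(tax$Class) & tax$Class == "Cyanobacteria" |
                     grp == "Cyanobacteria")
    if (length(cyano)) {
      eco <- ecotype_reannotate(seqs[tax$asv_id[cyano]], proportal_ref,
                                n_bootstrap = n_bootstrap,
                                confidence = confidence, seed = seed)
      tax[cyano, Proportal_ASV_Ecotype := eco]
    }
  }
  tax
}
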