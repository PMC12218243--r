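PIPELINE_KEYS <- c(
  "manifest", "ref16S", "ref18S", "chemistry", "out_dir",
  "tax16_fasta", "tax16_tsv", "tax18_fasta", "tax18_tsv",
  "proportal_fasta", "proportal_tsv", "metadata", "provinces",
  "mock_refs", "mock_members", "n_read_pairs", "bias_18S", "chimera_rate",
  "per_base_error", "read_len", "seed",
  "k_split", "min_votes", "min_margin", "max_mismatch_primer",
  "max_ee", "trunc_fwd", "trunc_rev", "spacer_len", "min_overlap",
  "max_mismatch_frac", "alpha", "max_dist", "min_depth",
  "nb_k", "n_bootstrap", "confidence")

#' Assemble and validate a pipeline configuration
#'
#' Named list of file paths and stage parameters; unknown keys are
#' rejected. Missing parameters take the package defaults. Configurations
#' can also be loaded from a JSON file with [read_config()].
#'
#' @param ... configuration entries (see `PIPELINE_KEYS` in the source)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1L]]) && is.null(names(cfg)))
    cfg <- cfg[[1L]]
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(
    seed = 1L, k_split = 31L, min_votes = 5L, min_margin = 2.0,
    max_mismatch_primer = 2L, max_ee = 2.0, trunc_fwd = 220L,
    trunc_rev = 180L, spacer_len = 10L, min_overlap = 20L,
    max_mismatch_frac = 0.10, alpha = 2.0, max_dist = 10L,
    min_depth = 5000L, nb_k = 8L, n_bootstrap = 100L, confidence = 0.7,
    read_len = 250L, bias_18S = 1.0, per_base_error = 0.001,
    chimera_rate = 0.0)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON configuration file
#' @export
read_config <- function(path) {
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

missing_input <- function(path, what) {
  stop(structure(class = c("ssufuse_missing_input", "error", "condition"),
                 list(message = paste0("missing ", what, ": ", path),
                      call = NULL)))
}

need_file <- function(cfg, key, what = key) {
  p <- cfg[[key]]
  if (is.null(p) || !file.exists(p)) missing_input(p %||% paste0("<", key, ">"), what)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_info <- function(cfg) {
  plain <- cfg
  class(plain) <- NULL
  list(package = "ssufuse",
       version = as.character(utils::packageVersion("ssufuse")),
       config_hash = md5_sequence(jsonlite::toJSON(plain, auto_unbox = TRUE,
                                                   null = "null")),
       config = plain)
}

stamp_run <- function(cfg) {
  jsonlite::write_json(run_info(cfg),
                       file.path(cfg$out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run a pipeline stage
#'
#' Subcommand interface over the whole pipeline: `simulate` writes mock
#' FASTQ pairs, truth, chemistry and a manifest into `out_dir`; `split`,
#' `prep`, `denoise`, `correct`, `classify` and `summarize` each consume
#' their predecessor's artifacts from `out_dir`; `all` chains
#' split -> prep -> denoise -> correct -> classify -> summarize. Every run
#' writes `run_info.json` with the package version and a hash of the
#' resolved configuration, so identical configs reproduce identical
#' artifacts.
#'
#' @param name one of simulate, split, prep, denoise, correct, classify,
#'   summarize, all
#' @param cfg a [pipeline_config()]
#' @return integer exit status (0 ok, 2 missing input, 3 invariant
#'   violation), invisibly
#' @export
run_subcommand <- function(name, cfg) {
  name <- match.arg(name, c("simulate", "split", "prep", "denoise",
                            "correct", "classify", "summarize", "all"))
  stopifnot(inherits(cfg, "pipeline_config"))
  status <- tryCatch({
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp_run(cfg)
    switch(name,
           simulate = stage_simulate(cfg),
           split = stage_split(cfg),
           prep = stage_prep(cfg),
           denoise = stage_denoise(cfg),
           correct = stage_correct(cfg),
           classify = stage_classify(cfg),
           summarize = stage_summarize(cfg),
           all = {
             stage_split(cfg); stage_prep(cfg); stage_denoise(cfg)
             stage_correct(cfg); stage_classify(cfg); stage_summarize(cfg)
           })
    0L
  },
  ssufuse_missing_input = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message(conditionMessage(e)); 3L })
  invisible(status)
}

stage_simulate <- function(cfg) {
  refs_path <- need_file(cfg, "mock_refs", "mock reference FASTA")
  members <- data.table::fread(need_file(cfg, "mock_members",
                                         "mock member table"), sep = "\t")
  spec <- mock_spec(members, n_read_pairs = cfg$n_read_pairs %||% 10000L,
                    read_len = cfg$read_len, bias_18S = cfg$bias_18S,
                    per_base_error = cfg$per_base_error,
                    chimera_rate = cfg$chimera_rate, seed = cfg$seed)
  sim <- simulate_run(spec, refs_path, sample_id = "mock1")
  od <- cfg$out_dir
  write_fastq_pairs(sim$pairs, file.path(od, "mock1_R1.fastq.gz"),
                    file.path(od, "mock1_R2.fastq.gz"))
  data.table::fwrite(sim$truth, file.path(od, "truth_mock1.tsv"), sep = "\t")
  conc <- emit_chemistry(spec)
  data.table::fwrite(data.table::data.table(
    run_id = "mockrun", conc_16S = conc[["conc_16S"]],
    conc_18S = conc[["conc_18S"]], seqs_16S = NA, seqs_18S = NA,
    borrowed_from = ""), file.path(od, "chemistry_conc.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    sample_id = "mock1",
    fwd_path = file.path(od, "mock1_R1.fastq.gz"),
    rev_path = file.path(od, "mock1_R2.fastq.gz"),
    run_id = "mockrun"), file.path(od, "manifest.tsv"), sep = "\t")
  invisible(NULL)
}

load_manifest_pairs <- function(cfg) {
  man <- read_manifest(need_file(cfg, "manifest", "sample manifest"))
  for (p in c(man$fwd_path, man$rev_path))
    if (!file.exists(p)) missing_input(p, "FASTQ")
  pairs <- lapply(seq_len(nrow(man)), function(i)
    read_fastq_pairs(man$fwd_path[i], man$rev_path[i], man$sample_id[i]))
  names(pairs) <- man$sample_id
  list(manifest = man, pairs = pairs)
}

stage_split <- function(cfg) {
  lm <- load_manifest_pairs(cfg)
  index <- build_split_index(need_file(cfg, "ref16S", "16S reference"),
                             need_file(cfg, "ref18S", "18S reference"),
                             k = cfg$k_split)
  od <- cfg$out_dir
  reports <- list()
  for (sid in names(lm$pairs)) {
    tr <- trim_primers(lm$pairs[[sid]],
                       max_mismatch = cfg$max_mismatch_primer)
    dec <- split_pairs(tr$pairs, index, min_votes = cfg$min_votes,
                       min_margin = cfg$min_margin)
    for (pool in POOLS) {
      sel <- tr$pairs[dec$pool == pool]
      tag <- if (pool == "SSU16S") "16S" else "18S"
      write_fastq_pairs(sel,
                        file.path(od, sprintf("%s_%s_R1.fastq.gz", sid, tag)),
                        file.path(od, sprintf("%s_%s_R2.fastq.gz", sid, tag)))
    }
    una <- tr$pairs[dec$pool == "UNASSIGNED"]
    write_fastq_pairs(una,
                      file.path(od, sprintf("%s_unassigned_R1.fastq.gz", sid)),
                      file.path(od, sprintf("%s_unassigned_R2.fastq.gz", sid)))
    rep <- split_report(sid, dec)
    rep[, n_primer_rejected := length(tr$rejected_ids)]
    reports[[sid]] <- rep
  }
  data.table::fwrite(data.table::rbindlist(reports),
                     file.path(od, "split_report.tsv"), sep = "\t")
  invisible(NULL)
}

stage_prep <- function(cfg) {
  od <- cfg$out_dir
  man <- read_manifest(need_file(cfg, "manifest", "sample manifest"))
  params <- prep_params(max_ee = cfg$max_ee, trunc_fwd = cfg$trunc_fwd,
                        trunc_rev = cfg$trunc_rev,
                        spacer_len = cfg$spacer_len,
                        min_overlap = cfg$min_overlap,
                        max_mismatch_frac = cfg$max_mismatch_frac)
  prepared <- list()
  reports <- list()
  for (sid in man$sample_id) {
    for (pool in POOLS) {
      tag <- if (pool == "SSU16S") "16S" else "18S"
      f1 <- file.path(od, sprintf("%s_%s_R1.fastq.gz", sid, tag))
      f2 <- file.path(od, sprintf("%s_%s_R2.fastq.gz", sid, tag))
      if (!file.exists(f1)) missing_input(f1, "pool FASTQ (run split first)")
      pp <- prep_pool(read_fastq_pairs(f1, f2, sid), pool, params)
      pp$report$sample_id <- sid
      prepared[[paste(sid, pool)]] <- pp$prepared
      reports[[paste(sid, pool)]] <- pp$report
    }
  }
  allprep <- data.table::rbindlist(prepared)
  for (pool in POOLS) {
    tag <- if (pool == "SSU16S") "16S" else "18S"
    sel <- which(allprep$pool == pool)
    data.table::fwrite(allprep[sel],
                       file.path(od, sprintf("prepared_%s.tsv", tag)),
                       sep = "\t")
  }
  data.table::fwrite(data.table::rbindlist(reports),
                     file.path(od, "prep_report.tsv"), sep = "\t")
  invisible(NULL)
}

stage_denoise <- function(cfg) {
  od <- cfg$out_dir
  split_rep <- data.table::fread(file.path(od, "split_report.tsv"))
  stats <- list()
  for (pool in POOLS) {
    tag <- if (pool == "SSU16S") "16S" else "18S"
    ppath <- file.path(od, sprintf("prepared_%s.tsv", tag))
    if (!file.exists(ppath)) missing_input(ppath, "prepared reads (run prep)")
    prep <- data.table::fread(ppath, colClasses = "character")
    samples <- unique(split_rep$sample_id)
    per_sample <- lapply(samples, function(sid)
      denoise_sample(prep[prep$sample_id == sid], alpha = cfg$alpha,
                     max_dist = cfg$max_dist))
    names(per_sample) <- samples
    tab <- raw_asv_table(per_sample, pool)
    rb <- remove_bimeras(tab)
    tab2 <- rb$table
    for (sid in samples) {
      n_in <- split_rep[[if (pool == "SSU16S") "n16S" else "n18S"]][
        match(sid, split_rep$sample_id)]
      n_filt <- sum(per_sample[[sid]]$count)
      n_nonchim <- if (nrow(tab2$counts)) sum(tab2$counts[sid, ]) else 0L
      stats[[paste(sid, pool)]] <- denoise_stats(sid, pool, n_in, n_filt,
                                                 n_filt, n_nonchim)
    }
    counts_long <- data.table::as.data.table(as.table(tab2$counts))
    data.table::setnames(counts_long, c("sample_id", "asv_id", "count"))
    data.table::fwrite(counts_long[counts_long$count > 0],
                       file.path(od, sprintf("asv_%s.tsv", tag)), sep = "\t")
    seqs <- Biostrings::DNAStringSet(tab2$seqs)
    Biostrings::writeXStringSet(seqs,
                                file.path(od, sprintf("asv_%s.fasta", tag)))
  }
  data.table::fwrite(data.table::rbindlist(stats),
                     file.path(od, "denoise_stats.tsv"), sep = "\t")
  invisible(NULL)
}

read_raw_table <- function(od, pool, samples) {
  tag <- if (pool == "SSU16S") "16S" else "18S"
  cpath <- file.path(od, sprintf("asv_%s.tsv", tag))
  if (!file.exists(cpath)) missing_input(cpath, "ASV table (run denoise)")
  long <- data.table::fread(cpath)
  seqs <- as.character(Biostrings::readDNAStringSet(
    file.path(od, sprintf("asv_%s.fasta", tag))))
  ids <- names(seqs)
  counts <- matrix(0L, nrow = length(samples), ncol = length(ids),
                   dimnames = list(samples, ids))
  if (nrow(long))
    counts[cbind(match(long$sample_id, samples),
                 match(long$asv_id, ids))] <- long$count
  structure(list(counts = counts, seqs = seqs, pool = pool),
            class = "raw_asv_table")
}

stage_correct <- function(cfg) {
  od <- cfg$out_dir
  man <- read_manifest(need_file(cfg, "manifest", "sample manifest"))
  chem_path <- need_file(cfg, "chemistry", "run chemistry table")
  stats <- data.table::fread(file.path(od, "denoise_stats.tsv"))
  split_rep <- data.table::fread(file.path(od, "split_report.tsv"))
  chem_in <- data.table::fread(chem_path)
  missing_runs <- setdiff(man$run_id, chem_in$run_id)
  if (length(missing_runs))
    missing_input(paste(missing_runs, collapse = ","),
                  "chemistry record for run")
  # fill post-split totals from this run's split report when absent
  if (!("seqs_16S" %in% names(chem_in)) ||
      any(is.na(chem_in$seqs_16S) | is.na(chem_in$seqs_18S))) {
    by_run <- merge(man[, c("sample_id", "run_id")], split_rep,
                    by = "sample_id")
    agg <- by_run[, .(s16 = sum(n16S), s18 = sum(n18S)), by = run_id]
    m <- match(chem_in$run_id, agg$run_id)
    fill <- is.na(chem_in$seqs_16S) | is.na(chem_in$seqs_18S)
    chem_in$seqs_16S[fill] <- agg$s16[m][fill]
    chem_in$seqs_18S[fill] <- agg$s18[m][fill]
  }
  bf <- if ("borrowed_from" %in% names(chem_in))
    as.character(chem_in$borrowed_from) else rep(NA_character_,
                                                 nrow(chem_in))
  bf[!nzchar(bf) | is.na(bf)] <- NA_character_
  chem <- run_chemistry(as.character(chem_in$run_id), chem_in$conc_16S,
                        chem_in$conc_18S, chem_in$seqs_16S,
                        chem_in$seqs_18S, borrowed_from = bf)
  t16 <- read_raw_table(od, "SSU16S", man$sample_id)
  t18 <- read_raw_table(od, "SSU18S", man$sample_id)
  merged <- merge_tables(t16, t18, chem, stats,
                         setNames(man$run_id, man$sample_id),
                         min_depth = cfg$min_depth)
  write_corrected_table(merged, file.path(od, "corrected_table.tsv"))
  write_chemistry(chem, file.path(od, "chemistry_resolved.tsv"))
  # pool-level sequences for downstream stages
  seqtab <- data.table::data.table(
    asv_id = names(merged$seqs), pool = unname(merged$pool[names(merged$seqs)]),
    sequence = unname(merged$seqs))
  data.table::fwrite(seqtab, file.path(od, "asv_registry.tsv"), sep = "\t")
  invisible(NULL)
}

load_ref_tax <- function(fasta, tsv, scheme) {
  seqs <- as.character(Biostrings::readDNAStringSet(fasta))
  ranks <- data.table::fread(tsv, colClasses = "character")
  reference_taxonomy(unname(seqs[ranks$id]), ranks$rank_path, scheme)
}

stage_classify <- function(cfg) {
  od <- cfg$out_dir
  reg_path <- file.path(od, "asv_registry.tsv")
  if (!file.exists(reg_path)) missing_input(reg_path, "ASV registry (run correct)")
  reg <- data.table::fread(reg_path, colClasses = "character")
  seqs <- setNames(reg$sequence, reg$asv_id)
  pools <- setNames(reg$pool, reg$asv_id)
  model16 <- model18 <- proportal <- NULL
  if (!is.null(cfg$tax16_fasta))
    model16 <- train_nb(load_ref_tax(need_file(cfg, "tax16_fasta"),
                                     need_file(cfg, "tax16_tsv"),
                                     "SILVA-like"), k = cfg$nb_k)
  if (!is.null(cfg$tax18_fasta))
    model18 <- train_nb(load_ref_tax(need_file(cfg, "tax18_fasta"),
                                     need_file(cfg, "tax18_tsv"),
                                     "PR2-like"), k = cfg$nb_k)
  if (!is.null(cfg$proportal_fasta))
    proportal <- load_ref_tax(need_file(cfg, "proportal_fasta"),
                              need_file(cfg, "proportal_tsv"),
                              "ProPortal-like")
  tax <- classify_table(seqs, pools, model16, model18, proportal,
                        n_bootstrap = cfg$n_bootstrap,
                        confidence = cfg$confidence, seed = cfg$seed)
  data.table::fwrite(tax, file.path(od, "taxonomy.tsv"), sep = "\t")
  invisible(NULL)
}

read_corrected <- function(od) {
  path <- file.path(od, "corrected_table.tsv")
  if (!file.exists(path)) missing_input(path, "corrected table (run correct)")
  long <- data.table::fread(path)
  reg <- data.table::fread(file.path(od, "asv_registry.tsv"),
                           colClasses = "character")
  samples <- sort(unique(long$sample_id))
  ids <- reg$asv_id
  counts <- matrix(0, nrow = length(samples), ncol = length(ids),
                   dimnames = list(samples, ids))
  if (nrow(long))
    counts[cbind(match(long$sample_id, samples),
                 match(long$asv_id, ids))] <- long$abundance
  structure(list(counts = counts,
                 seqs = setNames(reg$sequence, reg$asv_id),
                 pool = setNames(reg$pool, reg$asv_id),
                 provenance = NULL, dropped = character(0)),
            class = "corrected_asv_table")
}

stage_summarize <- function(cfg) {
  od <- cfg$out_dir
  tab <- read_corrected(od)
  tax_path <- file.path(od, "taxonomy.tsv")
  if (!file.exists(tax_path)) missing_input(tax_path, "taxonomy (run classify)")
  tax <- data.table::fread(tax_path, colClasses = "character")
  gra <- group_relative_abundance(tab, tax, grouping = "eco_groups")
  data.table::fwrite(gra$per_sample, file.path(od, "summary_groups.tsv"),
                     sep = "\t")
  data.table::fwrite(
    data.table::data.table(group = names(gra$mean),
                           mean_fraction = unname(gra$mean)),
    file.path(od, "summary_means.tsv"), sep = "\t")
  invisible(NULL)
}
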