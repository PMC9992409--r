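#' Pipeline configuration
#'
#' Bundles all inputs and thresholds of the end-to-end analysis: the
#' proteome manifest, the seed family sequences (aligned or not), the
#' E-value threshold for candidate retrieval, the minimum insert length
#' for a KID call, the number of motifs, and the bootstrap replicate
#' count.
#'
#' @param manifest Path to the proteome manifest.
#' @param seed_fasta Path to the seed family FASTA (gapped rows are taken
#'   as a ready alignment; ungapped rows are aligned internally).
#' @param out_dir Output directory.
#' @param seed Integer seed (mandatory; drives calibration, motif
#'   discovery and bootstrap).
#' @param e_value Candidate E-value threshold.
#' @param kid_min_length Minimum insert length called a KID.
#' @param n_motifs Motifs to discover.
#' @param bootstrap Bootstrap replicates for the trees.
#' @param stages Which optional stages to run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, seed_fasta, out_dir, seed,
                            e_value = 0.01, kid_min_length = 80,
                            n_motifs = 12, bootstrap = 100,
                            stages = c("search", "annotate", "disorder",
                                       "motifs", "phylo")) {
  if (missing(seed)) stop("seed is mandatory")
  for (p in c(manifest, seed_fasta))
    if (!file.exists(p)) stop("config path does not exist: ", p)
  structure(list(manifest = manifest, seed_fasta = seed_fasta,
                 out_dir = out_dir, seed = as.integer(seed),
                 e_value = e_value, kid_min_length = kid_min_length,
                 n_motifs = n_motifs, bootstrap = bootstrap,
                 stages = stages),
            class = "pipeline_config")
}

# content hash of the pipeline inputs + parameters, for stage skipping
pipeline_input_hash <- function(config, manifest_df) {
  files <- c(config$manifest, config$seed_fasta, manifest_df$fasta_path)
  md5 <- unname(tools::md5sum(files))
  param <- paste(config$seed, config$e_value, config$kid_min_length,
                 config$n_motifs, config$bootstrap,
                 paste(config$stages, collapse = ","), sep = "|")
  tf <- tempfile()
  writeLines(c(md5, param), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

stage_cached <- function(state_dir, stage, hash) {
  f <- file.path(state_dir, paste0(stage, ".rds"))
  h <- file.path(state_dir, paste0(stage, ".hash"))
  if (file.exists(f) && file.exists(h) && readLines(h, n = 1) == hash)
    readRDS(f) else NULL
}

stage_save <- function(state_dir, stage, hash, value) {
  saveRDS(value, file.path(state_dir, paste0(stage, ".rds")))
  writeLines(hash, file.path(state_dir, paste0(stage, ".hash")))
  value
}

#' Run the full KID discovery pipeline
#'
#' Executes, in dependency order: seed alignment and profile-HMM
#' construction, Gumbel calibration, proteome search, subdomain/KID/TM
#' annotation of the hits, candidate selection (hits that carry all five
#' subdomain anchors and a qualifying KID), disorder profiling with the
#' insert-versus-core contrast, KID extraction, motif discovery and
#' scanning, the positional motif-architecture matrix, NLS scanning and
#' motif overlap, and full-length versus KID-only bootstrapped
#' neighbor-joining trees. Every intermediate is persisted under
#' `out_dir`; rerunning with unchanged inputs and parameters reuses
#' completed stages via a content-hash check.
#'
#' @param config A `pipeline_config`.
#' @return Object of class `run_report` (invisibly also written as
#'   `report.json`): per-stage counts, candidate and KID statistics,
#'   motif and NLS tables, tree files, and a provenance block.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_dir <- file.path(out_dir, "state")
  dir.create(state_dir, showWarnings = FALSE)
  manifest_df <- read_manifest(config$manifest)
  hash <- pipeline_input_hash(config, manifest_df)

  report <- list(stages = list())

  # ---- model: seed alignment + HMM + calibration --------------------------
  model <- stage_cached(state_dir, "model", hash)
  if (is.null(model)) {
    seeds <- read_fasta(config$seed_fasta, allow_gaps = TRUE)
    seed_chr <- as.character(seeds)
    if (!any(grepl("[-.]", seed_chr))) {
      msa <- progressive_msa(seed_chr)
    } else {
      msa <- structure(seed_chr, class = "msa")
    }
    hmm <- build_profile_hmm(msa)
    model <- stage_save(state_dir, "model", hash,
                        list(msa = msa, hmm = hmm))
  }
  report$stages$model <- list(n_seeds = length(model$msa),
                              hmm_length = model$hmm$length)

  # ---- search -------------------------------------------------------------
  search <- stage_cached(state_dir, "search", hash)
  if (is.null(search)) {
    proteomes <- lapply(seq_len(nrow(manifest_df)),
                        function(i) read_fasta(manifest_df$fasta_path[i]))
    names(proteomes) <- manifest_df$species_name
    hits <- search_proteomes(model$hmm, proteomes, gumbel = NULL,
                             e_threshold = config$e_value,
                             calibration_seed = config$seed + 1L)
    all_seqs <- do.call(c, unname(lapply(proteomes, function(x)
      stats::setNames(as.character(x), names(x)))))
    hit_seqs <- all_seqs[hits$target_id]
    search <- stage_save(state_dir, "search", hash,
                         list(hits = hits, hit_seqs = hit_seqs,
                              n_db = attr(hits, "n_db")))
  }
  write_tsv(search$hits, file.path(out_dir, "hits.tsv"),
            sort_by = NULL)
  report$stages$search <- list(n_db = search$n_db,
                               n_hits = nrow(search$hits))

  # ---- annotate -----------------------------------------------------------
  annot <- stage_cached(state_dir, "annotate", hash)
  if (is.null(annot)) {
    ann <- annotate_architectures(search$hit_seqs,
                                  kid_min_length = config$kid_min_length)
    cand_ids <- ann$table$seq_id[ann$table$is_family_like %in% TRUE]
    cand_seqs <- search$hit_seqs[cand_ids]
    kid_seqs <- vapply(cand_ids, function(id) {
      k <- ann$architectures[[id]]$kid
      substr(search$hit_seqs[[id]], k$kid_start + 1, k$kid_end)
    }, "")
    annot <- stage_save(state_dir, "annotate", hash,
                        list(ann = ann, cand_ids = cand_ids,
                             cand_seqs = cand_seqs, kid_seqs = kid_seqs))
  }
  write_tsv(annot$ann$table, file.path(out_dir, "arch.tsv"))
  bed <- do.call(rbind, lapply(annot$cand_ids, function(id) {
    k <- annot$ann$architectures[[id]]$kid
    data.frame(seq_id = id, start = k$kid_start, end = k$kid_end,
               name = "KID", stringsAsFactors = FALSE)
  }))
  if (!is.null(bed)) write_bed(bed, file.path(out_dir, "domains.bed"))
  write_fasta(annot$cand_seqs, file.path(out_dir, "candidates.fasta"))
  write_fasta(annot$kid_seqs, file.path(out_dir, "kids.fasta"))
  kid_table <- annot$ann$table[, c("seq_id", "kid_start", "kid_end",
                                   "kid_length", "is_kid", "kid_status")]
  kid_stats <- summarize_kids(annot$ann$table[annot$ann$table$seq_id %in%
                                                annot$cand_ids, ])
  report$stages$annotate <- list(n_annotated = nrow(annot$ann$table),
                                 n_candidates = length(annot$cand_ids))
  report$kid_stats <- kid_stats

  # ---- disorder -----------------------------------------------------------
  if ("disorder" %in% config$stages) {
    diso <- stage_cached(state_dir, "disorder", hash)
    if (is.null(diso)) {
      rows <- lapply(annot$cand_ids, function(id) {
        prof <- disorder_profile(annot$cand_seqs[[id]], seq_id = id)
        ctr <- kid_core_contrast(prof, annot$ann$architectures[[id]])
        data.frame(seq_id = id, kid_mean = ctr$kid_mean,
                   core_mean = ctr$core_mean, contrast = ctr$contrast,
                   stringsAsFactors = FALSE)
      })
      diso <- stage_save(state_dir, "disorder", hash,
                         list(table = do.call(rbind, rows)))
    }
    write_tsv(diso$table, file.path(out_dir, "disorder.tsv"))
    report$stages$disorder <-
      list(n_profiled = nrow(diso$table),
           fraction_contrast_positive = mean(diso$table$contrast > 0))
  } else diso <- NULL

  # ---- motifs + NLS -------------------------------------------------------
  if ("motifs" %in% config$stages) {
    mot <- stage_cached(state_dir, "motifs", hash)
    if (is.null(mot)) {
      motifs <- discover_motifs(annot$kid_seqs, n_motifs = config$n_motifs,
                                seed = config$seed + 2L)
      hits <- scan_motifs(motifs, annot$kid_seqs)
      pm <- positional_architecture(hits, n_positions = config$n_motifs)
      nls <- scan_nls_many(annot$kid_seqs)
      overlap <- motif_nls_overlap(hits, nls)
      mot <- stage_save(state_dir, "motifs", hash,
                        list(motifs = motifs, hits = hits, pm = pm,
                             nls = nls, overlap = overlap))
    }
    write_motif_models(mot$motifs, file.path(out_dir, "motifs.txt"))
    write_tsv(mot$hits, file.path(out_dir, "motif_hits.tsv"),
              sort_by = c("seq_id", "start"))
    pm_df <- as.data.frame(mot$pm$counts)
    pm_df <- cbind(position = rownames(mot$pm$counts),
                   pm_df, modal_motif = mot$pm$modal_motif)
    write_tsv(pm_df, file.path(out_dir, "positional_matrix.tsv"),
              sort_by = NULL)
    write_tsv(mot$nls, file.path(out_dir, "nls.tsv"),
              sort_by = c("seq_id", "start"))
    write_tsv(mot$overlap, file.path(out_dir, "motif_nls_overlap.tsv"),
              sort_by = NULL)
    report$stages$motifs <- list(n_motifs = length(mot$motifs),
                                 n_motif_hits = nrow(mot$hits),
                                 n_nls_hits = nrow(mot$nls))
  } else mot <- NULL

  # ---- phylogeny ----------------------------------------------------------
  if ("phylo" %in% config$stages && length(annot$cand_ids) >= 4) {
    phy <- stage_cached(state_dir, "phylo", hash)
    if (is.null(phy)) {
      msa_full <- progressive_msa(annot$cand_seqs)
      tree_full <- bootstrap_support(msa_full, config$bootstrap,
                                     seed = config$seed + 3L)
      msa_kid <- progressive_msa(annot$kid_seqs)
      tree_kid <- bootstrap_support(msa_kid, config$bootstrap,
                                    seed = config$seed + 4L)
      cmp <- compare_topologies(tree_full, tree_kid)
      phy <- stage_save(state_dir, "phylo", hash,
                        list(tree_full = tree_full, tree_kid = tree_kid,
                             comparison = cmp))
    }
    ape::write.tree(phy$tree_full, file.path(out_dir, "full.nwk"))
    ape::write.tree(phy$tree_kid, file.path(out_dir, "kid.nwk"))
    write_run_json(phy$comparison, file.path(out_dir, "comparison.json"))
    report$stages$phylo <- list(n_taxa = length(annot$cand_ids),
                                rf_distance = phy$comparison$rf_distance)
  } else phy <- NULL

  report$provenance <- list(
    package = "kidscape",
    version = as.character(utils::packageVersion("kidscape")),
    seed = config$seed,
    e_value = config$e_value, kid_min_length = config$kid_min_length,
    n_motifs = config$n_motifs, bootstrap = config$bootstrap,
    candidate_check = paste("internal architecture classification",
                            "(all five subdomain anchors + qualifying KID)",
                            "in place of external domain-database",
                            "verification"))
  write_run_json(report, file.path(out_dir, "report.json"))
  structure(list(report = report, hits = search$hits,
                 architectures = annot$ann, candidate_ids = annot$cand_ids,
                 candidate_seqs = annot$cand_seqs,
                 kid_seqs = annot$kid_seqs, kid_table = kid_table,
                 kid_stats = kid_stats,
                 disorder = diso$table,
                 motifs = mot$motifs, motif_hits = mot$hits,
                 positional = mot$pm, nls_hits = mot$nls,
                 motif_nls_overlap = mot$overlap,
                 tree_full = phy$tree_full, tree_kid = phy$tree_kid,
                 tree_comparison = phy$comparison,
                 out_dir = out_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("kidscape run:", length(x$candidate_ids), "candidates from",
      x$report$stages$search$n_db, "proteins\n")
  if (!is.null(x$kid_stats$n) && x$kid_stats$n > 0)
    cat(sprintf("KID lengths: n=%d, min=%d, max=%d, mean=%d (longest: %s)\n",
                x$kid_stats$n, x$kid_stats$min, x$kid_stats$max,
                x$kid_stats$mean, x$kid_stats$longest_id))
  invisible(x)
}

# minimal text serialization of the discovered motif models
write_motif_models <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("MOTIF MODELS (minimal text format)", con)
  writeLines(paste("ALPHABET=", paste(AA20, collapse = "")), con)
  for (m in motifs) {
    writeLines(sprintf("\nMOTIF %s width=%d consensus=%s log_evalue_proxy=%.4f",
                       m$motif_id, m$width, m$consensus,
                       m$log_evalue_proxy), con)
    for (r in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$pwm[r, ]), collapse = " "), con)
  }
}

#' Summarize KID length statistics
#'
#' Statistics over records with a qualifying KID only; the mean is
#' reported to the nearest integer, and the longest-insert id breaks ties
#' lexicographically.
#'
#' @param kid_records data.frame with `seq_id`, `kid_length`, `is_kid`
#'   (e.g. the annotation table), or a list of `kid_record`s.
#' @return List `n`, `min`, `max`, `mean`, `longest_id` (`n = 0` and NULL
#'   fields when no KIDs).
#' @export
summarize_kids <- function(kid_records) {
  if (is.data.frame(kid_records)) {
    df <- kid_records[kid_records$is_kid %in% TRUE, ]
  } else {
    rows <- Filter(function(k) isTRUE(k$is_kid), kid_records)
    df <- do.call(rbind, lapply(rows, function(k)
      data.frame(seq_id = k$seq_id, kid_length = k$kid_length,
                 stringsAsFactors = FALSE)))
    if (is.null(df)) df <- data.frame(seq_id = character(0),
                                      kid_length = integer(0))
  }
  if (!nrow(df))
    return(list(n = 0L, min = NULL, max = NULL, mean = NULL,
                longest_id = NULL))
  longest <- df$seq_id[order(-df$kid_length, df$seq_id)][1]
  list(n = nrow(df), min = min(df$kid_length), max = max(df$kid_length),
       mean = as.integer(round(mean(df$kid_length))), longest_id = longest)
}
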