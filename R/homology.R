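#' Build a profile HMM from a seed family alignment
#'
#' Constructs a profile hidden Markov model from an aligned set of seed
#' sequences (the family model searched against each proteome). Columns
#' whose gap fraction is below `match_fraction_threshold` become match
#' states; all other columns are treated as insertions. Emission and
#' transition probabilities are Laplace-smoothed counts. Insert states emit
#' the background distribution (the smoothed overall amino-acid frequency
#' of the seed), so insertions are emission-neutral in log-odds scoring.
#'
#' @param seed_msa Aligned sequences of equal width: an `AAStringSet` or a
#'   named character vector, gaps as `-` or `.`.
#' @param match_fraction_threshold Columns with gap fraction strictly below
#'   this become match states.
#' @param pseudocount Laplace pseudocount added per residue/transition.
#' @return An object of class `profile_hmm`: `length`, `match_emissions`
#'   (length x 20), `insert_emissions`, `transitions`, `background`,
#'   `match_columns`.
#' @export
build_profile_hmm <- function(seed_msa, match_fraction_threshold = 0.5,
                              pseudocount = 1.0) {
  res <- toupper(as.character(seed_msa))
  if (length(res) < 2) stop("need at least 2 aligned seed sequences")
  widths <- nchar(res)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: sequence widths ", paste(unique(widths), collapse = ","))
  W <- widths[1]
  n <- length(res)
  chars <- do.call(rbind, strsplit(gsub("\\.", "-", res), "", fixed = TRUE))
  is_gap <- chars == "-"
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < match_fraction_threshold)
  L <- length(match_cols)
  if (L == 0) stop("alignment has zero match columns at threshold ",
                   match_fraction_threshold)

  # background: smoothed overall residue frequency of the seed
  all_res <- chars[!is_gap]
  bg_counts <- table(factor(all_res, levels = AA20))
  background <- (as.numeric(bg_counts) + 1) / (sum(bg_counts) + 20)
  names(background) <- AA20

  # match emissions with Laplace pseudocounts (X/non-standard ignored)
  memis <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(L)) {
    col <- chars[, match_cols[i]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    memis[i, ] <- (as.numeric(cnt) + pseudocount) /
      (sum(cnt) + 20 * pseudocount)
  }

  # transitions from per-sequence state paths through the alignment
  # state index k = number of match columns passed (0..L); M0 = begin
  nm <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")
  counts <- lapply(nm, function(x) numeric(L + 1))
  names(counts) <- nm
  col_is_match <- logical(W)
  col_is_match[match_cols] <- TRUE
  for (s in seq_len(n)) {
    prev_state <- "M"; prev_k <- 0L
    for (c in seq_len(W)) {
      if (col_is_match[c]) {
        st <- if (is_gap[s, c]) "D" else "M"
        k <- prev_k + 1L
      } else {
        if (is_gap[s, c]) next
        st <- "I"; k <- prev_k
      }
      key <- paste0(prev_state, st)
      counts[[key]][prev_k + 1L] <- counts[[key]][prev_k + 1L] + 1
      prev_state <- st
      prev_k <- if (st == "I") prev_k else k
    }
    key <- paste0(prev_state, "M") # to end state E (= M_{L+1})
    counts[[key]][prev_k + 1L] <- counts[[key]][prev_k + 1L] + 1
  }
  trans <- normalize_transitions(counts, L, pseudocount)

  structure(list(length = L, match_emissions = memis,
                 insert_emissions = background, transitions = trans,
                 background = background, match_columns = match_cols),
            class = "profile_hmm")
}

# Laplace-normalize transition counts; at k = L there is no D_{L+1}, so
# *D transitions are fixed at zero and mass is shared among {M(=E), I}.
normalize_transitions <- function(counts, L, pseudocount) {
  out <- counts
  for (k in 0:L) {
    i <- k + 1L
    last <- (k == L)
    for (from in c("M", "I", "D")) {
      tos <- if (last) c("M", "I") else c("M", "I", "D")
      keys <- paste0(from, tos)
      tot <- sum(vapply(keys, function(x) counts[[x]][i], 0)) +
        pseudocount * length(tos)
      for (x in keys) out[[x]][i] <- (counts[[x]][i] + pseudocount) / tot
      if (last) out[[paste0(from, "D")]][i] <- 0
    }
  }
  out
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM with %d match states (from %d alignment columns)\n",
              x$length, max(x$match_columns)))
  invisible(x)
}

#' Forward log-odds score of a sequence against a profile HMM
#'
#' Full-sequence forward algorithm with free-insertion flanking states at
#' both ends (local-in-target behaviour without Plan7 wing states). The
#' score is `log2` of the ratio of the forward likelihood under the model
#' to the likelihood under a null with the identical state machine but all
#' emissions replaced by the background — an i.i.d.-background emission
#' model over the same path distribution, so a model whose emissions all
#' equal the background scores exactly 0 bits. `X` residues are neutral.
#'
#' @param hmm A `profile_hmm`.
#' @param seq A residue string (or single named element of an
#'   `AAStringSet`).
#' @return Bit score (finite for any non-empty sequence).
#' @export
forward_score <- function(hmm, seq) {
  res <- as.character(seq)[1]
  if (!nzchar(res)) stop("empty sequence")
  idx <- aa_index0(res)
  cpp_forward_logodds(hmm$match_emissions, as.numeric(hmm$insert_emissions),
                      hmm$transitions, as.numeric(hmm$background), idx)
}

forward_score_many <- function(hmm, seqs) {
  idx <- lapply(as.character(seqs), aa_index0)
  cpp_forward_logodds_many(hmm$match_emissions,
                           as.numeric(hmm$insert_emissions),
                           hmm$transitions, as.numeric(hmm$background), idx)
}

#' Calibrate the Gumbel E-value model for a profile HMM
#'
#' Scores `n_decoys` i.i.d. sequences drawn from the model background and
#' fits a Gumbel distribution to the decoy scores by the method of moments:
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` (gamma the
#' Euler-Mascheroni constant). E-values are then
#' `E = N * exp(-lambda * (S - mu))` for a database of N sequences.
#'
#' @param hmm A `profile_hmm`.
#' @param n_decoys Number of decoy sequences (>= 50).
#' @param decoy_length Decoy length(s) in residues; a vector is sampled
#'   with replacement, so passing the target database's lengths calibrates
#'   against its length distribution.
#' @param seed Integer seed; calibration is deterministic given it.
#' @param composition Residue frequencies the decoys are drawn from
#'   (default: the model background). Pass the target database's
#'   composition to calibrate against the sequences actually searched,
#'   which is what [search_proteomes()] does.
#' @return Object of class `gumbel_params`: `mu`, `lambda`,
#'   `n_calibration`.
#' @export
calibrate_evalue <- function(hmm, n_decoys = 200, decoy_length = 350,
                             seed = 1, composition = NULL) {
  if (n_decoys < 50) stop("n_decoys must be >= 50")
  if (is.null(composition)) composition <- hmm$background
  rng <- local_rng(seed)
  scores <- withr_seed(rng, function() {
    lens <- if (length(decoy_length) == 1) rep(decoy_length, n_decoys)
            else sample(decoy_length, n_decoys, replace = TRUE)
    vapply(seq_len(n_decoys), function(i) {
      s <- paste(sample(AA20, lens[i], replace = TRUE,
                        prob = composition), collapse = "")
      forward_score(hmm, s)
    }, 0)
  })
  fit_gumbel_moments(scores)
}

# Method-of-moments Gumbel fit on a numeric score vector
fit_gumbel_moments <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) decoy scores")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.57721566490153286 / lambda
  structure(list(mu = mu, lambda = lambda, n_calibration = length(scores)),
            class = "gumbel_params")
}

#' Gumbel E-value of a bit score
#' @param score Bit score(s).
#' @param gumbel A `gumbel_params`.
#' @param n_db Number of sequences in the searched database.
#' @return E-value(s), `>= 0`, monotone decreasing in score.
#' @export
gumbel_evalue <- function(score, gumbel, n_db) {
  n_db * exp(-gumbel$lambda * (score - gumbel$mu))
}

#' Search proteomes with a calibrated profile HMM
#'
#' Scores every protein in every manifest proteome with [forward_score()],
#' converts scores to E-values with the database size N = total number of
#' target sequences, and returns hits below the E-value threshold sorted by
#' ascending E-value (the family-candidate retrieval step; the default
#' threshold 0.01 is the one used to call family candidates).
#'
#' @param hmm A `profile_hmm`.
#' @param manifest Manifest data.frame from [read_manifest()], or a named
#'   list of `AAStringSet`s keyed by species.
#' @param gumbel Calibration from [calibrate_evalue()], or NULL to
#'   calibrate here on decoys drawn from the database's own residue
#'   composition and length distribution (the recommended default: scores
#'   drift with target length and composition, so the decoys should
#'   emulate the sequences actually searched).
#' @param e_threshold Report hits with E-value strictly below this.
#' @param calibration_seed Seed for self-calibration when `gumbel` is
#'   NULL.
#' @param n_decoys Decoys for self-calibration.
#' @return data.frame of hits: `target_id`, `species_name`, `bit_score`,
#'   `e_value`, `target_length`, sorted by ascending `e_value`; the
#'   per-species scan counts are attached as attribute `species_counts`.
#' @export
search_proteomes <- function(hmm, manifest, gumbel = NULL,
                             e_threshold = 0.01, calibration_seed = 1,
                             n_decoys = 200) {
  if (is.data.frame(manifest)) {
    if (!nrow(manifest)) stop("empty manifest")
    proteomes <- lapply(seq_len(nrow(manifest)),
                        function(i) read_fasta(manifest$fasta_path[i]))
    names(proteomes) <- manifest$species_name
  } else {
    proteomes <- manifest
    if (!length(proteomes)) stop("empty manifest")
  }
  rows <- lapply(names(proteomes), function(sp) {
    x <- proteomes[[sp]]
    data.frame(target_id = names(x), species_name = sp,
               bit_score = forward_score_many(hmm, x),
               target_length = Biostrings::width(x),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  n_db <- nrow(all)
  if (is.null(gumbel)) {
    comp <- db_composition(proteomes)
    gumbel <- calibrate_evalue(hmm, n_decoys = n_decoys,
                               decoy_length = all$target_length,
                               seed = calibration_seed, composition = comp)
  }
  all$e_value <- gumbel_evalue(all$bit_score, gumbel, n_db)
  hits <- all[all$e_value < e_threshold, ]
  hits <- hits[order(hits$e_value, hits$target_id), ]
  hits <- hits[, c("target_id", "species_name", "bit_score", "e_value",
                   "target_length")]
  rownames(hits) <- NULL
  attr(hits, "species_counts") <-
    table(factor(hits$species_name, levels = names(proteomes)))
  attr(hits, "n_db") <- n_db
  attr(hits, "gumbel") <- gumbel
  hits
}

# pooled residue composition of a list of AAStringSets (smoothed)
db_composition <- function(proteomes) {
  cnt <- numeric(20); names(cnt) <- AA20
  for (x in proteomes) {
    f <- Biostrings::alphabetFrequency(x, collapse = TRUE)
    cnt <- cnt + f[AA20]
  }
  (cnt + 1) / (sum(cnt) + 20)
}

#' Local Smith-Waterman scan of a query against a sequence database
#'
#' Optimal local alignment score of the query against every target
#' (BLOSUM62, affine gaps), with significance from a Gumbel calibrated on
#' shuffled-target decoys — a local stand-in for a BLASTP search of a
#' user-supplied database. The default E-value threshold of 1 casts a wide
#' net, as appropriate when probing whether a segment occurs anywhere else.
#'
#' @param query Residue string or single-element `AAStringSet`.
#' @param database `AAStringSet` of targets.
#' @param substitution_matrix Matrix name in Biostrings (default
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param e_threshold Report hits with E-value below this.
#' @param n_decoys Shuffled decoys used for calibration.
#' @param seed Integer seed for decoy shuffling.
#' @return data.frame of hits: `target_id`, `score`, `e_value`, sorted by
#'   ascending `e_value` (descending score on ties).
#' @export
local_sw_scan <- function(query, database, substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1, e_threshold = 1.0,
                          n_decoys = 100, seed = 1) {
  if (!length(database)) stop("empty database")
  q <- Biostrings::AAString(as.character(query)[1])
  if (!length(q)) stop("empty query")
  submat <- substitution_matrix
  scores <- Biostrings::pairwiseAlignment(
    database, q, type = "local", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  rng <- local_rng(seed)
  decoys <- withr_seed(rng, function() {
    tgt <- sample(as.character(database), n_decoys, replace = TRUE)
    vapply(tgt, function(s)
      paste(sample(aa_chars(s)), collapse = ""), "")
  })
  decoy_scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(decoys)), q, type = "local",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  gum <- fit_gumbel_moments(decoy_scores)
  ev <- gumbel_evalue(scores, gum, length(database))
  hits <- data.frame(target_id = names(database), score = scores,
                     e_value = ev, stringsAsFactors = FALSE)
  hits <- hits[hits$e_value < e_threshold, ]
  hits <- hits[order(hits$e_value, -hits$score, hits$target_id), ]
  rownames(hits) <- NULL
  hits
}

# Seed handling: run `fn` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_rng <- function(seed) as.integer(seed)
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
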