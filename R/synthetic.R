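# Synthetic kinase proteomes with planted ground truth.
#
# Each dataset emulates the statistical structure the pipeline assumes: a
# set of species proteomes related by a two-clade species tree, each
# carrying a few true family members (receptor-like cytoplasmic kinases
# with a long disorder-biased insert between the DFG and APE anchors,
# twelve ordered motifs and nuclear localization signals inside the
# second/third motif), canonical-kinase decoys with a 20-35 residue
# activation segment, and i.i.d. background proteins.

# typical globular proteome composition used for cores/decoys/background
GLOBULAR_FREQ <- c(A = 0.08, C = 0.015, D = 0.054, E = 0.067, F = 0.039,
                   G = 0.071, H = 0.022, I = 0.059, K = 0.058, L = 0.096,
                   M = 0.024, N = 0.041, P = 0.047, Q = 0.039, R = 0.055,
                   S = 0.066, T = 0.053, V = 0.068, W = 0.011, Y = 0.029)

# disorder-promoting insert composition (heavy on K, E, S, P, Q)
KID_FREQ <- c(A = 0.02, C = 0.002, D = 0.06, E = 0.16, F = 0.005,
              G = 0.05, H = 0.02, I = 0.01, K = 0.16, L = 0.02,
              M = 0.005, N = 0.04, P = 0.12, Q = 0.10, R = 0.06,
              S = 0.14, T = 0.05, V = 0.02, W = 0.003, Y = 0.005)

TM_FREQ <- c(L = 0.35, I = 0.22, V = 0.18, F = 0.15, A = 0.10)

# planted motif consensi (A and P avoided so anchor-like substrings cannot
# arise from the consensus itself); nls_span marks the intact basic run
# carrying the planted NLS (0-based, half-open, motif-local)
PLANTED_MOTIFS <- list(
  list(consensus = "KEEDRKELEE",   nls = NULL),
  list(consensus = "DWWSKKKRKRQ",  nls = c(4L, 10L)),
  list(consensus = "EWWDKRKKRKSQ", nls = c(4L, 10L)),
  list(consensus = "KKQSEKKSQG",   nls = NULL),
  list(consensus = "QSDYEDELSDKE", nls = NULL),
  list(consensus = "EWGDSEDSYW",   nls = NULL),
  list(consensus = "SQTQSESQTQ",   nls = NULL),
  list(consensus = "GQDLSRELGQFM", nls = NULL),
  list(consensus = "YFDQSSGQKELD", nls = NULL),
  list(consensus = "SSSTSS",       nls = NULL),
  list(consensus = "KKSEKK",       nls = NULL),
  list(consensus = "QNGYDE",       nls = NULL))

#' Default synthetic-dataset configuration
#'
#' The defaults define the study conditions: 12 species in two deep
#' clades, two family members per species, ten canonical-kinase decoys
#' and 150 background proteins per species; insert lengths drawn from a
#' normal with mean 280 and sd 60 truncated to `[199, 527]`; twelve
#' planted motifs in a default order with a small per-sequence
#' adjacent-swap probability; NLS planted inside the second and third
#' motifs; anchors protected from mutation by default.
#'
#' @param seed Integer seed (mandatory; the generator is fully
#'   deterministic given it).
#' @param ... Overrides for any default field.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    n_species = 12,
    clade_stem = 0.5,        # branch length of each clade stem
    within_branch = 0.15,    # internal + leaf branch lengths inside clades
    copy_number_range = c(2L, 2L), # up to 8 supported
    n_decoy_kinases = 10,
    n_background = 150,
    background_length_range = c(150L, 600L),
    kid_length_mean = 280, kid_length_sd = 60,
    kid_length_bounds = c(199L, 527L),
    motif_noise = 0.10,      # per-position substitution prob in instances
    motif_swap_prob = 0.10,  # per-sequence adjacent-order-swap prob
    nls_plant_rate = 1.0,
    tail_nls_rate = 0.5,
    anchor_mutation_rate = 0.0,
    subst_rate = 0.4,        # per site per unit branch length
    indel_rate = 0.08,       # insert-confined indels per 100 sites per unit
    member_divergence = 0.03,
    decoy_divergence = 0.35)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  rates <- c(cfg$motif_noise, cfg$motif_swap_prob, cfg$nls_plant_rate,
             cfg$tail_nls_rate, cfg$anchor_mutation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(cfg$kid_length_bounds <= 0)) stop("kid bounds must be positive")
  structure(cfg, class = "synthetic_config")
}

sample_residues <- function(n, freq) {
  paste(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
}

# substitute residues along a branch; protected positions never change
evolve_subst <- function(chars, t, rate, freq, protected = integer(0)) {
  p <- 1 - exp(-rate * t)
  hit <- which(runif(length(chars)) < p)
  hit <- setdiff(hit, protected)
  if (length(hit))
    chars[hit] <- sample(names(freq), length(hit), replace = TRUE, prob = freq)
  chars
}

evolve_indel <- function(chars, t, indel_rate, freq) {
  n_events <- rpois(1, indel_rate * t * length(chars) / 100)
  for (e in seq_len(n_events)) {
    len <- 1 + rgeom(1, 0.35)
    pos <- sample(length(chars), 1)
    if (runif(1) < 0.5) { # deletion
      del <- pos:min(length(chars), pos + len - 1)
      if (length(chars) - length(del) > 50) chars <- chars[-del]
    } else {
      ins <- sample(names(freq), len, replace = TRUE, prob = freq)
      chars <- append(chars, ins, after = pos)
    }
  }
  chars
}

# replace anchor-like substrings inside a generated segment so the planted
# DFG/APE anchors stay the unique spacing-consistent combination
scrub_anchor_patterns <- function(res) {
  repeat {
    m <- regexpr("DFG", res)
    if (m == -1) break
    substr(res, m + 1, m + 1) <- "L" # DFG -> DLG
  }
  repeat {
    m <- regexpr("[AP].E", res)
    if (m == -1) break
    substr(res, m + 2, m + 2) <- "Q" # ..E -> ..Q
  }
  res
}

# balanced-ish ladder clade: list tree with branch lengths
build_clade <- function(species, blen) {
  if (length(species) == 1)
    return(list(leaf = species, blen = blen))
  k <- ceiling(length(species) / 2)
  list(left = build_clade(species[1:k], blen),
       right = build_clade(species[(k + 1):length(species)], blen),
       blen = blen)
}

tree_to_newick <- function(node) {
  if (!is.null(node$leaf))
    return(sprintf("%s:%g", node$leaf, node$blen))
  sprintf("(%s,%s):%g", tree_to_newick(node$left),
          tree_to_newick(node$right), node$blen)
}

#' Generate a synthetic proteome dataset with planted ground truth
#'
#' Builds an ancestral family protein — N-terminal segment, transmembrane
#' block, juxtamembrane, kinase subdomains I-VII ending in DFG, a
#' disorder-biased insert skeleton, subdomains VIII-XI starting with APE,
#' and a C-tail — evolves it along a two-clade species tree (substitutions
#' everywhere except protected anchors; indels confined to the insert
#' skeleton), and assembles per-species proteomes of family members,
#' canonical-kinase decoys and background proteins. Per-member inserts
#' draw their length from the configured truncated normal and carry the
#' twelve planted motifs in order (rare adjacent swaps) with NLS kept
#' intact inside the second and third motifs.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Directory to write per-species FASTA, `manifest.yaml`,
#'   `truth.json`, `species_tree.nwk` and `seeds.fasta`.
#' @return List: `manifest` (data.frame), `truth` (list), `seed_ids`
#'   (ids of the designated seed family members), `paths`.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr_seed(config$seed, function() simulate_dataset_impl(config, out_dir))
}

simulate_dataset_impl <- function(cfg, out_dir) {
  n_sp <- cfg$n_species
  species <- sprintf("sp%02d", seq_len(n_sp))
  half <- ceiling(n_sp / 2)
  cladeA <- species[seq_len(half)]; cladeB <- species[(half + 1):n_sp]
  lineages <- rep(c("bryophyte", "monocot", "dicot"), length.out = n_sp)
  tree <- list(left = build_clade(cladeA, cfg$within_branch),
               right = build_clade(cladeB, cfg$within_branch),
               blen = 0)
  tree$left$blen <- cfg$clade_stem
  tree$right$blen <- cfg$clade_stem
  newick <- paste0("(", tree_to_newick(tree$left), ",",
                   tree_to_newick(tree$right), ");")

  # --- ancestral family scaffold ------------------------------------------
  nterm <- c("M", aa_chars(sample_residues(4, GLOBULAR_FREQ)))
  tm <- aa_chars(sample_residues(23, TM_FREQ))
  juxta <- aa_chars(sample_residues(25, GLOBULAR_FREQ))
  core1 <- aa_chars(sample_residues(148, GLOBULAR_FREQ))
  core1[11:16] <- c("G", "E", "G", "S", "F", "G") # subdomain I (G.G..G)
  core1[31:33] <- c("A", "I", "K")                # subdomain II
  core1[121:123] <- c("H", "R", "D")              # subdomain VIb (RD-type)
  core1[146:148] <- c("D", "F", "G")              # subdomain VII
  core2 <- aa_chars(sample_residues(103, GLOBULAR_FREQ))
  core2[1:3] <- c("A", "P", "E")                  # subdomain VIII
  ctail <- aa_chars(sample_residues(30, GLOBULAR_FREQ))
  kid_skel <- aa_chars(sample_residues(600, KID_FREQ))
  anchor_pos_core1 <- c(11:16, 31:33, 121:123, 146:148)

  anc <- list(nterm = nterm, tm = tm, juxta = juxta, core1 = core1,
              core2 = core2, ctail = ctail, kid_skel = kid_skel)

  # --- evolve scaffold along the species tree -----------------------------
  evolve_branch <- function(seg, t) {
    seg$nterm <- evolve_subst(seg$nterm, t, cfg$subst_rate, GLOBULAR_FREQ,
                              protected = 1L)
    seg$tm <- evolve_subst(seg$tm, t, cfg$subst_rate * 0.5, TM_FREQ)
    seg$juxta <- evolve_subst(seg$juxta, t, cfg$subst_rate, GLOBULAR_FREQ)
    seg$core1 <- evolve_subst(seg$core1, t, cfg$subst_rate, GLOBULAR_FREQ,
                              protected = anchor_pos_core1)
    seg$core2 <- evolve_subst(seg$core2, t, cfg$subst_rate, GLOBULAR_FREQ,
                              protected = 1:3)
    seg$ctail <- evolve_subst(seg$ctail, t, cfg$subst_rate, GLOBULAR_FREQ)
    seg$kid_skel <- evolve_subst(seg$kid_skel, t, cfg$subst_rate, KID_FREQ)
    seg$kid_skel <- evolve_indel(seg$kid_skel, t, cfg$indel_rate, KID_FREQ)
    seg
  }
  leaves <- list()
  recurse <- function(node, seg) {
    seg <- evolve_branch(seg, node$blen)
    if (!is.null(node$leaf)) leaves[[node$leaf]] <<- seg
    else { recurse(node$left, seg); recurse(node$right, seg) }
  }
  recurse(tree$left, anc); recurse(tree$right, anc)

  # --- per-species proteomes ----------------------------------------------
  motif_widths <- vapply(PLANTED_MOTIFS, function(m) nchar(m$consensus), 0L)
  truth_seqs <- list()
  fasta_paths <- character(0)
  seed_ids <- character(0)

  for (si in seq_along(species)) {
    sp <- species[si]
    seg <- leaves[[sp]]
    records <- character(0)
    cr <- cfg$copy_number_range
    n_mem <- if (cr[1] == cr[2]) cr[1] else sample(cr[1]:cr[2], 1)
    for (mi in seq_len(n_mem)) {
      built <- build_family_member(seg, cfg, motif_widths)
      id <- sprintf("%s_fam%d", sp, mi)
      records[id] <- built$residues
      truth_seqs[[id]] <- c(list(id = id, species = sp, label = "family_member",
                                 clade = if (sp %in% cladeA) "clade1" else "clade2"),
                            built$truth)
      if (si %in% c(1, half + 1) && mi <= 2) seed_ids <- c(seed_ids, id)
    }
    for (di in seq_len(cfg$n_decoy_kinases)) {
      id <- sprintf("%s_dec%02d", sp, di)
      records[id] <- build_decoy_kinase(seg, cfg)
      truth_seqs[[id]] <- list(id = id, species = sp, label = "decoy_kinase")
    }
    lens <- sample(seq(cfg$background_length_range[1],
                       cfg$background_length_range[2]), cfg$n_background,
                   replace = TRUE)
    for (bi in seq_len(cfg$n_background)) {
      id <- sprintf("%s_bg%03d", sp, bi)
      records[id] <- sample_residues(lens[bi], GLOBULAR_FREQ)
      truth_seqs[[id]] <- list(id = id, species = sp, label = "background")
    }
    fp <- file.path(out_dir, paste0(sp, ".fasta"))
    write_fasta(records, fp)
    fasta_paths <- c(fasta_paths, fp)
  }

  manifest <- data.frame(species_name = species, lineage_tag = lineages,
                         fasta_path = normalizePath(fasta_paths),
                         stringsAsFactors = FALSE)
  # manifest on disk uses paths relative to its own directory
  rel <- manifest; rel$fasta_path <- basename(rel$fasta_path)
  write_manifest(rel, file.path(out_dir, "manifest.yaml"))
  writeLines(newick, file.path(out_dir, "species_tree.nwk"))

  # seed family members, re-read from the emitted proteomes
  all_fam <- unlist(lapply(seed_ids, function(id) {
    sp <- truth_seqs[[id]]$species
    x <- read_fasta(file.path(out_dir, paste0(sp, ".fasta")))
    stats::setNames(as.character(x[id]), id)
  }))
  write_fasta(all_fam, file.path(out_dir, "seeds.fasta"))

  truth <- list(
    species = data.frame(species_name = species, lineage_tag = lineages,
                         clade = ifelse(species %in% cladeA, "clade1",
                                        "clade2"), stringsAsFactors = FALSE),
    tree_newick = newick,
    motif_consensus = stats::setNames(
      vapply(PLANTED_MOTIFS, function(m) m$consensus, ""),
      paste0("M", seq_along(PLANTED_MOTIFS))),
    sequences = truth_seqs,
    seed = cfg$seed)
  write_run_json(truth_json_form(truth), file.path(out_dir, "truth.json"))

  list(manifest = manifest, truth = truth, seed_ids = seed_ids,
       paths = list(dir = out_dir,
                    manifest = file.path(out_dir, "manifest.yaml"),
                    truth = file.path(out_dir, "truth.json"),
                    tree = file.path(out_dir, "species_tree.nwk"),
                    seeds = file.path(out_dir, "seeds.fasta")))
}

truth_json_form <- function(truth) {
  truth$sequences <- lapply(truth$sequences, function(e) {
    if (!is.null(e$nls) && is.data.frame(e$nls) && !nrow(e$nls))
      e$nls <- NULL
    e
  })
  truth
}

build_family_member <- function(seg, cfg, motif_widths) {
  # member-level divergence (paralogs), anchors still protected
  anchor_pos_core1 <- c(11:16, 31:33, 121:123, 146:148)
  core1 <- evolve_subst(seg$core1, 1, cfg$member_divergence, GLOBULAR_FREQ,
                        protected = anchor_pos_core1)
  core2 <- evolve_subst(seg$core2, 1, cfg$member_divergence, GLOBULAR_FREQ,
                        protected = 1:3)
  if (cfg$anchor_mutation_rate > 0 && runif(1) < cfg$anchor_mutation_rate) {
    pos <- sample(anchor_pos_core1, 1)
    core1[pos] <- sample(AA20, 1)
  }
  pre <- c(seg$nterm, seg$tm, seg$juxta, core1)

  # insert length from the truncated normal
  len <- round(rnorm(1, cfg$kid_length_mean, cfg$kid_length_sd))
  len <- max(cfg$kid_length_bounds[1], min(cfg$kid_length_bounds[2], len))

  # motif order: default 1..12 with an occasional adjacent swap
  ord <- seq_along(motif_widths)
  if (runif(1) < cfg$motif_swap_prob) {
    i <- sample(length(ord) - 1, 1)
    ord[c(i, i + 1)] <- ord[c(i + 1, i)]
  }
  n_m <- length(ord)
  budget <- len - sum(motif_widths)
  w <- runif(n_m + 1, 0.5, 1.5)
  gaps <- floor(budget * w / sum(w))
  rem <- budget - sum(gaps)
  if (rem > 0) gaps[seq_len(rem)] <- gaps[seq_len(rem)] + 1L

  # insert background cut from the evolved skeleton at a member offset
  skel <- seg$kid_skel
  need <- sum(gaps)
  off <- sample(0:40, 1)
  if (off + need > length(skel))
    skel <- rep(skel, length.out = off + need)
  bgres <- skel[(off + 1):(off + need)]

  plant_nls <- runif(1) < cfg$nls_plant_rate
  motif_rows <- list()
  nls_rows <- list()
  cursor <- 0L # kid-local
  gpos <- cumsum(c(0, gaps))
  kid_chars <- character(0)
  for (k in seq_len(n_m)) {
    g <- gaps[k]
    kid_chars <- c(kid_chars, bgres[seq_len(g) + gpos[k]])
    cursor <- cursor + g
    m_idx <- ord[k]
    inst <- sample_motif_instance(PLANTED_MOTIFS[[m_idx]], cfg$motif_noise,
                                  plant_nls)
    kid_chars <- c(kid_chars, inst$chars)
    motif_rows[[k]] <- data.frame(planted_id = paste0("M", m_idx),
                                  rank = k, start = cursor,
                                  end = cursor + length(inst$chars),
                                  stringsAsFactors = FALSE)
    if (!is.null(inst$nls_span) && plant_nls)
      nls_rows[[length(nls_rows) + 1]] <-
        data.frame(start = cursor + inst$nls_span[1],
                   end = cursor + inst$nls_span[2],
                   in_motif = paste0("M", m_idx), stringsAsFactors = FALSE)
    cursor <- cursor + length(inst$chars)
  }
  kid_chars <- c(kid_chars, bgres[seq_len(gaps[n_m + 1]) + gpos[n_m + 1]])
  kid <- scrub_anchor_patterns(paste(kid_chars, collapse = ""))

  tail_chars <- evolve_subst(seg$ctail, 1, cfg$member_divergence,
                             GLOBULAR_FREQ)
  if (runif(1) < cfg$tail_nls_rate) {
    nls <- aa_chars("PKKKRKV")
    tail_chars[5:11] <- nls
  }
  residues <- paste(c(pre, aa_chars(kid), core2, tail_chars), collapse = "")
  kid_start <- length(pre)
  kid_end <- kid_start + nchar(kid)
  list(residues = residues,
       truth = list(kid_start = kid_start, kid_end = kid_end,
                    kid_length = nchar(kid),
                    motif_order = vapply(motif_rows, function(r)
                      r$planted_id, ""),
                    motifs = do.call(rbind, motif_rows),
                    nls = if (length(nls_rows)) do.call(rbind, nls_rows)
                          else data.frame(start = integer(0),
                                          end = integer(0),
                                          in_motif = character(0))))
}

sample_motif_instance <- function(motif, noise, keep_nls) {
  cons <- aa_chars(motif$consensus)
  w <- length(cons)
  protected <- if (!is.null(motif$nls) && keep_nls)
    (motif$nls[1] + 1):motif$nls[2] else integer(0)
  hit <- setdiff(which(runif(w) < noise), protected)
  if (length(hit))
    cons[hit] <- sample(names(KID_FREQ), length(hit), replace = TRUE,
                        prob = KID_FREQ)
  if (!is.null(motif$nls) && !keep_nls) {
    # degrade the basic run so no signal is planted
    span <- (motif$nls[1] + 1):motif$nls[2]
    cons[span] <- sample(c("S", "Q", "T"), length(span), replace = TRUE)
  }
  list(chars = cons,
       nls_span = if (!is.null(motif$nls) && keep_nls) motif$nls else NULL)
}

build_decoy_kinase <- function(seg, cfg) {
  anchor_pos_core1 <- c(11:16, 31:33, 121:123, 146:148)
  core1 <- evolve_subst(seg$core1, 1, cfg$decoy_divergence, GLOBULAR_FREQ,
                        protected = anchor_pos_core1)
  core2 <- evolve_subst(seg$core2, 1, cfg$decoy_divergence, GLOBULAR_FREQ,
                        protected = 1:3)
  act_len <- sample(20:35, 1)
  act <- scrub_anchor_patterns(sample_residues(act_len, GLOBULAR_FREQ))
  tail_chars <- evolve_subst(seg$ctail, 1, cfg$decoy_divergence,
                             GLOBULAR_FREQ)
  paste(c(seg$nterm, seg$tm, seg$juxta, core1, aa_chars(act), core2,
          tail_chars), collapse = "")
}

#' Evaluate pipeline predictions against planted truth
#'
#' Computes the recovery metrics the synthetic dataset supports:
#' homolog-retrieval sensitivity and background false positives, insert
#' boundary errors, motif recovery by per-column consensus agreement,
#' modal positional-order agreement, NLS recall/precision, the fraction
#' of members with positive insert-versus-core disorder contrast, and
#' two-clade recovery flags. Any subset of predictions may be supplied;
#' only the matching metrics are computed.
#'
#' @param predictions List with any of: `hits` (data.frame with
#'   `target_id`), `kid_table` (data.frame `seq_id`, `kid_start`,
#'   `kid_end`, `is_kid`), `motifs` (list of `motif_model`),
#'   `motif_hits` (data.frame `motif_id`, `seq_id`, `start`, `end`,
#'   KID-local; used to map discovered motifs onto planted ones by site
#'   overlap), `positional` (a `positional_matrix`), `nls_hits` (data.frame
#'   `seq_id`, `start`, `end`, KID-local), `disorder_contrasts`
#'   (data.frame `seq_id`, `contrast`), `tree_full`, `tree_kid`
#'   (`phylo` trees over family-member ids).
#' @param truth Ground truth from [simulate_dataset()].
#' @return Named list of metrics.
#' @export
truth_eval <- function(predictions, truth) {
  seqs <- truth$sequences
  fam_ids <- names(seqs)[vapply(seqs, function(e)
    e$label == "family_member", TRUE)]
  bg_ids <- names(seqs)[vapply(seqs, function(e)
    e$label == "background", TRUE)]
  out <- list(n_family = length(fam_ids))

  if (!is.null(predictions$hits)) {
    got <- predictions$hits$target_id
    unknown <- setdiff(got, names(seqs))
    if (length(unknown)) stop("prediction ids not in truth: ",
                              paste(utils::head(unknown, 3), collapse = ", "))
    out$homolog_sensitivity <- mean(fam_ids %in% got)
    out$background_false_positives <- sum(got %in% bg_ids)
  }
  if (!is.null(predictions$kid_table)) {
    kt <- predictions$kid_table
    errs <- vapply(fam_ids, function(id) {
      row <- kt[kt$seq_id == id, ]
      if (nrow(row) != 1 || !isTRUE(row$is_kid)) return(Inf)
      max(abs(row$kid_start - seqs[[id]]$kid_start),
          abs(row$kid_end - seqs[[id]]$kid_end))
    }, 0)
    out$kid_boundary_errors <- errs
    out$kid_recovered_within_5 <- mean(errs <= 5)
    out$kid_exact <- mean(errs == 0)
  }
  if (!is.null(predictions$motifs)) {
    planted <- truth$motif_consensus
    agree <- motif_agreement_matrix(predictions$motifs, planted)
    # greedy one-to-one assignment, best agreement first
    assign <- rep(NA_character_, length(planted))
    names(assign) <- names(planted)
    a <- agree
    for (step in seq_len(min(dim(a)))) {
      if (!any(is.finite(a))) break
      ij <- which(a == max(a[is.finite(a)]), arr.ind = TRUE)[1, ]
      assign[colnames(a)[ij[2]]] <- rownames(a)[ij[1]]
      a[ij[1], ] <- -Inf; a[, ij[2]] <- -Inf
    }
    best_agree <- vapply(names(planted), function(p) {
      d <- assign[p]
      if (is.na(d)) 0 else agree[d, p]
    }, 0)
    out$motif_agreement <- best_agree
    out$motifs_recovered <- sum(best_agree >= 0.6)
    out$motif_assignment <- assign
  }
  if (!is.null(predictions$positional)) {
    pm <- predictions$positional
    # discovered -> planted map: by majority site-interval overlap when
    # hits are supplied (robust to similar consensus strings), else by
    # the consensus-agreement assignment
    inv <- NULL
    if (!is.null(predictions$motif_hits))
      inv <- map_motifs_by_overlap(predictions$motif_hits, seqs)
    if (is.null(inv) && !is.null(out$motif_assignment)) {
      assign <- out$motif_assignment
      inv <- stats::setNames(names(assign), assign)
    }
    if (!is.null(inv)) {
      expected <- paste0("M", seq_len(pm$n_positions))
      modal_planted <- vapply(pm$modal_motif, function(d)
        if (!is.na(d) && d %in% names(inv)) inv[[d]] else NA_character_, "")
      out$positional_agreement <-
        sum(!is.na(modal_planted) & modal_planted == expected)
    }
    # order-isolating variant: ranks recomputed over the hits of mapped
    # motifs only, so a conserved block picked up in place of an
    # unrecovered planted motif does not shift every downstream rank
    if (!is.null(predictions$motif_hits) && !is.null(inv)) {
      h <- predictions$motif_hits
      h <- h[h$motif_id %in% names(inv), ]
      h$planted <- unname(inv[h$motif_id])
      mapped <- sort(unique(h$planted))
      mapped <- mapped[order(as.integer(sub("^M", "", mapped)))]
      ranks <- matrix(NA_character_, length(unique(h$seq_id)),
                      length(mapped))
      sids <- unique(h$seq_id)
      for (si in seq_along(sids)) {
        hs <- h[h$seq_id == sids[si], ]
        hs <- hs[order(hs$start), ]
        k <- min(nrow(hs), ncol(ranks))
        ranks[si, seq_len(k)] <- hs$planted[seq_len(k)]
      }
      modal_rank <- apply(ranks, 2, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return(NA_character_)
        tb <- sort(table(col), decreasing = TRUE)
        names(tb)[1]
      })
      out$positional_agreement_ordered <-
        sum(!is.na(modal_rank) & modal_rank == mapped)
      out$n_mapped_motifs <- length(mapped)
    }
  }
  if (!is.null(predictions$nls_hits)) {
    nh <- predictions$nls_hits
    planted <- list(); pred_cover <- 0; n_pred <- 0
    rec <- c()
    for (id in fam_ids) {
      tn <- seqs[[id]]$nls
      if (is.null(tn) || !nrow(tn)) next
      for (i in seq_len(nrow(tn))) {
        h <- nh[nh$seq_id == id, ]
        rec <- c(rec, any(h$start < tn$end[i] & tn$start[i] < h$end))
      }
    }
    out$nls_recall <- if (length(rec)) mean(rec) else NA_real_
    # precision: fraction of predicted NLS hits touching any planted one
    prec <- vapply(seq_len(nrow(nh)), function(i) {
      tn <- seqs[[nh$seq_id[i]]]$nls
      if (is.null(tn) || !nrow(tn)) return(FALSE)
      any(tn$start < nh$end[i] & nh$start[i] < tn$end)
    }, TRUE)
    out$nls_precision <- if (nrow(nh)) mean(prec) else NA_real_
  }
  if (!is.null(predictions$disorder_contrasts)) {
    dc <- predictions$disorder_contrasts
    dc <- dc[dc$seq_id %in% fam_ids, ]
    out$disorder_contrast_positive <- mean(dc$contrast > 0)
  }
  clades <- stats::setNames(
    vapply(seqs[fam_ids], function(e) e$clade, ""), fam_ids)
  for (nm in c("tree_full", "tree_kid")) {
    if (is.null(predictions[[nm]])) next
    tr <- predictions[[nm]]
    side <- names(clades)[clades == "clade1"]
    side <- intersect(side, tr$tip.label)
    out[[paste0(sub("tree_", "", nm), "_clade_split")]] <- has_split(tr, side)
    if (!is.null(tr$node.label))
      out[[paste0(sub("tree_", "", nm), "_clade_support")]] <-
        split_support(tr, side)
  }
  out
}

# one-to-one map from discovered motif ids to planted motif ids by
# majority overlap of hit intervals with planted site intervals
# (KID-local coordinates on family members); a discovered motif whose
# hits do not consistently overlap one planted site (majority share
# below min_share, counting non-overlapping hits) is left unmapped —
# e.g. a conserved background block picked up by discovery
map_motifs_by_overlap <- function(hits, seqs, min_share = 0.6) {
  votes <- list() # votes[[discovered]][planted] = overlap count
  n_hits <- table(hits$motif_id)
  for (i in seq_len(nrow(hits))) {
    e <- seqs[[hits$seq_id[i]]]
    if (is.null(e) || is.null(e$motifs)) next
    tm <- e$motifs
    ov <- pmin(tm$end, hits$end[i]) - pmax(tm$start, hits$start[i])
    if (max(ov) <= 0) next
    p <- tm$planted_id[which.max(ov)]
    d <- hits$motif_id[i]
    votes[[d]] <- c(votes[[d]], p)
  }
  if (!length(votes)) return(NULL)
  tab <- lapply(votes, function(v) sort(table(v), decreasing = TRUE))
  share <- vapply(names(tab), function(d)
    tab[[d]][1] / n_hits[[d]], 0)
  tab <- tab[share >= min_share]
  if (!length(tab)) return(NULL)
  # greedy one-to-one by strongest vote
  pairs <- do.call(rbind, lapply(names(tab), function(d)
    data.frame(d = d, p = names(tab[[d]]), n = as.integer(tab[[d]]),
               stringsAsFactors = FALSE)))
  pairs <- pairs[order(-pairs$n), ]
  map <- character(0)
  used_p <- character(0)
  for (i in seq_len(nrow(pairs))) {
    if (pairs$d[i] %in% names(map) || pairs$p[i] %in% used_p) next
    map[pairs$d[i]] <- pairs$p[i]
    used_p <- c(used_p, pairs$p[i])
  }
  map
}

# agreement[d, p]: fraction of planted consensus columns matched by the
# discovered consensus at the best ungapped offset
motif_agreement_matrix <- function(discovered, planted) {
  a <- matrix(-Inf, length(discovered), length(planted),
              dimnames = list(vapply(discovered, function(m) m$motif_id, ""),
                              names(planted)))
  for (i in seq_along(discovered)) {
    dc <- aa_chars(discovered[[i]]$consensus)
    for (j in seq_along(planted)) {
      pc <- aa_chars(planted[[j]])
      best <- 0
      for (off in (-length(dc) + 1):(length(pc) - 1)) {
        ip <- seq_along(pc)
        id <- ip - off
        ok <- id >= 1 & id <= length(dc)
        if (!any(ok)) next
        best <- max(best, sum(pc[ip[ok]] == dc[id[ok]]) / length(pc))
      }
      a[i, j] <- best
    }
  }
  a
}
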