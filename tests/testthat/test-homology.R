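test_that("profile HMM construction applies Laplace smoothing and the gap rule", {
  msa <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA", s3 = "AAAAAAAAAA",
           s4 = "AAAAAAAAAA")
  hmm <- build_profile_hmm(msa)
  expect_s3_class(hmm, "profile_hmm")
  expect_equal(hmm$length, 10)

  # match column with residues (A,A,A,C): P(A) = (3+1)/(4+20)
  msa2 <- c(s1 = "AC", s2 = "AC", s3 = "AC", s4 = "CC")
  hmm2 <- build_profile_hmm(msa2, pseudocount = 1)
  expect_equal(unname(hmm2$match_emissions[1, "A"]), 4 / 24,
               tolerance = 1e-12)
  expect_equal(unname(hmm2$match_emissions[1, "C"]), 2 / 24,
               tolerance = 1e-12)

  # a column with 3 gaps out of 4 at threshold 0.5 is not a match state
  msa3 <- c(s1 = "A-C", s2 = "A-C", s3 = "A-C", s4 = "AGC")
  hmm3 <- build_profile_hmm(msa3, match_fraction_threshold = 0.5)
  expect_equal(hmm3$length, 2)
  expect_identical(hmm3$match_columns, c(1L, 3L))

  # emission rows and transition triplets are probability vectors
  expect_true(all(abs(rowSums(hmm$match_emissions) - 1) < 1e-9))
  tr <- hmm$transitions
  for (k in 1:(hmm$length)) {
    expect_equal(tr$MM[k] + tr$MI[k] + tr$MD[k], 1, tolerance = 1e-9)
    expect_equal(tr$IM[k] + tr$II[k] + tr$ID[k], 1, tolerance = 1e-9)
    expect_equal(tr$DM[k] + tr$DI[k] + tr$DD[k], 1, tolerance = 1e-9)
  }
  expect_error(build_profile_hmm(c(a = "AC", b = "ACD")), "ragged")
  expect_error(build_profile_hmm(c(a = "--", b = "--", c = "AC", d = "AC")),
               "zero match columns", fixed = FALSE)
})

test_that("forward score equals brute-force path enumeration on toy models", {
  set.seed(42)
  n_checked <- 0
  for (trial in 1:10) {
    nseq <- sample(2:4, 1)
    W <- sample(2:3, 1)
    msa <- vapply(seq_len(nseq), function(i)
      paste(sample(c("A", "C", "D", "E", "-"), W, TRUE,
                   prob = c(.3, .25, .2, .2, .05)), collapse = ""), "")
    msa <- gsub("^-", "A", msa)
    names(msa) <- paste0("s", seq_len(nseq))
    hmm <- tryCatch(build_profile_hmm(msa), error = function(e) NULL)
    if (is.null(hmm)) next
    for (sl in 1:4) {
      s <- paste(sample(c("A", "C", "D", "E", "K"), sl, TRUE), collapse = "")
      expect_equal(forward_score(hmm, s), brute_forward_logodds(hmm, s),
                   tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("an HMM whose emissions equal the background scores 0 bits", {
  msa <- c(s1 = "ACDE", s2 = "ACDE", s3 = "ACDD", s4 = "ACDE")
  hmm <- build_profile_hmm(msa)
  hmm$match_emissions <- matrix(rep(hmm$background, each = hmm$length),
                                hmm$length, 20,
                                dimnames = dimnames(hmm$match_emissions))
  for (s in c("A", "ACDE", "KLMNPQRST"))
    expect_equal(forward_score(hmm, s), 0, tolerance = 1e-9)
  expect_error(forward_score(hmm, ""), "empty")
})

test_that("a planted seed member far outscores its shuffled version", {
  sim <- small_sim()
  seeds <- read_fasta(sim$paths$seeds)
  hmm <- build_profile_hmm(progressive_msa(seeds))
  member <- as.character(seeds[[1]])
  set.seed(9)
  shuffled <- paste(sample(strsplit(member, "")[[1]]), collapse = "")
  expect_gt(forward_score(hmm, member), forward_score(hmm, shuffled) + 100)
})

test_that("Gumbel calibration matches the closed-form moment equations", {
  scores <- 0:99 # known mean 49.5, sd ~29.0
  fit <- kidscape:::fit_gumbel_moments(scores)
  lambda_exp <- pi / (sd(scores) * sqrt(6))
  expect_equal(fit$lambda, lambda_exp, tolerance = 1e-12)
  expect_equal(fit$mu, mean(scores) - 0.5772156649015329 / lambda_exp,
               tolerance = 1e-10)
  expect_error(kidscape:::fit_gumbel_moments(rep(3, 60)), "degenerate")

  # E-value identity at S = mu: E = N * exp(0) would need S = mu exactly
  g <- structure(list(mu = 10, lambda = 0.3, n_calibration = 100),
                 class = "gumbel_params")
  expect_equal(gumbel_evalue(10, g, 500), 500)
  expect_equal(gumbel_evalue(20, g, 500), 500 * exp(-0.3 * 10))
  # monotone decreasing in score
  s <- seq(0, 50, by = 5)
  expect_true(all(diff(gumbel_evalue(s, g, 500)) < 0))
})

test_that("calibration is deterministic given the seed", {
  msa <- c(s1 = "ACDEFG", s2 = "ACDEFG", s3 = "ACDFFG", s4 = "ACDEFG")
  hmm <- build_profile_hmm(msa)
  g1 <- calibrate_evalue(hmm, n_decoys = 60, decoy_length = 30, seed = 5)
  g2 <- calibrate_evalue(hmm, n_decoys = 60, decoy_length = 30, seed = 5)
  expect_identical(g1, g2)
  expect_error(calibrate_evalue(hmm, n_decoys = 10), ">= 50")
})

test_that("proteome search recovers every planted member and no background", {
  sim <- small_sim()
  seeds <- read_fasta(sim$paths$seeds)
  hmm <- build_profile_hmm(progressive_msa(seeds))
  manifest <- read_manifest(sim$paths$manifest)
  hits <- search_proteomes(hmm, manifest, gumbel = NULL, e_threshold = 0.01,
                           calibration_seed = 5)
  ev <- truth_eval(list(hits = hits), sim$truth)
  expect_equal(ev$homolog_sensitivity, 1.0)
  expect_equal(ev$background_false_positives, 0L)
  # sorted ascending by E-value
  expect_true(!is.unsorted(hits$e_value))
  # tightening the threshold never increases the hit count; repeat run is identical
  g <- attr(hits, "gumbel")
  hits_tight <- search_proteomes(hmm, manifest, g, e_threshold = 1e-6)
  expect_lte(nrow(hits_tight), nrow(hits))
  hits2 <- search_proteomes(hmm, manifest, g, e_threshold = 0.01)
  expect_identical(hits$target_id, hits2$target_id)
  expect_error(search_proteomes(hmm, list(), g), "empty manifest")
})

test_that("Smith-Waterman scan matches an independent DP on a toy pair", {
  # linear-gap scheme reproduced via gap_open = 0, gap_extend = 1
  m <- matrix(-1, 24, 24,
              dimnames = list(c(AA20, "B", "X", "Z", "*"),
                              c(AA20, "B", "X", "Z", "*")))
  diag(m) <- 1
  db <- Biostrings::AAStringSet(c(t1 = "PAWHEAE"))
  hits <- local_sw_scan("HEAGAWGHEE", db, substitution_matrix = m,
                        gap_open = 0, gap_extend = 1, e_threshold = Inf,
                        n_decoys = 50, seed = 3)
  expect_equal(hits$score[1],
               brute_sw_linear("HEAGAWGHEE", "PAWHEAE"))
})

test_that("a query searched against itself is the top hit", {
  set.seed(21)
  seqs <- vapply(1:6, function(i)
    paste(sample(AA20, 60, TRUE), collapse = ""), "")
  names(seqs) <- paste0("t", 1:6)
  db <- Biostrings::AAStringSet(seqs)
  hits <- local_sw_scan(seqs[["t3"]], db, e_threshold = Inf,
                        n_decoys = 50, seed = 3)
  expect_identical(hits$target_id[1], "t3")
  expect_equal(max(hits$score), hits$score[1])
  expect_error(local_sw_scan("ACD", Biostrings::AAStringSet()), "empty")
})

test_that("unrelated random databases yield no confident local hits", {
  trials_clean <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    q <- paste(sample(AA20, 50, TRUE), collapse = "")
    db <- Biostrings::AAStringSet(stats::setNames(
      vapply(1:40, function(i) paste(sample(AA20, 80, TRUE), collapse = ""),
             ""), paste0("r", 1:40)))
    hits <- local_sw_scan(q, db, e_threshold = 0.01, n_decoys = 60,
                          seed = s)
    if (nrow(hits) == 0) trials_clean <- trials_clean + 1
  }
  expect_gte(trials_clean, 9) # >= 95% of seeded trials in expectation
})
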