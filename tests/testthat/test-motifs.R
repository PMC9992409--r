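# build a small set of disorder-like sequences with one planted motif each
planted_motif_seqs <- function(n = 8, len = 60, motif = "DWWEKKKRKE",
                               seed = 60) {
  set.seed(seed)
  bgalpha <- c("K", "E", "S", "P", "Q", "G", "T", "N")
  vapply(seq_len(n), function(i) {
    bg <- sample(bgalpha, len, TRUE)
    pos <- sample(len - nchar(motif) + 1, 1)
    bg[pos:(pos + nchar(motif) - 1)] <- strsplit(motif, "")[[1]]
    paste(bg, collapse = "")
  }, "") -> s
  names(s) <- paste0("k", seq_len(n))
  s
}

test_that("OOPS EM recovers a planted motif and is deterministic", {
  seqs <- planted_motif_seqs()
  m1 <- discover_motifs(seqs, n_motifs = 1, width_range = c(8, 11),
                        seed = 7, n_starts = 3)
  m2 <- discover_motifs(seqs, n_motifs = 1, width_range = c(8, 11),
                        seed = 7, n_starts = 3)
  expect_identical(m1[[1]]$pwm, m2[[1]]$pwm)

  # per-column argmax agrees with the planted consensus on >= 80% of columns
  agree <- kidscape:::motif_agreement_matrix(m1, c(M = "DWWEKKKRKE"))
  expect_gte(max(agree), 0.8)

  # EM objective is non-decreasing
  expect_true(all(diff(m1[[1]]$obj_trace) > -1e-8))
  # PWM rows are probability vectors
  expect_true(all(abs(rowSums(m1[[1]]$pwm) - 1) < 1e-9))
})

test_that("discovered motif lists are sorted by the significance proxy", {
  seqs <- planted_motif_seqs(n = 8, len = 80)
  ms <- discover_motifs(seqs, n_motifs = 3, width_range = c(6, 9),
                        seed = 8, n_starts = 2)
  lp <- vapply(ms, function(m) m$log_evalue_proxy, 0)
  expect_true(!is.unsorted(lp))
  expect_identical(vapply(ms, function(m) m$motif_id, ""),
                   c("M1", "M2", "M3"))
  expect_error(discover_motifs(seqs[1:3]), "at least 5")
  expect_error(discover_motifs(c(a = "SHORT", seqs[1:5]),
                               width_range = c(6, 15)), "shorter")
})

test_that("single-occurrence scanning finds a planted site and only one", {
  # near-indicator PWM for KRKR
  pwm <- matrix(0.03 / 19, 4, 20, dimnames = list(NULL, AA20))
  pwm[1, "K"] <- pwm[3, "K"] <- 0.97
  pwm[2, "R"] <- pwm[4, "R"] <- 0.97
  pwm <- pwm / rowSums(pwm)
  motif <- structure(list(motif_id = "M1", width = 4L, pwm = pwm,
                          background = rep(1 / 20, 20)),
                     class = "motif_model")
  s <- paste0(strrep("G", 17), "KRKR", strrep("G", 12))
  hit <- scan_motif(motif, s, seq_id = "x")
  expect_equal(hit$start, 17)
  expect_equal(hit$end, 21)
  expect_equal(nrow(hit), 1)
  # all-glycine sequence: no positive-scoring window
  expect_null(scan_motif(motif, strrep("G", 40)))
})

test_that("best-window score equals a brute-force scan over every offset", {
  set.seed(61)
  pwm <- matrix(stats::runif(6 * 20), 6, 20,
                dimnames = list(NULL, AA20))
  pwm <- pwm / rowSums(pwm)
  bg <- rep(1 / 20, 20)
  motif <- structure(list(motif_id = "M1", width = 6L, pwm = pwm,
                          background = bg), class = "motif_model")
  s <- paste(sample(AA20, 50, TRUE), collapse = "")
  ch <- strsplit(s, "")[[1]]
  brute <- vapply(1:(50 - 6 + 1), function(j) {
    sum(vapply(1:6, function(c)
      log(pwm[c, ch[j + c - 1]] / bg[match(ch[j + c - 1], AA20)]), 0))
  }, 0)
  hit <- scan_motif(motif, s, "x")
  if (max(brute) > 0) {
    expect_equal(hit$score, max(brute), tolerance = 1e-10)
    expect_equal(hit$start, which.max(brute) - 1L)
  } else {
    expect_null(hit)
  }
})

test_that("positional architecture tallies rank-ordered hits", {
  # 5-sequence toy with hand-written hit orders
  hits <- rbind(
    data.frame(motif_id = c("M1", "M2", "M3"), seq_id = "s1",
               start = c(0, 10, 20)),
    data.frame(motif_id = c("M2", "M1", "M3"), seq_id = "s2",
               start = c(0, 10, 20)),
    data.frame(motif_id = c("M1", "M2", "M3"), seq_id = "s3",
               start = c(5, 15, 25)),
    data.frame(motif_id = c("M1", "M3"), seq_id = "s4", start = c(0, 8)),
    data.frame(motif_id = c("M1", "M2", "M3"), seq_id = "s5",
               start = c(2, 4, 6)))
  pm <- positional_architecture(hits, n_positions = 3)
  expect_equal(unname(pm$counts["P1", ]), c(4L, 1L, 0L)) # hand tally
  expect_equal(unname(pm$counts["P2", ]), c(1L, 3L, 1L))
  expect_equal(unname(pm$counts["P3", ]), c(0L, 0L, 4L))
  expect_identical(unname(pm$modal_motif), c("M1", "M2", "M3"))
  # row sums equal the number of sequences with >= p hits
  expect_equal(unname(rowSums(pm$counts)), c(5, 5, 4))
  # a sequence with fewer hits contributes only to its first positions
  expect_equal(sum(pm$counts[, "M2"]), 4)
})

test_that("modal ties break toward the lower motif index", {
  hits <- rbind(data.frame(motif_id = "M2", seq_id = "a", start = 0),
                data.frame(motif_id = "M7", seq_id = "b", start = 0))
  pm <- positional_architecture(hits, n_positions = 1,
                                motif_ids = paste0("M", 1:8))
  expect_identical(unname(pm$modal_motif), "M2")
})

test_that("diagonal motif order gives the identity modal sequence", {
  hits <- do.call(rbind, lapply(paste0("s", 1:6), function(sid)
    data.frame(motif_id = paste0("M", 1:12), seq_id = sid,
               start = seq(0, 110, by = 10))))
  pm <- positional_architecture(hits, n_positions = 12)
  expect_true(all(diag(as.matrix(pm$counts)) == 6))
  expect_identical(unname(pm$modal_motif), paste0("M", 1:12))
})

test_that("NLS patterns match classical signals and reject neutral sequence", {
  # monopartite signal in a neutral context
  h <- scan_nls(paste0("GGGGGT", "PKKKRKV", "TGGGGG"), seq_id = "x")
  expect_true(any(grepl("Mono", h$class_name)))
  mono <- h[grepl("Mono", h$class_name), ]
  expect_true(any(mono$start >= 6 & mono$end <= 13))
  # matched_text equals the residue slice
  s <- paste0("GGGGGT", "PKKKRKV", "TGGGGG")
  for (i in seq_len(nrow(h)))
    expect_identical(h$matched_text[i],
                     substr(s, h$start[i] + 1, h$end[i]))
  # poly-alanine: nothing
  expect_equal(nrow(scan_nls(strrep("A", 60))), 0)
  # bipartite: KR + 10 neutral + KKRK
  hb <- scan_nls(paste0("GGG", "KR", strrep("G", 10), "KKRK", "GGG"))
  expect_true("TRG_NLS_Bipartite_1" %in% hb$class_name)
  bp <- hb[hb$class_name == "TRG_NLS_Bipartite_1", ][1, ]
  expect_lte(bp$start, 3)
  expect_gte(bp$end, 18)
})

test_that("malformed user pattern files are rejected", {
  f <- tempfile()
  writeLines(c("class_name\tpattern", "bad\t[KR{"), f)
  expect_error(nls_patterns(f), "malformed")
  f2 <- tempfile()
  writeLines("foo\tbar", f2)
  expect_error(nls_patterns(f2), "columns")
})

test_that("motif/NLS overlap counts non-empty intersections once per sequence", {
  mh <- data.frame(motif_id = c("M1", "M2", "M1", "M2"),
                   seq_id = c("a", "a", "b", "b"),
                   start = c(0, 20, 0, 20), end = c(10, 30, 10, 30))
  # disjoint
  nh0 <- data.frame(seq_id = c("a", "b"), start = c(50, 50),
                    end = c(55, 55))
  ov0 <- motif_nls_overlap(mh, nh0)
  expect_true(all(ov0$fraction == 0))
  # identical intervals overlap, counted once per sequence
  nh1 <- data.frame(seq_id = c("a", "b"), start = c(20, 20),
                    end = c(30, 30))
  ov1 <- motif_nls_overlap(mh, nh1)
  expect_equal(ov1$fraction[ov1$motif_id == "M2"], 1)
  expect_equal(ov1$fraction[ov1$motif_id == "M1"], 0)
})

test_that("planted NLS lie inside the second/third motif analogs", {
  sim <- small_sim()
  seqs <- sim_all_seqs(sim)
  fam <- sim_ids_with_label(sim, "family_member")
  tr <- sim$truth$sequences
  kid_seqs <- vapply(fam, function(id)
    substr(seqs[[id]], tr[[id]]$kid_start + 1, tr[[id]]$kid_end), "")
  nls <- scan_nls_many(kid_seqs)
  ev <- truth_eval(list(nls_hits = nls), sim$truth)
  expect_gte(ev$nls_recall, 0.9)
  # planted motif order is recorded and NLS sit inside motif instances
  for (id in fam[1:3]) {
    tn <- tr[[id]]$nls
    tm <- tr[[id]]$motifs
    for (i in seq_len(nrow(tn))) {
      host <- tm[tm$planted_id == tn$in_motif[i], ]
      expect_gte(tn$start[i], host$start)
      expect_lte(tn$end[i], host$end)
    }
  }
})
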