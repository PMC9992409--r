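test_that("all five anchors are found on a canonical kinase at planted positions", {
  s <- toy_canonical_kinase()
  anc <- find_subdomain_anchors(s)
  expect_identical(anc$key, c("gloop", "vaik", "hxd", "dfg", "ape"))
  expect_identical(anc$start, c(10L, 30L, 120L, 145L, 173L))
  expect_identical(anc$matched_text[anc$key == "dfg"], "DFG")
  # anchors are strictly increasing and non-overlapping
  expect_true(all(diff(anc$start) > 0))
  expect_true(all(utils::head(anc$end, -1) <= utils::tail(anc$start, -1)))
})

test_that("a featureless sequence yields an empty anchor set, not an error", {
  anc <- find_subdomain_anchors(strrep("A", 200))
  expect_equal(nrow(anc), 0)
})

test_that("spacing deviation disambiguates between two DFG occurrences", {
  # a second DFG close after HxD but at non-canonical spacing (5) must lose
  # to the one at canonical spacing (25)
  set.seed(401)
  pad <- function(n) paste(sample(c("T", "S", "N", "Q", "M", "C", "Y", "W"),
                                  n, TRUE), collapse = "")
  s <- paste0(pad(10), "GEGSFG", pad(14), "AIK", pad(87), "HRD",
              pad(2), "DFG", pad(17), "DFG", pad(25), "APE", pad(40))
  anc <- find_subdomain_anchors(s)
  expect_equal(anc$start[anc$key == "dfg"], 145L)
})

test_that("KID delineation separates canonical segments from long inserts", {
  s <- toy_canonical_kinase() # 25-residue activation segment
  anc <- find_subdomain_anchors(s)
  kid <- delineate_kid(anc, s, seq_id = "toy")
  expect_identical(kid$status, "determined")
  expect_equal(kid$kid_length, 25)
  expect_false(kid$is_kid)

  # degenerate: DFG immediately followed by APE
  set.seed(402)
  pad <- function(n) paste(sample(c("T", "S", "N", "Q", "M", "C", "Y", "W"),
                                  n, TRUE), collapse = "")
  s0 <- paste0(pad(10), "GEGSFG", pad(14), "AIK", pad(87), "HRD",
               pad(22), "DFG", "APE", pad(60))
  anc0 <- find_subdomain_anchors(s0)
  kid0 <- delineate_kid(anc0, s0)
  expect_equal(kid0$kid_length, 0)
  expect_false(kid0$is_kid)

  # missing anchors: undetermined, never a crash
  kidNA <- delineate_kid(find_subdomain_anchors(strrep("A", 150)),
                         strrep("A", 150))
  expect_identical(kidNA$status, "undetermined")
  expect_true(is.na(kidNA$is_kid))
})

test_that("KID boundaries are exact on planted members at zero anchor mutation", {
  sim <- small_sim()
  seqs <- sim_all_seqs(sim)
  fam <- sim_ids_with_label(sim, "family_member")
  rows <- lapply(fam, function(id) {
    anc <- find_subdomain_anchors(seqs[[id]])
    k <- delineate_kid(anc, seqs[[id]], seq_id = id)
    data.frame(seq_id = id, kid_start = k$kid_start, kid_end = k$kid_end,
               is_kid = k$is_kid)
  })
  ev <- truth_eval(list(kid_table = do.call(rbind, rows)), sim$truth)
  expect_equal(ev$kid_exact, 1.0)
})

test_that("is_kid is monotone in kid_min_length", {
  sim <- small_sim()
  seqs <- sim_all_seqs(sim)
  id <- sim_ids_with_label(sim, "family_member")[1]
  anc <- find_subdomain_anchors(seqs[[id]])
  thresholds <- c(20, 80, 150, 220, 600)
  calls <- vapply(thresholds, function(th)
    delineate_kid(anc, seqs[[id]], kid_min_length = th)$is_kid, TRUE)
  # once FALSE at a low threshold, never TRUE at a higher one
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("hydropathy TM prediction finds a planted hydrophobic block", {
  set.seed(403)
  charged <- function(n) paste(sample(c("K", "E", "R", "D", "S", "Q"),
                                      n, TRUE), collapse = "")
  s <- paste0(charged(30), strrep("L", 25), charged(40))
  tm <- predict_tm(s)
  expect_equal(nrow(tm), 1)
  # the predicted segment covers the core of the planted block (30..55)
  expect_lte(tm$start, 35)
  expect_gte(tm$end, 50)
  expect_gte(tm$end - tm$start, 15)
  expect_lte(tm$end - tm$start, 30)

  # all-lysine: nothing
  expect_equal(nrow(predict_tm(strrep("K", 100))), 0)
  # shorter than the window: empty with warning
  expect_warning(res <- predict_tm("ACDEF"), "shorter")
  expect_equal(nrow(res), 0)
})

test_that("window-mean hydropathy matches a hand sum of scale values", {
  s <- paste0(strrep("K", 9), "I", strrep("K", 9)) # 19-mer
  kd <- kidscape:::KD_SCALE
  hand <- (18 * kd[["K"]] + kd[["I"]]) / 19
  means <- stats::filter(kd[strsplit(s, "")[[1]]], rep(1 / 19, 19),
                         sides = 2)
  expect_equal(as.numeric(means[10]), hand, tolerance = 1e-12)
  expect_lt(hand, 1.6) # correctly below the TM threshold
})

test_that("architecture classification reads RD status and the family rule", {
  s <- toy_canonical_kinase()
  anc <- find_subdomain_anchors(s)
  kid <- delineate_kid(anc, s)
  arch <- classify_architecture(s, anc, kid, predict_tm(s), "toy")
  expect_identical(arch$rd_status, "RD") # HRD catalytic loop
  expect_true(arch$has_all_subdomains)
  expect_false(arch$is_family_like)     # canonical segment, no KID

  # HGD variant is non-RD
  s2 <- sub("HRD", "HGD", s, fixed = TRUE)
  anc2 <- find_subdomain_anchors(s2)
  arch2 <- classify_architecture(s2, anc2, delineate_kid(anc2, s2),
                                 predict_tm(s2), "toy2")
  expect_identical(arch2$rd_status, "non-RD")
})

test_that("planted members classify family-like; decoys never do", {
  sim <- small_sim()
  seqs <- sim_all_seqs(sim)
  fam <- sim_ids_with_label(sim, "family_member")
  dec <- sim_ids_with_label(sim, "decoy_kinase")
  ann <- annotate_architectures(c(seqs[fam], seqs[dec[1:6]]))
  tab <- ann$table
  expect_true(all(tab$is_family_like[tab$seq_id %in% fam]))
  expect_false(any(tab$is_family_like[tab$seq_id %in% dec]))
  # decoys carry a canonical activation segment
  expect_true(all(tab$kid_length[tab$seq_id %in% dec] <= 35))
})
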