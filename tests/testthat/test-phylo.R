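test_that("global alignment matches exhaustive enumeration on a toy pair", {
  # match +1 / mismatch -1 / linear gap -1: AAG vs AG -> +1 (AAG / A-G)
  m <- matrix(-1, 24, 24,
              dimnames = list(c(AA20, "B", "X", "Z", "*"),
                              c(AA20, "B", "X", "Z", "*")))
  diag(m) <- 1
  pa <- pairwise_align("AAG", "AG", matrix = m, gap_open = 0,
                       gap_extend = 1)
  expect_equal(pa$score, 1)
  # identical sequences: identity 100, score = sum of diagonal values
  pb <- pairwise_align("ACDE", "ACDE")
  expect_equal(pb$percent_identity, 100)
  B62 <- kidscape:::blosum62()
  expect_equal(pb$score, sum(diag(B62[c("A", "C", "D", "E"),
                                      c("A", "C", "D", "E")])))
  # score symmetric in argument order
  set.seed(70)
  x <- paste(sample(AA20, 30, TRUE), collapse = "")
  y <- paste(sample(AA20, 25, TRUE), collapse = "")
  expect_equal(pairwise_align(x, y)$score, pairwise_align(y, x)$score)
})

test_that("representative selection maximizes similarity to the reference", {
  ref <- "MKKLLVVAADDEEFFGGHHIIKK"
  fam <- c(zeta = "MKKLLVVAADDEEFFGGHHIIKK",   # identical
           beta = "MKKLLVVAADDEEFFGGHHIWWW",
           alpha = "WWWWWWWWWWWWWWWWWWWWWWW")
  expect_identical(pick_representative(fam, ref), "zeta")
  expect_identical(pick_representative(fam["beta"], ref), "beta")
  # ties break toward the lexicographically smaller id
  fam2 <- c(delta = "ACDEFG", carol = "ACDEFG")
  expect_identical(pick_representative(fam2, "ACDEFG"), "carol")
  expect_error(pick_representative(character(0), ref), "empty")
})

test_that("progressive alignment preserves content and handles indels", {
  # identical pair: gap-free
  m <- progressive_msa(c(a = "ACDEFGHIK", b = "ACDEFGHIK"))
  expect_false(any(grepl("-", m)))
  # degapping recovers every input
  set.seed(71)
  base <- paste(sample(AA20, 40, TRUE), collapse = "")
  seqs <- c(s1 = base,
            s2 = paste0(substr(base, 1, 20), substr(base, 24, 40)),
            s3 = base)
  msa <- progressive_msa(seqs)
  for (id in names(seqs))
    expect_identical(gsub("-", "", msa[[id]]), seqs[[id]])
  expect_equal(length(unique(nchar(msa))), 1)
  expect_gte(nchar(msa[[1]]), max(nchar(seqs)))
  # a single 3-residue deletion appears as gap columns in the deleted row
  expect_equal(sum(strsplit(msa[["s2"]], "")[[1]] == "-"), 3)
  expect_error(progressive_msa(c(a = "ACD")), "at least 2")
})

test_that("neighbor joining solves the three-point formulas", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 1)
  expect_equal(unname(bl["B"]), 1)
  expect_equal(unname(bl["C"]), 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d2 <- d; d2[1, 2] <- 5
  expect_error(nj_tree(d2), "non-symmetric")
})

test_that("NJ recovers additive trees exactly", {
  # distances built from a known 5-taxon tree:
  # ((A:1,B:2):1,(C:3,D:1):2,E:4)
  leaves <- c(A = 1, B = 2, C = 3, D = 1, E = 4)
  path <- function(i, j) {
    # hand-computed path lengths on that topology
    P <- matrix(0, 5, 5, dimnames = list(names(leaves), names(leaves)))
    P["A", "B"] <- 1 + 2
    P["A", "C"] <- 1 + 1 + 2 + 3; P["B", "C"] <- 2 + 1 + 2 + 3
    P["A", "D"] <- 1 + 1 + 2 + 1; P["B", "D"] <- 2 + 1 + 2 + 1
    P["C", "D"] <- 3 + 1
    P["A", "E"] <- 1 + 1 + 4; P["B", "E"] <- 2 + 1 + 4
    P["C", "E"] <- 3 + 2 + 4; P["D", "E"] <- 1 + 2 + 4
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
    P[i, j]
  }
  D <- outer(names(leaves), names(leaves), Vectorize(path))
  dimnames(D) <- list(names(leaves), names(leaves))
  tr <- nj_tree(D)
  # recovered tree distances equal the additive input distances
  ct <- ape::cophenetic.phylo(tr)[names(leaves), names(leaves)]
  expect_equal(unname(ct), unname(D), tolerance = 1e-10)
  expect_true(has_split(tr, c("A", "B")))
  expect_true(has_split(tr, c("C", "D")))
})

test_that("NJ topology is invariant to taxon order", {
  set.seed(72)
  base <- paste(sample(AA20, 60, TRUE), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(AA20, k, TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(a = mut(base, 3), b = mut(base, 3), c = mut(base, 25),
            d = mut(base, 25), e = mut(base, 40))
  msa <- progressive_msa(seqs)
  d1 <- msa_distance(msa)
  perm <- c("e", "c", "a", "d", "b")
  d2 <- d1[perm, perm]
  t1 <- suppressWarnings(nj_tree(d1))
  t2 <- suppressWarnings(nj_tree(d2))
  expect_equal(as.numeric(phangorn::RF.dist(t1, t2)), 0)
})

test_that("distance matrices are symmetric with zero diagonal", {
  sim <- small_sim()
  seeds <- read_fasta(sim$paths$seeds)
  msa <- progressive_msa(seeds)
  d <- msa_distance(msa)
  expect_equal(max(abs(d - t(d))), 0, tolerance = 1e-12)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
})

test_that("bootstrap supports are deterministic integers in [0, 100]", {
  set.seed(73)
  base <- paste(sample(AA20, 80, TRUE), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(AA20, k, TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(a = mut(base, 2), b = mut(base, 2),
            c = mut(base, 30), d = mut(base, 30),
            e = mut(base, 31), f = mut(base, 31))
  msa <- progressive_msa(seqs)
  t1 <- bootstrap_support(msa, n_replicates = 50, seed = 4)
  t2 <- bootstrap_support(msa, n_replicates = 50, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.integer(t1$node.label[t1$node.label != ""]))
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_support(structure(c(a = "AC", b = "AC", c = "AC"),
                                           class = "msa")), "at least 4")
})

test_that("topology comparison: identity, one NNI, symmetry", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(compare_topologies(t1, t1)$rf_distance, 0)
  # one nearest-neighbor interchange on 5 taxa (C/E swap around the
  # CD cherry) changes exactly one bipartition -> RF 2
  t2 <- ape::read.tree(text = "((A,B),(C,E),D);")
  cmp <- compare_topologies(t1, t2)
  expect_equal(cmp$rf_distance, 2)
  expect_equal(cmp$n_shared_bipartitions, 1)
  expect_equal(compare_topologies(t2, t1)$rf_distance, cmp$rf_distance)
  expect_error(compare_topologies(t1, ape::read.tree(text = "((A,B),(C,F),E);")),
               "leaf sets")
  # RF triangle inequality on a sampled triple
  t3 <- ape::read.tree(text = "((A,D),(B,C),E);")
  r12 <- compare_topologies(t1, t2)$rf_distance
  r23 <- compare_topologies(t2, t3)$rf_distance
  r13 <- compare_topologies(t1, t3)$rf_distance
  expect_lte(r13, r12 + r23)
})

test_that("clade labelling reports the planted split", {
  t1 <- ape::read.tree(text = "(((A,B),C),((D,E),F));")
  clades <- stats::setNames(c("one", "one", "one", "two", "two", "two"),
                            c("A", "B", "C", "D", "E", "F"))
  cmp <- compare_topologies(t1, t1, clades = clades)
  expect_true(cmp$clade_split_in_1)
  expect_true(cmp$clade_split_in_2)
  expect_false(has_split(t1, c("A", "D")))
})
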