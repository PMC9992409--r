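#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-style global alignment (BLOSUM62 by default) used both
#' for representative selection and as a building block elsewhere.
#'
#' @param a,b Residue strings or single-element `AAStringSet`s.
#' @param matrix Substitution matrix name known to Biostrings, or a
#'   numeric matrix.
#' @param gap_open,gap_extend Positive penalties.
#' @return List `score`, `aligned_a`, `aligned_b`, `percent_identity`
#'   (matches over alignment columns, in percent).
#' @export
pairwise_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 1) {
  sa <- as.character(a)[1]; sb <- as.character(b)[1]
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "global",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- aa_chars(al_a); cb <- aa_chars(al_b)
  pid <- 100 * sum(ca == cb & ca != "-") / length(ca)
  list(score = Biostrings::score(pa), aligned_a = al_a, aligned_b = al_b,
       percent_identity = pid)
}

#' Choose a family representative by similarity to a reference
#'
#' The member with the highest global alignment score against the
#' reference; ties break toward the lexicographically smallest id.
#'
#' @param family Named `AAStringSet` / character vector.
#' @param reference Residue string / single-element set.
#' @param ... Passed to [pairwise_align()].
#' @return The id of the chosen member.
#' @export
pick_representative <- function(family, reference, ...) {
  res <- as_named_chr(family)
  if (!length(res)) stop("empty family")
  scores <- vapply(res, function(s)
    pairwise_align(s, reference, ...)$score, 0)
  ord <- order(-scores, names(res))
  names(res)[ord[1]]
}

# k-mer (default 3) dissimilarity used for the guide tree
kmer_distance <- function(res, k = 3) {
  sets <- lapply(res, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(res)
  d <- matrix(0, n, n, dimnames = list(names(res), names(res)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    denom <- min(length(sets[[i]]), length(sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - if (denom) shared / denom else 0
  }
  d
}

profile_from_rows <- function(rows) {
  # rows: character matrix (sequences x columns) with '-' gaps
  L <- ncol(rows)
  p <- matrix(0, 20, L)
  for (j in seq_len(L)) {
    cnt <- table(factor(rows[, j][rows[, j] %in% AA20], levels = AA20))
    p[, j] <- as.numeric(cnt) / nrow(rows)
  }
  p
}

#' Progressive multiple sequence alignment
#'
#' Guide tree by average-linkage clustering on k-mer dissimilarity;
#' profiles merged bottom-up by global affine-gap profile-profile
#' alignment (BLOSUM62 expected column score). Column count is at least
#' the longest input and degapping any row recovers its input sequence.
#'
#' @param seqs Named `AAStringSet` / character vector (>= 2).
#' @param gap_open,gap_extend Positive penalties for the profile
#'   alignment.
#' @return Named character vector of aligned rows (equal width), class
#'   `msa`.
#' @export
progressive_msa <- function(seqs, gap_open = 10, gap_extend = 0.5) {
  res <- as_named_chr(seqs)
  if (length(res) < 2) stop("need at least 2 sequences")
  ids <- names(res)
  S <- blosum62()
  if (length(res) == 2) {
    pa <- pairwise_align(res[[1]], res[[2]])
    out <- c(pa$aligned_a, pa$aligned_b)
    names(out) <- ids
    return(structure(out, class = "msa"))
  }
  d <- kmer_distance(res)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # each node holds a character matrix of aligned rows
  leaves <- lapply(ids, function(id)
    matrix(aa_chars(res[[id]]), nrow = 1, dimnames = list(id, NULL)))
  nodes <- vector("list", nrow(hc$merge))
  get_node <- function(i) if (i < 0) leaves[[-i]] else nodes[[i]]
  for (m in seq_len(nrow(hc$merge))) {
    A <- get_node(hc$merge[m, 1]); B <- get_node(hc$merge[m, 2])
    pa <- cpp_profile_align(profile_from_rows(A), profile_from_rows(B), S,
                            gap_open, gap_extend)
    W <- length(pa$path_a)
    newA <- matrix("-", nrow(A), W, dimnames = list(rownames(A), NULL))
    newA[, pa$path_a > 0] <- A[, pa$path_a[pa$path_a > 0], drop = FALSE]
    newB <- matrix("-", nrow(B), W, dimnames = list(rownames(B), NULL))
    newB[, pa$path_b > 0] <- B[, pa$path_b[pa$path_b > 0], drop = FALSE]
    nodes[[m]] <- rbind(newA, newB)
  }
  final <- nodes[[nrow(hc$merge)]]
  out <- apply(final[ids, , drop = FALSE], 1, paste, collapse = "")
  structure(out, class = "msa")
}

#' Pairwise distances from a multiple alignment
#'
#' Normalized substitution-score distance (scoredist-style): for each row
#' pair, the BLOSUM62 score over mutually ungapped columns is normalized
#' between the expected random score and the mean self-score, and the
#' distance is `-log` of that normalized similarity. Values are symmetric,
#' zero on the diagonal and clamped to a large finite ceiling for
#' score-floor pairs.
#'
#' @param msa `msa` object or named character vector of equal-width rows.
#' @param columns Optional column index vector (1-based) for bootstrap
#'   resampling.
#' @return Object of class `dist_matrix`: symmetric numeric matrix with
#'   labels.
#' @export
msa_distance <- function(msa, columns = NULL) {
  rows <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  rownames(rows) <- names(msa)
  if (!is.null(columns)) rows <- rows[, columns, drop = FALSE]
  S <- blosum62()
  n <- nrow(rows)
  enc <- matrix(match(rows, AA20), n, ncol(rows))
  d <- matrix(0, n, n, dimnames = list(rownames(rows), rownames(rows)))
  self <- vapply(seq_len(n), function(i) {
    v <- enc[i, ]; v <- v[!is.na(v)]
    sum(S[cbind(v, v)])
  }, 0)
  # expected random score per column pair under the matrix's background
  bgs <- mean(S)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
    L <- sum(ok)
    if (L == 0) { d[i, j] <- d[j, i] <- 5; next }
    sobs <- sum(S[cbind(enc[i, ok], enc[j, ok])])
    srand <- L * bgs
    smax <- (self[i] / sum(!is.na(enc[i, ])) +
             self[j] / sum(!is.na(enc[j, ]))) / 2 * L
    sim <- (sobs - srand) / (smax - srand)
    d[i, j] <- d[j, i] <- if (sim <= 0.01) 5 else min(5, -log(sim))
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining; negative branch lengths are clamped to
#' zero with a warning.
#'
#' @param d `dist_matrix` or symmetric numeric matrix with labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- unclass(d)
  if (nrow(m) < 3) stop("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8) stop("non-symmetric distance matrix")
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for an alignment-derived NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing the same bipartition. Deterministic
#' given `seed`.
#'
#' @param msa `msa` object.
#' @param n_replicates Bootstrap replicates (display conventions in the
#'   field use 1000; tests use 100).
#' @param seed Integer seed.
#' @return The original NJ tree with integer `node.label` supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1) {
  if (length(msa) < 4) stop("need at least 4 rows for bootstrap support")
  W <- nchar(msa[[1]])
  tr <- nj_tree(msa_distance(msa))
  reps <- withr_seed(local_rng(seed), function() {
    lapply(seq_len(n_replicates), function(i) {
      cols <- sample.int(W, W, replace = TRUE)
      suppressWarnings(nj_tree(msa_distance(msa, columns = cols)))
    })
  })
  cnt <- ape::prop.clades(tr, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- as.integer(round(100 * cnt / n_replicates))
  tr$node.label <- as.character(support)
  tr$node.label[1] <- "" # root of the unrooted representation
  tr
}

#' Compare two tree topologies
#'
#' Robinson-Foulds distance, shared/unique non-trivial bipartitions, and
#' (optionally) whether each tree contains the bipartition separating a
#' given two-clade leaf labelling.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @param clades Optional named vector mapping every leaf to one of two
#'   clade labels.
#' @return List `rf_distance`, `n_shared_bipartitions`,
#'   `n_bipartitions_1`, `n_bipartitions_2`, and, with `clades`,
#'   `clade_split_in_1`, `clade_split_in_2`.
#' @export
compare_topologies <- function(t1, t2, clades = NULL) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  rf <- phangorn::RF.dist(t1, t2)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  shared <- sum(b1 %in% b2)
  out <- list(rf_distance = as.numeric(rf),
              n_shared_bipartitions = shared,
              n_bipartitions_1 = length(b1), n_bipartitions_2 = length(b2))
  if (!is.null(clades)) {
    out$clade_split_in_1 <- has_split(t1, names(clades)[clades == unique(clades)[1]])
    out$clade_split_in_2 <- has_split(t2, names(clades)[clades == unique(clades)[1]])
  }
  out
}

# canonical string form of each non-trivial bipartition of an unrooted tree
tree_bipartitions <- function(tr) {
  tips <- sort(tr$tip.label)
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    other <- setdiff(tips, side)
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

#' Does a tree contain the bipartition separating a leaf set?
#' @param tr `phylo` tree.
#' @param leafset Character vector of tip labels on one side.
#' @return TRUE/FALSE.
#' @export
has_split <- function(tr, leafset) {
  tips <- sort(tr$tip.label)
  side <- sort(intersect(leafset, tips))
  if (!length(side) || length(side) >= length(tips)) return(FALSE)
  if (length(side) == 1 || length(side) == length(tips) - 1) return(TRUE)
  other <- setdiff(tips, side)
  key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
    paste(side, collapse = ",") else paste(other, collapse = ",")
  key %in% tree_bipartitions(tr)
}

#' Bootstrap support of the edge separating a leaf set
#'
#' @param tr Tree with `node.label` supports from [bootstrap_support()].
#' @param leafset Tip labels on one side of the split.
#' @return Integer support in `[0, 100]`, or NA if the tree does not
#'   contain that split.
#' @export
split_support <- function(tr, leafset) {
  side <- intersect(leafset, tr$tip.label)
  if (!has_split(tr, side)) return(NA_integer_)
  n_tip <- length(tr$tip.label)
  tipidx <- match(side, tr$tip.label)
  # find the internal node whose descendant tip set equals side (or its
  # complement)
  for (node in (n_tip + 1):(n_tip + tr$Nnode)) {
    desc <- tip_descendants(tr, node)
    if (setequal(desc, tipidx) || setequal(desc, setdiff(seq_len(n_tip), tipidx))) {
      lab <- tr$node.label[node - n_tip]
      return(if (nzchar(lab)) as.integer(lab) else NA_integer_)
    }
  }
  NA_integer_
}

tip_descendants <- function(tr, node) {
  n_tip <- length(tr$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tr$edge[tr$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}
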