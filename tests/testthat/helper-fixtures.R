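# Shared fixtures: tiny synthetic datasets and toy models, built in code.

AA20 <- kidscape:::AA20

# small dataset used by most end-to-end unit tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 101, n_species = 4,
                              n_decoy_kinases = 3, n_background = 20)
      cache <<- simulate_dataset(cfg, file.path(tempdir(), "kidscape_sim_small"))
    }
    cache
  }
})

# all sequences of a simulated dataset as one named character vector
sim_all_seqs <- function(sim) {
  do.call(c, lapply(sim$manifest$fasta_path, function(p) {
    x <- read_fasta(p)
    stats::setNames(as.character(x), names(x))
  }))
}

sim_ids_with_label <- function(sim, label) {
  t <- sim$truth$sequences
  names(t)[vapply(t, function(e) e$label == label, TRUE)]
}

# brute-force path enumeration over the same profile-HMM state machine,
# independent of the C++ forward implementation
brute_forward_loglik <- function(hmm, idx, null = FALSE) {
  L <- hmm$length
  me <- if (null) matrix(rep(hmm$background, each = L), L, 20)
        else hmm$match_emissions
  ie <- if (null) hmm$background else hmm$insert_emissions
  tr <- hmm$transitions
  n <- length(idx)
  emit <- function(type, k, a) {
    if (a < 0) return(1)
    if (type == "M") me[k, a + 1] else ie[a + 1]
  }
  val <- function(type, k, i) {
    j <- k + 1
    succ <- if (type == "M") {
      if (k < L) list(c("M", k + 1, tr$MM[j]), c("I", k, tr$MI[j]),
                      c("D", k + 1, tr$MD[j]))
      else list(c("E", 0, tr$MM[j]), c("I", k, tr$MI[j]))
    } else if (type == "I") {
      if (k < L) list(c("M", k + 1, tr$IM[j]), c("I", k, tr$II[j]),
                      c("D", k + 1, tr$ID[j]))
      else list(c("E", 0, tr$IM[j]), c("I", k, tr$II[j]))
    } else {
      if (k < L) list(c("M", k + 1, tr$DM[j]), c("I", k, tr$DI[j]),
                      c("D", k + 1, tr$DD[j]))
      else list(c("E", 0, tr$DM[j]), c("I", k, tr$DI[j]))
    }
    tot <- 0
    for (s in succ) {
      ty <- s[1]; kk <- as.integer(s[2]); p <- as.numeric(s[3])
      if (p == 0) next
      if (ty == "E") { if (i == n) tot <- tot + p }
      else if (ty == "D") tot <- tot + p * val("D", kk, i)
      else if (i < n) tot <- tot + p * emit(ty, kk, idx[i + 1]) * val(ty, kk, i + 1)
    }
    tot
  }
  log(val("M", 0, 0))
}

brute_forward_logodds <- function(hmm, res) {
  idx <- kidscape:::aa_index0(res)
  unname((brute_forward_loglik(hmm, idx) -
            brute_forward_loglik(hmm, idx, null = TRUE)) / log(2))
}

# independent affine-free Smith-Waterman DP (linear gap penalties), used
# as the oracle for local alignment scores under a simple scheme
brute_sw_linear <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  H <- matrix(0, length(ca) + 1, length(cb) + 1)
  best <- 0
  for (i in seq_along(ca)) for (j in seq_along(cb)) {
    s <- if (ca[i] == cb[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                           H[i + 1, j] + gap)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# canonical kinase-like toy sequence with known anchor positions (0-based)
toy_canonical_kinase <- function() {
  set.seed(400)
  pad <- function(n) paste(sample(c("T", "S", "N", "Q", "M", "C", "Y", "W"),
                                  n, TRUE), collapse = "")
  paste0(pad(10),                # 0..9
         "GEGSFG",               # gloop at 10
         pad(14),                # 16..29
         "AIK",                  # vaik at 30
         pad(87),                # 33..119
         "HRD",                  # hxd at 120
         pad(22),                # 123..144
         "DFG",                  # dfg at 145
         pad(25),                # canonical activation segment
         "APE",                  # ape at 173
         pad(60))
}
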