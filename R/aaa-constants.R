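# 20-letter amino-acid alphabet used throughout (column order of all
# emission/frequency matrices)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
              H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
              P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
              W = -0.9, Y = -1.3)

# Per-residue disorder propensity (TOP-IDP-style ordering: aromatics and
# branched hydrophobics order-promoting, P/E/S/Q/K disorder-promoting)
DISORDER_SCALE <- c(A = 0.060, C = 0.020, D = 0.192, E = 0.736, F = -0.697,
                    G = 0.166, H = 0.303, I = -0.486, K = 0.586, L = -0.326,
                    M = -0.397, N = 0.007, P = 0.987, Q = 0.318, R = 0.180,
                    S = 0.341, T = 0.059, V = -0.121, W = -0.884, Y = -0.510)

# Map residues to 0-based indices into AA20; X and anything else -> NA
aa_index0 <- function(residues) {
  idx <- match(strsplit(residues, "", fixed = TRUE)[[1]], AA20) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

# split a residue string into a character vector
aa_chars <- function(residues) strsplit(residues, "", fixed = TRUE)[[1]]

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA20, AA20]
    }
    cache
  }
})

# coerce a sequence container to a named character vector, keeping names
# (as.character drops them for plain character vectors)
as_named_chr <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  if (is.null(names(out))) names(out) <- nm
  out
}
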