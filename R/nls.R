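# Nuclear localization signal scanning.
#
# The four shipped pattern classes approximate the classical monopartite
# (core, N-extended, C-extended) and bipartite basic NLS classes; they are
# editable data, not ground truth, and users may substitute their own
# pattern table (e.g. exact externally versioned class definitions).

#' Load NLS pattern classes
#'
#' @param path Optional TSV with columns `class_name`, `pattern`
#'   (Perl-compatible regular expressions over the amino-acid alphabet);
#'   default: the four shipped classes.
#' @return data.frame `class_name`, `pattern`.
#' @export
nls_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nls_patterns.tsv", package = "kidscape")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("class_name", "pattern") %in% names(df)))
    stop("NLS pattern file must have columns class_name, pattern")
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ grepl(df$pattern[i], "KKRK", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("malformed NLS pattern for class ", df$class_name[i],
                  ": ", df$pattern[i])
  }
  df[, c("class_name", "pattern")]
}

#' Scan a sequence for nuclear localization signals
#'
#' Matches every pattern class against the sequence; matches of different
#' classes may overlap and are all reported.
#'
#' @param seq Residue string or single-element `AAStringSet`.
#' @param classes Pattern table from [nls_patterns()] (default: shipped).
#' @param seq_id Identifier recorded in the hits.
#' @return data.frame `class_name`, `seq_id`, `start`, `end` (0-based
#'   half-open), `matched_text`; zero rows when nothing matches.
#' @export
scan_nls <- function(seq, classes = nls_patterns(), seq_id = NA_character_) {
  res <- as.character(seq)[1]
  rows <- list()
  for (i in seq_len(nrow(classes))) {
    m <- gregexpr(classes$pattern[i], res, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    rows[[length(rows) + 1]] <- data.frame(
      class_name = classes$class_name[i], seq_id = seq_id,
      start = starts, end = starts + lens,
      matched_text = substring(res, starts + 1L, starts + lens),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(class_name = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      matched_text = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$class_name), ]
  rownames(out) <- NULL
  out
}

#' Scan an NLS pattern set over many sequences
#' @param seqs Named `AAStringSet` / character vector.
#' @param classes Pattern table.
#' @return data.frame of hits over all sequences.
#' @export
scan_nls_many <- function(seqs, classes = nls_patterns()) {
  res <- as_named_chr(seqs)
  out <- do.call(rbind, lapply(names(res), function(id)
    scan_nls(res[[id]], classes, seq_id = id)))
  if (is.null(out)) scan_nls("AAAA", classes, seq_id = NA)[0, ] else out
}

#' Overlap between motif occurrences and NLS hits
#'
#' For each motif, the number and fraction of sequences in which its
#' single occurrence intersects at least one NLS hit (non-empty interval
#' intersection on the same sequence).
#'
#' @param motif_hits data.frame `motif_id`, `seq_id`, `start`, `end`.
#' @param nls_hits data.frame `seq_id`, `start`, `end`.
#' @return data.frame `motif_id`, `n_sequences_with_overlapping_NLS`,
#'   `n_sequences_with_motif`, `fraction`.
#' @export
motif_nls_overlap <- function(motif_hits, nls_hits) {
  ids <- unique(motif_hits$motif_id)
  ids <- ids[order(as.integer(sub("^M", "", ids)))]
  rows <- lapply(ids, function(m) {
    h <- motif_hits[motif_hits$motif_id == m, ]
    ov <- vapply(seq_len(nrow(h)), function(i) {
      nl <- nls_hits[nls_hits$seq_id == h$seq_id[i], ]
      any(nl$start < h$end[i] & h$start[i] < nl$end)
    }, TRUE)
    data.frame(motif_id = m,
               n_sequences_with_overlapping_NLS = sum(ov),
               n_sequences_with_motif = nrow(h),
               fraction = if (nrow(h)) sum(ov) / nrow(h) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
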