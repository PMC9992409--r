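#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a named [Biostrings::AAStringSet]. The record id
#' is the first whitespace-delimited token of the header; the remainder is
#' kept as the `description` metadata column. Residues are upper-cased and
#' any character outside `ACDEFGHIKLMNPQRSTVWY` plus `X` (e.g. B, Z, U, `*`,
#' gaps) is mapped to `X` with a warning — wild proteomes are dirty and must
#' not crash the pipeline.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Keep `-`/`.` characters (for aligned input) instead of
#'   mapping them to `X`.
#' @return An `AAStringSet` named by record id, with a `description`
#'   metadata column, in file order.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  res <- toupper(as.character(x))
  empty <- !nzchar(res)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  res <- sanitize_residues(res, ids, allow_gaps = allow_gaps)
  out <- Biostrings::AAStringSet(res)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

# map non-standard residues to X (keeping gaps if asked); warn once per file
sanitize_residues <- function(res, ids, allow_gaps = FALSE) {
  keep <- paste0(c(AA20, "X", if (allow_gaps) c("-", ".")), collapse = "")
  bad <- grepl(paste0("[^", gsub("\\.", "\\\\.", keep), "]"), res)
  if (any(bad)) {
    warning("non-standard residues mapped to X in: ",
            paste(utils::head(ids[bad], 5), collapse = ", "),
            if (sum(bad) > 5) sprintf(" (+%d more)", sum(bad) - 5))
    res[bad] <- gsub(paste0("[^", gsub("\\.", "\\\\.", keep), "]"), "X",
                     res[bad])
  }
  res
}

#' Write sequences to FASTA
#'
#' @param x Named character vector or `AAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a proteome manifest
#'
#' The manifest lists the per-species proteome FASTA files to search. It is
#' either a YAML file (a list of `{species_name, lineage_tag, fasta_path}`
#' entries) or a tab-separated table with those three columns. Relative
#' `fasta_path`s are resolved against the manifest's directory.
#'
#' @param path Manifest path (`.yaml`/`.yml` or TSV).
#' @return A data.frame with columns `species_name`, `lineage_tag`,
#'   `fasta_path` (absolute).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    if (!is.null(names(y)) && all(c("species_name", "fasta_path") %in% names(y)))
      df <- as.data.frame(y, stringsAsFactors = FALSE)
    else
      df <- do.call(rbind, lapply(y, function(e)
        data.frame(species_name = e$species_name,
                   lineage_tag = e$lineage_tag %||% NA_character_,
                   fasta_path = e$fasta_path, stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  req <- c("species_name", "fasta_path")
  if (!all(req %in% names(df)))
    stop("manifest must provide columns species_name, fasta_path")
  if (!"lineage_tag" %in% names(df)) df$lineage_tag <- NA_character_
  if (anyDuplicated(df$species_name))
    stop("duplicate species_name in manifest")
  rel <- !grepl("^(/|[A-Za-z]:)", df$fasta_path)
  df$fasta_path[rel] <- file.path(dirname(normalizePath(path)),
                                  df$fasta_path[rel])
  missing <- !file.exists(df$fasta_path)
  if (any(missing))
    stop("manifest FASTA file(s) not found: ",
         paste(df$fasta_path[missing], collapse = ", "))
  df[, c("species_name", "lineage_tag", "fasta_path")]
}

#' Write a proteome manifest as YAML
#' @param manifest data.frame with species_name, lineage_tag, fasta_path.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  entries <- lapply(seq_len(nrow(manifest)), function(i)
    list(species_name = manifest$species_name[i],
         lineage_tag = manifest$lineage_tag[i],
         fasta_path = manifest$fasta_path[i]))
  yaml::write_yaml(entries, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table as deterministic TSV
#'
#' Columns in their given order; rows sorted by `sort_by` (default the first
#' column) so repeated runs are byte-identical and diffable. An empty table
#' yields a header-only file.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param sort_by Column name(s) to sort rows by, or NULL to keep row order.
#' @export
write_tsv <- function(df, path, sort_by = names(df)[1]) {
  if (nrow(df) && length(sort_by))
    df <- df[do.call(order, df[sort_by]), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write intervals in BED-like form
#'
#' 0-based half-open `seq_id <TAB> start <TAB> end <TAB> name` lines, the
#' convention used for every interval in this package.
#'
#' @param intervals data.frame with columns seq_id, start, end, name.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("seq_id", "start", "end", "name") %in% names(intervals)))
  if (nrow(intervals)) {
    ok <- intervals$start >= 0 & intervals$start < intervals$end
    if (!all(ok))
      stop("invalid interval(s) (need 0 <= start < end): ",
           paste(intervals$name[!ok], collapse = ", "))
    intervals <- intervals[order(intervals$seq_id, intervals$start), ]
  }
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$seq_id,
                   as.integer(intervals$start), as.integer(intervals$end),
                   intervals$name)
  writeLines(lines, path)
  invisible(path)
}

#' Write a run summary as JSON
#' @param x List to serialize.
#' @param path Output path.
#' @export
write_run_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
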