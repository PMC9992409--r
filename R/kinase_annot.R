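# Anchor motifs for the five canonical kinase subdomain landmarks and the
# canonical start-to-start spacings (typical eukaryotic protein kinase
# geometry).  The DFG->APE spacing band is wide open at the top because the
# whole point of this package is that some families carry a several-hundred
# residue insert there.
ANCHOR_ORDER <- c("gloop", "vaik", "hxd", "dfg", "ape")
ANCHOR_LABELS <- c(gloop = "G-loop(I)", vaik = "VAIK-K(II)", hxd = "HxD(VIb)",
                   dfg = "DFG(VII)", ape = "APE(VIII)")
ANCHOR_SPACING <- list(
  # canon / low / high, start-to-start of consecutive anchors
  gloop_vaik = c(canon = 20, low = 5,  high = 80),
  vaik_hxd   = c(canon = 90, low = 40, high = 200),
  hxd_dfg    = c(canon = 25, low = 10, high = 90),
  dfg_ape    = c(canon = 30, low = 0,  high = 800)) # adjacency is legal
APE_VARIANT_PENALTY <- 50   # prefer an exact APE over a one-off variant
ANCHOR_SKIP_PENALTY <- 500  # cost of declaring an anchor absent mid-chain

anchor_regex <- function(max_mismatch = 0) {
  dfg <- if (max_mismatch >= 1) "(DFG|D.G|.FG|DF.)" else "DFG"
  list(gloop = "G.G..G", vaik = "[AVLI].K", hxd = "H.D", dfg = dfg,
       ape = "[AP].E")
}

find_all_matches <- function(res, pattern) {
  m <- gregexpr(pattern, res, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L # 0-based starts
}

#' Locate the conserved kinase subdomain anchors
#'
#' Scans a protein for the five canonical subdomain landmarks — the
#' glycine-rich loop `G.G..G` (subdomain I), the invariant lysine in
#' `[AVLI].K` (II), the catalytic loop `H.D` (VIb), `DFG` (VII) and `APE`
#' (VIII; one substitution tolerated, `[AP].E`) — and selects the
#' coordinate-increasing combination that minimizes total deviation from
#' canonical inter-anchor spacings, subject to configurable spacing bounds.
#' The DFG-to-APE spacing band is wide (up to 800 residues) so a long
#' insert between subdomains VII and VIII is accepted. Anchors for which no
#' spacing-consistent candidate exists are reported as absent, never as an
#' error.
#'
#' @param seq Residue string or single-element `AAStringSet`.
#' @param max_mismatch Mismatches tolerated in the DFG anchor (APE already
#'   tolerates one substitution by design).
#' @return data.frame of class `anchor_set`: `anchor`, `start`, `end`
#'   (0-based half-open), `matched_text`; one row per anchor found, in
#'   coordinate order.
#' @export
find_subdomain_anchors <- function(seq, max_mismatch = 0) {
  res <- as.character(seq)[1]
  pats <- anchor_regex(max_mismatch)
  cand <- lapply(pats, find_all_matches, res = res)
  # cap pathological candidate counts (low-complexity sequences)
  cand <- lapply(cand, function(x) if (length(x) > 200) x[seq_len(200)] else x)
  attr(cand, "ape_exact") <- if (length(cand$ape))
    cand$ape[substr(res, cand$ape + 1, cand$ape + 3) == "APE"] else integer(0)
  sel <- select_anchor_chain(cand)
  widths <- c(gloop = 6L, vaik = 3L, hxd = 3L, dfg = 3L, ape = 3L)
  rows <- lapply(names(sel), function(a) {
    s <- sel[[a]]
    data.frame(anchor = ANCHOR_LABELS[[a]], key = a, start = s,
               end = s + widths[[a]],
               matched_text = substr(res, s + 1, s + widths[[a]]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(anchor = character(0), key = character(0),
               start = integer(0), end = integer(0),
               matched_text = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  class(out) <- c("anchor_set", "data.frame")
  out
}

# Dynamic program over anchors in canonical order; skipping an anchor costs
# ANCHOR_SKIP_PENALTY and chains the spacing bounds across the gap.  The
# DFG->APE deviation is flat inside its band (both a 30-residue activation
# segment and a 500-residue insert are legitimate); other pairs pay the
# absolute deviation from the canonical spacing.  Ties resolve toward
# earlier coordinates.
select_anchor_chain <- function(cand) {
  anchors <- ANCHOR_ORDER
  present <- anchors[vapply(anchors, function(a) length(cand[[a]]) > 0, TRUE)]
  if (!length(present)) return(list())
  pair_dev <- function(from, to, spacing) {
    idx_from <- match(from, anchors); idx_to <- match(to, anchors)
    gaps <- names(ANCHOR_SPACING)[idx_from:(idx_to - 1)]
    canon <- sum(vapply(gaps, function(g) ANCHOR_SPACING[[g]]["canon"], 0))
    low <- sum(vapply(gaps, function(g) ANCHOR_SPACING[[g]]["low"], 0))
    high <- sum(vapply(gaps, function(g) ANCHOR_SPACING[[g]]["high"], 0))
    if (spacing < low || spacing > high) return(Inf)
    if ("dfg_ape" %in% gaps) {
      tight <- setdiff(gaps, "dfg_ape")
      lo2 <- sum(vapply(tight, function(g) ANCHOR_SPACING[[g]]["low"], 0))
      hi2 <- sum(vapply(tight, function(g) ANCHOR_SPACING[[g]]["high"], 0))
      # flat within band once the tight part of the chain is satisfiable
      return(if (spacing >= lo2) 0 else Inf)
    }
    abs(spacing - canon)
  }
  ape_exact <- attr(cand, "ape_exact", exact = TRUE)
  variant_pen <- function(a, pos) {
    if (a == "ape" && !is.null(ape_exact) && !(pos %in% ape_exact))
      APE_VARIANT_PENALTY else 0
  }
  # best[[a]][[c]] = list(cost, prev_anchor, prev_cand)
  cost <- list(); back <- list()
  for (ai in seq_along(present)) {
    a <- present[ai]
    pos <- cand[[a]]
    cost[[a]] <- rep(Inf, length(pos))
    back[[a]] <- vector("list", length(pos))
    for (ci in seq_along(pos)) {
      # start fresh at this anchor: pay skip penalty for anchors before it
      best_c <- skip_cost_before(a, present)
      best_b <- NULL
      if (ai > 1) {
        for (pj in seq_len(ai - 1)) {
          p <- present[pj]
          skip_between <- skip_cost_between(p, a, present)
          for (cj in seq_along(cand[[p]])) {
            if (cand[[p]][cj] >= pos[ci]) next
            dv <- pair_dev(p, a, pos[ci] - cand[[p]][cj])
            tot <- cost[[p]][cj] + dv + skip_between
            if (tot < best_c - 1e-9) { best_c <- tot; best_b <- c(p, cj) }
          }
        }
      }
      cost[[a]][ci] <- best_c + variant_pen(a, pos[ci])
      back[[a]][ci] <- list(best_b)
    }
  }
  # terminal: pay skip penalty for anchors after the chain end
  best_total <- Inf; best_end <- NULL
  for (a in present) {
    after <- skip_cost_after(a, present)
    for (ci in seq_along(cand[[a]])) {
      tot <- cost[[a]][ci] + after
      if (tot < best_total - 1e-9) { best_total <- tot; best_end <- c(a, ci) }
    }
  }
  sel <- list()
  cur <- best_end
  while (!is.null(cur)) {
    a <- cur[1]; ci <- as.integer(cur[2])
    sel[[a]] <- cand[[a]][ci]
    cur <- back[[a]][[ci]]
  }
  sel[order(match(names(sel), ANCHOR_ORDER))]
}

skip_cost_before <- function(a, present) {
  ANCHOR_SKIP_PENALTY * sum(match(present, ANCHOR_ORDER) < match(a, ANCHOR_ORDER))
}
skip_cost_after <- function(a, present) {
  ANCHOR_SKIP_PENALTY * sum(match(present, ANCHOR_ORDER) > match(a, ANCHOR_ORDER))
}
skip_cost_between <- function(p, a, present) {
  ANCHOR_SKIP_PENALTY * sum(match(present, ANCHOR_ORDER) > match(p, ANCHOR_ORDER) &
                            match(present, ANCHOR_ORDER) < match(a, ANCHOR_ORDER))
}

#' Delineate the insert between the DFG and APE anchors
#'
#' The segment strictly between the DFG and APE tripeptides (both
#' excluded): in canonical kinases this is the 20-35 residue activation
#' segment; a kinase insert domain (KID) is called when the segment length
#' reaches `kid_min_length`. With either anchor missing the status is
#' `"undetermined"` — explicitly distinct from a confident `is_kid =
#' FALSE`.
#'
#' @param anchors `anchor_set` from [find_subdomain_anchors()].
#' @param seq The annotated sequence (residue string or `AAStringSet`
#'   element); used for bounds only.
#' @param canonical_max Upper length of a canonical activation segment.
#' @param kid_min_length Minimum insert length to call a KID.
#' @param seq_id Identifier recorded in the result.
#' @return List of class `kid_record`: `seq_id`, `kid_start`, `kid_end`
#'   (0-based half-open), `kid_length`, `is_kid`, `status`
#'   (`"determined"`/`"undetermined"`).
#' @export
delineate_kid <- function(anchors, seq, canonical_max = 35,
                          kid_min_length = 80, seq_id = NA_character_) {
  dfg <- anchors[anchors$key == "dfg", ]
  ape <- anchors[anchors$key == "ape", ]
  if (nrow(dfg) != 1 || nrow(ape) != 1 || dfg$start >= ape$start) {
    return(structure(list(seq_id = seq_id, kid_start = NA_integer_,
                          kid_end = NA_integer_, kid_length = NA_integer_,
                          is_kid = NA, status = "undetermined"),
                     class = "kid_record"))
  }
  kid_start <- dfg$end
  kid_end <- ape$start
  len <- kid_end - kid_start
  is_kid <- len >= kid_min_length && len > canonical_max
  structure(list(seq_id = seq_id, kid_start = as.integer(kid_start),
                 kid_end = as.integer(kid_end), kid_length = as.integer(len),
                 is_kid = is_kid, status = "determined"),
            class = "kid_record")
}

#' Predict transmembrane segments by windowed hydropathy
#'
#' Kyte-Doolittle window-mean hydropathy; maximal runs of window centers
#' above the threshold are expanded to full window coverage, merged, then
#' trimmed to the 15-30 residue range typical of a single helix (shorter
#' runs are discarded, longer ones trimmed symmetrically).
#'
#' @param seq Residue string or `AAStringSet` element.
#' @param window Odd window width.
#' @param threshold Mean hydropathy above which a window is
#'   membrane-favourable.
#' @return data.frame of intervals `start`, `end` (0-based half-open),
#'   empty (with a warning) for sequences shorter than the window.
#' @export
predict_tm <- function(seq, window = 19, threshold = 1.6) {
  res <- as.character(seq)[1]
  n <- nchar(res)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < window) {
    warning("sequence shorter than hydropathy window; no TM prediction")
    return(empty)
  }
  h <- KD_SCALE[aa_chars(res)]
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold) # 1-based positions
  if (!length(centers)) return(empty)
  half <- (window - 1L) %/% 2L
  runs <- split(centers, cumsum(c(1, diff(centers) != 1)))
  segs <- lapply(runs, function(r) {
    s <- max(0L, min(r) - 1L - half)       # 0-based
    e <- min(n, max(r) + half)             # half-open
    c(s, e)
  })
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(segs))) {
    if (length(merged) && segs[i, 1] <= merged[[length(merged)]][2])
      merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], segs[i, 2])
    else merged[[length(merged) + 1]] <- segs[i, ]
  }
  out <- do.call(rbind, lapply(merged, function(s) {
    len <- s[2] - s[1]
    if (len < 15) return(NULL)
    if (len > 30) { # trim symmetrically around the center
      mid <- (s[1] + s[2]) / 2
      s <- c(floor(mid - 15), floor(mid - 15) + 30)
    }
    data.frame(start = as.integer(s[1]), end = as.integer(s[2]))
  }))
  if (is.null(out)) empty else out
}

#' Summarize the domain architecture of one protein
#'
#' Combines anchors, insert call and TM prediction into the per-protein
#' architecture record. `rd_status` reads the catalytic-loop anchor: RD if
#' the residue immediately preceding the catalytic aspartate is arginine
#' (HRD-type), non-RD otherwise. A protein is family-like
#' (`is_family_like`) iff all five anchors are present and the insert
#' qualifies as a KID.
#'
#' @param seq Residue string or `AAStringSet` element.
#' @param anchors `anchor_set`.
#' @param kid `kid_record`.
#' @param tm TM interval data.frame from [predict_tm()].
#' @param seq_id Identifier.
#' @return List of class `domain_architecture`.
#' @export
classify_architecture <- function(seq, anchors, kid, tm,
                                  seq_id = NA_character_) {
  has_all <- all(ANCHOR_ORDER %in% anchors$key)
  hxd <- anchors[anchors$key == "hxd", ]
  rd_status <- if (nrow(hxd) == 1 && substr(hxd$matched_text, 2, 2) == "R")
    "RD" else "non-RD"
  structure(list(seq_id = seq_id, anchors = anchors, kid = kid,
                 tm_segments = tm, has_all_subdomains = has_all,
                 rd_status = rd_status,
                 is_family_like = has_all && isTRUE(kid$is_kid),
                 nls_hits = NULL),
            class = "domain_architecture")
}

#' Annotate a set of candidate proteins
#'
#' Runs anchor detection, KID delineation and TM prediction over a
#' sequence set and returns one architecture per sequence plus a flat
#' summary table.
#'
#' @param seqs Named `AAStringSet` (or named character vector).
#' @param canonical_max,kid_min_length Passed to [delineate_kid()].
#' @return List with `architectures` (named list of
#'   `domain_architecture`) and `table` (one row per sequence).
#' @export
annotate_architectures <- function(seqs, canonical_max = 35,
                                   kid_min_length = 80) {
  res <- as_named_chr(seqs)
  ids <- names(res)
  archs <- lapply(ids, function(id) {
    anc <- find_subdomain_anchors(res[[id]])
    kid <- delineate_kid(anc, res[[id]], canonical_max = canonical_max,
                         kid_min_length = kid_min_length, seq_id = id)
    tm <- suppressWarnings(predict_tm(res[[id]]))
    classify_architecture(res[[id]], anc, kid, tm, seq_id = id)
  })
  names(archs) <- ids
  tab <- do.call(rbind, lapply(archs, function(a) {
    data.frame(seq_id = a$seq_id,
               n_anchors = nrow(a$anchors),
               has_all_subdomains = a$has_all_subdomains,
               kid_start = a$kid$kid_start, kid_end = a$kid$kid_end,
               kid_length = a$kid$kid_length,
               is_kid = a$kid$is_kid, kid_status = a$kid$status,
               rd_status = a$rd_status,
               n_tm = nrow(a$tm_segments),
               is_family_like = a$is_family_like,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(architectures = archs, table = tab)
}
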