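# One-occurrence-per-sequence (OOPS) EM motif discovery.
#
# The family's insert carries each conserved motif exactly once per
# sequence, so the occurrence model is OOPS: every sequence contributes
# exactly one site per motif, with a uniform prior over offsets.  Motifs
# are found sequentially; the sites of each accepted motif are
# probabilistically erased (offset weights multiplied down) before the
# next search, MEME-style.

MOTIF_ERASE_FACTOR <- 0.02
MOTIF_PSEUDOCOUNT <- 0.5 # scaled by background in the M-step

encode_seqs <- function(seqs) {
  lapply(as.character(seqs), function(s) {
    i <- match(aa_chars(s), AA20)
    i[is.na(i)] <- 0L # X / unknown
    as.integer(i)
  })
}

seq_background <- function(enc) {
  cnt <- tabulate(unlist(enc), nbins = 20)
  (cnt + 1) / (sum(cnt) + 20)
}

# log-odds of every offset of one encoded sequence against a PWM (rows =
# motif columns); X residues contribute 0
offset_logodds <- function(enc, lodds, w) {
  n <- length(enc)
  O <- n - w + 1L
  if (O < 1L) return(numeric(0))
  idx <- outer(seq_len(O), 0:(w - 1L), "+")
  r <- enc[idx]
  v <- numeric(length(r))
  known <- r > 0L
  col <- rep(seq_len(w), each = O)
  v[known] <- lodds[cbind(col[known], r[known])]
  rowSums(matrix(v, O, w))
}

oops_em <- function(enc, erase, w, init_pwm, bg, max_iter = 50, tol = 1e-6) {
  pwm <- init_pwm
  log_erase <- lapply(erase, function(e) log(e))
  ll_trace <- numeric(0)
  Z <- NULL
  for (it in seq_len(max_iter)) {
    lodds <- log(pwm) - rep(log(bg), each = w)
    ll <- 0
    Z <- vector("list", length(enc))
    counts <- matrix(0, w, 20)
    for (s in seq_along(enc)) {
      lo <- offset_logodds(enc[[s]], lodds, w)
      le <- log_erase[[s]]
      O <- length(lo)
      # erased positions down-weight any offset whose window covers them
      cs <- cumsum(c(0, le))
      win_erase <- cs[(seq_len(O)) + w] - cs[seq_len(O)]
      sc <- lo + win_erase
      m <- max(sc)
      p <- exp(sc - m)
      tot <- sum(p)
      ll <- ll + m + log(tot) - log(O)
      z <- p / tot
      Z[[s]] <- z
      for (c in seq_len(w)) { # expected residue counts per motif column
        rc <- enc[[s]][seq_len(O) + c - 1L]
        known <- rc > 0L
        if (!any(known)) next
        rs <- rowsum(z[known], rc[known])
        counts[c, as.integer(rownames(rs))] <-
          counts[c, as.integer(rownames(rs))] + as.numeric(rs)
      }
    }
    pc <- MOTIF_PSEUDOCOUNT * matrix(bg, w, 20, byrow = TRUE)
    new_pwm <- (counts + pc) / rowSums(counts + pc)
    ll_trace <- c(ll_trace, ll)
    # MAP-EM monotone quantity: likelihood + Dirichlet(pseudocount) prior
    obj <- ll + sum(pc * log(pwm))
    obj_trace <- if (it == 1) obj else c(obj_trace, obj)
    if (it > 1 && obj < obj_trace[it - 1] - 1e-8)
      stop("OOPS EM objective decreased (", obj_trace[it - 1], " -> ",
           obj, ")")
    if (it > 1 && obj - obj_trace[it - 1] < tol) { pwm <- new_pwm; break }
    pwm <- new_pwm
  }
  list(pwm = pwm, loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       obj_trace = obj_trace, Z = Z)
}

init_pwm_from_kmer <- function(enc_s, start, w, bg, weight = 0.6) {
  pwm <- matrix(rep(bg, each = w) * (1 - weight), w, 20)
  for (c in seq_len(w)) {
    a <- enc_s[start + c - 1L]
    if (a > 0L) pwm[c, a] <- pwm[c, a] + weight
    else pwm[c, ] <- bg # X: uninformative column
  }
  pwm / rowSums(pwm)
}

# Information-based significance proxy for a fitted motif: total site
# log-likelihood ratio at the maximum-likelihood sites, standardized
# against the exact mean/variance of a single-site LLR under the
# background, upper-tail normal log-p, Bonferroni over the widths tried.
motif_log_evalue_proxy <- function(pwm, bg, site_llr_total, n_seq, n_widths) {
  lodds <- log(pwm) - rep(log(bg), each = nrow(pwm))
  # per column: var = E[l^2] - (E[l])^2, summed over columns
  percol_mean <- as.numeric(lodds %*% bg)
  percol_var <- as.numeric((lodds^2) %*% bg) - percol_mean^2
  mu0 <- sum(percol_mean); var0 <- sum(percol_var)
  z <- (site_llr_total - n_seq * mu0) / sqrt(max(n_seq * var0, 1e-12))
  stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) + log(n_widths)
}

#' Discover single-occurrence motifs in a set of insert sequences
#'
#' Sequential EM motif discovery under a one-occurrence-per-sequence
#' (OOPS) model: for each motif, every width in `width_range` is fit with
#' several seeded restarts (initialized from sampled k-mers), the best
#' width is chosen by an information-content significance proxy, and the
#' accepted motif's maximum-likelihood sites are probabilistically erased
#' before the next motif is sought. The returned list is sorted by
#' ascending significance proxy and renumbered M1 (most significant)
#' upward. Fully deterministic given `seed`.
#'
#' @param kid_seqs Named `AAStringSet` / character vector of insert
#'   sequences (>= 5, each at least as long as the largest width).
#' @param n_motifs Number of motifs to extract.
#' @param width_range Integer c(min, max) motif widths tried.
#' @param seed Integer seed.
#' @param n_starts Seeded restarts per width.
#' @param max_iter EM iteration cap per restart.
#' @return List of `motif_model` objects: `motif_id`, `width`, `pwm`
#'   (width x 20, rows sum to 1), `evalue_proxy`, `log_evalue_proxy`,
#'   `n_sites`, `consensus`, `background`.
#' @export
discover_motifs <- function(kid_seqs, n_motifs = 12, width_range = c(6, 15),
                            seed = 1, n_starts = 4, max_iter = 50) {
  res <- as_named_chr(kid_seqs)
  if (length(res) < 5) stop("need at least 5 sequences for motif discovery")
  wmax <- max(width_range)
  if (any(nchar(res) < wmax))
    stop("sequence(s) shorter than the maximum motif width: ",
         paste(names(res)[nchar(res) < wmax], collapse = ", "))
  enc <- encode_seqs(res)
  bg <- seq_background(enc)
  widths <- seq(width_range[1], width_range[2])
  erase <- lapply(enc, function(e) rep(1, length(e)))
  motifs <- list()
  withr_seed(local_rng(seed), function() {
    for (r in seq_len(n_motifs)) {
      best <- NULL
      for (w in widths) {
        for (st in seq_len(n_starts)) {
          s_i <- sample(length(enc), 1)
          max_start <- length(enc[[s_i]]) - w + 1L
          # favour un-erased start k-mers
          wts <- vapply(seq_len(max_start), function(j)
            prod(erase[[s_i]][j:(j + w - 1L)]), 0)
          if (all(wts == 0)) wts <- rep(1, max_start)
          start <- sample(max_start, 1, prob = wts)
          init <- init_pwm_from_kmer(enc[[s_i]], start, w, bg)
          fit <- oops_em(enc, erase, w, init, bg, max_iter = max_iter)
          lodds <- log(fit$pwm) - rep(log(bg), each = w)
          site_llr <- 0; sites <- integer(length(enc))
          for (s in seq_along(enc)) {
            lo <- offset_logodds(enc[[s]], lodds, w)
            j <- which.max(lo)
            sites[s] <- j
            site_llr <- site_llr + lo[j]
          }
          lp <- motif_log_evalue_proxy(fit$pwm, bg, site_llr, length(enc),
                                       length(widths))
          if (is.null(best) || lp < best$log_evalue_proxy) {
            best <- list(pwm = fit$pwm, width = w, log_evalue_proxy = lp,
                         sites = sites, loglik = fit$loglik,
                         ll_trace = fit$ll_trace,
                         obj_trace = fit$obj_trace)
          }
        }
      }
      # erase the accepted motif's sites
      for (s in seq_along(enc)) {
        j <- best$sites[s]
        span <- j:(j + best$width - 1L)
        erase[[s]][span] <<- erase[[s]][span] * MOTIF_ERASE_FACTOR
      }
      motifs[[r]] <<- best
    }
  })
  ord <- order(vapply(motifs, function(m) m$log_evalue_proxy, 0))
  out <- lapply(seq_along(ord), function(i) {
    m <- motifs[[ord[i]]]
    structure(list(motif_id = paste0("M", i), width = m$width, pwm = m$pwm,
                   evalue_proxy = exp(m$log_evalue_proxy),
                   log_evalue_proxy = m$log_evalue_proxy,
                   n_sites = length(m$sites),
                   consensus = paste(AA20[apply(m$pwm, 1, which.max)],
                                     collapse = ""),
                   background = bg, ll_trace = m$ll_trace,
                   obj_trace = m$obj_trace),
              class = "motif_model")
  })
  out
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("%s  width %d  consensus %s  log-E proxy %.1f\n", x$motif_id,
              x$width, x$consensus, x$log_evalue_proxy))
  invisible(x)
}

#' Scan one motif over one sequence (single-occurrence)
#'
#' Best-scoring window under the PWM-versus-background log-odds; reported
#' only when the best score is positive, and at most one hit per
#' (motif, sequence) pair, reflecting the single-occurrence model.
#'
#' @param motif A `motif_model`.
#' @param seq Residue string or single-element `AAStringSet`.
#' @param seq_id Identifier recorded in the hit.
#' @return One-row data.frame `motif_id`, `seq_id`, `start`, `end`
#'   (0-based half-open), `score`, or NULL if no positive-scoring window.
#' @export
scan_motif <- function(motif, seq, seq_id = NA_character_) {
  enc <- encode_seqs(as.character(seq)[1])[[1]]
  w <- motif$width
  if (length(enc) < w) return(NULL)
  lodds <- log(motif$pwm) - rep(log(motif$background), each = w)
  lo <- offset_logodds(enc, lodds, w)
  j <- which.max(lo)
  if (lo[j] <= 0) return(NULL)
  data.frame(motif_id = motif$motif_id, seq_id = seq_id,
             start = j - 1L, end = j - 1L + w, score = lo[j],
             stringsAsFactors = FALSE)
}

#' Scan a motif set over a sequence set
#' @param motifs List of `motif_model`.
#' @param seqs Named `AAStringSet` / character vector.
#' @return data.frame of hits (possibly zero rows).
#' @export
scan_motifs <- function(motifs, seqs) {
  res <- as_named_chr(seqs)
  rows <- list()
  for (id in names(res))
    for (m in motifs) {
      h <- scan_motif(m, res[[id]], seq_id = id)
      if (!is.null(h)) rows[[length(rows) + 1]] <- h
    }
  if (!length(rows))
    return(data.frame(motif_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positional motif architecture
#'
#' Divides each insert into ordinal positions by the rank order of its
#' motif hits: within a sequence, hits sorted by start coordinate
#' contribute to positions P1, P2, ... in order. Counts are accumulated
#' over sequences into an `n_positions x n_motifs` table and the modal
#' motif per position is reported, ties broken toward the lower motif
#' index.
#'
#' @param hits data.frame of motif hits (`motif_id`, `seq_id`, `start`,
#'   and `end` for the bin mode).
#' @param n_positions Number of ordinal positions.
#' @param motif_ids Motif identifiers fixing column order (default: M1..Mk
#'   inferred from hits).
#' @param mode `"rank"` (default): the k-th hit of a sequence counts
#'   toward position Pk. `"bins"`: each insert is cut into `n_positions`
#'   equal-length bins and a hit counts toward the bin holding its
#'   midpoint (requires `seq_lengths`). The two readings of a positional
#'   architecture are both supported because the division of an insert
#'   into positions is a convention, not a measurement.
#' @param seq_lengths Named vector of insert lengths, required for
#'   `mode = "bins"`.
#' @return Object of class `positional_matrix`: `counts` (positions x
#'   motifs), `modal_motif` (per-position motif id), `n_positions`.
#' @export
positional_architecture <- function(hits, n_positions = 12,
                                    motif_ids = NULL,
                                    mode = c("rank", "bins"),
                                    seq_lengths = NULL) {
  mode <- match.arg(mode)
  if (is.null(motif_ids)) {
    ids <- unique(hits$motif_id)
    motif_ids <- ids[order(as.integer(sub("^M", "", ids)))]
  }
  counts <- matrix(0L, n_positions, length(motif_ids),
                   dimnames = list(paste0("P", seq_len(n_positions)),
                                   motif_ids))
  if (mode == "bins" && is.null(seq_lengths))
    stop("mode = 'bins' requires seq_lengths")
  for (sid in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == sid, ]
    h <- h[order(h$start), ]
    if (mode == "rank") {
      k <- min(nrow(h), n_positions)
      pos <- seq_len(k)
      h <- h[seq_len(k), ]
    } else {
      len <- seq_lengths[[sid]]
      mid <- (h$start + h$end) / 2
      pos <- pmin(n_positions, floor(n_positions * mid / len) + 1L)
    }
    for (p in seq_along(pos)) {
      m <- h$motif_id[p]
      counts[pos[p], m] <- counts[pos[p], m] + 1L
    }
  }
  modal <- apply(counts, 1, function(row) {
    if (all(row == 0)) NA_character_ else motif_ids[which.max(row)]
  })
  structure(list(counts = counts, modal_motif = modal,
                 n_positions = n_positions), class = "positional_matrix")
}

#' @export
print.positional_matrix <- function(x, ...) {
  cat("positional motif architecture (", x$n_positions, " positions)\n",
      sep = "")
  print(x$counts)
  cat("modal: ", paste(x$modal_motif, collapse = " "), "\n")
  invisible(x)
}
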