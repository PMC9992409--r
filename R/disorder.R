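# Logistic calibration for the disorder score: the midpoint is the mean of
# the shipped propensity scale (a uniform "median" composition maps to 0.5)
# and the slope spreads typical window means over most of [0, 1].
DISORDER_MIDPOINT <- mean(DISORDER_SCALE)
DISORDER_SLOPE <- 6
CHARGE_BONUS_WEIGHT <- 0.25      # net-charge-density bonus
HYDRO_CLUSTER_WEIGHT <- 0.35     # hydrophobic-cluster penalty
HYDROPHOBIC_SET <- c("I", "L", "V", "F", "W", "M")
CHARGE_SIGN <- c(K = 1, R = 1, D = -1, E = -1)

#' Per-residue intrinsic-disorder propensity profile
#'
#' A deterministic windowed propensity predictor: each residue carries a
#' fixed disorder propensity (TOP-IDP-style ordering — aromatic and
#' branched hydrophobic residues order-promoting; P, E, S, Q, K
#' disorder-promoting), averaged over a window truncated symmetrically at
#' the sequence ends, plus a net-charge-density bonus and a penalty
#' proportional to the fraction of the window inside hydrophobic runs of
#' three or more; the composite is squashed through a logistic whose
#' midpoint is the scale mean, so scores live in `[0, 1]` with 0.5 the
#' conventional order/disorder boundary.
#'
#' @param seq Residue string or single-element `AAStringSet`.
#' @param window Odd smoothing window (residues).
#' @param seq_id Identifier carried into the profile.
#' @return Object of class `disorder_profile`: `seq_id`, `scores`
#'   (length = sequence length, in `[0,1]`), `window`.
#' @export
disorder_profile <- function(seq, window = 21, seq_id = NA_character_) {
  res <- as.character(seq)[1]
  if (!nzchar(res)) stop("empty sequence")
  ch <- aa_chars(res)
  n <- length(ch)
  prop <- DISORDER_SCALE[ch]; prop[is.na(prop)] <- 0
  chg <- CHARGE_SIGN[ch]; chg[is.na(chg)] <- 0
  hyd <- as.numeric(ch %in% HYDROPHOBIC_SET)
  # mark residues inside hydrophobic runs of length >= 3
  r <- rle(hyd)
  incluster <- inverse.rle(list(lengths = r$lengths,
                                values = r$values * (r$lengths >= 3)))
  half <- (window - 1L) %/% 2L
  cs_prop <- cumsum(c(0, prop)); cs_chg <- cumsum(c(0, chg))
  cs_clu <- cumsum(c(0, incluster))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i) # symmetric truncation at the edges
  lo <- i - h; hi <- i + h; w <- hi - lo + 1
  mean_prop <- (cs_prop[hi + 1] - cs_prop[lo]) / w
  net_chg <- abs(cs_chg[hi + 1] - cs_chg[lo]) / w
  clu <- (cs_clu[hi + 1] - cs_clu[lo]) / w
  composite <- mean_prop + CHARGE_BONUS_WEIGHT * net_chg -
    HYDRO_CLUSTER_WEIGHT * clu
  scores <- 1 / (1 + exp(-DISORDER_SLOPE * (composite - DISORDER_MIDPOINT)))
  structure(list(seq_id = seq_id, scores = as.numeric(scores),
                 window = window), class = "disorder_profile")
}

#' Summarize disorder over named regions
#'
#' @param profile A `disorder_profile`.
#' @param regions data.frame with columns `region`, `start`, `end`
#'   (0-based half-open, within sequence bounds).
#' @return data.frame `region`, `mean`, `fraction_above_0.5`; empty input
#'   gives an empty table.
#' @export
region_disorder_summary <- function(profile, regions) {
  if (!nrow(regions))
    return(data.frame(region = character(0), mean = numeric(0),
                      fraction_above_0.5 = numeric(0)))
  n <- length(profile$scores)
  if (any(regions$start < 0 | regions$end > n | regions$start >= regions$end))
    stop("region out of sequence bounds")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- profile$scores[(regions$start[i] + 1):regions$end[i]]
    data.frame(region = regions$region[i], mean = mean(s),
               fraction_above_0.5 = mean(s >= 0.5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' KID versus kinase-core disorder contrast
#'
#' Mean disorder over the insert minus mean disorder over the kinase core
#' (subdomain I through the DFG anchor, plus the APE anchor through the
#' C-lobe). A positive contrast says the insert is more disorder-prone
#' than the surrounding kinase fold.
#'
#' @param profile A `disorder_profile`.
#' @param arch A `domain_architecture` with a determined KID.
#' @param clobe_span Residues after the APE anchor counted as C-lobe core.
#' @return List `kid_mean`, `core_mean`, `contrast`, or NULL when the KID
#'   is undetermined.
#' @export
kid_core_contrast <- function(profile, arch, clobe_span = 90) {
  kid <- arch$kid
  if (is.na(kid$kid_start) || !isTRUE(kid$is_kid)) return(NULL)
  anc <- arch$anchors
  n <- length(profile$scores)
  core_start <- if ("gloop" %in% anc$key) anc$start[anc$key == "gloop"] else 0L
  ape_start <- anc$start[anc$key == "ape"]
  core1 <- c(core_start, kid$kid_start - 3L) # up to and incl. DFG
  core2 <- c(ape_start, min(n, ape_start + clobe_span))
  kid_mean <- mean(profile$scores[(kid$kid_start + 1):kid$kid_end])
  core_scores <- c(profile$scores[(core1[1] + 1):core1[2]],
                   profile$scores[(core2[1] + 1):core2[2]])
  list(kid_mean = kid_mean, core_mean = mean(core_scores),
       contrast = kid_mean - mean(core_scores))
}
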