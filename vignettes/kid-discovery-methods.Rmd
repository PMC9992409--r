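---
title: "Methods: discovering and characterizing kinase insert domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing kinase insert domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`kidscape` is a desk-scale pipeline for finding a kinase family defined
by a long insert — a kinase insert domain, KID — between the DFG and APE
tripeptides of the protein kinase fold, and for characterizing that
insert's disorder, motif architecture, nuclear localization signals and
phylogenetic signal. This vignette is the package's own account of the
models it implements, the parameters that matter, the numerical
conventions, and what its synthetic validation does and does not
demonstrate.

## Homology retrieval

### The profile HMM

The family model is a classical profile hidden Markov model built from a
seed alignment: alignment columns whose gap fraction is below 0.5 become
match states; emissions and transitions are Laplace-smoothed counts
(pseudocount 1 per residue or transition), so a match column observed as
(A, A, A, C) in four seeds emits A with probability (3+1)/(4+20).
Insert states emit the background — the smoothed overall residue
frequency of the seed — which makes insertions emission-neutral in
log-odds scoring. The model is scored with a full-sequence scaled
forward algorithm with free-insertion flanking states at both ends:
long non-homologous flanks pass through the flank inserts at low cost,
giving local-in-target behaviour without Plan7 wing states.

The reported bit score is `log2` of the ratio between the forward
likelihood under the model and the likelihood under a null with the
*identical state machine* but every emission replaced by the background.
This transition-matched null is a deliberate choice: it makes the score
a pure measure of emission information (a model whose emissions all
equal the background scores exactly 0 bits for any sequence), it
cancels the path-structure terms that would otherwise penalize
sequences merely for their length, and it is exactly reproducible by
brute-force path enumeration, which the test suite exploits on toy
models.

### E-values

Significance uses the Gumbel form `E = N exp(-lambda (S - mu))` with
`N` the number of database sequences. `mu` and `lambda` come from a
method-of-moments fit (`lambda = pi / (sd sqrt(6))`,
`mu = mean - gamma / lambda`) to the scores of at least 50 (default
200) decoy sequences. Two properties of the forward score shaped the
calibration default: scores drift systematically with target length,
and they depend on the target's residue composition relative to the
seed-derived background. Decoys drawn from the model background at one
fixed length therefore misestimate the tail for a real proteome — in
particular, globular-composition proteins score tens of bits above
disorder-enriched-family-background decoys. `search_proteomes()`
consequently calibrates, by default, on decoys drawn from the *searched
database's* pooled composition with lengths resampled from the actual
target lengths, the same logic by which shuffled-target decoys
calibrate the local Smith–Waterman scan. The candidate threshold is
`E < 0.01`, applied to the full-sequence score.

### Local scans

The Smith–Waterman stand-in for database probes
(`local_sw_scan()`) uses Biostrings' optimal local alignment under
BLOSUM62 with affine gap penalties 11/1 and a default threshold of
`E < 1` — deliberately permissive, as appropriate when asking whether a
segment occurs anywhere else at all.

## Kinase annotation

Five anchors operationalize the subdomain landmarks: `G.G..G`
(glycine-rich loop, subdomain I), `[AVLI].K` (the invariant lysine,
II), `H.D` (catalytic loop, VIb — the middle residue deliberately
unrestricted so non-RD kinases are matched), `DFG` (VII, no mismatch by
default), and `[AP].E` (VIII, one substitution tolerated because this
motif drifts across subfamilies; an exact APE is preferred over a
variant by a fixed penalty). Because each pattern can match many times,
the reported anchor set is the coordinate-increasing combination
minimizing total deviation from canonical inter-anchor spacings
(20 / 90 / 25 / 30 residues start-to-start), under generous bounds; the
DFG-to-APE spacing is scored flat across 15–800 residues, since both a
30-residue activation segment and a 500-residue insert are legitimate
there. Ties resolve toward earlier coordinates. Anchors without any
spacing-consistent candidate are reported absent — never an error.
Subdomains III–V and IX–XI are not individually anchored; the five
anchors suffice for completeness checks and KID delineation. An
alternative delineation by profile alignment against reference kinases
would be more faithful to expert practice but is not implemented.

The KID is the segment *strictly between* the DFG and APE tripeptides,
both excluded — stated explicitly because the activation segment is
conventionally quoted DFG-through-APE inclusive; the inclusive reading
would shift every length by six residues. A record is a KID when the
segment reaches `kid_min_length = 80` residues: more than twice the
35-residue canonical upper bound, far below the ~200-residue lower end
of observed inserts, so the two regimes are separated with wide margins
on both sides. Records missing either anchor get status
`"undetermined"`, which is distinct from a confident negative. RD
status reads the residue preceding the catalytic aspartate (HRD-type =
RD). Transmembrane segments come from Kyte–Doolittle window-mean
hydropathy (window 19, threshold 1.6, segments trimmed/merged to the
15–30 residue range of a single helix); this is a deliberate
replacement of neural transmembrane predictors — the synthetic
validation only asks that strongly hydrophobic planted blocks be found,
not that any external tool's output be matched.

## Disorder profiling

The per-residue score is a logistic squash of a windowed composite:
the mean over a 21-residue window (truncated symmetrically at the ends)
of a fixed 20-value propensity scale with TOP-IDP-style ordering
(W, F, Y, I, L, V most order-promoting; P, E, S, Q, K most
disorder-promoting), plus 0.25 × the absolute net-charge density,
minus 0.35 × the fraction of the window inside hydrophobic runs of
three or more. The logistic midpoint is the scale mean, so a uniform
composition maps to 0.5; the slope (6) spreads typical window means
over most of the unit interval. The 0.5 order/disorder boundary is a
convention, not a fitted threshold, and all conclusions in the package
rest on the *ordinal contrast* between the KID and the kinase core
(subdomain I through DFG plus 90 residues after APE), never on
absolute agreement with any external disorder predictor — the pairwise
energy estimation of such predictors is intentionally not emulated.

## Motif architecture

Motif discovery is EM under a one-occurrence-per-sequence (OOPS) model:
the family observation that motivates it is that each conserved motif
occurs exactly once per insert. For each of the 12 motifs, every width
in 6–15 (the widths are a stated guess; the acceptance surface is motif
*recovery*, not width agreement) is fit with several k-mer-seeded
restarts; the E-step weights every offset of every sequence, the M-step
re-estimates the PWM with background-proportional pseudocounts
(weight 0.5). With those pseudocounts the EM is maximum-a-posteriori,
so the quantity guaranteed non-decreasing — and asserted non-decreasing
on every run — is the penalized objective (likelihood plus Dirichlet
log-prior), not the raw likelihood. Accepted motifs' maximum-likelihood
sites are probabilistically erased (offset weights × 0.02) before the
next motif is sought.

Significance is an information-content proxy, not a reimplementation of
any external motif tool's analytic E-value: the total site log-odds at
the ML sites is standardized against the exact mean and variance of a
single-site log-odds under the background, converted to an upper-tail
normal log-p, and Bonferroni-corrected over the widths tried. Only the
*ordering* this induces is load-bearing: motifs are renumbered M1
(most significant) upward.

Scanning reports at most one hit per motif per sequence (the best
window, only if its log-odds is positive). The positional architecture
divides each insert into 12 positions by the *rank order* of its hits —
the k-th hit counts toward position Pk — with ties in the modal motif
per position broken toward the lower motif index. Rank order was chosen
over equal-length bins because it is the reading consistent with short
motifs appearing "across multiple positions"; the equal-bin alternative
is available via `positional_architecture(mode = "bins")`, and the
ambiguity is documented rather than resolved.

NLS detection is a plain-text pattern table
(`inst/extdata/nls_patterns.tsv`) of four Perl-compatible regular
expressions approximating the classical monopartite core (with acidic
flank exclusions), its N- and C-extended variants, and the bipartite
two-cluster form. Shipping them as editable data is deliberate: the
canonical class definitions are versioned externally, and hard-coding
one snapshot as ground truth would be false precision. Users may drop
in exact patterns; malformed files are rejected at load.

## Phylogenetics

Pairwise alignment is global affine-gap BLOSUM62 (10/1); the family
representative is the member with the highest score against a
reference, ties to the lexicographically smallest id. The multiple
aligner is progressive: average-linkage guide tree on 3-mer
dissimilarity, profiles merged by affine-gap profile–profile dynamic
programming (expected BLOSUM62 column score, gap 10/0.5, in compiled
code). Tree inference is neighbor joining on scoredist-style distances:
the BLOSUM62 score of each row pair over mutually ungapped columns,
normalized between the expected random score and the mean self-score,
minus-log-transformed, clamped to a ceiling of 5 for score-floor pairs.
Maximum-likelihood inference was deliberately replaced by NJ — all
claims the package makes at this stage are topology- and clade-level
(shared bipartitions, Robinson–Foulds distance, presence and bootstrap
support of a two-clade split), never branch lengths or likelihoods, and
for those claims NJ on well-separated clades is sufficient and
dependency-free. Bootstrap resamples alignment columns with
replacement (default 1000 replicates in the field's display convention;
100 in tests and acceptance runs, where the supports of the deep split
saturate well above the 80 display threshold); supports are integer
percentages on the original tree's internal edges. Negative NJ branch
lengths are clamped to zero with a warning.

## The synthetic generator

The generator is the package's study-conditions definition, not a
tuning surface. Defaults: 12 species in two clades of six (clade stems
0.5 substitutions/site, within-clade branches 0.15), two family members
per species (the configuration supports 1–8 per species, echoing
copy-number expansion up to eight in some dicots), ten canonical-kinase
decoys and 150 i.i.d. background proteins per species (~2,000 proteins
— minutes on one CPU); insert lengths drawn per member from a normal
(mean 280, sd 60) truncated to [199, 527]; twelve planted motifs
(widths 6–15, themes matching the observed motif families: acidic/basic
runs, D/EWW cores in the second, third and sixth, lysine-rich fourth
and eleventh, serine-rich tenth) in default order with a 0.1
per-sequence adjacent-swap probability and 0.1 per-position instance
noise; intact basic NLS runs inside the second and third motif
instances (plant rate 1.0) and an SV40-style signal in half the
C-tails; substitution rate 0.4 per site per unit branch length with
indels confined to the insert; anchors protected
(`anchor_mutation_rate = 0`). The ancestral scaffold plants the five
anchors at canonical spacings; generated inserts are scrubbed of
chance `DFG` / `[AP].E` occurrences so the planted anchors are the
unique spacing-consistent combination — that is what makes exact
boundary recovery a meaningful closure property rather than a
coin-flip.

One property of the generator deserves emphasis: the insert's background
skeleton evolves along the species tree, so it is itself conserved
sequence. Motif discovery can therefore legitimately return a conserved
background block in place of the weakest planted motifs — those are real
single-occurrence conserved features of the data, just not planted ones.
The evaluation accounts for this by mapping discovered motifs onto
planted sites by majority interval overlap (a motif whose hits do not
consistently cover one planted site stays unmapped) and reporting both
the raw modal-position agreement over all twelve ordinal positions and
an order-isolating variant computed over the mapped motifs only.

What the generator does *not* emulate, and what passing tests therefore
do not show: real proteome size (tens of thousands of proteins per
species) and the attendant multiple-testing burden; domain architecture
diversity beyond one decoy scaffold; alignment-fragmenting indels in
the kinase core; sequencing/annotation artifacts beyond non-standard
residue letters; genuinely ambiguous anchor drift. Recovery at the
planted conditions validates the machinery, not field performance on
any particular proteome release.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open everywhere, including BED-like
output; only free-text report fields use 1-based inclusive phrasing.
Non-standard residues (B, Z, U, `*`, stray gaps) map to X with a
warning — X emits neutrally in HMM scoring, scores zero in motif
scans, and carries propensity 0 in the disorder scale. Emission and
transition vectors are validated to sum to one within 1e-9; the
forward recursion is scaled per position, so no underflow occurs at
realistic lengths. Empty sequences, empty databases, ragged alignments
and zero-match-column alignments are hard errors naming the offender;
missing anchors, sub-window sequences and empty hit tables are
well-formed empty results. Deterministic behaviour under a fixed seed
is part of the contract: every stochastic step (calibration decoys,
EM restarts, bootstrap resampling, generation) runs under an isolated,
seed-derived RNG state that is restored afterwards, and the pipeline
reruns byte-identically.

Problem sizes in the shipped tests were chosen to keep the whole suite
in the minutes range on a single core: the default 12-species dataset
for the end-to-end recovery checks, a 4-species dataset for unit-level
closures, 100 bootstrap replicates, 200 calibration decoys. These
sizes are the package's validation conditions; nothing in the science
depends on them beyond the statistical resolution they buy.

## Known limitations

- The profile HMM has no domain-envelope parsing: one full-sequence
  score per protein, no per-domain coordinates from the search itself
  (the anchor scan supplies coordinates downstream).
- The anchor scan prefers the earliest spacing-consistent combination;
  a genuine second APE-like motif inside a real insert earlier than the
  true subdomain VIII would shorten the delineated KID. The generator
  scrubs this case; real data may not oblige.
- The significance proxy for motifs orders them; its absolute values
  are not comparable to any external tool's E-values.
- The disorder scale is fixed and composition-based; it cannot see
  context effects that energy-estimation predictors model.
- NJ trees carry no substitution-model correction beyond the scoredist
  normalization; deep-branch attraction artifacts are possible on data
  far more saturated than the generator produces.
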