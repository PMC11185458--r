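---
title: "Models, simulation and numerical choices in chunktag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation and numerical choices in chunktag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunktag)
```

# The paradigm and its arithmetic

The package analyses an artificial-grammar paradigm in which isochronous
syllables (250 ms each) are grouped into 6-syllable chunks, each followed by
an 80-ms silence. The chunk period is therefore 1.58 s, the chunk rate
1/1.58 ≈ 0.63 Hz, and the mean syllable rate 6/1.58 ≈ 3.797 Hz. Analysis
epochs span 8 chunks (12.64 s), so the DFT grid has 1/12.64 ≈ 0.0791 Hz
spacing and the chunk and syllable rates fall on exact bins (8 and 48 cycles
per epoch). This exact-bin property is the reason the spectral stage uses a
rectangular window with no taper and no detrending beyond per-epoch mean
removal: any taper would smear a stimulus-locked line across bins and bias
the neighbour-based normalization.

Two remarks on published round-offs. A syllable rate of 6/1.58 is 3.797 Hz;
the commonly quoted "3.73 Hz" label is not derivable from the stated timing
and is not used anywhere — target bins are always selected as the DFT bin
nearest 1/1.58 and 6/1.58 Hz. Likewise "144 chunks per audio" implies an
audio of 144 × 1.58 ≈ 3.8 min; the generators follow the chunk counts, not
the "3-minute" label.

# Stream generation

Learning streams place the dependency pair at positions 2 and 5 of each
target chunk (within condition) or at position 5 / position 2 of consecutive
chunks (across condition). "Distributed evenly" for the free positions is
operationalized as sampling without replacement from the eligible syllable
set, refreshed one permutation at a time, which bounds any two syllables'
usage counts to within one of each other. The transitional probability from
the first to the second pair element is 1 by construction.

Violation trials replace the second pair element with the second element of
the participant's *other* learned pair (configurable). This keeps the
violating syllable familiar and matched in exposure — the violation is
relational, not acoustic novelty. List counterbalancing (which pair serves
which condition) is a generator parameter rotated by subject index rather
than an enforced experimental constraint, since a synthetic cohort needs no
assignment bookkeeping.

Time is in seconds from stream onset; positions are 1-based within chunks;
chunk and trial indices 0-based. Events are exchanged as BIDS-dialect TSV
(`onset`, `duration`, `trial_type`, …) with `# key: value` provenance lines.

# The synthetic EEG generator

Each recording is a superposition of

1. a raised-cosine kernel (200 ms, unit peak, closed-form energy) at every
   syllable onset, with amplitude `kernel_amp` (default 5 µV);
2. the same kernel scaled by `chunk_initial_gain` (default 2) at each
   chunk's *first* syllable;
3. an additive deflection at the second dependency element, with amplitude
   `nad_effect[[condition]][match|violation]` (defaults: within 3 vs 1 µV,
   across 1 vs 1 µV);
4. independent per-channel 1/f noise (`noise_alpha = 1`, `noise_sd = 10` µV),
   generated by spectrally shaping white Gaussian noise with `|f|^(-α/2)`
   and scaling so the expected sample SD equals `noise_sd`.

The chunk-rate response is induced by the gain on chunk-initial syllables
rather than by an explicit 0.63 Hz sinusoid, so the spectral peak emerges
from event structure exactly as in the paradigm, not by construction at the
analysis frequency. A consequence worth knowing: even at gain 1 the chunk
bin is not empty, because the boundary silences make the syllable train
itself 1.58 s-periodic. The added chunk-initial component interferes
destructively with that baseline component near gain ≈ 1.5 before
dominating, so the chunk-bin EPn is *not* monotone in the gain on a
continuum starting at 1; it is strictly increasing over the integer gains
1, 2, 3 and everywhere above ≈ 2, which is the regime the generator uses.

What the generator deliberately omits: volume conduction and realistic
topography (channels are an abstract labelled grid with rook adjacency;
`topography` defaults to uniform weights), eye/muscle/line artifacts (the
published preprocessing chain is out of scope because synthetic data need no
repair), and any behavioural response model. A green end-to-end test
therefore establishes that the *analysis* recovers the structure the
generator put in at realistic SNR and trial counts — it cannot validate
artifact robustness or anatomical claims.

Effect-size and noise defaults are not taken from the study (which does not
report its single-trial amplitudes); they were chosen once so that the
chunk/syllable peaks and the within-condition ERP effect are detectable at
the study's counts (72 epochs per condition, 36 trials per cell, 31
subjects) with comfortable but not degenerate margins — e.g. per-subject
chunk-bin EPn ≈ 0.6 against a neighbour baseline of ≈ 0.04, which also
reproduces the order of magnitude of the published EPn baseline (≈ 0.05).

# Spectral statistics

With `X_n(f)` the rectangular-window DFT coefficient of epoch *n* (per
channel), the package computes

* evoked power `EP(f) = |Σ_n X_n(f)|²/N` — phase-locked activity grows
  linearly in `N`, noise does not;
* normalized evoked power `EPn(f) = E(f) / Σ_w E(w)` over neighbour bins
  `|w − f| < 0.5 Hz`, `w ≠ f`. The defining equation divides by the *sum*
  of neighbours while its verbal gloss says "average"; the sum is the
  primary implementation (a flat spectrum then gives 1/12 ≈ 0.083 with the
  12 neighbours of the 0.0791 Hz grid, consistent with the published
  baseline ≈ 0.05), and `method = "avg"` exposes the verbal reading;
* `ITPC(f)`, the resultant length of the unit phase vectors across epochs.
  Coefficients of exactly zero magnitude have no phase; such epochs are
  excluded bin-wise and counted. For uniform phases
  `E[ITPC] ≈ √π/2/√N` (Rayleigh), which the tests verify at N = 72.

Learning-phase epochs from both conditions are pooled before EP/ITPC, as the
design intends (chunk tracking is condition-independent). Group inference
compares each subject's channel-averaged value at the target bin against the
mean of the 4 nearest non-target bins (2 per side) by a paired two-sided
t-test; whether the published statistics were channel-averaged is not
stated, and channel-averaging is the default here. Neighbourhoods are
intersected with the computed grid near its edges.

# ERP statistics

Test-phase epochs span −100 to 300 ms around the second dependency element,
baseline-corrected on [−100, 0] ms. The 25 Hz low-pass is a 4th-order
Butterworth applied forward and backward (zero phase, squared magnitude
response); no filter-design package exists in the target environment, so the
bilinear-transform design is implemented directly and verified against its
analytic frequency response (−3 dB at cutoff, unity DC gain, >95 %
attenuation at 100 Hz).

The cluster test follows the standard recipe: paired t at every
(channel, sample); two-sided thresholding at `alpha_cluster = 0.05`;
connected components under spatio-temporal adjacency (same channel and
adjacent samples, or neighbouring channels and the same sample), restricted
to sign-homogeneous members; cluster mass `Σ|t|^η`. The referenced
"weighted cluster mass" statistic is parameterized here by the exponent η
(default 1 — classic cluster mass, which already reflects both extent and
intensity); the original weighting scheme is not reproduced verbatim. The
null distribution is the maximum cluster mass over within-subject condition
swaps, i.e. sign flips of the paired differences — with per-subject
condition means as input, both are exactly equivalent. Random-permutation
p-values use the `(1 + b)/(1 + m)` estimator (valid under the null);
exhaustive enumeration (`exhaustive = TRUE`, up to 20 subjects) uses the
plain proportion over all 2^n assignments so it matches a brute-force
oracle exactly. Significance is `p < 0.05` on the cluster p.

The published effect window (≈ 0–50 ms, p = 0.0017) depends on the human
data; only the qualitative pattern — a significant within-condition cluster,
none in the across condition — is recoverable from synthetic cohorts, and
that is what the end-to-end acceptance test asserts (on three replicate
31-subject cohorts: peaks and within-cluster in 3/3, across clean in ≥ 2/3,
matching the ~95 % per-cohort true-negative rate a 5 % test implies).

# Mean dependency distance

For arcs within chunk *i* the word-level span `|v − u|` accrues to `cdd_i`;
for crossing arcs the default "combined" reading counts span plus
chunk-level distance, `|v − u| + |chunk(v) − chunk(u)|`, and
`MDD = (Σ_i |cdd_i| + |ldd_i|)/(n − 1)`. The combined reading is the minimal
one that (a) collapses to the classical `Σ|v − u|/(n − 1)` when all elements
share one chunk, and (b) makes boundary-crossing strictly more expensive —
under it, inserting a chunk boundary anywhere never decreases the score
(property-tested on 1,000 random structures). The alternative `chunk_only`
reading (crossing arcs count only the chunk distance) is exposed because the
defining equation does not disambiguate it, but note it is *not*
boundary-monotone: splitting a same-chunk arc trades its span for a chunk
distance of 1. The canonical design comparison uses 12 elements in two
chunks — within: arc 2→5 in the first chunk (the second chunk being the
interleaved filler), 3/11; across: arc 5→8, 4/11.

# Numerical and engineering choices

* Sampling rates must put the 250 ms syllable and 80 ms silence on integer
  sample counts (multiples of 100 Hz for the default timing); epoching and
  event alignment are then exact and the stream's period is an exact bin.
* The permutation core and the IIR recursion are compiled (Rcpp): the
  calibration criterion (500 null simulations at 2,000 permutations each)
  is infeasible in pure R within the test budget.
* Degenerate inputs: a zero neighbour aggregate with positive target power
  yields `Inf` (flagged, not an error); all-equal target/neighbour values
  give t = 0, p = 1; epochs extending past the recording are dropped and
  counted rather than failing the whole analysis; an event table with
  mismatched inter-onset intervals or unbalanced dependency roles is
  rejected at construction.
* Determinism: every stochastic step takes a seed; generators restore the
  caller's RNG state; a fixed pipeline seed yields byte-identical reports.
  Derived seeds stay below 2³¹.
* Cohort-scale tests run at 100 Hz / 16 channels instead of 500 Hz / 63
  channels to fit the compute budget; subject counts, epoch counts, trial
  counts and all amplitude/noise parameters stay at the stated values. The
  montage reduction loses nothing tested here (the synthetic topography is
  uniform; adjacency only shapes cluster formation, which is exercised at
  both scales).
* Recordings are exchanged as little-endian float32 flat binary with a JSON
  sidecar (primary) or as minimal 16-bit EDF (one continuous data record;
  round trips exact to the per-channel quantization step).
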