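# chunktag

Frequency-tagging and ERP analysis of chunked syllable streams with
non-adjacent dependencies (NADs), as an end-to-end tested R pipeline with a
synthetic EEG generator in place of human recordings.

## The scientific problem

Listeners sample continuous speech in chunks of limited duration, yet
language routinely links elements that are far apart. Artificial-grammar
(AG) studies probe this tension with isochronous syllable streams: syllables
of 250 ms are grouped into 6-syllable chunks, and an extra 80-ms silence
marks each chunk boundary, so chunks recur every

```
T_chunk = 6 x 0.250 s + 0.080 s = 1.58 s   =>   f_chunk = 1/1.58 ≈ 0.63 Hz
```

with a mean syllable rate of `6/1.58 ≈ 3.8 Hz`. If the brain tracks the
chunks, its spectrum shows a peak at `f_chunk` (frequency tagging). On top of
the chunks, the streams carry learned dependency pairs placed either inside
one chunk (positions 2 and 5) or across a boundary (position 5 of one chunk
to position 2 of the next). The question is whether dependencies that cross a
chunk boundary are processed as readily as dependencies confined to a chunk.

The package implements the full desk-scale analysis:

* **Design** — learning-phase streams and balanced 2x2 test trials
  (within/across x NAD/violation) as validated event tables.
* **Simulation** — multichannel EEG-like recordings: a response kernel at
  every syllable onset, a gain on chunk-initial syllables (so the chunk-rate
  peak emerges from event structure), a condition-dependent deflection at the
  second dependency element, and 1/f background noise.
* **Spectral statistics** — per-epoch DFT coefficients `X_n(f)` and

  ```
  EP(f)   = |Σ_n X_n(f)|² / N                                  (evoked power)
  EPn(f)  = E(f) / Σ_w E(w),  |w − f| < 0.5 Hz, w ≠ f          (normalized)
  ITPC(f) = √[(Σ_n cos θ_n)² + (Σ_n sin θ_n)²] / N             (phase coherence)
  ```

  with paired target-vs-neighbour-bin group tests.
* **ERP statistics** — epoching (−100 to 300 ms, baseline −100 to 0 ms), a
  zero-phase 25 Hz Butterworth low-pass, and a spatio-temporal
  cluster-mass sign-flip permutation test (cluster mass `Σ|t|^η`, maximum
  statistic over within-subject condition swaps).
* **MDD** — a chunk-aware mean dependency distance
  `MDD = (Σ_i |cdd_i| + |ldd_i|) / (n − 1)` separating within-chunk (`cdd`)
  and between-chunk (`ldd`) arc contributions.

## Worked example

A reduced synthetic cohort (12 subjects, one audio per condition, 100 Hz,
8 channels, 500 permutations; ~30 s on one CPU):

```r
library(chunktag)
report <- run_all(reduced_config(n_subjects = 12L, seed = 5L))
print(report)
```

```
<chunktag_report> 12 subjects, seed 5
  EPn_chunk     target 0.0888 vs neighbours 0.0642, p = 0.0188
  EPn_syllable  target 14.3409 vs neighbours 0.0056, p = 6.16e-12
  ITPC_chunk    target 0.3002 vs neighbours 0.2461, p = 0.00727
  ITPC_syllable target 0.9844 vs neighbours 0.2598, p = 7.99e-19
  ERP within  min cluster p = 0.001996
  ERP across  min cluster p = 0.7844
```

Reading: the normalized evoked power and phase coherence peak at the chunk
(~0.63 Hz) and syllable bins relative to their neighbouring frequency bins
(the streams were learned/tracked), and the NAD-vs-violation ERP difference
forms a significant spatio-temporal cluster only when the dependency is
confined to a chunk — the paradigm's qualitative signature. At the full
default scale (`pipeline_config()`: 31 subjects, 72 epochs per condition,
36 test trials per cell) the same pattern appears with far larger margins.

The dependency-distance contrast of the two designs:

```r
mean_dependency_distance(nad_design_structure("within"))   # 3/11 ≈ 0.273
mean_dependency_distance(nad_design_structure("across"))   # 4/11 ≈ 0.364
```

A boundary between the arc's endpoints always raises the score: crossing
dependencies are structurally more expensive.

## Command line

```sh
Rscript inst/cli/chunktag.R design --condition within --pair 1 --n 72 \
    --seed 1 --out events.tsv
Rscript inst/cli/chunktag.R simulate --events events.tsv --seed 1 --out rec.bin
Rscript inst/cli/chunktag.R spectral --recording rec.bin --out learn
Rscript inst/cli/chunktag.R mdd --structure structure.tsv
Rscript inst/cli/chunktag.R run-all --preset reduced --seed 1 --out out/
```

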