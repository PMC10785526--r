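---
title: "Clustered metagene profiles: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered metagene profiles: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustagene)
```

## Why cluster metagene curves

A metagene plot compresses thousands of per-feature coverage profiles into
one average curve. Averaging is destructive when the population is a
mixture: a subpopulation with 5'-biased signal and one with 3'-biased
signal average to a plateau that describes neither. `clustagene` treats
each feature's length-normalized coverage vector as a point in
$\mathbb{R}^L$ and partitions the points by k-means before averaging, so
each cluster's center *is* a metagene curve for an internally coherent
subpopulation. The conventional unclustered curve is always emitted too —
it equals the member-weighted mean of the cluster centers, which the test
suite asserts.

## The procedure and its assumptions

1. **Coverage.** One pass over a SAM file produces one integer depth array
   per chromosome declared in the `@SQ` headers. A record contributes +1 to
   every reference position consumed by CIGAR `M`, `=` or `X`; `N`
   (splice skip) and `D` (deletion) advance along the reference without
   contributing; `I`, `S`, `H`, `P` consume no reference. Unmapped,
   secondary and supplementary records are excluded; duplicates and low
   MAPQ are *included* by default (no filters beyond the structural ones),
   both togglable (`keep_duplicates`, `min_mapq`). Mates of a pair count
   independently. Memory scales with genome size, not read count.
2. **Length normalization.** A vector of length $m$ becomes $L$ bins
   (default $L = 100$, a common metagene resolution) by averaging the
   underlying step function over windows of width $r = m/L$:
   $\text{bin}_j = \frac{1}{r}\int_{jr}^{(j+1)r} f(x)\,dx$, with boundary
   positions weighted by fractional overlap. "Average over windows of size
   $r$" is only well-defined verbatim for integer $r$; the fractional-
   overlap integral is the unique extension that is exact for all $r$
   (up-, down-, or non-sampling) and preserves the mean to floating-point
   accuracy — both properties are tested (|Δmean| ≤ 1e−9 over 1000 random
   vectors, identity at $L = m$).
3. **Clustering.** For fixed $k$: centers initialize as i.i.d. uniform
   draws from $[\min X, \max X]$ (one *global* range — "the range of the
   data" read most naturally; per-position ranges were the considered
   alternative), rows are assigned to the center minimizing
   $\sum_j d(x_j, c_j)$, centers update to positionwise member means, and
   the loop stops when assignments stabilize or after `max_iter = 300`
   iterations. $d$ is the squared difference by default; mean-update
   centers are the exact minimizer only under squared distance, which
   yields a provably non-increasing objective (asserted every iteration).
   An `"absolute"` mode honors the literal "distance at each point"
   reading, at the cost of those guarantees.
4. **Choosing k.** $k$ grows from 1; the search stops at the first
   $k \ge 2$ whose relative improvement
   $(D(k{-}1) - D(k))/D(k{-}1)$ is at or below the threshold
   (default 0.20 — boundary equality counts as "failed to exceed"), and the
   model for $k-1$ is returned. A zero objective returns immediately;
   `k_max = 10` caps pathological growth with a warning.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `bins` (L) | 100 | bins per feature | common metagene resolution; runtime and resolution scale linearly |
| `threshold` | 0.20 | fraction in (0,1) | elbow sensitivity; smaller → more clusters |
| `restarts` | 5 | runs per k | damps random-init variance; 1 mirrors the single-init procedure |
| `seed` | 1337 | integer | full reproducibility of text outputs |
| `k_max` | 10 | clusters | termination guarantee |
| `distance` | squared | squared/absolute | squared gives monotone convergence with mean updates |
| `reverse_minus` | TRUE | — | 5' end at position 0 regardless of strand (metagene convention) |
| `scale_rows` | FALSE | — | TRUE clusters shape only (each row / its mean); default clusters absolute depth |
| `pseudocount` | 1 | counts | log2-ratio mode: log2((t+1)/(c+1)) per base, before binning |

## Design choices that were genuinely open

* **Empty-cluster reseeding.** Random reseeding makes convergence and
  tests flaky; instead an empty cluster deterministically captures the row
  farthest from its assigned center. This strictly decreases the
  objective, so monotonicity survives.
* **Warm start across k.** Best-of-random-restarts does not guarantee
  $D(k) \le D(k-1)$ — a desirable sanity property of the trace. Each
  $k \ge 2$ therefore also evaluates one candidate seeded with the
  previous best centers plus the farthest row; its initial assignment
  already scores $\le D(k-1)$ and iterations only improve it, so the trace
  is provably non-increasing. Set `warm_start = FALSE` with `restarts = 1`
  for the plain single-random-initialization algorithm.
* **Ties** in assignment go to the lowest center index; equal-objective
  restarts keep the earliest candidate. Both make reruns byte-identical.
* **Zero-coverage features are retained** as zero rows (dropping them
  would silently alter cluster composition; the skipped/retained counts go
  to the log and `run_report.json`).
* **Minus-strand reversal defaults ON** (disable with
  `--no-reverse-minus`); whether the upstream convention reverses is
  unknowable from format alone, so it is a flag.
* **Cluster files are numbered from 1** (`cluster_1.txt`), the R
  convention; every plotted series is also written as TSV so numeric
  content never has to be recovered from images.

## What the simulator emulates — and what it does not

`generate_fixture()` plants per-feature expected-depth profiles (uniform
baseline 5×, Gaussian bump to 30× centered at 10%/50%/90% of the feature,
σ = 10% of feature length) and realizes them by *sampling read start
positions* from the profile density (read length 50, fully inside the
feature), so depth noise is Poisson-like by construction and the real
SAM → coverage → binning path is exercised, including mirrored profiles on
minus-strand features. Feature lengths are uniform on 200–1000 bp — a
deliberate, fixed choice spanning short-to-typical CDS lengths so that the
binning step sees ratios both near and far from integral. What it does
*not* emulate: mappability gaps, GC bias, paired-end fragments, spliced
reads, sequence content (SEQ/QUAL are `*`), or between-feature expression
dispersion beyond Poisson counting noise. A green recovery test therefore
establishes that the pipeline separates genuinely distinct shape classes
at realistic depth — not that it would resolve subtler mixtures in
real libraries.

## Numerical notes and degenerate inputs

Binning uses the cumulative-sum representation of the step-function
integral, so bin sums telescope and the mean is preserved exactly up to
round-off; $L = m$ short-circuits to the identity. Squared distances are
computed via the Gram expansion with negative round-off clamped at zero.
A constant matrix has $D(1) = 0$ and selects $k = 1$ immediately. Features
out of chromosome bounds, on undeclared chromosomes, or with malformed
annotation lines are skipped with counted warnings; an alignment record on
an undeclared chromosome is fatal (it indicates the wrong reference).
`k > n` is an error; `n < k` distinct rows fall back to random-in-range
centers during reseeding.

## Known limitations

Uniform-in-range initialization can place centers far from any data in
high dimensions, which is why restarts default to 5. K-means prefers
spherical, similar-size clusters; strongly unbalanced mixtures may need a
lower threshold. The elbow rule with a 20% threshold can keep splitting
diffuse low-dimensional clouds (splitting a 2-D Gaussian buys ~30%);
at metagene dimensionality (L = 100) this is not observed in practice.
Flanking regions, TSS-anchored windows and per-library depth normalization
(CPM/RPKM) are out of scope; BAM users convert with `samtools view -h`
upstream.
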