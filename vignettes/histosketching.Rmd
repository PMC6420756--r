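---
title: "Histosketching microbiome k-mer spectra: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histosketching microbiome k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histosketchr)
```

## The problem

Comparing shotgun microbiome samples by their k-mer content normally requires
either full k-mer spectra (memory grows with diversity) or MinHash sketches
(fixed memory, but blind to k-mer *frequency*, which carries most of the
taxonomic-abundance signal).  `histosketchr` implements the middle road: a
fixed-memory, single-pass reduction of a read stream to a **histosketch** — a
Z-slot summary of the sample's *weighted* k-mer spectrum whose slot-match rate
between two samples is an unbiased estimate of the weighted Jaccard
similarity of their spectra.

## The model

**Binning.** Each read is decomposed into canonical k-mers (2-bit packed,
minimum of forward and reverse-complement encodings; windows containing
non-ACGT symbols are skipped).  Encoded k-mers are hashed uniformly into `X`
histogram bins.  The spectrum being sketched is the histogram `V` of bin
frequencies `W_i`.

**Counting.** Bin frequencies are tracked by count-min sketches — `d` hash
tables of `w` counters with `d = ceiling(log(1 - delta)/log(0.5))` and
`w = ceiling(2/epsilon)`.  At the defaults (`epsilon = 1e-4`,
`delta = 0.9`) this is 4 x 20,000 counters; estimates never underestimate
and overestimate by at most `epsilon * N` with probability `delta` (`N` =
total mass).  `X` defaults to `d * w` = 80,000, so bin identity is
well-defined while the counter budget stays fixed.  Counters are real-valued
so decay scaling composes with increments.

**Consistent weighted sampling.** For bin `i` and sketch slot `j`, three
variables are drawn: `r, c ~ Gamma(shape 2, scale 1)` and
`beta ~ Uniform(0, 1)`.  The hash of a bin with frequency `W_i` is

    y = exp(log W_i - r * beta)
    a = c / (y * exp(r))

and slot `j` keeps the bin with minimal `a` (the sketch `S_j`) together with
that minimum (`A_j`).  The minimum is attained by bin `i` with probability
proportional to `W_i`, which is what makes the slot-match rate between two
sketches estimate the weighted Jaccard similarity of the underlying spectra
(standard error `sqrt(J(1-J)/Z)`).

A note on the Gamma parameterization: the scheme is sometimes written
"gamma(1, 2)" with the shape/scale order left implicit.  The
weighted-Jaccard guarantee requires the density `x * exp(-x)`, i.e.
Gamma(shape 2, scale 1), which is what this package draws (each `r` and `c`
is a sum of two unit exponentials).  Draws are **counter-based**: a pure
64-bit hash function of `(i, j, master_seed)`, never precomputed or stored —
storing `3 * X * Z` reals would defeat the fixed-memory goal — and therefore
identical across calls, processes and samples.

**Incremental updating.** When an element `(bin, amount)` arrives, the
persistent count-min sketch is credited, the bin is re-hashed at its
*cumulative* frequency estimate, and any slot where the new hash beats the
stored `A_j` is replaced (strict improvement only, so ties keep the
incumbent and the lower bin index wins at creation).  Because the hash
depends only on the cumulative frequency, the final sketch is independent of
element order and partitioning whenever the count-min estimates are exact —
the incremental-equals-batch property the test suite asserts bit-for-bit.

**Concept drift.** With decay ratio `q`, before each flush the persistent
counters are scaled by `w = 1 - q` and every stored hash is divided by `w`,
so old minima become progressively easier to displace and the sketch tracks
the recent composition of a drifting stream.  The cadence (once per flush)
and the weight form follow the gradual-forgetting scheme; with `q = 0` the
pipeline is exactly order-invariant.

**Streaming architecture.** `sketch_stream()` deals reads round-robin to
`num_counters` counting workers, each with a local count-min sketch keyed by
bin.  Every `interval` reads a worker flushes its touched `(bin, estimate)`
elements — in ascending bin order, a deterministic choice that is
result-equivalent to any order because updates depend only on cumulative
counts — to the single sketcher, wipes its store, and a snapshot is emitted.
Snapshots are what the streaming classifier consumes.

## Downstream layers

* **Distances** (`pairwise_matrix()`): slot-match Jaccard; weighted Jaccard
  distance `1 - sum(min(u, v)) / sum(max(u, v))` on per-slot weight
  surrogates `u_j = 1/A_j` (the stored hash is inversely monotone in the
  underlying weight), with the min-term zeroed where the slot bins disagree
  since disagreeing slots share no mass; Bray-Curtis and Euclidean on the
  same surrogates.  The surrogate transform is isolated in one internal
  function so alternatives (raw `A`, ranks) can be swapped.
* **LSH forest** (`lsh_index_*()`): the S-vector (never `A`) is split into
  `L` chunks of `K` slots, each serialized little-endian into a table key; a
  query's candidates are entries colliding in any chunk, post-filtered by
  exact slot-Jaccard so the threshold contract is literal.  Tuning
  enumerates `(K, L)` pairs with `K * L` dividing `Z` under the collision
  model `p(s) = 1 - (1 - s^K)^L`, scoring `fn = 1 - p(t)` and
  `fp = p(t - 0.05)`, and minimizes `fp + fn` (ties prefer larger `K`).  The
  0.05 false-positive margin is a fixed, configurable choice.  Hash tables
  are kept as keyed maps; the sorted-array search form of the original
  implementation is a performance detail with identical results.
* **Classifier** (`train_sketch_classifier()`): a random forest of 1000
  bootstrapped trees on raw S-vectors (one feature per slot), stratified
  80/20 split plus stratified ten-fold cross-validation, all under one seed.
  Stratification and seeding are reproducibility choices of this package.
  Raw integer bin identifiers are representation-sensitive for tree splits,
  so an optional `"frequency"` encoding (vocabulary-bin occurrence counts)
  is provided; the default stays with raw S.  `classify_stream()` predicts
  on each snapshot and signals termination once the maximal class
  probability reaches the threshold — cooperative stopping, with the
  sketcher owning the stream.

## Defaults and units

| parameter | default | meaning |
|---|---|---|
| `k` | 21 | k-mer length (bases); pipeline supports 1-31 |
| `sketch_size` (Z) | 512 | sketch slots; similarity SE `sqrt(J(1-J)/Z)` |
| `epsilon` | 1e-4 | count-min relative accuracy (fraction of total mass) |
| `delta` | 0.9 | probability the epsilon bound holds |
| `num_bins` (X) | 80,000 | histogram bins (= `d * w` at defaults) |
| `decay_ratio` | 0 | per-flush forgetting fraction (0 = off) |
| `interval` | 0 | reads per worker between flushes (0 = whole input) |
| `min_quality` | 0 | 3' BWA-style trimming threshold (Phred; 0 = off) |
| LSH `threshold` | 0.9 | Jaccard similarity cutoff |
| `prob_threshold` | 0.9 | streaming classification stop probability |

Quality trimming uses the BWA running-sum rule (maximize the suffix sum of
`min_quality - q_i`; ties keep the longer read).  It defaults to off so that
sketches are reproducible functions of the raw reads.

## What the synthetic generator emulates — and what it does not

`make_community()` builds taxa as i.i.d. uniform ACGT "genomes" with a
relative-abundance vector; `generate_reads()` draws reads proportional to
abundance with uniform positions/strands, substitution errors at a flat
rate, and constant Phred-40 qualities.  At `k = 21`, random 21-mers
essentially never collide between taxa, so the overlap of two communities is
controlled purely by shared taxa and abundances: `perturb_community()`
therefore *plants* a known weighted Jaccard (for uniform abundances,
swapping a fraction `s` of taxa leaves `J ~ (1-s)/(1+s)`), and
`exact_spectrum()` provides the dictionary-count oracle all approximations
are validated against.

This emulates the structure of multi-body-site, diet-shift and
treatment-versus-control designs at desk scale.  It does **not** model real
platform noise (indels, quality decay along reads), host contamination,
strain-level sharing of k-mers between taxa, or realistic genome sizes — so
green tests demonstrate the correctness and statistical calibration of the
sketching machinery, not classification performance on real cohorts.

## Numerical choices and degenerate inputs

* Hashing is splitmix64-based and counter-based throughout; bin assignment,
  count-min tables and CWS draws use domain-separated seeds derived from one
  `master_seed`.  Two sketches are comparable iff
  `(k, sketch_size, num_bins, master_seed)` agree; every cross-sketch
  operation enforces this and names the mismatched parameter.
* Uniform variates are taken strictly inside (0, 1) so logs are finite;
  hashes are computed in the log domain and exponentiated once.
* Empty slots hold `A = +Inf` (any finite hash wins); an all-zero spectrum
  or a stream with no ACGT k-mers is an error (`"empty spectrum"`,
  `"nothing to sketch"`), not a silent empty sketch.
* Count-min collisions break exact incremental-equals-batch equivalence;
  equivalence tests use `epsilon = 1e-5` with at most 1,000 occupied bins
  (collision probability ~1e-9) and integer-valued spectra so partial sums
  are exact in doubles, making the comparison bit-level.
* k-mer encodings surface to R as doubles — exact integers for `k <= 26`;
  the C++ stream pipeline carries native 64-bit values for any `k <= 31`.

## Validation scales

The test suite validates each layer against an independent oracle at sizes
chosen to keep the whole suite around three minutes: similarity calibration
on ten planted community pairs (20 taxa x 300 bp) x 20 seeds at `Z = 512`;
bit-identical batch/stream equivalence on 20 spectra (`X = 1000`,
`Z = 128`) x 3 orderings; proportional CWS selection on a 5-bin toy spectrum
over 10,000 slots (chi-square, alpha 0.001); count-min soundness against a
dictionary on 10^5 adds; LSH recall against brute force on 20 x 50 planted
sketches; clustering of 5 planted groups x 6 replicate read sets (8 taxa x
500 bp, 3,000 reads); and two-class classification over 60 read-derived
samples (16 taxa x 400 bp, taxon-swap 0.5, 1,500 reads each, `Z = 128`)
including the stream-termination law at intervals 100/250/500 over 10
seeds.

## Known limitations

* Exact k-mer counting is out of scope by design; all counts are count-min
  estimates (one-sided error).
* The weighted-Jaccard weight surrogate `1/A` is monotone in the underlying
  weight but not equal to it; weighted-Jaccard *distances* are therefore
  comparative, not calibrated estimates of the spectral distance (the
  slot-match similarity is the calibrated estimator).
* Paired-end mates are treated as independent reads; FASTA input, adapter
  trimming and assembly-based features are out of scope.
* The LSH tuning objective models chunk collisions as independent; measured
  recall is asserted only up to the modelled false-negative rate.
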