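---
title: "Conditional (m,n)-mer features: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional (m,n)-mer features: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condmer)
```

## The feature model

A k-mer frequency vector summarizes a nucleotide sequence by the relative
frequency of each of the $4^k$ length-k words. Under the digit map A=0,
C=1, G=2, T=3 every word maps to a base-4 integer (ACCTGA has digits
011320, code 376), so the vector is indexed by code: $f^k_v = c^k_v / N_k$
where $c^k_v$ counts the sliding windows equal to word $v$ and $N_k$ is the
number of valid windows. When $N_k = 0$ the vector is all zero.

The (m,n)-mer replaces the unconditional word probability with a
conditional one. Think of the sequence as emitted by a stationary Markov
chain: the full order-d transition matrix over k-mer states has $4^{2k}$
entries, which is prohibitive, but a reduced $4^m \times 4^n$ matrix
$P^*$ — the probability of an n-mer suffix given its immediately preceding
m-mer context — keeps the conditional structure at the size of a plain
(m+n)-mer vector:

$$f^{m,n}_{u,v} = \frac{c^{m+n}_{4^n u + v}}{c^{(m)}_u},$$

where $c^{(m)}_u$ counts the occurrences of context $u$. Each observed
context's row sums to 1, the whole vector sums to the number of observed
contexts (at most $M = 4^m$), and dividing by $M$ yields a vector with the
same length and the same $[0, 1]$ range as the (m+n)-mer vector — so any
software consuming k-mer frequency tables accepts (m,n)-mer tables
unchanged. `mer_spec(0, k)` degenerates exactly to the plain k-mer.

Note the joint index above is $4^n u + v$ (context digits are the most
significant): this is the row-major flattening of the $M \times N$ matrix
and the only indexing consistent with the base-4 code of the concatenated
word when $M \neq N$.

### The context denominator

Two denominators are defensible for $c^{(m)}_u$. Dividing the (m+n)-mer
frequency by the *whole-sequence* m-mer frequency follows the conditional
probability formula literally, but edge effects — the trailing $m$
positions of the sequence, and m-mers whose following suffix window
contains an ambiguous base — break exact row-stochasticity: for ACCTGA at
(1,1) the vector sums to 4.2 rather than 4. The package's default instead
counts contexts only at positions where a full unambiguous (m+n)-window
starts (`context_counts()`), which makes every observed row sum to exactly
1 and the sum-to-$M$ normalization exact. The literal variant remains
available via `mn_frequencies(..., context = "sequence")` for parity
experiments; for long sequences with few ambiguous bases the two differ by
$O(m / L)$.

## Counting and preprocessing rules

* **Ambiguity.** Any window containing a non-ACGT character is skipped
  entirely — no partial credit, no imputation — so counts remain exact
  window tallies. Contexts observed zero times get all-zero rows,
  extending the zero-total rule for unconditional vectors.
* **Strand and case.** Forward strand only (no reverse-complement
  collapsing); lowercase input is uppercased; U is rejected (DNA only).
* **Size cap.** `m + n` is capped at 12 by default: vectors are dense, and
  $4^{12} \approx 16.8$M doubles is the practical ceiling for the simple
  CSV contract. Typical use is $k \le 5$.
* **Record filtering.** Records whose ambiguous-base fraction *strictly
  exceeds* 2% of their length are dropped (boundary cases kept); the drop
  report records each removed id and its fraction.
* **Fragmentation.** Up to 3 non-overlapping fragments of a fixed length
  (the benchmark ladder uses 300–10,000 bp) are cut per record.
  Head-anchored consecutive windows are the default because they are
  deterministic; seeded random non-overlapping placement is available.
  Coordinates are 0-based half-open and embedded in fragment ids.

## The synthetic benchmark generator

Real benchmark collections (viral genome sets, metagenomic contig bins)
are not shipped; the package instead simulates labeled datasets from
stationary Markov chains, which is the generative mechanism the feature is
designed around. A class is an order-d chain (`transition_model()`); a
second class at controlled separation is made by mixing every transition
row with an independent random stochastic row,
$(1-\varepsilon)\,\text{row} + \varepsilon\,\text{random}$
(`perturb_model()`). The default benchmark preset is order-2 chains,
$\varepsilon = 0.15$, 500 sequences per class, at fragment lengths
300–3000 bp — 300 bp being the hard end of the ladder. One master seed
fans out to per-sequence sub-seeds through a fixed counter, so datasets
are reproducible and order-independent.

What the simulator deliberately does not emulate: indels, repeats,
chimeric joins, sequencing error, GC skew that drifts along the genome,
and — most importantly — the polyphyletic, non-Markovian structure of real
viral and bacterial collections. Passing benchmarks here show the
machinery is correct and calibrated, not that conditional features will
win on any particular real dataset.

A useful identity links the simulator back to the feature: for an order-d
chain, the (d,1)-mer conditional matrix of a simulated sequence is exactly
the maximum-likelihood estimate of the generating transition matrix. At
length $10^5$ the max-abs estimation error for d=1 is below 0.02 (a
~3-sigma multinomial bound at that window count), which the tests check
over seeded replicates.

## The evaluation harness

Classification follows a resampling protocol: for each of `n_resamples`
random resamplings a balanced stratified sample (`per_class` per class,
without replacement) is drawn, 10-fold cross-validation is repeated 3
times with random splits, out-of-fold class scores are pooled within each
repeat, the AUC (Mann–Whitney form; macro-averaged one-vs-rest beyond two
classes, with accuracy recorded alongside) is computed per repeat and
averaged. The per-resample AUCs give the report's mean and a
normal-approximation 95% CI. The full-scale protocol is 50 resamplings of
500 per class; the package's tests run scaled-down versions (10
resamplings of 100 per class from a 500-per-class population) so the whole
suite stays in the low minutes on one CPU.

The classifier registry holds three deterministic-given-seed model
families with fixed small hyperparameters — 5-nearest-neighbour (the
default), ridge-regularized logistic regression ($\lambda = 0.01$, well
posed when features outnumber samples), and a 200-tree probability random
forest. No tuning grid: determinism and runtime were preferred, and the
comparison of interest is between feature families, not classifiers.

Two feature families are compared by a ternary test on their per-resample
metrics: Welch's two-sided t test at $\alpha = 0.05$, verdict by the sign
of the mean difference when the null is rejected, tie otherwise. A
permutation test (10,000 shuffles) serves as a cross-check in the tests.
Constant metric vectors on both sides are handled explicitly (tie when
equal). Per-resample metrics from overlapping resamples are positively
correlated, so the test is anti-conservative in absolute terms; it is used
as a symmetric decision rule between families measured under identical
resamples, where that bias cancels.

Clustering quality is scored by the adjusted Rand index against the true
labels, averaged over 3 seeded replicates, with k-means (5 restarts), Ward
agglomerative (deterministic — replicates coincide by design) and spectral
clustering in the registry. The ARI returns 1 in the degenerate case where
the chance-correction denominator vanishes (e.g. one cluster vs one
class), since the partitions then agree exactly.

## Numerical choices

* Frequencies are exact ratios of integer counts; invariants
  (row-stochasticity, sum-to-observed-contexts, chain rule
  conditional × marginal = joint) hold to 1e-12 and are tested at that
  tolerance.
* Feature-matrix CSVs are written with `%.15g` so a write/read round trip
  is faithful below 1e-12 per cell; column order is a pure function of the
  spec list (spec order, then code order), and labels use `context|suffix`
  with a `m<m>n<n>.` prefix when several families are concatenated, which
  keeps them comma-free and unique.
* Sub-seeds derive from the master seed as
  $(\text{seed} + 1000003\,i) \bmod 2147483629 + 1$, keeping every seed a
  valid 32-bit integer.
* k-means ties, knn ties and forest bootstraps are all seeded through the
  same fan-out, so every report is a pure function of (data, seed).

## Known limitations

* Dense vectors only: no sparse or streaming counting beyond
  $m + n = 12$, no protein alphabets, no gapped/spaced mers.
* Redundancy removal at a given identity threshold (the curation step that
  usually precedes benchmark construction) is out of scope — use a
  dedicated clustering tool beforehand.
* The simulator's Markov world is the feature's home turf; conclusions
  about real polyphyletic data require real data.
* The ternary test inherits the usual caveats of comparing resampled
  metrics (correlated resamples, unadjusted multiplicity when many
  families are screened).
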