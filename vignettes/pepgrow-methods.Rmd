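---
title: "Models and methods behind pepgrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepgrow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepgrow)
```

pepgrow analyzes competitive growth experiments in which a pool of cell
clones, each expressing a different short open reading frame, is passaged
serially while the relative abundance of every clone is tracked by amplicon
sequencing of the insert itself. The insert doubles as the clone's barcode.
This vignette explains the models the package implements, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The library model

Each clone carries one integrated construct expressing a 174-nt ORF
(58 codons): a start codon and one constant codon, 50 random codons
(150 random nt), and a six-histidine tag, with a HindIII site plus Kozak
context upstream and a stop codon plus NotI site downstream
(`library_design()`). Two conventions are fixed here that the construct
itself leaves open:

* **Codon layout.** Codon 1 is the start codon and codon 2 the second
  constant codon; the random region occupies codons 3–52 and the His tag
  codons 53–58. The identity of the second constant codon is a property of
  the cloning design, not of the analysis, so it is a parameter (default
  `GCC`, a G-initial codon consistent with a strong Kozak context and a
  frequently used human alanine codon). The His codon default is `CAC`, the
  most used human histidine codon.
* **Peptide length counts the start residue.** A peptide truncated by a
  stop at the first random codon therefore has length 2.

### The geometric length null

A random codon is a stop with probability $P$ (3/64 under uniform
nucleotide usage; `p_stop` is exposed so biased libraries can supply an
empirical value). The number of random codons translated before the first
stop is geometric, so a peptide truncated at trial $k$ has probability
$(1-P)^{k-1}P$ and length $k+1$, and the full-length 58-residue class (no
internal stop over 50 trials) carries the atom $(1-P)^{50}$, about 0.0907.
`peptide_length_null()` returns the complete probability mass, which sums
to 1 by construction; multiplying by the library size gives expected counts
per length class. The count of distinct peptide sequences of length $k$ is
$20^k$; because $20^{58}$ has 76 digits, `unique_combinations()` returns
exact decimal digit strings rather than doubles.

## The synthetic-data generator

`generate_library()` draws unique, motif-free inserts (HindIII/NotI
recognition sites are resampled away so the cloning sites remain
unambiguous) under a per-position nucleotide distribution, which can
reproduce the slight thymine-up/adenine-down bias seen in synthesized
libraries. `simulate_growth()` then emulates the passaging design:

* five replicate flasks, ten sampled timepoints, one-fourth of cells
  carried over per passage (defaults of `growth_sim_config()`);
* fitness acts multiplicatively per doubling:
  $f_i' \propto f_i (1+s_i)^d$ with $d = 2$ doublings per passage by
  default (a 1/4 carryover returning to confluence implies two doublings);
* the carryover bottleneck and the sequenced aliquot are independent
  multinomial draws of `cells_per_passage` cells (default $3\times10^6$,
  the seeding count of the flask-scale experiment; the pool-scale wrapper
  `make_mdng_pool()` uses $7\times10^5$ and 3 replicates over 5 cycles).
  The true effective bottleneck of the wet experiment is unknown; these are
  configuration, not inference.

Timepoint $t$ records the flask composition after the $t$-th growth step,
so nine passages separate the first and last of ten timepoints. A
deterministic mode propagates expectations without sampling and is used by
the closed-form tests (frequency conservation holds there to 1e-12).

`simulate_reads()` draws reads multinomially from clone frequencies at a
configurable depth and applies independent per-base substitution errors
(default rate 0.001). Error positions are generated by geometric
gap-skipping, which is the exact same model as per-base Bernoulli draws but
costs time proportional to the number of errors. Indels, PCR bias, chimeras
and paired-end structure are deliberately not modeled: the downstream
mapper is a fixed-length Hamming matcher, and declaring indels out of scope
keeps read assignment exact and fast. Consequently, passing tests say
nothing about indel robustness on real data; real libraries are also less
uniform in founding abundance than the default equal-frequency start
(`initial_freq` accepts any distribution).

## Barcode counting

`build_reference()` tabulates the inserts seen at the first timepoint,
ranks candidates by abundance (ties broken lexicographically, so the result
is deterministic), and greedily absorbs any candidate within Hamming
distance `collapse_radius` (default 2) of a more abundant retained center;
retained centers need a founding abundance of at least `min_count`
(default 2). This folds sequencing-error variants back into their source
barcode. `map_reads()` assigns a read to the unique reference insert within
`max_mismatch` (default 2); distance ties are deliberately unmapped rather
than guessed. With 150-nt random barcodes, pairs of distinct clones are
essentially never within distance 4, so radius-2 collapse plus mismatch-2
mapping is conservative. Both steps run on unique sequences weighted by
multiplicity, with the inner loops in C++.

At the default error rate the probability that a read's insert carries more
than two substitutions is about $1 - \sum_{k\le2}\binom{150}{k}
0.001^k\,0.999^{150-k} \approx 4\times10^{-4}$, which is why mapping rates
in simulations sit above 0.99; real experiments report lower rates because
of read cleaning and library impurities the simulator does not emulate.

## Differential abundance

The first-vs-last timepoint contrast uses a deliberately compact
reimplementation of the standard negative-binomial count workflow:

* **Normalization** by median-of-ratios size factors (`size_factors()`).
* **Dispersion** per clone by method-of-moments on normalized counts pooled
  within condition, shrunk halfway (`shrink_weight = 0.5`) toward a fitted
  mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$. Moment estimates on
  five replicates are individually noisy; the trend stabilizes them the
  same way trended-dispersion shrinkage does in the established packages.
* **Testing** by a Wald test on the condition coefficient of a per-clone NB
  GLM with log link, fitted by IRLS with weights $\mu/(1+\alpha\mu)$
  **on the normalized counts**. With a two-group design this makes the
  fold-change estimate exactly the ratio of normalized group means, and
  therefore exactly invariant to rescaling any sample's counts. (P-values
  are invariant only up to a global depth-rebaseline effect: rescaling one
  of $m$ samples shifts all median-of-ratios factors by $c^{1/m}$, and no
  depth-aware variance model is indifferent to a uniform change of apparent
  depth.) No fold-change shrinkage and no outlier filtering are applied.
* **Multiple testing** by Benjamini–Hochberg over the non-missing p-values
  (`adjust_bh()`), and classification as UP/DOWN at adjusted $p <$ 0.05 by
  fold-change sign, everything else (including untestable clones) NS
  (`classify_clones()`).

Clones whose IRLS fit does not converge (for example, a group with all-zero
counts, where the coefficient diverges) are flagged and default to NS —
consistent with treating "not testable" as "no significant change".

The small-pool experiment is summarized differently: `rank_pool_growth()`
computes each clone's frequency ratio between the final cycle and the
start, per replicate, and ranks clones by the mean ratio. Clones with zero
counts at the final cycle in every replicate are flagged failed-to-grow and
excluded from the ranking rather than ranked last, mirroring how
not-applicable entries are handled in the downstream rank correlation.

## Group comparisons and meta-analyses

Per-class feature distributions are compared with a two-sample
Kolmogorov–Smirnov test (`ks_two_sample()`): own ECDF-supremum statistic,
asymptotic Kolmogorov p-value at effective size $n_x n_y/(n_x+n_y)$. The
background of `group_feature_tests()` includes the tested class by default,
mirroring density panels drawn over the whole-library distribution; this
makes the test conservative for large classes, and an exclusive-background
mode is provided for calibrated nulls. Box statistics use interpolated
quartiles (quantile type 7 — no convention was prescribed, so R's default
is used and frozen by tests) and Tukey whiskers at 1.5 IQR. Aggregation
propensity flags use the inclusive boundary (energy of −5 or less).

The meta-analysis operations work on ingested per-gene summary tables (the
package never recomputes disorder scores, aggregation energies or the
RNA-seq differential expression itself):

* `spearman_with_ties()` uses average ranks and the two-tailed
  t approximation, which reproduces both printed correlations from the
  packaged tables (rho −0.21 with p ≈ 0.4 for expression level vs response
  strength over 16 genes; rho −0.07 with p ≈ 0.8 for disorder score vs
  growth rank over the 14 ranked genes). An exact permutation option exists
  for very small n.
* `classify_foldability()` applies strict boundaries (low if IDS > 0.4,
  high if IDS < 0.1); boundary values are intermediate.
* `de_filter()`, `top_n_sets()` and `recurrence_matrix()` implement the
  significant-responder filter (adjusted $p<0.05$, at least 2-fold), the
  top-10-per-direction selection ranked by log2 fold change with
  lexicographic tie-breaks, and the cross-experiment recurrence matrix with
  direction-conflict flags.

## Problem sizes and verification scope

The test suite verifies the length null on a simulated library of $10^5$
clones and the full pipeline (simulate, build reference, count, test,
classify) at 2,000 clones with 10% beneficial and 20% deleterious members
($s = \pm 0.05$ per doubling), five replicates, ten timepoints and $10^6$
reads per sequenced sample — the scale at which sign recovery above 90% for
selected clones and below 7% false calls among neutral clones is expected
and observed. Oracle equivalences (translation, BH, KS statistic, Spearman)
are checked against independent brute-force implementations at 1e-12.

What these tests do *not* show: behavior under indels or adapter
contamination, unequal founding abundances unless configured, PCR
amplification bias, or the exact reproduction of any specific wet
experiment's clone counts — the deposited classification tables of a real
experiment can be tallied with `tally_classes()`, but raw-read reanalysis
is outside desk scale.
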