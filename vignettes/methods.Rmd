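---
title: "Methods: admixture-based population structure and discriminative SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture-based population structure and discriminative SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, the defaults and why they are what they are, what the synthetic
generator does and does not emulate, and the numerical choices that a
user re-deriving results should know about.

## 1. Genotype encoding and preprocessing

Genotypes are numeric: 1.0 homozygous reference, 0.5 heterozygous, 0.0
homozygous alternate, `NA` missing.  A locus's allele frequency is the
mean of its non-missing values — the reference-allele frequency.  This
single orientation is used everywhere: the generator's ancestral
frequencies, the fitted `F` matrix, and the VCF writer (which converts
the reference dose back to alternate-allele GT calls) all share it, and
the tests assert the round trip.

`filter_maf_callrate()` evaluates call rate first and then the minor
allele frequency `min(p, 1 - p)` on the surviving non-missing calls
(defaults 0.70 and 0.05, standard for genotyping-by-sequencing panels).
The order matters for marginal loci and is therefore fixed and stated.
MAF uses only non-missing calls; missing calls do not count as either
allele.  `filter_biallelic_homozygous()` is a variant-level filter: a
locus is dropped if any accession carries a heterozygous call, and
missing calls are ignored — it filters variants, not calls.
`impute_mean()` replaces missing entries by locus means; imputed values
are intentionally allowed off the {0, 0.5, 1} grid, since the consumers
(PCA, k-means, distances) are numeric.

## 2. The admixture model

`fit_admixture()` maximises the binomial admixture log-likelihood

$$\ell(Q,F) = \sum_{ij} \left[ 2 g_{ij} \ln \textstyle\sum_k q_{ik} f_{kj}
  + 2 (1-g_{ij}) \ln \left(1 - \textstyle\sum_k q_{ik} f_{kj}\right) \right]$$

with missing genotypes contributing zero.  The optimiser is the classic
monotone EM for this model: each observed allele is fractionally
attributed to an ancestor in the E-step and both $Q$ and $F$ are
renormalised in the M-step.  EM was chosen over quasi-Newton because
its monotonicity is a testable invariant and it is robust at the scale
this package targets (hundreds of accessions, thousands of loci); the
inner loop is compiled (RcppArmadillo).  One numerical subtlety is
load-bearing: frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ to keep
logs finite, and after the clamp the Q-update rows are renormalised by
their *realised* sums rather than the theoretical allele totals —
normalising by the theoretical totals lets a sub-part-per-million drift
accumulate over hundreds of iterations into divergence on strongly
inbred data, where many frequencies sit at the clamp boundary.

Defaults: `tol = 1e-4` on the log-likelihood change, `max_iter = 2000`,
`n_starts = 3` seeded random restarts keeping the best likelihood.  On
the reference design the EM routinely uses the full iteration budget;
the ancestry estimates stabilise long before the likelihood meets the
tolerance (mean absolute error of Q below 0.01), so the iteration cap
is a compute choice, not an accuracy one.  `K = 1` is solved in closed
form (sample frequencies).

**Choosing K.**  `select_K_elbow()` fits each candidate K and forms
successive gains $\mathrm{gain}(K)=\ell(K)-\ell(K-1)$; the chosen K
maximises $\mathrm{gain}(K)-\mathrm{gain}(K+1)$, the sharpest drop in
marginal gain.  Ties break toward smaller K.  Because between-K
likelihood differences are orders of magnitude larger than within-fit
convergence error, the per-K fits use lighter settings
(`n_starts = 2`, `tol = 1e-2`, `max_iter = 500`); the full curve is
returned so the user can override the choice.  When 1 is included in
the candidate range, its gain is anchored against a constant-frequency
baseline (all loci at the pooled mean frequency); that makes a
structureless panel elect K = 1, but it also means the K = 1 candidate
dominates most structured panels — start the range at 2 unless the
no-structure null is the question being asked.

**Ancestral FST.**  `ancestral_fst()` applies the ratio-of-means
Hudson-type estimator to inferred ancestral frequencies:
$F_{ST}(k,l) = \overline{(f_k-f_l)^2} \,/\,
\overline{f_k(1-f_l)+f_l(1-f_k)}$.  Under the Balding–Nichols
generator with per-ancestor parameters $c_k$, the pairwise expectation
is $(c_k+c_l)/2$ — the package's tests verify this against Monte-Carlo
simulation.  Identical rows give 0 by convention.  Because different
FST estimators differ in their treatment of within-population terms,
published values computed by other tools are approximated, not matched
digit for digit.

## 3. Subpopulation clustering

Accessions are clustered on their ancestry-ratio vectors (rows of Q)
with k-means (base R `stats::kmeans`, 20 seeded random restarts, up to
300 iterations — the same algorithm family the analysis this package
operationalises used).  Cluster quality is the BCTSS ratio
$(TSS - WSS)/TSS$: 0 for a single cluster, 1 for perfect separation,
and 0 by convention when all rows are identical.

**Choosing k.**  `select_k_elbow()` returns the largest k whose
marginal BCTSS gain is still at least `min_gain` (default 0.02, i.e. a
split must keep explaining at least 2% of total variance).  This "last
significant gain" reading was chosen deliberately over the curvature
criterion (maximising the second difference of the curve): with four
well-separated ancestral groups plus one admixed group sitting between
two of them, the curvature criterion elects k = 4 — the admixed group's
split explains genuinely less variance than the splits between pure
groups — while the flattening-point criterion correctly elects k = 5.
The 2% bar is calibrated to ancestry-ratio clustering, where real
subpopulations each explain several percent of total variance; on
arbitrary feature matrices it should be revisited.  The full curve is
always emitted.

**Bootstrap support.**  The support of a cluster is its clusterwise
bootstrap stability: resample n accessions with replacement, re-cluster
at the reference k, match each reference cluster to the replicate
cluster of maximal Jaccard similarity on the resampled multiset, and
average that Jaccard value over replicates.  This operationalises
"the likelihood that each cluster has the same set of members"; it is
the standard stability formalisation of that sentence, and reported
support values depend on it (a membership-probability definition would
give different numbers).  The analysis default is 10,000 replicates;
the package's own tests use 200, which is enough to separate stable
(≥ 0.95) from unstable clusters.  Replicates where a reference cluster
has no resampled member are skipped for that cluster and counted.
Whether to resample accessions or loci is a genuine openness;
accessions are resampled because the support is attached to accession
sets.

## 4. Structure summaries

PCA column-centers the complete numeric matrix without unit-variance
scaling (the convention of the common genotype-PCA tools; scaling is
available as a flag) and decomposes by SVD.  The neighbor-joining tree
uses the mean-absolute-difference distance $d(a,b) = \mathrm{mean}_j
|g_{aj}-g_{bj}|$ — one minus mean identity-by-state, the simplest
metric on the numeric encoding — and classic Saitou–Nei NJ; negative
branch lengths (possible on non-additive inputs) are clamped to zero
with a warning.  The origin association test is a Pearson chi-square
with no continuity correction; zero-total rows/columns are dropped with
a warning, and expected counts are returned for diagnostics.  The
packaged origin table for the 300-accession Thai panel reports 53/68
accessions for two subpopulations where the clustering summary reports
54/67; the discrepancy exists in the published tables themselves and is
preserved as printed.

## 5. Phenotypes

Broad-sense heritability uses the one-way random-effects ANOVA method
of moments: $\hat\sigma^2_e = MS_{within}$, $\hat\sigma^2_G =
(MS_{between}-MS_{within})/r$ floored at zero, and
$h^2_B = \hat\sigma^2_G/(\hat\sigma^2_G + \hat\sigma^2_e/r)$.
Method-of-moments was preferred to REML because it is closed-form and
hand-checkable; at the panel sizes involved the two agree to well
within the estimator's own sampling noise.  Unbalanced designs use the
mean replicate count with a warning; a single replicate leaves
$\sigma^2_e$ inestimable and errors.  Note that on a structured panel
the "genetic" variance includes between-subpopulation differences, so
panel-level h² is higher than the within-subpopulation value the
generator parameters imply.

Domination graphs compare accession-level trait values (means over
replicates — populations of accessions are compared, not plots, to
avoid pseudo-replication) between every pair of subpopulations with
both one-sided Mann–Whitney tests; an edge points from the
stochastically greater group at the fixed per-test level α = 0.001.  No
multiplicity correction is applied across the 10 pairs — α is a
per-test level by design, and the null calibration test shows the
family edge rate stays below 5%.  The U statistic counts pairs with
$x_i > y_j$ plus half-ties; p-values are exact by enumeration when
min(n) ≤ 8 with no ties, otherwise the normal approximation with tie
and continuity corrections (the two agree to |Δp| ≤ 0.01 at n = 8).
Both one-sided tests cannot pass simultaneously at α < 0.5, so the edge
set is antisymmetric by construction.

## 6. Discriminative SNP panels and classification

The scan treats membership of one subpopulation as a binary trait and
regresses it on each locus separately, reporting
$LOD_j = (n_j/2)\log_{10}(RSS_0/RSS_1)$ — the minimal single-marker
formulation of a binary-trait QTL scan, chosen because it is exactly
checkable against a least-squares oracle — together with the
allele-frequency difference between members and non-members.  A perfect
fit is capped at LOD 50.  Ranking is lexicographic: frequency
difference first, LOD second; both are reported so the tie-break is
auditable.  Per population the top loci are taken within a 50–100 band
(truncated by the number of loci with positive frequency difference),
lists are unioned with deduplication, and each panel locus is
attributed to the population where its frequency difference is largest.

Classification is stratified seeded k-fold cross-validation (default
10) with a random-forest default classifier behind a fit/predict
contract — the scientific surface is the protocol and the metrics, not
the tree implementation.  Missing panel genotypes are mean-imputed from
training folds only, to avoid leakage.  Pooled out-of-fold predictions
are scored one-vs-rest per class: precision TP/(TP+FP), recall
TP/(TP+FN), F1 = 2PR/(P+R) defined as 0 when P+R = 0.

Gene annotation is strand-agnostic 1-based inclusive interval
containment against GFF3 `gene` features, plus a flanking report: runs
of panel SNPs with inter-SNP gaps ≤ 100 kb (sub-megabase intervals are
where predictive SNPs cluster in practice) are spanned and all
overlapping genes reported.

## 7. The synthetic generator: what it emulates, and what not

The generator exists because the analysis needs known truth.  It is the
standard generative counterpart of the admixture likelihood:

* **Ancestral frequencies** (`simulate_ancestral_freqs`): per locus a
  base frequency $p \sim U(0.1, 0.9)$, then per ancestor
  $f_{kj} \sim \mathrm{Beta}(p(1-c_k)/c_k,\,(1-p)(1-c_k)/c_k)$ — the
  Balding–Nichols model, in which $c_k$ plays the ancestor's FST
  against the common base.  K = 1 returns the base draw itself.
* **Ancestry** (`simulate_accessions`): pure subpopulations draw their
  dominant weight uniformly from [0.95, 1]; the admixed subpopulation
  draws its mixing proportion from Beta(6, 6) over its two parent
  ancestors.  The concentration 6 gives mixing ratios centred on
  50:50 with spread ≈ 0.14 — a clearly admixed but coherent group.
* **Genotypes** (`simulate_genotypes`): reference dose Binomial(2,
  $\textstyle\sum_k q_{ik} f_{kj}$) divided by 2, with independent
  missingness.  An `inbreeding` coefficient (default 0) makes a
  genotype fully homozygous with that probability; the default rice
  design uses 0.98, because rice is predominantly selfing and a
  homozygous-variant filter on outbred Binomial genotypes at n = 300
  would retain essentially nothing.
* **Phenotypes** (`simulate_phenotypes`): accession genetic value
  Normal(subpopulation mean, σ²_G), plus Normal(0, σ²_e) per replicate.

The reference design (`simulate_rice_panel`): 300 accessions in five
subpopulations of 54/45/67/92/42 (the second admixed between ancestors
A and B), K = 4 ancestors all at c = 0.3 (pairwise ancestral FST ≈ 0.3,
inside the 0.18–0.51 range such panels show), 5,000 loci, 10% missing
calls, inbreeding 0.98, and three traits with subpopulation-ordered
means — flowering (days) 95/105/115/130/97, grain length (mm)
7.6/7.4/7.2/6.2/6.8, plant height (cm) 120/130/140/150/110 — with
variance components (σ²_G, σ²_e, r = 3) = (64, 16), (0.25, 0.04),
(100, 9), i.e. within-subpopulation h² of 0.92–0.97.  The trait
geography mirrors the motivating panel: the admixed group intermediate
in flowering between its parents, the southern group latest-flowering
and shortest-grained, the japonica-like group distinct.

Deliberately **not** emulated: linkage disequilibrium (loci are
independent given ancestry), selection, within-subpopulation
relatedness structure (accessions are exchangeable within groups),
genotyping-error or read-depth artifacts, and trait-by-environment
interaction.  Passing recovery tests on this generator therefore shows
the estimators are correct under the admixture model itself, not that
real GBS data satisfy that model.

## 8. Pipeline, determinism, and problem sizes

`run_pipeline()` executes the stages in order, writes every
intermediate as plain text (VCF, TSV, CSV, newick, .Q/.P, DOT) so any
stage can be replaced by an external tool's output, and records a JSON
manifest with seeds, locus counts before/after filtering and headline
numbers.  Every stochastic stage derives its seed from the master seed;
two runs with the same configuration are byte-identical.

The package's own test and verification runs use the reference design
at 5,000 loci with 200 bootstrap replicates and 1,000 null simulations,
and smaller variants (300–800 loci) for unit tests — sizes chosen so
the full suite exercises every stage, including several complete
pipeline runs, in minutes on a single core while leaving the
estimators' recovery margins wide (ancestry MAE ≈ 0.01 against a 0.05
bound; adjusted Rand index ≈ 0.97 against a 0.95 bound).

## 9. Known limitations

* The EM can be slow to meet a tight likelihood tolerance on strongly
  structured data; parameter estimates converge much earlier.  The
  per-K elbow fits deliberately use coarse tolerances.
* The BCTSS `min_gain` bar (2%) is calibrated for ancestry-ratio
  clustering; very small true clusters (≪ 2% of variance) would be
  missed.
* Bootstrap support values depend on the Jaccard-stability definition;
  they are comparable within this package, not across tools with other
  definitions.
* The LOD scan is single-marker; linked markers are ranked
  individually, and the panel band plus deduplication — not an LD
  model — controls redundancy.
* `mann_whitney_one_sided()` switches to the normal approximation above
  n = 8 per group; at the extreme α = 0.001 used for domination graphs
  this is slightly conservative with the continuity correction.
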