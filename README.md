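# ricepopstruct

Population-structure analysis for diploid SNP panels — built for
national rice (*Oryza sativa*) germplasm collections, usable for any
bi-allelic genotype matrix with replicated phenotypes.

Rice diversity panels typically contain a few hundred accessions drawn
from several gene pools (indica and japonica subspecies, regional
landraces, elite lines) plus admixed material that mixes two of them.
The questions this package answers, end to end:

* How many ancestral populations shaped the panel, and what is each
  accession's ancestry composition?
* Which subpopulations do the accessions form, and how stable are those
  groups under resampling?
* How differentiated are the inferred ancestral gene pools (FST), and
  is subpopulation membership associated with geographic origin?
* How heritable are the measured traits, and which subpopulations
  dominate which (flowering time, grain length, plant height)?
* Which small set of SNPs best discriminates the subpopulations, and
  how well does a classifier trained on that panel assign accessions?

## The model at the core

Genotypes are encoded numerically: `1.0` homozygous reference, `0.5`
heterozygous, `0.0` homozygous alternate, `NA` missing.  The central
estimator is the admixture model: accession *i* carries ancestry
proportions *q<sub>i·</sub>* (rows of the n×K matrix **Q**, summing
to 1) from K ancestral populations with reference-allele frequencies
*f<sub>·j</sub>* (the K×L matrix **F**), and the observed allele dose is
binomial,

&nbsp;&nbsp;&nbsp;&nbsp;ℓ(Q, F) = Σ<sub>ij</sub> [ 2g<sub>ij</sub>·ln(Σ<sub>k</sub> q<sub>ik</sub> f<sub>kj</sub>) + 2(1−g<sub>ij</sub>)·ln(1 − Σ<sub>k</sub> q<sub>ik</sub> f<sub>kj</sub>) ].

`fit_admixture()` maximises ℓ by monotone EM block updates (compiled
core, seeded random restarts) and returns a classed model object with
`print`, `summary`, `coef` (**Q**), `logLik`, `fitted`, `residuals`,
`plot` (stacked ancestry bars) and `simulate` methods.  Around it:

* `select_K_elbow()` — number of ancestors by the log-likelihood elbow;
* `ancestral_fst()` — Hudson-type FST between inferred ancestral
  frequency vectors;
* `kmeans_cluster()`, `select_k_elbow()`, `bootstrap_support()` —
  subpopulations from ancestry-ratio vectors, the between-cluster/total
  sum-of-squares (BCTSS) elbow, and clusterwise bootstrap Jaccard
  support;
* `pca()`, `nj_tree()`, `origin_association_test()` — structure
  summaries and the origin×subpopulation chi-square test;
* `broad_sense_heritability()` — h²_B = σ²_G/(σ²_G + σ²_e/r) by one-way
  ANOVA method of moments; `domination_graph()` — directed
  subpopulation comparisons from one-sided Mann–Whitney tests;
* `one_vs_rest_scan()`, `select_panel()`, `annotate_genes()`,
  `crossval_classify()` — discriminative SNP panels (LOD + allele
  frequency difference), GFF3 gene overlay, and stratified 10-fold
  cross-validated population classification;
* `simulate_rice_panel()` and friends — a Balding–Nichols /
  Dirichlet-admixture generator with known truth, so every stage has a
  parameter-recovery test;
* `run_pipeline()` — configuration-driven orchestration of the whole
  analysis with plain-text artifacts and a JSON run manifest.

## Worked example

```r
library(ricepopstruct)

# simulate a 300-accession panel from 4 ancestors (one admixed group)
syn <- simulate_rice_panel(L = 2000, seed = 42)
G <- filter_maf_callrate(syn$G)       # call rate >= 70%, MAF >= 5%
G
#> genotype_matrix: 300 accessions x 1891 loci (10.1% missing)

fit <- fit_admixture(G, K = 4, seed = 1)
summary(fit)
#> Admixture model: K = 4, log-likelihood -469552.64
#>   mean dominant ancestry ratio: 0.915
#>   accessions per dominant ancestor:
#>  1  2  3  4
#> 88 92 78 42
#>   pairwise FST between inferred ancestral populations:
#>           ancestor1 ancestor2 ancestor3 ancestor4
#> ancestor1     0.000     0.316     0.314     0.323
#> ancestor2     0.316     0.000     0.299     0.308
#> ancestor3     0.314     0.299     0.000     0.315
#> ancestor4     0.323     0.308     0.315     0.000

cl <- bootstrap_support(fit, kmeans_cluster(fit, k = 5, seed = 1),
                        n_boot = 200, seed = 2)
cl
#> cluster_assignment: k = 5, n = 300, BCTSS ratio 0.990
#> cluster
#>  1  2  3  4  5
#> 38 92 70 42 58
#> bootstrap support (200 replicates):
#> [1] 0.920 0.983 0.991 0.997 0.960

broad_sense_heritability(syn$phenotypes, "plant_height_cm")$h2
#> [1] 0.9900799

res <- origin_association_test(thai_rice_origin_table())
c(chi2 = res$chi2, dof = res$dof, p = res$p)
#>         chi2          dof            p
#> 5.581655e+02 3.600000e+01 7.070974e-95
```

Reading the output: the generator plants four equally diverged
ancestors (pairwise FST ≈ 0.3) and five subpopulations, one of which
mixes two ancestors.  The fitted FST matrix recovers the 0.3 regime;
clustering at k = 5 recovers the groups; the admixed cluster (here
cluster 1, 38 members) has visibly the lowest bootstrap support —
admixed accessions are the ones that wander between clusters under
resampling.  The heritability of the height trait is high because the
panel's genetic variance (including subpopulation differences) dwarfs
the replicate noise.  The packaged origin×subpopulation table for the
300-accession Thai panel is strongly associated (36 degrees of
freedom, p ≪ 0.01).

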