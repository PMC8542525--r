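#' Per-locus reference-allele frequency
#'
#' The allele frequency of a locus is the mean of its non-missing numeric
#' genotypes (1.0 = homozygous reference), i.e. the reference-allele
#' frequency under the package encoding.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return numeric vector of length L in [0,1]; \code{NaN} (with a
#'   warning) for loci whose calls are all missing.
#' @export
allele_freq <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- colMeans(G$values, na.rm = TRUE)
  if (anyNA(p) || any(is.nan(p)))
    warning("all-missing loci produce undefined allele frequencies")
  unname(p)
}

#' Filter loci by call rate and minor allele frequency
#'
#' Loci are kept when the fraction of non-missing calls is at least
#' \code{callrate_min} and the minor allele frequency min(p, 1-p),
#' computed on non-missing calls only, is at least \code{maf_min}.
#' Call rate is evaluated first, then MAF on the surviving calls; the
#' accession set is never changed.  Defaults mirror standard GBS
#' preprocessing (MAF 0.05, call rate 70%).
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param maf_min minimum minor allele frequency in [0, 1].
#' @param callrate_min minimum per-locus call rate in [0, 1].
#' @return the filtered \code{\link{genotype_matrix}}; empty locus sets
#'   are allowed (with a warning).
#' @export
filter_maf_callrate <- function(G, maf_min = 0.05, callrate_min = 0.70) {
  stopifnot(inherits(G, "genotype_matrix"),
            maf_min >= 0, maf_min <= 1, callrate_min >= 0, callrate_min <= 1)
  cr <- colMeans(!is.na(G$values))
  keep_cr <- cr >= callrate_min
  p <- suppressWarnings(colMeans(G$values, na.rm = TRUE))
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- -Inf                      # all-missing: fails MAF too
  keep <- keep_cr & maf >= maf_min
  if (!any(keep)) warning("no loci pass the call-rate/MAF filter")
  subset_loci(G, keep)
}

#' Keep only loci with no heterozygous calls
#'
#' Retains loci whose non-missing calls are all homozygous (no 0.5
#' values).  This is a variant-level filter: a locus survives as long as
#' no accession carries a heterozygous call, and missing calls are
#' ignored.  Used upstream of the discriminative SNP scan.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return the filtered \code{\link{genotype_matrix}}.
#' @export
filter_biallelic_homozygous <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  has_het <- colSums(!is.na(G$values) & G$values == 0.5) > 0
  subset_loci(G, !has_het)
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing entry by the mean of the locus's non-missing
#' numeric genotypes; observed entries are untouched.  Complete matrices
#' are required by PCA, k-means and distance computations.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @return a plain numeric matrix (accessions x loci) with no missing
#'   entries; imputed values need not lie in \{0, 0.5, 1\}.
#' @export
impute_mean <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- G$values
  mu <- colMeans(m, na.rm = TRUE)
  if (any(is.nan(mu)))
    stop("all-missing loci cannot be imputed; run filter_maf_callrate first")
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2]]
  m
}

subset_loci <- function(G, keep) {
  genotype_matrix(G$values[, keep, drop = FALSE],
                  loci = G$loci[keep, , drop = FALSE],
                  accession_ids = G$accession_ids)
}

subset_accessions <- function(G, keep) {
  genotype_matrix(G$values[keep, , drop = FALSE],
                  loci = G$loci,
                  accession_ids = G$accession_ids[keep])
}
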