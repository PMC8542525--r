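#' Simulate ancestral allele frequencies under the Balding-Nichols model
#'
#' For each locus a base reference-allele frequency p is drawn uniformly
#' from \code{base_freq_range}; each ancestral population k then draws
#' its frequency from Beta(p(1-c_k)/c_k, (1-p)(1-c_k)/c_k), where c_k is
#' that ancestor's differentiation parameter (playing the role of its
#' FST against the common base).  The pairwise Hudson FST between two
#' ancestors generated this way is (c_k + c_l)/2 in expectation.
#'
#' @param K number of ancestral populations (>= 1).
#' @param L number of loci (>= 1).
#' @param fst differentiation parameter per ancestor, each in (0, 1);
#'   recycled to length K.
#' @param base_freq_range length-2 interval inside (0, 1) for the shared
#'   base frequency.
#' @param seed integer seed; output is deterministic given the seed.
#' @return K x L matrix of ancestral reference-allele frequencies.
#' @export
simulate_ancestral_freqs <- function(K, L, fst = 0.3,
                                     base_freq_range = c(0.1, 0.9),
                                     seed = 1L) {
  stopifnot(K >= 1, L >= 1, length(base_freq_range) == 2,
            base_freq_range[1] > 0, base_freq_range[2] < 1,
            base_freq_range[1] < base_freq_range[2])
  fst <- rep_len(fst, K)
  if (any(!is.finite(fst)) || any(fst <= 0) || any(fst >= 1))
    stop("fst parameters must lie strictly inside (0, 1); ",
         "c = 0 gives non-finite Beta parameters")
  set.seed(seed)
  p <- runif(L, base_freq_range[1], base_freq_range[2])
  if (K == 1L) return(matrix(p, 1, L))   # no differentiation structure
  F <- matrix(0, K, L)
  for (k in seq_len(K)) {
    c_k <- fst[k]
    F[k, ] <- rbeta(L, p * (1 - c_k) / c_k, (1 - p) * (1 - c_k) / c_k)
  }
  F
}

#' Simulate accession ancestry ratios and subpopulation labels
#'
#' Pure subpopulations receive near-degenerate ancestry rows: the
#' dominant ancestor's weight is drawn uniformly from
#' \code{purity_range} (default [0.95, 1]) and the remainder is split
#' across the other ancestors by a flat Dirichlet.  Admixed
#' subpopulations mix exactly two parent ancestors with mixing
#' proportion Beta(conc, conc) — a symmetric Dirichlet over the two
#' parents.
#'
#' @param pop_sizes integer vector of accessions per subpopulation;
#'   names become subpopulation labels (default POP1..POPk).
#' @param pop_ancestors list, one element per subpopulation: a single
#'   ancestor index for a pure subpopulation, or two indices for an
#'   admixed one.
#' @param K number of ancestors; defaults to the largest index used.
#' @param conc Dirichlet concentration of the admixed mixing proportion.
#' @param purity_range dominant-ancestor weight interval for pure rows.
#' @param seed integer seed.
#' @return list with \code{trueQ} (n x K, rows sum to 1) and
#'   \code{true_labels} (factor of subpopulation labels, one per row).
#' @export
simulate_accessions <- function(pop_sizes, pop_ancestors, K = NULL,
                                conc = 6, purity_range = c(0.95, 1),
                                seed = 1L) {
  stopifnot(length(pop_sizes) == length(pop_ancestors), all(pop_sizes >= 1))
  idx_all <- unlist(pop_ancestors)
  if (is.null(K)) K <- max(idx_all)
  if (any(idx_all < 1 | idx_all > K))
    stop("admixture specification references an unknown ancestor index")
  if (is.null(names(pop_sizes)))
    names(pop_sizes) <- paste0("POP", seq_along(pop_sizes))
  set.seed(seed)
  rows <- vector("list", length(pop_sizes))
  for (g in seq_along(pop_sizes)) {
    m <- pop_sizes[g]
    anc <- pop_ancestors[[g]]
    Qg <- matrix(0, m, K)
    if (length(anc) == 1) {
      w <- runif(m, purity_range[1], purity_range[2])
      Qg[, anc] <- w
      if (K > 1) {
        rest <- rdirichlet(m, rep(1, K - 1))
        Qg[, -anc] <- rest * (1 - w)
      } else Qg[, anc] <- 1
    } else if (length(anc) == 2) {
      w <- rbeta(m, conc, conc)
      Qg[, anc[1]] <- w
      Qg[, anc[2]] <- 1 - w
    } else stop("each subpopulation mixes one or two ancestors")
    rows[[g]] <- Qg
  }
  trueQ <- do.call(rbind, rows)
  labels <- factor(rep(names(pop_sizes), pop_sizes), levels = names(pop_sizes))
  list(trueQ = trueQ, true_labels = labels)
}

#' Simulate genotypes under the admixture model
#'
#' Each accession i at locus j has individual reference-allele frequency
#' pi_ij = sum_k q_ik f_kj.  With \code{inbreeding = 0} the reference
#' dose is Binomial(2, pi_ij) and the numeric genotype is dose/2.  With
#' inbreeding coefficient F_is > 0 a genotype is fully homozygous (dose
#' = 2*Bernoulli(pi)) with probability F_is, reflecting selfing species
#' such as rice.  Entries are masked missing independently at
#' \code{missing_rate}.
#'
#' @param trueQ n x K ancestry ratios (rows sum to 1).
#' @param trueF K x L ancestral reference-allele frequencies.
#' @param missing_rate per-entry missingness probability.
#' @param inbreeding within-accession inbreeding coefficient in [0, 1].
#' @param seed integer seed.
#' @param chrom_count number of chromosomes over which loci metadata are
#'   laid out.
#' @return a \code{\link{genotype_matrix}}.
#' @export
simulate_genotypes <- function(trueQ, trueF, missing_rate = 0,
                               inbreeding = 0, seed = 1L, chrom_count = 12L) {
  trueQ <- as.matrix(trueQ); trueF <- as.matrix(trueF)
  if (ncol(trueQ) != nrow(trueF))
    stop("shape mismatch: ncol(trueQ) must equal nrow(trueF)")
  stopifnot(missing_rate >= 0, missing_rate < 1,
            inbreeding >= 0, inbreeding <= 1)
  n <- nrow(trueQ); L <- ncol(trueF)
  set.seed(seed)
  P <- trueQ %*% trueF
  hom <- matrix(runif(n * L) < inbreeding, n, L)
  dose <- matrix(rbinom(n * L, 2L, P), n, L)
  dose[hom] <- 2L * (matrix(runif(n * L), n, L)[hom] < P[hom])
  g <- dose / 2
  if (missing_rate > 0)
    g[matrix(runif(n * L) < missing_rate, n, L)] <- NA_real_
  chrom <- sprintf("chr%02d", 1L + (seq_len(L) - 1L) %% chrom_count)
  pos <- 1000L + 500L * ((seq_len(L) - 1L) %/% chrom_count)
  ra <- cbind(sample(c("A", "C", "G", "T"), L, TRUE))
  alt <- vapply(ra, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  loci <- data.frame(chrom = chrom, pos = pos, ref = as.vector(ra),
                     alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(g, loci = loci)
}

#' Simulate replicated phenotypes with known heritability
#'
#' Each accession draws a genetic value Normal(subpopulation mean,
#' sigma_g2); each of its r replicate records adds independent
#' Normal(0, sigma_e2) noise.  Within a single subpopulation the
#' expected broad-sense heritability of accession means is
#' sigma_g2 / (sigma_g2 + sigma_e2 / r).
#'
#' @param true_labels factor of subpopulation labels, one per accession.
#' @param pop_trait_means named list, one element per trait: a numeric
#'   vector of per-subpopulation means (recycled across subpopulations).
#' @param sigma_g2,sigma_e2 genetic and residual variance per trait
#'   (recycled across traits); non-negative.
#' @param r number of replicate records per accession (>= 1).
#' @param accession_ids optional accession names.
#' @param seed integer seed.
#' @return data.frame with columns \code{accession_id}, \code{replicate},
#'   \code{trait}, \code{value}.
#' @export
simulate_phenotypes <- function(true_labels, pop_trait_means,
                                sigma_g2, sigma_e2, r = 3L,
                                accession_ids = NULL, seed = 1L) {
  if (r < 1) stop("r must be >= 1")
  if (any(sigma_g2 < 0) || any(sigma_e2 < 0)) stop("variances must be >= 0")
  true_labels <- as.factor(true_labels)
  n <- length(true_labels)
  traits <- names(pop_trait_means)
  if (is.null(traits)) traits <- paste0("trait", seq_along(pop_trait_means))
  sigma_g2 <- rep_len(sigma_g2, length(traits))
  sigma_e2 <- rep_len(sigma_e2, length(traits))
  if (is.null(accession_ids)) accession_ids <- sprintf("ACC%04d", seq_len(n))
  set.seed(seed)
  out <- vector("list", length(traits))
  for (t in seq_along(traits)) {
    mu <- rep_len(pop_trait_means[[t]], nlevels(true_labels))
    gval <- rnorm(n, mu[as.integer(true_labels)], sqrt(sigma_g2[t]))
    rec <- data.frame(
      accession_id = rep(accession_ids, each = r),
      replicate = rep(seq_len(r), times = n),
      trait = traits[t],
      value = rep(gval, each = r) + rnorm(n * r, 0, sqrt(sigma_e2[t])),
      stringsAsFactors = FALSE)
    out[[t]] <- rec
  }
  do.call(rbind, out)
}

#' Simulate origin labels associated with subpopulations
#'
#' Each subpopulation is assigned a modal geographic origin; each
#' accession reports that origin with probability \code{fidelity} and a
#' uniformly random origin otherwise, producing an origin x
#' subpopulation contingency table with a strong but imperfect
#' association.
#'
#' @param true_labels factor of subpopulation labels.
#' @param origins character vector of origin names (recycled to the
#'   number of subpopulations for the modal assignment).
#' @param fidelity probability of reporting the modal origin.
#' @param seed integer seed.
#' @return factor of origin labels, one per accession.
#' @export
simulate_origins <- function(true_labels,
                             origins = c("North", "North-East", "Central",
                                         "South", "IRRI"),
                             fidelity = 0.7, seed = 1L) {
  true_labels <- as.factor(true_labels)
  modal <- rep_len(origins, nlevels(true_labels))
  set.seed(seed)
  n <- length(true_labels)
  out <- modal[as.integer(true_labels)]
  flip <- runif(n) >= fidelity
  out[flip] <- sample(origins, sum(flip), replace = TRUE)
  factor(out, levels = origins)
}

#' Default synthetic rice diversity panel
#'
#' One call that generates the package's reference study conditions: 300
#' accessions in five subpopulations of sizes 54, 45, 67, 92 and 42 from
#' K = 4 ancestral populations, with the second subpopulation admixed
#' between ancestors 1 and 2 and all ancestors at Balding-Nichols
#' differentiation c = 0.3 (pairwise ancestral FST about 0.3).
#' Genotypes are highly inbred (F_is = 0.98, selfing rice) with 10%
#' missing calls; three replicated traits (days to flowering, grain
#' length in mm, plant height in cm) have subpopulation-specific means
#' and broad-sense heritability above 0.9.
#'
#' @param L number of loci.
#' @param fst per-ancestor differentiation parameter(s).
#' @param pop_sizes accessions per subpopulation.
#' @param conc admixture Dirichlet concentration.
#' @param missing_rate,inbreeding genotype noise parameters.
#' @param r phenotype replicates per accession.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return list with elements \code{G} (\code{\link{genotype_matrix}}),
#'   \code{phenotypes}, \code{origins}, and \code{truth} (trueQ, trueF,
#'   true_labels, and the generating parameters).
#' @export
simulate_rice_panel <- function(L = 5000, fst = 0.3,
                                pop_sizes = c(POP1 = 54, POP2 = 45,
                                              POP3 = 67, POP4 = 92,
                                              POP5 = 42),
                                conc = 6, missing_rate = 0.1,
                                inbreeding = 0.98, r = 3L, seed = 1L) {
  pop_ancestors <- list(1L, c(1L, 2L), 2L, 3L, 4L)
  if (length(pop_sizes) != 5L)
    stop("the default panel has five subpopulations; ",
         "use the individual simulators for other designs")
  trueF <- simulate_ancestral_freqs(K = 4, L = L, fst = fst,
                                    seed = stage_seed(seed, 101))
  acc <- simulate_accessions(pop_sizes, pop_ancestors, K = 4, conc = conc,
                             seed = stage_seed(seed, 202))
  G <- simulate_genotypes(acc$trueQ, trueF, missing_rate = missing_rate,
                          inbreeding = inbreeding,
                          seed = stage_seed(seed, 303))
  pop_trait_means <- list(
    flowering_days = c(95, 105, 115, 130, 97),
    grain_length_mm = c(7.6, 7.4, 7.2, 6.2, 6.8),
    plant_height_cm = c(120, 130, 140, 150, 110))
  sigma_g2 <- c(64, 0.25, 100)
  sigma_e2 <- c(16, 0.04, 9)
  phen <- simulate_phenotypes(acc$true_labels, pop_trait_means,
                              sigma_g2, sigma_e2, r = r,
                              accession_ids = G$accession_ids,
                              seed = stage_seed(seed, 404))
  origins <- simulate_origins(acc$true_labels, seed = stage_seed(seed, 505))
  list(G = G, phenotypes = phen, origins = origins,
       truth = list(trueQ = acc$trueQ, trueF = trueF,
                    true_labels = acc$true_labels, fst = fst, conc = conc,
                    pop_trait_means = pop_trait_means,
                    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, r = r,
                    missing_rate = missing_rate, inbreeding = inbreeding,
                    seed = seed))
}

#' Write a synthetic GFF3 gene annotation
#'
#' Lays non-overlapping synthetic gene intervals along the chromosomes
#' of a genotype matrix so annotation overlap logic can be exercised
#' without external data.
#'
#' @param G a \code{\link{genotype_matrix}} supplying the chromosome
#'   layout.
#' @param path output GFF3 path.
#' @param gene_every one gene is placed for roughly this many loci.
#' @param gene_span gene length in bp.
#' @param seed integer seed.
#' @return \code{path}, invisibly.
#' @export
write_synthetic_gff <- function(G, path, gene_every = 10L,
                                gene_span = 400L, seed = 1L) {
  set.seed(seed)
  loci <- G$loci
  lines <- c("##gff-version 3")
  gid <- 0L
  for (ch in unique(loci$chrom)) {
    pos <- sort(loci$pos[loci$chrom == ch])
    anchors <- pos[seq(1, length(pos), by = gene_every)]
    for (a in anchors) {
      gid <- gid + 1L
      start <- max(1L, a - sample.int(gene_span, 1L))
      end <- start + gene_span
      lines <- c(lines, paste(ch, "synthetic", "gene", start, end, ".",
                              sample(c("+", "-"), 1), ".",
                              sprintf("ID=gene%05d;Name=SynGene%05d", gid, gid),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
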