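test_that("one-vs-rest scan matches a brute-force least-squares oracle", {
  # 12-accession toy with printed genotypes, two populations
  g <- rbind(
    c(1, 1, 0, 1), c(1, 1, 1, 0), c(1, 0, 0, 1), c(1, 1, 0, 0),
    c(1, 0, 1, 1), c(1, 1, 0, 1),
    c(0, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1),
    c(0, 1, 1, 0), c(0, 0, 1, NA))
  G <- genotype_matrix(g)
  labels <- rep(c("in", "out"), each = 6)
  scan <- one_vs_rest_scan(G, labels, "in")
  y <- as.numeric(labels == "in")
  expect_equal(scan$lod, lod_lm_oracle(g, y), tolerance = 1e-9)

  # locus 1 is fixed-different: freq diff 1, LOD at the cap
  expect_equal(scan$freq_diff[1], 1)
  expect_equal(scan$lod[1], 50)
  # freq diff arithmetic on the missing-value locus
  expect_equal(scan$freq_diff[4], abs(mean(g[1:6, 4]) - mean(g[7:11, 4])))

  # identical in/out frequencies: freq diff 0, LOD ~ 0
  g2 <- rbind(matrix(rep(c(1, 0), 3), 6, 2, byrow = FALSE),
              matrix(rep(c(1, 0), 3), 6, 2, byrow = FALSE))
  s2 <- one_vs_rest_scan(genotype_matrix(g2), labels, "in")
  expect_equal(s2$freq_diff, c(0, 0))
  expect_lt(max(s2$lod), 1e-8)

  expect_error(one_vs_rest_scan(G, labels, "absent"), "not present")
})

test_that("panel selection ranks by frequency difference, dedups, and respects the band", {
  # three populations; A and B each privately fixed at 60 disjoint loci
  n_g <- 20
  blk <- function(a, b, c, L)
    rbind(matrix(a, n_g, L), matrix(b, n_g, L), matrix(c, n_g, L))
  g <- cbind(blk(1, 0, 0, 60),             # private to A (diff 1 for A)
             blk(0, 1, 0, 60),             # private to B
             blk(1, 1, 1, 30))             # uninformative
  G <- genotype_matrix(g)
  labels <- rep(c("A", "B", "C"), each = n_g)
  scans <- list(A = one_vs_rest_scan(G, labels, "A"),
                B = one_vs_rest_scan(G, labels, "B"))
  panel <- select_panel(scans, per_pop_min = 50, per_pop_max = 60)
  expect_equal(panel$union_size, 120L)
  expect_equal(sort(as.vector(table(panel$panel$population))), c(60L, 60L))

  # a locus selected by two scans appears once in the union
  expect_warning(panel2 <- select_panel(list(A = scans$A, B = scans$A),
                                        per_pop_min = 50, per_pop_max = 60),
                 NA)
  expect_equal(panel2$union_size, 60L)
  expect_false(any(duplicated(panel2$panel$locus)))

  # indistinguishable populations: empty panel with warning
  gid <- genotype_matrix(matrix(rep(c(1, 0, 1, 0), each = 10), 20, 2))
  lid <- rep(c("A", "B"), 10)
  sid <- list(A = one_vs_rest_scan(gid, lid, "A"),
              B = one_vs_rest_scan(gid, lid, "B"))
  w <- capture_warnings(pid <- select_panel(sid))
  expect_true(any(grepl("empty panel", w)))
  expect_equal(pid$union_size, 0L)

  # invariance to locus order in the input
  set.seed(41)
  perm <- sample(ncol(g))
  Gp <- genotype_matrix(g[, perm])
  scans_p <- list(A = one_vs_rest_scan(Gp, labels, "A"),
                  B = one_vs_rest_scan(Gp, labels, "B"))
  panel_p <- select_panel(scans_p, per_pop_min = 50, per_pop_max = 60)
  expect_equal(sort(perm[panel_p$panel$pos]), sort(panel$panel$pos))
})

test_that("scan ranking is enriched for truly differentiated loci", {
  # loci drawn at c = 0.8 against a c = 0.02 background; the truly
  # differentiated set is defined from the generating frequencies
  # (under Balding-Nichols at high c the two populations still land on
  # the same fixed allele at some loci, which are not differentiated)
  S <- 60; L_bg <- 440
  Fhi <- simulate_ancestral_freqs(2, S, fst = 0.8, seed = 31)
  Flo <- simulate_ancestral_freqs(2, L_bg, fst = 0.02, seed = 32)
  F <- cbind(Fhi, Flo)
  true_diff <- abs(F[1, ] - F[2, ])
  hi <- which(true_diff > 0.4)
  expect_true(all(hi <= S))                 # background never qualifies
  acc <- simulate_accessions(c(A = 50, B = 50), list(1L, 2L), K = 2, seed = 33)
  G <- simulate_genotypes(acc$trueQ, F, inbreeding = 1, seed = 34)
  scan <- one_vs_rest_scan(G, acc$true_labels, "A")
  top <- order(-scan$freq_diff, -scan$lod)[seq_along(hi)]
  expect_gte(mean(top %in% hi), 0.9)
})

test_that("gene annotation counts match the brute-force interval oracle and use inclusive bounds", {
  syn <- small_panel()
  Gf <- filter_maf_callrate(syn$G)
  Ghom <- filter_biallelic_homozygous(Gf)
  labels <- as.character(syn$truth$true_labels)
  scans <- lapply(sort(unique(labels)), function(p)
    one_vs_rest_scan(Ghom, labels, p))
  names(scans) <- sort(unique(labels))
  panel <- suppressWarnings(select_panel(scans, per_pop_min = 10,
                                         per_pop_max = 30))
  gff <- tempfile(fileext = ".gff3")
  write_synthetic_gff(syn$G, gff, seed = 35)
  ann <- annotate_genes(panel, gff)
  genes <- ape::read.gff(gff)
  genes <- genes[genes$type == "gene", ]
  expect_equal(nrow(ann$hits),
               gene_hit_oracle(panel$panel$pos, panel$panel$chrom, genes))
  expect_true(all(ann$intervals$n_snps >= 1))

  # boundary inclusivity: SNP exactly at a gene end is a hit
  p1 <- panel
  p1$panel <- data.frame(locus = "chrZ:200", chrom = "chrZ", pos = 200L,
                         population = "A", freq_diff = 1, lod = 50,
                         stringsAsFactors = FALSE)
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrZ\tsyn\tgene\t100\t200\t.\t+\t.\tID=geneX"), gff2)
  ann2 <- annotate_genes(p1, gff2)
  expect_equal(nrow(ann2$hits), 1L)
  expect_equal(ann2$hits$gene_id, "geneX")
})

test_that("cross-validated classification scores satisfy the F1 identity and count constraints", {
  syn <- small_panel()
  labels <- as.character(syn$truth$true_labels)
  Gf <- filter_maf_callrate(syn$G)
  Ghom <- filter_biallelic_homozygous(Gf)
  scans <- lapply(sort(unique(labels)), function(p)
    one_vs_rest_scan(Ghom, labels, p))
  names(scans) <- sort(unique(labels))
  panel <- suppressWarnings(select_panel(scans, per_pop_min = 10,
                                         per_pop_max = 50))
  cv <- crossval_classify(subset_panel(syn$G, panel), labels,
                          folds = 5, seed = 3)
  m <- cv$metrics
  # F1 identity to 1e-12 wherever precision + recall > 0
  pr <- m$precision + m$recall
  expect_true(all(abs(m$F1[pr > 0] -
                        2 * m$precision[pr > 0] * m$recall[pr > 0] / pr[pr > 0])
                  < 1e-12))
  # every accession scored exactly once out of fold
  expect_equal(sum(m$TP) + sum(m$FN), length(labels))
  expect_false(anyNA(cv$predicted))

  # perfect/degenerate F1 limits via a pluggable classifier
  always_a <- list(
    fit = function(x, y) levels(y),
    pred = function(fit, x) factor(rep("POP1", nrow(x)), levels = fit))
  cv0 <- crossval_classify(subset_panel(syn$G, panel), labels, folds = 5,
                           seed = 3, fit_fun = always_a$fit,
                           predict_fun = always_a$pred)
  m0 <- cv0$metrics
  expect_equal(m0$recall[m0$class == "POP1"], 1)
  expect_equal(m0$F1[m0$class != "POP1"], rep(0, 4))

  expect_warning(crossval_classify(matrix(rnorm(40), 20, 2),
                                   rep(c("a", "b"), c(15, 5)), folds = 10,
                                   seed = 1),
                 "reducing folds")
})
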