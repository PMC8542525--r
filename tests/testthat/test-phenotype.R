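test_that("heritability estimator honors its degenerate limits and design contracts", {
  # zero within-accession variance, nonzero between -> 1
  P <- data.frame(accession_id = rep(c("a", "b", "c"), each = 2),
                  replicate = rep(1:2, 3), trait = "t",
                  value = rep(c(1, 5, 9), each = 2))
  expect_equal(broad_sense_heritability(P, "t")$h2, 1)

  # identical accession means, noisy replicates -> floored near 0
  set.seed(11)
  P0 <- data.frame(accession_id = rep(sprintf("a%02d", 1:30), each = 4),
                   replicate = rep(1:4, 30), trait = "t",
                   value = rnorm(120))
  expect_lt(broad_sense_heritability(P0, "t")$h2, 0.3)

  P1 <- P[P$replicate == 1, ]
  expect_error(broad_sense_heritability(P1, "t"), "r = 1")
  expect_warning(broad_sense_heritability(P[-1, ], "t"), "unbalanced")
  expect_error(broad_sense_heritability(P, "nope"), "no records")
})

test_that("heritability estimator is nearly unbiased across the designed range", {
  # bias below 0.02 at n = 500 for h2 in {0.5, 0.8, 0.95} (20 seeds each)
  lab <- factor(rep("A", 500))
  r <- 4
  for (h2_true in c(0.5, 0.8, 0.95)) {
    sigma_g2 <- 1
    sigma_e2 <- r * sigma_g2 * (1 - h2_true) / h2_true
    est <- vapply(1:20, function(s) {
      P <- simulate_phenotypes(lab, list(t = 0), sigma_g2, sigma_e2,
                               r = r, seed = 100 + s)
      broad_sense_heritability(P, "t")$h2
    }, 0)
    expect_lt(abs(mean(est) - h2_true), 0.02)
  }
})

test_that("one-sided Mann-Whitney agrees with full enumeration and its symmetry identity", {
  res <- mann_whitney_one_sided(c(5, 6), c(1, 2))
  expect_equal(res$U, 4)
  expect_equal(res$p, 1 / 6)
  oracle <- mw_enum_oracle(c(5, 6), c(1, 2))
  expect_equal(res$p, oracle$p)

  # identical samples: no evidence of dominance
  expect_gte(mann_whitney_one_sided(c(1, 2, 3), c(1, 2, 3))$p, 0.5)

  # U(x,y) + U(y,x) = nx * ny
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    expect_equal(mann_whitney_one_sided(x, y)$U +
                   mann_whitney_one_sided(y, x)$U,
                 length(x) * length(y))
    expect_equal(mann_whitney_one_sided(x, y)$p, mw_enum_oracle(x, y)$p)
  }
})

test_that("exact and normal-approximation p-values agree closely at n = 8", {
  set.seed(13)
  deltas <- vapply(1:100, function(i) {
    x <- rnorm(8); y <- rnorm(8)
    p_exact <- mann_whitney_one_sided(x, y)$p
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                              exact = FALSE, correct = TRUE))
    abs(p_exact - wt$p.value)
  }, 0)
  expect_lt(max(deltas), 0.01)
})

test_that("domination graphs orient edges by stochastic dominance and respect alpha", {
  # strictly ordered well-separated groups: full transitive tournament
  set.seed(14)
  n <- 30
  P <- data.frame(
    accession_id = rep(sprintf("g%d_%02d", rep(1:5, each = n), 1:n), each = 2),
    replicate = rep(1:2, 5 * n), trait = "t",
    value = rep(rnorm(5 * n, rep(c(100, 80, 60, 40, 20), each = n), 2),
                each = 2))
  labels <- stats::setNames(rep(paste0("P", 1:5), each = n),
                            sprintf("g%d_%02d", rep(1:5, each = n), 1:n))
  g <- domination_graph(P, labels, "t", alpha = 0.001)
  expect_equal(nrow(g$edges), 10)
  expect_true(all(g$edges$p <= 0.001))
  # higher-mean group always dominates: P1 > P2 > ... > P5
  rank_of <- c(P1 = 1, P2 = 2, P3 = 3, P4 = 4, P5 = 5)
  expect_true(all(rank_of[g$edges$from] < rank_of[g$edges$to]))
  # antisymmetry: no pair appears twice
  expect_false(any(duplicated(t(apply(g$edges[, c("from", "to")], 1, sort)))))

  # equal-mean groups: no edge
  set.seed(15)
  P2 <- data.frame(accession_id = rep(sprintf("h%02d", 1:40), each = 2),
                   replicate = rep(1:2, 40), trait = "t",
                   value = rep(rnorm(40, 50, 5), each = 2))
  lab2 <- stats::setNames(rep(c("A", "B"), 20), sprintf("h%02d", 1:40))
  g2 <- domination_graph(P2, lab2, "t", alpha = 0.001)
  expect_equal(nrow(g2$edges), 0)

  expect_warning(
    domination_graph(rbind(P2, data.frame(accession_id = "solo",
                                          replicate = 1:2, trait = "t",
                                          value = c(1, 2))),
                     c(lab2, solo = "C"), "t"),
    "excluding")
})

test_that("flowering-time domination on the reference design places the admixed group between its parents", {
  syn <- small_panel()
  labels <- stats::setNames(as.character(syn$truth$true_labels),
                            syn$G$accession_ids)
  g <- domination_graph(syn$phenotypes, labels, "flowering_days",
                        alpha = 0.001)
  edges <- paste(g$edges$from, g$edges$to, sep = ">")
  # designed means: POP1 95 < POP2 105 < POP3 115 < POP4 130; POP5 ~ POP1
  expect_true(all(c("POP2>POP1", "POP3>POP2", "POP4>POP3") %in% edges))
  expect_false(any(c("POP1>POP2", "POP2>POP3", "POP3>POP4") %in% edges))
})

test_that("domination graph DOT output is well formed", {
  set.seed(16)
  P <- data.frame(accession_id = rep(sprintf("x%02d", 1:20), each = 2),
                  replicate = rep(1:2, 20), trait = "t",
                  value = rep(c(rnorm(10, 0), rnorm(10, 50)), each = 2))
  lab <- stats::setNames(rep(c("A", "B"), each = 10), sprintf("x%02d", 1:20))
  g <- domination_graph(P, lab, "t", alpha = 0.001)
  path <- tempfile(fileext = ".dot")
  write_dot(g, path)
  txt <- readLines(path)
  expect_match(txt[1], "^digraph")
  expect_true(any(grepl("->", txt)))
})
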