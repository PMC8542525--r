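test_that("K = 1 fit is the closed-form maximum likelihood at sample frequencies", {
  syn <- simulate_genotypes(matrix(1, 20, 1),
                            simulate_ancestral_freqs(1, 50, seed = 3),
                            missing_rate = 0.1, seed = 4)
  fit <- fit_admixture(syn, K = 1)
  expect_equal(unname(fit$Q), matrix(1, 20, 1))
  p_hat <- allele_freq(syn)
  expect_equal(unname(fit$F[1, ]), p_hat, tolerance = 1e-12)
  # closed-form binomial log-likelihood at those frequencies
  g <- syn$values
  a <- 2 * g; b <- 2 - 2 * g
  ll <- sum(a * log(p_hat)[col(g)] + b * log(1 - p_hat)[col(g)], na.rm = TRUE)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone and reaches the grid-search optimum on a toy", {
  g <- rbind(c(1, 0), c(0, 1))       # 2 accessions x 2 loci
  G <- genotype_matrix(g)
  fit <- fit_admixture(G, K = 2, seed = 1, tol = 1e-10, max_iter = 5000,
                       n_starts = 10)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))

  # independent oracle: exhaustive grid over Q rows and per-locus F
  # columns at step 0.01 (loci decouple given Q)
  qs <- seq(0, 1, by = 0.01)
  eps <- 1e-6
  cl <- function(x) pmin(pmax(x, eps), 1 - eps)
  fgrid <- as.matrix(expand.grid(f1 = qs, f2 = qs))   # f for both ancestors
  best <- -Inf
  # contrib[qi, fcombo] = loglik of one accession at one locus
  locus_ll <- function(a_i, q_i, f) {
    p <- cl(q_i * f[, 1] + (1 - q_i) * f[, 2])
    a_i * log(p) + (2 - a_i) * log(1 - p)
  }
  per_locus_best <- matrix(0, length(qs), length(qs))
  for (j in 1:2) {
    c1 <- vapply(qs, function(q) locus_ll(2 * g[1, j], q, fgrid), numeric(nrow(fgrid)))
    c2 <- vapply(qs, function(q) locus_ll(2 * g[2, j], q, fgrid), numeric(nrow(fgrid)))
    # best f for each (q1, q2): max over rows of c1[,q1] + c2[,q2]
    M <- matrix(0, length(qs), length(qs))
    for (i1 in seq_along(qs)) M[i1, ] <- apply(c1[, i1] + c2, 2, max)
    per_locus_best <- per_locus_best + M
  }
  grid_opt <- max(per_locus_best)
  expect_gte(fit$loglik, grid_opt - 1e-3)
})

test_that("fitted model recovers the generating ancestry on a structured panel", {
  syn <- small_panel()
  Gf <- filter_maf_callrate(syn$G)
  fit <- fit_admixture(Gf, K = 4, seed = 2)
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-6))
  expect_true(all(fit$Q >= 0 & fit$Q <= 1))
  expect_true(all(fit$F >= 0 & fit$F <= 1))
  m <- match_columns(fit$Q, syn$truth$trueQ)
  expect_lt(m$mae, 0.07)

  # permuting ancestor columns leaves the likelihood unchanged
  g <- Gf$values
  ll_at <- function(Q, F) {
    P <- pmin(pmax(Q %*% F, 1e-9), 1 - 1e-9)
    sum(2 * g * log(P) + 2 * (1 - g) * log(1 - P), na.rm = TRUE)
  }
  perm <- c(3, 1, 4, 2)
  expect_equal(ll_at(fit$Q[, perm], fit$F[perm, ]), ll_at(fit$Q, fit$F),
               tolerance = 1e-8)
})

test_that("model accessors behave like a standard fitted-model object", {
  syn <- small_panel()
  Gf <- filter_maf_callrate(syn$G)
  fit <- fit_admixture(Gf, K = 2, seed = 1, max_iter = 200, n_starts = 1)
  expect_s3_class(fit, "admixture_fit")
  expect_identical(coef(fit), fit$Q)
  expect_equal(dim(fitted(fit)), dim(Gf$values))
  expect_equal(residuals(fit), Gf$values - fitted(fit))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_output(print(fit), "Admixture model fit")
  expect_output(print(summary(fit)), "pairwise FST")
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "genotype_matrix")
  expect_error(fit_admixture(Gf, K = 400), "exceed")
})

test_that("elbow selection over K recovers the generating number of ancestors", {
  syn <- small_panel()
  Gf <- filter_maf_callrate(syn$G)
  sel <- select_K_elbow(Gf, K_range = 2:6, seed = 1)
  expect_equal(sel$K, 4)
  expect_equal(nrow(sel$curve), 6)       # includes the K = 1 anchor fit
  sel2 <- select_K_elbow(Gf, K_range = 2:6, seed = 1)
  expect_equal(sel2$curve$loglik, sel$curve$loglik)   # deterministic

  # structureless panel (c ~ 0, one ancestor) elects K = 1
  F0 <- simulate_ancestral_freqs(1, 300, seed = 11)
  G0 <- simulate_genotypes(matrix(1, 80, 1), F0, seed = 12)
  sel0 <- select_K_elbow(G0, K_range = 1:3, seed = 1)
  expect_equal(sel0$K, 1)
})

test_that("ancestral FST matches fixation expectations and the MC-derived value", {
  F <- rbind(rep(0.3, 10), rep(0.3, 10))
  expect_equal(ancestral_fst(F), matrix(0, 2, 2))
  F <- rbind(rep(1, 10), rep(0, 10))
  expect_equal(ancestral_fst(F)[1, 2], 1)

  # frozen MC oracle: two Balding-Nichols rows at c = 0.2 give FST 0.20
  est <- mean(vapply(1:10, function(s) {
    F <- simulate_ancestral_freqs(2, 10000, fst = 0.2, seed = s)
    ancestral_fst(F)[1, 2]
  }, 0))
  expect_lt(abs(est - 0.2), 0.05)
  expect_error(ancestral_fst(matrix(0.5, 1, 10)), "at least two")
})

test_that("ancestral FST increases with the differentiation parameter and flags a distant ancestor", {
  mean_fst <- vapply(c(0.1, 0.3, 0.5), function(c_par) {
    F <- simulate_ancestral_freqs(4, 5000, fst = c_par, seed = 21)
    f <- ancestral_fst(F)
    mean(f[upper.tri(f)])
  }, 0)
  expect_true(all(diff(mean_fst) > 0))

  # one distant ancestor dominates every pairwise comparison, as for a
  # japonica ancestor against three indica ancestors
  F <- simulate_ancestral_freqs(4, 5000, fst = c(0.15, 0.15, 0.15, 0.5),
                                seed = 22)
  f <- ancestral_fst(F)
  distant <- f[4, 1:3]
  others <- f[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
  expect_true(min(distant) > max(others))
})

test_that("Q/F matrices survive the .Q/.P text round trip", {
  syn <- small_panel()
  Gf <- filter_maf_callrate(syn$G)
  fit <- fit_admixture(Gf, K = 2, seed = 1, max_iter = 100, n_starts = 1)
  qp <- tempfile(); fp <- tempfile()
  write_q_matrix(fit, qp); write_f_matrix(fit, fp)
  expect_equal(unname(read_q_matrix(qp)), unname(fit$Q), tolerance = 1e-5)
  expect_equal(unname(read_f_matrix(fp)), unname(fit$F), tolerance = 1e-5)
})
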