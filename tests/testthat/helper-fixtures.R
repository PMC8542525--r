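# Shared fixtures (computed once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small panel for fast unit tests: same generative design, fewer loci
small_panel <- function() cached("small_panel", simulate_rice_panel(L = 600, seed = 7))

# full-size reference panel used by the end-to-end recovery checks
full_panel <- function() cached("full_panel", simulate_rice_panel(L = 5000, seed = 1))

full_fit <- function() cached("full_fit", {
  Gf <- filter_maf_callrate(full_panel()$G)
  fit_admixture(Gf, K = 4, seed = 1)
})

full_clusters <- function() cached("full_clusters", {
  kmeans_cluster(full_fit()$Q, k = 5, seed = 1)
})

# four pure populations fixed-different at per-ancestor marker blocks
# plus one admixed population (mixing ancestors 1 and 2); fully inbred
# so the homozygous-variant filter is the identity.  The broad mixing
# spread (conc = 2) makes a few admixed accessions near-pure, so the
# admixed class is genuinely the hardest while the pure classes stay
# cleanly separable.
marker_block_fixture <- function(block = 60L, seed = 31L) {
  K <- 4L
  F <- matrix(0.01, K, K * block)
  for (k in seq_len(K))
    F[k, ((k - 1L) * block + 1L):(k * block)] <- 0.99
  acc <- simulate_accessions(
    c(POP1 = 54, POP2 = 45, POP3 = 67, POP4 = 92, POP5 = 42),
    list(1L, c(1L, 2L), 2L, 3L, 4L), K = K, conc = 2, seed = seed)
  G <- simulate_genotypes(acc$trueQ, F, inbreeding = 1,
                          seed = seed + 1L)
  list(G = G, labels = acc$true_labels, trueQ = acc$trueQ, trueF = F)
}

# ---- independent oracles ------------------------------------------------

# Mann-Whitney one-sided p by full enumeration of group assignments
mw_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  u_stat <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  u_obs <- u_stat(x, y)
  combos <- combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) u_stat(z[ix], z[-ix]))
  list(U = u_obs, p = mean(us >= u_obs))
}

# exhaustive minimum-WSS bipartition of a small point set
brute_best_bipartition <- function(X) {
  n <- nrow(X)
  best <- NULL; best_wss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {        # fix point 1 in group 0
    grp <- as.integer(intToBits(code))[1:n]
    if (all(grp == 0) || all(grp == 1)) next
    wss <- 0
    for (g in 0:1) {
      rows <- X[grp == g, , drop = FALSE]
      wss <- wss + sum(sweep(rows, 2, colMeans(rows))^2)
    }
    if (wss < best_wss) { best_wss <- wss; best <- grp }
  }
  list(labels = best + 1L, wss = best_wss)
}

# per-locus LOD by explicit lm() fits
lod_lm_oracle <- function(g, y, cap = 50) {
  vapply(seq_len(ncol(g)), function(j) {
    ok <- !is.na(g[, j])
    yy <- y[ok]; gg <- g[ok, j]
    rss0 <- sum(stats::resid(stats::lm(yy ~ 1))^2)
    if (stats::sd(gg) == 0) return(0)
    rss1 <- sum(stats::resid(stats::lm(yy ~ gg))^2)
    if (rss1 < 1e-12) return(cap)
    min((sum(ok) / 2) * log10(rss0 / rss1), cap)
  }, 0)
}

# brute-force interval containment counts for gene annotation
gene_hit_oracle <- function(pos, chrom, genes) {
  sum(vapply(seq_along(pos), function(i)
    sum(genes$seqid == chrom[i] & genes$start <= pos[i] & genes$end >= pos[i]),
    0L))
}

# adjusted Rand index between two labelings (independent of mclust)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
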