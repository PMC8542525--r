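#' Fit the admixture model by maximum likelihood
#'
#' Estimates per-accession ancestry ratios Q (n x K, rows summing to 1)
#' and ancestral reference-allele frequencies F (K x L) by maximising
#' the binomial admixture log-likelihood
#' \deqn{\ell(Q,F) = \sum_{ij} 2 g_{ij} \log(\sum_k q_{ik} f_{kj}) +
#'   2 (1-g_{ij}) \log(1 - \sum_k q_{ik} f_{kj})}
#' over numeric genotypes g in \{0, 0.5, 1\}.  Missing genotypes
#' contribute zero to the likelihood.  Optimisation is by monotone EM
#' block updates (the classic frappe/ADMIXTURE EM) from seeded random
#' starts, keeping the best of \code{n_starts} runs.  Frequencies are
#' clamped to [1e-6, 1 - 1e-6] so the log-likelihood stays finite.
#'
#' K = 1 is solved in closed form: the maximum-likelihood frequency row
#' is the per-locus sample allele frequency.
#'
#' @param G a \code{\link{genotype_matrix}} (missing entries allowed).
#' @param K number of ancestral populations, 1 <= K <= n.
#' @param seed integer seed controlling the random starts.
#' @param tol EM stops when the log-likelihood improves by less than
#'   this between iterations.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts random restarts; the best log-likelihood wins.
#' @return object of class \code{admixture_fit}: list with \code{Q},
#'   \code{F}, \code{loglik}, \code{loglik_trace}, \code{K},
#'   \code{converged}, \code{n_iter}, \code{G} (the data).
#' @seealso \code{\link{select_K_elbow}}, \code{\link{ancestral_fst}}
#' @export
fit_admixture <- function(G, K, seed = 1L, tol = 1e-4, max_iter = 2000L,
                          n_starts = 3L) {
  stopifnot(inherits(G, "genotype_matrix"), K >= 1)
  g <- G$values
  n <- nrow(g); L <- ncol(g)
  if (K > n) stop("K must not exceed the number of accessions")
  A <- 2 * g; A[is.na(A)] <- 0          # reference-allele counts
  B <- 2 - 2 * g; B[is.na(B)] <- 0      # alternate-allele counts
  eps <- 1e-6

  if (K == 1L) {
    p <- colSums(A) / pmax(colSums(A + B), 1)
    p <- pmin(pmax(p, eps), 1 - eps)
    ll <- sum(A %*% log(p)) + sum(B %*% log(1 - p))
    return(new_admixture_fit(Q = matrix(1, n, 1), F = matrix(p, 1, L),
                             loglik = ll, trace = ll, K = 1L,
                             converged = TRUE, n_iter = 0L, G = G))
  }

  p_hat <- colSums(A) / pmax(colSums(A + B), 1)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    Q0 <- rdirichlet(n, rep(1, K))
    F0 <- matrix(pmin(pmax(rep(p_hat, each = K) +
                             runif(K * L, -0.1, 0.1), eps), 1 - eps), K, L)
    fit <- .admixture_em_cpp(A, B, Q0, F0, tol, as.integer(max_iter), eps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  new_admixture_fit(Q = best$Q, F = best$F, loglik = best$loglik,
                    trace = best$trace, K = as.integer(K),
                    converged = best$converged,
                    n_iter = best$n_iter, G = G)
}

new_admixture_fit <- function(Q, F, loglik, trace, K, converged, n_iter, G) {
  rownames(Q) <- G$accession_ids
  colnames(Q) <- paste0("ancestor", seq_len(K))
  rownames(F) <- colnames(Q)
  colnames(F) <- colnames(G$values)
  structure(list(Q = Q, F = F, loglik = loglik, loglik_trace = trace,
                 K = K, converged = converged, n_iter = n_iter, G = G),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture model fit: K = %d ancestors, %d accessions x %d loci\n",
              x$K, nrow(x$Q), ncol(x$F)))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}

#' @export
summary.admixture_fit <- function(object, ...) {
  dom <- apply(object$Q, 1, which.max)
  out <- list(K = object$K, loglik = object$loglik,
              converged = object$converged, n_iter = object$n_iter,
              mean_dominant_ratio = mean(object$Q[cbind(seq_len(nrow(object$Q)), dom)]),
              ancestor_sizes = table(factor(dom, levels = seq_len(object$K))),
              fst = if (object$K >= 2) ancestral_fst(object$F) else NULL)
  class(out) <- "summary.admixture_fit"
  out
}

#' @export
print.summary.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture model: K = %d, log-likelihood %.2f\n", x$K, x$loglik))
  cat(sprintf("  mean dominant ancestry ratio: %.3f\n", x$mean_dominant_ratio))
  cat("  accessions per dominant ancestor:\n")
  print(x$ancestor_sizes)
  if (!is.null(x$fst)) {
    cat("  pairwise FST between inferred ancestral populations:\n")
    print(round(x$fst, 3))
  }
  invisible(x)
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik,
            df = (nrow(object$Q) * (object$K - 1) + object$K * ncol(object$F)),
            class = "logLik")
}

#' @export
fitted.admixture_fit <- function(object, ...) object$Q %*% object$F

#' @export
residuals.admixture_fit <- function(object, ...) {
  object$G$values - fitted(object)
}

#' Stacked ancestry bar plot of a fitted admixture model
#'
#' @param x an \code{admixture_fit}.
#' @param order_by optional grouping factor used to order accessions.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.admixture_fit <- function(x, order_by = NULL, ...) {
  Q <- x$Q
  ord <- if (!is.null(order_by)) order(order_by, -Q[, 1]) else
    order(apply(Q, 1, which.max), -apply(Q, 1, max))
  graphics::barplot(t(Q[ord, , drop = FALSE]), border = NA, space = 0,
                    col = grDevices::hcl.colors(x$K, "Dark 3"),
                    names.arg = rep("", nrow(Q)),
                    ylab = "ancestry ratio", ...)
  invisible(x)
}

#' Simulate genotypes from a fitted admixture model
#'
#' @param object an \code{admixture_fit}.
#' @param nsim number of replicate matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of \code{\link{genotype_matrix}} objects.
#' @export
simulate.admixture_fit <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_genotypes(object$Q, object$F, seed = stage_seed(seed, i)))
}

#' Choose the number of ancestors by the log-likelihood elbow
#'
#' Fits the admixture model for each K in \code{K_range} (plus K-1 below
#' the range minimum when needed) and forms the successive gains
#' gain(K) = loglik(K) - loglik(K-1).  The chosen K* maximises
#' gain(K*) - gain(K*+1), the sharpest drop in marginal gain — the elbow
#' of the likelihood curve.  Ties break toward smaller K.  Lighter
#' convergence settings than \code{\link{fit_admixture}} are used by
#' default because between-K likelihood differences are orders of
#' magnitude larger than within-fit convergence error.
#'
#' When the candidate range includes K = 1 its gain is measured against
#' a constant-frequency baseline (every locus at the pooled mean
#' frequency, a "K = 0" model), so a structureless panel elects K = 1.
#' With that anchor the K = 1 candidate tests "any locus-specific
#' structure at all" and dominates on most panels; start the range at 2
#' unless a no-structure null is the question.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param K_range sorted integer vector of candidate K (length >= 3).
#' @param seed integer seed.
#' @param n_starts,tol,max_iter EM settings per candidate fit.
#' @return list with \code{K} (the choice), \code{curve} (data.frame of
#'   K, loglik, gain) and \code{fits} (the fitted models, named by K).
#' @export
select_K_elbow <- function(G, K_range = 2:7, seed = 1L, n_starts = 2L,
                           tol = 1e-2, max_iter = 500L) {
  K_range <- sort(unique(as.integer(K_range)))
  stopifnot(length(K_range) >= 3, all(K_range >= 1))
  Ks <- K_range
  if (min(Ks) > 1) Ks <- c(min(Ks) - 1L, Ks)   # need loglik(Kmin - 1) for gain
  fits <- lapply(Ks, function(K)
    fit_admixture(G, K, seed = stage_seed(seed, K), tol = tol,
                  max_iter = max_iter, n_starts = n_starts))
  names(fits) <- Ks
  ll <- vapply(fits, `[[`, 0, "loglik")
  if (any(diff(ll) < 0))
    warning("log-likelihood not monotone across K; optimizer may have ",
            "stalled for some K")
  gain <- c(NA, diff(ll))                       # gain(K) = ll(K) - ll(K-1)
  if (min(Ks) == 1L) {
    g <- G$values
    a <- 2 * g[!is.na(g)]
    pbar <- min(max(mean(a) / 2, 1e-6), 1 - 1e-6)
    ll0 <- sum(a) * log(pbar) + sum(2 - a) * log(1 - pbar)
    gain[1] <- ll[1] - ll0
  }
  # candidates: members of K_range with both gain(K) and gain(K+1) available
  crit <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)) {
    if (!is.na(gain[i]) && i < length(Ks))
      crit[i] <- gain[i] - gain[i + 1]
  }
  ok <- which(Ks %in% K_range & !is.na(crit))
  best <- ok[which.max(crit[ok])]               # which.max breaks ties low
  list(K = Ks[best],
       curve = data.frame(K = Ks, loglik = ll, gain = gain,
                          gain_drop = crit),
       fits = fits)
}

#' Hudson-type FST between ancestral populations
#'
#' Given ancestral allele frequencies F (K x L), the pairwise divergence
#' between ancestors k and l is
#' \deqn{F_{ST}(k,l) = \frac{\mathrm{mean}_j (f_{kj}-f_{lj})^2}
#'   {\mathrm{mean}_j [f_{kj}(1-f_{lj}) + f_{lj}(1-f_{kj})]}}
#' the ratio-of-means Hudson estimator applied to the inferred
#' frequencies.  Identical rows give 0 by convention (including the 0/0
#' case of completely fixed identical frequencies).
#'
#' @param F K x L matrix of ancestral allele frequencies (K >= 2) or an
#'   \code{admixture_fit}.
#' @return K x K symmetric matrix, zero diagonal.
#' @export
ancestral_fst <- function(F) {
  if (inherits(F, "admixture_fit")) F <- F$F
  F <- as.matrix(F)
  K <- nrow(F)
  if (K < 2) stop("ancestral_fst needs at least two ancestral populations")
  out <- matrix(0, K, K)
  for (k in seq_len(K - 1)) for (l in (k + 1):K) {
    num <- mean((F[k, ] - F[l, ])^2)
    den <- mean(F[k, ] * (1 - F[l, ]) + F[l, ] * (1 - F[k, ]))
    out[k, l] <- out[l, k] <- if (den == 0) 0 else num / den
  }
  if (!is.null(rownames(F))) dimnames(out) <- list(rownames(F), rownames(F))
  out
}

#' Read/write ancestry matrices in the whitespace .Q/.P convention
#'
#' \code{write_q_matrix} writes one row per accession with K
#' whitespace-separated ancestry ratios (the .Q file convention);
#' \code{write_f_matrix} writes one row per locus with K ancestral
#' frequencies (.P convention).  The readers accept the same formats so
#' externally estimated matrices can enter the pipeline.
#'
#' @param Q,F matrices (or an \code{admixture_fit} for the writers).
#' @param path file path.
#' @return the matrix (readers) or \code{path} invisibly (writers).
#' @export
write_q_matrix <- function(Q, path) {
  if (inherits(Q, "admixture_fit")) Q <- Q$Q
  utils::write.table(format(Q, digits = 6, scientific = FALSE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_q_matrix
#' @export
write_f_matrix <- function(F, path) {
  if (inherits(F, "admixture_fit")) F <- F$F
  utils::write.table(format(t(F), digits = 6, scientific = FALSE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_q_matrix
#' @export
read_q_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname write_q_matrix
#' @export
read_f_matrix <- function(path) {
  t(as.matrix(utils::read.table(path, header = FALSE)))
}
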