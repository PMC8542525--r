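#' @useDynLib ricepopstruct, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbeta rbinom rnorm runif aov chisq.test kmeans prcomp
#'   pchisq wilcox.test sd predict
#' @importFrom utils read.csv write.csv read.table write.table combn
NULL

# Dirichlet draws, one row per sample
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Match the columns of an estimated matrix to a reference by permutation
#'
#' Ancestry components are identified only up to label switching: a fitted
#' ancestry-ratio matrix can have its columns in any order relative to the
#' truth.  This exhaustively searches the K! column permutations of
#' \code{estimate} and returns the one minimising the mean absolute
#' difference to \code{reference}.
#'
#' @param estimate,reference numeric matrices of identical dimension.
#' @return list with \code{permutation} (column order to apply to
#'   \code{estimate}), \code{matched} (the permuted estimate) and
#'   \code{mae} (mean absolute error after matching).
#' @export
match_columns <- function(estimate, reference) {
  stopifnot(is.matrix(estimate), is.matrix(reference),
            all(dim(estimate) == dim(reference)))
  K <- ncol(estimate)
  perms <- permutations_of(K)
  best <- NULL
  best_mae <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    mae <- mean(abs(estimate[, p, drop = FALSE] - reference))
    if (mae < best_mae) {
      best_mae <- mae
      best <- p
    }
  }
  list(permutation = best,
       matched = estimate[, best, drop = FALSE],
       mae = best_mae)
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  out <- matrix(0L, nrow(sub) * K, K)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(K)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], K, after = pos - 1L)
    }
  }
  out
}

# seeded child seed for a named pipeline stage; stays below 2^31
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
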