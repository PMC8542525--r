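#' Principal component analysis of numeric genotypes
#'
#' Column-centers (without unit-variance scaling, the common default for
#' genotype PCA) the complete numeric genotype matrix and decomposes it
#' by SVD.  Scores are the centered data projected on the right singular
#' vectors, ordered by decreasing explained variance.
#'
#' @param G_complete complete numeric matrix (accessions x loci), e.g.
#'   from \code{\link{impute_mean}}, or a \code{\link{genotype_matrix}}
#'   with no missing entries.
#' @param m number of components to return; truncated with a warning if
#'   it exceeds the matrix rank.
#' @param scale. also scale columns to unit variance (off by default).
#' @return object of class \code{pca_result}: list with \code{scores}
#'   (n x m) and \code{explained_variance} (fraction per component).
#' @export
pca <- function(G_complete, m = 10L, scale. = FALSE) {
  if (inherits(G_complete, "genotype_matrix")) {
    if (anyNA(G_complete$values))
      stop("matrix has missing entries; run impute_mean first")
    G_complete <- G_complete$values
  }
  if (anyNA(G_complete)) stop("matrix has missing entries; impute first")
  r <- min(nrow(G_complete) - 1L, ncol(G_complete))
  if (m > r) {
    warning("m exceeds the matrix rank; truncating to ", r)
    m <- r
  }
  if (scale.) {
    keep <- apply(G_complete, 2, stats::sd) > 0
    G_complete <- G_complete[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(G_complete, center = TRUE, scale. = scale., rank. = m)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(m), drop = FALSE],
                 explained_variance = ev[seq_len(m)],
                 rotation = pc$rotation),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d accessions, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Mean-absolute-difference (1 - IBS) genotype distance matrix
#'
#' d(a, b) = mean_j |g_aj - g_bj| over the numeric encoding, i.e. one
#' minus the mean identity-by-state.  Symmetric with zero diagonal,
#' entries in [0, 1].
#'
#' @param G_complete complete numeric matrix or
#'   \code{\link{genotype_matrix}} with no missing entries.
#' @return n x n symmetric distance matrix.
#' @export
distance_matrix <- function(G_complete) {
  if (inherits(G_complete, "genotype_matrix")) {
    if (anyNA(G_complete$values)) stop("impute missing entries first")
    G_complete <- G_complete$values
  }
  d <- as.matrix(stats::dist(G_complete, method = "manhattan")) / ncol(G_complete)
  rownames(d) <- colnames(d) <- rownames(G_complete)
  d
}

#' Neighbor-joining tree with newick output
#'
#' Classic Saitou-Nei neighbor joining (via \code{\link[ape]{nj}}) on a
#' symmetric distance matrix.  Negative branch lengths, which NJ can
#' produce on non-additive matrices, are clamped to zero with a warning.
#'
#' @param D symmetric distance matrix with zero diagonal, n >= 3.
#' @param leaf_names optional leaf names (defaults to D's dimnames).
#' @return list with \code{tree} (an \pkg{ape} \code{phylo}) and
#'   \code{newick} (the newick string with branch lengths).
#' @export
nj_tree <- function(D, leaf_names = NULL) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D), nrow(D) >= 3,
            isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  if (!is.null(leaf_names)) rownames(D) <- colnames(D) <- leaf_names
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Chi-square test of independence between origin and subpopulation
#'
#' Pearson chi-square on an origins x subpopulations contingency table
#' with dof = (rows - 1)(cols - 1); zero-total rows or columns are
#' dropped with a warning before testing.  Expected counts are returned
#' for diagnostics.
#'
#' @param counts non-negative integer matrix (or table/data.frame) with
#'   origin rows and subpopulation columns.
#' @return list with \code{chi2}, \code{dof}, \code{p} and
#'   \code{expected}.
#' @export
origin_association_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table")
  rz <- rowSums(counts) == 0
  cz <- colSums(counts) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-total rows/columns before testing")
    counts <- counts[!rz, !cz, drop = FALSE]
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
       p = unname(ct$p.value), expected = ct$expected)
}

#' Origins-by-subpopulation table of the 300-accession Thai rice panel
#'
#' Returns the packaged published contingency table of geographic origin
#' (10 rows, including IRRI introductions and unknown origins) against
#' the five inferred subpopulations of the 300-accession Thai rice
#' diversity panel.  Row and column totals match the published marginal
#' totals (grand total 300).  Note this table reports 53 and 68
#' accessions for POP1/POP3 where the clustering summary elsewhere
#' reports 54 and 67; the discrepancy exists in the source tables and is
#' preserved as printed.
#'
#' @return integer matrix with origin rownames and POP1..POP5 columns.
#' @export
thai_rice_origin_table <- function() {
  path <- system.file("extdata", "table1_origins.csv",
                      package = "ricepopstruct", mustWork = TRUE)
  read_contingency_csv(path)
}

#' Read/write a labeled contingency table CSV
#'
#' First column holds row labels; header holds column labels.
#'
#' @param path file path.
#' @return integer matrix with dimnames.
#' @export
read_contingency_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_contingency_csv
#' @param counts labeled matrix to write.
#' @export
write_contingency_csv <- function(counts, path) {
  d <- data.frame(origin = rownames(counts), counts, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
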