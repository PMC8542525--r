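#' Broad-sense heritability from replicated trait records
#'
#' One-way random-effects ANOVA method-of-moments on the long-format
#' phenotype table: with accessions as the random factor and r
#' replicates per accession, sigma2_e = MS_within and sigma2_G =
#' (MS_between - MS_within)/r (floored at 0), giving
#' \deqn{h^2_B = \sigma^2_G / (\sigma^2_G + \sigma^2_e / r)}
#' the repeatability of accession means.  Unbalanced designs use the
#' mean replicate count with a warning; r = 1 leaves the residual
#' variance inestimable and is an error.
#'
#' @param P phenotype data.frame with columns \code{accession_id},
#'   \code{replicate}, \code{trait}, \code{value}.
#' @param trait trait name to analyse.
#' @return list with \code{h2}, \code{sigma_g2}, \code{sigma_e2},
#'   \code{r}, \code{n_accessions}.
#' @export
broad_sense_heritability <- function(P, trait) {
  d <- P[P$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("no records for trait '", trait, "'")
  d$accession_id <- factor(d$accession_id)
  if (nlevels(d$accession_id) < 2) stop("need at least two accessions")
  reps <- table(d$accession_id)
  r <- mean(reps)
  if (max(reps) == 1) stop("r = 1: residual variance is inestimable")
  if (length(unique(reps)) > 1)
    warning("unbalanced replicates; using mean r = ", round(r, 2))
  fit <- stats::aov(value ~ accession_id, data = d)
  ss_within <- stats::deviance(fit)
  ss_total <- sum((d$value - mean(d$value))^2)
  ms_between <- (ss_total - ss_within) / (nlevels(d$accession_id) - 1)
  ms_within <- ss_within / stats::df.residual(fit)
  sigma_e2 <- ms_within
  sigma_g2 <- max((ms_between - ms_within) / r, 0)
  h2 <- if (sigma_g2 == 0) 0 else sigma_g2 / (sigma_g2 + sigma_e2 / r)
  list(h2 = h2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
       r = r, n_accessions = nlevels(d$accession_id))
}

#' One-sided Mann-Whitney U test (x stochastically greater than y)
#'
#' U counts the pairs with x_i > y_j plus half the ties.  The p-value is
#' exact (full enumeration of rank arrangements) when min(n_x, n_y) <= 8
#' and the data carry no ties, otherwise the normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @return list with \code{U}, \code{p} and \code{method}.
#' @export
mann_whitney_one_sided <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Infer a per-trait domination graph over subpopulations
#'
#' Accession-level trait values (means over replicates) are compared
#' between every unordered pair of subpopulations with both one-sided
#' Mann-Whitney tests; a directed edge A -> B is added when the test of
#' "A stochastically greater than B" has p <= alpha.  Both directions
#' cannot pass simultaneously at alpha < 0.5, so the edge set is
#' antisymmetric by construction.  Subpopulations with fewer than two
#' accessions are excluded with a warning.  No multiplicity correction
#' is applied across pairs; alpha is the fixed per-test level.
#'
#' @param P phenotype data.frame (see
#'   \code{\link{broad_sense_heritability}}).
#' @param labels subpopulation label per accession, named by
#'   accession_id or aligned with the unique accession ids of \code{P}.
#' @param trait trait name.
#' @param alpha per-test significance level (default 0.001).
#' @return object of class \code{domination_graph}: list with
#'   \code{nodes}, \code{edges} (data.frame trait, from, to, U, p),
#'   \code{alpha}, \code{trait}.
#' @export
domination_graph <- function(P, labels, trait, alpha = 0.001) {
  d <- P[P$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("no records for trait '", trait, "'")
  acc_means <- tapply(d$value, d$accession_id, mean)
  ids <- names(acc_means)
  lab <- if (!is.null(names(labels))) labels[ids]
         else stats::setNames(as.character(labels), unique(P$accession_id))[ids]
  lab <- as.character(lab)
  groups <- split(as.numeric(acc_means), lab)
  small <- names(groups)[vapply(groups, length, 0L) < 2]
  if (length(small)) {
    warning("excluding subpopulations with < 2 accessions: ",
            paste(small, collapse = ", "))
    groups <- groups[!(names(groups) %in% small)]
  }
  if (length(groups) < 2) stop("need at least two usable subpopulations")
  nodes <- names(groups)
  edges <- data.frame(trait = character(), from = character(),
                      to = character(), U = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  for (pair in combn(nodes, 2, simplify = FALSE)) {
    a <- pair[1]; b <- pair[2]
    ab <- mann_whitney_one_sided(groups[[a]], groups[[b]])
    ba <- mann_whitney_one_sided(groups[[b]], groups[[a]])
    if (ab$p <= alpha)
      edges[nrow(edges) + 1L, ] <- list(trait, a, b, ab$U, ab$p)
    else if (ba$p <= alpha)
      edges[nrow(edges) + 1L, ] <- list(trait, b, a, ba$U, ba$p)
  }
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 trait = trait),
            class = "domination_graph")
}

#' @export
print.domination_graph <- function(x, ...) {
  cat(sprintf("domination_graph for '%s' (alpha = %g): %d nodes, %d edges\n",
              x$trait, x$alpha, length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to,
               sprintf("  (U = %g, p = %.2g)", x$edges$U, x$edges$p),
               collapse = "\n"), "\n")
  invisible(x)
}

#' Write a domination graph as DOT text
#'
#' @param g a \code{domination_graph}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dot <- function(g, path) {
  stopifnot(inherits(g, "domination_graph"))
  lines <- c(sprintf("digraph \"%s\" {", g$trait),
             sprintf("  \"%s\";", g$nodes),
             if (nrow(g$edges))
               sprintf("  \"%s\" -> \"%s\" [label=\"p=%.2g\"];",
                       g$edges$from, g$edges$to, g$edges$p),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the long-format traits CSV
#'
#' Columns: accession_id, replicate, trait, value.
#'
#' @param path file path.
#' @return data.frame (reader) or \code{path} invisibly (writer).
#' @export
read_traits_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_traits_csv
#' @param P phenotype data.frame.
#' @export
write_traits_csv <- function(P, path) {
  utils::write.csv(P, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
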