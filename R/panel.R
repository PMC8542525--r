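#' One-vs-rest discriminative SNP scan for one subpopulation
#'
#' Treats membership of \code{target_pop} as a binary trait y (1 =
#' member) and, locus by locus, regresses y on the numeric genotype.
#' The reported score is the single-marker LOD
#' \deqn{LOD_j = (n_j / 2)\,\log_{10}(RSS_0 / RSS_1)}
#' with RSS_0 the intercept-only residual sum of squares and n_j the
#' non-missing sample size at locus j; a perfect fit (RSS_1 underflow)
#' is capped at \code{lod_cap}.  The allele-frequency difference
#' |p_in - p_out| between member and non-member accessions (non-missing
#' calls) is reported alongside.  Intended for matrices that passed
#' \code{\link{filter_biallelic_homozygous}}.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param labels subpopulation label per accession.
#' @param target_pop the label scanned against the rest.
#' @param lod_cap LOD value reported when the genotype explains y
#'   perfectly.
#' @return data.frame of class \code{scan_result}: locus, chrom, pos,
#'   lod, freq_diff, ordered as in \code{G}.
#' @export
one_vs_rest_scan <- function(G, labels, target_pop, lod_cap = 50) {
  stopifnot(inherits(G, "genotype_matrix"))
  labels <- as.character(labels)
  if (!target_pop %in% labels) stop("target_pop not present in labels")
  y <- as.numeric(labels == target_pop)
  g <- G$values
  obs <- !is.na(g)
  g0 <- ifelse(obs, g, 0)
  nj <- colSums(obs)
  sy <- colSums(y * obs)                 # per-locus sums over non-missing
  syy <- colSums(y^2 * obs)
  sg <- colSums(g0)
  sgg <- colSums(g0^2)
  sgy <- colSums(g0 * y)
  rss0 <- syy - sy^2 / nj
  sxx <- sgg - sg^2 / nj
  sxy <- sgy - sg * sy / nj
  beta_term <- ifelse(sxx > 1e-12, sxy^2 / sxx, 0)
  rss1 <- pmax(rss0 - beta_term, 0)
  lod <- ifelse(sxx <= 1e-12 | rss0 <= 1e-12, 0,
                ifelse(rss1 < 1e-12, lod_cap,
                       (nj / 2) * log10(rss0 / rss1)))
  lod <- pmin(lod, lod_cap)
  p_in <- colSums(g0 * y) / pmax(colSums(obs * y), 1)
  p_out <- colSums(g0 * (1 - y)) / pmax(colSums(obs * (1 - y)), 1)
  out <- data.frame(locus = colnames(g), chrom = G$loci$chrom,
                    pos = G$loci$pos, lod = lod,
                    freq_diff = abs(p_in - p_out),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  attr(out, "target_pop") <- target_pop
  out
}

#' Assemble a discriminative SNP panel from per-population scans
#'
#' Within each subpopulation's scan, loci are ranked lexicographically
#' by (allele-frequency difference, LOD) descending and the top m are
#' taken, where m is \code{per_pop_max} truncated by the number of loci
#' with a positive frequency difference; fewer than \code{per_pop_min}
#' informative loci triggers a warning and all are taken.  The
#' per-population lists are unioned with deduplication; each panel locus
#' is attributed to the population for which its frequency difference is
#' largest.
#'
#' @param scans named list of \code{\link{one_vs_rest_scan}} results,
#'   one per subpopulation.
#' @param per_pop_min,per_pop_max per-population panel size band.
#' @return object of class \code{discriminative_panel}: list with
#'   \code{panel} (data.frame locus, chrom, pos, population, freq_diff,
#'   lod), \code{per_population} (selected locus lists),
#'   \code{union_size}, \code{thresholds}.
#' @export
select_panel <- function(scans, per_pop_min = 50L, per_pop_max = 100L) {
  stopifnot(length(scans) >= 1)
  if (is.null(names(scans)))
    names(scans) <- vapply(scans, attr, "", "target_pop")
  per_pop <- list()
  rows <- list()
  for (pop in names(scans)) {
    s <- scans[[pop]]
    informative <- s[s$freq_diff > 0, , drop = FALSE]
    ord <- order(-informative$freq_diff, -informative$lod,
                 informative$chrom, informative$pos)
    informative <- informative[ord, , drop = FALSE]
    m <- min(nrow(informative), per_pop_max)
    if (m < per_pop_min)
      warning("only ", m, " informative loci for ", pop,
              " (requested at least ", per_pop_min, ")")
    sel <- informative[seq_len(m), , drop = FALSE]
    per_pop[[pop]] <- sel$locus
    if (m > 0) rows[[pop]] <- cbind(sel, population = pop,
                                    stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows) || !nrow(all_rows)) {
    warning("empty panel: no informative loci in any scan")
    panel <- data.frame(locus = character(), chrom = character(),
                        pos = integer(), population = character(),
                        freq_diff = numeric(), lod = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    # dedup: keep, per locus, the attribution with the largest freq diff
    all_rows <- all_rows[order(-all_rows$freq_diff, -all_rows$lod), ]
    panel <- all_rows[!duplicated(all_rows$locus),
                      c("locus", "chrom", "pos", "population",
                        "freq_diff", "lod")]
    panel <- panel[order(panel$chrom, panel$pos), ]
    rownames(panel) <- NULL
  }
  structure(list(panel = panel, per_population = per_pop,
                 union_size = nrow(panel),
                 thresholds = c(per_pop_min = per_pop_min,
                                per_pop_max = per_pop_max)),
            class = "discriminative_panel")
}

#' @export
print.discriminative_panel <- function(x, ...) {
  cat(sprintf("discriminative_panel: %d unique loci (band %d-%d per population)\n",
              x$union_size, x$thresholds["per_pop_min"],
              x$thresholds["per_pop_max"]))
  print(table(attributed_to = x$panel$population))
  invisible(x)
}

#' Overlay gene annotation on a discriminative panel
#'
#' For each panel locus, reports the genes whose [start, end] interval
#' (1-based, inclusive on both ends, strand-agnostic) contains the SNP
#' position.  Additionally, panel SNPs on one chromosome whose
#' inter-SNP gaps are at most \code{window} are grouped into runs, and
#' all genes overlapping each run's span are reported as flanking-
#' interval genes.
#'
#' @param panel a \code{discriminative_panel}.
#' @param gff_path path to a GFF3 file with \code{gene} features
#'   (parsed with \code{\link[ape]{read.gff}}; malformed lines are
#'   dropped by the parser).
#' @param window maximum gap (bp) within a run of closely spaced SNPs.
#' @return list with \code{hits} (data.frame locus, chrom, pos,
#'   gene_id, start, end) and \code{intervals} (data.frame chrom,
#'   span_start, span_end, n_snps, genes).
#' @export
annotate_genes <- function(panel, gff_path, window = 1e5) {
  stopifnot(inherits(panel, "discriminative_panel"))
  gff <- ape::read.gff(gff_path)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  gene_id <- sub(".*ID=([^;]+).*", "\\1", genes$attributes)
  p <- panel$panel
  hits <- list()
  for (i in seq_len(nrow(p))) {
    inside <- genes$seqid == p$chrom[i] &
      genes$start <= p$pos[i] & genes$end >= p$pos[i]
    if (any(inside))
      hits[[length(hits) + 1L]] <- data.frame(
        locus = p$locus[i], chrom = p$chrom[i], pos = p$pos[i],
        gene_id = gene_id[inside], start = genes$start[inside],
        end = genes$end[inside], stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(locus = character(), chrom = character(), pos = integer(),
               gene_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  intervals <- list()
  for (ch in unique(p$chrom)) {
    pos <- sort(p$pos[p$chrom == ch])
    run_id <- cumsum(c(1, diff(pos) > window))
    for (rid in unique(run_id)) {
      span <- range(pos[run_id == rid])
      g_in <- genes$seqid == ch & genes$start <= span[2] & genes$end >= span[1]
      intervals[[length(intervals) + 1L]] <- data.frame(
        chrom = ch, span_start = span[1], span_end = span[2],
        n_snps = sum(run_id == rid),
        genes = paste(gene_id[g_in], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(intervals)) do.call(rbind, intervals) else
    data.frame(chrom = character(), span_start = integer(),
               span_end = integer(), n_snps = integer(),
               genes = character(), stringsAsFactors = FALSE)
  list(hits = hits, intervals = intervals)
}

#' Cross-validated population classification from a SNP panel
#'
#' Stratified, seeded k-fold cross-validation of a classifier predicting
#' subpopulation membership from the panel genotypes.  Missing
#' genotypes are mean-imputed from the training folds only.  Out-of-fold
#' predictions are pooled and scored one-vs-rest per class: precision =
#' TP/(TP+FP), recall = TP/(TP+FN), and F1 = 2PR/(P+R) (defined as 0
#' when P + R = 0).  The default classifier is a random forest; any
#' fit/predict pair can be plugged in.
#'
#' @param G_panel a \code{\link{genotype_matrix}} restricted to panel
#'   loci, or a plain numeric matrix.
#' @param labels subpopulation label per accession.
#' @param folds number of folds (default 10), reduced with a warning if
#'   some class is smaller.
#' @param seed integer seed (fold assignment and classifier).
#' @param fit_fun function(x, y) returning a fitted classifier (y is a
#'   factor); defaults to \code{randomForest::randomForest}.
#' @param predict_fun function(fit, x) returning predicted labels.
#' @return object of class \code{cv_report}: list with \code{metrics}
#'   (data.frame class, precision, recall, F1, TP, FP, FN),
#'   \code{confusion}, \code{folds}, \code{seed}, \code{predicted}.
#' @export
crossval_classify <- function(G_panel, labels, folds = 10L, seed = 1L,
                              fit_fun = NULL, predict_fun = NULL) {
  x <- if (inherits(G_panel, "genotype_matrix")) G_panel$values else
    as.matrix(G_panel)
  y <- factor(labels)
  stopifnot(nrow(x) == length(y))
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class has ", min_class,
            " members; reducing folds to ", min_class)
    folds <- min_class
  }
  if (folds < 2) stop("need at least 2 usable folds")
  if (is.null(fit_fun))
    fit_fun <- function(x, y)
      randomForest::randomForest(x, y, ntree = 500)
  if (is.null(predict_fun))
    predict_fun <- function(fit, x) stats::predict(fit, x)

  set.seed(seed)
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (any(table(y[tr]) == 0))
      stop("a class is absent from a training fold; use fewer folds")
    xtr <- x[tr, , drop = FALSE]
    mu <- colMeans(xtr, na.rm = TRUE)
    mu[is.nan(mu)] <- 0.5
    fill <- function(m) {
      idx <- which(is.na(m), arr.ind = TRUE)
      if (nrow(idx)) m[idx] <- mu[idx[, 2]]
      m
    }
    fit <- fit_fun(fill(xtr), droplevels(y[tr]))
    p <- predict_fun(fit, fill(x[!tr, , drop = FALSE]))
    pred[!tr] <- factor(as.character(p), levels = levels(y))
  }
  conf <- table(truth = y, predicted = pred)
  metrics <- do.call(rbind, lapply(levels(y), function(cl) {
    tp <- sum(y == cl & pred == cl)
    fp <- sum(y != cl & pred == cl)
    fn <- sum(y == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, F1 = f1,
               TP = tp, FP = fp, FN = fn, stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, confusion = conf,
                 folds = as.integer(folds), seed = seed, predicted = pred),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold stratified cross-validation\n", x$folds))
  m <- x$metrics
  m[, c("precision", "recall", "F1")] <-
    round(m[, c("precision", "recall", "F1")], 3)
  print(m[, c("class", "precision", "recall", "F1")], row.names = FALSE)
  invisible(x)
}

#' Restrict a genotype matrix to panel loci
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param panel a \code{discriminative_panel} (or character vector of
#'   \code{chrom:pos} locus names).
#' @return the restricted \code{\link{genotype_matrix}}.
#' @export
subset_panel <- function(G, panel) {
  loci <- if (inherits(panel, "discriminative_panel")) panel$panel$locus
          else as.character(panel)
  keep <- colnames(G$values) %in% loci
  subset_loci(G, keep)
}

#' Write a discriminative panel as TSV
#'
#' Columns: population, chrom, pos, freq_diff, lod.
#'
#' @param panel a \code{discriminative_panel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel$panel[, c("population", "chrom", "pos",
                                     "freq_diff", "lod")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
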