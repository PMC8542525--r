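#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by
#' \code{\link{run_pipeline}}, pre-filled with the analysis defaults:
#' MAF 0.05, call rate 0.70, ancestor candidates K 2..6, cluster
#' candidates k 2..7, bootstrap replicates, per-test alpha 0.001,
#' panel band 50-100 per population and 10 CV folds.  Any element can
#' be overridden via \code{...}; a YAML file with the same keys can be
#' loaded with \code{\link{read_pipeline_config}}.
#'
#' @param out_dir output directory for stage artifacts.
#' @param ... overrides of individual config entries.
#' @return named list (class \code{pipeline_config}).
#' @export
pipeline_config <- function(out_dir = tempfile("rps_run_"), ...) {
  cfg <- list(
    out_dir = out_dir,
    synthetic = list(L = 5000, fst = 0.3, seed = 1L),
    vcf = NULL,                 # alternatively: path to an input VCF
    traits_csv = NULL,          # long-format phenotype CSV
    labels_csv = NULL,          # accession origin labels CSV
    maf_min = 0.05,
    callrate_min = 0.70,
    K_range = 2:6,
    k_range = 2:7,
    fit = list(tol = 1e-4, max_iter = 2000L, n_starts = 3L),
    elbow = list(tol = 1e-2, max_iter = 500L, n_starts = 2L),
    n_boot = 10000L,
    alpha = 0.001,
    per_pop_min = 50L,
    per_pop_max = 100L,
    folds = 10L,
    gff = NULL,                 # gene annotation; synthetic runs make one
    annotation_window = 1e5,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file whose keys override the defaults.
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over)
}

#' Run the full population-structure pipeline
#'
#' Executes, in order: data simulation (or VCF ingestion), call-rate/MAF
#' filtering, admixture-model ancestry estimation with elbow selection
#' of K, k-means subpopulation clustering with BCTSS elbow and bootstrap
#' support, PCA, neighbor-joining tree, origin chi-square association,
#' broad-sense heritability, per-trait domination graphs, discriminative
#' SNP panel selection and cross-validated population classification.
#' Every stage writes a plain-text artifact into \code{config$out_dir}
#' and a machine-readable JSON manifest records file names, seeds,
#' locus counts and headline numbers.  Re-running with the same config
#' reproduces every output.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) list with all stage results plus \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(seed = seed, artifacts = character())
  note <- function(name, file) {
    manifest$artifacts[name] <<- file
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- data ------------------------------------------------------------
  phen <- NULL; origins <- NULL; truth <- NULL
  if (!is.null(config$vcf)) {
    G <- stage("input", read_vcf(config$vcf))
    if (!is.null(config$traits_csv)) phen <- read_traits_csv(config$traits_csv)
    if (!is.null(config$labels_csv)) {
      lab <- utils::read.csv(config$labels_csv, stringsAsFactors = FALSE)
      origins <- stats::setNames(lab[[2]], lab[[1]])[G$accession_ids]
    }
  } else {
    syn <- stage("simulate", do.call(simulate_rice_panel, config$synthetic))
    G <- syn$G; phen <- syn$phenotypes; origins <- syn$origins
    truth <- syn$truth
    write_vcf(G, file.path(out, "genotypes.vcf"))
    write_traits_csv(phen, file.path(out, "traits.csv"))
    utils::write.csv(data.frame(accession_id = G$accession_ids,
                                subpopulation = truth$true_labels,
                                origin = origins),
                     file.path(out, "labels.csv"), row.names = FALSE)
    note("genotypes", "genotypes.vcf"); note("traits", "traits.csv")
    note("labels", "labels.csv")
  }
  manifest$n_accessions <- nrow(G$values)
  manifest$loci_input <- ncol(G$values)

  # -- filtering -------------------------------------------------------
  Gf <- stage("filter",
              filter_maf_callrate(G, config$maf_min, config$callrate_min))
  manifest$loci_filtered <- ncol(Gf$values)
  write_genotype_tsv(Gf, file.path(out, "genotypes_filtered.tsv"))
  note("filtered_matrix", "genotypes_filtered.tsv")

  # -- ancestry --------------------------------------------------------
  elbowK <- stage("ancestry",
                  select_K_elbow(Gf, config$K_range,
                                 seed = stage_seed(seed, 11),
                                 n_starts = config$elbow$n_starts,
                                 tol = config$elbow$tol,
                                 max_iter = config$elbow$max_iter))
  fit <- stage("ancestry",
               fit_admixture(Gf, elbowK$K, seed = stage_seed(seed, 12),
                             tol = config$fit$tol,
                             max_iter = config$fit$max_iter,
                             n_starts = config$fit$n_starts))
  write_q_matrix(fit, file.path(out, "ancestry.Q"))
  write_f_matrix(fit, file.path(out, "ancestry.P"))
  utils::write.csv(elbowK$curve, file.path(out, "loglik_curve.csv"),
                   row.names = FALSE)
  note("Q", "ancestry.Q"); note("F", "ancestry.P")
  note("loglik_curve", "loglik_curve.csv")
  manifest$K <- elbowK$K
  fst <- ancestral_fst(fit)
  utils::write.csv(round(fst, 4), file.path(out, "ancestral_fst.csv"))
  note("ancestral_fst", "ancestral_fst.csv")

  # -- clustering ------------------------------------------------------
  elbowk <- stage("cluster", select_k_elbow(fit$Q, config$k_range,
                                            seed = stage_seed(seed, 21)))
  cl <- elbowk$assignments[[as.character(elbowk$k)]]
  cl <- stage("cluster",
              bootstrap_support(fit$Q, cl, n_boot = config$n_boot,
                                seed = stage_seed(seed, 22)))
  pop_labels <- paste0("POP", cl$labels)
  utils::write.csv(data.frame(accession_id = G$accession_ids,
                              cluster = pop_labels),
                   file.path(out, "clusters.csv"), row.names = FALSE)
  utils::write.csv(elbowk$curve, file.path(out, "bctss_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(population = paste0("POP", seq_len(cl$k)),
                              n = as.vector(table(cl$labels)),
                              support = round(cl$support, 3)),
                   file.path(out, "cluster_support.csv"), row.names = FALSE)
  note("clusters", "clusters.csv"); note("bctss_curve", "bctss_curve.csv")
  note("cluster_support", "cluster_support.csv")
  manifest$k <- cl$k

  # -- structure summaries --------------------------------------------
  Gi <- impute_mean(Gf)
  pc <- stage("summarize", pca(Gi, m = min(10L, nrow(Gi) - 1L)))
  utils::write.csv(data.frame(accession_id = G$accession_ids,
                              cluster = pop_labels, pc$scores),
                   file.path(out, "pca_scores.csv"), row.names = FALSE)
  note("pca_scores", "pca_scores.csv")
  nj <- stage("summarize", nj_tree(distance_matrix(Gi)))
  writeLines(nj$newick, file.path(out, "nj_tree.nwk"))
  note("nj_tree", "nj_tree.nwk")
  chisq <- NULL
  if (!is.null(origins)) {
    tab <- table(origin = origins, subpopulation = pop_labels)
    chisq <- stage("summarize", origin_association_test(tab))
    utils::write.csv(data.frame(chi2 = chisq$chi2, dof = chisq$dof,
                                p = chisq$p),
                     file.path(out, "origin_chisq.csv"), row.names = FALSE)
    note("origin_chisq", "origin_chisq.csv")
  }

  # -- phenotypes ------------------------------------------------------
  h2 <- NULL; dom <- list()
  if (!is.null(phen)) {
    traits <- unique(phen$trait)
    h2 <- do.call(rbind, lapply(traits, function(tr) {
      est <- broad_sense_heritability(phen, tr)
      data.frame(trait = tr, h2 = est$h2, sigma_g2 = est$sigma_g2,
                 sigma_e2 = est$sigma_e2, r = est$r)
    }))
    utils::write.csv(h2, file.path(out, "heritability.csv"),
                     row.names = FALSE)
    note("heritability", "heritability.csv")
    lab_named <- stats::setNames(pop_labels, G$accession_ids)
    dom <- lapply(traits, function(tr)
      stage("phenotype",
            domination_graph(phen, lab_named, tr, alpha = config$alpha)))
    names(dom) <- traits
    edges <- do.call(rbind, lapply(dom, `[[`, "edges"))
    utils::write.csv(edges, file.path(out, "domination_edges.csv"),
                     row.names = FALSE)
    for (tr in traits)
      write_dot(dom[[tr]], file.path(out, paste0("domination_", tr, ".dot")))
    note("domination_edges", "domination_edges.csv")
  }

  # -- discriminative panel + CV --------------------------------------
  Ghom <- stage("panel", filter_biallelic_homozygous(Gf))
  manifest$loci_homozygous <- ncol(Ghom$values)
  pops <- sort(unique(pop_labels))
  scans <- lapply(pops, function(p) one_vs_rest_scan(Ghom, pop_labels, p))
  names(scans) <- pops
  panel <- stage("panel",
                 select_panel(scans, config$per_pop_min, config$per_pop_max))
  write_panel_tsv(panel, file.path(out, "panel.tsv"))
  note("panel", "panel.tsv")
  manifest$panel_size <- panel$union_size
  gff <- config$gff
  if (is.null(gff) && is.null(config$vcf)) {
    gff <- file.path(out, "genes_synthetic.gff3")
    write_synthetic_gff(G, gff, seed = stage_seed(seed, 41))
    note("gff", "genes_synthetic.gff3")
  }
  annotation <- NULL
  if (!is.null(gff) && panel$union_size > 0) {
    annotation <- stage("annotate",
                        annotate_genes(panel, gff,
                                       window = config$annotation_window))
    utils::write.table(annotation$hits, file.path(out, "gene_overlay.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(annotation$intervals,
                       file.path(out, "gene_intervals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("gene_overlay", "gene_overlay.tsv")
    note("gene_intervals", "gene_intervals.tsv")
  }
  cv <- NULL
  if (panel$union_size > 0) {
    cv <- stage("classify",
                crossval_classify(subset_panel(G, panel), pop_labels,
                                  folds = config$folds,
                                  seed = stage_seed(seed, 31)))
    utils::write.csv(cv$metrics[, c("class", "precision", "recall", "F1")],
                     file.path(out, "cv_report.csv"), row.names = FALSE)
    note("cv_report", "cv_report.csv")
  }

  manifest$config <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(G = G, filtered = Gf, fit = fit, elbow_K = elbowK,
                 clusters = cl, elbow_k = elbowk, pca = pc, nj = nj,
                 chisq = chisq, heritability = h2, domination = dom,
                 panel = panel, annotation = annotation, cv = cv,
                 truth = truth, manifest = manifest, out_dir = out))
}
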