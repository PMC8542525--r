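#' Numeric genotype matrix
#'
#' Container for bi-allelic diploid SNP genotypes in the numeric encoding
#' used throughout the package: 1.0 = homozygous reference, 0.5 =
#' heterozygous, 0.0 = homozygous alternate, \code{NA} = missing call.
#' Rows are accessions, columns are loci.
#'
#' @param values numeric matrix (accessions x loci) with entries in
#'   \{0, 0.5, 1\} or \code{NA}.
#' @param loci data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}; one row per locus.  Generated if omitted.
#' @param accession_ids character vector of unique accession names.
#' @return an object of class \code{genotype_matrix}: a list with elements
#'   \code{values}, \code{loci}, \code{accession_ids}.
#' @export
genotype_matrix <- function(values, loci = NULL, accession_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); L <- ncol(values)
  if (is.null(accession_ids)) {
    accession_ids <- rownames(values)
    if (is.null(accession_ids)) accession_ids <- sprintf("ACC%04d", seq_len(n))
  }
  if (anyDuplicated(accession_ids))
    stop("accession_ids must be unique")
  if (is.null(loci)) {
    loci <- data.frame(chrom = "chr1", pos = seq_len(L),
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci)
  stopifnot(nrow(loci) == L,
            all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("loci must be unique by (chrom, pos)")
  bad <- values[!is.na(values) & !(values %in% c(0, 0.5, 1))]
  if (length(bad))
    stop("non-missing genotype values must be in {0, 0.5, 1}; found ",
         paste(utils::head(unique(bad), 3), collapse = ", "))
  rownames(values) <- accession_ids
  colnames(values) <- paste(loci$chrom, loci$pos, sep = ":")
  structure(list(values = values, loci = loci,
                 accession_ids = as.character(accession_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Encode diploid genotype calls numerically
#'
#' Converts textual bi-allelic diploid calls into the numeric code
#' 0/0 -> 1.0, 0/1 or 1/0 -> 0.5, 1/1 -> 0.0, missing ("./.", ".", "")
#' -> \code{NA}.  Phased separators ("|") are accepted.
#'
#' @param calls character matrix (accessions x loci) of GT-style calls.
#' @param loci,accession_ids passed to \code{\link{genotype_matrix}}.
#' @return a \code{\link{genotype_matrix}}.
#' @export
encode_numeric <- function(calls, loci = NULL, accession_ids = NULL) {
  calls <- as.matrix(calls)
  gt <- gsub("\\|", "/", calls)
  num <- matrix(NA_real_, nrow(gt), ncol(gt))
  num[gt %in% c("0/0")] <- 1
  num[gt %in% c("0/1", "1/0")] <- 0.5
  num[gt %in% c("1/1")] <- 0
  known <- gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".", "", NA) | is.na(gt)
  if (!all(known)) {
    idx <- which(!known, arr.ind = TRUE)[1, ]
    site <- if (!is.null(loci)) paste0(loci$chrom[idx[2]], ":", loci$pos[idx[2]])
            else paste0("column ", idx[2])
    stop("non-bi-allelic or non-diploid call '", gt[!known][1],
         "' at ", site)
  }
  if (is.null(accession_ids)) accession_ids <- rownames(calls)
  genotype_matrix(num, loci = loci, accession_ids = accession_ids)
}

#' Read a VCF into a numeric genotype matrix
#'
#' Reads the GT field of a VCF 4.x file (via \pkg{vcfR}) and applies the
#' numeric encoding of \code{\link{encode_numeric}}.  Only bi-allelic
#' diploid sites are accepted.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic site at ", fix$CHROM[multi][1], ":", fix$POS[multi][1])
  gt <- vcfR::extract.gt(v, element = "GT")   # loci x samples
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  encode_numeric(t(gt), loci = loci, accession_ids = colnames(gt))
}

#' Write a numeric genotype matrix as VCF 4.2
#'
#' Emits bi-allelic GT records; numeric 1.0 becomes \code{0/0}, 0.5
#' \code{0/1}, 0.0 \code{1/1} and missing \code{./.}.
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c(`1` = "0/0", `0.5` = "0/1", `0` = "1/1")
  vals <- t(G$values)                      # loci x accessions
  gt <- matrix("./.", nrow(vals), ncol(vals))
  for (v in names(gt_code)) gt[!is.na(vals) & vals == as.numeric(v)] <- gt_code[[v]]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$accession_ids), collapse = "\t"))
  body <- paste(G$loci$chrom, G$loci$pos,
                paste0(G$loci$chrom, "_", G$loci$pos),
                G$loci$ref, G$loci$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the plain TSV genotype matrix format
#'
#' Rows are accessions (first column \code{accession_id}), remaining
#' column names are \code{chrom:pos}.  Ref/alt alleles are not carried by
#' this format and are filled with placeholders on read.
#'
#' @param path file path.
#' @return \code{read_genotype_tsv}: a \code{\link{genotype_matrix}}.
#' @export
read_genotype_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  loci <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     pos = as.integer(vapply(parts, `[`, "", 2)),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  genotype_matrix(m, loci = loci, accession_ids = ids)
}

#' @rdname read_genotype_tsv
#' @param G a \code{\link{genotype_matrix}}.
#' @export
write_genotype_tsv <- function(G, path) {
  d <- data.frame(accession_id = G$accession_ids,
                  G$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
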