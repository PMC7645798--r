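#' Genotype, table and configuration file I/O
#'
#' Genotype matrices travel as plain TSV (patients in rows, SNP ids in the
#' header, additive dosages 0/1/2 with NA for missing) or as minimal
#' unphased GT-only VCF. Covariate/outcome tables are TSV; configurations are
#' YAML or JSON.
#'
#' @name mechstrat_io
NULL

#' Write a genotype matrix as TSV
#' @param genotypes dosage matrix (or `synthetic_cohort`).
#' @param path output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  if (inherits(genotypes, "synthetic_cohort")) genotypes <- genotypes$genotypes
  df <- data.frame(patient_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#' @param path TSV written by [write_genotypes_tsv()] (first column patient id).
#' @return numeric dosage matrix with patient/SNP dimnames.
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  bad <- m[!is.na(m)]
  if (length(bad) && any(!bad %in% 0:2))
    stop("genotype TSV contains dosages outside {0,1,2}")
  m
}

#' Write a minimal unphased GT-only VCF
#'
#' Dosage 0/1/2 is encoded as 0/0, 0/1, 1/1; NA as ./. . Positions default to
#' consecutive placeholder coordinates when no SNP position table is given.
#'
#' @param genotypes dosage matrix (patients x SNPs).
#' @param path output `.vcf` file.
#' @param snp_positions optional data frame (`snp`, `chrom`, `pos`).
#' @export
write_vcf_minimal <- function(genotypes, path, snp_positions = NULL) {
  if (inherits(genotypes, "synthetic_cohort")) genotypes <- genotypes$genotypes
  snps <- colnames(genotypes)
  if (is.null(snp_positions)) {
    snp_positions <- data.frame(snp = snps, chrom = "chr1",
                                pos = seq_along(snps) * 1000L)
  }
  idx <- match(snps, snp_positions$snp)
  gt <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_along(snps), function(j) {
    calls <- ifelse(is.na(genotypes[, j]), "./.", gt[genotypes[, j] + 1L])
    paste(c(snp_positions$chrom[idx[j]], snp_positions$pos[idx[j]], snps[j],
            "A", "G", ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF (GT field, additive dosage)
#'
#' Counts ALT alleles in the GT field; missing GT (`./.`) becomes NA.
#'
#' @param path VCF file.
#' @return numeric dosage matrix, patients in rows, SNP ids in columns.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), 0))
  }
  m <- t(apply(gt, 1, count_alt))
  dimnames(m) <- dimnames(gt)
  t(m)
}

#' Write / read a pipeline or synthetic configuration
#'
#' Matrices are stored as nested lists; `read_config` restores the signature
#' matrix if present.
#'
#' @param config a list-like configuration.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$signature)) cfg$signature <- apply(cfg$signature, 1, as.integer, simplify = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$signature)) {
    sig <- cfg$signature
    cfg$signature <- if (is.matrix(sig)) {
      storage.mode(sig) <- "integer"
      sig
    } else {
      do.call(rbind, lapply(sig, as.integer))
    }
  }
  cfg
}
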