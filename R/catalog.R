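#' Mechanism catalogues and SNP-to-mechanism grouping
#'
#' A mechanism catalogue is the bridge between raw genotypes and the
#' mechanism-level burden scores used for clustering: it names a set of
#' molecular mechanisms (gene sets derived from cause-effect subgraphs present
#' in both AD and PD disease maps), carries genomic gene annotations, and maps
#' SNPs to genes either by proximity or via precomputed eQTL pairs.
#'
#' @name mechanism_catalog
NULL

new_mechanism_catalog <- function(mechanisms, gene_annotations = NULL, snp_map = NULL) {
  structure(
    list(mechanisms = mechanisms,
         gene_annotations = gene_annotations,
         snp_map = snp_map),
    class = "mechanism_catalog")
}

#' @export
print.mechanism_catalog <- function(x, ...) {
  genes <- unique(unlist(x$mechanisms, use.names = FALSE))
  cat("mechanism_catalog:", length(x$mechanisms), "mechanisms,",
      length(genes), "distinct genes")
  if (!is.null(x$snp_map)) {
    cat(",", length(unique(x$snp_map$snp)), "mapped SNPs")
  }
  cat("\n")
  invisible(x)
}

#' Load a mechanism catalogue from GMT or JSON
#'
#' Reads named mechanism gene sets from a GMT file (tab-separated: name,
#' description, genes...) or a JSON file (object mapping mechanism name to an
#' array of gene symbols). Genes may appear in several mechanisms; mechanism
#' names must be unique and gene sets non-empty. Optionally attaches gene
#' annotations and builds the SNP-to-gene map by proximity (and eQTL pairs).
#'
#' @param path path to a `.gmt` or `.json` catalogue file.
#' @param gene_annotations optional data frame with columns `gene`, `chrom`,
#'   `start`, `end` (1-based, closed intervals).
#' @param snp_positions optional data frame with columns `snp`, `chrom`, `pos`;
#'   when given together with `gene_annotations` the SNP map is computed with
#'   [map_snps_to_genes()].
#' @param window_bp proximity window in base pairs applied to both gene ends
#'   (default 10000).
#' @param eqtl_pairs optional two-column data frame (`snp`, `gene`) of
#'   precomputed eQTL pairs, unioned into the SNP map with source tag "eqtl".
#' @return a `mechanism_catalog` object.
#' @export
load_catalog <- function(path, gene_annotations = NULL, snp_positions = NULL,
                         window_bp = 10000, eqtl_pairs = NULL) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    mechanisms <- jsonlite::read_json(path, simplifyVector = TRUE)
    mechanisms <- lapply(mechanisms, as.character)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    if (length(lines) == 0) stop("catalogue file is empty: ", path)
    if (requireNamespace("fgsea", quietly = TRUE)) {
      mechanisms <- fgsea::gmtPathways(path)
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      mechanisms <- lapply(fields, function(f) f[-(1:2)])
      names(mechanisms) <- vapply(fields, `[`, "", 1L)
    }
  }
  if (length(mechanisms) == 0) stop("catalogue file is empty: ", path)
  if (anyDuplicated(names(mechanisms))) {
    stop("duplicate mechanism names in catalogue: ",
         paste(unique(names(mechanisms)[duplicated(names(mechanisms))]), collapse = ", "))
  }
  if (any(lengths(mechanisms) == 0)) {
    stop("mechanism(s) with empty gene set: ",
         paste(names(mechanisms)[lengths(mechanisms) == 0], collapse = ", "))
  }
  snp_map <- NULL
  if (!is.null(gene_annotations) && !is.null(snp_positions)) {
    snp_map <- map_snps_to_genes(snp_positions, gene_annotations,
                                 window_bp = window_bp, eqtl_pairs = eqtl_pairs)
  }
  cat_obj <- new_mechanism_catalog(mechanisms, gene_annotations, snp_map)
  if (!is.null(snp_map)) {
    in_mech <- snp_map$gene %in% unlist(mechanisms, use.names = FALSE)
    if (any(!in_mech)) {
      warning(sum(!in_mech), " SNP-gene mapping(s) point to genes absent from",
              " every mechanism; they are kept but flagged")
      cat_obj$snp_map$orphan <- !in_mech
    }
  }
  cat_obj
}

#' Map SNPs to genes by genomic proximity
#'
#' A SNP is mapped to every gene whose interval, extended by `window_bp` on
#' both sides, contains its position (1-based, closed intervals). SNPs on a
#' chromosome without annotated genes silently receive no mapping. Precomputed
#' eQTL pairs are unioned in with source tag `"eqtl"`.
#'
#' @param snp_positions data frame with columns `snp`, `chrom`, `pos`.
#' @param gene_annotations data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param window_bp non-negative proximity window in base pairs (default 10000).
#' @param eqtl_pairs optional data frame (`snp`, `gene`).
#' @return data frame with columns `snp`, `gene`, `source`.
#' @export
map_snps_to_genes <- function(snp_positions, gene_annotations,
                              window_bp = 10000, eqtl_pairs = NULL) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snp_positions)),
            all(c("gene", "chrom", "start", "end") %in% names(gene_annotations)))
  out <- list()
  for (g in seq_len(nrow(gene_annotations))) {
    lo <- gene_annotations$start[g] - window_bp
    hi <- gene_annotations$end[g] + window_bp
    hit <- snp_positions$chrom == gene_annotations$chrom[g] &
      snp_positions$pos >= lo & snp_positions$pos <= hi
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        snp = snp_positions$snp[hit],
        gene = gene_annotations$gene[g],
        source = "proximity",
        stringsAsFactors = FALSE)
    }
  }
  map <- if (length(out)) do.call(rbind, out) else
    data.frame(snp = character(), gene = character(), source = character(),
               stringsAsFactors = FALSE)
  if (!is.null(eqtl_pairs) && nrow(eqtl_pairs) > 0) {
    eq <- data.frame(snp = as.character(eqtl_pairs[[1]]),
                     gene = as.character(eqtl_pairs[[2]]),
                     source = "eqtl", stringsAsFactors = FALSE)
    new <- !paste(eq$snp, eq$gene) %in% paste(map$snp, map$gene)
    map <- rbind(map, eq[new, , drop = FALSE])
  }
  map <- map[order(map$snp, map$gene), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Group genotype columns by mechanism
#'
#' Induces, for each mechanism, the ordered list of SNP ids (genotype matrix
#' columns) mapping to any of its genes. A SNP whose gene belongs to several
#' mechanisms appears in each of their groups. Mechanisms without any mapped
#' SNP are dropped with a warning; if no mechanism retains a SNP the grouping
#' is impossible and an error is raised.
#'
#' @param catalog a `mechanism_catalog` with a non-NULL `snp_map`.
#' @param genotypes a patients x SNPs dosage matrix with SNP ids as column
#'   names (or a `synthetic_cohort`, whose `genotypes` element is used).
#' @return named list of character vectors of SNP ids, class `snp_grouping`.
#' @export
group_snps_by_mechanism <- function(catalog, genotypes) {
  if (inherits(genotypes, "synthetic_cohort")) genotypes <- genotypes$genotypes
  stopifnot(inherits(catalog, "mechanism_catalog"))
  if (is.null(catalog$snp_map)) stop("catalogue has no SNP map")
  snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) stop("genotype matrix has no SNP column names")
  map <- catalog$snp_map[catalog$snp_map$snp %in% snp_ids, , drop = FALSE]
  groups <- lapply(catalog$mechanisms, function(genes) {
    ids <- unique(map$snp[map$gene %in% genes])
    ids[order(ids)]
  })
  empty <- lengths(groups) == 0
  if (all(empty)) stop("no mechanism has any SNP present in the genotype matrix")
  if (any(empty)) {
    warning("dropping mechanism(s) with no mapped SNPs: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  structure(groups, class = "snp_grouping")
}

#' Packaged default mechanism catalogue
#'
#' Loads the catalogue shipped with the package: 15 mechanisms over 27 genes
#' (the 16 genes named in the underlying disease maps plus clearly-labelled
#' synthetic placeholder symbols), with synthetic gene coordinates and 148
#' synthetic SNP positions that map 1:1 to the default synthetic cohort's SNP
#' panel. APOE belongs to two mechanisms, so group sizes sum to more than 148
#' while the union of all groups covers exactly 148 SNPs.
#'
#' @return a `mechanism_catalog`.
#' @export
default_catalog <- function() {
  ext <- function(f) system.file("extdata", f, package = "mechstrat", mustWork = TRUE)
  genes <- read.delim(ext("genes_synthetic.tsv"), stringsAsFactors = FALSE)
  snps <- read.delim(ext("snps_synthetic.tsv"), stringsAsFactors = FALSE)
  load_catalog(ext("mechanisms.gmt"),
               gene_annotations = genes, snp_positions = snps)
}
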