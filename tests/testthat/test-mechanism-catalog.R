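test_that("packaged catalogue reproduces the design constants", {
  cat1 <- default_catalog()
  expect_equal(length(cat1$mechanisms), 15)
  expect_equal(length(unique(unlist(cat1$mechanisms))), 27)
  expect_equal(length(unique(cat1$snp_map$snp)), 148)
  # a gene may sit in two mechanisms (APOE by design)
  expect_true("APOE" %in% cat1$mechanisms$M05_lipoprotein_APOE)
  expect_true("APOE" %in% cat1$mechanisms$M11_apoptosis_cytc)
})

test_that("catalogue loading validates its input", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), f)
  expect_error(load_catalog(f), "empty")
  writeLines(c("m1\td\tAPOE\tMAPT", "m1\td\tSNCA"), f)
  expect_error(load_catalog(f), "duplicate")
  writeLines(c("m1\td\tAPOE", "m2\td\tAPOE\tSNCA"), f)
  cat2 <- load_catalog(f)
  expect_equal(cat2$mechanisms$m1, "APOE")
  expect_true("APOE" %in% cat2$mechanisms$m2)
  expect_error(load_catalog(tempfile()), "not found")
})

test_that("JSON catalogues load equivalently to GMT", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(m1 = c("APOE", "MAPT"), m2 = "SNCA"), f)
  cat3 <- load_catalog(f)
  expect_equal(cat3$mechanisms, list(m1 = c("APOE", "MAPT"), m2 = "SNCA"))
})

test_that("proximity mapping honors the closed 10 kbp window", {
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 50000, end = 60000)
  snps <- data.frame(snp = c("s_in", "s_out", "s_right", "s_far", "s_chr"),
                     chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                     pos = c(40000, 39999, 70000, 70001, 55000))
  m <- map_snps_to_genes(snps, genes)
  expect_setequal(m$snp, c("s_in", "s_right"))
  expect_error(map_snps_to_genes(snps, genes, window_bp = -1), "non-negative")
})

test_that("proximity mapping equals the exhaustive interval check", {
  set.seed(4)
  genes <- data.frame(gene = paste0("G", 1:3), chrom = c("chr1", "chr1", "chr2"),
                      start = c(1e5, 5e5, 2e5), end = c(1.2e5, 5.4e5, 2.1e5))
  snps <- data.frame(snp = paste0("s", 1:5),
                     chrom = sample(c("chr1", "chr2"), 5, TRUE),
                     pos = round(runif(5, 5e4, 6e5)))
  w <- 10000
  m <- map_snps_to_genes(snps, genes, window_bp = w)
  for (i in 1:5) for (g in 1:3) {
    inside <- snps$chrom[i] == genes$chrom[g] &&
      snps$pos[i] >= genes$start[g] - w && snps$pos[i] <= genes$end[g] + w
    mapped <- any(m$snp == snps$snp[i] & m$gene == genes$gene[g])
    expect_equal(mapped, inside)
  }
})

test_that("eQTL pairs are unioned in with their source tag", {
  cat1 <- default_catalog()
  eq <- read.delim(system.file("extdata", "eqtl_pairs_synthetic.tsv",
                               package = "mechstrat"))
  genes <- read.delim(system.file("extdata", "genes_synthetic.tsv",
                                  package = "mechstrat"))
  snps <- read.delim(system.file("extdata", "snps_synthetic.tsv",
                                 package = "mechstrat"))
  m <- map_snps_to_genes(snps, genes, eqtl_pairs = eq)
  expect_true(any(m$source == "eqtl"))
  expect_true(all(m$source[m$snp == "snp001" & m$gene == "IL6"] == "eqtl"))
  # proximity mappings unchanged by the union
  expect_equal(sum(m$source == "proximity"), nrow(cat1$snp_map))
})

test_that("grouping covers the SNP panel and respects sharing", {
  cat1 <- default_catalog()
  co <- default_cohort()
  g <- group_snps_by_mechanism(cat1, co$genotypes)
  expect_equal(length(g), 15)
  expect_equal(length(unique(unlist(g))), 148)
  expect_gt(sum(lengths(g)), 148)  # APOE SNPs counted in two mechanisms
  apoe_snps <- cat1$snp_map$snp[cat1$snp_map$gene == "APOE"]
  expect_true(all(apoe_snps %in% g$M05_lipoprotein_APOE))
  expect_true(all(apoe_snps %in% g$M11_apoptosis_cytc))
})

test_that("grouping is invariant to genotype column order", {
  cat1 <- default_catalog()
  co <- default_cohort()
  perm <- sample(ncol(co$genotypes))
  g1 <- group_snps_by_mechanism(cat1, co$genotypes)
  g2 <- group_snps_by_mechanism(cat1, co$genotypes[, perm])
  expect_identical(g1, g2)
})

test_that("empty mechanisms are dropped with a warning, all-empty is fatal", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("m1\td\tAPOE", "m2\td\tNOSUCHGENE"), f)
  genes <- read.delim(system.file("extdata", "genes_synthetic.tsv",
                                  package = "mechstrat"))
  snps <- read.delim(system.file("extdata", "snps_synthetic.tsv",
                                 package = "mechstrat"))
  cat2 <- suppressWarnings(  # most fixture SNPs map to genes outside this toy catalogue
    load_catalog(f, gene_annotations = genes, snp_positions = snps))
  co <- default_cohort()
  expect_warning(g <- group_snps_by_mechanism(cat2, co$genotypes), "dropping")
  expect_equal(names(g), "m1")
  expect_equal(length(g$m1), 9)  # the APOE SNPs
  writeLines("m2\td\tNOSUCHGENE", f)
  cat3 <- suppressWarnings(
    load_catalog(f, gene_annotations = genes, snp_positions = snps))
  expect_error(group_snps_by_mechanism(cat3, co$genotypes), "no mechanism")
})

test_that("single-mechanism grouping returns its SNPs", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("solo\td\tCYCS", f)
  genes <- read.delim(system.file("extdata", "genes_synthetic.tsv",
                                  package = "mechstrat"))
  snps <- read.delim(system.file("extdata", "snps_synthetic.tsv",
                                 package = "mechstrat"))
  cat2 <- suppressWarnings(
    load_catalog(f, gene_annotations = genes, snp_positions = snps))
  g <- group_snps_by_mechanism(cat2, default_cohort()$genotypes)
  expect_equal(length(g), 1)
  expect_equal(length(g$solo), 4)
})
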