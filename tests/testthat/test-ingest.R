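write_toy_qtl <- function(lines, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  path <- file.path(dir, "toy.tsv")
  writeLines(c("rsid\tchrom\tpos\tgene\ttissue\tp\tbeta\tea\tnea", lines),
             path)
  path
}

toy_entry <- function(path, ...) {
  manifest_entry(name = "toy", path = path, source = "TOY", ...)
}

test_that("QTL tables are read, normalized and reconciled", {
  gi <- tiny_gene_index()
  path <- write_toy_qtl(c(
    "rs1\tchr3\t138120000\tMRAS\theart\t1e-5\t0.4\ta\tg",
    "rs2\t3\t138125000\tENSG02\tliver\t0.02\t\tC\tT",
    "rs3\t3\t138130000\tRAS3\tHeart\t0.5\t-0.1\tG\tA"))
  rec <- read_qtl_table(path, toy_entry(path), gi)
  expect_equal(nrow(rec), 3L)
  expect_equal(sort(unique(rec$tissue)), c("Heart", "Liver"))
  expect_equal(rec[rsid == "rs1", chrom], "3")           # chr prefix stripped
  expect_equal(rec[rsid == "rs1", ea], "A")              # upper-cased
  expect_true(is.na(rec[rsid == "rs2", beta]))           # absent beta kept
  expect_equal(rec[rsid == "rs3", gene_id], "ENSG01")    # synonym resolved
  log <- attr(rec, "log")
  expect_equal(log$n_rows - length(unlist(log$rejected)) - log$collisions,
               log$n_records)
})

test_that("malformed rows are rejected with diagnostics, bad tissue is fatal", {
  gi <- tiny_gene_index()
  path <- write_toy_qtl(c(
    "rs1\t3\t138120000\tMRAS\tHeart\t0\t0.4\tA\tG",      # P = 0
    "rs2\t3\t138125000\tMRAS\tHeart\t1e-5\t0.4\tA\tG"))
  rec <- read_qtl_table(path, toy_entry(path), gi)
  expect_equal(nrow(rec), 1L)
  expect_named(attr(rec, "log")$rejected, "p_value outside (0,1]")

  bad_tissue <- write_toy_qtl(
    "rs1\t3\t138120000\tMRAS\tKidney cortex\t1e-5\t0.4\tA\tG")
  expect_error(read_qtl_table(bad_tissue, toy_entry(bad_tissue), gi),
               "Kidney cortex")

  no_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\tgene\tp", "rs1\t3\t1\tMRAS\t0.1"), no_col)
  expect_error(read_qtl_table(no_col, toy_entry(no_col), gi),
               "missing mandatory column")
})

test_that("duplicate quadruples keep the smallest P and log the collision", {
  gi <- tiny_gene_index()
  path <- write_toy_qtl(c(
    "rs1\t3\t138120000\tMRAS\tHeart\t1e-3\t0.4\tA\tG",
    "rs1\t3\t138120000\tMRAS\tHeart\t1e-8\t0.4\tA\tG"))
  rec <- read_qtl_table(path, toy_entry(path), gi)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$p_value, 1e-8)
  expect_equal(attr(rec, "log")$collisions, 1L)
})

test_that("BED TADs convert to 1-based inclusive and reject bad rows", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t5000", "chr1\t7000\t7000", "chr2\t10\t20"), bed)
  tads <- read_tads(bed)
  expect_equal(length(tads), 2L)
  expect_equal(GenomicRanges::start(tads)[1], 1001L)
  expect_equal(GenomicRanges::end(tads)[1], 5000L)
  expect_equal(S4Vectors::metadata(tads)$n_rejected, 1L)

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_length(read_tads(empty), 0L)
})

test_that("synthetic TAD sets at the integrated-corpus moments round-trip", {
  # 3054 intervals with mean length 853 kb pass through unchanged
  set.seed(42)
  n <- 3054L
  len <- pmax(800L, round(rlnorm(n, log(853000) - 0.405, 0.9)))
  len <- round(len * 853000 / mean(len))
  # spread over chromosomes so coordinates stay within genome-like bounds
  chroms <- rep(paste0("chr", 1:22), length.out = n)
  starts <- unlist(lapply(split(len, chroms), function(l)
    cumsum(c(0L, utils::head(l, -1L) + 1000L))), use.names = FALSE)
  len_ord <- unlist(split(len, chroms), use.names = FALSE)
  chr_ord <- rep(names(split(len, chroms)),
                 lengths(split(len, chroms)))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste0(chr_ord, "\t", starts, "\t", starts + len_ord), bed)
  s <- tad_summary(read_tads(bed))
  expect_equal(s$n, 3054L)
  expect_equal(s$mean_length_kb, 853, tolerance = 1e-3)
})

test_that("GTF and TSV gene dialects yield identical gene records", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tchrom\tstart\tend\tstrand",
               "ENSG01\tMRAS\t3\t138100000\t138150000\t+",
               "ENSG02\tABC1\t3\t139000000\t139050000\t-"), tsv)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("3\ttest\tgene\t138100000\t138150000\t.\t+\t.\t",
           "gene_id \"ENSG01\"; gene_name \"MRAS\";"),
    paste0("3\ttest\tgene\t139000000\t139050000\t.\t-\t.\t",
           "gene_id \"ENSG02\"; gene_name \"ABC1\";")), gtf)
  a <- read_genes(tsv)$genes
  b <- read_genes(gtf)$genes
  cols <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  expect_equal(as.data.frame(a[, ..cols]), as.data.frame(b[, ..cols]))
})

test_that("GWAS catalog rows index by variant and by gene; junk is skipped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene\tphenotype\taccession",
               "rs11\t\ttrait1\tGCST1",
               "\tMRAS\ttrait2\tGCST2",
               "rs12\tABC1\ttrait3\tGCST3",
               "rs13\t\ttrait4\tGCST4",
               "\t\ttrait5\tGCST5"), path)
  cat5 <- read_gwas_catalog(path)
  expect_equal(nrow(cat5$entries), 4L)
  expect_equal(cat5$n_skipped, 1L)
  expect_true("rs11" %in% cat5$variants)
  expect_true("MRAS" %in% cat5$genes)
  expect_false("MRAS" %in% cat5$variants)
})

test_that("ingestion is idempotent: re-reading yields an identical store", {
  b <- cached_bundle(101, n_genes = 8L, n_sources = 2L, n_tissues = 3L,
                     sharing_genes = 2L, sharing_m = 3L, n_hap = 200L)
  s1 <- ingest_bundle(b)
  s2 <- ingest_bundle(b)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
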