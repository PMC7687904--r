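test_that("the FWER threshold is the Bonferroni bound over all tests", {
  expect_equal(fwer_threshold(0.05, 1e6, 5e4), 1e-12)
  expect_equal(fwer_threshold(0.05, 1, 1), 0.05)
  expect_equal(fwer_threshold(0.05, 10, 10), 5e-4)
  expect_error(fwer_threshold(0.05, 0, 10), ">= 1")
  expect_error(fwer_threshold(1.2, 10, 10), "alpha")
})

test_that("study-wide significance uses an inclusive boundary", {
  rec <- toy_records(c(1e-13, 1e-12, 1.0000001e-12, 0.5),
                     tissue = c("Heart", "Liver", "Whole blood", "Heart"),
                     variant = c("rs1", "rs2", "rs3", "rs4"))
  flag_sw_significant(rec)
  expect_equal(rec$is_sw_significant, c(TRUE, TRUE, FALSE, FALSE))

  set.seed(4)
  p <- c(exp(runif(3, log(1e-16), log(1e-13))),
         exp(runif(7, log(1e-11), 0)))
  rec <- toy_records(sample(p), variant = sprintf("rs%d", 1:10),
                     tissue = "Heart")
  flag_sw_significant(rec)
  expect_equal(sum(rec$is_sw_significant), 3L)
})

test_that("source-provided significance overrides the FWER rule", {
  rec <- toy_records(c(0.04, 1e-14), variant = c("rs1", "rs2"),
                     tissue = c("Heart", "Liver"))
  rec[, "source_significant" := c(TRUE, FALSE)]
  pol <- list(S1 = list(provenance = "source_provided",
                        threshold = NA_real_))
  flag_sw_significant(rec, pol)
  expect_equal(rec$is_sw_significant, c(TRUE, FALSE))
})

test_that("best flags are per tissue-specific study with ties kept", {
  one <- toy_records(0.3)
  flag_best(one)
  expect_true(one$is_best)

  two <- toy_records(c(1e-5, 1e-9), variant = c("rs1", "rs2"))
  flag_best(two)
  expect_equal(two[order(p_value), is_best], c(TRUE, FALSE))

  tie <- toy_records(c(1e-7, 1e-7), variant = c("rs1", "rs2"))
  flag_best(tie)
  expect_true(all(tie$is_best))

  # separate (source, tissue) groups each have their own best
  grp <- rbind(toy_records(c(1e-5, 1e-2), variant = c("rs1", "rs2")),
               toy_records(c(1e-3, 1e-4), variant = c("rs1", "rs2"),
                           source = "S2"))
  flag_best(grp)
  expect_equal(sum(grp$is_best), 2L)
})

test_that("best-in-LD-group compares only LD-linked records", {
  ld <- ld_store(data.table(variant_a = "rsA", variant_b = "rsB",
                            r2 = 0.8, dprime = 0.9),
                 universe = c("rsA", "rsB", "rsC"))
  rec <- toy_records(c(1e-8, 1e-4, 1e-2),
                     variant = c("rsA", "rsB", "rsC"))
  flag_best_in_ld_group(rec, ld)
  got <- setNames(rec$is_best_in_ld_group, rec$variant_id)
  expect_true(got[["rsA"]])     # beats rsB inside the group
  expect_false(got[["rsB"]])
  expect_true(got[["rsC"]])     # singleton group

  # variant absent from the LD universe is its own group
  rec2 <- toy_records(1e-2, variant = "rsZ")
  flag_best_in_ld_group(rec2, ld)
  expect_true(rec2$is_best_in_ld_group)
})

test_that("the gene restriction of the LD-group comparison is switchable", {
  ld <- ld_store(data.table(variant_a = "rsA", variant_b = "rsB",
                            r2 = 0.8, dprime = 0.9))
  rec <- rbind(toy_records(1e-4, variant = "rsA", gene = "ENSG01"),
               toy_records(1e-8, variant = "rsB", gene = "ENSG02"))
  flag_best_in_ld_group(rec, ld, per_gene = TRUE)
  expect_true(all(rec$is_best_in_ld_group))  # different genes, no contest
  flag_best_in_ld_group(rec, ld, per_gene = FALSE)
  expect_equal(rec[order(p_value), is_best_in_ld_group], c(TRUE, FALSE))
})

test_that("cis requires one TAD containing both variant and gene anchor", {
  tad_df <- data.frame(chrom = c("3", "3"),
                       start = c(138000000, 138200001),
                       end = c(138200000, 138400000))
  tads <- GenomicRanges::GRanges(tad_df$chrom,
                                 IRanges::IRanges(tad_df$start, tad_df$end))
  inside <- toy_records(0.1, pos = 138120000L, gene_start = 138100000L)
  classify_cis_trans(inside, tads)
  expect_equal(inside$colocalization, "cis")

  # adjacent TADs: close in distance, still trans
  split_tad <- toy_records(0.1, pos = 138190000L, gene_start = 138210000L,
                           gene_end = 138260000L)
  classify_cis_trans(split_tad, tads)
  expect_equal(split_tad$colocalization, "trans")

  other_chr <- toy_records(0.1, chrom = "5")
  other_chr[, "gene_chrom" := "3"]
  classify_cis_trans(other_chr, tads)
  expect_equal(other_chr$colocalization, "trans")

  classify_cis_trans(inside, GenomicRanges::GRanges())
  expect_equal(inside$colocalization, "trans")   # no TADs: all trans
})

test_that("cis/trans agrees with the containment oracle on random layouts", {
  set.seed(21)
  for (i in 1:10) {
    n_tad <- sample(0:6, 1)
    starts <- sort(sample(seq(1e6, 9e6, 1e4), 6))[seq_len(n_tad)]
    tad_df <- data.frame(chrom = rep("1", n_tad), start = starts,
                         end = starts + sample(2e5:2e6, 6,
                                               TRUE)[seq_len(n_tad)])
    tads <- if (n_tad) GenomicRanges::GRanges(
      tad_df$chrom, IRanges::IRanges(tad_df$start, tad_df$end)) else
      GenomicRanges::GRanges()
    st <- random_store(i, n_records = 60)$records
    classify_cis_trans(st, tads)
    expect_equal(st$colocalization, oracle_cis(st, tad_df))
  }
})

test_that("distances are 0 inside the gene and signed outside", {
  intronic <- compute_distance(toy_records(0.1, pos = 138120000L))
  expect_equal(intronic$distance_kb, 0)

  down <- compute_distance(toy_records(0.1, pos = 138178000L))
  expect_equal(down$distance_kb, 28)       # 28,000 bp past the gene end

  up <- compute_distance(toy_records(0.1, pos = 138095000L))
  expect_equal(up$distance_kb, -5)

  off <- toy_records(0.1, chrom = "5")
  off[, "gene_chrom" := "3"]
  expect_true(is.na(compute_distance(off)$distance_kb))
})

test_that("GWAS links equal independent set intersections", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene\tphenotype\taccession",
               "rs1001\t\tt\tG1", "\tENSG00002\tt\tG2"), path)
  catalog <- read_gwas_catalog(path)
  st <- random_store(5)$records
  st[, "symbol" := gene_id]          # catalog carries these labels
  link_gwas(st, catalog)
  expect_equal(st$gwas_variant_hit, st$rsid %in% "rs1001")
  expect_equal(st$gwas_gene_hit, st$symbol %in% "ENSG00002")
})

test_that("flags and counts equal brute-force recomputation on random stores", {
  thr <- fwer_threshold()
  for (seed in c(2, 3, 4)) {
    rs <- random_store(seed)
    rec <- rs$records
    ld <- ld_store(rs$pairs, universe = unique(rec$variant_id))
    ann <- annotate_store(copy(rec), ld)
    o <- oracle_annotate(ann, rs$pairs, thr)
    expect_equal(ann$is_sw_significant, o$sw)
    expect_equal(ann$is_best, o$best)
    expect_equal(ann$is_best_in_ld_group, o$bilg)
    expect_equal(ann$n_occ, o$n_occ)
    expect_equal(ann$n_best, o$n_best)
    expect_equal(ann$n_sw_significant, o$n_sw)
    expect_equal(ann$n_qtls, o$n_qtls)
    expect_true(all(ann$is_best_in_ld_group[ann$is_best]))
  }
})

test_that("annotation is order-independent", {
  rs <- random_store(9)
  ld <- ld_store(rs$pairs, universe = unique(rs$records$variant_id))
  a <- annotate_store(copy(rs$records), ld)
  set.seed(1)
  shuffled <- copy(rs$records)[sample(.N)]
  b <- annotate_store(shuffled, ld)
  setkey(a, variant_id, gene_id, tissue, source)
  setkey(b, variant_id, gene_id, tissue, source)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("count examples follow the per-pair and per-study definitions", {
  rec <- rbind(
    toy_records(1e-13, tissue = "Heart"),
    toy_records(1e-3, tissue = "Liver"),
    toy_records(1e-4, tissue = "Heart", source = "S2"),
    toy_records(1e-2, variant = "rs9", tissue = "Heart", source = "S2"))
  ld <- ld_store(data.table(variant_a = character(),
                            variant_b = character(), r2 = numeric(),
                            dprime = numeric()),
                 universe = unique(rec$variant_id))
  ann <- annotate_store(rec, ld)
  rs1 <- ann[variant_id == "rs1"]
  expect_equal(unique(rs1$n_occ), 3L)     # three source/tissue pairs
  expect_equal(unique(rs1$n_sw_significant), 1L)
  # 2 variant records for the gene in (S2, Heart)
  expect_equal(unique(ann[source == "S2" & tissue == "Heart", n_qtls]), 2L)
})
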