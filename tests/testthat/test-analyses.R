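empty_ld <- function(universe) {
  ld_store(data.table(variant_a = character(), variant_b = character(),
                      r2 = numeric(), dprime = numeric()),
           universe = universe)
}

test_that("a single significant eQTL yields its exact distance", {
  rec <- toy_records(1e-13, pos = 138178000L)  # 28 kb past the gene end
  ann <- annotate_store(rec, empty_ld("rs1"))
  s <- best_eqtl_distances(ann)
  expect_equal(s$n, 1L)
  expect_equal(s$median_kb, 78)   # gene start to variant: 78,000 bp
  expect_equal(s$distances$distance_bp, 78000)
})

test_that("distance selection takes the minimal-P significant record", {
  rec <- rbind(
    toy_records(1e-13, variant = "rs1", pos = 138090000L),
    toy_records(1e-15, variant = "rs2", pos = 138130000L),
    toy_records(1e-3, variant = "rs3", pos = 139000000L))
  ann <- annotate_store(rec, empty_ld(rec$variant_id))
  s <- best_eqtl_distances(ann)
  expect_equal(s$distances$variant_id, "rs2")
  # another chromosome: no distance, but the trans stratum counts it
  far <- toy_records(1e-14, variant = "rs7", chrom = "9",
                     tissue = "Liver")
  far[, "gene_chrom" := "3"]
  ann2 <- annotate_store(rbind(rec[2], far), empty_ld(c("rs2", "rs7")))
  s2 <- best_eqtl_distances(ann2)
  expect_equal(s2$strata$trans$n, 2L)   # no TADs: both records trans
  expect_true(is.na(s2$distances[variant_id == "rs7", distance_bp]))
  # the moments are computed over the records that carry a distance
  expect_equal(s2$median_kb, 30)
})

test_that("planted log-normal lead distances are recovered", {
  ann <- cached_annotated(31)
  b <- cached_bundle(31)
  s <- best_eqtl_distances(ann)
  # one distance per gene effectively (same lead across studies); compare
  # the per-gene median of |distance| against the generator's parameters
  per_gene <- s$distances[!is.na(distance_bp),
                          .(d = median(abs(distance_bp))), by = gene_id]
  n <- nrow(per_gene)
  log_med <- log(median(per_gene$d))
  se <- 1.2533 * b$truth$dist_sdlog / sqrt(n)
  expect_lt(abs(log_med - b$truth$dist_meanlog), 4 * se + 0.3)
})

test_that("the distance histogram bins log-scaled magnitudes per stratum", {
  ann <- cached_annotated(31)
  h <- distance_histogram(best_eqtl_distances(ann))
  expect_true(all(c("cis", "total") %in% h$stratum))
  expect_equal(sum(h[stratum == "total", count]),
               sum(h[stratum != "total", count]))
})

test_that("sharing counts follow hand-computed LD-block partitions", {
  # same rsid best in 5 studies: count 5 at every threshold including none
  rec <- rbindlist(lapply(1:5, function(i)
    toy_records(1e-13, variant = "rsX",
                tissue = c("Heart", "Liver", "Whole blood", "Heart",
                           "Liver")[i],
                source = c("S1", "S1", "S1", "S2", "S2")[i])))
  sh <- sharing_analysis(rec |> copy() |> annotate_store(empty_ld("rsX")),
                         empty_ld("rsX"))
  expect_true(all(sh$max_block_count == 5L))

  # two variants at r2 = 0.97, best in 3 + 2 studies: 5 until the
  # threshold passes 0.97, then 3
  ld <- ld_store(data.table(variant_a = "rsA", variant_b = "rsB",
                            r2 = 0.97, dprime = 1))
  rec2 <- rbindlist(lapply(1:5, function(i)
    toy_records(1e-13, variant = c("rsA", "rsA", "rsA", "rsB", "rsB")[i],
                tissue = c("Heart", "Liver", "Whole blood", "Heart",
                           "Liver")[i],
                source = c("S1", "S1", "S1", "S2", "S2")[i])))
  ann2 <- annotate_store(rec2, ld)
  sh2 <- sharing_analysis(ann2, ld)
  expect_equal(sh2[threshold == "0.95", max_block_count], 5L)
  expect_equal(sh2[threshold == "1", max_block_count], 3L)
  expect_equal(sh2[threshold == "none", max_block_count], 3L)
})

test_that("LD-block grouping is single linkage over the pairwise graph", {
  ld <- ld_store(data.table(variant_a = c("a", "b"),
                            variant_b = c("b", "c"),
                            r2 = c(0.9, 0.9), dprime = c(1, 1)))
  bl <- ld_blocks(c("a", "b", "c", "d"), ld, 0.8)
  expect_equal(bl[["a"]], bl[["c"]])     # chained through b
  expect_false(bl[["a"]] == bl[["d"]])
  none <- ld_blocks(c("a", "b", "c"), ld, "none")
  expect_equal(length(unique(none)), 3L)
})

test_that("sharing recovers planted blocks and is monotone in threshold", {
  ann <- cached_annotated(31)
  b <- cached_bundle(31)
  sh <- sharing_analysis(ann, b$ld)
  got <- merge(sh[threshold == "0.95"], b$truth$sharing, by = "gene_id")
  expect_equal(got$max_block_count, got$m)
  got6 <- merge(sh[threshold == "0.6"], b$truth$sharing, by = "gene_id")
  expect_equal(got6$max_block_count, got6$m)

  wide <- dcast(sh, gene_id ~ threshold, value.var = "max_block_count")
  expect_true(all(wide[["none"]] <= wide[["1"]]))
  expect_true(all(wide[["1"]] <= wide[["0.95"]]))
  expect_true(all(wide[["0.95"]] <= wide[["0.9"]]))
  expect_true(all(wide[["0.9"]] <= wide[["0.8"]]))
  expect_true(all(wide[["0.8"]] <= wide[["0.6"]]))
})

test_that("hypergeometric enrichment is exact on small universes", {
  # universe 10, reference 5, top 4 all in the reference: 5/210
  sharing <- data.table(gene_id = sprintf("g%02d", 1:10),
                        threshold = "0.95",
                        max_block_count = c(9:6, rep(1L, 6)),
                        n_studies = 9L, n_blocks = 1L)
  res <- rank_and_enrich(sharing,
                         list(ref = sprintf("g%02d", 1:5)), k = 4)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  # exhaustive-enumeration agreement over random small configurations
  set.seed(13)
  for (i in 1:25) {
    N <- sample(5:20, 1)
    m <- sample(1:N, 1)
    k <- sample(1:N, 1)
    uni <- sprintf("u%02d", 1:N)
    sh <- data.table(gene_id = uni, threshold = "1",
                     max_block_count = sample(1:50, N, TRUE),
                     n_studies = 1L, n_blocks = 1L)
    ref <- sample(uni, m)
    res <- rank_and_enrich(sh, list(r = ref), k = k)
    topk <- sh[order(-max_block_count, gene_id)][seq_len(k), gene_id]
    q <- length(intersect(topk, ref))
    expect_equal(res$p_value, oracle_hyper(q, m, N, k), tolerance = 1e-12)
  }

  # degenerate references
  allref <- rank_and_enrich(sharing, list(all = sharing$gene_id), k = 4)
  expect_equal(allref$overlap, 4L)
  expect_equal(allref$p_value, 1)
  disjoint <- rank_and_enrich(sharing, list(none = c("zz1", "zz2")), k = 4)
  expect_equal(disjoint$overlap, 0L)
  expect_equal(disjoint$p_value, 1)
})

test_that("planted housekeeping sharing is detected at BH FDR < 0.05", {
  ann <- cached_annotated(31)
  b <- cached_bundle(31)
  sh <- sharing_analysis(ann, b$ld)
  en <- rank_and_enrich(sh,
                        list(housekeeping = b$gene_sets$housekeeping,
                             top_expressed = b$gene_sets$top_expressed),
                        k = 10)
  hk <- en[set == "housekeeping" & threshold == "0.95"]
  expect_lt(hk$p_adjusted, 0.05)
})

test_that("the top-expressed helper returns the top decile by mean", {
  m <- matrix(c(10, 10, 1, 1, 5, 5, 100, 100, 2, 2,
                3, 3, 4, 4, 6, 6, 7, 7, 8, 8), nrow = 10, byrow = TRUE)
  rownames(m) <- sprintf("g%02d", 1:10)
  expect_equal(top_expressed_genes(m, 0.1), "g04")
  expect_setequal(top_expressed_genes(m, 0.3), c("g04", "g01", "g10"))
})
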