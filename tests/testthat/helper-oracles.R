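# Independent brute-force oracles. These deliberately share no code with
# the implementation: LD from explicit 2x2 haplotype counts, flags and
# counts from nested loops, cis/trans from row-wise interval scans, and
# the hypergeometric tail from exact binomial-coefficient sums.

oracle_ld <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  pAB <- n11 / n
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  c(r2 = r2, d_prime = if (dmax == 0) 0 else abs(D) / dmax)
}

# pairwise r2 lookup from a plain pair table (both orders scanned)
oracle_r2 <- function(pairs, a, b) {
  if (a == b) return(1)
  i <- which((pairs$variant_a == a & pairs$variant_b == b) |
             (pairs$variant_a == b & pairs$variant_b == a))
  if (length(i)) pairs$r2[i[1]] else 0
}

# loop-based recomputation of every flag and count over a record table
oracle_annotate <- function(rec, pairs, threshold) {
  n <- nrow(rec)
  sw <- rec$p_value <= threshold
  best <- logical(n)
  bilg <- logical(n)
  for (i in seq_len(n)) {
    grp <- rec$source == rec$source[i] & rec$tissue == rec$tissue[i]
    best[i] <- rec$p_value[i] == min(rec$p_value[grp])
    members <- unique(c(rec$variant_id[i],
      unlist(lapply(unique(rec$variant_id), function(v)
        if (v != rec$variant_id[i] &&
            oracle_r2(pairs, rec$variant_id[i], v) > 0.2) v else NULL))))
    comp <- grp & rec$gene_id == rec$gene_id[i] &
      rec$variant_id %in% members
    bilg[i] <- rec$p_value[i] <= min(rec$p_value[comp])
  }
  n_occ <- integer(n); n_best <- integer(n); n_sw <- integer(n)
  n_qtls <- integer(n)
  for (i in seq_len(n)) {
    pair <- rec$variant_id == rec$variant_id[i] &
      rec$gene_id == rec$gene_id[i]
    st <- paste(rec$source, rec$tissue)
    n_occ[i] <- length(unique(st[pair]))
    n_best[i] <- length(unique(st[pair & best]))
    n_sw[i] <- length(unique(st[pair & sw]))
    n_qtls[i] <- sum(rec$gene_id == rec$gene_id[i] &
                       rec$source == rec$source[i] &
                       rec$tissue == rec$tissue[i])
  }
  list(sw = sw, best = best, bilg = bilg, n_occ = n_occ, n_best = n_best,
       n_sw = n_sw, n_qtls = n_qtls)
}

# row-wise interval containment: cis iff one TAD row holds both anchors
oracle_cis <- function(rec, tad_df) {
  vapply(seq_len(nrow(rec)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(tad_df))) {
      if (tad_df$chrom[j] == rec$chrom[i] &&
          tad_df$chrom[j] == rec$gene_chrom[i] &&
          rec$pos[i] >= tad_df$start[j] && rec$pos[i] <= tad_df$end[j] &&
          rec$gene_start[i] >= tad_df$start[j] &&
          rec$gene_start[i] <= tad_df$end[j]) { hit <- TRUE; break }
    }
    if (hit) "cis" else "trans"
  }, character(1))
}

# exact upper-tail hypergeometric by binomial-coefficient enumeration
oracle_hyper <- function(q, m, N, k) {
  js <- q:min(m, k)
  sum(choose(m, js) * choose(N - m, k - js)) / choose(N, k)
}

# random small record tables for property tests (no synth module involved)
random_store <- function(seed, n_records = 120, n_variants = 12,
                         n_genes = 6, n_sources = 3, n_tissues = 3) {
  set.seed(seed)
  vs <- sprintf("rs%d", 1000 + seq_len(n_variants))
  gs <- sprintf("ENSG%05d", seq_len(n_genes))
  rec <- data.table::data.table(
    variant_id = sample(vs, n_records, TRUE),
    rsid = NA_character_, build = "hg19",
    gene_id = sample(gs, n_records, TRUE),
    tissue = sample(c("Heart", "Liver", "Whole blood")[seq_len(n_tissues)],
                    n_records, TRUE),
    source = sample(paste0("S", seq_len(n_sources)), n_records, TRUE),
    p_value = exp(runif(n_records, log(1e-16), 0)),
    beta = rnorm(n_records), ea = "A", nea = "G",
    qtl_type = "eQTL")
  rec[, rsid := variant_id]
  rec[, dataset := source]
  rec[, study := paste0(source, "-x")]
  # positions and gene coordinates on one chromosome
  vpos <- setNames(sort(sample(1e6:9e6, n_variants)), vs)
  gpos <- setNames(sort(sample(1e6:9e6, n_genes)), gs)
  rec[, chrom := "1"]
  rec[, pos := as.integer(vpos[variant_id])]
  rec[, gene_chrom := "1"]
  rec[, gene_start := as.integer(gpos[gene_id])]
  rec[, gene_end := gene_start + 20000L]
  rec[, gene_strand := "+"]
  rec[, symbol := toupper(gene_id)]
  # deduplicate quadruples, keep the smallest P (ingest contract)
  data.table::setorder(rec, p_value)
  rec <- rec[!duplicated(paste(variant_id, gene_id, tissue, source, study))]
  # random sparse LD among the variants
  cmb <- t(utils::combn(vs, 2))
  keep <- runif(nrow(cmb)) < 0.4
  pairs <- data.table::data.table(variant_a = cmb[keep, 1],
                                  variant_b = cmb[keep, 2],
                                  r2 = runif(sum(keep)),
                                  dprime = runif(sum(keep)))
  list(records = rec, pairs = pairs)
}
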