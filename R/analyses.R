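# Explorative pipeline stages over an annotated store: gene-to-best-eQTL
# distance distributions, cross-tissue sharing of best eQTL signals per
# LD block, and gene-set enrichment of the top shared genes.

#' Best study-wide-significant eQTL per gene and tissue-specific study
#'
#' For each (gene, source, tissue) with at least one study-wide
#' significant record, the minimal-P record is selected (exact ties broken
#' deterministically by variant id).
#'
#' @param records Annotated QTL record table.
#' @return `data.table` with one row per (gene, source, tissue):
#'   `gene_id`, `source`, `tissue`, `variant_id`, `chrom`, `pos`,
#'   `p_value`, `distance_bp` (signed, gene start to variant),
#'   `colocalization`.
#' @export
best_sw_eqtls <- function(records) {
  sig <- records[isTRUE_vec(is_sw_significant)]
  if (nrow(sig) == 0L)
    return(data.table(gene_id = character(), source = character(),
                      tissue = character(), variant_id = character(),
                      chrom = character(), pos = integer(),
                      p_value = numeric(), distance_bp = numeric(),
                      colocalization = character()))
  setorder(sig, gene_id, source, tissue, p_value, variant_id)
  best <- sig[, .SD[1L], by = .(gene_id, source, tissue)]
  best[, "distance_bp" := fifelse(chrom == gene_chrom,
                                  as.numeric(pos - gene_start), NA_real_)]
  best[, .(gene_id, source, tissue, variant_id, chrom, pos, p_value,
           distance_bp, colocalization)]
}

#' Distance distribution between genes and their best eQTLs
#'
#' Per tissue-specific study and gene, the signed base-pair distance from
#' the gene start position to the best (minimal P) study-wide significant
#' eQTL. Summaries report the mean and median of absolute distances in
#' kilobases, overall and stratified by cis/trans (trans records on
#' another chromosome carry no distance and are excluded from the distance
#' moments but counted).
#'
#' @param records Annotated QTL record table.
#' @return List of class `distance_summary`: `distances` (per-record
#'   table), `mean_kb`, `median_kb`, `strata` (per colocalization label:
#'   n, mean_kb, median_kb).
#' @export
best_eqtl_distances <- function(records) {
  best <- best_sw_eqtls(records)
  d <- best$distance_bp
  summarize <- function(x) list(
    n = length(x),
    mean_kb = if (any(!is.na(x))) mean(abs(x), na.rm = TRUE) / 1000
      else NA_real_,
    median_kb = if (any(!is.na(x))) median(abs(x), na.rm = TRUE) / 1000
      else NA_real_)
  strata <- lapply(split(d, best$colocalization), summarize)
  structure(c(list(distances = best), summarize(d),
              list(strata = strata)),
            class = "distance_summary")
}

#' @exportS3Method print distance_summary
print.distance_summary <- function(x, ...) {
  cat("<distance_summary> ", x$n, " best eQTLs; |distance| mean ",
      round(x$mean_kb, 1), " kb, median ", round(x$median_kb, 1),
      " kb\n", sep = "")
  invisible(x)
}

#' Log-scaled histogram of best-eQTL distances
#'
#' @param summary A [best_eqtl_distances()] result.
#' @param breaks_per_decade Bins per log10 decade (default 4).
#' @return `data.table` with `log10_lo`, `log10_hi`, `count` per
#'   colocalization stratum plus `total`.
#' @export
distance_histogram <- function(summary, breaks_per_decade = 4L) {
  d <- summary$distances[!is.na(distance_bp) & distance_bp != 0]
  lg <- log10(abs(d$distance_bp))
  if (!nrow(d))
    return(data.table(stratum = character(), log10_lo = numeric(),
                      log10_hi = numeric(), count = integer()))
  edges <- seq(floor(min(lg)), ceiling(max(lg)), by = 1 / breaks_per_decade)
  bins <- cut(lg, edges, include.lowest = TRUE, labels = FALSE)
  tab <- data.table(stratum = c(d$colocalization, rep("total", nrow(d))),
                    bin = c(bins, bins))
  out <- tab[, .(count = .N), by = .(stratum, bin)]
  out[, c("log10_lo", "log10_hi") := list(edges[bin], edges[bin + 1L])]
  setorder(out, stratum, bin)
  out[, "bin" := NULL]
  out[]
}

#' Partition variants into LD blocks at an r-squared threshold
#'
#' Single-linkage (transitive) clustering over the pairwise graph with an
#' edge where r-squared exceeds the threshold. `threshold = "none"` puts
#' every variant in its own block (the strictest partition);
#' `threshold = 1` links only perfect proxies (r-squared equal to 1,
#' within numerical tolerance); a numeric threshold below 1 links pairs
#' with r-squared strictly above it. Pairs with unknown LD count as
#' unlinked (r-squared 0).
#'
#' @param variants Character vector of variant ids.
#' @param ld An `ld_store`.
#' @param threshold `"none"`, or a number in `[0, 1]`.
#' @return Integer vector of block ids, parallel to `variants`.
#' @export
ld_blocks <- function(variants, ld, threshold) {
  variants <- unique(variants)
  if (identical(threshold, "none") || length(variants) <= 1L)
    return(setNames(seq_along(variants), variants))
  pr <- ld$pairs[variant_a %chin% variants & variant_b %chin% variants]
  eps <- 1e-9
  pr <- if (is.numeric(threshold) && threshold >= 1) pr[r2 >= 1 - eps]
        else pr[r2 > threshold]
  g <- igraph::graph_from_data_frame(
    pr[, .(variant_a, variant_b)], directed = FALSE,
    vertices = data.frame(name = variants))
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp[variants]), variants)
}

#' Cross-tissue sharing of best eQTL signals per LD block
#'
#' Per gene, the best study-wide significant eQTL of every
#' tissue-specific study (source/tissue pair) is pooled; the pooled
#' variants are grouped into eQTL LD blocks at each r-squared threshold;
#' each block is scored by the number of distinct tissue-specific studies
#' it represents, and the gene is assigned the maximum over its blocks.
#' The count is non-increasing as the threshold rises, and the `"none"`
#' grouping (every variant its own block) is the strictest.
#'
#' @param records Annotated QTL record table.
#' @param ld An `ld_store`.
#' @param thresholds Vector of thresholds; the default mirrors the
#'   grouping ladder `0.6, 0.8, 0.9, 0.95, 1` plus `"none"`.
#' @return `data.table` with `gene_id`, `threshold` (character),
#'   `max_block_count`, `n_studies` (total pooled studies for the gene),
#'   `n_blocks`.
#' @export
sharing_analysis <- function(records, ld,
                             thresholds = c("0.6", "0.8", "0.9", "0.95",
                                            "1", "none")) {
  best <- best_sw_eqtls(records)
  if (nrow(best) == 0L)
    return(data.table(gene_id = character(), threshold = character(),
                      max_block_count = integer(), n_studies = integer(),
                      n_blocks = integer()))
  best[, "study_key" := paste(source, tissue, sep = "\r")]
  out <- rbindlist(lapply(thresholds, function(th) {
    thr <- if (identical(th, "none")) "none" else as.numeric(th)
    best[, {
      blocks <- ld_blocks(variant_id, ld, thr)
      bl <- blocks[variant_id]
      cnt <- tapply(study_key, bl, function(s) length(unique(s)))
      .(max_block_count = as.integer(max(cnt)),
        n_studies = as.integer(length(unique(study_key))),
        n_blocks = as.integer(length(cnt)))
    }, by = gene_id][, "threshold" := as.character(th)]
  }))
  setcolorder(out, c("gene_id", "threshold"))
  setorder(out, gene_id)
  out[]
}

#' Rank genes by sharing and test gene-set enrichment
#'
#' For each r-squared threshold, the `k` genes with the highest maximum
#' count of tissue-specific studies per eQTL LD block (ties at the k-th
#' count included, then truncated deterministically by gene id) are tested
#' for overlap with each reference gene set using the one-sided
#' (upper-tail) hypergeometric test over the universe of genes with at
#' least one best study-wide significant eQTL. P values are
#' Benjamini-Hochberg adjusted across all threshold x set tests.
#'
#' @param sharing [sharing_analysis()] result.
#' @param reference_sets Named list of gene-id character vectors (e.g.
#'   housekeeping genes, top-10%-expressed genes).
#' @param k Ranking cutoff (default 100).
#' @return `data.table` with `threshold`, `set`, `k_used`, `overlap`,
#'   `universe`, `set_in_universe`, `p_value`, `p_adjusted`.
#' @export
rank_and_enrich <- function(sharing, reference_sets, k = 100L) {
  stopifnot(length(reference_sets) > 0, !is.null(names(reference_sets)))
  out <- rbindlist(lapply(split(sharing, sharing$threshold), function(sh) {
    universe <- sh$gene_id
    setorder(sh, -max_block_count, gene_id)
    kk <- min(k, nrow(sh))
    top <- sh$gene_id[seq_len(kk)]
    rbindlist(lapply(names(reference_sets), function(nm) {
      ref <- intersect(reference_sets[[nm]], universe)
      q <- length(intersect(top, ref))
      p <- if (length(ref) == 0L) 1 else
        phyper(q - 1L, length(ref), length(universe) - length(ref), kk,
               lower.tail = FALSE)
      data.table(threshold = sh$threshold[1L], set = nm,
                 k_used = kk, overlap = q,
                 universe = length(universe),
                 set_in_universe = length(ref), p_value = p)
    }))
  }))
  out[, "p_adjusted" := p.adjust(p_value, method = "BH")]
  setorder(out, set, threshold)
  out[]
}

#' Top decile of expressed genes from an expression matrix
#'
#' Helper for building the "top 10% highest expressed" reference set from
#' a genes x samples expression matrix: ranks genes by mean expression
#' across samples and returns the top decile of gene ids.
#'
#' @param expr Numeric matrix with gene ids as row names.
#' @param fraction Fraction of top genes (default 0.1).
#' @return Character vector of gene ids.
#' @export
top_expressed_genes <- function(expr, fraction = 0.1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  m <- rowMeans(expr)
  n <- max(1L, floor(length(m) * fraction))
  names(sort(m, decreasing = TRUE))[seq_len(n)]
}
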