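# Per-record flags, cis/trans labels, distances, GWAS links and count
# statistics over the ingested store. All computations are deterministic
# and order-independent; annotating a shuffled store yields the same
# result row-for-row.

#' Family-wise error rate significance threshold
#'
#' Bonferroni threshold over all variant-gene tests of a study:
#' `alpha / (n_variants * n_genes)`. With the defaults of one million
#' variants and fifty thousand genes (approximately the Ensembl gene set
#' without pseudogenes) at a 5% FWER this gives the study-wide significance
#' level of 1e-12 applied to datasets that do not declare their own
#' significance rule.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_variants,n_genes Positive test dimensions.
#' @return P-value threshold.
#' @export
fwer_threshold <- function(alpha = 0.05, n_variants = 1e6, n_genes = 5e4) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  n_variants <- as.numeric(n_variants)
  n_genes <- as.numeric(n_genes)
  if (is.na(n_variants) || is.na(n_genes) || n_variants < 1 || n_genes < 1)
    stop("n_variants and n_genes must be >= 1")
  alpha / (n_variants * n_genes)
}

#' Resolve the significance policy of a dataset
#'
#' @param entry A [manifest_entry()].
#' @return List with `provenance` (`source_provided` or `fwer_derived`),
#'   `threshold` (NA when source-provided), `n_variants`, `n_genes`.
#' @export
significance_policy <- function(entry) {
  if (entry$significance_policy == "source_provided")
    list(provenance = "source_provided", threshold = NA_real_,
         n_variants = NA_real_, n_genes = NA_real_)
  else
    list(provenance = "fwer_derived",
         threshold = fwer_threshold(entry$alpha, entry$n_variants,
                                    entry$n_genes),
         n_variants = entry$n_variants, n_genes = entry$n_genes)
}

#' Flag study-wide significant records
#'
#' Under the `fwer_derived` policy a record is flagged when
#' `p_value <= threshold` (boundary inclusive); under `source_provided`
#' the dataset's own significance flag is taken as-is.
#'
#' @param records QTL record table.
#' @param policies Named list (by dataset name) of [significance_policy()]
#'   results; datasets not listed fall back to the default FWER threshold.
#' @param default_threshold Fallback threshold (default
#'   [fwer_threshold()] = 1e-12).
#' @return The table with logical `is_sw_significant` and numeric
#'   `sig_threshold` columns set (by reference).
#' @export
flag_sw_significant <- function(records, policies = list(),
                                default_threshold = fwer_threshold()) {
  thr <- vapply(records$dataset, function(d) {
    p <- policies[[d]]
    if (is.null(p) || is.na(p$threshold)) default_threshold else p$threshold
  }, numeric(1))
  prov <- vapply(records$dataset, function(d) {
    p <- policies[[d]]
    if (!is.null(p)) p$provenance else "fwer_derived"
  }, character(1))
  src_sig <- if ("source_significant" %in% names(records))
    records$source_significant else rep(NA, nrow(records))
  sw <- ifelse(prov == "source_provided" & !is.na(src_sig),
               src_sig, records$p_value <= thr)
  records[, c("is_sw_significant", "sig_threshold") := list(sw, thr)]
  records[]
}

#' Flag the best record of each tissue-specific study
#'
#' Within each (source, tissue) group — the unit of a tissue-specific
#' QTL study — the record(s) with the minimal P value are
#' flagged `is_best`. Exact P ties are all flagged; inventing a
#' tie-break would fabricate a distinction the data does not make.
#'
#' @param records QTL record table.
#' @return The table with logical `is_best` set.
#' @export
flag_best <- function(records) {
  records[, "is_best" := p_value == min(p_value), by = .(source, tissue)]
  records[]
}

#' Flag records best within their LD group
#'
#' For each record, the LD group of its variant (the variant plus all
#' variants with r-squared strictly above 0.2 against it) is looked up and
#' the record is flagged when its P value is minimal among records of
#' LD-group member variants in the same (source, tissue) — by default
#' restricted to the same gene, since a QTL is a variant-gene claim
#' (`per_gene = FALSE` compares across genes). Variants without LD data
#' form singleton groups and are therefore flagged.
#'
#' @param records QTL record table.
#' @param ld An `ld_store`.
#' @param r2_threshold Strict LD-group bound (default 0.2).
#' @param per_gene Restrict comparison to records of the same gene
#'   (default TRUE).
#' @return The table with logical `is_best_in_ld_group` set.
#' @export
flag_best_in_ld_group <- function(records, ld, r2_threshold = 0.2,
                                  per_gene = TRUE) {
  stopifnot(inherits(ld, "ld_store"))
  seeds <- unique(records$variant_id)
  groups <- lapply(seeds, function(s)
    build_ld_group(ld, s, r2_threshold)$members)
  names(groups) <- seeds
  grp_by <- if (per_gene) c("source", "tissue", "gene_id") else
    c("source", "tissue")
  # minimal P per variant within each comparison stratum
  minp <- records[, .(min_p = min(p_value)),
                  by = c(grp_by, "variant_id")]
  setkeyv(minp, c(grp_by, "variant_id"))
  flag <- vapply(seq_len(nrow(records)), function(i) {
    mem <- groups[[records$variant_id[i]]]
    sub <- minp[as.list(records[i, grp_by, with = FALSE])]
    comp <- sub[variant_id %in% mem, min_p]
    records$p_value[i] <= min(comp)
  }, logical(1))
  records[, "is_best_in_ld_group" := flag]
  records[]
}

#' Classify records as cis or trans by TAD co-localization
#'
#' A record is cis when at least one TAD interval contains both the
#' variant position and the gene's anchor point, and trans otherwise —
#' including variant and gene on different chromosomes, positions outside
#' every TAD, and an empty TAD set (which classifies everything trans).
#' The anchor is the gene start; with `strand_aware = TRUE` it is the
#' transcription start site (gene end on the minus strand).
#'
#' @param records QTL record table.
#' @param tads `GRanges` from [read_tads()].
#' @param strand_aware Use the strand-aware TSS as gene anchor (default
#'   FALSE).
#' @return The table with a `colocalization` column in `{"cis","trans"}`.
#' @export
classify_cis_trans <- function(records, tads, strand_aware = FALSE) {
  anchor <- gene_anchor(records, strand_aware)
  lab <- rep("trans", nrow(records))
  if (length(tads) > 0L && nrow(records) > 0L) {
    vgr <- GenomicRanges::GRanges(records$chrom,
                                  IRanges::IRanges(records$pos,
                                                   records$pos))
    ggr <- GenomicRanges::GRanges(records$gene_chrom,
                                  IRanges::IRanges(anchor, anchor))
    # chromosome sets may legitimately differ between store and TADs
    hv <- suppressWarnings(GenomicRanges::findOverlaps(vgr, tads))
    hg <- suppressWarnings(GenomicRanges::findOverlaps(ggr, tads))
    dv <- data.table(rec = S4Vectors::queryHits(hv),
                     tad = S4Vectors::subjectHits(hv))
    dg <- data.table(rec = S4Vectors::queryHits(hg),
                     tad = S4Vectors::subjectHits(hg))
    both <- merge(dv, dg, by = c("rec", "tad"))
    lab[unique(both$rec)] <- "cis"
  }
  records[, "colocalization" := lab]
  records[]
}

gene_anchor <- function(records, strand_aware = FALSE) {
  if (strand_aware)
    ifelse(records$gene_strand == "-", records$gene_end,
           records$gene_start)
  else records$gene_start
}

#' Signed variant-gene distance in kilobases
#'
#' Zero when the variant lies within the gene boundaries (the intronic
#' case); otherwise the distance from the nearest gene boundary, positive
#' when the variant is downstream of the gene interval (pos > end),
#' negative when upstream (pos < start). Absent (NA) when variant and gene
#' sit on different chromosomes.
#'
#' @param records QTL record table.
#' @return The table with a numeric `distance_kb` column.
#' @export
compute_distance <- function(records) {
  d <- rep(NA_real_, nrow(records))
  same <- records$chrom == records$gene_chrom
  inside <- same & records$pos >= records$gene_start &
    records$pos <= records$gene_end
  below <- same & records$pos < records$gene_start
  above <- same & records$pos > records$gene_end
  d[inside] <- 0
  d[below] <- (records$pos[below] - records$gene_start[below]) / 1000
  d[above] <- (records$pos[above] - records$gene_end[above]) / 1000
  records[, "distance_kb" := d]
  records[]
}

#' Link records to GWAS Catalog associations
#'
#' @param records QTL record table.
#' @param catalog A [read_gwas_catalog()] result.
#' @return The table with logical `gwas_variant_hit` (rsID matches a
#'   catalog variant) and `gwas_gene_hit` (gene symbol matches a mapped
#'   gene) columns.
#' @export
link_gwas <- function(records, catalog) {
  stopifnot(inherits(catalog, "gwas_catalog"))
  records[, c("gwas_variant_hit", "gwas_gene_hit") := list(
    !is.na(rsid) & rsid %chin% catalog$variants,
    symbol %chin% catalog$genes)]
  records[]
}

#' Count characteristics per putative QTL
#'
#' Per (variant, gene) pair across all tissue-specific studies
#' (source/tissue pairs): `n_occ` = number of studies in which the pair
#' occurs, `n_best` = studies where it carries `is_best`,
#' `n_sw_significant` = studies where it is study-wide significant. Per
#' (gene, source, tissue): `n_qtls` = number of variant records for the
#' gene in that study.
#'
#' @param records QTL record table with flags computed.
#' @return The table with integer columns `n_qtls`, `n_best`,
#'   `n_sw_significant`, `n_occ`.
#' @export
compute_counts <- function(records) {
  records[, "n_occ" := as.integer(uniqueN(paste(source, tissue, sep = "\r"))),
          by = .(variant_id, gene_id)]
  records[, "n_best" := as.integer(
    uniqueN(paste(source, tissue, sep = "\r")[is_best])),
    by = .(variant_id, gene_id)]
  records[, "n_sw_significant" := as.integer(
    uniqueN(paste(source, tissue, sep = "\r")[is_sw_significant])),
    by = .(variant_id, gene_id)]
  records[, "n_qtls" := .N, by = .(gene_id, source, tissue)]
  records[]
}

#' Annotate a store end to end
#'
#' Runs the full transformation: study-wide significance, per-study best
#' flags, best-in-LD-group flags, TAD-based cis/trans labels, distances,
#' GWAS Catalog links and count characteristics, then checks the
#' annotation invariants.
#'
#' @param records Ingested QTL record table.
#' @param ld An `ld_store`.
#' @param tads TAD `GRanges` (empty set allowed).
#' @param catalog Optional [read_gwas_catalog()] result.
#' @param policies Named per-dataset [significance_policy()] list.
#' @param r2_threshold LD-group bound (default 0.2).
#' @param per_gene_ld_group See [flag_best_in_ld_group()].
#' @param strand_aware See [classify_cis_trans()].
#' @return The annotated table (also modified by reference).
#' @export
annotate_store <- function(records, ld, tads = GenomicRanges::GRanges(),
                           catalog = NULL, policies = list(),
                           r2_threshold = 0.2, per_gene_ld_group = TRUE,
                           strand_aware = FALSE) {
  records <- as.data.table(records)
  setorder(records, variant_id, gene_id, tissue, source, study, p_value)
  flag_sw_significant(records, policies)
  flag_best(records)
  flag_best_in_ld_group(records, ld, r2_threshold, per_gene_ld_group)
  classify_cis_trans(records, tads, strand_aware)
  compute_distance(records)
  if (is.null(catalog))
    records[, c("gwas_variant_hit", "gwas_gene_hit") := FALSE]
  else link_gwas(records, catalog)
  compute_counts(records)
  validate_annotations(records)
  records[]
}

#' Export an annotated store as TSV
#'
#' One row per annotated record; flags serialized as a semicolon-joined
#' token column (e.g. `is_sw_significant;is_best;is_best_in_ld_group`).
#' Output columns follow the result-table view: variant, proxy, gene,
#' distance, tissue, statistics, source, flags, GWAS links and counts.
#'
#' @param records Annotated QTL record table.
#' @param path Output TSV path; `#`-prefixed metadata headers may precede
#'   the table.
#' @param header Optional character vector of metadata lines (written with
#'   a leading `#`).
#' @return Invisibly, the exported `data.table`.
#' @export
export_annotated <- function(records, path, header = NULL) {
  flags <- with(records, {
    f <- function(flag, name) ifelse(flag, name, NA_character_)
    apply(cbind(f(is_sw_significant, "is_sw_significant"),
                f(is_best, "is_best"),
                f(is_best_in_ld_group, "is_best_in_ld_group")), 1,
          function(r) paste(r[!is.na(r)], collapse = ";"))
  })
  out <- records[, .(rsid, variant_id, chrom, pos, gene_id, symbol,
                     distance_kb, tissue, p_value, beta, ea, nea, source,
                     study, qtl_type, colocalization,
                     gwas_variant_hit, gwas_gene_hit,
                     n_qtls, n_best, n_sw_significant, n_occ)]
  out[, "flags" := flags]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(lapply(out, function(col)
      ifelse(is.na(col), "", as.character(col))), sep = "\t")), con)
  invisible(out[])
}
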