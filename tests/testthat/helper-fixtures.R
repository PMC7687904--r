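# Shared small fixtures, built in code. Bundles are cached per seed since
# several files exercise the same generated corpus.

.bundle_cache <- new.env(parent = emptyenv())

cached_bundle <- function(seed, ...) {
  key <- paste0("b", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- qtlannot::synth_bundle(
      qtlannot::fixture_spec(seed = seed, ...))
  .bundle_cache[[key]]
}

cached_annotated <- function(seed, ...) {
  key <- paste0("a", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.bundle_cache[[key]])) {
    b <- cached_bundle(seed, ...)
    st <- qtlannot::ingest_bundle(b)
    pol <- lapply(b$manifest_entries, qtlannot::significance_policy)
    names(pol) <- vapply(b$manifest_entries, `[[`, "", "name")
    .bundle_cache[[key]] <- qtlannot::annotate_store(
      st, b$ld, qtlannot::bundle_tads(b), policies = pol)
  }
  .bundle_cache[[key]]
}

tiny_gene_index <- function() {
  qtlannot::gene_index(data.table::data.table(
    gene_id = c("ENSG01", "ENSG02", "ENSG03"),
    symbol = c("MRAS", "ABC1", "XYZ2"),
    chrom = "3",
    start = c(138100000L, 139000000L, 140000000L),
    end = c(138150000L, 139050000L, 140050000L),
    strand = c("+", "-", "+"),
    synonyms = c("RAS3", "SHARED", "SHARED")))
}

tiny_ld_store <- function() {
  qtlannot::ld_store(data.table::data.table(
    variant_a = c("rs1", "rs2", "rs1", "rs1"),
    variant_b = c("rs2", "rs3", "rs3", "rs4"),
    r2 = c(0.5, 0.5, 0.1, 0.95),
    dprime = c(0.9, 0.8, 0.4, 1.0)),
    universe = c("rs1", "rs2", "rs3", "rs4", "rs5"))
}

# minimal valid record table builder
toy_records <- function(p_values, variant = "rs1", gene = "ENSG01",
                        tissue = "Heart", source = "S1",
                        pos = 138120000L, gene_start = 138100000L,
                        gene_end = 138150000L, chrom = "3") {
  n <- length(p_values)
  rep_or <- function(x) rep_len(x, n)
  data.table::data.table(
    variant_id = rep_or(variant), rsid = rep_or(variant),
    chrom = rep_or(chrom), pos = rep_or(as.integer(pos)), build = "hg19",
    gene_id = rep_or(gene), symbol = rep_or(toupper(gene)),
    gene_chrom = rep_or(chrom), gene_start = rep_or(as.integer(gene_start)),
    gene_end = rep_or(as.integer(gene_end)), gene_strand = "+",
    tissue = rep_or(tissue), source = rep_or(source),
    study = rep_or(paste0(source, "-x")), qtl_type = "eQTL",
    p_value = p_values, beta = 0.1, ea = "A", nea = "G",
    dataset = rep_or(source))
}
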