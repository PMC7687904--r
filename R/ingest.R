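# Readers and the "T" of ETL: harmonize heterogeneous QTL summary
# statistics, TAD boundaries, gene annotation and GWAS Catalog tables into
# the canonical store. Every reader reconciles rows in vs records out and
# attaches a diagnostic log as the "log" attribute.

#' Default tissue normalization map
#'
#' Tissue names are curated so that they are consistent across datasets.
#' The map is total on the ingested data: every raw tissue string must
#' resolve or ingestion fails listing the offenders. Users extend or
#' replace this map via a two-column TSV (`raw`, `normalized`).
#'
#' @return Named character vector (names = raw strings, values =
#'   normalized tissue names).
#' @export
default_tissue_map <- function() {
  c("artery aorta"           = "Artery-Aorta",
    "Artery - Aorta"         = "Artery-Aorta",
    "Artery-Aorta"           = "Artery-Aorta",
    "artery tibial"          = "Artery-Tibial",
    "Artery - Tibial"        = "Artery-Tibial",
    "Artery-Tibial"          = "Artery-Tibial",
    "heart atrial appendage" = "Heart-Atrial appendage",
    "Heart - Atrial Appendage" = "Heart-Atrial appendage",
    "Heart-Atrial appendage" = "Heart-Atrial appendage",
    "heart"                  = "Heart",
    "Heart"                  = "Heart",
    "whole blood"            = "Whole blood",
    "Whole Blood"            = "Whole blood",
    "Whole blood"            = "Whole blood",
    "liver"                  = "Liver",
    "Liver"                  = "Liver",
    "monocytes"              = "Monocytes",
    "Monocytes"              = "Monocytes",
    "LCL"                    = "Lymphoblastoid cell lines",
    "lymphoblastoid cell lines" = "Lymphoblastoid cell lines",
    "Lymphoblastoid cell lines" = "Lymphoblastoid cell lines")
}

#' Read a tissue normalization map from TSV
#'
#' @param path TSV with header columns `raw` and `normalized`.
#' @return Named character vector usable as `tissue_map`.
#' @export
read_tissue_map <- function(path) {
  tab <- fread(path, sep = "\t", colClasses = "character")
  if (!all(c("raw", "normalized") %in% names(tab)))
    stop("tissue map needs columns raw, normalized")
  setNames(tab$normalized, tab$raw)
}

#' Describe one QTL summary-statistics dataset
#'
#' A manifest entry records where a dataset lives, how its columns map onto
#' the canonical fields, its study key (source, study, tissue handling, QTL
#' type) and its significance policy. Datasets that ship only
#' source-declared significant associations use `source_provided` with a
#' flag column; all others use the family-wise error rate rule
#' ([fwer_threshold()]) with the dataset's test dimensions.
#'
#' @param name Short dataset label (used in logs).
#' @param path File path of the TSV.
#' @param source Data-source name (e.g. repository).
#' @param study Publication/dataset label; defaults to `source`.
#' @param qtl_type One of `"eQTL"`, `"pQTL"`, `"reQTL"`.
#' @param columns Named list mapping canonical fields (`rsid`, `chrom`,
#'   `pos`, `gene`, `tissue`, `p_value`, `beta`, `ea`, `nea`, optionally
#'   `significant`) to column names in the file.
#' @param significance_policy `"fwer_derived"` or `"source_provided"`.
#' @param n_variants,n_genes Test dimensions for the FWER rule.
#' @param alpha Family-wise error rate (default 0.05).
#' @param build Genome build of the coordinates, `"hg19"` or `"hg38"`.
#' @param pubmed_id Optional PubMed id.
#' @return A list of class `manifest_entry`.
#' @export
manifest_entry <- function(name, path, source, study = source,
                           qtl_type = "eQTL",
                           columns = list(rsid = "rsid", chrom = "chrom",
                                          pos = "pos", gene = "gene",
                                          tissue = "tissue",
                                          p_value = "p", beta = "beta",
                                          ea = "ea", nea = "nea"),
                           significance_policy = c("fwer_derived",
                                                   "source_provided"),
                           n_variants = 1e6, n_genes = 5e4, alpha = 0.05,
                           build = "hg19", pubmed_id = NA_character_) {
  significance_policy <- match.arg(significance_policy)
  if (significance_policy == "source_provided" &&
      is.null(columns$significant))
    stop("source_provided policy needs a 'significant' column mapping")
  structure(list(name = name, path = path, source = source, study = study,
                 qtl_type = qtl_type, columns = columns,
                 significance_policy = significance_policy,
                 n_variants = n_variants, n_genes = n_genes, alpha = alpha,
                 build = build, pubmed_id = pubmed_id),
            class = "manifest_entry")
}

#' Read a dataset manifest from JSON
#'
#' @param path JSON file holding an array of manifest-entry objects.
#' @param base_dir Directory against which relative dataset paths resolve.
#' @return List of `manifest_entry` objects.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    e$columns <- lapply(e$columns, as.character)
    p <- e$path
    if (!grepl("^/", p)) p <- file.path(base_dir, p)
    do.call(manifest_entry, modifyList(e, list(path = p)))
  })
}

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read one QTL summary-statistics table
#'
#' Applies the per-dataset column map, normalizes tissue names and
#' chromosome labels, upper-cases alleles (indels are multi-base allele
#' strings), resolves gene labels against the gene index, and drops
#' malformed rows with row-level diagnostics. Duplicate QTL objects (same
#' variant/gene/tissue/study quadruple) within a dataset keep the row with
#' the smallest P; collisions are logged.
#'
#' @param path TSV file with a header.
#' @param entry A [manifest_entry()].
#' @param genes A [gene_index()] used to resolve the gene column.
#' @param tissue_map Named character vector raw -> normalized tissue.
#' @return `data.table` of QTL records (see [qtl_record_columns()]) with a
#'   `log` attribute: `list(n_rows, n_records, rejected, collisions)`.
#' @export
read_qtl_table <- function(path, entry, genes,
                           tissue_map = default_tissue_map()) {
  stopifnot(inherits(entry, "manifest_entry"), inherits(genes, "gene_index"))
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = c("", "NA", "."))
  cm <- entry$columns
  mandatory <- c("rsid", "chrom", "pos", "gene", "tissue", "p_value")
  miss <- setdiff(unlist(cm[mandatory]), names(tab))
  if (length(miss))
    stop("dataset ", entry$name, ": missing mandatory column(s): ",
         paste(miss, collapse = ", "))

  get_col <- function(field, default = NA_character_) {
    if (!is.null(cm[[field]]) && cm[[field]] %in% names(tab))
      tab[[cm[[field]]]] else rep(default, nrow(tab))
  }
  rec <- data.table(
    rsid = get_col("rsid"),
    chrom = normalize_chrom(get_col("chrom")),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    gene_label = get_col("gene"),
    tissue_raw = get_col("tissue"),
    p_value = suppressWarnings(as.numeric(get_col("p_value"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    ea = toupper(get_col("ea")),
    nea = toupper(get_col("nea")),
    source_significant = if (!is.null(cm$significant))
      toupper(get_col("significant")) %in% c("1", "TRUE", "YES") else
      rep(NA, nrow(tab)),
    row = seq_len(nrow(tab)))

  rejected <- list()
  reject <- function(mask, why) {
    if (any(mask)) rejected[[why]] <<- rec$row[mask]
    mask
  }
  bad <- reject(is.na(rec$p_value) | rec$p_value <= 0 | rec$p_value > 1,
                "p_value outside (0,1]")
  bad <- bad | reject(is.na(rec$pos) | rec$pos < 1L, "bad position")
  bad <- bad | reject(is.na(rec$chrom) | !nzchar(rec$chrom), "missing chrom")

  # tissue normalization must be total on the surviving rows
  raw_t <- unique(rec$tissue_raw[!bad])
  unmapped <- setdiff(raw_t, names(tissue_map))
  if (length(unmapped))
    stop("dataset ", entry$name, ": unmappable tissue name(s): ",
         paste(unmapped, collapse = ", "),
         " - extend the tissue normalization map")
  rec[, "tissue" := tissue_map[tissue_raw]]

  # gene resolution: stable id first, then primary symbol, then synonym
  gmap <- resolve_gene_vector(rec$gene_label, genes)
  bad <- bad | reject(is.na(gmap), "unknown gene label")
  rec[, "gene_id" := gmap]

  out <- rec[!bad]
  gtab <- genes$genes
  out <- gtab[, .(gene_id, symbol, gene_chrom = normalize_chrom(chrom),
                  gene_start = start, gene_end = end, gene_strand = strand)
              ][out, on = "gene_id"]
  out[, "variant_id" := variant_key(rsid, chrom, pos)]
  out[, c("source", "study", "qtl_type", "build", "dataset") :=
        list(entry$source, entry$study, entry$qtl_type, entry$build,
             entry$name)]

  # duplicate quadruples within a dataset: keep smallest P, log collision
  out[, "identity" := record_identity(out)]
  setorder(out, identity, p_value, variant_id)
  dup <- duplicated(out$identity)
  collisions <- sum(dup)
  out <- out[!dup]
  out[, c("identity", "tissue_raw", "gene_label", "row") := NULL]
  setcolorder(out, intersect(qtl_record_columns(), names(out)))
  validate_records(out)
  setattr(out, "log",
          list(n_rows = nrow(tab), n_records = nrow(out),
               rejected = rejected, collisions = collisions))
  out[]
}

#' Ingest every dataset of a manifest into one store
#'
#' @param manifest List of [manifest_entry()] objects.
#' @param genes A [gene_index()].
#' @param tissue_map Tissue normalization map.
#' @return Combined record `data.table`; per-dataset logs in the `log`
#'   attribute. Mixing genome builds across datasets is an error.
#' @export
ingest_datasets <- function(manifest, genes,
                            tissue_map = default_tissue_map()) {
  parts <- lapply(manifest, function(e)
    read_qtl_table(e$path, e, genes, tissue_map))
  logs <- lapply(parts, attr, "log")
  names(logs) <- vapply(manifest, `[[`, "", "name")
  store <- rbindlist(parts)
  validate_records(store)
  setattr(store, "log", logs)
  store[]
}

#' Read TAD boundaries from BED
#'
#' BED intervals are 0-based half-open on disk and are converted to the
#' internal 1-based inclusive convention, so a row `chr1 1000 5000` covers
#' positions 1001..5000. Rows with start >= end are rejected with a
#' diagnostic. Intervals on a chromosome are not assumed disjoint.
#'
#' @param path BED3+ file.
#' @return A `GRanges` of TAD intervals (class also `tad_set` semantics via
#'   metadata); empty file yields an empty set and downstream classifies
#'   every record trans.
#' @export
read_tads <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L)
    return(GenomicRanges::GRanges())
  tab <- fread(path, sep = "\t", header = FALSE,
               colClasses = list(character = 1, integer = 2:3),
               select = 1:3)
  if (nrow(tab) == 0L)
    return(GenomicRanges::GRanges())
  bad <- is.na(tab$V2) | is.na(tab$V3) | tab$V2 >= tab$V3
  tads <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(tab$V1[!bad]),
    ranges = IRanges::IRanges(start = tab$V2[!bad] + 1L, end = tab$V3[!bad]))
  S4Vectors::metadata(tads) <- list(n_rejected = sum(bad))
  tads
}

#' Summarize a TAD set
#'
#' @param tads `GRanges` from [read_tads()].
#' @return List with `n`, `mean_length_kb`, `min_length_kb`,
#'   `max_length_kb` (lengths in kilobases).
#' @export
tad_summary <- function(tads) {
  w <- GenomicRanges::width(tads)
  list(n = length(tads),
       mean_length_kb = mean(w) / 1000,
       min_length_kb = if (length(w)) min(w) / 1000 else NA_real_,
       max_length_kb = if (length(w)) max(w) / 1000 else NA_real_)
}

#' Read gene annotation from GTF or TSV
#'
#' The TSV dialect needs header columns `gene_id`, `symbol`, `chrom`,
#' `start`, `end`, `strand` and optionally `synonyms` (semicolon-joined);
#' coordinates 1-based inclusive. The GTF path keeps `gene` features and
#' uses the `gene_id` / `gene_name` attributes. Both dialects yield
#' identical gene records.
#'
#' @param path File path; dialect chosen by extension (`.gtf`/`.gff` vs
#'   anything else).
#' @return A [gene_index()].
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    tab <- data.table(
      gene_id = gr$gene_id,
      symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      synonyms = "")
  } else {
    tab <- fread(path, sep = "\t", header = TRUE)
    tab <- as.data.table(tab)
    if (!"synonyms" %in% names(tab)) tab[, "synonyms" := ""]
    tab[, "synonyms" := ifelse(is.na(synonyms), "", synonyms)]
    tab[, "chrom" := normalize_chrom(chrom)]
  }
  gene_index(tab)
}

#' Read GWAS Catalog associations
#'
#' Accepts the catalog download dialect (columns `SNPS` and
#' `MAPPED_GENE`, plus `DISEASE/TRAIT` and `STUDY ACCESSION`) or a plain
#' dialect (`rsid`, `gene`, `phenotype`, `accession`). Rows lacking both a
#' variant and a gene are skipped and counted.
#'
#' @param path TSV file.
#' @return List of class `gwas_catalog` with `entries` (data.table),
#'   `variants` (rsid set), `genes` (symbol set) and `n_skipped`.
#' @export
read_gwas_catalog <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = c("", "NA"))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    rep(NA_character_, nrow(tab))
  }
  entries <- data.table(
    rsid = pick("SNPS", "rsid"),
    gene_symbol = pick("MAPPED_GENE", "gene"),
    phenotype = pick("DISEASE/TRAIT", "phenotype"),
    accession = pick("STUDY ACCESSION", "accession"))
  skip <- is.na(entries$rsid) & is.na(entries$gene_symbol)
  entries <- entries[!skip]
  structure(list(entries = entries,
                 variants = unique(entries$rsid[!is.na(entries$rsid)]),
                 genes = unique(entries$gene_symbol[
                   !is.na(entries$gene_symbol)]),
                 n_skipped = sum(skip)),
            class = "gwas_catalog")
}

#' @exportS3Method print gwas_catalog
print.gwas_catalog <- function(x, ...) {
  cat("<gwas_catalog> ", nrow(x$entries), " entries (",
      length(x$variants), " variants, ", length(x$genes), " genes, ",
      x$n_skipped, " skipped)\n", sep = "")
  invisible(x)
}
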