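#' @import data.table
#' @importFrom stats median p.adjust phyper rbinom rlnorm runif setNames
#' @importFrom utils head modifyList
NULL

# Canonical in-memory model. A QTL store is a data.table with one row per
# QTL record; the quadruple (variant, gene, tissue, source study) is the
# record's identity, statistics (P, beta, alleles) are payload. Internal
# coordinates are 1-based inclusive throughout; BED input is converted on
# read, GTF/VCF/TSV coordinates pass through unchanged.

#' Columns every QTL record table carries after ingestion
#'
#' @return Character vector of mandatory column names.
#' @export
qtl_record_columns <- function() {
  c("variant_id", "rsid", "chrom", "pos", "build",
    "gene_id", "symbol", "gene_chrom", "gene_start", "gene_end", "gene_strand",
    "tissue", "source", "study", "qtl_type",
    "p_value", "beta", "ea", "nea", "dataset")
}

#' Construct a variant key string
#'
#' A variant is addressed by its rsID when available, else by its
#' chromosomal position as `chrom:pos`. At least one of the two must be
#' present.
#'
#' @param rsid rsID string or `NA`.
#' @param chrom Chromosome label or `NA`.
#' @param pos 1-based position or `NA`.
#' @return Character key, one per element.
#' @export
variant_key <- function(rsid, chrom = NA_character_, pos = NA_integer_) {
  n <- max(length(rsid), length(chrom), length(pos))
  rsid <- rep_len(as.character(rsid), n)
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  key <- ifelse(!is.na(rsid) & nzchar(rsid), rsid,
                paste0(chrom, ":", pos))
  bad <- (is.na(rsid) | !nzchar(rsid)) & (is.na(chrom) | is.na(pos))
  if (any(bad)) {
    stop("variant needs an rsid or a (chrom, pos) pair; ",
         sum(bad), " record(s) have neither")
  }
  key
}

#' Identity tuple of QTL records
#'
#' Two rows describe the same QTL object if and only if they agree on the
#' quadruple (variant, gene, tissue, source study). Statistics such as P
#' and beta are excluded. Tissue names must already be normalized.
#'
#' @param records A QTL record `data.table` (see [qtl_record_columns()]).
#' @return Character vector of identity keys, one per row.
#' @export
record_identity <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("variant_id", "gene_id", "tissue", "source", "study")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack identity columns: ",
                         paste(miss, collapse = ", "))
  paste(records$variant_id, records$gene_id, records$tissue,
        records$source, records$study, sep = "\r")
}

#' Validate a QTL record table
#'
#' Checks the structural invariants of the canonical store: P values in
#' (0, 1], positive positions, gene start <= end, non-empty chromosome and
#' tissue labels, and a single genome build.
#'
#' @param records QTL record `data.table`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_records <- function(records) {
  miss <- setdiff(qtl_record_columns(), names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(TRUE))
  if (any(is.na(records$p_value) | records$p_value <= 0 | records$p_value > 1))
    stop("p_value out of (0, 1]")
  if (any(records$pos < 1L, na.rm = TRUE)) stop("pos must be >= 1")
  if (any(records$gene_start > records$gene_end, na.rm = TRUE))
    stop("gene start > end")
  if (any(!nzchar(records$chrom) | is.na(records$chrom))) stop("empty chrom")
  if (any(!nzchar(records$tissue) | is.na(records$tissue))) stop("empty tissue")
  if (length(unique(records$build)) > 1L)
    stop("mixed genome builds in one store: ",
         paste(unique(records$build), collapse = ", "))
  invisible(TRUE)
}

#' Check annotated-store flag and count invariants
#'
#' `is_best` implies `is_best_in_ld_group`; `n_best <= n_occ` and
#' `n_sw_significant <= n_occ` for every record; exactly one cis/trans
#' label per record.
#'
#' @param records Annotated QTL record table (after [annotate_store()]).
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_annotations <- function(records) {
  if (any(records$is_best & !records$is_best_in_ld_group))
    stop("record flagged is_best but not is_best_in_ld_group")
  if (any(records$n_best > records$n_occ)) stop("n_best > n_occ")
  if (any(records$n_sw_significant > records$n_occ))
    stop("n_sw_significant > n_occ")
  if (!all(records$colocalization %in% c("cis", "trans")))
    stop("colocalization must be exactly one of cis/trans")
  invisible(TRUE)
}

#' Build a gene index from a gene table
#'
#' Wraps a gene annotation table with lookup maps used by the query
#' resolver: stable id, primary symbol, and synonyms. Symbols may clash;
#' ambiguity is resolved (and reported) at query time.
#'
#' @param genes `data.table` with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `strand` and optionally `synonyms` (semicolon-joined).
#' @return An object of class `gene_index`.
#' @export
gene_index <- function(genes) {
  genes <- as.data.table(genes)
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  if (any(genes$start > genes$end)) stop("gene start > end")
  if (!"synonyms" %in% names(genes)) genes[, "synonyms" := ""]
  syn <- genes[nzchar(synonyms),
               .(synonym = as.character(unlist(
                 strsplit(synonyms, ";", fixed = TRUE)))),
               by = gene_id]
  structure(list(genes = genes, synonyms = syn), class = "gene_index")
}

#' @exportS3Method print gene_index
print.gene_index <- function(x, ...) {
  cat("<gene_index> ", nrow(x$genes), " genes, ",
      nrow(x$synonyms), " synonyms\n", sep = "")
  invisible(x)
}
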