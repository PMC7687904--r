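# Deterministic synthetic fixtures emulating every input the pipeline
# consumes: QTL summary-statistics TSVs, a phased-genotype VCF, TAD BED,
# gene annotation, GWAS Catalog table and gene-set lists, with a
# ground-truth sidecar recording what was planted. Haplotypes are
# structured noise sufficient to hit r-squared targets, not a
# population-genetic simulation.

#' Specification of a synthetic fixture bundle
#'
#' The defaults define the study conditions the test-bed emulates at desk
#' scale: a grid of tissue-specific studies (source/tissue pairs), genes
#' with local variant sets whose lead eQTL sits at a log-normal distance
#' from the gene start (median 28 kb, mean about 101 kb — the scale
#' observed in real eQTL corpora), a subset of "sharing" genes whose best
#' eQTL recurs in m studies within one tightly linked block, and TAD
#' intervals with a controllable count and mean length.
#'
#' @param seed Integer seed; fully determines the bundle.
#' @param n_genes Number of genes.
#' @param n_sources,n_tissues Study grid; every (source, tissue) pair is
#'   one tissue-specific study.
#' @param variants_per_gene Local variants per gene (>= 2).
#' @param n_hap Haplotypes in the genotype panel (even, >= 8).
#' @param block_r2 Within-block r-squared target for planted sharing
#'   blocks.
#' @param frac_significant Probability that a (gene, study) pair carries a
#'   study-wide significant signal.
#' @param p_present Probability that a (gene, study) pair is reported at
#'   all.
#' @param sharing_genes Number of planted sharing genes.
#' @param sharing_m Number of studies the planted best eQTL recurs in
#'   (recycled over sharing genes).
#' @param dist_meanlog,dist_sdlog Log-normal parameters of the planted
#'   lead-eQTL distance in bp.
#' @param n_tads,mean_tad_kb TAD layout.
#' @param alpha,n_variants_fwer,n_genes_fwer FWER significance rule of the
#'   synthetic studies.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 30L, n_sources = 4L,
                         n_tissues = 5L, variants_per_gene = 4L,
                         n_hap = 400L, block_r2 = 0.98,
                         frac_significant = 0.5, p_present = 0.7,
                         sharing_genes = 6L, sharing_m = c(8L, 10L, 12L),
                         dist_meanlog = log(28000), dist_sdlog = 1.6,
                         n_tads = 40L, mean_tad_kb = 800,
                         alpha = 0.05, n_variants_fwer = 1e6,
                         n_genes_fwer = 5e4) {
  spec <- as.list(environment())
  if (variants_per_gene < 2L) stop("need >= 2 variants per gene")
  if (n_hap < 8L || n_hap %% 2L != 0L) stop("n_hap must be even and >= 8")
  if (sharing_genes > n_genes) stop("more sharing genes than genes")
  if (max(sharing_m) > n_sources * n_tissues)
    stop("planted sharing m exceeds the number of studies")
  structure(spec, class = "fixture_spec")
}

#' Two-variant haplotype panel with a target r-squared
#'
#' Generates a reference column and a partner obtained by random allele
#' flips, rejection-sampling until the realized r-squared lies within
#' tolerance of the target. Target 1 duplicates the column exactly;
#' target 0 draws independently.
#'
#' @param n_hap Number of haplotypes (>= 8).
#' @param r2_target Target r-squared in `[0, 1]`.
#' @param seed Optional seed (uses the current stream when NULL).
#' @param tol Acceptance tolerance (default 0.05).
#' @param max_tries Rejection-sampling budget.
#' @return Two-column 0/1 matrix.
#' @export
haplotypes_with_target_r2 <- function(n_hap, r2_target, seed = NULL,
                                      tol = 0.05, max_tries = 2000L) {
  stopifnot(n_hap >= 8L, r2_target >= 0, r2_target <= 1)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    x <- draw_polymorphic(n_hap)
    if (r2_target >= 1) return(cbind(x, x))
    y <- flip_toward(x, r2_target, n_hap)
    if (length(unique(y)) < 2L) next
    r2 <- suppressWarnings(stats::cor(x, y)^2)
    if (!is.na(r2) && abs(r2 - r2_target) <= tol) return(cbind(x, y))
  }
  stop("could not realize r2 = ", r2_target, " within +/-", tol,
       " at n_hap = ", n_hap, "; try a larger panel")
}

draw_polymorphic <- function(n_hap, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.2, 0.8)
  repeat {
    x <- rbinom(n_hap, 1L, p)
    if (length(unique(x)) == 2L) return(x)
  }
}

flip_toward <- function(x, r2_target, n_hap) {
  f <- (1 - sqrt(r2_target)) / 2
  flips <- rbinom(n_hap, 1L, f)
  as.integer(xor(x, flips))
}

# extend a block around a seed column: each member is the seed with one
# distinct flipped haplotype, so r2 against the seed sits just below 1
# and every member pair differs in at most two haplotypes. Pairwise r2
# within the block stays above `pairwise_min`, so single-linkage grouping
# at any threshold below that keeps the block whole regardless of which
# members surface as best eQTLs — but no two members are identical, so
# grouping at r2 = 1 splits them.
block_columns <- function(seed_col, k, r2_target = 0.98, tol = 0.02,
                          pairwise_min = 0.952) {
  n <- length(seed_col)
  out <- matrix(0L, n, k)
  positions <- sample(n)
  pi <- 0L
  for (j in seq_len(k)) {
    if (r2_target >= 1) { out[, j] <- seed_col; next }
    ok <- FALSE
    while (pi < length(positions)) {
      pi <- pi + 1L
      y <- seed_col
      y[positions[pi]] <- 1L - y[positions[pi]]
      if (abs(stats::cor(seed_col, y)^2 - r2_target) > tol) next
      prev_ok <- j == 1L || all(vapply(seq_len(j - 1L), function(q)
        stats::cor(out[, q], y)^2 > pairwise_min, logical(1)))
      if (prev_ok) { out[, j] <- y; ok <- TRUE; break }
    }
    if (!ok) stop("could not realize block r2 target ", r2_target,
                  "; try a larger panel")
  }
  out
}

#' Generate a synthetic fixture bundle in memory
#'
#' @param spec A [fixture_spec()].
#' @return List of class `fixture_bundle`: `genes` (gene table), `gene_idx`
#'   ([gene_index()]), `panel` (`haplotype_panel`), `ld` (`ld_store`),
#'   `tads` (`GRanges`), `records` (raw study tables, one per source),
#'   `gwas` (catalog table), `gene_sets`, `tissue_map`, `manifest_entries`
#'   and `truth` (planted ground truth).
#' @export
synth_bundle <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  thr <- fwer_threshold(spec$alpha, spec$n_variants_fwer, spec$n_genes_fwer)

  tissues <- c("Artery-Aorta", "Artery-Tibial", "Heart-Atrial appendage",
               "Heart", "Whole blood", "Liver", "Monocytes",
               "Lymphoblastoid cell lines")[seq_len(spec$n_tissues)]
  sources <- paste0("SRC", seq_len(spec$n_sources))
  studies <- CJ(source = sources, tissue = tissues)

  # genes spaced 2 Mb apart on chromosome 1
  genes <- data.table(
    gene_id = sprintf("ENSG%08d", seq_len(spec$n_genes)),
    symbol = sprintf("GENE%d", seq_len(spec$n_genes)),
    chrom = "1",
    start = as.integer(10e6 + (seq_len(spec$n_genes) - 1L) * 2e6),
    strand = rep(c("+", "-"), length.out = spec$n_genes),
    synonyms = "")
  genes[, "end" := start + 20000L]
  setcolorder(genes, c("gene_id", "symbol", "chrom", "start", "end",
                       "strand", "synonyms"))

  # TADs tile the gene region back-to-back
  tad_len <- pmax(1000, round(rlnorm(spec$n_tads,
                                     log(spec$mean_tad_kb * 1000) - 0.5,
                                     1)))
  tad_start <- cumsum(c(9.5e6, head(tad_len, -1L)))
  tads_dt <- data.table(chrom = "1", start0 = as.integer(tad_start),
                        end0 = as.integer(tad_start + tad_len))

  # variants: a planted lead per gene at a log-normal distance from the
  # gene start, plus block partners nearby
  k <- spec$variants_per_gene
  sharing_ids <- genes$gene_id[seq_len(spec$sharing_genes)]
  m_plan <- rep_len(spec$sharing_m, spec$sharing_genes)
  variants <- list(); geno_cols <- list()
  vid_counter <- 0L
  truth_blocks <- list()
  for (gi in seq_len(spec$n_genes)) {
    g <- genes[gi]
    sgn <- sample(c(-1L, 1L), 1L)
    d <- round(rlnorm(1, spec$dist_meanlog, spec$dist_sdlog))
    lead_pos <- as.integer(max(1, g$start + sgn * d))
    offs <- sort(sample(1000:50000, k - 1L))
    pos <- as.integer(c(lead_pos, lead_pos + offs))
    ids <- sprintf("rs%d", 100000L + vid_counter + seq_len(k))
    vid_counter <- vid_counter + k
    is_sharing <- g$gene_id %in% sharing_ids
    # balanced seed frequency keeps single-flip r2 close to 1
    seed_col <- draw_polymorphic(spec$n_hap,
                                 p = if (is_sharing) runif(1, 0.4, 0.6)
                                     else NULL)
    if (is_sharing) {
      others <- block_columns(seed_col, k - 1L, spec$block_r2)
      truth_blocks[[g$gene_id]] <- ids
    } else {
      r2s <- runif(k - 1L, 0.05, 0.55)
      others <- vapply(r2s, function(r2) {
        repeat {
          y <- flip_toward(seed_col, r2, spec$n_hap)
          if (length(unique(y)) == 2L) return(y)
        }
      }, integer(spec$n_hap))
    }
    cols <- cbind(seed_col, others)
    colnames(cols) <- ids
    geno_cols[[gi]] <- cols
    variants[[gi]] <- data.table(rsid = ids, chrom = "1", pos = pos,
                                 gene_id = g$gene_id, lead = c(TRUE,
                                 rep(FALSE, k - 1L)))
  }
  vtab <- rbindlist(variants)
  geno <- do.call(cbind, geno_cols)
  panel <- haplotype_panel(geno, chrom = vtab$chrom, pos = vtab$pos)
  ld <- ld_store_from_panel(panel, window = 1e6)

  # QTL records per (source, tissue, gene): planted sharing genes carry a
  # significant block signal in exactly m designated studies; other genes
  # are independently significant with the configured probability
  rec_parts <- list()
  truth_sig <- list()
  study_idx <- seq_len(nrow(studies))
  sharing_studies <- lapply(seq_len(spec$sharing_genes), function(i)
    sample(study_idx, m_plan[i]))
  names(sharing_studies) <- sharing_ids
  alleles <- c("A", "C", "G", "T")
  for (si in study_idx) {
    st <- studies[si]
    for (gi in seq_len(spec$n_genes)) {
      g <- genes[gi]
      vs <- vtab[gene_id == g$gene_id]
      is_sharing <- g$gene_id %in% sharing_ids
      planted_here <- is_sharing && si %in% sharing_studies[[g$gene_id]]
      present <- planted_here || runif(1) < spec$p_present
      if (!present) next
      sig <- if (is_sharing) planted_here else
        runif(1) < spec$frac_significant
      n_v <- nrow(vs)
      p <- exp(runif(n_v, log(thr * 1.01), log(1)))  # non-significant
      if (sig) {
        best_i <- if (planted_here) sample(n_v, 1L) else sample(n_v, 1L)
        p[best_i] <- exp(runif(1, log(1e-20), log(thr * 0.99)))
        # a second significant but weaker record now and then
        if (n_v > 1L && runif(1) < 0.3) {
          j <- sample(setdiff(seq_len(n_v), best_i), 1L)
          p[j] <- exp(runif(1, log(p[best_i]), log(thr * 0.99)))
        }
      }
      ea <- sample(alleles, n_v, replace = TRUE)
      rec_parts[[length(rec_parts) + 1L]] <- data.table(
        rsid = vs$rsid, chrom = vs$chrom, pos = vs$pos,
        gene = g$gene_id, tissue = st$tissue, p = p,
        beta = round(stats::rnorm(n_v, 0, 0.5), 3),
        ea = ea,
        nea = vapply(ea, function(a) sample(setdiff(alleles, a), 1L), ""),
        source = st$source)
      truth_sig[[length(truth_sig) + 1L]] <- data.table(
        rsid = vs$rsid, gene_id = g$gene_id, source = st$source,
        tissue = st$tissue, expect_sw = p <= thr)
    }
  }
  raw <- rbindlist(rec_parts)
  raw_by_source <- split(raw, raw$source)

  # raw tissue spellings differ by source to exercise normalization
  respell <- function(x, src) {
    if (src == "SRC1") tolower(x)
    else if (src == "SRC2") sub("-", " - ", x, fixed = TRUE)
    else x
  }
  tm <- default_tissue_map()
  for (src in names(raw_by_source)) {
    t0 <- raw_by_source[[src]]$tissue
    t1 <- respell(t0, src)
    ok <- t1 %in% names(tm) & tm[t1] == t0
    t1[!ok | is.na(ok)] <- t0[!ok | is.na(ok)]
    raw_by_source[[src]][, "tissue" := t1]
  }

  # GWAS catalog: a sample of planted variants plus gene-only entries
  gw_v <- sort(sample(vtab$rsid, max(2L, nrow(vtab) %/% 10L)))
  gw_g <- sort(sample(genes$symbol, max(2L, spec$n_genes %/% 5L)))
  gwas <- rbind(
    data.table(rsid = gw_v, gene = NA_character_,
               phenotype = "synthetic trait",
               accession = sprintf("GCST%06d", seq_along(gw_v))),
    data.table(rsid = NA_character_, gene = gw_g,
               phenotype = "synthetic trait",
               accession = sprintf("GCST9%05d", seq_along(gw_g))))

  gene_sets <- list(
    housekeeping = sharing_ids,
    top_expressed = sort(sample(genes$gene_id,
                                max(1L, spec$n_genes %/% 10L))))

  manifest_entries <- lapply(names(raw_by_source), function(src)
    manifest_entry(
      name = src, path = paste0("qtl_", src, ".tsv"), source = src,
      study = paste0(src, "-2020"),
      columns = list(rsid = "rsid", chrom = "chrom", pos = "pos",
                     gene = "gene", tissue = "tissue", p_value = "p",
                     beta = "beta", ea = "ea", nea = "nea"),
      significance_policy = "fwer_derived",
      n_variants = spec$n_variants_fwer, n_genes = spec$n_genes_fwer,
      alpha = spec$alpha))

  truth <- list(
    seed = spec$seed,
    fwer_threshold = thr,
    sharing = data.table(gene_id = sharing_ids, m = m_plan),
    blocks = truth_blocks,
    significance = rbindlist(truth_sig),
    enriched_set = "housekeeping",
    dist_meanlog = spec$dist_meanlog,
    dist_sdlog = spec$dist_sdlog)

  structure(list(spec = spec, genes = genes, gene_idx = gene_index(genes),
                 panel = panel, ld = ld,
                 tads_dt = tads_dt, variants = vtab,
                 records_raw = raw_by_source, gwas = gwas,
                 gene_sets = gene_sets, tissue_map = tm,
                 manifest_entries = manifest_entries, truth = truth),
            class = "fixture_bundle")
}

#' TAD `GRanges` of a bundle
#' @param bundle A `fixture_bundle`.
#' @return `GRanges` in internal coordinates.
#' @export
bundle_tads <- function(bundle) {
  GenomicRanges::GRanges(bundle$tads_dt$chrom,
                         IRanges::IRanges(bundle$tads_dt$start0 + 1L,
                                          bundle$tads_dt$end0))
}

#' Ingest a bundle straight from memory
#'
#' Convenience path used by tests and the analyses: writes nothing,
#' produces the same store as writing the bundle and re-reading it.
#'
#' @param bundle A `fixture_bundle`.
#' @return QTL record `data.table`.
#' @export
ingest_bundle <- function(bundle) {
  dir <- tempfile("bundle")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write_fixture_bundle(bundle, dir)
  manifest <- read_manifest(file.path(dir, "manifest.json"))
  genes <- read_genes(file.path(dir, "genes.tsv"))
  ingest_datasets(manifest, genes, bundle$tissue_map)
}

#' Write a fixture bundle to disk
#'
#' Emits the exact dialects the readers consume: per-source QTL TSVs, a
#' gene TSV, TAD BED (0-based half-open), a phased-genotype VCF, a
#' precomputed LD TSV, a GWAS Catalog TSV, gene-set lists, the tissue map,
#' a dataset manifest (JSON) and the ground-truth sidecar (JSON). Equal
#' seeds yield byte-identical bundles.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(name) { p <- file.path(dir, name); paths <<- c(paths, p); p }

  for (src in names(bundle$records_raw))
    fwrite(bundle$records_raw[[src]][, -"source"],
           w(paste0("qtl_", src, ".tsv")), sep = "\t", na = "")
  fwrite(bundle$genes, w("genes.tsv"), sep = "\t")
  fwrite(bundle$tads_dt[, .(chrom = paste0("chr", chrom), start0, end0)],
         w("tads.bed"), sep = "\t", col.names = FALSE)
  fwrite(bundle$gwas, w("gwas_catalog.tsv"), sep = "\t", na = "")
  fwrite(data.table(raw = names(bundle$tissue_map),
                    normalized = unname(bundle$tissue_map)),
         w("tissue_map.tsv"), sep = "\t")
  fwrite(unique(bundle$ld$pairs[variant_a < variant_b]),
         w("ld.tsv"), sep = "\t")
  for (nm in names(bundle$gene_sets))
    writeLines(bundle$gene_sets[[nm]], w(paste0("geneset_", nm, ".txt")))
  write_vcf(bundle$panel, w("panel.vcf"))
  jsonlite::write_json(
    lapply(bundle$manifest_entries, function(e) unclass(e)),
    w("manifest.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = bundle$truth$seed,
         fwer_threshold = bundle$truth$fwer_threshold,
         sharing = bundle$truth$sharing,
         blocks = bundle$truth$blocks,
         significance = bundle$truth$significance,
         enriched_set = bundle$truth$enriched_set,
         dist_meanlog = bundle$truth$dist_meanlog,
         dist_sdlog = bundle$truth$dist_sdlog),
    w("truth.json"), auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(paths)
}

# minimal VCFv4.2 writer for phased biallelic panels
write_vcf <- function(panel, path) {
  g <- panel$geno
  v <- panel$variants
  n_hap <- nrow(g)
  n_smp <- n_hap %/% 2L
  smp <- sprintf("S%04d", seq_len(n_smp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", smp), collapse = "\t")),
             con)
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    gt <- paste0(g[seq_len(n_smp), j], "|",
                 g[n_smp + seq_len(n_smp), j])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], "A", "G",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a gene-set list (one gene id per line)
#' @param path Text file.
#' @return Character vector.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Build the worked-example store
#'
#' An annotated in-memory store shaped like the coronary-artery-disease
#' locus walk-through: a single index SNP inside the boundaries of one
#' gene, with 31 eQTL records over 7 genes across tissue-specific studies,
#' of which the 14 records of the index gene are study-wide significant.
#' Used to exercise the query -> aggregate -> filter workflow against a
#' known census.
#'
#' @param seed Seed controlling the synthetic statistics.
#' @return List with `records` (annotated store), `gene_idx`, `ld`
#'   (empty `ld_store`), `tads`.
#' @export
use_case_store <- function(seed = 1L) {
  set.seed(seed)
  thr <- fwer_threshold()
  rsid <- "rs2306374"; chrom <- "3"; pos <- 138119952L
  g <- data.table(
    gene_id = sprintf("ENSG%08d", 1:7),
    symbol = c("MRAS", paste0("G", 2:7)),
    chrom = chrom,
    start = as.integer(c(pos - 10000L,
                         pos + cumsum(rep(300000L, 6)))),
    strand = "+", synonyms = "")
  g[, "end" := start + 50000L]
  tissues <- c("Artery-Aorta", "Artery-Tibial", "Heart-Atrial appendage",
               "Heart", "Whole blood", "Liver", "Monocytes")
  sources <- c("SRCA", "SRCB")
  grid <- CJ(source = sources, tissue = tissues)  # 14 studies
  # 14 significant records for the index gene, one per study
  mras <- data.table(grid, gene_id = g$gene_id[1L],
                     p = exp(runif(14, log(1e-20), log(thr * 0.9))))
  # 17 further records spread over the 6 remaining genes, not significant
  other_n <- c(3L, 3L, 3L, 3L, 3L, 2L)
  others <- rbindlist(lapply(1:6, function(i)
    data.table(grid[sample(.N, other_n[i])], gene_id = g$gene_id[i + 1L],
               p = exp(runif(other_n[i], log(thr * 10), log(0.1))))))
  rows <- rbind(mras, others)
  records <- data.table(
    variant_id = rsid, rsid = rsid, chrom = chrom, pos = pos,
    build = "hg19",
    gene_id = rows$gene_id,
    tissue = rows$tissue, source = rows$source,
    study = paste0(rows$source, "-2020"), qtl_type = "eQTL",
    p_value = rows$p, beta = round(stats::rnorm(nrow(rows), 0, 0.5), 3),
    ea = "C", nea = "T", dataset = rows$source)
  records <- g[, .(gene_id, symbol, gene_chrom = chrom,
                   gene_start = start, gene_end = end, gene_strand = strand)
               ][records, on = "gene_id"]
  setcolorder(records, intersect(qtl_record_columns(), names(records)))
  ld <- ld_store(data.table(variant_a = character(),
                            variant_b = character(), r2 = numeric(),
                            dprime = numeric()), universe = rsid)
  tads <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(pos - 400000L,
                                                  pos + 400000L))
  ann <- annotate_store(records, ld, tads)
  list(records = ann, gene_idx = gene_index(g), ld = ld, tads = tads)
}
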