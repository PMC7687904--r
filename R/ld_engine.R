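# Pairwise linkage disequilibrium from phased haplotypes, LD groups and
# proxy search. LD is computed by direct haplotype counting (phased input
# only; no EM): D = p_AB - p_A p_B, r^2 = D^2 / (p_A q_A p_B q_B),
# D' = |D| / D_max.

#' Read a phased haplotype panel from VCF
#'
#' Keeps biallelic variants with fully phased, non-missing genotypes and
#' splits each sample into two haplotypes. Alleles are coded 0 (REF) / 1
#' (ALT).
#'
#' @param path VCF file (plain or bgzipped) with phased `GT`.
#' @param samples Optional character vector restricting to a sample subset
#'   (e.g. one population); or a file with one sample id per line.
#' @return List of class `haplotype_panel`: `geno` (haplotypes x variants
#'   0/1 matrix, columns named by variant id), `variants` (data.table with
#'   `variant_id`, `rsid`, `chrom`, `pos`).
#' @export
read_haplotypes <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(vcf))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.null(samples)) {
    if (length(samples) == 1L && file.exists(samples))
      samples <- readLines(samples)
    keep <- colnames(gt) %in% samples
    if (!any(keep)) stop("no requested samples present in VCF")
    gt <- gt[, keep, drop = FALSE]
  }
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE)
  phased <- rowSums(is.na(gt) | !grepl("^[01]\\|[01]$", gt)) == 0L
  keep <- biallelic & phased
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep]
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  geno <- rbind(t(a1), t(a2))  # first haplotype of every sample, then second
  vid <- ifelse(!is.na(fix$ID) & nzchar(fix$ID), fix$ID,
                paste0(normalize_chrom(fix$CHROM), ":", fix$POS))
  colnames(geno) <- vid
  structure(list(geno = geno,
                 variants = data.table(variant_id = vid, rsid = fix$ID,
                                       chrom = normalize_chrom(fix$CHROM),
                                       pos = as.integer(fix$POS))),
            class = "haplotype_panel")
}

#' Construct a haplotype panel from a 0/1 matrix
#'
#' @param geno Haplotypes x variants 0/1 matrix with variant ids as column
#'   names.
#' @param chrom,pos Optional per-variant coordinates.
#' @return A `haplotype_panel`.
#' @export
haplotype_panel <- function(geno, chrom = NULL, pos = NULL) {
  stopifnot(is.matrix(geno), nrow(geno) >= 2L, all(geno %in% c(0L, 1L)))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("v", seq_len(ncol(geno)))
  structure(list(geno = geno,
                 variants = data.table(
                   variant_id = colnames(geno),
                   rsid = colnames(geno),
                   chrom = if (is.null(chrom)) "1" else chrom,
                   pos = if (is.null(pos)) seq_len(ncol(geno)) else
                     as.integer(pos))),
            class = "haplotype_panel")
}

#' Pairwise r-squared and D-prime between two variants
#'
#' Both variants must be polymorphic in the panel; LD is undefined for a
#' monomorphic variant and an error is raised (callers typically skip such
#' pairs). The statistics are symmetric in the arguments and invariant
#' under swapping allele labels at either locus.
#'
#' @param panel A `haplotype_panel`.
#' @param variant_a,variant_b Variant ids (column names of the panel).
#' @return Named numeric vector `c(r2 = , d_prime = )`, both in `[0, 1]`.
#' @export
ld_stats <- function(panel, variant_a, variant_b) {
  x <- panel$geno[, variant_a]
  y <- panel$geno[, variant_b]
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("LD undefined: monomorphic variant in panel")
  pab <- mean(x == 1L & y == 1L)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  dp <- if (dmax == 0) 0 else abs(D) / dmax
  c(r2 = min(r2, 1), d_prime = min(dp, 1))
}

#' Build an LD store from a haplotype panel
#'
#' Computes r-squared and D-prime for every variant pair within a genomic
#' window (monomorphic variants are skipped). The window bounds computation;
#' pairs farther apart are treated as unlinked.
#'
#' @param panel A `haplotype_panel`.
#' @param window Maximum pair distance in bp (default 1 Mb). `Inf` for all
#'   pairs.
#' @return An `ld_store`.
#' @export
ld_store_from_panel <- function(panel, window = 1e6) {
  g <- panel$geno
  v <- panel$variants
  poly <- colMeans(g) > 0 & colMeans(g) < 1
  ids <- v$variant_id[poly]
  pairs <- list()
  if (length(ids) >= 2L) {
    idx <- which(poly)
    cmb <- utils::combn(seq_along(idx), 2L)
    keep <- rep(TRUE, ncol(cmb))
    same_chr <- v$chrom[idx[cmb[1, ]]] == v$chrom[idx[cmb[2, ]]]
    dist_ok <- abs(v$pos[idx[cmb[1, ]]] - v$pos[idx[cmb[2, ]]]) <= window
    keep <- same_chr & dist_ok
    cmb <- cmb[, keep, drop = FALSE]
    if (ncol(cmb)) {
      stats <- vapply(seq_len(ncol(cmb)), function(k)
        ld_stats(panel, ids[cmb[1, k]], ids[cmb[2, k]]),
        c(r2 = 0, d_prime = 0))
      pairs <- data.table(variant_a = ids[cmb[1, ]],
                          variant_b = ids[cmb[2, ]],
                          r2 = stats["r2", ], dprime = stats["d_prime", ])
    }
  }
  if (!is.data.table(pairs)) pairs <- data.table(
    variant_a = character(), variant_b = character(),
    r2 = numeric(), dprime = numeric())
  ld_store(pairs, universe = v$variant_id)
}

#' Construct an LD store from a pairwise table
#'
#' @param pairs `data.table` with columns `variant_a`, `variant_b`, `r2`,
#'   `dprime`; each unordered pair listed once (symmetrized internally).
#' @param universe Optional full variant universe (variants with LD data
#'   plus isolated ones).
#' @return Object of class `ld_store`.
#' @export
ld_store <- function(pairs, universe = NULL) {
  pairs <- as.data.table(pairs)
  need <- c("variant_a", "variant_b", "r2", "dprime")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("LD table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(pairs) && (any(pairs$r2 < 0 | pairs$r2 > 1) ||
                      any(pairs$dprime < 0 | pairs$dprime > 1)))
    stop("r2 and dprime must lie in [0, 1]")
  sym <- rbind(pairs[, .(variant_a, variant_b, r2, dprime)],
               pairs[, .(variant_a = variant_b, variant_b = variant_a,
                         r2, dprime)])
  sym <- unique(sym, by = c("variant_a", "variant_b"))
  setkey(sym, variant_a)
  if (is.null(universe))
    universe <- unique(c(sym$variant_a, sym$variant_b))
  structure(list(pairs = sym, universe = unique(universe)),
            class = "ld_store")
}

#' Read a precomputed LD table
#'
#' @param path TSV with header `variant_a variant_b r2 dprime`.
#' @param universe Optional variant universe.
#' @return An `ld_store`.
#' @export
read_ld_table <- function(path, universe = NULL) {
  ld_store(fread(path, sep = "\t", header = TRUE), universe = universe)
}

#' @exportS3Method print ld_store
print.ld_store <- function(x, ...) {
  cat("<ld_store> ", nrow(x$pairs) / 2, " pairs over ",
      length(x$universe), " variants\n", sep = "")
  invisible(x)
}

#' LD group of a seed variant
#'
#' The LD group is the seed plus all variants with pairwise r-squared
#' strictly above the threshold against the seed (no transitive closure).
#' A seed absent from the LD store's universe forms a singleton group
#' flagged as lacking LD data.
#'
#' @param ld An `ld_store`.
#' @param seed Variant id.
#' @param r2_threshold Strict lower bound on r-squared (default 0.2).
#' @return List with `seed`, `members` (seed included), `threshold`,
#'   `no_ld_data` flag.
#' @export
build_ld_group <- function(ld, seed, r2_threshold = 0.2) {
  stopifnot(inherits(ld, "ld_store"))
  no_data <- !(seed %in% ld$universe)
  nb <- ld$pairs[.(seed)][r2 > r2_threshold & !is.na(r2), variant_b]
  list(seed = seed, members = unique(c(seed, nb)),
       threshold = r2_threshold, no_ld_data = no_data)
}

#' Proxy variants of a seed at an LD threshold
#'
#' Returns all variants whose r-squared (or D-prime) with the seed is at
#' least the threshold, sorted by the chosen metric descending. Proxy sets
#' are antitone in the threshold: raising it can only shrink the set.
#'
#' @param ld An `ld_store`.
#' @param seed Variant id (the index variant).
#' @param metric `"r2"` or `"dprime"`.
#' @param threshold Inclusive lower bound in `[0, 1]`.
#' @return `data.table` with `variant`, `r2`, `dprime`, `index_variant`.
#' @export
find_proxies <- function(ld, seed, metric = c("r2", "dprime"),
                         threshold = 0.8) {
  metric <- match.arg(metric)
  stopifnot(threshold >= 0, threshold <= 1)
  hits <- ld$pairs[.(seed)][!is.na(variant_b)]
  hits <- hits[hits[[metric]] >= threshold]
  out <- hits[, .(variant = variant_b, r2, dprime, index_variant = seed)]
  setorderv(out, c(metric, "variant"), order = c(-1L, 1L))
  out[]
}

#' Pairwise r-squared lookup
#'
#' @param ld An `ld_store`.
#' @param a,b Variant ids.
#' @param default Value for pairs with no LD data (default 0: treated as
#'   unlinked).
#' @return Numeric r-squared.
#' @export
ld_r2 <- function(ld, a, b, default = 0) {
  if (a == b) return(1)
  hit <- ld$pairs[.(a)][variant_b == b]
  if (nrow(hit) == 0L || is.na(hit$r2[1L])) default else hit$r2[1L]
}
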