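# Free-format query parsing, variant/gene resolution, proxy expansion,
# result assembly, filtering and haplotype-block aggregation.

RSID_PATTERN <- "^rs[0-9]+$"
CHRPOS_PATTERN <- "^(chr)?([0-9XYM]+|MT):([0-9]+)(:hg(19|38))?$"
SYMBOL_PATTERN <- "^[A-Z][A-Z0-9-]*$"

#' Parse free-format query terms
#'
#' Tokens may be separated by tabs, commas, semicolons, newlines, spaces
#' or a mixture of all. Each token is matched, in order, against the rsID
#' pattern (`rs` followed by digits), the chromosomal-position pattern
#' (`chr` prefix optional, build tag `:hg19`/`:hg38` optional, default
#' hg19) and gene identifier/symbol patterns (upper-case letters and
#' Arabic numerals, or any identifier present in the gene index).
#' Unmatched tokens become `unresolved` terms — reported, not fatal.
#'
#' @param text Query text.
#' @param genes Optional [gene_index()] used to resolve gene terms.
#' @param max_terms Maximum number of accepted tokens (default 50);
#'   exceeding it is an error citing the limit.
#' @return `data.table` with columns `raw`, `kind`
#'   (`variant`/`gene`/`unresolved`), `rsid`, `chrom`, `pos`, `build`,
#'   `gene_id`, `ambiguity` (semicolon-joined alternative gene ids).
#' @export
parse_terms <- function(text, genes = NULL, max_terms = 50L) {
  toks <- unlist(strsplit(paste(text, collapse = " "), "[,;[:space:]]+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) > max_terms)
    stop("query has ", length(toks), " terms; the maximum is ", max_terms)
  out <- data.table(raw = toks, kind = "unresolved",
                    rsid = NA_character_, chrom = NA_character_,
                    pos = NA_integer_, build = NA_character_,
                    gene_id = NA_character_, ambiguity = NA_character_)
  if (!nrow(out)) return(out)
  is_rs <- grepl(RSID_PATTERN, toks)
  out[is_rs, c("kind", "rsid") := list("variant", raw)]
  m <- regmatches(toks, regexec(CHRPOS_PATTERN, toks))
  is_cp <- !is_rs & lengths(m) > 0
  if (any(is_cp)) {
    parts <- do.call(rbind, m[is_cp])
    out[is_cp, c("kind", "chrom", "pos", "build") := list(
      "variant", parts[, 3], as.integer(parts[, 4]),
      ifelse(nzchar(parts[, 6]), paste0("hg", parts[, 6]), "hg19"))]
  }
  rest <- which(out$kind == "unresolved")
  if (length(rest) && !is.null(genes)) {
    res <- lapply(toks[rest], resolve_gene, genes = genes)
    ok <- !vapply(res, function(r) is.na(r$gene_id), logical(1))
    out[rest[ok], c("kind", "gene_id", "ambiguity") := list(
      "gene",
      vapply(res[ok], `[[`, "", "gene_id"),
      vapply(res[ok], function(r)
        paste(r$ambiguity, collapse = ";"), ""))]
  } else if (length(rest) && is.null(genes)) {
    looks_gene <- grepl(SYMBOL_PATTERN, toks[rest])
    out[rest[looks_gene], "kind" := "gene"]
  }
  out[]
}

#' Resolve a gene term against the gene index
#'
#' Exact-match priority: stable gene id, then primary symbol, then
#' synonym. A synonym shared by several genes resolves to the
#' lexicographically smallest gene id, with the alternatives recorded.
#'
#' @param term Gene term string.
#' @param genes A [gene_index()].
#' @return List with `gene_id` (NA when unresolved) and `ambiguity`
#'   (character vector of alternative gene ids).
#' @export
resolve_gene <- function(term, genes) {
  g <- genes$genes
  if (term %chin% g$gene_id)
    return(list(gene_id = term, ambiguity = character()))
  hits <- g$gene_id[g$symbol == term]
  if (!length(hits) && nrow(genes$synonyms))
    hits <- genes$synonyms$gene_id[genes$synonyms$synonym == term]
  hits <- sort(unique(hits))
  if (!length(hits)) return(list(gene_id = NA_character_,
                                 ambiguity = character()))
  list(gene_id = hits[1L], ambiguity = hits[-1L])
}

resolve_gene_vector <- function(labels, genes) {
  u <- unique(labels)
  map <- vapply(u, function(l) {
    if (is.na(l)) NA_character_ else resolve_gene(l, genes)$gene_id
  }, character(1))
  unname(map[match(labels, u)])
}

#' Run a query against an annotated store
#'
#' Variant terms return every record of the variant; with proxy options
#' set, records of proxy variants are added, each tagged with the index
#' variant and the proxy's r-squared / D-prime. A record reachable through
#' both the index variant and a proxy is reported once, through the
#' closest (highest-r-squared) route. Gene terms return every record of
#' the gene. Row order is query-term order, then P ascending; the result
#' is capped at `max_rows` with an explicit truncation flag.
#'
#' @param terms [parse_terms()] output (or query text, parsed on the fly).
#' @param records Annotated QTL record table.
#' @param ld Optional `ld_store` for proxy expansion.
#' @param proxy_metric `"r2"` or `"dprime"`; `NULL` disables expansion.
#' @param proxy_threshold Inclusive LD threshold for proxies.
#' @param genes Optional [gene_index()] (needed when `terms` is text).
#' @param max_rows Result cap (default 10000).
#' @return `data.table` of result rows: record columns plus `search_type`
#'   (`Variant`/`Gene`), `query_term`, `proxy_of`, `proxy_r2`,
#'   `proxy_dprime`; attribute `truncated` reports capping; attribute
#'   `diagnostics` lists unresolved terms.
#' @export
run_query <- function(terms, records, ld = NULL, proxy_metric = NULL,
                      proxy_threshold = 0.8, genes = NULL,
                      max_rows = 10000L) {
  if (is.character(terms)) terms <- parse_terms(terms, genes)
  unresolved <- terms$raw[terms$kind == "unresolved"]
  parts <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    t <- terms[i]
    if (t$kind == "variant") {
      hit <- if (!is.na(t$rsid)) records[rsid == t$rsid] else
        records[chrom == t$chrom & pos == t$pos]
      if (nrow(hit)) {
        hit <- copy(hit)
        hit[, c("search_type", "query_term", "proxy_of", "proxy_r2",
                "proxy_dprime") :=
              list("Variant", t$raw, NA_character_, NA_real_, NA_real_)]
      } else hit <- NULL
      prox <- NULL
      if (!is.null(proxy_metric) && !is.null(ld)) {
        seed <- if (!is.na(t$rsid)) t$rsid else paste0(t$chrom, ":", t$pos)
        px <- find_proxies(ld, seed, proxy_metric, proxy_threshold)
        px <- px[variant != seed]
        if (nrow(px)) {
          prox <- records[variant_id %in% px$variant]
          if (nrow(prox)) {
            prox <- copy(prox)
            prox <- px[, .(variant_id = variant, proxy_r2 = r2,
                           proxy_dprime = dprime)][prox, on = "variant_id"]
            prox[, c("search_type", "query_term", "proxy_of") :=
                   list("Variant", t$raw, seed)]
          } else prox <- NULL
        }
      }
      parts[[i]] <- rbindlist(list(hit, prox), use.names = TRUE,
                              fill = TRUE)
    } else if (t$kind == "gene") {
      hit <- records[gene_id == t$gene_id]
      if (nrow(hit)) {
        hit <- copy(hit)
        hit[, c("search_type", "query_term", "proxy_of", "proxy_r2",
                "proxy_dprime") :=
              list("Gene", t$raw, NA_character_, NA_real_, NA_real_)]
        parts[[i]] <- hit
      }
    }
  }
  out <- rbindlist(parts, use.names = TRUE, fill = TRUE)
  if (nrow(out) == 0L) {
    out <- records[0]
    out[, c("search_type", "query_term", "proxy_of", "proxy_r2",
            "proxy_dprime") :=
          list(character(), character(), character(), numeric(),
               numeric())]
  } else {
    # deduplicate a record reached via index and proxy: keep best route
    out[, "route_rank" := fifelse(is.na(proxy_of), 2, proxy_r2)]
    setorder(out, -route_rank)
    key <- paste(record_identity(out), out$query_term, sep = "\r")
    out <- out[!duplicated(key)]
    out[, "route_rank" := NULL]
    ord <- match(out$query_term, terms$raw)
    setorder(out[, "term_ord" := ord], term_ord, p_value)
    out[, "term_ord" := NULL]
  }
  truncated <- nrow(out) > max_rows
  if (truncated) out <- out[seq_len(max_rows)]
  setattr(out, "truncated", truncated)
  setattr(out, "diagnostics",
          if (length(unresolved))
            paste("unresolved terms:", paste(unresolved, collapse = ", "))
          else character())
  out[]
}

#' Filter result rows with column predicates
#'
#' Predicates are strings of the form `column <op> value` with `<op>` one
#' of `<`, `<=`, `>`, `>=`, `==`, `!=`, value-set membership
#' `column=a|b|c`, or flag containment `flags~token` (matching the
#' serialized flag tokens, e.g. `flags~is_sw_significant`). Predicates are
#' conjoined; row order is preserved. An unknown column is an error
#' listing the valid columns.
#'
#' @param rows Result rows from [run_query()] (or any record table).
#' @param predicates Character vector of predicate strings; empty vector
#'   is the identity.
#' @return Filtered `data.table`.
#' @export
filter_rows <- function(rows, predicates = character()) {
  keep <- rep(TRUE, nrow(rows))
  for (p in predicates) {
    if (grepl("~", p, fixed = TRUE)) {
      kv <- strsplit(p, "~", fixed = TRUE)[[1]]
      col <- trimws(kv[1]); tok <- trimws(kv[2])
      if (col == "flags") {
        keep <- keep & flag_column(rows, tok)
        next
      }
      stop("flag predicate only supported on 'flags'")
    }
    m <- regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*(<=|>=|==|!=|<|>|=)\\s*(.+)$",
                 p)
    mm <- regmatches(p, m)[[1]]
    if (!length(mm)) stop("cannot parse predicate: ", p)
    col <- mm[2]; op <- mm[3]; val <- trimws(mm[4])
    if (!col %in% names(rows))
      stop("unknown column '", col, "'; valid columns: ",
           paste(names(rows), collapse = ", "))
    x <- rows[[col]]
    if (op == "=" || (op == "==" && grepl("|", val, fixed = TRUE))) {
      set <- trimws(strsplit(val, "|", fixed = TRUE)[[1]])
      keep <- keep & (as.character(x) %in% set)
    } else {
      v <- if (is.numeric(x)) as.numeric(val) else val
      keep <- keep & !is.na(x) & switch(op,
        "<" = x < v, "<=" = x <= v, ">" = x > v, ">=" = x >= v,
        "==" = x == v, "!=" = x != v)
    }
  }
  rows[keep]
}

flag_column <- function(rows, token) {
  if (token %in% c("is_sw_significant", "is_best", "is_best_in_ld_group") &&
      token %in% names(rows))
    return(isTRUE_vec(rows[[token]]))
  if ("flags" %in% names(rows))
    return(vapply(strsplit(rows$flags, ";", fixed = TRUE),
                  function(f) token %in% f, logical(1)))
  stop("no flag information in rows for token ", token)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Aggregate result rows into a haplotype-block-centric view
#'
#' Rows are grouped by (index variant, gene), where records of proxy
#' variants collapse onto their index variant. Per group, tissues are
#' unioned and the best (minimum) P value reported. The aggregation
#' conserves records: the `n_merged` column sums to the number of input
#' rows.
#'
#' @param rows Result rows from [run_query()].
#' @return `data.table` with `index_variant`, `gene_id`, `symbol`,
#'   `tissues` (semicolon-joined, sorted), `best_p`, `n_merged`.
#' @export
aggregate_rows <- function(rows) {
  if (nrow(rows) == 0L)
    return(data.table(index_variant = character(), gene_id = character(),
                      symbol = character(), tissues = character(),
                      best_p = numeric(), n_merged = integer()))
  idx <- ifelse(is.na(rows$proxy_of), rows$variant_id, rows$proxy_of)
  out <- rows[, .(symbol = symbol[1L],
                  tissues = paste(sort(unique(tissue)), collapse = ";"),
                  best_p = min(p_value), n_merged = .N),
              by = .(index_variant = idx, gene_id)]
  setorder(out, index_variant, best_p)
  out[]
}
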