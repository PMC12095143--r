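# Hypergeometric over-representation analysis against a user-supplied
# gene-set collection (GMT). Self-contained stand-in for a GO annotation
# step: ontology-agnostic, no DAG handling or redundancy trimming.

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (names are pathway ids), or
#'   a data frame with columns `pathway_id`, `name` and a list-column
#'   `genes`.
#' @param names Optional character vector of human-readable pathway names
#'   (defaults to the ids).
#' @param universe Optional background gene universe; defaults to the union
#'   of all set members. Every set must be a subset of the universe.
#'
#' @return A `gene_set_collection` with elements `sets` (tibble
#'   `pathway_id`, `name`, `genes`) and `universe` (sorted character).
#' @export
#' @examples
#' gene_set_collection(list(p1 = c("TP53", "IL6"), p2 = c("IL6", "TNF")))
gene_set_collection <- function(sets, names = NULL, universe = NULL) {
  if (is.data.frame(sets)) {
    assert_columns(sets, c("pathway_id", "genes"), what = "gene sets")
    tbl <- tibble::tibble(
      pathway_id = as.character(sets$pathway_id),
      name = if ("name" %in% base::names(sets)) {
        as.character(sets$name)
      } else {
        as.character(sets$pathway_id)
      },
      genes = purrr::map(sets$genes, function(g) sort(unique(norm_symbols(g))))
    )
  } else {
    if (length(sets) == 0) abort_validation("empty gene-set collection")
    if (is.null(base::names(sets))) {
      abort_validation("gene sets must be a named list")
    }
    tbl <- tibble::tibble(
      pathway_id = base::names(sets),
      name = names %||% base::names(sets),
      genes = purrr::map(sets, function(g) sort(unique(norm_symbols(g))))
    )
  }
  if (nrow(tbl) == 0) abort_validation("empty gene-set collection")
  if (anyDuplicated(tbl$pathway_id) > 0) {
    abort_validation("duplicated pathway_id in gene-set collection")
  }
  all_genes <- sort(unique(unlist(tbl$genes)))
  universe <- if (is.null(universe)) {
    all_genes
  } else {
    sort(unique(norm_symbols(universe)))
  }
  if (length(universe) == 0) abort_validation("gene universe is empty")
  outside <- setdiff(all_genes, universe)
  if (length(outside) > 0) {
    abort_validation(sprintf(
      "gene set members outside the universe: %s",
      paste(head(outside, 5), collapse = ", ")
    ))
  }
  structure(list(sets = tbl, universe = universe),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection: %d sets over a universe of %d genes>\n",
    nrow(x$sets), length(x$universe)
  ))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @param universe Optional background universe (default: union of sets).
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_validation("empty gene-set collection")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3
  if (any(bad)) {
    abort_validation(
      "malformed GMT: every line needs id, description and >= 1 gene"
    )
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  descs <- vapply(fields, `[[`, character(1), 2)
  genes <- purrr::map(fields, function(f) f[-(1:2)])
  gene_set_collection(stats::setNames(genes, ids),
    names = descs, universe = universe
  )
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    collection$sets,
    function(pathway_id, name, genes) {
      paste(c(pathway_id, name, genes), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` that a random draw of `q` genes from
#' a universe of `N` genes, of which `m` belong to the pathway, contains at
#' least `k` pathway genes.
#'
#' @param k Observed overlap count.
#' @param q Query (drug target) set size.
#' @param m Pathway set size.
#' @param N Universe size.
#'
#' @return p-value in (0, 1].
#' @export
#' @examples
#' hypergeometric_p(4, 4, 5, 10) # 5 / 210
hypergeometric_p <- function(k, q, m, N) {
  vals <- c(k = k, q = q, m = m, N = N)
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0)) {
    abort_validation("k, q, m, N must be nonnegative integers")
  }
  if (k > min(q, m) || q > N || m > N) {
    abort_validation(
      "inconsistent counts: need 0 <= k <= min(q, m) and q, m <= N"
    )
  }
  stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
}

#' Pathway over-representation of a drug-target set
#'
#' Tests each pathway in the collection for over-representation of the
#' query genes with the exact hypergeometric upper tail, then keeps
#' pathways with `p < p_cutoff` and at least `min_genes` enriched (overlap)
#' genes. Raw p-values are used by default; set `adjust = "BH"` to filter
#' on Benjamini-Hochberg adjusted values instead. The returned pathway ids
#' constitute the pathway-level prediction set used by the DePy indicator.
#'
#' @param drug_targets Character vector of query gene symbols. Symbols
#'   outside the universe are dropped with a warning; an empty query yields
#'   an empty result.
#' @param collection A `gene_set_collection`.
#' @param p_cutoff Significance threshold on the (possibly adjusted)
#'   p-value; default 0.05.
#' @param min_genes Minimum overlap count; default 10. Small collections
#'   and fixtures need this lowered.
#' @param adjust `"none"` (default, raw p) or `"BH"`.
#'
#' @return Tibble with columns `pathway_id`, `name`, `overlap_count`,
#'   `p_value` (plus `p_adjust` when `adjust = "BH"`) and list-column
#'   `genes`, sorted by ascending p (ties broken by `pathway_id`).
#' @export
enrich <- function(drug_targets, collection, p_cutoff = 0.05,
                   min_genes = 10, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!inherits(collection, "gene_set_collection") ||
    nrow(collection$sets) == 0) {
    abort_validation("empty or invalid gene-set collection")
  }
  query <- sort(unique(norm_symbols(drug_targets)))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0) {
    rlang::warn(sprintf(
      "dropping %d query gene(s) outside the universe: %s",
      length(outside), paste(head(outside, 5), collapse = ", ")
    ))
    query <- setdiff(query, outside)
  }
  empty <- tibble::tibble(
    pathway_id = character(), name = character(),
    overlap_count = integer(), p_value = double(), genes = list()
  )
  if (length(query) == 0) {
    return(empty)
  }
  N <- length(collection$universe)
  q <- length(query)
  res <- purrr::pmap_dfr(
    collection$sets,
    function(pathway_id, name, genes) {
      overlap <- intersect(query, genes)
      tibble::tibble(
        pathway_id = pathway_id, name = name,
        overlap_count = length(overlap),
        p_value = hypergeometric_p(length(overlap), q, length(genes), N),
        genes = list(overlap)
      )
    }
  )
  if (adjust == "BH") {
    res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
    keep <- res$p_adjust < p_cutoff & res$overlap_count >= min_genes
  } else {
    keep <- res$p_value < p_cutoff & res$overlap_count >= min_genes
  }
  res <- res[keep, ]
  dplyr::arrange(res, .data$p_value, .data$pathway_id)
}

#' Write enrichment results as TSV
#'
#' @param results Tibble from [enrich()].
#' @param path Output path; the `genes` list-column is comma-joined.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$genes <- vapply(out$genes, paste, character(1), collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}
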