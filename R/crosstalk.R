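#' Build a crosstalk index at a hierarchy level
#'
#' Maps every gene to the set of pathways at the chosen level whose subtree
#' gene set contains it. Crosstalk — the sharing of gene products between
#' pathways — is then read directly off this membership map. The default
#' level is 2, the second ring of the hierarchy, where pathway families are
#' broad enough to share components but still distinct.
#'
#' @param h A `pathway_hierarchy`.
#' @param level Hierarchy depth at which pathways are compared (roots are 1).
#' @return A `crosstalk_index`: a tibble with columns `symbol` and
#'   `pathway_id` (one row per membership), with the level stored as an
#'   attribute.
#' @export
crosstalk_index <- function(h, level = 2L) {
  if (!is.numeric(level) || length(level) != 1L || level < 1) {
    value_abort("level must be a single integer >= 1")
  }
  ids <- nodes_at_depth(h, level)
  membership <- tibble(
    pathway_id = rep(ids, vapply(ids, function(i) length(subtree_genes(h, i)),
                                 integer(1))),
    symbol = unlist(lapply(ids, function(i) subtree_genes(h, i)),
                    use.names = FALSE) %||% character()
  )[, c("symbol", "pathway_id")]
  structure(membership, class = c("crosstalk_index", class(membership)),
            level = as.integer(level))
}

#' Cross-talking gene products
#'
#' The genes belonging to two or more pathways at the index's level.
#'
#' @param idx A `crosstalk_index`.
#' @return Sorted character vector of symbols.
#' @export
crosstalk_genes <- function(idx) {
  counts <- table(idx$symbol)
  sort(names(counts)[counts >= 2L])
}

#' Pathway-pair crosstalk edges
#'
#' One edge per unordered pair of same-level pathways sharing at least one
#' gene, with the shared genes and their count. Edges are canonically ordered
#' (`pathway_a < pathway_b` lexicographically, rows sorted by the pair), so
#' the edge set is symmetric by construction.
#'
#' @param idx A `crosstalk_index`.
#' @return A tibble with columns `pathway_a`, `pathway_b`, `n_shared`, and
#'   `shared_genes` (list column of sorted symbols).
#' @export
crosstalk_edges <- function(idx) {
  empty <- tibble(pathway_a = character(), pathway_b = character(),
                  n_shared = integer(), shared_genes = list())
  if (nrow(idx) == 0L) return(empty)
  pairs <- inner_join(as_tibble(idx), as_tibble(idx), by = "symbol",
                      relationship = "many-to-many") |>
    filter(.data$pathway_id.x < .data$pathway_id.y)
  if (nrow(pairs) == 0L) return(empty)
  pairs |>
    group_by(pathway_a = .data$pathway_id.x, pathway_b = .data$pathway_id.y) |>
    summarise(n_shared = dplyr::n_distinct(.data$symbol),
              shared_genes = list(sort(unique(.data$symbol))),
              .groups = "drop") |>
    arrange(.data$pathway_a, .data$pathway_b)
}

#' Number of cross-talking pathways influenced by a gene
#'
#' A gene present in only one pathway influences no crosstalk, so its count
#' is 0; a gene in k >= 2 pathways influences all k.
#'
#' @param idx A `crosstalk_index`.
#' @param symbol A gene symbol.
#' @return Integer count.
#' @export
crosstalk_count <- function(idx, symbol) {
  k <- sum(idx$symbol == canonical_symbol(symbol))
  if (k >= 2L) as.integer(k) else 0L
}

#' Pathways highlighted for a cross-talking gene
#'
#' The pathway set a viewer would highlight when selecting a gene in the
#' crosstalk table: the gene's full membership set when it is cross-talking,
#' empty otherwise.
#'
#' @inheritParams crosstalk_count
#' @return Character vector of pathway ids.
#' @export
highlight_targets <- function(idx, symbol) {
  sym <- canonical_symbol(symbol)
  ids <- sort(unique(idx$pathway_id[idx$symbol == sym]))
  if (length(ids) >= 2L) ids else character()
}

#' @method glance crosstalk_index
#' @export
glance.crosstalk_index <- function(x, ...) {
  edges <- crosstalk_edges(x)
  tibble(
    level = attr(x, "level"),
    n_pathways = length(unique(x$pathway_id)),
    n_genes = length(unique(x$symbol)),
    n_crosstalk_genes = length(crosstalk_genes(x)),
    n_edges = nrow(edges)
  )
}

#' Write a crosstalk report
#'
#' Columns: pathway_a, pathway_b, n_shared, semicolon-joined shared symbols.
#'
#' @param edges A tibble from [crosstalk_edges()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_crosstalk <- function(edges, path) {
  out <- edges |>
    mutate(shared_genes = map_chr(.data$shared_genes, paste, collapse = ";"))
  readr::write_tsv(out, path)
  invisible(path)
}
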