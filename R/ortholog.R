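#' Parse an ortholog map
#'
#' Two-column TSV: reference gene symbol, target gene symbol. Symbols are
#' canonicalized to upper case and duplicate pairs collapsed; many-to-many
#' mappings are allowed.
#'
#' @inheritParams parse_relations
#' @param reference,target Species names recorded on the map.
#' @return An `ortholog_map`: a tibble with columns `reference` and `target`
#'   plus `species` attributes.
#' @examples
#' parse_ortholog_map("TP53\tTp53g", reference = "human", target = "chicken")
#' @export
parse_ortholog_map <- function(x, reference = "reference", target = "target") {
  lines <- as_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    m <- tibble(reference = character(), target = character())
  } else {
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2L |
                   vapply(fields, function(f) any(!nzchar(trimws(f))), logical(1)))
    if (length(bad) > 0L) {
      parse_abort("ortholog map line must have exactly 2 non-empty tab-separated fields",
                  line = idx[bad[1]])
    }
    m <- distinct(tibble(
      reference = canonical_symbol(vapply(fields, `[[`, "", 1L)),
      target = canonical_symbol(vapply(fields, `[[`, "", 2L))
    ))
  }
  structure(m, class = c("ortholog_map", class(m)),
            species_reference = reference, species_target = target)
}

#' Reference genes covered by an ortholog map
#'
#' @param m An `ortholog_map`.
#' @return Sorted character vector of distinct reference symbols.
#' @export
reference_genes <- function(m) sort(unique(m$reference))

#' Classify a pathway's ortholog status
#'
#' A pathway is `COMPLETE` when every one of its genes has an ortholog in the
#' target species, `PARTIAL` when only some do, and `EMPTY` when none do.
#' Presence is evaluated on the reference side: a gene counts as orthologous
#' when it appears as a reference gene in the map, regardless of how many
#' target genes it maps to. A gene-less pathway classifies as `EMPTY` (the
#' projection carries a `geneless` flag to keep the degenerate case visible).
#'
#' @param genes Character vector of gene symbols (a pathway's gene set).
#' @param m An `ortholog_map`.
#' @return One of `"COMPLETE"`, `"PARTIAL"`, `"EMPTY"`.
#' @export
classify_orthology <- function(genes, m) {
  genes <- unique(canonical_symbol(genes))
  covered <- sum(genes %in% reference_genes(m))
  if (length(genes) > 0L && covered == length(genes)) "COMPLETE"
  else if (covered == 0L) "EMPTY"
  else "PARTIAL"
}

ortholog_status_levels <- c("COMPLETE", "PARTIAL", "EMPTY")

#' Project a hierarchy onto a target species
#'
#' Classifies every pathway as complete/partial/empty against an ortholog map
#' and counts its subtree genes and the orthologous subset.
#'
#' @param h A `pathway_hierarchy`.
#' @param m An `ortholog_map`.
#' @return An `ortholog_projection` tibble, one row per pathway in layout
#'   order: `pathway_id`, `name`, `depth`, `n_genes`, `n_ortho`, `status`
#'   (factor), `geneless`. The map's reference-gene set is attached as the
#'   `ref_genes` attribute for downstream expression matching.
#' @export
project_orthology <- function(h, m) {
  refs <- reference_genes(m)
  res <- h$nodes |>
    mutate(
      genes_set = map(.data$pathway_id, function(id) subtree_genes(h, id)),
      n_genes = lengths(.data$genes_set),
      n_ortho = map_int(.data$genes_set, function(g) sum(g %in% refs)),
      status = factor(
        ifelse(.data$n_genes > 0L & .data$n_ortho == .data$n_genes, "COMPLETE",
               ifelse(.data$n_ortho == 0L, "EMPTY", "PARTIAL")),
        levels = ortholog_status_levels),
      geneless = .data$n_genes == 0L
    ) |>
    select("pathway_id", "name", "depth", "n_genes", "n_ortho", "status",
           "geneless")
  attr(res, "ref_genes") <- refs
  class(res) <- c("ortholog_projection", class(res))
  res
}

#' One-row summary of an ortholog projection
#'
#' @param x An `ortholog_projection`.
#' @param ... Unused.
#' @return A one-row tibble with pathway counts per status and the overall
#'   orthologous-gene fraction.
#' @method glance ortholog_projection
#' @export
glance.ortholog_projection <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_complete = sum(x$status == "COMPLETE"),
    n_partial = sum(x$status == "PARTIAL"),
    n_empty = sum(x$status == "EMPTY"),
    n_geneless = sum(x$geneless),
    frac_ortho = if (sum(x$n_genes) > 0) {
      sum(x$n_ortho[x$depth == 1]) / sum(x$n_genes[x$depth == 1])
    } else NA_real_
  )
}

# number of leaf sub-pathways under `pathway_id` whose gene set contains the
# gene; the stand-in for "number of gene products in the pathway"
n_products <- function(h, pathway_id, symbol) {
  ids <- c(pathway_id, descendant_ids(h, pathway_id))
  leaves <- ids[vapply(ids, function(i) length(h$children[[i]] %||% character()) == 0L,
                       logical(1))]
  sym <- canonical_symbol(symbol)
  sum(vapply(leaves, function(l) sym %in% h$genes$symbol[h$genes$pathway_id == l],
             logical(1)))
}

#' Parse a rate-limiting annotation
#'
#' Two-column TSV: gene symbol, 0/1 flag. Rate-limiting status is an input
#' annotation, not computed.
#'
#' @inheritParams parse_relations
#' @return A tibble with columns `symbol` and `rate_limiting` (logical).
#' @export
parse_rate_limiting <- function(x) {
  lines <- as_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(symbol = character(), rate_limiting = logical()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L |
                 !vapply(fields, function(f) trimws(f[2]) %in% c("0", "1"), logical(1)))
  if (length(bad) > 0L) {
    parse_abort("rate-limiting line must be 'symbol<TAB>0|1'", line = idx[bad[1]])
  }
  distinct(tibble(
    symbol = canonical_symbol(vapply(fields, `[[`, "", 1L)),
    rate_limiting = vapply(fields, function(f) trimws(f[2]) == "1", logical(1))
  ))
}

#' Ortholog table for one pathway
#'
#' One row per orthologous gene of the pathway: the gene symbol, the number
#' of gene products in the pathway (leaf sub-pathways carrying the gene), the
#' number of cross-talking pathways influenced by the gene, and its
#' rate-limiting status (`FALSE` when the gene is absent from the
#' annotation).
#'
#' @param h A `pathway_hierarchy`.
#' @param pathway_id A single pathway id.
#' @param m An `ortholog_map`.
#' @param idx A `crosstalk_index` (see [crosstalk_index()]).
#' @param rate_limiting Optional tibble from [parse_rate_limiting()].
#' @return A tibble with columns `symbol`, `n_products`,
#'   `n_crosstalk_pathways`, `rate_limiting`, sorted by symbol.
#' @export
ortholog_table <- function(h, pathway_id, m, idx = NULL,
                           rate_limiting = NULL) {
  check_pathway_id(h, pathway_id)
  genes <- intersect(subtree_genes(h, pathway_id), reference_genes(m))
  if (length(genes) == 0L) {
    return(tibble(symbol = character(), n_products = integer(),
                  n_crosstalk_pathways = integer(), rate_limiting = logical()))
  }
  rl <- rate_limiting %||% tibble(symbol = character(), rate_limiting = logical())
  tibble(
    symbol = genes,
    n_products = map_int(genes, function(g) n_products(h, pathway_id, g)),
    n_crosstalk_pathways = if (is.null(idx)) 0L else
      map_int(genes, function(g) crosstalk_count(idx, g)),
    rate_limiting = genes %in% rl$symbol[rl$rate_limiting]
  )
}

#' Stable sort of a gene/ortholog table
#'
#' Reorders table rows by one column, keeping the prior order on ties (a
#' stable sort, as repeated header clicks would). Character columns compare
#' case-insensitively.
#'
#' @param rows A tibble (e.g. from [ortholog_table()] or [gene_table()]).
#' @param column Column name to sort by.
#' @param descending Sort direction.
#' @return The reordered tibble.
#' @export
sort_table <- function(rows, column, descending = FALSE) {
  if (!column %in% names(rows)) {
    value_abort(sprintf("unknown column '%s'", column))
  }
  key <- rows[[column]]
  if (is.character(key)) key <- toupper(key)
  rows[order(key, decreasing = descending, method = "radix"), , drop = FALSE]
}

#' Write a projection report
#'
#' @param proj An `ortholog_projection`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path) {
  readr::write_tsv(as_tibble(proj)[, c("pathway_id", "name", "depth",
                                       "n_genes", "n_ortho", "status")], path)
  invisible(path)
}
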