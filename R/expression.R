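#' Read a gene expression table
#'
#' TSV with a header and columns `entrez`, `symbol`, `log2_ratio`. The ratio
#' is expected to be log2-transformed already; set `linear_ratio = TRUE` to
#' apply log2 on load for tables of linear fold changes. Rows with a missing
#' or non-finite ratio are dropped with a warning (the drop count is kept in
#' the `n_dropped` attribute). Duplicate records for one gene (Entrez id when
#' present, otherwise canonical symbol) keep the record with the largest
#' absolute ratio, again with a warning.
#'
#' @inheritParams parse_relations
#' @param linear_ratio Apply `log2()` to the ratio column on load.
#' @return A tibble with columns `entrez` (integer, `NA` when blank),
#'   `symbol` (canonical), `log2_ratio`.
#' @export
parse_expression <- function(x, linear_ratio = FALSE) {
  lines <- as_lines(x)
  if (length(lines) == 0L) parse_abort("empty expression table")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  header <- tolower(trimws(header))
  required <- c("entrez", "symbol", "log2_ratio")
  missing_col <- setdiff(required, header)
  if (length(missing_col) > 0L) {
    parse_abort(sprintf("missing required column '%s' in expression header",
                        missing_col[1]))
  }
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(tab) <- tolower(names(tab))
  ratio <- suppressWarnings(as.numeric(tab$log2_ratio))
  ok <- !is.na(ratio) & is.finite(ratio)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warn(sprintf("dropped %d expression record(s) with missing or non-finite ratio",
                 n_dropped), class = "pathburst_dropped_records")
  }
  rec <- tibble(
    entrez = suppressWarnings(as.integer(tab$entrez[ok])),
    symbol = canonical_symbol(tab$symbol[ok]),
    log2_ratio = if (linear_ratio) log2(ratio[ok]) else ratio[ok]
  )
  key <- ifelse(is.na(rec$entrez), paste0("S:", rec$symbol),
                paste0("E:", rec$entrez))
  if (anyDuplicated(key)) {
    warn(sprintf("%d duplicate gene record(s); keeping the largest |log2_ratio|",
                 sum(duplicated(key))), class = "pathburst_duplicate_records")
    o <- order(-abs(rec$log2_ratio))
    rec <- rec[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
    rec <- arrange(rec, .data$symbol)
  }
  attr(rec, "n_dropped") <- n_dropped
  rec
}

#' Classify differential expression
#'
#' Up when the log2 ratio is at or above the cutoff, down at or below the
#' negative cutoff (the boundary counts as differentially expressed),
#' unchanged otherwise.
#'
#' @param log2_ratio Numeric vector of log2 expression ratios.
#' @param cutoff Positive threshold on `|log2_ratio|`; the default 1
#'   corresponds to a two-fold change.
#' @return Factor with levels `UP`, `DOWN`, `UNCHANGED`.
#' @export
classify_de <- function(log2_ratio, cutoff = 1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    value_abort("cutoff must be a single positive number")
  }
  factor(ifelse(log2_ratio >= cutoff, "UP",
                ifelse(log2_ratio <= -cutoff, "DOWN", "UNCHANGED")),
         levels = c("UP", "DOWN", "UNCHANGED"))
}

# match expression records to a set of pathway gene symbols
match_records <- function(records, genes) {
  records[records$symbol %in% genes, , drop = FALSE]
}

#' Summarize expression for one pathway
#'
#' Matches expression records to the pathway's orthologous gene set, counts
#' up- and down-regulated genes at the cutoff, and computes the DE ratio:
#' (up + down) / total orthologous genes (0 when the pathway has no
#' orthologous genes). Records matching pathway genes that are not
#' orthologous are counted separately as `n_unmapped`.
#'
#' @param h A `pathway_hierarchy`.
#' @param pathway_id A single pathway id.
#' @param records Expression tibble from [parse_expression()].
#' @param proj An `ortholog_projection` for the same hierarchy.
#' @param cutoff Positive DE threshold on `|log2_ratio|`.
#' @return A one-row tibble: `pathway_id`, `n_up`, `n_down`, `n_ortho`,
#'   `de_ratio`, `n_unmapped`.
#' @export
summarize_pathway <- function(h, pathway_id, records, proj, cutoff = 1) {
  check_pathway_id(h, pathway_id)
  refs <- attr(proj, "ref_genes")
  genes <- subtree_genes(h, pathway_id)
  ortho <- intersect(genes, refs)
  matched <- match_records(records, ortho)
  status <- classify_de(matched$log2_ratio, cutoff)
  n_up <- sum(status == "UP")
  n_down <- sum(status == "DOWN")
  n_ortho <- length(ortho)
  tibble(
    pathway_id = pathway_id,
    n_up = n_up,
    n_down = n_down,
    n_ortho = n_ortho,
    de_ratio = if (n_ortho > 0L) (n_up + n_down) / n_ortho else 0,
    n_unmapped = nrow(match_records(records, setdiff(genes, refs)))
  )
}

#' Summarize expression for every pathway
#'
#' @inheritParams summarize_pathway
#' @return A `pathway_expression_summary` tibble, one row per pathway in
#'   layout order, columns as in [summarize_pathway()] plus `name` and
#'   `depth`.
#' @export
summarize_expression <- function(h, records, proj, cutoff = 1) {
  rows <- bind_rows(lapply(h$nodes$pathway_id, function(id) {
    summarize_pathway(h, id, records, proj, cutoff)
  }))
  res <- left_join(h$nodes[, c("pathway_id", "name", "depth")], rows,
                   by = "pathway_id")
  attr(res, "cutoff") <- cutoff
  class(res) <- c("pathway_expression_summary", class(res))
  res
}

#' @method glance pathway_expression_summary
#' @export
glance.pathway_expression_summary <- function(x, ...) {
  tibble(
    cutoff = attr(x, "cutoff"),
    n_pathways = nrow(x),
    n_de_pathways = sum(x$n_up + x$n_down > 0),
    max_de_ratio = if (nrow(x)) max(x$de_ratio) else NA_real_,
    total_up = sum(x$n_up),
    total_down = sum(x$n_down)
  )
}

#' Per-gene expression table for one pathway
#'
#' One row per expression record matched to an orthologous gene of the
#' pathway, joining the regulation status, the number of gene products in
#' the pathway, the crosstalk count and the rate-limiting flag — the columns
#' a viewer would list when querying a pathway.
#'
#' @inheritParams summarize_pathway
#' @param idx Optional `crosstalk_index`.
#' @param rate_limiting Optional tibble from [parse_rate_limiting()].
#' @return A tibble with columns `entrez`, `symbol`, `n_products`,
#'   `log2_ratio`, `status`, `n_crosstalk_pathways`, `rate_limiting`.
#' @export
gene_table <- function(h, pathway_id, records, proj, idx = NULL,
                       rate_limiting = NULL, cutoff = 1) {
  check_pathway_id(h, pathway_id)
  refs <- attr(proj, "ref_genes")
  ortho <- intersect(subtree_genes(h, pathway_id), refs)
  matched <- match_records(records, ortho)
  rl <- rate_limiting %||% tibble(symbol = character(), rate_limiting = logical())
  tibble(
    entrez = matched$entrez,
    symbol = matched$symbol,
    n_products = map_int(matched$symbol,
                         function(g) n_products(h, pathway_id, g)),
    log2_ratio = matched$log2_ratio,
    status = classify_de(matched$log2_ratio, cutoff),
    n_crosstalk_pathways = if (is.null(idx)) 0L else
      map_int(matched$symbol, function(g) crosstalk_count(idx, g)),
    rate_limiting = matched$symbol %in% rl$symbol[rl$rate_limiting]
  ) |> arrange(toupper(.data$symbol))
}

#' Write an expression summary report
#'
#' @param summary A `pathway_expression_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  readr::write_tsv(as_tibble(summary)[, c("pathway_id", "n_up", "n_down",
                                          "n_ortho", "de_ratio")], path)
  invisible(path)
}
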