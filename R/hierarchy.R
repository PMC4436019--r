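#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
#' @importFrom purrr map map_int map_chr
NULL

# Resolve `x` into a character vector of text lines. Accepts a single file
# path or a character vector of lines (possibly one string with embedded
# newlines). CRLF is tolerated everywhere.
as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  sub("\r$", "", as.character(x))
}

canonical_symbol <- function(x) toupper(trimws(x))

parse_abort <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  abort(msg, class = "pathburst_parse_error")
}

structure_abort <- function(msg) abort(msg, class = "pathburst_structure_error")
key_abort <- function(msg) abort(msg, class = "pathburst_key_error")
value_abort <- function(msg) abort(msg, class = "pathburst_value_error")

#' Parse pathway parent-child relations
#'
#' Reads the two-column tab-separated relations dialect used by Reactome-style
#' hierarchy exports: one `parent<TAB>child` pair per line, `#` comment lines
#' and blank lines skipped. Duplicate edges are collapsed; a child listed under
#' two distinct parents violates the forest property and is rejected.
#'
#' @param x A file path, a single string with embedded newlines, or a
#'   character vector of lines.
#' @return A tibble with columns `parent` and `child`, in file order.
#' @examples
#' parse_relations("P1\tP2\nP1\tP3")
#' @export
parse_relations <- function(x) {
  lines <- as_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(parent = character(), child = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L | vapply(fields, function(f) any(!nzchar(trimws(f))), logical(1)))
  if (length(bad) > 0L) {
    parse_abort("relations line must have exactly 2 non-empty tab-separated fields",
                line = idx[bad[1]])
  }
  edges <- tibble(
    parent = trimws(vapply(fields, `[[`, "", 1L)),
    child  = trimws(vapply(fields, `[[`, "", 2L))
  )
  edges <- distinct(edges)
  dup <- edges$child[duplicated(edges$child)]
  if (length(dup) > 0L) {
    structure_abort(sprintf(
      "pathway '%s' has more than one parent; the hierarchy must be a forest",
      dup[1]))
  }
  edges
}

#' Parse gene sets in GMT format
#'
#' One gene set per line: set id, description, then zero or more gene symbols,
#' tab-separated. Symbols are canonicalized to upper case and deduplicated
#' within a set.
#'
#' @inheritParams parse_relations
#' @return A tibble with columns `pathway_id`, `description`, and `genes`
#'   (a list column of character vectors of canonical symbols).
#' @examples
#' parse_gmt("P2\tapoptosis\tTp53\tMYC")
#' @export
parse_gmt <- function(x) {
  lines <- as_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(pathway_id = character(), description = character(),
                  genes = list()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    parse_abort("GMT line must have at least 2 tab-separated fields (id, description)",
                line = idx[bad[1]])
  }
  tibble(
    pathway_id = trimws(vapply(fields, `[[`, "", 1L)),
    description = trimws(vapply(fields, `[[`, "", 2L)),
    genes = map(fields, function(f) {
      g <- canonical_symbol(f[-(1:2)])
      unique(g[nzchar(g)])
    })
  )
}

#' Build a pathway hierarchy from relations and gene sets
#'
#' Assembles the rooted forest of pathways. Every id appearing in `edges` or
#' `gene_sets` becomes a node; ids present only in `gene_sets` become roots.
#' Roots are ordered lexicographically, and each node's children are kept in
#' lexicographic order, which fixes the deterministic layout order used by all
#' downstream modules.
#'
#' @param edges A tibble with `parent`/`child` columns (as from
#'   [parse_relations()]), or `NULL` for an edge-less forest.
#' @param gene_sets A tibble as from [parse_gmt()], or `NULL`.
#' @return An object of class `pathway_hierarchy`.
#' @examples
#' h <- build_hierarchy(parse_relations("P1\tP2"), parse_gmt("P2\tleaf\tTP53"))
#' @export
build_hierarchy <- function(edges = NULL, gene_sets = NULL) {
  if (is.null(edges)) edges <- tibble(parent = character(), child = character())
  edges <- as_tibble(edges)
  stopifnot(all(c("parent", "child") %in% names(edges)))
  edges <- distinct(edges, .data$parent, .data$child)
  dup <- edges$child[duplicated(edges$child)]
  if (length(dup) > 0L) {
    structure_abort(sprintf(
      "pathway '%s' has more than one parent; the hierarchy must be a forest",
      dup[1]))
  }
  if (is.null(gene_sets)) {
    gene_sets <- tibble(pathway_id = character(), description = character(),
                        genes = list())
  }

  ids <- sort(unique(c(edges$parent, edges$child, gene_sets$pathway_id)))
  parent_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  parent_of[edges$child] <- edges$parent

  # cycle check: walk each node's parent chain
  state <- stats::setNames(integer(length(ids)), ids) # 0 unseen, 1 active, 2 done
  for (id in ids) {
    if (state[[id]] != 0L) next
    chain <- character()
    cur <- id
    while (!is.na(cur)) {
      if (state[[cur]] == 1L) {
        cyc <- chain[which(chain == cur):length(chain)]
        structure_abort(sprintf("cycle detected among pathways: %s",
                                paste(c(cyc, cur), collapse = " -> ")))
      }
      if (state[[cur]] == 2L) break
      state[[cur]] <- 1L
      chain <- c(chain, cur)
      cur <- parent_of[[cur]]
    }
    state[chain] <- 2L
  }

  roots <- ids[is.na(parent_of[ids])]
  children <- split(edges$child, edges$parent)
  children <- map(children, sort)

  # depth (roots are depth 1) and DFS preorder layout index
  depth <- stats::setNames(integer(length(ids)), ids)
  ord <- stats::setNames(integer(length(ids)), ids)
  counter <- 0L
  stack <- rev(roots)
  depth[roots] <- 1L
  while (length(stack) > 0L) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    counter <- counter + 1L
    ord[[cur]] <- counter
    kids <- children[[cur]]
    if (!is.null(kids) && length(kids) > 0L) {
      depth[kids] <- depth[[cur]] + 1L
      stack <- c(stack, rev(kids))
    }
  }

  name_of <- stats::setNames(ids, ids)
  if (nrow(gene_sets) > 0L) {
    has_desc <- nzchar(gene_sets$description)
    name_of[gene_sets$pathway_id[has_desc]] <- gene_sets$description[has_desc]
  }

  genes_long <- tibble(
    pathway_id = rep(gene_sets$pathway_id, lengths(gene_sets$genes)),
    symbol = unlist(gene_sets$genes, use.names = FALSE) %||% character()
  )
  genes_long <- distinct(genes_long)

  nodes <- tibble(
    pathway_id = ids,
    name = unname(name_of[ids]),
    parent_id = unname(parent_of[ids]),
    depth = unname(depth[ids]),
    layout_order = unname(ord[ids])
  ) |> arrange(.data$layout_order)

  structure(
    list(nodes = nodes, genes = genes_long, roots = roots, children = children),
    class = "pathway_hierarchy"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_pathway_id <- function(h, pathway_id) {
  if (length(pathway_id) != 1L || !pathway_id %in% h$nodes$pathway_id) {
    key_abort(sprintf("unknown pathway id '%s'", paste(pathway_id, collapse = ",")))
  }
  invisible(pathway_id)
}

# all descendant ids of `pathway_id` (excluding itself), iterative
descendant_ids <- function(h, pathway_id) {
  out <- character()
  stack <- h$children[[pathway_id]] %||% character()
  while (length(stack) > 0L) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    stack <- c(stack, h$children[[cur]] %||% character())
  }
  out
}

#' Gene complement of a pathway subtree
#'
#' The gene set of a pathway is the union of the direct gene memberships of
#' the node and all of its descendant sub-pathways.
#'
#' @param h A `pathway_hierarchy`.
#' @param pathway_id A single pathway id.
#' @return A sorted character vector of canonical gene symbols.
#' @export
subtree_genes <- function(h, pathway_id) {
  check_pathway_id(h, pathway_id)
  ids <- c(pathway_id, descendant_ids(h, pathway_id))
  sort(unique(h$genes$symbol[h$genes$pathway_id %in% ids]))
}

#' Pathways at a hierarchy depth
#'
#' Roots are depth 1 ("level one"); depth 2 is the second
#' ring of the sunburst. Results are in layout order (depth-first preorder
#' with lexicographic siblings).
#'
#' @param h A `pathway_hierarchy`.
#' @param depth Integer depth, >= 1.
#' @return Character vector of pathway ids (empty beyond the tree height).
#' @export
nodes_at_depth <- function(h, depth) {
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    value_abort("depth must be a single integer >= 1")
  }
  n <- h$nodes[h$nodes$depth == as.integer(depth), , drop = FALSE]
  n$pathway_id[order(n$layout_order)]
}

#' Number of leaf pathways under a node
#'
#' A leaf counts itself, so the result is always >= 1. Used as the angular
#' weight in the sunburst layout.
#'
#' @inheritParams subtree_genes
#' @return Integer count of leaf descendants.
#' @export
leaf_count <- function(h, pathway_id) {
  check_pathway_id(h, pathway_id)
  ids <- c(pathway_id, descendant_ids(h, pathway_id))
  sum(vapply(ids, function(i) length(h$children[[i]] %||% character()) == 0L,
             logical(1)))
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat(sprintf("<pathway_hierarchy> %d pathways, %d roots, max depth %d, %d distinct genes\n",
              nrow(x$nodes), length(x$roots),
              if (nrow(x$nodes)) max(x$nodes$depth) else 0L,
              length(unique(x$genes$symbol))))
  invisible(x)
}

#' Serialize a hierarchy to canonical JSON
#'
#' Nodes are emitted sorted by id with sorted gene lists, so identical
#' hierarchies serialize byte-identically and the parse/build/serialize
#' cycle round-trips.
#'
#' @param h A `pathway_hierarchy`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
hierarchy_to_json <- function(h, path = NULL) {
  ids <- sort(h$nodes$pathway_id)
  nodes <- lapply(ids, function(id) {
    row <- h$nodes[h$nodes$pathway_id == id, ]
    list(
      name = row$name,
      parent = if (is.na(row$parent_id)) NULL else row$parent_id,
      genes = sort(h$genes$symbol[h$genes$pathway_id == id])
    )
  })
  names(nodes) <- ids
  js <- jsonlite::toJSON(list(nodes = nodes, roots = h$roots),
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Deserialize a hierarchy from canonical JSON
#'
#' @param x A JSON string or file path produced by [hierarchy_to_json()].
#' @return A `pathway_hierarchy`.
#' @export
hierarchy_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  ids <- names(obj$nodes)
  edges <- tibble(
    parent = map_chr(obj$nodes, function(n) n$parent %||% NA_character_),
    child = ids
  )
  edges <- edges[!is.na(edges$parent), , drop = FALSE]
  gene_sets <- tibble(
    pathway_id = ids,
    description = map_chr(obj$nodes, function(n) n$name %||% ""),
    genes = map(obj$nodes, function(n) unlist(n$genes) %||% character())
  )
  build_hierarchy(edges, gene_sets)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pathway hierarchy into a node table
#'
#' @param x A `pathway_hierarchy`.
#' @param ... Unused.
#' @return A tibble with one row per pathway: id, name, parent, depth,
#'   layout order, direct and subtree gene counts, and leaf count.
#' @method tidy pathway_hierarchy
#' @export
tidy.pathway_hierarchy <- function(x, ...) {
  x$nodes |>
    mutate(
      n_direct_genes = map_int(.data$pathway_id,
                               function(id) sum(x$genes$pathway_id == id)),
      n_subtree_genes = map_int(.data$pathway_id,
                                function(id) length(subtree_genes(x, id))),
      n_leaves = map_int(.data$pathway_id, function(id) leaf_count(x, id))
    )
}

#' One-row summary of a pathway hierarchy
#'
#' @inheritParams tidy.pathway_hierarchy
#' @return A one-row tibble: pathway, root, leaf and gene counts, max depth.
#' @method glance pathway_hierarchy
#' @export
glance.pathway_hierarchy <- function(x, ...) {
  leaves <- sum(vapply(x$nodes$pathway_id,
                       function(i) length(x$children[[i]] %||% character()) == 0L,
                       logical(1)))
  tibble(
    n_pathways = nrow(x$nodes),
    n_roots = length(x$roots),
    n_leaves = leaves,
    max_depth = if (nrow(x$nodes)) max(x$nodes$depth) else 0L,
    n_genes = length(unique(x$genes$symbol))
  )
}
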