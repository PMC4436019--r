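# Fixtures are built in code; the raw representation (edges + direct gene
# assignments) is kept alongside the built hierarchy so oracle functions can
# recompute every quantity from first principles without touching the
# package's query functions.

tiny_hierarchy <- function() {
  edges <- tibble::tibble(parent = "P1", child = c("P2", "P3"))
  gmt <- pathburst::parse_gmt(c("P2\tleft\tA\tB", "P3\tright\tB\tC"))
  list(edges = edges,
       genes = tibble::tibble(pathway_id = c("P2", "P2", "P3", "P3"),
                              symbol = c("A", "B", "B", "C")),
       h = pathburst::build_hierarchy(edges, gmt))
}

# random forest with genes allowed on internal nodes too
random_instance <- function(seed, max_pathways = 8, max_genes = 30) {
  withr::with_seed(seed, {
    n_p <- sample(2:max_pathways, 1)
    ids <- sprintf("P%02d", seq_len(n_p))
    parent <- c(NA_character_, vapply(2:n_p, function(i) {
      if (stats::runif(1) < 0.25) NA_character_ else sample(ids[1:(i - 1)], 1)
    }, character(1)))
    has_parent <- !is.na(parent)
    edges <- tibble::tibble(parent = parent[has_parent],
                            child = ids[has_parent])
    n_g <- sample(1:max_genes, 1)
    syms <- sprintf("G%03d", seq_len(n_g))
    assign <- tibble::tibble(
      pathway_id = sample(ids, n_g, replace = TRUE),
      symbol = syms
    )
    # some genes in several pathways
    extra_n <- stats::rbinom(1, n_g, 0.4)
    if (extra_n > 0) {
      extra <- tibble::tibble(
        pathway_id = sample(ids, extra_n, replace = TRUE),
        symbol = sample(syms, extra_n)
      )
      assign <- dplyr::distinct(dplyr::bind_rows(assign, extra))
    }
    gene_sets <- assign |>
      dplyr::group_by(pathway_id) |>
      dplyr::summarise(genes = list(sort(symbol)), .groups = "drop") |>
      dplyr::mutate(description = pathway_id) |>
      dplyr::select(pathway_id, description, genes)
    list(edges = edges, genes = assign,
         h = pathburst::build_hierarchy(edges, gene_sets))
  })
}

# ---- oracles (first-principles recomputation on the raw representation) ----

oracle_descendants <- function(edges, id) {
  kids <- edges$child[edges$parent == id]
  if (length(kids) == 0) return(character())
  unique(c(kids, unlist(lapply(kids, function(k) oracle_descendants(edges, k)))))
}

oracle_subtree_genes <- function(inst, id) {
  ids <- c(id, oracle_descendants(inst$edges, id))
  sort(unique(inst$genes$symbol[inst$genes$pathway_id %in% ids]))
}

oracle_leaf_count <- function(inst, id) {
  ids <- c(id, oracle_descendants(inst$edges, id))
  sum(vapply(ids, function(i) !i %in% inst$edges$parent, logical(1)))
}

# BFS level sets; level 1 = roots
oracle_nodes_at_depth <- function(inst, depth) {
  all_ids <- sort(unique(c(inst$edges$parent, inst$edges$child,
                           inst$genes$pathway_id)))
  frontier <- setdiff(all_ids, inst$edges$child)
  d <- 1
  while (d < depth && length(frontier) > 0) {
    frontier <- inst$edges$child[inst$edges$parent %in% frontier]
    d <- d + 1
  }
  sort(frontier)
}

# all-pairs shared-gene scan among pathways at `level`
oracle_crosstalk_edges <- function(inst, level = 2) {
  ids <- oracle_nodes_at_depth(inst, level)
  out <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        shared <- intersect(oracle_subtree_genes(inst, ids[i]),
                            oracle_subtree_genes(inst, ids[j]))
        if (length(shared) > 0) {
          out[[length(out) + 1]] <- tibble::tibble(
            pathway_a = ids[i], pathway_b = ids[j],
            n_shared = length(shared), shared_genes = list(sort(shared)))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(pathway_a = character(), pathway_b = character(),
                          n_shared = integer(), shared_genes = list()))
  }
  dplyr::arrange(dplyr::bind_rows(out), pathway_a, pathway_b)
}

# membership of genes among level pathways, nested-loop
oracle_membership <- function(inst, level = 2) {
  ids <- oracle_nodes_at_depth(inst, level)
  sets <- lapply(ids, function(i) oracle_subtree_genes(inst, i))
  names(sets) <- ids
  genes <- sort(unique(unlist(sets)))
  lapply(stats::setNames(genes, genes), function(g) {
    ids[vapply(ids, function(i) g %in% sets[[i]], logical(1))]
  })
}
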