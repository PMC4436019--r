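#' Parameters for the synthetic pathway study
#'
#' One bundle of generator settings covering hierarchy shape, gene content,
#' crosstalk, ortholog coverage and differential expression. Defaults
#' describe a small but structured study: a two-family hierarchy three
#' levels deep, eight genes per leaf pathway, 10% of genes shared across
#' pathways, 70% ortholog coverage in the target species, 30% of genes
#' differentially expressed at a four-fold mean effect.
#'
#' @param seed Integer seed; one seed drives one pseudo-random stream per
#'   generator call, so reruns are bit-stable.
#' @param n_roots Number of root pathways.
#' @param depth Depth of the complete branching forest (roots are depth 1).
#' @param branching Children per internal node.
#' @param genes_per_leaf Unique genes assigned to each leaf pathway.
#' @param crosstalk_fraction Fraction of genes additionally inserted into a
#'   second random leaf, creating cross-talking gene products.
#' @param ortho_coverage Probability that a reference gene has a target
#'   ortholog.
#' @param frac_de Fraction of orthologous genes that are differentially
#'   expressed.
#' @param de_effect Mean `|log2 ratio|` of differentially expressed genes.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(seed = 1L, n_roots = 2L, depth = 3L, branching = 3L,
                       genes_per_leaf = 8L, crosstalk_fraction = 0.1,
                       ortho_coverage = 0.7, frac_de = 0.3, de_effect = 2) {
  stopifnot(n_roots >= 1, depth >= 1, branching >= 1, genes_per_leaf >= 0,
            crosstalk_fraction >= 0, crosstalk_fraction <= 1,
            ortho_coverage >= 0, ortho_coverage <= 1,
            frac_de >= 0, frac_de <= 1, de_effect > 0)
  structure(list(seed = as.integer(seed), n_roots = as.integer(n_roots),
                 depth = as.integer(depth), branching = as.integer(branching),
                 genes_per_leaf = as.integer(genes_per_leaf),
                 crosstalk_fraction = crosstalk_fraction,
                 ortho_coverage = ortho_coverage, frac_de = frac_de,
                 de_effect = de_effect),
            class = "sim_params")
}

# fabricated Entrez ids live in a reserved high range to avoid colliding
# with real identifiers
entrez_base <- 900000000L

#' Generate a synthetic pathway hierarchy
#'
#' Builds a complete branching forest of the configured depth. Each leaf
#' receives `genes_per_leaf` unique synthetic genes (symbols `G000001`, ...);
#' then `crosstalk_fraction` of all genes are inserted into a second,
#' randomly chosen leaf, which is what makes crosstalk detectable
#' downstream. Output streams parse cleanly through [parse_relations()] and
#' [parse_gmt()]; identical seeds give byte-identical streams.
#'
#' @param p A [sim_params()] bundle.
#' @return A list with `hierarchy` (a `pathway_hierarchy`), `relations` and
#'   `gmt` (character vectors of file lines), and `genes` (tibble of symbol
#'   and fabricated Entrez id).
#' @export
sim_hierarchy <- function(p) {
  withr::with_seed(p$seed, {
    # ids: roots P01, children P01.01, grandchildren P01.01.01, ...
    make_children <- function(id) sprintf("%s.%02d", id, seq_len(p$branching))
    level_ids <- list(sprintf("P%02d", seq_len(p$n_roots)))
    if (p$depth > 1) {
      for (d in 2:p$depth) {
        level_ids[[d]] <- unlist(lapply(level_ids[[d - 1]], make_children))
      }
    }
    edges <- bind_rows(lapply(seq_len(p$depth - 1), function(d) {
      tibble(parent = rep(level_ids[[d]], each = p$branching),
             child = level_ids[[d + 1]])
    }))
    if (p$depth == 1) edges <- tibble(parent = character(), child = character())
    leaves <- level_ids[[p$depth]]

    n_genes <- length(leaves) * p$genes_per_leaf
    symbols <- sprintf("G%06d", seq_len(n_genes))
    home_leaf <- rep(leaves, each = p$genes_per_leaf)
    assign <- tibble(pathway_id = home_leaf, symbol = symbols)

    n_ct <- floor(p$crosstalk_fraction * n_genes)
    if (n_ct > 0 && length(leaves) > 1) {
      ct_genes <- sort(sample(symbols, n_ct))
      second <- vapply(ct_genes, function(g) {
        home <- home_leaf[match(g, symbols)]
        sample(setdiff(leaves, home), 1L)
      }, character(1))
      assign <- bind_rows(assign, tibble(pathway_id = second, symbol = ct_genes))
    }

    gmt_ids <- sort(unique(c(unlist(level_ids))))
    leaf_genes <- split(assign$symbol, assign$pathway_id)
    gmt_lines <- vapply(leaves, function(id) {
      g <- sort(unique(leaf_genes[[id]] %||% character()))
      paste(c(id, sprintf("synthetic pathway %s", id), g), collapse = "\t")
    }, character(1))
    rel_lines <- sprintf("%s\t%s", edges$parent, edges$child)

    list(
      hierarchy = build_hierarchy(
        edges, parse_gmt(gmt_lines %||% character())),
      relations = rel_lines,
      gmt = unname(gmt_lines),
      genes = tibble(symbol = symbols,
                     entrez = entrez_base + seq_len(n_genes))
    )
  })
}

#' Generate a synthetic ortholog map
#'
#' Each reference gene is included independently with probability
#' `coverage`; the target symbol is the reference symbol suffixed `"_T"`.
#'
#' @param h A `pathway_hierarchy`.
#' @param coverage Inclusion probability in \[0, 1\].
#' @param seed Integer seed.
#' @return Character vector of ortholog-map TSV lines (possibly empty),
#'   parseable by [parse_ortholog_map()].
#' @export
sim_ortholog_map <- function(h, coverage, seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1)
  genes <- sort(unique(h$genes$symbol))
  withr::with_seed(seed, {
    keep <- stats::runif(length(genes)) < coverage
    sprintf("%s\t%s_T", genes[keep], genes[keep])
  })
}

#' Generate a synthetic expression table
#'
#' Emulates a two-state expression experiment over the orthologous genes:
#' a fraction `frac_de` of them get log2 ratios of magnitude `de_effect`
#' (sign equiprobable) plus Gaussian noise (sd 0.1); the rest get small
#' ratios drawn uniformly inside (-0.9, 0.9), below the default two-fold
#' cutoff. Deterministic per seed.
#'
#' @param sim Output of [sim_hierarchy()] (for the Entrez lookup).
#' @param m An `ortholog_map`.
#' @param p A [sim_params()] bundle (`frac_de`, `de_effect`, `seed`).
#' @return Character vector of expression TSV lines (with header),
#'   parseable by [parse_expression()].
#' @export
sim_expression <- function(sim, m, p) {
  genes <- reference_genes(m)
  withr::with_seed(p$seed + 1L, {
    is_de <- stats::runif(length(genes)) < p$frac_de
    sign <- ifelse(stats::runif(length(genes)) < 0.5, -1, 1)
    ratio <- ifelse(
      is_de,
      sign * (p$de_effect + stats::rnorm(length(genes), 0, 0.1)),
      stats::runif(length(genes), -0.9, 0.9)
    )
    entrez <- sim$genes$entrez[match(genes, sim$genes$symbol)]
    c("entrez\tsymbol\tlog2_ratio",
      sprintf("%d\t%s\t%.6f", entrez, genes, ratio))
  })
}

#' Generate a synthetic rate-limiting annotation
#'
#' Deterministic Bernoulli flags per gene.
#'
#' @param genes Character vector of gene symbols.
#' @param fraction Probability of the rate-limiting flag in \[0, 1\].
#' @param seed Integer seed.
#' @return Character vector of `symbol<TAB>0|1` lines, parseable by
#'   [parse_rate_limiting()].
#' @export
sim_rate_limiting <- function(genes, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  withr::with_seed(seed, {
    flag <- as.integer(stats::runif(length(genes)) < fraction)
    sprintf("%s\t%d", genes, flag)
  })
}

#' Write a full synthetic input bundle to a directory
#'
#' Writes relations.tsv, pathways.gmt, orthologs.tsv, expression.tsv and
#' rate_limiting.tsv — everything the analysis commands consume.
#'
#' @param p A [sim_params()] bundle.
#' @param dir Output directory (created if needed).
#' @param rl_fraction Fraction of rate-limiting genes.
#' @return Named character vector of the written paths, invisibly.
#' @export
sim_write_bundle <- function(p, dir, rl_fraction = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- sim_hierarchy(p)
  ortho_lines <- sim_ortholog_map(sim$hierarchy, p$ortho_coverage, p$seed)
  m <- parse_ortholog_map(ortho_lines)
  expr_lines <- sim_expression(sim, m, p)
  rl_lines <- sim_rate_limiting(sort(unique(sim$genes$symbol)), rl_fraction,
                                p$seed + 2L)
  paths <- c(
    relations = file.path(dir, "relations.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    orthologs = file.path(dir, "orthologs.tsv"),
    expression = file.path(dir, "expression.tsv"),
    rate_limiting = file.path(dir, "rate_limiting.tsv")
  )
  writeLines(sim$relations, paths[["relations"]])
  writeLines(sim$gmt, paths[["gmt"]])
  writeLines(ortho_lines, paths[["orthologs"]])
  writeLines(expr_lines, paths[["expression"]])
  writeLines(rl_lines, paths[["rate_limiting"]])
  invisible(paths)
}
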