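#' Radial sunburst layout of a pathway hierarchy
#'
#' Assigns every pathway an annular arc: depth maps to concentric rings
#' (depth 1 innermost) and each node's angular span is proportional to its
#' leaf count. Roots partition the full circle; each node's children
#' partition the parent's interval, in lexicographic pathway-id order.
#' Angles are radians measured clockwise from 12 o'clock.
#'
#' @param h A `pathway_hierarchy`.
#' @param inner_radius Inner edge of ring 1, in user units.
#' @param ring_width Radial width of each ring.
#' @param max_depth Deepest ring laid out (`Inf` for the full hierarchy).
#' @param root Optional pathway id: lay out only that subtree, re-rooted at
#'   depth 1 — the static counterpart of dragging a sub-pathway out into its
#'   own sunburst.
#' @param start_angle Angle of the first root's leading edge, radians
#'   clockwise from 12 o'clock.
#' @return A `sunburst_layout` tibble: `pathway_id`, `name`, `depth`,
#'   `start_angle`, `end_angle`, `r_inner`, `r_outer`.
#' @export
sunburst_layout <- function(h, inner_radius = 40, ring_width = 20,
                            max_depth = Inf, root = NULL, start_angle = 0) {
  if (inner_radius <= 0 || ring_width <= 0) {
    value_abort("inner_radius and ring_width must be positive")
  }
  if (is.null(root)) {
    tops <- h$roots
  } else {
    check_pathway_id(h, root)
    tops <- root
  }
  weights <- vapply(tops, function(i) leaf_count(h, i), integer(1))
  total <- sum(weights)

  rows <- vector("list", nrow(h$nodes))
  k <- 0L
  recurse <- function(id, a0, a1, depth) {
    if (depth > max_depth) return(invisible(NULL))
    k <<- k + 1L
    rows[[k]] <<- tibble(
      pathway_id = id,
      depth = depth,
      start_angle = a0,
      end_angle = a1,
      r_inner = inner_radius + (depth - 1) * ring_width,
      r_outer = inner_radius + depth * ring_width
    )
    kids <- h$children[[id]] %||% character()
    if (length(kids) == 0L) return(invisible(NULL))
    w <- vapply(kids, function(i) leaf_count(h, i), integer(1))
    bounds <- a0 + (a1 - a0) * cumsum(c(0, w)) / sum(w)
    for (j in seq_along(kids)) {
      recurse(kids[j], bounds[j], bounds[j + 1], depth + 1L)
    }
  }
  bounds <- start_angle + 2 * pi * cumsum(c(0, weights)) / total
  for (j in seq_along(tops)) {
    recurse(tops[j], bounds[j], bounds[j + 1], 1L)
  }
  arcs <- bind_rows(rows[seq_len(k)]) |>
    left_join(h$nodes[, c("pathway_id", "name")], by = "pathway_id") |>
    select("pathway_id", "name", "depth", "start_angle", "end_angle",
           "r_inner", "r_outer")
  structure(arcs, class = c("sunburst_layout", class(arcs)),
            inner_radius = inner_radius, ring_width = ring_width)
}

status_colors <- c(COMPLETE = "#33a02c", PARTIAL = "#ffd92f", EMPTY = "#7b3294")
de_ramp <- grDevices::colorRampPalette(c("#ffffff", "#b30000"))

#' Color sunburst arcs by ortholog status or DE ratio
#'
#' Ortholog-status mode uses the fixed green/yellow/purple encoding for
#' complete/partial/empty pathways; expression mode maps the DE ratio
#' through a sequential white-to-red ramp (0 light, 1 dark).
#'
#' @param arcs A `sunburst_layout`.
#' @param data An `ortholog_projection` (mode `"status"`) or a
#'   `pathway_expression_summary` (mode `"expression"`). Every arc's pathway
#'   must be present.
#' @param mode `"status"` or `"expression"`.
#' @return `arcs` with a `fill` column of hex colors.
#' @export
colorize_arcs <- function(arcs, data, mode = c("status", "expression")) {
  mode <- match.arg(mode)
  missing_ids <- setdiff(arcs$pathway_id, data$pathway_id)
  if (length(missing_ids) > 0L) {
    key_abort(sprintf("pathway '%s' missing from the coloring data",
                      missing_ids[1]))
  }
  if (mode == "status") {
    st <- stats::setNames(as.character(data$status), data$pathway_id)
    arcs$fill <- unname(status_colors[st[arcs$pathway_id]])
  } else {
    ramp <- de_ramp(101)
    r <- stats::setNames(data$de_ratio, data$pathway_id)
    arcs$fill <- ramp[1 + round(100 * pmin(pmax(r[arcs$pathway_id], 0), 1))]
  }
  arcs
}

#' Attach OOMM encodings to arcs
#'
#' Arcs whose pathway has a value get the dual-bar encoding of that value;
#' others carry no marker.
#'
#' @param arcs A `sunburst_layout`.
#' @param values Named numeric vector (names are pathway ids) of
#'   non-negative magnitudes, e.g. per-pathway DE-gene or crosstalk-gene
#'   counts.
#' @return `arcs` with columns `oomm_mantissa`, `oomm_exponent`,
#'   `oomm_saturated` (`NA` where no value was supplied).
#' @export
attach_oomm <- function(arcs, values) {
  enc <- oomm_encode(unname(values))
  pos <- match(arcs$pathway_id, names(values))
  arcs$oomm_mantissa <- enc$mantissa[pos]
  arcs$oomm_exponent <- ifelse(is.na(pos), NA_integer_, enc$exponent[pos])
  arcs$oomm_saturated <- enc$saturated[pos]
  arcs
}

#' Crosstalk chord overlay geometry
#'
#' One chord per crosstalk edge, connecting the angular midpoints of the two
#' pathway arcs at their inner radii. Edges whose endpoints were pruned from
#' the layout (e.g. by `max_depth`) are skipped with a warning.
#'
#' @param arcs A `sunburst_layout`.
#' @param edges A tibble from [crosstalk_edges()].
#' @return A tibble: `pathway_a`, `pathway_b`, `angle_a`, `angle_b`,
#'   `r_a`, `r_b`, `n_shared`.
#' @export
crosstalk_overlay <- function(arcs, edges) {
  present <- edges$pathway_a %in% arcs$pathway_id &
    edges$pathway_b %in% arcs$pathway_id
  if (any(!present)) {
    warn(sprintf("skipping %d crosstalk edge(s) with endpoints outside the layout",
                 sum(!present)), class = "pathburst_pruned_edges")
  }
  edges <- edges[present, , drop = FALSE]
  mid <- stats::setNames((arcs$start_angle + arcs$end_angle) / 2,
                         arcs$pathway_id)
  rin <- stats::setNames(arcs$r_inner, arcs$pathway_id)
  tibble(
    pathway_a = edges$pathway_a,
    pathway_b = edges$pathway_b,
    angle_a = unname(mid[edges$pathway_a]),
    angle_b = unname(mid[edges$pathway_b]),
    r_a = unname(rin[edges$pathway_a]),
    r_b = unname(rin[edges$pathway_b]),
    n_shared = edges$n_shared
  )
}

# polar -> cartesian, angle clockwise from 12 o'clock, y down (SVG)
polar_xy <- function(cx, cy, r, theta) {
  c(x = cx + r * sin(theta), y = cy - r * cos(theta))
}

fmt <- function(x) sprintf("%.4f", x)

annular_sector_path <- function(cx, cy, r0, r1, a0, a1) {
  span <- a1 - a0
  if (span >= 2 * pi - 1e-9) a1 <- a0 + 2 * pi - 1e-6
  large <- if ((a1 - a0) > pi) 1L else 0L
  p1 <- polar_xy(cx, cy, r1, a0); p2 <- polar_xy(cx, cy, r1, a1)
  p3 <- polar_xy(cx, cy, r0, a1); p4 <- polar_xy(cx, cy, r0, a0)
  sprintf("M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
          fmt(p1["x"]), fmt(p1["y"]), fmt(r1), fmt(r1), large,
          fmt(p2["x"]), fmt(p2["y"]), fmt(p3["x"]), fmt(p3["y"]),
          fmt(r0), fmt(r0), large, fmt(p4["x"]), fmt(p4["y"]))
}

radial_bar_path <- function(cx, cy, r0, len, theta, half_width) {
  a0 <- theta - half_width; a1 <- theta + half_width
  p1 <- polar_xy(cx, cy, r0, a0); p2 <- polar_xy(cx, cy, r0 + len, a0)
  p3 <- polar_xy(cx, cy, r0 + len, a1); p4 <- polar_xy(cx, cy, r0, a1)
  sprintf("M %s %s L %s %s L %s %s L %s %s Z",
          fmt(p1["x"]), fmt(p1["y"]), fmt(p2["x"]), fmt(p2["y"]),
          fmt(p3["x"]), fmt(p3["y"]), fmt(p4["x"]), fmt(p4["y"]))
}

#' Render a sunburst layout to static SVG
#'
#' Emits one annular-sector `<path>` per arc (class `arc`), one chord per
#' crosstalk overlay (a quadratic curve through the center, class `chord`),
#' and for each arc carrying an OOMM encoding a pair of radial bars along
#' the arc's outer edge (wide bar for the exponent, narrow for the
#' mantissa; classes `oomm-wide`/`oomm-narrow`). Output is deterministic:
#' identical input yields byte-identical SVG.
#'
#' @param arcs A `sunburst_layout`, optionally colored and with OOMM
#'   columns.
#' @param overlays Optional tibble from [crosstalk_overlay()].
#' @param path Output file path, or `NULL` to return the SVG text.
#' @param margin Canvas margin around the outermost ring, in user units.
#' @return The SVG document as a character string (invisibly when written).
#' @export
render_svg <- function(arcs, overlays = NULL, path = NULL, margin = 30) {
  if (nrow(arcs) == 0L) value_abort("cannot render an empty arc list")
  ring_width <- attr(arcs, "ring_width") %||%
    (arcs$r_outer[1] - arcs$r_inner[1])
  rmax <- max(arcs$r_outer) + ring_width # head room for OOMM bars
  size <- 2 * (rmax + margin)
  cx <- cy <- size / 2
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(size), fmt(size), fmt(size), fmt(size)),
    '<g class="arcs">'
  )
  has_fill <- "fill" %in% names(arcs)
  for (i in seq_len(nrow(arcs))) {
    d <- annular_sector_path(cx, cy, arcs$r_inner[i], arcs$r_outer[i],
                             arcs$start_angle[i], arcs$end_angle[i])
    fill <- if (has_fill && !is.na(arcs$fill[i])) arcs$fill[i] else "#cccccc"
    out <- c(out, sprintf(
      '<path class="arc" id="arc-%s" d="%s" fill="%s" stroke="#ffffff" stroke-width="0.5"><title>%s</title></path>',
      arcs$pathway_id[i], d, fill, arcs$name[i]))
  }
  out <- c(out, "</g>")
  if (!is.null(overlays) && nrow(overlays) > 0L) {
    out <- c(out, '<g class="chords">')
    for (i in seq_len(nrow(overlays))) {
      pa <- polar_xy(cx, cy, overlays$r_a[i], overlays$angle_a[i])
      pb <- polar_xy(cx, cy, overlays$r_b[i], overlays$angle_b[i])
      out <- c(out, sprintf(
        '<path class="chord" data-n-shared="%d" d="M %s %s Q %s %s %s %s" fill="none" stroke="#555555" stroke-opacity="0.6" stroke-width="%s"/>',
        overlays$n_shared[i], fmt(pa["x"]), fmt(pa["y"]), fmt(cx), fmt(cy),
        fmt(pb["x"]), fmt(pb["y"]), fmt(1 + log1p(overlays$n_shared[i]))))
    }
    out <- c(out, "</g>")
  }
  if ("oomm_mantissa" %in% names(arcs)) {
    unit <- ring_width / 10
    out <- c(out, '<g class="oomm">')
    for (i in seq_len(nrow(arcs))) {
      if (is.na(arcs$oomm_mantissa[i])) next
      bars <- oomm_bar_lengths(
        tibble(mantissa = arcs$oomm_mantissa[i],
               exponent = arcs$oomm_exponent[i],
               saturated = arcs$oomm_saturated[i]), unit)
      mid <- (arcs$start_angle[i] + arcs$end_angle[i]) / 2
      r0 <- arcs$r_outer[i]
      out <- c(out, sprintf(
        '<path class="oomm-wide" d="%s" fill="#1f78b4"/>',
        radial_bar_path(cx, cy, r0, bars$wide, mid - 0.03, 0.025)),
        sprintf('<path class="oomm-narrow" d="%s" fill="#ff7f00"/>',
                radial_bar_path(cx, cy, r0, bars$narrow, mid + 0.02, 0.012)))
    }
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  svg <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path, sep = "")
    return(invisible(svg))
  }
  svg
}

#' Serialize a sunburst layout to JSON
#'
#' @param arcs A `sunburst_layout`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
layout_to_json <- function(arcs, path = NULL) {
  js <- jsonlite::toJSON(as_tibble(arcs), auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sunburst layout with ggplot2
#'
#' A quick-look polar rendering of the layout; the SVG writer
#' ([render_svg()]) is the publication-quality path.
#'
#' @param object A `sunburst_layout`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sunburst_layout
#' @export
autoplot.sunburst_layout <- function(object, ...) {
  df <- as_tibble(object)
  if (!"fill" %in% names(df)) df$fill <- "#cccccc"
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_angle, xmax = .data$end_angle,
      ymin = .data$r_inner, ymax = .data$r_outer, fill = .data$fill),
      color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::xlim(0, 2 * pi) +
    ggplot2::theme_void()
}
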