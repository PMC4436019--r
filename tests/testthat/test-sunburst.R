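test_that("children split the parent span proportionally to leaf weight", {
  # one root, two children with equal leaves -> pi each
  h <- build_hierarchy(parse_relations(c("P1\tP2", "P1\tP3")))
  arcs <- sunburst_layout(h)
  spans <- stats::setNames(arcs$end_angle - arcs$start_angle, arcs$pathway_id)
  expect_equal(unname(spans["P1"]), 2 * pi)
  expect_equal(unname(spans["P2"]), pi)
  expect_equal(unname(spans["P3"]), pi)

  # leaves weighted 1:3 -> pi/2 and 3*pi/2
  h2 <- build_hierarchy(parse_relations(
    c("R\tA", "R\tB", "B\tB1", "B\tB2", "B\tB3")))
  arcs2 <- sunburst_layout(h2)
  spans2 <- stats::setNames(arcs2$end_angle - arcs2$start_angle,
                            arcs2$pathway_id)
  expect_equal(unname(spans2["A"]), pi / 2)
  expect_equal(unname(spans2["B"]), 3 * pi / 2)
})

test_that("angular spans conserve and siblings never overlap", {
  for (seed in 1:30) {
    h <- random_instance(seed)$h
    arcs <- sunburst_layout(h)
    spans <- stats::setNames(arcs$end_angle - arcs$start_angle,
                             arcs$pathway_id)
    expect_true(all(spans > 0))
    expect_equal(sum(spans[h$roots]), 2 * pi, tolerance = 1e-12)
    for (id in arcs$pathway_id) {
      kids <- h$children[[id]]
      if (!is.null(kids) && length(kids) > 0) {
        expect_equal(sum(spans[kids]), unname(spans[id]), tolerance = 1e-12)
        ivals <- arcs[arcs$pathway_id %in% kids, ] |>
          dplyr::arrange(start_angle)
        if (nrow(ivals) > 1) {
          expect_true(all(ivals$start_angle[-1] >=
                            ivals$end_angle[-nrow(ivals)] - 1e-9))
        }
      }
    }
    # ring radii follow depth
    expect_equal(arcs$r_outer - arcs$r_inner,
                 rep(attr(arcs, "ring_width"), nrow(arcs)))
  }
})

test_that("max_depth prunes exactly to the level sets and --root re-roots", {
  inst <- random_instance(11)
  h <- inst$h
  arcs <- sunburst_layout(h, max_depth = 2)
  expect_setequal(arcs$pathway_id,
                  c(nodes_at_depth(h, 1), nodes_at_depth(h, 2)))

  top <- h$roots[1]
  sub <- sunburst_layout(h, root = top)
  expect_setequal(sub$pathway_id,
                  c(top, oracle_descendants(inst$edges, top)))
  expect_equal(sub$depth[sub$pathway_id == top], 1L)
  expect_equal(unname(sub$end_angle[sub$pathway_id == top] -
                        sub$start_angle[sub$pathway_id == top]), 2 * pi)
  expect_error(sunburst_layout(h, root = "NOPE"),
               class = "pathburst_key_error")
})

test_that("status and DE-ratio coloring follow their encodings", {
  t <- tiny_hierarchy()
  m <- parse_ortholog_map(c("A\tA_T", "B\tB_T"))
  proj <- project_orthology(t$h, m)
  arcs <- colorize_arcs(sunburst_layout(t$h), proj, "status")
  fills <- stats::setNames(arcs$fill, arcs$pathway_id)
  expect_equal(unname(fills["P2"]), "#33a02c") # complete -> green
  expect_equal(unname(fills["P3"]), "#ffd92f") # partial -> yellow
  m0 <- parse_ortholog_map(character())
  arcs0 <- colorize_arcs(sunburst_layout(t$h),
                         project_orthology(t$h, m0), "status")
  expect_true(all(arcs0$fill == "#7b3294")) # empty -> purple

  smry <- tibble::tibble(pathway_id = c("P1", "P2", "P3"),
                         de_ratio = c(0, 1, 0.5))
  arcs_de <- colorize_arcs(sunburst_layout(t$h), smry, "expression")
  f <- stats::setNames(arcs_de$fill, arcs_de$pathway_id)
  expect_equal(unname(f["P1"]), "#FFFFFF") # ratio 0 -> ramp minimum
  expect_equal(unname(f["P2"]), "#B30000") # ratio 1 -> ramp maximum

  expect_error(colorize_arcs(sunburst_layout(t$h),
                             proj[proj$pathway_id != "P2", ], "status"),
               class = "pathburst_key_error")
})

test_that("OOMM attachment and chord overlays carry the right geometry", {
  t <- tiny_hierarchy()
  arcs <- attach_oomm(sunburst_layout(t$h), c(P2 = 99, P3 = 0))
  expect_equal(arcs$oomm_mantissa[arcs$pathway_id == "P2"], 9.9)
  expect_equal(arcs$oomm_exponent[arcs$pathway_id == "P2"], 1L)
  expect_equal(arcs$oomm_mantissa[arcs$pathway_id == "P3"], 0)
  expect_true(is.na(arcs$oomm_mantissa[arcs$pathway_id == "P1"]))
  expect_error(attach_oomm(sunburst_layout(t$h), c(P2 = -1)),
               class = "pathburst_value_error")

  idx <- crosstalk_index(t$h, 2)
  ov <- crosstalk_overlay(arcs, crosstalk_edges(idx))
  expect_equal(nrow(ov), 1L)
  a2 <- arcs[arcs$pathway_id == "P2", ]
  expect_equal(ov$angle_a, unname((a2$start_angle + a2$end_angle) / 2))
  expect_equal(ov$r_a, unname(a2$r_inner))

  # pruned endpoint -> edge skipped with a warning
  pruned <- sunburst_layout(t$h, max_depth = 1)
  expect_warning(ov2 <- crosstalk_overlay(pruned, crosstalk_edges(idx)),
                 class = "pathburst_pruned_edges")
  expect_equal(nrow(ov2), 0L)
})

test_that("SVG output is valid XML, deterministic, and one sector per arc", {
  skip_if_not_installed("xml2")
  t <- tiny_hierarchy()
  m <- parse_ortholog_map(c("A\tA_T", "B\tB_T"))
  arcs <- colorize_arcs(sunburst_layout(t$h), project_orthology(t$h, m),
                        "status")
  arcs <- attach_oomm(arcs, c(P1 = 3, P2 = 99))
  ov <- crosstalk_overlay(arcs, crosstalk_edges(crosstalk_index(t$h, 2)))
  svg1 <- render_svg(arcs, ov)
  svg2 <- render_svg(arcs, ov)
  expect_identical(svg1, svg2)

  doc <- xml2::read_xml(svg1)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "svg")
  sectors <- xml2::xml_find_all(doc, "//svg:path[@class='arc']", ns)
  expect_equal(length(sectors), nrow(arcs))
  chords <- xml2::xml_find_all(doc, "//svg:path[@class='chord']", ns)
  expect_equal(length(chords), nrow(ov))
  wide <- xml2::xml_find_all(doc, "//svg:path[@class='oomm-wide']", ns)
  expect_equal(length(wide), 2L)

  single <- sunburst_layout(build_hierarchy(NULL, parse_gmt("P1\tonly\tA")))
  doc1 <- xml2::read_xml(render_svg(single))
  expect_equal(length(xml2::xml_find_all(doc1, "//svg:path[@class='arc']",
                                         xml2::xml_ns_rename(xml2::xml_ns(doc1), d1 = "svg"))), 1L)
  expect_error(render_svg(single[0, ]), class = "pathburst_value_error")
})

test_that("layout JSON and autoplot round the visualization surface out", {
  t <- tiny_hierarchy()
  arcs <- sunburst_layout(t$h)
  js <- jsonlite::fromJSON(layout_to_json(arcs))
  expect_equal(nrow(js), nrow(arcs))
  p <- ggplot2::ggplot_build(autoplot(arcs))
  expect_equal(nrow(p$data[[1]]), nrow(arcs))
})
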