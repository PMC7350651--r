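grouped_ds <- function() correct_dataset(tiny_dataset(), tracer_spec("C"))

test_that("the largest default color scheme has exactly 15 entries", {
  sizes <- vapply(color_schemes(), length, integer(1L))
  expect_equal(unname(sizes[["default15"]]), 15L)
  expect_equal(max(sizes), 15L)
})

test_that("colors cycle with a warning beyond the scheme length", {
  expect_warning(cols <- scheme_colors("default15", 16L), "cycle")
  expect_length(cols, 16L)
  expect_equal(cols[16L], cols[1L])
  expect_no_warning(scheme_colors("default15", 15L))
  expect_no_warning(scheme_colors(c("#000000", "#ffffff"), 2L))
})

test_that("graph_spec validates its twelve types and prerequisites", {
  expect_error(graph_spec("pie", "cit273"), "arg")
  expect_error(graph_spec("single_isotopologue_label", "cit273"),
               "isotopologue")
  ds <- grouped_ds()
  expect_error(graph_stats(ds, graph_spec("kinetic_enrichment", "cit273")),
               "time points")
  expect_error(graph_stats(ds, graph_spec("quantitative_abundance", "cit273")),
               "standards")
  ds$fragments$cit273$n_labelable <- NA_integer_
  expect_error(graph_stats(ds, graph_spec("enrichment", "cit273")),
               "labelable")
})

test_that("MID bar graph draws groups x isotopologues bars", {
  ds <- grouped_ds()
  sp <- graph_spec("mid", "cit273")
  doc <- render_graph(sp, graph_stats(ds, sp))
  # rects = 2 groups x 4 isotopologues bars + 2 legend swatches
  expect_equal(count_elements(doc, "rect"), 2L * 4L + 2L)
  # every group appears in the legend exactly once, insertion order
  legend_texts <- Filter(function(e) e$type == "text" &&
                           e$text %in% c("ctrl", "treat"), doc$elements)
  expect_equal(vapply(legend_texts, `[[`, character(1L), "text"),
               c("ctrl", "treat"))
})

test_that("rendering is deterministic and SVG is byte-stable", {
  ds <- grouped_ds()
  for (type in c("mid", "stacked_mid", "abundance", "enrichment")) {
    sp <- graph_spec(type, "cit273")
    s1 <- svg_serialize(render_graph(sp, graph_stats(ds, sp)))
    s2 <- svg_serialize(render_graph(sp, graph_stats(ds, sp)))
    expect_identical(s1, s2, label = type)
  }
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  sp <- graph_spec("mid", "cit273")
  export_figure(render_graph(sp, graph_stats(ds, sp)), p1)
  export_figure(render_graph(sp, graph_stats(ds, sp)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("stacked segments sum to the group totals on the drawn scale", {
  ds <- grouped_ds()
  sp <- graph_spec("stacked_mid", "cit273")
  st <- graph_stats(ds, sp)
  doc <- render_graph(sp, st)
  bars <- Filter(function(e) e$type == "rect" && e$h != 10, doc$elements)
  # 2 groups x 4 segments
  expect_equal(length(bars), 8L)
  for (g in unique(st$group)) {
    expected <- sum(st$mean[st$group == g])
    expect_equal(expected, 1, tolerance = 1e-9)  # MIDs stack to 1
  }
  # drawn heights per group sum to the full bar height within 1e-9
  xs <- vapply(bars, `[[`, numeric(1L), "x")
  for (x0 in unique(xs)) {
    hsum <- sum(vapply(bars[xs == x0], `[[`, numeric(1L), "h"))
    py0 <- 280 - 44; py1 <- 34
    expect_equal(hsum / (py0 - py1), 1, tolerance = 1e-9)
  }
})

test_that("editing title/y-label changes only text, not geometry", {
  ds <- grouped_ds()
  a <- render_graph(graph_spec("mid", "cit273", title = "A", ylab = "y1"),
                    graph_stats(ds, graph_spec("mid", "cit273")))
  b <- render_graph(graph_spec("mid", "cit273", title = "B", ylab = "y2"),
                    graph_stats(ds, graph_spec("mid", "cit273")))
  strip_text <- function(doc) Filter(function(e) e$type != "text", doc$elements)
  expect_identical(strip_text(a), strip_text(b))
})

test_that("individual data points overlay when requested", {
  ds <- grouped_ds()
  sp0 <- graph_spec("enrichment", "cit273")
  sp1 <- graph_spec("enrichment", "cit273", plot_individual_values = TRUE)
  st <- graph_stats(ds, sp0)
  extra <- count_elements(render_graph(sp1, st), "circle") -
    count_elements(render_graph(sp0, st), "circle")
  expect_equal(extra, 4L)  # 2 groups x 2 replicates
})

test_that("kinetic graphs draw the time-ordered series", {
  ds <- grouped_ds()
  ds$groups$ctrl$time <- 6
  ds$groups$treat$time <- 0
  sp <- graph_spec("kinetic_enrichment", "cit273")
  st <- graph_stats(ds, sp)
  expect_equal(st$group, c("treat", "ctrl"))
  doc <- render_graph(sp, st)
  expect_equal(count_elements(doc, "polyline"), 1L)
})

test_that("carbon diagrams fill exactly the labeled positions", {
  d5 <- render_carbon_diagram(5, 0:4)
  circles <- Filter(function(e) e$type == "circle", d5$elements)
  expect_length(circles, 5L)
  expect_true(all(vapply(circles, `[[`, character(1L), "fill") != "none"))
  d6 <- render_carbon_diagram(6, integer(0))
  expect_true(all(vapply(Filter(function(e) e$type == "circle", d6$elements),
                         `[[`, character(1L), "fill") == "none"))
  expect_equal(count_elements(render_carbon_diagram(0), "circle"), 0L)
  expect_error(render_carbon_diagram(3, 3), "\\[0, 3\\)")
})

test_that("export dispatches on format and rejects unknown tokens", {
  doc <- render_carbon_diagram(3, 1)
  svg <- tempfile(fileext = ".svg")
  export_figure(doc, svg)
  expect_match(readLines(svg, n = 2)[2L], "<svg")
  png <- tempfile(fileext = ".png")
  export_figure(doc, png, dpi = 192)
  expect_gt(file.size(png), 0)
  expect_error(export_figure(doc, tempfile(fileext = ".pdf")), "unsupported")
})

test_that("pathway figures place mapped graphs and a sidebar", {
  fx <- make_huh7_like_fixture(tempdir(), seed = 7, cv = 0)
  ds <- read_uncorrected_csv(fx$csv)
  ds <- set_groups(ds, isotrace:::read_groups_json(fx$groups))
  ds <- correct_dataset(ds, tracer_spec("C"))
  map <- read_escher_map(fx$map)
  fig <- render_pathway_figure(ds, map, "mid")
  expect_s3_class(fig, "trace_document")
  # 8 mapped fragments' titles appear; the unmapped standard is in the sidebar
  texts <- vapply(Filter(function(e) e$type == "text", fig$elements),
                  `[[`, character(1L), "text")
  expect_true(all(names(ds$fragments) %in% texts))
  # metabolites-to-display filter restricts rendering
  ds$settings$metabolites_to_display <- "cit273"
  fig2 <- render_pathway_figure(ds, map, "mid")
  texts2 <- vapply(Filter(function(e) e$type == "text", fig2$elements),
                   `[[`, character(1L), "text")
  expect_true("cit273" %in% texts2)
  expect_false("nor260" %in% texts2)
  # determinism across runs
  expect_identical(svg_serialize(render_pathway_figure(ds, map, "mid")),
                   svg_serialize(render_pathway_figure(ds, map, "mid")))
})
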