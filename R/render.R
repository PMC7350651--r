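GRAPH_TYPES <- c("mid", "stacked_mid", "single_isotopologue_label",
                 "kinetic_single_label", "abundance", "stacked_abundance",
                 "single_isotopologue_abundance", "kinetic_single_abundance",
                 "quantitative_abundance", "kinetic_total_abundance",
                 "enrichment", "kinetic_enrichment")

# built-in palettes; the largest default scheme has exactly 15 entries
.color_schemes <- list(
  default15 = c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
                "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5"),
  grayscale5 = c("#252525", "#636363", "#969696", "#bdbdbd", "#d9d9d9")
)

#' Built-in color schemes
#'
#' @return Named list of hex-color vectors. The largest default scheme,
#'   `default15`, has exactly 15 entries; datasets with more groups cycle
#'   colors (with a warning) or can supply their own scheme.
#' @export
color_schemes <- function() .color_schemes

#' Resolve `n` colors from a scheme
#'
#' @param scheme A scheme name or a character vector of hex colors.
#' @param n Number of colors needed; colors cycle with a warning when `n`
#'   exceeds the scheme length.
#' @return Character vector of `n` colors.
#' @export
scheme_colors <- function(scheme = "default15", n) {
  cols <- if (is.character(scheme) && length(scheme) == 1L &&
              scheme %in% names(.color_schemes)) {
    .color_schemes[[scheme]]
  } else if (is.character(scheme) && length(scheme) >= 1L) {
    scheme
  } else {
    stop("unknown color scheme")
  }
  if (n > length(cols)) {
    warning("needed ", n, " colors but the scheme has ", length(cols),
            "; colors will cycle")
  }
  rep_len(cols, n)
}

#' Specify a graph
#'
#' The twelve available graph types mirror the standard views of a tracing
#' experiment: MID and stacked MID bars, single-isotopologue label bars,
#' per-isotopologue and stacked abundance bars, quantitative abundance,
#' mole percent enrichment, and kinetic (time-course) variants of each
#' single-valued quantity.
#'
#' @param type One of `"mid"`, `"stacked_mid"`,
#'   `"single_isotopologue_label"`, `"kinetic_single_label"`,
#'   `"abundance"`, `"stacked_abundance"`,
#'   `"single_isotopologue_abundance"`, `"kinetic_single_abundance"`,
#'   `"quantitative_abundance"`, `"kinetic_total_abundance"`,
#'   `"enrichment"`, `"kinetic_enrichment"`.
#' @param fragment Fragment name.
#' @param groups Optional group-name selection (default: all groups).
#' @param isotopologue M-number (0-based integer) for the
#'   single-isotopologue types.
#' @param title,ylab Title and y-axis text; sensible defaults per type.
#'   Editing them changes only text elements, never geometry.
#' @param plot_individual_values Overlay each sample's value on the bars.
#' @param scheme Color scheme name or vector (see [scheme_colors]).
#' @return An object of class `graph_spec`.
#' @export
graph_spec <- function(type, fragment, groups = NULL, isotopologue = NULL,
                       title = NULL, ylab = NULL,
                       plot_individual_values = FALSE, scheme = "default15") {
  type <- match.arg(type, GRAPH_TYPES)
  single <- type %in% c("single_isotopologue_label", "kinetic_single_label",
                        "single_isotopologue_abundance",
                        "kinetic_single_abundance")
  if (single && is.null(isotopologue)) {
    stop("graph type '", type, "' needs an isotopologue (M-number)")
  }
  default_ylab <- switch(type,
    mid = , stacked_mid = "Fraction of pool",
    single_isotopologue_label = , kinetic_single_label = "Isotopologue fraction",
    abundance = , stacked_abundance = ,
    single_isotopologue_abundance = , kinetic_single_abundance = ,
    kinetic_total_abundance = "Abundance (ion counts)",
    quantitative_abundance = "Amount",
    enrichment = , kinetic_enrichment = "Mole percent enrichment")
  structure(list(type = type, fragment = fragment, groups = groups,
                 isotopologue = if (is.null(isotopologue)) NULL else
                   as.integer(isotopologue),
                 title = title %||% fragment,
                 ylab = ylab %||% default_ylab,
                 plot_individual_values = isTRUE(plot_individual_values),
                 scheme = scheme),
            class = "graph_spec")
}

is_kinetic <- function(type) startsWith(type, "kinetic_")
is_stacked <- function(type) startsWith(type, "stacked_")
is_by_channel <- function(type) type %in% c("mid", "stacked_mid", "abundance",
                                            "stacked_abundance")

# per-channel absolute values: raw counts when uncorrected, fractions x
# corrected scale when corrected
channel_abundances <- function(data, fragment) {
  v <- data$values[[fragment]]
  if (!isTRUE(data$corrected) || is.null(data$scales)) return(v)
  sweep(v, 2L, data$scales[fragment, ], "*")
}

#' Compute the statistics behind a graph
#'
#' Validates the graph's prerequisites (time points for kinetic types,
#' quantitative standards, labelable-atom count for enrichment) and
#' produces the per-group statistics [render_graph] draws.
#'
#' @param data A grouped [trace_dataset].
#' @param spec A [graph_spec].
#' @return A data frame of group statistics; by-channel types carry one row
#'   per (isotopologue, group), kinetic types carry a `time` column. The
#'   `kind` attribute records the drawing family.
#' @export
graph_stats <- function(data, spec) {
  stopifnot(inherits(data, "trace_dataset"), inherits(spec, "graph_spec"))
  if (!length(data$groups)) stop("dataset has no groups")
  groups <- if (is.null(spec$groups)) data$groups else data$groups[spec$groups]
  if (any(vapply(groups, is.null, logical(1L)))) {
    stop("unknown group(s) in graph spec")
  }
  frag <- data$fragments[[spec$fragment]]
  if (is.null(frag)) stop("fragment '", spec$fragment, "' not in the dataset")
  type <- spec$type

  if (is_kinetic(type)) {
    times <- vapply(groups, function(g) g$time, numeric(1L))
    if (anyNA(times)) {
      stop("kinetic graphs need time points; missing for group(s): ",
           paste(names(groups)[is.na(times)], collapse = ", "))
    }
  }
  if (type == "quantitative_abundance" &&
      is.null(data$normalization$spec$standards)) {
    stop("quantitative abundance needs quantitative standards")
  }
  if (type %in% c("enrichment", "kinetic_enrichment") &&
      (is.na(frag$n_labelable) || frag$n_labelable < 1L)) {
    stop("enrichment needs the fragment's labelable tracer-atom count")
  }

  if (is_by_channel(type)) {
    label_kind <- type %in% c("mid", "stacked_mid")
    mat <- if (label_kind) fraction_matrix(data, spec$fragment)
           else channel_abundances(data, spec$fragment)
    nshow <- display_channels(data, spec$fragment)
    rows <- list()
    for (k in seq_len(nshow) - 1L) {
      st <- group_stats(mat[k + 1L, ], groups)
      st$isotopologue <- paste0("M", k)
      rows[[k + 1L]] <- st
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "kind") <- if (is_stacked(type)) "stacked" else "by_channel"
    return(out)
  }

  values <- switch(type,
    single_isotopologue_label = , kinetic_single_label = {
      m <- fraction_matrix(data, spec$fragment)
      if (spec$isotopologue + 1L > nrow(m)) {
        stop("isotopologue M", spec$isotopologue, " out of range for '",
             spec$fragment, "'")
      }
      m[spec$isotopologue + 1L, ]
    },
    single_isotopologue_abundance = , kinetic_single_abundance = {
      m <- channel_abundances(data, spec$fragment)
      if (spec$isotopologue + 1L > nrow(m)) {
        stop("isotopologue M", spec$isotopologue, " out of range for '",
             spec$fragment, "'")
      }
      m[spec$isotopologue + 1L, ]
    },
    quantitative_abundance = {
      qa <- quantitative_abundance(data, data$normalization$spec,
                                   fragments = spec$fragment)
      if (spec$fragment %in% qa$unquantified) {
        stop("no usable quantitative standard for '", spec$fragment, "'")
      }
      qa$amounts[spec$fragment, ]
    },
    kinetic_total_abundance = abundance_matrix(data)[spec$fragment, ],
    enrichment = , kinetic_enrichment =
      sample_values(data, spec$fragment, "enrichment")
  )
  if (length(data$excluded_samples)) {
    values[names(values) %in% data$excluded_samples] <- NA_real_
  }
  if (is_kinetic(type)) {
    times <- vapply(groups, function(g) g$time, numeric(1L))
    ord <- order(times, names(groups))
    st <- group_stats(values, groups[ord])
    st$time <- as.numeric(times[ord])
    attr(st, "kind") <- "kinetic"
  } else {
    st <- group_stats(values, groups)
    attr(st, "kind") <- "single"
  }
  st
}

GRAPH_W <- 400
GRAPH_H <- 280
MARGIN <- list(left = 56, right = 118, top = 34, bottom = 44)

#' Render a graph to a vector-graphic document
#'
#' Bar graphs show group means with symmetric capped +/- 1 SD error bars;
#' stacked variants stack isotopologue means per group; kinetic variants
#' draw the time-ordered series with SD bars. Individual sample points are
#' overlaid when the spec asks for them. Output is a pure function of
#' (spec, stats, scheme).
#'
#' @param spec A [graph_spec].
#' @param stats The matching [graph_stats] data frame.
#' @return A `trace_document` (see [export_figure]).
#' @export
render_graph <- function(spec, stats) {
  stopifnot(inherits(spec, "graph_spec"))
  kind <- attr(stats, "kind")
  if (is.null(kind)) stop("stats must come from graph_stats()")
  doc <- new_document(GRAPH_W, GRAPH_H)
  doc <- doc_text(doc, GRAPH_W / 2, 20, spec$title, size = 14,
                  anchor = "middle")
  px0 <- MARGIN$left
  px1 <- GRAPH_W - MARGIN$right
  py0 <- GRAPH_H - MARGIN$bottom  # y pixel of value 0
  py1 <- MARGIN$top

  switch(kind,
    by_channel = render_bars_by_channel(doc, spec, stats, px0, px1, py0, py1),
    stacked = render_stacked(doc, spec, stats, px0, px1, py0, py1),
    single = render_single_bars(doc, spec, stats, px0, px1, py0, py1),
    kinetic = render_kinetic(doc, spec, stats, px0, px1, py0, py1),
    stop("unknown stats kind '", kind, "'")
  )
}

y_axis <- function(doc, ymax, px0, py0, py1, ylab) {
  ticks <- pretty(c(0, ymax), n = 5)
  ticks <- ticks[ticks <= ymax * 1.0001 & ticks >= 0]
  if (!length(ticks)) ticks <- c(0, ymax)
  yfun <- function(v) py0 - (v / ymax) * (py0 - py1)
  doc <- doc_line(doc, px0, py0, px0, py1)
  for (t in ticks) {
    doc <- doc_line(doc, px0 - 4, yfun(t), px0, yfun(t))
    doc <- doc_text(doc, px0 - 7, yfun(t) + 3.5, format(t, trim = TRUE),
                    size = 9, anchor = "end")
  }
  doc <- doc_text(doc, 14, (py0 + py1) / 2, ylab, size = 11,
                  anchor = "middle", rotate = -90)
  list(doc = doc, yfun = yfun)
}

error_bar <- function(doc, x, ytop, ybottom, cap = 3) {
  doc <- doc_line(doc, x, ybottom, x, ytop)
  doc <- doc_line(doc, x - cap, ytop, x + cap, ytop)
  doc_line(doc, x - cap, ybottom, x + cap, ybottom)
}

legend_box <- function(doc, labels, colors, x, ytop) {
  y <- ytop
  for (i in seq_along(labels)) {
    doc <- doc_rect(doc, x, y, 10, 10, fill = colors[i], stroke = "#000000",
                    stroke_width = 0.5)
    doc <- doc_text(doc, x + 14, y + 9, labels[i], size = 10)
    y <- y + 16
  }
  doc
}

overlay_points <- function(doc, values, xcenter, width, yfun, color) {
  n <- length(values)
  if (!n) return(doc)
  xs <- if (n == 1L) xcenter else
    xcenter + ((seq_len(n) - 1) / (n - 1) - 0.5) * width * 0.6
  for (i in seq_len(n)) {
    doc <- doc_circle(doc, xs[i], yfun(values[i]), 2.2, fill = "#000000",
                      stroke = color, stroke_width = 0.5)
  }
  doc
}

render_bars_by_channel <- function(doc, spec, stats, px0, px1, py0, py1) {
  channels <- unique(stats$isotopologue)
  groups <- unique(stats$group)
  cols <- suppressWarnings(scheme_colors(spec$scheme, length(groups)))
  if (length(groups) > length(if (is.character(spec$scheme) &&
      length(spec$scheme) == 1L) .color_schemes[[spec$scheme]] else spec$scheme)) {
    warning("more groups than colors in scheme; colors cycle")
  }
  ymax <- max(stats$mean + ifelse(is.na(stats$sd), 0, stats$sd),
              unlist(stats$values), 0, na.rm = TRUE)
  if (!is.finite(ymax) || ymax <= 0) ymax <- 1
  ax <- y_axis(doc, ymax, px0, py0, py1, spec$ylab)
  doc <- ax$doc; yfun <- ax$yfun
  slot_w <- (px1 - px0) / length(channels)
  bar_w <- slot_w * 0.8 / length(groups)
  for (ci in seq_along(channels)) {
    x_slot <- px0 + (ci - 1) * slot_w
    for (gi in seq_along(groups)) {
      row <- stats[stats$isotopologue == channels[ci] &
                   stats$group == groups[gi], ]
      if (!nrow(row) || is.na(row$mean)) next
      x <- x_slot + slot_w * 0.1 + (gi - 1) * bar_w
      doc <- doc_rect(doc, x, yfun(row$mean), bar_w, py0 - yfun(row$mean),
                      fill = cols[gi], stroke = "#000000", stroke_width = 0.5)
      if (!is.na(row$sd) && row$sd > 0) {
        doc <- error_bar(doc, x + bar_w / 2,
                         yfun(min(row$mean + row$sd, ymax)),
                         yfun(max(row$mean - row$sd, 0)))
      }
      if (spec$plot_individual_values) {
        doc <- overlay_points(doc, row$values[[1L]], x + bar_w / 2, bar_w,
                              yfun, cols[gi])
      }
    }
    doc <- doc_text(doc, x_slot + slot_w / 2, py0 + 14, channels[ci],
                    size = 10, anchor = "middle")
  }
  doc <- doc_line(doc, px0, py0, px1, py0)
  legend_box(doc, groups, cols, px1 + 10, py1)
}

render_stacked <- function(doc, spec, stats, px0, px1, py0, py1) {
  channels <- unique(stats$isotopologue)
  groups <- unique(stats$group)
  cols <- suppressWarnings(scheme_colors(spec$scheme, length(channels)))
  totals <- vapply(groups, function(g)
    sum(stats$mean[stats$group == g], na.rm = TRUE), numeric(1L))
  ymax <- max(totals, 0, na.rm = TRUE)
  if (!is.finite(ymax) || ymax <= 0) ymax <- 1
  ax <- y_axis(doc, ymax, px0, py0, py1, spec$ylab)
  doc <- ax$doc; yfun <- ax$yfun
  slot_w <- (px1 - px0) / length(groups)
  bar_w <- slot_w * 0.6
  for (gi in seq_along(groups)) {
    x <- px0 + (gi - 1) * slot_w + slot_w * 0.2
    base <- 0
    for (ci in seq_along(channels)) {
      row <- stats[stats$isotopologue == channels[ci] &
                   stats$group == groups[gi], ]
      if (!nrow(row) || is.na(row$mean) || row$mean <= 0) next
      doc <- doc_rect(doc, x, yfun(base + row$mean), bar_w,
                      yfun(base) - yfun(base + row$mean),
                      fill = cols[ci], stroke = "#000000", stroke_width = 0.5)
      base <- base + row$mean
    }
    doc <- doc_text(doc, x + bar_w / 2, py0 + 14, groups[gi], size = 10,
                    anchor = "middle")
  }
  doc <- doc_line(doc, px0, py0, px1, py0)
  legend_box(doc, channels, cols, px1 + 10, py1)
}

render_single_bars <- function(doc, spec, stats, px0, px1, py0, py1) {
  groups <- stats$group
  cols <- suppressWarnings(scheme_colors(spec$scheme, length(groups)))
  ymax <- max(stats$mean + ifelse(is.na(stats$sd), 0, stats$sd),
              unlist(stats$values), 0, na.rm = TRUE)
  if (!is.finite(ymax) || ymax <= 0) ymax <- 1
  ax <- y_axis(doc, ymax, px0, py0, py1, spec$ylab)
  doc <- ax$doc; yfun <- ax$yfun
  slot_w <- (px1 - px0) / length(groups)
  bar_w <- slot_w * 0.6
  for (gi in seq_along(groups)) {
    x <- px0 + (gi - 1) * slot_w + slot_w * 0.2
    if (!is.na(stats$mean[gi])) {
      doc <- doc_rect(doc, x, yfun(stats$mean[gi]), bar_w,
                      py0 - yfun(stats$mean[gi]),
                      fill = cols[gi], stroke = "#000000", stroke_width = 0.5)
      if (!is.na(stats$sd[gi]) && stats$sd[gi] > 0) {
        doc <- error_bar(doc, x + bar_w / 2,
                         yfun(min(stats$mean[gi] + stats$sd[gi], ymax)),
                         yfun(max(stats$mean[gi] - stats$sd[gi], 0)))
      }
      if (spec$plot_individual_values) {
        doc <- overlay_points(doc, stats$values[[gi]], x + bar_w / 2, bar_w,
                              yfun, cols[gi])
      }
    }
    doc <- doc_text(doc, x + bar_w / 2, py0 + 14, groups[gi], size = 10,
                    anchor = "middle")
  }
  doc <- doc_line(doc, px0, py0, px1, py0)
  legend_box(doc, groups, cols, px1 + 10, py1)
}

render_kinetic <- function(doc, spec, stats, px0, px1, py0, py1) {
  groups <- stats$group
  cols <- suppressWarnings(scheme_colors(spec$scheme, length(groups)))
  ymax <- max(stats$mean + ifelse(is.na(stats$sd), 0, stats$sd), 0,
              na.rm = TRUE)
  if (!is.finite(ymax) || ymax <= 0) ymax <- 1
  ax <- y_axis(doc, ymax, px0, py0, py1, spec$ylab)
  doc <- ax$doc; yfun <- ax$yfun
  trange <- range(stats$time)
  xfun <- function(t) {
    if (diff(trange) == 0) (px0 + px1) / 2
    else px0 + (t - trange[1]) / diff(trange) * (px1 - px0)
  }
  xs <- vapply(stats$time, xfun, numeric(1L))
  ok <- !is.na(stats$mean)
  doc <- doc_polyline(doc, xs[ok], vapply(stats$mean[ok], yfun, numeric(1L)),
                      stroke = cols[1L])
  for (i in which(ok)) {
    if (!is.na(stats$sd[i]) && stats$sd[i] > 0) {
      doc <- error_bar(doc, xs[i], yfun(min(stats$mean[i] + stats$sd[i], ymax)),
                       yfun(max(stats$mean[i] - stats$sd[i], 0)))
    }
    doc <- doc_circle(doc, xs[i], yfun(stats$mean[i]), 3, fill = cols[i])
  }
  for (t in unique(stats$time)) {
    doc <- doc_line(doc, xfun(t), py0, xfun(t), py0 + 4)
    doc <- doc_text(doc, xfun(t), py0 + 16, format(t, trim = TRUE), size = 9,
                    anchor = "middle")
  }
  doc <- doc_text(doc, (px0 + px1) / 2, GRAPH_H - 8, "Time", size = 11,
                  anchor = "middle")
  doc <- doc_line(doc, px0, py0, px1, py0)
  legend_box(doc, groups, cols, px1 + 10, py1)
}

#' Render a carbon-circle labeling diagram
#'
#' A row of `n_atoms` circles, one per tracer-element position; labeled
#' positions are drawn filled, unlabeled ones open. Used to annotate
#' pathway figures with a substrate's labeling pattern (e.g. all five
#' circles filled for a uniformly labeled 5-carbon tracer).
#'
#' @param n_atoms Number of atom positions (>= 0; 0 gives an empty
#'   element).
#' @param labeled_positions Integer set of 0-based labeled positions,
#'   each in `[0, n_atoms)`.
#' @param radius Circle radius in canvas units.
#' @param fill Fill color for labeled positions.
#' @return A `trace_document`.
#' @export
render_carbon_diagram <- function(n_atoms, labeled_positions = integer(0),
                                  radius = 7, fill = "#d62728") {
  n_atoms <- as.integer(n_atoms)
  stopifnot(n_atoms >= 0L)
  labeled_positions <- as.integer(labeled_positions)
  if (length(labeled_positions) &&
      (any(labeled_positions < 0L) || any(labeled_positions >= n_atoms))) {
    stop("labeled positions must lie in [0, ", n_atoms, ")")
  }
  spacing <- radius * 2.6
  doc <- new_document(max(n_atoms * spacing, 1), spacing)
  for (i in seq_len(n_atoms) - 1L) {
    doc <- doc_circle(doc, spacing / 2 + i * spacing, spacing / 2, radius,
                      fill = if (i %in% labeled_positions) fill else "none",
                      stroke = "#000000", stroke_width = 1.2)
  }
  doc
}

#' Compose a full pathway figure
#'
#' Places one graph per mapped fragment next to its metabolite node on the
#' map canvas, renders unmapped fragments in a left-hand sidebar, and
#' returns the whole canvas as one exportable document. Placement is
#' deterministic: graphs sit to the right of their node; collisions are
#' resolved by a clockwise quadrant search (right, below, left, above),
#' then by downward stepping.
#'
#' @param data A grouped [trace_dataset].
#' @param map An [read_escher_map] result.
#' @param graph_type Graph type drawn beside every node (see
#'   [graph_spec]); by-channel and single-value types are supported.
#' @param isotopologue M-number for single-isotopologue types.
#' @param ignore_compartment Passed to [map_data_to_nodes].
#' @param scale Scale factor applied to each mini graph (default 0.55).
#' @param carbon_diagrams Optional named list fragment -> integer vector of
#'   labeled positions; draws a carbon-circle diagram beneath that
#'   fragment's graph (atom count from the fragment's labelable count).
#' @return A `trace_document` covering the map canvas plus sidebar.
#' @export
render_pathway_figure <- function(data, map, graph_type = "mid",
                                  isotopologue = NULL,
                                  ignore_compartment = FALSE, scale = 0.55,
                                  carbon_diagrams = NULL) {
  stopifnot(inherits(data, "trace_dataset"), inherits(map, "escher_map_view"))
  show <- data$settings$metabolites_to_display
  frags <- names(data$fragments)
  if (!is.null(show)) frags <- intersect(frags, show)
  mapping <- map_data_to_nodes(data, map, ignore_compartment)
  mapped <- mapping$mapped[intersect(names(mapping$mapped), frags)]
  unmapped <- intersect(mapping$unmapped, frags)

  gw <- GRAPH_W * scale
  gh <- GRAPH_H * scale
  sidebar_w <- if (length(unmapped)) gw + 40 else 0
  off_x <- sidebar_w - map$canvas$x
  off_y <- -map$canvas$y
  W <- map$canvas$width + sidebar_w
  H <- max(map$canvas$height,
           length(unmapped) * (gh + 20) + 40)
  doc <- new_document(W, H)
  doc <- doc_rect(doc, 0, 0, W, H, fill = "#ffffff")

  # node markers and labels
  for (i in seq_len(nrow(map$nodes))) {
    n <- map$nodes[i, ]
    doc <- doc_circle(doc, n$x + off_x, n$y + off_y, 6, fill = "#334e75")
    doc <- doc_text(doc, n$label_x + off_x, n$label_y + off_y, n$bigg_id,
                    size = 12)
  }

  occupied <- list()
  overlaps <- function(r) {
    for (o in occupied) {
      if (r$x < o$x + o$w && r$x + r$w > o$x &&
          r$y < o$y + o$h && r$y + r$h > o$y) return(TRUE)
    }
    FALSE
  }
  place_rect <- function(nx, ny) {
    offs <- list(c(20, -gh / 2), c(-gw / 2, 20), c(-gw - 20, -gh / 2),
                 c(-gw / 2, -gh - 20))
    for (step in 0:10) {
      for (o in offs) {
        r <- list(x = nx + o[1L], y = ny + o[2L] + step * 30, w = gw, h = gh)
        if (!overlaps(r)) return(r)
      }
    }
    list(x = nx + 20, y = ny + 200, w = gw, h = gh)
  }

  scale_doc <- function(g, s) {
    g$elements <- lapply(g$elements, scale_element, s = s)
    g$width <- g$width * s
    g$height <- g$height * s
    g
  }

  for (fn in names(mapped)) {
    sp <- graph_spec(graph_type, fn, isotopologue = isotopologue)
    g <- scale_doc(render_graph(sp, graph_stats(data, sp)), scale)
    for (i in seq_len(nrow(mapped[[fn]]))) {
      node <- mapped[[fn]][i, ]
      r <- place_rect(node$x + off_x, node$y + off_y)
      occupied[[length(occupied) + 1L]] <- r
      doc <- doc_place(doc, g, r$x, r$y)
      doc <- add_carbon_diagram(doc, data, carbon_diagrams, fn, r, gh)
    }
  }

  y <- 20
  for (fn in unmapped) {
    sp <- graph_spec(graph_type, fn, isotopologue = isotopologue)
    g <- scale_doc(render_graph(sp, graph_stats(data, sp)), scale)
    doc <- doc_place(doc, g, 20, y)
    doc <- add_carbon_diagram(doc, data, carbon_diagrams, fn,
                              list(x = 20, y = y), gh)
    y <- y + gh + 20
  }
  doc
}

add_carbon_diagram <- function(doc, data, carbon_diagrams, fn, r, gh) {
  if (is.null(carbon_diagrams) || is.null(carbon_diagrams[[fn]])) return(doc)
  n <- data$fragments[[fn]]$n_labelable
  if (is.na(n)) return(doc)
  cd <- render_carbon_diagram(n, carbon_diagrams[[fn]])
  doc_place(doc, cd, r$x, r$y + gh + 2)
}

scale_element <- function(el, s) {
  switch(el$type,
    rect = { el$x <- el$x * s; el$y <- el$y * s
             el$w <- el$w * s; el$h <- el$h * s; el },
    line = { el$x1 <- el$x1 * s; el$y1 <- el$y1 * s
             el$x2 <- el$x2 * s; el$y2 <- el$y2 * s; el },
    polyline = { el$xs <- el$xs * s; el$ys <- el$ys * s; el },
    circle = { el$cx <- el$cx * s; el$cy <- el$cy * s; el$r <- el$r * s; el },
    text = { el$x <- el$x * s; el$y <- el$y * s; el$size <- el$size * s; el }
  )
}
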