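#' Read an Escher map
#'
#' Parses a standard Escher map JSON document (a two-element array: header
#' object, then the map body) and extracts all metabolite-type nodes with
#' their BiGG IDs and canvas coordinates. Midmarker and multimarker nodes
#' (reaction-path geometry) are excluded.
#'
#' @param path Path to an Escher map JSON file.
#' @return An object of class `escher_map_view`: `name`, a data frame
#'   `nodes` (`bigg_id`, `x`, `y`, `label_x`, `label_y`), and `canvas`
#'   (`x`, `y`, `width`, `height`). BiGG IDs may repeat across
#'   compartments. A map with zero metabolite nodes loads with a warning.
#' @export
read_escher_map <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse Escher map '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(doc) || length(doc) < 2L || is.null(doc[[2L]]$nodes)) {
    stop("'", path, "' is not an Escher map (expected [header, body] with ",
         "a 'nodes' table)")
  }
  header <- doc[[1L]]
  body <- doc[[2L]]
  nodes <- body$nodes
  met <- Filter(function(n) identical(n$node_type, "metabolite"), nodes)
  df <- if (length(met)) {
    do.call(rbind, lapply(met, function(n) data.frame(
      bigg_id = n$bigg_id %||% "",
      x = as.numeric(n$x), y = as.numeric(n$y),
      label_x = as.numeric(n$label_x %||% n$x),
      label_y = as.numeric(n$label_y %||% n$y),
      stringsAsFactors = FALSE
    )))
  } else {
    warning("Escher map '", path, "' contains no metabolite nodes")
    data.frame(bigg_id = character(0), x = numeric(0), y = numeric(0),
               label_x = numeric(0), label_y = numeric(0))
  }
  if (nrow(df) && any(!is.finite(df$x) | !is.finite(df$y))) {
    stop("Escher map '", path, "' has non-finite node coordinates")
  }
  canvas <- body$canvas
  cv <- if (is.null(canvas)) {
    pad <- 200
    list(x = min(df$x, 0) - pad, y = min(df$y, 0) - pad,
         width = diff(range(c(df$x, 0))) + 2 * pad,
         height = diff(range(c(df$y, 0))) + 2 * pad)
  } else {
    list(x = as.numeric(canvas$x), y = as.numeric(canvas$y),
         width = as.numeric(canvas$width), height = as.numeric(canvas$height))
  }
  structure(list(name = header$map_name %||% basename(path),
                 nodes = df, canvas = cv),
            class = "escher_map_view")
}

#' @export
print.escher_map_view <- function(x, ...) {
  cat("<escher_map_view> ", x$name, ": ", nrow(x$nodes),
      " metabolite node(s)\n", sep = "")
  invisible(x)
}

#' Map dataset fragments onto Escher metabolite nodes
#'
#' Matches fragment BiGG IDs to map node BiGG IDs by exact string
#' comparison (optionally ignoring a trailing compartment tag). A fragment
#' maps to every node sharing its ID; fragments with empty or unmatched IDs
#' are reported unmapped, in dataset order.
#'
#' @param data A [trace_dataset].
#' @param map An [read_escher_map] result.
#' @param ignore_compartment If `TRUE`, a trailing `_<tag>` is stripped
#'   from both sides before matching.
#' @return A list: `mapped`, a named list fragment -> data frame of
#'   matching node rows; `unmapped`, a character vector of fragment names.
#'   Together they cover every fragment exactly once.
#' @export
map_data_to_nodes <- function(data, map, ignore_compartment = FALSE) {
  stopifnot(inherits(data, "trace_dataset"), inherits(map, "escher_map_view"))
  strip <- function(x) if (ignore_compartment) sub("_[A-Za-z0-9]+$", "", x) else x
  node_ids <- strip(map$nodes$bigg_id)
  mapped <- list()
  unmapped <- character(0)
  for (fn in names(data$fragments)) {
    bid <- data$fragments[[fn]]$bigg_id
    hit <- if (nzchar(bid)) which(node_ids == strip(bid)) else integer(0)
    if (length(hit)) {
      mapped[[fn]] <- map$nodes[hit, , drop = FALSE]
    } else {
      unmapped <- c(unmapped, fn)
    }
  }
  list(mapped = mapped, unmapped = unmapped)
}
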