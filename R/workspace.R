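WORKSPACE_SCHEMA_VERSION <- "1.0"

matrix_to_json <- function(m) {
  list(rownames = rownames(m), colnames = colnames(m),
       data = lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
}

matrix_from_json <- function(x) {
  data <- x$data
  m <- if (length(data)) {
    do.call(rbind, lapply(data, as.numeric))
  } else {
    matrix(numeric(0), nrow = 0L, ncol = length(x$colnames))
  }
  dimnames(m) <- list(unlist(x$rownames), unlist(x$colnames))
  m
}

#' Save a workspace
#'
#' Serializes the complete dataset — fragments, values, groups, tracer,
#' normalization state, display settings — to a versioned JSON document
#' that [load_workspace] restores losslessly. The abundance-table version
#' used for correction is embedded so reloads are reproducible.
#'
#' @param data A [trace_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_workspace <- function(data, path) {
  stopifnot(inherits(data, "trace_dataset"))
  doc <- list(
    schema_version = WORKSPACE_SCHEMA_VERSION,
    abundance_table_version = isotope_table_version(),
    corrected = data$corrected,
    tracer = if (is.null(data$tracer)) NULL else
      list(element = data$tracer$element, shift = data$tracer$shift),
    samples = data$samples,
    fragments = lapply(data$fragments, function(f) list(
      name = f$name, metabolite = f$metabolite, bigg_id = f$bigg_id,
      formula = if (is.null(f$composition)) NULL else format_formula(f$composition),
      n_labelable = if (is.na(f$n_labelable)) NULL else f$n_labelable
    )),
    values = lapply(data$values, matrix_to_json),
    abundance = matrix_to_json(data$abundance),
    scales = if (is.null(data$scales)) NULL else matrix_to_json(data$scales),
    norm_abundance = if (is.null(data$norm_abundance)) NULL else
      matrix_to_json(data$norm_abundance),
    normalization = if (is.null(data$normalization)) NULL else list(
      steps = data$normalization$steps,
      internal_standard = data$normalization$spec$internal_standard,
      cell_counts = as.list(data$normalization$spec$cell_counts),
      reference_group = data$normalization$spec$reference_group,
      standards = data$normalization$spec$standards
    ),
    excluded_samples = data$excluded_samples,
    groups = lapply(data$groups, function(g) list(
      name = g$name, samples = g$samples,
      time = if (is.na(g$time)) NULL else g$time,
      cell_count = if (is.na(g$cell_count)) NULL else g$cell_count,
      color = g$color
    )),
    settings = data$settings
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a workspace
#'
#' @param path A JSON file written by [save_workspace]. Files from a
#'   different schema version are rejected by name.
#' @return The restored [trace_dataset].
#' @export
load_workspace <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse workspace '", path,
                                           "': ", conditionMessage(e)))
  ver <- doc$schema_version
  if (is.null(ver) || !identical(ver, WORKSPACE_SCHEMA_VERSION)) {
    stop("workspace schema version mismatch: file has '",
         if (is.null(ver)) "<missing>" else ver, "', this build reads '",
         WORKSPACE_SCHEMA_VERSION, "'")
  }
  fragments <- lapply(doc$fragments, function(f) fragment_spec(
    f$name,
    formula = f$formula,
    n_labelable = if (is.null(f$n_labelable)) NA_integer_ else f$n_labelable,
    bigg_id = f$bigg_id %||% "",
    metabolite = f$metabolite %||% f$name
  ))
  values <- lapply(doc$values, matrix_from_json)
  tracer <- if (is.null(doc$tracer)) NULL else
    tracer_spec(doc$tracer$element, doc$tracer$shift)
  ds <- trace_dataset(fragments, values, corrected = isTRUE(doc$corrected),
                      tracer = tracer)
  ds$abundance <- matrix_from_json(doc$abundance)
  if (!is.null(doc$scales)) ds$scales <- matrix_from_json(doc$scales)
  if (!is.null(doc$norm_abundance)) {
    ds$norm_abundance <- matrix_from_json(doc$norm_abundance)
  }
  if (!is.null(doc$normalization)) {
    nz <- doc$normalization
    cc <- if (length(nz$cell_counts)) {
      setNames(vapply(nz$cell_counts, as.numeric, numeric(1L)),
               names(nz$cell_counts))
    } else NULL
    std <- if (is.null(nz$standards)) NULL else
      do.call(rbind, lapply(nz$standards, function(r)
        data.frame(fragment = r$fragment, amount = as.numeric(r$amount),
                   response = as.numeric(r$response), stringsAsFactors = FALSE)))
    ds$normalization <- list(
      spec = normalization_spec(nz$internal_standard, cc, nz$reference_group, std),
      steps = unlist(nz$steps)
    )
  }
  ds$excluded_samples <- as.character(unlist(doc$excluded_samples))
  if (length(doc$groups)) {
    groups <- lapply(doc$groups, function(g) sample_group(
      g$name, as.character(unlist(g$samples)),
      time = if (is.null(g$time)) NA_real_ else g$time,
      cell_count = if (is.null(g$cell_count)) NA_real_ else g$cell_count,
      color = g$color
    ))
    ds <- set_groups(ds, groups)
  }
  if (!is.null(doc$settings)) {
    lims <- lapply(doc$settings$isotopologue_limits, as.integer)
    ds$settings <- list(
      metabolites_to_display =
        if (is.null(doc$settings$metabolites_to_display)) NULL else
          as.character(unlist(doc$settings$metabolites_to_display)),
      isotopologue_limits = lims,
      color_scheme = doc$settings$color_scheme %||% "default15"
    )
  }
  ds
}
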