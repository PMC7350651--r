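#' Define a sample group
#'
#' Groups collect replicate sample columns measured under one experimental
#' condition. Optional per-group metadata drives kinetic plots (time point)
#' and per-cell normalization (cell count).
#'
#' @param name Group name, unique within a dataset.
#' @param samples Character vector of sample identifiers.
#' @param time Optional time point (numeric, user units).
#' @param cell_count Optional positive cell count.
#' @param color Optional display color (hex string).
#' @return An object of class `sample_group`.
#' @export
sample_group <- function(name, samples, time = NA_real_,
                         cell_count = NA_real_, color = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(samples), length(samples) >= 1L)
  if (anyDuplicated(samples)) stop("group '", name, "': duplicate sample ids")
  time <- as.numeric(time)
  cell_count <- as.numeric(cell_count)
  if (!is.na(cell_count) && cell_count <= 0) {
    stop("group '", name, "': cell count must be positive")
  }
  structure(list(name = name, samples = samples, time = time,
                 cell_count = cell_count, color = color),
            class = "sample_group")
}

#' Assemble a tracing dataset
#'
#' The central container: measured fragments, their per-sample isotopologue
#' vectors, sample grouping, tracer and normalization state. Equivalent to
#' one analysis workspace.
#'
#' @param fragments List of [fragment_spec]; names taken from each spec.
#' @param values Named list (by fragment name) of numeric matrices,
#'   channels (rows, `M0..`) x samples (columns). Row counts may differ per
#'   fragment; column names must be identical across fragments.
#' @param corrected Logical: are the values already corrected for natural
#'   isotope abundance (and hence fractions)?
#' @param groups Optional list of [sample_group].
#' @param tracer Optional [tracer_spec].
#' @return An object of class `trace_dataset`. The per-fragment x sample
#'   channel sums are captured in `$abundance` at construction: for
#'   uncorrected data these are the raw (pre-correction) ion-count totals
#'   used as the abundance basis throughout.
#' @export
trace_dataset <- function(fragments, values, corrected = FALSE,
                          groups = list(), tracer = NULL) {
  stopifnot(is.list(fragments), length(fragments) >= 1L)
  fragnames <- vapply(fragments, function(f) f$name, character(1L))
  if (anyDuplicated(fragnames)) stop("duplicate fragment names")
  names(fragments) <- fragnames
  if (!setequal(names(values), fragnames)) {
    stop("values must be a named list matching the fragment names")
  }
  values <- values[fragnames]
  samples <- colnames(values[[1L]])
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("sample columns must be uniquely named")
  }
  for (fn in fragnames) {
    v <- values[[fn]]
    if (!is.matrix(v) || !identical(colnames(v), samples)) {
      stop("fragment '", fn, "': sample columns inconsistent with the dataset")
    }
    if (is.null(rownames(v))) {
      rownames(values[[fn]]) <- paste0("M", seq_len(nrow(v)) - 1L)
    }
  }
  abundance <- do.call(rbind, lapply(values, function(v) colSums(v, na.rm = TRUE)))
  rownames(abundance) <- fragnames
  ds <- structure(list(
    fragments = fragments,
    samples = samples,
    values = values,
    abundance = abundance,
    scales = NULL,
    groups = list(),
    tracer = tracer,
    corrected = isTRUE(corrected),
    normalization = NULL,
    norm_abundance = NULL,
    excluded_samples = character(0),
    settings = list(metabolites_to_display = NULL,
                    isotopologue_limits = list(),
                    color_scheme = "default15")
  ), class = "trace_dataset")
  if (length(groups)) ds <- set_groups(ds, groups)
  ds
}

#' Attach sample groups to a dataset
#'
#' @param data A [trace_dataset].
#' @param groups List of [sample_group]; together they must reference only
#'   samples present in the dataset, each sample at most once, and carry
#'   unique group names.
#' @return The dataset with groups attached.
#' @export
set_groups <- function(data, groups) {
  stopifnot(inherits(data, "trace_dataset"))
  gnames <- vapply(groups, function(g) g$name, character(1L))
  if (anyDuplicated(gnames)) stop("duplicate group names")
  all_s <- unlist(lapply(groups, function(g) g$samples))
  if (anyDuplicated(all_s)) {
    stop("sample(s) assigned to more than one group: ",
         paste(unique(all_s[duplicated(all_s)]), collapse = ", "))
  }
  missing <- setdiff(all_s, data$samples)
  if (length(missing)) {
    stop("group sample(s) not in the dataset: ", paste(missing, collapse = ", "))
  }
  names(groups) <- gnames
  data$groups <- groups
  data
}

#' @export
print.trace_dataset <- function(x, ...) {
  cat("<trace_dataset> ", length(x$fragments), " fragments x ",
      length(x$samples), " samples",
      if (x$corrected) " (NIA-corrected)" else " (uncorrected)", "\n", sep = "")
  if (length(x$groups)) {
    cat("  groups: ", paste(names(x$groups), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$tracer)) {
    cat("  tracer: ", x$tracer$element, "\n", sep = "")
  }
  if (!is.null(x$normalization)) {
    cat("  abundances normalized (",
        paste(x$normalization$steps, collapse = " -> "), ")\n", sep = "")
  }
  invisible(x)
}

# map sample id -> group name (NA when ungrouped)
sample_group_map <- function(data) {
  m <- setNames(rep(NA_character_, length(data$samples)), data$samples)
  for (g in data$groups) m[g$samples] <- g$name
  m
}

# active abundance matrix: normalized if present, raw sums otherwise
abundance_matrix <- function(data) {
  if (!is.null(data$norm_abundance)) data$norm_abundance else data$abundance
}
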