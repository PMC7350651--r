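#' Describe how abundances should be normalized
#'
#' All three steps are optional and applied in a fixed order:
#' internal standard (per sample), then cell counts (per group), then
#' reference group (per metabolite).
#'
#' @param internal_standard Optional fragment name used as the internal
#'   standard (e.g. a spiked norvaline fragment).
#' @param cell_counts Optional named numeric vector of cell counts per
#'   group name.
#' @param reference_group Optional group name; abundances are expressed
#'   relative to this group's mean.
#' @param standards Optional quantitative standards: a data frame with
#'   columns `fragment`, `amount` (known amount) and `response` (measured
#'   instrument response for that amount).
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(internal_standard = NULL, cell_counts = NULL,
                               reference_group = NULL, standards = NULL) {
  if (!is.null(standards)) {
    stopifnot(is.data.frame(standards),
              all(c("fragment", "amount", "response") %in% names(standards)))
  }
  structure(list(internal_standard = internal_standard,
                 cell_counts = cell_counts,
                 reference_group = reference_group,
                 standards = standards),
            class = "normalization_spec")
}

#' Normalize metabolite abundances
#'
#' Applies up to three rescalings to the per-fragment x sample abundance
#' matrix, in this fixed order:
#' \enumerate{
#'   \item internal standard: `A'(m,s) = A(m,s) / A(std,s)` per sample;
#'   \item cell counts: `A''(m,s) = A'(m,s) / cells(group(s))` per group;
#'   \item reference group: `A'''(m,s) = A''(m,s) / mean over the
#'     reference group of A''(m,.)` per metabolite, which fixes the
#'     reference group's mean at exactly 1.
#' }
#' A sample in which the internal standard reads zero is flagged and
#' excluded from group statistics (with a warning), never silently zeroed.
#'
#' @param data A grouped [trace_dataset].
#' @param spec A [normalization_spec].
#' @return The dataset with `norm_abundance` set and the normalization
#'   recorded.
#' @export
normalize_abundances <- function(data, spec) {
  stopifnot(inherits(data, "trace_dataset"), inherits(spec, "normalization_spec"))
  A <- data$abundance
  steps <- character(0)
  excluded <- character(0)

  if (!is.null(spec$internal_standard)) {
    std <- spec$internal_standard
    if (!std %in% rownames(A)) {
      stop("internal standard fragment '", std, "' not in the dataset")
    }
    stdv <- A[std, ]
    bad <- names(stdv)[stdv == 0]
    if (length(bad)) {
      warning("internal standard '", std, "' is zero in sample(s) ",
              paste(bad, collapse = ", "), "; excluded from group statistics")
      excluded <- union(excluded, bad)
      stdv[stdv == 0] <- NA_real_
    }
    A <- sweep(A, 2L, stdv, "/")
    steps <- c(steps, "internal_standard")
  }

  if (!is.null(spec$cell_counts)) {
    if (!length(data$groups)) stop("cell-count normalization requires groups")
    missing <- setdiff(names(spec$cell_counts), names(data$groups))
    if (length(missing)) {
      stop("cell counts given for unknown group(s): ",
           paste(missing, collapse = ", "))
    }
    gm <- sample_group_map(data)
    per_sample <- spec$cell_counts[gm[colnames(A)]]
    if (anyNA(per_sample)) {
      stop("cell counts missing for group(s): ",
           paste(unique(gm[colnames(A)][is.na(per_sample)]), collapse = ", "))
    }
    A <- sweep(A, 2L, as.numeric(per_sample), "/")
    steps <- c(steps, "cell_counts")
  }

  if (!is.null(spec$reference_group)) {
    ref <- spec$reference_group
    if (!ref %in% names(data$groups)) {
      stop("reference group '", ref, "' not in the dataset")
    }
    ref_samples <- setdiff(data$groups[[ref]]$samples, excluded)
    if (!length(ref_samples)) stop("reference group '", ref, "' has no usable samples")
    ref_means <- rowMeans(A[, ref_samples, drop = FALSE], na.rm = TRUE)
    A <- sweep(A, 1L, ref_means, "/")
    steps <- c(steps, "reference_group")
  }

  data$norm_abundance <- A
  data$excluded_samples <- union(data$excluded_samples, excluded)
  data$normalization <- list(spec = spec, steps = steps)
  data
}

#' Quantitative abundance via single-point calibration
#'
#' Converts abundances to absolute amounts using one quantitative standard
#' per fragment: `amount(m, s) = A(m, s) * known_amount(m) / response(m)`.
#'
#' @param data A [trace_dataset].
#' @param spec A [normalization_spec] whose `standards` table covers the
#'   requested fragments.
#' @param fragments Fragment names to quantify (default: those with
#'   standards).
#' @return A list: `amounts`, a fragments x samples matrix of amounts, and
#'   `unquantified`, the fragments lacking a usable standard (absent or
#'   zero-response), reported rather than errored.
#' @export
quantitative_abundance <- function(data, spec,
                                   fragments = unique(spec$standards$fragment)) {
  stopifnot(inherits(spec, "normalization_spec"))
  std <- spec$standards
  if (is.null(std)) stop("no quantitative standards in the normalization spec")
  A <- abundance_matrix(data)
  ok <- character(0)
  unquantified <- character(0)
  rows <- list()
  for (m in fragments) {
    i <- match(m, std$fragment)
    if (!m %in% rownames(A) || is.na(i) || std$response[i] == 0) {
      unquantified <- c(unquantified, m)
      next
    }
    rows[[m]] <- A[m, ] * std$amount[i] / std$response[i]
    ok <- c(ok, m)
  }
  amounts <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), ncol = ncol(A), dimnames = list(NULL, colnames(A)))
  list(amounts = amounts, unquantified = unquantified)
}
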