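#' Tracing-data CSV dialect
#'
#' Both upload dialects are long-format CSV, UTF-8, comma-separated, first
#' row header:
#'
#' ```
#' metabolite,bigg_id,formula,n_labelable,isotopologue,<sample1>,<sample2>,...
#' ```
#'
#' One row per fragment-channel; isotopologue written `M0`, `M1`, ...;
#' every fragment carries a contiguous block `M0..M(R-1)` whose length
#' fixes its channel count. The uncorrected dialect requires `formula` and
#' `n_labelable` for any fragment that is to be corrected; the corrected
#' dialect stores MID fractions and ignores missing formulas.
#'
#' @name csv-dialect
NULL

read_trace_csv <- function(path, corrected) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot read '", path, "': ", conditionMessage(e))
  )
  if (!nrow(df)) stop("no data rows in '", path, "'")
  meta_cols <- c("metabolite", "bigg_id", "formula", "n_labelable", "isotopologue")
  missing <- setdiff(meta_cols, names(df))
  if (length(missing)) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  samples <- setdiff(names(df), meta_cols)
  if (!length(samples)) stop("'", path, "' has no sample columns")

  key <- paste(df$metabolite, df$isotopologue, sep = "/")
  if (anyDuplicated(key)) {
    dup_rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (fragment, isotopologue) rows in '", path, "': rows ",
         paste(dup_rows + 1L, collapse = ", "))  # +1 for the header line
  }

  fragments <- list()
  values <- list()
  uncorrectable <- character(0)
  renorm_warned <- character(0)
  for (m in unique(df$metabolite)) {
    rows <- df[df$metabolite == m, , drop = FALSE]
    idx <- suppressWarnings(as.integer(sub("^M", "", rows$isotopologue)))
    if (anyNA(idx) || !setequal(idx, seq_len(nrow(rows)) - 1L)) {
      stop("fragment '", m, "' in '", path,
           "': isotopologue labels must be a contiguous M0..M(R-1) block")
    }
    rows <- rows[order(idx), , drop = FALSE]
    mat <- matrix(NA_real_, nrow = nrow(rows), ncol = length(samples),
                  dimnames = list(paste0("M", seq_len(nrow(rows)) - 1L), samples))
    for (s in samples) {
      v <- suppressWarnings(as.numeric(rows[[s]]))
      bad <- which(is.na(v) & nzchar(trimws(rows[[s]])))
      if (length(bad)) {
        stop("non-numeric value in '", path, "', fragment '", m,
             "', sample '", s, "', isotopologue M", bad[1L] - 1L)
      }
      v[is.na(v)] <- 0
      mat[, s] <- v
    }
    formula_txt <- trimws(rows$formula[1L])
    nlab_txt <- trimws(rows$n_labelable[1L])
    comp <- if (nzchar(formula_txt)) parse_formula(formula_txt) else NULL
    nlab <- if (nzchar(nlab_txt)) as.integer(nlab_txt) else NA_integer_
    if (!corrected && (is.null(comp) || is.na(nlab))) uncorrectable <- c(uncorrectable, m)
    if (corrected) {
      # corrected files carry MID fractions; tolerate small drift, warn otherwise
      for (s in samples) {
        tot <- sum(mat[, s])
        if (tot == 0) {
          mat[, s] <- NA_real_
        } else if (abs(tot - 1) > 1e-3) {
          renorm_warned <- union(renorm_warned, m)
          mat[, s] <- mat[, s] / tot
        } else if (tot != 1) {
          mat[, s] <- mat[, s] / tot
        }
      }
    }
    fragments[[m]] <- fragment_spec(m, formula = comp, n_labelable = nlab,
                                    bigg_id = trimws(rows$bigg_id[1L]))
    values[[m]] <- mat
  }
  if (length(uncorrectable)) {
    warning("fragment(s) without formula or labelable-atom count cannot be ",
            "corrected: ", paste(uncorrectable, collapse = ", "))
  }
  if (length(renorm_warned)) {
    warning("corrected fractions did not sum to 1 (tolerance 1e-3) for ",
            "fragment(s) ", paste(renorm_warned, collapse = ", "),
            "; renormalized")
  }
  trace_dataset(fragments, values, corrected = corrected)
}

#' Read an uncorrected tracing-data CSV
#'
#' Baseline-corrected but not natural-isotope-abundance-corrected MS counts
#' in the package's long CSV dialect (see [csv-dialect]).
#'
#' @param path File path.
#' @return A [trace_dataset] flagged uncorrected.
#' @export
read_uncorrected_csv <- function(path) read_trace_csv(path, corrected = FALSE)

#' Read a pre-corrected tracing-data CSV
#'
#' Data corrected for natural isotope abundance elsewhere (required for
#' data outside the nominal-resolution small-molecule regime). Values are
#' MID fractions; row-groups whose fractions do not sum to 1 within 1e-3
#' are accepted with a renormalization warning. The resulting dataset
#' refuses further correction.
#'
#' @param path File path.
#' @return A [trace_dataset] flagged corrected.
#' @export
read_corrected_csv <- function(path) read_trace_csv(path, corrected = TRUE)

#' Write a dataset in the tracing CSV dialect
#'
#' @param data A [trace_dataset].
#' @param path Output file path; the corrected/uncorrected flavor follows
#'   the dataset's own flag.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(data, path) {
  stopifnot(inherits(data, "trace_dataset"))
  rows <- lapply(names(data$fragments), function(fn) {
    frag <- data$fragments[[fn]]
    v <- data$values[[fn]]
    meta <- data.frame(
      metabolite = fn,
      bigg_id = frag$bigg_id,
      formula = if (is.null(frag$composition)) "" else format_formula(frag$composition),
      n_labelable = if (is.na(frag$n_labelable)) "" else as.character(frag$n_labelable),
      isotopologue = rownames(v),
      stringsAsFactors = FALSE
    )
    vals <- as.data.frame(v, check.names = FALSE)
    vals[] <- lapply(vals, function(col) ifelse(is.na(col), 0, col))
    cbind(meta, vals)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
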