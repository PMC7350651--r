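#' Mass isotopomer distribution of a measured vector
#'
#' Divides each isotopologue's abundance by the summed abundance of all
#' isotopologues of the fragment.
#'
#' @param counts Non-negative numeric vector M0..Mn.
#' @return Fraction vector summing to 1, or all-`NA` (flagged missing) for
#'   an all-zero input.
#' @export
#' @examples
#' mid(c(50, 30, 20))
mid <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("isotopologue counts must be non-negative")
  s <- sum(counts)
  if (is.na(s) || s == 0) return(rep(NA_real_, length(counts)))
  counts / s
}

#' Mole percent enrichment
#'
#' The average fraction of tracer-element positions carrying label:
#' `sum(i * mid[i]) / N` over isotopologues `i = 0..n`.
#'
#' @param mid Fraction vector (a MID), length at most `n_tracer_atoms + 1`.
#' @param n_tracer_atoms Labelable tracer-atom count N (>= 1).
#' @return A value in `[0, 1]`; `NA` if the MID is flagged missing.
#' @export
#' @examples
#' enrichment(c(0.5, 0, 0.5), 2)  # 0.5
enrichment <- function(mid, n_tracer_atoms) {
  n_tracer_atoms <- as.integer(n_tracer_atoms)
  if (is.na(n_tracer_atoms) || n_tracer_atoms < 1L) {
    stop("n_tracer_atoms must be >= 1")
  }
  if (length(mid) > n_tracer_atoms + 1L) {
    stop("MID has ", length(mid), " entries but only ", n_tracer_atoms,
         " labelable atoms")
  }
  if (anyNA(mid)) return(NA_real_)
  sum((seq_along(mid) - 1L) * mid) / n_tracer_atoms
}

#' Total abundance of a measured vector
#'
#' The sum of baseline-corrected counts over the measured channels — the
#' conventional raw ion-count abundance basis, computed before natural
#' isotope abundance correction.
#'
#' @param counts Non-negative numeric vector.
#' @return Numeric scalar.
#' @export
total_abundance <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("isotopologue counts must be non-negative")
  sum(counts, na.rm = TRUE)
}

#' Per-group mean and standard deviation
#'
#' @param values Named numeric vector, one entry per sample.
#' @param groups List of [sample_group].
#' @return A data frame with one row per group: `group`, `mean`, `sd`
#'   (sample SD, n-1 denominator; 0 when n = 1), `n`, and a list column
#'   `values` of the individual retained values. Missing (`NA`) samples are
#'   excluded with `n` reduced; a group left empty is flagged with `n = 0`.
#' @export
group_stats <- function(values, groups) {
  rows <- lapply(groups, function(g) {
    v <- values[g$samples]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(group = g$name,
               mean = if (n) mean(v) else NA_real_,
               sd = if (n >= 2L) stats::sd(v) else if (n == 1L) 0 else NA_real_,
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$values <- lapply(groups, function(g) {
    v <- values[g$samples]
    as.numeric(v[!is.na(v)])
  })
  out
}

# per-sample numeric vector for one fragment and one quantity selector.
# quantity: "abundance", "enrichment", or "M<k>" (single isotopologue).
sample_values <- function(data, fragment, quantity) {
  frag <- data$fragments[[fragment]]
  if (is.null(frag)) stop("fragment '", fragment, "' not in the dataset")
  excl <- data$excluded_samples
  if (identical(quantity, "abundance")) {
    v <- abundance_matrix(data)[fragment, ]
  } else {
    mids <- fraction_matrix(data, fragment)
    if (identical(quantity, "enrichment")) {
      if (is.na(frag$n_labelable) || frag$n_labelable < 1L) {
        stop("fragment '", fragment, "' has no labelable-atom count; ",
             "enrichment requires it")
      }
      v <- apply(mids, 2L, enrichment, n_tracer_atoms = frag$n_labelable)
    } else if (grepl("^M[0-9]+$", quantity)) {
      k <- as.integer(sub("^M", "", quantity))
      if (k + 1L > nrow(mids)) {
        stop("isotopologue ", quantity, " out of range for fragment '",
             fragment, "' (", nrow(mids), " channels)")
      }
      v <- mids[k + 1L, ]
    } else {
      stop("unknown quantity '", quantity, "'")
    }
  }
  if (length(excl)) v[names(v) %in% excl] <- NA_real_
  v
}

# per-sample MID fractions for one fragment (corrects nothing; uses stored
# fractions when corrected, else normalizes raw counts per sample)
fraction_matrix <- function(data, fragment) {
  v <- data$values[[fragment]]
  if (isTRUE(data$corrected)) return(v)
  apply(v, 2L, mid)
}

#' Time-course series of group statistics
#'
#' Computes a quantity per group, ordered by each group's time point
#' (ascending; ties broken by group name).
#'
#' @param data A [trace_dataset] whose groups all carry time points.
#' @param fragment Fragment name.
#' @param quantity `"abundance"`, `"enrichment"`, or `"M<k>"`.
#' @return A [group_stats] data frame with an extra `time` column, rows in
#'   time order.
#' @export
kinetic_series <- function(data, fragment, quantity = "enrichment") {
  if (!length(data$groups)) stop("dataset has no groups")
  times <- vapply(data$groups, function(g) g$time, numeric(1L))
  missing <- names(times)[is.na(times)]
  if (length(missing)) {
    stop("group(s) missing a time point: ", paste(missing, collapse = ", "))
  }
  ord <- order(times, names(times))
  st <- group_stats(sample_values(data, fragment, quantity), data$groups[ord])
  st$time <- as.numeric(times[ord])
  st
}

#' Cross-metabolite comparison table
#'
#' Builds the (metabolite x group) statistics behind a grouped bar chart
#' comparing abundance, enrichment, or a single isotopologue across
#' metabolites and conditions.
#'
#' @param data A grouped [trace_dataset].
#' @param metabolites Character vector of fragment names.
#' @param groups Character vector of group names (default: all).
#' @param quantity `"abundance"`, `"enrichment"`, or `"M<k>"`.
#' @return A data frame of group statistics keyed by `fragment` and
#'   `group`; fragments that are absent or out of range for the requested
#'   isotopologue are collected in the `skipped` attribute, not errors.
#' @export
compare_metabolites <- function(data, metabolites, groups = names(data$groups),
                                quantity = "enrichment") {
  sel_groups <- data$groups[groups]
  if (anyNA(names(sel_groups))) {
    stop("unknown group(s): ",
         paste(setdiff(groups, names(data$groups)), collapse = ", "))
  }
  rows <- list()
  skipped <- character(0)
  for (m in metabolites) {
    if (!m %in% names(data$fragments)) {
      skipped <- c(skipped, m)
      next
    }
    st <- tryCatch(group_stats(sample_values(data, m, quantity), sel_groups),
                   error = function(e) NULL)
    if (is.null(st)) {
      skipped <- c(skipped, m)
      next
    }
    st$fragment <- m
    rows[[m]] <- st
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(group = character(0), mean = numeric(0), sd = numeric(0),
               n = integer(0), fragment = character(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Limit the isotopologues shown for a fragment
#'
#' A display-side truncation: graphs show channels M0..M(limit-1) only. The
#' underlying data are unchanged and the displayed MID fractions are NOT
#' renormalized, so truncated plots remain honest about hidden tail mass.
#'
#' @param data A [trace_dataset].
#' @param fragment Fragment name.
#' @param limit Number of isotopologues to display, in
#'   `1..channel count`.
#' @return The dataset with the display limit recorded in its settings.
#' @export
isotopologue_limit <- function(data, fragment, limit) {
  if (!fragment %in% names(data$fragments)) {
    stop("fragment '", fragment, "' not in the dataset")
  }
  nchan <- nrow(data$values[[fragment]])
  limit <- as.integer(limit)
  if (is.na(limit) || limit < 1L || limit > nchan) {
    stop("isotopologue limit for '", fragment, "' must be in 1..", nchan)
  }
  data$settings$isotopologue_limits[[fragment]] <- limit
  data
}

# channels of a fragment honoring any display limit
display_channels <- function(data, fragment) {
  nchan <- nrow(data$values[[fragment]])
  lim <- data$settings$isotopologue_limits[[fragment]]
  if (is.null(lim)) nchan else min(lim, nchan)
}
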