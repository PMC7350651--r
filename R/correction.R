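#' Build the natural-isotope-abundance correction matrix
#'
#' Constructs the matrix that maps a fragment's true tracer-labeling
#' distribution onto the isotopologue intensities a nominal-resolution mass
#' spectrometer observes. Column `j` (true label count j, 0-based) is the
#' natural-abundance spectrum of the fragment with `j` tracer atoms fixed as
#' labeled: the spectrum of the composition minus all N labelable atoms,
#' convolved with the natural pattern of the remaining `N - j` labelable
#' atoms, shifted by `j * shift` rows. Non-labelable atoms of the tracer
#' element (e.g. derivatization carbons) always contribute natural
#' abundance.
#'
#' @param frag A [fragment_spec] with a formula and `n_labelable` set.
#' @param tracer A [tracer_spec].
#' @param channels Number of measured mass channels R (M0..M(R-1)).
#' @return An `R x (N+1)` matrix of class `correction_matrix`; entry
#'   `[i, j]` is the probability that a molecule carrying exactly `j - 1`
#'   labels is observed at shift `i - 1`. Columns sum to <= 1 (tail mass
#'   beyond the measured channels is truncated, never renormalized).
#' @export
#' @examples
#' frag <- fragment_spec("pyr174", "C6H12NO2", 3)
#' build_correction_matrix(frag, tracer_spec("C"), channels = 4)
build_correction_matrix <- function(frag, tracer, channels) {
  stopifnot(inherits(frag, "fragment_spec"), inherits(tracer, "tracer_spec"))
  channels <- as.integer(channels)
  if (is.na(channels) || channels < 1L) stop("channels must be >= 1")
  if (is.null(frag$composition) || is.na(frag$n_labelable)) {
    stop("fragment '", frag$name, "' has no formula or labelable-atom count; ",
         "cannot build a correction matrix")
  }
  n_lab <- frag$n_labelable
  comp <- frag$composition
  n_tracer <- if (tracer$element %in% names(comp)) comp[[tracer$element]] else 0L
  if (n_lab > n_tracer) {
    stop("fragment '", frag$name, "': n_labelable (", n_lab,
         ") exceeds the ", tracer$element, " atom count in ",
         format_formula(comp), " (", n_tracer, ")")
  }
  if (channels < n_lab + 1L) {
    stop("fragment '", frag$name, "' is under-measured: ", channels,
         " channels for ", n_lab, " labelable atoms (need >= ", n_lab + 1L, ")")
  }
  max_shift <- channels - 1L
  # composition with all labelable tracer atoms removed
  base <- unclass(comp)
  base[tracer$element] <- n_tracer - n_lab
  base_spec <- composition_spectrum(element_composition(base), max_shift)
  tracer_dense <- pattern_dense(natural_pattern(tracer$element), max_shift)

  cm <- matrix(0, nrow = channels, ncol = n_lab + 1L,
               dimnames = list(paste0("M", 0:max_shift),
                               paste0("L", 0:n_lab)))
  for (j in 0:n_lab) {
    unl <- element_power(tracer_dense, n_lab - j, max_shift)
    col <- convolve_dist(base_spec, unl, max_shift)
    offset <- j * tracer$shift
    if (offset <= max_shift) {
      keep <- seq_len(channels - offset)
      cm[keep + offset, j + 1L] <- col[keep]
    }
  }
  structure(cm, class = c("correction_matrix", "matrix", "array"),
            fragment = frag$name, tracer = tracer$element)
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("<correction_matrix> fragment ", attr(x, "fragment"),
      ", tracer ", attr(x, "tracer"),
      " (", nrow(x), " channels x ", ncol(x), " label states)\n", sep = "")
  print(round(unclass(x), 5), ...)
  invisible(x)
}

#' Correct one measured isotopologue vector for natural abundance
#'
#' Solves `cm %*% x = raw` in the least-squares sense, clamps negative
#' components (baseline noise) to zero, and renormalizes to a mass
#' isotopomer distribution. Fractional output is invariant to overall
#' scaling of `raw`; the pre-normalization sum is returned as `scale` for
#' abundance work on a corrected basis.
#'
#' @param raw Non-negative numeric vector, one entry per measured channel
#'   M0..M(R-1).
#' @param cm A [build_correction_matrix] result with `R` rows.
#' @return A list: `fractions` (simplex of length N+1, or zeros), `scale`
#'   (sum of the clamped solution), and `status` (`"ok"` or `"empty"` for
#'   an all-zero measurement).
#' @export
correct_vector <- function(raw, cm) {
  raw <- as.numeric(raw)
  if (length(raw) != nrow(cm)) {
    stop("raw vector has ", length(raw), " channels but the correction matrix has ",
         nrow(cm), " rows")
  }
  if (all(raw == 0)) {
    return(list(fractions = numeric(ncol(cm)), scale = 0, status = "empty"))
  }
  x <- qr.coef(qr(unclass(cm)), raw)
  x[is.na(x)] <- 0
  x[x < 0] <- 0
  s <- sum(x)
  if (s == 0) {
    return(list(fractions = numeric(ncol(cm)), scale = 0, status = "empty"))
  }
  list(fractions = as.numeric(x / s), scale = s, status = "ok")
}

#' Correct a whole dataset for natural isotope abundance
#'
#' Applies [correct_vector] to every fragment x sample vector, each with its
#' own correction matrix, and flags the dataset corrected. Correcting an
#' already-corrected dataset is rejected (idempotence guard). Fragments
#' lacking a formula or labelable-atom count are skipped with a warning.
#'
#' @param data A [trace_dataset] flagged uncorrected.
#' @param tracer A [tracer_spec]; defaults to the tracer stored on the
#'   dataset.
#' @return The dataset with `values` holding corrected MID fractions,
#'   `scales` holding per-fragment x sample corrected absolute scales, and
#'   `corrected = TRUE`. The pre-correction channel sums remain in
#'   `abundance`.
#' @export
correct_dataset <- function(data, tracer = data$tracer) {
  stopifnot(inherits(data, "trace_dataset"))
  if (isTRUE(data$corrected)) {
    stop("dataset is already corrected for natural isotope abundance; ",
         "correction is not idempotent and has been refused")
  }
  if (is.null(tracer)) stop("no tracer specified for correction")
  stopifnot(inherits(tracer, "tracer_spec"))

  scales <- matrix(NA_real_, nrow = length(data$fragments),
                   ncol = length(data$samples),
                   dimnames = list(names(data$fragments), data$samples))
  skipped <- character(0)
  for (fn in names(data$fragments)) {
    frag <- data$fragments[[fn]]
    if (is.null(frag$composition) || is.na(frag$n_labelable)) {
      skipped <- c(skipped, fn)
      next
    }
    vals <- data$values[[fn]]
    cm <- build_correction_matrix(frag, tracer, channels = nrow(vals))
    out <- matrix(NA_real_, nrow = ncol(cm), ncol = ncol(vals),
                  dimnames = list(colnames(cm), colnames(vals)))
    rownames(out) <- paste0("M", seq_len(nrow(out)) - 1L)
    for (s in seq_len(ncol(vals))) {
      res <- correct_vector(vals[, s], cm)
      out[, s] <- if (res$status == "empty") NA_real_ else res$fractions
      scales[fn, s] <- res$scale
    }
    data$values[[fn]] <- out
  }
  if (length(skipped)) {
    warning("skipped fragment(s) with no formula or labelable-atom count: ",
            paste(skipped, collapse = ", "))
  }
  data$corrected <- TRUE
  data$tracer <- tracer
  data$scales <- scales
  data
}
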