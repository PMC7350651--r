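#' Natural isotope abundance table
#'
#' The package ships a read-only JSON table of representative terrestrial
#' isotopic compositions (IUPAC/CIAAW 2021 representative values) in
#' `inst/extdata/isotope_abundances.json`. Each element maps to a set of
#' integer nominal-mass shifts (0 = monoisotopic) and their probabilities,
#' which sum to 1. Users can audit the table with
#' [isotope_table_path()] or substitute their own with
#' [load_isotope_table()].
#'
#' @name isotope-table
NULL

# package-level cache for the active abundance table
.isotrace_env <- new.env(parent = emptyenv())

#' Path to the shipped isotope abundance JSON document
#'
#' @return Absolute path to the JSON file installed with the package.
#' @export
isotope_table_path <- function() {
  system.file("extdata", "isotope_abundances.json", package = "isotrace",
              mustWork = TRUE)
}

#' Load (or reload) an isotope abundance table
#'
#' Parses an abundance JSON document, validates it, and makes it the active
#' table for all spectrum and correction computations in this session.
#'
#' @param path Path to an abundance JSON document. Defaults to the table
#'   shipped with the package.
#' @return The table, invisibly: a list with `version` and `elements`, the
#'   latter a named list of [isotope_pattern] objects.
#' @export
load_isotope_table <- function(path = isotope_table_path()) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$elements) || !length(doc$elements)) {
    stop("abundance table at '", path, "' has no 'elements' entry")
  }
  elements <- lapply(names(doc$elements), function(sym) {
    e <- doc$elements[[sym]]
    isotope_pattern(sym, as.integer(e$shifts), as.numeric(e$abundances))
  })
  names(elements) <- names(doc$elements)
  tab <- list(version = doc$version %||% "unversioned", elements = elements)
  assign("isotope_table", tab, envir = .isotrace_env)
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

isotope_table <- function() {
  if (!exists("isotope_table", envir = .isotrace_env)) load_isotope_table()
  get("isotope_table", envir = .isotrace_env)
}

#' Version string of the active abundance table
#' @return Character scalar, e.g. `"IUPAC-2021-representative"`.
#' @export
isotope_table_version <- function() isotope_table()$version

#' Element symbols available in the active abundance table
#' @return Character vector of element symbols.
#' @export
list_elements <- function() names(isotope_table()$elements)

#' Construct an isotope pattern
#'
#' An isotope pattern is the natural-abundance distribution of one element:
#' integer mass shifts (strictly increasing, starting at 0) paired with
#' probabilities summing to 1.
#'
#' @param element Element symbol.
#' @param shifts Integer mass shifts, strictly increasing from 0.
#' @param abundances Probabilities in `[0, 1]` summing to 1 (within 1e-12;
#'   values are renormalized to machine precision).
#' @return An object of class `isotope_pattern`.
#' @export
isotope_pattern <- function(element, shifts, abundances) {
  stopifnot(is.character(element), length(element) == 1L)
  shifts <- as.integer(shifts)
  abundances <- as.numeric(abundances)
  if (length(shifts) != length(abundances) || !length(shifts)) {
    stop("pattern for '", element, "': shifts and abundances must be equal, nonzero length")
  }
  if (shifts[1L] != 0L || any(diff(shifts) <= 0L)) {
    stop("pattern for '", element, "': mass shifts must be strictly increasing from 0")
  }
  if (any(abundances < 0) || any(abundances > 1)) {
    stop("pattern for '", element, "': abundances must lie in [0, 1]")
  }
  s <- sum(abundances)
  if (abs(s - 1) > 1e-12) {
    stop("pattern for '", element, "': abundances sum to ", format(s), ", not 1")
  }
  structure(list(element = element, shifts = shifts, abundances = abundances / s),
            class = "isotope_pattern")
}

#' Natural abundance pattern of an element
#'
#' @param element Element symbol present in the active abundance table
#'   (at minimum C, H, N, O, Si, S, P).
#' @return An [isotope_pattern].
#' @export
#' @examples
#' natural_pattern("C")
natural_pattern <- function(element) {
  tab <- isotope_table()$elements
  if (!element %in% names(tab)) {
    stop("element '", element, "' is not in the abundance table (have: ",
         paste(names(tab), collapse = ", "), ")")
  }
  tab[[element]]
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> ", x$element, "\n", sep = "")
  for (i in seq_along(x$shifts)) {
    cat(sprintf("  M+%d  %.6f\n", x$shifts[i], x$abundances[i]))
  }
  invisible(x)
}

# dense probability vector indexed by shift 0..max_shift
pattern_dense <- function(pat, max_shift = max(pat$shifts)) {
  v <- numeric(max_shift + 1L)
  keep <- pat$shifts <= max_shift
  v[pat$shifts[keep] + 1L] <- pat$abundances[keep]
  v
}
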