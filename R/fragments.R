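#' Describe a measured metabolite fragment
#'
#' A fragment is the unit of measurement in single-tracer GC-MS tracing:
#' a metabolite-derived ion with a known total elemental composition
#' (including any derivatization atoms) of which only `n_labelable` atoms of
#' the tracer element can carry label. All other tracer-element atoms
#' contribute natural abundance only.
#'
#' @param name Display name, unique within a dataset (e.g. `"cit273"`).
#' @param formula Total ion formula (Hill notation) or an
#'   [element_composition]; may be `NULL` for pre-corrected data.
#' @param n_labelable Number of labelable tracer-element atoms N (>= 0);
#'   may be `NA` for pre-corrected data.
#' @param bigg_id BiGG metabolite identifier used for map overlay; empty
#'   string means unmapped.
#' @param metabolite Metabolite display name; defaults to `name`.
#' @return An object of class `fragment_spec`.
#' @export
fragment_spec <- function(name, formula = NULL, n_labelable = NA_integer_,
                          bigg_id = "", metabolite = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  comp <- NULL
  if (!is.null(formula)) {
    comp <- if (is.character(formula)) parse_formula(formula) else formula
    stopifnot(inherits(comp, "element_composition"))
  }
  n_labelable <- as.integer(n_labelable)
  if (!is.na(n_labelable) && n_labelable < 0L) {
    stop("fragment '", name, "': n_labelable must be >= 0")
  }
  structure(list(name = name, metabolite = metabolite, bigg_id = bigg_id,
                 composition = comp, n_labelable = n_labelable),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat("<fragment_spec> ", x$name,
      " (", x$metabolite,
      if (nzchar(x$bigg_id)) paste0(", BiGG ", x$bigg_id) else ", unmapped",
      ")\n", sep = "")
  cat("  formula: ",
      if (is.null(x$composition)) "<none>" else format_formula(x$composition),
      "   labelable atoms: ", x$n_labelable, "\n", sep = "")
  invisible(x)
}

#' Describe the tracer isotope
#'
#' @param element Tracer element symbol (must be in the abundance table).
#' @param shift Nominal mass shift per incorporated label; 1 for the common
#'   single-neutron tracers (13C, 15N, 2H).
#' @return An object of class `tracer_spec`.
#' @export
#' @examples
#' tracer_spec("C")          # 13C
#' tracer_spec("N")          # 15N
tracer_spec <- function(element, shift = 1L) {
  if (!element %in% list_elements()) {
    stop("tracer element '", element, "' is not in the abundance table")
  }
  shift <- as.integer(shift)
  if (is.na(shift) || shift < 1L) stop("tracer mass shift must be >= 1")
  structure(list(element = element, shift = shift), class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat("<tracer_spec> element ", x$element, ", +", x$shift,
      " mass unit(s) per label\n", sep = "")
  invisible(x)
}

# accept "13C" / "C13" / "2H" style tokens from the CLI
parse_tracer_token <- function(token) {
  m <- regmatches(token, regexec("^([0-9]*)([A-Z][a-z]?)([0-9]*)$", token))[[1L]]
  if (length(m) < 3L || !nzchar(m[3L])) stop("cannot parse tracer '", token, "'")
  tracer_spec(m[3L], 1L)
}
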