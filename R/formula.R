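#' Parse an elemental formula
#'
#' Parses plain Hill-style notation: element symbols (one uppercase letter
#' plus an optional lowercase letter), each followed by an optional positive
#' integer count. No parentheses, charges, or isotope prefixes — the dialect
#' matches how GC-MS fragment ion formulas are conventionally written
#' (e.g. `"C6H19NO3Si2"` for a TBDMS-derivatized fragment).
#'
#' @param formula_text A formula string, e.g. `"C6H12O6"`.
#' @return A named integer vector of per-element atom counts (an element
#'   composition). Repeated symbols accumulate. The empty string yields an
#'   empty composition.
#' @export
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C6H19NO3Si2")
parse_formula <- function(formula_text) {
  stopifnot(is.character(formula_text), length(formula_text) == 1L)
  txt <- trimws(formula_text)
  comp <- integer(0)
  if (!nzchar(txt)) return(element_composition(comp))
  known <- list_elements()
  pos <- 1L
  n <- nchar(txt)
  while (pos <= n) {
    rest <- substr(txt, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1L]]
    if (!length(m) || !nzchar(m[2L])) {
      stop("malformed formula '", formula_text, "': unexpected character '",
           substr(txt, pos, pos), "' at position ", pos)
    }
    sym <- m[2L]
    # a two-letter match may swallow the start of the next symbol when the
    # one-letter element is the valid one (e.g. "CO" is C then O, not Co)
    if (nchar(sym) == 2L && !sym %in% known && substr(sym, 1L, 1L) %in% known) {
      sym <- substr(sym, 1L, 1L)
      m[3L] <- ""
    }
    if (!sym %in% known) {
      stop("unknown element symbol '", sym, "' in formula '", formula_text,
           "' at position ", pos)
    }
    cnt <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    if (is.na(cnt) || cnt < 1L) {
      stop("malformed formula '", formula_text, "': bad count at position ", pos)
    }
    comp[sym] <- (if (sym %in% names(comp)) comp[[sym]] else 0L) + cnt
    pos <- pos + nchar(sym) + nchar(m[3L])
  }
  element_composition(comp)
}

#' Construct / validate an element composition
#'
#' @param counts Named integer vector of element symbol -> atom count.
#' @return A validated named integer vector of class `element_composition`.
#'   Zero-count entries are dropped; an empty composition is valid and
#'   represents a massless placeholder.
#' @export
element_composition <- function(counts = integer(0)) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("element composition entries must be named by element symbol")
    }
    counts <- vapply(counts, as.integer, integer(1L))
    if (any(is.na(counts)) || any(counts < 0L)) {
      stop("element counts must be non-negative integers")
    }
    unknown <- setdiff(names(counts), list_elements())
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
    counts <- counts[counts > 0L]
  }
  structure(as.integer(counts), names = names(counts),
            class = "element_composition")
}

#' @export
print.element_composition <- function(x, ...) {
  if (!length(x)) {
    cat("<element_composition> (empty)\n")
  } else {
    cat("<element_composition> ",
        paste0(names(x), ifelse(x > 1L, x, ""), collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Format a composition back to a formula string
#' @param comp An `element_composition`.
#' @return Character scalar in the symbol-count concatenation used on input.
#' @export
format_formula <- function(comp) {
  if (!length(comp)) return("")
  paste0(names(comp), ifelse(unclass(comp) > 1L, unclass(comp), ""), collapse = "")
}
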