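# Independent oracles, built from first principles and deliberately not
# sharing code paths with the package implementation:
#  - oracle_spectrum: brute-force enumeration over every atom's isotope
#    assignment (no convolution)
#  - oracle_correction_matrix: the matrix construction re-derived on top of
#    oracle_spectrum
#  - oracle_correct: pseudo-inverse solve (MASS::ginv, SVD-based) instead of
#    the package's QR least squares

oracle_spectrum <- function(comp, max_shift) {
  shifts_list <- list()
  probs_list <- list()
  for (sym in names(comp)) {
    pat <- natural_pattern(sym)
    for (i in seq_len(comp[[sym]])) {
      shifts_list[[length(shifts_list) + 1L]] <- pat$shifts
      probs_list[[length(probs_list) + 1L]] <- pat$abundances
    }
  }
  if (!length(shifts_list)) return(c(1, numeric(max_shift)))
  idx <- as.matrix(expand.grid(lapply(shifts_list, seq_along),
                               KEEP.OUT.ATTRS = FALSE))
  S <- vapply(seq_along(shifts_list),
              function(a) shifts_list[[a]][idx[, a]], numeric(nrow(idx)))
  P <- vapply(seq_along(probs_list),
              function(a) probs_list[[a]][idx[, a]], numeric(nrow(idx)))
  s <- rowSums(matrix(S, nrow = nrow(idx)))
  p <- Reduce(`*`, asplit(matrix(P, nrow = nrow(idx)), 2L))
  out <- numeric(max_shift + 1L)
  keep <- s <= max_shift
  agg <- tapply(p[keep], s[keep], sum)
  out[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  out
}

oracle_correction_matrix <- function(frag, tracer, channels) {
  comp <- unclass(frag$composition)
  n_lab <- frag$n_labelable
  base <- comp
  base[tracer$element] <- base[tracer$element] - n_lab
  max_shift <- channels - 1L
  cm <- matrix(0, nrow = channels, ncol = n_lab + 1L)
  for (j in 0:n_lab) {
    unl <- base
    unl[tracer$element] <- unl[tracer$element] + (n_lab - j)
    col <- oracle_spectrum(element_composition(unl), max_shift)
    offset <- j * tracer$shift
    if (offset <= max_shift) {
      keep <- seq_len(channels - offset)
      cm[keep + offset, j + 1L] <- col[keep]
    }
  }
  cm
}

oracle_correct <- function(raw, cm) {
  x <- as.numeric(MASS::ginv(cm) %*% raw)
  x[x < 0] <- 0
  if (sum(x) == 0) return(numeric(ncol(cm)))
  x / sum(x)
}

# a random small fragment suitable for full-atom enumeration
random_small_fragment <- function(name = "frag") {
  n_lab <- sample(1:4, 1L)
  comp <- c(C = n_lab + sample(0:2, 1L))
  hetero <- sample(c("H", "N", "O", "Si", "S", "P"), sample(1:3, 1L))
  for (h in hetero) comp[h] <- sample(1:2, 1L)
  fragment_spec(name, element_composition(comp), n_lab)
}

# a random fragment for round-trip tests (no enumeration, can be larger)
random_fragment <- function(name = "frag", max_tracer = 8L) {
  n_lab <- sample(1:max_tracer, 1L)
  comp <- c(C = n_lab + sample(0:6, 1L))
  hetero <- sample(c("H", "N", "O", "Si", "S", "P"), sample(1:4, 1L))
  for (h in hetero) comp[h] <- sample(1:12, 1L)
  fragment_spec(name, element_composition(comp), n_lab)
}

random_simplex <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

# tiny two-fragment grouped dataset used across analytics / io tests
tiny_dataset <- function(corrected = FALSE) {
  f1 <- fragment_spec("cit273", "C6H8O7", 3L, bigg_id = "cit_c",
                      metabolite = "Citrate")
  f2 <- fragment_spec("pyr174", "C3H4O3", 2L, bigg_id = "pyr_c",
                      metabolite = "Pyruvate")
  v1 <- matrix(c(50, 30, 15, 5,
                 40, 35, 18, 7,
                 20, 30, 30, 20,
                 22, 28, 31, 19), nrow = 4,
               dimnames = list(paste0("M", 0:3),
                               c("a1", "a2", "b1", "b2")))
  v2 <- matrix(c(80, 15, 5,
                 82, 13, 5,
                 60, 25, 15,
                 58, 27, 15), nrow = 3,
               dimnames = list(paste0("M", 0:2),
                               c("a1", "a2", "b1", "b2")))
  if (corrected) {
    v1 <- apply(v1, 2L, function(x) x / sum(x))
    v2 <- apply(v2, 2L, function(x) x / sum(x))
  }
  trace_dataset(
    list(f1, f2), list(cit273 = v1, pyr174 = v2), corrected = corrected,
    groups = list(sample_group("ctrl", c("a1", "a2"), cell_count = 1e5),
                  sample_group("treat", c("b1", "b2"), cell_count = 2e5))
  )
}

count_elements <- function(doc, type) {
  sum(vapply(doc$elements, function(e) identical(e$type, type), logical(1L)))
}
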