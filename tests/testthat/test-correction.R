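tr13C <- tracer_spec("C")

test_that("correction matrix columns follow the closed form for C2", {
  p <- 0.0107
  frag <- fragment_spec("c2", "C2", 2L)
  cm <- build_correction_matrix(frag, tr13C, channels = 3L)
  expect_equal(unclass(cm),
               matrix(c((1 - p)^2, 2 * p * (1 - p), p^2,
                        0, 1 - p, p,
                        0, 0, 1), nrow = 3,
                      dimnames = list(paste0("M", 0:2), paste0("L", 0:2))),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("N = 0 gives a single column equal to the natural spectrum", {
  frag <- fragment_spec("glc", "C6H12O6", 0L)
  cm <- build_correction_matrix(frag, tr13C, channels = 4L)
  expect_equal(ncol(cm), 1L)
  expect_equal(as.numeric(cm), composition_spectrum("C6H12O6", 3L))
})

test_that("column 0 top entry is the product of monoisotopic probabilities", {
  frag <- fragment_spec("x", "C6H19NO3Si2", 2L)
  cm <- build_correction_matrix(frag, tr13C, channels = 3L)
  tab <- c(C = 0.9893, H = 0.999885, N = 0.99636, O = 0.99757, Si = 0.92223)
  expect_equal(cm[1L, 1L],
               prod(tab[c("C", "H", "N", "O", "Si")] ^ c(6, 19, 1, 3, 2)),
               tolerance = 1e-12)
})

test_that("matrix structure: label-lower-triangular, column 0 = full spectrum", {
  set.seed(3)
  for (i in 1:10) {
    frag <- random_fragment()
    channels <- frag$n_labelable + 1L + sample(0:2, 1L)
    cm <- build_correction_matrix(frag, tr13C, channels)
    for (j in seq_len(ncol(cm))) {
      if (j > 1L) expect_true(all(cm[seq_len(j - 1L), j] == 0))
      expect_lte(sum(cm[, j]), 1 + 1e-9)
    }
    expect_equal(as.numeric(cm[, 1L]),
                 composition_spectrum(frag$composition, channels - 1L),
                 tolerance = 1e-12)
  }
})

test_that("matrix construction guards its preconditions", {
  expect_error(build_correction_matrix(fragment_spec("x", "C2H4", 3L),
                                       tr13C, 4L), "exceeds")
  # under-measured: fewer channels than label states
  expect_error(build_correction_matrix(fragment_spec("x", "C4", 4L),
                                       tr13C, 3L), "under-measured")
  expect_error(build_correction_matrix(fragment_spec("x", NULL, 2L),
                                       tr13C, 3L), "no formula")
})

test_that("an unlabeled sample corrects to pure M0 at any scale", {
  frag <- fragment_spec("x", "C6H19NO3Si2", 3L)
  cm <- build_correction_matrix(frag, tr13C, channels = 4L)
  nat <- composition_spectrum(frag$composition, 3L)
  for (scale in c(1, 1e-3, 2.7e6)) {
    res <- correct_vector(nat * scale, cm)
    expect_equal(res$fractions, c(1, 0, 0, 0), tolerance = 1e-6)
  }
})

test_that("round-trip recovers random simplex MIDs", {
  set.seed(19)
  for (i in 1:25) {
    frag <- random_fragment(max_tracer = 8L)
    channels <- frag$n_labelable + 1L
    cm <- build_correction_matrix(frag, tr13C, channels)
    x <- random_simplex(channels)
    res <- correct_vector(as.numeric(cm %*% x), cm)
    expect_lt(max(abs(res$fractions - x)), 1e-8)
  }
})

test_that("overdetermined systems (extra channels) still round-trip", {
  set.seed(23)
  frag <- fragment_spec("x", "C5H9NO4", 3L)
  cm <- build_correction_matrix(frag, tr13C, channels = 6L)
  expect_equal(dim(unclass(cm)), c(6L, 4L))
  x <- random_simplex(4L)
  res <- correct_vector(as.numeric(cm %*% x), cm)
  expect_lt(max(abs(res$fractions - x)), 1e-8)
})

test_that("corrected output is always a simplex, even under negative noise", {
  frag <- fragment_spec("x", "C3H4O3", 2L)
  cm <- build_correction_matrix(frag, tr13C, channels = 3L)
  raw <- as.numeric(cm %*% c(0.9, 0.05, 0.05))
  raw[2L] <- raw[2L] - 0.06  # baseline dip below the natural contribution
  res <- correct_vector(raw, cm)
  expect_true(all(res$fractions >= 0))
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
})

test_that("fractional output is scale-equivariant; scale tracks the input", {
  set.seed(5)
  frag <- random_fragment()
  cm <- build_correction_matrix(frag, tr13C, frag$n_labelable + 1L)
  raw <- as.numeric(cm %*% random_simplex(ncol(cm))) * 1e5
  base <- correct_vector(raw, cm)
  for (c in c(0.01, 3, 1e4)) {
    res <- correct_vector(c * raw, cm)
    expect_equal(res$fractions, base$fractions, tolerance = 1e-12)
    expect_equal(res$scale, c * base$scale, tolerance = 1e-9)
  }
})

test_that("all-zero measurements are flagged empty, not errors", {
  frag <- fragment_spec("x", "C2", 2L)
  cm <- build_correction_matrix(frag, tr13C, 3L)
  res <- correct_vector(c(0, 0, 0), cm)
  expect_equal(res$status, "empty")
  expect_equal(res$fractions, c(0, 0, 0))
  expect_equal(res$scale, 0)
})

test_that("corrected MIDs agree with the independent enumeration oracle", {
  skip_if_not_installed("MASS")
  set.seed(31)
  for (i in 1:20) {
    frag <- random_small_fragment()
    channels <- frag$n_labelable + 1L
    cm <- build_correction_matrix(frag, tr13C, channels)
    ocm <- oracle_correction_matrix(frag, tr13C, channels)
    expect_equal(unclass(cm), ocm, tolerance = 1e-10,
                 ignore_attr = TRUE)
    raw <- as.numeric(ocm %*% random_simplex(channels)) *
      stats::runif(1, 1e3, 1e6)
    expect_equal(correct_vector(raw, cm)$fractions, oracle_correct(raw, ocm),
                 tolerance = 1e-6)
  }
})

test_that("correct_dataset corrects every vector and guards idempotence", {
  ds <- tiny_dataset()
  cds <- correct_dataset(ds, tr13C)
  expect_true(cds$corrected)
  for (fn in names(cds$fragments)) {
    sums <- colSums(cds$values[[fn]])
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
  # pre-correction abundance basis survives correction
  expect_equal(cds$abundance, ds$abundance)
  expect_error(correct_dataset(cds, tr13C), "already corrected")
})

test_that("fragments without formulas are skipped with a warning", {
  f1 <- fragment_spec("good", "C2", 2L)
  f2 <- fragment_spec("bad")  # no formula, no N
  v <- matrix(c(10, 1, 0.1), nrow = 3,
              dimnames = list(paste0("M", 0:2), "s1"))
  ds <- trace_dataset(list(f1, f2), list(good = v, bad = v))
  expect_warning(cds <- correct_dataset(ds, tr13C), "bad")
  expect_true(cds$corrected)
  expect_equal(cds$values$bad, v)  # untouched
})
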