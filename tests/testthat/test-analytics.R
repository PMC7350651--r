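test_that("mid divides by the isotopologue total", {
  expect_equal(mid(c(10, 0, 0)), c(1, 0, 0))
  expect_equal(mid(c(50, 30, 20)), c(0.5, 0.3, 0.2))
  expect_equal(mid(rep(2, 4)), rep(0.25, 4))
  expect_error(mid(c(-1, 2)), "non-negative")
  expect_true(all(is.na(mid(c(0, 0, 0)))))  # flagged missing, not NaN
})

test_that("mid always sums to 1 for non-empty non-negative input", {
  set.seed(2)
  for (i in 1:50) {
    v <- stats::runif(sample(1:9, 1L), 0, 1e6)
    expect_equal(sum(mid(v)), 1, tolerance = 1e-12)
  }
})

test_that("enrichment is the label-weighted mean fraction", {
  expect_equal(enrichment(c(0, 0, 0, 0, 0, 1), 5), 1)
  expect_equal(enrichment(c(1, 0, 0), 2), 0)
  expect_equal(enrichment(c(0.5, 0, 0.5), 2), 0.5)
  expect_error(enrichment(c(1, 0), 0), ">= 1")
  expect_error(enrichment(c(0.5, 0.25, 0.25), 1), "labelable")
  expect_true(is.na(enrichment(c(NA, NA), 1)))
})

test_that("enrichment stays in [0,1] and is monotone under upward mass moves", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(2:8, 1L)
    m <- random_simplex(n + 1L)
    e <- enrichment(m, n)
    expect_gte(e, 0)
    expect_lte(e, 1)
    # move mass from a lower to a higher isotopologue
    lo <- which(m[-length(m)] > 0)[1L]
    m2 <- m
    d <- m[lo] / 2
    m2[lo] <- m2[lo] - d
    m2[length(m2)] <- m2[length(m2)] + d
    expect_gte(enrichment(m2, n), e)
  }
})

test_that("total_abundance sums the measured channels", {
  expect_equal(total_abundance(c(50, 30, 20)), 100)
  expect_equal(total_abundance(numeric(3)), 0)
  expect_equal(total_abundance(7), 7)
})

test_that("group_stats follows the sample-SD convention", {
  g <- list(sample_group("a", c("s1", "s2", "s3")),
            sample_group("b", "s4"),
            sample_group("c", c("s5", "s6", "s7")))
  v <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 5, s5 = 0.1, s6 = 0.1, s7 = 0.1)
  st <- group_stats(v, g)
  expect_equal(st$mean, c(2, 5, 0.1))
  expect_equal(st$sd, c(1, 0, 0))   # n-1 denominator; SD 0 for singletons
  expect_equal(st$n, c(3L, 1L, 3L))
})

test_that("group_stats excludes missing values and flags empty groups", {
  g <- list(sample_group("a", c("s1", "s2")), sample_group("b", c("s3", "s4")))
  v <- c(s1 = 1, s2 = NA, s3 = NA, s4 = NA)
  st <- group_stats(v, g)
  expect_equal(st$n, c(1L, 0L))
  expect_equal(st$mean[1L], 1)
  expect_true(is.na(st$mean[2L]))
})

test_that("duplicated sample columns double n and preserve the mean", {
  g1 <- list(sample_group("a", c("s1", "s2")))
  g2 <- list(sample_group("a", c("s1", "s2", "s1b", "s2b")))
  v <- c(s1 = 2, s2 = 4)
  v2 <- c(v, s1b = 2, s2b = 4)
  expect_equal(group_stats(v2, g2)$n, 2L * group_stats(v, g1)$n)
  expect_equal(group_stats(v2, g2)$mean, group_stats(v, g1)$mean)
})

test_that("normalization applies standard -> cells -> reference in order", {
  ds <- tiny_dataset()
  spec <- normalization_spec(internal_standard = "pyr174",
                             cell_counts = c(ctrl = 1e5, treat = 2e5),
                             reference_group = "ctrl")
  nds <- normalize_abundances(ds, spec)
  A <- ds$abundance
  # one-shot composite scaling must agree with the sequential contract
  comp <- A
  comp <- sweep(comp, 2L, A["pyr174", ], "/")
  comp <- sweep(comp, 2L, c(1e5, 1e5, 2e5, 2e5), "/")
  comp <- sweep(comp, 1L, rowMeans(comp[, c("a1", "a2")]), "/")
  expect_equal(nds$norm_abundance, comp, tolerance = 1e-12)
  # reference group mean is exactly 1 for every metabolite
  expect_equal(unname(rowMeans(nds$norm_abundance[, c("a1", "a2")])),
               c(1, 1))
})

test_that("single normalization steps behave as documented", {
  ds <- tiny_dataset()
  # standard only: A(m)/A(std) per sample
  n1 <- normalize_abundances(ds, normalization_spec(internal_standard = "pyr174"))
  expect_equal(n1$norm_abundance["cit273", "a1"],
               ds$abundance["cit273", "a1"] / ds$abundance["pyr174", "a1"])
  # cell counts only: group-wise division by the entered counts
  n2 <- normalize_abundances(ds, normalization_spec(
    cell_counts = c(ctrl = 638333, treat = 668750)))
  expect_equal(n2$norm_abundance["cit273", "a1"],
               ds$abundance["cit273", "a1"] / 638333)
  expect_equal(n2$norm_abundance["cit273", "b1"],
               ds$abundance["cit273", "b1"] / 668750)
  expect_error(normalize_abundances(ds, normalization_spec(
    internal_standard = "nope")), "not in the dataset")
})

test_that("a zero internal standard flags the sample, never divides by 0", {
  ds <- tiny_dataset()
  ds$abundance["pyr174", "b1"] <- 0
  expect_warning(
    nds <- normalize_abundances(ds, normalization_spec(internal_standard = "pyr174")),
    "b1")
  expect_true("b1" %in% nds$excluded_samples)
  st <- group_stats(isotrace:::sample_values(nds, "cit273", "abundance"),
                    nds$groups)
  expect_equal(st$n, c(2L, 1L))  # b1 excluded from the treat group
})

test_that("quantitative abundance is single-point linear calibration", {
  ds <- tiny_dataset()
  ds$abundance["cit273", ] <- 200
  spec <- normalization_spec(standards = data.frame(
    fragment = c("cit273", "pyr174"), amount = c(10, 5), response = c(100, 0)))
  qa <- quantitative_abundance(ds, spec)
  expect_equal(unname(qa$amounts["cit273", "a1"]), 20)
  expect_equal(qa$unquantified, "pyr174")  # zero response -> unquantified
  ds$abundance["cit273", ] <- 0
  expect_equal(unname(quantitative_abundance(ds, spec)$amounts["cit273", "a1"]), 0)
})

test_that("kinetic_series sorts by time with group-name tie-break", {
  ds <- tiny_dataset()
  ds$groups$ctrl$time <- 4
  ds$groups$treat$time <- 0
  st <- kinetic_series(ds, "cit273", "abundance")
  expect_equal(st$group, c("treat", "ctrl"))
  expect_equal(st$time, c(0, 4))
  # duplicate time points: both kept, ordered by name
  ds$groups$ctrl$time <- 0
  st2 <- kinetic_series(ds, "cit273", "abundance")
  expect_equal(st2$group, c("ctrl", "treat"))
  ds$groups$treat$time <- NA_real_
  expect_error(kinetic_series(ds, "cit273"), "treat")
})

test_that("compare_metabolites yields metabolite x group statistics", {
  ds <- correct_dataset(tiny_dataset(), tracer_spec("C"))
  tab <- compare_metabolites(ds, c("cit273", "pyr174"), quantity = "enrichment")
  expect_equal(nrow(tab), 4L)  # 2 metabolites x 2 groups
  expect_setequal(unique(tab$fragment), c("cit273", "pyr174"))
  empty <- compare_metabolites(ds, character(0))
  expect_equal(nrow(empty), 0L)
  # absent metabolite and out-of-range isotopologue land in 'skipped'
  tab2 <- compare_metabolites(ds, c("cit273", "ghost"), quantity = "M9")
  expect_setequal(attr(tab2, "skipped"), c("cit273", "ghost"))
})

test_that("isotopologue_limit truncates the view without renormalizing", {
  ds <- tiny_dataset()
  ds <- isotopologue_limit(ds, "cit273", 3L)
  expect_equal(isotrace:::display_channels(ds, "cit273"), 3L)
  expect_equal(nrow(ds$values$cit273), 4L)  # data untouched
  sp <- graph_spec("mid", "cit273")
  st <- graph_stats(ds, sp)
  expect_setequal(unique(st$isotopologue), c("M0", "M1", "M2"))
  # displayed fractions keep their full-MID values (no renormalization)
  full <- mid(ds$values$cit273[, "a1"])
  expect_equal(st$mean[st$isotopologue == "M0" & st$group == "ctrl"],
               mean(c(full[1L], mid(ds$values$cit273[, "a2"])[1L])))
  expect_error(isotopologue_limit(ds, "cit273", 0L), "1..4")
  expect_error(isotopologue_limit(ds, "cit273", 5L), "1..4")
  expect_equal(isotrace:::display_channels(
    isotopologue_limit(ds, "cit273", 4L), "cit273"), 4L)
})
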