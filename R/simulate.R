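#' Specify a synthetic tracing experiment
#'
#' The generator is the package's forward model: choose true MIDs and
#' abundance scales per fragment and group, push them through the same
#' correction matrices the solver uses, add multiplicative noise, and emit
#' an uncorrected dataset with known ground truth.
#'
#' @param fragments List of [fragment_spec] (formula and `n_labelable`
#'   required).
#' @param groups List of lists with `name`, `n_reps`, and optional `time`
#'   and `cell_count`.
#' @param true_mids Named list fragment -> named list group -> simplex of
#'   length `n_labelable + 1` (the planted labeling distribution).
#' @param scales Named list fragment -> named list group -> positive
#'   abundance scale (total ion counts).
#' @param cv Coefficient of variation of the per-channel multiplicative
#'   Gaussian noise (>= 0); the noise factor is truncated below at 0.
#' @param seed Integer seed controlling all randomness.
#' @param tracer A [tracer_spec] for the forward model.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(fragments, groups, true_mids, scales, cv = 0,
                            seed = 42L, tracer = tracer_spec("C")) {
  stopifnot(cv >= 0)
  for (f in fragments) {
    stopifnot(inherits(f, "fragment_spec"))
    for (g in groups) {
      m <- true_mids[[f$name]][[g$name]]
      if (is.null(m) || length(m) != f$n_labelable + 1L) {
        stop("true MID for fragment '", f$name, "', group '", g$name,
             "' must have length ", f$n_labelable + 1L)
      }
      if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
        stop("true MID for '", f$name, "'/'", g$name, "' is not a simplex")
      }
    }
  }
  structure(list(fragments = fragments, groups = groups,
                 true_mids = true_mids, scales = scales, cv = cv,
                 seed = as.integer(seed), tracer = tracer),
            class = "simulation_spec")
}

#' Simulate an uncorrected dataset from planted ground truth
#'
#' For every fragment x sample the raw channel vector is
#' `scale * (cm %*% true_mid) * (1 + noise)`, with `cm` the fragment's
#' correction matrix (the forward natural-abundance model) and per-channel
#' independent Gaussian noise of standard deviation `cv`, truncated so the
#' multiplicative factor is never negative. A fixed seed reproduces the
#' output exactly.
#'
#' @param spec A [simulation_spec].
#' @return A [trace_dataset], uncorrected and grouped, with the planted
#'   truth attached as attributes `true_mids` and `scales`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  sample_ids <- unlist(lapply(spec$groups, function(g)
    paste0(g$name, "_", seq_len(g$n_reps))))
  values <- list()
  for (f in spec$fragments) {
    channels <- f$n_labelable + 1L
    cm <- build_correction_matrix(f, spec$tracer, channels)
    mat <- matrix(0, nrow = channels, ncol = length(sample_ids),
                  dimnames = list(paste0("M", 0:(channels - 1L)), sample_ids))
    col <- 1L
    for (g in spec$groups) {
      expected <- as.numeric(cm %*% spec$true_mids[[f$name]][[g$name]]) *
        spec$scales[[f$name]][[g$name]]
      for (r in seq_len(g$n_reps)) {
        noise <- pmax(1 + stats::rnorm(channels, 0, spec$cv), 0)
        mat[, col] <- expected * noise
        col <- col + 1L
      }
    }
    values[[f$name]] <- mat
  }
  groups <- lapply(spec$groups, function(g) sample_group(
    g$name, paste0(g$name, "_", seq_len(g$n_reps)),
    time = g$time %||% NA_real_, cell_count = g$cell_count %||% NA_real_))
  ds <- trace_dataset(spec$fragments, values, corrected = FALSE,
                      groups = groups, tracer = spec$tracer)
  attr(ds, "true_mids") <- spec$true_mids
  attr(ds, "scales") <- spec$scales
  ds
}

#' Simulate and serialize an uncorrected CSV
#'
#' @param spec A [simulation_spec].
#' @param path Optional output path; when `NULL` the CSV content is
#'   returned as a character vector of lines.
#' @return `path` invisibly, or the CSV lines.
#' @export
simulate_uncorrected <- function(spec, path = NULL) {
  ds <- simulate_dataset(spec)
  tmp <- path %||% tempfile(fileext = ".csv")
  write_trace_csv(ds, tmp)
  if (is.null(path)) {
    on.exit(unlink(tmp))
    return(readLines(tmp))
  }
  invisible(path)
}

huh7_truth <- function() {
  # planted labeling for a [U-13C5]glutamine-style two-condition experiment:
  # hypoxia shows reductive carboxylation (high M5 citrate, 9x normoxia)
  frag <- function(name, formula, n, bigg, met) {
    fragment_spec(name, formula, n, bigg_id = bigg, metabolite = met)
  }
  fragments <- list(
    frag("cit273", "C20H39O7Si2", 6L, "cit_c", "Citrate"),
    frag("akg346", "C14H28NO5Si2", 5L, "akg_c", "alpha-Ketoglutarate"),
    frag("succ289", "C12H25O4Si2", 4L, "succ_c", "Succinate"),
    frag("fum287", "C12H23O4Si2", 4L, "fum_c", "Fumarate"),
    frag("mal419", "C18H39O5Si3", 4L, "mal__L_c", "Malate"),
    frag("glu432", "C19H42NO4Si3", 5L, "glu__L_c", "Glutamate"),
    frag("pyr174", "C6H12NO2", 3L, "pyr_c", "Pyruvate"),
    frag("lac261", "C11H25O3Si2", 3L, "lac__L_c", "Lactate"),
    frag("nor260", "C11H26NO2Si", 5L, "", "Norvaline (internal standard)")
  )
  mids <- list(
    cit273 = list(Normoxia = c(0.35, 0.05, 0.18, 0.06, 0.25, 0.02, 0.09),
                  Hypoxia  = c(0.25, 0.04, 0.10, 0.08, 0.20, 0.18, 0.15)),
    akg346 = list(Normoxia = c(0.30, 0.04, 0.12, 0.08, 0.10, 0.36),
                  Hypoxia  = c(0.22, 0.04, 0.08, 0.08, 0.12, 0.46)),
    succ289 = list(Normoxia = c(0.40, 0.06, 0.14, 0.10, 0.30),
                   Hypoxia  = c(0.36, 0.06, 0.12, 0.14, 0.32)),
    fum287 = list(Normoxia = c(0.42, 0.06, 0.14, 0.10, 0.28),
                  Hypoxia  = c(0.40, 0.06, 0.12, 0.14, 0.28)),
    mal419 = list(Normoxia = c(0.44, 0.06, 0.14, 0.10, 0.26),
                  Hypoxia  = c(0.38, 0.06, 0.12, 0.16, 0.28)),
    glu432 = list(Normoxia = c(0.25, 0.04, 0.10, 0.08, 0.08, 0.45),
                  Hypoxia  = c(0.20, 0.04, 0.08, 0.08, 0.10, 0.50)),
    pyr174 = list(Normoxia = c(0.88, 0.04, 0.05, 0.03),
                  Hypoxia  = c(0.86, 0.04, 0.06, 0.04)),
    lac261 = list(Normoxia = c(0.90, 0.03, 0.04, 0.03),
                  Hypoxia  = c(0.88, 0.03, 0.05, 0.04)),
    nor260 = list(Normoxia = c(1, 0, 0, 0, 0, 0),
                  Hypoxia  = c(1, 0, 0, 0, 0, 0))
  )
  # raw-count scales: TCA pools drop in hypoxia; the spiked standard is flat
  scales <- list(
    cit273 = list(Normoxia = 8.0e5, Hypoxia = 4.5e5),
    akg346 = list(Normoxia = 3.0e5, Hypoxia = 2.0e5),
    succ289 = list(Normoxia = 5.0e5, Hypoxia = 3.6e5),
    fum287 = list(Normoxia = 2.4e5, Hypoxia = 1.7e5),
    mal419 = list(Normoxia = 6.0e5, Hypoxia = 4.0e5),
    glu432 = list(Normoxia = 9.0e5, Hypoxia = 7.0e5),
    pyr174 = list(Normoxia = 4.0e5, Hypoxia = 4.4e5),
    lac261 = list(Normoxia = 7.0e5, Hypoxia = 9.0e5),
    nor260 = list(Normoxia = 2.5e5, Hypoxia = 2.5e5)
  )
  list(fragments = fragments, mids = mids, scales = scales)
}

toy_escher_map <- function() {
  node <- function(bigg, x, y) {
    list(node_type = "metabolite", bigg_id = bigg, x = x, y = y,
         label_x = x + 15, label_y = y - 10)
  }
  list(
    list(map_name = "toy TCA map (synthetic)", map_id = "toy_tca",
         schema = "https://escher.github.io/escher/jsonschema/1-0-0#",
         homepage = "https://escher.github.io"),
    list(nodes = list(
           n1 = node("cit_c", 400, 200),
           n2 = node("akg_c", 600, 350),
           n3 = node("succ_c", 500, 550),
           n4 = node("fum_c", 300, 600),
           n5 = node("mal__L_c", 150, 450),
           n6 = node("glu__L_c", 800, 350),
           n7 = node("pyr_c", 400, 50),
           n8 = node("lac__L_c", 650, 50),
           m1 = list(node_type = "midmarker", x = 500, y = 275),
           m2 = list(node_type = "multimarker", x = 550, y = 450)
         ),
         reactions = list(),
         canvas = list(x = 0, y = -50, width = 1000, height = 750))
  )
}

#' Build the synthetic two-condition demonstration fixture
#'
#' Writes a complete, self-contained synthetic experiment emulating a
#' uniformly 13C-labeled glutamine tracing study in normoxic vs hypoxic
#' cultured cells:
#' TCA and glycolysis fragments plus a norvaline-like internal standard,
#' two groups ("Normoxia", cell count 638333; "Hypoxia", cell count
#' 668750), and planted MIDs whose hypoxia M5-citrate fraction is 9x the
#' normoxic one — the reductive-carboxylation signature, rebuilt as known
#' ground truth. All data are simulated; no measured values are included.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param cv Noise coefficient of variation (default 0.05, a realistic
#'   GC-MS technical variability).
#' @param n_reps Replicates per group.
#' @return A list with paths (`csv`, `map`, `groups`), the
#'   [simulation_spec] used, and the planted `truth`.
#' @export
make_huh7_like_fixture <- function(dir = tempdir(), seed = 42L, cv = 0.05,
                                   n_reps = 3L) {
  truth <- huh7_truth()
  groups <- list(
    list(name = "Normoxia", n_reps = n_reps, cell_count = 638333),
    list(name = "Hypoxia", n_reps = n_reps, cell_count = 668750)
  )
  spec <- simulation_spec(truth$fragments, groups, truth$mids, truth$scales,
                          cv = cv, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "synthetic_huh7_like_uncorrected.csv")
  map_path <- file.path(dir, "synthetic_toy_map.escher.json")
  grp_path <- file.path(dir, "synthetic_groups.json")
  simulate_uncorrected(spec, csv_path)
  jsonlite::write_json(toy_escher_map(), map_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(groups, function(g) list(
    name = g$name, samples = paste0(g$name, "_", seq_len(g$n_reps)),
    cell_count = g$cell_count
  )), grp_path, auto_unbox = TRUE, pretty = TRUE)
  list(csv = csv_path, map = map_path, groups = grp_path, spec = spec,
       truth = truth)
}
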