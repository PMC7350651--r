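---
title: "Methods: natural isotope abundance correction and tracing analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: natural isotope abundance correction and tracing analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotrace)
```

## The problem

Single-tracer GC-MS experiments report, for each metabolite fragment, the
intensities of its isotopologues M0..Mn. Two signals are mixed in those
intensities: tracer-derived labeling, and the natural occurrence of heavy
isotopes (1.07% ¹³C, 4.7% ²⁹Si, 0.2% ¹⁸O, ...). Because GC-MS fragments are
usually derivatized, a fragment can carry dozens of atoms beyond the
metabolite backbone, and the natural contribution is large — for the
TBDMS-citrate ion used in the examples, only about 67% of unlabeled
molecules appear at M0. All downstream quantities (MIDs, enrichment,
labeling comparisons) require removing this contribution first.

## The correction model and its assumptions

Let the fragment have total composition $F$ and $N$ labelable atoms of the
tracer element. For a molecule carrying exactly $j$ labels, the observed
mass shift is $j \cdot s$ (tracer shift $s$, 1 for ¹³C/¹⁵N/²H) plus the
natural shift of all remaining atoms. Column $j$ of the correction matrix
$C$ is therefore the spectrum of $F$ minus its $N$ labelable atoms,
convolved with the natural pattern of the $N-j$ unlabeled labelable atoms,
offset by $j \cdot s$ rows. Spectra are built by truncated convolution of
per-element patterns; truncation never renormalizes, so matrix columns are
true probabilities and column sums below 1 expose tail mass beyond the
measured channels.

Assumptions this encodes:

- **Nominal resolution.** Isotopologues are binned by integer mass shift;
  isotopic fine structure is not resolved. Data outside this regime must be
  corrected elsewhere and loaded with `read_corrected_csv()`.
- **Tracer purity 100%.** No impurity parameter is offered; a purity model
  would add a second convolution on the labeled atoms and is out of scope.
- **Total-ion formulas.** The fragment formula includes derivatization
  atoms; only the declared $N$ atoms can carry label, all other
  tracer-element atoms contribute natural abundance. This is the only
  reading consistent with a separate labelable-atom count input.
- **No exchange.** A ²H tracer treats unlabeled hydrogens at natural
  abundance with no solvent-exchange modeling.

## Solving and numerical choices

`correct_vector()` solves $Cx = m$ by QR least squares, then clamps
negative components to zero and renormalizes. Reasoning:

- Channel counts are taken from the data, not forced to $N+1$. Extra
  scanned channels make the system overdetermined, which least squares
  handles naturally; *fewer* channels than label states is rejected as
  under-measured rather than silently padded.
- Baseline noise routinely drives small components negative; clamping then
  renormalizing is the established, deterministic behavior class for this
  problem. A constrained (NNLS) solve would differ only in pathological
  cases and is harder to reason about; the clamp choice is documented here
  as this package's decision, not a claim about any other tool.
- An all-zero measurement returns a flagged `"empty"` status, never NaN
  arithmetic; empties propagate through statistics by exclusion.
- The pre-normalization solution sum is kept as `scale`, a corrected
  absolute intensity usable for abundance work.

The fractional output is exactly scale-invariant, and round-trip recovery
of random simplex distributions is verified to 1e-8 in the test suite,
including against an independent oracle that enumerates every atom's
isotope assignment and solves with an SVD pseudo-inverse.

## Abundance table

Values are IUPAC/CIAAW 2021 representative terrestrial compositions,
pinned in `inst/extdata/isotope_abundances.json` (version string
`IUPAC-2021-representative`) and embedded in every saved workspace so a
reload reproduces the same correction. Users can audit the file or load an
override with `load_isotope_table()`. Pinning one versioned source keeps
tests deterministic; agreement with tools embedding different tables is
expected only up to abundance-table differences.

## Analytics conventions

- **Abundance basis.** Total abundance is the sum of baseline-corrected
  measured channels *before* NIA correction. Correction redistributes
  signal and its clamping can drop mass, so raw ion-count sums are the
  conventional, monotone basis; the corrected scale is available in
  `$scales` for users who prefer a corrected-sum basis.
- **Error bars are SD**, sample convention ($n-1$), zero for singleton
  groups. SEM is deliberately not offered.
- **Normalization order** is fixed: internal standard (per sample), cell
  counts (per group), reference group (per metabolite). The per-sample and
  per-group steps are diagonal rescalings and commute; the reference step
  must come last so the reference mean lands at exactly 1. Tests assert
  the sequential result equals one-shot composite scaling.
- **Zero internal standard** excludes the sample (flag + warning) rather
  than dividing by zero or dropping it silently.
- **Kinetic ordering**: groups sort by time ascending, ties broken by
  group name — a documented, deterministic tie-break.
- **Isotopologue display limits** truncate the view only; displayed MID
  fractions are not renormalized, so a truncated plot remains honest about
  hidden tail mass.
- **Single-isotopologue selection** is by M-number, 0-based (`"M5"` is the
  species five mass units above monoisotopic).

## Rendering

Figures are built as a flat list of geometric primitives and serialized to
SVG with fixed-precision formatting: output is a pure function of (spec,
stats, scheme), with no timestamps or generated ids, so identical inputs
give byte-identical files — a testable property the suite asserts. PNG
export rasterizes the same primitive list through base graphics, so the
two formats cannot drift apart.

Design choices where the field's GUI conventions had to be reinterpreted
for static output:

- Bar graphs draw group means with symmetric capped ±1 SD bars; stacked
  variants stack isotopologue means per group; individual sample points
  overlay at deterministic (not jittered) offsets.
- Kinetic graphs draw one polyline through the time-ordered group means.
  Since each group carries a single time point, "one line per group" would
  degenerate to isolated points; the connected series with per-point SD
  bars is the informative static rendering.
- The largest built-in color scheme has exactly 15 entries; more groups
  than colors cycles the palette with a warning, and user-supplied schemes
  of any length are accepted.
- Pathway figures place each mapped fragment's graph to the right of its
  node, resolving collisions by a clockwise quadrant search then downward
  stepping — deterministic, if not aesthetically optimal. Unmapped
  fragments stack in a left sidebar in dataset order. BiGG ID matching is
  exact by default; `ignore_compartment` strips a trailing `_<tag>`.

## The synthetic generator

`simulate_dataset()` is the package's forward model: planted MIDs and
abundance scales are pushed through the same correction matrices the
solver inverts, then multiplied by per-channel Gaussian noise
(`1 + N(0, cv)`, truncated at zero). `make_huh7_like_fixture()` instantiates
a two-condition experiment emulating a hypoxia-vs-normoxia glutamine
tracing study: TCA and glycolysis fragments with plausible derivatized
formulas, a norvaline-like internal standard, cell counts 638333 and
668750, and hypoxic M5 citrate planted at 9× normoxia — the
reductive-carboxylation signature as known ground truth. Default noise is
CV 0.05 with 3 replicates per group, a realistic technical variability for
GC-MS; chosen once and not tuned.

What the generator does **not** emulate: chromatographic peaks, baseline
drift and integration error (inputs are assumed baseline-corrected),
correlated channel noise, detector saturation, or biological replicate
variance structure. A green round-trip test therefore establishes that the
correction mathematics and pipeline plumbing are right, not that the
pipeline is robust to every artifact of real instrument data. Because the
fixture is synthetic, tests against it validate internal consistency —
recovery of planted truth — never agreement with any measured dataset.

## Known limitations

- Single tracer only; dual-label experiments and high-resolution
  fine-structure correction are out of scope by design.
- No tracer impurity correction (see assumptions).
- No hypothesis testing or flux estimation; the package computes means and
  SDs and leaves inference to the user.
- Maps are consumed from local Escher JSON files; no database fetching.
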