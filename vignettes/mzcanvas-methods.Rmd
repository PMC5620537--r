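---
title: "mzcanvas: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mzcanvas: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzcanvas)
```

mzcanvas is a headless toolkit for the kind of hands-on interrogation of
LC-MS/MS data that usually happens in an interactive desktop viewer:
checking a peptide-spectrum match by eye, moving a phosphate to the next
serine to see which placement the fragments support, re-processing a
spectrum before re-searching it, and keeping a defensible record of every
one of those decisions. This vignette explains the models behind each
component, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the design decisions that
were genuinely open.

## Mass model

All masses are monoisotopic. The package uses the community-standard
constants: proton 1.007276 Da, water 18.010565 Da, ammonia 17.026549 Da,
and a heavy-isotope spacing of 1.0033548 Da (the ^13^C–^12^C difference,
which dominates peptide isotope patterns). Residue masses come from the
standard monoisotopic table at six-decimal precision.

A peptide's neutral mass is the sum of its residue masses, one water for
the termini, and the deltas of its positioned modifications. Positions run
from 0 (N-terminus) through 1..n (residues) to n+1 (C-terminus), with at
most one modification per position; modification *stacking* is deliberately
disallowed because a stacked pair is indistinguishable from a single
combined delta and breaks the site-permutation logic.

Fragment ions follow the usual nomenclature: b/y pairs for collisional
activation (CAD/HCD), c/z pairs for electron transfer (ETD). The neutral
b-ion mass at cleavage *i* is the N-terminal residue sum plus modifications
at positions ≤ *i*; y ions are indexed by fragment length and carry the
water and the C-terminal modifications. c = b + NH~3~; for z we generate
the z-dot radical (z = y − 16.01872 Da), the species actually observed in
ETD spectra. These conventions give two exact identities used throughout
the tests:

* b~i~ + y~n−i~ (singly charged) = M + 2 × 1.007276
* c~i~ + z~n−i~ (singly charged) = M + 2 × 1.007276 + 1.00783

Neutral-loss satellite series (−H~2~O, −NH~3~), internal fragments,
immonium and a-ions are out of scope in this version; annotation is
restricted to the primary series.

## Spectrum annotation

`annotate_spectrum()` matches each theoretical ion to the nearest peak
within a ppm tolerance (default 10 ppm, configurable). One peak may satisfy
several ions — fragment m/z values genuinely coincide — but each ion claims
at most one peak. Exact ties break toward the lower-m/z peak, a fixed rule
chosen so results are reproducible rather than order-dependent. The
implementation is checked against a brute-force all-pairs matcher in the
test suite.

## MS1 feature detection

Features are isotopic clusters traced over retention time. Detection is a
two-stage greedy algorithm:

1. **Per-scan envelope detection.** Peaks are visited in order of
   decreasing intensity (ties toward lower m/z, for determinism). Each
   unused peak seeds a candidate envelope at every charge in
   `charge_range`; members are collected at the expected spacings
   1.0033548/z within `spacing_tol_ppm`, walking both up (heavier
   isotopes) and down (toward the monoisotope). Candidates are scored by
   cosine similarity between observed intensities and the isotope
   abundances predicted by the averagine model — a Poisson approximation
   whose rate scales linearly with neutral mass (λ ≈ 4.76 × 10⁻⁴ × M),
   the field-standard stand-in when the elemental composition is unknown.
   The charge that explains the most peaks wins, with score and then lower
   charge as tie-breaks; ranking by explained-peak count first is what
   prevents a divisor charge (z = 1 "seeing" every second peak of a z = 2
   envelope) from outscoring the true charge. Envelopes need at least
   `min_isotopes` (2) peaks and a score of `min_score` (0.9); accepted
   members are consumed, so no peak ever belongs to two envelopes.
2. **Cross-scan linking.** Envelopes in adjacent MS1 scans are linked when
   charges agree and mono m/z match within `link_tol_ppm`; a trace may miss
   up to `max_gap` consecutive scans (dropouts near the elution edges are
   common), and becomes a feature once it spans `min_scans` scans. The
   feature area is the trapezoidal integral of the monoisotope intensity
   over retention time.

Defaults: `charge_range` 1–6, `spacing_tol_ppm` and `link_tol_ppm` 10 ppm
(typical Orbitrap-class mass accuracy with margin), `max_gap` 1,
`min_scans` 3, `rt_pad` 0.2 min. All are configurable via
`feature_params()`.

MS/MS scans are linked to a feature when the precursor m/z falls within
tolerance of *any* isotope of the envelope (instruments routinely isolate
the +1 isotope) and the scan's rt lies inside the padded feature range;
when several features qualify, the nearest mono m/z wins, and each MS/MS
scan links to at most one feature. Unassigned-feature mining is then a set
difference against the results store, ordered by descending area — the
biggest unexplained signals first.

## Spectral pre-processing and provenance

The processing pipeline is a registry of named steps applied left to
right. Three built-ins cover the common re-search preparations:

* `filter_ions` removes peaks inside windows around exclusion m/z values
  (e.g. ions diagnostic of a covalent inhibitor that depress search
  scores).
* `deisotope` applies the same envelope machinery as the MS1 detector to
  an MS/MS spectrum and collapses each envelope to its monoisotopic peak
  with the summed envelope intensity. Every examined peak receives a
  charge-state determination: envelope monos get their charge, leftovers
  get 0 ("no isotope partner found"). Because only never-examined peaks
  (charge `NA`) participate in clustering, the operation is idempotent by
  construction — a second pass finds nothing to do. This closes a real
  edge case: without the annotation, removing envelope peaks could change
  the neighbourhood of a previously rejected seed and make a repeated run
  differ.
* `charge_reduce` re-places every annotated peak of charge z > 1 at its
  singly charged m/z (z·m/z − (z−1)·1.007276), conserving the inferred
  neutral mass exactly; reduced peaks landing within `merge_tol` (0.01 Th)
  of an existing singly charged peak are merged by intensity summation.
  Unannotated peaks are left alone with a warning, since charge reduction
  without de-isotoping is undefined.

User steps register through the same interface (`register_step()`), as
plain functions — no sandboxing, matching how analysts actually iterate on
processing scripts.

`apply_pipeline()` returns the processed spectrum together with a
processing record: sha256 digests of the input and output peak lists plus
the ordered step names and parameters. Replaying the record on the input
must reproduce the output digest — a forensic chain of custody for every
processed spectrum. The wall-clock timestamp is stored but never digested,
so identical inputs and steps always give identical digests. Exported MGF
blocks carry the record digest in their TITLE, so results imported after a
re-search link back to the exact processed form of each scan.

## Results store

PSMs live in a single-file SQLite database with Mascot-style worksheet
headers (`"Peptide Sequence"`, `"Variable Modifications"`, ...). Importers
accept the canonical TSV/CSV dialect and minimal pepXML (top-ranked hits by
default). Query access is read-only — only SELECT statements are accepted —
and column shortcuts (`varmods`, `peptide`, `score`, `mz`, ...) are expanded
to their quoted canonical columns before execution, outside string
literals. The autocompleter ranks SQL keywords first, then shortcuts, then
canonical columns, alphabetical within each group; shortcuts outrank the
columns they abbreviate because they are what a user is typing toward.
The schema here is declared canonical for this package; it is not claimed
identical to any external worksheet format.

Live search-engine integration (Mascot/X!Tandem/Comet servers) is
deliberately replaced by the MGF-export / results-import contract: engines
need licenses and servers, files do not.

## Quantification

Reporter intensities are the most intense peak within a window (default
0.003 Th) around each channel m/z of the chosen panel (TMT6/TMT10,
iTRAQ4/iTRAQ8 built in). Reagent impurity correction solves the full
linear system C·x = raw rather than subtracting sequentially — exact and
symmetric in the channels. The matrix convention is columns = reagent
channels, rows = observed channels, built from vendor-certificate
−2/−1/+1/+2 percentage offsets; bleed past the panel edge is dropped, so
columns sum to ≤ 1. Corrected values driven negative by over-subtraction
are clamped to zero and flagged rather than silently propagated.
Normalization divides each channel by its protein-input factor and scales
each scan by reference_time / injection_time: a spectrum accumulated twice
as long is down-weighted twofold. The multiply-vs-divide orientation of
the injection-time correction was an open choice; this package defines
corrected = value × reference_time / injection_time and documents it here.

XIC peak areas are trapezoidal integrals over the points inside the rt
range; the XIC window itself is closed on both ends and accepts either ppm
or Th tolerances (both semantics appear in practice, and a closed window
makes the brute-force oracle in the tests unambiguous).

## Provenance notebook

Notebook entries embed their data in full — peak lists, chromatograms,
results excerpts, processing records, attachments — so a saved bundle
renders and replays with zero access to raw run files. The bundle is a
single structured JSON document with a manifest of per-entry sha256
digests; on load every digest is recomputed and mismatches are flagged per
entry. A zip-of-documents layout was considered and rejected: R's zip
support depends on an external binary, and one JSON file is equally
diff-able and supplement-ready. Annotations anchor in data coordinates
(m/z or rt, intensity), not canvas pixels, so they survive re-rendering at
any size; anchors outside the item's data range are rejected at creation
time. SVG export is generated directly (deterministic, byte-identical
across repeated exports); PNG/PDF go through the standard graphics
devices. Peak lists export as NIST-style MSP text records — the open
library-interchange form accepted by NIST search tools — rather than the
undocumented binary .sdb format. PowerPoint export is a non-goal.

## Synthetic data generator

`make_run()` writes a complete mzML run with known ground truth: each
peptide spec becomes an averagine-shaped isotopic envelope whose
monoisotope elutes as a Gaussian (apex, σ, abundance), emitted in every
MS1 scan within 2.5σ of the apex; MS/MS scans with exact theoretical
fragment peaks (b/y or c/z per activation mode) are triggered after the
MS1 scan nearest each apex. Noise is a baseline of uniform-m/z,
exponential-intensity peaks plus optional Gaussian ppm jitter on signal
positions, fully determined by the seed — identical seeds give
byte-identical files (m/z is encoded at 64 bit so 10⁻⁶ Th round trips are
honest). The generator shares its isotope model with the detector on
purpose: tests should fail on algorithmic regressions, not on model
mismatch between simulator and detector.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: chimeric/co-isolated spectra, peak
shape asymmetry and tailing, retention-time drift between runs, detector
saturation, profile-mode peak shapes, and FAIMS/ion-mobility dimensions.
Results on real files will degrade with deviations from these
idealizations, most sensitively through the envelope score threshold.

The test suite's standard conditions are deliberately desk-scale: runs of
~100 scans with 10 planted peptides over a 10-minute gradient at 6-second
MS1 intervals, signal-to-noise 10 for the noisy variants (apex mono
intensity 10× the mean noise intensity, 20 noise peaks per 100 Th per
scan, 2 ppm jitter). The acceptance checks for the detector demand perfect
recall/precision in the noiseless case and ≥ 95% at SNR 10.

## Numerical choices

* Matching and spacing tolerances are relative (ppm) everywhere masses
  scale, absolute (Th) where windows are instrument-fixed (reporter
  windows, merge collisions).
* All greedy orders (seed selection, tie-breaks) are total and documented,
  so every algorithm is deterministic.
* Trapezoidal integration is used for all areas; with ≥ 2 points it is
  exact for the piecewise-linear traces the generator produces and within
  1% of the closed form for densely sampled Gaussians.
* Degenerate inputs are first-class: empty runs, empty spectra, empty
  pipelines and empty notebooks all round-trip rather than erroring.

## Command line

The `mzcanvas` executable (in `exec/`) is a thin wrapper over the exported
functions with a fixed exit-code contract: 0 success, 1 usage error, 2
data error. All file outputs are written atomically (temp file + rename).
Every subcommand is equally reachable from R; the CLI exists for shell
pipelines, not as a separate implementation.
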