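# mzcanvas

Headless interrogation of LC-MS/MS proteomics data in R.

Large-scale pipelines reduce mass-spectrometry experiments to peptide and
protein lists, but the detective work — validating a peptide-spectrum match
(PSM) by eye, testing where a phosphate really sits, re-processing a
spectrum before re-searching it, and keeping a defensible record of the
evidence — usually lives in interactive desktop viewers. mzcanvas provides
that workflow as a scriptable, testable library for analysts and
bioinformaticians:

* **Spectra I/O** — mzML read/write with random access by scan id and
  retention time, an LRU cache over multi-run experiments, extracted ion
  chromatograms (XICs), and MGF peak-list export for database re-search.
* **Peptide calculator** — monoisotopic masses and theoretical b/y (CAD/HCD)
  and c/z (ETD) fragment ions with positioned modifications, modification
  repositioning and site-permutation for localization work, and spectrum
  annotation. Core identity: singly charged
  `b_i + y_(n−i) = M + 2 × 1.007276` Th.
* **MS1 feature detection** — greedy isotopic-envelope detection scored
  against the averagine model (Poisson approximation, cosine similarity),
  traced across retention time with gap bridging, linked to MS/MS scans,
  and mined for unassigned features worth re-searching.
* **Spectral pre-processing** — de-isotoping, charge reduction
  (`m/z → z·m/z − (z−1)·1.007276`), diagnostic-ion filtering, and
  user-registered steps, every pipeline run captured in a replayable
  sha256-digested processing record.
* **Results store** — PSMs in single-file SQLite with Mascot-style
  worksheet columns, TSV/CSV/pepXML importers, a read-only SELECT interface
  with column shortcuts and autocompletion, and re-linking of any PSM row
  to its raw scan.
* **Quantification** — reporter-ion extraction (TMT/iTRAQ panels built in),
  reagent impurity correction by solving `C·x = raw`, protein-input and
  injection-time normalization, and trapezoidal XIC peak areas.
* **Provenance notebook** — annotated, self-contained evidence bundles
  (spectra, XICs, results excerpts, scripts, parameters) that render and
  replay with zero access to raw files, with per-entry digest verification
  and SVG/PNG/PDF/MSP export.
* **Synthetic generator** — deterministic mzML runs with full ground truth,
  used as the oracle throughout the test suite.

See `vignettes/mzcanvas-methods.Rmd` for the models, parameter defaults and
design decisions.

## Worked example

```r
library(mzcanvas)

# 1. simulate a small run with known ground truth
sim <- make_run(default_synth_specs(5), seed = 42,
                gradient = list(rt_range = c(0, 6), scan_interval = 6),
                path = file.path(tempdir(), "demo.mzML"))
run <- read_run(sim$path)
glance(run)
#> # A tibble: 1 × 6
#>   source    n_scans n_ms1 n_ms2 rt_min rt_max
#>   <chr>       <int> <int> <int>  <dbl>  <dbl>
#> 1 demo.mzML      66    61     5      0      6

# 2. detect MS1 features and link their MS/MS scans
features <- detect_features(run) |> link_ms2(run)
tidy(features)
#> # A tibble: 5 × 10
#>   feature_id mono_mz charge rt_start rt_end apex_rt   area n_scans ms2_scans
#>        <int>   <dbl>  <int>    <dbl>  <dbl>   <dbl>  <dbl>   <int> <chr>
#> 1          1    347.      3      4.8    5.2     5   23484.       5 56
#> 2          2    486.      2      1.6    2       1.8 23484.       5 20
#> 3          3    489.      2      2.4    2.8     2.6 23484.       5 29
#> 4          4    515.      2      3.2    3.6     3.4 23484.       5 38
#> 5          5    894.      2      4      4.4     4.2 23484.       5 47
```

All five planted peptides are recovered with their charges, elution
windows and triggered MS/MS scans. Next, the PSM-inspection loop:
theoretical fragments of the generating peptide annotated on its matched
spectrum (16/16 ions, 0 ppm error on this noiseless run):

```r
p <- peptide(sim$truth$sequence[1])
scan <- get_scan(run, sim$truth$ms2_scan_id[1])
annotate_spectrum(scan, fragment_ions(p, c("b", "y"), 1), tol_ppm = 10)
#> # A tibble: 16 × 7
#>    series index charge mz_theo mz_obs intensity error_ppm
#>    <chr>  <int>  <int>   <dbl>  <dbl>     <dbl>     <dbl>
#>  1 b          1      1    114.   114.      809.         0
#>  2 b          2      1    213.   213.      555.         0
#>  ...
#> 16 y          8      1    858.   858.      491.         0
```

Reporter quantification with reagent impurity correction (the bundled
certificate is synthetic):

```r
cert <- system.file("extdata", "tmt6_impurities_synthetic.csv", package = "mzcanvas")
C <- read_impurity_matrix(cert)
impurity_correct(c(100, 205, 301, 404, 502, 598), C)
#>      126      127      128      129      130      131
#> 105.2993 207.0011 299.5754 400.7993 497.2316 618.0158
```

The corrected vector is the solution of `C·x = raw`; channels that would
go negative are clamped to zero and flagged via the `clamped` attribute.

A command-line wrapper is installed as `exec/mzcanvas`
(`mzcanvas --help` lists the `synth`, `pepcalc`, `xic`, `features`,
`process`, `results`, `quant`, `notebook` subcommands; exit codes: 0 ok,
1 usage error, 2 data error).

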