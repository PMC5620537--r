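# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

# a small deterministic run: `n` peptides, optional noise, written to tempdir
fixture_run <- function(n = 3, seed = 11, noise = noise_model(),
                        rt_span = c(0, 5), interval = 6, abundance = 1e5) {
  make_run(default_synth_specs(n, abundance = abundance), noise = noise,
           gradient = list(rt_range = rt_span, scan_interval = interval),
           seed = seed, path = tempfile(fileext = ".mzML"))
}

# a hand-built MS/MS spectrum from explicit peaks
fixture_ms2 <- function(mz, intensity, precursor_mz = 500.25, charge = 2L,
                        scan_id = 1L, rt = 1, activation = "HCD") {
  spectrum(scan_id, 2L, rt, tibble::tibble(mz = mz, intensity = intensity),
           precursor_mz = precursor_mz, precursor_charge = charge,
           activation = activation)
}

# an isotope envelope peak block at given mono m/z / charge / depth
envelope_peaks <- function(mono_mz, z, intensities) {
  k <- seq_along(intensities) - 1
  tibble::tibble(mz = mono_mz + k * 1.0033548 / z, intensity = intensities)
}

# brute-force all-pairs ion/peak matcher: the independent oracle for
# annotate_spectrum (nearest peak within tol, ties toward lower m/z)
brute_annotate <- function(s, ions, tol_ppm) {
  out <- list()
  for (r in seq_len(nrow(ions))) {
    mz <- ions$mz[r]
    best <- NULL
    for (q in seq_len(nrow(s$peaks))) {
      d <- abs(s$peaks$mz[q] - mz)
      if (d <= mz * tol_ppm * 1e-6) {
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 && s$peaks$mz[q] < best$mz)) {
          best <- list(d = d, mz = s$peaks$mz[q], int = s$peaks$intensity[q])
        }
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- data.frame(
        series = ions$series[r], index = ions$index[r], charge = ions$charge[r],
        mz_theo = mz, mz_obs = best$mz)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(df)
  df[order(df$series, df$index, df$charge), ]
}

expect_run_cleanup <- function(sim) unlink(sim$path)
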