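test_that("detect_envelopes resolves a z=2 triplet to one envelope", {
  pk <- envelope_peaks(500.000, 2, c(100, 60, 20))
  s <- spectrum(1, 1, 1, pk)
  env <- detect_envelopes(s, feature_params())
  expect_equal(nrow(env), 1L)
  expect_equal(env$charge, 2L)
  expect_equal(env$mono_mz, 500.000, tolerance = 1e-9)
  expect_equal(env$n_isotopes, 3L)
  expect_equal(env$total_intensity, 180)
})

test_that("isolated single peaks yield no envelopes", {
  s <- spectrum(1, 1, 1, tibble::tibble(mz = c(400.1, 812.7), intensity = c(50, 80)))
  expect_equal(nrow(detect_envelopes(s, feature_params())), 0L)
})

test_that("disjoint z=1 and z=2 envelopes are both recovered, sharing no peak", {
  p1 <- envelope_peaks(600.30, 1, c(100, 45, 12))
  p2 <- envelope_peaks(450.20, 2, c(80, 35, 9))
  s <- spectrum(1, 1, 1, rbind(p1, p2))
  env <- detect_envelopes(s, feature_params())
  expect_equal(nrow(env), 2L)
  expect_setequal(env$charge, c(1L, 2L))
  expect_equal(sort(env$mono_mz), c(450.20, 600.30), tolerance = 1e-9)
  # disjointness audit
  idx <- unlist(env$peak_idx)
  expect_equal(anyDuplicated(idx), 0L)
})

test_that("zero-noise synthetic run: every planted feature found, nothing else", {
  sim <- fixture_run(n = 10, seed = 21, rt_span = c(0, 10))
  run <- read_run(sim$path)
  fx <- detect_features(run)
  expect_equal(nrow(fx), 10L)
  # match each truth row to one detected feature
  for (i in seq_len(nrow(sim$truth))) {
    d_ppm <- abs(fx$mono_mz - sim$truth$mono_mz[i]) / sim$truth$mono_mz[i] * 1e6
    j <- which.min(d_ppm)
    expect_lt(d_ppm[j], 5)
    expect_equal(fx$charge[j], sim$truth$charge[i])
    expect_lt(abs(fx$apex_rt[j] - sim$truth$apex_rt[i]), 6 / 60 + 1e-9)
  }
  expect_run_cleanup(sim)
})

test_that("min_scans suppresses one-scan features; max_gap bridges dropouts", {
  # a species eluting so narrowly it appears in a single scan
  brief <- peptide_spec("HLQLAIR", charge = 1, apex_rt = 2, sigma_rt = 0.01,
                        abundance = 1e5, include_ms2 = FALSE)
  sim <- make_run(list(brief), gradient = list(rt_range = c(0, 4), scan_interval = 6),
                  seed = 4, path = tempfile(fileext = ".mzML"))
  run <- read_run(sim$path)
  expect_equal(nrow(detect_features(run, feature_params(min_scans = 3))), 0L)
  expect_run_cleanup(sim)

  # dropout bridged by max_gap = 1: build a run in memory with a hole
  pkfun <- function(g) envelope_peaks(500.0, 2, c(100, 55, 15) * g)
  gains <- c(0.4, 0.8, 1.0, 0.8, 0.4)
  spectra <- lapply(1:5, function(k) {
    pk <- if (k == 3) tibble::tibble(mz = numeric(), intensity = numeric()) else pkfun(gains[k])
    spectrum(k, 1, k * 0.1, pk)
  })
  f <- tempfile(fileext = ".mzML")
  write_run_mzml(spectra, f)
  fx <- detect_features(read_run(f), feature_params(max_gap = 1, min_scans = 3))
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$n_scans, 4L)
  expect_equal(fx$rt_start, 0.1)
  expect_equal(fx$rt_end, 0.5)
  fx0 <- detect_features(read_run(f), feature_params(max_gap = 0, min_scans = 3))
  expect_equal(nrow(fx0), 0L)   # without gap bridging the trace splits in two
  unlink(f)
})

test_that("feature area equals the brute-force trapezoid over the mono trace", {
  sim <- fixture_run(n = 2, seed = 31)
  run <- read_run(sim$path)
  fx <- detect_features(run)
  expect_equal(nrow(fx), 2L)
  for (j in seq_len(nrow(fx))) {
    ids <- fx$scan_ids[[j]]
    rts <- run$scans$rt[match(ids, run$scans$scan_id)]
    mono <- vapply(ids, function(id) {
      p <- get_scan(run, id)$peaks
      p$intensity[which.min(abs(p$mz - fx$mono_mz[j]))]
    }, numeric(1))
    brute <- sum(diff(rts) * (head(mono, -1) + tail(mono, -1)) / 2)
    expect_equal(fx$area[j], brute, tolerance = 0.01)
  }
  expect_run_cleanup(sim)
})

test_that("link_ms2 associates scans by precursor, including +1 isotopes", {
  sim <- fixture_run(n = 5, seed = 41, rt_span = c(0, 6))
  run <- read_run(sim$path)
  fx <- link_ms2(detect_features(run), run)
  # brute-force over all (feature, ms2) pairs
  ms2 <- run$scans[run$scans$ms_level == 2, ]
  for (k in seq_len(nrow(ms2))) {
    cand <- which(vapply(seq_len(nrow(fx)), function(i) {
      ms2$rt[k] >= fx$rt_start[i] - 0.2 && ms2$rt[k] <= fx$rt_end[i] + 0.2 &&
        any(abs(fx$iso_mz[[i]] - ms2$precursor_mz[k]) <=
              fx$iso_mz[[i]] * 10e-6)
    }, logical(1)))
    linked <- which(vapply(fx$ms2_scan_ids, function(s) ms2$scan_id[k] %in% s, logical(1)))
    if (length(cand)) {
      expect_length(linked, 1L)
      expect_true(linked %in% cand)
    } else {
      expect_length(linked, 0L)
    }
  }
  # every truth MS2 linked to the feature at its truth mono m/z
  for (i in seq_len(nrow(sim$truth))) {
    j <- which.min(abs(fx$mono_mz - sim$truth$mono_mz[i]))
    expect_true(sim$truth$ms2_scan_id[i] %in% fx$ms2_scan_ids[[j]])
  }
  expect_run_cleanup(sim)
})

test_that("an MS2 whose precursor is a +1 isotope still links to the feature", {
  pk <- envelope_peaks(500.0, 2, c(100, 55, 15))
  spectra <- lapply(1:4, function(k) spectrum(k, 1, k * 0.1, pk))
  iso1 <- 500.0 + 1.0033548 / 2
  spectra[[5]] <- spectrum(5, 2, 0.25,
                           tibble::tibble(mz = c(200, 300), intensity = c(10, 20)),
                           precursor_mz = iso1, precursor_charge = 2)
  f <- tempfile(fileext = ".mzML")
  write_run_mzml(spectra, f)
  run <- read_run(f)
  fx <- link_ms2(detect_features(run), run)
  expect_equal(fx$ms2_scan_ids[[1]], 5L)
  # far-away rt: unlinked
  spectra[[5]] <- spectrum(5, 2, 9.9, tibble::tibble(mz = 200, intensity = 10),
                           precursor_mz = iso1, precursor_charge = 2)
  write_run_mzml(spectra, f)
  run2 <- read_run(f)
  fx2 <- link_ms2(detect_features(run2), run2)
  expect_length(fx2$ms2_scan_ids[[1]], 0L)
  unlink(f)
})

test_that("unassigned_features is the set difference against the results store", {
  sim <- fixture_run(n = 6, seed = 51, rt_span = c(0, 7))
  run <- read_run(sim$path)
  fx <- link_ms2(detect_features(run), run)
  # empty db: everything unassigned, ordered by descending area
  db0 <- results_db()
  all_un <- unassigned_features(fx, db0)
  expect_equal(nrow(all_un), nrow(fx))
  expect_true(all(diff(all_un$area) <= 1e-12))
  results_close(db0)
  # assign 3 of 6
  assigned_ids <- sim$truth$spec_id[1:3]
  res <- tempfile(fileext = ".tsv")
  make_results_fixture(sim$truth, res, "tsv", assign_spec_ids = assigned_ids)
  db <- results_db()
  import_results(db, res)
  un <- unassigned_features(fx, db)
  expect_equal(nrow(un), 3L)
  got_scans <- sort(unlist(un$ms2_scan_ids))
  want_scans <- sort(sim$truth$ms2_scan_id[4:6])
  expect_equal(got_scans, want_scans)
  # all assigned: empty
  make_results_fixture(sim$truth, res, "tsv")
  db2 <- results_db(); import_results(db2, res)
  expect_equal(nrow(unassigned_features(fx, db2)), 0L)
  results_close(db); results_close(db2)
  unlink(res); expect_run_cleanup(sim)
})
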