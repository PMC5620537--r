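test_that("deisotope collapses envelopes to summed mono peaks", {
  pk <- envelope_peaks(500.000, 2, c(100, 60, 20))
  s <- fixture_ms2(pk$mz, pk$intensity)
  out <- deisotope(s)
  expect_equal(nrow(out$peaks), 1L)
  expect_equal(out$peaks$mz, 500.000, tolerance = 1e-9)
  expect_equal(out$peaks$intensity, 180)
  expect_equal(out$peaks$charge, 2L)
})

test_that("deisotope is the identity on envelope-free spectra and idempotent", {
  s <- fixture_ms2(c(210.5, 333.3, 489.9), c(5, 50, 7))
  out <- deisotope(s)
  expect_equal(out$peaks$mz, s$peaks$mz)
  expect_equal(out$peaks$intensity, s$peaks$intensity)
  # idempotence + never increasing the peak count, over seeded random spectra
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    s2 <- fixture_ms2(sort(runif(n, 150, 1400)), rexp(n, 1e-3) + 1)
    d1 <- deisotope(s2)
    d2 <- deisotope(d1)
    expect_lte(nrow(d1$peaks), nrow(s2$peaks))
    expect_equal(d2$peaks, d1$peaks)
    # TIC conserved (collapse only sums, never drops)
    expect_equal(sum(d1$peaks$intensity), sum(s2$peaks$intensity))
  }
})

test_that("charge_reduce moves annotated peaks to singly charged m/z exactly", {
  s <- fixture_ms2(500.000, 100)
  s$peaks$charge <- 2L
  out <- charge_reduce(s)
  expect_equal(out$peaks$mz, 2 * 500.000 - 1.007276, tolerance = 1e-12)
  expect_equal(out$peaks$charge, 1L)
  # neutral mass conservation, closed form, per peak
  set.seed(17)
  for (rep in 1:20) {
    n <- 15
    mzs <- sort(runif(n, 200, 900))
    zs <- sample(1:4, n, replace = TRUE)
    s2 <- fixture_ms2(mzs, runif(n, 10, 100))
    s2$peaks$charge <- as.integer(zs)
    out2 <- charge_reduce(s2, merge_tol = 1e-9)   # no accidental merges
    neutral_in <- sort(zs * mzs - zs * 1.007276)
    neutral_out <- sort(out2$peaks$charge * out2$peaks$mz -
                          out2$peaks$charge * 1.007276)
    expect_equal(length(neutral_out), length(neutral_in))
    expect_lt(max(abs(neutral_out - neutral_in)), 1e-9)
  }
})

test_that("charge_reduce merges collisions and warns on unannotated peaks", {
  # z=2 peak that reduces exactly onto an existing z=1 peak
  target <- 998.992724
  s <- fixture_ms2(c(500.000, target), c(40, 60))
  s$peaks$charge <- c(2L, 1L)
  out <- charge_reduce(s, merge_tol = 0.01)
  expect_equal(nrow(out$peaks), 1L)
  expect_equal(out$peaks$intensity, 100)
  expect_equal(out$peaks$mz, target)
  # all singly charged: identity
  s1 <- fixture_ms2(c(300, 400), c(1, 2)); s1$peaks$charge <- c(1L, 1L)
  expect_equal(charge_reduce(s1)$peaks, s1$peaks)
  # unannotated: unchanged with warning
  s_na <- fixture_ms2(c(300, 400), c(1, 2))
  expect_warning(out_na <- charge_reduce(s_na), "without charge annotation")
  expect_equal(out_na$peaks$mz, s_na$peaks$mz)
})

test_that("filter_ions removes exactly the windowed peaks", {
  mzs <- seq(100, 1000, by = 100)
  s <- fixture_ms2(mzs, rep(10, 10))
  expect_equal(filter_ions(s, numeric(0))$peaks, s$peaks)
  out <- filter_ions(s, c(200, 500, 900), tol = 0.5)
  expect_equal(out$peaks$mz, setdiff(mzs, c(200, 500, 900)))
  gone <- filter_ions(s, mzs, tol = 0.5)
  expect_equal(nrow(gone$peaks), 0L)
  # brute-force window test per peak
  set.seed(23)
  excl <- runif(5, 100, 1000)
  out2 <- filter_ions(s, excl, tol = 30)
  keep_brute <- mzs[vapply(mzs, function(m) all(abs(m - excl) > 30), logical(1))]
  expect_equal(out2$peaks$mz, keep_brute)
})

test_that("apply_pipeline composes steps and records replayable provenance", {
  # Fig.-2-style spectrum: fragments + contaminant ions + a z=2 envelope
  p <- peptide("VLDELTLAR")
  base <- make_msms(p, charge = 2)
  contaminants <- c(216.042, 302.713, 560.128)
  extra <- rbind(base$peaks[, c("mz", "intensity")],
                 data.frame(mz = contaminants, intensity = c(500, 700, 900)),
                 data.frame(mz = envelope_peaks(450.17, 2, c(300, 160, 50))$mz,
                            intensity = c(300, 160, 50)))
  s <- fixture_ms2(extra$mz, extra$intensity, precursor_mz = base$precursor_mz)
  steps <- list(processing_step("filter_ions", exclusion_mzs = contaminants, tol = 0.01),
                processing_step("deisotope"),
                processing_step("charge_reduce"))
  res <- apply_pipeline(s, steps)
  manual <- charge_reduce(deisotope(filter_ions(s, contaminants, tol = 0.01)))
  expect_equal(res$spectrum$peaks, manual$peaks)
  expect_true(res$record$complete)
  expect_length(res$record$steps, 3L)
  # replay reproduces the output digest
  replayed <- replay_record(res$record, s)
  expect_equal(replayed$peaks, res$spectrum$peaks)
  # determinism of digests
  res2 <- apply_pipeline(s, steps)
  expect_equal(res2$record$input_digest, res$record$input_digest)
  expect_equal(res2$record$output_digest, res$record$output_digest)
  # empty pipeline: identity, zero steps
  res0 <- apply_pipeline(s, list())
  expect_equal(res0$spectrum$peaks, s$peaks)
  expect_length(res0$record$steps, 0L)
  expect_equal(res0$record$input_digest, res0$record$output_digest)
})

test_that("unknown and failing steps abort with a flagged partial record", {
  s <- fixture_ms2(c(200, 300), c(1, 2))
  expect_error(apply_pipeline(s, list(processing_step("no_such_step"))),
               "unknown processing step")
  register_step("explode", function(s, params) stop("boom"))
  err <- tryCatch(apply_pipeline(s, list(processing_step("explode"))),
                  error = function(e) e)
  expect_s3_class(err, "mzc_pipeline_error")
  expect_false(err$record$complete)
  expect_equal(err$record$failed_step, "explode")
})

test_that("user-registered steps run inside pipelines", {
  register_step("scale", function(s, params) {
    s$peaks$intensity <- s$peaks$intensity * params$factor
    s
  })
  s <- fixture_ms2(c(200, 300), c(10, 20))
  res <- apply_pipeline(s, list(processing_step("scale", factor = 3)))
  expect_equal(res$spectrum$peaks$intensity, c(30, 60))
  expect_true("scale" %in% registered_steps())
})

test_that("export_for_research stamps TITLEs with record digests", {
  p <- peptide("EGIPPDQQR")
  s1 <- make_msms(p, charge = 2, scan_id = 10L)
  s2 <- make_msms(peptide("HLQLAIR"), charge = 2, scan_id = 11L)
  steps <- list(processing_step("deisotope"))
  proc <- list(apply_pipeline(s1, steps), apply_pipeline(s2, steps))
  f <- tempfile(fileext = ".mgf")
  export_for_research(proc, f, run_name = "demo")
  lines <- readLines(f)
  expect_equal(sum(lines == "BEGIN IONS"), 2L)
  expect_equal(sum(grepl("record=[0-9a-f]{64}", lines)), 2L)
  back <- read_mgf(f)
  digs <- vapply(back, function(b) attr(b, "record_digest"), character(1))
  expect_equal(digs, vapply(proc, function(x) x$record$output_digest, character(1)))
  # precursor fields identical between raw and processed export of a scan
  raw_f <- tempfile(fileext = ".mgf")
  write_mgf(list(s1), raw_f, run_name = "demo")
  raw_back <- read_mgf(raw_f)[[1]]
  expect_equal(raw_back$precursor_mz, back[[1]]$precursor_mz)
  expect_equal(raw_back$precursor_charge, back[[1]]$precursor_charge)
  expect_equal(raw_back$rt, back[[1]]$rt)
  # byte-identical on repeated export (pipeline determinism)
  f2 <- tempfile(fileext = ".mgf")
  export_for_research(list(apply_pipeline(s1, steps), apply_pipeline(s2, steps)),
                      f2, run_name = "demo")
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2, raw_f))
})
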