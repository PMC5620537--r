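# in-memory brute-force evaluation keeps the SQL engine honest
psm_tibble <- function(db) results_query(db, "SELECT * FROM psms")

fixture_db <- function(n_runs = 1, n = 6, seed = 61) {
  sims <- lapply(seq_len(n_runs), function(i)
    fixture_run(n = n, seed = seed + i, rt_span = c(0, 7)))
  db <- results_db()
  files <- character(n_runs)
  for (i in seq_len(n_runs)) {
    files[i] <- tempfile(fileext = ".tsv")
    make_results_fixture(sims[[i]]$truth, files[i], "tsv")
    import_results(db, files[i])
  }
  lapply(sims, expect_run_cleanup)
  unlink(files)
  list(db = db, sims = sims)
}

test_that("TSV import produces one record per row, combined runs keep basenames", {
  fx <- fixture_db(n_runs = 2, n = 5)
  df <- psm_tibble(fx$db)
  expect_equal(nrow(df), 10L)
  expect_length(unique(df$Run), 2L)
  expect_true(all(df$Charge >= 1))
  results_close(fx$db)
})

test_that("pepXML import takes top hits and agrees with the TSV of the same truth", {
  sim <- fixture_run(n = 4, seed = 71)
  ftsv <- tempfile(fileext = ".tsv"); fxml <- tempfile(fileext = ".pepxml")
  make_results_fixture(sim$truth, ftsv, "tsv")
  make_results_fixture(sim$truth, fxml, "pepxml")
  db1 <- results_db(); import_results(db1, ftsv)
  db2 <- results_db(); import_results(db2, fxml)
  a <- psm_tibble(db1); b <- psm_tibble(db2)
  expect_equal(nrow(a), nrow(b))
  o1 <- order(a$Scan); o2 <- order(b$Scan)
  expect_equal(a$`Peptide Sequence`[o1], b$`Peptide Sequence`[o2])
  expect_equal(a$`Variable Modifications`[o1], b$`Variable Modifications`[o2])
  expect_equal(a$Charge[o1], b$Charge[o2])
  expect_equal(a$`Precursor MZ`[o1], b$`Precursor MZ`[o2], tolerance = 1e-9)
  expect_equal(a$RT[o1], b$RT[o2], tolerance = 1e-9)
  results_close(db1); results_close(db2)
  unlink(c(ftsv, fxml)); expect_run_cleanup(sim)
})

test_that("import -> export -> import is lossless for the TSV dialect", {
  fx <- fixture_db(n = 5)
  out <- tempfile(fileext = ".tsv")
  export_results(fx$db, out)
  db2 <- results_db(); import_results(db2, out)
  a <- psm_tibble(fx$db); b <- psm_tibble(db2)
  expect_equal(as.data.frame(a), as.data.frame(b))
  results_close(fx$db); results_close(db2); unlink(out)
})

test_that("import errors name the problem", {
  db <- results_db()
  expect_error(import_results(db, tempfile(fileext = ".tsv")), "not found")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("Run\tScan", "a\t1"), bad)
  expect_error(import_results(db, bad), "Peptide Sequence")
  weird <- tempfile(fileext = ".xyz")
  writeLines("x", weird)
  expect_error(import_results(db, weird), "unknown results format")
  results_close(db); unlink(c(bad, weird))
})

test_that("query expands shortcuts, stays read-only, surfaces row sets correctly", {
  fx <- fixture_db(n = 5)
  db <- fx$db
  df <- psm_tibble(db)
  expect_equal(results_query(db, "SELECT COUNT(*) AS n FROM psms")$n, nrow(df))
  # shortcut expansion: varmods / peptide / score
  got <- results_query(db, "SELECT peptide, varmods FROM psms WHERE varmods LIKE '%phospho%'")
  want <- df[grepl("phospho", df$`Variable Modifications`), ]
  expect_equal(nrow(got), nrow(want))
  got2 <- results_query(db, "SELECT * FROM psms WHERE score > 32 ORDER BY score DESC")
  want2 <- df[df$`Peptide Score` > 32, ]
  expect_equal(nrow(got2), nrow(want2))
  expect_equal(got2$`Peptide Score`, sort(want2$`Peptide Score`, decreasing = TRUE))
  # mutating statements rejected
  expect_error(results_query(db, "UPDATE psms SET Charge = 9"), "read-only")
  expect_error(results_query(db, "DELETE FROM psms"), "read-only")
  results_close(db)
})

test_that("a battery of generated queries agrees with dplyr brute force", {
  fx <- fixture_db(n_runs = 2, n = 10)
  db <- fx$db
  df <- psm_tibble(db)
  # make the table bigger and more varied: re-import with jittered scores
  set.seed(81)
  thresholds <- quantile(df$`Peptide Score`, seq(0.1, 0.9, length.out = 10))
  for (th in thresholds) {
    got <- results_query(db, sprintf("SELECT * FROM psms WHERE score >= %.6f", th))
    want <- df[df$`Peptide Score` >= th, ]
    expect_equal(nrow(got), nrow(want))
    expect_setequal(got$Scan, want$Scan)
  }
  for (run in unique(df$Run)) {
    got <- results_query(db, sprintf(
      "SELECT Scan, score FROM psms WHERE Run = '%s' ORDER BY Scan", run))
    want <- df[df$Run == run, ]
    expect_equal(got$Scan, sort(want$Scan))
  }
  got <- results_query(db, "SELECT Run, COUNT(*) AS n FROM psms GROUP BY Run ORDER BY Run")
  want <- dplyr::count(df, Run, name = "n")
  expect_equal(as.data.frame(got), as.data.frame(want))
  got <- results_query(db, "SELECT DISTINCT Charge FROM psms ORDER BY Charge")
  expect_equal(got$Charge, sort(unique(df$Charge)))
  got <- results_query(db, "SELECT peptide FROM psms WHERE Charge = 2 AND score < 36 ORDER BY peptide")
  want <- sort(df$`Peptide Sequence`[df$Charge == 2 & df$`Peptide Score` < 36])
  expect_equal(got$`Peptide Sequence`, want)
  results_close(db)
})

test_that("completion ranks keywords, then shortcuts, then columns", {
  expect_equal(results_complete(NULL, "SEL"), "SELECT")
  all_out <- results_complete(NULL, "")
  expect_equal(all_out[1], "AND")                       # keywords first, alphabetical
  expect_true(all(c("varmods", "Peptide Sequence") %in% all_out))
  var_out <- results_complete(NULL, "SELECT var")
  expect_equal(var_out[1], "varmods")                   # the shortcut outranks the column
  expect_true("Variable Modifications" %in% var_out)
  # case-insensitive prefix, cursor mid-string
  expect_equal(results_complete(NULL, "sel FROM psms", cursor = 3)[1], "SELECT")
})

test_that("psm_to_scan re-links records to raw spectra through the cache", {
  sim <- fixture_run(n = 4, seed = 91)
  res <- tempfile(fileext = ".tsv")
  make_results_fixture(sim$truth, res, "tsv")
  db <- results_db(); import_results(db, res)
  cache <- run_cache(2)
  run_paths <- stats::setNames(sim$path, sim$truth$run[1])
  df <- psm_tibble(db)
  for (i in seq_len(nrow(df))) {
    s <- psm_to_scan(db, df[i, ], cache, run_paths)
    expect_equal(s$scan_id, df$Scan[i])
    expect_lt(abs(s$precursor_mz - df$`Precursor MZ`[i]) / s$precursor_mz * 1e6, 10)
  }
  # missing run errors with the basename
  df_bad <- df[1, ]; df_bad$Run <- "elsewhere"
  expect_error(psm_to_scan(db, df_bad, cache, run_paths), "elsewhere")
  results_close(db); unlink(res); expect_run_cleanup(sim)
})
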