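nb_fixture <- function() {
  s <- make_msms(peptide("EGIPPDQQR"), charge = 2, scan_id = 5L, rt = 2.2)
  ch <- structure(tibble::tibble(rt = seq(1, 3, by = 0.1),
                                 intensity = exp(-((seq(1, 3, by = 0.1) - 2)^2) / 0.02) * 1e4),
                  class = c("mz_chromatogram", class(tibble::tibble())),
                  query_mz = 500.25, tol = 10, tol_unit = "ppm")
  res <- tibble::tibble(Run = "demo", Scan = 5L, `Peptide Sequence` = "EGIPPDQQR")
  nb <- notebook() |>
    nb_add_entry(s, "assigned spectrum") |>
    nb_add_entry(ch, "precursor XIC") |>
    nb_add_entry(res, "results excerpt")
  list(nb = nb, s = s, ch = ch)
}

test_that("entries accept in-range annotations and reject out-of-range anchors", {
  fx <- nb_fixture()
  nb <- fx$nb
  mz1 <- fx$s$peaks$mz[3]; int1 <- fx$s$peaks$intensity[3]
  nb <- nb_annotate(nb, 1, "text", x = mz1, y = int1, text = "b3")
  nb <- nb_annotate(nb, 1, "highlight-region", x = range(fx$s$peaks$mz[1:4]))
  expect_length(nb_entry(nb, 1)$annotations, 2L)
  expect_error(nb_annotate(nb, 1, "text", x = max(fx$s$peaks$mz) + 100),
               "outside data range")
  expect_error(nb_annotate(nb, 2, "arrow", x = 0.5), "outside data range")
})

test_that("attachments and processing records replay inside a saved bundle", {
  s <- make_msms(peptide("VLDELTLAR"), charge = 2, scan_id = 9L)
  steps <- list(processing_step("deisotope"), processing_step("charge_reduce"))
  proc <- apply_pipeline(s, steps)
  nb <- notebook() |>
    nb_add_entry(s, "raw scan") |>
    nb_add_entry(proc$spectrum, "processed scan", record = proc$record) |>
    nb_attach(2, "script", "steps: deisotope, charge_reduce") |>
    nb_attach(2, "search_parameters", list(tol_ppm = 10, engine = "internal"))
  f <- tempfile(fileext = ".json")
  save_bundle(nb, f)
  nb2 <- load_bundle(f)
  # the bundle carries everything: replay the record against the embedded raw
  rec <- nb_entry(nb2, 2)$record
  raw <- nb_entry(nb2, 1)$item
  replayed <- replay_record(rec, raw)
  expect_equal(replayed$peaks$mz, nb_entry(nb2, 2)$item$peaks$mz, tolerance = 1e-9)
  expect_equal(nb_entry(nb2, 2)$attachments$search_parameters$tol_ppm, 10)
  unlink(f)
})

test_that("save/load round trips entries field for field", {
  fx <- nb_fixture()
  nb <- nb_annotate(fx$nb, 1, "arrow", x = fx$s$peaks$mz[1],
                    y = fx$s$peaks$intensity[1], text = "y1")
  f <- tempfile(fileext = ".json")
  save_bundle(nb, f)
  nb2 <- load_bundle(f)
  expect_length(nb2$entries, 3L)
  for (i in 1:3) {
    e1 <- nb_entry(nb, i); e2 <- nb_entry(nb2, i)
    expect_equal(e1$title, e2$title)
    expect_equal(e1$type, e2$type)
    expect_false(isTRUE(e2$tampered))
  }
  expect_equal(nb_entry(nb2, 1)$item$peaks$mz, fx$s$peaks$mz)
  expect_equal(nb_entry(nb2, 2)$item$rt, fx$ch$rt)
  expect_equal(nb_entry(nb2, 1)$annotations[[1]]$text, "y1")
  # empty notebook round trips too
  f0 <- tempfile(fileext = ".json")
  save_bundle(notebook(), f0)
  expect_length(load_bundle(f0)$entries, 0L)
  unlink(c(f, f0))
})

test_that("a tampered peak value is flagged on load", {
  fx <- nb_fixture()
  f <- tempfile(fileext = ".json")
  save_bundle(fx$nb, f)
  txt <- readLines(f)
  # mutate the digits of the first entry's m/z array
  i <- grep('"mz": \\[', txt)[1]
  expect_false(is.na(i))
  txt[i] <- chartr("123456789", "234567891", txt[i])
  writeLines(txt, f)
  expect_warning(nb2 <- load_bundle(f), "digest mismatch")
  flags <- vapply(nb2$entries, function(e) isTRUE(e$tampered), logical(1))
  expect_equal(sum(flags), 1L)
  expect_true(flags[1])
  unlink(f)
})

test_that("SVG export draws one stick per peak, deterministically", {
  s <- fixture_ms2(c(150.1, 220.2, 390.5, 410.8, 880.3), c(10, 40, 5, 100, 60))
  nb <- notebook() |> nb_add_entry(s, "five peaks")
  nb <- nb_annotate(nb, 1, "text", x = 410.8, y = 100, text = "base peak")
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  export_graphic(nb_entry(nb, 1), f1, "svg")
  doc <- xml2::read_xml(f1)
  sticks <- xml2::xml_find_all(doc, "//*[@class='peak']")
  expect_length(sticks, 5L)
  expect_length(xml2::xml_find_all(doc, "//*[@class='annotation']"), 1L)
  export_graphic(nb_entry(nb, 1), f2, "svg")
  expect_identical(readLines(f1), readLines(f2))
  # chromatogram renders as a trace
  ch <- nb_fixture()$ch
  nb2 <- notebook() |> nb_add_entry(ch, "xic")
  f3 <- tempfile(fileext = ".svg")
  export_graphic(nb_entry(nb2, 1), f3, "svg")
  expect_length(xml2::xml_find_all(xml2::read_xml(f3), "//*[@class='trace']"), 1L)
  unlink(c(f1, f2, f3))
})

test_that("png and pdf devices render; ppt is refused", {
  s <- fixture_ms2(c(150.1, 220.2), c(10, 40))
  nb <- notebook() |> nb_add_entry(s, "two peaks")
  fp <- tempfile(fileext = ".png")
  export_graphic(nb_entry(nb, 1), fp, "png")
  expect_gt(file.info(fp)$size, 0)
  fd <- tempfile(fileext = ".pdf")
  export_graphic(nb_entry(nb, 1), fd, "pdf")
  expect_gt(file.info(fd)$size, 0)
  expect_error(export_graphic(nb_entry(nb, 1), tempfile(), "ppt"), "unsupported")
  unlink(c(fp, fd))
})

test_that("MSP export writes NIST-style records that round trip", {
  s <- fixture_ms2(c(150.1, 220.2, 390.5, 410.8, 880.3), c(10, 40, 5, 100, 60))
  nb <- notebook() |> nb_add_entry(s, "library candidate")
  f <- tempfile(fileext = ".msp")
  export_peaklist(nb_entry(nb, 1), f)
  lines <- readLines(f)
  expect_true(any(lines == "Num peaks: 5"))
  back <- read_msp(f)[[1]]
  expect_equal(back$name, "library candidate")
  expect_lt(max(abs(back$peaks$mz - s$peaks$mz)), 1e-4)
  expect_equal(back$charge, 2L)
  # processed entries export the processed peaks, not the raw ones
  raw <- make_msms(peptide("VLDELTLAR"), charge = 2)
  proc <- apply_pipeline(raw, list(processing_step("deisotope")))
  nb2 <- notebook() |> nb_add_entry(proc$spectrum, "processed", record = proc$record)
  f2 <- tempfile(fileext = ".msp")
  export_peaklist(nb_entry(nb2, 1), f2)
  back2 <- read_msp(f2)[[1]]
  expect_equal(nrow(back2$peaks), nrow(proc$spectrum$peaks))
  # non-spectrum entries refused
  nb3 <- notebook() |> nb_add_entry(tibble::tibble(a = 1), "table")
  expect_error(export_peaklist(nb_entry(nb3, 1), tempfile()), "spectrum entry")
  unlink(c(f, f2))
})
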