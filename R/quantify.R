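#' Built-in reporter-ion panels
#'
#' Channel labels and reporter m/z values for the common isobaric reagents.
#'
#' @param name One of `"tmt6"`, `"tmt10"`, `"itraq4"`, `"itraq8"`, or a
#'   custom tibble with columns `label`, `mz` (passed through, validated).
#' @return A tibble of class `reporter_panel` with columns `label`, `mz`
#'   (strictly increasing).
#' @export
reporter_panel <- function(name = "tmt6") {
  if (is.data.frame(name)) {
    panel <- as_tibble(name)
    stopifnot(all(c("label", "mz") %in% names(panel)))
    pname <- "custom"
  } else {
    pname <- match.arg(tolower(name), c("tmt6", "tmt10", "itraq4", "itraq8"))
    panel <- switch(pname,
      tmt6 = tibble(
        label = c("126", "127", "128", "129", "130", "131"),
        mz = c(126.127726, 127.124761, 128.134436, 129.131471, 130.141145, 131.138180)),
      tmt10 = tibble(
        label = c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C", "131"),
        mz = c(126.127726, 127.124761, 127.131081, 128.128116, 128.134436,
               129.131471, 129.137790, 130.134825, 130.141145, 131.138180)),
      itraq4 = tibble(
        label = c("114", "115", "116", "117"),
        mz = c(114.110679, 115.107715, 116.111069, 117.114424)),
      itraq8 = tibble(
        label = c("113", "114", "115", "116", "117", "118", "119", "121"),
        mz = c(113.107325, 114.110679, 115.107715, 116.111069, 117.114424,
               118.111459, 119.114814, 121.121524))
    )
  }
  if (nrow(panel) < 2L) abort("a reporter panel needs >= 2 channels")
  if (any(diff(panel$mz) <= 0)) abort("panel channel m/z must be strictly increasing")
  structure(panel, class = c("reporter_panel", class(tibble())), panel_name = pname)
}

#' Extract raw reporter intensities from one MS/MS scan
#'
#' Per channel: the intensity of the most intense peak within `tol` of the
#' channel m/z, or 0 when no peak falls in the window.
#'
#' @param s An MS/MS `mz_spectrum`.
#' @param panel A [reporter_panel()].
#' @param tol Window half-width (default 0.003).
#' @param tol_unit `"Th"` (default) or `"ppm"`.
#' @return Named numeric vector of raw channel intensities.
#' @export
reporter_intensities <- function(s, panel, tol = 0.003, tol_unit = c("Th", "ppm")) {
  stopifnot(inherits(s, "mz_spectrum"))
  tol_unit <- match.arg(tol_unit)
  if (tol <= 0) abort("tol must be > 0")
  if (s$ms_level < 2L) abort("reporter ions live in MS/MS scans", class = "mzc_data_error")
  win <- ppm_window(panel$mz, tol, tol_unit)
  v <- vapply(seq_len(nrow(panel)), function(i) {
    hits <- s$peaks$intensity[s$peaks$mz >= win[i, "lo"] & s$peaks$mz <= win[i, "hi"]]
    if (length(hits)) max(hits) else 0
  }, numeric(1))
  stats::setNames(v, panel$label)
}

#' Read a reagent impurity certificate
#'
#' Vendor certificates report, per channel, the percentage of reagent signal
#' appearing -2/-1/+1/+2 channels away. The loader maps those offsets into a
#' square matrix C with columns = reagent channels and rows = observed
#' channels: `C[i, j]` is the fraction of channel j's reagent observed in
#' channel i. Signal bleeding off the panel edge is dropped, so columns sum
#' to at most 1.
#'
#' @param path CSV with columns `channel`, `minus2`, `minus1`, `plus1`,
#'   `plus2` (percent values).
#' @return An impurity matrix (class `impurity_matrix`).
#' @export
read_impurity_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "minus2", "minus1", "plus1", "plus2")
  if (!all(need %in% names(df))) {
    abort(paste0("impurity certificate needs columns: ", paste(need, collapse = ", ")),
          class = "mzc_data_error")
  }
  impurity_matrix_from_offsets(df$channel, df$minus2, df$minus1, df$plus1, df$plus2)
}

#' @rdname read_impurity_matrix
#' @param channels Channel labels in panel order.
#' @param minus2,minus1,plus1,plus2 Percent of each reagent observed at the
#'   corresponding channel offset.
#' @export
impurity_matrix_from_offsets <- function(channels, minus2, minus1, plus1, plus2) {
  n <- length(channels)
  C <- matrix(0, n, n, dimnames = list(channels, channels))
  off <- rbind(minus2, minus1, plus1, plus2) / 100
  shift <- c(-2L, -1L, 1L, 2L)
  for (j in seq_len(n)) {
    C[j, j] <- 1 - sum(off[, j])
    for (k in seq_along(shift)) {
      i <- j + shift[k]
      if (i >= 1L && i <= n) C[i, j] <- off[k, j]
    }
  }
  validate_impurity_matrix(C)
}

validate_impurity_matrix <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (any(C < 0)) abort("impurity matrix entries must be >= 0")
  if (any(colSums(C) > 1 + 1e-9)) abort("impurity matrix columns must sum to <= 1")
  if (any(diag(C) <= apply(C - diag(diag(C)), 2, max))) {
    warn("impurity matrix is not diagonally dominant")
  }
  structure(C, class = c("impurity_matrix", "matrix", "array"))
}

#' Correct reporter intensities for reagent isotopic impurities
#'
#' Solves the full linear system `C x = raw` (not sequential subtraction:
#' exact and symmetric in the channels). Components driven negative by
#' over-subtraction are clamped to 0 and flagged.
#'
#' @param raw Raw channel intensity vector.
#' @param C Impurity matrix from [read_impurity_matrix()] /
#'   [impurity_matrix_from_offsets()].
#' @return Corrected vector with attribute `clamped` (logical vector marking
#'   channels clamped to zero).
#' @export
impurity_correct <- function(raw, C) {
  if (length(raw) != nrow(C)) abort("raw vector and impurity matrix dimensions differ")
  x <- tryCatch(solve(C, raw),
                error = function(e) abort(paste0("singular impurity matrix: ",
                                                 conditionMessage(e)),
                                          class = "mzc_data_error"))
  clamped <- x < 0
  x[clamped] <- 0
  attr(x, "clamped") <- clamped
  if (!is.null(names(raw))) names(x) <- names(raw)
  x
}

#' Assemble quantification rows for a run
#'
#' One row per MS/MS scan: raw and impurity-corrected channel intensities.
#'
#' @param run An `mz_run`.
#' @param panel A [reporter_panel()].
#' @param impurities Optional impurity matrix (identity when `NULL`).
#' @param tol,tol_unit Passed to [reporter_intensities()].
#' @return Tibble: `scan_id`, `rt`, `injection_time`, one `raw_<label>` and
#'   one `corr_<label>` column per channel, `clamped` flag.
#' @export
quantify_run <- function(run, panel, impurities = NULL, tol = 0.003,
                         tol_unit = "Th") {
  stopifnot(inherits(run, "mz_run"))
  ms2 <- run$scans[run$scans$ms_level == 2L, ]
  n <- nrow(panel)
  if (is.null(impurities)) impurities <- validate_impurity_matrix(diag(n))
  rows <- purrr::map_dfr(seq_len(nrow(ms2)), function(k) {
    s <- run$spectra[[as.character(ms2$scan_id[k])]]
    raw <- reporter_intensities(s, panel, tol = tol, tol_unit = tol_unit)
    corr <- impurity_correct(raw, impurities)
    out <- tibble(scan_id = ms2$scan_id[k], rt = ms2$rt[k],
                  injection_time = ms2$injection_time[k])
    out[paste0("raw_", panel$label)] <- as.list(unname(raw))
    out[paste0("corr_", panel$label)] <- as.list(unname(as.numeric(corr)))
    out$clamped <- any(attr(corr, "clamped"))
    out
  })
  rows
}

#' Normalize corrected intensities
#'
#' Divides each channel by its protein-input factor, then scales every scan
#' by `reference_time / injection_time` (spectra accumulated for longer get
#' proportionally down-weighted). The applied factors are recorded as
#' attributes.
#'
#' @param rows Quant tibble from [quantify_run()] (needs `corr_*` columns and
#'   `injection_time`).
#' @param protein_factors Per-channel positive scalars, in panel order.
#' @param injection_times Optional override of per-scan injection times (ms);
#'   default: the `injection_time` column.
#' @param reference_time Reference injection time (same units).
#' @return `rows` with `corr_*` columns normalized; attributes
#'   `protein_factors` and `reference_time` record what was applied.
#' @export
normalize_quant <- function(rows, protein_factors, injection_times = NULL,
                            reference_time = 1) {
  corr_cols <- grep("^corr_", names(rows), value = TRUE)
  if (length(protein_factors) != length(corr_cols)) {
    abort("protein_factors length must match the number of channels")
  }
  if (any(protein_factors <= 0)) abort("protein factors must be > 0")
  if (is.null(injection_times)) injection_times <- rows$injection_time
  if (any(is.na(injection_times) | injection_times <= 0)) {
    abort("injection times must be positive")
  }
  if (reference_time <= 0) abort("reference_time must be > 0")
  scale_scan <- reference_time / injection_times
  for (i in seq_along(corr_cols)) {
    rows[[corr_cols[i]]] <- rows[[corr_cols[i]]] / protein_factors[i] * scale_scan
  }
  attr(rows, "protein_factors") <- protein_factors
  attr(rows, "reference_time") <- reference_time
  rows
}

#' Write a quant table as TSV
#'
#' @param rows Quant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(rows, path) {
  header <- paste(names(rows), collapse = "\t")
  cells <- lapply(rows, function(col) {
    if (is.double(col)) sprintf("%.6g", col) else as.character(col)
  })
  write_atomic(c(header, do.call(paste, c(cells, sep = "\t"))), path)
}
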