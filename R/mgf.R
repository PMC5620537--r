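#' Write MS/MS spectra to Mascot Generic Format
#'
#' One `BEGIN IONS` block per spectrum. The TITLE encodes the source run and
#' scan id as `<run basename>.<scan>.<scan>.<charge>`, a widely parsed
#' convention that lets imported search results re-link to scans. `PEPMASS`
#' and `RTINSECONDS` are always emitted; `CHARGE` is omitted when the
#' precursor charge is unknown. Peak lines are `mz intensity` with six
#' decimal places on m/z.
#'
#' @param spectra List of `mz_spectrum`, all MS level >= 2 with a precursor.
#' @param path Output path.
#' @param run_name Run basename used in TITLEs (default `"run"`).
#' @param title_suffix Optional per-spectrum character vector appended to
#'   each TITLE (used by [export_for_research()] to carry provenance digests).
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, run_name = "run", title_suffix = NULL) {
  if (inherits(spectra, "mz_spectrum")) spectra <- list(spectra)
  if (!is.null(title_suffix)) stopifnot(length(title_suffix) == length(spectra))
  blocks <- purrr::imap(spectra, function(s, i) {
    stopifnot(inherits(s, "mz_spectrum"))
    if (s$ms_level < 2L) abort("write_mgf: MS1 spectrum in input", class = "mzc_data_error")
    if (is.null(s$precursor_mz)) abort("write_mgf: spectrum lacks precursor m/z",
                                       class = "mzc_data_error")
    z <- s$precursor_charge
    title <- sprintf("%s.%d.%d.%s", run_name, s$scan_id, s$scan_id,
                     if (is.na(z)) "0" else as.character(z))
    if (!is.null(title_suffix) && nzchar(title_suffix[[i]])) {
      title <- paste0(title, " ", title_suffix[[i]])
    }
    c("BEGIN IONS",
      paste0("TITLE=", title),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      if (!is.na(z)) sprintf("CHARGE=%d+", z),
      sprintf("RTINSECONDS=%.3f", s$rt * 60),
      sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity),
      "END IONS", "")
  })
  write_atomic(unlist(blocks), path)
}

#' Read a Mascot Generic Format peak list
#'
#' Counterpart of [write_mgf()]; scan id and run name are recovered from the
#' TITLE convention when present.
#'
#' @param path MGF file path.
#' @return List of `mz_spectrum`; each carries attributes `title` and (when
#'   present in the TITLE) `record_digest`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "mzc_data_error")
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) abort("malformed MGF", class = "mzc_data_error")
  purrr::map2(starts, ends, function(a, b) {
    body <- lines[(a + 1):(b - 1)]
    kv <- grepl("=", body, fixed = TRUE)
    meta <- body[kv]
    keys <- sub("=.*", "", meta)
    vals <- sub("^[^=]*=", "", meta)
    names(vals) <- keys
    pk <- body[!kv & nzchar(trimws(body))]
    pm <- do.call(rbind, strsplit(trimws(pk), "[ \t]+"))
    title <- unname(vals["TITLE"])
    tparts <- strsplit(strsplit(title, " ")[[1]][1], ".", fixed = TRUE)[[1]]
    scan_id <- if (length(tparts) >= 3) suppressWarnings(as.integer(tparts[length(tparts) - 1])) else NA_integer_
    charge <- if ("CHARGE" %in% keys) as.integer(sub("[+-]", "", vals["CHARGE"])) else NA_integer_
    dig <- regmatches(title, regexpr("record=[0-9a-f]+", title))
    s <- spectrum(
      scan_id = if (is.na(scan_id)) 1L else scan_id,
      ms_level = 2L,
      rt = if ("RTINSECONDS" %in% keys) as.numeric(vals["RTINSECONDS"]) / 60 else 0,
      peaks = if (length(pk)) tibble(mz = as.numeric(pm[, 1]), intensity = as.numeric(pm[, 2]))
              else tibble(mz = numeric(), intensity = numeric()),
      precursor_mz = as.numeric(vals["PEPMASS"]),
      precursor_charge = charge,
      activation = "unknown", centroided = TRUE
    )
    attr(s, "title") <- title
    if (length(dig)) attr(s, "record_digest") <- sub("record=", "", dig)
    s
  })
}
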