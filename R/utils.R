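#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup
NULL

ppm_window <- function(mz, tol, tol_unit = c("ppm", "Th")) {
  tol_unit <- match.arg(tol_unit)
  if (tol <= 0) abort("tolerance must be > 0")
  w <- if (tol_unit == "ppm") mz * tol * 1e-6 else rep_len(tol, length(mz))
  cbind(lo = mz - w, hi = mz + w)
}

ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

# atomic file write: write to tempfile in the same directory, then rename
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) abort(paste0("cannot write ", path))
  invisible(path)
}

# sha256 of a canonical character representation
sha256_of <- function(x) digest::digest(x, algo = "sha256", serialize = FALSE)

# canonical string form of a peak list + precursor fields, for provenance digests
spectrum_digest <- function(s) {
  stopifnot(inherits(s, "mz_spectrum"))
  sha256_of(paste(
    paste(sprintf("%.6f", s$peaks$mz), collapse = ","),
    paste(sprintf("%.4f", s$peaks$intensity), collapse = ","),
    if (is.null(s$precursor_mz)) "NA" else sprintf("%.6f", s$precursor_mz),
    if (is.null(s$precursor_charge) || is.na(s$precursor_charge)) "NA" else s$precursor_charge,
    s$ms_level, s$activation,
    sep = "|"
  ))
}

trapezoid_area <- function(x, y) {
  if (length(x) < 2L) abort("need at least 2 points for trapezoidal integration")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
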