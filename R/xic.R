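#' Extract an ion chromatogram
#'
#' One point per MS1 scan inside `rt_range`: the summed intensity of all
#' peaks inside the closed m/z window `[mz - w, mz + w]`, where `w` is the
#' tolerance in Th, or `mz * tol * 1e-6` for ppm. Scans with no peak in the
#' window contribute zero.
#'
#' @param run An `mz_run`.
#' @param mz Query m/z (Th).
#' @param tol Tolerance half-width (> 0).
#' @param tol_unit `"ppm"` or `"Th"`.
#' @param rt_range Numeric length-2 retention-time interval in minutes, or
#'   `NULL` for the whole run. An empty interval yields an empty chromatogram.
#' @return An `mz_chromatogram`: a tibble of `rt`, `intensity` (rt strictly
#'   increasing) with the query parameters as attributes.
#' @export
extract_xic <- function(run, mz, tol, tol_unit = c("ppm", "Th"), rt_range = NULL) {
  stopifnot(inherits(run, "mz_run"))
  tol_unit <- match.arg(tol_unit)
  win <- ppm_window(mz, tol, tol_unit)
  idx <- run$scans[run$scans$ms_level == 1L, ]
  if (!is.null(rt_range)) {
    stopifnot(length(rt_range) == 2L)
    idx <- idx[idx$rt >= rt_range[1] & idx$rt <= rt_range[2], ]
  }
  ii <- vapply(idx$scan_id, function(id) {
    p <- run$spectra[[as.character(id)]]$peaks
    sum(p$intensity[p$mz >= win[1, "lo"] & p$mz <= win[1, "hi"]])
  }, numeric(1))
  out <- tibble(rt = idx$rt, intensity = ii)
  structure(out, class = c("mz_chromatogram", class(out)),
            query_mz = mz, tol = tol, tol_unit = tol_unit)
}

#' Trapezoidal peak area of a chromatogram
#'
#' @param chrom An `mz_chromatogram` (or any tibble with `rt`, `intensity`).
#' @param rt_range Optional closed rt interval (minutes) to integrate over.
#' @return Area in minutes x intensity units.
#' @export
xic_area <- function(chrom, rt_range = NULL) {
  stopifnot(all(c("rt", "intensity") %in% names(chrom)))
  df <- chrom
  if (!is.null(rt_range)) {
    stopifnot(length(rt_range) == 2L)
    df <- df[df$rt >= rt_range[1] & df$rt <= rt_range[2], ]
  }
  if (nrow(df) < 2L) abort("need >= 2 chromatogram points in rt_range")
  trapezoid_area(df$rt, df$intensity)
}

#' @method autoplot mz_chromatogram
#' @export
autoplot.mz_chromatogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity",
                  title = sprintf("XIC m/z %.4f ± %g %s",
                                  attr(object, "query_mz"), attr(object, "tol"),
                                  attr(object, "tol_unit"))) +
    ggplot2::theme_minimal()
}
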