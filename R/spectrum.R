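#' Construct a mass spectrum
#'
#' The central scan object: a peak table plus acquisition metadata. Peaks are
#' stored as a tibble with columns `mz` (Th, strictly increasing), `intensity`
#' (non-negative) and optionally `charge` (per-peak charge annotation filled
#' in by de-isotoping; `NA` = never examined, `0` = examined, no isotope
#' partner found).
#'
#' @param scan_id Positive integer scan number.
#' @param ms_level Integer >= 1.
#' @param rt Retention time in minutes.
#' @param peaks A data frame with columns `mz` and `intensity` (and optional
#'   `charge`). Rows are sorted by `mz` on construction.
#' @param precursor_mz Precursor m/z (Th); must be `NULL` iff `ms_level == 1`.
#' @param precursor_charge Integer precursor charge, or `NA` if unknown.
#' @param activation One of `"CAD"`, `"HCD"`, `"ETD"`, `"unknown"`.
#' @param centroided Logical; downstream algorithms require centroided data.
#' @return An object of class `mz_spectrum`.
#' @export
spectrum <- function(scan_id, ms_level, rt, peaks,
                     precursor_mz = NULL, precursor_charge = NA_integer_,
                     activation = "unknown", centroided = TRUE) {
  scan_id <- as.integer(scan_id)
  ms_level <- as.integer(ms_level)
  if (is.na(scan_id) || scan_id < 1L) abort("scan_id must be a positive integer")
  if (is.na(ms_level) || ms_level < 1L) abort("ms_level must be >= 1")
  if (!activation %in% c("CAD", "HCD", "ETD", "unknown")) {
    abort("activation must be one of CAD, HCD, ETD, unknown")
  }
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0L && !"mz" %in% names(peaks)) {
    peaks <- tibble(mz = numeric(), intensity = numeric())
  }
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (!"charge" %in% names(peaks)) peaks$charge <- NA_integer_
  peaks <- peaks[order(peaks$mz), c("mz", "intensity", "charge")]
  if (any(peaks$mz <= 0)) abort("peak m/z must be > 0")
  if (any(peaks$intensity < 0)) abort("peak intensity must be >= 0")
  if (anyDuplicated(peaks$mz)) abort("peaks must be strictly sorted by m/z (duplicates found)")
  if (ms_level == 1L && !is.null(precursor_mz)) {
    abort("MS1 spectra cannot carry a precursor descriptor")
  }
  structure(list(
    scan_id = scan_id, ms_level = ms_level, rt = as.numeric(rt),
    peaks = peaks,
    precursor_mz = if (is.null(precursor_mz)) NULL else as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    activation = activation, centroided = isTRUE(centroided)
  ), class = "mz_spectrum")
}

#' @export
print.mz_spectrum <- function(x, ...) {
  cat(sprintf("<mz_spectrum> scan %d  MS%d  rt %.3f min  %d peaks",
              x$scan_id, x$ms_level, x$rt, nrow(x$peaks)))
  if (!is.null(x$precursor_mz)) {
    cat(sprintf("  precursor %.4f Th (z=%s, %s)", x$precursor_mz,
                ifelse(is.na(x$precursor_charge), "?", x$precursor_charge),
                x$activation))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a spectrum into its peak table
#'
#' @param x An `mz_spectrum`.
#' @param ... Unused.
#' @return The peak tibble, with scan metadata columns prepended.
#' @importFrom generics tidy
#' @method tidy mz_spectrum
#' @export
tidy.mz_spectrum <- function(x, ...) {
  dplyr::bind_cols(
    tibble(scan_id = x$scan_id, ms_level = x$ms_level, rt = x$rt),
    x$peaks
  )
}

#' @importFrom generics glance
#' @method glance mz_spectrum
#' @export
glance.mz_spectrum <- function(x, ...) {
  tibble(
    scan_id = x$scan_id, ms_level = x$ms_level, rt = x$rt,
    n_peaks = nrow(x$peaks),
    tic = sum(x$peaks$intensity),
    base_peak_mz = if (nrow(x$peaks)) x$peaks$mz[which.max(x$peaks$intensity)] else NA_real_,
    precursor_mz = if (is.null(x$precursor_mz)) NA_real_ else x$precursor_mz,
    activation = x$activation
  )
}

#' Centroid a profile-mode spectrum (utility)
#'
#' Collapses each local maximum of the profile trace to a single centroided
#' peak (intensity-weighted m/z over the maximum and its direct neighbours).
#' Provided so profile inputs can enter the centroid-only pipeline; it is a
#' plain utility, not a profile-fitting algorithm.
#'
#' @param s An `mz_spectrum` with `centroided = FALSE`.
#' @return A centroided `mz_spectrum`.
#' @export
centroid_spectrum <- function(s) {
  stopifnot(inherits(s, "mz_spectrum"))
  if (s$centroided) return(s)
  y <- s$peaks$intensity
  n <- length(y)
  if (n < 3L) {
    s$centroided <- TRUE
    return(s)
  }
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  mz <- vapply(idx, function(i) {
    j <- max(1L, i - 1L):min(n, i + 1L)
    sum(s$peaks$mz[j] * y[j]) / sum(y[j])
  }, numeric(1))
  out <- s
  out$peaks <- tibble(mz = mz, intensity = y[idx], charge = NA_integer_)
  out$peaks <- out$peaks[order(out$peaks$mz), ]
  out$centroided <- TRUE
  out
}

#' Stick plot of a spectrum
#'
#' @param object An `mz_spectrum`.
#' @param invert Plot sticks downward (classic mirrored display).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mz_spectrum
#' @export
autoplot.mz_spectrum <- function(object, invert = FALSE, ...) {
  df <- object$peaks
  if (invert) df$intensity <- -df$intensity
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(
      x = "m/z (Th)", y = "intensity",
      title = sprintf("scan %d (MS%d, rt %.2f min)",
                      object$scan_id, object$ms_level, object$rt)
    ) +
    ggplot2::theme_minimal()
}
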