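#' De-isotope an MS/MS spectrum
#'
#' Isotopic envelopes (found with the same greedy averagine-scored clustering
#' as the MS1 detector) are collapsed to their monoisotopic peak carrying the
#' summed envelope intensity and a per-peak charge annotation. Peaks outside
#' any envelope are kept untouched but annotated with charge 0 ("examined, no
#' isotope partner"), so the operation is idempotent by construction: only
#' never-examined (charge `NA`) peaks participate in clustering.
#'
#' @param s A centroided MS/MS `mz_spectrum`.
#' @param charge_range Candidate fragment charges (default 1:6).
#' @param tol_ppm Isotope spacing tolerance (ppm).
#' @param min_score Averagine cosine threshold (default 0.9).
#' @return The de-isotoped `mz_spectrum`, sorted by m/z, with the `charge`
#'   peak column filled.
#' @export
deisotope <- function(s, charge_range = 1:6, tol_ppm = 10, min_score = 0.9) {
  stopifnot(inherits(s, "mz_spectrum"))
  if (!s$centroided) abort("deisotope requires a centroided spectrum",
                           class = "mzc_data_error")
  fresh <- is.na(s$peaks$charge)
  if (!any(fresh)) return(s)
  sub <- s
  sub$peaks <- s$peaks[fresh, ]
  env <- detect_envelopes(sub, feature_params(charge_range = charge_range,
                                              spacing_tol_ppm = tol_ppm,
                                              min_score = min_score,
                                              min_isotopes = 2L))
  in_env <- integer(0)
  mono <- tibble(mz = numeric(), intensity = numeric(), charge = integer())
  if (nrow(env)) {
    in_env <- unlist(env$peak_idx)
    mono <- tibble(mz = env$mono_mz,
                   intensity = env$total_intensity,
                   charge = as.integer(env$charge))
  }
  leftover <- sub$peaks[setdiff(seq_len(nrow(sub$peaks)), in_env), ]
  leftover$charge <- 0L
  out_peaks <- dplyr::bind_rows(s$peaks[!fresh, ], leftover, mono)
  out_peaks <- out_peaks[order(out_peaks$mz), ]
  s$peaks <- out_peaks
  s
}

#' Reduce multiply charged peaks to singly charged m/z
#'
#' Every annotated peak with charge z > 1 is re-placed at its singly charged
#' m/z (`z * mz - (z - 1) * 1.007276`), conserving the inferred neutral mass
#' exactly. Reduced peaks landing within `merge_tol` Th of an existing
#' singly-charged peak are merged (intensities summed, the existing m/z
#' kept). Peaks without a charge annotation (`NA`) are left unchanged and a
#' single warning is emitted; run [deisotope()] first.
#'
#' @param s A de-isotoped `mz_spectrum` with per-peak charge annotations.
#' @param merge_tol Collision merge tolerance in Th (default 0.01).
#' @return The charge-reduced `mz_spectrum`, sorted by m/z.
#' @export
charge_reduce <- function(s, merge_tol = 0.01) {
  stopifnot(inherits(s, "mz_spectrum"))
  pk <- s$peaks
  if (!nrow(pk)) return(s)
  if (any(is.na(pk$charge))) {
    warn("charge_reduce: peaks without charge annotation left unchanged (run deisotope first)")
  }
  hi <- !is.na(pk$charge) & pk$charge > 1L
  keep <- pk[!hi, ]
  red <- pk[hi, ]
  if (nrow(red)) {
    red$mz <- red$charge * red$mz - (red$charge - 1L) * PROTON_MASS
    red$charge <- 1L
    # merge into an existing singly-charged peak within merge_tol
    singly <- which(!is.na(keep$charge) & keep$charge <= 1L)
    drop <- logical(nrow(red))
    for (i in seq_len(nrow(red))) {
      if (!length(singly)) break
      d <- abs(keep$mz[singly] - red$mz[i])
      j <- which.min(d)
      if (d[j] <= merge_tol) {
        keep$intensity[singly[j]] <- keep$intensity[singly[j]] + red$intensity[i]
        drop[i] <- TRUE
      }
    }
    red <- red[!drop, ]
    # collisions among reduced peaks themselves
    if (nrow(red) > 1L) {
      o <- order(red$mz)
      red <- red[o, ]
      grp <- cumsum(c(TRUE, diff(red$mz) > merge_tol))
      red <- red |>
        dplyr::mutate(.grp = grp) |>
        dplyr::group_by(.data$.grp) |>
        dplyr::summarise(mz = .data$mz[1],
                         intensity = sum(.data$intensity),
                         charge = 1L, .groups = "drop") |>
        dplyr::select("mz", "intensity", "charge")
    }
  }
  out <- dplyr::bind_rows(keep, red)
  s$peaks <- out[order(out$mz), ]
  s
}

#' Remove diagnostic / contaminant ions
#'
#' Peaks within `tol` of any exclusion m/z are removed (e.g. kinase-inhibitor
#' related ions that depress search scores); everything else is preserved
#' with order and intensities intact.
#'
#' @param s An `mz_spectrum`.
#' @param exclusion_mzs Numeric vector of m/z values to excise.
#' @param tol Window half-width (> 0).
#' @param tol_unit `"Th"` (default) or `"ppm"`.
#' @return The filtered `mz_spectrum`.
#' @export
filter_ions <- function(s, exclusion_mzs, tol = 0.01, tol_unit = c("Th", "ppm")) {
  stopifnot(inherits(s, "mz_spectrum"))
  tol_unit <- match.arg(tol_unit)
  if (tol <= 0) abort("tol must be > 0")
  if (!length(exclusion_mzs) || !nrow(s$peaks)) return(s)
  w <- if (tol_unit == "ppm") exclusion_mzs * tol * 1e-6 else rep_len(tol, length(exclusion_mzs))
  kill <- rep(FALSE, nrow(s$peaks))
  for (k in seq_along(exclusion_mzs)) {
    kill <- kill | (s$peaks$mz >= exclusion_mzs[k] - w[k] &
                      s$peaks$mz <= exclusion_mzs[k] + w[k])
  }
  s$peaks <- s$peaks[!kill, ]
  s
}

# ---- step registry ---------------------------------------------------------

builtin_steps <- function() {
  list(
    filter_ions = function(s, params) {
      do.call(filter_ions, c(list(s = s), params))
    },
    deisotope = function(s, params) do.call(deisotope, c(list(s = s), params)),
    charge_reduce = function(s, params) do.call(charge_reduce, c(list(s = s), params))
  )
}

step_registry <- function() {
  if (is.null(.mzc$steps)) .mzc$steps <- builtin_steps()
  .mzc$steps
}

#' Register a custom spectral-processing step
#'
#' User routines plug into the same pipeline machinery as the built-ins
#' (`filter_ions`, `deisotope`, `charge_reduce`). A step is a plain function
#' `function(s, params)` returning a new `mz_spectrum`.
#'
#' @param name Step identifier used in pipelines.
#' @param fn Function of `(s, params)`.
#' @return Invisibly, the registered step names.
#' @export
register_step <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  reg <- step_registry()
  reg[[name]] <- fn
  .mzc$steps <- reg
  invisible(names(reg))
}

#' @rdname register_step
#' @export
registered_steps <- function() names(step_registry())

#' Build a processing step description
#'
#' @param name Registered step name.
#' @param ... Step parameters (name = value).
#' @return A `processing_step` list.
#' @export
processing_step <- function(name, ...) {
  structure(list(name = name, params = list(...)), class = "processing_step")
}

#' Apply an ordered processing pipeline with provenance
#'
#' Steps are applied left to right. The returned record captures the step
#' names and parameters plus sha256 digests of the input and output peak
#' lists — the forensic chain-of-custody: replaying the steps on the input
#' must reproduce the output digest. Identical inputs and steps give
#' identical digests (the wall-clock timestamp is stored but never digested).
#'
#' @param s Input `mz_spectrum`.
#' @param steps List of [processing_step()] (or bare lists with `name`,
#'   `params`).
#' @return List with elements `spectrum` (processed) and `record`
#'   (`processing_record`: `input_digest`, `steps`, `output_digest`,
#'   `timestamp`, `complete`).
#' @export
apply_pipeline <- function(s, steps = list()) {
  stopifnot(inherits(s, "mz_spectrum"))
  reg <- step_registry()
  in_dig <- spectrum_digest(s)
  rec_steps <- list()
  cur <- s
  for (st in steps) {
    if (!st$name %in% names(reg)) {
      abort(paste0("unknown processing step: '", st$name, "'"), class = "mzc_data_error")
    }
    res <- tryCatch(reg[[st$name]](cur, st$params), error = function(e) e)
    if (inherits(res, "error")) {
      rec <- structure(list(input_digest = in_dig, steps = rec_steps,
                            output_digest = NA_character_,
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                            complete = FALSE, failed_step = st$name),
                       class = "processing_record")
      abort(paste0("pipeline aborted in step '", st$name, "': ",
                   conditionMessage(res)),
            class = "mzc_pipeline_error", record = rec)
    }
    cur <- res
    rec_steps[[length(rec_steps) + 1L]] <- list(name = st$name, params = st$params)
  }
  rec <- structure(list(input_digest = in_dig, steps = rec_steps,
                        output_digest = spectrum_digest(cur),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                        complete = TRUE),
                   class = "processing_record")
  list(spectrum = cur, record = rec)
}

#' Replay a processing record
#'
#' Re-applies a record's steps to an input spectrum and verifies both
#' digests, proving the record describes exactly this transformation.
#'
#' @param record A `processing_record`.
#' @param s The input `mz_spectrum` (must match `record$input_digest`).
#' @return The reproduced output `mz_spectrum` (errors on digest mismatch).
#' @export
replay_record <- function(record, s) {
  stopifnot(inherits(record, "processing_record"), inherits(s, "mz_spectrum"))
  if (spectrum_digest(s) != record$input_digest) {
    abort("input spectrum does not match the record's input digest",
          class = "mzc_data_error")
  }
  res <- apply_pipeline(s, purrr::map(record$steps, function(st)
    structure(st, class = "processing_step")))
  if (res$record$output_digest != record$output_digest) {
    abort("replay did not reproduce the recorded output digest",
          class = "mzc_data_error")
  }
  res$spectrum
}

#' Export processed spectra for re-search
#'
#' Writes an MGF whose TITLEs carry each spectrum's processing-record digest
#' (`record=<sha256>`), so results imported after a re-search link back to
#' the exact processed form of every scan.
#'
#' @param processed List of `list(spectrum=, record=)` as returned by
#'   [apply_pipeline()].
#' @param path Output MGF path.
#' @param run_name Run basename for TITLEs.
#' @return `path`, invisibly.
#' @export
export_for_research <- function(processed, path, run_name = "run") {
  spectra <- purrr::map(processed, "spectrum")
  digests <- purrr::map_chr(processed, function(p) {
    paste0("record=", p$record$output_digest)
  })
  write_mgf(spectra, path, run_name = run_name, title_suffix = digests)
}
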