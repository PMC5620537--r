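#' Read an mzML run into memory
#'
#' Loads every scan of a (centroided or profile-flagged) mzML file and
#' indexes it by scan id and by retention time per MS level. Scan ids are
#' the 1-based integers parsed from the mzML native id (matching instrument
#' scan numbering used by search engines). Activation type is recovered from
#' the filter string when present (`ACT=HCD|CAD|ETD`).
#'
#' @param path Path to an mzML file.
#' @return An object of class `mz_run` with fields `source_path`, `spectra`
#'   (list keyed by scan id), and `scans` (index tibble: `scan_id`,
#'   `ms_level`, `rt`, `n_peaks`, `precursor_mz`, `injection_time`).
#' @export
read_run <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "mzc_data_error")
  h <- tryCatch({
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh), add = TRUE)
    hd <- mzR::header(fh)
    pk <- if (nrow(hd)) mzR::peaks(fh) else list()
    if (nrow(hd) == 1L && is.matrix(pk)) pk <- list(pk)
    list(header = hd, peaks = pk)
  }, error = function(e) abort(paste0("malformed mzML: ", conditionMessage(e)),
                               class = "mzc_data_error"))
  hd <- h$header
  ids <- extract_scan_ids(hd)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate scan id(s) in ", basename(path), ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "mzc_data_error")
  }
  spectra <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    act <- parse_activation(hd$filterString[i])
    ms1 <- hd$msLevel[i] == 1L
    pm <- hd$precursorMZ[i]
    spectra[[i]] <- spectrum(
      scan_id = ids[i], ms_level = hd$msLevel[i],
      rt = hd$retentionTime[i] / 60,
      peaks = tibble(mz = h$peaks[[i]][, 1], intensity = h$peaks[[i]][, 2]),
      precursor_mz = if (ms1 || is.na(pm) || pm <= 0) NULL else pm,
      precursor_charge = if (ms1) NA_integer_ else {
        pc <- hd$precursorCharge[i]
        if (is.na(pc) || pc < 1L) NA_integer_ else as.integer(pc)
      },
      activation = if (ms1) "unknown" else act,
      centroided = isTRUE(hd$centroided[i])
    )
  }
  names(spectra) <- as.character(ids)
  scans <- tibble(
    scan_id = ids, ms_level = as.integer(hd$msLevel),
    rt = hd$retentionTime / 60,
    n_peaks = as.integer(hd$peaksCount),
    precursor_mz = ifelse(hd$msLevel == 1L, NA_real_, hd$precursorMZ),
    injection_time = if ("injectionTime" %in% names(hd)) hd$injectionTime else NA_real_
  )
  structure(list(source_path = path, spectra = spectra, scans = scans),
            class = "mz_run")
}

extract_scan_ids <- function(hd) {
  if (nrow(hd) == 0L) return(integer())
  sid <- hd$spectrumId
  m <- regmatches(sid, regexpr("scan=[0-9]+", sid))
  if (length(m) == nrow(hd) && all(nzchar(m))) {
    as.integer(sub("scan=", "", m))
  } else {
    as.integer(hd$acquisitionNum)
  }
}

parse_activation <- function(fs) {
  if (is.null(fs) || is.na(fs)) return("unknown")
  m <- regmatches(fs, regexpr("ACT=(HCD|CAD|ETD)", fs))
  if (length(m) && nzchar(m)) sub("ACT=", "", m) else "unknown"
}

#' @export
print.mz_run <- function(x, ...) {
  cat(sprintf("<mz_run> %s  %d scans (%d MS1, %d MSn)  rt %.2f-%.2f min\n",
              basename(x$source_path), nrow(x$scans),
              sum(x$scans$ms_level == 1L), sum(x$scans$ms_level > 1L),
              min(x$scans$rt, Inf), max(x$scans$rt, -Inf)))
  invisible(x)
}

#' @method glance mz_run
#' @export
glance.mz_run <- function(x, ...) {
  tibble(
    source = basename(x$source_path),
    n_scans = nrow(x$scans),
    n_ms1 = sum(x$scans$ms_level == 1L),
    n_ms2 = sum(x$scans$ms_level == 2L),
    rt_min = if (nrow(x$scans)) min(x$scans$rt) else NA_real_,
    rt_max = if (nrow(x$scans)) max(x$scans$rt) else NA_real_
  )
}

#' Random access to a scan
#'
#' @param run An `mz_run`.
#' @param scan_id Scan id to fetch.
#' @return The stored `mz_spectrum`; repeated calls return identical objects.
#' @export
get_scan <- function(run, scan_id) {
  stopifnot(inherits(run, "mz_run"))
  key <- as.character(as.integer(scan_id))
  s <- run$spectra[[key]]
  if (is.null(s)) {
    abort(paste0("no scan with id ", scan_id, " in ", basename(run$source_path)),
          class = "mzc_data_error")
  }
  s
}

#' Scan nearest a retention time
#'
#' @param run An `mz_run`.
#' @param rt Retention time in minutes.
#' @param ms_level MS level to search within.
#' @return The `mz_spectrum` of that level whose rt is closest; ties are
#'   broken toward the lower scan id.
#' @export
scan_near_rt <- function(run, rt, ms_level = 1L) {
  stopifnot(inherits(run, "mz_run"))
  idx <- run$scans[run$scans$ms_level == as.integer(ms_level), ]
  if (!nrow(idx)) abort(paste0("run has no scans at MS level ", ms_level),
                        class = "mzc_data_error")
  d <- abs(idx$rt - rt)
  best <- order(d, idx$scan_id)[1]
  get_scan(run, idx$scan_id[best])
}

#' LRU cache over multiple runs
#'
#' Raw files for a multi-run experiment may be loaded all at once or cached
#' sequentially: the cache holds at most `capacity` loaded runs and evicts
#' the least-recently-used one; accessing an evicted run transparently
#' reloads it from disk.
#'
#' @param capacity Maximum number of simultaneously loaded runs.
#' @return An object of class `mz_run_cache`.
#' @export
run_cache <- function(capacity = 2L) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 1L) abort("capacity must be >= 1")
  e <- new.env(parent = emptyenv())
  e$capacity <- capacity
  e$runs <- list()          # path -> mz_run, most recent last
  e$n_loads <- 0L
  class(e) <- "mz_run_cache"
  e
}

#' @rdname run_cache
#' @param cache An `mz_run_cache`.
#' @param path Path of the run to fetch (loaded on miss).
#' @export
cache_get <- function(cache, path) {
  stopifnot(inherits(cache, "mz_run_cache"))
  if (path %in% names(cache$runs)) {
    run <- cache$runs[[path]]
    cache$runs[[path]] <- NULL        # refresh recency
    cache$runs[[path]] <- run
    return(run)
  }
  run <- read_run(path)
  cache$n_loads <- cache$n_loads + 1L
  cache$runs[[path]] <- run
  while (length(cache$runs) > cache$capacity) {
    cache$runs[[1L]] <- NULL          # evict least recently used
  }
  run
}

#' @rdname run_cache
#' @export
cache_loaded <- function(cache) names(cache$runs)

#' Write spectra to an mzML file
#'
#' Serializes a list of `mz_spectrum` (one run) to mzML 1.1 via the
#' proteowizard backend, with 64-bit m/z encoding so sub-ppm round trips are
#' preserved. Activation is encoded in the filter string (`ACT=...`), scan
#' ids in the native id (`scan=N`).
#'
#' @param spectra List of `mz_spectrum`, in acquisition order.
#' @param path Output path (`.mzML`).
#' @param injection_times Optional numeric vector of ion injection times (ms).
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(spectra, path, injection_times = NULL) {
  n <- length(spectra)
  if (is.null(injection_times)) injection_times <- rep(10, n)
  ids <- vapply(spectra, function(s) s$scan_id, integer(1))
  if (anyDuplicated(ids)) abort("duplicate scan ids", class = "mzc_data_error")
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = ids,
    msLevel = vapply(spectra, function(s) s$ms_level, integer(1)),
    polarity = rep(1L, n),
    peaksCount = vapply(spectra, function(s) nrow(s$peaks), integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$peaks$intensity), numeric(1)),
    retentionTime = vapply(spectra, function(s) s$rt * 60, numeric(1)),
    basePeakMZ = vapply(spectra, function(s)
      if (nrow(s$peaks)) s$peaks$mz[which.max(s$peaks$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s)
      if (nrow(s$peaks)) max(s$peaks$intensity) else 0, numeric(1)),
    collisionEnergy = vapply(spectra, function(s)
      if (s$ms_level > 1L && s$activation %in% c("HCD", "CAD")) 30 else 0, numeric(1)),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(spectra, function(s)
      if (nrow(s$peaks)) min(s$peaks$mz) else 0, numeric(1)),
    highMZ = vapply(spectra, function(s)
      if (nrow(s$peaks)) max(s$peaks$mz) else 0, numeric(1)),
    precursorScanNum = rep(0L, n),
    precursorMZ = vapply(spectra, function(s)
      if (is.null(s$precursor_mz)) 0 else s$precursor_mz, numeric(1)),
    precursorCharge = vapply(spectra, function(s)
      if (is.null(s$precursor_mz) || is.na(s$precursor_charge)) 0L else s$precursor_charge,
      integer(1)),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = as.numeric(injection_times),
    filterString = vapply(spectra, function(s)
      sprintf("MS%d ACT=%s", s$ms_level, s$activation), character(1)),
    spectrumId = sprintf("scan=%d", ids),
    centroided = vapply(spectra, function(s) s$centroided, logical(1)),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = vapply(spectra, function(s)
      if (is.null(s$precursor_mz)) NA_real_ else s$precursor_mz, numeric(1)),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  pk <- lapply(spectra, function(s) cbind(mz = s$peaks$mz, intensity = s$peaks$intensity))
  suppressWarnings(
    mzR::writeMSData(pk, path, header = hd, outformat = "mzml", rtime_seconds = TRUE)
  )
  invisible(path)
}
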