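#' Feature detection parameters
#'
#' Defaults for the unbiased MS1 feature detector. Spacing/link tolerances
#' are in ppm; `min_score` is the cosine similarity against the averagine
#' isotope model below which a candidate envelope is rejected; `max_gap` is
#' the number of consecutive MS1 scans a trace may miss and still continue;
#' `rt_pad` (minutes) pads the feature rt range when linking MS/MS scans.
#'
#' @param charge_range Integer vector of candidate charges.
#' @param spacing_tol_ppm Isotope spacing tolerance (ppm).
#' @param link_tol_ppm Scan-to-scan mono m/z link tolerance (ppm).
#' @param max_gap Allowed missed scans inside a trace.
#' @param min_scans Minimum member MS1 scans per feature.
#' @param min_isotopes Minimum isotope peaks per envelope.
#' @param min_score Minimum averagine cosine score in \[0, 1\].
#' @param rt_pad MS/MS link pad in minutes.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(charge_range = 1:6, spacing_tol_ppm = 10,
                           link_tol_ppm = 10, max_gap = 1L, min_scans = 3L,
                           min_isotopes = 2L, min_score = 0.9, rt_pad = 0.2) {
  structure(list(charge_range = as.integer(charge_range),
                 spacing_tol_ppm = spacing_tol_ppm, link_tol_ppm = link_tol_ppm,
                 max_gap = as.integer(max_gap), min_scans = as.integer(min_scans),
                 min_isotopes = as.integer(min_isotopes), min_score = min_score,
                 rt_pad = rt_pad),
            class = "feature_params")
}

# Chain unused peaks outward from a seed at spacings ISOTOPE_SPACING / z.
# Returns integer indices of chain members (sorted by m/z), seed included.
chain_envelope <- function(mz, usable, seed, z, tol_ppm) {
  step <- ISOTOPE_SPACING / z
  members <- seed
  # upward
  cur <- mz[seed]
  repeat {
    expect <- cur + step
    tol <- expect * tol_ppm * 1e-6
    cand <- which(usable & abs(mz - expect) <= tol)
    cand <- setdiff(cand, members)
    if (!length(cand)) break
    nxt <- cand[order(abs(mz[cand] - expect), mz[cand])][1]
    members <- c(members, nxt)
    cur <- mz[nxt]
  }
  # downward (toward the monoisotope)
  cur <- mz[seed]
  repeat {
    expect <- cur - step
    tol <- expect * tol_ppm * 1e-6
    cand <- which(usable & abs(mz - expect) <= tol)
    cand <- setdiff(cand, members)
    if (!length(cand)) break
    nxt <- cand[order(abs(mz[cand] - expect), mz[cand])][1]
    members <- c(members, nxt)
    cur <- mz[nxt]
  }
  sort(members)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Detect isotopic envelopes in one centroided spectrum
#'
#' Greedy highest-intensity-first grouping: each unused peak seeds candidate
#' envelopes at every charge in `params$charge_range`, collecting unused
#' peaks at the expected isotope spacings within `spacing_tol_ppm`. A
#' candidate is scored by cosine similarity between its observed intensities
#' and the averagine-predicted isotope distribution at its neutral mass; the
#' charge explaining the most peaks wins (ties by score, then lower charge —
#' so a sub-sampled chain at a divisor charge never beats the full envelope).
#' Envelopes need at
#' least `min_isotopes` peaks and `min_score`; accepted members are consumed,
#' so no peak belongs to two envelopes.
#'
#' @param s A centroided `mz_spectrum`.
#' @param params A [feature_params()] list.
#' @return Tibble of envelopes: `mono_mz`, `charge`, `n_isotopes`,
#'   `envelope_score`, `mono_intensity`, `total_intensity`, `peak_idx`
#'   (list of member row indices into `s$peaks`), `iso_mz` (list of member
#'   m/z), ordered by descending seed intensity (detection order).
#' @export
detect_envelopes <- function(s, params = feature_params()) {
  stopifnot(inherits(s, "mz_spectrum"))
  if (!s$centroided) abort("detect_envelopes requires a centroided spectrum",
                           class = "mzc_data_error")
  pk <- s$peaks
  n <- nrow(pk)
  empty <- tibble(mono_mz = numeric(), charge = integer(), n_isotopes = integer(),
                  envelope_score = numeric(), mono_intensity = numeric(),
                  total_intensity = numeric(), peak_idx = list(), iso_mz = list())
  if (n < params$min_isotopes) return(empty)
  usable <- pk$intensity > 0
  order_seeds <- order(-pk$intensity, pk$mz)
  out <- list()
  for (seed in order_seeds) {
    if (!usable[seed]) next
    best <- NULL
    for (z in params$charge_range) {
      members <- chain_envelope(pk$mz, usable, seed, z, params$spacing_tol_ppm)
      if (length(members) < params$min_isotopes) next
      mono_mz <- pk$mz[members[1]]
      neutral <- (mono_mz - PROTON_MASS) * z
      if (neutral <= 0) next
      score <- cosine_sim(pk$intensity[members],
                          averagine_envelope(neutral, length(members)))
      better <- is.null(best) ||
        length(members) > length(best$members) ||
        (length(members) == length(best$members) && score > best$score + 1e-12)
      if (better) best <- list(members = members, z = z, score = score)
    }
    if (!is.null(best) && best$score >= params$min_score) {
      m <- best$members
      usable[m] <- FALSE
      out[[length(out) + 1L]] <- tibble(
        mono_mz = pk$mz[m[1]], charge = best$z, n_isotopes = length(m),
        envelope_score = best$score, mono_intensity = pk$intensity[m[1]],
        total_intensity = sum(pk$intensity[m]),
        peak_idx = list(m), iso_mz = list(pk$mz[m])
      )
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Detect MS1 features across a run
#'
#' Per-scan envelopes are linked across adjacent MS1 scans when their mono
#' m/z agree within `link_tol_ppm` at the same charge; traces survive gaps of
#' up to `max_gap` scans and become features when they span at least
#' `min_scans` member scans. The feature area is the trapezoidal integral of
#' the monoisotope intensity trace over retention time.
#'
#' @param run An `mz_run` with MS1 scans.
#' @param params A [feature_params()] list.
#' @return Tibble of class `mz_features`: `feature_id`, `mono_mz` (at apex),
#'   `charge`, `rt_start`, `rt_end`, `apex_rt`, `apex_intensity`, `area`,
#'   `n_scans`, `scan_ids` (list), `iso_mz` (apex envelope, list),
#'   `ms2_scan_ids` (list, empty until [link_ms2()]), `assigned`.
#' @export
detect_features <- function(run, params = feature_params()) {
  stopifnot(inherits(run, "mz_run"))
  ms1 <- run$scans[run$scans$ms_level == 1L, ]
  open <- list()    # active traces
  done <- list()
  for (k in seq_len(nrow(ms1))) {
    sid <- ms1$scan_id[k]; rt <- ms1$rt[k]
    env <- detect_envelopes(run$spectra[[as.character(sid)]], params)
    used_env <- rep(FALSE, nrow(env))
    if (length(open)) {
      for (ti in seq_along(open)) {
        tr <- open[[ti]]
        cand <- which(!used_env & env$charge == tr$charge &
                        abs(env$mono_mz - tr$mono_mz) <=
                          tr$mono_mz * params$link_tol_ppm * 1e-6)
        if (length(cand)) {
          j <- cand[order(abs(env$mono_mz[cand] - tr$mono_mz))][1]
          used_env[j] <- TRUE
          tr$scan_ids <- c(tr$scan_ids, sid)
          tr$rts <- c(tr$rts, rt)
          tr$mono_int <- c(tr$mono_int, env$mono_intensity[j])
          tr$mono_mzs <- c(tr$mono_mzs, env$mono_mz[j])
          tr$iso_mz_list <- c(tr$iso_mz_list, env$iso_mz[j])
          tr$mono_mz <- env$mono_mz[j]   # track drift
          tr$gap <- 0L
        } else {
          tr$gap <- tr$gap + 1L
        }
        open[[ti]] <- tr
      }
      closing <- vapply(open, function(tr) tr$gap > params$max_gap, logical(1))
      done <- c(done, open[closing])
      open <- open[!closing]
    }
    if (nrow(env)) {
      for (j in which(!used_env)) {
        open[[length(open) + 1L]] <- list(
          charge = env$charge[j], mono_mz = env$mono_mz[j],
          scan_ids = sid, rts = rt, mono_int = env$mono_intensity[j],
          mono_mzs = env$mono_mz[j], iso_mz_list = env$iso_mz[j], gap = 0L
        )
      }
    }
  }
  done <- c(done, open)
  done <- purrr::keep(done, function(tr) length(tr$scan_ids) >= params$min_scans)
  rows <- purrr::imap(done, function(tr, i) {
    apex <- which.max(tr$mono_int)
    tibble(
      feature_id = NA_integer_,
      mono_mz = tr$mono_mzs[apex], charge = tr$charge,
      rt_start = tr$rts[1], rt_end = tr$rts[length(tr$rts)],
      apex_rt = tr$rts[apex], apex_intensity = tr$mono_int[apex],
      area = if (length(tr$rts) >= 2) trapezoid_area(tr$rts, tr$mono_int) else 0,
      n_scans = length(tr$scan_ids),
      scan_ids = list(tr$scan_ids),
      iso_mz = tr$iso_mz_list[apex],
      ms2_scan_ids = list(integer()),
      assigned = FALSE
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    feature_id = integer(), mono_mz = numeric(), charge = integer(),
    rt_start = numeric(), rt_end = numeric(), apex_rt = numeric(),
    apex_intensity = numeric(), area = numeric(), n_scans = integer(),
    scan_ids = list(), iso_mz = list(), ms2_scan_ids = list(), assigned = logical()
  )
  out <- dplyr::arrange(out, .data$mono_mz, .data$rt_start)
  out$feature_id <- seq_len(nrow(out))
  structure(out, class = c("mz_features", class(tibble())),
            run_basename = strip_mz_ext(basename(run$source_path)))
}

strip_mz_ext <- function(x) sub("\\.(mzML|mzml|mgf)$", "", x)

#' Link MS/MS scans to detected features
#'
#' An MS2 scan is linked to a feature iff its precursor m/z lies within
#' `mz_tol_ppm` of any isotope of the feature's (apex) envelope and its rt
#' falls inside the feature's rt range padded by `rt_pad` minutes. Each MS2
#' scan links to at most one feature; when several qualify, the feature whose
#' mono m/z is nearest the precursor wins.
#'
#' @param features An `mz_features` tibble.
#' @param run The source `mz_run`.
#' @param rt_pad Pad in minutes (default 0.2).
#' @param mz_tol_ppm Precursor match tolerance (default 10 ppm).
#' @return `features` with `ms2_scan_ids` filled in.
#' @export
link_ms2 <- function(features, run, rt_pad = 0.2, mz_tol_ppm = 10) {
  stopifnot(inherits(run, "mz_run"))
  ms2 <- run$scans[run$scans$ms_level == 2L & !is.na(run$scans$precursor_mz), ]
  features$ms2_scan_ids <- purrr::map(features$ms2_scan_ids, function(x) integer())
  if (!nrow(ms2) || !nrow(features)) return(features)
  for (k in seq_len(nrow(ms2))) {
    pmz <- ms2$precursor_mz[k]; rt <- ms2$rt[k]
    ok <- which(vapply(seq_len(nrow(features)), function(i) {
      rt >= features$rt_start[i] - rt_pad && rt <= features$rt_end[i] + rt_pad &&
        any(abs(features$iso_mz[[i]] - pmz) <= features$iso_mz[[i]] * mz_tol_ppm * 1e-6)
    }, logical(1)))
    if (!length(ok)) next
    best <- ok[order(abs(features$mono_mz[ok] - pmz))][1]
    features$ms2_scan_ids[[best]] <- c(features$ms2_scan_ids[[best]], ms2$scan_id[k])
  }
  features
}

#' Features with no sequence assignment in the results store
#'
#' Returns the features none of whose linked MS/MS scans appear as matched
#' spectra in the results database, ordered by descending area — the mining
#' loop for spectra worth re-searching.
#'
#' @param features An `mz_features` tibble (after [link_ms2()]).
#' @param db An `mz_results_db`.
#' @return Subset of `features`, descending by `area`; `assigned` updated on
#'   the full input is available via attribute `assigned_ids`.
#' @export
unassigned_features <- function(features, db) {
  matched <- results_matched_scans(db)
  rb <- attr(features, "run_basename")
  hit <- vapply(seq_len(nrow(features)), function(i) {
    sc <- features$ms2_scan_ids[[i]]
    length(sc) > 0 && any(paste(rb, sc) %in% paste(matched$run, matched$scan))
  }, logical(1))
  out <- features[!hit, ]
  dplyr::arrange(out, dplyr::desc(.data$area))
}

#' Tidy features to a flat table
#'
#' @param x An `mz_features` tibble.
#' @param ... Unused.
#' @return A plain tibble with list columns collapsed to counts/strings.
#' @method tidy mz_features
#' @export
tidy.mz_features <- function(x, ...) {
  tibble(
    feature_id = x$feature_id, mono_mz = x$mono_mz, charge = x$charge,
    rt_start = x$rt_start, rt_end = x$rt_end, apex_rt = x$apex_rt,
    area = x$area, n_scans = x$n_scans,
    ms2_scans = vapply(x$ms2_scan_ids, function(s) paste(s, collapse = ";"), character(1)),
    assigned = x$assigned
  )
}

#' Write a feature table as TSV
#'
#' @param features An `mz_features` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  df <- tidy.mz_features(features)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(df, 1, function(r) paste(r, collapse = "\t")))
  write_atomic(lines, path)
}

#' Map view of detected features
#'
#' @param object An `mz_features` tibble.
#' @param ... Unused.
#' @return A ggplot: features as rt-extent segments at their mono m/z.
#' @method autoplot mz_features
#' @export
autoplot.mz_features <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rt_start, xend = .data$rt_end,
                                       y = .data$mono_mz, yend = .data$mono_mz,
                                       colour = factor(.data$charge))) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::labs(x = "retention time (min)", y = "mono m/z (Th)",
                  colour = "charge") +
    ggplot2::theme_minimal()
}
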