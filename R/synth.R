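#' Describe a synthetic peptide for run generation
#'
#' One precursor species: an averagine-shaped isotopic envelope eluting as a
#' Gaussian over retention time, optionally fragmented into an MS/MS scan
#' near its apex.
#'
#' @param p An `mz_peptide` (or a sequence string).
#' @param charge Precursor charge.
#' @param apex_rt Elution apex (minutes).
#' @param sigma_rt Gaussian elution width sigma (minutes).
#' @param abundance Apex intensity of the monoisotopic peak.
#' @param include_ms2 Plant an MS/MS scan near the apex?
#' @param isotope_depth Number of isotope peaks emitted (>= 2).
#' @param activation Fragmentation mode for the MS/MS scan (`"HCD"`,
#'   `"CAD"` give b/y; `"ETD"` gives c/z).
#' @param reporter Optional `list(panel = reporter_panel(), intensities = )`
#'   to plant reporter ions in the MS/MS scan.
#' @return A `synthetic_peptide_spec`.
#' @export
peptide_spec <- function(p, charge = 2L, apex_rt = 5, sigma_rt = 0.1,
                         abundance = 1e5, include_ms2 = TRUE,
                         isotope_depth = 4L, activation = "HCD",
                         reporter = NULL) {
  if (is.character(p)) p <- peptide(p)
  stopifnot(inherits(p, "mz_peptide"), sigma_rt > 0, abundance > 0,
            isotope_depth >= 2L)
  structure(list(peptide = p, charge = as.integer(charge), apex_rt = apex_rt,
                 sigma_rt = sigma_rt, abundance = abundance,
                 include_ms2 = isTRUE(include_ms2),
                 isotope_depth = as.integer(isotope_depth),
                 activation = activation, reporter = reporter),
            class = "synthetic_peptide_spec")
}

#' Noise model for synthetic runs
#'
#' Baseline noise peaks are uniform in m/z and exponential in intensity;
#' signal peak positions can carry Gaussian m/z jitter. Fully determined by
#' the run seed.
#'
#' @param baseline_density Noise peaks per 100 Th per scan.
#' @param intensity_mean Mean of the exponential noise intensity.
#' @param mz_jitter_ppm Gaussian sigma of signal m/z jitter (ppm).
#' @return A `noise_model`.
#' @export
noise_model <- function(baseline_density = 0, intensity_mean = 1e3,
                        mz_jitter_ppm = 0) {
  structure(list(baseline_density = baseline_density,
                 intensity_mean = intensity_mean,
                 mz_jitter_ppm = mz_jitter_ppm),
            class = "noise_model")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

series_for_activation <- function(activation) {
  if (activation == "ETD") c("c", "z") else c("b", "y")
}

# deterministic fragment intensity pattern (no RNG: annotation tests need it)
fragment_intensity_pattern <- function(n) {
  1000 * (0.3 + 0.7 * (((seq_len(n) * 7L) %% 11L) + 1L) / 11L)
}

#' Build a synthetic MS/MS spectrum for a peptide
#'
#' Peaks at every theoretical singly-charged fragment m/z of the series the
#' activation mode produces, with a fixed deterministic intensity pattern,
#' plus optional planted reporter ions and seeded baseline noise.
#'
#' @param p An `mz_peptide` (or sequence string).
#' @param charge Precursor charge.
#' @param activation `"HCD"`, `"CAD"`, or `"ETD"`.
#' @param noise Optional [noise_model()]; the caller controls the RNG state.
#' @param reporter Optional `list(panel =, intensities =)`.
#' @param scan_id,rt Scan metadata.
#' @param mz_range Instrument m/z range for noise placement.
#' @return An `mz_spectrum` (MS level 2).
#' @export
make_msms <- function(p, charge = 2L, activation = "HCD", noise = NULL,
                      reporter = NULL, scan_id = 1L, rt = 0,
                      mz_range = c(100, 2000)) {
  if (is.character(p)) p <- peptide(p)
  ions <- fragment_ions(p, series = series_for_activation(activation),
                        max_charge = 1L)
  pk <- tibble(mz = ions$mz, intensity = fragment_intensity_pattern(nrow(ions)))
  if (!is.null(reporter)) {
    pk <- dplyr::bind_rows(pk, tibble(mz = reporter$panel$mz,
                                      intensity = reporter$intensities))
  }
  if (!is.null(noise) && noise$baseline_density > 0) {
    n_noise <- round(noise$baseline_density * diff(mz_range) / 100)
    if (n_noise > 0) {
      pk <- dplyr::bind_rows(pk, tibble(
        mz = stats::runif(n_noise, mz_range[1], mz_range[2]),
        intensity = stats::rexp(n_noise, 1 / noise$intensity_mean)))
    }
  }
  pk <- pk[!duplicated(pk$mz), ]
  spectrum(scan_id, 2L, rt, pk,
           precursor_mz = (peptide_mass(p) + charge * PROTON_MASS) / charge,
           precursor_charge = charge, activation = activation)
}

#' Generate a synthetic LC-MS/MS run with ground truth
#'
#' Writes an mzML file of MS1 scans carrying averagine-shaped isotopic
#' envelopes (Gaussian elution per spec, emitted within 2.5 sigma of the
#' apex) interleaved with MS/MS scans triggered near each spec's apex, plus
#' seeded baseline noise. The returned truth table lists every feature and
#' MS/MS scan with its generating spec. Identical seeds give byte-identical
#' files. Specs whose envelopes overlap closer than one isotope spacing at
#' the same rt are flagged `merged` in the truth table with a warning.
#'
#' @param specs List of [peptide_spec()].
#' @param noise A [noise_model()] (default: noiseless).
#' @param gradient `list(rt_range = c(start, end) minutes, scan_interval =
#'   seconds)`.
#' @param seed Integer RNG seed.
#' @param path Output mzML path.
#' @param mz_range Instrument m/z range.
#' @param injection_time Ion injection time (ms) written per scan; scalar or
#'   vector recycled over scans.
#' @return List: `path`, `truth` (tibble), `spectra` (the in-memory scan
#'   list, generator truth for round-trip tests).
#' @export
make_run <- function(specs, noise = noise_model(), gradient = list(
                       rt_range = c(0, 10), scan_interval = 6),
                     seed = 1L, path = tempfile(fileext = ".mzML"),
                     mz_range = c(100, 2000), injection_time = 10) {
  if (inherits(specs, "synthetic_peptide_spec")) specs <- list(specs)
  ms1_rts <- seq(gradient$rt_range[1], gradient$rt_range[2],
                 by = gradient$scan_interval / 60)
  n_spec <- length(specs)
  mono_mzs <- vapply(specs, function(sp)
    (peptide_mass(sp$peptide) + sp$charge * PROTON_MASS) / sp$charge, numeric(1))
  # overlap audit
  merged <- rep(FALSE, n_spec)
  if (n_spec > 1) {
    for (i in seq_len(n_spec - 1)) for (j in (i + 1):n_spec) {
      rt_overlap <- abs(specs[[i]]$apex_rt - specs[[j]]$apex_rt) <
        2.5 * (specs[[i]]$sigma_rt + specs[[j]]$sigma_rt)
      if (rt_overlap && abs(mono_mzs[i] - mono_mzs[j]) <
          ISOTOPE_SPACING / max(specs[[i]]$charge, specs[[j]]$charge)) {
        merged[i] <- merged[j] <- TRUE
      }
    }
    if (any(merged)) warn("overlapping specs closer than one isotope spacing; truth table marks the merge")
  }

  with_seed(seed, {
    spectra <- list()
    sid <- 0L
    ms1_ids_per_spec <- purrr::map(specs, function(sp) integer())
    ms2_id_per_spec <- rep(NA_integer_, n_spec)
    ms2_rt_per_spec <- rep(NA_real_, n_spec)
    apex_scan <- vapply(specs, function(sp)
      which.min(abs(ms1_rts - sp$apex_rt)), integer(1))
    for (k in seq_along(ms1_rts)) {
      rt <- ms1_rts[k]
      pk <- tibble(mz = numeric(), intensity = numeric())
      for (si in seq_len(n_spec)) {
        sp <- specs[[si]]
        if (abs(rt - sp$apex_rt) > 2.5 * sp$sigma_rt) next
        depth <- sp$isotope_depth
        rel <- averagine_envelope(peptide_mass(sp$peptide), depth)
        rel <- rel / rel[1]
        gaus <- exp(-(rt - sp$apex_rt)^2 / (2 * sp$sigma_rt^2))
        mzs <- mono_mzs[si] + (seq_len(depth) - 1L) * ISOTOPE_SPACING / sp$charge
        if (noise$mz_jitter_ppm > 0) {
          mzs <- mzs * (1 + stats::rnorm(depth, 0, noise$mz_jitter_ppm * 1e-6))
        }
        pk <- dplyr::bind_rows(pk, tibble(mz = mzs,
                                          intensity = sp$abundance * gaus * rel))
        ms1_ids_per_spec[[si]] <- c(ms1_ids_per_spec[[si]], sid + 1L)
      }
      if (noise$baseline_density > 0) {
        n_noise <- round(noise$baseline_density * diff(mz_range) / 100)
        if (n_noise > 0) {
          pk <- dplyr::bind_rows(pk, tibble(
            mz = stats::runif(n_noise, mz_range[1], mz_range[2]),
            intensity = stats::rexp(n_noise, 1 / noise$intensity_mean)))
        }
      }
      pk <- pk[!duplicated(pk$mz), ]
      sid <- sid + 1L
      spectra[[sid]] <- spectrum(sid, 1L, rt, pk)
      # trigger MS/MS for specs whose apex MS1 is this scan
      for (si in which(apex_scan == k)) {
        sp <- specs[[si]]
        if (!sp$include_ms2) next
        sid <- sid + 1L
        ms2_rt <- rt + 0.3 * gradient$scan_interval / 60
        spectra[[sid]] <- make_msms(sp$peptide, sp$charge, sp$activation,
                                    noise = noise, reporter = sp$reporter,
                                    scan_id = sid, rt = ms2_rt,
                                    mz_range = mz_range)
        ms2_id_per_spec[si] <- sid
        ms2_rt_per_spec[si] <- ms2_rt
      }
    }
    write_run_mzml(spectra, path,
                   injection_times = rep_len(injection_time, length(spectra)))
    truth <- tibble(
      spec_id = seq_len(n_spec),
      sequence = vapply(specs, function(sp) sp$peptide$sequence, character(1)),
      mods = vapply(specs, function(sp) {
        if (nrow(sp$peptide$mods))
          paste(sprintf("%d:%s", sp$peptide$mods$position, sp$peptide$mods$label),
                collapse = ", ")
        else ""
      }, character(1)),
      charge = vapply(specs, function(sp) sp$charge, integer(1)),
      mono_mz = mono_mzs,
      neutral_mass = vapply(specs, function(sp) peptide_mass(sp$peptide), numeric(1)),
      apex_rt = vapply(specs, function(sp) sp$apex_rt, numeric(1)),
      sigma_rt = vapply(specs, function(sp) sp$sigma_rt, numeric(1)),
      abundance = vapply(specs, function(sp) sp$abundance, numeric(1)),
      activation = vapply(specs, function(sp) sp$activation, character(1)),
      ms1_scan_ids = ms1_ids_per_spec,
      n_ms1_scans = lengths(ms1_ids_per_spec),
      ms2_scan_id = ms2_id_per_spec,
      ms2_rt = ms2_rt_per_spec,
      run = strip_mz_ext(basename(path)),
      merged = merged
    )
    list(path = path, truth = truth, spectra = spectra)
  })
}

#' Write a PSM results fixture from a truth table
#'
#' Emits search-result files (canonical TSV/CSV dialect or minimal pepXML)
#' assigning the generating peptide to a chosen subset of the truth table's
#' MS/MS scans. Scores are deterministic (`30 + spec_id`). Multi-run
#' combined fixtures: pass a list of truth tables.
#'
#' @param truth Truth tibble from [make_run()] (or a list of them).
#' @param path Output file.
#' @param engine_style `"tsv"`, `"csv"`, or `"pepxml"`.
#' @param assign_spec_ids Spec ids to assign (default: all with an MS/MS
#'   scan).
#' @param engine Engine name recorded in delimited output.
#' @return `path`, invisibly.
#' @export
make_results_fixture <- function(truth, path, engine_style = c("tsv", "csv", "pepxml"),
                                 assign_spec_ids = NULL, engine = "internal") {
  engine_style <- match.arg(engine_style)
  if (!is.data.frame(truth)) truth <- dplyr::bind_rows(truth)
  rows <- truth[!is.na(truth$ms2_scan_id), ]
  if (!is.null(assign_spec_ids)) rows <- rows[rows$spec_id %in% assign_spec_ids, ]
  df <- tibble(
    Run = rows$run,
    Scan = rows$ms2_scan_id,
    `Peptide Sequence` = rows$sequence,
    `Variable Modifications` = rows$mods,
    Charge = rows$charge,
    `Peptide Score` = 30 + rows$spec_id,
    Engine = engine,
    `Protein Accessions` = sprintf("SYN|P%d", rows$spec_id),
    `Precursor MZ` = rows$mono_mz,
    RT = rows$ms2_rt
  )
  if (engine_style %in% c("tsv", "csv")) {
    sep <- if (engine_style == "tsv") "\t" else ","
    cells <- lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    })
    write_atomic(c(paste(names(df), collapse = sep),
                   do.call(paste, c(cells, sep = sep))), path)
  } else {
    write_pepxml(df, path)
  }
  invisible(path)
}

write_pepxml <- function(df, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", as.character(x)))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<msms_pipeline_analysis>')
  for (run in unique(df$Run)) {
    sub <- df[df$Run == run, ]
    lines <- c(lines, sprintf('<msms_run_summary base_name="%s">', esc(run)),
               '<search_summary search_engine="internal"/>')
    for (i in seq_len(nrow(sub))) {
      z <- sub$Charge[i]
      nm <- sub$`Precursor MZ`[i] * z - z * PROTON_MASS
      lines <- c(lines, sprintf(
        '<spectrum_query start_scan="%d" end_scan="%d" precursor_neutral_mass="%.17g" assumed_charge="%d" retention_time_sec="%.17g">',
        sub$Scan[i], sub$Scan[i], nm, z, sub$RT[i] * 60))
      lines <- c(lines, '<search_result>', sprintf(
        '<search_hit hit_rank="1" peptide="%s" protein="%s">',
        esc(sub$`Peptide Sequence`[i]), esc(sub$`Protein Accessions`[i])))
      vm <- sub$`Variable Modifications`[i]
      if (nzchar(vm)) {
        lines <- c(lines, '<modification_info>')
        for (m in strsplit(vm, ",\\s*")[[1]]) {
          kv <- strsplit(m, ":")[[1]]
          lab <- trimws(kv[2])
          lines <- c(lines, sprintf(
            '<mod_aminoacid_mass position="%s" massdiff="%.17g" label="%s"/>',
            trimws(kv[1]), mod_mass(lab), esc(lab)))
        }
        lines <- c(lines, '</modification_info>')
      }
      lines <- c(lines, sprintf(
        '<search_score name="score" value="%.17g"/>', sub$`Peptide Score`[i]),
        '</search_hit>', '</search_result>', '</spectrum_query>')
    }
    lines <- c(lines, '</msms_run_summary>')
  }
  write_atomic(c(lines, '</msms_pipeline_analysis>'), path)
}
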