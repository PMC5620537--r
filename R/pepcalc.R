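#' Construct a peptide with positioned modifications
#'
#' A peptide is an amino-acid sequence over the 20 canonical residues plus a
#' table of positioned mass-delta modifications. Position 0 is the N-terminus,
#' 1..n the residues, n+1 the C-terminus. At most one modification may occupy
#' a position (no stacking).
#'
#' @param sequence Character scalar, e.g. `"PEPTIDE"`.
#' @param mods Either `NULL`, a compact string `"4:phospho,7:oxidation"`, or a
#'   data frame with columns `position`, `label` and optionally `delta`
#'   (looked up in [mod_vocabulary()] when absent).
#' @return An object of class `mz_peptide` with fields `sequence` and `mods`
#'   (tibble: `position`, `delta`, `label`).
#' @export
peptide <- function(sequence, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1L) abort("sequence must have length >= 1")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_MASSES))
  if (length(bad)) abort(paste0("unknown residue character(s): ", paste(unique(bad), collapse = ", ")))

  mods <- parse_mods(mods)
  if (nrow(mods)) {
    if (any(mods$position < 0 | mods$position > n + 1)) {
      abort(paste0("modification position out of range 0..", n + 1))
    }
    if (anyDuplicated(mods$position)) abort("at most one modification per position")
    mods <- mods[order(mods$position), ]
  }
  structure(list(sequence = sequence, mods = mods), class = "mz_peptide")
}

parse_mods <- function(mods) {
  empty <- tibble(position = integer(), delta = numeric(), label = character())
  if (is.null(mods) || (is.character(mods) && !nzchar(mods))) return(empty)
  if (is.character(mods)) {
    parts <- strsplit(trimws(strsplit(mods, ",")[[1]]), ":")
    mods <- tibble(
      position = as.integer(vapply(parts, `[`, "", 1L)),
      label = trimws(vapply(parts, `[`, "", 2L))
    )
  }
  mods <- as_tibble(mods)
  if (!nrow(mods)) return(empty)
  stopifnot(all(c("position", "label") %in% names(mods)))
  if (!"delta" %in% names(mods)) {
    mods$delta <- vapply(mods$label, mod_mass, numeric(1))
  }
  mods$position <- as.integer(mods$position)
  mods[, c("position", "delta", "label")]
}

#' @export
print.mz_peptide <- function(x, ...) {
  m <- if (nrow(x$mods)) {
    paste0(" + ", paste(sprintf("%d:%s", x$mods$position, x$mods$label), collapse = ", "))
  } else ""
  cat(sprintf("<mz_peptide> %s%s  (M = %.5f Da)\n", x$sequence, m, peptide_mass(x)))
  invisible(x)
}

#' Monoisotopic neutral peptide mass
#'
#' Sum of residue monoisotopic masses, one water (termini), and all
#' modification deltas.
#'
#' @param p An `mz_peptide`.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(p) {
  stopifnot(inherits(p, "mz_peptide"))
  aa <- strsplit(p$sequence, "")[[1]]
  sum(RESIDUE_MASSES[aa]) + WATER_MASS + sum(p$mods$delta)
}

#' Theoretical fragment ions
#'
#' Generates b/y (collisional activation) and/or c/z (electron transfer)
#' ions for every cleavage position and charge state. Modifications at or
#' before the cleavage point contribute to the N-terminal series (b/c),
#' after it to the C-terminal series (y/z); the N-terminal mod (position 0)
#' always travels with b/c, the C-terminal mod (position n+1) with y/z.
#' Conventions: c = b + NH3 (17.026549 Da); z is the z-dot radical,
#' z = y - 16.01872 Da.
#'
#' @param p An `mz_peptide`.
#' @param series Character subset of `c("b","y","c","z")`.
#' @param max_charge Highest fragment charge state (>= 1).
#' @return Tibble with columns `series`, `index`, `charge`, `neutral_mass`,
#'   `mz`, sorted by series, index, charge.
#' @export
fragment_ions <- function(p, series = c("b", "y"), max_charge = 1L) {
  stopifnot(inherits(p, "mz_peptide"))
  series <- unique(series)
  if (!length(series)) abort("series set must be non-empty")
  if (!all(series %in% c("b", "y", "c", "z"))) abort("series must be among b, y, c, z")
  max_charge <- as.integer(max_charge)
  if (max_charge < 1L) abort("max_charge must be >= 1")

  aa <- strsplit(p$sequence, "")[[1]]
  n <- length(aa)
  if (n < 2L) return(tibble(series = character(), index = integer(),
                            charge = integer(), neutral_mass = numeric(), mz = numeric()))
  res <- unname(RESIDUE_MASSES[aa])
  # modification mass attributed to each cleavage side
  mod_at <- numeric(n + 2L)  # index = position + 1
  if (nrow(p$mods)) mod_at[p$mods$position + 1L] <- p$mods$delta
  cum_res <- cumsum(res)
  nterm_mod <- cumsum(mod_at)[2:(n + 1L)]        # mods at positions 0..i
  total_mod <- sum(mod_at)

  i <- seq_len(n - 1L)
  b_neutral <- cum_res[i] + nterm_mod[i]                     # residues 1..i + mods <= i
  # y_j is the C-terminal fragment of length j = n - i (cleavage at i)
  y_at_cleavage <- (sum(res) - cum_res[i]) + WATER_MASS + (total_mod - nterm_mod[i])
  y_neutral <- rev(y_at_cleavage)                            # index by fragment length

  neutral <- list(
    b = b_neutral,
    y = y_neutral,
    c = b_neutral + NH3_MASS,
    z = y_neutral - ZDOT_SHIFT
  )
  out <- purrr::map_dfr(series, function(s) {
    purrr::map_dfr(seq_len(max_charge), function(z) {
      tibble(series = s, index = i, charge = z,
             neutral_mass = neutral[[s]],
             mz = (neutral[[s]] + z * PROTON_MASS) / z)
    })
  })
  dplyr::arrange(out, .data$series, .data$index, .data$charge)
}

#' Move a named modification to a new position
#'
#' The classic site-localization move: identical peptide except for the
#' placement of one modification. Total peptide mass is unchanged.
#'
#' @param p An `mz_peptide` carrying exactly one modification with `label`.
#' @param label Modification label to move.
#' @param new_position Target position (must be in range and unoccupied).
#' @return The repositioned `mz_peptide`.
#' @export
reposition_mod <- function(p, label, new_position) {
  stopifnot(inherits(p, "mz_peptide"))
  hit <- which(p$mods$label == label)
  if (length(hit) == 0L) abort(paste0("no modification labelled '", label, "'"))
  if (length(hit) > 1L) abort(paste0("modification label '", label, "' is ambiguous (", length(hit), " instances)"))
  new_position <- as.integer(new_position)
  n <- nchar(p$sequence)
  if (new_position < 0L || new_position > n + 1L) abort("new_position out of range")
  occupied <- setdiff(p$mods$position, p$mods$position[hit])
  if (new_position %in% occupied) abort("target position already carries a modification")
  mods <- p$mods
  mods$position[hit] <- new_position
  peptide(p$sequence, mods)
}

#' All candidate placements of k like modifications
#'
#' For site-localization scoring: every C(m, k) placement of the peptide's k
#' modifications labelled `label` over the m residues of the allowed type.
#'
#' @param p An `mz_peptide` carrying k >= 1 mods with `label`.
#' @param label Modification label.
#' @param allowed_residues Character vector of residue letters that can carry
#'   the modification (default `c("S","T","Y")` for phosphorylation).
#' @return List of `mz_peptide`, ordered lexicographically by position vector.
#'   All share the same [peptide_mass()].
#' @export
candidate_site_peptides <- function(p, label, allowed_residues = c("S", "T", "Y")) {
  stopifnot(inherits(p, "mz_peptide"))
  k <- sum(p$mods$label == label)
  if (k < 1L) abort(paste0("peptide carries no modification labelled '", label, "'"))
  aa <- strsplit(p$sequence, "")[[1]]
  sites <- which(aa %in% allowed_residues)
  # sites already occupied by a *different* mod are unavailable
  other <- p$mods$position[p$mods$label != label]
  sites <- setdiff(sites, other)
  if (length(sites) < k) {
    abort(sprintf("only %d allowed site(s) for %d '%s' modification(s)", length(sites), k, label))
  }
  delta <- p$mods$delta[p$mods$label == label][1]
  keep <- p$mods[p$mods$label != label, ]
  combos <- utils::combn(sites, k, simplify = FALSE)  # combn is lexicographic
  purrr::map(combos, function(pos) {
    peptide(p$sequence, dplyr::bind_rows(
      keep, tibble(position = as.integer(pos), delta = delta, label = label)
    ))
  })
}

#' Match theoretical ions to spectrum peaks
#'
#' Each ion is matched to the nearest peak within `tol_ppm`; one peak may
#' satisfy several ions, each ion claims at most one peak. Equidistant peaks
#' are resolved toward lower m/z.
#'
#' @param s A centroided `mz_spectrum`.
#' @param ions Fragment table from [fragment_ions()].
#' @param tol_ppm Match tolerance in ppm (default 10).
#' @return Tibble of matches: `series`, `index`, `charge`, `mz_theo`,
#'   `mz_obs`, `intensity`, `error_ppm`, sorted by series then index.
#' @export
annotate_spectrum <- function(s, ions, tol_ppm = 10) {
  stopifnot(inherits(s, "mz_spectrum"))
  if (!s$centroided) abort("annotate_spectrum requires a centroided spectrum")
  if (tol_ppm <= 0) abort("tol_ppm must be > 0")
  empty <- tibble(series = character(), index = integer(), charge = integer(),
                  mz_theo = numeric(), mz_obs = numeric(), intensity = numeric(),
                  error_ppm = numeric())
  if (nrow(s$peaks) == 0L || nrow(ions) == 0L) return(empty)
  pk <- s$peaks
  rows <- purrr::pmap_dfr(ions, function(series, index, charge, neutral_mass, mz, ...) {
    d <- abs(pk$mz - mz)
    tol <- mz * tol_ppm * 1e-6
    ok <- which(d <= tol)
    if (!length(ok)) return(NULL)
    best <- ok[order(d[ok], pk$mz[ok])][1]   # nearest; ties toward lower m/z
    tibble(series = series, index = index, charge = charge,
           mz_theo = mz, mz_obs = pk$mz[best], intensity = pk$intensity[best],
           error_ppm = ppm_error(pk$mz[best], mz))
  })
  if (!nrow(rows)) return(empty)
  dplyr::arrange(rows, .data$series, .data$index, .data$charge)
}
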