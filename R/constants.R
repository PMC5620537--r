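#' Physical constants and residue masses
#'
#' Monoisotopic mass constants used throughout the package. All masses are
#' in Daltons; m/z values in Thomson (Th).
#'
#' @format Named numeric scalars / vectors.
#' @name mass-constants
NULL

# proton (charge carrier), water (peptide termini), ammonia (c-ion shift),
# C13-C12 spacing (isotopic envelope), z-dot shift relative to y
PROTON_MASS   <- 1.007276
WATER_MASS    <- 18.010565
NH3_MASS      <- 17.026549
ISOTOPE_SPACING <- 1.0033548
ZDOT_SHIFT    <- 16.01872  # z = y - ZDOT_SHIFT (z-dot radical species, ETD)

# Monoisotopic residue masses (Da), 20 canonical amino acids
RESIDUE_MASSES <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

# Default variable-modification vocabulary: label -> monoisotopic delta (Da).
# Users can extend via mod_vocabulary().
DEFAULT_MODS <- c(
  phospho          = 79.96633,
  oxidation        = 15.994915,
  acetyl           = 42.010565,
  carbamidomethyl  = 57.021464,
  methyl           = 14.015650,
  dimethyl         = 28.031300,
  trimethyl        = 42.046950,
  gg               = 114.042927,
  tmt6             = 229.162932,
  itraq4           = 144.102063
)

.mzc <- new.env(parent = emptyenv())

#' Modification vocabulary
#'
#' The mapping from modification labels (e.g. `"phospho"`) to monoisotopic
#' mass deltas in Da. `mod_vocabulary()` returns the current table;
#' `register_mod()` adds or overrides an entry for the session.
#'
#' @param label Short modification name.
#' @param delta Monoisotopic mass shift in Da.
#' @return A tibble with columns `label`, `delta`.
#' @export
mod_vocabulary <- function() {
  v <- .mzc$mods
  if (is.null(v)) v <- DEFAULT_MODS
  tibble::tibble(label = names(v), delta = unname(v))
}

#' @rdname mod_vocabulary
#' @export
register_mod <- function(label, delta) {
  stopifnot(is.character(label), length(label) == 1L, is.numeric(delta))
  v <- .mzc$mods
  if (is.null(v)) v <- DEFAULT_MODS
  v[label] <- delta
  .mzc$mods <- v
  invisible(mod_vocabulary())
}

mod_mass <- function(label) {
  v <- .mzc$mods
  if (is.null(v)) v <- DEFAULT_MODS
  if (!label %in% names(v)) {
    stop("unknown modification label: '", label, "'", call. = FALSE)
  }
  unname(v[[label]])
}

#' Averagine isotope-abundance model
#'
#' Predicts relative isotope abundances for a peptide-like molecule of a
#' given neutral monoisotopic mass using the Poisson approximation to the
#' averagine elemental composition. The rate parameter scales linearly with
#' mass (about one heavy-isotope event per 2.1 kDa).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param n_isotopes Number of isotope peaks to return (k = 0 .. n-1).
#' @return Numeric vector of relative abundances summing to at most 1.
#' @export
averagine_envelope <- function(neutral_mass, n_isotopes = 5L) {
  stopifnot(neutral_mass > 0, n_isotopes >= 1)
  lambda <- 4.7551e-4 * neutral_mass
  stats::dpois(seq_len(n_isotopes) - 1L, lambda)
}
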