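# Isotope arithmetic: delta-notation conversions, atom-percent excess, and
# tracer dose stoichiometry. All enrichments are expressed in atom% 15N
# (percentage of N atoms that are 15N), all delta values in permil versus the
# atmospheric N2 standard. Conversions use exact isotope-ratio algebra, never
# the linear small-delta approximation.

# Atomic masses (g/mol)
.MASS_K <- 39.098
.MASS_O <- 15.999
.MASS_N14 <- 14.003
.MASS_N15 <- 15.000

#' Isotope reference configuration
#'
#' Holds the two reference enrichments used throughout the package and keeps
#' them distinct: the international standard (atmospheric N2, 0.3663 atom%
#' 15N), against which delta values are expressed, and the empirical
#' natural-abundance baseline of unlabelled plant tissue, which is subtracted
#' when computing tracer-derived (excess) 15N. The default baseline, 0.3733
#' atom%, is the measured natural abundance of unlabelled greenhouse-grown
#' maize; unlabelled tissue can sit slightly above or below the atmospheric
#' standard, which is why the two constants must never be conflated.
#'
#' @param standard_atom_percent atom% 15N of the international standard
#'   (atmospheric N2). Default 0.3663.
#' @param baseline_atom_percent atom% 15N used as the natural-abundance
#'   baseline when computing excess 15N. Default 0.3733.
#' @return An object of class `iso_config`.
#' @examples
#' cfg <- iso_config()
#' cfg$baseline_atom_percent
#' @export
iso_config <- function(standard_atom_percent = 0.3663,
                       baseline_atom_percent = 0.3733) {
  stopifnot(is.numeric(standard_atom_percent), length(standard_atom_percent) == 1,
            is.numeric(baseline_atom_percent), length(baseline_atom_percent) == 1)
  if (standard_atom_percent <= 0 || standard_atom_percent >= 100)
    stop("standard_atom_percent must lie in (0, 100)", call. = FALSE)
  if (baseline_atom_percent <= 0 || baseline_atom_percent >= 100)
    stop("baseline_atom_percent must lie in (0, 100)", call. = FALSE)
  structure(list(standard_atom_percent = standard_atom_percent,
                 baseline_atom_percent = baseline_atom_percent),
            class = "iso_config")
}

#' @export
print.iso_config <- function(x, ...) {
  cat("<iso_config>\n")
  cat("  standard (atmospheric N2):", x$standard_atom_percent, "atom% 15N\n")
  cat("  natural-abundance baseline:", x$baseline_atom_percent, "atom% 15N\n")
  invisible(x)
}

#' Convert delta-15N (permil) to atom% 15N
#'
#' Exact isotope-ratio algebra: the standard's atom% is converted to an
#' isotope ratio `R_std = ap / (100 - ap)`, the sample ratio is
#' `R = R_std * (1 + delta/1000)`, and the result is `100 * R / (1 + R)`.
#'
#' @param delta_permil delta-15N in permil relative to the standard; must be
#'   greater than -1000 (at -1000 the sample would contain no 15N at all).
#' @param standard_atom_percent atom% 15N of the standard (default the
#'   atmospheric N2 value, 0.3663).
#' @return atom% 15N, same length as `delta_permil`.
#' @examples
#' delta_to_atom_percent(0)                     # the standard itself
#' delta_to_atom_percent(c(-1.59, -3.88))       # slightly depleted tissue
#' @export
delta_to_atom_percent <- function(delta_permil, standard_atom_percent = 0.3663) {
  stopifnot(is.numeric(delta_permil), is.numeric(standard_atom_percent))
  if (standard_atom_percent <= 0 || standard_atom_percent >= 100)
    stop("standard_atom_percent must lie in (0, 100)", call. = FALSE)
  if (any(delta_permil <= -1000))
    stop("delta_permil must exceed -1000 permil (isotope ratio would be non-positive)",
         call. = FALSE)
  r_std <- standard_atom_percent / (100 - standard_atom_percent)
  r <- r_std * (1 + delta_permil / 1000)
  100 * r / (1 + r)
}

#' Convert atom% 15N to delta-15N (permil)
#'
#' Exact inverse of [delta_to_atom_percent()]; the round trip is accurate to
#' well below 1e-10 permil.
#'
#' @param atom_percent atom% 15N of the sample, in (0, 100).
#' @param standard_atom_percent atom% 15N of the standard, in (0, 100).
#' @return delta-15N in permil.
#' @examples
#' atom_percent_to_delta(0.3733)   # unlabelled maize vs atmospheric N2
#' @export
atom_percent_to_delta <- function(atom_percent, standard_atom_percent = 0.3663) {
  stopifnot(is.numeric(atom_percent), is.numeric(standard_atom_percent))
  if (any(atom_percent <= 0 | atom_percent >= 100))
    stop("atom_percent must lie in (0, 100)", call. = FALSE)
  if (standard_atom_percent <= 0 || standard_atom_percent >= 100)
    stop("standard_atom_percent must lie in (0, 100)", call. = FALSE)
  r <- atom_percent / (100 - atom_percent)
  r_std <- standard_atom_percent / (100 - standard_atom_percent)
  1000 * (r / r_std - 1)
}

#' Tracer-derived (excess) 15N mass in an organ
#'
#' The mass of 15N in an organ attributable to labelled fertilizer:
#' `q(x) = (A(x) - A_O) / 100 * Q_x`, where `A(x)` is the organ's measured
#' enrichment, `A_O` the natural-abundance baseline and `Q_x` the organ's
#' total N content in grams. Depleted samples (below baseline) give a
#' negative value; this function returns it as-is, and the budget layer
#' decides whether a small negative excess is measurement noise (clamped to
#' zero) or a data problem (error).
#'
#' @param atom_percent_sample measured enrichment of the organ, atom% 15N.
#' @param config an [iso_config()]; its `baseline_atom_percent` is `A_O`.
#' @param organ_n_content total N content of the organ, g N (must be >= 0).
#' @return g 15N in excess of natural abundance (possibly negative).
#' @examples
#' excess_n15_mass(0.4733, iso_config(), organ_n_content = 1.0)
#' @export
excess_n15_mass <- function(atom_percent_sample, config = iso_config(),
                            organ_n_content) {
  stopifnot(inherits(config, "iso_config"),
            is.numeric(atom_percent_sample), is.numeric(organ_n_content))
  if (any(organ_n_content < 0))
    stop("organ_n_content must be >= 0", call. = FALSE)
  (atom_percent_sample - config$baseline_atom_percent) / 100 * organ_n_content
}

#' Mass of 15N delivered by a potassium nitrate tracer dose
#'
#' Stoichiometry of K15NO3 enriched to a given atom% 15N. The nitrogen in the
#' salt's molar mass is the label-weighted mean of the two isotopes (at 10
#' atom%: 0.9 * 14.003 + 0.1 * 15.000 g/mol), so the computation is exact for
#' any enrichment from natural abundance to 100 atom%.
#'
#' @param salt_mass_mg mg of KNO3 salt dissolved (>= 0).
#' @param atom_percent_label atom% 15N of the salt, in (0, 100].
#' @return mg of 15N delivered.
#' @examples
#' tracer_n15_mass(680, 10)   # ~10 mg 15N per syringe application
#' @export
tracer_n15_mass <- function(salt_mass_mg, atom_percent_label) {
  stopifnot(is.numeric(salt_mass_mg), is.numeric(atom_percent_label))
  if (any(salt_mass_mg < 0))
    stop("salt_mass_mg must be >= 0", call. = FALSE)
  if (any(atom_percent_label <= 0 | atom_percent_label > 100))
    stop("atom_percent_label must lie in (0, 100]", call. = FALSE)
  f <- atom_percent_label / 100
  mass_n <- (1 - f) * .MASS_N14 + f * .MASS_N15
  molar_mass <- .MASS_K + mass_n + 3 * .MASS_O
  salt_mass_mg / molar_mass * f * .MASS_N15
}

#' Describe a tracer dose
#'
#' A dose can be entered either as the salt mass actually dissolved (the 15N
#' mass is then computed stoichiometrically) or as a stated 15N mass taken at
#' face value. Both entry modes are kept because published doses are
#' sometimes reported as nominal 15N masses that do not match the salt
#' stoichiometry exactly; the `source` field records which mode was used.
#'
#' @param salt_mass_mg mg of KNO3 salt (mutually exclusive with `n15_mass_mg`).
#' @param atom_percent_label atom% 15N of the salt.
#' @param n15_mass_mg stated mg of 15N, taken at face value.
#' @return A list of class `tracer_dose` with fields `salt_mass_mg`,
#'   `atom_percent_label`, `n15_mass_mg`, `n_mass_mg` (total N delivered) and
#'   `source` ("salt_mass" or "stated").
#' @examples
#' tracer_dose(salt_mass_mg = 680, atom_percent_label = 10)
#' tracer_dose(n15_mass_mg = 40, atom_percent_label = 10)
#' @export
tracer_dose <- function(salt_mass_mg = NULL, atom_percent_label = 10,
                        n15_mass_mg = NULL) {
  if (is.null(salt_mass_mg) == is.null(n15_mass_mg))
    stop("supply exactly one of salt_mass_mg or n15_mass_mg", call. = FALSE)
  if (atom_percent_label <= 0 || atom_percent_label > 100)
    stop("atom_percent_label must lie in (0, 100]", call. = FALSE)
  f <- atom_percent_label / 100
  if (!is.null(salt_mass_mg)) {
    n15 <- tracer_n15_mass(salt_mass_mg, atom_percent_label)
    src <- "salt_mass"
  } else {
    if (n15_mass_mg < 0) stop("n15_mass_mg must be >= 0", call. = FALSE)
    n15 <- n15_mass_mg
    salt_mass_mg <- NA_real_
    src <- "stated"
  }
  # total N mass delivered: n15 mg of 15N implies n15/f/15.000 mmol N
  n_total <- n15 / .MASS_N15 / f * ((1 - f) * .MASS_N14 + f * .MASS_N15)
  structure(list(salt_mass_mg = salt_mass_mg,
                 atom_percent_label = atom_percent_label,
                 n15_mass_mg = n15, n_mass_mg = n_total, source = src),
            class = "tracer_dose")
}

#' @export
print.tracer_dose <- function(x, ...) {
  cat("<tracer_dose>", format(x$n15_mass_mg, digits = 4), "mg 15N at",
      x$atom_percent_label, "atom% (", x$source, ")\n")
  invisible(x)
}
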