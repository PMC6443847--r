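# Delimited-text input/output and YAML configuration.

#' Read isotope configuration from a YAML file
#'
#' Expects keys `isotope.standard_atom_percent` and
#' `isotope.baseline_atom_percent`; missing keys fall back to the defaults
#' of [iso_config()].
#'
#' @param path YAML file path.
#' @return An [iso_config()].
#' @export
read_iso_config <- function(path) {
  y <- yaml::read_yaml(path)
  iso <- y$isotope
  iso_config(
    standard_atom_percent = iso$standard_atom_percent %||% 0.3663,
    baseline_atom_percent = iso$baseline_atom_percent %||% 0.3733)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a plant-organ CSV
#'
#' Reads a long plant-organ table. Enrichment may be given as
#' `atom_percent_15N` or as `delta15N_permil` (converted with the
#' configured standard); exactly one of the two must be present per row —
#' rows carrying both, or labelled rows carrying neither, are errors.
#'
#' @param path CSV path.
#' @param config an [iso_config()] (supplies the delta standard).
#' @return Validated plant-organ tibble (see [validate_plants()]).
#' @export
read_plants_csv <- function(path, config = iso_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_ap <- "atom_percent_15N" %in% names(df)
  has_d <- "delta15N_permil" %in% names(df)
  if (!has_ap && !has_d)
    stop("need an atom_percent_15N or delta15N_permil column", call. = FALSE)
  ap <- if (has_ap) df$atom_percent_15N else rep(NA_real_, nrow(df))
  dl <- if (has_d) df$delta15N_permil else rep(NA_real_, nrow(df))
  both <- !is.na(ap) & !is.na(dl)
  if (any(both))
    stop("row(s) ", paste(which(both), collapse = ", "),
         " carry both atom_percent_15N and delta15N_permil; supply exactly one",
         call. = FALSE)
  use_d <- is.na(ap) & !is.na(dl)
  ap[use_d] <- delta_to_atom_percent(dl[use_d], config$standard_atom_percent)
  df$atom_percent_15N <- ap
  df$delta15N_permil <- NULL
  validate_plants(df)
}

#' Write a plant-organ table to CSV
#'
#' @param plants plant-organ table.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_plants_csv <- function(plants, path) {
  utils::write.csv(plants, path, row.names = FALSE)
  invisible(path)
}

#' Write the machine-readable N-budget table
#'
#' Raw (unrounded) per-plant budgets; the rounded presentation tables come
#' from [render_tables()].
#'
#' @param budgets table from [nitrogen_budget()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_budgets_csv <- function(budgets, path) {
  utils::write.csv(budgets, path, row.names = FALSE)
  invisible(path)
}
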