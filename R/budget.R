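# Per-plant 15N mass-balance calculus: remobilization of pre-silking N to the
# grain (vegetative-labelled plants), partitioning of post-silking N uptake
# (reproductive-labelled plants), and the two routes to the fraction of grain
# N derived from remobilization.
#
# Plant data are held long: one row per plant x organ with the plant's
# metadata repeated. Organ vocabularies are fixed per growth stage and
# unknown labels are errors, never silently skipped.

MATURITY_ORGANS <- c("green_leaves", "senesced_leaves", "stalk", "roots",
                     "grain", "repro_nongrain")
SILKING_ORGANS <- c("leaves", "stalk", "roots", "reproductive")

#' Organ taxonomy: maturity organs and their silking-stage groups
#'
#' Maturity harvests dissect plants into six organ groups, silking harvests
#' into four; this fixed mapping relates them (green and senesced leaves both
#' descend from the silking leaf pool; grain and non-grain reproductive parts
#' from the silking reproductive pool).
#'
#' @return A data frame with columns `maturity_organ` and `silking_group`.
#' @export
organ_taxonomy <- function() {
  data.frame(
    maturity_organ = MATURITY_ORGANS,
    silking_group = c("leaves", "leaves", "stalk", "roots",
                      "reproductive", "reproductive"),
    stringsAsFactors = FALSE
  )
}

# Internal: check one plant's organ rows against the stage vocabulary.
.check_organs <- function(organs, stage, plant_id = "<plant>") {
  allowed <- if (identical(stage, "silking")) SILKING_ORGANS else MATURITY_ORGANS
  bad <- setdiff(organs, allowed)
  if (length(bad) > 0)
    stop("unknown organ label(s) for stage '", stage, "' in plant ", plant_id,
         ": ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(organs))
    stop("duplicate organ labels in plant ", plant_id, call. = FALSE)
  invisible(TRUE)
}

#' Validate a long plant-organ table
#'
#' Checks the structural invariants of a plant-organ table: required columns,
#' stage-appropriate and unique organ labels, enrichment present on every
#' organ of labelled plants, no grain organ and no reproductive treatment on
#' silking-stage plants, and physically sensible masses and concentrations
#' (N concentration as a fraction of dry mass, at most 0.1). Adds an
#' `n_content` column (g N = dry mass x N concentration) if absent.
#'
#' @param plants data frame, one row per plant x organ, with columns
#'   `plant_id`, `veg_treatment`, `rep_treatment`, `label_phase`, `stage`,
#'   `organ`, `dry_mass`, `n_concentration`, and `atom_percent_15N`
#'   (NA allowed on unlabelled plants).
#' @return The validated table (tibble) with `n_content` populated.
#' @export
validate_plants <- function(plants) {
  required <- c("plant_id", "veg_treatment", "rep_treatment", "label_phase",
                "stage", "organ", "dry_mass", "n_concentration")
  missing_cols <- setdiff(required, names(plants))
  if (length(missing_cols) > 0)
    stop("plant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"atom_percent_15N" %in% names(plants))
    stop("plant table needs an atom_percent_15N column (see read_plants_csv ",
         "for delta15N input)", call. = FALSE)
  plants <- tibble::as_tibble(plants)
  if (any(!plants$stage %in% c("silking", "maturity")))
    stop("stage must be 'silking' or 'maturity'", call. = FALSE)
  if (any(!plants$label_phase %in% c("vegetative", "reproductive", "unlabelled")))
    stop("label_phase must be vegetative, reproductive or unlabelled",
         call. = FALSE)
  if (any(plants$dry_mass < 0, na.rm = TRUE))
    stop("dry_mass must be >= 0", call. = FALSE)
  if (any(plants$n_concentration < 0 | plants$n_concentration > 0.1,
          na.rm = TRUE))
    stop("n_concentration must be a fraction of dry mass in [0, 0.1]",
         call. = FALSE)
  for (pid in unique(plants$plant_id)) {
    rows <- plants[plants$plant_id == pid, ]
    stage <- unique(rows$stage)
    if (length(stage) != 1)
      stop("plant ", pid, " appears at more than one stage", call. = FALSE)
    .check_organs(rows$organ, stage, pid)
    if (stage == "silking" && any(rows$rep_treatment != "none"))
      stop("silking-stage plant ", pid,
           " must have rep_treatment 'none' (harvested before the ",
           "reproductive treatments were imposed)", call. = FALSE)
    phase <- unique(rows$label_phase)
    if (length(phase) != 1)
      stop("plant ", pid, " has inconsistent label_phase", call. = FALSE)
    if (phase != "unlabelled" && anyNA(rows$atom_percent_15N))
      stop("labelled plant ", pid, " is missing enrichment on some organs",
           call. = FALSE)
  }
  if (!"n_content" %in% names(plants))
    plants$n_content <- plants$dry_mass * plants$n_concentration
  plants
}

#' Whole-plant N content
#'
#' Sums organ N contents per plant. For silking-stage plants this is the
#' pre-silking uptake Q_wps; at maturity it is Q_wpm.
#'
#' @param organs data frame of organ rows with `n_content` (or `dry_mass` and
#'   `n_concentration`), optionally a `plant_id` column.
#' @return If `plant_id` is present, a named numeric vector of g N per plant;
#'   otherwise a single total.
#' @export
whole_plant_n <- function(organs) {
  if (nrow(organs) == 0)
    stop("no organ rows: cannot compute whole-plant N", call. = FALSE)
  if (!"n_content" %in% names(organs))
    organs$n_content <- organs$dry_mass * organs$n_concentration
  if ("plant_id" %in% names(organs)) {
    out <- tapply(organs$n_content, organs$plant_id, sum)
    res <- as.numeric(out)
    names(res) <- names(out)
    if (length(res) == 1) unname(res) else res
  } else {
    sum(organs$n_content)
  }
}

#' Treatment-mean pre-silking N uptake (Q_wps reference)
#'
#' The mass-balance equations reference pre-silking uptake through the mean
#' over silking-harvested plants of each vegetative treatment, not through
#' the (unobservable) pre-silking uptake of the individual maturity plant.
#'
#' @param plants validated plant-organ table containing silking-stage plants.
#' @return Tibble with columns `veg_treatment`, `q_wps` (mean g N) and `n`.
#' @export
q_wps_reference <- function(plants) {
  silking <- plants[plants$stage == "silking", , drop = FALSE]
  if (nrow(silking) == 0)
    stop("no silking-stage plants available to estimate Q_wps", call. = FALSE)
  if (!"n_content" %in% names(silking))
    silking$n_content <- silking$dry_mass * silking$n_concentration
  per_plant <- stats::aggregate(n_content ~ plant_id + veg_treatment,
                                data = silking, FUN = sum)
  out <- stats::aggregate(n_content ~ veg_treatment, data = per_plant,
                          FUN = mean)
  n <- stats::aggregate(n_content ~ veg_treatment, data = per_plant,
                        FUN = length)
  tibble::tibble(veg_treatment = out$veg_treatment, q_wps = out$n_content,
                 n = n$n_content)
}

# Internal: per-organ excess 15N with the negative-excess policy.
# Small negative excess (|q| <= clamp_tol g) is treated as measurement noise
# around an unenriched or barely enriched organ and clamped to zero with a
# warning; larger negative excess indicates a data or baseline problem and is
# an error.
.organ_excess <- function(organs, config, clamp_tol = 1e-3) {
  q <- excess_n15_mass(organs$atom_percent_15N, config, organs$n_content)
  neg <- which(q < 0)
  if (length(neg) > 0) {
    too_neg <- neg[abs(q[neg]) > clamp_tol]
    if (length(too_neg) > 0)
      stop("organ excess 15N below -clamp_tol (", clamp_tol, " g) for organ(s) ",
           paste(organs$organ[too_neg], collapse = ", "),
           ": enrichment far below baseline", call. = FALSE)
    warning("clamping small negative excess 15N to zero for organ(s) ",
            paste(organs$organ[neg], collapse = ", "), call. = FALSE)
    q[neg] <- 0
  }
  q
}

#' Percent of pre-silking N remobilized (vegetative-labelled plant)
#'
#' For a plant labelled during vegetative growth, all excess 15N found in the
#' grain at maturity must have been remobilized there, so
#' `rem% = 100 * q(grain) / q(whole plant at maturity)`.
#'
#' @param organs organ rows of one maturity-stage, vegetative-labelled plant.
#' @param config an [iso_config()].
#' @param clamp_tol tolerance (g 15N) below which a negative organ excess is
#'   clamped to zero rather than raising an error.
#' @return rem% on the 0-100 scale.
#' @export
remobilized_fraction <- function(organs, config = iso_config(),
                                 clamp_tol = 1e-3) {
  if (!"n_content" %in% names(organs))
    organs$n_content <- organs$dry_mass * organs$n_concentration
  .check_organs(organs$organ, "maturity")
  if (!"grain" %in% organs$organ)
    stop("maturity plant has no grain organ", call. = FALSE)
  q <- .organ_excess(organs, config, clamp_tol)
  q_wpm <- sum(q)
  if (q_wpm <= 0)
    stop("degenerate label: whole-plant excess 15N is not positive",
         call. = FALSE)
  100 * q[organs$organ == "grain"] / q_wpm
}

#' Pre-silking N remobilized to the grain (g)
#'
#' `Q_rem(grain) = Q_wps * rem% / 100`, with `Q_wps` the (treatment-mean)
#' whole-plant N content at silking.
#'
#' @param q_wps pre-silking whole-plant N, g.
#' @param rem_pct percent of pre-silking N remobilized, 0-100.
#' @return g N remobilized to the grain.
#' @export
remobilized_to_grain <- function(q_wps, rem_pct) {
  stopifnot(is.numeric(q_wps), is.numeric(rem_pct))
  if (any(q_wps < 0)) stop("q_wps must be >= 0", call. = FALSE)
  if (any(rem_pct < 0 | rem_pct > 100))
    stop("rem_pct must lie in [0, 100]", call. = FALSE)
  q_wps * rem_pct / 100
}

#' Percent of grain N derived from remobilization (vegetative label route)
#'
#' `100 * Q_rem(grain) / Q_grain`. With noisy data the value can leave
#' [0, 100]; it is reported raw (the caller attaches a quality flag), never
#' silently clipped.
#'
#' @param q_rem_grain g N remobilized to the grain.
#' @param q_grain grain N content, g (must be > 0).
#' @return percent, possibly outside [0, 100] for noisy inputs.
#' @export
grain_fraction_from_remobilization <- function(q_rem_grain, q_grain) {
  stopifnot(is.numeric(q_rem_grain), is.numeric(q_grain))
  if (any(q_grain <= 0)) stop("q_grain must be > 0", call. = FALSE)
  100 * q_rem_grain / q_grain
}

#' Partitioning of post-silking N uptake across organs
#'
#' For a plant labelled during reproductive growth, the share of post-silking
#' N uptake recovered in each organ is `Post%(x) = 100 * q(x) / q(wpm)`.
#' The shares sum to exactly 100 by construction.
#'
#' @inheritParams remobilized_fraction
#' @return Named numeric vector of percentages (names = organ labels),
#'   summing to 100.
#' @export
postsilking_partition <- function(organs, config = iso_config(),
                                  clamp_tol = 1e-3) {
  if (!"n_content" %in% names(organs))
    organs$n_content <- organs$dry_mass * organs$n_concentration
  .check_organs(organs$organ, "maturity")
  q <- .organ_excess(organs, config, clamp_tol)
  q_wpm <- sum(q)
  if (q_wpm <= 0)
    stop("degenerate label: whole-plant excess 15N is not positive",
         call. = FALSE)
  out <- 100 * q / q_wpm
  names(out) <- organs$organ
  out
}

#' Post-silking N uptake
#'
#' `Q_wpm - Q_wps`: whole-plant N gained between silking and maturity. A
#' negative value would mean net N loss during grain fill, which violates the
#' no-loss assumption of the mass balance; it is returned as-is with a
#' warning so the violation stays visible.
#'
#' @param q_wpm whole-plant N at maturity, g.
#' @param q_wps whole-plant N at silking (treatment mean), g.
#' @return g N, possibly negative (with warning).
#' @export
postsilking_uptake <- function(q_wpm, q_wps) {
  stopifnot(is.numeric(q_wpm), is.numeric(q_wps))
  if (any(q_wpm < 0) || any(q_wps < 0))
    stop("N contents must be >= 0", call. = FALSE)
  u <- q_wpm - q_wps
  if (any(u < 0))
    warning("negative post-silking N uptake: apparent net N loss during ",
            "grain fill (mass-balance assumption violated)", call. = FALSE)
  u
}

#' Post-silking N delivered to one organ (g)
#'
#' `Q_post(x) = (Q_wpm - Q_wps) * Post%(x) / 100`.
#'
#' @inheritParams postsilking_uptake
#' @param post_pct_organ the organ's share of post-silking uptake, 0-100.
#' @return g N.
#' @export
postsilking_to_organ <- function(q_wpm, q_wps, post_pct_organ) {
  if (any(post_pct_organ < 0 | post_pct_organ > 100))
    stop("post_pct_organ must lie in [0, 100]", call. = FALSE)
  postsilking_uptake(q_wpm, q_wps) * post_pct_organ / 100
}

#' Percent of grain N derived from remobilization (reproductive label route)
#'
#' From a reproductive-labelled plant the remobilized share of grain N is
#' obtained by difference: `100 * (1 - Q_post(grain) / Q_grain)`.
#'
#' @param q_post_grain grain N originating from post-silking uptake, g.
#' @param q_grain grain N content, g (> 0).
#' @return percent, possibly outside [0, 100] for noisy inputs.
#' @export
grain_rem_from_reproductive_label <- function(q_post_grain, q_grain) {
  stopifnot(is.numeric(q_post_grain), is.numeric(q_grain))
  if (any(q_grain <= 0)) stop("q_grain must be > 0", call. = FALSE)
  100 * (1 - q_post_grain / q_grain)
}

#' Assemble the full N budget of one maturity plant
#'
#' Dispatches on the plant's labelling phase: vegetative-labelled plants get
#' the remobilization block (rem%, grams remobilized, remobilized share of
#' grain N), reproductive-labelled plants the post-silking block (per-organ
#' partition percentages and gram amounts, remobilized share by difference),
#' and unlabelled plants N totals only. The pre-silking reference `q_wps_ref`
#' is normally the treatment mean over silking-harvested plants.
#'
#' @param organs organ rows of one maturity-stage plant, including metadata
#'   columns (`plant_id`, treatments, `label_phase`).
#' @param q_wps_ref reference pre-silking whole-plant N for this plant's
#'   vegetative treatment, g.
#' @param config an [iso_config()].
#' @param clamp_tol negative-excess clamp tolerance, g 15N.
#' @return One-row tibble (an N-budget record) with N totals, excess 15N per
#'   organ, the phase-appropriate derived quantities and a semicolon-joined
#'   `flags` field for quality issues (never silently clipped values).
#' @export
budget_assemble <- function(organs, q_wps_ref, config = iso_config(),
                            clamp_tol = 1e-3) {
  if (nrow(organs) == 0) stop("empty organ list", call. = FALSE)
  stage <- unique(organs$stage)
  if (!identical(stage, "maturity"))
    stop("budget_assemble expects a maturity-stage plant", call. = FALSE)
  if (!"n_content" %in% names(organs))
    organs$n_content <- organs$dry_mass * organs$n_concentration
  .check_organs(organs$organ, "maturity", organs$plant_id[1])
  phase <- unique(organs$label_phase)

  q_wpm_n <- sum(organs$n_content)
  q_grain <- if ("grain" %in% organs$organ)
    organs$n_content[organs$organ == "grain"] else NA_real_
  flags <- character(0)

  post_uptake <- suppressWarnings(postsilking_uptake(q_wpm_n, q_wps_ref))
  if (post_uptake < 0) flags <- c(flags, "negative_post_uptake")

  out <- tibble::tibble(
    plant_id = organs$plant_id[1],
    veg_treatment = organs$veg_treatment[1],
    rep_treatment = organs$rep_treatment[1],
    label_phase = phase,
    q_wps_used = q_wps_ref,
    q_wpm_n = q_wpm_n,
    q_grain_n = q_grain,
    post_uptake = post_uptake,
    q_wpm_excess = NA_real_,
    rem_pct = NA_real_,
    q_rem_grain = NA_real_,
    grain_rem_pct = NA_real_
  )
  for (org in MATURITY_ORGANS) {
    out[[paste0("q_excess_", org)]] <- NA_real_
    out[[paste0("post_pct_", org)]] <- NA_real_
    out[[paste0("q_post_", org)]] <- NA_real_
  }

  if (phase == "vegetative") {
    q <- .organ_excess(organs, config, clamp_tol)
    out$q_wpm_excess <- sum(q)
    for (i in seq_along(q)) out[[paste0("q_excess_", organs$organ[i])]] <- q[i]
    out$rem_pct <- remobilized_fraction(organs, config, clamp_tol)
    out$q_rem_grain <- remobilized_to_grain(q_wps_ref, out$rem_pct)
    out$grain_rem_pct <- grain_fraction_from_remobilization(out$q_rem_grain,
                                                            q_grain)
  } else if (phase == "reproductive") {
    q <- .organ_excess(organs, config, clamp_tol)
    out$q_wpm_excess <- sum(q)
    for (i in seq_along(q)) out[[paste0("q_excess_", organs$organ[i])]] <- q[i]
    pct <- postsilking_partition(organs, config, clamp_tol)
    for (org in names(pct)) {
      out[[paste0("post_pct_", org)]] <- pct[[org]]
      out[[paste0("q_post_", org)]] <-
        suppressWarnings(postsilking_to_organ(q_wpm_n, q_wps_ref, pct[[org]]))
    }
    if (!is.na(q_grain)) {
      out$grain_rem_pct <-
        grain_rem_from_reproductive_label(out$q_post_grain, q_grain)
    }
  }
  if (!is.na(out$grain_rem_pct) &&
      (out$grain_rem_pct > 100 || out$grain_rem_pct < 0))
    flags <- c(flags, "grain_rem_pct_outside_0_100")
  out$flags <- paste(flags, collapse = ";")
  out
}

#' Nitrogen budgets for a cohort of plants
#'
#' Runs [budget_assemble()] on every maturity-stage plant of a long
#' plant-organ table. The pre-silking reference defaults to the treatment
#' mean over the silking-stage plants in the same table (the design's own
#' construction); alternatively supply a named vector of Q_wps values by
#' vegetative treatment, or set `per_plant_q_wps` to the name of a column
#' holding a per-plant override (useful for sensitivity analysis and for
#' noiseless simulation checks).
#'
#' @param plants long plant-organ table (validated with [validate_plants()]).
#' @param q_wps NULL (estimate from silking plants in `plants`) or a named
#'   numeric vector of g N by vegetative treatment.
#' @param config an [iso_config()].
#' @param clamp_tol negative-excess clamp tolerance, g 15N.
#' @param per_plant_q_wps optional name of a column in `plants` giving each
#'   plant its own Q_wps reference.
#' @return Tibble of N-budget records, one row per maturity plant.
#' @export
nitrogen_budget <- function(plants, q_wps = NULL, config = iso_config(),
                            clamp_tol = 1e-3, per_plant_q_wps = NULL) {
  plants <- validate_plants(plants)
  maturity <- plants[plants$stage == "maturity", , drop = FALSE]
  if (nrow(maturity) == 0)
    stop("no maturity-stage plants to budget", call. = FALSE)
  if (is.null(q_wps) && is.null(per_plant_q_wps)) {
    ref <- q_wps_reference(plants)
    q_wps <- stats::setNames(ref$q_wps, ref$veg_treatment)
  }
  ids <- unique(maturity$plant_id)
  rows <- lapply(ids, function(pid) {
    organs <- maturity[maturity$plant_id == pid, , drop = FALSE]
    ref_i <- if (!is.null(per_plant_q_wps)) {
      unique(organs[[per_plant_q_wps]])
    } else {
      vt <- organs$veg_treatment[1]
      if (!vt %in% names(q_wps))
        stop("no Q_wps reference for vegetative treatment '", vt, "'",
             call. = FALSE)
      q_wps[[vt]]
    }
    budget_assemble(organs, ref_i, config, clamp_tol)
  })
  dplyr::bind_rows(rows)
}
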