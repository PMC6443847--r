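# Treatment-cell aggregation (mean +/- SE), the cross-treatment averages
# used in narrative comparisons, and table rendering. Reporting rounds
# (1 d.p. for percentages, 2 d.p. for grams); computation never does.

VEG_ORDER <- c("Nveg", "nveg")
REP_ORDER <- c("NW", "nW", "Nw", "nw")

#' Treatment-cell means and standard errors
#'
#' Groups per-plant values by the given keys and reports n, mean and SE
#' (sample SD / sqrt(n); reported as NA when n = 1). Rows are ordered with
#' high vegetative N before low, and reproductive treatments in the order
#' NW, nW, Nw, nw. Groups whose values are all missing are dropped with a
#' warning.
#'
#' @param data data frame of per-plant values.
#' @param metric name of the value column.
#' @param by character vector of grouping columns (default vegetative and
#'   reproductive treatment).
#' @return Tibble with the grouping keys, `metric`, `n`, `mean`, `se`.
#' @export
treatment_summary <- function(data, metric,
                              by = c("veg_treatment", "rep_treatment")) {
  stopifnot(metric %in% names(data), all(by %in% names(data)))
  if (nrow(data) == 0) stop("no data to summarize", call. = FALSE)
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    n = sum(!is.na(.data[[metric]])),
    mean = mean(.data[[metric]], na.rm = TRUE),
    se = stats::sd(.data[[metric]], na.rm = TRUE) /
      sqrt(sum(!is.na(.data[[metric]]))),
    .groups = "drop")
  empty <- out$n == 0
  if (any(empty)) {
    warning(sum(empty), " group(s) with no non-missing values omitted",
            call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  out$se[out$n == 1] <- NA_real_
  out$metric <- metric
  if ("veg_treatment" %in% by)
    out <- out[order(match(out$veg_treatment, VEG_ORDER)), , drop = FALSE]
  if ("rep_treatment" %in% by)
    out <- out[order(match(out$rep_treatment, REP_ORDER),
                     if ("veg_treatment" %in% by)
                       match(out$veg_treatment, VEG_ORDER) else 0L), ,
               drop = FALSE]
  dplyr::relocate(tibble::as_tibble(out), "metric")
}

#' Unweighted average of named treatment-cell means
#'
#' The construction behind cross-treatment statements such as "the average
#' over the stress treatments": an unweighted mean of the selected cell
#' means (not a pooled per-plant mean). Over a single cell it is the
#' identity.
#'
#' @param cell_means named numeric vector of cell means (names are
#'   reproductive-treatment cells), or a data frame with columns
#'   `rep_treatment` and `mean`.
#' @param cells character vector naming the cells to average.
#' @return The unweighted mean of the selected cell means.
#' @examples
#' stress_average(c(NW = 45.4, nW = 64.0, Nw = 72.1, nw = 61.2),
#'                cells = c("nW", "Nw", "nw"))
#' @export
stress_average <- function(cell_means, cells) {
  if (is.data.frame(cell_means)) {
    stopifnot(all(c("rep_treatment", "mean") %in% names(cell_means)))
    cell_means <- stats::setNames(cell_means$mean, cell_means$rep_treatment)
  }
  if (length(cells) < 1) stop("need at least one cell", call. = FALSE)
  unknown <- setdiff(cells, names(cell_means))
  if (length(unknown) > 0)
    stop("unknown cell(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  mean(cell_means[cells])
}

# report-layer rounding: half away from zero (so 0.5 -> 1, -0.5 -> -1),
# unlike R's banker's rounding
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.round_cols <- function(df, cols, digits) {
  for (cl in intersect(cols, names(df)))
    df[[cl]] <- round_half_away(df[[cl]], digits)
  df
}

#' Render treatment-summary tables to files
#'
#' Writes the four standard report tables as CSV (and optionally aligned
#' plain text): silking parameters by vegetative treatment (if silking data
#' are supplied), grain-N sources (remobilized share and grams remobilized,
#' vegetative-labelled plants), post-silking N uptake and partitioning
#' (reproductive-labelled plants), and yield components. Percentages are
#' rounded to 1 decimal, gram quantities to 2, counts to whole numbers —
#' in the rendered files only; pass the unrounded budgets on for any
#' further computation.
#'
#' @param budgets N-budget table from [nitrogen_budget()].
#' @param phenotypes per-plant phenotype table (`veg_treatment`,
#'   `rep_treatment`, `spikelet_count`, `kernel_number`, `grain_mass`).
#' @param silking optional long organ table of silking-stage plants.
#' @param out_dir output directory (created if needed).
#' @param format "csv" or "txt" (aligned text next to each CSV).
#' @return Invisibly, the paths of the files written.
#' @export
render_tables <- function(budgets, phenotypes, silking = NULL,
                          out_dir = ".", format = c("csv", "txt")) {
  format <- match.arg(format)
  if (nrow(budgets) == 0) stop("empty budget table", call. = FALSE)
  if (nrow(phenotypes) == 0) stop("empty phenotype table", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    paths <<- c(paths, path)
    if (format == "txt") {
      tpath <- file.path(out_dir, paste0(name, ".txt"))
      writeLines(utils::capture.output(print.data.frame(df, row.names = FALSE)),
                 tpath)
      paths <<- c(paths, tpath)
    }
  }
  wide_summary <- function(data, metrics, pct_metrics = character(0)) {
    pieces <- lapply(metrics, function(m) {
      s <- treatment_summary(data, m)
      digits <- if (m %in% pct_metrics) 1 else 2
      s$mean <- round_half_away(s$mean, digits)
      s$se <- round_half_away(s$se, digits)
      names(s)[names(s) %in% c("n", "mean", "se")] <-
        paste0(m, c("_n", "_mean", "_se"))
      s$metric <- NULL
      s
    })
    Reduce(function(a, b) merge(a, b, sort = FALSE), pieces)
  }

  if (!is.null(silking) && nrow(silking) > 0) {
    per_plant <- stats::aggregate(
      cbind(dry_mass, n_content = dry_mass * n_concentration) ~
        plant_id + veg_treatment, data = silking, FUN = sum)
    s1 <- merge(
      treatment_summary(per_plant, "dry_mass", by = "veg_treatment"),
      treatment_summary(per_plant, "n_content", by = "veg_treatment"),
      by = "veg_treatment", suffixes = c("_biomass", "_n_uptake"))
    s1 <- .round_cols(s1, c("mean_biomass", "se_biomass"), 1)
    s1 <- .round_cols(s1, c("mean_n_uptake", "se_n_uptake"), 2)
    s1 <- s1[, !grepl("^metric", names(s1))]
    emit(s1, "table_silking_parameters")
  }

  veg_lab <- budgets[budgets$label_phase == "vegetative", , drop = FALSE]
  if (nrow(veg_lab) > 0)
    emit(wide_summary(veg_lab, c("grain_rem_pct", "q_rem_grain"),
                      pct_metrics = "grain_rem_pct"),
         "table_grain_n_sources")

  rep_lab <- budgets[budgets$label_phase == "reproductive", , drop = FALSE]
  if (nrow(rep_lab) > 0) {
    metrics <- c("post_uptake", paste0("post_pct_", MATURITY_ORGANS))
    emit(wide_summary(rep_lab, metrics,
                      pct_metrics = grep("^post_pct_", metrics, value = TRUE)),
         "table_postsilking_partitioning")
  }

  ph <- phenotypes
  ph$kernel_weight_mg <- kernel_weight(ph$grain_mass, ph$kernel_number)
  s4 <- wide_summary(ph, c("grain_mass", "kernel_number", "kernel_weight_mg"))
  s4 <- .round_cols(s4, c("kernel_number_mean", "kernel_number_se"), 0)
  s4 <- .round_cols(s4, c("kernel_weight_mg_mean", "kernel_weight_mg_se"), 1)
  s4 <- .round_cols(s4, c("grain_mass_mean", "grain_mass_se"), 1)
  emit(s4, "table_yield_components")

  invisible(paths)
}
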