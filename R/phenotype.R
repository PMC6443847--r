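# Yield-component and canopy arithmetic: the luxury-N reserve, spikelet
# abortion, kernel weight, and the two leaf-area calibration regressions
# (length x width, or dry weight) used to track green leaf area during
# grain fill from senesced-leaf weights.

#' Luxury N reserve at silking
#'
#' The N accumulated by the high-N vegetative treatment in excess of the
#' low-N treatment at equal biomass: `uptake_high - uptake_low` (g N per
#' plant). A negative result (low-N plants holding more N) is returned as-is
#' with a warning, since it usually indicates swapped arguments.
#'
#' @param uptake_high whole-plant N at silking under high vegetative N, g.
#' @param uptake_low whole-plant N at silking under low vegetative N, g.
#' @return g N per plant.
#' @examples
#' luxury_reserve(2.76, 1.61)
#' @export
luxury_reserve <- function(uptake_high, uptake_low) {
  stopifnot(is.numeric(uptake_high), is.numeric(uptake_low))
  if (any(uptake_high < 0) || any(uptake_low < 0))
    stop("N uptakes must be >= 0", call. = FALSE)
  res <- uptake_high - uptake_low
  if (any(res < 0))
    warning("negative luxury reserve: high-N uptake below low-N uptake",
            call. = FALSE)
  res
}

#' Spikelet abortion fraction
#'
#' Share of spikelets present at silking that failed to become mature
#' kernels: `100 * (1 - kernel_number / spikelet_count)`. Treatment-mean
#' kernel numbers are an accepted input (the value need not be an integer).
#' Kernel numbers exceeding the spikelet count are flagged with a warning
#' (the negative abortion value is reported raw).
#'
#' @param spikelet_count spikelets per plant at silking (> 0).
#' @param kernel_number mature kernels per plant (count or mean).
#' @return percent aborted, 0-100 for consistent inputs. Rounding to whole
#'   percent happens only at the report layer.
#' @examples
#' abortion_fraction(805, 575)
#' @export
abortion_fraction <- function(spikelet_count, kernel_number) {
  stopifnot(is.numeric(spikelet_count), is.numeric(kernel_number))
  if (any(spikelet_count <= 0))
    stop("spikelet_count must be > 0", call. = FALSE)
  if (any(kernel_number < 0))
    stop("kernel_number must be >= 0", call. = FALSE)
  if (any(kernel_number > spikelet_count))
    warning("kernel_number exceeds spikelet_count for some plants",
            call. = FALSE)
  100 * (1 - kernel_number / spikelet_count)
}

#' Mean kernel weight
#'
#' `1000 * grain_mass / kernel_number`, in mg per kernel.
#'
#' @param grain_mass grain dry mass per plant, g.
#' @param kernel_number kernels per plant (> 0).
#' @return mg per kernel.
#' @examples
#' kernel_weight(133.0, 575)
#' @export
kernel_weight <- function(grain_mass, kernel_number) {
  stopifnot(is.numeric(grain_mass), is.numeric(kernel_number))
  if (any(kernel_number <= 0))
    stop("kernel_number must be > 0", call. = FALSE)
  1000 * grain_mass / kernel_number
}

#' Fit a leaf-area calibration model
#'
#' Two calibration modes are supported, both ordinary least squares on pairs
#' measured destructively at silking:
#' \describe{
#'   \item{dimensions}{area as a function of length x width. The default is
#'     the Montgomery form `area = k * L * W` (no intercept; k is the leaf
#'     shape factor, ~0.75 in maize); set `intercept = TRUE` for an affine
#'     fit.}
#'   \item{dry_weight}{area as a function of leaf dry weight, affine by
#'     default (specific leaf area changes little within a harvest).}
#' }
#'
#' @param pairs data frame of calibration pairs with column `area` (cm2,
#'   from a leaf-area meter) and, depending on mode, `length`/`width` (cm)
#'   or `dry_weight` (g). At least 3 pairs are required.
#' @param mode "dimensions" or "dry_weight".
#' @param intercept include an intercept term? Default FALSE for dimensions
#'   (Montgomery form), TRUE for dry weight.
#' @return An object of class `leaf_area_model`: mode, coefficients,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @examples
#' pairs <- data.frame(length = c(60, 70, 80), width = c(7, 8, 9))
#' pairs$area <- 0.75 * pairs$length * pairs$width
#' fit_leaf_area_model(pairs, "dimensions")
#' @export
fit_leaf_area_model <- function(pairs, mode = c("dimensions", "dry_weight"),
                                intercept = NULL) {
  mode <- match.arg(mode)
  if (nrow(pairs) < 3)
    stop("need at least 3 calibration pairs", call. = FALSE)
  if (!"area" %in% names(pairs))
    stop("calibration pairs need an 'area' column", call. = FALSE)
  if (is.null(intercept)) intercept <- (mode == "dry_weight")
  if (mode == "dimensions") {
    if (!all(c("length", "width") %in% names(pairs)))
      stop("dimensions mode needs 'length' and 'width' columns", call. = FALSE)
    if (any(pairs$length <= 0 | pairs$width <= 0 | pairs$area <= 0))
      stop("calibration measurements must be > 0", call. = FALSE)
    x <- pairs$length * pairs$width
  } else {
    if (!"dry_weight" %in% names(pairs))
      stop("dry_weight mode needs a 'dry_weight' column", call. = FALSE)
    if (any(pairs$dry_weight <= 0 | pairs$area <= 0))
      stop("calibration measurements must be > 0", call. = FALSE)
    x <- pairs$dry_weight
  }
  if (isTRUE(all.equal(stats::var(x), 0)))
    stop("constant predictor: cannot fit calibration", call. = FALSE)
  df <- data.frame(x = x, area = pairs$area)
  fit <- if (intercept) stats::lm(area ~ x, data = df)
         else stats::lm(area ~ 0 + x, data = df)
  slope <- unname(stats::coef(fit)[if (intercept) "x" else "x"])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate calibration fit: non-positive slope", call. = FALSE)
  # R2 about the mean (or about zero for the no-intercept Montgomery form);
  # perfect-fit warnings from summary.lm are expected for exact calibrations
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    mode = mode,
    intercept = if (intercept) unname(stats::coef(fit)["(Intercept)"]) else 0,
    slope = slope,
    r_squared = r2,
    n = nrow(pairs),
    fit = fit
  ), class = "leaf_area_model")
}

#' @export
print.leaf_area_model <- function(x, ...) {
  pred <- if (x$mode == "dimensions") "length x width" else "dry weight"
  cat("<leaf_area_model> area ~ ", format(x$slope, digits = 4), " * ", pred,
      if (x$intercept != 0) paste0(" + ", format(x$intercept, digits = 4)),
      "  (R2 = ", format(x$r_squared, digits = 3), ", n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Predict leaf area from a calibration model
#'
#' Predictions are clamped at zero (a leaf cannot have negative area); when
#' clamping occurs the result carries a `clamped` attribute.
#'
#' @param model a [fit_leaf_area_model()] object.
#' @param length,width leaf dimensions, cm (dimensions mode).
#' @param dry_weight leaf dry weight, g (dry-weight mode).
#' @return predicted leaf area, cm2.
#' @export
estimate_leaf_area <- function(model, length = NULL, width = NULL,
                               dry_weight = NULL) {
  if (!inherits(model, "leaf_area_model"))
    stop("model must come from fit_leaf_area_model()", call. = FALSE)
  if (model$mode == "dimensions") {
    if (is.null(length) || is.null(width))
      stop("dimensions model needs length and width", call. = FALSE)
    if (any(length <= 0) || any(width <= 0))
      stop("length and width must be > 0", call. = FALSE)
    pred <- model$intercept + model$slope * length * width
  } else {
    if (is.null(dry_weight))
      stop("dry-weight model needs dry_weight", call. = FALSE)
    if (any(dry_weight < 0))
      stop("dry_weight must be >= 0", call. = FALSE)
    pred <- model$intercept + model$slope * dry_weight
  }
  clamped <- pred < 0
  pred[clamped] <- 0
  if (any(clamped)) {
    warning("negative area prediction clamped to 0", call. = FALSE)
    attr(pred, "clamped") <- clamped
  }
  pred
}

#' Green leaf area over grain fill from senesced-leaf weights
#'
#' Senesced leaf material removed at successive timepoints is converted to
#' area through a dry-weight calibration and subtracted cumulatively from the
#' initial (silking) leaf area. The series is non-increasing by construction
#' and floored at zero; if the floor is hit the result carries a `floored`
#' attribute.
#'
#' @param initial_area green leaf area at silking, cm2 (> 0).
#' @param senesced_weights vector of senesced dry weights (g) removed at each
#'   timepoint, in time order.
#' @param weight_model a dry-weight [fit_leaf_area_model()].
#' @return vector of green leaf areas (cm2), one per timepoint.
#' @export
green_leaf_area_series <- function(initial_area, senesced_weights,
                                   weight_model) {
  if (initial_area <= 0) stop("initial_area must be > 0", call. = FALSE)
  if (any(senesced_weights < 0))
    stop("senesced weights must be >= 0", call. = FALSE)
  if (!inherits(weight_model, "leaf_area_model") ||
      weight_model$mode != "dry_weight")
    stop("weight_model must be a dry-weight leaf_area_model", call. = FALSE)
  if (length(senesced_weights) == 0) return(numeric(0))
  lost <- vapply(senesced_weights, function(w) {
    if (w == 0) 0 else estimate_leaf_area(weight_model, dry_weight = w)
  }, numeric(1))
  series <- initial_area - cumsum(lost)
  floored <- series < 0
  series[floored] <- 0
  if (any(floored)) {
    warning("senesced area exceeds initial area: series floored at 0",
            call. = FALSE)
    attr(series, "floored") <- floored
  }
  series
}
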