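#' Normative model configuration
#'
#' Controls how thinning and denudation thresholds are derived from the
#' control cohort. The default (`fraction_of_mean`) takes the per-landmark
#' arithmetic mean over controls and thresholds thinning at
#' `loss_fraction` (95%) and denudation at `denudation_fraction` (5%) of
#' that mean. The alternative `percentile_of_controls` mode stores the
#' empirical per-landmark control-distribution quantiles at those same
#' probabilities (linear interpolation, inclusive endpoints) and uses them
#' directly as thresholds.
#'
#' @param mode `"fraction_of_mean"` (default) or `"percentile_of_controls"`.
#' @param loss_fraction Thinning threshold as a fraction of normative
#'   thickness (default 0.95), in `(0, 1]`.
#' @param denudation_fraction Denudation threshold fraction (default 0.05),
#'   in `[0, loss_fraction)`.
#' @param min_normative_mm Landmarks whose normative mean falls below this
#'   (mm, default 0.1) carry essentially no cartilage cover and are
#'   excluded from area denominators.
#' @return A list of class `qm_normative_config`.
#' @export
normative_config <- function(mode = c("fraction_of_mean",
                                      "percentile_of_controls"),
                             loss_fraction = 0.95,
                             denudation_fraction = 0.05,
                             min_normative_mm = 0.1) {
  mode <- match.arg(mode)
  stopifnot(loss_fraction > 0, loss_fraction <= 1,
            denudation_fraction >= 0, denudation_fraction < loss_fraction,
            min_normative_mm >= 0)
  structure(list(mode = mode, loss_fraction = loss_fraction,
                 denudation_fraction = denudation_fraction,
                 min_normative_mm = min_normative_mm),
            class = "qm_normative_config")
}

# Internal constructor shared by build_normative and the generator (which
# builds a truth model directly from the noise-free field).
new_normative_model <- function(normative_mean, atlas, n_controls, config,
                                percentile_low = NULL,
                                percentile_high = NULL) {
  if (length(normative_mean) != nrow(atlas)) {
    stop("normative mean length must equal atlas landmark count")
  }
  included <- normative_mean >= config$min_normative_mm
  if (config$mode == "percentile_of_controls") {
    bad <- included & !(percentile_low < percentile_high)
    if (any(bad)) {
      stop("denudation threshold not strictly below loss threshold at ",
           sum(bad), " included landmark(s); control distribution may be ",
           "degenerate - use fraction_of_mean mode")
    }
  }
  structure(list(normative_mean = as.numeric(normative_mean),
                 landmark_id = atlas$landmark_id,
                 atlas = atlas,
                 n_controls = n_controls,
                 mode = config$mode,
                 loss_fraction = config$loss_fraction,
                 denudation_fraction = config$denudation_fraction,
                 min_normative_mm = config$min_normative_mm,
                 percentile_low = percentile_low,
                 percentile_high = percentile_high,
                 included = included),
            class = "qm_normative")
}

#' Build the per-landmark normative thickness model
#'
#' The normative thickness at each corresponded landmark is the arithmetic
#' mean over the control cohort of that landmark's thickness. In percentile
#' mode the empirical control-distribution quantiles at
#' `denudation_fraction` and `loss_fraction` are additionally stored and
#' used as the thresholds.
#'
#' @param controls A `qm_thickness` cohort of control knees (>= 2 maps).
#' @param atlas The [qm_atlas()] the controls must be measured on.
#' @param config A [normative_config()].
#' @return An object of class `qm_normative`.
#' @export
build_normative <- function(controls, atlas = controls$atlas,
                            config = normative_config()) {
  stopifnot(inherits(controls, "qm_thickness"),
            inherits(config, "qm_normative_config"))
  if (!identical(controls$atlas$landmark_id, atlas$landmark_id) ||
      !identical(as.character(controls$atlas$region),
                 as.character(atlas$region))) {
    stop("controls are not measured on the supplied atlas")
  }
  if (ncol(controls$values) < 2) stop("need at least 2 control knees")
  nm <- rowMeans(controls$values)
  plo <- phi <- NULL
  if (config$mode == "percentile_of_controls") {
    qs <- t(apply(controls$values, 1, stats::quantile,
                  probs = c(config$denudation_fraction,
                            config$loss_fraction),
                  type = 7, names = FALSE))
    plo <- qs[, 1]; phi <- qs[, 2]
  }
  new_normative_model(nm, atlas, ncol(controls$values), config,
                      percentile_low = plo, percentile_high = phi)
}

#' Thinning and denudation thresholds at a landmark
#'
#' @param model A `qm_normative` model.
#' @param landmark_id One or more landmark ids present in the model's
#'   atlas.
#' @return A data.frame with columns `landmark_id`, `loss_threshold_mm`,
#'   `denudation_threshold_mm`, `included` (FALSE where the normative mean
#'   falls below `min_normative_mm`).
#' @export
thresholds_at <- function(model, landmark_id) {
  stopifnot(inherits(model, "qm_normative"))
  pos <- match(as.integer(landmark_id), model$landmark_id)
  if (anyNA(pos)) {
    stop("unknown landmark_id: ",
         paste(landmark_id[is.na(pos)], collapse = ", "))
  }
  th <- threshold_vectors(model)
  data.frame(landmark_id = as.integer(landmark_id),
             loss_threshold_mm = th$loss[pos],
             denudation_threshold_mm = th$denudation[pos],
             included = model$included[pos])
}

# Full per-landmark threshold vectors (atlas order).
threshold_vectors <- function(model) {
  if (model$mode == "fraction_of_mean") {
    list(loss = model$loss_fraction * model$normative_mean,
         denudation = model$denudation_fraction * model$normative_mean)
  } else {
    list(loss = model$percentile_high, denudation = model$percentile_low)
  }
}

#' @export
print.qm_normative <- function(x, ...) {
  cat("<qm_normative> ", length(x$normative_mean), " landmarks, mode ",
      x$mode, ", thresholds ", x$loss_fraction, "/", x$denudation_fraction,
      ", ", sum(!x$included), " landmark(s) excluded (< ",
      x$min_normative_mm, " mm)\n", sep = "")
  invisible(x)
}

#' Serialise a normative model to JSON
#'
#' @param model A `qm_normative` model.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_normative_json <- function(model, path) {
  stopifnot(inherits(model, "qm_normative"))
  payload <- list(
    mode = model$mode,
    loss_fraction = model$loss_fraction,
    denudation_fraction = model$denudation_fraction,
    min_normative_mm = model$min_normative_mm,
    n_controls = model$n_controls,
    landmark_id = model$landmark_id,
    region = as.character(model$atlas$region),
    area_weight = model$atlas$area_weight,
    normative_mean = model$normative_mean,
    percentile_low = model$percentile_low,
    percentile_high = model$percentile_high
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a normative model from JSON
#'
#' @param path Path written by [write_normative_json()].
#' @return A `qm_normative` model.
#' @export
read_normative_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlas <- qm_atlas(p$landmark_id, p$region, p$area_weight)
  cfg <- normative_config(mode = p$mode, loss_fraction = p$loss_fraction,
                          denudation_fraction = p$denudation_fraction,
                          min_normative_mm = p$min_normative_mm)
  new_normative_model(p$normative_mean, atlas,
                      n_controls = if (is.null(p$n_controls)) NA_integer_
                                   else p$n_controls,
                      config = cfg,
                      percentile_low = p$percentile_low,
                      percentile_high = p$percentile_high)
}
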