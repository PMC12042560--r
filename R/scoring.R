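#' Classify one landmark's thickness against the normative model
#'
#' A landmark is *denuded* when its thickness is strictly below the
#' denudation threshold (5% of normative by default), *thinned* when
#' strictly below the thinning threshold (95% of normative) but not
#' denuded, and *normal* otherwise. Strict inequalities throughout: a
#' thickness exactly at a threshold is not below it. For area accounting a
#' denuded landmark also counts as thinned.
#'
#' @param thickness Thickness in mm (scalar or vector, one per landmark).
#' @param model A `qm_normative` model.
#' @param landmark_id Landmark id(s), same length as `thickness`.
#' @return Character vector in `{"normal", "thinned", "denuded"}`.
#' @export
classify_landmark <- function(thickness, model, landmark_id) {
  th <- thresholds_at(model, landmark_id)
  if (any(!th$included)) {
    stop("landmark(s) excluded by the normative model (normative mean < ",
         model$min_normative_mm, " mm): ",
         paste(th$landmark_id[!th$included], collapse = ", "),
         "; mask excluded landmarks before classifying")
  }
  ifelse(thickness < th$denudation_threshold_mm, "denuded",
         ifelse(thickness < th$loss_threshold_mm, "thinned", "normal"))
}

# Status codes for a full map: 0 normal, 1 thinned, 2 denuded, NA excluded.
classify_map <- function(values, model) {
  th <- threshold_vectors(model)
  status <- matrix(0L, nrow(as.matrix(values)), ncol(as.matrix(values)))
  values <- as.matrix(values)
  status[values < th$loss] <- 1L
  status[values < th$denudation] <- 2L
  status[!model$included, ] <- NA_integer_
  status
}

#' Per-region area percentages of thinning and denudation
#'
#' `thqcm_pct` is 100 times the area-weighted fraction of the region's
#' included landmarks that are thinned or denuded; `dqcm_pct` counts the
#' denuded landmarks only. Landmarks excluded by the normative model
#' (negligible normative cover) enter neither numerator nor denominator.
#'
#' @param map Numeric per-landmark thickness vector (atlas order).
#' @param model A `qm_normative` model (carries the atlas and weights).
#' @param region A subregion code.
#' @return Named numeric vector `c(thqcm_pct = , dqcm_pct = )`.
#' @export
region_percents <- function(map, model, region) {
  atlas <- model$atlas
  idx <- region_landmarks(atlas, region)
  inc <- idx[model$included[idx]]
  if (length(inc) == 0) {
    stop("region ", region, " has no normative cartilage cover")
  }
  status <- classify_map(matrix(map, ncol = 1), model)[inc, 1]
  w <- atlas$area_weight[inc]
  denom <- sum(w)
  c(thqcm_pct = 100 * sum(w[status >= 1L]) / denom,
    dqcm_pct = 100 * sum(w[status == 2L]) / denom)
}

#' Band an area percentage into the ordinal 0-3 score
#'
#' Banding follows the semi-quantitative convention: 0 = none (exactly
#' 0%), 1 = up to 10%, 2 = over 10% and up to 75%, 3 = over 75%. Interval
#' edges are left-open/right-closed, with 0 reserved for exactly zero so
#' that "none" is distinguishable from any positive loss.
#'
#' @param pct Numeric vector of percentages in `[0, 100]`.
#' @return Integer vector of scores in `{0, 1, 2, 3}`.
#' @export
band <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100)) {
    stop("percentages must be finite and within [0, 100]")
  }
  ifelse(pct == 0, 0L, ifelse(pct <= 10, 1L, ifelse(pct <= 75, 2L, 3L)))
}

#' Regional mean cartilage thickness (ThCtAB)
#'
#' The area-weighted mean thickness over *all* landmarks of a subregion -
#' the plain quantitative thickness construct, which by default ignores
#' the normative exclusion mask. Set `masked = TRUE` to restrict the mean
#' to model-included landmarks for sensitivity analyses.
#'
#' @param map Numeric per-landmark thickness vector.
#' @param atlas A [qm_atlas()].
#' @param region A subregion code.
#' @param model Optional `qm_normative` model, required when
#'   `masked = TRUE`.
#' @param masked Restrict to model-included landmarks (default FALSE).
#' @return Mean thickness in mm.
#' @export
thctab <- function(map, atlas, region, model = NULL, masked = FALSE) {
  idx <- region_landmarks(atlas, region)
  if (masked) {
    stopifnot(inherits(model, "qm_normative"))
    idx <- idx[model$included[idx]]
  }
  if (length(idx) == 0) stop("region ", region, " is empty")
  stats::weighted.mean(map[idx], atlas$area_weight[idx])
}

#' Score a cohort of thickness maps
#'
#' Computes, for every (knee, visit, region): the thinning and denudation
#' area percentages (ThQCM%, dQCM%), their banded ordinal scores (ThQCM,
#' dQCM) and the regional mean thickness (ThCtAB).
#'
#' @param x A `qm_thickness` cohort.
#' @param model A `qm_normative` model on the same atlas.
#' @param masked_thctab Use the exclusion-masked ThCtAB variant
#'   (default FALSE).
#' @return A data.frame of class `qm_scores` with columns `knee_id`,
#'   `visit_month`, `region`, `thqcm_pct`, `dqcm_pct`, `thqcm_score`,
#'   `dqcm_score`, `thctab_mm`, one row per knee-visit-region, ordered by
#'   (knee_id, visit_month, canonical region order).
#' @export
score_cohort <- function(x, model, masked_thctab = FALSE) {
  stopifnot(inherits(x, "qm_thickness"), inherits(model, "qm_normative"))
  atlas <- model$atlas
  if (!identical(x$atlas$landmark_id, atlas$landmark_id)) {
    stop("cohort and model are on different atlases")
  }
  status <- classify_map(x$values, model)
  S <- ncol(x$values)
  res <- vector("list", length(region_codes()))
  for (k in seq_along(region_codes())) {
    rg <- region_codes()[k]
    idx <- region_landmarks(atlas, rg)
    inc <- idx[model$included[idx]]
    if (length(inc) == 0) {
      stop("region ", rg, " has no normative cartilage cover")
    }
    w <- atlas$area_weight[inc]
    denom <- sum(w)
    st <- status[inc, , drop = FALSE]
    thq <- 100 * as.numeric(crossprod(w, st >= 1L)) / denom
    dq <- 100 * as.numeric(crossprod(w, st == 2L)) / denom
    tidx <- if (masked_thctab) inc else idx
    tw <- atlas$area_weight[tidx]
    tc <- as.numeric(crossprod(tw, x$values[tidx, , drop = FALSE])) / sum(tw)
    res[[k]] <- data.frame(knee_id = x$samples$knee_id,
                           visit_month = x$samples$visit_month,
                           region = rg,
                           thqcm_pct = thq, dqcm_pct = dq,
                           thqcm_score = band(thq), dqcm_score = band(dq),
                           thctab_mm = tc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$knee_id, out$visit_month,
                   match(out$region, region_codes())), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qm_scores", "data.frame")
  out
}

#' Numeric change between semi-quantitative records
#'
#' Whole-grade follow-up records yield `followup - previous`; the
#' within-grade codes +0.5 / -0.5 yield +0.5 / -0.5 directly (worsening or
#' improvement that did not cross a grade boundary).
#'
#' @param prev_score Previous whole-grade score(s) in `{0, 1, 2, 3}`.
#' @param followup_record Follow-up record(s) in
#'   `{0, 1, 2, 3, 0.5, -0.5}`.
#' @return Numeric change in score units.
#' @export
moaks_numeric_change <- function(prev_score, followup_record) {
  if (!all(prev_score %in% c(0, 1, 2, 3))) {
    stop("prev_score must be a whole grade in {0,1,2,3}")
  }
  if (!all(followup_record %in% c(0, 1, 2, 3, 0.5, -0.5))) {
    stop("followup_record must be in {0,1,2,3,0.5,-0.5}")
  }
  ifelse(followup_record %in% c(0.5, -0.5), followup_record,
         followup_record - prev_score)
}

#' Write scored results to CSV
#' @param x A `qm_scores` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "qm_scores"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
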