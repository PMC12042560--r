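#' Paired change vector over a follow-up interval
#'
#' Computes per-knee change (follow-up minus baseline, signed) for one
#' measure in one region. Quantitative measures (`"ThQCM%"`, `"dQCM%"`,
#' `"ThCtAB"`) are taken from a `qm_scores` table; semi-quantitative
#' measures (`"ThMCM"`, `"dMCM"`) from a `qm_moaks` table, resolving
#' within-grade codes through [moaks_numeric_change()]. Knees missing
#' either visit are dropped (complete-case), with the dropped count kept
#' on the result.
#'
#' @param scores A `qm_scores` table (required for quantitative measures).
#' @param moaks A `qm_moaks` table (required for semi-quantitative
#'   measures).
#' @param measure One of `"ThMCM"`, `"dMCM"` (semi-quantitative),
#'   `"ThQCM%"`, `"dQCM%"`, `"ThCtAB"` (quantitative), or `"ThQCM"`,
#'   `"dQCM"` (the banded ordinal quantitative scores).
#' @param region A subregion code.
#' @param interval Length-2 integer `c(baseline_month, followup_month)`.
#' @param within_grade How a within-grade code at an intermediate visit is
#'   reconciled for multi-visit intervals: `"direct"` (default) computes
#'   change from the follow-up record against baseline directly;
#'   `"chained"` accumulates visit-to-visit changes (so two half-steps sum
#'   to 1).
#' @param drop_improvement Exclude within-grade -0.5 improvements instead
#'   of keeping them as negative deltas (default FALSE: kept).
#' @return A list of class `qm_changes`: `deltas`, `n`, `n_dropped`,
#'   `measure`, `region`, `interval`.
#' @export
paired_change <- function(scores = NULL, moaks = NULL, measure, region,
                          interval = c(0L, 12L),
                          within_grade = c("direct", "chained"),
                          drop_improvement = FALSE) {
  within_grade <- match.arg(within_grade)
  stopifnot(region %in% region_codes(), length(interval) == 2,
            interval[1] < interval[2])
  measure <- match.arg(measure,
                       c("ThMCM", "dMCM", "ThQCM%", "dQCM%", "ThCtAB",
                         "ThQCM", "dQCM"))
  if (measure %in% c("ThMCM", "dMCM")) {
    stopifnot(inherits(moaks, "qm_moaks"))
    sub <- moaks[moaks$region == region & moaks$measure == measure, ,
                 drop = FALSE]
    base <- sub[sub$visit_month == interval[1], c("knee_id", "score")]
    fup <- sub[sub$visit_month == interval[2], c("knee_id", "score")]
    j <- merge(base, fup, by = "knee_id", suffixes = c("_base", "_fup"))
    n_dropped <- length(union(base$knee_id, fup$knee_id)) - nrow(j)
    if (within_grade == "chained" && interval[1] == 0L &&
        interval[2] > 12L) {
      # accumulate 0 -> 12 -> interval[2]; a +-0.5 leaves the whole-grade
      # state unchanged but contributes its half-step to the total
      mid <- sub[sub$visit_month == 12L, c("knee_id", "score")]
      names(mid)[2] <- "score_mid"
      j2 <- merge(j, mid, by = "knee_id")
      n_dropped <- n_dropped + (nrow(j) - nrow(j2))
      d1 <- moaks_numeric_change(j2$score_base, j2$score_mid)
      state_mid <- ifelse(j2$score_mid %in% c(0.5, -0.5), j2$score_base,
                          j2$score_mid)
      d2 <- moaks_numeric_change(state_mid, j2$score_fup)
      deltas <- d1 + d2
      codes <- cbind(j2$score_mid, j2$score_fup)
      j <- j2
    } else {
      deltas <- moaks_numeric_change(j$score_base, j$score_fup)
      codes <- cbind(j$score_fup)
    }
    if (drop_improvement) {
      keep <- !apply(codes == -0.5, 1, any)
      deltas <- deltas[keep]
      j <- j[keep, , drop = FALSE]
    }
  } else {
    stopifnot(inherits(scores, "qm_scores"))
    col <- switch(measure, "ThQCM%" = "thqcm_pct", "dQCM%" = "dqcm_pct",
                  "ThCtAB" = "thctab_mm", "ThQCM" = "thqcm_score",
                  "dQCM" = "dqcm_score")
    sub <- scores[scores$region == region, , drop = FALSE]
    base <- sub[sub$visit_month == interval[1], c("knee_id", col)]
    fup <- sub[sub$visit_month == interval[2], c("knee_id", col)]
    j <- merge(base, fup, by = "knee_id", suffixes = c("_base", "_fup"))
    n_dropped <- length(union(base$knee_id, fup$knee_id)) - nrow(j)
    deltas <- j[[paste0(col, "_fup")]] - j[[paste0(col, "_base")]]
  }
  if (length(deltas) == 0) {
    stop("no complete cases for ", measure, " in ", region, " over ",
         interval[1], "->", interval[2], " months")
  }
  structure(list(deltas = as.numeric(deltas), n = length(deltas),
                 n_dropped = n_dropped, measure = measure, region = region,
                 interval = as.integer(interval)),
            class = "qm_changes")
}

#' Standardised response mean
#'
#' `SRM = mean(change) / sd(change)` with the sample (n - 1) standard
#' deviation. Progressive cartilage loss yields positive score/percentage
#' SRMs and a negative thickness SRM.
#'
#' @param changes A `qm_changes` object or plain numeric delta vector.
#' @return A list of class `qm_srm`: `mean_change`, `sd_change`, `srm`,
#'   `n`. When the deltas have zero variance `srm` is `NA` and a warning
#'   of class `qm_degenerate` is raised.
#' @export
srm <- function(changes) {
  deltas <- if (inherits(changes, "qm_changes")) changes$deltas
            else as.numeric(changes)
  if (length(deltas) < 2) stop("need at least 2 changes")
  m <- mean(deltas)
  s <- stats::sd(deltas)
  est <- if (s > 0) m / s else {
    warning(warningCondition("zero SD of change; SRM undefined",
                             class = "qm_degenerate"))
    NA_real_
  }
  structure(list(mean_change = m, sd_change = s, srm = est,
                 n = length(deltas)),
            class = "qm_srm")
}

#' Percentile-bootstrap confidence interval for the SRM
#'
#' Resamples knees with replacement `n_boot` times and takes the 2.5/97.5
#' percentiles of the resampled SRMs (percentile method). Degenerate
#' resamples with zero SD are skipped and counted.
#'
#' @param changes A `qm_changes` object or numeric delta vector.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed (deterministic CI for a fixed seed).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(ci_low = , ci_high = )` with attributes
#'   `n_boot` and `n_degenerate`.
#' @export
bootstrap_srm_ci <- function(changes, n_boot = 1000L, seed = 1L,
                             conf = 0.95) {
  deltas <- if (inherits(changes, "qm_changes")) changes$deltas
            else as.numeric(changes)
  n <- length(deltas)
  if (n < 2) stop("need at least 2 changes")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  bm <- colMeans(matrix(deltas[idx], nrow = n))
  bs <- apply(matrix(deltas[idx], nrow = n), 2, stats::sd)
  ok <- bs > 0
  if (!any(ok)) stop("all bootstrap resamples degenerate (zero SD)")
  stat <- bm[ok] / bs[ok]
  qs <- stats::quantile(stat, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        type = 7, names = FALSE)
  structure(c(ci_low = qs[1], ci_high = qs[2]),
            n_boot = as.integer(n_boot), n_degenerate = sum(!ok))
}

#' SRM with bootstrap CI as a one-row summary
#'
#' @inheritParams bootstrap_srm_ci
#' @return One-row data.frame: `region`, `measure`, `interval_start`,
#'   `interval_end`, `n`, `mean_change`, `sd_change`, `srm`, `ci_low`,
#'   `ci_high`.
#' @export
srm_with_ci <- function(changes, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(changes, "qm_changes"))
  point <- withCallingHandlers(
    srm(changes),
    qm_degenerate = function(w) invokeRestart("muffleWarning"))
  ci <- c(ci_low = NA_real_, ci_high = NA_real_)
  if (is.finite(point$srm)) {
    ci <- tryCatch(bootstrap_srm_ci(changes, n_boot = n_boot, seed = seed),
                   error = function(e) c(ci_low = NA_real_,
                                         ci_high = NA_real_))
  }
  data.frame(region = changes$region, measure = changes$measure,
             interval_start = changes$interval[1],
             interval_end = changes$interval[2],
             n = changes$n, mean_change = point$mean_change,
             sd_change = point$sd_change, srm = point$srm,
             ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
             stringsAsFactors = FALSE)
}

#' Region-by-measure responsiveness table
#'
#' SRM point estimates with percentile-bootstrap CIs for every subregion,
#' all five measures and each follow-up interval; the longitudinal
#' responsiveness summary. Cells whose change vector is degenerate (zero
#' SD) or empty are reported as `NA` ("n/a" when formatted).
#'
#' @param scores A `qm_scores` table covering all visits.
#' @param moaks A `qm_moaks` table covering all visits.
#' @param intervals List of length-2 intervals (default
#'   `list(c(0, 12), c(0, 24))`).
#' @param measures Measures to include.
#' @param n_boot,seed Bootstrap settings.
#' @param within_grade Passed to [paired_change()].
#' @return data.frame with one row per region x measure x interval.
#' @export
responsiveness_table <- function(scores, moaks,
                                 intervals = list(c(0L, 12L), c(0L, 24L)),
                                 measures = c("ThMCM", "dMCM", "ThQCM%",
                                              "dQCM%", "ThCtAB"),
                                 n_boot = 1000L, seed = 1L,
                                 within_grade = "direct") {
  rows <- list()
  cell_seed <- 0L
  for (iv in intervals) {
    for (rg in region_codes()) {
      for (ms in measures) {
        cell_seed <- cell_seed + 1L
        row <- tryCatch({
          ch <- paired_change(scores = scores, moaks = moaks, measure = ms,
                              region = rg, interval = iv,
                              within_grade = within_grade)
          srm_with_ci(ch, n_boot = n_boot,
                      seed = substream_seed(seed, cell_seed, salt = 5L))
        }, error = function(e) {
          data.frame(region = rg, measure = ms, interval_start = iv[1],
                     interval_end = iv[2], n = 0L, mean_change = NA_real_,
                     sd_change = NA_real_, srm = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format an SRM cell as "SRM (low, high)" or "n/a"
#'
#' @param srm,ci_low,ci_high Numeric vectors (NA allowed).
#' @param digits Decimal places (default 2).
#' @return Character vector.
#' @export
format_srm_cell <- function(srm, ci_low, ci_high, digits = 2) {
  ifelse(is.na(srm), "n/a",
         sprintf("%.*f (%.*f, %.*f)", digits, srm, digits, ci_low,
                 digits, ci_high))
}
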