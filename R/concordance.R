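#' Cross-tabulate semi-quantitative against quantitative scores
#'
#' @param moaks_score,qmoaks_score Paired ordinal scores in `{0, 1, 2, 3}`
#'   (within-grade codes are follow-up change markers, not states, and are
#'   not permitted here). May be empty.
#' @param region,measure Optional labels carried as attributes.
#' @return A `qm_crosstab`: 4x4 integer matrix (rows = semi-quantitative
#'   score 0-3, cols = quantitative score 0-3) with attributes `region`,
#'   `measure` and `n`.
#' @export
crosstab <- function(moaks_score, qmoaks_score, region = NA, measure = NA) {
  if (length(moaks_score) != length(qmoaks_score)) {
    stop("paired score vectors must have equal length")
  }
  ok <- function(s) all(s %in% c(0, 1, 2, 3))
  if (!ok(moaks_score) || !ok(qmoaks_score)) {
    stop("scores must be whole grades in {0,1,2,3}")
  }
  counts <- table(factor(moaks_score, levels = 0:3),
                  factor(qmoaks_score, levels = 0:3))
  m <- matrix(as.integer(counts), 4, 4,
              dimnames = list(moaks = 0:3, qmoaks = 0:3))
  structure(m, region = region, measure = measure, n = length(moaks_score),
            class = c("qm_crosstab", "matrix", "array"))
}

#' Expand a cross-tabulation back into paired scores
#'
#' @param tab A `qm_crosstab`.
#' @return data.frame with columns `moaks_score`, `qmoaks_score`, one row
#'   per original pair (deterministic order: row-major over the table).
#' @export
expand_crosstab <- function(tab) {
  stopifnot(inherits(tab, "qm_crosstab"))
  idx <- which(tab > 0, arr.ind = TRUE)
  n <- tab[tab > 0]
  data.frame(moaks_score = rep(idx[, 1] - 1L, n),
             qmoaks_score = rep(idx[, 2] - 1L, n))
}

#' Row-wise concordance proportion
#'
#' The proportion of knees with a given semi-quantitative score that fall
#' in a given quantitative score column.
#'
#' @param tab A `qm_crosstab`.
#' @param row,col Scores in `{0, 1, 2, 3}` (row = semi-quantitative).
#' @return Proportion in `[0, 1]`.
#' @export
row_concordance <- function(tab, row, col) {
  stopifnot(inherits(tab, "qm_crosstab"),
            row %in% 0:3, col %in% 0:3)
  rt <- sum(tab[row + 1, ])
  if (rt == 0) stop("row ", row, " has zero total; proportion undefined")
  tab[row + 1, col + 1] / rt
}

# Midranks of a vector: for each tied group, the average of the ranks the
# group occupies. Computed from counts rather than sorting, so it applies
# unchanged to weighted/ordinal data.
midranks <- function(x) {
  ux <- sort(unique(x))
  cnt <- vapply(ux, function(u) sum(x == u), numeric(1))
  below <- cumsum(c(0, cnt[-length(cnt)]))
  mr <- below + (cnt + 1) / 2
  mr[match(x, ux)]
}

#' Tie-corrected Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of midranks, which
#' is the standard tie correction for heavily tied ordinal data. Can be
#' called on two paired vectors or directly on a `qm_crosstab` (the
#' correlation is then computed from the counts without materialising the
#' pair list).
#'
#' @param x Numeric/ordinal vector, or a `qm_crosstab`.
#' @param y Paired vector (ignored for crosstabs).
#' @return rho in `[-1, 1]`, or `NA` with a warning of class
#'   `qm_degenerate` when either margin has zero variance.
#' @export
spearman_midrank <- function(x, y = NULL) {
  UseMethod("spearman_midrank")
}

#' @export
spearman_midrank.default <- function(x, y = NULL) {
  if (is.null(y) || length(x) != length(y)) {
    stop("need two paired vectors of equal length")
  }
  if (length(x) < 3) stop("need n >= 3 pairs")
  rx <- midranks(x); ry <- midranks(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    warning(warningCondition("zero variance in a margin; rho undefined",
                             class = "qm_degenerate"))
    return(NA_real_)
  }
  sum(dx * dy) / sqrt(sx * sy)
}

#' @export
spearman_midrank.qm_crosstab <- function(x, y = NULL) {
  n <- sum(x)
  if (n < 3) stop("need n >= 3 pairs")
  # Midrank of each ordinal level from the margin counts.
  margin_mid <- function(cnt) {
    below <- cumsum(c(0, cnt[-length(cnt)]))
    below + (cnt + 1) / 2
  }
  rmid <- margin_mid(rowSums(x))
  cmid <- margin_mid(colSums(x))
  w <- as.numeric(x)
  rx <- rep(rmid, times = 4); ry <- rep(cmid, each = 4)
  mx <- sum(w * rx) / n; my <- sum(w * ry) / n
  sx <- sum(w * (rx - mx)^2); sy <- sum(w * (ry - my)^2)
  if (sx == 0 || sy == 0) {
    warning(warningCondition("zero variance in a margin; rho undefined",
                             class = "qm_degenerate"))
    return(NA_real_)
  }
  sum(w * (rx - mx) * (ry - my)) / sqrt(sx * sy)
}

#' Fisher-z confidence interval for Spearman's rho
#'
#' `tanh(atanh(rho) +/- z * sqrt(1 / (n - 3)))` with `z` the standard
#' normal quantile for the requested confidence level.
#'
#' @param rho Correlation with `|rho| < 1`.
#' @param n Number of pairs (>= 4).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low = , ci_high = )`.
#' @export
spearman_ci <- function(rho, n, conf = 0.95) {
  if (n < 4) stop("need n >= 4 for a Fisher-z interval")
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("|rho| must be strictly below 1")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z / sqrt(n - 3)
  c(ci_low = tanh(atanh(rho) - half), ci_high = tanh(atanh(rho) + half))
}

#' Region-by-measure correlation table
#'
#' Joins quantitative scores and semi-quantitative records at one visit
#' and computes the tie-corrected Spearman correlation with Fisher-z CI
#' for every subregion and both measures. Regions with a degenerate margin
#' (e.g. a region never scored above 0) are reported as `NA`.
#'
#' @param scores A `qm_scores` table.
#' @param moaks A `qm_moaks` table.
#' @param visit_month Visit to analyse (default 0).
#' @return data.frame: `region`, `measure`, `rho`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
correlation_table <- function(scores, moaks, visit_month = 0L) {
  out <- list()
  for (rg in region_codes()) {
    for (ms in c("ThMCM", "dMCM")) {
      qcol <- if (ms == "ThMCM") "thqcm_score" else "dqcm_score"
      sq <- moaks[moaks$region == rg & moaks$measure == ms &
                    moaks$visit_month == visit_month, ]
      qd <- scores[scores$region == rg &
                     scores$visit_month == visit_month, ]
      j <- merge(sq[, c("knee_id", "score")],
                 qd[, c("knee_id", qcol)], by = "knee_id")
      rho <- NA_real_; ci <- c(ci_low = NA_real_, ci_high = NA_real_)
      if (nrow(j) >= 3) {
        rho <- withCallingHandlers(
          spearman_midrank(j$score, j[[qcol]]),
          qm_degenerate = function(w) invokeRestart("muffleWarning"))
        if (is.finite(rho) && abs(rho) < 1 && nrow(j) >= 4) {
          ci <- spearman_ci(rho, nrow(j))
        }
      }
      out[[paste(rg, ms)]] <- data.frame(
        region = rg, measure = ms, rho = rho,
        ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]], n = nrow(j),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tidy data for score-vs-percentage boxplots
#'
#' One row per knee at the requested visit: the reported semi-quantitative
#' score alongside the quantitative area percentage for the same region,
#' for plotting the distribution of measured percentages within each
#' reported grade. The banding thresholds (0, 10, 75) are attached as the
#' `thresholds` attribute for reference lines.
#'
#' @param scores A `qm_scores` table.
#' @param moaks A `qm_moaks` table.
#' @param region Subregion code.
#' @param measure `"ThMCM"` or `"dMCM"`.
#' @param visit_month Visit to analyse (default 0).
#' @return data.frame: `knee_id`, `visit_month`, `moaks_score`,
#'   `qmoaks_pct`.
#' @export
boxplot_export <- function(scores, moaks, region, measure,
                           visit_month = 0L) {
  stopifnot(region %in% region_codes(), measure %in% c("ThMCM", "dMCM"))
  pcol <- if (measure == "ThMCM") "thqcm_pct" else "dqcm_pct"
  sq <- moaks[moaks$region == region & moaks$measure == measure &
                moaks$visit_month == visit_month, ]
  qd <- scores[scores$region == region &
                 scores$visit_month == visit_month, ]
  j <- merge(sq[, c("knee_id", "score")],
             qd[, c("knee_id", pcol)], by = "knee_id")
  unmatched <- setdiff(sq$knee_id, j$knee_id)
  if (length(unmatched) > 0) {
    stop("no quantitative result for knee(s): ",
         paste(utils::head(unmatched, 5), collapse = ", "))
  }
  out <- data.frame(knee_id = j$knee_id, visit_month = visit_month,
                    moaks_score = j$score, qmoaks_pct = j[[pcol]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$knee_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(0, 10, 75)
  out
}

#' Published reference cross-tabulations
#'
#' Cross-tabulations of radiologist semi-quantitative scores against
#' quantitative Q-MOAKS scores for the central medial femur and tibia in
#' 297 knees of a radiographic-progression cohort, as published. Shipped
#' as a plain-text fixture; used to reproduce the published concordance
#' statistics.
#'
#' @param path CSV path; defaults to the bundled copy.
#' @return Named list of `qm_crosstab` objects keyed `"<region>_<measure>"`.
#' @export
published_crosstabs <- function(path = system.file("extdata",
                                                   "published_crosstabs.csv",
                                                   package = "qmoaks")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$region, df$measure, sep = "_"))) {
    sub <- df[paste(df$region, df$measure, sep = "_") == key, ]
    m <- matrix(0L, 4, 4, dimnames = list(moaks = 0:3, qmoaks = 0:3))
    m[cbind(sub$moaks_score + 1, sub$qmoaks_score + 1)] <-
      as.integer(sub$count)
    out[[key]] <- structure(m, region = sub$region[1],
                            measure = sub$measure[1], n = sum(m),
                            class = c("qm_crosstab", "matrix", "array"))
  }
  out
}
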