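#' Construct a thickness cohort
#'
#' A thickness cohort holds one per-landmark cartilage thickness map (mm,
#' measured orthogonal to the bone surface at each corresponded landmark)
#' per knee-visit, as a landmarks-by-samples matrix aligned to an atlas.
#'
#' @param values Numeric matrix, `nrow(atlas)` rows (landmarks, in atlas
#'   order) by one column per knee-visit. All values finite and >= 0.
#' @param knee_id Character vector, one per column.
#' @param visit_month Integer vector, one per column; must lie in `visits`.
#' @param atlas A [qm_atlas()] object.
#' @param visits Allowed visit months (default 0, 12, 24).
#' @return An object of class `qm_thickness`: list with elements `values`,
#'   `samples` (data.frame `knee_id`, `visit_month`) and `atlas`. Columns
#'   are ordered deterministically by (knee_id, visit_month).
#' @export
qm_thickness <- function(values, knee_id, visit_month, atlas,
                         visits = c(0L, 12L, 24L)) {
  stopifnot(inherits(atlas, "qm_atlas"))
  values <- as.matrix(values)
  if (nrow(values) != nrow(atlas)) {
    stop("thickness has ", nrow(values), " landmarks but atlas has ",
         nrow(atlas))
  }
  if (ncol(values) != length(knee_id) || ncol(values) != length(visit_month)) {
    stop("one knee_id and visit_month required per thickness column")
  }
  if (any(!is.finite(values))) stop("thickness values must be finite")
  if (any(values < 0)) stop("negative thickness values are not allowed")
  visit_month <- as.integer(visit_month)
  if (!all(visit_month %in% as.integer(visits))) {
    stop("visit_month outside configured visit set {",
         paste(visits, collapse = ", "), "}")
  }
  key <- paste(as.character(knee_id), visit_month)
  if (anyDuplicated(key)) stop("duplicate (knee_id, visit_month) pair")
  ord <- order(as.character(knee_id), visit_month)
  obj <- list(
    values = values[, ord, drop = FALSE],
    samples = data.frame(knee_id = as.character(knee_id)[ord],
                         visit_month = visit_month[ord],
                         stringsAsFactors = FALSE),
    atlas = atlas,
    visits = as.integer(visits)
  )
  colnames(obj$values) <- paste(obj$samples$knee_id, obj$samples$visit_month,
                                sep = "@")
  class(obj) <- "qm_thickness"
  obj
}

#' @export
print.qm_thickness <- function(x, ...) {
  cat("<qm_thickness> ", nrow(x$values), " landmarks x ", ncol(x$values),
      " knee-visits (", length(unique(x$samples$knee_id)), " knees)\n",
      sep = "")
  invisible(x)
}

#' Number of knee-visit maps in a cohort
#' @param x A `qm_thickness` object.
#' @return Integer count of columns (knee-visit maps).
#' @export
n_maps <- function(x) {
  stopifnot(inherits(x, "qm_thickness"))
  ncol(x$values)
}

#' Extract one knee-visit thickness map
#'
#' @param x A `qm_thickness` cohort.
#' @param knee_id Knee identifier.
#' @param visit_month Visit month.
#' @return Numeric vector of per-landmark thickness (mm), atlas order.
#' @export
thickness_map <- function(x, knee_id, visit_month) {
  stopifnot(inherits(x, "qm_thickness"))
  j <- which(x$samples$knee_id == knee_id &
               x$samples$visit_month == as.integer(visit_month))
  if (length(j) != 1) {
    stop("no thickness map for knee ", knee_id, " visit ", visit_month)
  }
  x$values[, j]
}

#' Read a long-format thickness table
#'
#' Columns: `knee_id`, `visit_month`, `landmark_id`, `thickness_mm`. Every
#' (knee, visit) must cover the full atlas landmark set exactly once.
#'
#' @param path CSV file path.
#' @param atlas A [qm_atlas()] object the table must conform to.
#' @param visits Allowed visit months.
#' @return A `qm_thickness` cohort, ordered by (knee_id, visit_month).
#' @export
load_thickness_table <- function(path, atlas, visits = c(0L, 12L, 24L)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("knee_id", "visit_month", "landmark_id", "thickness_mm")
  if (!all(need %in% names(df))) {
    stop("thickness CSV must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$thickness_mm)) || any(df$thickness_mm < 0)) {
    stop("negative or non-finite thickness_mm in ", path)
  }
  key <- paste(df$knee_id, df$visit_month)
  groups <- split(seq_len(nrow(df)), key)
  lm_pos <- match(df$landmark_id, atlas$landmark_id)
  if (anyNA(lm_pos)) {
    stop("landmark_id not in atlas: ",
         paste(utils::head(unique(df$landmark_id[is.na(lm_pos)]), 5),
               collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(atlas), length(groups))
  kid <- character(length(groups)); vm <- integer(length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    pos <- lm_pos[rows]
    if (anyDuplicated(pos) || length(pos) != nrow(atlas)) {
      missing <- setdiff(seq_len(nrow(atlas)), pos)
      stop("knee ", df$knee_id[rows[1]], " visit ", df$visit_month[rows[1]],
           ": landmark coverage incomplete (missing landmark_id ",
           paste(utils::head(atlas$landmark_id[missing], 5), collapse = ", "),
           ")")
    }
    vals[pos, g] <- df$thickness_mm[rows]
    kid[g] <- as.character(df$knee_id[rows[1]])
    vm[g] <- as.integer(df$visit_month[rows[1]])
  }
  qm_thickness(vals, kid, vm, atlas, visits = visits)
}

#' Write a thickness cohort as a long-format CSV
#'
#' Values are written with 6 decimal places; a write-read round trip is
#' exact at that declared precision.
#'
#' @param x A `qm_thickness` cohort.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_thickness_table <- function(x, path) {
  stopifnot(inherits(x, "qm_thickness"))
  L <- nrow(x$values); S <- ncol(x$values)
  out <- data.frame(
    knee_id = rep(x$samples$knee_id, each = L),
    visit_month = rep(x$samples$visit_month, each = L),
    landmark_id = rep(x$atlas$landmark_id, times = S),
    thickness_mm = sprintf("%.6f", as.vector(x$values))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate and construct semi-quantitative score records
#'
#' Scores are the ordinal 0-3 MOAKS cartilage morphology grades. At
#' follow-up visits only, the special codes +0.5 (within-grade worsening:
#' definite structural worsening without a whole-grade transition) and -0.5
#' (within-grade improvement) are additionally allowed.
#'
#' @param knee_id,visit_month,region,measure,score Record fields; `measure`
#'   is "ThMCM" (area of any thickness loss) or "dMCM" (denuded area).
#' @param baseline_month Visit month regarded as baseline (default 0).
#' @return A data.frame of class `qm_moaks`, ordered by
#'   (knee_id, visit_month, region, measure).
#' @export
qm_moaks <- function(knee_id, visit_month, region, measure, score,
                     baseline_month = 0L) {
  visit_month <- as.integer(visit_month)
  score <- as.numeric(score)
  if (!all(region %in% region_codes())) {
    stop("unknown region code(s): ",
         paste(unique(region[!region %in% region_codes()]), collapse = ", "))
  }
  if (!all(measure %in% c("ThMCM", "dMCM"))) {
    stop("measure must be ThMCM or dMCM")
  }
  ok_base <- score %in% c(0, 1, 2, 3)
  ok_follow <- ok_base | score %in% c(0.5, -0.5)
  is_base <- visit_month == as.integer(baseline_month)
  if (any(is_base & !ok_base)) {
    i <- which(is_base & !ok_base)[1]
    stop("within-grade value at baseline (knee ", knee_id[i], ", score ",
         score[i], "); baseline scores must be in {0,1,2,3}")
  }
  if (any(!is_base & !ok_follow)) {
    i <- which(!is_base & !ok_follow)[1]
    stop("invalid score ", score[i], " (knee ", knee_id[i],
         "); allowed: 0,1,2,3 and, at follow-up, 0.5/-0.5")
  }
  df <- data.frame(knee_id = as.character(knee_id),
                   visit_month = visit_month,
                   region = as.character(region),
                   measure = as.character(measure),
                   score = score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$knee_id, df$visit_month, df$region, df$measure), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("qm_moaks", "data.frame")
  df
}

#' Read a semi-quantitative score table from CSV
#'
#' Columns: `knee_id`, `visit_month`, `region`, `measure`, `score`.
#'
#' @inheritParams qm_moaks
#' @param path CSV file path.
#' @return A validated `qm_moaks` data.frame.
#' @export
load_moaks_table <- function(path, baseline_month = 0L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("knee_id", "visit_month", "region", "measure", "score")
  if (!all(need %in% names(df))) {
    stop("score CSV must have columns ", paste(need, collapse = ", "))
  }
  qm_moaks(df$knee_id, df$visit_month, df$region, df$measure, df$score,
           baseline_month = baseline_month)
}

#' Write a semi-quantitative score table to CSV
#' @param x A `qm_moaks` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_moaks_table <- function(x, path) {
  stopifnot(inherits(x, "qm_moaks"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
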