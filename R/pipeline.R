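#' Read and validate a run configuration
#'
#' The configuration is a single JSON file. Recognised keys:
#' \describe{
#'   \item{simulate}{Optional block: `n_controls`, `n_progressors`,
#'     `visits`, `seed`, and optional `field`, `lesion`, `reader`
#'     parameter blocks. When present, the pipeline generates its own
#'     inputs.}
#'   \item{atlas, controls, thickness, moaks}{Input CSV paths (used when
#'     `simulate` is absent).}
#'   \item{normative}{`mode`, `loss_fraction`, `denudation_fraction`,
#'     `min_normative_mm`.}
#'   \item{banding}{Must be `"none_zero_left_open"` (the only supported
#'     convention; validated fail-fast).}
#'   \item{concordance_visit}{Visit month for cross-sectional analyses.}
#'   \item{intervals}{List of `[baseline, follow-up]` month pairs.}
#'   \item{n_boot, seed}{Bootstrap settings.}
#' }
#'
#' @param path JSON file path, or a list already parsed.
#' @return Validated configuration list of class `qm_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  defaults <- list(banding = "none_zero_left_open", concordance_visit = 0L,
                   intervals = list(c(0L, 12L), c(0L, 24L)),
                   n_boot = 1000L, seed = 1L,
                   normative = list(mode = "fraction_of_mean",
                                    loss_fraction = 0.95,
                                    denudation_fraction = 0.05,
                                    min_normative_mm = 0.1))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!identical(cfg$banding, "none_zero_left_open")) {
    stop("unknown banding convention '", cfg$banding,
         "'; supported: none_zero_left_open")
  }
  if (is.matrix(cfg$intervals)) {
    cfg$intervals <- lapply(seq_len(nrow(cfg$intervals)),
                            function(i) cfg$intervals[i, ])
  }
  if (is.null(cfg$simulate)) {
    for (k in c("atlas", "controls", "thickness", "moaks")) {
      if (is.null(cfg[[k]])) stop("config key '", k, "' required when not ",
                                  "simulating")
      if (!file.exists(cfg[[k]])) stop("input file not found: ", cfg[[k]])
    }
  }
  class(cfg) <- c("qm_config", "list")
  cfg
}

# Tiny FNV-1a over a string; enough to fingerprint a config in a manifest.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> normative build -> scoring ->
#' concordance -> responsiveness, writing all report tables plus a run
#' manifest to `out_dir`. Outputs: `qmoaks_results.csv`,
#' `normative_model.json`, `crosstab.csv`, `correlations.csv`,
#' `boxplot_data.csv`, `srm_table.csv`, `manifest.json` (and, when
#' simulating, the generated `atlas.csv`, `controls.csv`, `thickness.csv`,
#' `moaks.csv`, `ground_truth.csv`).
#'
#' @param config Path to a JSON config or a list (see
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with the in-memory `scores`,
#'   `correlations`, `srm_table` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    fp <- do.call(field_params, if (is.null(sim$field)) list()
                  else sim$field)
    lp <- do.call(lesion_params, if (is.null(sim$lesion)) list()
                  else sim$lesion)
    rp <- do.call(reader_params, if (is.null(sim$reader)) list()
                  else sim$reader)
    visits <- if (is.null(sim$visits)) c(0L, 12L, 24L)
              else as.integer(sim$visits)
    sim_seed <- if (is.null(sim$seed)) cfg$seed else as.integer(sim$seed)
    atlas <- make_grid_atlas(fp$grid_shape)
    # controls and progressors share one population normative field
    field <- make_mean_field(atlas, fp, sim_seed)
    ctrl <- generate_controls(sim$n_controls, atlas, fp, seed = sim_seed,
                              field = field)
    prog <- generate_progression_cohort(sim$n_progressors, atlas, fp, lp,
                                        visits = visits,
                                        seed = sim_seed + 1L,
                                        field = field)
    moaks <- simulate_sq_reader(prog$truth, rp, seed = sim_seed + 2L)
    write_atlas(atlas, path("atlas.csv"))
    write_thickness_table(ctrl$thickness, path("controls.csv"))
    write_thickness_table(prog$thickness, path("thickness.csv"))
    write_moaks_table(moaks, path("moaks.csv"))
    utils::write.csv(prog$truth, path("ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    controls <- ctrl$thickness
    cohort <- prog$thickness
  } else {
    atlas <- load_atlas(cfg$atlas)
    controls <- load_thickness_table(cfg$controls, atlas,
                                     visits = c(0L, 12L, 24L))
    cohort <- load_thickness_table(cfg$thickness, atlas,
                                   visits = c(0L, 12L, 24L))
    moaks <- load_moaks_table(cfg$moaks)
  }

  ncfg <- normative_config(mode = cfg$normative$mode,
                           loss_fraction = cfg$normative$loss_fraction,
                           denudation_fraction =
                             cfg$normative$denudation_fraction,
                           min_normative_mm =
                             cfg$normative$min_normative_mm)
  model <- build_normative(controls, atlas, ncfg)
  write_normative_json(model, path("normative_model.json"))

  scores <- score_cohort(cohort, model)
  write_scores(scores, path("qmoaks_results.csv"))

  cv <- cfg$concordance_visit
  tabs <- list()
  for (rg in c("cMF", "cMT")) {
    for (ms in c("ThMCM", "dMCM")) {
      qcol <- if (ms == "ThMCM") "thqcm_score" else "dqcm_score"
      sq <- moaks[moaks$region == rg & moaks$measure == ms &
                    moaks$visit_month == cv, ]
      qd <- scores[scores$region == rg & scores$visit_month == cv, ]
      j <- merge(sq[, c("knee_id", "score")],
                 qd[, c("knee_id", qcol)], by = "knee_id")
      if (nrow(j) > 0 && all(j$score %in% 0:3)) {
        tabs[[paste(rg, ms, sep = "_")]] <-
          crosstab(j$score, j[[qcol]], region = rg, measure = ms)
      }
    }
  }
  tab_rows <- do.call(rbind, lapply(names(tabs), function(key) {
    tb <- tabs[[key]]
    idx <- expand.grid(moaks_score = 0:3, qmoaks_score = 0:3)
    data.frame(region = attr(tb, "region"), measure = attr(tb, "measure"),
               idx, count = as.integer(tb[cbind(idx$moaks_score + 1,
                                                idx$qmoaks_score + 1)]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab_rows, path("crosstab.csv"), row.names = FALSE,
                   quote = FALSE)

  corr <- correlation_table(scores, moaks, visit_month = cv)
  utils::write.csv(corr, path("correlations.csv"), row.names = FALSE,
                   quote = FALSE)

  box <- do.call(rbind, lapply(c("cMF", "cMT"), function(rg) {
    do.call(rbind, lapply(c("ThMCM", "dMCM"), function(ms) {
      b <- boxplot_export(scores, moaks, rg, ms, visit_month = cv)
      cbind(region = rg, measure = ms, b)
    }))
  }))
  utils::write.csv(box, path("boxplot_data.csv"), row.names = FALSE,
                   quote = FALSE)

  srm_tab <- responsiveness_table(scores, moaks,
                                  intervals = cfg$intervals,
                                  n_boot = cfg$n_boot, seed = cfg$seed)
  utils::write.csv(srm_tab, path("srm_table.csv"), row.names = FALSE,
                   quote = FALSE)

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "qmoaks",
    version = as.character(utils::packageVersion("qmoaks")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = fnv1a(as.character(cfg_json)),
    config = unclass(cfg),
    outputs = c("normative_model.json", "qmoaks_results.csv",
                "crosstab.csv", "correlations.csv", "boxplot_data.csv",
                "srm_table.csv")
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(scores = scores, crosstabs = tabs, correlations = corr,
                 srm_table = srm_tab, manifest = manifest))
}
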