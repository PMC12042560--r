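# Shared in-code fixtures. Everything is generated; no binary files.

# Minimal atlas: one landmark per region.
tiny_atlas <- function() {
  qm_atlas(landmark_id = 0:9, region = region_codes())
}

# Small grid atlas used by most synthetic tests (10 regions x 20 landmarks).
small_atlas <- function() make_grid_atlas(c(5L, 4L))

# A normative model with constant normative mean, built directly from a
# two-knee constant control cohort.
constant_model <- function(mean_mm = 2, atlas = tiny_atlas(), ...) {
  vals <- matrix(mean_mm, nrow(atlas), 2)
  ctrl <- qm_thickness(vals, c("c1", "c2"), c(0L, 0L), atlas)
  build_normative(ctrl, atlas, normative_config(...))
}

# Brute-force per-landmark enumeration oracle for region percentages:
# no vectorisation, no shared code with region_percents.
oracle_region_percents <- function(map, model, region) {
  atlas <- model$atlas
  num_th <- num_d <- den <- 0
  for (i in seq_len(nrow(atlas))) {
    if (as.character(atlas$region[i]) != region) next
    if (!model$included[i]) next
    th <- thresholds_at(model, atlas$landmark_id[i])
    w <- atlas$area_weight[i]
    den <- den + w
    if (map[i] < th$loss_threshold_mm) num_th <- num_th + w
    if (map[i] < th$denudation_threshold_mm) num_d <- num_d + w
  }
  c(thqcm_pct = 100 * num_th / den, dqcm_pct = 100 * num_d / den)
}

# Write a data.frame to a temp CSV and return the path.
tmp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}
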