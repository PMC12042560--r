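test_that("landmark classification uses strict thresholds", {
  model <- constant_model(2) # thresholds 1.9 / 0.1
  expect_equal(classify_landmark(1.5, model, 0L), "thinned")
  expect_equal(classify_landmark(0.05, model, 0L), "denuded")
  expect_equal(classify_landmark(1.90, model, 0L), "normal") # strict <
  expect_equal(classify_landmark(0.10, model, 0L), "thinned") # strict <
  expect_equal(classify_landmark(2.2, model, 0L), "normal")
  # excluded landmarks must be masked by the caller
  atlas <- tiny_atlas()
  vals <- matrix(2, 10, 2); vals[1, ] <- 0.01
  ctrl <- qm_thickness(vals, c("a", "b"), c(0L, 0L), atlas)
  mex <- build_normative(ctrl, atlas)
  expect_error(classify_landmark(1.0, mex, atlas$landmark_id[1]),
               "excluded")
})

test_that("banding follows the none/0-10/10-75/>75 convention", {
  expect_identical(band(0), 0L)
  expect_identical(band(50), 2L)
  # boundary table: left-open/right-closed, 0 reserved for exactly none
  expect_identical(band(c(0, 1e-9, 10, 10.0001, 75, 75.01, 100)),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(band(-1), "\\[0, 100\\]")
  expect_error(band(100.5), "\\[0, 100\\]")
  expect_error(band(NaN), "finite")
  # monotone non-decreasing in pct
  pct <- sort(stats::runif(100, 0, 100))
  expect_true(all(diff(band(pct)) >= 0))
})

test_that("region percentages count areas with and without weights", {
  # 20 uniform landmarks in cMF (5x4 grid), 7 thinned
  atlas <- small_atlas()
  model <- constant_model(2, atlas)
  map <- rep(2, nrow(atlas))
  idx <- region_landmarks(atlas, "cMF")
  map[idx[1:7]] <- 1.5
  expect_equal(region_percents(map, model, "cMF"),
               c(thqcm_pct = 35, dqcm_pct = 0))
  # weighted: lost landmark w=2, 9 others w=1 -> 100*2/11
  a10 <- qm_atlas(0:9, region_codes(),
                  area_weight = c(2, rep(1, 9)))
  mw <- constant_model(2, a10)
  mapw <- rep(2, 10); mapw[1] <- 0.5 # landmark 0 is in cMF
  expect_equal(region_percents(mapw, mw, "cMF")[["thqcm_pct"]],
               100 * 2 / 2) # cMF has only landmark 0 in the tiny atlas
  # denuded counts toward both percentages
  mapd <- rep(2, nrow(atlas)); mapd[idx[1:3]] <- 0.0
  pc <- region_percents(mapd, model, "cMF")
  expect_equal(pc[["dqcm_pct"]], 15)
  expect_equal(pc[["thqcm_pct"]], 15)
})

test_that("a double-weight lost landmark among ten yields 2/11 of area", {
  # one region populated with 10 landmarks: weight 2 on the lost one
  atlas <- qm_atlas(0:18,
                    c(rep("cMF", 10), region_codes()[-1]),
                    area_weight = c(2, rep(1, 18)))
  model <- constant_model(2, atlas)
  map <- rep(2, 19); map[1] <- 1.0
  expect_equal(region_percents(map, model, "cMF")[["thqcm_pct"]],
               100 * 2 / 11)
})

test_that("region_percents equals the brute-force oracle on random maps", {
  set.seed(42)
  for (rep in 1:25) {
    w <- stats::runif(10, 0.2, 3)
    atlas <- qm_atlas(0:9, region_codes(), area_weight = w)
    vals <- matrix(stats::runif(20, 0.5, 3), 10, 2)
    ctrl <- qm_thickness(vals, c("a", "b"), c(0L, 0L), atlas)
    model <- build_normative(ctrl, atlas)
    map <- stats::runif(10, 0, 3)
    for (rg in c("cMF", "cMT", "pLT")) {
      expect_identical(region_percents(map, model, rg),
                       oracle_region_percents(map, model, rg))
    }
  }
})

test_that("all-excluded regions raise the no-cover error", {
  atlas <- tiny_atlas()
  vals <- matrix(2, 10, 2)
  vals[region_landmarks(atlas, "aLT"), ] <- 0.01
  ctrl <- qm_thickness(vals, c("a", "b"), c(0L, 0L), atlas)
  model <- build_normative(ctrl, atlas)
  expect_error(region_percents(rep(1, 10), model, "aLT"),
               "no normative cartilage cover")
})

test_that("thctab is the (weighted) regional mean over all landmarks", {
  atlas <- qm_atlas(0:11, c(rep("cMF", 3), region_codes()[-1]),
                    area_weight = 1)
  map <- c(1, 2, 3, rep(9, 9))
  expect_equal(thctab(map, atlas, "cMF"), 2.0)
  # all-zero region -> 0 (fully denuded limit)
  expect_equal(thctab(rep(0, 12), atlas, "cMF"), 0.0)
  # weighted {1 w=1, 3 w=3} -> 2.5
  aw <- qm_atlas(0:10, c(rep("cMF", 2), region_codes()[-1]),
                 area_weight = c(1, 3, rep(1, 9)))
  expect_equal(thctab(c(1, 3, rep(9, 9)), aw, "cMF"), 2.5)
  # masked variant drops model-excluded landmarks
  vals <- matrix(2, 12, 2); vals[1, ] <- 0.01
  ctrl <- qm_thickness(vals, c("a", "b"), c(0L, 0L), atlas)
  model <- build_normative(ctrl, atlas)
  expect_equal(thctab(map, atlas, "cMF", model, masked = TRUE), 2.5)
})

test_that("score_cohort emits one consistent row per knee-visit-region", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L))
  field <- make_mean_field(atlas, fp, seed = 3)
  ctrl <- generate_controls(30, atlas, fp, seed = 3, field = field)
  model <- build_normative(ctrl$thickness)
  prog <- generate_progression_cohort(7, atlas, fp, lesion_params(),
                                      seed = 5, field = field)
  sc <- score_cohort(prog$thickness, model)
  expect_equal(nrow(sc), 7 * 3 * 10)
  expect_true(all(sc$dqcm_pct <= sc$thqcm_pct + 1e-12))
  expect_identical(sc$thqcm_score, band(sc$thqcm_pct))
  expect_identical(sc$dqcm_score, band(sc$dqcm_pct))
  # spot-check one cell against the single-map API
  row <- sc[17, ]
  map <- thickness_map(prog$thickness, row$knee_id, row$visit_month)
  expect_equal(row$thqcm_pct,
               region_percents(map, model, row$region)[["thqcm_pct"]])
  expect_equal(row$thctab_mm, thctab(map, atlas, row$region))
})

test_that("banding and percentages are invariant to weight rescaling", {
  set.seed(7)
  w <- stats::runif(10, 0.5, 2)
  base <- qm_atlas(0:9, region_codes(), area_weight = w)
  scaled <- qm_atlas(0:9, region_codes(), area_weight = 3.7 * w)
  vals <- matrix(stats::runif(20, 0.5, 3), 10, 2)
  m1 <- build_normative(qm_thickness(vals, c("a", "b"), c(0L, 0L), base),
                        base)
  m2 <- build_normative(qm_thickness(vals, c("a", "b"), c(0L, 0L), scaled),
                        scaled)
  map <- stats::runif(10, 0, 3)
  for (rg in region_codes()) {
    expect_equal(region_percents(map, m1, rg),
                 region_percents(map, m2, rg))
  }
})

test_that("pointwise thinning never improves any score component", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L))
  ctrl <- generate_controls(20, atlas, fp, seed = 15)
  model <- build_normative(ctrl$thickness)
  set.seed(99)
  map <- generate_controls(1, atlas, fp, seed = 77)$thickness$values[, 1]
  for (rep in 1:10) {
    shrink <- map * stats::runif(length(map), 0.3, 1) # pointwise decrease
    for (rg in c("cMF", "cMT", "pLF")) {
      before <- region_percents(map, model, rg)
      after <- region_percents(shrink, model, rg)
      expect_gte(after[["thqcm_pct"]], before[["thqcm_pct"]])
      expect_gte(after[["dqcm_pct"]], before[["dqcm_pct"]])
      expect_lte(thctab(shrink, atlas, rg), thctab(map, atlas, rg))
    }
  }
})

test_that("numeric change resolves whole grades and within-grade codes", {
  expect_equal(moaks_numeric_change(2, 3), 1)
  expect_equal(moaks_numeric_change(2, 0.5), 0.5)
  expect_equal(moaks_numeric_change(1, -0.5), -0.5)
  expect_equal(moaks_numeric_change(3, 1), -2)
  expect_equal(moaks_numeric_change(c(0, 2), c(0.5, 2)), c(0.5, 0))
  expect_error(moaks_numeric_change(2.5, 3), "whole grade")
  expect_error(moaks_numeric_change(2, 4), "followup_record")
})
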