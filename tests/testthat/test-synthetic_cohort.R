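test_that("mean field is smooth, bounded, and deterministic", {
  atlas <- small_atlas()
  # degenerate smoothness: zero amplitude -> constant at base_mean
  f0 <- make_mean_field(atlas, field_params(grid_shape = c(5L, 4L),
                                            spatial_amplitude = 0),
                        seed = 3)
  expect_equal(f0, rep(2.2, nrow(atlas)))
  # default amplitude 0.3 around 2.2 -> everything in [1.9, 2.5]
  f <- make_mean_field(atlas, field_params(grid_shape = c(5L, 4L)), seed = 3)
  expect_true(all(f >= 1.9 - 1e-12 & f <= 2.5 + 1e-12))
  # determinism
  expect_identical(f, make_mean_field(atlas,
                                      field_params(grid_shape = c(5L, 4L)),
                                      seed = 3))
  expect_false(identical(f, make_mean_field(
    atlas, field_params(grid_shape = c(5L, 4L)), seed = 4)))
})

test_that("controls reduce to the truth field in the noise-free limit", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L), subject_scale_sd = 0,
                     noise_sd = 0)
  ctrl <- generate_controls(4, atlas, fp, seed = 5)
  for (j in 1:4) {
    expect_equal(ctrl$thickness$values[, j], ctrl$truth_field)
  }
  expect_error(generate_controls(0, atlas, fp, seed = 5), "n must be")
})

test_that("measurement noise is clamped at zero thickness", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L), base_mean = 0.02,
                     spatial_amplitude = 0, subject_scale_sd = 0,
                     noise_sd = 0.05)
  ctrl <- generate_controls(30, atlas, fp, seed = 8)
  expect_true(all(ctrl$thickness$values >= 0))
  expect_true(any(ctrl$thickness$values == 0)) # clamp actually fired
})

test_that("per-knee substreams: growing n never reshuffles earlier knees", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L))
  small <- generate_controls(5, atlas, fp, seed = 12)
  big <- generate_controls(9, atlas, fp, seed = 12)
  expect_identical(small$thickness$values, big$thickness$values[, 1:5])
})

test_that("static lesions give constant ground truth across visits", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L), subject_scale_sd = 0,
                     noise_sd = 0)
  lp <- lesion_params(radius_growth_per_year = 0,
                      depth_growth_per_year = 0)
  prog <- generate_progression_cohort(6, atlas, fp, lp, seed = 2)
  tr <- prog$truth
  for (k in unique(tr$knee_id)) {
    for (rg in region_codes()) {
      sub <- tr[tr$knee_id == k & tr$region == rg, ]
      expect_equal(diff(range(sub$lesion_area_pct)), 0)
      expect_equal(diff(range(sub$denuded_area_pct)), 0)
      expect_equal(diff(range(sub$mean_thickness_mm)), 0)
    }
  }
})

test_that("full-depth flat lesion over a known disc forces exact fractions", {
  atlas <- small_atlas() # 5 x 4 grid, 20 landmarks per region
  fp <- field_params(grid_shape = c(5L, 4L), subject_scale_sd = 0,
                     noise_sd = 0)
  # centre (1,1), radius 2: grid points at distance {0,1,1,sqrt2,2,2}
  # -> exactly 6 of 20 landmarks (30%) inside the disc
  lp <- lesion_params(region_probs = c(cMF = 1), initial_radius = 2,
                      initial_depth_fraction = 1,
                      radius_growth_per_year = 0,
                      depth_growth_per_year = 0,
                      profile = "flat", fixed_center = c(1, 1))
  prog <- generate_progression_cohort(2, atlas, fp, lp,
                                      visits = c(0L, 12L), seed = 4)
  cmf <- prog$truth[prog$truth$region == "cMF", ]
  expect_equal(cmf$denuded_area_pct, rep(30, nrow(cmf)))
  expect_equal(cmf$lesion_area_pct, rep(30, nrow(cmf)))
  expect_equal(cmf$footprint_pct, rep(30, nrow(cmf)))
})

test_that("deeper-only growth: fixed footprint, strictly thinning region", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L), subject_scale_sd = 0,
                     noise_sd = 0)
  lp <- lesion_params(region_probs = c(cMF = 1),
                      initial_depth_fraction = 0.3,
                      radius_growth_per_year = 0,
                      depth_growth_per_year = 0.25)
  prog <- generate_progression_cohort(5, atlas, fp, lp, seed = 9)
  tr <- prog$truth[prog$truth$region == "cMF", ]
  for (k in unique(tr$knee_id)) {
    sub <- tr[tr$knee_id == k, ]
    sub <- sub[order(sub$visit_month), ]
    # geometric footprint is constant when only depth grows
    expect_equal(diff(range(sub$footprint_pct)), 0)
    # mean thickness strictly decreases; threshold-based area cannot shrink
    expect_true(all(diff(sub$mean_thickness_mm) < 0))
    expect_true(all(diff(sub$lesion_area_pct) >= 0))
  }
})

test_that("ground truth is consistent: denuded <= lost, fractions in range", {
  atlas <- small_atlas()
  prog <- generate_progression_cohort(
    8, atlas, field_params(grid_shape = c(5L, 4L)),
    lesion_params(), seed = 21)
  tr <- prog$truth
  expect_true(all(tr$denuded_area_pct <= tr$lesion_area_pct + 1e-12))
  expect_true(all(tr$lesion_area_pct >= 0 & tr$lesion_area_pct <= 100))
  expect_true(all(tr$denuded_area_pct >= 0 & tr$denuded_area_pct <= 100))
  # full generator determinism
  prog2 <- generate_progression_cohort(
    8, atlas, field_params(grid_shape = c(5L, 4L)),
    lesion_params(), seed = 21)
  expect_identical(prog$thickness$values, prog2$thickness$values)
  expect_identical(prog$truth, prog2$truth)
})

test_that("identity reader reports the true bands exactly", {
  atlas <- small_atlas()
  prog <- generate_progression_cohort(
    5, atlas, field_params(grid_shape = c(5L, 4L)), lesion_params(),
    seed = 6)
  moaks <- simulate_sq_reader(prog$truth, reader_params(), seed = 1)
  j <- merge(moaks, prog$truth,
             by = c("knee_id", "visit_month", "region"))
  truth_col <- ifelse(j$measure == "ThMCM", j$lesion_area_pct,
                      j$denuded_area_pct)
  expect_equal(j$score, as.numeric(band(truth_col)))
})

test_that("a confusion matrix shifting band 1 to band 2 is forced through", {
  atlas <- small_atlas()
  prog <- generate_progression_cohort(
    6, atlas, field_params(grid_shape = c(5L, 4L)), lesion_params(),
    seed = 13)
  conf <- diag(4); conf[2, ] <- c(0, 0, 1, 0) # all band-1 mass to band 2
  moaks <- simulate_sq_reader(prog$truth,
                              reader_params(confusion = conf), seed = 2)
  j <- merge(moaks[moaks$measure == "ThMCM", ], prog$truth,
             by = c("knee_id", "visit_month", "region"))
  b <- band(j$lesion_area_pct)
  expect_true(all(j$score[b == 1] == 2))
  expect_equal(j$score[b == 0], rep(0, sum(b == 0)))
})

test_that("reader parameter validation rejects non-stochastic confusion", {
  bad <- diag(4); bad[1, 1] <- 0.7
  expect_error(reader_params(confusion = bad), "row-stochastic")
  expect_error(reader_params(confusion = matrix(1, 3, 3)),
               "row-stochastic")
})

test_that("overcall bias raises the mean reported band (Monte Carlo)", {
  atlas <- small_atlas()
  prog <- generate_progression_cohort(
    25, atlas, field_params(grid_shape = c(5L, 4L)), lesion_params(),
    seed = 30) # 25 knees x 3 visits x 10 regions = 750 region readings
  mean_reported <- function(bias, seed) {
    m <- simulate_sq_reader(prog$truth,
                            reader_params(overcall_bias = bias),
                            seed = seed)
    mean(m$score[m$measure == "ThMCM"])
  }
  truth_mean <- mean(band(prog$truth$lesion_area_pct))
  biased <- mean_reported(0.3, seed = 7)
  expect_gt(biased, truth_mean)
  # and the identity reader sits exactly at the truth mean
  expect_equal(mean_reported(0, seed = 7), truth_mean)
})

test_that("within-grade sensitivity emits +0.5 at eligible follow-ups only", {
  atlas <- small_atlas()
  fp <- field_params(grid_shape = c(5L, 4L), subject_scale_sd = 0,
                     noise_sd = 0)
  lp <- lesion_params(region_probs = c(cMF = 1),
                      initial_depth_fraction = 0.2,
                      radius_growth_per_year = 0,
                      depth_growth_per_year = 0.3)
  prog <- generate_progression_cohort(10, atlas, fp, lp, seed = 17)
  moaks <- simulate_sq_reader(
    prog$truth, reader_params(within_grade_sensitivity = 1), seed = 3)
  expect_true(any(moaks$score == 0.5)) # sensitivity 1 must fire somewhere
  expect_true(all(moaks$score[moaks$visit_month == 0] %in% 0:3))
  # with sensitivity 0 no within-grade codes at all
  m0 <- simulate_sq_reader(prog$truth, reader_params(), seed = 3)
  expect_true(all(m0$score %in% 0:3))
})
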