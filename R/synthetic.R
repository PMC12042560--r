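#' Parameters of the synthetic normative thickness field
#'
#' The generator models each subregion's landmarks on a `u x v` parameter
#' grid carrying a smooth normative thickness surface. Subject thickness is
#' the field times a subject-level mean-one lognormal factor
#' `exp(N(-subject_scale_sd^2 / 2, subject_scale_sd))` plus i.i.d.
#' per-landmark Gaussian measurement noise, clamped at zero. The mean-one
#' parameterisation makes the truth field the exact population mean, so
#' the control-cohort average is an unbiased normative estimator.
#'
#' @param grid_shape Integer vector `c(u, v)`: landmarks per region arranged
#'   on a u-by-v grid (row-major). Default `c(8, 5)` (40 landmarks/region).
#' @param base_mean Mean field level in mm (default 2.2).
#' @param spatial_amplitude Amplitude in mm of the smooth within-region
#'   variation (default 0.3); the field stays within
#'   `base_mean +/- spatial_amplitude` by construction.
#' @param subject_scale_sd Log-scale SD of the per-subject multiplicative
#'   thickness factor (default 0.10).
#' @param noise_sd Per-landmark additive measurement noise SD in mm
#'   (default 0.05, about the reported test-retest precision of
#'   landmark-based thickness measurement).
#' @return A list of class `qm_field_params`.
#' @export
field_params <- function(grid_shape = c(8L, 5L), base_mean = 2.2,
                         spatial_amplitude = 0.3, subject_scale_sd = 0.10,
                         noise_sd = 0.05) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            base_mean > 0, spatial_amplitude >= 0,
            subject_scale_sd >= 0, noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape), base_mean = base_mean,
                 spatial_amplitude = spatial_amplitude,
                 subject_scale_sd = subject_scale_sd, noise_sd = noise_sd),
            class = "qm_field_params")
}

#' Parameters of synthetic focal cartilage lesions
#'
#' Lesions are radial depressions on a region's parameter grid: at grid
#' distance `d` from the lesion centre, a fraction
#' `depth * (1 + cos(pi * d / radius)) / 2` of the local normative
#' thickness is removed (cosine taper: full depth at the centre, zero at
#' the rim). Radius and centre depth advance linearly per elapsed year,
#' which supports deeper-only, wider-only and mixed growth modes.
#'
#' @param region_probs Named numeric vector of per-region lesion placement
#'   probabilities (normalised internally). The default concentrates
#'   lesions in the central medial compartments, where progression in a
#'   medial-JSW-loss cohort is expected.
#' @param n_lesions Lesions per knee (default 1; every knee gets at least
#'   one).
#' @param initial_radius Lesion radius at baseline, in grid units.
#' @param initial_depth_fraction Fraction of local normative thickness
#'   removed at the lesion centre at baseline, in `[0, 1]`.
#' @param radius_growth_per_year Radius increase per year (grid units).
#' @param depth_growth_per_year Centre depth-fraction increase per year;
#'   depth is clamped to `[0, 1]`.
#' @param profile `"cosine"` (default: full depth at the centre tapering
#'   to zero at the rim) or `"flat"` (uniform depth over the whole disc,
#'   useful for constructing exact-fraction scenarios).
#' @param fixed_center Optional `c(u, v)` grid coordinates; when given,
#'   every lesion is centred there instead of uniformly at random.
#' @return A list of class `qm_lesion_params`.
#' @export
lesion_params <- function(region_probs = c(cMF = 0.35, cMT = 0.30,
                                           pMF = 0.15, aMT = 0.10,
                                           cLF = 0.05, cLT = 0.05),
                          n_lesions = 1L,
                          initial_radius = 1.8,
                          initial_depth_fraction = 0.35,
                          radius_growth_per_year = 0.4,
                          depth_growth_per_year = 0.25,
                          profile = c("cosine", "flat"),
                          fixed_center = NULL) {
  profile <- match.arg(profile)
  stopifnot(all(names(region_probs) %in% region_codes()),
            all(region_probs >= 0), sum(region_probs) > 0,
            n_lesions >= 1, initial_radius >= 0,
            initial_depth_fraction >= 0, initial_depth_fraction <= 1,
            radius_growth_per_year >= 0, depth_growth_per_year >= 0,
            is.null(fixed_center) || length(fixed_center) == 2)
  structure(list(region_probs = region_probs / sum(region_probs),
                 n_lesions = as.integer(n_lesions),
                 initial_radius = initial_radius,
                 initial_depth_fraction = initial_depth_fraction,
                 radius_growth_per_year = radius_growth_per_year,
                 depth_growth_per_year = depth_growth_per_year,
                 profile = profile, fixed_center = fixed_center),
            class = "qm_lesion_params")
}

#' Parameters of the simulated semi-quantitative reader
#'
#' The reader maps each region's true ordinal band through a 4x4
#' row-stochastic confusion matrix. `overcall_bias` is a shorthand that
#' builds an identity matrix with probability mass `overcall_bias` shifted
#' one band upward (band 3 has nowhere to go), emulating systematic
#' overcalling of the affected area.
#'
#' @param confusion Optional 4x4 row-stochastic matrix (rows/cols = bands
#'   0-3, row = true band). Overrides `overcall_bias` when given.
#' @param overcall_bias Probability mass shifted one band up (default 0).
#' @param within_grade_sensitivity Probability that a true sub-band
#'   worsening (area fraction rose, band unchanged) is recorded as the
#'   within-grade code +0.5 at follow-up (default 0).
#' @return A list of class `qm_reader_params`.
#' @export
reader_params <- function(confusion = NULL, overcall_bias = 0,
                          within_grade_sensitivity = 0) {
  stopifnot(overcall_bias >= 0, overcall_bias <= 1,
            within_grade_sensitivity >= 0, within_grade_sensitivity <= 1)
  if (is.null(confusion)) {
    confusion <- diag(4)
    if (overcall_bias > 0) {
      for (k in 1:3) { # rows for true bands 0..2
        confusion[k, k] <- 1 - overcall_bias
        confusion[k, k + 1] <- overcall_bias
      }
    }
  }
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4, 4)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion must be a 4x4 row-stochastic matrix")
  }
  dimnames(confusion) <- list(true = 0:3, reported = 0:3)
  structure(list(confusion = confusion,
                 within_grade_sensitivity = within_grade_sensitivity),
            class = "qm_reader_params")
}

#' Build a grid-structured atlas
#'
#' Convenience constructor for the synthetic world: each of the 10
#' subregions holds `u * v` landmarks laid out row-major on a u-by-v grid,
#' with uniform unit area weights. Landmark ids are 0-based and contiguous,
#' regions in canonical [region_codes()] order.
#'
#' @param grid_shape Integer `c(u, v)` per region (default `c(8, 5)`).
#' @return A [qm_atlas()] with `10 * u * v` landmarks.
#' @export
make_grid_atlas <- function(grid_shape = c(8L, 5L)) {
  per <- prod(grid_shape)
  qm_atlas(landmark_id = seq_len(10 * per) - 1L,
           region = rep(region_codes(), each = per))
}

# Grid coordinates (u, v), 1-based, of each landmark within its region,
# assuming row-major layout with n_per_region = u * v landmarks per region.
grid_coords <- function(atlas, grid_shape) {
  per <- prod(grid_shape)
  counts <- table(atlas$region)
  if (!all(counts == per)) {
    stop("atlas region sizes must all equal prod(grid_shape) = ", per,
         " for grid-based generation")
  }
  pos <- integer(nrow(atlas))
  for (rg in region_codes()) {
    idx <- region_landmarks(atlas, rg)
    pos[idx] <- seq_along(idx)
  }
  cbind(u = ((pos - 1) %% grid_shape[1]) + 1,
        v = ((pos - 1) %/% grid_shape[1]) + 1)
}

# Stable per-knee substream seed: changing n never reshuffles earlier knees.
substream_seed <- function(master, i, salt = 0L) {
  h <- (as.double(master) %% 2147483647) * 48271 %% 2147483647
  as.integer((h + as.double(i) * 104729 + as.double(salt) * 7919) %%
               2147483647)
}

#' Generate the smooth normative truth field
#'
#' Each region gets an independent low-frequency sinusoidal surface over
#' its parameter grid: `base_mean + spatial_amplitude * cos(2 pi (a u + b
#' v) + phi)` with region-specific random direction `(a, b)` and phase
#' `phi`. Values therefore lie in `base_mean +/- spatial_amplitude`
#' exactly, and the field is a pure function of `(atlas, params, seed)`.
#'
#' @param atlas A grid-structured [qm_atlas()].
#' @param params A [field_params()] object.
#' @param seed Integer seed.
#' @return Numeric vector of per-landmark normative thickness (mm).
#' @export
make_mean_field <- function(atlas, params = field_params(), seed = 1L) {
  stopifnot(inherits(atlas, "qm_atlas"), inherits(params, "qm_field_params"))
  gc2 <- grid_coords(atlas, params$grid_shape)
  u <- (gc2[, "u"] - 1) / max(1, params$grid_shape[1] - 1)
  v <- (gc2[, "v"] - 1) / max(1, params$grid_shape[2] - 1)
  field <- numeric(nrow(atlas))
  for (k in seq_along(region_codes())) {
    rg <- region_codes()[k]
    idx <- region_landmarks(atlas, rg)
    set.seed(substream_seed(seed, k, salt = 1L))
    ab <- stats::runif(2, 0.3, 1.0)
    phi <- stats::runif(1, 0, 2 * pi)
    field[idx] <- params$base_mean + params$spatial_amplitude *
      cos(2 * pi * (ab[1] * u[idx] + ab[2] * v[idx]) + phi)
  }
  field
}

# Draw one subject's map from a noise-free per-landmark profile.
add_measurement_noise <- function(noisefree, noise_sd) {
  if (noise_sd > 0) {
    noisefree <- noisefree + stats::rnorm(length(noisefree), 0, noise_sd)
  }
  pmax(noisefree, 0)
}

#' Generate a non-OA control cohort
#'
#' Controls are baseline-only knees drawn from the normative field:
#' `thickness_i = field * exp(N(0, subject_scale_sd)) + N(0, noise_sd)`,
#' clamped at 0.
#'
#' @param n Number of control knees (>= 1).
#' @param atlas A grid-structured [qm_atlas()].
#' @param params A [field_params()] object.
#' @param seed Integer master seed; per-knee substreams are derived by
#'   stable hashing so earlier knees are unchanged when `n` grows.
#' @param field Optional pre-computed normative field. Controls and a
#'   study cohort drawn from the same population must share one field;
#'   pass the same vector to both generators (default: generated from
#'   `seed`).
#' @return List with `thickness` (a `qm_thickness` cohort at visit 0) and
#'   `truth_field` (the noise-free normative field).
#' @export
generate_controls <- function(n, atlas, params = field_params(), seed = 1L,
                              field = NULL) {
  if (n <= 0) stop("n must be >= 1")
  if (is.null(field)) field <- make_mean_field(atlas, params, seed)
  stopifnot(length(field) == nrow(atlas))
  vals <- matrix(0, nrow(atlas), n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i, salt = 2L))
    s <- exp(stats::rnorm(1, -params$subject_scale_sd^2 / 2,
                          params$subject_scale_sd))
    vals[, i] <- add_measurement_noise(field * s, params$noise_sd)
  }
  ids <- sprintf("ctrl%04d", seq_len(n))
  list(thickness = qm_thickness(vals, ids, rep(0L, n), atlas),
       truth_field = field)
}

# Combined lesion depth fraction over landmarks for one knee at one visit.
# lesions: list of lists(region, cu, cv, r0, d0); years elapsed since baseline.
lesion_depth_fraction <- function(atlas, gc2, lesions, years, lp) {
  frac <- numeric(nrow(atlas))
  keep <- rep(1, nrow(atlas)) # product of (1 - depth_j)
  for (les in lesions) {
    r <- les$r0 + lp$radius_growth_per_year * years
    d <- min(1, les$d0 + lp$depth_growth_per_year * years)
    idx <- region_landmarks(atlas, les$region)
    dist <- sqrt((gc2[idx, "u"] - les$cu)^2 + (gc2[idx, "v"] - les$cv)^2)
    inside <- dist <= r & r > 0
    dep <- numeric(length(idx))
    dep[inside] <- if (lp$profile == "flat") d else
      d * 0.5 * (1 + cos(pi * dist[inside] / r))
    keep[idx] <- keep[idx] * (1 - dep)
  }
  pmin(pmax(1 - keep, 0), 1)
}

#' Generate a progressing-OA cohort with ground truth
#'
#' Each knee receives at least one focal lesion whose radius and centre
#' depth advance linearly with elapsed years. Observed thickness at a
#' landmark is `subject_scale * field * (1 - lesion depth fraction) +
#' noise`, clamped at 0. Ground truth is obtained by scoring the noise-free
#' maps against a normative model built from the truth field, i.e. with
#' exactly the same thresholds contract as [score_cohort()], so a
#' noise-free run reproduces the ground truth identically.
#'
#' @param n Number of knees.
#' @param atlas A grid-structured [qm_atlas()].
#' @param fp A [field_params()] object.
#' @param lp A [lesion_params()] object.
#' @param visits Ascending integer months starting at 0 (default 0, 12, 24).
#' @param seed Integer master seed.
#' @param field Optional shared normative field (see
#'   [generate_controls()]).
#' @return List with elements `thickness` (noisy `qm_thickness` over all
#'   visits), `truth` (data.frame: knee_id, visit_month, region,
#'   lesion_area_pct, denuded_area_pct, mean_thickness_mm, footprint_pct),
#'   `truth_field`, `truth_model` (the normative model used for truth), and
#'   `lesions` (per-knee lesion geometry).
#' @export
generate_progression_cohort <- function(n, atlas, fp = field_params(),
                                        lp = lesion_params(),
                                        visits = c(0L, 12L, 24L),
                                        seed = 1L, field = NULL) {
  if (length(visits) == 0) stop("visit list must be non-empty")
  visits <- as.integer(visits)
  if (is.unsorted(visits, strictly = TRUE) || visits[1] != 0L) {
    stop("visits must be strictly ascending and start at 0")
  }
  if (n <= 0) stop("n must be >= 1")
  if (is.null(field)) field <- make_mean_field(atlas, fp, seed)
  stopifnot(length(field) == nrow(atlas))
  gc2 <- grid_coords(atlas, fp$grid_shape)
  regions_av <- names(lp$region_probs)
  nv <- length(visits)
  noisy <- matrix(0, nrow(atlas), n * nv)
  clean <- matrix(0, nrow(atlas), n * nv)
  footprint <- matrix(0, length(region_codes()), n * nv,
                      dimnames = list(region_codes(), NULL))
  kid <- character(n * nv); vm <- integer(n * nv)
  all_lesions <- vector("list", n)
  region_n <- table(atlas$region)[region_codes()]
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i, salt = 3L))
    s <- exp(stats::rnorm(1, -fp$subject_scale_sd^2 / 2,
                          fp$subject_scale_sd))
    lesions <- lapply(seq_len(lp$n_lesions), function(j) {
      rg <- sample(regions_av, 1, prob = lp$region_probs)
      ctr <- if (is.null(lp$fixed_center)) {
        c(stats::runif(1, 1, fp$grid_shape[1]),
          stats::runif(1, 1, fp$grid_shape[2]))
      } else lp$fixed_center
      list(region = rg, cu = ctr[1], cv = ctr[2],
           r0 = lp$initial_radius, d0 = lp$initial_depth_fraction)
    })
    all_lesions[[i]] <- lesions
    for (vi in seq_len(nv)) {
      col <- (i - 1) * nv + vi
      years <- visits[vi] / 12
      frac <- lesion_depth_fraction(atlas, gc2, lesions, years, lp)
      nf <- field * s * (1 - frac)
      clean[, col] <- nf
      noisy[, col] <- add_measurement_noise(nf, fp$noise_sd)
      fp_counts <- tapply(frac > 0, atlas$region, sum)[region_codes()]
      footprint[, col] <- 100 * as.numeric(fp_counts) / as.numeric(region_n)
      kid[col] <- sprintf("knee%04d", i)
      vm[col] <- visits[vi]
    }
  }
  thick <- qm_thickness(noisy, kid, vm, atlas, visits = visits)
  cleanc <- qm_thickness(clean, kid, vm, atlas, visits = visits)
  model <- new_normative_model(normative_mean = field, atlas = atlas,
                               n_controls = NA_integer_,
                               config = normative_config())
  truth_scores <- score_cohort(cleanc, model)
  truth <- data.frame(
    knee_id = truth_scores$knee_id,
    visit_month = truth_scores$visit_month,
    region = truth_scores$region,
    lesion_area_pct = truth_scores$thqcm_pct,
    denuded_area_pct = truth_scores$dqcm_pct,
    mean_thickness_mm = truth_scores$thctab_mm,
    stringsAsFactors = FALSE
  )
  fp_key <- match(paste(truth$knee_id, truth$visit_month),
                  paste(kid, vm))
  truth$footprint_pct <- footprint[cbind(match(truth$region,
                                               region_codes()), fp_key)]
  list(thickness = thick, truth = truth, truth_field = field,
       truth_model = model, lesions = all_lesions)
}

#' Simulate a semi-quantitative reader over ground truth
#'
#' The true ordinal band of each (knee, visit, region, measure) is computed
#' from the true area fractions with [band()], then passed through the
#' reader's confusion matrix. At follow-up visits, when the true fraction
#' rose but the true band did not, the record becomes the within-grade code
#' +0.5 with probability `within_grade_sensitivity` (provided the confusion
#' draw also kept the reported band unchanged).
#'
#' @param truth Ground-truth data.frame from
#'   [generate_progression_cohort()].
#' @param reader A [reader_params()] object.
#' @param seed Integer seed.
#' @return A `qm_moaks` table with both measures (ThMCM from
#'   `lesion_area_pct`, dMCM from `denuded_area_pct`).
#' @export
simulate_sq_reader <- function(truth, reader = reader_params(), seed = 1L) {
  stopifnot(inherits(reader, "qm_reader_params"))
  set.seed(substream_seed(seed, 0L, salt = 4L))
  out <- vector("list", 2L)
  names(out) <- c("ThMCM", "dMCM")
  cols <- c(ThMCM = "lesion_area_pct", dMCM = "denuded_area_pct")
  for (ms in names(cols)) {
    tr <- truth[order(truth$knee_id, truth$region, truth$visit_month), ,
                drop = FALSE]
    frac <- tr[[cols[ms]]]
    true_band <- band(frac)
    reported <- vapply(true_band, function(b) {
      sample(0:3, 1, prob = reader$confusion[b + 1, ])
    }, numeric(1))
    score <- as.numeric(reported)
    grp <- paste(tr$knee_id, tr$region)
    first <- !duplicated(grp)
    prev <- c(NA, frac[-length(frac)]); prev[first] <- NA
    prev_band <- c(NA, true_band[-length(true_band)]); prev_band[first] <- NA
    prev_rep <- c(NA, reported[-length(reported)]); prev_rep[first] <- NA
    cand <- which(!first & frac > prev & true_band == prev_band &
                    reported == prev_rep)
    if (length(cand) > 0 && reader$within_grade_sensitivity > 0) {
      hit <- cand[stats::runif(length(cand)) <
                    reader$within_grade_sensitivity]
      score[hit] <- 0.5
    }
    out[[ms]] <- data.frame(knee_id = tr$knee_id,
                            visit_month = tr$visit_month,
                            region = tr$region, measure = ms,
                            score = score, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  qm_moaks(rec$knee_id, rec$visit_month, rec$region, rec$measure, rec$score)
}
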