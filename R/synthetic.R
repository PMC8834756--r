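# Synthetic cohorts and rater panels: landmark sets realized by inverse
# geometry from known latent surrogate-PI and HKL-C angles, and simulated
# raters with configurable confusion structure.

#' Specification of a synthetic landmark cohort
#'
#' Defaults emulate the reference cohort: 125 subjects, 71 male, surrogate
#' PI normal with mean 47.0 and SD 6.2 degrees overall (male 45.4 +/- 5.1,
#' female 49.1 +/- 7.0).  The latent HKL angle C is linear in PI with
#' Gaussian noise; the default slope and intercept map the PI class
#' boundaries 42/51 degrees onto the screening thresholds 18.5/21.5, and
#' the default noise SD is calibrated so the S/ML dichotomy reaches a
#' trapezoidal AUC near 0.93 at n = 125 (a synthetic-module calibration
#' target, not a claim about real anthropometry).  PI draws are truncated
#' to `pi_range` to keep the geometry realizable.
#'
#' @param n subject count (at least 4).
#' @param pi_mean,pi_sd surrogate-PI distribution for unspecified-sex draws
#'   (degrees).
#' @param sex_ratio proportion of male subjects.
#' @param male_pi_mean,male_pi_sd,female_pi_mean,female_pi_sd sex-specific
#'   surrogate-PI moments (degrees).
#' @param hkl_slope,hkl_intercept linear link from PI to latent HKL angle C
#'   (degrees per degree; defaults 1/3 and 4.5).
#' @param hkl_noise_sd SD of the Gaussian noise on the latent HKL angle C.
#' @param pi_range truncation interval for PI draws (degrees).
#' @param seed RNG seed governing sex, PI and noise draws through
#'   independent sub-streams.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 125, pi_mean = 47.0, pi_sd = 6.2,
                        sex_ratio = 71 / 125,
                        male_pi_mean = 45.4, male_pi_sd = 5.1,
                        female_pi_mean = 49.1, female_pi_sd = 7.0,
                        hkl_slope = 1 / 3, hkl_intercept = 4.5,
                        hkl_noise_sd = 1.2, pi_range = c(25, 75),
                        seed = NULL) {
  stopifnot(n >= 4, pi_sd > 0, male_pi_sd > 0, female_pi_sd > 0,
            hkl_noise_sd >= 0, sex_ratio >= 0, sex_ratio <= 1,
            length(pi_range) == 2L, pi_range[1L] < pi_range[2L])
  structure(list(n = as.integer(n), pi_mean = pi_mean, pi_sd = pi_sd,
                 sex_ratio = sex_ratio, male_pi_mean = male_pi_mean,
                 male_pi_sd = male_pi_sd, female_pi_mean = female_pi_mean,
                 female_pi_sd = female_pi_sd, hkl_slope = hkl_slope,
                 hkl_intercept = hkl_intercept, hkl_noise_sd = hkl_noise_sd,
                 pi_range = pi_range, seed = seed),
            class = "cohort_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Realize a landmark set from target angles by inverse geometry
#'
#' Places landmarks of an upright stick body (units roughly centimeters,
#' knee at 45, thigh center at 75, head at 170) so that the HKL angle C and
#' the surrogate-PI angle reproduce the requested values exactly: the
#' buttock apex sits on the circle around the knee center realizing
#' `hkl_c_angle` against the vertical femoral axis, and the
#' buttock-at-trochanter point is placed so the angle at the iliac crest
#' equals `pi_angle`.  A uniform scale and translation may be applied
#' (angles are invariant to both).
#'
#' @param subject_id identifier.
#' @param pi_angle target surrogate-PI angle, degrees in (0, 90).
#' @param hkl_c_angle target HKL angle C, degrees in (0, 90).
#' @param sex subject sex.
#' @param scale uniform scale factor.
#' @param origin translation applied after scaling, `(x, y)`.
#' @return a [landmark_set()].
#' @export
realize_landmarks <- function(subject_id, pi_angle, hkl_c_angle,
                              sex = "unspecified", scale = 1,
                              origin = c(0, 0)) {
  stopifnot(pi_angle > 0, pi_angle < 90, hkl_c_angle > 0, hkl_c_angle < 90,
            scale > 0)
  th <- hkl_c_angle * pi / 180
  phi <- pi_angle * pi / 180
  r <- 40  # knee-center-to-buttock-apex distance before scaling
  crest_drop <- 12  # iliac crest sits 12 above the trochanter
  pts <- list(
    knee_anterior = c(5, 45), knee_posterior = c(-5, 45),
    knee_central = c(0, 45), thigh_center = c(0, 75),
    head_top = c(2, 170),
    buttock_apex = c(-r * sin(th), 45 + r * cos(th)),
    trochanter_top = c(0, 85), iliac_crest_top = c(0, 85 + crest_drop),
    buttock_at_trochanter = c(-crest_drop * tan(phi), 85)
  )
  pts <- lapply(pts, function(p)
    c(x = p[1L] * scale + origin[1L], y = p[2L] * scale + origin[2L]))
  do.call(landmark_set,
          c(list(subject_id = subject_id, sex = sex), pts))
}

#' Generate a synthetic landmark cohort with known latent truth
#'
#' Draws sex, then surrogate PI from the sex-specific truncated normal,
#' then the latent HKL angle C from the linear link with Gaussian noise
#' (redrawing the noise while the angle falls outside (0, 90) degrees), and
#' realizes each subject's landmark set exactly by [realize_landmarks()]
#' under a random per-subject scale and translation.  Identical seeds give
#' identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return list with `landmarks` (list of [landmark_set()]) and `truth`
#'   (data frame `subject_id, sex, pi, hkl_c` of the latent values).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 10, seed = 1))
#' head(cohort$truth)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  male <- with_seed(sub_seed(spec$seed, 1L),
                    rbinom(n, 1L, spec$sex_ratio) == 1L)
  sex <- ifelse(male, "male", "female")
  mu <- ifelse(male, spec$male_pi_mean, spec$female_pi_mean)
  sdv <- ifelse(male, spec$male_pi_sd, spec$female_pi_sd)
  pi_angle <- with_seed(sub_seed(spec$seed, 2L),
                        rtruncnorm(n, mu, sdv, spec$pi_range[1L],
                                   spec$pi_range[2L]))
  hkl <- with_seed(sub_seed(spec$seed, 3L), {
    x <- spec$hkl_intercept + spec$hkl_slope * pi_angle +
      rnorm(n, 0, spec$hkl_noise_sd)
    bad <- which(x <= 0 | x >= 90)
    while (length(bad)) {
      x[bad] <- spec$hkl_intercept + spec$hkl_slope * pi_angle[bad] +
        rnorm(length(bad), 0, spec$hkl_noise_sd)
      bad <- bad[x[bad] <= 0 | x[bad] >= 90]
    }
    x
  })
  jitter <- with_seed(sub_seed(spec$seed, 4L),
                      list(scale = runif(n, 0.8, 1.2),
                           dx = runif(n, -50, 50),
                           dy = runif(n, -50, 50)))
  ids <- sprintf("synth%03d", seq_len(n))
  landmarks <- lapply(seq_len(n), function(i)
    realize_landmarks(ids[i], pi_angle[i], hkl[i], sex[i],
                      scale = jitter$scale[i],
                      origin = c(jitter$dx[i], jitter$dy[i])))
  list(landmarks = landmarks,
       truth = data.frame(subject_id = ids, sex = sex, pi = pi_angle,
                          hkl_c = hkl, stringsAsFactors = FALSE))
}

#' Specification of a simulated rater panel
#'
#' Each rater classifies photos by drawing from the row of a 3x3
#' row-stochastic confusion matrix `P(rated | true)`.  In session 2 the
#' off-diagonal mass of every row is shrunk by `session2_sharpening`
#' (a simple training effect).  Per-rater mean classification times are
#' drawn from session-specific normals truncated below at 5 s.
#'
#' @param n_raters number of raters.
#' @param confusion one 3x3 matrix applied to every rater, or a list of
#'   `n_raters` matrices; `NULL` uses the `"reference"` preset.
#' @param session2_sharpening off-diagonal shrink factor in `[0, 1]`.
#' @param time_mean,time_sd length-2 numerics: mean and SD of per-rater
#'   mean times (s/photo) for sessions 1 and 2.
#' @param seed RNG seed.
#' @return object of class `rater_spec`.
#' @seealso [rater_preset()], [simulate_ratings()]
#' @export
rater_spec <- function(n_raters = 14, confusion = NULL,
                       session2_sharpening = 0.08,
                       time_mean = c(17.0, 13.6), time_sd = c(4.7, 2.9),
                       seed = NULL) {
  stopifnot(n_raters >= 1, session2_sharpening >= 0,
            session2_sharpening <= 1)
  if (is.null(confusion)) confusion <- reference_confusion(n_raters)
  if (is.matrix(confusion)) confusion <- rep(list(confusion), n_raters)
  stopifnot(length(confusion) == n_raters)
  for (m in confusion) {
    stopifnot(is.matrix(m), dim(m) == c(3L, 3L), all(m >= 0))
    if (any(abs(rowSums(m) - 1) > 1e-8))
      stop("confusion matrix rows must sum to 1", call. = FALSE)
  }
  structure(list(n_raters = as.integer(n_raters), confusion = confusion,
                 session2_sharpening = session2_sharpening,
                 time_mean = time_mean, time_sd = time_sd, seed = seed),
            class = "rater_spec")
}

shrink_offdiagonal <- function(m, s) {
  out <- m * (1 - s)
  diag(out) <- 0
  diag(out) <- 1 - rowSums(out)
  out
}

#' Rater confusion presets
#'
#' `"identity"`: error-free raters.  `"uniform"`: raters who guess
#' uniformly, independent of the true class.  `"reference"`: a
#' heterogeneous panel calibrated so that test-retest (Cohen) agreement
#' lands in the substantial Landis band and between-rater quadratic-
#' weighted agreement in the moderate band, as reported for trained
#' examiners of the screening tool; most raters are neutral, and roughly
#' 3 in 14 lean S and as many lean L, so that between-rater disagreement
#' exceeds within-rater disagreement.
#'
#' @param preset preset name.
#' @param n_raters number of raters.
#' @param ... further arguments passed to [rater_spec()].
#' @return a [rater_spec()].
#' @export
rater_preset <- function(preset = c("reference", "identity", "uniform"),
                         n_raters = 14, ...) {
  preset <- match.arg(preset)
  confusion <- switch(preset,
    identity = diag(3),
    uniform = matrix(1 / 3, 3, 3),
    reference = reference_confusion(n_raters)
  )
  rater_spec(n_raters = n_raters, confusion = confusion, ...)
}

# Heterogeneous panel.  Most raters are neutral and read near the true
# class with adjacent-only errors; a minority carry a strong systematic
# bias shifting readings one class down (S-leaning) or up (L-leaning).
# The bias is consistent within a rater, so test-retest agreement stays
# substantial while between-rater agreement drops to moderate -- with
# independent draws per session, uniformly accurate raters cannot be both
# highly self-consistent and mutually discordant.  Rows are
# P(rated S, M, L | true class).
reference_confusion <- function(n_raters) {
  neutral <- matrix(c(
    0.94, 0.06, 0.00,
    0.03, 0.94, 0.03,
    0.00, 0.06, 0.94), 3, 3, byrow = TRUE)
  s_lean <- matrix(c(
    1.00, 0.00, 0.00,
    0.90, 0.10, 0.00,
    0.00, 0.90, 0.10), 3, 3, byrow = TRUE)
  l_lean <- matrix(c(
    0.10, 0.90, 0.00,
    0.00, 0.10, 0.90,
    0.00, 0.00, 1.00), 3, 3, byrow = TRUE)
  dimnames(neutral) <- dimnames(s_lean) <- dimnames(l_lean) <-
    list(PI_LEVELS, PI_LEVELS)
  n_bias <- max(0L, round(n_raters * 3 / 14))
  pool <- c(rep(list(neutral), n_raters - 2L * n_bias),
            rep(list(s_lean), n_bias), rep(list(l_lean), n_bias))
  pool[seq_len(n_raters)]
}

#' Criterion labels with an exact 1:2:1 S:M:L mix
#'
#' @param n photo count, a multiple of 4 (default 24, giving 6/12/6).
#' @param seed seed for the random ordering.
#' @return factor of S/M/L labels of length `n`.
#' @export
photo_mix <- function(n = 24, seed = NULL) {
  if (n %% 4 != 0)
    stop("photo count must be a multiple of 4 for an exact 1:2:1 mix",
         call. = FALSE)
  lab <- rep(PI_LEVELS, times = c(n / 4, n / 2, n / 4))
  lab <- with_seed(seed, sample(lab))
  factor(lab, levels = PI_LEVELS, ordered = TRUE)
}

#' Simulate a rating table from criterion labels and a rater panel
#'
#' Every (rater, photo, session) rating is an independent draw from the
#' rater's confusion row for the photo's true class; session 2 uses the
#' sharpened matrix.  Deterministic under the spec's seed.
#'
#' @param criterion factor/character vector of true S/M/L labels, one per
#'   photo, or a data frame with columns `photo_id`, `criterion` and
#'   optionally `sex`.
#' @param spec a [rater_spec()].
#' @return a [rating_table()] including simulated per-rater times.
#' @examples
#' rt <- simulate_ratings(photo_mix(24, seed = 1),
#'                        rater_preset("identity", n_raters = 3, seed = 1))
#' correct_rate(ratings_matrix(rt, 1)[, 1], rt$criterion$criterion)
#' @export
simulate_ratings <- function(criterion, spec = rater_spec()) {
  stopifnot(inherits(spec, "rater_spec"))
  if (is.data.frame(criterion)) {
    crit_df <- criterion
    stopifnot(all(c("photo_id", "criterion") %in% names(crit_df)))
  } else {
    crit_df <- data.frame(photo_id = sprintf("photo%02d",
                                             seq_along(criterion)),
                          criterion = as.character(criterion),
                          stringsAsFactors = FALSE)
  }
  truth_idx <- match(crit_df$criterion, PI_LEVELS)
  n_photo <- nrow(crit_df)
  rater_ids <- sprintf("rater%02d", seq_len(spec$n_raters))
  ratings <- with_seed(sub_seed(spec$seed, 11L), {
    rows <- list()
    for (r in seq_len(spec$n_raters)) {
      for (s in 1:2) {
        m <- spec$confusion[[r]]
        if (s == 2L) m <- shrink_offdiagonal(m, spec$session2_sharpening)
        lab <- vapply(truth_idx, function(tix)
          sample(PI_LEVELS, 1L, prob = m[tix, ]), character(1))
        rows[[length(rows) + 1L]] <-
          data.frame(photo_id = crit_df$photo_id, rater_id = rater_ids[r],
                     session = s, label = lab, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  times <- with_seed(sub_seed(spec$seed, 12L), {
    data.frame(
      rater_id = rep(rater_ids, times = 2L),
      session = rep(1:2, each = spec$n_raters),
      mean_time_s = c(pmax(5, rnorm(spec$n_raters, spec$time_mean[1L],
                                    spec$time_sd[1L])),
                      pmax(5, rnorm(spec$n_raters, spec$time_mean[2L],
                                    spec$time_sd[2L]))),
      stringsAsFactors = FALSE)
  })
  rating_table(ratings, crit_df, times)
}
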