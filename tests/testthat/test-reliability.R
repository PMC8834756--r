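test_that("Landis-Koch bands honour the printed cut-points after rounding", {
  expect_equal(landis_band(c(0.79, 0.50, 0)),
               c("substantial", "moderate", "poor"))
  expect_equal(landis_band(c(-0.3, 0.004, 0.20, 0.21, 0.40, 0.60, 0.61,
                             0.80, 0.81, 1)),
               c("poor", "poor", "slight", "fair", "fair", "moderate",
                 "substantial", "substantial", "almost perfect",
                 "almost perfect"))
  # rounding to two decimals happens before banding
  expect_equal(landis_band(0.604), "moderate")
  expect_equal(landis_band(0.606), "substantial")
})

test_that("correct rate is the percentage agreeing with the criterion", {
  crit <- rep(c("S", "M", "L"), 8)
  ratings <- crit
  ratings[1:3] <- c("M", "S", "M")
  expect_equal(correct_rate(ratings, crit), 100 * 21 / 24)
  expect_equal(correct_rate(crit, crit), 100)
})

test_that("Cohen's kappa matches the direct po/pe computation", {
  # 3x3 with diagonal (10, 20, 10) plus one S->M and one L->M error
  s1 <- c(rep("S", 11), rep("M", 20), rep("L", 11))
  s2 <- c(rep("S", 10), "M", rep("M", 20), "M", rep("L", 10))
  k <- cohen_kappa(s1, s2)
  po <- 40 / 42
  pe <- (11 * 10 + 20 * 22 + 11 * 10) / 42^2
  expect_equal(k$statistic, (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(k$po, po)
  expect_equal(k$pe, pe)
  expect_true(k$ci_low <= k$statistic && k$statistic <= k$ci_high)
})

test_that("Cohen's kappa is symmetric, permutation-invariant and 1 at perfect agreement", {
  set.seed(61)
  x <- sample(c("S", "M", "L"), 60, replace = TRUE)
  y <- sample(c("S", "M", "L"), 60, replace = TRUE)
  expect_equal(cohen_kappa(x, y)$statistic, cohen_kappa(y, x)$statistic)
  perm <- c(S = "L", M = "S", L = "M")
  expect_equal(cohen_kappa(unname(perm[x]), unname(perm[y]))$statistic,
               cohen_kappa(x, y)$statistic, tolerance = 1e-12)
  expect_equal(cohen_kappa(x, x)$statistic, 1)
  expect_true(is.na(cohen_kappa(rep("M", 5), rep("M", 5))$statistic))
})

test_that("Cohen's kappa agrees with an independent implementation", {
  set.seed(62)
  x <- sample(c("S", "M", "L"), 80, replace = TRUE, prob = c(2, 3, 1))
  y <- ifelse(runif(80) < 0.6, x, sample(c("S", "M", "L"), 80, TRUE))
  ref <- e1071::classAgreement(table(factor(x, c("S", "M", "L")),
                                     factor(y, c("S", "M", "L"))))$kappa
  expect_equal(cohen_kappa(x, y)$statistic, ref, tolerance = 1e-12)
})

test_that("independent raters give kappa near zero within its standard error", {
  set.seed(63)
  x <- sample(c("S", "M", "L"), 600, replace = TRUE)
  y <- sample(c("S", "M", "L"), 600, replace = TRUE)
  k <- cohen_kappa(x, y)
  expect_lt(abs(k$statistic), 3 * k$se)
})

test_that("identity-weighted kappa equals unweighted Cohen's kappa", {
  set.seed(64)
  for (i in 1:10) {
    x <- sample(c("S", "M", "L"), 40, replace = TRUE)
    y <- ifelse(runif(40) < 0.5, x, sample(c("S", "M", "L"), 40, TRUE))
    expect_equal(weighted_kappa(x, y, weights = "identity"),
                 cohen_kappa(x, y)$statistic, tolerance = 1e-12)
  }
})

test_that("quadratic weights penalize two-step disagreements more", {
  base <- rep(c("S", "M", "L"), times = c(6, 12, 6))
  adj <- base; adj[1] <- "M"    # S mistaken for M
  far <- base; far[1] <- "L"    # S mistaken for L
  expect_gt(weighted_kappa(base, adj), weighted_kappa(base, far))
  expect_equal(weighted_kappa(base, base), 1)
})

test_that("multirater kappa reduces to Cohen's kappa for two raters (identity weights)", {
  set.seed(65)
  m <- cbind(sample(c("S", "M", "L"), 30, replace = TRUE),
             sample(c("S", "M", "L"), 30, replace = TRUE))
  k <- multirater_kappa(m, weights = "identity", ci = FALSE)
  expect_equal(k$statistic, cohen_kappa(m[, 1], m[, 2])$statistic,
               tolerance = 1e-12)
})

test_that("multirater kappa is 1 for unanimous raters and errors on gaps", {
  m <- matrix(rep(rep(c("S", "M", "L"), times = c(6, 12, 6)), 4), ncol = 4)
  k <- multirater_kappa(m, ci = FALSE)
  expect_equal(k$statistic, 1)
  m[3, 2] <- NA
  expect_error(multirater_kappa(m, ci = FALSE), "incomplete design")
})

test_that("mean pairwise kappa approaches its enumerated expectation", {
  # three raters with known confusion rows, many photos: the empirical
  # statistic should sit near the exact large-sample value computed by
  # enumeration over category pairs
  conf <- list(
    matrix(c(.9, .1, 0, .05, .9, .05, 0, .1, .9), 3, 3, byrow = TRUE),
    matrix(c(.8, .2, 0, .1, .8, .1, 0, .2, .8), 3, 3, byrow = TRUE),
    matrix(c(.7, .3, 0, .3, .6, .1, .05, .35, .6), 3, 3, byrow = TRUE)
  )
  pi_true <- c(S = .25, M = .5, L = .25)
  w <- 1 - hklpi:::disagreement_weights(3, "quadratic")
  # exact pairwise quadratic-weighted kappa from the joint distribution
  exact_pair <- function(a, b) {
    joint <- matrix(0, 3, 3)
    for (t in 1:3) joint <- joint + pi_true[t] * outer(a[t, ], b[t, ])
    po <- sum(w * joint)
    pe <- sum(w * outer(rowSums(joint), colSums(joint)))
    (po - pe) / (1 - pe)
  }
  exact <- mean(c(exact_pair(conf[[1]], conf[[2]]),
                  exact_pair(conf[[1]], conf[[3]]),
                  exact_pair(conf[[2]], conf[[3]])))
  rt <- simulate_ratings(photo_mix(3000, seed = 8),
                         rater_spec(n_raters = 3, confusion = conf,
                                    session2_sharpening = 0, seed = 8))
  emp <- multirater_kappa(ratings_matrix(rt, 1), ci = FALSE)$statistic
  expect_equal(emp, exact, tolerance = 0.03)
})

test_that("bootstrap interval brackets the multirater statistic", {
  rt <- simulate_ratings(photo_mix(24, seed = 12),
                         rater_preset("reference", seed = 12))
  k <- multirater_kappa(ratings_matrix(rt, 1), B = 200, seed = 1)
  expect_true(k$ci_low <= k$statistic && k$statistic <= k$ci_high)
  # seeded bootstrap is reproducible
  k2 <- multirater_kappa(ratings_matrix(rt, 1), B = 200, seed = 1)
  expect_equal(k$ci_low, k2$ci_low)
})

test_that("paired t matches the closed-form computation and is antisymmetric", {
  a <- c(12.1, 9.8, 14.2, 11.0, 10.5, 13.3)
  b <- c(10.0, 10.2, 12.9, 10.1, 9.9, 12.0)
  res <- paired_t(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$mean_difference, mean(d), tolerance = 1e-10)
  expect_equal(res$df, length(d) - 1)
  half <- qt(0.975, length(d) - 1) * sd(d) / sqrt(length(d))
  expect_equal(res$ci_low, mean(d) - half, tolerance = 1e-10)
  swapped <- paired_t(b, a)
  expect_equal(swapped$statistic, -res$statistic, tolerance = 1e-10)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  degen <- paired_t(a, a)
  expect_true(degen$degenerate)
  expect_equal(degen$mean_difference, 0)
})

test_that("the reference panel lands in the published agreement bands", {
  inter1 <- intra <- numeric(10)
  for (s in 1:10) {
    rt <- simulate_ratings(photo_mix(24, seed = 100 + s),
                           rater_preset("reference", seed = 100 + s))
    m1 <- ratings_matrix(rt, 1)
    m2 <- ratings_matrix(rt, 2)
    inter1[s] <- multirater_kappa(m1, ci = FALSE)$statistic
    intra[s] <- mean(vapply(rt$raters, function(r)
      cohen_kappa(m1[, r], m2[, r])$statistic, numeric(1)), na.rm = TRUE)
  }
  expect_gte(mean(landis_band(inter1) == "moderate"), 0.9)
  expect_gte(mean(landis_band(intra) == "substantial"), 0.9)
})
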