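# Similarity transforms on landmark sets, used by the geometric-invariance
# property tests.

transform_landmarks <- function(lm, scale = 1, rotate_deg = 0,
                                translate = c(0, 0), mirror_x = FALSE) {
  th <- rotate_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- lm
  for (nm in hklpi:::LANDMARK_NAMES) {
    p <- lm[[nm]]
    if (is.null(p)) next
    v <- unname(p)
    if (mirror_x) v[1L] <- -v[1L]
    v <- drop(rot %*% v) * scale + translate
    out[[nm]] <- c(x = v[1L], y = v[2L])
  }
  out
}

# a plausible asymmetric subject used across geometry tests
example_subject <- function() {
  landmark_set(
    "ex1",
    head_top = c(3, 170), buttock_apex = c(-13, 84),
    knee_anterior = c(6, 45), knee_posterior = c(-4, 45),
    thigh_center = c(1, 75),
    trochanter_top = c(0, 85), iliac_crest_top = c(1, 97),
    buttock_at_trochanter = c(-13, 85)
  )
}

# Mann-Whitney pair-counting AUC: proportion of (high, low) pairs correctly
# ordered, ties counted half.
pair_count_auc <- function(scores_hi, scores_lo) {
  cmp <- outer(scores_hi, scores_lo, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}
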