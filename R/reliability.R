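# Rater reliability of the screening tool: correct rates, Cohen's kappa,
# weighted multi-rater kappa, paired session comparisons, Landis-Koch bands.

#' Landis-Koch interpretation band for a kappa value
#'
#' Values are rounded to 2 decimals before banding, so band boundaries
#' behave as printed: 0.60 is moderate, 0.61 substantial.  Zero and
#' negative values are poor.
#'
#' @param kappa numeric vector of kappa values in `[-1, 1]`.
#' @return character vector of bands (`poor`, `slight`, `fair`, `moderate`,
#'   `substantial`, `almost perfect`).
#' @examples
#' landis_band(c(0.79, 0.5, 0))
#' @export
landis_band <- function(kappa) {
  stopifnot(is.numeric(kappa), all(is.na(kappa) | abs(kappa) <= 1))
  k <- round(kappa, 2)
  ifelse(is.na(k), NA_character_,
    ifelse(k <= 0, "poor",
      ifelse(k <= 0.20, "slight",
        ifelse(k <= 0.40, "fair",
          ifelse(k <= 0.60, "moderate",
            ifelse(k <= 0.80, "substantial", "almost perfect"))))))
}

#' Correct rate against an external criterion
#'
#' Percentage of a rater's classifications that match the criterion label.
#'
#' @param ratings vector of assigned labels.
#' @param criterion vector of criterion labels, same length.
#' @return percent in `[0, 100]`.
#' @examples
#' correct_rate(c("S", "M", "M", "L"), c("S", "M", "L", "L")) # 75
#' @export
correct_rate <- function(ratings, criterion) {
  stopifnot(length(ratings) == length(criterion), length(ratings) > 0)
  100 * mean(as.character(ratings) == as.character(criterion))
}

as_rating_factor <- function(x, levels) factor(as.character(x), levels = levels)

rating_levels <- function(x, y = NULL, levels = NULL) {
  if (!is.null(levels)) return(levels)
  vals <- unique(c(as.character(x), if (!is.null(y)) as.character(y)))
  if (all(vals %in% PI_LEVELS)) PI_LEVELS else sort(vals)
}

#' Cohen's kappa with an analytic confidence interval
#'
#' Unweighted chance-corrected agreement between two label sequences (here
#' typically a rater's first- and second-session readings of the same
#' photos).  The 95% interval uses the large-sample delta-method standard
#' error of Fleiss, Cohen and Everitt, with normal quantiles, clipped to
#' `[-1, 1]`.  When both sequences contain only a single common category the
#' statistic is undefined and returned as `NA`.
#'
#' @param x,y equal-length label vectors.
#' @param levels category levels; defaults to `S`, `M`, `L` when the data
#'   fit, otherwise the sorted observed values.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `kappa_result`: list with `statistic`, `se`,
#'   `ci_low`, `ci_high`, `landis_band`, `po`, `pe`, `n`, `method`.
#' @examples
#' cohen_kappa(c("S", "M", "L", "M"), c("S", "M", "L", "L"))
#' @export
cohen_kappa <- function(x, y, levels = NULL, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) > 0)
  levels <- rating_levels(x, y, levels)
  xf <- as_rating_factor(x, levels)
  yf <- as_rating_factor(y, levels)
  keep <- !is.na(xf) & !is.na(yf)
  xf <- xf[keep]; yf <- yf[keep]
  n <- length(xf)
  tab <- table(xf, yf)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  observed <- union(as.character(unique(xf)), as.character(unique(yf)))
  if (length(observed) < 2L || pe >= 1) {
    return(kappa_result(NA_real_, NA_real_, NA_real_, NA_real_, po, pe, n,
                        "Cohen's kappa (undefined: single observed category)"))
  }
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance
  i <- seq_along(levels)
  a <- sum(diag(p) * (1 - (pr + pc) * (1 - k))^2)
  b <- 0
  for (r in i) for (s in i) if (r != s)
    b <- b + p[r, s] * (pc[r] + pr[s])^2
  b <- (1 - k)^2 * b
  cc <- (k - pe * (1 - k))^2
  var_k <- (a + b - cc) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  kappa_result(k, se, max(-1, k - z * se), min(1, k + z * se), po, pe, n,
               "Cohen's kappa (analytic CI)")
}

kappa_result <- function(statistic, se, ci_low, ci_high, po, pe, n, method) {
  structure(list(statistic = statistic, se = se, ci_low = ci_low,
                 ci_high = ci_high,
                 landis_band = if (is.na(statistic)) NA_character_
                   else landis_band(statistic),
                 po = po, pe = pe, n = n, method = method),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("<kappa_result>", x$method, "\n")
  if (is.na(x$statistic)) {
    cat("  statistic undefined\n")
  } else {
    ci <- if (!is.na(x$ci_low))
      sprintf(" (95%% CI %0.2f-%0.2f)", x$ci_low, x$ci_high) else ""
    cat(sprintf("  kappa %0.3f%s, %s, n = %d\n", x$statistic, ci,
                x$landis_band, x$n))
  }
  invisible(x)
}

# Disagreement-weight matrix on ordinal categories coded 0..k-1.
disagreement_weights <- function(k, weights = c("quadratic", "linear",
                                                "identity")) {
  weights <- match.arg(weights)
  d <- abs(outer(seq_len(k) - 1L, seq_len(k) - 1L, "-"))
  switch(weights,
         quadratic = (d / (k - 1L))^2,
         linear = d / (k - 1L),
         identity = (d > 0) * 1)
}

#' Weighted kappa between two raters
#'
#' Cohen's weighted kappa on ordinal categories, with quadratic (default),
#' linear or identity disagreement weights.  With identity weights this is
#' exactly the unweighted Cohen's kappa.  Categories are coded by their
#' position in `levels` (S = 0, M = 1, L = 2 for the PI labels).
#'
#' @param x,y equal-length label vectors.
#' @param weights `"quadratic"`, `"linear"` or `"identity"`.
#' @param levels ordered category levels (see [cohen_kappa()]).
#' @return the weighted kappa value (`NA` when undefined).
#' @export
weighted_kappa <- function(x, y, weights = "quadratic", levels = NULL) {
  stopifnot(length(x) == length(y), length(x) > 0)
  levels <- rating_levels(x, y, levels)
  xf <- as_rating_factor(x, levels)
  yf <- as_rating_factor(y, levels)
  keep <- !is.na(xf) & !is.na(yf)
  tab <- table(xf[keep], yf[keep])
  p <- tab / sum(tab)
  w <- disagreement_weights(length(levels), weights)
  expected <- sum(w * outer(rowSums(p), colSums(p)))
  if (expected == 0) return(NA_real_)
  1 - sum(w * p) / expected
}

#' Weighted multi-rater kappa (mean pairwise)
#'
#' Inter-rater agreement for two or more raters on ordinal categories:
#' the mean of [weighted_kappa()] over all rater pairs (a Conger-style
#' generalization; with quadratic weights this implements the "weighted
#' Fleiss-type" statistic used for ordinal S/M/L readings).  The 95%
#' interval is a seeded nonparametric percentile bootstrap over photos,
#' since the pairwise mean has no convenient closed-form variance.
#'
#' @param ratings matrix or data frame, photos in rows and raters in
#'   columns; a complete design (no missing cells) is required.
#' @param weights passed to [weighted_kappa()].
#' @param levels ordered category levels.
#' @param ci compute the bootstrap interval (default `TRUE`).
#' @param B bootstrap resamples (default 2000).
#' @param conf_level confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `kappa_result` (`po`/`pe` slots are `NA`; the
#'   pairwise values are attached as attribute `pairwise`).
#' @seealso [fleiss_kappa()] for the unweighted nominal statistic.
#' @export
multirater_kappa <- function(ratings, weights = "quadratic", levels = NULL,
                             ci = TRUE, B = 2000, conf_level = 0.95,
                             seed = NULL) {
  m <- as.matrix(ratings)
  if (ncol(m) < 2L) stop("need at least two raters", call. = FALSE)
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete design: missing ratings at photo ",
         paste(miss[, 1L], collapse = ", "), " (rater ",
         paste(miss[, 2L], collapse = ", "), ")", call. = FALSE)
  }
  levels <- rating_levels(as.vector(m), levels = levels)
  pair_mean <- function(mat) {
    ks <- combn(ncol(mat), 2, function(ij)
      weighted_kappa(mat[, ij[1L]], mat[, ij[2L]], weights, levels))
    mean(ks, na.rm = TRUE)
  }
  k <- pair_mean(m)
  pairwise <- combn(ncol(m), 2, function(ij)
    weighted_kappa(m[, ij[1L]], m[, ij[2L]], weights, levels))
  ci_low <- ci_high <- NA_real_
  if (ci) {
    boot <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        rows <- sample.int(nrow(m), replace = TRUE)
        pair_mean(m[rows, , drop = FALSE])
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    qs <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    ci_low <- qs[1L]
    ci_high <- qs[2L]
  }
  out <- kappa_result(k, NA_real_, ci_low, ci_high, NA_real_, NA_real_,
                      nrow(m),
                      sprintf("mean pairwise %s-weighted kappa (%d raters%s)",
                              weights, ncol(m),
                              if (ci) ", bootstrap CI" else ""))
  attr(out, "pairwise") <- pairwise
  out
}

#' Fleiss' kappa (unweighted, nominal)
#'
#' The classical multi-rater agreement statistic for nominal categories,
#' provided for comparison with the weighted pairwise statistic of
#' [multirater_kappa()].
#'
#' @param ratings matrix or data frame, photos in rows, raters in columns,
#'   complete design.
#' @param levels category levels.
#' @return kappa value.
#' @export
fleiss_kappa <- function(ratings, levels = NULL) {
  m <- as.matrix(ratings)
  stopifnot(ncol(m) >= 2L, !anyNA(m))
  levels <- rating_levels(as.vector(m), levels = levels)
  n <- nrow(m)
  r <- ncol(m)
  counts <- t(apply(m, 1L, function(row)
    tabulate(factor(row, levels = levels), nbins = length(levels))))
  pj <- colSums(counts) / (n * r)
  pi_ <- (rowSums(counts^2) - r) / (r * (r - 1L))
  pbar <- mean(pi_)
  pe <- sum(pj^2)
  if (pe >= 1) return(NA_real_)
  (pbar - pe) / (1 - pe)
}

#' Paired t-test between sessions
#'
#' Classical paired t-test on `first - second` with a 95% confidence
#' interval from the t quantile at `n - 1` degrees of freedom.  Zero
#' variance of the differences (for example identical sessions) yields a
#' degenerate-test report rather than an error.
#'
#' @param first,second equal-length numeric vectors (one value per rater).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `paired_t`: list with `mean_difference`,
#'   `ci_low`, `ci_high`, `statistic`, `df`, `p_value`, `degenerate`.
#' @export
paired_t <- function(first, second, conf_level = 0.95) {
  stopifnot(is.numeric(first), is.numeric(second),
            length(first) == length(second), length(first) >= 2L)
  d <- first - second
  if (sd(d) == 0) {
    return(structure(list(mean_difference = mean(d), ci_low = NA_real_,
                          ci_high = NA_real_, statistic = NA_real_,
                          df = length(d) - 1L, p_value = NA_real_,
                          degenerate = TRUE), class = "paired_t"))
  }
  tt <- t.test(first, second, paired = TRUE, conf.level = conf_level)
  structure(list(mean_difference = unname(tt$estimate),
                 ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 degenerate = FALSE), class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<paired_t> degenerate: zero-variance differences (mean %g)\n",
                x$mean_difference))
  } else {
    cat(sprintf(
      "<paired_t> mean difference %0.2f (95%% CI %0.2f-%0.2f), t(%d) = %0.2f, p = %0.3f\n",
      x$mean_difference, x$ci_low, x$ci_high, x$df, x$statistic, x$p_value))
  }
  invisible(x)
}
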