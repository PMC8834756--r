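# S/M/L labelling of surrogate PI and the HKL-angle screening rule.

PI_LEVELS <- c("S", "M", "L")

#' Quartile boundaries of a surrogate-PI sample
#'
#' First and third quartiles of the empirical distribution, used as the
#' S/M and M/L class boundaries.  Quantiles use linear interpolation between
#' order statistics (R's default type 7).
#'
#' @param angles numeric vector of surrogate-PI angles (degrees), `NA`
#'   dropped.
#' @return named numeric vector `c(s_boundary = , l_boundary = )`.
#' @examples
#' quartile_boundaries(1:8) # 2.75, 6.25
#' @export
quartile_boundaries <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 4L)
    stop("quartile boundaries need at least 4 values", call. = FALSE)
  q <- quantile(angles, c(0.25, 0.75), names = FALSE, type = 7)
  c(s_boundary = q[1L], l_boundary = q[2L])
}

#' Ordinal S/M/L label for surrogate-PI angles
#'
#' Classifies angles as small (`S`, below `s_boundary`), medium (`M`, from
#' `s_boundary` up to but excluding `l_boundary`) or large (`L`, at or above
#' `l_boundary`).  Boundary membership follows the convention that a value
#' equal to a boundary belongs to the upper class (42 is M, 51 is L with the
#' default boundaries).
#'
#' Equal boundaries (a degenerate, e.g. constant, cohort) collapse the M
#' band; values at the common boundary are then labelled `M`, so a constant
#' cohort is all-medium rather than all-large.
#'
#' @param angle numeric vector of surrogate-PI angles in degrees.
#' @param s_boundary,l_boundary class boundaries in degrees (defaults 42
#'   and 51, the first and third quartiles of the reference cohort).
#' @return ordered factor with levels `S < M < L`.
#' @examples
#' label_pi(c(41.9, 42, 51)) # S M L
#' @export
label_pi <- function(angle, s_boundary = 42, l_boundary = 51) {
  stopifnot(is.numeric(angle), s_boundary <= l_boundary)
  is_l <- angle > l_boundary | (angle == l_boundary & l_boundary > s_boundary)
  out <- ifelse(is.na(angle), NA_character_,
                ifelse(angle < s_boundary, "S",
                       ifelse(is_l, "L", "M")))
  factor(out, levels = PI_LEVELS, ordered = TRUE)
}

#' Dichotomize ordinal PI labels
#'
#' The ordinal S/M/L outcome induces two binary splits used in the ROC
#' analyses: `s_vs_ml` (small vs medium-or-large) and `sm_vs_l`
#' (small-or-medium vs large).
#'
#' @param labels factor of S/M/L labels from [label_pi()].
#' @return data frame with factor columns `s_vs_ml` (levels `S`, `ML`) and
#'   `sm_vs_l` (levels `SM`, `L`).
#' @export
pi_dichotomies <- function(labels) {
  lab <- as.character(labels)
  data.frame(
    s_vs_ml = factor(ifelse(is.na(lab), NA, ifelse(lab == "S", "S", "ML")),
                     levels = c("S", "ML")),
    sm_vs_l = factor(ifelse(is.na(lab), NA, ifelse(lab == "L", "L", "SM")),
                     levels = c("SM", "L"))
  )
}

#' Screening-tool thresholds on HKL angle C
#'
#' The screening tool splits the HKL angle C scale into S/M/L regions at two
#' thresholds.  The thresholds must be at least `min_separation` degrees
#' apart so the M band stays readable on the physical tool.
#'
#' @param s_ml_cutoff degrees; below it the tool reads S (default 18.5).
#' @param sm_l_cutoff degrees; at or above it the tool reads L (default
#'   21.5).
#' @param min_separation minimum allowed `sm_l_cutoff - s_ml_cutoff`
#'   (default 3).
#' @return object of class `tool_thresholds`.
#' @export
tool_thresholds <- function(s_ml_cutoff = 18.5, sm_l_cutoff = 21.5,
                            min_separation = 3) {
  stopifnot(is.numeric(s_ml_cutoff), is.numeric(sm_l_cutoff),
            s_ml_cutoff > 0, sm_l_cutoff > 0)
  if (sm_l_cutoff - s_ml_cutoff < min_separation)
    stop("tool thresholds must be separated by at least ", min_separation,
         " degrees", call. = FALSE)
  structure(list(s_ml_cutoff = s_ml_cutoff, sm_l_cutoff = sm_l_cutoff,
                 min_separation = min_separation),
            class = "tool_thresholds")
}

#' @export
print.tool_thresholds <- function(x, ...) {
  cat(sprintf("<tool_thresholds> S | %g | M | %g | L (min separation %g)\n",
              x$s_ml_cutoff, x$sm_l_cutoff, x$min_separation))
  invisible(x)
}

#' Apply the screening tool to HKL angle C values
#'
#' The hard classification rule of the tool: `S` below the S/ML threshold,
#' `L` at or above the SM/L threshold, `M` in between.
#'
#' @param hkl_c numeric vector of HKL angle C values in degrees.
#' @param thresholds a [tool_thresholds()] object.
#' @return ordered factor with levels `S < M < L`.
#' @examples
#' classify_by_tool(c(17, 19, 23)) # S M L
#' @export
classify_by_tool <- function(hkl_c, thresholds = tool_thresholds()) {
  stopifnot(is.numeric(hkl_c), inherits(thresholds, "tool_thresholds"))
  out <- ifelse(is.na(hkl_c), NA_character_,
                ifelse(hkl_c < thresholds$s_ml_cutoff, "S",
                       ifelse(hkl_c < thresholds$sm_l_cutoff, "M", "L")))
  factor(out, levels = PI_LEVELS, ordered = TRUE)
}

#' Per-subject label table
#'
#' Combines surrogate-PI labels, their dichotomies and the tool reading for
#' a cohort, ready to write as the label CSV.
#'
#' @param angles data frame from [hkl_angle_table()] (needs columns
#'   `subject_id`, `surrogate_pi`, `c`).
#' @param s_boundary,l_boundary PI class boundaries; `NULL` (default) uses
#'   the cohort quartiles via [quartile_boundaries()].
#' @param thresholds a [tool_thresholds()] object for the tool reading.
#' @return data frame `subject_id, surrogate_pi, ordinal, s_vs_ml, sm_vs_l,
#'   tool_label`.
#' @export
label_table <- function(angles, s_boundary = NULL, l_boundary = NULL,
                        thresholds = tool_thresholds()) {
  stopifnot(all(c("subject_id", "surrogate_pi", "c") %in% names(angles)))
  if (is.null(s_boundary) || is.null(l_boundary)) {
    qb <- quartile_boundaries(angles$surrogate_pi)
    s_boundary <- s_boundary %||% qb[["s_boundary"]]
    l_boundary <- l_boundary %||% qb[["l_boundary"]]
  }
  ord <- label_pi(angles$surrogate_pi, s_boundary, l_boundary)
  dich <- pi_dichotomies(ord)
  out <- data.frame(subject_id = angles$subject_id,
                    surrogate_pi = angles$surrogate_pi,
                    ordinal = ord, dich,
                    tool_label = classify_by_tool(angles$c, thresholds),
                    stringsAsFactors = FALSE)
  attr(out, "boundaries") <- c(s_boundary = s_boundary,
                               l_boundary = l_boundary)
  out
}
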