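# Diagnostic accuracy: cut-off grids, trapezoidal ROC AUC, accuracy bands,
# and the cut-off acceptance procedure.

#' Sensitivity/specificity/Youden grid over candidate cut-offs
#'
#' For each cut-off, a subject tests positive when its score falls on the
#' `direction` side of the cut-off (`"<"`: below; `">="`: at or above).
#' Sensitivity is the true-positive rate among subjects in the positive
#' class, specificity the true-negative rate among the rest, and the Youden
#' index their sum minus one.
#'
#' When reproducing the published grids for the PI dichotomies, the positive
#' class is the upper-PI side (`ML` or `L`) and the test is positive at or
#' above the cut-off (`direction = ">="`), since a larger HKL angle indicates
#' a larger PI; [run_study1()] uses that orientation.
#'
#' @param scores numeric vector of per-subject HKL angles (degrees).
#' @param labels class labels (factor, character or logical), one per score.
#' @param cutoffs ascending candidate cut-offs; `NULL` (default) uses the
#'   midpoints between consecutive distinct scores plus one point below and
#'   one above the observed range.
#' @param positive the level of `labels` counted as the positive (detected)
#'   class; defaults to `TRUE` for logical labels and to the value
#'   `"positive"` when present.
#' @param direction `"<"` (test positive below the cut-off) or `">="` (at or
#'   above).
#' @param dichotomy,stratum optional descriptors carried into the result.
#' @return data frame of class `cutoff_grid` with columns `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, plus attributes `positive`,
#'   `direction`, `n_pos`, `n_neg`, `dichotomy`, `stratum`.
#' @examples
#' cutoff_grid(c(10, 30), c("positive", "negative"), cutoffs = 20)
#' @export
cutoff_grid <- function(scores, labels, cutoffs = NULL, positive = NULL,
                        direction = c("<", ">="), dichotomy = NA_character_,
                        stratum = "total") {
  direction <- match.arg(direction)
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (is.null(positive)) {
    positive <- if (is.logical(labels)) TRUE
      else if ("positive" %in% as.character(labels)) "positive"
      else stop("'positive' must name the detected class", call. = FALSE)
  }
  is_pos <- if (is.logical(labels)) labels == positive
            else as.character(labels) == as.character(positive)
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate labels: need at least one positive and one negative ",
         "subject", call. = FALSE)
  if (is.null(cutoffs)) cutoffs <- default_cutoffs(scores)
  stopifnot(length(cutoffs) > 0, !is.unsorted(cutoffs, strictly = TRUE))
  rows <- vapply(cutoffs, function(cc) {
    test_pos <- if (direction == "<") scores < cc else scores >= cc
    c(sensitivity = mean(test_pos[is_pos]),
      specificity = mean(!test_pos[!is_pos]))
  }, numeric(2))
  out <- data.frame(cutoff = cutoffs, sensitivity = rows["sensitivity", ],
                    specificity = rows["specificity", ])
  out$youden <- out$sensitivity + out$specificity - 1
  structure(out, class = c("cutoff_grid", "data.frame"),
            positive = positive, direction = direction,
            n_pos = n_pos, n_neg = n_neg,
            dichotomy = dichotomy, stratum = stratum)
}

# Candidate cut-offs from raw scores: midpoints between consecutive distinct
# values, flanked by one point below and one above the observed range (the
# published grids use the same pattern for half-degree-recorded angles).
default_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) return(c(u - 0.5, u + 0.5))
  mids <- (u[-1L] + u[-length(u)]) / 2
  h <- max(stats::median(diff(u)) / 2, .Machine$double.eps * max(abs(u), 1))
  c(u[1L] - h, mids, u[length(u)] + h)
}

#' Assemble a cutoff grid from stored sensitivity/specificity values
#'
#' Wraps an existing table of cut-off rows (for instance a published grid)
#' as a `cutoff_grid`, recomputing the Youden column where absent and
#' flagging rows whose stored Youden index disagrees with
#' `sensitivity + specificity - 1` beyond `tol` (printed tables are rounded,
#' so small discrepancies are expected; larger ones indicate typos and are
#' reported in attribute `inconsistent_rows`).
#'
#' @param df data frame with columns `cutoff`, `sensitivity`, `specificity`
#'   and optionally `youden`.
#' @param dichotomy,stratum descriptors carried into the result.
#' @param tol tolerance for the stored-Youden consistency check (default
#'   0.015, the rounding slack of 2-decimal tables).
#' @return a `cutoff_grid` (rows with missing sensitivity/specificity are
#'   kept as `NA`).
#' @export
as_cutoff_grid <- function(df, dichotomy = NA_character_, stratum = "total",
                           tol = 0.015) {
  stopifnot(all(c("cutoff", "sensitivity", "specificity") %in% names(df)))
  df <- df[order(df$cutoff), , drop = FALSE]
  if (anyDuplicated(df$cutoff))
    stop("cut-offs must be strictly increasing", call. = FALSE)
  recomputed <- df$sensitivity + df$specificity - 1
  if (is.null(df$youden)) df$youden <- recomputed
  bad <- which(!is.na(df$youden) & !is.na(recomputed) &
                 abs(df$youden - recomputed) > tol)
  out <- df[c("cutoff", "sensitivity", "specificity", "youden")]
  rownames(out) <- NULL
  structure(out, class = c("cutoff_grid", "data.frame"),
            positive = NA_character_, direction = ">=",
            n_pos = NA_integer_, n_neg = NA_integer_,
            dichotomy = dichotomy, stratum = stratum,
            inconsistent_rows = df$cutoff[bad])
}

#' Trapezoidal area under the empirical ROC curve
#'
#' Operating points `(1 - specificity, sensitivity)` are augmented with the
#' corners (0,0) and (1,1), sorted by false-positive rate and then by
#' sensitivity, and integrated with the trapezoid rule; vertical runs of the
#' curve contribute zero width and tied scores their diagonal segments, so
#' on a grid containing every achievable threshold the result equals the
#' Mann-Whitney statistic (ties counted half).  Rows with missing
#' sensitivity or specificity are dropped.
#'
#' @param grid a [cutoff_grid()] or any data frame with `sensitivity` and
#'   `specificity` columns.
#' @return AUC in `[0, 1]`.
#' @examples
#' trapezoidal_auc(data.frame(sensitivity = 1, specificity = 1)) # 1
#' @export
trapezoidal_auc <- function(grid) {
  stopifnot(all(c("sensitivity", "specificity") %in% names(grid)))
  ok <- !is.na(grid$sensitivity) & !is.na(grid$specificity)
  if (!any(ok)) stop("empty grid: no complete operating points",
                     call. = FALSE)
  fpr <- c(1 - grid$specificity[ok], 0, 1)
  tpr <- c(grid$sensitivity[ok], 0, 1)
  o <- order(fpr, tpr)
  x <- fpr[o]
  y <- tpr[o]
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Verbal accuracy band for an AUC
#'
#' Discrimination bands: below-chance under 0.5, low in `[0.5, 0.7)`,
#' moderate in `[0.7, 0.9]`, high above 0.9.
#'
#' @param auc numeric vector of AUC values in `[0, 1]`.
#' @return character vector of bands.
#' @examples
#' accuracy_band(c(0.93, 0.82, 0.61))
#' @export
accuracy_band <- function(auc) {
  stopifnot(is.numeric(auc), all(is.na(auc) | (auc >= 0 & auc <= 1)))
  ifelse(is.na(auc), NA_character_,
         ifelse(auc < 0.5, "below-chance",
                ifelse(auc < 0.7, "low",
                       ifelse(auc <= 0.9, "moderate", "high"))))
}

#' Cut-off acceptance procedure
#'
#' A cut-off is acceptable when both sensitivity and specificity clear the
#' floor; with `strict = TRUE` (default) they must strictly exceed it after
#' rounding to `digits` decimals, with `strict = FALSE` equality passes.
#' The acceptable range should contain the cut-off with the maximum Youden
#' index; the result records whether it does (`youden_in_range`) rather than
#' failing when it does not.  The chosen cut-off is the lower endpoint of
#' the acceptable range.  An empty range is a legitimate outcome (some
#' strata admit no acceptable cut-off) and is returned with diagnostics.
#'
#' @param grid a [cutoff_grid()].
#' @param floor minimum sensitivity and specificity (default 0.7).
#' @param strict require strict exceedance of the floor (default `TRUE`).
#' @param digits decimals at which values are compared against the floor
#'   (default 2, matching published precision).
#' @return object of class `cutoff_selection`: list with
#'   `acceptable_cutoffs`, `acceptable_range` (length-2 numeric or `NULL`),
#'   `chosen_cutoff` (`NA` when the range is empty), `max_youden`,
#'   `max_youden_cutoff`, `youden_in_range`, `floor`, `strict`, `dichotomy`,
#'   `stratum`.
#' @export
select_cutoffs <- function(grid, floor = 0.7, strict = TRUE, digits = 2) {
  stopifnot(inherits(grid, "data.frame"),
            all(c("cutoff", "sensitivity", "specificity", "youden") %in%
                  names(grid)))
  sens <- round(grid$sensitivity, digits)
  spec <- round(grid$specificity, digits)
  ok <- if (strict) sens > floor & spec > floor
        else sens >= floor & spec >= floor
  ok[is.na(ok)] <- FALSE
  yi <- grid$youden
  max_youden <- if (all(is.na(yi))) NA_real_ else max(yi, na.rm = TRUE)
  max_youden_cutoff <- if (is.na(max_youden)) NA_real_
    else grid$cutoff[which.max(yi)]
  idx <- which(ok)
  if (length(idx) && any(diff(idx) > 1L)) {
    # non-contiguous qualifying set: keep the run containing the Youden
    # maximum if it qualifies, else the longest run
    runs <- split(idx, cumsum(c(1L, diff(idx) > 1L)))
    hit <- vapply(runs, function(r) max_youden_cutoff %in% grid$cutoff[r],
                  logical(1))
    idx <- if (any(hit)) runs[[which(hit)[1L]]]
      else runs[[which.max(lengths(runs))]]
    warning("acceptable cut-offs are not contiguous; keeping one run",
            call. = FALSE)
  }
  acceptable <- grid$cutoff[idx]
  structure(list(
    acceptable_cutoffs = acceptable,
    acceptable_range = if (length(acceptable))
      c(min(acceptable), max(acceptable)) else NULL,
    chosen_cutoff = if (length(acceptable)) min(acceptable) else NA_real_,
    max_youden = max_youden,
    max_youden_cutoff = max_youden_cutoff,
    youden_in_range = length(acceptable) > 0 &&
      !is.na(max_youden_cutoff) && max_youden_cutoff %in% acceptable,
    floor = floor, strict = strict,
    dichotomy = attr(grid, "dichotomy"), stratum = attr(grid, "stratum")
  ), class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  hdr <- sprintf("<cutoff_selection> %s / %s",
                 x$dichotomy %||% "?", x$stratum %||% "?")
  cat(hdr, "\n")
  if (is.null(x$acceptable_range)) {
    cat("  no acceptable cut-off (floor", x$floor,
        if (x$strict) "strict" else "non-strict", ")\n")
  } else {
    cat(sprintf("  acceptable range: %g-%g, chosen %g\n",
                x$acceptable_range[1L], x$acceptable_range[2L],
                x$chosen_cutoff))
  }
  cat(sprintf("  max Youden %0.2f at %g (inside range: %s)\n",
              x$max_youden, x$max_youden_cutoff, x$youden_in_range))
  invisible(x)
}

#' Joint selection of the two tool thresholds
#'
#' Applies [select_cutoffs()] to the S/ML and SM/L grids and pairs the
#' results into screening-tool thresholds: the S/ML threshold is the lower
#' endpoint of its acceptable range, and the SM/L threshold is the smallest
#' acceptable cut-off at least `min_separation` degrees above it (falling
#' back, with `separation_ok = FALSE`, to the lower endpoint of the SM/L
#' range when none is).
#'
#' @param grid_s_ml,grid_sm_l [cutoff_grid()]s for the two dichotomies.
#' @param floor,strict,digits passed to [select_cutoffs()].
#' @param min_separation minimum threshold separation in degrees (default 3).
#' @return list with the two `cutoff_selection`s, `s_ml_cutoff`,
#'   `sm_l_cutoff`, `separation_ok` and (when both thresholds exist and are
#'   separated) a [tool_thresholds()] object under `thresholds`.
#' @export
select_tool_thresholds <- function(grid_s_ml, grid_sm_l, floor = 0.7,
                                   strict = TRUE, digits = 2,
                                   min_separation = 3) {
  sel1 <- select_cutoffs(grid_s_ml, floor, strict, digits)
  sel2 <- select_cutoffs(grid_sm_l, floor, strict, digits)
  s_ml <- sel1$chosen_cutoff
  sm_l <- NA_real_
  separation_ok <- FALSE
  if (!is.na(s_ml) && length(sel2$acceptable_cutoffs)) {
    cand <- sel2$acceptable_cutoffs[sel2$acceptable_cutoffs >=
                                      s_ml + min_separation]
    if (length(cand)) {
      sm_l <- min(cand)
      separation_ok <- TRUE
    } else {
      sm_l <- sel2$chosen_cutoff
    }
  }
  list(selection_s_ml = sel1, selection_sm_l = sel2,
       s_ml_cutoff = s_ml, sm_l_cutoff = sm_l,
       separation_ok = separation_ok,
       thresholds = if (separation_ok)
         tool_thresholds(s_ml, sm_l, min_separation) else NULL)
}
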