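# Access to the packaged reference tables: the published cut-off grid for
# HKL angle C (per dichotomy and stratum) and the published per-rater
# usability/reliability table.  Values are stored verbatim, including
# absent cells and printed rounding.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "hklpi")
  if (p == "") stop("fixture '", file, "' not found", call. = FALSE)
  p
}

#' Published cut-off grid for HKL angle C
#'
#' Sensitivity/specificity/Youden rows of the reference study's grid for
#' one dichotomy and stratum, as a [cutoff_grid()].  Values are the printed
#' 2-decimal numbers; rows absent in the printed table have `NA` entries.
#' Rows whose printed Youden index disagrees with
#' `sensitivity + specificity - 1` beyond printed-rounding tolerance are
#' listed in attribute `inconsistent_rows` (three such typos exist in the
#' source table, all outside the total stratum's acceptable ranges).
#'
#' @param dichotomy `"s_ml"` or `"sm_l"`.
#' @param stratum `"total"`, `"male"` or `"female"`.
#' @return a `cutoff_grid`.
#' @examples
#' round(trapezoidal_auc(table1_grid("s_ml", "total")), 2) # 0.93
#' @export
table1_grid <- function(dichotomy = c("s_ml", "sm_l"),
                        stratum = c("total", "male", "female")) {
  dichotomy <- match.arg(dichotomy)
  stratum <- match.arg(stratum)
  df <- read.csv(fixture_path("table1_hkl_c.csv"), stringsAsFactors = FALSE)
  df <- df[df$dichotomy == dichotomy & df$stratum == stratum,
           c("cutoff", "sensitivity", "specificity", "youden")]
  as_cutoff_grid(df, dichotomy = dichotomy, stratum = stratum)
}

#' Published usability and reliability table
#'
#' Per-rater mean times (s/photo), correct rates (%), and intra-rater
#' Cohen's kappa with 95% CI (total and by photographed-subject sex) for
#' the 14 examiners of the reference study, plus the session-level
#' inter-rater weighted kappa values.  The per-rater kappas are stored as
#' printed; only column summaries are reproducible without the raw ratings.
#'
#' @return list with data frames `per_rater` and `interrater`.
#' @examples
#' round(mean(table2_reliability()$per_rater$time_s1), 1) # 17.0
#' @export
table2_reliability <- function() {
  list(per_rater = read.csv(fixture_path("table2_reliability.csv"),
                            stringsAsFactors = FALSE),
       interrater = read.csv(fixture_path("table2_interrater.csv"),
                             stringsAsFactors = FALSE))
}

#' Column summaries of the published reliability table
#'
#' Recomputes the derived statistics of the usability/reliability table
#' from its per-rater rows: session means and SDs of time and correct
#' rate, mean intra-rater kappas, and the paired t-tests comparing the two
#' sessions.
#'
#' @return list with `mean_time` (length-2), `sd_time`, `mean_correct`,
#'   `sd_correct`, `mean_kappa` (total/male/female), `t_time` and
#'   `t_correct` ([paired_t()] results).
#' @export
table2_summary <- function() {
  pr <- table2_reliability()$per_rater
  list(
    mean_time = c(mean(pr$time_s1), mean(pr$time_s2)),
    sd_time = c(sd(pr$time_s1), sd(pr$time_s2)),
    mean_correct = c(mean(pr$correct_s1), mean(pr$correct_s2)),
    sd_correct = c(sd(pr$correct_s1), sd(pr$correct_s2)),
    mean_kappa = c(total = mean(pr$kappa_total),
                   male = mean(pr$kappa_male),
                   female = mean(pr$kappa_female)),
    t_time = paired_t(pr$time_s1, pr$time_s2),
    t_correct = paired_t(pr$correct_s1, pr$correct_s2)
  )
}
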