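#!/usr/bin/env Rscript

# Thin command-line wrapper over the hklpi package.
#
#   Rscript scripts/hklpi.R angles --landmarks in.csv --out angles.csv [--y-down]
#   Rscript scripts/hklpi.R classify --landmarks in.csv --out labels.csv
#   Rscript scripts/hklpi.R roc --landmarks in.csv --out report_dir [--seed N]
#   Rscript scripts/hklpi.R select-cutoffs --grid grid.csv --dichotomy s_ml
#       [--floor 0.7] [--non-strict]
#   Rscript scripts/hklpi.R reliability --ratings r.csv [--times t.csv]
#       --out report_dir [--seed N]
#   Rscript scripts/hklpi.R simulate-cohort --n 125 --seed 42
#       --out landmarks.csv --truth truth.csv
#   Rscript scripts/hklpi.R simulate-ratings --photos 24 --seed 7
#       --preset reference --out ratings.csv --times times.csv
#   Rscript scripts/hklpi.R reproduce-paper

suppressPackageStartupMessages({
  library(optparse)
  library(hklpi)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0) stop("usage: hklpi.R <subcommand> [options]")
cmd <- argv[1L]
rest <- argv[-1L]

opt <- function(...) parse_args(OptionParser(option_list = list(...)),
                                args = rest)
note <- function(...) message(...)  # logging goes to stderr

if (cmd == "angles" || cmd == "classify") {
  o <- opt(make_option("--landmarks", type = "character"),
           make_option("--out", type = "character"),
           make_option("--y-down", action = "store_true", default = FALSE,
                       dest = "y_down"),
           make_option("--digits", type = "integer", default = NULL))
  lms <- read_landmarks(o$landmarks, y_down = o$y_down)
  ang <- hkl_angle_table(lms)
  if (cmd == "angles") {
    write_angles(ang, o$out, digits = o$digits)
  } else {
    write.csv(label_table(ang), o$out, row.names = FALSE, na = "")
  }
  note("wrote ", o$out, " (", nrow(ang), " subjects)")

} else if (cmd == "roc") {
  o <- opt(make_option("--landmarks", type = "character"),
           make_option("--out", type = "character", default = "roc_report"),
           make_option("--floor", type = "double", default = 0.7),
           make_option("--non-strict", action = "store_false",
                       default = TRUE, dest = "strict"),
           make_option("--seed", type = "integer", default = NULL))
  lms <- read_landmarks(o$landmarks)
  res <- run_study1(lms, floor = o$floor, strict = o$strict)
  print(res)
  write_report(res, o$out, seed = o$seed,
               inputs = list(landmarks = o$landmarks))
  note("report in ", o$out)

} else if (cmd == "select-cutoffs") {
  o <- opt(make_option("--grid", type = "character"),
           make_option("--dichotomy", type = "character", default = "s_ml"),
           make_option("--stratum", type = "character", default = "total"),
           make_option("--floor", type = "double", default = 0.7),
           make_option("--non-strict", action = "store_false",
                       default = TRUE, dest = "strict"))
  df <- read.csv(o$grid, stringsAsFactors = FALSE)
  if ("dichotomy" %in% names(df))
    df <- df[df$dichotomy == o$dichotomy & df$stratum == o$stratum, ]
  g <- as_cutoff_grid(df, o$dichotomy, o$stratum)
  print(select_cutoffs(g, floor = o$floor, strict = o$strict))

} else if (cmd == "reliability") {
  o <- opt(make_option("--ratings", type = "character"),
           make_option("--times", type = "character", default = NULL),
           make_option("--out", type = "character",
                       default = "reliability_report"),
           make_option("--seed", type = "integer", default = NULL),
           make_option("--bootstrap", type = "integer", default = 2000))
  rt <- read_ratings(o$ratings, o$times)
  res <- run_study2(rt, B = o$bootstrap, seed = o$seed)
  print(res)
  write_report(res, o$out, seed = o$seed,
               inputs = list(ratings = o$ratings, times = o$times))
  note("report in ", o$out)

} else if (cmd == "simulate-cohort") {
  o <- opt(make_option("--n", type = "integer", default = 125),
           make_option("--seed", type = "integer", default = 1L),
           make_option("--out", type = "character", default = "landmarks.csv"),
           make_option("--truth", type = "character", default = NULL))
  co <- generate_cohort(cohort_spec(n = o$n, seed = o$seed))
  write_landmarks(co$landmarks, o$out)
  if (!is.null(o$truth)) write.csv(co$truth, o$truth, row.names = FALSE)
  note("wrote ", o$out)

} else if (cmd == "simulate-ratings") {
  o <- opt(make_option("--photos", type = "integer", default = 24),
           make_option("--seed", type = "integer", default = 1L),
           make_option("--preset", type = "character", default = "reference"),
           make_option("--raters", type = "integer", default = 14),
           make_option("--out", type = "character", default = "ratings.csv"),
           make_option("--times", type = "character", default = NULL))
  rt <- simulate_ratings(photo_mix(o$photos, seed = o$seed),
                         rater_preset(o$preset, n_raters = o$raters,
                                      seed = o$seed))
  write_ratings(rt, o$out, o$times)
  note("wrote ", o$out)

} else if (cmd == "reproduce-paper") {
  checks <- reproduce_paper()
  if (!all(checks$pass)) quit(status = 1L)

} else {
  stop("unknown subcommand: ", cmd)
}
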