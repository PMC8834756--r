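# Container for rater x photo x session ordinal classifications with an
# external criterion label per photo, plus optional per-rater times.

#' Assemble a rating table
#'
#' Holds the full Study-2-style design: every rater classifies every photo
#' as S/M/L in each of two sessions, each photo carries a criterion label
#' (its surrogate-PI class), and each rater may carry a mean classification
#' time per session.  The design must be complete; missing cells are named
#' in the error.
#'
#' @param ratings long data frame with columns `photo_id`, `rater_id`,
#'   `session` (1 or 2), `label` (S/M/L).
#' @param criterion data frame with columns `photo_id`, `criterion`, and
#'   optionally `sex` (sex of the photographed subject, for stratified
#'   reliability).
#' @param times optional data frame with columns `rater_id`, `session`,
#'   `mean_time_s`.
#' @return object of class `rating_table`.
#' @seealso [simulate_ratings()], [read_ratings()], [run_study2()]
#' @export
rating_table <- function(ratings, criterion, times = NULL) {
  stopifnot(all(c("photo_id", "rater_id", "session", "label") %in%
                  names(ratings)),
            all(c("photo_id", "criterion") %in% names(criterion)))
  ratings$photo_id <- as.character(ratings$photo_id)
  ratings$rater_id <- as.character(ratings$rater_id)
  ratings$session <- as.integer(ratings$session)
  ratings$label <- as.character(ratings$label)
  criterion$photo_id <- as.character(criterion$photo_id)
  if (!all(ratings$label %in% PI_LEVELS))
    stop("rating labels must be S, M or L", call. = FALSE)
  if (!all(criterion$criterion %in% PI_LEVELS))
    stop("criterion labels must be S, M or L", call. = FALSE)
  if (anyDuplicated(criterion$photo_id))
    stop("duplicate photo_id in criterion table", call. = FALSE)
  if (!all(ratings$photo_id %in% criterion$photo_id))
    stop("ratings reference photos absent from the criterion table",
         call. = FALSE)
  photos <- criterion$photo_id
  raters <- sort(unique(ratings$rater_id))
  sessions <- sort(unique(ratings$session))
  want <- expand.grid(photo_id = photos, rater_id = raters,
                      session = sessions, stringsAsFactors = FALSE)
  key <- function(d) paste(d$photo_id, d$rater_id, d$session, sep = "\r")
  missing <- setdiff(key(want), key(ratings))
  if (length(missing)) {
    parts <- strsplit(missing[seq_len(min(5L, length(missing)))], "\r")
    stop("incomplete design: missing ", length(missing), " cell(s), e.g. ",
         paste(vapply(parts, function(p)
           sprintf("photo %s / rater %s / session %s", p[1L], p[2L], p[3L]),
           character(1)), collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(key(ratings)))
    stop("duplicate (photo, rater, session) cells in ratings",
         call. = FALSE)
  structure(list(ratings = ratings, criterion = criterion, times = times,
                 photos = photos, raters = raters, sessions = sessions),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating_table> %d photos x %d raters x %d sessions\n",
              length(x$photos), length(x$raters), length(x$sessions)))
  mix <- table(factor(x$criterion$criterion, levels = PI_LEVELS))
  cat("  criterion mix:", paste(names(mix), mix, sep = "=", collapse = " "),
      "\n")
  if (!is.null(x$times)) cat("  per-rater times available\n")
  invisible(x)
}

#' Photos-by-raters matrix for one session
#'
#' @param rt a [rating_table()].
#' @param session session number.
#' @return character matrix, photos in rows (criterion order), raters in
#'   columns.
#' @export
ratings_matrix <- function(rt, session) {
  stopifnot(inherits(rt, "rating_table"), session %in% rt$sessions)
  sub <- rt$ratings[rt$ratings$session == session, ]
  m <- matrix(NA_character_, nrow = length(rt$photos),
              ncol = length(rt$raters),
              dimnames = list(rt$photos, rt$raters))
  m[cbind(match(sub$photo_id, rt$photos),
          match(sub$rater_id, rt$raters))] <- sub$label
  m
}

#' Read ratings (and optional times) from CSV
#'
#' The rating CSV has columns `photo_id`, `criterion`, `rater_id`,
#' `session`, `label`, optionally `sex` (of the photographed subject); the
#' times CSV has `rater_id`, `session`, `mean_time_s`.
#'
#' @param path rating CSV path.
#' @param times_path optional times CSV path.
#' @return a [rating_table()].
#' @export
read_ratings <- function(path, times_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  crit_cols <- intersect(c("photo_id", "criterion", "sex"), names(df))
  criterion <- unique(df[crit_cols])
  times <- if (!is.null(times_path))
    read.csv(times_path, stringsAsFactors = FALSE)
  rating_table(df[c("photo_id", "rater_id", "session", "label")],
               criterion, times)
}

#' Write a rating table to CSV
#'
#' @param rt a [rating_table()].
#' @param path rating CSV path.
#' @param times_path optional path for the times CSV.
#' @export
write_ratings <- function(rt, path, times_path = NULL) {
  stopifnot(inherits(rt, "rating_table"))
  df <- merge(rt$ratings, rt$criterion, by = "photo_id", sort = FALSE)
  df <- df[order(df$session, df$rater_id,
                 match(df$photo_id, rt$photos)), ]
  write.csv(df, path, row.names = FALSE)
  if (!is.null(times_path) && !is.null(rt$times))
    write.csv(rt$times, times_path, row.names = FALSE)
  invisible(path)
}
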