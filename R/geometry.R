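# Geometry of sagittal-plane landmarks: HKL angle variants and surrogate PI.
#
# Coordinate convention: x increases toward the subject's front, y increases
# upward (photographs digitized with y growing downward must be flipped at
# ingest; see read_landmarks(y_down = TRUE)).  All angles are unsigned
# degrees and are scale-free, so the length unit only has to be consistent
# within one landmark set.

LANDMARK_NAMES <- c(
  "head_top", "buttock_apex", "knee_anterior", "knee_central",
  "knee_posterior", "thigh_center", "trochanter_top", "iliac_crest_top",
  "buttock_at_trochanter"
)

#' Construct a 2-D sagittal-plane point
#'
#' @param x horizontal coordinate, positive toward the subject's front.
#' @param y vertical coordinate, positive upward.
#' @return named numeric vector `c(x = , y = )`.
#' @examples
#' point2d(1.5, 90)
#' @export
point2d <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L)
    stop("point2d() needs scalar numeric x and y", call. = FALSE)
  if (!is.finite(x) || !is.finite(y))
    stop("point2d() coordinates must be finite", call. = FALSE)
  c(x = as.numeric(x), y = as.numeric(y))
}

is_point <- function(p) is.numeric(p) && length(p) == 2L && all(is.finite(p))

as_point <- function(p, name) {
  if (is.null(p)) return(NULL)
  if (!is_point(p))
    stop("landmark '", name, "' must be a finite numeric (x, y) pair",
         call. = FALSE)
  c(x = unname(p[[1L]]), y = unname(p[[2L]]))
}

#' Assemble a named landmark set for one subject
#'
#' Collects the sagittal-plane landmarks used by the HKL angle variants and
#' the surrogate-PI angle.  Any landmark may be omitted (`NULL`); operations
#' that need a missing landmark return `NA` or raise an informative error.
#' `knee_central` defaults, where needed, to the midpoint of
#' `knee_anterior`--`knee_posterior`.
#'
#' Basic posture invariants are checked when `validate = TRUE`: knee
#' landmarks lie below the thigh center and the buttock apex, and the
#' anterior knee point lies in front of (larger x than) the posterior one.
#'
#' @param subject_id identifier for the subject.
#' @param sex `"male"`, `"female"` or `"unspecified"`.
#' @param head_top,buttock_apex,knee_anterior,knee_central,knee_posterior,thigh_center
#'   silhouette landmarks as `(x, y)` pairs (see [point2d()]), or `NULL`.
#' @param trochanter_top,iliac_crest_top,buttock_at_trochanter palpation
#'   landmarks for the surrogate-PI angle, or `NULL`.
#' @param validate check posture invariants (default `TRUE`).
#' @return an object of class `landmark_set`.
#' @seealso [hkl_variants()], [surrogate_pi()], [read_landmarks()]
#' @examples
#' lm <- landmark_set("s1",
#'   buttock_apex = c(-14, 83), knee_anterior = c(5, 45),
#'   knee_posterior = c(-5, 45), thigh_center = c(0, 75)
#' )
#' hkl_c(lm)
#' @export
landmark_set <- function(subject_id, sex = c("unspecified", "male", "female"),
                         head_top = NULL, buttock_apex = NULL,
                         knee_anterior = NULL, knee_central = NULL,
                         knee_posterior = NULL, thigh_center = NULL,
                         trochanter_top = NULL, iliac_crest_top = NULL,
                         buttock_at_trochanter = NULL, validate = TRUE) {
  sex <- match.arg(sex)
  pts <- list(
    head_top = head_top, buttock_apex = buttock_apex,
    knee_anterior = knee_anterior, knee_central = knee_central,
    knee_posterior = knee_posterior, thigh_center = thigh_center,
    trochanter_top = trochanter_top, iliac_crest_top = iliac_crest_top,
    buttock_at_trochanter = buttock_at_trochanter
  )
  pts <- mapply(as_point, pts, names(pts), SIMPLIFY = FALSE)
  lm <- structure(c(list(subject_id = subject_id, sex = sex), pts),
                  class = "landmark_set")
  if (validate) validate_landmarks(lm)
  lm
}

validate_landmarks <- function(lm) {
  ka <- lm$knee_anterior; kp <- lm$knee_posterior
  if (!is.null(ka) && !is.null(kp) && ka[["x"]] <= kp[["x"]])
    stop("subject '", lm$subject_id,
         "': knee_anterior must lie in front of knee_posterior (larger x)",
         call. = FALSE)
  knees <- Filter(Negate(is.null), lm[c("knee_anterior", "knee_central",
                                        "knee_posterior")])
  knee_y <- vapply(knees, `[[`, numeric(1), "y")
  if (length(knee_y)) {
    if (!is.null(lm$thigh_center) && any(knee_y >= lm$thigh_center[["y"]]))
      stop("subject '", lm$subject_id,
           "': knee landmarks must lie below thigh_center", call. = FALSE)
    if (!is.null(lm$buttock_apex) && any(knee_y >= lm$buttock_apex[["y"]]))
      stop("subject '", lm$subject_id,
           "': knee landmarks must lie below buttock_apex", call. = FALSE)
  }
  # knee_central should sit on the anterior-posterior knee segment
  if (!is.null(lm$knee_central) && !is.null(ka) && !is.null(kp)) {
    mid <- (ka + kp) / 2
    off <- sqrt(sum((lm$knee_central - mid)^2))
    width <- sqrt(sum((ka - kp)^2))
    if (width > 0 && off > 0.25 * width)
      warning("subject '", lm$subject_id,
              "': knee_central is far from the anterior-posterior midpoint",
              call. = FALSE)
  }
  invisible(lm)
}

#' @export
print.landmark_set <- function(x, ...) {
  present <- LANDMARK_NAMES[!vapply(x[LANDMARK_NAMES], is.null, logical(1))]
  cat("<landmark_set> subject", x$subject_id, "(", x$sex, ")\n")
  cat("  landmarks:", paste(present, collapse = ", "), "\n")
  invisible(x)
}

#' Unsigned angle at an apex between two rays
#'
#' Returns the angle in degrees at `apex` between the rays `apex -> p1` and
#' `apex -> p2`, in `[0, 180]`.  Collinear but distinct points give 0 (or
#' 180) rather than an error; a point coinciding with the apex is a
#' degenerate geometry and raises an error naming the offending landmark.
#'
#' @param apex,p1,p2 points as `(x, y)` pairs.
#' @param labels length-3 character vector used in error messages.
#' @return angle in degrees.
#' @examples
#' angle_between(c(0, 0), c(1, 0), c(0, 1)) # 90
#' angle_between(c(0, 0), c(1, 0), c(1, 1)) # 45
#' @export
angle_between <- function(apex, p1, p2, labels = c("apex", "p1", "p2")) {
  stopifnot(is_point(apex), is_point(p1), is_point(p2))
  v1 <- p1 - apex
  v2 <- p2 - apex
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0)
    stop("degenerate geometry: '", labels[2L], "' coincides with '",
         labels[1L], "'", call. = FALSE)
  if (n2 == 0)
    stop("degenerate geometry: '", labels[3L], "' coincides with '",
         labels[1L], "'", call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

knee_central_point <- function(lm) {
  if (!is.null(lm$knee_central)) return(lm$knee_central)
  if (is.null(lm$knee_anterior) || is.null(lm$knee_posterior)) return(NULL)
  (lm$knee_anterior + lm$knee_posterior) / 2
}

#' HKL angle C: buttock apex vs the femoral axis
#'
#' Variant C of the hip-knee line angle: the angle at the knee center
#' between the ray toward the buttock apex and the ray toward the thigh
#' center (the femoral axis, i.e. the midthigh line).  The knee center
#' defaults to the midpoint of the anterior and posterior knee points.
#' This is the variant used by the screening tool; it is invariant under
#' translation, rotation and uniform scaling of the landmark coordinates.
#'
#' In normal posture the buttock apex lies posterior to the femoral axis; an
#' apex found anterior to the axis is physiologically implausible and
#' triggers a warning (the unsigned angle is still returned).
#'
#' @param lm a [landmark_set()].
#' @return angle C in degrees, or `NA` if required landmarks are absent.
#' @examples
#' lm <- landmark_set("s1",
#'   buttock_apex = c(-14, 83), knee_anterior = c(5, 45),
#'   knee_posterior = c(-5, 45), thigh_center = c(0, 75)
#' )
#' hkl_c(lm)
#' @export
hkl_c <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  kc <- knee_central_point(lm)
  if (is.null(kc) || is.null(lm$buttock_apex) || is.null(lm$thigh_center))
    return(NA_real_)
  ang <- angle_between(kc, lm$buttock_apex, lm$thigh_center,
                       labels = c("knee_central", "buttock_apex",
                                  "thigh_center"))
  # sign check: buttock apex should be posterior to the femoral axis
  a <- lm$thigh_center - kc
  b <- lm$buttock_apex - kc
  cross <- a[["x"]] * b[["y"]] - a[["y"]] * b[["x"]]
  if (cross < 0)
    warning("subject '", lm$subject_id,
            "': buttock apex lies anterior to the femoral axis",
            call. = FALSE)
  ang
}

#' All five HKL angle variants for one subject
#'
#' The hip-knee line runs from the buttock apex to a knee landmark; each
#' variant pairs it with a different reference line at the knee:
#' \describe{
#'   \item{A1}{at the anterior knee point, against the line to the head top
#'     (whole-body alignment reference).}
#'   \item{A2}{at the posterior knee point, against the line to the head top.}
#'   \item{B1}{at the anterior knee point, against the upward vertical.}
#'   \item{B2}{at the posterior knee point, against the upward vertical.}
#'   \item{C}{at the knee center, against the femoral axis (see [hkl_c()]).}
#' }
#' Variants whose landmarks are missing come back `NA` without affecting the
#' others; if no variant is computable an error is raised.
#'
#' @param lm a [landmark_set()].
#' @return named numeric vector `c(a1, a2, b1, b2, c)` in degrees, with the
#'   subject id as attribute `subject_id`.
#' @export
hkl_variants <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  ba <- lm$buttock_apex
  up <- c(x = 0, y = 1)
  ang <- c(a1 = NA_real_, a2 = NA_real_, b1 = NA_real_, b2 = NA_real_,
           c = NA_real_)
  if (!is.null(ba)) {
    if (!is.null(lm$knee_anterior)) {
      if (!is.null(lm$head_top))
        ang[["a1"]] <- angle_between(lm$knee_anterior, ba, lm$head_top,
                                     c("knee_anterior", "buttock_apex",
                                       "head_top"))
      ang[["b1"]] <- angle_between(lm$knee_anterior, ba,
                                   lm$knee_anterior + up,
                                   c("knee_anterior", "buttock_apex",
                                     "vertical"))
    }
    if (!is.null(lm$knee_posterior)) {
      if (!is.null(lm$head_top))
        ang[["a2"]] <- angle_between(lm$knee_posterior, ba, lm$head_top,
                                     c("knee_posterior", "buttock_apex",
                                       "head_top"))
      ang[["b2"]] <- angle_between(lm$knee_posterior, ba,
                                   lm$knee_posterior + up,
                                   c("knee_posterior", "buttock_apex",
                                     "vertical"))
    }
    ang[["c"]] <- suppressWarnings(hkl_c(lm))
  }
  if (all(is.na(ang)))
    stop("subject '", lm$subject_id,
         "': no HKL angle computable from the available landmarks",
         call. = FALSE)
  attr(ang, "subject_id") <- lm$subject_id
  ang
}

#' Surrogate-PI angle from palpation landmarks
#'
#' The body-surface proxy for pelvic incidence: the angle at the upper edge
#' of the iliac crest between the line to the upper edge of the greater
#' trochanter and the line to the buttock surface at trochanter height.
#' The buttock point must lie at the same height as the trochanter top;
#' a mismatch beyond `tol` times the trochanter-crest distance is an error
#' (palpation precision scale).
#'
#' @param lm a [landmark_set()] carrying `trochanter_top`,
#'   `iliac_crest_top` and `buttock_at_trochanter`.
#' @param tol height-match tolerance as a fraction of the trochanter-to-crest
#'   distance (default 0.01).
#' @return the surrogate-PI angle in degrees, or `NA` if the palpation
#'   landmarks are absent.
#' @examples
#' lm <- landmark_set("s1",
#'   trochanter_top = c(0, 0), iliac_crest_top = c(0, 10),
#'   buttock_at_trochanter = c(-10, 0)
#' )
#' surrogate_pi(lm) # 45
#' @export
surrogate_pi <- function(lm, tol = 0.01) {
  stopifnot(inherits(lm, "landmark_set"))
  tr <- lm$trochanter_top
  ic <- lm$iliac_crest_top
  bt <- lm$buttock_at_trochanter
  if (is.null(tr) || is.null(ic) || is.null(bt)) return(NA_real_)
  if (all(tr == bt))
    stop("subject '", lm$subject_id,
         "': degenerate geometry: 'buttock_at_trochanter' coincides with ",
         "'trochanter_top'", call. = FALSE)
  ref <- sqrt(sum((ic - tr)^2))
  if (ref == 0)
    stop("subject '", lm$subject_id,
         "': degenerate geometry: 'iliac_crest_top' coincides with ",
         "'trochanter_top'", call. = FALSE)
  if (abs(bt[["y"]] - tr[["y"]]) > tol * ref)
    stop("subject '", lm$subject_id,
         "': buttock_at_trochanter height differs from trochanter_top ",
         "beyond tolerance", call. = FALSE)
  angle_between(ic, tr, bt,
                labels = c("iliac_crest_top", "trochanter_top",
                           "buttock_at_trochanter"))
}

#' Angle table for a cohort of landmark sets
#'
#' @param landmarks list of [landmark_set()] objects.
#' @return data frame with columns `subject_id`, `sex`, `a1`, `a2`, `b1`,
#'   `b2`, `c`, `surrogate_pi` (degrees, full precision).
#' @seealso [write_angles()]
#' @export
hkl_angle_table <- function(landmarks) {
  stopifnot(is.list(landmarks), length(landmarks) > 0)
  rows <- lapply(landmarks, function(lm) {
    ang <- suppressWarnings(hkl_variants(lm))
    spi <- tryCatch(surrogate_pi(lm), error = function(e) NA_real_)
    data.frame(subject_id = as.character(lm$subject_id), sex = lm$sex,
               a1 = ang[["a1"]], a2 = ang[["a2"]], b1 = ang[["b1"]],
               b2 = ang[["b2"]], c = ang[["c"]], surrogate_pi = spi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read landmark coordinates from CSV
#'
#' One row per subject with columns `subject_id`, optionally `sex`, and
#' `<landmark>_x`, `<landmark>_y` pairs for each named landmark
#' (`head_top`, `buttock_apex`, `knee_anterior`, `knee_central`,
#' `knee_posterior`, `thigh_center`, `trochanter_top`, `iliac_crest_top`,
#' `buttock_at_trochanter`).  Empty cells mean the landmark is missing.
#'
#' @param path CSV file path.
#' @param y_down set `TRUE` when coordinates come from image software whose
#'   y axis grows downward; the vertical axis is flipped at ingest.
#' @param validate check posture invariants per subject.
#' @return list of [landmark_set()] objects.
#' @export
read_landmarks <- function(path, y_down = FALSE, validate = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop("landmark CSV must have a 'subject_id' column", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    pts <- lapply(LANDMARK_NAMES, function(nm) {
      cx <- row[[paste0(nm, "_x")]]
      cy <- row[[paste0(nm, "_y")]]
      if (is.null(cx) || is.null(cy)) return(NULL)
      cx <- suppressWarnings(as.numeric(cx))
      cy <- suppressWarnings(as.numeric(cy))
      if (is.na(cx) || is.na(cy)) return(NULL)
      if (y_down) cy <- -cy
      c(x = cx, y = cy)
    })
    names(pts) <- LANDMARK_NAMES
    do.call(landmark_set,
            c(list(subject_id = row$subject_id,
                   sex = if (!is.null(row$sex) && row$sex %in%
                               c("male", "female")) row$sex
                         else "unspecified",
                   validate = validate),
              Filter(Negate(is.null), pts)))
  })
}

#' Write a landmark cohort to CSV
#'
#' Inverse of [read_landmarks()]; missing landmarks become empty cells.
#'
#' @param landmarks list of [landmark_set()] objects.
#' @param path output CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- lapply(landmarks, function(lm) {
    out <- list(subject_id = as.character(lm$subject_id), sex = lm$sex)
    for (nm in LANDMARK_NAMES) {
      p <- lm[[nm]]
      out[[paste0(nm, "_x")]] <- if (is.null(p)) NA_real_ else p[["x"]]
      out[[paste0(nm, "_y")]] <- if (is.null(p)) NA_real_ else p[["y"]]
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an angle table to CSV
#'
#' @param angles data frame from [hkl_angle_table()].
#' @param path output CSV path.
#' @param digits round angles for a human-readable report, or `NULL`
#'   (default) to keep full machine precision.
#' @export
write_angles <- function(angles, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(angles, is.numeric, logical(1))
    angles[num] <- lapply(angles[num], round, digits = digits)
  }
  write.csv(angles, path, row.names = FALSE, na = "")
  invisible(path)
}
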