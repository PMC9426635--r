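#' Per-image index-point threshold
#'
#' The threshold a candidate landmark's residual must exceed before it can
#' count as having left the circle. It is derived from the residuals of
#' the circle-fit landmarks (15-28): a well-fitting spherical head gives a
#' small threshold, an aspherical one a larger threshold. Model versions 1
#' and 2 use the maximum signed residual (floored at zero so all-inside
#' fits cannot produce a negative threshold). Models 3 and 4 use the
#' maximum absolute residual -- points lying inside the circle count too,
#' after sign flip -- and floor it at 1 mm, the approximate limit of what
#' is discernible by eye on the image.
#'
#' @param profile Residual tibble from [compute_residuals()]; only
#'   landmarks in `fit_landmarks` are used.
#' @param model_version Integer 1-4.
#' @param fit_landmarks Landmarks over which the threshold is taken.
#' @param min_threshold_mm Floor applied in models 3-4 (1 mm).
#' @return Threshold in mm.
#' @export
index_point_threshold <- function(profile, model_version = 4,
                                  fit_landmarks = 15:28,
                                  min_threshold_mm = 1) {
  stopifnot(model_version %in% 1:4)
  r <- profile$residual[profile$landmark %in% fit_landmarks]
  if (length(r) == 0) stop("empty residual profile", call. = FALSE)
  if (model_version <= 2) {
    max(0, max(r))
  } else {
    max(min_threshold_mm, max(abs(r)))
  }
}

#' Find the index point
#'
#' The index point is the first outline landmark judged to be truly
#' outside the circle of best fit. Candidates are scanned in increasing
#' landmark order starting just past the circle-fit range (29 by default,
#' up to 37 so that two following landmarks always exist within the used
#' range). Writing `r(c)` for the residual of candidate `c` and `T` for
#' the threshold, the rules are:
#'
#' * model 1: `r(c) > T` and `r(c+1) > r(c)`;
#' * models 2 and 3: `r(c) > T`, `r(c+1) > r(c)`, `r(c+2) > r(c+1)`
#'   (three consecutive points leaving the circle by increasing residual;
#'   the models differ only in how `T` is computed);
#' * model 4: `r(c) > T`, `r(c+1) > T`, `r(c+2) > T` (the following
#'   residuals must stay above the threshold but need not keep
#'   increasing).
#'
#' Comparisons are exact floating point, with no epsilon: a residual
#' 0.04 mm below the 1 mm floor misses, by design. Candidates whose
#' required successors are missing from the profile are skipped. If no
#' candidate qualifies the status is `NO_DEVIATION`.
#'
#' @param profile Residual tibble covering the candidate landmarks and
#'   their successors (15-39 in normal use).
#' @param threshold_mm Threshold from [index_point_threshold()].
#' @param model_version Integer 1-4.
#' @param candidates Candidate landmark numbers, scanned in order.
#' @return An object of class `index_point`: list with `index_landmark`
#'   (or `NA`), `threshold_mm`, `status` (`"FOUND"` or `"NO_DEVIATION"`)
#'   and `model_version`.
#' @export
find_index_point <- function(profile, threshold_mm, model_version = 4,
                             candidates = 29:37) {
  stopifnot(model_version %in% 1:4, threshold_mm >= 0)
  res <- function(lm) {
    i <- match(lm, profile$landmark)
    if (is.na(i)) NA_real_ else profile$residual[i]
  }
  needed <- if (model_version == 1) 1L else 2L
  found <- NA_integer_
  for (c in candidates) {
    r <- vapply(c + 0:needed, res, numeric(1))
    if (anyNA(r)) next
    ok <- switch(model_version,
      r[1] > threshold_mm && r[2] > r[1],                      # 1
      r[1] > threshold_mm && r[2] > r[1] && r[3] > r[2],       # 2
      r[1] > threshold_mm && r[2] > r[1] && r[3] > r[2],       # 3
      all(r > threshold_mm))                                   # 4
    if (ok) { found <- as.integer(c); break }
  }
  structure(list(index_landmark = found, threshold_mm = threshold_mm,
                 status = if (is.na(found)) "NO_DEVIATION" else "FOUND",
                 model_version = as.integer(model_version)),
            class = "index_point")
}

#' @export
print.index_point <- function(x, ...) {
  cat(sprintf("<index_point> %s (threshold %.3f mm, model %d)%s\n",
              x$status, x$threshold_mm, x$model_version,
              if (x$status == "FOUND")
                sprintf(", landmark %d", x$index_landmark) else ""))
  invisible(x)
}

#' Intersection position: where the outline leaves the circle
#'
#' If the landmark preceding the index point lies inside the circle
#' (negative residual), the intersection is the exact crossing of the
#' segment from that landmark to the index point with the circle
#' (`EXACT_CROSSING`). If the preceding landmark is outside the circle,
#' or the segment is tangent and produces no crossing, the position is
#' approximated by an outline landmark (`APPROXIMATED`): under models 1
#' and 2 the landmark before the index point; under models 3 and 4
#' whichever of the landmark before, the index landmark itself, or the
#' landmark after has the smallest absolute residual, i.e. sits closest
#' to the circle.
#'
#' @param op An [outline_points()] object.
#' @param circle A [fit_circle()] result.
#' @param index A [find_index_point()] result with status `"FOUND"`.
#' @param model_version Integer 1-4.
#' @return An object of class `intersection_position`: list with `coords`
#'   (xy, mm), `method` and, for approximations, the `landmark` used.
#' @export
intersection_position <- function(op, circle, index, model_version = 4) {
  stopifnot(model_version %in% 1:4)
  if (index$status != "FOUND") {
    stop("no index point: intersection position undefined", call. = FALSE)
  }
  idx <- index$index_landmark
  prof <- compute_residuals(op, circle, idx - 1, idx + 1)
  res <- function(lm) prof$residual[match(lm, prof$landmark)]

  if (res(idx - 1) < 0) {
    p_in <- drop(landmark_mm(op, idx - 1))
    p_out <- drop(landmark_mm(op, idx))
    hit <- segment_circle_intersection(p_in, p_out, circle)
    if (!is.null(hit)) {
      return(structure(list(coords = hit, method = "EXACT_CROSSING",
                            landmark = NA_integer_),
                       class = "intersection_position"))
    }
  }
  lm <- if (model_version <= 2) {
    idx - 1L
  } else {
    cand <- c(idx - 1L, idx, idx + 1L)
    cand[which.min(abs(vapply(cand, res, numeric(1))))]
  }
  structure(list(coords = drop(landmark_mm(op, lm)), method = "APPROXIMATED",
                 landmark = as.integer(lm)),
            class = "intersection_position")
}

#' Alpha angle from its three defining features
#'
#' The angle between the line from the femoral-neck midpoint to the centre
#' of the head circle and the line from that centre to the point where the
#' outline leaves the circle, via the arccosine of the normalised dot
#' product. Result in degrees in \[0, 180\].
#'
#' @param circle A [fit_circle()] result.
#' @param neck A [neck_narrowest()] result.
#' @param intersection An [intersection_position()] result.
#' @return Angle in degrees.
#' @export
alpha_angle <- function(circle, neck, intersection) {
  v1 <- neck$midpoint - circle$centre
  v2 <- intersection$coords - circle$centre
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("zero-length vector: neck midpoint or intersection coincides ",
         "with the circle centre", call. = FALSE)
  }
  ca <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, ca))) * 180 / pi
}

#' Classify cam morphology from an alpha angle
#'
#' Cam morphology is present when the alpha angle meets or exceeds the
#' threshold; 60 degrees is the conventional cut-off (50, 55 and 83 have
#' also been used in the literature, hence the argument).
#'
#' @param alpha_deg Alpha angle(s) in degrees, in \[0, 180\].
#' @param cam_threshold_deg Classification threshold (default 60).
#' @return Logical vector.
#' @export
classify_cam <- function(alpha_deg, cam_threshold_deg = 60) {
  stopifnot(all(is.na(alpha_deg) | (alpha_deg >= 0 & alpha_deg <= 180)))
  alpha_deg >= cam_threshold_deg
}

#' Measure the alpha angle of one outline
#'
#' Runs the full pipeline: circle of best fit to landmarks 15-28, signed
#' residuals over 15-39, narrowest-neck search over 8-12 vs 32-36,
#' index-point threshold and scan under the requested model version,
#' intersection position, alpha angle, cam classification. When no
#' landmark satisfies the index-point rule the result carries status
#' `NO_DEVIATION` with no angle but all intermediate measurements
#' populated.
#'
#' @param op An [outline_points()] object, left-hip orientation (mirror
#'   right hips first with [mirror_points()]).
#' @param model_version Index-point decision rule, 1-4 (default 4, the
#'   final model).
#' @param cam_threshold_deg Cam classification threshold in degrees.
#' @return An object of class `alpha_result`; see [glance.alpha_result()]
#'   for the one-row summary and [tidy.alpha_result()] for the residual
#'   table.
#' @examples
#' hip <- generate_outline(synthetic_hip_spec(cam_onset_deg = 80,
#'                                            cam_amplitude = 4, seed = 7))
#' res <- compute_alpha(hip$points)
#' glance(res)
#' @export
compute_alpha <- function(op, model_version = 4, cam_threshold_deg = 60) {
  stopifnot(inherits(op, "outline_points"), model_version %in% 1:4)
  if (attr(op, "side") != "left") {
    stop("outline for image '", attr(op, "source_id"),
         "' is right-sided; mirror it with mirror_points() first",
         call. = FALSE)
  }
  sid <- attr(op, "source_id")
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", sid, conditionMessage(e)), call. = FALSE)
    })
  }
  circle <- wrap(fit_circle(op))
  residuals <- wrap(compute_residuals(op, circle, 15, 39))
  neck <- wrap(neck_narrowest(op))
  threshold <- wrap(index_point_threshold(residuals, model_version))
  index <- wrap(find_index_point(residuals, threshold, model_version))

  if (index$status == "NO_DEVIATION") {
    intersection <- NULL
    alpha <- NA_real_
    cam <- NA
  } else {
    intersection <- wrap(intersection_position(op, circle, index,
                                               model_version))
    alpha <- wrap(alpha_angle(circle, neck, intersection))
    cam <- classify_cam(alpha, cam_threshold_deg)
  }
  structure(list(source_id = sid,
                 model_version = as.integer(model_version),
                 status = if (is.na(alpha)) "NO_DEVIATION" else "OK",
                 alpha_deg = alpha, cam = cam,
                 cam_threshold_deg = cam_threshold_deg,
                 circle = circle, neck = neck, index = index,
                 intersection = intersection, residuals = residuals,
                 points = op),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  if (x$status == "OK") {
    cat(sprintf(
      "<alpha_result> \"%s\": alpha %.1f deg (model %d), cam: %s\n",
      x$source_id, x$alpha_deg, x$model_version,
      if (x$cam) "yes" else "no"))
  } else {
    cat(sprintf(
      "<alpha_result> \"%s\": NO_DEVIATION (model %d) -- outline never leaves the circle\n",
      x$source_id, x$model_version))
  }
  invisible(x)
}

#' Glance at an alpha-angle result
#'
#' @param x An [compute_alpha()] result.
#' @param ... Unused.
#' @return A one-row tibble with `source_id`, `alpha_angle_deg`, `cam`,
#'   `index_point_landmark`, `status`, `model_version`, plus the fitted
#'   head radius, neck width and index-point threshold.
#' @method glance alpha_result
#' @export
glance.alpha_result <- function(x, ...) {
  tibble::tibble(
    source_id = x$source_id,
    alpha_angle_deg = x$alpha_deg,
    cam = if (is.na(x$alpha_deg)) NA else x$cam,
    index_point_landmark = x$index$index_landmark,
    status = x$status,
    model_version = x$model_version,
    head_radius_mm = x$circle$radius,
    neck_width_mm = x$neck$width,
    threshold_mm = x$index$threshold_mm)
}

#' Tidy an alpha-angle result into its residual profile
#'
#' @param x An [compute_alpha()] result.
#' @param ... Unused.
#' @return The residual tibble (landmark, residual in mm) with flags for
#'   the circle-fit range and the index point.
#' @method tidy alpha_result
#' @export
tidy.alpha_result <- function(x, ...) {
  dplyr::mutate(
    x$residuals,
    in_fit_range = .data$landmark >= 15 & .data$landmark <= 28,
    is_index_point = !is.na(x$index$index_landmark) &
      .data$landmark == x$index$index_landmark)
}

#' Measure alpha angles for a batch of outlines
#'
#' Per-image failures are recorded as rows with status `"ERROR"` rather
#' than aborting the batch, mirroring how poor-quality images are data to
#' be flagged, not fatal conditions.
#'
#' @param ops A list of [outline_points()] objects.
#' @inheritParams compute_alpha
#' @return A tibble with one row per outline (the columns of
#'   [glance.alpha_result()], plus an `error` message column).
#' @export
compute_alpha_batch <- function(ops, model_version = 4,
                                cam_threshold_deg = 60) {
  rows <- purrr::map(ops, function(op) {
    tryCatch(
      dplyr::mutate(glance(compute_alpha(op, model_version,
                                         cam_threshold_deg)),
                    error = NA_character_),
      error = function(e) tibble::tibble(
        source_id = attr(op, "source_id") %||% NA_character_,
        alpha_angle_deg = NA_real_, cam = NA,
        index_point_landmark = NA_integer_, status = "ERROR",
        model_version = as.integer(model_version),
        head_radius_mm = NA_real_, neck_width_mm = NA_real_,
        threshold_mm = NA_real_, error = conditionMessage(e)))
  })
  dplyr::bind_rows(rows)
}
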