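#' Least-squares circle of best fit to the femoral head
#'
#' Fits a circle to the head landmarks (15 to 28 by default; the fit stops
#' two landmarks short of the superior-lateral curvature so a cam bulge
#' does not drag the circle outward) by algebraic least squares: the
#' Kasa linearisation minimises \eqn{\sum_i (x_i^2 + y_i^2 + D x_i + E y_i
#' + F)^2}, a 3x3 linear system whose solution gives centre
#' \eqn{(-D/2, -E/2)} and radius \eqn{\sqrt{D^2/4 + E^2/4 - F}}. For
#' near-circular landmark sets this agrees with the geometric
#' (Gauss-Newton) fit far below the millimetre decision scale used
#' downstream. The root-mean-square radial residual is reported for
#' information.
#'
#' @param op An [outline_points()] object.
#' @param first_landmark,last_landmark Landmark range fitted (inclusive).
#' @return An object of class `circle_fit`: list with `centre` (xy, mm),
#'   `radius` (mm), `rms_error` (mm) and `landmarks`.
#' @export
fit_circle <- function(op, first_landmark = 15, last_landmark = 28) {
  lms <- first_landmark:last_landmark
  if (length(lms) < 3) stop("need at least 3 landmarks to fit a circle",
                            call. = FALSE)
  p <- landmark_mm(op, lms)
  x <- p[, 1]; y <- p[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  # collinear points make t(A) %*% A singular
  sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
  if (is.null(sol)) {
    stop("degenerate circle fit: landmarks are collinear or coincident",
         call. = FALSE)
  }
  D <- sol[1]; E <- sol[2]; F_ <- sol[3]
  r2 <- D^2 / 4 + E^2 / 4 - F_
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate circle fit: non-positive squared radius", call. = FALSE)
  }
  centre <- c(x = -D / 2, y = -E / 2)
  radius <- sqrt(r2)
  d <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  structure(list(centre = centre, radius = radius,
                 rms_error = sqrt(mean((d - radius)^2)),
                 landmarks = lms),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "<circle_fit> centre (%.3f, %.3f) mm, radius %.3f mm, rms %.4f mm\n",
    x$centre[1], x$centre[2], x$radius, x$rms_error))
  invisible(x)
}

#' Signed distance-to-circle residuals
#'
#' For each landmark in the range, the residual is the distance from the
#' point to the circle centre minus the radius: positive outside the
#' circle, negative inside, zero on it. All values are in mm.
#'
#' @param op An [outline_points()] object.
#' @param circle A [fit_circle()] result.
#' @param first_landmark,last_landmark Landmark range (inclusive).
#' @return A tibble with columns `landmark` and `residual` (mm).
#' @export
compute_residuals <- function(op, circle, first_landmark = 15,
                              last_landmark = 39) {
  lms <- first_landmark:last_landmark
  p <- landmark_mm(op, lms)
  d <- sqrt((p[, 1] - circle$centre[1])^2 + (p[, 2] - circle$centre[2])^2)
  tibble::tibble(landmark = lms, residual = d - circle$radius)
}

#' Shortest distance from a point to a line segment
#'
#' Distance to the closest location on the segment itself: the
#' perpendicular foot when it falls within the segment, otherwise the
#' nearer endpoint.
#'
#' @param seg_start,seg_end Segment endpoints, length-2 numeric (xy).
#' @param point Query point, length-2 numeric (xy).
#' @return List with `distance` and `closest` (the realising location on
#'   the segment).
#' @export
segment_point_distance <- function(seg_start, seg_end, point) {
  v <- seg_end - seg_start
  len2 <- sum(v^2)
  if (len2 == 0) stop("degenerate segment: identical endpoints", call. = FALSE)
  t <- sum((point - seg_start) * v) / len2
  t <- min(1, max(0, t))
  closest <- seg_start + t * v
  list(distance = sqrt(sum((point - closest)^2)), closest = closest)
}

#' Narrowest width of the femoral neck
#'
#' The neck is demarcated by the medial landmarks (8-12) and the lateral
#' landmarks (32-36). A straight segment joins each consecutive landmark
#' pair on one side; for every such segment the shortest distance to each
#' landmark on the opposing side is measured (both directions: medial
#' segments against lateral points and lateral segments against medial
#' points). The global minimum is the neck width; its endpoints are the
#' realising point and the closest location on the segment, and their
#' average is the femoral neck midpoint used in the alpha angle. Ties are
#' broken in favour of the pair met first in landmark order, comparing
#' widths exactly.
#'
#' @param op An [outline_points()] object.
#' @param medial_landmarks,lateral_landmarks Landmark runs demarcating the
#'   two sides of the neck.
#' @return An object of class `neck_measurement`: list with `endpoint_a`,
#'   `endpoint_b`, `width` (mm) and `midpoint` (xy, mm).
#' @export
neck_narrowest <- function(op, medial_landmarks = 8:12,
                           lateral_landmarks = 32:36) {
  med <- landmark_mm(op, medial_landmarks)
  lat <- landmark_mm(op, lateral_landmarks)

  best <- NULL
  scan <- function(chain, points, best) {
    for (i in seq_len(nrow(chain) - 1)) {
      a <- chain[i, ]; b <- chain[i + 1, ]
      for (j in seq_len(nrow(points))) {
        hit <- segment_point_distance(a, b, points[j, ])
        if (is.null(best) || hit$distance < best$width) {
          best <- list(width = hit$distance, endpoint_a = hit$closest,
                       endpoint_b = points[j, ])
        }
      }
    }
    best
  }
  best <- scan(med, lat, best)
  best <- scan(lat, med, best)
  if (best$width <= 0) {
    stop("degenerate neck: opposing outlines touch", call. = FALSE)
  }
  structure(list(endpoint_a = best$endpoint_a, endpoint_b = best$endpoint_b,
                 width = best$width,
                 midpoint = (best$endpoint_a + best$endpoint_b) / 2),
            class = "neck_measurement")
}

#' @export
print.neck_measurement <- function(x, ...) {
  cat(sprintf("<neck_measurement> width %.3f mm, midpoint (%.3f, %.3f) mm\n",
              x$width, x$midpoint[1], x$midpoint[2]))
  invisible(x)
}

#' Intersection of a segment with a circle
#'
#' Returns the point where the segment from `p_inside` to `p_outside`
#' crosses the circle boundary, or `NULL` when the segment does not cross
#' it. When two crossings fall on the segment the one nearer `p_outside`
#' is returned. Tangency (discriminant below `1e-12 * radius^2`) counts as
#' no crossing, since a grazing line has no clear intersection position.
#'
#' @param p_inside,p_outside Segment endpoints, length-2 numeric (xy, mm).
#'   Callers establish the inside/outside semantics; the function itself
#'   only intersects.
#' @param circle A [fit_circle()] result (or any list with `centre` and
#'   `radius`).
#' @return Length-2 numeric (xy) or `NULL`.
#' @export
segment_circle_intersection <- function(p_inside, p_outside, circle) {
  d <- p_outside - p_inside
  if (sum(d^2) == 0) stop("coincident segment endpoints", call. = FALSE)
  f <- p_inside - circle$centre
  a <- sum(d^2)
  b <- 2 * sum(f * d)
  cc <- sum(f^2) - circle$radius^2
  disc <- b^2 - 4 * a * cc
  if (disc < 1e-12 * circle$radius^2) return(NULL)
  sq <- sqrt(disc)
  ts <- sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
  on_seg <- ts[ts >= 0 & ts <= 1]
  if (length(on_seg) == 0) return(NULL)
  t <- max(on_seg)  # nearest p_outside
  unname(p_inside + t * d)
}
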