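#' Construct an outline-points table
#'
#' An `outline_points` object is a tibble with one row per landmark and
#' columns `landmark`, `x`, `y`, carrying the side, pixel spacing and an
#' image identifier as attributes. Landmarks are numbered 1-based in the
#' standard proximal-femur scheme; numbers 8 to 39 (medial neck, femoral
#' head, lateral neck) must all be present because every downstream
#' measurement consumes them. All geometry assumes a left-hip orientation;
#' right hips must be mirrored first with [mirror_points()].
#'
#' @param points A data frame with columns `landmark`, `x`, `y`, or a
#'   two-column matrix/data frame of coordinates in file order (row 1 =
#'   landmark 1).
#' @param side `"left"` or `"right"`.
#' @param pixel_spacing_mm Millimetres per coordinate unit (> 0). The
#'   default 1 means coordinates are already in mm, which matters because
#'   the minimum index-point threshold is defined in mm.
#' @param source_id Opaque image identifier carried through to results.
#' @return A tibble of class `outline_points`.
#' @examples
#' xy <- generate_outline(synthetic_hip_spec(seed = 1))$points
#' head(xy)
#' @export
outline_points <- function(points, side = c("left", "right"),
                           pixel_spacing_mm = 1, source_id = "image") {
  side <- match.arg(side)
  if (is.matrix(points)) points <- as.data.frame(points)
  stopifnot(is.data.frame(points))
  if (!all(c("landmark", "x", "y") %in% names(points))) {
    if (ncol(points) < 2) {
      stop("`points` must have columns landmark/x/y or two coordinate columns",
           call. = FALSE)
    }
    points <- tibble::tibble(landmark = seq_len(nrow(points)),
                             x = as.numeric(points[[1]]),
                             y = as.numeric(points[[2]]))
  }
  pts <- tibble::tibble(landmark = as.integer(points$landmark),
                        x = as.numeric(points$x),
                        y = as.numeric(points$y))
  validate_outline_points(pts, side, pixel_spacing_mm)
  structure(pts,
            side = side,
            pixel_spacing_mm = pixel_spacing_mm,
            source_id = source_id,
            class = c("outline_points", class(tibble::tibble())))
}

validate_outline_points <- function(pts, side, pixel_spacing_mm) {
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1 ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0) {
    stop("`pixel_spacing_mm` must be a single positive number", call. = FALSE)
  }
  if (anyDuplicated(pts$landmark)) {
    stop("duplicate landmark numbers in outline", call. = FALSE)
  }
  missing <- setdiff(8:39, pts$landmark)
  if (length(missing) > 0) {
    stop("outline does not cover landmarks 8-39; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(pts$x) | !is.finite(pts$y)
  if (any(bad)) {
    stop("non-finite coordinates at landmark(s) ",
         paste(pts$landmark[bad], collapse = ", "), call. = FALSE)
  }
  invisible(pts)
}

#' @export
print.outline_points <- function(x, ...) {
  cat(sprintf("<outline_points> %s hip, %d landmarks, %.4g mm/unit, id \"%s\"\n",
              attr(x, "side"), nrow(x), attr(x, "pixel_spacing_mm"),
              attr(x, "source_id")))
  NextMethod()
}

# coordinates of requested landmarks in mm, as an n x 2 matrix
landmark_mm <- function(op, landmarks) {
  idx <- match(landmarks, op$landmark)
  if (anyNA(idx)) {
    stop("landmark(s) ", paste(landmarks[is.na(idx)], collapse = ", "),
         " absent from outline", call. = FALSE)
  }
  s <- attr(op, "pixel_spacing_mm") %||% 1
  cbind(x = op$x[idx] * s, y = op$y[idx] * s)
}

#' Read a landmark point file
#'
#' Two text dialects are supported. `simple_xy` holds one whitespace-
#' separated "x y" pair per line (lines starting with `#` are ignored);
#' the first coordinate line is landmark 1. `pts` is the common annotation-
#' tool format with a `version:` line, an `n_points:` line and the
#' coordinates enclosed in braces.
#'
#' @param path Path to the point file.
#' @param dialect `"simple_xy"` or `"pts"`.
#' @inheritParams outline_points
#' @return An [outline_points()] tibble.
#' @export
read_points <- function(path, dialect = c("simple_xy", "pts"),
                        pixel_spacing_mm = 1, side = c("left", "right"),
                        source_id = NULL) {
  dialect <- match.arg(dialect)
  side <- match.arg(side)
  if (!file.exists(path)) stop("point file not found: ", path, call. = FALSE)
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)

  if (dialect == "pts") {
    open <- which(trimws(lines) == "{")
    close <- which(trimws(lines) == "}")
    if (length(open) != 1 || length(close) != 1 || close < open) {
      stop("malformed pts file (expected one '{' ... '}' block): ", path,
           call. = FALSE)
    }
    coord_lines <- lines[seq(open + 1, close - 1)]
    offset <- open
  } else {
    coord_lines <- lines
    offset <- 0L
  }

  keep <- !grepl("^\\s*(#|$)", coord_lines)
  coord_lines <- coord_lines[keep]
  line_no <- (seq_along(keep))[keep] + offset
  if (length(coord_lines) == 0) {
    stop("no coordinate lines in ", path, call. = FALSE)
  }

  parts <- strsplit(trimws(coord_lines), "\\s+")
  n_tok <- lengths(parts)
  if (any(n_tok < 2)) {
    stop(sprintf("parse error in %s at line %d: expected 'x y'",
                 path, line_no[which(n_tok < 2)[1]]), call. = FALSE)
  }
  xs <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  ys <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  bad <- is.na(xs) | is.na(ys)
  if (any(bad)) {
    stop(sprintf("parse error in %s at line %d: non-numeric token",
                 path, line_no[which(bad)[1]]), call. = FALSE)
  }
  if (length(xs) < 39) {
    stop(sprintf(
      "coverage error in %s: %d points but landmarks up to 39 are required",
      path, length(xs)), call. = FALSE)
  }
  outline_points(tibble::tibble(landmark = seq_along(xs), x = xs, y = ys),
                 side = side, pixel_spacing_mm = pixel_spacing_mm,
                 source_id = source_id)
}

#' Write a landmark point file
#'
#' Inverse of [read_points()]; `read_points(write_points(op, f))` restores
#' the coordinates to full double precision. Landmarks are written in
#' numeric order starting at the smallest present; files written from
#' outlines that do not start at landmark 1 are padded with leading zero
#' points so file order still equals landmark number.
#'
#' @param op An [outline_points()] object.
#' @param path Output path.
#' @param dialect `"simple_xy"` or `"pts"`.
#' @return `path`, invisibly.
#' @export
write_points <- function(op, path, dialect = c("simple_xy", "pts")) {
  dialect <- match.arg(dialect)
  ord <- order(op$landmark)
  lm <- op$landmark[ord]
  full <- seq_len(max(lm))
  xs <- rep(0, length(full)); ys <- rep(0, length(full))
  xs[lm] <- op$x[ord]; ys[lm] <- op$y[ord]
  coords <- sprintf("%.17g %.17g", xs, ys)
  lines <- switch(dialect,
    simple_xy = coords,
    pts = c("version: 1", sprintf("n_points: %d", length(full)), "{",
            coords, "}"))
  writeLines(lines, path)
  invisible(path)
}

#' Mirror a right-hip outline into left-hip orientation
#'
#' All geometry in the package assumes a left hip; right-hip images are
#' mirrored about the vertical image midline before the outline is used.
#' Mirroring maps `x` to `image_width - x`, leaves `y` untouched and flips
#' the recorded side. Mirroring an outline that is already left-sided is a
#' no-op with a warning unless `force = TRUE` (useful for testing that the
#' reflection is an involution).
#'
#' @param op An [outline_points()] object.
#' @param image_width Image width in the same coordinate units as `x`.
#' @param force Reflect even if the side is already `"left"`.
#' @return The mirrored [outline_points()] object with `side == "left"`.
#' @export
mirror_points <- function(op, image_width, force = FALSE) {
  stopifnot(inherits(op, "outline_points"),
            is.numeric(image_width), image_width > 0)
  if (attr(op, "side") == "left" && !force) {
    warning("outline is already left-sided; not mirrored", call. = FALSE)
    return(op)
  }
  new_side <- if (attr(op, "side") == "right") "left" else "right"
  outline_points(tibble::tibble(landmark = op$landmark,
                                x = image_width - op$x, y = op$y),
                 side = new_side,
                 pixel_spacing_mm = attr(op, "pixel_spacing_mm"),
                 source_id = attr(op, "source_id"))
}

results_columns <- c("source_id", "alpha_angle_deg", "cam",
                     "index_point_landmark", "status", "model_version")

#' Write alpha-angle results to CSV
#'
#' One row per image with a fixed column order: `source_id`,
#' `alpha_angle_deg`, `cam` (0/1, empty when no angle was measured),
#' `index_point_landmark`, `status`, `model_version`.
#'
#' @param results A tibble as returned by [compute_alpha_batch()], or a
#'   list of [compute_alpha()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results)) {
    results <- dplyr::bind_rows(lapply(results, glance))
  }
  out <- tibble::tibble(
    source_id = as.character(results$source_id),
    alpha_angle_deg = as.numeric(results$alpha_angle_deg),
    cam = as.integer(results$cam),
    index_point_landmark = as.integer(results$index_point_landmark),
    status = as.character(results$status),
    model_version = as.integer(results$model_version))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read an alpha-angle results CSV
#'
#' @param path CSV written by [write_results()] (or any CSV with at least
#'   `source_id` and `alpha_angle_deg` columns).
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"source_id" %in% names(out)) {
    stop("results file lacks a source_id column: ", path, call. = FALSE)
  }
  if ("cam" %in% names(out)) out$cam <- as.integer(out$cam)
  out
}
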