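# Internal layout constants for the synthetic outline. Angles are measured
# from the neck axis at the head centre (lateral side positive); landmarks
# 15-30 cover the head arc the long way round through the far pole. The
# sampled neck is a short stub held just inside the head circle (radial
# deficit <= STUB_DEFICIT_MM) so a pristine spherical hip produces residuals
# below the 1 mm detection floor everywhere the index-point scan looks.
SYN_ARC_MEDIAL_DEG <- 55    # |angle| of landmark 15 (inferior-medial curvature)
SYN_ARC_LATERAL_DEG <- 63   # angle of landmark 30 (superior-lateral curvature)
STUB_DEFICIT_MM <- 0.6
STUB_ANGLE_RATIOS <- c(1.52, 1.36, 1.22, 1.10, 1.00)   # landmarks 32-36
STUB_DEFICIT_RATIOS <- c(0.25, 0.50, 0.75, 0.92, 1.00)

#' Specification of a synthetic proximal-femur outline
#'
#' Describes a parametric left-hip outline with a near-circular femoral
#' head, a neck narrowing to a controllable width, and an optional cam
#' bump: a smooth radial bulge that begins (with zero slope, via a
#' raised-cosine ramp) at `cam_onset_deg` from the neck axis and reaches
#' its full amplitude `cam_extent_deg` closer to the neck, staying at that
#' amplitude through the head-neck junction as a real cam lesion does.
#' Because the neck is symmetric about its axis, the line from the neck
#' midpoint to the head centre lies along the axis, so the onset angle is
#' by construction the ground-truth alpha angle of the outline.
#'
#' @param head_centre Head centre in mm (length-2).
#' @param head_radius Femoral head radius in mm (default 25, a typical
#'   adult head).
#' @param neck_axis_deg Direction from head centre toward the neck,
#'   degrees in image coordinates.
#' @param neck_width Narrowest neck width in mm (must leave the neck
#'   attachable to the head; see Details in the methods vignette).
#' @param neck_length Axial distance from the head centre to the most
#'   distal sampled neck landmark, mm.
#' @param cam_onset_deg Angle from the neck axis at which the bump begins,
#'   in (0, 180), or `NULL` for no cam.
#' @param cam_amplitude Bump height in mm.
#' @param cam_extent_deg Angular width of the bump's rise from zero to
#'   full amplitude.
#' @param noise_sd SD of i.i.d. Gaussian noise added to both coordinates,
#'   mm.
#' @param pixel_spacing_mm mm per emitted coordinate unit.
#' @param seed Integer seed making the outline reproducible, or `NULL` to
#'   draw from the ambient RNG stream.
#' @param source_id Identifier attached to the outline.
#' @return An object of class `synthetic_hip_spec`.
#' @export
synthetic_hip_spec <- function(head_centre = c(90, 80), head_radius = 25,
                               neck_axis_deg = 210, neck_width = 20,
                               neck_length = 22.5, cam_onset_deg = NULL,
                               cam_amplitude = 3, cam_extent_deg = 40,
                               noise_sd = 0, pixel_spacing_mm = 1,
                               seed = NULL, source_id = "synthetic") {
  stopifnot(length(head_centre) == 2, is.finite(head_centre),
            head_radius > 0, neck_width > 0, neck_length > 0,
            cam_amplitude >= 0, cam_extent_deg > 0, noise_sd >= 0,
            pixel_spacing_mm > 0)
  if (!is.null(cam_onset_deg) &&
      (cam_onset_deg <= 0 || cam_onset_deg >= 180)) {
    stop("cam_onset_deg must lie in (0, 180)", call. = FALSE)
  }
  if (neck_width >= 2 * head_radius) {
    stop("impossible geometry: neck wider than the head", call. = FALSE)
  }
  rho_stub <- head_radius - STUB_DEFICIT_MM
  g36 <- asin((neck_width / 2) / rho_stub) * 180 / pi
  if (g36 * max(STUB_ANGLE_RATIOS) + 10 >= SYN_ARC_LATERAL_DEG) {
    stop("impossible geometry: neck too wide to attach below the head arc",
         call. = FALSE)
  }
  if (neck_length >= rho_stub) {
    stop("impossible geometry: neck_length places landmarks outside the head circle",
         call. = FALSE)
  }
  if (neck_length <= rho_stub * cos(g36 * pi / 180)) {
    stop("impossible geometry: neck_length shorter than the narrowest-neck region",
         call. = FALSE)
  }
  structure(list(head_centre = head_centre, head_radius = head_radius,
                 neck_axis_deg = neck_axis_deg, neck_width = neck_width,
                 neck_length = neck_length, cam_onset_deg = cam_onset_deg,
                 cam_amplitude = cam_amplitude,
                 cam_extent_deg = cam_extent_deg, noise_sd = noise_sd,
                 pixel_spacing_mm = pixel_spacing_mm, seed = seed,
                 source_id = source_id),
            class = "synthetic_hip_spec")
}

#' @export
print.synthetic_hip_spec <- function(x, ...) {
  cam <- if (is.null(x$cam_onset_deg)) "no cam" else
    sprintf("cam onset %g deg, amplitude %g mm", x$cam_onset_deg,
            x$cam_amplitude)
  cat(sprintf(
    "<synthetic_hip_spec> \"%s\": head r=%g mm, neck %g mm, %s, noise %g mm\n",
    x$source_id, x$head_radius, x$neck_width, cam, x$noise_sd))
  invisible(x)
}

#' Inter-landmark angular spacing of the synthetic head arc
#'
#' Landmarks 15-30 are equally spaced over the head arc; this spacing is
#' the angular resolution at which the measured alpha angle can track the
#' ground-truth onset.
#'
#' @param spec A [synthetic_hip_spec()].
#' @return Spacing in degrees (arc span / 15).
#' @export
landmark_spacing_deg <- function(spec) {
  (360 - SYN_ARC_MEDIAL_DEG - SYN_ARC_LATERAL_DEG) / 15
}

# signed angle from the neck axis (lateral positive) and radial deficit for
# every landmark 8-39, before any cam bump
syn_landmark_layout <- function(spec) {
  R <- spec$head_radius
  rho_stub <- R - STUB_DEFICIT_MM
  g <- asin((spec$neck_width / 2) / rho_stub) * 180 / pi
  stub_angles <- g * STUB_ANGLE_RATIOS            # landmarks 32-36
  stub_deficits <- STUB_DEFICIT_MM * STUB_DEFICIT_RATIOS
  g39 <- acos(spec$neck_length / rho_stub) * 180 / pi
  distal <- g + (g39 - g) * (1:3) / 3             # landmarks 37-39

  span <- 360 - SYN_ARC_MEDIAL_DEG - SYN_ARC_LATERAL_DEG
  arc <- -SYN_ARC_MEDIAL_DEG - (0:15) * span / 15 # landmarks 15-30
  arc <- ((arc + 180) %% 360) - 180               # wrap to (-180, 180]

  g13 <- -(stub_angles[1] + 5)
  g14 <- (g13 - SYN_ARC_MEDIAL_DEG) / 2
  tibble::tibble(
    landmark = 8:39,
    gamma = c(-rev(stub_angles),                  # 8-12 medial neck
              g13, g14,                           # 13-14 medial transition
              arc,                                # 15-30 head arc
              stub_angles[1] + 10,                # 31 lateral transition
              stub_angles,                        # 32-36 lateral neck
              distal),                            # 37-39 distal lateral neck
    deficit = c(rev(stub_deficits), 0, 0, rep(0, 16), 0, stub_deficits,
                rep(STUB_DEFICIT_MM, 3)))
}

# raised-cosine ramp: 0 at x <= 0 (zero slope), 1 at x >= width
syn_ramp <- function(x, width) {
  ifelse(x <= 0, 0, ifelse(x >= width, 1, (1 - cos(pi * x / width)) / 2))
}

#' Generate a synthetic proximal-femur outline
#'
#' Emits landmarks 8-39 of the standard scheme: 8-12 along the medial
#' neck, 13-14 transition, 15-30 equally spaced on the head arc from the
#' inferior-medial to the superior-lateral curvature, 31 transition, and
#' 32-39 along the lateral neck with 32-36 spanning the narrowest-width
#' region. Without a cam the head landmarks lie exactly on the generating
#' circle and the neck landmarks stay within the 1 mm detection floor, so
#' the measurement reports `NO_DEVIATION`. With a cam, the outline on the
#' lateral side follows the bulged radius and the ground-truth alpha
#' angle equals the bump onset angle.
#'
#' @param spec A [synthetic_hip_spec()].
#' @return A list with `points` (an [outline_points()] tibble),
#'   `truth_alpha_deg` (the onset angle, or `NA` when there is no cam or
#'   the bump amplitude is at or below the 1 mm floor) and
#'   `spacing_deg` (see [landmark_spacing_deg()]).
#' @examples
#' hip <- generate_outline(synthetic_hip_spec(cam_onset_deg = 75,
#'                                            cam_amplitude = 4, seed = 1))
#' hip$truth_alpha_deg
#' @export
generate_outline <- function(spec) {
  stopifnot(inherits(spec, "synthetic_hip_spec"))
  build <- function() {
    lay <- syn_landmark_layout(spec)
    bump <- 0
    if (!is.null(spec$cam_onset_deg)) {
      bump <- ifelse(lay$gamma > 0,
                     spec$cam_amplitude *
                       syn_ramp(spec$cam_onset_deg - lay$gamma,
                                spec$cam_extent_deg),
                     0)
    }
    rho <- spec$head_radius - lay$deficit + bump
    th <- spec$neck_axis_deg * pi / 180
    u <- c(cos(th), sin(th))
    v <- c(-sin(th), cos(th))
    gr <- lay$gamma * pi / 180
    xs <- spec$head_centre[1] + rho * (cos(gr) * u[1] + sin(gr) * v[1])
    ys <- spec$head_centre[2] + rho * (cos(gr) * u[2] + sin(gr) * v[2])
    if (spec$noise_sd > 0) {
      xs <- xs + stats::rnorm(length(xs), 0, spec$noise_sd)
      ys <- ys + stats::rnorm(length(ys), 0, spec$noise_sd)
    }
    outline_points(
      tibble::tibble(landmark = lay$landmark,
                     x = xs / spec$pixel_spacing_mm,
                     y = ys / spec$pixel_spacing_mm),
      side = "left", pixel_spacing_mm = spec$pixel_spacing_mm,
      source_id = spec$source_id)
  }
  pts <- if (is.null(spec$seed)) build() else
    withr::with_seed(spec$seed, build())
  truth <- if (!is.null(spec$cam_onset_deg) && spec$cam_amplitude > 1) {
    spec$cam_onset_deg
  } else {
    NA_real_
  }
  list(points = pts, truth_alpha_deg = truth,
       spacing_deg = landmark_spacing_deg(spec))
}

#' Generate a cohort of synthetic hips with known ground truth
#'
#' Draws `n` outlines, each cam-bearing independently with probability
#' `cam_fraction` (roughly one third in the validation samples this
#' emulates). Head size, neck proportions, axis direction, bump onset and
#' amplitude vary across the cohort; all randomness flows from `seed`.
#'
#' @param n Number of outlines (>= 1).
#' @param cam_fraction Probability that an outline carries a cam, in
#'   \[0, 1\].
#' @param seed Integer seed for the whole cohort.
#' @param noise_sd Landmark noise SD in mm (default 0.2, of the order of
#'   the manual point-correction distances seen on real images).
#' @param onset_range Range from which cam onset angles are drawn
#'   uniformly, degrees.
#' @param amplitude_range Range from which cam bump amplitudes are drawn
#'   uniformly, mm.
#' @param cam_extent_deg Bump rise width, degrees.
#' @param pixel_spacing_mm mm per coordinate unit of the emitted outlines.
#' @return A tibble with one row per hip: `source_id`, `points`
#'   (list-column of [outline_points()]), `truth_alpha_deg`, `truth_cam`
#'   (at the 60 degree threshold; `FALSE` when no cam is present),
#'   `cam_onset_deg`, `cam_amplitude`, `spacing_deg`.
#' @export
generate_cohort <- function(n, cam_fraction = 1 / 3, seed = 1,
                            noise_sd = 0.2, onset_range = c(40, 100),
                            amplitude_range = c(2, 6), cam_extent_deg = 40,
                            pixel_spacing_mm = 1) {
  stopifnot(n >= 1, cam_fraction >= 0, cam_fraction <= 1)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      has_cam <- stats::runif(1) < cam_fraction
      R <- stats::runif(1, 23, 27)
      centre <- c(90, 80) + stats::runif(2, -10, 10)
      axis <- stats::runif(1, 190, 230)
      width <- 0.8 * R * stats::runif(1, 0.95, 1.05)
      onset <- if (has_cam)
        stats::runif(1, onset_range[1], onset_range[2]) else NULL
      amplitude <- stats::runif(1, amplitude_range[1], amplitude_range[2])
      spec <- synthetic_hip_spec(
        head_centre = centre, head_radius = R, neck_axis_deg = axis,
        neck_width = width, neck_length = 0.93 * R,
        cam_onset_deg = onset, cam_amplitude = amplitude,
        cam_extent_deg = cam_extent_deg,
        noise_sd = noise_sd, pixel_spacing_mm = pixel_spacing_mm,
        seed = NULL, source_id = sprintf("synthetic_%04d", i))
      out <- generate_outline(spec)
      tibble::tibble(source_id = spec$source_id,
                     points = list(out$points),
                     truth_alpha_deg = out$truth_alpha_deg,
                     truth_cam = !is.na(out$truth_alpha_deg) &
                       out$truth_alpha_deg >= 60,
                     cam_onset_deg = if (has_cam) spec$cam_onset_deg
                                     else NA_real_,
                     cam_amplitude = if (has_cam) spec$cam_amplitude
                                     else NA_real_,
                     spacing_deg = out$spacing_deg)
    })
    dplyr::bind_rows(rows)
  })
}
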