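test_that("index-point threshold follows the per-model definition", {
  # models 1-2: signed maximum over the fit landmarks, floored at zero
  p <- profile_of("20" = 2.5, "24" = -3.1)
  expect_equal(index_point_threshold(p, 1), 2.5)
  expect_equal(index_point_threshold(p, 2), 2.5)
  # models 3-4: absolute maximum, so the deep inside point dominates
  expect_equal(index_point_threshold(p, 3), 3.1)
  expect_equal(index_point_threshold(p, 4), 3.1)

  # 1 mm floor engages when every fit residual is small
  q <- profile_of("20" = 0.3, "24" = -0.2)
  expect_equal(index_point_threshold(q, 4), 1.0)
  expect_equal(index_point_threshold(q, 3), 1.0)
  # ... but not for models 1-2
  expect_equal(index_point_threshold(q, 1), 0.3)
  # all-inside fits cannot give a negative threshold under models 1-2
  expect_equal(index_point_threshold(profile_of("20" = -0.5), 1), 0)

  expect_error(index_point_threshold(tibble::tibble(landmark = integer(),
                                                    residual = numeric()), 4),
               "empty")
})

test_that("index-point scan reproduces hand-traced outcomes for all four models", {
  # Each case: residuals from landmark 29 onward (unlisted landmarks are 0),
  # threshold, model, expected index landmark (NA = NO_DEVIATION).
  # Expectations hand-traced from the per-model rules.
  battery <- list(
    # profile A: single sharp spike then decay
    list(r = c(1.5, 1.2, 1.3, 0.4, 0.2), t = 1, m = 1, want = 30),
    list(r = c(1.5, 1.2, 1.3, 0.4, 0.2), t = 1, m = 2, want = NA),
    list(r = c(1.5, 1.2, 1.3, 0.4, 0.2), t = 1, m = 3, want = NA),
    list(r = c(1.5, 1.2, 1.3, 0.4, 0.2), t = 1, m = 4, want = 29),
    # profile B: clean monotone departure
    list(r = c(1.1, 1.6, 2.2, 3.0), t = 1, m = 1, want = 29),
    list(r = c(1.1, 1.6, 2.2, 3.0), t = 1, m = 2, want = 29),
    list(r = c(1.1, 1.6, 2.2, 3.0), t = 1, m = 4, want = 29),
    # profile C: above threshold but never increasing
    list(r = c(2.0, 1.9, 1.8, 1.7, 1.6), t = 1, m = 1, want = NA),
    list(r = c(2.0, 1.9, 1.8, 1.7, 1.6), t = 2, m = 4, want = NA),
    list(r = c(2.0, 1.9, 1.8, 1.7, 1.6), t = 1, m = 4, want = 29),
    # profile D: dip below threshold interrupts model 4's run
    list(r = c(1.4, 0.9, 1.5, 1.6, 1.7), t = 1, m = 4, want = 31),
    list(r = c(1.4, 0.9, 1.5, 1.6, 1.7), t = 2, m = 4, want = NA),
    list(r = c(1.4, 0.9, 1.5, 1.6, 1.7), t = 1, m = 2, want = 31),
    # profile E: first candidate below threshold, second qualifies
    list(r = c(0.8, 1.2, 1.9, 2.4), t = 1, m = 1, want = 30),
    list(r = c(0.8, 1.2, 1.9, 2.4), t = 1, m = 2, want = 30),
    # profile F: increasing pair but flat third point
    list(r = c(1.2, 1.5, 1.5, 1.5), t = 1, m = 1, want = 29),
    list(r = c(1.2, 1.5, 1.5, 1.5), t = 1, m = 2, want = NA),
    list(r = c(1.2, 1.5, 1.5, 1.5), t = 1, m = 4, want = 29),
    # profile G: everything at or below threshold
    list(r = c(1.0, 1.0, 0.7, 0.4), t = 1, m = 1, want = NA),
    list(r = c(1.0, 1.0, 0.7, 0.4), t = 1, m = 4, want = NA),
    # profile H: late departure only
    list(r = c(0.1, 0.2, 0.1, 0.2, 0.3, 1.2, 1.4, 1.6), t = 1, m = 2,
         want = 34),
    list(r = c(0.1, 0.2, 0.1, 0.2, 0.3, 1.2, 1.4, 1.6), t = 1, m = 4,
         want = 34))
  for (case in battery) {
    prof <- tibble::tibble(landmark = 29 + seq_along(case$r) - 1,
                           residual = case$r)
    got <- find_index_point(prof, case$t, case$m)
    if (is.na(case$want)) {
      expect_equal(got$status, "NO_DEVIATION",
                   label = sprintf("model %d on (%s), T=%g", case$m,
                                   toString(case$r), case$t))
    } else {
      expect_equal(got$index_landmark, case$want,
                   label = sprintf("model %d on (%s), T=%g", case$m,
                                   toString(case$r), case$t))
    }
  }
})

test_that("model 1 flags an early spurious index that stricter rules suppress", {
  # small non-monotone wobble just outside the circle, followed by the
  # real departure further along the outline
  prof <- tibble::tibble(landmark = 29:39,
                         residual = c(0.25, 0.3, 0.1, 0.05, 0.3, 0.5,
                                      0.8, 1.2, 1.5, 1.7, 1.9))
  t12 <- 0.2  # signed-max threshold of a near-perfect fit
  m1 <- find_index_point(prof, t12, 1)
  m2 <- find_index_point(prof, t12, 2)
  expect_equal(m1$index_landmark, 29L)   # the spurious early wobble
  expect_equal(m2$index_landmark, 33L)   # the true departure
  # with the 1 mm floor (models 3-4) only the tail of the run qualifies
  m4 <- find_index_point(prof, 1, 4)
  expect_equal(m4$index_landmark, 36L)
})

test_that("a 0.96 mm bump misses the 1 mm floor under models 3-4", {
  prof <- profile_of("20" = 0.4, "25" = -0.5,
                     "32" = 0.7, "33" = 0.96, "34" = 0.9, "35" = 0.8)
  t4 <- index_point_threshold(prof, 4)
  expect_equal(t4, 1.0)
  expect_equal(find_index_point(prof, t4, 4)$status, "NO_DEVIATION")
  expect_equal(find_index_point(prof, index_point_threshold(prof, 3),
                                3)$status, "NO_DEVIATION")
  # the same bump is picked up by model 1, whose threshold is only 0.4
  t1 <- index_point_threshold(prof, 1)
  expect_equal(find_index_point(prof, t1, 1)$index_landmark, 32L)
})

test_that("candidates without the required successors are skipped", {
  prof <- tibble::tibble(landmark = 29:39,
                         residual = c(rep(0, 9), 2, 3))
  # landmark 38 exceeds the threshold but is beyond the candidate range,
  # and 37 (in range) has no qualifying run
  expect_equal(find_index_point(prof, 1, 4)$status, "NO_DEVIATION")
  prof2 <- tibble::tibble(landmark = 29:39,
                          residual = c(rep(0, 8), 2, 3, 4))
  expect_equal(find_index_point(prof2, 1, 4)$index_landmark, 37L)
})

test_that("intersection position: exact crossing when the previous point is inside", {
  circ <- structure(list(centre = c(x = 0, y = 0), radius = 10),
                    class = "circle_fit")
  # landmark 30 inside (r = -0.5), 31 outside (r = +2)
  pts <- tibble::tibble(landmark = 30:32,
                        x = c(9.5, 12, 12.5), y = c(0, 0, 1))
  idx <- structure(list(index_landmark = 31L, threshold_mm = 1,
                        status = "FOUND", model_version = 4L),
                   class = "index_point")
  hit <- intersection_position(pts, circ, idx, 4)
  expect_equal(hit$method, "EXACT_CROSSING")
  expect_equal(hit$coords, c(10, 0), tolerance = 1e-12)
  expect_lt(abs(sqrt(sum((hit$coords - circ$centre)^2)) - circ$radius),
            1e-9 * circ$radius)
})

test_that("intersection position: approximation rules differ between model eras", {
  circ <- structure(list(centre = c(x = 0, y = 0), radius = 10),
                    class = "circle_fit")
  # previous landmark outside (+0.9), index (+1.4), following (+0.2)
  pts <- tibble::tibble(landmark = 30:32,
                        x = c(10.9, 11.4, 10.2), y = c(0, 0, 0))
  idx <- structure(list(index_landmark = 31L, threshold_mm = 1,
                        status = "FOUND", model_version = 4L),
                   class = "index_point")
  # models 1-2: always the point before the index point
  m1 <- intersection_position(pts, circ, idx, 1)
  expect_equal(m1$method, "APPROXIMATED")
  expect_equal(m1$landmark, 30L)
  # models 3-4: the neighbour closest to the circle (smallest |residual|)
  m4 <- intersection_position(pts, circ, idx, 4)
  expect_equal(m4$landmark, 32L)

  err <- structure(list(index_landmark = NA_integer_, threshold_mm = 1,
                        status = "NO_DEVIATION", model_version = 4L),
                   class = "index_point")
  expect_error(intersection_position(pts, circ, err, 4), "no index point")
})

test_that("alpha angle is the angle at the circle centre between neck and exit rays", {
  circ <- list(centre = c(0, 0), radius = 10)
  neck <- list(midpoint = c(0, -20))
  expect_equal(alpha_angle(circ, neck, list(coords = c(10, 0))), 90)
  expect_equal(alpha_angle(circ, neck, list(coords = c(0, 20))), 180)
  # a ray constructed 60 degrees from the neck direction
  th <- (-90 + 60) * pi / 180
  expect_equal(alpha_angle(circ, neck,
                           list(coords = 10 * c(cos(th), sin(th)))), 60,
               tolerance = 1e-10)
  expect_error(alpha_angle(circ, list(midpoint = c(0, 0)),
                           list(coords = c(1, 0))), "zero-length")
})

test_that("cam classification uses an inclusive 60 degree threshold", {
  expect_true(classify_cam(60))
  expect_false(classify_cam(59.999))
  expect_true(classify_cam(106.2))
  expect_equal(classify_cam(c(45, 72)), c(FALSE, TRUE))
  expect_error(classify_cam(190))
})

test_that("full pipeline: spherical head gives NO_DEVIATION, cam is measured", {
  quiet <- generate_outline(synthetic_hip_spec(seed = 41))
  r0 <- compute_alpha(quiet$points)
  expect_equal(r0$status, "NO_DEVIATION")
  expect_true(is.na(r0$alpha_deg))
  expect_true(is.na(glance(r0)$cam))
  # intermediates are still populated
  expect_s3_class(r0$circle, "circle_fit")
  expect_s3_class(r0$neck, "neck_measurement")

  spec <- synthetic_hip_spec(cam_onset_deg = 75, cam_amplitude = 3,
                             seed = 42)
  hip <- generate_outline(spec)
  r1 <- compute_alpha(hip$points)
  expect_equal(r1$status, "OK")
  expect_lt(abs(r1$alpha_deg - 75), landmark_spacing_deg(spec))
  expect_true(r1$cam)
})

test_that("alpha angle is invariant to units when spacing compensates scale", {
  hip <- generate_outline(synthetic_hip_spec(cam_onset_deg = 80,
                                             cam_amplitude = 4, seed = 43))
  op <- hip$points
  doubled <- outline_points(
    tibble::tibble(landmark = op$landmark, x = op$x * 2, y = op$y * 2),
    side = "left", pixel_spacing_mm = attr(op, "pixel_spacing_mm") / 2,
    source_id = "doubled")
  expect_equal(compute_alpha(doubled)$alpha_deg, compute_alpha(op)$alpha_deg,
               tolerance = 1e-9)
})

test_that("computed AA tracks cam onset across 40-110 degrees at the landmark resolution", {
  spec0 <- synthetic_hip_spec()
  spacing <- landmark_spacing_deg(spec0)
  onsets <- seq(40, 110, by = 5)
  alphas <- vapply(onsets, function(o) {
    hip <- generate_outline(synthetic_hip_spec(cam_onset_deg = o,
                                               cam_amplitude = 6, seed = 1))
    compute_alpha(hip$points)$alpha_deg
  }, numeric(1))
  expect_false(anyNA(alphas))
  expect_true(all(abs(alphas - onsets) <= spacing))
  # non-decreasing at the landmark quantisation; sub-degree wobble can
  # arise from the neck midpoint shifting slightly with the bump
  expect_true(all(diff(alphas) >= -1))
  expect_gt(alphas[length(alphas)], alphas[1])
})

test_that("model 4 finds an index at least as often as model 2 at equal threshold", {
  withr::local_seed(107)
  for (i in 1:200) {
    prof <- tibble::tibble(landmark = 29:37, residual = runif(9, 0, 2))
    t <- runif(1, 0.2, 1.5)
    m2 <- find_index_point(prof, t, 2)
    m4 <- find_index_point(prof, t, 4)
    if (m2$status == "FOUND") {
      expect_equal(m4$status, "FOUND")
      expect_lte(m4$index_landmark, m2$index_landmark)
    }
  }
})

test_that("with the 1 mm floor, any model-4 index implies three residuals above 1 mm", {
  withr::local_seed(108)
  for (i in 1:200) {
    prof <- tibble::tibble(landmark = 15:39, residual = runif(25, -2, 2))
    t <- index_point_threshold(prof, 4)
    got <- find_index_point(prof, t, 4)
    if (got$status == "FOUND") {
      run <- prof$residual[match(got$index_landmark + 0:2, prof$landmark)]
      expect_true(all(run > 1))
    }
  }
})

test_that("batch computation records per-image failures instead of aborting", {
  cohort <- generate_cohort(4, cam_fraction = 0.5, seed = 51)
  broken <- cohort$points[[2]]
  broken$x[broken$landmark == 20] <- NA  # corrupt a head landmark
  ops <- cohort$points
  ops[[2]] <- broken
  res <- compute_alpha_batch(ops)
  expect_equal(nrow(res), 4)
  expect_equal(sum(res$status == "ERROR"), 1)
  expect_true(all(res$status[-2] != "ERROR"))
  expect_match(res$error[2], "degenerate")
})
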