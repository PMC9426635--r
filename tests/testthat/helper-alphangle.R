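# Shared fixtures and independent oracles, all built in code.

# landmark table of points on a circle at given angles (degrees)
circle_points <- function(centre, radius, angles_deg, landmarks = NULL) {
  th <- angles_deg * pi / 180
  tibble::tibble(
    landmark = landmarks %||% seq_along(th),
    x = centre[1] + radius * cos(th),
    y = centre[2] + radius * sin(th))
}

# independent geometric circle fit: minimise sum of squared radial
# residuals over the centre by Nelder-Mead, radius = mean distance
geometric_circle_fit <- function(x, y) {
  obj <- function(c0) {
    d <- sqrt((x - c0[1])^2 + (y - c0[2])^2)
    sum((d - mean(d))^2)
  }
  fit <- stats::optim(c(mean(x), mean(y)), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  d <- sqrt((x - fit$par[1])^2 + (y - fit$par[2])^2)
  list(centre = fit$par, radius = mean(d))
}

# brute-force narrowest-neck oracle: dense grid of locations along every
# consecutive segment of one chain against every point of the other,
# in both directions
brute_neck_width <- function(med, lat, n_grid = 10001) {
  ts <- seq(0, 1, length.out = n_grid)
  side_min <- function(chain, pts) {
    best <- Inf
    for (i in seq_len(nrow(chain) - 1)) {
      sx <- chain[i, 1] + ts * (chain[i + 1, 1] - chain[i, 1])
      sy <- chain[i, 2] + ts * (chain[i + 1, 2] - chain[i, 2])
      for (j in seq_len(nrow(pts))) {
        best <- min(best, sqrt((sx - pts[j, 1])^2 + (sy - pts[j, 2])^2))
      }
    }
    best
  }
  min(side_min(med, lat), side_min(lat, med))
}

# full residual profile (landmarks 15-39) with chosen values; unlisted
# landmarks default to a quiet on-circle 0
profile_of <- function(...) {
  vals <- c(...)
  lm <- as.integer(names(vals))
  full <- tibble::tibble(landmark = 15:39, residual = 0)
  full$residual[match(lm, full$landmark)] <- unname(vals)
  full
}

# random rigid motion applied to an outline_points object
rigid_transform <- function(op, angle_deg = 0, shift = c(0, 0)) {
  th <- angle_deg * pi / 180
  x2 <- cos(th) * op$x - sin(th) * op$y + shift[1]
  y2 <- sin(th) * op$x + cos(th) * op$y + shift[2]
  outline_points(tibble::tibble(landmark = op$landmark, x = x2, y = y2),
                 side = attr(op, "side"),
                 pixel_spacing_mm = attr(op, "pixel_spacing_mm"),
                 source_id = attr(op, "source_id"))
}
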