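#' Lin's concordance correlation coefficient
#'
#' Agreement between two continuous measurements of the same quantity.
#' Lin's estimator is
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x, y)}
#'   {\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2}}
#' with population (1/n) moments, so it penalises loss of correlation and
#' location/scale shift alike. The confidence interval is built on the
#' Fisher z transform of the estimate with Lin's asymptotic variance and
#' back-transformed (the construction used by common statistical
#' software).
#'
#' @param x,y Equal-length numeric vectors (n >= 3). Pairs with a missing
#'   value in either vector are dropped listwise with a message.
#' @param ci_level Confidence level (default 0.95).
#' @return A list with `estimate`, `ci_low`, `ci_high`, `n`.
#' @export
concordance_correlation <- function(x, y, ci_level = 0.95) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with missing values dropped")
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) {
    stop("both sequences are constant: concordance undefined", call. = FALSE)
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)

  # Fisher z CI with Lin's asymptotic variance of atanh(ccc)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  if (is.finite(r) && abs(r) > 0 && abs(ccc) < 1) {
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    sz <- sqrt(max(0, sz2))
    zq <- stats::qnorm(1 - (1 - ci_level) / 2)
    z <- atanh(ccc)
    ci <- tanh(c(z - zq * sz, z + zq * sz))
  } else {
    ci <- c(ccc, ccc)
  }
  list(estimate = ccc, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Cohen's kappa for binary ratings
#'
#' Chance-corrected agreement from the 2x2 cross-tabulation:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, with observed agreement
#' \eqn{p_o} and chance agreement \eqn{p_e} from the marginal rates.
#' Percentage agreement is \eqn{100 p_o}. When both raters use a single
#' identical category, \eqn{p_e = 1} and kappa is undefined (`NA`), though
#' the percentage agreement is still 100.
#'
#' @param a,b Equal-length logical vectors. Missing pairs are dropped
#'   listwise with a message.
#' @return A list with `kappa`, `percent_agreement`, `n` and the 2x2
#'   `table`.
#' @export
cohen_kappa_binary <- function(a, b) {
  if (length(a) != length(b)) stop("a and b differ in length", call. = FALSE)
  keep <- stats::complete.cases(a, b)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with missing values dropped")
    a <- a[keep]; b <- b[keep]
  }
  n <- length(a)
  if (n < 1) stop("no complete rating pairs", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  tab <- table(factor(a, levels = c(TRUE, FALSE)),
               factor(b, levels = c(TRUE, FALSE)))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(kappa = kappa, percent_agreement = 100 * po, n = n, table = tab)
}

#' Mean absolute difference between paired measurements
#'
#' @param x,y Equal-length numeric vectors (>= 2 complete pairs). Missing
#'   pairs are dropped listwise with a message.
#' @return A list with `mean` and `sd` (sample SD, n - 1 denominator) of
#'   the absolute pairwise differences, and `n`.
#' @export
mean_absolute_difference <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with missing values dropped")
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- abs(x - y)
  list(mean = mean(d), sd = stats::sd(d), n = length(d))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y` are summarised by their mean and the limits of
#' agreement, mean +/- 1.96 sample SD, between which roughly 95% of
#' differences fall for Gaussian disagreement. Pairs whose difference
#' lies strictly outside the limits are flagged as outliers. Use
#' [ggplot2::autoplot()] on the result for the standard difference vs
#' pairwise-mean plot.
#'
#' @param x,y Equal-length numeric vectors (n >= 3); typically automatic
#'   and manual measurements. Missing pairs are dropped listwise with a
#'   message.
#' @param ids Optional identifiers for each pair (defaults to positions).
#' @return An object of class `bland_altman`: list with `mean_diff`,
#'   `loa_low`, `loa_high`, `outlier_ids` and a `data` tibble (id,
#'   pairwise mean, difference, outlier flag).
#' @export
bland_altman <- function(x, y, ids = NULL) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  keep <- stats::complete.cases(x, y)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with missing values dropped")
    x <- x[keep]; y <- y[keep]; ids <- ids[keep]
  }
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  dat <- tibble::tibble(id = ids, pair_mean = (x + y) / 2, diff = d,
                        outlier = d < loa[1] | d > loa[2])
  structure(list(mean_diff = m, loa_low = loa[1], loa_high = loa[2],
                 outlier_ids = dat$id[dat$outlier], data = dat),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.3f, limits of agreement [%.3f, %.3f], %d outlier(s)\n",
    x$mean_diff, x$loa_low, x$loa_high, length(x$outlier_ids)))
  invisible(x)
}

#' Full agreement battery between two alpha-angle measurement sets
#'
#' Runs every statistic used to validate an automatic measure against a
#' manual one: Lin's concordance correlation (with CI), Cohen's kappa on
#' the cam classification (with percentage agreement), mean absolute
#' difference (with SD) and Bland-Altman limits with outlier
#' identification.
#'
#' @param data A data frame with one row per image holding both
#'   measurements.
#' @param auto,manual Column names (strings) of the automatic and manual
#'   alpha angles, in degrees.
#' @param id Column name of the image identifier (optional).
#' @param cam_threshold_deg Cam classification threshold applied to both
#'   columns.
#' @param ci_level Confidence level for the CCC interval.
#' @return An object of class `agreement_stats`; [tidy()] gives a
#'   long-format tibble of statistics, [glance()] a one-row tibble.
#' @examples
#' cohort <- generate_cohort(40, cam_fraction = 0.4, seed = 2)
#' auto <- compute_alpha_batch(cohort$points)
#' paired <- data.frame(id = auto$source_id, auto = auto$alpha_angle_deg,
#'                      manual = cohort$truth_alpha_deg + rnorm(40, 0, 3))
#' agreement_stats(paired, "auto", "manual", id = "id")
#' @export
agreement_stats <- function(data, auto = "auto", manual = "manual",
                            id = NULL, cam_threshold_deg = 60,
                            ci_level = 0.95) {
  stopifnot(is.data.frame(data), auto %in% names(data),
            manual %in% names(data))
  x <- as.numeric(data[[auto]])
  y <- as.numeric(data[[manual]])
  ids <- if (!is.null(id)) as.character(data[[id]])
         else as.character(seq_along(x))
  keep <- stats::complete.cases(x, y)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with missing values dropped")
    x <- x[keep]; y <- y[keep]; ids <- ids[keep]
  }
  ccc <- concordance_correlation(x, y, ci_level)
  kap <- cohen_kappa_binary(classify_cam(x, cam_threshold_deg),
                            classify_cam(y, cam_threshold_deg))
  mad <- mean_absolute_difference(x, y)
  ba <- bland_altman(x, y, ids)
  structure(list(ccc = ccc$estimate, ccc_ci_low = ccc$ci_low,
                 ccc_ci_high = ccc$ci_high, kappa = kap$kappa,
                 percent_agreement = kap$percent_agreement,
                 mean_abs_diff = mad$mean, mad_sd = mad$sd,
                 bland_altman_mean = ba$mean_diff,
                 bland_altman_loa_low = ba$loa_low,
                 bland_altman_loa_high = ba$loa_high,
                 outlier_ids = ba$outlier_ids,
                 n = ccc$n, cam_threshold_deg = cam_threshold_deg,
                 bland_altman = ba),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats>", x$n, "paired measurements\n")
  cat(sprintf("  CCC                 %.3f [%.3f, %.3f]\n",
              x$ccc, x$ccc_ci_low, x$ccc_ci_high))
  cat(sprintf("  kappa (cam >= %g)   %.3f [%g%% agreement]\n",
              x$cam_threshold_deg, x$kappa, round(x$percent_agreement)))
  cat(sprintf("  mean abs diff       %.2f [SD %.2f]\n",
              x$mean_abs_diff, x$mad_sd))
  cat(sprintf("  Bland-Altman        %.2f [%.2f, %.2f], %d outlier(s)\n",
              x$bland_altman_mean, x$bland_altman_loa_low,
              x$bland_altman_loa_high, length(x$outlier_ids)))
  invisible(x)
}

#' Tidy an agreement battery
#'
#' @param x An [agreement_stats()] result.
#' @param ... Unused.
#' @return A tibble with `statistic` and `value` columns.
#' @method tidy agreement_stats
#' @export
tidy.agreement_stats <- function(x, ...) {
  tibble::tibble(
    statistic = c("ccc", "ccc_ci_low", "ccc_ci_high", "kappa",
                  "percent_agreement", "mean_abs_diff", "mad_sd",
                  "bland_altman_mean", "bland_altman_loa_low",
                  "bland_altman_loa_high", "n_outliers", "n"),
    value = c(x$ccc, x$ccc_ci_low, x$ccc_ci_high, x$kappa,
              x$percent_agreement, x$mean_abs_diff, x$mad_sd,
              x$bland_altman_mean, x$bland_altman_loa_low,
              x$bland_altman_loa_high, length(x$outlier_ids), x$n))
}

#' @rdname tidy.agreement_stats
#' @return For `glance`, a one-row tibble of the same statistics.
#' @method glance agreement_stats
#' @export
glance.agreement_stats <- function(x, ...) {
  tibble::tibble(ccc = x$ccc, ccc_ci_low = x$ccc_ci_low,
                 ccc_ci_high = x$ccc_ci_high, kappa = x$kappa,
                 percent_agreement = x$percent_agreement,
                 mean_abs_diff = x$mean_abs_diff, mad_sd = x$mad_sd,
                 bland_altman_mean = x$bland_altman_mean,
                 bland_altman_loa_low = x$bland_altman_loa_low,
                 bland_altman_loa_high = x$bland_altman_loa_high,
                 n_outliers = length(x$outlier_ids), n = x$n)
}
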