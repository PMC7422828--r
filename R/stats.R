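#' Mean sensitivity of a test
#'
#' The overall index of a visual field test: the arithmetic mean of the 44
#' test-role sensitivities. The two blind-spot locations are excluded — they
#' are validity checks, not measurements of the field.
#'
#' @param result A `test_result`, or a data frame with columns `role` and
#'   `dls_db`.
#' @return Mean sensitivity, dB.
#' @export
mean_sensitivity <- function(result) {
  loc <- if (inherits(result, "test_result")) result$locations else result
  stopifnot(all(c("role", "dls_db") %in% names(loc)))
  mean(loc$dls_db[loc$role == "test"])
}

#' Bland-Altman test-retest repeatability
#'
#' Agreement between two runs of the same test on the same observers. The
#' 95% coefficient of repeatability is defined as 1.96 times the sample SD of
#' the paired differences (run 2 minus run 1); the limits of agreement are
#' the mean difference plus or minus the coefficient.
#'
#' @param run1,run2 Paired numeric vectors (e.g. per-observer mean
#'   sensitivities), equal length >= 2.
#' @param conf_level Level defining the coefficient (1.96 at 0.95).
#' @return An object of class `bland_altman`: `mean_difference`, `cor95`,
#'   `limits_of_agreement`, `sd_diff`, `n`, and the differences.
#' @export
bland_altman <- function(run1, run2, conf_level = 0.95) {
  stopifnot(length(run1) == length(run2))
  if (length(run1) < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- run2 - run1
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  md <- mean(d)
  cor95 <- z * stats::sd(d)
  structure(list(mean_difference = md, cor95 = cor95,
                 limits_of_agreement = c(lower = md - cor95,
                                         upper = md + cor95),
                 sd_diff = stats::sd(d), n = length(d),
                 differences = d, means = (run1 + run2) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman repeatability (n = %d pairs)\n", x$n))
  cat(sprintf("  mean difference: %.3f dB\n", x$mean_difference))
  cat(sprintf("  CoR95: +/-%.3f dB\n", x$cor95))
  cat(sprintf("  95%% limits of agreement: [%.3f, %.3f] dB\n",
              x$limits_of_agreement[1], x$limits_of_agreement[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of runs (dB)",
                              ylab = "Difference, run 2 - run 1 (dB)", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$mean_difference, lty = 1)
  graphics::abline(h = x$limits_of_agreement, lty = 2, col = "red")
  invisible(x)
}

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' BCa percentile interval for an arbitrary statistic: the bias correction
#' `z0` comes from the fraction of bootstrap replicates below the point
#' estimate, and the acceleration `a` from the jackknife skewness of the
#' statistic. Reproducible under `seed`; with a degenerate bootstrap
#' distribution (all replicates equal, or bias correction undefined) it
#' falls back to the plain percentile interval with a warning.
#'
#' @param data Numeric vector (or data frame resampled by rows).
#' @param statistic Function of the (resampled) data returning a scalar.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return List: `ci` (`c(lower, upper)`), `estimate`, `z0`, `acceleration`,
#'   `method` (`"bca"` or `"percentile"`), `n_boot`, `level`.
#' @export
bca_bootstrap_ci <- function(data, statistic, n_boot = 20000, level = 0.95,
                             seed = 1) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stopifnot(n >= 2, n_boot >= 100, level > 0, level < 1)
  # canonical order: the interval is then exactly permutation-invariant for
  # plain samples; data frames (paired rows) keep the user's row order
  if (!is.data.frame(data) && is.numeric(data)) data <- sort(data)
  take <- function(idx) if (is.data.frame(data)) data[idx, , drop = FALSE]
  else data[idx]
  theta_hat <- statistic(data)
  boot_stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      statistic(take(sample.int(n, n, replace = TRUE))), numeric(1))
  })
  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)

  if (diff(range(boot_stats)) == 0)
    return(list(ci = stats::setNames(rep(boot_stats[1], 2), c("lower", "upper")),
                estimate = theta_hat, z0 = 0, acceleration = 0,
                method = "degenerate", n_boot = n_boot, level = level))

  prop <- mean(boot_stats < theta_hat)
  if (prop == 0 || prop == 1) {
    warning("degenerate bootstrap distribution; using percentile interval")
    ci <- stats::quantile(boot_stats, alpha, names = FALSE, type = 7)
    return(list(ci = stats::setNames(ci, c("lower", "upper")),
                estimate = theta_hat, z0 = NA_real_, acceleration = NA_real_,
                method = "percentile", n_boot = n_boot, level = level))
  }
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  zalpha <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  ci <- stats::quantile(boot_stats, adj, names = FALSE, type = 7)
  list(ci = stats::setNames(ci, c("lower", "upper")), estimate = theta_hat,
       z0 = z0, acceleration = a, method = "bca", n_boot = n_boot,
       level = level)
}

#' Bootstrap test for a difference in repeatability between devices
#'
#' Compares the 95% coefficient of repeatability of two devices measured on
#' the same observers. The observed statistic is `CoR_A - CoR_B`. The null
#' distribution is built by exchanging the device labels within each
#' observer at random (each observer's pair of run-differences is swapped
#' between devices with probability 1/2), which is exchangeable under the
#' hypothesis that both devices are equally repeatable. The two-sided
#' p-value is the smoothed fraction of null replicates at least as extreme
#' as the observation, `(1 + #(|D*| >= |D|)) / (n_boot + 1)`, so it always
#' lies in (0, 1].
#'
#' @param a_run1,a_run2 Device A paired runs (per-observer values).
#' @param b_run1,b_run2 Device B paired runs, same observers in the same
#'   order.
#' @param n_boot Number of label-permutation resamples.
#' @param seed RNG seed.
#' @return List: `p_value`, `observed_difference`, `cor_a`, `cor_b`,
#'   `n_boot`.
#' @export
cor_difference_test <- function(a_run1, a_run2, b_run1, b_run2,
                                n_boot = 20000, seed = 1) {
  n <- length(a_run1)
  stopifnot(length(a_run2) == n, length(b_run1) == n, length(b_run2) == n)
  if (n < 2) stop("repeatability comparison needs at least 2 observers")
  da <- a_run2 - a_run1
  db <- b_run2 - b_run1
  z <- stats::qnorm(0.975)
  obs <- z * (stats::sd(da) - stats::sd(db))
  null_diff <- with_seed(seed, {
    swap <- matrix(stats::runif(n * n_boot) < 0.5, n, n_boot)
    A <- ifelse(swap, db, da)   # n x n_boot
    B <- ifelse(swap, da, db)
    colsd <- function(m) {
      cm <- colMeans(m)
      sqrt((colSums(m^2) - n * cm^2) / (n - 1))
    }
    z * (colsd(A) - colsd(B))
  })
  p <- (1 + sum(abs(null_diff) >= abs(obs))) / (n_boot + 1)
  list(p_value = p, observed_difference = obs,
       cor_a = z * stats::sd(da), cor_b = z * stats::sd(db), n_boot = n_boot)
}

#' Pointwise paired comparison of two devices
#'
#' Paired t-test per grid location between devices, with Bonferroni control
#' of the family-wise error rate: a location is flagged only when its
#' p-value is below `alpha / m` over the `m` locations tested. The verdict
#' direction is the sign of the mean difference (A minus B).
#'
#' @param a_values,b_values Matrices (observers x locations) of paired
#'   per-location sensitivities for devices A and B.
#' @param alpha Family-wise significance level.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Data frame per location: `mean_difference`, `t`, `p_value`,
#'   `significant`, `direction` (`"a_higher"`, `"b_higher"`, `"none"`).
#' @export
pointwise_comparison <- function(a_values, b_values, alpha = 0.01,
                                 correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  a_values <- as.matrix(a_values)
  b_values <- as.matrix(b_values)
  stopifnot(all(dim(a_values) == dim(b_values)), nrow(a_values) >= 2)
  m <- ncol(a_values)
  thresh <- if (correction == "bonferroni") alpha / m else alpha
  out <- lapply(seq_len(m), function(j) {
    tt <- stats::t.test(a_values[, j], b_values[, j], paired = TRUE)
    data.frame(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_value < thresh
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$mean_difference > 0, "a_higher", "b_higher"))
  out
}

#' Normative pointwise table for a cohort
#'
#' Pools all tests of a cohort (e.g. 2 runs x n observers) per grid location
#' and reports the mean with the 2.5th and 97.5th percentiles — the 95%
#' population limits. Percentiles use linear interpolation between order
#' statistics (R quantile type 7); inputs are assumed already in right-eye
#' format.
#'
#' @param values Matrix (tests x locations) of pointwise sensitivities.
#' @param grid The [build_grid()] result giving location coordinates.
#' @return Data frame: `x_deg`, `y_deg`, `role`, `mean_db`, `p2.5_db`,
#'   `p97.5_db`, with attribute `percentile_convention`.
#' @export
normative_table <- function(values, grid = build_grid("right")) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(grid))
  q <- apply(values, 2, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE, type = 7)
  out <- data.frame(x_deg = grid$x_deg, y_deg = grid$y_deg, role = grid$role,
                    mean_db = colMeans(values),
                    p2.5_db = q[1, ], p97.5_db = q[2, ])
  attr(out, "percentile_convention") <-
    "linear interpolation between order statistics (R quantile type 7)"
  out
}

#' Minimum detectable difference of a paired design
#'
#' Post hoc sensitivity of a paired t-test: the smallest true mean difference
#' detectable with the given power, using the central-t approximation
#' `(t_{1 - alpha/2, n-1} + t_{power, n-1}) * sd / sqrt(n)`.
#'
#' @param n Number of pairs (>= 2).
#' @param sd_paired_diff SD of the paired differences.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power (default 0.80).
#' @return Minimum detectable difference, same units as `sd_paired_diff`.
#' @examples
#' min_detectable_difference(64, 1.548)  # ~0.55 dB
#' @export
min_detectable_difference <- function(n, sd_paired_diff, alpha = 0.05,
                                      power = 0.80) {
  stopifnot(n >= 2, sd_paired_diff > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  (stats::qt(1 - alpha / 2, n - 1) + stats::qt(power, n - 1)) *
    sd_paired_diff / sqrt(n)
}
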