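#' Power of the F-test for an intraclass correlation
#'
#' Exact power of the one-sided F-test of H0: ICC = `rho0` against
#' H1: ICC = `rho1` in the one-way reliability design with `n` subjects and
#' `k` repeated observations. With `C(rho) = 1 + k rho / (1 - rho)`, the
#' between/within F statistic scales by `C(rho)` under the truth, so
#'
#' `power = P[ F(n-1, n(k-1)) > (C(rho0) / C(rho1)) * F_crit(1 - alpha) ]`.
#'
#' At `rho1 = rho0` the power equals `alpha` exactly. Set
#' `two_sided = TRUE` to spend `alpha / 2` in the upper tail instead.
#'
#' @param n Number of subjects (>= 2).
#' @param k Observations (visits) per subject (>= 2).
#' @param rho0 Null ICC, in \[0, 1).
#' @param rho1 Alternative ICC, in \[rho0, 1).
#' @param alpha Significance level, in (0, 0.5).
#' @param two_sided Use alpha / 2 in the upper tail.
#' @return Power in (0, 1).
#' @examples
#' icc_test_power(n = 30, k = 2, rho0 = 0.5, rho1 = 0.77) # ~0.81
#' @export
icc_test_power <- function(n, k, rho0, rho1, alpha = 0.05, two_sided = FALSE) {
  n <- assert_count(n, "n", lower = 2)
  k <- assert_count(k, "k", lower = 2)
  assert_scalar_number(rho0, "rho0", 0, 1 - 1e-12)
  assert_scalar_number(rho1, "rho1", 0, 1 - 1e-12)
  assert_scalar_number(alpha, "alpha", 1e-12, 0.5 - 1e-12)
  if (rho1 < rho0) stop_config("`rho1` must be at least `rho0`.")
  a <- if (two_sided) alpha / 2 else alpha
  cc <- function(r) 1 + k * r / (1 - r)
  df1 <- n - 1
  df2 <- n * (k - 1)
  1 - pf(cc(rho0) / cc(rho1) * qf(1 - a, df1, df2), df1, df2)
}

#' Smallest detectable ICC at a target power
#'
#' The unique alternative `rho1` in `(rho0, 1)` at which
#' [icc_test_power()] reaches `target_power`, found by bracketed
#' root-finding to 1e-6.
#'
#' @inheritParams icc_test_power
#' @param target_power Desired power, in (alpha, 1).
#' @return The detectable ICC `rho1`.
#' @examples
#' detectable_icc(n = 30, k = 2, rho0 = 0.5, target_power = 0.8) # ~0.767
#' @export
detectable_icc <- function(n, k, rho0, target_power, alpha = 0.05, two_sided = FALSE) {
  assert_scalar_number(target_power, "target_power", alpha + 1e-9, 1 - 1e-12)
  f <- function(r) icc_test_power(n, k, rho0, r, alpha, two_sided) - target_power
  lo <- rho0 + 1e-9
  hi <- 1 - 1e-9
  if (f(hi) < 0) {
    stop_config("No detectable ICC below 1 reaches the target power for this design.")
  }
  uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Required sample size for an ICC reliability design
#'
#' Smallest integer `n` whose exact F-test power reaches `target_power`
#' (simple upward search). [required_n_approx()] is the Walter-Eliasziw-
#' Donner closed-form approximation for comparison.
#'
#' @inheritParams detectable_icc
#' @param n_max Search cap; exceeding it raises an infeasible-design error.
#' @return Integer sample size.
#' @export
required_n <- function(k, rho0, rho1, target_power, alpha = 0.05,
                       two_sided = FALSE, n_max = 1e6) {
  assert_scalar_number(target_power, "target_power", alpha + 1e-9, 1 - 1e-12)
  if (rho1 <= rho0) stop_config("`rho1` must exceed `rho0`.")
  n <- 2
  while (n <= n_max) {
    if (icc_test_power(n, k, rho0, rho1, alpha, two_sided) >= target_power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop_config(sprintf("Required n exceeds the cap of %g.", n_max))
}

#' @rdname required_n
#' @export
required_n_approx <- function(k, rho0, rho1, target_power, alpha = 0.05,
                              two_sided = FALSE) {
  if (rho1 <= rho0) stop_config("`rho1` must exceed `rho0`.")
  a <- if (two_sided) alpha / 2 else alpha
  za <- stats::qnorm(1 - a)
  zb <- stats::qnorm(target_power)
  cc <- function(r) 1 + k * r / (1 - r)
  theta <- log(cc(rho1) / cc(rho0))
  ceiling(1 + 2 * (za + zb)^2 * k / ((k - 1) * theta^2))
}

#' Power curve across candidate alternative ICCs
#'
#' @inheritParams icc_test_power
#' @param rho1_grid Alternatives to evaluate.
#' @return A tibble with columns `rho1` and `power`.
#' @export
power_curve <- function(n, k, rho0, rho1_grid = seq(rho0 + 0.01, 0.99, by = 0.01),
                        alpha = 0.05, two_sided = FALSE) {
  tibble::tibble(
    rho1 = rho1_grid,
    power = vapply(rho1_grid, function(r) {
      icc_test_power(n, k, rho0, r, alpha, two_sided)
    }, 0)
  )
}
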