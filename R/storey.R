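#' Storey q-values
#'
#' Estimates the proportion of truly null hypotheses as
#' \eqn{\hat\pi_0 = \#\{p > \lambda\} / (m (1 - \lambda))}, clipped to
#' (0, 1], and converts p-values to q-values by the step-up rule
#' \eqn{q(p_{(i)}) = \min_{j \ge i} \hat\pi_0 \, m \, p_{(j)} / j},
#' capped at 1. With \code{lambda_grid = TRUE}, \eqn{\hat\pi_0(\lambda)} is
#' evaluated on the grid 0.05, 0.10, ..., 0.90, smoothed with a cubic
#' spline, and read off at the grid maximum (the smoother variant of the
#' estimator); the single-\eqn{\lambda} default is fully deterministic and
#' is what the pipeline uses.
#'
#' @param p p-values in (0, 1].
#' @param lambda tuning proportion in [0, 1) (default 0.5).
#' @param lambda_grid use the spline-smoothed lambda grid estimate of pi0.
#' @return An object of class \code{"storey_result"}: list with
#'   \code{pi0_hat}, \code{lambda}, \code{q_values} (aligned with \code{p}).
#' @examples
#' storey_qvalues(c(0.001, 0.02, 0.4, 0.9))$q_values
#' @export
storey_qvalues <- function(p, lambda = 0.5, lambda_grid = FALSE) {
  if (lambda < 0 || lambda >= 1) stop("'lambda' must lie in [0, 1)")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)

  if (lambda_grid) {
    grid <- seq(0.05, 0.90, by = 0.05)
    pi0_l <- vapply(grid, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(grid))$y
    lambda <- max(grid)
  } else {
    pi0 <- sum(p > lambda) / (m * (1 - lambda))
  }
  # clip into (0, 1]: a zero estimate is replaced by the smallest value the
  # estimator can resolve at this lambda
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) pi0 <- 1 / (m * (1 - lambda))

  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted

  structure(list(pi0_hat = pi0, lambda = lambda, q_values = q),
            class = "storey_result")
}

#' @export
print.storey_result <- function(x, ...) {
  cat(sprintf("storey_result: m = %d, lambda = %.2f, pi0_hat = %.4f\n",
              length(x$q_values), x$lambda, x$pi0_hat))
  invisible(x)
}
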