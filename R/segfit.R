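#' Two-segment continuous least-squares fit with breakpoint search
#'
#' Fits `y = b0 + b1 * x + b2 * max(0, x - psi)` (continuous at the breakpoint
#' `psi`) by profiling the residual sum of squares over a uniform grid of
#' candidate breakpoints spanning the admissible interior of `x` (between the
#' 2nd smallest and 2nd largest distinct values, so both segments retain at
#' least two support points), then refining the grid minimizer by
#' golden-section search between its neighbouring grid points.  Also fits the
#' nested straight line for model selection.
#'
#' @param x predictor (EC, dS/m)
#' @param y response (group abundance)
#' @param grid_points number of candidate breakpoints (default 201)
#' @return list of class `ht_segfit`: `psi`, `intercept`, `left_slope`,
#'   `slope_change`, `rss_segmented`, `rss_linear`, `n`, plus the linear-fit
#'   coefficients
#' @export
fit_segmented <- function(x, y, grid_points = 201L) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 6L) stop("need at least 6 points for a segmented fit")
  ux <- sort(unique(x))
  if (length(ux) < 4L) stop("need at least 4 distinct x values")
  lo <- ux[2L]; hi <- ux[length(ux) - 1L]
  if (!(lo < hi)) stop("admissible breakpoint interval is empty")
  rss_at <- function(psi) {
    X <- cbind(1, x, pmax(0, x - psi))
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }
  # exclude the interval endpoints themselves: at psi = max admissible x the
  # hinge column can become collinear
  eps <- (hi - lo) * 1e-6
  grid <- seq(lo + eps, hi - eps, length.out = grid_points)
  rss <- vapply(grid, rss_at, numeric(1))
  k <- which.min(rss)
  a <- grid[max(1L, k - 1L)]; b <- grid[min(grid_points, k + 1L)]
  # golden-section refinement of the RSS profile between grid neighbours
  gr <- (sqrt(5) - 1) / 2
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- rss_at(c1); f2 <- rss_at(c2)
  for (it in seq_len(60L)) {
    if (b - a < 1e-9) break
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- rss_at(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- rss_at(c2) }
  }
  psi <- (a + b) / 2
  cand <- c(psi, grid[k])
  psi <- cand[which.min(vapply(cand, rss_at, numeric(1)))]
  X <- cbind(1, x, pmax(0, x - psi))
  f <- stats::lm.fit(X, y)
  lin <- stats::lm.fit(cbind(1, x), y)
  structure(list(psi = psi,
                 intercept = unname(f$coefficients[1]),
                 left_slope = unname(f$coefficients[2]),
                 slope_change = unname(f$coefficients[3]),
                 rss_segmented = sum(f$residuals^2),
                 rss_linear = sum(lin$residuals^2),
                 linear_intercept = unname(lin$coefficients[1]),
                 linear_slope = unname(lin$coefficients[2]),
                 tss = sum((y - mean(y))^2),
                 n = n),
            class = "ht_segfit")
}

#' Linear-versus-segmented model selection
#'
#' The segmented model (4 parameters: intercept, slope, slope change,
#' breakpoint) is compared with the nested straight line (2 parameters)
#' either by the F statistic
#' `F = ((rss_linear - rss_segmented)/2) / (rss_segmented/(n-4))` with p from
#' `F(2, n-4)`, or by BIC.  Because the breakpoint is estimated from the same
#' data, the F test is anti-conservative; its empirical type-I behaviour is
#' characterised in the test suite.
#'
#' @param fit an `ht_segfit` from [fit_segmented()]
#' @param alpha significance level for the F criterion (default 0.05)
#' @param criterion `"f_test"` (default) or `"bic"`
#' @return list with `chosen_model` (`"linear"`/`"segmented"`), `statistic`,
#'   and `p_value` (F criterion) or `delta_bic` (BIC criterion,
#'   linear minus segmented)
#' @export
select_model <- function(fit, alpha = 0.05, criterion = c("f_test", "bic")) {
  criterion <- match.arg(criterion)
  n <- fit$n
  if (n <= 4L) stop("model selection needs n > 4")
  if (criterion == "f_test") {
    # scale-free near-zero threshold: RSS below 1e-10 of the total sum of
    # squares counts as a perfect fit
    tol <- 1e-10 * max(if (!is.null(fit$tss)) fit$tss else fit$rss_linear, 0)
    if (fit$rss_linear <= tol)
      return(list(chosen_model = "linear", statistic = 0, p_value = 1))
    if (fit$rss_segmented <= tol) {
      # perfect segmented fit while the line is imperfect
      return(list(chosen_model = "segmented", statistic = Inf, p_value = 0))
    }
    stat <- ((fit$rss_linear - fit$rss_segmented) / 2) /
      (fit$rss_segmented / (n - 4))
    p <- stats::pf(stat, 2, n - 4, lower.tail = FALSE)
    list(chosen_model = if (p < alpha) "segmented" else "linear",
         statistic = stat, p_value = p)
  } else {
    bic <- function(rss, k) n * log(rss / n) + k * log(n)
    db <- bic(fit$rss_linear, 2L) - bic(fit$rss_segmented, 4L)
    list(chosen_model = if (db > 0) "segmented" else "linear",
         statistic = db, delta_bic = db)
  }
}

#' @export
print.ht_segfit <- function(x, ...) {
  cat(sprintf(paste0("segmented fit: psi = %.4g, left slope = %.4g, ",
                     "slope change = %.4g, RSS %.4g (linear %.4g), n = %d\n"),
              x$psi, x$left_slope, x$slope_change,
              x$rss_segmented, x$rss_linear, x$n))
  invisible(x)
}
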