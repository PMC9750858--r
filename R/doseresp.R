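# Four-parameter logistic (4PL) dose-response fitting with asymptotic
# confidence intervals on log10(EC50).

#' Simulated or measured dose-response data layout
#'
#' All dose-response functions take a data frame with one row per measured
#' well: a concentration column (molar, or any single consistent unit) and a
#' response column (assay units). Replicates are fitted as individual
#' points, never pre-averaged.
#'
#' @name dose_response_data
NULL

fourpl <- function(x, bottom, top, lec50, hill) {
  # response = bottom + (top - bottom) / (1 + (EC50/x)^hill), EC50 on log10
  r <- 10^(hill * (lec50 - log10(x)))
  ifelse(x == 0, bottom, bottom + (top - bottom) / (1 + r))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (EC50 / x)^hill)` with EC50
#' parameterized on the log10 scale, variable slope, and unconstrained
#' asymptotes. Multi-start Levenberg-Marquardt initialization (slope sign
#' and EC50 location grid); the best converged start by residual sum of
#' squares wins. The 95% confidence interval for EC50 is asymptotic on
#' log10(EC50) with a t(n - 4) quantile. After fitting, orientation is
#' normalized so `bottom <= top` (the hill slope flips sign accordingly;
#' the fitted curve is unchanged).
#'
#' @param data Data frame of dose-response points.
#' @param conc,resp Column names (tidy-eval) for concentration and response;
#'   defaults `concentration`, `response`.
#' @param conf_level Confidence level for the EC50 interval (default 0.95).
#' @return An object of class `dr_fit`: list with `ec50`, `hill`, `top`,
#'   `bottom`, `ec50_ci` (length 2), `rss`, `n`, `converged`, `data`, and
#'   the underlying `nls` fit.
#' @examples
#' d <- simulate_curve(ec50 = 5e-8, concentrations = 10^seq(-9, -5, 0.5),
#'                     noise_sd = 0, seed = 1)
#' fit_4pl(d)$ec50
#' @export
fit_4pl <- function(data, conc = "concentration", resp = "response",
                    conf_level = 0.95) {
  x <- data[[conc]]
  y <- data[[resp]]
  stopifnot(length(x) == length(y), all(is.finite(y)), all(x >= 0))
  if (length(unique(x[x > 0])) < 4) {
    stop("need at least 4 distinct non-zero concentrations", call. = FALSE)
  }
  n <- length(y)
  lx <- log10(x[x > 0])
  starts <- tidyr::expand_grid(
    lec50 = stats::quantile(lx, c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(-1, 0.8, 2))
  span <- max(y) - min(y)
  fits <- purrr::pmap(starts, function(lec50, hill) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ fourpl(x, bottom, top, lec50, hill),
        start = list(bottom = min(y), top = max(y),
                     lec50 = lec50, hill = hill),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  converged <- length(fits) > 0
  if (!converged) {
    stop("4PL fit failed to converge from any start", call. = FALSE)
  }
  rss <- vapply(fits, stats::deviance, numeric(1))
  fit <- fits[[which.min(rss)]]
  cf <- stats::coef(fit)

  # orientation normalization: identical curve with bottom <= top
  if (cf[["bottom"]] > cf[["top"]]) {
    cf <- c(bottom = cf[["top"]], top = cf[["bottom"]],
            lec50 = cf[["lec50"]], hill = -cf[["hill"]])
  }
  se_l <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lec50"]],
                   error = function(e) NA_real_)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 4)
  ci <- 10^(cf[["lec50"]] + c(-1, 1) * tq * se_l)

  # warn if the dose-means are non-monotone beyond the residual noise
  sig <- sqrt(min(rss) / max(n - 4, 1))
  med <- stats::aggregate(list(m = y), list(x = x), mean)
  med <- med[order(med$x), ]
  if (nrow(med) >= 3) {
    d <- diff(med$m)
    if (any(d > 3 * sig) && any(d < -3 * sig)) {
      warning("dose-response means are non-monotone beyond the noise level",
              call. = FALSE)
    }
  }
  structure(list(
    ec50 = unname(10^cf[["lec50"]]),
    hill = unname(cf[["hill"]]),
    top = unname(cf[["top"]]),
    bottom = unname(cf[["bottom"]]),
    ec50_ci = ci,
    rss = min(rss),
    sigma = sqrt(min(rss) / (n - 4)),
    n = n,
    conf_level = conf_level,
    converged = converged,
    data = tibble::tibble(concentration = x, response = y),
    fit = fit
  ), class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf(
    "<dr_fit> EC50 %.3g [%.3g, %.3g], hill %.2f, bottom %.3g, top %.3g (n = %d)\n",
    x$ec50, x$ec50_ci[1], x$ec50_ci[2], x$hill, x$bottom, x$top, x$n))
  invisible(x)
}

#' @rdname fit_4pl
#' @param x A `dr_fit`.
#' @param ... Unused.
#' @method tidy dr_fit
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ec50", "hill", "top", "bottom"),
    estimate = c(x$ec50, x$hill, x$top, x$bottom),
    conf.low = c(x$ec50_ci[1], NA, NA, NA),
    conf.high = c(x$ec50_ci[2], NA, NA, NA))
}

#' @rdname fit_4pl
#' @method glance dr_fit
#' @export
glance.dr_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, ec50_low = x$ec50_ci[1],
                 ec50_high = x$ec50_ci[2], hill = x$hill, top = x$top,
                 bottom = x$bottom, rss = x$rss, sigma = x$sigma, n = x$n,
                 converged = x$converged)
}

#' @export
predict.dr_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration else
    newdata$concentration
  fourpl(x, object$bottom, object$top, log10(object$ec50), object$hill)
}

#' Plot a fitted dose-response curve
#'
#' Points plus the fitted 4PL curve on a log10 concentration axis.
#'
#' @param object A `dr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dr_fit
#' @export
autoplot.dr_fit <- function(object, ...) {
  dat <- object$data[object$data$concentration > 0, ]
  grid <- tibble::tibble(concentration = 10^seq(
    log10(min(dat$concentration)), log10(max(dat$concentration)),
    length.out = 200))
  grid$response <- predict(object, grid)
  ggplot2::ggplot(dat, ggplot2::aes(.data$concentration, .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "response") +
    ggplot2::theme_minimal()
}
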