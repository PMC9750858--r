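# Immunoassay limit of detection by the blank + 3 x SD rule on a
# low-linear-range regression of signal against log10(concentration).

# Largest contiguous low-concentration window of >= 3 distinct
# concentrations with regression R^2 >= r2_min and mean response below half
# of the overall maximum. Returns the concentrations in the window.
select_linear_range <- function(x, y, r2_min = 0.98) {
  ux <- sort(unique(x[x > 0]))
  half_max <- max(y) / 2
  best <- NULL
  for (len in rev(seq(3, length(ux)))) {
    for (start in seq_len(length(ux) - len + 1)) {
      win <- ux[start:(start + len - 1)]
      sel <- x %in% win
      if (mean(y[sel]) >= half_max) next
      fit <- stats::lm(y[sel] ~ log10(x[sel]))
      r2 <- summary(fit)$r.squared
      if (is.finite(r2) && r2 >= r2_min) {
        best <- win
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

#' Limit of detection from a dose-response series and blank replicates
#'
#' Fits `response ~ log10(concentration)` on the low linear range and
#' inverts the line at the detection threshold
#' `blank mean + 3 x blank SD`. The linear range defaults to the largest
#' contiguous low-concentration window of at least 3 points with
#' R^2 >= 0.98 and mean response below half the observed maximum; an
#' explicit `range` always wins.
#'
#' @param data Data frame of dose-response points (one row per well).
#' @param blanks Numeric vector of blank (zero-analyte) responses,
#'   length >= 2 (or >= 1 if you accept a degenerate SD of 0).
#' @param conc,resp Column names; defaults `concentration`, `response`.
#' @param range Optional numeric vector of concentrations to use as the
#'   linear range (overrides automatic selection).
#' @param r2_min R^2 threshold for automatic range selection.
#' @return Object of class `lod_result`: list with `lod`, `slope`,
#'   `intercept`, `blank_mean`, `blank_sd`, `threshold`, `range`
#'   (concentrations used), `extrapolated` (logical).
#' @examples
#' d <- data.frame(concentration = 10^seq(-2, 1, length.out = 6))
#' d$response <- 0.5 + 0.3 * log10(d$concentration)
#' estimate_lod(d, blanks = c(0.04, 0.05, 0.06), range = d$concentration)$lod
#' @export
estimate_lod <- function(data, blanks, conc = "concentration",
                         resp = "response", range = NULL, r2_min = 0.98) {
  x <- data[[conc]]
  y <- data[[resp]]
  stopifnot(length(blanks) >= 1, all(is.finite(blanks)), all(x >= 0))
  if (is.null(range)) {
    range <- select_linear_range(x, y, r2_min)
    if (is.null(range)) {
      stop("no linear low range found (>= 3 concentrations, R^2 >= ",
           r2_min, "); supply `range` explicitly", call. = FALSE)
    }
  }
  sel <- x %in% range & x > 0
  if (sum(sel) < 3) stop("fewer than 3 points in the linear range",
                         call. = FALSE)
  fit <- stats::lm(y[sel] ~ log10(x[sel]))
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 1e-12 * max(abs(y), 1)) {
    stop("no dose dependence: regression slope is not positive",
         call. = FALSE)
  }
  blank_mean <- mean(blanks)
  blank_sd <- if (length(blanks) >= 2) stats::sd(blanks) else 0
  threshold <- blank_mean + 3 * blank_sd
  lod <- 10^((threshold - intercept) / slope)
  extrapolated <- lod < min(x[sel]) || lod > max(x[sel])
  if (extrapolated) {
    warning("LOD lies outside the regression range (extrapolated)",
            call. = FALSE)
  }
  structure(list(lod = lod, slope = slope, intercept = intercept,
                 blank_mean = blank_mean, blank_sd = blank_sd,
                 threshold = threshold, range = sort(unique(x[sel])),
                 n_points = sum(sel), extrapolated = extrapolated,
                 data = tibble::tibble(concentration = x, response = y)),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf(
    "<lod_result> LOD %.3g (threshold %.4g = blank %.4g + 3 x SD %.4g; slope %.3g)\n",
    x$lod, x$threshold, x$blank_mean, x$blank_sd, x$slope))
  invisible(x)
}

#' @rdname estimate_lod
#' @param x An `lod_result`.
#' @param ... Unused.
#' @method glance lod_result
#' @export
glance.lod_result <- function(x, ...) {
  tibble::tibble(lod = x$lod, slope = x$slope, intercept = x$intercept,
                 blank_mean = x$blank_mean, blank_sd = x$blank_sd,
                 threshold = x$threshold, n_points = x$n_points,
                 extrapolated = x$extrapolated)
}

#' Plot an LOD determination
#'
#' Points, the linear-range regression line, the detection threshold and
#' the LOD.
#'
#' @param object An `lod_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lod_result
#' @export
autoplot.lod_result <- function(object, ...) {
  dat <- object$data[object$data$concentration > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(log10(.data$concentration),
                                    .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "#2166ac") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = log10(object$lod), linetype = 3) +
    ggplot2::labs(x = "log10 concentration", y = "response") +
    ggplot2::theme_minimal()
}
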