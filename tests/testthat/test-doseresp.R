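test_that("noiseless 4PL data are recovered essentially exactly", {
  conc <- 10^seq(-9, -5.5, 0.5)
  d <- simulate_curve(ec50 = 5e-8, hill = 1, bottom = 0, top = 1,
                      concentrations = conc, noise_sd = 0, seed = 1)
  f <- fit_4pl(d)
  expect_equal(f$ec50, 5e-8, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-4)
  expect_equal(f$bottom, 0, tolerance = 1e-6)
  expect_equal(f$top, 1, tolerance = 1e-6)

  # closed form of the 4PL: the fitted curve passes (EC50, midpoint)
  mid <- predict(f, data.frame(concentration = f$ec50))
  expect_equal(mid, (f$top + f$bottom) / 2, tolerance = 1e-8)
})

test_that("EC50 scales with concentration units, shape does not", {
  d <- simulate_curve(ec50 = 5e-8, hill = 1.3, bottom = 0.1, top = 0.9,
                      noise_sd = 0.02, seed = 7)
  f1 <- fit_4pl(d)
  d2 <- d
  d2$concentration <- d2$concentration * 1e9 # molar -> nM
  f2 <- fit_4pl(d2)
  expect_equal(f2$ec50, f1$ec50 * 1e9, tolerance = 1e-4)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
  expect_equal(f2$top, f1$top, tolerance = 1e-6)
  expect_equal(f2$bottom, f1$bottom, tolerance = 1e-6)
})

test_that("decreasing curves are normalized to bottom <= top", {
  d <- simulate_curve(ec50 = 1e-7, hill = -1, bottom = 0.05, top = 0.95,
                      noise_sd = 0.01, seed = 9)
  f <- fit_4pl(d)
  expect_lte(f$bottom, f$top)
  expect_equal(f$ec50, 1e-7, tolerance = 0.2)
})

test_that("the EC50 interval covers and the tidiers are coherent", {
  d <- simulate_curve(ec50 = 5e-8, noise_sd = 0.05, seed = 11)
  f <- fit_4pl(d)
  expect_lte(f$ec50_ci[1], f$ec50)
  expect_gte(f$ec50_ci[2], f$ec50)

  td <- tidy(f)
  expect_identical(td$term, c("ec50", "hill", "top", "bottom"))
  expect_equal(td$estimate[1], f$ec50)
  g <- glance(f)
  expect_identical(nrow(g), 1L)
  expect_true(g$converged)
})

test_that("parameter recovery holds across seeded noisy datasets", {
  res <- vapply(1:40, function(s) {
    d <- simulate_curve(ec50 = 5e-8, noise_sd = 0.05, seed = 4000 + s)
    f <- suppressWarnings(fit_4pl(d))
    c(abs(log10(f$ec50 / 5e-8)),
      f$ec50_ci[1] <= 5e-8 && 5e-8 <= f$ec50_ci[2])
  }, numeric(2))
  expect_lt(median(res[1, ]), 0.05)
  expect_gte(mean(res[2, ]), 0.8)
})

test_that("too few concentrations is an explicit error", {
  d <- data.frame(concentration = c(1e-8, 1e-7, 1e-6),
                  response = c(0.1, 0.5, 0.9))
  expect_error(fit_4pl(d), "at least 4 distinct")
})

test_that("LOD inverts the calibration line at blank + 3 SD", {
  # line: A450 = 0.5 + 0.3 * log10(c); blanks mean 0.05, SD 0.01
  conc <- 10^seq(-2, 1, length.out = 8)
  d <- data.frame(concentration = conc,
                  response = 0.5 + 0.3 * log10(conc))
  blanks <- c(0.04, 0.05, 0.06) # mean 0.05, sd 0.01 exactly
  r <- suppressWarnings(estimate_lod(d, blanks, range = conc))
  expect_equal(r$threshold, 0.08)
  expect_equal(r$lod, 10^((0.08 - 0.5) / 0.3), tolerance = 1e-9)
  expect_equal(r$lod, 0.0398, tolerance = 1e-3)

  # degenerate blanks: threshold collapses onto the blank mean
  r0 <- suppressWarnings(estimate_lod(d, rep(0.05, 3), range = conc))
  expect_equal(r0$threshold, 0.05)
  expect_equal(0.5 + 0.3 * log10(r0$lod), 0.05, tolerance = 1e-9)

  # LOD is monotone increasing in the blank SD
  lods <- vapply(c(0.005, 0.01, 0.02, 0.04), function(s) {
    b <- 0.05 + c(-1, 0, 1) * s
    suppressWarnings(estimate_lod(d, b, range = conc))$lod
  }, numeric(1))
  expect_true(all(diff(lods) > 0))

  # a flat (or decreasing) series has no dose dependence
  flat <- data.frame(concentration = conc, response = rep(0.2, 8))
  expect_error(estimate_lod(flat, blanks, range = conc),
               "no dose dependence")
})

test_that("automatic linear-range selection finds the low window", {
  # saturating curve: linear in log10(c) at low c, flat above the kink
  conc <- 10^seq(-3, 2, 0.5)
  resp <- pmin(0.5 + 0.25 * log10(conc), 0.4)
  d <- data.frame(concentration = rep(conc, each = 2),
                  response = rep(resp, each = 2))
  r <- suppressWarnings(estimate_lod(d, c(0.04, 0.05, 0.06)))
  # stated contract: a contiguous low window of >= 3 concentrations,
  # mean response under half the maximum, window regression R^2 >= 0.98,
  # and the saturated top excluded
  expect_gte(length(r$range), 3)
  expect_identical(min(r$range), min(conc))
  expect_identical(r$range, conc[seq_along(r$range)])
  sel <- d$concentration %in% r$range
  expect_lt(mean(d$response[sel]), max(d$response) / 2)
  win_fit <- stats::lm(d$response[sel] ~ log10(d$concentration[sel]))
  expect_gte(summary(win_fit)$r.squared, 0.98)
  expect_lt(max(r$range), 10)

  # an explicit range always wins over the automatic rule
  r2 <- suppressWarnings(
    estimate_lod(d, c(0.04, 0.05, 0.06), range = conc[1:4]))
  expect_identical(r2$range, conc[1:4])
  expect_equal(r2$slope, 0.25, tolerance = 1e-9)
})

test_that("selectivity folds reproduce the printed EC50 arithmetic", {
  fits <- data.frame(receptor = "DIAZI",
                     ligand = c("diazinon", "azinphos"),
                     ec50 = c(43e-9, 1.1e-6))
  sel <- selectivity_matrix(fits, c(DIAZI = "diazinon"))
  off <- sel$folds[!sel$folds$on_target, ]
  expect_equal(off$fold, 1.1e-6 / 43e-9, tolerance = 1e-9)
  expect_gt(off$fold, 10)
  expect_true(sel$classification$selective)

  # equal potency is not selective
  eq <- data.frame(receptor = "R", ligand = c("on", "off"),
                   ec50 = c(1e-7, 1e-7))
  expect_false(selectivity_matrix(eq, c(R = "on"))$classification$selective)

  # censored off-target propagates as a bound
  cen <- data.frame(receptor = "R", ligand = c("on", "off"),
                    ec50 = c(1e-7, 1e-5),
                    censored = c(FALSE, TRUE))
  sc <- selectivity_matrix(cen, c(R = "on"))
  offc <- sc$folds[!sc$folds$on_target, ]
  expect_identical(offc$fold_label, "> 100")
  expect_true(sc$classification$selective)

  expect_error(selectivity_matrix(fits, c(OTHER = "diazinon")),
               "no on-target")
  cen_on <- data.frame(receptor = "R", ligand = "on", ec50 = 1e-5,
                       censored = TRUE)
  expect_error(selectivity_matrix(cen_on, c(R = "on")), "finite on-target")
})

test_that("dose-response tables round-trip through the CSV reader", {
  d <- simulate_curve(ec50 = 2e-8, noise_sd = 0.02, seed = 13)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  back <- read_dose_response(path)
  f <- fit_4pl(back)
  expect_equal(f$ec50, 2e-8, tolerance = 0.2)
  expect_error(read_dose_response({
    p <- tempfile(fileext = ".csv")
    readr::write_csv(data.frame(x = 1), p)
    p
  }), "lacks column")
})
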