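# Synthetic curve families for fit tests: a smooth, monotone-in-mu family
# H(d; mu) with known analytic form, packaged into hs_curve / calibration_set
# structures.  The relaxation steepens as mu decreases, mirroring the real
# statistic ("a larger value of mu will correspond to a lower curve").

fake_curve <- function(mu, n_bins = 60, H0 = 7.5e-5, Hbar = 6.5e-4,
                       noise = 0, n_sites = 1e6) {
  d <- seq(0, 0.1, length.out = n_bins + 1)[-1]
  # relaxation amplitude decreases linearly in mu ("larger mu = lower
  # curve"); linearity in mu makes the spline interpolant exact, so fit
  # accuracy is tested separately from interpolation curvature error
  f <- 1 - exp(-d / 0.02)
  H <- H0 + f * (6e-4 - 1e4 * mu)
  if (noise > 0) H <- H + rnorm(n_bins, 0, noise)
  structure(list(bin_lo = d - d[1], bin_hi = d,
                 n_het = H * n_sites, n_sites = rep(n_sites, n_bins),
                 H = H, H0 = H0, hbar_sr = Hbar, hbar_genome = Hbar,
                 var = rep((2e-6)^2, n_bins), n_points = 100,
                 by_chrom = list(), n_bins = n_bins, d_max = 0.1),
            class = "hs_curve")
}

fake_calib <- function(mu_grid = c(1, 2, 4) * 1e-8, ...) {
  structure(list(mu_grid = mu_grid,
                 curves = lapply(mu_grid, fake_curve, ...),
                 alpha = 3000, pi = 0.09, n_reps = rep(1, length(mu_grid)),
                 S = c(5, 10), n_bins = 60, d_max = 0.1),
            class = "calibration_set")
}

test_that("fitting a grid curve returns the grid mu (identity property)", {
  calib <- fake_calib()
  for (mu in calib$mu_grid) {
    fit <- fit_mu(fake_curve(mu), calib, adjust = FALSE)
    expect_equal(as.numeric(fit), mu, tolerance = 1e-4)
  }
})

test_that("fit recovers off-grid rates of a smooth family within 1%", {
  calib <- fake_calib()
  for (mu in c(1.4, 2.5, 3.2) * 1e-8) {
    fit <- fit_mu(fake_curve(mu), calib, adjust = FALSE)
    expect_lt(abs(as.numeric(fit) - mu) / mu, 0.01)
  }
})

test_that("a lower observed curve fits a larger mu", {
  calib <- fake_calib()
  obs <- fake_curve(2e-8)
  lower <- obs
  lower$H <- obs$H0 + (obs$H - obs$H0) * 0.9   # slower apparent relaxation
  expect_gt(as.numeric(fit_mu(lower, calib, adjust = FALSE)),
            as.numeric(fit_mu(obs, calib, adjust = FALSE)))
})

test_that("an observed curve far outside the family raises an extrapolation error", {
  calib <- fake_calib()
  obs <- fake_curve(2e-8)
  obs$H <- obs$H * 3
  obs$var <- rep((1e-7)^2, 60)
  expect_error(fit_mu(obs, calib, adjust = FALSE), "extrapolation")
})

test_that("weighted jackknife reduces to the classical estimator for equal blocks", {
  set.seed(14)
  x <- rnorm(12)
  loo <- vapply(seq_along(x), function(i) mean(x[-i]), 0)
  res <- weighted_jackknife(mean(x), loo, rep(5, 12))
  expect_equal(res$se, sd(x) / sqrt(length(x)), tolerance = 1e-10)
  expect_equal(res$est, mean(x), tolerance = 1e-10)
})

test_that("jackknife SE matches the closed-form SE for iid blocks of known variance", {
  # per-chromosome estimates are iid draws: the jackknife SE of the mean
  # should match sigma/sqrt(G) on average over many replicates
  set.seed(15)
  sigma <- 0.3
  G <- 10
  ses <- replicate(300, {
    x <- rnorm(G, sd = sigma)
    loo <- vapply(seq_len(G), function(i) mean(x[-i]), 0)
    weighted_jackknife(mean(x), loo, rep(1, G))$se
  })
  truth <- sigma / sqrt(G)
  expect_lt(abs(mean(ses) - truth) / truth, 0.1)
})

test_that("alpha uncertainty propagates through the regression slope", {
  fit_at_alpha <- function(a) 1.5e-8 + 1.66e-12 * a   # slope 1.66e-4 x 1e-8 / Mor^-1
  res <- propagate_alpha_uncertainty(fit_at_alpha, alpha_se = 300)
  expect_equal(res$slope, 1.66e-12, tolerance = 1e-6)
  expect_equal(res$se, 1.66e-12 * 300, tolerance = 1e-6)  # ~0.05e-8
  expect_equal(round(res$se / 1e-8, 2), 0.05)
  expect_equal(propagate_alpha_uncertainty(fit_at_alpha, alpha_se = 0)$se, 0)
})

test_that("error combination is a root sum of squares, order-invariant", {
  expect_equal(combine_uncertainty(0.3, 0.4), 0.5)
  expect_equal(combine_uncertainty(0.4, 0.3), 0.5)
  expect_equal(combine_uncertainty(7, 0, 0), 7)
  expect_equal(combine_uncertainty(c(1, 2), 2), 3)
})

test_that("report conversions: per-year rate and TMRCA of a heterozygosity", {
  expect_equal(per_year_rate(1.61e-8), 1.61e-8 / 29)
  expect_equal(round(per_year_rate(1.61e-8) * 1e9, 2), 0.56)  # 0.555e-9
  expect_equal(tmrca_of_het(5e-5, 1.61e-8), 5e-5 / (2 * 1.61e-8))
  expect_equal(round(tmrca_of_het(5e-5, 1.61e-8) / 50) * 50, 1550)
  expect_error(tmrca_of_het(5e-5, 0), "positive")
})

test_that("averaging calibrations takes the mean of the replicate fits", {
  vals <- c(1.9e-8, 2.1e-8, 2.0e-8)
  res <- average_calibrations(function(i) vals[i], n_reps = 3)
  expect_equal(res$mu, mean(vals))
  expect_equal(average_calibrations(function(i) 3e-8, n_reps = 1)$mu, 3e-8)
})
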