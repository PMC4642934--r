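# Fitting the mutation rate.  At each distance bin a natural cubic spline
# maps mu -> H(d; mu) through the calibration curves; the fitted rate
# minimises the variance-weighted squared distance between the observed
# curve and the interpolated calibration family.  The d = 0 anchor is not
# part of the sum: it is fixed by ascertainment in both data sets.

.cal_adjusted <- function(calib, hbar_real, drop_chrom = NULL) {
  lapply(calib$curves, function(cv) {
    if (!is.null(drop_chrom))
      cv <- finalize_hs_curve(cv$by_chrom, calib$n_bins, calib$d_max,
                              drop_chrom = drop_chrom)
    asymptote_adjust(smooth_calibration_curve(cv), hbar_real)
  })
}

# The true relaxation curve is a smooth function of distance; the simulated
# calibration curves measure it with per-bin sampling noise whose magnitude
# differs systematically across the mu grid (higher-mu calibrations
# ascertain more windows).  Unsmoothed, that noise both inflates the fit
# variance and biases weighted least squares toward the least-noisy curve.
# A site-count-weighted smoothing spline along d (moderate df: the curve
# has one rise and a flattening) removes most of it; the observed curve is
# never smoothed -- its noise is what the fit weights account for.
smooth_calibration_curve <- function(cv, df = 10) {
  ok <- is.finite(cv$H) & cv$n_sites > 0
  if (sum(ok) < df + 2) return(cv)
  mid <- (cv$bin_lo + cv$bin_hi) / 2
  fit <- stats::smooth.spline(mid[ok], cv$H[ok], w = cv$n_sites[ok], df = df)
  cv$H[ok] <- stats::predict(fit, mid[ok])$y
  cv
}

#' Fit the mutation rate against a calibration set
#'
#' Interpolates the observed relaxation curve within the calibration family
#' (natural cubic spline across the mu grid at each bin) and minimises the
#' variance-weighted least-squares objective over mu by a dense grid search
#' refined with golden-section minimisation (absolute tolerance 1e-11 on
#' mu, far below the reported precision).  Calibration curves are
#' asymptote-adjusted to the observed super-region heterozygosity before
#' fitting.  Per-bin weights are the reciprocal leave-one-chromosome
#' jackknife variances of the observed curve; zero variances are replaced
#' by the smallest positive one with a warning.
#'
#' @param obs observed `hs_curve`.
#' @param calib a [build_calibration()] result.
#' @param adjust apply the asymptote adjustment (default TRUE).
#' @return fitted mu (per base per generation), with attribute `objective`.
#' @export
fit_mu <- function(obs, calib, adjust = TRUE) {
  cal <- if (adjust) .cal_adjusted(calib, obs$hbar_sr) else calib$curves
  C <- vapply(cal, `[[`, numeric(obs$n_bins), "H")
  ok_bin <- obs$n_sites > 0 & rowSums(!is.finite(C)) == 0
  if (sum(ok_bin) < 3) stop("too few usable bins to fit")
  w <- fit_weights(obs)[ok_bin]
  Hobs <- obs$H[ok_bin]
  Cm <- C[ok_bin, , drop = FALSE]
  # extrapolation guard: the observed curve should live inside the envelope
  # of the calibration family; per-bin sampling noise is allowed for (with
  # finite counts a matched curve still leaves the min/max envelope of a
  # handful of noisy curves in about half the bins by exchangeability)
  sd_bin <- sqrt(1 / w)
  outside <- Hobs < apply(Cm, 1, min) - 2 * sd_bin |
    Hobs > apply(Cm, 1, max) + 2 * sd_bin
  if (mean(outside) > 0.5)
    stop("extrapolation: observed curve outside the calibration envelope ",
         "in more than half of the bins")
  splines <- apply(Cm, 1, function(h)
    splinefun(calib$mu_grid, h, method = "natural"))
  obj <- function(mu) {
    pred <- vapply(splines, function(f) f(mu), 0)
    sum(w * (Hobs - pred)^2)
  }
  lo <- 0.5 * min(calib$mu_grid)
  hi <- 2 * max(calib$mu_grid)
  cand <- exp(seq(log(lo), log(hi), length.out = 240))
  vals <- vapply(cand, obj, 0)
  i <- which.min(vals)
  br <- c(cand[max(1, i - 1)], cand[min(length(cand), i + 1)])
  opt <- optimize(obj, interval = br, tol = 1e-11)
  structure(opt$minimum, objective = opt$objective)
}

# Per-bin weights for the variance-weighted fit.  The leave-one-chromosome
# jackknife gives an unbiased per-bin variance, but with a modest number of
# chromosomes each estimate has a large relative error, and raw reciprocal
# weights would concentrate the fit on whichever bins drew a small variance
# by chance.  The variances are therefore stabilized through a
# one-parameter model, var_d = phi * H_d / n_d (binomial sampling variance
# times a common overdispersion factor phi, estimated as the median ratio
# of the jackknife variances to H_d/n_d).  With many chromosomes the
# stabilized and raw weights agree; with few they differ only in noise.
fit_weights <- function(obs) {
  v <- obs$var
  base <- ifelse(obs$n_sites > 0, pmax(obs$H, 1e-12) / obs$n_sites, NA_real_)
  ratio <- v / base
  phi <- median(ratio[is.finite(ratio) & ratio > 0])
  if (!is.finite(phi) || phi <= 0) phi <- 1
  w <- 1 / (phi * base)
  w[!is.finite(w)] <- 0
  if (all(w == 0)) w <- rep(1, obs$n_bins)
  w
}

#' Weighted delete-one block jackknife
#'
#' Standard error of an estimator over unequally sized blocks (here:
#' chromosomes weighted by their number of starting points), using the
#' delete-one weighted jackknife.  With equal weights it reduces to the
#' ordinary delete-one jackknife.
#'
#' @param theta_hat full-data estimate.
#' @param theta_loo vector of leave-one-block-out estimates.
#' @param weights block sizes (same order as `theta_loo`).
#' @return list with `se` and the jackknife mean `est`.
#' @export
weighted_jackknife <- function(theta_hat, theta_loo, weights) {
  g <- length(theta_loo)
  stopifnot(g == length(weights), g >= 2, all(weights > 0))
  n <- sum(weights)
  h <- n / weights
  est <- g * theta_hat - sum((1 - weights / n) * theta_loo)
  tau <- h * theta_hat - (h - 1) * theta_loo
  se <- sqrt(mean((tau - est)^2 / (h - 1)))
  list(est = est, se = se)
}

#' Leave-one-chromosome jackknife of the fitted rate
#'
#' Re-fits mu with each chromosome removed from both the observed curve and
#' the calibration curves (the asymptote adjustment is recomputed per
#' replicate; the simulated calibration data themselves are not re-drawn,
#' and the same demographic history underlies every replicate).  Blocks are
#' weighted by their starting-point counts.
#'
#' @param obs observed `hs_curve`.
#' @param calib a [build_calibration()] result.
#' @param mu_hat optional full-data fit (recomputed when missing).
#' @return list with `se`, `est` (bias-corrected jackknife mean), `loo`
#'   (per-chromosome estimates).
#' @export
jackknife_mu <- function(obs, calib, mu_hat = NULL) {
  chroms <- names(obs$by_chrom)
  if (length(chroms) < 2) stop("jackknife needs at least 2 chromosomes")
  if (is.null(mu_hat)) mu_hat <- fit_mu(obs, calib)
  loo <- vapply(chroms, function(cc) {
    o <- finalize_hs_curve(obs$by_chrom, obs$n_bins, obs$d_max,
                           hbar_genome = obs$hbar_genome, drop_chrom = cc)
    cal <- calib
    cal$curves <- lapply(calib$curves, function(cv)
      finalize_hs_curve(cv$by_chrom, calib$n_bins, calib$d_max,
                        drop_chrom = cc))
    fit_mu(o, cal)
  }, 0)
  w <- vapply(chroms, function(cc) obs$by_chrom[[cc]]$n_points, 0)
  res <- weighted_jackknife(as.numeric(mu_hat), loo, w)
  res$loo <- loo
  res
}

#' Average independent calibrations
#'
#' The point estimate for real data averages repeated calibrations (fresh
#' perturbed map and fresh simulations each), removing most randomisation
#' noise; 25 replicates by default.
#'
#' @param calibrate_fit function taking a replicate index and returning a
#'   fitted mu (it should draw its own fresh calibration).
#' @param n_reps number of independent calibrations.
#' @return list with `mu` (the averaged estimate) and `reps`.
#' @export
average_calibrations <- function(calibrate_fit, n_reps = 25) {
  stopifnot(n_reps >= 1)
  reps <- vapply(seq_len(n_reps), function(i) as.numeric(calibrate_fit(i)), 0)
  list(mu = mean(reps), reps = reps)
}

#' Propagate map-accuracy uncertainty into the rate
#'
#' Reruns the inference at a grid of map-accuracy values and converts the
#' uncertainty in alpha into a standard-error contribution via the slope of
#' a linear regression of the fitted rate on alpha.
#'
#' @param fit_at_alpha function alpha -> fitted mu.
#' @param alpha_grid at least 3 values (default 2500-4500).
#' @param alpha_se standard error of alpha (Morgan^-1).
#' @return list with `se`, `slope`, and the per-alpha fits `mu`.
#' @export
propagate_alpha_uncertainty <- function(fit_at_alpha,
                                        alpha_grid = c(2500, 3000, 3500, 4000, 4500),
                                        alpha_se = 300) {
  stopifnot(length(alpha_grid) >= 3, alpha_se >= 0)
  mus <- vapply(alpha_grid, function(a) as.numeric(fit_at_alpha(a)), 0)
  slope <- unname(coef(lm(mus ~ alpha_grid))[2])
  list(se = abs(slope) * alpha_se, slope = slope, mu = mus)
}

#' Combine independent error components
#'
#' Root-sum-of-squares of a jackknife standard error and any number of
#' propagated parameter standard errors, under the assumption that the
#' component errors are independent and normally distributed.
#'
#' @param ... numeric standard errors.
#' @return combined standard error.
#' @examples
#' combine_uncertainty(0.3, 0.4)  # 0.5
#' @export
combine_uncertainty <- function(...) {
  x <- unlist(list(...))
  stopifnot(all(x >= 0))
  sqrt(sum(x^2))
}

#' Convert a per-generation rate to a per-year rate
#'
#' @param mu per-generation rate.
#' @param generation_years mean generation interval (default 29 years).
#' @export
per_year_rate <- function(mu, generation_years = 29) {
  stopifnot(generation_years > 0)
  mu / generation_years
}

#' TMRCA implied by a heterozygosity level
#'
#' In expectation `H = 2 * T * mu`, so `T = H / (2 * mu)` generations.
#'
#' @param H heterozygosity (per base).
#' @param mu per-generation mutation rate.
#' @export
tmrca_of_het <- function(H, mu) {
  if (any(mu <= 0)) stop("mu must be positive")
  H / (2 * mu)
}
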