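# End-to-end simulation study: simulate scenario genomes, ascertain, compute
# the relaxation curve, calibrate, fit, correct, and summarise recovery of
# the known true rate across independent trials.

# local/genome recombination-rate ratio of the test regions on the base map
# (rate in a 10-kb window at each starting point over the genome mean)
region_rate_ratio <- function(regions, map, window_bp = 1e4) {
  local <- vapply(seq_len(nrow(regions)), function(i) {
    g <- map$chroms[[regions$chrom[i]]]
    a <- max(regions$mid[i] - window_bp / 2, g$pos[1])
    b <- min(regions$mid[i] + window_bp / 2, g$pos[nrow(g)])
    (map_cm(map, regions$chrom[i], b) - map_cm(map, regions$chrom[i], a)) / (b - a)
  }, 0)
  mean(local) / (map_total_cm(map) / (map_total_mb(map) * 1e6))
}

#' Run one full inference trial on a simulated scenario
#'
#' Generates a scenario data set, runs the complete pipeline (tile,
#' ascertain, super-regions, observed curve, calibration, fit, corrections,
#' jackknife) and returns the estimates next to the generating truth.
#' Corrections are applied as the scenario requires: the gene-conversion
#' subtraction when conversion was simulated (with the known conversion
#' rate and the measured local-rate ratio), and the genotype-error factor
#' with a directly counted error rate when errors were injected.
#'
#' @param scenario scenario name (see [scenario_genomes()]).
#' @param scale a [scale_profile()].
#' @param S ascertainment range (het per 100 kb).
#' @param mu_grid calibration grid.
#' @param n_calibrations independent calibrations averaged for the point
#'   estimate (1 is the simulation-study default; real-data practice is 25).
#' @param data optional pre-generated [scenario_genomes()] output (the
#'   scenario is then not re-simulated).
#' @return list with `mu_raw`, `mu_corrected`, `se_jack`, `estimate`
#'   (the [apply_corrections()] ledger), `truth`, curve summaries and sizes.
#' @export
run_trial <- function(scenario, scale = scale_profile("desk"), S = c(5, 10),
                      mu_grid = c(1, 2, 4) * 1e-8, n_calibrations = 1,
                      data = NULL) {
  if (is.null(data)) data <- scenario_genomes(scenario, scale)
  cfg <- data$truth$config
  windows <- tile_and_count(data$profiles)
  points <- ascertain(windows, S = S)
  regions <- define_super_regions(points, data$map_base,
                                  profiles = data$profiles)
  obs <- compute_hs_curve(data$profiles, regions, data$map_base)

  # calibration demography: the generating scaled history stands in for a
  # PSMC fit of the simulated data (theta and the scaled epochs are exactly
  # what PSMC would be asked to recover; using the truth isolates the
  # method's own accuracy from PSMC's)
  dem_cal <- data$truth$dem
  model <- map_error_model(alpha = cfg$alpha, pi = cfg$pi)

  # per-region simulation budget: the adaptive batching in
  # build_calibration targets min_accept ascertained replicates per region
  # and rate, within a cap that is wider for the lower grid rates (their
  # conditional acceptance is lower)
  caps <- pmax(12L, as.integer(round(3 * scale$n_cal_reps *
                                       (mu_grid[2] / mu_grid)^0.5)))
  one_fit <- function(i) {
    calib <- build_calibration(regions, data$map_base, dem_cal, model,
                               mu_grid = mu_grid, n_reps = caps,
                               min_accept = 4, S = S)
    list(mu = fit_mu(obs, calib), calib = calib)
  }
  first <- one_fit(1)
  mu_raw <- as.numeric(first$mu)
  if (n_calibrations > 1) {
    more <- vapply(seq_len(n_calibrations - 1) + 1,
                   function(i) as.numeric(one_fit(i)$mu), 0)
    mu_raw <- mean(c(mu_raw, more))
  }
  jk <- jackknife_mu(obs, first$calib, mu_hat = first$mu)

  eps <- 0
  if (cfg$err_rate > 0) eps <- count_error_rate(data$profiles, regions)
  gc <- NULL
  if (cfg$gc_rate > 0)
    gc <- gene_conversion_decrement(c_rate = cfg$gc_rate,
                                    rate_ratio = region_rate_ratio(regions, data$map_base),
                                    hbar = obs$hbar_genome, H0 = obs$H0)
  est <- apply_corrections(mu_raw, H0 = obs$H0, jackknife_se = jk$se,
                           eps = eps, gc = gc)

  list(mu_raw = mu_raw, mu_corrected = est$mu_corrected, se_jack = jk$se,
       estimate = est, truth = data$truth,
       H0 = obs$H0, hbar = obs$hbar_genome,
       n_points = nrow(regions), n_chrom = length(obs$by_chrom))
}

#' Run a simulation-study scenario over independent trials
#'
#' Repeats [run_trial()] with independent seeds and summarises recovery:
#' mean and SD of the corrected estimates across trials next to the mean
#' jackknife SE (the jackknife is expected to be on average conservative).
#' Trials that fail (e.g. ascertain no windows) are recorded and excluded
#' from the summary, never silently dropped.
#'
#' @param scenario scenario name.
#' @param n_trials number of independent trials.
#' @param scale a [scale_profile()].
#' @param seed integer seed; per-trial seeds are derived from it.
#' @param ... passed to [run_trial()].
#' @return object of class `scenario_result`: `trials` (data.frame with
#'   one row per trial), `summary` list, `failures`.
#' @export
run_scenario <- function(scenario, n_trials = 5, scale = scale_profile("desk"),
                         seed = 1, ...) {
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1, n_trials)
  rows <- list(); fails <- list()
  for (i in seq_len(n_trials)) {
    set.seed(trial_seeds[i])
    res <- tryCatch(run_trial(scenario, scale = scale, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- list(trial = i, message = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      scenario = scenario, trial = i, seed = trial_seeds[i],
      mu_true = res$truth$mu, mu_raw = res$mu_raw,
      mu_corrected = res$mu_corrected, se_jack = res$se_jack,
      n_points = res$n_points, H0 = res$H0, stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  if (is.null(trials)) stop("all trials failed for scenario ", scenario)
  summ <- list(
    scenario = scenario, n_trials = nrow(trials), n_failed = length(fails),
    mu_true = trials$mu_true[1],
    mean_mu = mean(trials$mu_corrected),
    sd_mu = if (nrow(trials) > 1) sd(trials$mu_corrected) else 0,
    mean_mu_raw = mean(trials$mu_raw),
    mean_se_jack = mean(trials$se_jack),
    mean_n_points = mean(trials$n_points))
  structure(list(trials = trials, summary = summ, failures = fails),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("scenario %s: %d trial(s)%s, true mu = %.3g\n", s$scenario,
              s$n_trials,
              if (s$n_failed > 0) sprintf(" (+%d failed)", s$n_failed) else "",
              s$mu_true))
  cat(sprintf("  corrected mu: mean %.3g, SD %.2g (raw mean %.3g)\n",
              s$mean_mu, s$sd_mu, s$mean_mu_raw))
  cat(sprintf("  mean jackknife SE %.2g; mean starting points %.0f\n",
              s$mean_se_jack, s$mean_n_points))
  invisible(x)
}

#' @importFrom stats sd
NULL
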