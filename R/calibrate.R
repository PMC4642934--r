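# Calibration data: for every ascertained super-region, coalescent
# simulations under the sample's demography and perturbed realizations of
# the base map, at each mutation rate of the calibration grid.  The scaled
# demography makes rho = theta * r / mu_c automatic for each grid rate
# mu_c, preserving both the diversity and the mutation/recombination ratio
# that the curve shape encodes.  Simulated replicates pass through the same
# ascertainment rule (central-window heterozygosity in S, half rule) as the
# real data, and the same genome-matched masks, so the calibration curves
# inherit the real intercept H_S(0) by construction.
#
# Map error enters the calibration through ascertainment as well as through
# distance: windows whose perturbed local rate came out low are both more
# likely to reach a narrow low-heterozygosity band and slower to relax
# around it in base-map coordinates.  The real data realize this selection
# across many regions of a single (unknown) true map, i.e. across many
# independent interval draws.  The calibration therefore draws a fresh
# local perturbation for every simulated replicate, which integrates the
# gamma error model into the conditional ensemble exactly, at any region
# count; pooling a handful of whole-genome perturbed maps achieves the same
# only in the limit of many regions or many maps.

#' Build a set of calibration curves
#'
#' Simulates `n_reps` diploid replicates of every super-region at each grid
#' mutation rate, each replicate under a fresh perturbed realization of the
#' region's base map (the gamma error model with the pseudo-count prior),
#' and accumulates the ascertained replicates into one
#' [compute_hs_curve()]-compatible curve per grid rate.
#'
#' @param regions data.frame from [define_super_regions()].
#' @param map_base the base [genetic_map()] (distance scale for binning).
#' @param dem a [demography()] describing the sample (typically theta from
#'   PSMC or, in simulation studies, the generating truth).
#' @param model a [map_error_model()] for the perturbation.
#' @param mu_grid calibration mutation rates (default `c(1, 2, 4) * 1e-8`;
#'   the class-mode CpG grid is `c(0.2, 0.4, 0.8) * 1e-8`).
#' @param n_reps maximum simulated replicates per curve and region; either
#'   a scalar or one value per grid rate.
#' @param min_accept target number of ascertained replicates per region and
#'   grid rate.  Simulation proceeds in batches until the target is reached
#'   or `n_reps` is exhausted, which concentrates effort on regions and
#'   rates with low conditional acceptance (lower-rate calibrations
#'   ascertain fewer windows per replicate, because stronger recombination
#'   averages the window heterozygosity toward the mean).
#' @param S,half_rule,window ascertainment settings, matching the real data.
#' @param n_bins,d_max curve binning, matching the real data.
#' @param masks optional named list (by sample) of per-chromosome masks for
#'   genome-matched filtering of the simulated data.
#' @return object of class `calibration_set`: `mu_grid`, `curves` (one
#'   `hs_curve` per grid rate, unadjusted), and provenance.
#' @export
build_calibration <- function(regions, map_base, dem, model = map_error_model(),
                              mu_grid = c(1, 2, 4) * 1e-8, n_reps = 30,
                              min_accept = 4,
                              S = c(5, 10), half_rule = TRUE, window = 1e5,
                              n_bins = 60, d_max = 0.1, masks = NULL) {
  stopifnot(length(mu_grid) >= 3, !is.unsorted(mu_grid))
  n_reps <- rep_len(n_reps, length(mu_grid))
  gam <- gamma_const(map_base, model)
  accs <- lapply(mu_grid, function(m) list())

  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    mask <- if (!is.null(masks)) masks[[r$sample]][[r$chrom]] else iv_empty()
    if (is.null(mask)) mask <- iv_empty()
    bins <- point_bins(map_base, r$chrom, r$mid, n_bins, d_max)
    lm_base <- local_map(map_base, r$chrom, r$start, r$end)
    win_lo <- r$mid - window / 2
    win_hi <- r$mid + window / 2
    win_unm <- window -
      (if (nrow(mask) > 0) iv_overlap_width(mask, win_lo, win_hi) else 0)
    reg_sites <- (r$end - r$start) -
      (if (nrow(mask) > 0) iv_overlap_width(mask, r$start, r$end) else 0)

    for (mi in seq_along(mu_grid)) {
      # accepted replicates are averaged within the region before pooling:
      # the observed curve counts every ascertained region exactly once, so
      # the calibration must too -- pooling raw accepted replicates would
      # weight each region by its acceptance probability, which varies
      # several-fold across the map and correlates with the local curve
      # shape (a systematic distortion on heterogeneous maps)
      n_acc <- 0
      reg_het <- numeric(n_bins); reg_h0 <- 0; reg_sr <- 0
      used <- 0
      while (n_acc < min_accept && used < n_reps[mi]) {
        p_hat <- if (used == 0) 0.35 else max(n_acc / used, 0.05)
        nb <- min(n_reps[mi] - used,
                  max(4, ceiling((min_accept - n_acc) / p_hat)))
        blocks <- simulate_diploid_region(lm_base, dem, mu_grid[mi], nb,
                                          perturb = model, gamma_total = gam)
        hets <- place_mutations_by_rep(blocks, mu_grid[mi], nb)
        used <- used + nb
        for (rep in seq_len(nb)) {
          het <- hets[[rep]] + r$start
          if (nrow(mask) > 0) het <- het[!iv_covers(mask, het)]
          n_w <- sum(het >= win_lo & het < win_hi)
          rate <- n_w / win_unm * 1e5
          if (rate < S[1] || rate > S[2]) next
          if (half_rule) {
            n_l <- sum(het >= win_lo & het < r$mid)
            if (n_l == 0 || n_w - n_l == 0) next
          }
          tot <- .point_totals(list(het = het), bins, mask)
          reg_het <- reg_het + tot$het
          reg_h0 <- reg_h0 + n_w
          reg_sr <- reg_sr + length(het)
          n_acc <- n_acc + 1
        }
      }
      if (n_acc == 0) next
      acc <- accs[[mi]][[r$chrom]]
      if (is.null(acc)) acc <- new_hs_acc(n_bins)
      acc$het <- acc$het + reg_het / n_acc
      acc$sites <- acc$sites + tot_sites_bins(bins, mask)
      acc$h0_het <- acc$h0_het + reg_h0 / n_acc
      acc$h0_sites <- acc$h0_sites + win_unm
      acc$sr_het <- acc$sr_het + reg_sr / n_acc
      acc$sr_sites <- acc$sr_sites + reg_sites
      acc$n_points <- acc$n_points + 1
      accs[[mi]][[r$chrom]] <- acc
    }
  }
  curves <- lapply(accs, finalize_hs_curve, n_bins = n_bins, d_max = d_max)
  for (cv in curves)
    if (cv$n_points == 0)
      warning("a calibration curve ascertained no simulated windows")
  structure(list(mu_grid = mu_grid, curves = curves,
                 alpha = model$alpha, pi = model$pi, n_reps = n_reps,
                 S = S, n_bins = n_bins, d_max = d_max),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("calibration_set: mu grid",
      paste(format(x$mu_grid, digits = 3), collapse = ", "),
      "-", paste(x$n_reps, collapse = "/"), "replicates/region, alpha =",
      x$alpha, "\n")
  for (i in seq_along(x$mu_grid))
    cat(sprintf("  mu = %.3g: %d ascertained windows, H0 = %.3g\n",
                x$mu_grid[i], x$curves[[i]]$n_points, x$curves[[i]]$H0))
  invisible(x)
}
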