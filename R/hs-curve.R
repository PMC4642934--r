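# The relaxation statistic H_S(d): average heterozygosity as a function of
# genetic distance d from the ascertained starting points, computed in 60
# half-open bins over (0, 0.1] cM on the base map, pooled over starting
# points and genomes (site-weighted).  Both directions from a starting point
# contribute to the same bins.  The d = 0 anchor H_S(0) is the pooled
# heterozygosity of the ascertained windows themselves, not bin 1.

# integer bin edges around a starting point: for bin j (1..n), right-side
# positions lie in [aR[j], aR[j+1]) and left-side in [aL[j+1], aL[j]);
# the midpoint site itself is counted once, on the right at d = 0.
point_bins <- function(map, chrom, mid, n_bins = 60, d_max = 0.1) {
  d <- seq(0, d_max, length.out = n_bins + 1)
  cm_mid <- map_cm(map, chrom, mid)
  aR <- ceiling(map_pos(map, chrom, cm_mid + d))
  aL <- pmin(floor(map_pos(map, chrom, cm_mid - d)) + 1, mid)
  list(aR = aR, aL = aL)
}

# het counts per bin for sorted positions and monotone integer edges
.edge_counts <- function(het, edges_lo, edges_hi) {
  # edges define [lo_j, hi_j) per bin; both monotone in j
  if (length(het) == 0) return(numeric(length(edges_lo)))
  findInterval(edges_hi - 0.5, het) - findInterval(edges_lo - 0.5, het)
}

# accumulate one starting point into per-bin totals
.point_totals <- function(ch, bins, mask) {
  n <- length(bins$aR) - 1
  hR <- .edge_counts(ch$het, bins$aR[-(n + 1)], bins$aR[-1])
  hL <- .edge_counts(ch$het, bins$aL[-1], bins$aL[-(n + 1)])
  sR <- (bins$aR[-1] - bins$aR[-(n + 1)])
  sL <- (bins$aL[-(n + 1)] - bins$aL[-1])
  if (nrow(mask) > 0) {
    sR <- sR - iv_overlap_width(mask, bins$aR[-(n + 1)], bins$aR[-1])
    sL <- sL - iv_overlap_width(mask, bins$aL[-1], bins$aL[-(n + 1)])
  }
  list(het = hR + hL, sites = sR + sL)
}

# unmasked-site widths per bin (the denominator a starting point contributes)
tot_sites_bins <- function(bins, mask)
  .point_totals(list(het = numeric(0)), bins, mask)$sites

new_hs_acc <- function(n_bins) {
  list(het = numeric(n_bins), sites = numeric(n_bins),
       h0_het = 0, h0_sites = 0, sr_het = 0, sr_sites = 0, n_points = 0)
}

#' Compute the H_S(d) relaxation curve
#'
#' Pools heterozygous-site and unmasked-site counts per genetic-distance bin
#' over all starting points and genomes; per-bin totals are kept per
#' chromosome so that leave-one-chromosome jackknife variances (and
#' jackknife refits downstream) come for free.
#'
#' @param profiles list of [het_profile()] (or a single profile).
#' @param regions data.frame from [define_super_regions()]; every region is
#'   guaranteed at least `d_max` cM of mapped sequence on both sides.
#' @param map the base [genetic_map()] used as the distance scale.
#' @param n_bins number of distance bins (default 60).
#' @param d_max maximum genetic distance in cM (default 0.1).
#' @param window ascertainment window size (bases).
#' @return object of class `hs_curve`: per-bin pooled heterozygosity `H`
#'   with counts, the anchor `H0`, the mean heterozygosity over the
#'   super-regions `hbar_sr`, the genome-wide mean `hbar_genome`,
#'   per-chromosome totals, and per-bin jackknife variances `var`.
#' @export
compute_hs_curve <- function(profiles, regions, map, n_bins = 60,
                             d_max = 0.1, window = 1e5) {
  if (inherits(profiles, "het_profile")) profiles <- list(profiles)
  names(profiles) <- vapply(profiles, `[[`, "", "sample")
  if (nrow(regions) == 0) stop("no starting points")
  by_chrom <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    ch <- profiles[[r$sample]]$chroms[[r$chrom]]
    bins <- point_bins(map, r$chrom, r$mid, n_bins, d_max)
    tot <- .point_totals(ch, bins, ch$mask)
    acc <- by_chrom[[r$chrom]]
    if (is.null(acc)) acc <- new_hs_acc(n_bins)
    acc$het <- acc$het + tot$het
    acc$sites <- acc$sites + tot$sites
    acc$h0_het <- acc$h0_het + r$n_het
    acc$h0_sites <- acc$h0_sites + r$n_unmasked
    sr_h <- sum(ch$het >= r$start & ch$het < r$end)
    sr_s <- (r$end - r$start) -
      (if (nrow(ch$mask) > 0) iv_overlap_width(ch$mask, r$start, r$end) else 0)
    acc$sr_het <- acc$sr_het + sr_h
    acc$sr_sites <- acc$sr_sites + sr_s
    acc$n_points <- acc$n_points + 1
    by_chrom[[r$chrom]] <- acc
  }
  finalize_hs_curve(by_chrom, n_bins, d_max,
                    hbar_genome = profile_hbar(profiles))
}

# pool per-chromosome accumulators into a curve with jackknife variances
finalize_hs_curve <- function(by_chrom, n_bins, d_max, hbar_genome = NA,
                              drop_chrom = NULL) {
  if (!is.null(drop_chrom)) by_chrom <- by_chrom[setdiff(names(by_chrom), drop_chrom)]
  het <- Reduce(`+`, lapply(by_chrom, `[[`, "het"))
  sites <- Reduce(`+`, lapply(by_chrom, `[[`, "sites"))
  h0_het <- sum(vapply(by_chrom, `[[`, 0, "h0_het"))
  h0_sites <- sum(vapply(by_chrom, `[[`, 0, "h0_sites"))
  sr_het <- sum(vapply(by_chrom, `[[`, 0, "sr_het"))
  sr_sites <- sum(vapply(by_chrom, `[[`, 0, "sr_sites"))
  H <- ifelse(sites > 0, het / sites, NA_real_)
  G <- length(by_chrom)
  v <- rep(NA_real_, n_bins)
  if (G >= 2) {
    loo <- vapply(names(by_chrom), function(nm) {
      h <- het - by_chrom[[nm]]$het
      s <- sites - by_chrom[[nm]]$sites
      ifelse(s > 0, h / s, NA_real_)
    }, numeric(n_bins))
    mloo <- rowMeans(loo, na.rm = TRUE)
    v <- (G - 1) / G * rowSums((loo - mloo)^2, na.rm = TRUE)
  }
  edges <- seq(0, d_max, length.out = n_bins + 1)
  structure(list(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                 n_het = het, n_sites = sites, H = H,
                 H0 = h0_het / h0_sites,
                 hbar_sr = sr_het / sr_sites,
                 hbar_genome = hbar_genome,
                 var = v,
                 n_points = sum(vapply(by_chrom, `[[`, 0, "n_points")),
                 by_chrom = by_chrom, n_bins = n_bins, d_max = d_max),
            class = "hs_curve")
}

#' @export
print.hs_curve <- function(x, ...) {
  cat(sprintf(paste0("hs_curve: %d points, H0 = %.3g, Hbar(super-regions) = %.3g,",
                     " %d bins over (0, %g] cM\n"),
              x$n_points, x$H0, x$hbar_sr, x$n_bins, x$d_max))
  invisible(x)
}

#' Curve table for export
#'
#' @param curve an `hs_curve`.
#' @return data.frame (`bin_lo_cm`, `bin_hi_cm`, `n_sites`, `n_het`, `H`,
#'   `var`).
#' @export
hs_curve_table <- function(curve) {
  data.frame(bin_lo_cm = curve$bin_lo, bin_hi_cm = curve$bin_hi,
             n_sites = curve$n_sites, n_het = curve$n_het,
             H = curve$H, var = curve$var)
}

#' Asymptote adjustment of a calibration curve
#'
#' Rescales the relaxation portion of a calibration curve,
#' `H'(d) = H0 + (H(d) - H0) * hbar_real / hbar_sim`, so that residual
#' mismatch in mean heterozygosity between real and simulated super-regions
#' (demography reconstruction is never perfect) does not misalign the
#' asymptotes.  The intercept is unchanged.  The correction is expected to
#' be small; a ratio outside [0.5, 2] triggers a warning.
#'
#' @param curve calibration `hs_curve`.
#' @param hbar_real mean heterozygosity of the real data over the
#'   super-regions.
#' @param hbar_sim same quantity for the matching simulated data (defaults
#'   to the curve's own `hbar_sr`).
#' @return the adjusted `hs_curve`.
#' @export
asymptote_adjust <- function(curve, hbar_real, hbar_sim = curve$hbar_sr) {
  stopifnot(hbar_real > 0, hbar_sim > 0)
  ratio <- hbar_real / hbar_sim
  if (ratio < 0.5 || ratio > 2)
    warning(sprintf("asymptote ratio %.2f outside [0.5, 2]", ratio))
  curve$H <- curve$H0 + (curve$H - curve$H0) * ratio
  curve$asymptote_ratio <- ratio
  curve
}
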