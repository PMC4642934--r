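# Post-fit corrections.  The fitted rate is corrected in a fixed order:
# (1) multiply by the genotype-error factor, (2) subtract the non-crossover
# gene-conversion contribution, (3) multiply by the base-content mutability
# factor.  Each correction contributes one independent standard-error
# component to the combined uncertainty.

#' Genotype-error correction factor
#'
#' False heterozygotes inflate the local heterozygosity of the starting
#' windows without changing the relaxation rate, so the raw fit is too
#' high by the ratio of true to observed starting heterozygosity:
#' multiply by `(H0 - eps) / H0`.
#'
#' @param H0 starting heterozygosity (includes the errors).
#' @param eps false-heterozygote rate per base, `0 <= eps < H0`.
#' @return multiplicative factor in (0, 1].
#' @export
genotype_error_factor <- function(H0, eps) {
  stopifnot(H0 > 0, eps >= 0)
  if (eps >= H0) stop("error rate eps >= H0: correction undefined")
  (H0 - eps) / H0
}

#' Non-crossover gene-conversion decrement
#'
#' Gene conversion copies short tracts between homologues and so introduces
#' heterozygous sites into young test regions at a rate that mimics
#' mutation.  The decrement subtracted from the (error-corrected) rate is
#' `c * rate_ratio * (hbar - H0) / 2`: the probability per base per
#' generation of being covered by a conversion tract, adjusted for the
#' local/genome recombination-rate ratio of the test regions, times the
#' probability that the copied-in base differs -- the excess of
#' population-average over test-region heterozygosity, halved because the
#' tract copies one of the two donor haplotypes.
#'
#' @param c_rate per-base per-generation probability of being covered by a
#'   non-crossover tract (default 5.9e-6, 95% CI 4.6-7.4e-6).
#' @param rate_ratio local-to-genome recombination-rate ratio of the test
#'   regions (conversion initiations track crossover initiations).
#' @param hbar genome-wide mean heterozygosity.
#' @param H0 starting-region heterozygosity.
#' @param c_ci 95% confidence interval on `c_rate`, for the propagated SE.
#' @return list with `decrement` (per base per generation) and `se`.
#' @export
gene_conversion_decrement <- function(c_rate = 5.9e-6, rate_ratio = 1,
                                      hbar, H0, c_ci = c(4.6e-6, 7.4e-6)) {
  stopifnot(c_rate >= 0, rate_ratio >= 0, hbar > 0, H0 > 0)
  if (hbar <= H0) {
    warning("hbar <= H0: test regions not younger than average; decrement 0")
    return(list(decrement = 0, se = 0))
  }
  scale <- rate_ratio * (hbar - H0) / 2
  list(decrement = c_rate * scale,
       se = (diff(c_ci) / (2 * 1.96)) * scale)
}

#' Base-content mutability factor
#'
#' Converts a rate measured on the ascertained regions to a genome-wide
#' equivalent when the regions deviate from the genome in base composition.
#' The relative-mutability score of a sequence set is
#' `M = 1 + b_cpg * f_cpg + b_gc * f_gc + b_int * f_cpg * f_gc`, with
#' compositions measured on filtered sites (30-kb windows around starting
#' points for the regions); the factor is `M(genome) / M(regions)`.  The
#' default coefficients give CpG sites roughly tenfold mutability and a mild
#' GC effect; they are configurable because they summarise an empirical
#' mutation spectrum rather than a first-principles model.
#'
#' @param f_cpg_region,f_gc_region CpG-site and GC fractions of the
#'   ascertained regions.
#' @param f_cpg_genome,f_gc_genome same fractions genome-wide.
#' @param beta coefficients `c(cpg, gc, int)`.
#' @return multiplicative factor (> 1 when the regions are CpG/GC-poorer
#'   than the genome).
#' @export
base_content_factor <- function(f_cpg_region, f_gc_region,
                                f_cpg_genome, f_gc_genome,
                                beta = c(cpg = 9, gc = 0.5, int = 0)) {
  fr <- c(f_cpg_region, f_gc_region, f_cpg_genome, f_gc_genome)
  if (any(fr < 0 | fr > 1)) stop("composition fractions must lie in [0, 1]")
  score <- function(fc, fg) 1 + beta[[1]] * fc + beta[[2]] * fg + beta[[3]] * fc * fg
  score(f_cpg_genome, f_gc_genome) / score(f_cpg_region, f_gc_region)
}

#' Estimate the genotype-error rate from CpG dilution
#'
#' CpG transitions are roughly an order of magnitude more mutable than other
#' sites, so they are strongly over-represented among genuine heterozygous
#' sites but not among errors.  In low-heterozygosity regions the local
#' ratio of errors to genuine sites is highest, which dilutes the local CpG
#' fraction; the mixture deconvolution
#' `eps = H0 * (f_true - f_obs) / (f_true - f_err)` recovers the error rate,
#' where `f_true` is the genome-wide CpG-transition fraction among
#' heterozygous sites, `f_obs` the fraction observed near the ascertained
#' starting points and `f_err` the fraction expected among errors (by
#' default the CpG-site fraction of callable sequence: errors are assumed
#' composition-uniform).
#'
#' @param profiles list of [het_profile()] whose het sites carry `is_cpg`
#'   labels (see [label_cpg_sites()]).
#' @param regions ascertained regions ([define_super_regions()]).
#' @param f_err CpG fraction expected among errors.
#' @param H0 starting heterozygosity (pooled over ascertained windows).
#' @param window ascertainment window size.
#' @return list with `eps`, `se` (leave-one-chromosome jackknife), `f_true`,
#'   `f_obs`.
#' @export
estimate_genotype_error_cpg <- function(profiles, regions, f_err, H0,
                                        window = 1e5) {
  if (inherits(profiles, "het_profile")) profiles <- list(profiles)
  names(profiles) <- vapply(profiles, `[[`, "", "sample")
  tot <- list()  # per chromosome: genome cpg/all, window cpg/all
  for (p in profiles) for (nm in names(p$chroms)) {
    ch <- p$chroms[[nm]]
    if (is.null(ch$is_cpg)) stop("profiles lack is_cpg labels")
    t <- tot[[nm]]
    if (is.null(t)) t <- c(g_cpg = 0, g_all = 0, w_cpg = 0, w_all = 0)
    t["g_cpg"] <- t["g_cpg"] + sum(ch$is_cpg)
    t["g_all"] <- t["g_all"] + length(ch$het)
    sel <- regions[regions$sample == p$sample & regions$chrom == nm, , drop = FALSE]
    if (nrow(sel) > 0) {
      inw <- rep(FALSE, length(ch$het))
      for (k in seq_len(nrow(sel)))
        inw <- inw | (ch$het >= sel$mid[k] - window / 2 &
                        ch$het < sel$mid[k] + window / 2)
      t["w_cpg"] <- t["w_cpg"] + sum(ch$is_cpg[inw])
      t["w_all"] <- t["w_all"] + sum(inw)
    }
    tot[[nm]] <- t
  }
  m <- do.call(rbind, tot)
  est <- function(mm) {
    f_true <- sum(mm[, "g_cpg"]) / sum(mm[, "g_all"])
    f_obs <- sum(mm[, "w_cpg"]) / sum(mm[, "w_all"])
    if (f_true <= f_err)
      stop("f_true <= f_err: CpG error model unidentifiable")
    H0 * (f_true - f_obs) / (f_true - f_err)
  }
  eps <- est(m)
  g <- nrow(m)
  se <- NA_real_
  if (g >= 2) {
    loo <- vapply(seq_len(g), function(i) est(m[-i, , drop = FALSE]), 0)
    w <- m[, "w_all"]
    if (all(w > 0)) se <- weighted_jackknife(eps, loo, w)$se
    else se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  }
  f_true <- sum(m[, "g_cpg"]) / sum(m[, "g_all"])
  f_obs <- sum(m[, "w_cpg"]) / sum(m[, "w_all"])
  list(eps = eps, se = se, f_true = f_true, f_obs = f_obs)
}

#' Directly counted error rate in ascertained windows
#'
#' For simulated data with injected false heterozygotes the realized error
#' rate in the ascertained windows is counted directly from the recorded
#' injection positions (simulated sequence has no nucleotide identities, so
#' the CpG-based estimator does not apply).
#'
#' @param profiles profiles carrying `injected` positions.
#' @param regions ascertained regions.
#' @param window window size.
#' @return per-base error rate among the ascertained windows.
#' @export
count_error_rate <- function(profiles, regions, window = 1e5) {
  if (inherits(profiles, "het_profile")) profiles <- list(profiles)
  names(profiles) <- vapply(profiles, `[[`, "", "sample")
  n_err <- 0; n_sites <- 0
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    ch <- profiles[[r$sample]]$chroms[[r$chrom]]
    inj <- ch$injected
    if (!is.null(inj))
      n_err <- n_err + sum(inj >= r$mid - window / 2 & inj < r$mid + window / 2)
    n_sites <- n_sites + r$n_unmasked
  }
  n_err / n_sites
}

#' Partition heterozygous sites into CpG-transition and other classes
#'
#' Splits labelled profiles into a CpG-transition-only and a complementary
#' profile set, and returns the class-mode analysis settings: the sparse
#' CpG ascertainment range `S = 0.1-2` per 100 kb (one site per window
#' after filtering) with the half rule disabled and a lowered calibration
#' grid, the complementary range `S = 4.375-8.75`, class-scaled error rates
#' and the gene-conversion split.
#'
#' @param profiles list of labelled [het_profile()] objects.
#' @param eps_full full-data genotype-error rate (scaled by the class site
#'   fractions).
#' @return list with `cpg`, `non_cpg` (profile lists) and `settings`.
#' @export
class_partition <- function(profiles, eps_full = 1.08e-5) {
  if (inherits(profiles, "het_profile")) profiles <- list(profiles)
  take <- function(p, keep_cpg) {
    chroms <- lapply(p$chroms, function(ch) {
      if (is.null(ch$is_cpg)) stop("profiles lack is_cpg labels")
      sel <- if (keep_cpg) ch$is_cpg else !ch$is_cpg
      list(het = ch$het[sel], mask = ch$mask, length = ch$length,
           segments = ch$segments)
    })
    het_profile(paste0(p$sample, if (keep_cpg) ".cpg" else ".noncpg"), chroms)
  }
  n_cpg <- sum(vapply(profiles, function(p)
    sum(vapply(p$chroms, function(ch) sum(ch$is_cpg), 0)), 0))
  n_all <- sum(vapply(profiles, function(p)
    sum(vapply(p$chroms, function(ch) length(ch$het), 0)), 0))
  frac <- n_cpg / n_all
  list(cpg = lapply(profiles, take, keep_cpg = TRUE),
       non_cpg = lapply(profiles, take, keep_cpg = FALSE),
       settings = list(
         S_cpg = c(0.1, 2), S_non_cpg = c(4.375, 8.75),
         half_rule_cpg = FALSE,
         mu_grid_cpg = c(0.2, 0.4, 0.8) * 1e-8,
         het_fraction = c(cpg = frac, non_cpg = 1 - frac),
         eps = c(cpg = eps_full * frac, non_cpg = eps_full * (1 - frac)),
         gc_split = c(cpg = 0.09, non_cpg = 0.91)))
}

#' Label heterozygous sites as CpG transitions from a reference sequence
#'
#' A heterozygous site is a candidate CpG transition when the reference
#' context is CG (the site is the C, followed by G, or the G preceded by C)
#' and, when alleles are recorded, the alleles are C/T (or G/A on the
#' reverse strand).
#'
#' @param profile a [het_profile()].
#' @param reference a named `Biostrings::DNAStringSet` (or plain character
#'   vector of sequences) keyed by chromosome.
#' @return the profile with `is_cpg` filled per chromosome.
#' @export
label_cpg_sites <- function(profile, reference) {
  getseq <- function(nm) {
    s <- reference[[nm]]
    if (is.null(s)) stop("no reference sequence for ", nm)
    toupper(as.character(s))
  }
  for (nm in names(profile$chroms)) {
    ch <- profile$chroms[[nm]]
    if (length(ch$het) == 0) { profile$chroms[[nm]]$is_cpg <- logical(0); next }
    seq <- getseq(nm)
    p1 <- ch$het + 1  # 1-based index into the sequence
    base <- substring(seq, p1, p1)
    nxt <- substring(seq, p1 + 1, p1 + 1)
    prv <- substring(seq, pmax(p1 - 1, 1), pmax(p1 - 1, 1))
    profile$chroms[[nm]]$is_cpg <-
      (base == "C" & nxt == "G") | (base == "G" & prv == "C")
  }
  profile
}

#' Apply the correction chain to a raw fitted rate
#'
#' Applies, in order: the genotype-error factor, the gene-conversion
#' subtraction, and the base-content factor; accumulates each correction's
#' standard-error contribution and combines them with the jackknife SE by
#' root-sum-of-squares.  With all corrections disabled the corrected rate
#' equals the raw rate.
#'
#' @param mu_raw raw fitted rate.
#' @param H0 starting heterozygosity.
#' @param jackknife_se jackknife SE of the raw fit.
#' @param eps,eps_se genotype-error rate and its SE (0 disables).
#' @param gc `NULL`, or a list from [gene_conversion_decrement()].
#' @param bc_factor,bc_se base-content factor and its SE (1/0 disable).
#' @param alpha_se_mu SE contribution from map-accuracy uncertainty.
#' @return object of class `rate_estimate` with the correction ledger.
#' @export
apply_corrections <- function(mu_raw, H0, jackknife_se = 0,
                              eps = 0, eps_se = 0, gc = NULL,
                              bc_factor = 1, bc_se = 0, alpha_se_mu = 0) {
  stopifnot(mu_raw > 0)
  f_err <- genotype_error_factor(H0, eps)
  mu1 <- mu_raw * f_err
  se_eps <- mu_raw * eps_se / H0
  dec <- if (is.null(gc)) list(decrement = 0, se = 0) else gc
  mu2 <- mu1 - dec$decrement
  mu3 <- mu2 * bc_factor
  se_bc <- mu2 * bc_se
  if (mu3 <= 0) stop("corrected mu not positive")
  combined <- combine_uncertainty(jackknife_se * f_err * bc_factor,
                                  se_eps, dec$se, se_bc, alpha_se_mu)
  structure(list(mu_raw = mu_raw, mu_corrected = mu3,
                 ledger = list(genotype_error_factor = f_err,
                               gene_conversion_decrement = dec$decrement,
                               base_content_factor = bc_factor),
                 se = list(jackknife = jackknife_se, genotype_error = se_eps,
                           gene_conversion = dec$se, base_content = se_bc,
                           alpha = alpha_se_mu, combined = combined)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: mu = %.3g +/- %.2g (raw %.3g)\n",
              x$mu_corrected, x$se$combined, x$mu_raw))
  cat(sprintf("  corrections: error factor %.4f, gene conversion -%.3g, base content x%.4f\n",
              x$ledger$genotype_error_factor,
              x$ledger$gene_conversion_decrement,
              x$ledger$base_content_factor))
  invisible(x)
}
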