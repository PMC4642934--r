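test_that("genotype-error factor is (H0 - eps)/H0 with its sanity checks", {
  expect_equal(genotype_error_factor(8.5e-5, 0), 1)
  expect_equal(genotype_error_factor(8.5e-5, 1e-5), 7.5 / 8.5)
  # monotone decreasing in eps
  f <- vapply(seq(0, 8e-5, length.out = 9), genotype_error_factor, H0 = 8.5e-5, 0)
  expect_true(all(diff(f) < 0))
  expect_error(genotype_error_factor(8.5e-5, 9e-5), "undefined")
})

test_that("gene-conversion decrement reproduces the expected magnitudes", {
  # c * ratio * (hbar - H0)/2 with the default conversion rate
  d <- gene_conversion_decrement(c_rate = 5.9e-6, rate_ratio = 1,
                                 hbar = 6.5e-4, H0 = 0.75e-4)
  expect_equal(d$decrement, 5.9e-6 * (6.5e-4 - 0.75e-4) / 2)
  expect_equal(round(d$decrement / 1e-8, 2), 0.17)
  lo <- gene_conversion_decrement(hbar = 5.4e-4, H0 = 0.75e-4)
  expect_equal(round(lo$decrement / 1e-8, 2), 0.14)
  expect_equal(gene_conversion_decrement(c_rate = 0, rate_ratio = 1,
                                         hbar = 6.5e-4, H0 = 7.5e-5)$decrement, 0)
  expect_warning(z <- gene_conversion_decrement(hbar = 5e-5, H0 = 7.5e-5),
                 "decrement 0")
  expect_equal(z$decrement, 0)
  # SE propagated from the rate's confidence interval
  expect_gt(d$se, 0)
  expect_lt(d$se, d$decrement)
})

test_that("base-content factor is 1 at equal composition and has the right sign", {
  expect_equal(base_content_factor(0.02, 0.4, 0.02, 0.4), 1)
  # CpG-poorer regions than genome: factor above 1
  expect_gt(base_content_factor(0.01, 0.4, 0.02, 0.4), 1)
  # CpG-richer: below 1
  expect_lt(base_content_factor(0.04, 0.4, 0.02, 0.4), 1)
  expect_error(base_content_factor(-0.1, 0.4, 0.02, 0.4), "\\[0, 1\\]")
})

test_that("correction chain applies factor, subtraction, factor in order", {
  est <- apply_corrections(2e-8, H0 = 8.5e-5, jackknife_se = 1e-9,
                           eps = 1e-5, eps_se = 2e-6,
                           gc = list(decrement = 1.5e-9, se = 2e-10),
                           bc_factor = 1.027, bc_se = 0.003 * 2e-8 / 2e-8 * 0)
  manual <- (2e-8 * (8.5e-5 - 1e-5) / 8.5e-5 - 1.5e-9) * 1.027
  expect_equal(est$mu_corrected, manual)
  # each SE component enters the combination exactly once
  expect_equal(est$se$combined,
               combine_uncertainty(1e-9 * est$ledger$genotype_error_factor * 1.027,
                                   est$se$genotype_error, 2e-10, 0, 0))
  # all corrections disabled: corrected equals raw
  none <- apply_corrections(2e-8, H0 = 8.5e-5, jackknife_se = 1e-9)
  expect_equal(none$mu_corrected, none$mu_raw)
})

test_that("CpG-dilution error estimator recovers an injected error rate", {
  # labelled profiles with known composition: the low-heterozygosity
  # windows hold 6 genuine sites (CpG with probability f_true) plus 3
  # errors (CpG with probability f_err) per 100 kb; the genome background
  # carries the genuine CpG fraction.  Counts are fixed so the expected
  # dilution signal is exact: eps = H0 (f_true - f_obs)/(f_true - f_err).
  set.seed(21)
  f_true <- 0.17; f_err <- 0.02
  n_true <- 6; n_err <- 3
  H0 <- (n_true + n_err) / 1e5
  eps_true <- n_err / 1e5
  n_chrom <- 24; len <- 2e6
  chroms <- list()
  for (k in seq_len(n_chrom)) {
    win <- sort(sample(9.5e5:(1.05e6 - 1), n_true + n_err))
    lab_win <- sample(c(runif(n_true) < f_true, runif(n_err) < f_err))
    n_bg <- rpois(1, 6.5e-4 * (len - 1e5))
    bg <- sort(sample(setdiff(0:(len - 1), 9.5e5:(1.05e6 - 1)), n_bg))
    het <- c(win, bg)
    ord <- order(het)
    chroms[[paste0("chr", k)]] <- list(
      het = het[ord],
      is_cpg = c(lab_win, runif(n_bg) < f_true)[ord],
      length = len)
  }
  prof <- het_profile("s1", chroms)
  regions <- data.frame(sample = "s1", chrom = names(chroms), mid = 1e6,
                        start = 8e5, end = 1.2e6, stringsAsFactors = FALSE)
  est <- estimate_genotype_error_cpg(prof, regions, f_err = f_err, H0 = H0)
  expect_gt(est$f_true, est$f_obs)   # errors dilute the CpG fraction
  expect_lt(abs(est$eps - eps_true), 2.5 * max(est$se, 5e-6))
})

test_that("f_obs equal to f_true implies zero estimated error", {
  het <- seq(0, 995000, by = 5000)              # 200 sites, 1 in 5 is CpG,
  lab <- (seq_along(het) %% 5) == 1             # exactly so in every window
  chroms <- list(chr1 = list(het = het, is_cpg = lab, length = 2e6),
                 chr2 = list(het = het, is_cpg = lab, length = 2e6))
  prof <- het_profile("s1", chroms)
  regions <- data.frame(sample = "s1", chrom = c("chr1", "chr2"), mid = 5e5,
                        start = 0, end = 1e6, stringsAsFactors = FALSE)
  est <- estimate_genotype_error_cpg(prof, regions, f_err = 0.02, H0 = 8e-5)
  expect_equal(est$eps, 0, tolerance = 1e-12)
  expect_error(estimate_genotype_error_cpg(prof, regions, f_err = 0.5, H0 = 8e-5),
               "unidentifiable")
})

test_that("directly counted error rates match the injected truth", {
  set.seed(33)
  p <- het_profile("s1", list(chr1 = list(het = seq(0, 1e6, by = 1e4),
                                          length = 2e6)))
  p <- inject_genotype_errors(p, 1e-4)
  regions <- data.frame(sample = "s1", chrom = "chr1", mid = 5e5,
                        n_unmasked = 1e5, stringsAsFactors = FALSE)
  rate <- count_error_rate(list(p), regions)
  inj <- p$chroms$chr1$injected
  expect_equal(rate, sum(inj >= 4.5e5 & inj < 5.5e5) / 1e5)
})

test_that("class partition is exhaustive, disjoint, and carries class settings", {
  set.seed(41)
  het <- sort(sample(1e6, 200)) - 1
  is_cpg <- runif(200) < 0.12
  prof <- het_profile("s1", list(chr1 = list(het = het, is_cpg = is_cpg,
                                             length = 1e6)))
  cp <- class_partition(list(prof))
  h_cpg <- cp$cpg[[1]]$chroms$chr1$het
  h_non <- cp$non_cpg[[1]]$chroms$chr1$het
  expect_setequal(c(h_cpg, h_non), het)
  expect_length(intersect(h_cpg, h_non), 0)
  expect_equal(cp$settings$S_cpg, c(0.1, 2))
  expect_equal(cp$settings$S_non_cpg, c(4.375, 8.75))
  expect_false(cp$settings$half_rule_cpg)
  expect_equal(cp$settings$mu_grid_cpg, c(0.2, 0.4, 0.8) * 1e-8)
  expect_equal(sum(cp$settings$eps), 1.08e-5)
  expect_equal(unname(cp$settings$het_fraction["cpg"]), mean(is_cpg))
})

test_that("CpG labelling reads the reference CG context on both strands", {
  #            0123456789
  refseq <- c(chr1 = "ATCGGCGTAA")
  prof <- het_profile("s1", list(chr1 = list(het = c(2, 3, 6, 8),
                                             length = 10)))
  lab <- label_cpg_sites(prof, refseq)
  # pos 2 = C followed by G -> CpG; pos 3 = G preceded by C -> CpG;
  # pos 6 = G preceded by C -> CpG; pos 8 = A -> no
  expect_equal(lab$chroms$chr1$is_cpg, c(TRUE, TRUE, TRUE, FALSE))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    dss <- Biostrings::DNAStringSet(refseq)
    lab2 <- label_cpg_sites(prof, dss)
    expect_equal(lab2$chroms$chr1$is_cpg, lab$chroms$chr1$is_cpg)
  }
})
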