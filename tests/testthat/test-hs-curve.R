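flat_map <- function(len = 1e6, rate = 1) {
  genetic_map(list(chr1 = data.frame(pos = c(0, len), cm = c(0, len * rate / 1e6))))
}

region_row <- function(mid, map, n_het = 7, chrom = "chr1", sample = "s1",
                       flank_cm = 0.1) {
  cm_mid <- map_cm(map, chrom, mid)
  data.frame(sample = sample, chrom = chrom, mid = mid,
             start = min(map_pos(map, chrom, cm_mid - flank_cm), mid - 5e4),
             end = max(map_pos(map, chrom, cm_mid + flank_cm), mid + 5e4),
             cm_mid = cm_mid, n_het = n_het, n_unmasked = 1e5,
             stringsAsFactors = FALSE)
}

test_that("hand-placed sites land in the bins a brute-force computation gives", {
  map <- flat_map()          # 1 cM/Mb: 0.1 cM = 100 kb; bins are 5/3 kb wide
  mid <- 5e5
  set.seed(31)
  het <- sort(sample(setdiff(0:(1e6 - 1), mid), 400))
  prof <- het_profile("s1", list(chr1 = list(het = het, length = 1e6)))
  curve <- compute_hs_curve(prof, region_row(mid, map), map)
  expect_equal(curve$n_bins, 60)
  expect_equal(curve$bin_hi[60], 0.1)
  # brute force: per-site genetic distance, half-open bins [lo, hi)
  d_site <- abs(het - mid) / 1e6   # cM under the 1 cM/Mb map
  width <- 0.1 / 60
  brute <- vapply(seq_len(60), function(j)
    sum(d_site >= (j - 1) * width & d_site < j * width), 0)
  expect_equal(curve$n_het, brute)
  # a site exactly at 0.1 cM is excluded
  prof2 <- het_profile("s1", list(chr1 = list(het = c(mid + 1e5), length = 1e6)))
  c2 <- compute_hs_curve(prof2, region_row(mid, map), map)
  expect_equal(sum(c2$n_het), 0)
  # ... but a site just inside is counted once
  prof3 <- het_profile("s1", list(chr1 = list(het = c(mid + 1e5 - 1), length = 1e6)))
  c3 <- compute_hs_curve(prof3, region_row(mid, map), map)
  expect_equal(sum(c3$n_het), 1)
})

test_that("a profile with no heterozygous sites yields a flat zero curve", {
  map <- flat_map()
  prof <- het_profile("s1", list(chr1 = list(het = numeric(0), length = 1e6)))
  curve <- compute_hs_curve(prof, region_row(5e5, map, n_het = 0), map)
  expect_true(all(curve$H == 0))
  expect_equal(curve$H0, 0)
  expect_error(compute_hs_curve(prof, region_row(5e5, map)[0, ], map),
               "no starting points")
})

test_that("both directions pool into the same bins and masks reduce sites", {
  map <- flat_map()
  mid <- 5e5
  # symmetric pair of sites at the same genetic distance
  prof <- het_profile("s1", list(chr1 = list(het = c(mid - 2e4, mid + 2e4),
                                             length = 1e6)))
  curve <- compute_hs_curve(prof, region_row(mid, map), map)
  j <- findInterval(2, seq(0, 10, length.out = 61) / 1)  # 0.02 cM bin index
  expect_equal(curve$n_het[12 + 1], 2)   # d = 0.02 cM -> bin 13 ([0.02,...))
  # masking one side removes its sites from the denominator
  mask <- iv(mid + 1e4, mid + 3e4)
  prof_m <- het_profile("s1", list(chr1 = list(het = c(mid - 2e4),
                                               mask = mask, length = 1e6)))
  cm <- compute_hs_curve(prof_m, region_row(mid, map), map)
  expect_lt(sum(cm$n_sites), sum(curve$n_sites))
})

test_that("curve pooling is invariant to genome and chromosome order", {
  map <- genetic_map(list(
    chr1 = data.frame(pos = c(0, 1e6), cm = c(0, 1)),
    chr2 = data.frame(pos = c(0, 1e6), cm = c(0, 1))))
  set.seed(5)
  mk <- function(s) het_profile(s, list(
    chr1 = list(het = sort(sample(1e6, 120)) - 1, length = 1e6),
    chr2 = list(het = sort(sample(1e6, 80)) - 1, length = 1e6)))
  p1 <- mk("a"); p2 <- mk("b")
  regs <- rbind(region_row(5e5, map, sample = "a"),
                region_row(5e5, map, sample = "b", chrom = "chr2"))
  c12 <- compute_hs_curve(list(p1, p2), regs, map)
  c21 <- compute_hs_curve(list(p2, p1), regs[2:1, ], map)
  expect_equal(c12$H, c21$H)
  expect_equal(c12$H0, c21$H0)
})

test_that("asymptote adjustment scales the relaxation and fixes the intercept", {
  map <- flat_map()
  set.seed(8)
  het <- sort(sample(1e6, 300)) - 1
  prof <- het_profile("s1", list(chr1 = list(het = het, length = 1e6)))
  curve <- compute_hs_curve(prof, region_row(5e5, map), map)
  same <- asymptote_adjust(curve, hbar_real = curve$hbar_sr)
  expect_equal(same$H, curve$H)                         # ratio 1: unchanged
  up <- asymptote_adjust(curve, hbar_real = curve$hbar_sr * 1.05)
  expect_equal(up$H - curve$H0, (curve$H - curve$H0) * 1.05)
  # intercept invariance for an arbitrary ratio
  expect_equal(up$H0, curve$H0)
  expect_warning(asymptote_adjust(curve, hbar_real = curve$hbar_sr * 3),
                 "outside")
})

test_that("per-bin jackknife variance is zero when chromosomes agree exactly", {
  map <- genetic_map(list(
    chr1 = data.frame(pos = c(0, 1e6), cm = c(0, 1)),
    chr2 = data.frame(pos = c(0, 1e6), cm = c(0, 1))))
  het <- seq(1000, 999000, by = 4000)
  prof <- het_profile("s1", list(
    chr1 = list(het = het, length = 1e6),
    chr2 = list(het = het, length = 1e6)))
  regs <- rbind(region_row(5e5, map), region_row(5e5, map, chrom = "chr2"))
  curve <- compute_hs_curve(prof, regs, map)
  expect_true(all(curve$var[curve$n_sites > 0] < 1e-20))
})
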