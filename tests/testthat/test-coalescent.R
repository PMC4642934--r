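const_map <- function(L, rate_cm_mb = 1.25)
  list(pos = c(0, L), cm = c(0, L * rate_cm_mb / 1e6))

test_that("expected block length is 1/(2*T*r) and scales accordingly", {
  expect_equal(expected_block_length(2000, 1.25e-8), 20000)
  expect_equal(expected_block_length(4000, 1.25e-8),
               expected_block_length(2000, 1.25e-8) / 2)
  expect_error(expected_block_length(0, 1e-8))
})

test_that("single-site TMRCA distribution matches the piecewise coalescent", {
  set.seed(101)
  dem <- demography_gen(N0 = 1e4, mu = 2.5e-8,
                        epoch_start_gen = c(0, 1000, 2000),
                        N = c(1e4, 1e3, 1e4))
  bl <- simulate_diploid_region(const_map(100), dem, 2.5e-8, n_reps = 6000)
  w <- bl$end - bl$start
  Tm <- tapply(bl$tmrca * w, bl$rep, sum) / tapply(w, bl$rep, sum)
  n <- length(Tm)
  # survival probabilities at the bottleneck edges
  p1 <- exp(-1000 / 2e4)
  p2 <- p1 * exp(-1000 / 2e3)
  expect_lt(abs(mean(Tm > 1000) - p1), 3 * sqrt(p1 * (1 - p1) / n))
  expect_lt(abs(mean(Tm > 2000) - p2), 3 * sqrt(p2 * (1 - p2) / n))
})

test_that("mean heterozygosity of constant-N simulations approaches theta", {
  set.seed(102)
  dem <- demography_gen(N0 = 1e4, mu = 2.5e-8)      # theta = 1e-3
  bl <- simulate_diploid_region(const_map(5e5), dem, 2.5e-8, n_reps = 60)
  H <- vapply(split(seq_len(nrow(bl)), bl$rep), function(i)
    length(place_mutations(bl[i, ], 2.5e-8)) / 5e5, 0)
  expect_lt(abs(mean(H) - 1e-3), 3 * sd(H) / sqrt(length(H)))
})

test_that("rho = theta*r/mu scaling: calibration rates rescale the time axis", {
  # same scaled demography realized at two mutation rates: N0 = theta/(4 mu)
  dem <- demography_gen(N0 = 1e4, mu = 2.5e-8)
  rd1 <- hetrelax:::realize_demography(dem, 2.5e-8)
  rd2 <- hetrelax:::realize_demography(dem, 1e-8)
  expect_equal(rd1$N0, 1e4)
  expect_equal(rd2$N0, 2.5e4)        # theta/(4e-8)
  expect_equal(4 * rd2$N0 * 1e-8, dem$theta)
})

test_that("identical seeds give identical block tables", {
  dem <- demography_gen(N0 = 1e4, mu = 2.5e-8)
  set.seed(77)
  a <- simulate_diploid_region(const_map(2e5), dem, 2.5e-8, n_reps = 3)
  set.seed(77)
  b <- simulate_diploid_region(const_map(2e5), dem, 2.5e-8, n_reps = 3)
  expect_identical(a, b)
})

test_that("blocks partition the region and TMRCAs are positive", {
  set.seed(55)
  dem <- demography_gen(N0 = 1e4, mu = 2.5e-8,
                        epoch_start_gen = c(0, 1000, 2000),
                        N = c(1e4, 1e3, 1e4))
  bl <- simulate_diploid_region(const_map(3e5), dem, 2.5e-8, n_reps = 5)
  for (r in unique(bl$rep)) {
    b <- bl[bl$rep == r, ]
    b <- b[order(b$start), ]
    expect_equal(sum(b$end - b$start), 3e5, tolerance = 1e-6)
    expect_true(all(b$tmrca > 0))
  }
  expect_error(simulate_diploid_region(list(pos = c(0, 100), cm = c(0, 0)),
                                       dem, 2.5e-8),
               "zero genetic length")
})

test_that("gene conversion adds short-tract TMRCA switches", {
  set.seed(66)
  dem <- demography_gen(N0 = 1e4, mu = 1.5e-8)
  no_gc <- simulate_diploid_region(const_map(2e5), dem, 1.5e-8, n_reps = 40)
  with_gc <- simulate_diploid_region(const_map(2e5), dem, 1.5e-8, n_reps = 40,
                                     gc_rate = 5.9e-6, gc_tract = 100)
  # conversion tracts split blocks: more, shorter blocks on average
  expect_gt(nrow(with_gc), nrow(no_gc) * 1.1)
})

test_that("injected genotype errors are Poisson-many, novel and recorded", {
  set.seed(9)
  p <- het_profile("s", list(chr1 = list(het = c(10, 20, 30), length = 1e6)))
  p0 <- inject_genotype_errors(p, 0)
  expect_identical(p0$chroms$chr1$het, p$chroms$chr1$het)
  rate <- 1e-4
  counts <- replicate(40, {
    pe <- inject_genotype_errors(p, rate)
    expect_false(any(pe$chroms$chr1$injected %in% c(10, 20, 30)))
    expect_true(all(pe$chroms$chr1$injected %in% pe$chroms$chr1$het))
    length(pe$chroms$chr1$injected)
  })
  lambda <- rate * 1e6
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 40))
})

test_that("admixture split delays coalescence for lineages in different demes", {
  set.seed(12)
  dem <- demography_gen(N0 = 1e4, mu = 2.5e-8)
  mixed <- simulate_diploid_region(const_map(100), dem, 2.5e-8, n_reps = 2000,
                                   split_time_gen = 3000, admix_frac = 0.5)
  plain <- simulate_diploid_region(const_map(100), dem, 2.5e-8, n_reps = 2000)
  wm <- mixed$end - mixed$start; wp <- plain$end - plain$start
  Tm <- sum(mixed$tmrca * wm) / sum(wm)
  Tp <- sum(plain$tmrca * wp) / sum(wp)
  # half the pairs cannot coalesce before the split: mean TMRCA up by ~1500
  expect_gt(Tm, Tp + 500)
})
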