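profile_with <- function(het, len = 1e6, mask = iv(), segments = NULL) {
  het_profile("s1", list(chr1 = list(het = het, length = len, mask = mask,
                                     segments = segments)))
}

test_that("window counts match a brute-force recount on random placements", {
  set.seed(11)
  for (trial in 1:10) {
    het <- sort(sample(0:(1e6 - 1), 300))
    w <- tile_and_count(profile_with(het))
    expect_equal(nrow(w), 10)
    brute <- vapply(seq_len(10), function(k)
      sum(het >= (k - 1) * 1e5 & het < k * 1e5), 0)
    expect_equal(w$n_het, brute)
    brute_left <- vapply(seq_len(10), function(k)
      sum(het >= (k - 1) * 1e5 & het < (k - 1) * 1e5 + 5e4), 0)
    expect_equal(w$n_het_left, brute_left)
  }
})

test_that("empty profiles give zero counts and short chromosomes warn", {
  w <- tile_and_count(profile_with(numeric(0)))
  expect_true(all(w$n_het == 0))
  expect_warning(tile_and_count(profile_with(numeric(0), len = 5e4)),
                 "shorter")
})

test_that("masked windows use unmasked-site rates and the 50% rule", {
  # 7 het sites with 20% of the window masked: rate 8.75 per 100 kb
  mask <- iv(8e4, 10e4 + 0)
  het <- c(seq(1e3, 4e4, length.out = 4), seq(4.2e4, 7.5e4, length.out = 3))
  w <- tile_and_count(profile_with(floor(het), len = 1e5, mask = mask))
  expect_equal(w$n_het[1], 7)
  expect_equal(w$rate[1], 7 / 8e4 * 1e5)
  expect_true(w$usable[1])
  pts <- ascertain(w, S = c(5, 10))
  expect_equal(nrow(pts), 1)
  # over half masked: unusable
  w2 <- tile_and_count(profile_with(c(1e3, 2e3), len = 1e5,
                                    mask = iv(4e4, 10e4)))
  expect_false(w2$usable[1])
})

test_that("S bounds are inclusive and the half rule rejects one-sided windows", {
  mk <- function(counts_left, counts_right) {
    het <- c(seq_len(counts_left) * 100,
             5e4 + seq_len(counts_right) * 100)
    floor(het)
  }
  # counts 4, 5, 10, 11 across four separate chromosomes
  chroms <- list(
    chr1 = list(het = mk(2, 2), length = 1e5),
    chr2 = list(het = mk(2, 3), length = 1e5),
    chr3 = list(het = mk(5, 5), length = 1e5),
    chr4 = list(het = mk(5, 6), length = 1e5))
  w <- tile_and_count(het_profile("s", chroms))
  pts <- ascertain(w, S = c(5, 10))
  expect_setequal(pts$chrom, c("chr2", "chr3"))
  # all six sites in one half: excluded by the half rule, kept without it
  one_sided <- profile_with(seq(1e3, 4e4, length.out = 6), len = 1e5)
  w1 <- tile_and_count(one_sided)
  expect_error(ascertain(w1, S = c(5, 10)), "no windows")
  expect_equal(nrow(ascertain(w1, S = c(5, 10), half_rule = FALSE)), 1)
})

test_that("widening S selects a superset of starting points", {
  set.seed(23)
  het <- sort(sample(0:(2e6 - 1), 150))
  w <- tile_and_count(profile_with(het, len = 2e6))
  narrow <- tryCatch(ascertain(w, S = c(5, 10)), error = function(e) NULL)
  wide <- ascertain(w, S = c(1, 15))
  if (!is.null(narrow))
    expect_true(all(narrow$mid %in% wide$mid))
  expect_gte(nrow(wide), if (is.null(narrow)) 0 else nrow(narrow))
})

test_that("super-regions have >= 0.1 cM genetic flank on re-measurement", {
  map <- genetic_map(list(chr1 = data.frame(pos = c(0, 1e6),
                                            cm = c(0, 1))))  # 1 cM/Mb
  pts <- data.frame(sample = "s1", chrom = "chr1", mid = 5e5,
                    n_het = 7, n_unmasked = 1e5, stringsAsFactors = FALSE)
  reg <- define_super_regions(pts, map)
  expect_equal(reg$start, 4e5)   # 0.1 cM = 100 kb each side of the midpoint
  expect_equal(reg$end, 6e5)
  expect_gte(map_cm(map, "chr1", reg$mid) - map_cm(map, "chr1", reg$start),
             0.1 - 1e-9)
  expect_gte(map_cm(map, "chr1", reg$end) - map_cm(map, "chr1", reg$mid),
             0.1 - 1e-9)
  # flank 0: the super-region collapses to the ascertainment window
  reg0 <- define_super_regions(pts, map, flank_cm = 0)
  expect_equal(c(reg0$start, reg0$end), c(4.5e5, 5.5e5))
})

test_that("points too close to the map edge or a chunk boundary are dropped", {
  map <- genetic_map(list(chr1 = data.frame(pos = c(0, 1e6), cm = c(0, 1))))
  pts <- data.frame(sample = "s1", chrom = "chr1", mid = c(5e4, 5e5),
                    n_het = c(7, 7), n_unmasked = 1e5,
                    stringsAsFactors = FALSE)
  expect_warning(reg <- define_super_regions(pts, map), "dropped")
  expect_equal(nrow(reg), 1)         # the 50-kb point cannot host the flank
  expect_equal(attr(reg, "n_dropped"), 1)
  # chunk boundary at 450 kb: region [400,600] kb straddles it
  prof <- profile_with(numeric(0), len = 1e6,
                       segments = iv(c(0, 4.5e5), c(4.5e5, 1e6)))
  expect_warning(expect_error(
    define_super_regions(pts, map, profiles = prof), "all starting points"))
})
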