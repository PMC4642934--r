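# Synthetic-data scenarios for the simulation study.  Each scenario defines
# a known true mutation rate, a bottleneck demography resembling the
# out-of-Africa history of non-African samples, and zero or more model
# violations (gene conversion, genotype error, mutation-rate heterogeneity,
# admixture).  Scenario defaults are the study conditions; the scale profile
# only controls how much sequence is simulated.

#' Scale profiles for the simulation study
#'
#' `"paper"` mirrors the full study conditions (20 diploid genomes, 25
#' trials, 30 simulated genomes per calibration curve) and takes hours;
#' `"desk"` is the documented reduced setting used by the test-suite and
#' acceptance runs (4 genomes, 12 chromosomes of 4 Mb, 5 trials, 12 simulated
#' genomes per calibration curve), which yields 200+ super-regions per trial
#' and completes in minutes on one CPU.
#'
#' @param name `"paper"` or `"desk"`.
#' @return list of scale settings.
#' @export
scale_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  switch(name,
    desk = list(name = "desk", n_genomes = 4L, n_chrom = 12L,
                chrom_length = 4e6, chunk = 2e6, n_cal_reps = 12L,
                n_trials = 5L, map_grid_bp = 5000),
    paper = list(name = "paper", n_genomes = 20L, n_chrom = 22L,
                 chrom_length = 2e7, chunk = 2.5e6, n_cal_reps = 30L,
                 n_trials = 25L, map_grid_bp = 5000))
}

scenario_names <- c("baseline", "low_mu", "gene_conversion",
                    "genotype_error", "variable_mu", "admixture", "combined")

# resolved parameter set for one scenario
scenario_config <- function(scenario) {
  scenario <- match.arg(scenario, scenario_names)
  cfg <- list(scenario = scenario, mu = 2.5e-8, N0 = 1e4,
              bneck_gen = c(1000, 2000), bneck_frac = 0.1,
              gc_rate = 0, gc_tract = 100, err_rate = 0,
              mu_cv = 0, mu_window = 1e5,
              split_time_gen = 0, admix_frac = 1,
              alpha = 3000, pi = 0.09)
  if (scenario %in% c("low_mu", "gene_conversion")) {
    cfg$mu <- 1.5e-8
    cfg$N0 <- 16666           # keeps theta = 4*N0*mu = 1e-3
  }
  if (scenario == "gene_conversion") cfg$gc_rate <- 5.9e-6
  if (scenario == "genotype_error") cfg$err_rate <- 1e-5
  if (scenario == "variable_mu") cfg$mu_cv <- 0.3
  if (scenario == "admixture") { cfg$split_time_gen <- 3000; cfg$admix_frac <- 0.5 }
  if (scenario == "combined") {
    cfg$err_rate <- 1 / 1.5e5
    cfg$mu_cv <- 0.3
    cfg$split_time_gen <- 3000; cfg$admix_frac <- 0.5
  }
  cfg
}

# piecewise-constant mutation-rate multiplier field, one value per window,
# shared by all genomes (rate heterogeneity is a property of the genome)
make_mu_field <- function(chrom_lengths, cv, window) {
  if (cv <= 0) return(NULL)
  sdlog <- sqrt(log(1 + cv^2))
  lapply(chrom_lengths, function(len) {
    n <- ceiling(len / window)
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
  })
}

mu_multiplier_fun <- function(field, chrom, window) {
  if (is.null(field)) return(NULL)
  mult <- field[[chrom]]
  function(pos) mult[pmin(length(mult), floor(pos / window) + 1)]
}

#' Generate synthetic diploid genomes for a simulation scenario
#'
#' Simulates `n_genomes` diploid genomes under the scenario's demography --
#' an ancestral diploid size of 10,000 (16,666 for the low-rate scenarios,
#' preserving theta) with a 10x bottleneck 1000-2000 generations ago -- on a
#' perturbed realization of a synthetic hotspot-punctuated base map
#' (`alpha = 3000` M^-1, `pi = 0.09` cM/Mb).  Chromosomes are simulated in
#' genealogically independent chunks (recorded in each profile's `segments`
#' so that downstream region selection never spans a chunk boundary).
#' Scenario extras: non-crossover gene conversion, injected genotype errors,
#' a log-normal window-level mutation-rate field, and a two-population
#' admixture history.
#'
#' @param scenario one of `"baseline"`, `"low_mu"`, `"gene_conversion"`,
#'   `"genotype_error"`, `"variable_mu"`, `"admixture"`, `"combined"`.
#' @param scale a [scale_profile()].
#' @param map_base optional pre-built base [genetic_map()]; generated with
#'   [synthetic_map()] when absent.
#' @return list with `profiles` (list of [het_profile()]), `map_base`,
#'   `map_tests` (the perturbed realizations that played the role of each
#'   genome's true map), and `truth` (true mu, [demography()], scenario
#'   config; injected error positions are inside the profiles).
#' @export
scenario_genomes <- function(scenario, scale = scale_profile("desk"),
                             map_base = NULL) {
  cfg <- scenario_config(scenario)
  n_chrom <- scale$n_chrom
  if (cfg$mu < 2e-8 && scale$name == "desk") {
    # a lower true rate thins the eligible windows (the ascertainment band
    # no longer coincides with the bottleneck TMRCA mass), so the reduced
    # profile carries proportionally more sequence to keep the number of
    # super-regions above the 200 the reduced study design calls for
    n_chrom <- as.integer(2.5 * n_chrom)
  }
  chunk <- scale$chunk
  if (cfg$gc_rate > 0) {
    # gene-conversion tracts inflate the ARG lineage count superlinearly
    # with segment length; shorter independent chunks keep the full-ARG
    # cost manageable at identical marginal statistics
    chunk <- min(chunk, 1.25e6)
  }
  chrom_lengths <- setNames(rep(scale$chrom_length, n_chrom),
                            paste0("chr", seq_len(n_chrom)))
  if (is.null(map_base))
    map_base <- synthetic_map(chrom_lengths, grid_bp = scale$map_grid_bp)
  model <- map_error_model(alpha = cfg$alpha, pi = cfg$pi)
  # one independent map-error realization per genome: each genome's
  # landscape deviates from the base map with the modelled magnitude, and
  # the test-data ensemble is exactly the ensemble the calibration
  # integrates over.  (With a single shared realization, a window
  # ascertained in several genomes at once would carry extra information
  # about its local map draw that a per-region calibration cannot
  # condition on; see the methods vignette.)
  map_tests <- replicate(scale$n_genomes, perturb_map(map_base, model),
                         simplify = FALSE)
  dem <- demography_gen(N0 = cfg$N0, mu = cfg$mu,
                        epoch_start_gen = c(0, cfg$bneck_gen[1], cfg$bneck_gen[2]),
                        N = cfg$N0 * c(1, cfg$bneck_frac, 1))
  mu_field <- make_mu_field(chrom_lengths, cfg$mu_cv, cfg$mu_window)

  hets <- lapply(seq_len(scale$n_genomes), function(i) list())
  segments <- list()
  for (nm in names(chrom_lengths)) {
    len <- chrom_lengths[[nm]]
    edges <- unique(c(seq(0, len, by = chunk), len))
    segments[[nm]] <- iv(edges[-length(edges)], edges[-1])
    mfun <- mu_multiplier_fun(mu_field, nm, cfg$mu_window)
    for (k in seq_len(nrow(segments[[nm]]))) {
      a <- segments[[nm]][k, 1]; b <- segments[[nm]][k, 2]
      for (g in seq_len(scale$n_genomes)) {
        lm <- local_map(map_tests[[g]], nm, a, b)
        bl <- simulate_diploid_region(lm, dem, cfg$mu, n_reps = 1,
                                      gc_rate = cfg$gc_rate,
                                      gc_tract = cfg$gc_tract,
                                      split_time_gen = cfg$split_time_gen,
                                      admix_frac = cfg$admix_frac)
        bl$start <- bl$start + a; bl$end <- bl$end + a
        pos <- place_mutations(bl, cfg$mu, mfun)
        hets[[g]][[nm]] <- c(hets[[g]][[nm]], pos)
      }
    }
  }

  profiles <- lapply(seq_len(scale$n_genomes), function(g) {
    chroms <- lapply(names(chrom_lengths), function(nm)
      list(het = hets[[g]][[nm]], length = chrom_lengths[[nm]],
           segments = segments[[nm]]))
    names(chroms) <- names(chrom_lengths)
    het_profile(paste0("sim", g), chroms)
  })
  if (cfg$err_rate > 0)
    profiles <- lapply(profiles, inject_genotype_errors, rate = cfg$err_rate)

  list(profiles = profiles, map_base = map_base, map_tests = map_tests,
       truth = list(mu = cfg$mu, dem = dem, config = cfg))
}
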