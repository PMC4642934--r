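# R-side interface to the ancestral-recombination-graph engine.  The engine
# realises the full ARG for the two lineages of a diploid sample (it is not
# a sequentially Markovian approximation: trapped non-ancestral material
# recombines and distant blocks can share coalescences), returning the
# piecewise-constant TMRCA blocks along the simulated segment.  Mutations
# are then placed by a Poisson process at rate 2*T*mu per base.

#' Simulate TMRCA blocks for diploid samples over a mapped region
#'
#' Low-level entry point: simulates `n_reps` independent diploid samples
#' (two lineages each) over a local genetic map under a piecewise-constant
#' demography, optionally with non-crossover gene conversion and a
#' two-population admixture history.
#'
#' @param map_local list with `pos` (physical breakpoints, bases, starting
#'   at 0) and `cm` (cumulative cM at the breakpoints).
#' @param dem a [demography()].
#' @param mu_sim mutation rate defining the realized baseline size
#'   `N0 = theta/(4*mu_sim)` (and hence `rho = theta*r/mu_sim`).
#' @param n_reps number of independent diploid samples.
#' @param gc_rate probability per base per generation of being covered by a
#'   non-crossover gene-conversion tract (0 disables).
#' @param gc_tract mean tract length in bases (exponential lengths).
#' @param split_time_gen if positive, two populations with the shared
#'   demography merge this many generations ago; each sampled lineage is
#'   drawn from population 1 with probability `admix_frac`.
#' @param admix_frac admixture fraction for the two-population scenario.
#' @param perturb optional per-replicate map-error realization: a
#'   [map_error_model()].  Each replicate then runs on a fresh gamma draw of
#'   the interval lengths, `Z ~ Gamma(alpha*g', alpha)` with
#'   `g' = gamma*(g + pi*p)` (the calibration contract); `gamma` must be
#'   supplied via `gamma_total` (genome-wide constant of the base map).
#' @param gamma_total total-length-preserving constant for `perturb`.
#' @return data.frame with columns `rep`, `start`, `end`, `tmrca`
#'   (generations); blocks partition `[0, L)` within each rep.
#' @export
simulate_diploid_region <- function(map_local, dem, mu_sim, n_reps = 1,
                                    gc_rate = 0, gc_tract = 100,
                                    split_time_gen = 0, admix_frac = 1,
                                    perturb = NULL, gamma_total = 1) {
  stopifnot(mu_sim > 0, n_reps >= 1, gc_rate >= 0)
  if (map_local$cm[length(map_local$cm)] - map_local$cm[1] <= 0)
    stop("region has zero genetic length")
  rd <- realize_demography(dem, mu_sim)
  gc_init <- if (gc_rate > 0) gc_rate / gc_tract else 0
  pos0 <- map_local$pos - map_local$pos[1]
  if (is.null(perturb)) {
    res <- arg_sim_cpp(pos0, (map_local$cm - map_local$cm[1]) / 100,
                       rd$epoch_start_gen, rd$N, as.integer(n_reps),
                       gc_init, gc_tract, split_time_gen, admix_frac, 5e8)
  } else {
    gprime <- gamma_total *
      (diff(map_local$cm) + perturb$pi * diff(map_local$pos) / 1e6) / 100
    res <- arg_sim_pert_cpp(pos0, gprime, perturb$alpha,
                            rd$epoch_start_gen, rd$N, as.integer(n_reps),
                            gc_init, gc_tract, split_time_gen, admix_frac, 5e8)
  }
  out <- data.frame(rep = res$rep, start = res$start, end = res$end,
                    tmrca = res$tmrca)
  # crossover breakpoints that fell on ancestral material: these partition
  # the sequence into the "inherited together" blocks of the mu/r law
  attr(out, "breakpoints") <- data.frame(rep = res$bp_rep, x = res$bp_x)
  out
}

# local (relative-coordinate) map for [start, end) of a chromosome
local_map <- function(map, chrom, start, end) {
  g <- map$chroms[[chrom]]
  inner <- g$pos > start & g$pos < end
  pos <- c(start, g$pos[inner], end)
  cm <- c(map_cm(map, chrom, start), g$cm[inner], map_cm(map, chrom, end))
  list(pos = pos, cm = cm)
}

#' Place mutations on TMRCA blocks
#'
#' Heterozygous sites are a Poisson process at rate `2 * T * mu` per base on
#' a block with TMRCA `T`.  An optional multiplier function models a
#' spatially varying mutation rate.
#'
#' @param blocks data.frame from [simulate_diploid_region()] (one rep).
#' @param mu per-base per-generation mutation rate.
#' @param mu_multiplier optional function of physical position returning a
#'   rate multiplier (evaluated at block midpoints; tracts are short
#'   relative to any realistic rate field).
#' @return sorted unique integer (0-based) heterozygous positions.
#' @export
place_mutations <- function(blocks, mu, mu_multiplier = NULL) {
  if (nrow(blocks) == 0) return(numeric(0))
  len <- blocks$end - blocks$start
  mult <- if (is.null(mu_multiplier)) 1
          else mu_multiplier((blocks$start + blocks$end) / 2)
  n <- rpois(nrow(blocks), 2 * blocks$tmrca * len * mu * mult)
  if (sum(n) == 0) return(numeric(0))
  i <- rep.int(seq_len(nrow(blocks)), n)
  sort(unique(floor(runif(sum(n), blocks$start[i], blocks$end[i]))))
}

# vectorised multi-rep variant: one Poisson pass over all blocks, split by
# replicate (the per-rep positions are sorted unique integers as above)
place_mutations_by_rep <- function(blocks, mu, n_reps) {
  out <- rep(list(numeric(0)), n_reps)
  if (nrow(blocks) == 0) return(out)
  len <- blocks$end - blocks$start
  n <- rpois(nrow(blocks), 2 * blocks$tmrca * len * mu)
  keep <- n > 0
  if (!any(keep)) return(out)
  i <- rep.int(which(keep), n[keep])
  pos <- floor(runif(length(i), blocks$start[i], blocks$end[i]))
  for (r in split(seq_along(i), blocks$rep[i]))
    out[[blocks$rep[i[r[1]]]]] <- sort(unique(pos[r]))
  out
}

#' Expected TMRCA-block length
#'
#' For a block with TMRCA `T` generations and per-base per-generation
#' recombination rate `r`, the expected block length is `1/(2*T*r)` bases:
#' recombinations accumulate on both lineages at rate `2*T*r` per base.
#'
#' @param T TMRCA in generations.
#' @param r recombination rate per base per generation.
#' @return expected length in bases.
#' @examples
#' expected_block_length(2000, 1.25e-8)  # 20,000 bases
#' @export
expected_block_length <- function(T, r) {
  stopifnot(all(T > 0), all(r > 0))
  1 / (2 * T * r)
}

#' Inject false heterozygous sites into a profile
#'
#' Adds artificial heterozygous calls uniformly at unmasked positions that
#' are not already heterozygous, at the given per-base rate (Poisson counts
#' per chromosome).  Injected positions are recorded in each chromosome's
#' `injected` field so that simulation studies can count realized errors in
#' ascertained regions directly.
#'
#' @param profile a [het_profile()].
#' @param rate false-heterozygote rate per unmasked base (e.g. 1e-5 for one
#'   per 100 kb).
#' @return the modified profile.
#' @export
inject_genotype_errors <- function(profile, rate) {
  stopifnot(rate >= 0)
  if (rate == 0) return(profile)
  for (nm in names(profile$chroms)) {
    ch <- profile$chroms[[nm]]
    n <- rpois(1, rate * ch$callable)
    if (n == 0) { ch$injected <- numeric(0); profile$chroms[[nm]] <- ch; next }
    cand <- floor(runif(2 * n + 20, 0, ch$length))
    cand <- cand[!iv_covers(ch$mask, cand)]
    cand <- setdiff(cand, ch$het)
    cand <- unique(cand)[seq_len(min(n, length(unique(cand))))]
    ch$injected <- sort(cand)
    ch$het <- sort(unique(c(ch$het, cand)))
    profile$chroms[[nm]] <- ch
  }
  profile
}
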