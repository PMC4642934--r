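#' Filtering configuration for genotype calls
#'
#' Bundles the thresholds of the site-filtering scheme: a genotype-quality
#' threshold `Q` on phred-scaled genotype likelihoods (PL), a heterozygosity
#' prior offset `P` reflecting the genome-wide prior odds against a
#' heterozygote, a central-mass fraction for the per-genome coverage filter,
#' and a mask dilation radius.  With the defaults (`Q = 60`, `P = 31`) a site
#' is called heterozygous only when its heterozygote PL is at least 91 below
#' the better homozygote PL, called homozygous when it is at least 29 above,
#' and masked as low-quality in between.
#'
#' @param mq_threshold mapping-quality threshold (informational; applied
#'   upstream by the caller that produced the VCF).
#' @param gq_threshold quality threshold `Q` (phred units), must be positive.
#' @param het_prior prior offset `P` (phred units).
#' @param coverage_central_mass fraction of the per-genome depth
#'   distribution retained by the coverage filter (default the central 95%).
#' @param dilation_radius bases; sites within this distance of any masked
#'   base are masked too.
#' @param mask_paths optional character vector of BED files with external
#'   masks (tandem repeats, alignability, ...).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(mq_threshold = 30, gq_threshold = 60,
                          het_prior = 31, coverage_central_mass = 0.95,
                          dilation_radius = 2, mask_paths = character(0)) {
  stopifnot(gq_threshold > 0,
            coverage_central_mass > 0, coverage_central_mass < 1,
            dilation_radius >= 0)
  structure(list(mq_threshold = mq_threshold, gq_threshold = gq_threshold,
                 het_prior = het_prior,
                 coverage_central_mass = coverage_central_mass,
                 dilation_radius = dilation_radius,
                 mask_paths = mask_paths),
            class = "filter_config")
}

#' Call a genotype from PL scores
#'
#' Compares the heterozygote PL to the minimum of the two homozygote PLs.
#' The site is `"HET"` if the heterozygote is at least `Q + P` phred units
#' more likely, `"HOM"` if it is at least `Q - P` units less likely, and
#' `"MASKED"` otherwise (the in-between band is treated as low quality).
#' Vectorised over sites.
#'
#' @param pl_het phred-scaled likelihood of the heterozygous genotype
#'   (smaller is more likely).
#' @param pl_hom_min minimum of the two homozygote PLs.
#' @param config a [filter_config()].
#' @return character vector in `c("HET", "HOM", "MASKED")`.  Records with
#'   negative PLs are rejected as `"MASKED"` and counted in the
#'   `"n_rejected"` attribute.
#' @examples
#' call_genotype(0, 100)   # "HET": 100 - 0 >= 91
#' call_genotype(50, 50)   # "MASKED"
#' @export
call_genotype <- function(pl_het, pl_hom_min, config = filter_config()) {
  stopifnot(length(pl_het) == length(pl_hom_min))
  bad <- is.na(pl_het) | is.na(pl_hom_min) | pl_het < 0 | pl_hom_min < 0
  if (any(bad)) warning(sum(bad), " record(s) with negative or missing PL rejected")
  out <- rep("MASKED", length(pl_het))
  q <- config$gq_threshold
  p <- config$het_prior
  out[!bad & (pl_hom_min - pl_het >= q + p)] <- "HET"
  out[!bad & (pl_het - pl_hom_min >= q - p)] <- "HOM"
  out[bad] <- "MASKED"
  structure(out, n_rejected = sum(bad))
}

#' Coverage mask from a per-site depth sequence
#'
#' Masks every site whose depth falls outside the central mass of that
#' genome's empirical depth distribution (default the central 95%, i.e. the
#' 2.5 and 97.5 nearest-rank percentiles).  Depth thresholds are computed per
#' genome, so coverage filtering is genome-specific.
#'
#' @param depths integer vector of per-site depths for one genome (index i
#'   is the 0-based position i).
#' @param config a [filter_config()].
#' @return mask matrix of 0-based half-open intervals.
#' @export
build_coverage_mask <- function(depths, config = filter_config()) {
  if (length(depths) == 0) stop("empty depth input")
  tail_mass <- (1 - config$coverage_central_mass) / 2
  srt <- sort(depths)
  n <- length(srt)
  lo <- srt[max(1, ceiling(tail_mass * n))]
  hi <- srt[min(n, ceiling((1 - tail_mass) * n))]
  bad <- depths < lo | depths > hi
  runs_to_iv(bad)
}

# logical vector (index i = 0-based position i-1) -> interval matrix
runs_to_iv <- function(flag) {
  if (!any(flag)) return(iv_empty())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv(starts[r$values], ends[r$values])
}
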