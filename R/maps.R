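#' Genetic maps on a SNP grid
#'
#' A `genetic_map` stores, per chromosome, a strictly increasing grid of
#' physical positions (0-based bases) with non-decreasing cumulative genetic
#' positions (cM).  Genetic positions of individual sites are obtained by
#' linear interpolation within the grid.
#'
#' @param chroms named list of data frames with columns `pos` (bases) and
#'   `cm` (cumulative cM).
#' @return object of class `genetic_map`.
#' @export
genetic_map <- function(chroms) {
  for (nm in names(chroms)) {
    g <- chroms[[nm]]
    stopifnot(all(c("pos", "cm") %in% names(g)))
    if (is.unsorted(g$pos, strictly = TRUE)) stop("map grid not strictly increasing on ", nm)
    if (is.unsorted(g$cm)) stop("cumulative cM decreasing on ", nm)
    chroms[[nm]] <- g[, c("pos", "cm")]
  }
  structure(list(chroms = chroms), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d chromosome(s), %.1f cM over %.1f Mb (mean %.2f cM/Mb)%s\n",
              length(x$chroms), map_total_cm(x), map_total_mb(x),
              map_total_cm(x) / map_total_mb(x),
              if (isTRUE(attr(x, "perturbed"))) " [perturbed]" else ""))
  invisible(x)
}

map_total_cm <- function(map)
  sum(vapply(map$chroms, function(g) g$cm[nrow(g)] - g$cm[1], 0))

map_total_mb <- function(map)
  sum(vapply(map$chroms, function(g) (g$pos[nrow(g)] - g$pos[1]) / 1e6, 0))

#' Interpolate genetic position
#'
#' Linear interpolation of the cumulative genetic position (cM) at physical
#' positions, exact at grid points.  Positions outside the grid span are an
#' error: regions must be truncated to the map before use.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome name.
#' @param pos physical positions (bases, 0-based); vectorised.
#' @return genetic positions in cM.
#' @export
map_cm <- function(map, chrom, pos) {
  g <- map$chroms[[chrom]]
  if (is.null(g)) stop("chromosome not on map: ", chrom)
  if (any(pos < g$pos[1] | pos > g$pos[nrow(g)]))
    stop("position outside map grid on ", chrom)
  approx(g$pos, g$cm, xout = pos, ties = "ordered")$y
}

#' Inverse interpolation: physical position at a genetic position
#'
#' For plateaus (zero-rate stretches) the leftmost physical position is
#' returned.
#'
#' @inheritParams map_cm
#' @param cm genetic positions in cM; vectorised.
#' @return physical positions (bases).
#' @export
map_pos <- function(map, chrom, cm) {
  g <- map$chroms[[chrom]]
  if (is.null(g)) stop("chromosome not on map: ", chrom)
  if (any(cm < g$cm[1] - 1e-12 | cm > g$cm[nrow(g)] + 1e-12))
    stop("genetic position outside map span on ", chrom)
  approx(g$cm, g$pos, xout = pmin(pmax(cm, g$cm[1]), g$cm[nrow(g)]),
         ties = min)$y
}

#' Read / write a genetic map table
#'
#' Tab-separated dialect with three columns per chromosome file section:
#' physical position (bases), rate (cM/Mb, informational) and cumulative cM;
#' a header line is tolerated.  The cumulative column is authoritative.
#'
#' @param path TSV path; must contain columns `chrom`, `pos`, `rate_cm_mb`,
#'   `cm` (header required on write, tolerated on read).
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1]][2])
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (!has_header) names(tab)[1:4] <- c("chrom", "pos", "rate_cm_mb", "cm")
  chroms <- lapply(split(tab, tab$chrom),
                   function(d) data.frame(pos = d$pos, cm = d$cm))
  genetic_map(chroms)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  rows <- lapply(names(map$chroms), function(nm) {
    g <- map$chroms[[nm]]
    rate <- c(diff(g$cm) / (diff(g$pos) / 1e6), 0)
    data.frame(chrom = nm, pos = g$pos, rate_cm_mb = rate, cm = g$cm)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Gamma model of genetic-map error
#'
#' The true genetic length `Z` of a map interval with observed length `g`
#' (cM) and physical length `p` is modelled as
#' `Z ~ Gamma(shape = alpha * g', rate = alpha)` with
#' `g' = gamma * (g + pi * p)`, so that `E[Z] = g'` and `var(Z) = g'/alpha`.
#' `alpha` (Morgan^-1) measures map accuracy: `1/alpha` is the interval
#' length at which the coefficient of variation reaches 1.  The pseudo-count
#' prior `pi` (cM/Mb) spreads a small uniform rate over the grid because very
#' short intervals in empirical maps are systematically underestimated (an
#' interval observed at length zero need not truly have length zero);
#' `gamma = G/(G + pi*P) < 1` rescales so that the expected total map length
#' is preserved.
#'
#' @param alpha map accuracy in Morgan^-1 (default 3100).
#' @param alpha_se standard error of `alpha` (default 300).
#' @param pi pseudo-count prior in cM/Mb (default 0.09).
#' @return object of class `map_error_model`.
#' @export
map_error_model <- function(alpha = 3100, alpha_se = 300, pi = 0.09) {
  stopifnot(alpha > 0, pi >= 0, alpha_se >= 0)
  structure(list(alpha = alpha, alpha_se = alpha_se, pi = pi),
            class = "map_error_model")
}

#' Total-length-preserving constant of the perturbation model
#'
#' `gamma = G / (G + pi * P)` for total genetic length `G` (cM) and total
#' physical length `P` (Mb), computed genome-wide.
#'
#' @param map a [genetic_map()].
#' @param model a [map_error_model()].
#' @export
gamma_const <- function(map, model) {
  G <- map_total_cm(map)
  P <- map_total_mb(map)
  G / (G + model$pi * P)
}

#' Draw a perturbed genetic map
#'
#' Replaces every grid interval's genetic length by an independent gamma
#' draw with mean `g' = gamma*(g + pi*p)` and variance `g'/alpha`; the grid
#' itself is unchanged and the expected total length equals the parent map's
#' total length.  Gamma shapes are computed in Morgans so that `alpha` keeps
#' its Morgan^-1 units.
#'
#' @param map a [genetic_map()] (the base map).
#' @param model a [map_error_model()].
#' @return a `genetic_map` flagged as perturbed, with provenance attributes
#'   `alpha` and `pi`.
#' @export
perturb_map <- function(map, model) {
  gam <- gamma_const(map, model)
  chroms <- lapply(map$chroms, function(g) {
    gcm <- diff(g$cm)
    pbp <- diff(g$pos)
    gprime_m <- gam * (gcm + model$pi * pbp / 1e6) / 100   # Morgans
    z <- ifelse(gprime_m > 0,
                rgamma(length(gprime_m), shape = model$alpha * gprime_m,
                       rate = model$alpha),
                0)
    data.frame(pos = g$pos, cm = g$cm[1] + c(0, cumsum(z * 100)))
  })
  out <- genetic_map(chroms)
  attr(out, "perturbed") <- TRUE
  attr(out, "alpha") <- model$alpha
  attr(out, "pi") <- model$pi
  out
}

#' Length scale of map accuracy
#'
#' Returns `1/alpha` in cM: the interval length at which the perturbation's
#' coefficient of variation equals 1 (intervals of this length have standard
#' deviation equal to their mean).
#'
#' @param alpha map accuracy in Morgan^-1.
#' @return length scale in cM.
#' @examples
#' interpret_alpha(3100)  # ~0.032 cM
#' @export
interpret_alpha <- function(alpha) {
  stopifnot(alpha > 0)
  100 / alpha
}

#' Synthetic human-like recombination map
#'
#' Generates a base map on a regular SNP grid with a heterogeneous,
#' hotspot-punctuated rate landscape: a gamma-distributed background plus
#' sparse exponential hotspot contributions, rescaled genome-wide to a target
#' mean rate.  Used by the simulation study as the "published" base map that
#' both the synthetic genomes and the calibration data perturb.
#'
#' @param chrom_lengths named vector of chromosome lengths (bases).
#' @param grid_bp grid spacing in bases.
#' @param mean_rate_cm_mb target genome-wide mean rate.
#' @param hotspot_prob per-interval probability of a hotspot.
#' @param hotspot_mean mean added hotspot rate (cM/Mb).
#' @return a [genetic_map()].
#' @export
synthetic_map <- function(chrom_lengths, grid_bp = 5000,
                          mean_rate_cm_mb = 1.25, hotspot_prob = 0.04,
                          hotspot_mean = 12) {
  rates <- list()
  for (nm in names(chrom_lengths)) {
    pos <- seq(0, chrom_lengths[[nm]], by = grid_bp)
    if (pos[length(pos)] < chrom_lengths[[nm]])
      pos <- c(pos, chrom_lengths[[nm]])
    n <- length(pos) - 1
    r <- rgamma(n, shape = 0.6, rate = 1)                     # background
    hs <- runif(n) < hotspot_prob
    r[hs] <- r[hs] + rgamma(sum(hs), shape = 1, rate = 1 / hotspot_mean)
    rates[[nm]] <- list(pos = pos, r = r)
  }
  tot_cm <- sum(vapply(rates, function(x) sum(x$r * diff(x$pos) / 1e6), 0))
  tot_mb <- sum(chrom_lengths) / 1e6
  scale <- mean_rate_cm_mb * tot_mb / tot_cm
  chroms <- lapply(rates, function(x)
    data.frame(pos = x$pos,
               cm = c(0, cumsum(x$r * scale * diff(x$pos) / 1e6))))
  genetic_map(chroms)
}
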