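#' Piecewise-constant demographic history in coalescent scaling
#'
#' The history is stored the way pairwise sequentially Markovian coalescent
#' (PSMC) software reports it: a scaled diversity `theta = 4*N0*mu` per base,
#' and epochs with start times in units of `2*N0` generations and relative
#' sizes `lambda = N/N0`.  This scaled form is what calibration needs: for a
#' calibration mutation rate `mu_c`, the baseline size is
#' `N0 = theta/(4*mu_c)` and epoch times stretch accordingly, which
#' automatically enforces the scaling `rho = theta * r / mu_c` between the
#' scaled recombination and mutation rates.
#'
#' @param theta scaled diversity per base (4*N0*mu).
#' @param t_scaled epoch start times in units of 2*N0 generations
#'   (non-decreasing, first element 0).
#' @param lambda relative population sizes per epoch (N/N0, positive).
#' @param source provenance tag, `"native"` or `"psmc"`.
#' @return object of class `demography`.
#' @export
demography <- function(theta, t_scaled = 0, lambda = 1, source = "native") {
  stopifnot(theta > 0, length(t_scaled) == length(lambda),
            all(lambda > 0), t_scaled[1] == 0, !is.unsorted(t_scaled))
  structure(list(theta = theta, t_scaled = as.numeric(t_scaled),
                 lambda = as.numeric(lambda), source = source),
            class = "demography")
}

#' Demography from absolute sizes and times
#'
#' Convenience constructor for simulation truth: epochs given in generations
#' with absolute diploid sizes, plus the mutation rate that defines theta.
#'
#' @param N0 baseline diploid population size.
#' @param mu per-base per-generation mutation rate defining
#'   `theta = 4*N0*mu`.
#' @param epoch_start_gen epoch start times in generations (first 0).
#' @param N absolute diploid size in each epoch.
#' @export
demography_gen <- function(N0, mu, epoch_start_gen = 0, N = N0) {
  demography(theta = 4 * N0 * mu,
             t_scaled = epoch_start_gen / (2 * N0),
             lambda = N / N0)
}

# absolute generations/sizes for a concrete simulated mutation rate
realize_demography <- function(dem, mu_sim) {
  stopifnot(inherits(dem, "demography"), mu_sim > 0)
  N0 <- dem$theta / (4 * mu_sim)
  list(epoch_start_gen = dem$t_scaled * 2 * N0, N = dem$lambda * N0, N0 = N0)
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("demography (%s): theta = %.3g, %d epoch(s)\n",
              x$source, x$theta, length(x$lambda)))
  invisible(x)
}

#' Parse PSMC output into a demography
#'
#' Reads the text emitted by PSMC and extracts, from the last reported
#' round, the scaled mutation rate (TR line) and the discretised size
#' history (RS lines: time in units of 2*N0, relative size lambda).  The
#' parser is tolerant of leading/trailing whitespace and of extra columns.
#' PSMC's theta is per analysis bin; `bin_size` converts it to a per-base
#' diversity.
#'
#' @param path PSMC output file.
#' @param bin_size bases per PSMC bin (PSMC default 100).
#' @return a [demography()] with `source = "psmc"`.
#' @export
parse_psmc <- function(path, bin_size = 100) {
  lines <- readLines(path)
  rounds <- which(grepl("^RD\t", lines) | grepl("^RD ", lines))
  if (length(rounds) == 0) stop("no RD record found in PSMC output: ", path)
  block <- lines[rounds[length(rounds)]:length(lines)]
  tr <- block[startsWith(block, "TR")]
  rs <- block[startsWith(block, "RS")]
  if (length(tr) == 0 || length(rs) == 0)
    stop("incomplete final PSMC round in ", path)
  theta <- as.numeric(strsplit(trimws(tr[1]), "[ \t]+")[[1]][2]) / bin_size
  fields <- strsplit(trimws(rs), "[ \t]+")
  t_scaled <- vapply(fields, function(f) as.numeric(f[3]), 0)
  lambda <- vapply(fields, function(f) as.numeric(f[4]), 0)
  demography(theta, t_scaled, lambda, source = "psmc")
}
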