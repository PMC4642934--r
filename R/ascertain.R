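# Window tiling, starting-point ascertainment and super-region layout.

#' Tile the genome into fixed windows and count heterozygous sites
#'
#' Non-overlapping windows aligned to physical coordinates, per genome.
#' Windows with more than half of their sites masked are flagged unusable.
#' Heterozygosity is expressed per 100 kb of unmasked sequence, so the count
#' range used for ascertainment compares against `n_het / n_unmasked * 1e5`.
#'
#' @param profiles list of [het_profile()] objects.
#' @param window window size in bases (default 100 kb).
#' @return data.frame with one row per (genome, window): `sample`, `chrom`,
#'   `start`, `end`, `n_unmasked`, `n_het`, `n_het_left`, `n_het_right`
#'   (counts per half-window), `rate` (het per 100 kb unmasked), `usable`.
#' @export
tile_and_count <- function(profiles, window = 1e5) {
  if (inherits(profiles, "het_profile")) profiles <- list(profiles)
  rows <- list()
  for (p in profiles) {
    for (nm in names(p$chroms)) {
      ch <- p$chroms[[nm]]
      n_win <- floor(ch$length / window)
      if (n_win == 0) {
        warning("chromosome ", nm, " shorter than one window; skipped")
        next
      }
      starts <- (seq_len(n_win) - 1) * window
      ends <- starts + window
      mids <- starts + window / 2
      cuts <- findInterval(ch$het, c(starts[1], ends)) # windows are contiguous
      n_het <- tabulate(cuts, nbins = n_win)
      left <- tabulate(findInterval(ch$het[ch$het %% window < window / 2],
                                    c(starts[1], ends)), nbins = n_win)
      masked <- iv_overlap_width(ch$mask, starts, ends)
      n_unm <- window - masked
      rows[[length(rows) + 1]] <- data.frame(
        sample = p$sample, chrom = nm, start = starts, end = ends,
        n_unmasked = n_unm, n_het = n_het, n_het_left = left,
        n_het_right = n_het - left,
        rate = ifelse(n_unm > 0, n_het / n_unm * 1e5, NA_real_),
        usable = n_unm >= window / 2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Ascertain starting points in a heterozygosity range
#'
#' Selects the midpoints of usable windows whose heterozygosity (per 100 kb
#' unmasked) lies in the closed range `S`.  Unless disabled, each
#' half-window must carry at least one heterozygous site, which guards
#' against windows whose few sites all cluster on one side of a
#' recombination breakpoint (the half rule is dropped for the sparse
#' CpG-class analysis, where windows hold a single site).
#'
#' @param windows data.frame from [tile_and_count()].
#' @param S inclusive numeric range (length 2) of heterozygous sites per
#'   100 kb; the default 5-10 targets blocks roughly one-tenth as old as the
#'   genome-wide average.
#' @param half_rule require at least one heterozygous site per half-window.
#' @return data.frame of starting points: `sample`, `chrom`, `mid`,
#'   `n_het`, `n_unmasked`.
#' @export
ascertain <- function(windows, S = c(5, 10), half_rule = TRUE) {
  stopifnot(length(S) == 2, S[1] <= S[2])
  ok <- windows$usable & !is.na(windows$rate) &
    windows$rate >= S[1] & windows$rate <= S[2]
  if (half_rule)
    ok <- ok & windows$n_het_left >= 1 & windows$n_het_right >= 1
  if (!any(ok))
    stop(sprintf("no windows ascertained in S = [%g, %g]", S[1], S[2]))
  sel <- windows[ok, , drop = FALSE]
  data.frame(sample = sel$sample, chrom = sel$chrom,
             mid = (sel$start + sel$end) / 2,
             n_het = sel$n_het, n_unmasked = sel$n_unmasked,
             stringsAsFactors = FALSE)
}

#' Lay out simulation super-regions around starting points
#'
#' For each starting point, the minimal physical span whose genetic distance
#' from the starting point to either edge is at least `flank_cm` on the base
#' map (and which contains the full ascertainment window).  Points whose
#' span would be truncated by the map edge, or would straddle a boundary
#' between independently generated spans of a synthetic genome, are dropped
#' with a warning.
#'
#' @param points data.frame from [ascertain()].
#' @param map the base [genetic_map()].
#' @param flank_cm genetic flank on each side (default 0.1 cM, the distance
#'   range over which the relaxation curve is computed).
#' @param window ascertainment window size in bases.
#' @param profiles optional list of profiles supplying `segments`
#'   boundaries of independently simulated chunks.
#' @return data.frame of super-regions: `sample`, `chrom`, `mid`, `start`,
#'   `end`, `cm_mid`, `n_het`, `n_unmasked`; attribute `n_dropped`.
#' @export
define_super_regions <- function(points, map, flank_cm = 0.1, window = 1e5,
                                 profiles = NULL) {
  segs <- NULL
  if (!is.null(profiles)) {
    if (inherits(profiles, "het_profile")) profiles <- list(profiles)
    segs <- lapply(profiles, function(p) lapply(p$chroms, `[[`, "segments"))
    names(segs) <- vapply(profiles, `[[`, "", "sample")
  }
  out <- vector("list", nrow(points))
  n_dropped <- 0
  for (i in seq_len(nrow(points))) {
    chrom <- points$chrom[i]; mid <- points$mid[i]
    g <- map$chroms[[chrom]]
    if (is.null(g) || mid < g$pos[1] || mid > g$pos[nrow(g)]) {
      n_dropped <- n_dropped + 1; next
    }
    cm_mid <- map_cm(map, chrom, mid)
    if (cm_mid - flank_cm < g$cm[1] || cm_mid + flank_cm > g$cm[nrow(g)]) {
      n_dropped <- n_dropped + 1; next
    }
    start <- min(map_pos(map, chrom, cm_mid - flank_cm), mid - window / 2)
    end <- max(map_pos(map, chrom, cm_mid + flank_cm), mid + window / 2)
    if (!is.null(segs)) {
      sm <- segs[[points$sample[i]]][[chrom]]
      k <- findInterval(mid, sm[, 1])
      if (k < 1 || start < sm[k, 1] || end > sm[k, 2]) {
        n_dropped <- n_dropped + 1; next
      }
    }
    out[[i]] <- data.frame(sample = points$sample[i], chrom = chrom,
                           mid = mid, start = start, end = end,
                           cm_mid = cm_mid, n_het = points$n_het[i],
                           n_unmasked = points$n_unmasked[i],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (n_dropped > 0)
    warning(n_dropped, " starting point(s) dropped at map or segment edges")
  if (is.null(res)) stop("all starting points dropped")
  attr(res, "n_dropped") <- n_dropped
  res
}
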