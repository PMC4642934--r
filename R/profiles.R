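#' Diploid heterozygosity profile
#'
#' A `het_profile` holds one diploid genome's called heterozygous sites and
#' accessibility mask, per chromosome.  Positions are 0-based; masks are
#' 0-based half-open interval matrices.  `segments` records spans that were
#' generated (or can be treated) as genealogically independent pieces --
#' whole chromosomes for real data, simulation chunks for synthetic data --
#' and is consulted when super-regions are laid out.
#'
#' @param sample sample identifier.
#' @param chroms named list; each element a list with fields `het` (sorted
#'   0-based heterozygous positions), `length` (chromosome length in bases),
#'   and optionally `mask` (interval matrix), `is_cpg` (logical per het
#'   site), `segments` (interval matrix of independent spans), `injected`
#'   (positions of artificial false heterozygotes, for simulation truth).
#' @return an object of class `het_profile`.
#' @export
het_profile <- function(sample, chroms) {
  for (nm in names(chroms)) {
    ch <- chroms[[nm]]
    stopifnot(!is.null(ch$length))
    if (is.null(ch$mask)) ch$mask <- iv_empty()
    ch$het <- sort(unique(as.numeric(ch$het)))
    if (length(ch$het) > 0 && any(iv_covers(ch$mask, ch$het)))
      stop("heterozygous positions inside the mask on ", nm)
    if (any(ch$het >= ch$length | ch$het < 0))
      stop("heterozygous position outside chromosome ", nm)
    if (is.null(ch$segments)) ch$segments <- iv(0, ch$length)
    ch$callable <- ch$length - iv_width(ch$mask)
    chroms[[nm]] <- ch
  }
  structure(list(sample = sample, chroms = chroms), class = "het_profile")
}

#' @export
print.het_profile <- function(x, ...) {
  nh <- sum(vapply(x$chroms, function(c) length(c$het), 0))
  nc <- sum(vapply(x$chroms, function(c) c$callable, 0))
  cat("het_profile:", x$sample, "-", length(x$chroms), "chromosome(s),",
      nh, "heterozygous sites,",
      format(nc, big.mark = ","), "callable bases",
      sprintf("(mean het %.3g)\n", nh / nc))
  invisible(x)
}

# pooled heterozygosity over all callable sequence, and per-chromosome parts
profile_hbar <- function(profiles) {
  het <- 0; sites <- 0
  for (p in profiles) for (ch in p$chroms) {
    het <- het + length(ch$het)
    sites <- sites + ch$callable
  }
  het / sites
}

#' Write / read a heterozygosity profile as TSV
#'
#' Plain-text dump (`chrom`, `pos`) of heterozygous positions for inspection
#' and interchange; masks and lengths travel in a `#` header.  The format
#' round-trips through [read_profile_tsv()].
#'
#' @param profile a [het_profile()].
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sample=", profile$sample), con)
  for (nm in names(profile$chroms)) {
    ch <- profile$chroms[[nm]]
    writeLines(paste0("#chrom=", nm, " length=", format(ch$length, scientific = FALSE)), con)
    if (nrow(ch$mask) > 0)
      writeLines(paste0("#mask=", nm, " ",
                        paste(ch$mask[, 1], ch$mask[, 2], sep = ":", collapse = ",")), con)
  }
  writeLines("chrom\tpos", con)
  for (nm in names(profile$chroms)) {
    h <- profile$chroms[[nm]]$het
    if (length(h) > 0)
      writeLines(paste(nm, format(h, scientific = FALSE, trim = TRUE), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param path TSV file produced by [write_profile_tsv()].
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  sample <- sub("^#sample=", "", hdr[startsWith(hdr, "#sample=")][1])
  chroms <- list()
  for (l in hdr[startsWith(hdr, "#chrom=")]) {
    toks <- strsplit(sub("^#chrom=", "", l), " length=")[[1]]
    chroms[[toks[1]]] <- list(het = numeric(0), length = as.numeric(toks[2]),
                              mask = iv_empty())
  }
  for (l in hdr[startsWith(hdr, "#mask=")]) {
    toks <- strsplit(sub("^#mask=", "", l), " ")[[1]]
    prs <- do.call(rbind, strsplit(strsplit(toks[2], ",")[[1]], ":"))
    chroms[[toks[1]]]$mask <- iv(as.numeric(prs[, 1]), as.numeric(prs[, 2]))
  }
  body <- lines[!startsWith(lines, "#")][-1]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t")
    cc <- vapply(parts, `[`, "", 1)
    pp <- as.numeric(vapply(parts, `[`, "", 2))
    for (nm in unique(cc)) chroms[[nm]]$het <- pp[cc == nm]
  }
  het_profile(sample, chroms)
}
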