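# Reading real inputs: diploid VCFs with PL genotype likelihoods, BED masks,
# and per-site depth tracks.  All coordinates are converted to the internal
# 0-based convention on read (VCF POS is 1-based; BED already matches).

#' Read a BED mask
#'
#' @param path BED file (first three columns used).
#' @return named list of interval matrices, one per contig.
#' @export
read_bed_mask <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- list()
    for (nm in as.character(unique(GenomicRanges::seqnames(gr)))) {
      g <- gr[GenomicRanges::seqnames(gr) == nm]
      out[[nm]] <- iv_merge(iv(BiocGenerics::start(g) - 1, BiocGenerics::end(g)))
    }
    return(out)
  }
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  split_iv <- split(seq_len(nrow(tab)), tab[, 1])
  lapply(split_iv, function(i) iv_merge(iv(tab[i, 2], tab[i, 3])))
}

#' Build heterozygosity profiles from VCFs and masks
#'
#' Applies the full filtering chain to one VCF per genome: the union of
#' external BED masks, a genome-specific coverage mask (central mass of the
#' per-site depth distribution, from the VCF `DP` format field when per-site
#' depths are not supplied), and the PL quality band from [call_genotype()];
#' the union is dilated by the configured radius and heterozygous calls are
#' retained only at unmasked sites.  Multi-allelic records are masked: the
#' method models biallelic heterozygosity only.
#'
#' @param vcf_paths named character vector of VCF paths (names = sample ids).
#' @param chrom_lengths named numeric vector of contig lengths.
#' @param mask_paths character vector of BED mask files applied to every
#'   genome (tandem-repeat, alignability, ...).
#' @param config a [filter_config()].
#' @param depths optional list (per sample) of lists (per contig) of per-site
#'   depth vectors; when absent, the DP field of the VCF is used for the
#'   coverage mask at covered sites only.
#' @return list of [het_profile()] objects.
#' @export
read_profiles <- function(vcf_paths, chrom_lengths, mask_paths = character(0),
                          config = filter_config(), depths = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the vcfR package")
  ext_masks <- lapply(mask_paths, read_bed_mask)
  bad_contigs <- unique(unlist(lapply(ext_masks, function(m)
    setdiff(names(m), names(chrom_lengths)))))
  if (length(bad_contigs) > 0)
    stop("mask contigs absent from chrom_lengths: ",
         paste(bad_contigs, collapse = ", "))

  out <- list()
  for (si in seq_along(vcf_paths)) {
    sample <- names(vcf_paths)[si]
    v <- vcfR::read.vcfR(vcf_paths[[si]], verbose = FALSE)
    chrom <- vcfR::getCHROM(v)
    unknown <- setdiff(unique(chrom), names(chrom_lengths))
    if (length(unknown) > 0)
      stop("VCF contigs absent from chrom_lengths: ",
           paste(unknown, collapse = ", "))
    pos0 <- vcfR::getPOS(v) - 1
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    pl <- vcfR::extract.gt(v, element = "PL")[, 1]
    plm <- t(vapply(strsplit(pl, ","), function(x) {
      x <- suppressWarnings(as.numeric(x))
      if (length(x) < 3 || anyNA(x)) c(NA_real_, NA_real_)
      else c(x[2], min(x[1], x[3]))
    }, numeric(2)))
    dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1]))

    chroms <- list()
    for (nm in unique(chrom)) {
      sel <- chrom == nm
      p <- pos0[sel]
      call <- call_genotype(plm[sel, 1], plm[sel, 2], config)
      call[multi[sel]] <- "MASKED"
      qmask <- if (any(call == "MASKED"))
        iv(p[call == "MASKED"], p[call == "MASKED"] + 1) else iv_empty()
      cmask <- if (!is.null(depths)) {
        build_coverage_mask(depths[[sample]][[nm]], config)
      } else if (!all(is.na(dp[sel]))) {
        # mask VCF sites whose own depth is outside the genome's central band
        d <- dp[sel]
        ok <- !is.na(d)
        srt <- sort(d[ok]); n <- length(srt)
        tm <- (1 - config$coverage_central_mass) / 2
        lo <- srt[max(1, ceiling(tm * n))]
        hi <- srt[min(n, ceiling((1 - tm) * n))]
        bad <- ok & (d < lo | d > hi)
        if (any(bad)) iv(p[bad], p[bad] + 1) else iv_empty()
      } else iv_empty()
      ext <- lapply(ext_masks, function(m) if (!is.null(m[[nm]])) m[[nm]] else iv_empty())
      mask <- dilate_mask(do.call(iv_union, c(list(qmask, cmask), ext)),
                          config$dilation_radius)
      hets <- p[call == "HET"]
      hets <- hets[!iv_covers(mask, hets)]
      chroms[[nm]] <- list(het = hets, mask = mask,
                           length = chrom_lengths[[nm]])
    }
    out[[sample]] <- het_profile(sample, chroms)
  }
  out
}
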