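# Interval utilities.  Throughout the package genomic intervals are 0-based,
# half-open [start, end) -- the BED convention -- and are represented as
# two-column numeric matrices.  The arithmetic itself is delegated to
# IRanges; these helpers only shift between the two coordinate conventions.

iv <- function(start = numeric(0), end = numeric(0)) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (any(m[, 2] < m[, 1])) stop("interval end before start")
  m
}

iv_empty <- function() iv()

# 0-based half-open -> IRanges (1-based closed)
.iv_to_ir <- function(m) {
  keep <- m[, 2] > m[, 1]
  IRanges::IRanges(start = m[keep, 1] + 1, end = m[keep, 2])
}

.ir_to_iv <- function(ir) {
  if (length(ir) == 0) return(iv_empty())
  iv(IRanges::start(ir) - 1, IRanges::end(ir))
}

iv_merge <- function(m) .ir_to_iv(IRanges::reduce(.iv_to_ir(m)))

iv_union <- function(...) {
  ms <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(ms) == 0) return(iv_empty())
  iv_merge(do.call(rbind, ms))
}

iv_width <- function(m) if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])

#' Dilate a mask by a fixed radius
#'
#' Every position within `radius` bases of a masked base becomes masked, and
#' touching intervals are merged.  Used to remove the immediate neighbourhood
#' of filtered bases, where alignment artefacts cluster.
#'
#' @param mask two-column matrix of 0-based half-open intervals.
#' @param radius non-negative integer dilation radius in bases.
#' @return merged mask matrix in the same convention.
#' @examples
#' dilate_mask(cbind(10, 11), 2)  # positions 8..12
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(radius >= 0)
  if (nrow(mask) == 0) return(iv_empty())
  iv_merge(iv(pmax(mask[, 1] - radius, 0), mask[, 2] + radius))
}

# total masked width within [a, b); vectorised over query intervals
iv_overlap_width <- function(mask, a, b) {
  if (nrow(mask) == 0 || all(b <= a)) return(numeric(length(a)))
  ir <- .iv_to_ir(mask)
  q <- IRanges::IRanges(start = a + 1, end = pmax(b, a))  # b <= a: width 0
  hits <- IRanges::findOverlaps(q, ir)
  w <- numeric(length(a))
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(IRanges::end(ir)[sh], IRanges::end(q)[qh]) -
      pmax(IRanges::start(ir)[sh], IRanges::start(q)[qh]) + 1
    w <- as.numeric(tapply(ov, factor(qh, levels = seq_along(a)), sum,
                           default = 0))
    w[is.na(w)] <- 0
  }
  w
}

# is each (0-based) position masked?
iv_covers <- function(mask, pos) {
  if (nrow(mask) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  ir <- .iv_to_ir(mask)
  IRanges::overlapsAny(IRanges::IRanges(start = pos + 1, width = 1), ir)
}
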