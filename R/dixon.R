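#' Two-point Dixon water-fat decomposition
#'
#' From an in-phase / out-of-phase image pair, the water-only signal is
#' `S_w = (IP + OP) / 2` and the fat-only signal `S_f = IP - S_w`; the fat
#' signal fraction is `S_f / (S_f + S_w)`. Negative `S_w` or `S_f` (noise
#' can drive OP above IP) are clamped to 0. Voxels whose denominator falls
#' below `eps` (default `1e-6` times the 99th-percentile in-phase
#' intensity) get fat fraction 0 and are flagged; flagged voxels are
#' excluded from ROI means downstream.
#'
#' @param inPhase,outPhase [ImageVolume-class] on a common grid.
#' @param eps denominator guard; `NULL` for the intensity-scaled default.
#' @return a [FatWaterMaps-class].
#' @examples
#' ip <- ImageVolume(array(2, c(2, 2, 1)))
#' op <- ImageVolume(array(0, c(2, 2, 1)))
#' imgData(dixonDecompose(ip, op)@fatFraction)[1]  # 0.5
#' @export
dixonDecompose <- function(inPhase, outPhase, eps = NULL) {
  ip <- imgData(inPhase)
  op <- imgData(outPhase)
  if (!identical(dim(ip), dim(op)) ||
      any(abs(voxelSpacing(inPhase) - voxelSpacing(outPhase)) > 1e-9))
    stop("in-phase and out-of-phase images must share one grid")
  if (is.null(eps))
    eps <- 1e-6 * stats::quantile(ip, 0.99, names = FALSE)
  w <- (ip + op) / 2
  f <- ip - w
  w[w < 0] <- 0
  f[f < 0] <- 0
  den <- f + w
  flagged <- !(den > eps)
  ff <- array(0, dim(ip))
  ff[!flagged] <- f[!flagged] / den[!flagged]
  ff[ff > 1] <- 1
  sp <- voxelSpacing(inPhase)
  org <- imgOrigin(inPhase)
  new("FatWaterMaps",
      water = ImageVolume(w, sp, org), fat = ImageVolume(f, sp, org),
      fatFraction = ImageVolume(ff, sp, org), flagged = flagged)
}

#' Fraction of masked voxels above a fat-fraction threshold
#'
#' @param fatFraction fat-fraction [ImageVolume-class] (or the
#'   [FatWaterMaps-class] holding one).
#' @param mask label [ImageVolume-class] on the same grid (resample
#'   first); voxels with label > 0 count.
#' @param threshold fat-fraction cutoff (default 0.45).
#' @return proportion in `[0, 1]` of masked voxels with fat fraction
#'   strictly above the threshold.
#' @export
fractionAbove <- function(fatFraction, mask, threshold = 0.45) {
  if (is(fatFraction, "FatWaterMaps")) fatFraction <- fatFraction@fatFraction
  ff <- imgData(fatFraction)
  mk <- imgData(mask)
  if (!identical(dim(ff), dim(mk)))
    stop("mask must be on the fat-fraction grid; resample it first")
  inside <- mk > 0
  n <- sum(inside)
  if (n == 0) stop("mask is empty; the fraction is undefined")
  sum(ff[inside] > threshold) / n
}
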