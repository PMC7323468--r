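#' Assign labeled voxels to vertebral-level slabs
#'
#' Each voxel is assigned by its axial world coordinate to one of six
#' half-open slabs `[lower, upper)` delimited by seven strictly increasing
#' boundary coordinates (the midplanes between adjacent vertebrae plus the
#' closing S1-bottom and L1-top edges); the L1 top edge is inclusive so no
#' voxel on the superior face is lost. Slabs are named S1 (bottom) through
#' L1 (top).
#'
#' @param mask label [ImageVolume-class].
#' @param edges numeric length 7, strictly increasing world z (mm).
#' @return [ImageVolume-class] of integer level codes: 0 outside the mask
#'   or outside the slabs, otherwise 1..6 meaning L1..S1 (attribute
#'   `levels` gives the names).
#' @export
sliceLevels <- function(mask, edges) {
  if (length(edges) != 7L || any(diff(edges) <= 0))
    stop("edges must be 7 strictly increasing axial coordinates")
  mk <- imgData(mask)
  d <- dim(mk)
  zc <- axisCoords(mask, 3)
  slab <- findInterval(zc, edges, rightmost.closed = TRUE)
  slab[slab < 1L | slab > 6L] <- NA_integer_
  lvl <- 7L - slab                      # slab 6 (top) -> level 1 (L1)
  out <- array(0L, d)
  planes <- rep(lvl, each = prod(d[1:2]))
  inside <- mk > 0 & !is.na(planes)
  out[inside] <- planes[inside]
  res <- ImageVolume(out, voxelSpacing(mask), imgOrigin(mask))
  attr(res@data, "levels") <- LEVELS
  res
}

#' Resample a label mask onto another grid
#'
#' Nearest-neighbor assignment at the target voxel centers: labels are
#' preserved exactly and no interpolation-created labels can appear.
#' Matches the behavior of conventional nearest-neighbor resamplers used
#' to carry anatomical masks onto coarser quantitative grids.
#'
#' @param mask label [ImageVolume-class].
#' @param target an object carrying the destination grid
#'   ([ImageVolume-class], [DwiSeries-class] or [TensorField-class]).
#' @return label [ImageVolume-class] on the target grid.
#' @export
resampleMask <- function(mask, target) {
  out <- resampleVolume(mask, target, method = "nearest", fill = 0)
  storage.mode(out@data) <- storage.mode(imgData(mask))
  if (all(out@data == 0) && any(imgData(mask) != 0))
    stop("fields of view are disjoint: no mask voxel maps into the target grid")
  out
}

#' Aggregate maps into a per-subject level table
#'
#' Produces one record per muscle and vertebral level: `volume_ml` from
#' the anatomical-grid voxel count times voxel volume, and the mean of
#' each supplied scalar map over the valid masked voxels on that map's
#' native grid (the anatomical mask is resampled to each map's grid with
#' [resampleMask()]; metrics are never interpolated to a common grid).
#' Empty ROIs yield NA and are flagged in the `missing` column rather
#' than silently zeroed.
#'
#' @param subject subject identifier for the records.
#' @param labels anatomical label [ImageVolume-class] (1 = multifidus,
#'   2 = erector spinae).
#' @param edges the seven level slab edges (world z, mm).
#' @param fatWater optional [FatWaterMaps-class]; flagged voxels are
#'   excluded from the mean.
#' @param diffusion optional [DiffusionMaps-class]; NA (invalid) voxels
#'   are excluded.
#' @return data.frame with columns subject, muscle, level, volume_ml,
#'   fat_fraction, fa, md, rd, lambda1..3, missing.
#' @export
aggregateLevels <- function(subject, labels, edges, fatWater = NULL,
                            diffusion = NULL) {
  lvlAnat <- imgData(sliceLevels(labels, edges))
  lab <- imgData(labels)
  voxVol <- prod(voxelSpacing(labels))
  out <- expand.grid(muscle = MUSCLES, level = LEVELS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(subject = subject, out)
  sel <- which(lab > 0L & lvlAnat > 0L)
  counts <- tabulate((lab[sel] - 1L) * 6L + lvlAnat[sel], nbins = 12L)
  m_ <- match(out$muscle, MUSCLES)
  l_ <- match(out$level, LEVELS)
  out$volume_ml <- counts[(m_ - 1L) * 6L + l_] * voxVol / 1000
  roiMean <- function(map, maskGrid, lvlGrid, exclude = NULL) {
    vals <- imgData(map)
    res <- rep(NA_real_, nrow(out))
    for (r in seq_len(nrow(out))) {
      m <- match(out$muscle[r], MUSCLES)
      l <- match(out$level[r], LEVELS)
      inside <- maskGrid == m & lvlGrid == l
      if (!is.null(exclude)) inside <- inside & !exclude
      v <- vals[inside]
      v <- v[is.finite(v)]
      res[r] <- if (length(v)) mean(v) else NA_real_
    }
    res
  }
  if (!is.null(fatWater)) {
    ffMap <- fatWater@fatFraction
    mkD <- resampleMask(labels, ffMap)
    lvlD <- imgData(sliceLevels(mkD, edges))
    out$fat_fraction <- roiMean(ffMap, imgData(mkD), lvlD,
                                exclude = fatWater@flagged)
  } else out$fat_fraction <- NA_real_
  if (!is.null(diffusion)) {
    mkT <- resampleMask(labels, diffusion@fa)
    lvlT <- imgData(sliceLevels(mkT, edges))
    mg <- imgData(mkT)
    for (nm in c("fa", "md", "rd", "lambda1", "lambda2", "lambda3"))
      out[[nm]] <- roiMean(slot(diffusion, nm), mg, lvlT)
  } else out[c("fa", "md", "rd", "lambda1", "lambda2", "lambda3")] <- NA_real_
  out$missing <- out$volume_ml == 0 |
    (!is.null(fatWater) & !is.finite(out$fat_fraction)) |
    (!is.null(diffusion) & !is.finite(out$fa))
  out
}
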