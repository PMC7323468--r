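#' Tractography configuration
#'
#' @param angle_threshold_deg termination criterion: the streamline stops
#'   before any turn between successive steps exceeding this angle
#'   (default 15 degrees).
#' @param step_mm integration step (default 0.75 mm, half the DWI
#'   in-plane voxel).
#' @param min_length_mm tracks shorter than this are discarded
#'   (default 10 mm).
#' @param seeds_per_voxel seeds per mask voxel; additional seeds are
#'   jittered uniformly within the voxel under the supplied rng seed.
#' @param fa_floor tracking stops where FA of the interpolated tensor
#'   falls below this value (default 0.1).
#' @param max_seeds optional cap on the number of seed voxels (evenly
#'   subsampled, deterministic); NULL seeds every mask voxel.
#' @return validated list of settings.
#' @export
tractographyConfig <- function(angle_threshold_deg = 15, step_mm = 0.75,
                               min_length_mm = 10, seeds_per_voxel = 1L,
                               fa_floor = 0.1, max_seeds = NULL) {
  stopifnot(angle_threshold_deg > 0, angle_threshold_deg < 90,
            step_mm > 0, min_length_mm >= 0, seeds_per_voxel >= 1)
  list(angle_threshold_deg = as.numeric(angle_threshold_deg),
       step_mm = as.numeric(step_mm),
       min_length_mm = as.numeric(min_length_mm),
       seeds_per_voxel = as.integer(seeds_per_voxel),
       fa_floor = as.numeric(fa_floor),
       max_seeds = if (is.null(max_seeds)) NULL else as.integer(max_seeds))
}

#' Deterministic interpolated-streamline tractography
#'
#' Integrates streamlines bidirectionally from every seed along the
#' principal eigenvector of the trilinearly interpolated tensor field with
#' a fixed step. At each step the eigenvector sign is aligned with the
#' previous direction (the per-voxel sign is arbitrary and must not cause
#' doubling back). A streamline terminates when it leaves the mask, when
#' the turn between successive steps would exceed the angular threshold,
#' or when FA at the interpolated position falls below the FA floor.
#' Tracks shorter than the minimum length are discarded.
#'
#' @param field a [TensorField-class].
#' @param mask label [ImageVolume-class] (or logical/integer array) on the
#'   field grid; tracking is confined to mask voxels.
#' @param config settings from [tractographyConfig()].
#' @param refAxis unit vector the per-track pennation angle refers to
#'   (default superior-inferior, `c(0, 0, 1)`).
#' @param seed rng seed for seed jitter (used only when
#'   `seeds_per_voxel > 1`).
#' @return a [StreamlineSet-class]; empty (with a warning) for an empty
#'   mask.
#' @export
trackStreamlines <- function(field, mask, config = tractographyConfig(),
                             refAxis = c(0, 0, 1), seed = 0L) {
  stopifnot(is(field, "TensorField"))
  d <- dim(field@tensors)[1:3]
  mk <- if (is(mask, "ImageVolume")) imgData(mask) else mask
  if (!identical(dim(mk), d)) stop("mask must be on the tensor-field grid")
  mk <- mk > 0 & field@valid
  refAxis <- refAxis / sqrt(sum(refAxis^2))
  empty <- new("StreamlineSet", tracks = list(), lengthMm = numeric(),
               meanDirection = matrix(0, 0, 3), pennationDeg = numeric(),
               refAxis = refAxis, stepMm = config$step_mm)
  voxIdx <- which(mk)
  if (!length(voxIdx)) {
    warning("mask is empty; returning an empty streamline set")
    return(empty)
  }
  if (any(!is.finite(field@tensors[as.vector(outer(which(field@valid),
                                                   (0:5) * prod(d), "+"))])))
    stop("tensor field contains non-finite values")
  if (!is.null(config$max_seeds) && length(voxIdx) > config$max_seeds)
    voxIdx <- voxIdx[round(seq(1, length(voxIdx),
                               length.out = config$max_seeds))]
  ijk <- arrayInd(voxIdx, d) - 1L
  seeds <- voxelToWorld(field, ijk)
  if (config$seeds_per_voxel > 1L) {
    extra <- do.call(rbind, withSeed(seed, lapply(
      seq_len(config$seeds_per_voxel - 1L), function(i)
        seeds + sweep(matrix(stats::runif(length(voxIdx) * 3, -0.5, 0.5),
                             ncol = 3), 2, field@spacing, "*"))))
    seeds <- rbind(seeds, extra)
  }
  cosThr <- cos(config$angle_threshold_deg * pi / 180)
  halves <- integrateStreamlines(field, mk, seeds, config, cosThr)
  tracks <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    fw <- halves$fwd[[i]]
    bw <- halves$bwd[[i]]
    # backward half reversed, seed point shared
    pts <- rbind(bw[rev(seq_len(nrow(bw))), , drop = FALSE],
                 fw[-1, , drop = FALSE])
    tracks[[i]] <- pts
  }
  len <- vapply(tracks, function(p)
    if (nrow(p) < 2) 0 else sum(sqrt(rowSums(diff(p)^2))), numeric(1))
  keep <- len >= config$min_length_mm & vapply(tracks, nrow, 1L) >= 2L
  if (!any(keep)) return(empty)
  tracks <- tracks[keep]
  len <- len[keep]
  mdir <- t(vapply(tracks, function(p) {
    steps <- diff(p)
    u <- steps / sqrt(rowSums(steps^2))
    # align all step directions into one hemisphere before averaging
    s <- sign(u %*% u[1, ])
    s[s == 0] <- 1
    v <- colSums(u * as.vector(s))
    v / sqrt(sum(v^2))
  }, numeric(3)))
  flip <- as.vector(mdir %*% refAxis) < 0
  mdir[flip, ] <- -mdir[flip, , drop = FALSE]
  penn <- acos(pmin(pmax(mdir %*% refAxis, -1), 1)) * 180 / pi
  new("StreamlineSet", tracks = tracks, lengthMm = len,
      meanDirection = mdir, pennationDeg = as.vector(penn),
      refAxis = refAxis, stepMm = config$step_mm)
}

# Vectorized bidirectional Euler integration: all active streamlines are
# advanced together; per iteration one batched trilinear interpolation of
# the six tensor components.
integrateStreamlines <- function(field, mk, seeds, config, cosThr) {
  n <- nrow(seeds)
  d <- dim(field@tensors)[1:3]
  step <- config$step_mm
  maxSteps <- ceiling(4000 / step) # generous hard cap against cycles
  interpDir <- function(pts) {
    V6 <- vapply(1:6, function(k)
      sampleVolume(field@tensors[, , , k], field@spacing, field@origin,
                   pts, method = "trilinear"), numeric(nrow(pts)))
    V6 <- matrix(V6, ncol = 6)
    ev <- symEigenValues3(V6)
    evc <- ev
    evc[evc < 0] <- 0
    md <- rowMeans(evc)
    den <- rowSums(evc^2)
    fa <- ifelse(den > 0,
                 sqrt(1.5) * sqrt(((evc[, 1] - md)^2 + (evc[, 2] - md)^2 +
                                     (evc[, 3] - md)^2) / den), 0)
    list(v = symEigenVector3(V6, ev), fa = fa)
  }
  inMask <- function(pts) {
    sampleVolume(mk * 1, field@spacing, field@origin, pts,
                 method = "nearest", fill = 0) > 0
  }
  runDir <- function(sgn) {
    paths <- lapply(seq_len(n), function(i) seeds[i, , drop = FALSE])
    active <- inMask(seeds)
    pos <- seeds
    first <- interpDir(seeds)
    dir <- first$v * sgn
    active <- active & first$fa >= config$fa_floor &
      rowSums(dir^2) > 0.5
    it <- 0L
    while (any(active) && it < maxSteps) {
      it <- it + 1L
      idx <- which(active)
      nxt <- pos[idx, , drop = FALSE] + step * dir[idx, , drop = FALSE]
      ok <- inMask(nxt)
      intp <- interpDir(nxt)
      v <- intp$v
      # sign-align with the incoming direction
      dots <- rowSums(v * dir[idx, , drop = FALSE])
      v[dots < 0, ] <- -v[dots < 0, , drop = FALSE]
      dots <- abs(dots)
      ok <- ok & intp$fa >= config$fa_floor & dots >= cosThr &
        rowSums(v^2) > 0.5 & rowSums(is.finite(nxt)) == 3
      goodIdx <- idx[ok]
      if (length(goodIdx)) {
        for (jj in seq_along(goodIdx)) {
          i <- goodIdx[jj]
          paths[[i]] <- rbind(paths[[i]], nxt[ok, , drop = FALSE][jj, ])
        }
        pos[goodIdx, ] <- nxt[ok, , drop = FALSE]
        dir[goodIdx, ] <- v[ok, , drop = FALSE]
      }
      active[idx[!ok]] <- FALSE
    }
    paths
  }
  list(fwd = runDir(1), bwd = runDir(-1))
}
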