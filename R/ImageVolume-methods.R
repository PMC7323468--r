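#' Construct an ImageVolume
#'
#' @param data 3D array (numeric, integer or logical).
#' @param spacing voxel edge lengths in mm (length 3).
#' @param origin world coordinate (mm) of the center of voxel (0, 0, 0).
#' @return an [ImageVolume-class].
#' @examples
#' v <- ImageVolume(array(0, c(4, 4, 2)), spacing = c(1, 1, 3))
#' dim(v)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(data)) storage.mode(data) <- "integer"
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname imgData
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @rdname imgData
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname imgData
#' @export
setMethod("imgOrigin", "ImageVolume", function(x) x@origin)

#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x "),
              paste(format(object@origin, trim = TRUE), collapse = ", ")))
  rng <- suppressWarnings(range(object@data, na.rm = TRUE))
  if (all(is.finite(rng)))
    cat(sprintf("  intensity range [%g, %g]\n", rng[1], rng[2]))
})

#' @rdname imgData
#' @export
setMethod("imgData", "DwiSeries", function(x) x@data)

#' @rdname imgData
#' @export
setMethod("voxelSpacing", "DwiSeries", function(x) x@spacing)

#' @rdname imgData
#' @export
setMethod("imgOrigin", "DwiSeries", function(x) x@origin)

setMethod("show", "DwiSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DwiSeries %d x %d x %d, %d volumes (%d b=0, %d diffusion-weighted)\n",
    d[1], d[2], d[3], d[4], sum(object@bvals == 0), sum(object@bvals > 0)))
  cat(sprintf("  b-values: %s s/mm^2; spacing %s mm\n",
              paste(unique(object@bvals), collapse = ", "),
              paste(format(object@spacing, trim = TRUE), collapse = " x ")))
})

#' @rdname imgData
#' @export
setMethod("imgData", "TensorField", function(x) x@tensors)

#' @rdname imgData
#' @export
setMethod("voxelSpacing", "TensorField", function(x) x@spacing)

#' @rdname imgData
#' @export
setMethod("imgOrigin", "TensorField", function(x) x@origin)

#' @rdname validMask
#' @export
setMethod("validMask", "TensorField", function(x) x@valid)

setMethod("show", "TensorField", function(object) {
  d <- dim(object@tensors)
  cat(sprintf("TensorField %d x %d x %d (%d valid voxels)\n",
              d[1], d[2], d[3], sum(object@valid)))
})

#' @rdname streamlines
#' @export
setMethod("streamlines", "StreamlineSet", function(x) x@tracks)

#' @rdname streamlines
#' @export
setMethod("trackLengths", "StreamlineSet", function(x) x@lengthMm)

#' @rdname streamlines
#' @export
setMethod("pennationAngles", "StreamlineSet", function(x) x@pennationDeg)

#' @export
setMethod("length", "StreamlineSet", function(x) length(x@tracks))

setMethod("show", "StreamlineSet", function(object) {
  n <- length(object@tracks)
  cat(sprintf("StreamlineSet with %d tracks\n", n))
  if (n) {
    cat(sprintf("  length: %.1f-%.1f mm (median %.1f)\n",
                min(object@lengthMm), max(object@lengthMm),
                stats::median(object@lengthMm)))
    cat(sprintf("  pennation vs (%s): median %.1f deg\n",
                paste(format(object@refAxis, digits = 3), collapse = ", "),
                stats::median(object@pennationDeg)))
  }
})

#' @rdname anovaEffects
#' @export
setMethod("anovaEffects", "AnovaResult", function(x) x@effects)

#' @rdname anovaEffects
#' @export
setMethod("anovaPosthoc", "AnovaResult", function(x) x@posthoc)

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("Two-way repeated-measures ANOVA of '%s' (n = %d subjects",
              object@metric, object@nSubjects))
  if (object@nDropped > 0)
    cat(sprintf(", %d dropped for missing cells", object@nDropped))
  cat(")\n")
  if (object@correction != "none")
    cat(sprintf("  sphericity correction: %s\n", object@correction))
  ef <- object@effects
  for (i in seq_len(nrow(ef)))
    cat(sprintf("  %-14s F(%g, %g) = %8.3f, p = %.4g\n",
                ef$effect[i], ef$df1[i], ef$df2[i], ef$F[i], ef$p[i]))
  if (nrow(object@posthoc)) {
    sig <- object@posthoc$level[object@posthoc$significant]
    cat(sprintf("  Sidak post hoc (alpha = %g): significant at %s\n",
                object@alpha,
                if (length(sig)) paste(sig, collapse = ", ") else "no level"))
  }
})

# ---- world <-> voxel coordinate helpers -----------------------------------

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel coordinates are 0-based and continuous; integer values address
#' voxel centers.
#'
#' @param x an object with grid geometry ([ImageVolume-class],
#'   [DwiSeries-class] or [TensorField-class]).
#' @param pts n x 3 matrix (or length-3 vector) of coordinates.
#' @return n x 3 matrix of converted coordinates.
#' @export
worldToVoxel <- function(x, pts) {
  pts <- rbindPoints(pts)
  sweep(sweep(pts, 2, imgOrigin(x), "-"), 2, voxelSpacing(x), "/")
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(x, pts) {
  pts <- rbindPoints(pts)
  sweep(sweep(pts, 2, voxelSpacing(x), "*"), 2, imgOrigin(x), "+")
}

rbindPoints <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  pts
}

#' World coordinates of the voxel centers along one axis
#' @param x object with grid geometry.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of mm positions.
#' @export
axisCoords <- function(x, axis) {
  n <- if (is(x, "DwiSeries") || is(x, "TensorField"))
    dim(imgData(x))[axis] else dim(x)[axis]
  imgOrigin(x)[axis] + (seq_len(n) - 1) * voxelSpacing(x)[axis]
}

# Sample a 3D array at arbitrary world points.
# method "nearest" or "trilinear"; points outside the grid get `fill`.
sampleVolume <- function(arr, spacing, origin, ptsWorld,
                         method = c("trilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(arr)
  v <- sweep(sweep(rbindPoints(ptsWorld), 2, origin, "-"), 2, spacing, "/")
  lin <- function(ix, iy, iz) 1 + ix + d[1] * (iy + d[2] * iz)
  if (method == "nearest") {
    iv <- round(v)
    ok <- iv[, 1] >= 0 & iv[, 1] < d[1] & iv[, 2] >= 0 & iv[, 2] < d[2] &
      iv[, 3] >= 0 & iv[, 3] < d[3]
    out <- rep(fill, nrow(v))
    if (any(ok))
      out[ok] <- arr[lin(iv[ok, 1], iv[ok, 2], iv[ok, 3])]
    return(out)
  }
  i0 <- floor(v)
  f <- v - i0
  ok <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 & v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
    v[, 3] >= 0 & v[, 3] <= d[3] - 1
  out <- rep(fill, nrow(v))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  # clamp the upper corner for points exactly on the last plane
  i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(i0)), ncol = 3))
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    ix <- if (cx) i1[, 1] else i0[, 1]
    iy <- if (cy) i1[, 2] else i0[, 2]
    iz <- if (cz) i1[, 3] else i0[, 3]
    acc <- acc + w * arr[lin(ix, iy, iz)]
  }
  out[ok] <- acc
  out
}

# Full-grid resampling of a volume onto the grid of `target`, exploiting
# axis alignment (both grids share the world frame).
resampleVolume <- function(vol, target, method = c("trilinear", "nearest"),
                           fill = 0) {
  method <- match.arg(method)
  src <- imgData(vol)
  td <- if (is(target, "DwiSeries") || is(target, "TensorField"))
    dim(imgData(target))[1:3] else dim(target)
  if (method == "nearest") {
    # separable nearest-neighbor index mapping per axis
    maps <- lapply(1:3, function(a) {
      w <- imgOrigin(target)[a] + (seq_len(td[a]) - 1) * voxelSpacing(target)[a]
      i <- round((w - imgOrigin(vol)[a]) / voxelSpacing(vol)[a]) + 1
      list(idx = pmin(pmax(i, 1L), dim(src)[a]), ok = i >= 1 & i <= dim(src)[a])
    })
    out <- src[maps[[1]]$idx, maps[[2]]$idx, maps[[3]]$idx, drop = FALSE]
    if (!all(maps[[1]]$ok)) out[!maps[[1]]$ok, , ] <- fill
    if (!all(maps[[2]]$ok)) out[, !maps[[2]]$ok, ] <- fill
    if (!all(maps[[3]]$ok)) out[, , !maps[[3]]$ok] <- fill
  } else {
    pts <- as.matrix(expand.grid(
      x = axisCoords(target, 1), y = axisCoords(target, 2),
      z = axisCoords(target, 3)))
    out <- array(sampleVolume(src, voxelSpacing(vol), imgOrigin(vol), pts,
                              method = "trilinear", fill = fill), dim = td)
  }
  ImageVolume(out, spacing = voxelSpacing(target), origin = imgOrigin(target))
}
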