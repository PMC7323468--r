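#' Fit diffusion tensors by log-linear least squares
#'
#' Per masked voxel, solves `ln(S_i / S0) = -b g_i' D g_i` over the six
#' unique tensor elements, with design rows
#' `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)`. Multiple b = 0
#' volumes are averaged into `S0` before fitting. Voxels with any
#' non-positive signal are marked invalid. With ordinary least squares
#' (the default) the solution is a single precomputed pseudoinverse
#' applied to all voxels; `weighted = TRUE` uses per-voxel weights
#' proportional to the squared signal (slower).
#'
#' @param dwi a [DwiSeries-class] with at least one b = 0 volume and at
#'   least 6 non-collinear directions.
#' @param mask [ImageVolume-class] (or logical/integer array) on the DWI
#'   grid; voxels with value > 0 are fitted.
#' @param weighted use weighted least squares.
#' @return a [TensorField-class].
#' @export
fitTensor <- function(dwi, mask = NULL, weighted = FALSE) {
  stopifnot(is(dwi, "DwiSeries"))
  d <- dim(dwi@data)[1:3]
  mk <- if (is.null(mask)) array(TRUE, d) else {
    m <- if (is(mask, "ImageVolume")) imgData(mask) else mask
    if (!identical(dim(m), d))
      stop("mask must be on the DWI grid; resample it first")
    m > 0
  }
  b0 <- which(dwi@bvals == 0)
  dwv <- which(dwi@bvals > 0)
  if (!length(b0)) stop("at least one b = 0 volume is required")
  if (length(dwv) < 6L) stop("at least 6 diffusion-weighted volumes required")
  g <- dwi@bvecs[, dwv, drop = FALSE]
  b <- dwi@bvals[dwv]
  A <- cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
             2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ]) * b
  qrA <- qr(A)
  if (qrA$rank < 6L)
    stop("gradient direction set is rank deficient; tensor not identifiable")
  nvox <- prod(d)
  sel <- which(mk)
  get4d <- function(j) dwi@data[sel + (j - 1L) * nvox]
  s0 <- 0
  for (j in b0) s0 <- s0 + get4d(j)
  s0 <- s0 / length(b0)
  S <- matrix(vapply(dwv, get4d, numeric(length(sel))),
              nrow = length(sel))                   # nvox x ndir
  ok <- s0 > 0 & rowSums(S <= 0) == 0
  T6 <- array(0, c(d, 6L))
  valid <- array(FALSE, d)
  if (any(ok)) {
    Y <- -log(S[ok, , drop = FALSE] / s0[ok])       # nvox_ok x ndir
    if (!weighted) {
      P <- solve(crossprod(A), t(A))                # 6 x ndir
      Dv <- Y %*% t(P)                              # nvox_ok x 6
    } else {
      Dv <- matrix(0, sum(ok), 6L)
      W <- S[ok, , drop = FALSE]^2
      for (i in seq_len(sum(ok)))
        Dv[i, ] <- stats::lm.wfit(A, Y[i, ], W[i, ])$coefficients
    }
    fin <- rowSums(!is.finite(Dv)) == 0
    iok <- sel[ok][fin]
    for (k in 1:6) T6[iok + (k - 1L) * nvox] <- Dv[fin, k]
    valid[iok] <- TRUE
  }
  s0arr <- array(0, d)
  s0arr[sel] <- s0
  new("TensorField", tensors = T6, s0 = s0arr, valid = valid,
      spacing = dwi@spacing, origin = dwi@origin)
}

#' Eigenvalue metrics of a tensor field
#'
#' Eigenvalues are sorted descending and negatives clamped to 0 before the
#' metrics are formed: `MD = (l1 + l2 + l3) / 3`, `RD = (l2 + l3) / 2` and
#' `FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))`, defined as 0
#' when all eigenvalues vanish. FA is 0 for perfectly isotropic diffusion
#' and 1 when a single eigenvalue carries all diffusion. Invalid voxels
#' propagate as NA.
#'
#' @param field a [TensorField-class].
#' @return a [DiffusionMaps-class].
#' @examples
#' tf <- new("TensorField",
#'   tensors = array(c(1.5e-3, 1.5e-3, 1.5e-3, 0, 0, 0), c(1, 1, 1, 6)),
#'   s0 = array(1, c(1, 1, 1)), valid = array(TRUE, c(1, 1, 1)),
#'   spacing = c(1, 1, 1), origin = c(0, 0, 0))
#' imgData(eigenMetrics(tf)@fa)[1]  # 0: perfectly isotropic
#' @export
eigenMetrics <- function(field) {
  stopifnot(is(field, "TensorField"))
  d <- dim(field@tensors)[1:3]
  nvox <- prod(d)
  sel <- which(field@valid)
  mk <- function(vals) {
    a <- array(NA_real_, d)
    a[sel] <- vals
    ImageVolume(a, field@spacing, field@origin)
  }
  if (!length(sel)) {
    e <- array(NA_real_, d)
    v <- ImageVolume(e, field@spacing, field@origin)
    return(new("DiffusionMaps", md = v, rd = v, fa = v,
               lambda1 = v, lambda2 = v, lambda3 = v))
  }
  V6 <- matrix(field@tensors[as.vector(outer(sel, (0:5) * nvox, "+"))],
               ncol = 6)
  ev <- symEigenValues3(V6)
  ev[ev < 0] <- 0
  md <- rowMeans(ev)
  rd <- (ev[, 2] + ev[, 3]) / 2
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- rowSums(ev^2)
  fa <- ifelse(den > 0, sqrt(1.5) * sqrt(num / den), 0)
  new("DiffusionMaps", md = mk(md), rd = mk(rd), fa = mk(fa),
      lambda1 = mk(ev[, 1]), lambda2 = mk(ev[, 2]), lambda3 = mk(ev[, 3]))
}
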