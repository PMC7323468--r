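# Fat model constants: bulk and epimuscular-tail mixture components, and
# the fascial fat rim just outside each muscle contour.
FAT_TAIL_MEAN <- 0.70
FAT_TAIL_SD <- 0.08
FAT_BULK_SD <- 0.05
FAT_RIM_MEAN <- 0.75
FAT_RIM_SD <- 0.05

#' Assign the ground-truth fat-fraction field
#'
#' Within each muscle-by-level region, voxelwise fat fractions are drawn
#' from a two-component mixture: a bulk component centered so the region
#' mean equals the region's `fat_fraction_mean`, and a high-fat
#' (epimuscular) component with mean 0.70 and weight
#' `fat_fraction_tail_weight`, concentrated at the region boundary (the
#' outermost voxels by in-plane edge rank). Voxels in the fascial rim just
#' outside the muscles receive fat-like values around 0.75; all values are
#' clipped to `[0, 1]`.
#'
#' @param geom geometry list from [buildGeometry()].
#' @param config the [PhantomConfig-class].
#' @param subjectIndex subject number (seeds the draw).
#' @return [ImageVolume-class] of ground-truth fat fraction on the
#'   anatomical grid.
#' @export
assignFatField <- function(geom, config, subjectIndex = 1L) {
  lab <- imgData(geom$labels)
  tr <- geom$truth
  ff <- array(0, dim(lab))
  edges <- geom$levelEdges
  zc <- axisCoords(geom$labels, 3)
  slab <- findInterval(zc, edges, rightmost.closed = TRUE)
  slabArr <- array(rep(slab, each = prod(dim(lab)[1:2])), dim(lab))
  withSeed(subjectSeed(config, subjectIndex, "fat"), {
    nrim <- sum(geom$rim)
    if (nrim)
      ff[geom$rim] <- stats::rnorm(nrim, FAT_RIM_MEAN, FAT_RIM_SD)
    for (m in seq_along(MUSCLES)) {
      for (l in seq_along(LEVELS)) {
        row <- tr[tr$muscle == MUSCLES[m] & tr$level == LEVELS[l], ]
        sel <- which(lab == m & slabArr == 7L - l)
        if (!length(sel)) next
        w <- row$fat_fraction_tail_weight
        mu <- row$fat_fraction_mean
        if (mu == 0 && w == 0) {           # fat-free region, exactly
          ff[sel] <- 0
          next
        }
        bulkMean <- (mu - w * FAT_TAIL_MEAN) / (1 - w)
        if (bulkMean < 0)
          bulkMean <- 0 # tail alone exceeds the target mean; clip
        # exact tail count region-wide, taken from the outermost voxels
        nTail <- round(w * length(sel))
        tail <- logical(length(sel))
        if (nTail > 0)
          tail[order(geom$edgeRank[sel], decreasing = TRUE)[seq_len(nTail)]] <-
            TRUE
        ff[sel[tail]] <- stats::rnorm(sum(tail), FAT_TAIL_MEAN, FAT_TAIL_SD)
        ff[sel[!tail]] <- stats::rnorm(sum(!tail), bulkMean, FAT_BULK_SD)
      }
    }
  })
  ff[ff < 0] <- 0
  ff[ff > 1] <- 1
  ImageVolume(ff, spacing = voxelSpacing(geom$labels),
              origin = imgOrigin(geom$labels))
}

#' Assign the ground-truth diffusion tensor field
#'
#' Every labeled voxel receives `D = R diag(l3, l2, l1) R^T`, where `R`
#' rotates the z axis onto the region's fiber axis, so the principal
#' eigenvalue lies along the fiber direction. Background voxels are
#' invalid.
#'
#' @param labels [ImageVolume-class] of integer labels (any grid).
#' @param edges the seven level slab edges (world z, mm).
#' @param truth truth table with eigenvalues and fiber axes.
#' @param s0 reference non-diffusion-weighted signal stored with the field.
#' @return a [TensorField-class] on the label grid.
#' @export
assignTensorField <- function(labels, edges, truth, s0 = 100) {
  lab <- imgData(labels)
  d <- dim(lab)
  T6 <- array(0, c(d, 6L))
  valid <- array(FALSE, d)
  zc <- axisCoords(labels, 3)
  slab <- findInterval(zc, edges, rightmost.closed = TRUE)
  slabArr <- array(rep(slab, each = prod(d[1:2])), d)
  nvox <- prod(d)
  for (m in seq_along(MUSCLES)) {
    for (l in seq_along(LEVELS)) {
      row <- truth[truth$muscle == MUSCLES[m] & truth$level == LEVELS[l], ]
      sel <- which(lab == m & slabArr == 7L - l)
      if (!length(sel)) next
      ax <- c(row$axis_x, row$axis_y, row$axis_z)
      if (abs(sqrt(sum(ax^2)) - 1) > 1e-6)
        stop("fiber_axis must be a unit vector")
      D <- tensorFromAxis(c(row$lambda1, row$lambda2, row$lambda3), ax)
      comps <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
      for (k in 1:6) T6[sel + (k - 1L) * nvox] <- comps[k]
      valid[sel] <- TRUE
    }
  }
  new("TensorField", tensors = T6, s0 = array(s0, d), valid = valid,
      spacing = voxelSpacing(labels), origin = imgOrigin(labels))
}

# D = R diag(l3, l2, l1) R^T with R the minimal rotation taking +z onto
# `axis` (Rodrigues formula).
tensorFromAxis <- function(lambda, axis) {
  R <- rotationFromZ(axis)
  R %*% diag(c(lambda[3], lambda[2], lambda[1])) %*% t(R)
}

rotationFromZ <- function(axis) {
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c_ <- sum(z * axis)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # antiparallel: rotate pi about x
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Sample magnitude (Rician) image noise
#'
#' Returns `sign(x) * |(|x| + n1) + i n2|` with `n1, n2 ~ N(0, sigma)`:
#' magnitude noise on the modulus, with the sign of a phase-sensitive
#' reconstruction preserved (relevant for the signed out-of-phase Dixon
#' image).
#'
#' @param x noiseless signal (array or vector).
#' @param sigma Gaussian channel noise; 0 returns `x` unchanged.
#' @return same shape as `x`.
#' @export
riceNoise <- function(x, sigma) {
  if (sigma == 0) return(x)
  n <- length(x)
  s <- sign(x)
  s[s == 0] <- 1
  out <- s * sqrt((abs(x) + stats::rnorm(n, 0, sigma))^2 +
                    stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Simulate the Dixon in-phase / out-of-phase image pair
#'
#' The ground-truth fat fraction is resampled to the Dixon grid with
#' trilinear interpolation; the noiseless images are `IP = W + F` and
#' `OP = W - F` with `F = s0 * ff`, `W = s0 * (1 - ff)`. Rician noise with
#' `sigma = s0 / snr` is added to both (sign of OP preserved, see
#' [riceNoise()]). Inverting the noiseless pair through [dixonDecompose()]
#' returns the resampled truth exactly.
#'
#' @param truthFF ground-truth fat-fraction [ImageVolume-class].
#' @param spec Dixon acquisition geometry ([acquisitionSpec()]).
#' @param snr signal-to-noise ratio (`Inf` = noiseless).
#' @param s0 reference intensity.
#' @param seed integer seed for the noise draw (ignored when noiseless).
#' @return list with `inPhase`, `outPhase` ([ImageVolume-class]) and
#'   `ffOnGrid`, the resampled ground truth.
#' @export
simulateDixon <- function(truthFF, spec, snr = Inf, s0 = 100, seed = 0L) {
  if (snr <= 0) stop("snr must be > 0")
  target <- ImageVolume(array(0, spec$grid_shape),
                        spacing = spec$voxel_size_mm, origin = spec$origin_mm)
  ffg <- resampleVolume(truthFF, target, method = "trilinear")
  ff <- imgData(ffg)
  W <- s0 * (1 - ff)
  F_ <- s0 * ff
  ip <- W + F_
  op <- W - F_
  if (is.finite(snr)) {
    sigma <- s0 / snr
    withSeed(seed, {
      ip <- riceNoise(ip, sigma)
      op <- riceNoise(op, sigma)
    })
  }
  list(inPhase = ImageVolume(ip, spec$voxel_size_mm, spec$origin_mm),
       outPhase = ImageVolume(op, spec$voxel_size_mm, spec$origin_mm),
       ffOnGrid = ffg)
}

#' Deterministic electrostatic-repulsion gradient scheme
#'
#' Unit directions initialised on a Fibonacci hemisphere and relaxed by
#' fixed-step gradient descent on the antipodally symmetric Coulomb
#' energy. The construction is fully deterministic.
#'
#' @param n number of directions.
#' @param iterations relaxation sweeps.
#' @return 3 x n matrix of unit column vectors.
#' @export
gradientScheme <- function(n = 45L, iterations = 200L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n                      # hemisphere: z in (0, 1)
  r <- sqrt(pmax(1 - z^2, 0))
  P <- cbind(r * cos(phi), r * sin(phi), z)
  step <- 0.003
  for (it in seq_len(iterations)) {
    G <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      dif <- sweep(P[-k, , drop = FALSE], 2, P[k, ], "-")
      sum_ <- sweep(P[-k, , drop = FALSE], 2, P[k, ], "+")
      d1 <- rowSums(dif^2); d2 <- rowSums(sum_^2)
      rep1 <- -colSums(dif / (d1^1.5 + 1e-12))
      rep2 <- colSums(sum_ / (d2^1.5 + 1e-12))
      G[k, ] <- rep1 + rep2
    }
    P <- P + step * G
    P <- P / sqrt(rowSums(P^2))
  }
  P[P[, 3] < 0, ] <- -P[P[, 3] < 0, , drop = FALSE]
  t(P)
}

#' Simulate a diffusion-weighted series from a tensor field
#'
#' Emits one b = 0 volume plus `spec$n_directions` diffusion-weighted
#' volumes `S_i = s0 exp(-b g_i' D g_i)` using the deterministic
#' [gradientScheme()], with Rician noise of `sigma = s0 / snr`.
#'
#' @param field a [TensorField-class] on the DWI grid.
#' @param spec DWI acquisition geometry (provides `n_directions` and
#'   `b_value`).
#' @param snr signal-to-noise ratio (`Inf` = noiseless).
#' @param s0 reference b = 0 intensity.
#' @param seed integer seed for the noise draw.
#' @return a [DwiSeries-class].
#' @export
simulateDwi <- function(field, spec, snr = Inf, s0 = 100, seed = 0L) {
  if (snr <= 0) stop("snr must be > 0")
  d <- dim(field@tensors)[1:3]
  stopifnot(identical(as.integer(d), as.integer(spec$grid_shape)))
  ndir <- spec$n_directions
  b <- spec$b_value
  g <- gradientScheme(ndir)
  sel <- which(field@valid)
  V6 <- matrix(field@tensors[as.vector(outer(sel, (0:5) * prod(d),
                                             "+"))], ncol = 6)
  ev <- symEigenValues3(V6)
  if (any(ev[, 3] <= 0))
    stop("non-positive-definite tensor at a labeled voxel")
  # quadratic forms g' D g for all voxels x directions
  Gq <- rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
              2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ])
  atten <- exp(-b * (V6 %*% Gq))          # nvox x ndir
  out <- array(0, c(d, ndir + 1L))
  out[as.vector(sel)] <- s0               # b = 0 volume
  nvox <- prod(d)
  for (j in seq_len(ndir))
    out[sel + j * nvox] <- s0 * atten[, j]
  if (is.finite(snr)) {
    sigma <- s0 / snr
    withSeed(seed, out <- riceNoise(out, sigma))
  }
  new("DwiSeries", data = out, bvecs = cbind(c(0, 0, 0), g),
      bvals = c(0, rep(b, ndir)), spacing = field@spacing,
      origin = field@origin)
}

#' Simulate one complete synthetic subject
#'
#' Runs geometry construction, fat-field assignment, Dixon simulation and
#' (optionally) tensor-field assignment plus DWI simulation for one
#' subject of the configured study.
#'
#' @param config a [PhantomConfig-class].
#' @param subjectIndex subject number (1-based).
#' @param withDwi simulate the diffusion series (slower); when FALSE the
#'   `dwi` and `truthTensors` slots are NULL.
#' @return a [PhantomDataset-class].
#' @examples
#' \donttest{
#' cfg <- phantomConfig(nSubjects = 1, seed = 1)
#' ds <- simulateSubject(cfg, 1, withDwi = FALSE)
#' ds@truth[1:2, 1:4]
#' }
#' @export
simulateSubject <- function(config, subjectIndex = 1L, withDwi = TRUE) {
  geom <- buildGeometry(config, subjectIndex)
  truthFF <- assignFatField(geom, config, subjectIndex)
  dx <- simulateDixon(truthFF, config@dixon, snr = config@snr, s0 = config@s0,
                      seed = subjectSeed(config, subjectIndex, "dixon"))
  dwi <- NULL
  tens <- NULL
  if (withDwi) {
    target <- ImageVolume(array(0L, config@dwi$grid_shape),
                          spacing = config@dwi$voxel_size_mm,
                          origin = config@dwi$origin_mm)
    labDwi <- resampleMask(geom$labels, target)
    tens <- assignTensorField(labDwi, geom$levelEdges, geom$truth,
                              s0 = config@s0)
    dwi <- simulateDwi(tens, config@dwi, snr = config@snr, s0 = config@s0,
                       seed = subjectSeed(config, subjectIndex, "dwi"))
  }
  new("PhantomDataset", subject = as.integer(subjectIndex),
      labels = geom$labels, levelEdges = geom$levelEdges,
      inPhase = dx$inPhase, outPhase = dx$outPhase, truthFF = truthFF,
      dwi = dwi, truthTensors = tens, truth = geom$truth)
}

#' Write a phantom dataset to standard formats
#'
#' Volumes go to NIfTI-1 (`.nii.gz`), the gradient table to FSL-style
#' `bvecs`/`bvals` text files, and the level boundaries and truth table to
#' CSV. Re-reading the NIfTI files reproduces the arrays bit-exactly.
#'
#' @param dataset a [PhantomDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of file paths.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- c()
  wr <- function(vol, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    writeNiftiVolume(vol, p)
    paths[name] <<- p
    p
  }
  wr(dataset@labels, "labels")
  wr(dataset@inPhase, "dixon_ip")
  wr(dataset@outPhase, "dixon_op")
  wr(dataset@truthFF, "truth_ff")
  if (!is.null(dataset@dwi)) {
    dwi <- dataset@dwi
    p <- file.path(dir, "dwi.nii.gz")
    img <- RNifti::asNifti(dwi@data,
                           pixdim = c(dwi@spacing, 1))
    RNifti::writeNifti(img, p, datatype = "double")
    paths["dwi"] <- p
    paths["bvecs"] <- file.path(dir, "dwi.bvecs")
    writeLines(apply(dwi@bvecs, 1, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = " ")),
      paths["bvecs"])
    paths["bvals"] <- file.path(dir, "dwi.bvals")
    writeLines(paste(formatC(dwi@bvals, digits = 17, format = "g"),
                     collapse = " "), paths["bvals"])
  }
  paths["level_boundaries"] <- file.path(dir, "level_boundaries.csv")
  utils::write.csv(
    data.frame(edge = seq_along(dataset@levelEdges),
               z_mm = dataset@levelEdges),
    paths["level_boundaries"], row.names = FALSE)
  paths["truth"] <- file.path(dir, "truth.csv")
  utils::write.csv(dataset@truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

writeNiftiVolume <- function(vol, path) {
  img <- RNifti::asNifti(imgData(vol), pixdim = voxelSpacing(vol))
  RNifti::writeNifti(img, path, datatype = "double")
  path
}

#' Simulate measurement tables directly from a truth table
#'
#' A table-level shortcut used for statistical calibration: per subject and
#' muscle-by-level cell, each metric is the truth value times
#' `(1 + subject effect) * (1 + cell noise)` with Gaussian relative errors.
#' Under a flat truth table this realises the null hypothesis of the
#' repeated-measures design exactly.
#'
#' @param truth truth table (see [defaultTruthTable()]); columns
#'   `volume_ml` and `fat_fraction_mean` become metrics `volume_ml` and
#'   `fat_fraction`.
#' @param nSubjects number of subjects.
#' @param cv relative cell noise (coefficient of variation).
#' @param subjectCV relative between-subject offset common to all cells.
#' @param seed integer seed.
#' @return a level-table data.frame (subject, muscle, level, volume_ml,
#'   fat_fraction).
#' @export
simulateLevelTable <- function(truth, nSubjects = 10L, cv = 0.1,
                               subjectCV = 0.05, seed = 0L) {
  cells <- truth[, c("muscle", "level")]
  k <- nrow(cells)
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(nSubjects), function(s) {
      bs <- 1 + stats::rnorm(1, 0, subjectCV)
      data.frame(subject = s, muscle = cells$muscle, level = cells$level,
                 volume_ml = truth$volume_ml * bs *
                   (1 + stats::rnorm(k, 0, cv)),
                 fat_fraction = pmin(pmax(
                   truth$fat_fraction_mean * bs *
                     (1 + stats::rnorm(k, 0, cv)), 0), 1))
    }))
  })
  out
}
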