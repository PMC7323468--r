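#' Build the label geometry of one synthetic subject
#'
#' Constructs two tube-like muscle regions (medial multifidus, lateral
#' erector spinae), mirrored left/right, spanning six axial vertebral-level
#' slabs. Within each slab the per-muscle voxel count is matched exactly to
#' the (subject-perturbed) target volume by taking the nearest in-plane
#' voxels around each tube center, so level volumes are recovered to
#' rounding precision of a single voxel. An outer one-to-two-voxel rim of
#' epimuscular/fascial fat is marked around each muscle, and every labeled
#' voxel is annotated with its normalized in-plane edge rank (1 = outermost)
#' so the fat model can place its high-fat shell at the region boundary.
#'
#' @param config a [PhantomConfig-class].
#' @param subjectIndex subject number (1-based); determines the
#'   between-subject volume perturbation.
#' @return list with `labels` ([ImageVolume-class], 0 background,
#'   1 multifidus, 2 erector spinae), `levelEdges` (numeric 7), `edgeRank`
#'   (array, 0 outside labels), `rim` (logical array), `counts` (2 x 6
#'   matrix of per-region voxel counts) and `truth` (the subject-perturbed
#'   truth table).
#' @export
buildGeometry <- function(config, subjectIndex = 1L) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  spec <- config@anat
  d <- spec$grid_shape
  sp <- spec$voxel_size_mm
  org <- spec$origin_mm
  voxVol <- prod(sp)                     # mm^3
  tr <- subjectTruth(config, subjectIndex)
  edges <- levelEdges(config)
  zc <- org[3] + (seq_len(d[3]) - 1) * sp[3]

  labels <- array(0L, d)
  edgeRank <- array(0, d)
  rim <- array(FALSE, d)
  counts <- matrix(0L, 2, 6, dimnames = list(MUSCLES, LEVELS))

  xs <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  # In-plane orderings by anisotropic distance from each tube center, one
  # per muscle x side; identical for all slices of that muscle. The
  # multifidus cross-section is tall and narrow (it hugs the midline), the
  # erector spinae near-circular; the metric weights keep the ellipse area
  # equal to that of a circle of the same metric radius.
  aniso <- list(multifidus = c(0.60, 1 / 0.60),
                erector_spinae = c(0.95, 1 / 0.95))
  plane <- expand.grid(ix = seq_len(d[1]), iy = seq_len(d[2]))
  orderings <- list()
  for (m in seq_along(MUSCLES)) {
    cx <- config@centersMm[[MUSCLES[m]]]
    w <- aniso[[MUSCLES[m]]]
    for (side in c(-1, 1)) {
      d2 <- ((xs[plane$ix] - side * cx) / w[1])^2 + (ys[plane$iy] / w[2])^2
      o <- order(d2)
      orderings[[paste(m, side)]] <- list(ix = plane$ix[o], iy = plane$iy[o],
                                          dist = sqrt(d2[o]))
    }
  }
  rimTh <- 1.25 # mm

  for (m in seq_along(MUSCLES)) {
    for (l in seq_along(LEVELS)) {
      # level l (L1 first) occupies slab 7 - l counted from the bottom edge
      lo <- edges[7 - l]; hi <- edges[8 - l]
      slices <- which(zc >= lo & zc < hi)
      if (l == 1L) slices <- which(zc >= lo & zc <= hi) # L1 top inclusive
      if (!length(slices))
        stop("level ", LEVELS[l], " lies outside the anatomical field of view")
      row <- tr[tr$muscle == MUSCLES[m] & tr$level == LEVELS[l], ]
      N <- round(row$volume_ml * 1000 / voxVol)
      perSlice <- diff(round(seq(0, N, length.out = length(slices) + 1)))
      for (s in seq_along(slices)) {
        iz <- slices[s]
        n <- perSlice[s]
        if (n == 0) next
        nl <- (n + s %% 2) %/% 2
        for (side in c(-1, 1)) {
          k <- if (side < 0) nl else n - nl
          if (k == 0) next
          o <- orderings[[paste(m, side)]]
          # skip voxels already taken by another region (muscles pack
          # against each other); counts stay exact
          free <- labels[cbind(o$ix, o$iy, iz)] == 0L
          sel <- which(free)
          if (length(sel) < k)
            stop("target volume for ", MUSCLES[m], " ", LEVELS[l],
                 " is not representable within the field of view")
          sel <- sel[seq_len(k)]
          idx <- cbind(o$ix[sel], o$iy[sel], iz)
          if (any(idx[, 1] <= 2L | idx[, 1] >= d[1] - 1L |
                    idx[, 2] <= 2L | idx[, 2] >= d[2] - 1L))
            stop("region for ", MUSCLES[m], " ", LEVELS[l],
                 " would exceed the field of view")
          labels[idx] <- m
          edgeRank[idx] <- seq_len(k) / k
          # rim: next voxels out to rimTh beyond the region edge
          edge <- o$dist[sel[k]]
          beyond <- which(o$dist > edge & o$dist <= edge + rimTh)
          if (length(beyond))
            rim[cbind(o$ix[beyond], o$iy[beyond], iz)] <- TRUE
        }
      }
      counts[m, l] <- N
    }
  }
  rim[labels != 0L] <- FALSE
  list(labels = ImageVolume(labels, spacing = sp, origin = org),
       levelEdges = edges, edgeRank = edgeRank, rim = rim,
       counts = counts, truth = tr)
}
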