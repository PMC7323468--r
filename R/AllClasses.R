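#' @import methods
NULL

#' ImageVolume: a 3D scalar grid with world geometry
#'
#' Carrier for anatomical label volumes, Dixon images and derived scalar
#' maps. World coordinates follow a RAS-like frame with a voxel-center
#' convention: the center of voxel `(i, j, k)` (0-based) lies at
#' `origin + c(i, j, k) * spacing` (mm).
#'
#' @slot data 3D numeric (or integer/logical) array.
#' @slot spacing positive numeric length 3, voxel edge lengths in mm.
#' @slot origin numeric length 3, world position (mm) of the first voxel
#'   center.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0))
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' DwiSeries: a diffusion-weighted 4D stack with gradient table
#'
#' @slot data 4D array (x, y, z, volume); arbitrary signal units.
#' @slot bvecs 3 x n matrix of unit gradient directions (columns); the
#'   direction of b = 0 volumes is ignored.
#' @slot bvals numeric length n of b-values (s/mm^2).
#' @slot spacing,origin world geometry as for [ImageVolume-class].
#' @export
setClass("DwiSeries",
  representation(data = "array", bvecs = "matrix", bvals = "numeric",
                 spacing = "numeric", origin = "numeric")
)

setValidity("DwiSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array")
  n <- dim(object@data)[4L]
  if (length(object@bvals) != n)
    msg <- c(msg, "length(bvals) must equal the number of volumes")
  if (nrow(object@bvecs) != 3L || ncol(object@bvecs) != n)
    msg <- c(msg, "bvecs must be a 3 x n matrix")
  if (any(object@bvals < 0)) msg <- c(msg, "b-values must be >= 0")
  dw <- object@bvals > 0
  if (any(dw)) {
    nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "diffusion-weighted gradient directions must be unit vectors")
  }
  if (sum(dw) > 0 && sum(dw) < 6L)
    msg <- c(msg, "at least 6 diffusion-weighted directions are required")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' TensorField: per-voxel symmetric diffusion tensors
#'
#' Tensors are stored as a 4D array whose fourth dimension holds the six
#' unique elements in the order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), in mm^2/s.
#'
#' @slot tensors 4D array (x, y, z, 6).
#' @slot s0 3D array of non-diffusion-weighted signal (0 where unknown).
#' @slot valid 3D logical array; TRUE where a tensor is defined.
#' @slot spacing,origin world geometry.
#' @export
setClass("TensorField",
  representation(tensors = "array", s0 = "array", valid = "array",
                 spacing = "numeric", origin = "numeric")
)

setValidity("TensorField", function(object) {
  msg <- character()
  d <- dim(object@tensors)
  if (length(d) != 4L || d[4L] != 6L)
    msg <- c(msg, "tensors must be an (x, y, z, 6) array")
  if (!identical(dim(object@valid), d[1:3]))
    msg <- c(msg, "valid mask must match the spatial grid")
  if (!identical(dim(object@s0), d[1:3]))
    msg <- c(msg, "s0 must match the spatial grid")
  if (!is.logical(object@valid))
    msg <- c(msg, "valid must be a logical array")
  if (length(msg)) msg else TRUE
})

#' FatWaterMaps: outputs of the two-point Dixon decomposition
#'
#' @slot water,fat,fatFraction [ImageVolume-class] maps on the input grid;
#'   `fatFraction` lies in `[0, 1]`.
#' @slot flagged 3D logical array; TRUE where the denominator fell below
#'   the guard threshold and the fat fraction was set to 0. Flagged voxels
#'   are excluded from ROI means.
#' @export
setClass("FatWaterMaps",
  representation(water = "ImageVolume", fat = "ImageVolume",
                 fatFraction = "ImageVolume", flagged = "array")
)

setValidity("FatWaterMaps", function(object) {
  msg <- character()
  d <- dim(object@water@data)
  if (!identical(dim(object@fat@data), d) ||
      !identical(dim(object@fatFraction@data), d) ||
      !identical(dim(object@flagged), d))
    msg <- c(msg, "all maps must share one grid")
  ff <- object@fatFraction@data
  if (any(ff < -1e-12 | ff > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "fatFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DiffusionMaps: eigenvalue metrics of a tensor field
#'
#' Voxelwise mean diffusivity `MD = (l1+l2+l3)/3`, radial diffusivity
#' `RD = (l2+l3)/2`, fractional anisotropy `FA` in `[0, 1]`, and the sorted
#' eigenvalues `l1 >= l2 >= l3` (mm^2/s). Voxels without a valid tensor
#' are NA.
#'
#' @slot md,rd,fa,lambda1,lambda2,lambda3 [ImageVolume-class] maps.
#' @export
setClass("DiffusionMaps",
  representation(md = "ImageVolume", rd = "ImageVolume", fa = "ImageVolume",
                 lambda1 = "ImageVolume", lambda2 = "ImageVolume",
                 lambda3 = "ImageVolume")
)

#' StreamlineSet: deterministic streamline tractography output
#'
#' @slot tracks list of n x 3 matrices of ordered world coordinates (mm).
#' @slot lengthMm numeric polyline length per track.
#' @slot meanDirection n x 3 matrix of unit mean propagation directions,
#'   sign-aligned with the reference axis.
#' @slot pennationDeg angle (degrees) between each track's mean direction
#'   and the reference axis.
#' @slot refAxis unit 3-vector the pennation angles refer to.
#' @slot stepMm integration step used (mm).
#' @export
setClass("StreamlineSet",
  representation(tracks = "list", lengthMm = "numeric",
                 meanDirection = "matrix", pennationDeg = "numeric",
                 refAxis = "numeric", stepMm = "numeric")
)

setValidity("StreamlineSet", function(object) {
  n <- length(object@tracks)
  if (length(object@lengthMm) != n || length(object@pennationDeg) != n)
    return("per-track metadata must match the number of tracks")
  if (n && nrow(object@meanDirection) != n)
    return("meanDirection must have one row per track")
  TRUE
})

#' AnovaResult: repeated-measures ANOVA summary with post hoc comparisons
#'
#' @slot metric name of the analysed metric.
#' @slot effects data.frame with one row per effect (muscle, level,
#'   muscle:level): F, df1, df2, p.
#' @slot posthoc data.frame of per-level paired comparisons with Sidak
#'   adjustment (may have zero rows if not computed).
#' @slot alpha significance threshold used for flags.
#' @slot nSubjects number of subjects analysed (after dropping
#'   incomplete ones).
#' @slot nDropped number of subjects dropped for missing cells.
#' @slot correction "none" or "greenhouse-geisser".
#' @export
setClass("AnovaResult",
  representation(metric = "character", effects = "data.frame",
                 posthoc = "data.frame", alpha = "numeric",
                 nSubjects = "integer", nDropped = "integer",
                 correction = "character")
)

#' PhantomConfig: full specification of a synthetic study
#'
#' See [phantomConfig()] for construction and defaults.
#'
#' @slot nSubjects integer >= 1.
#' @slot truth data.frame with 12 rows (muscle x level), see
#'   [defaultTruthTable()].
#' @slot betweenSubjectCV coefficient of variation applied per subject and
#'   region to volumes and fat fractions.
#' @slot snr signal-to-noise ratio of the Rician noise (S0 / sigma);
#'   `Inf` means noiseless.
#' @slot s0 reference signal intensity.
#' @slot seed integer; fully determines all generated data.
#' @slot anat,dixon,dwi acquisition geometries (lists from
#'   [acquisitionSpec()]).
#' @slot centersMm named numeric: lateral (x) offsets of the multifidus and
#'   erector spinae tube centers, mirrored left/right.
#' @slot slabHeightMm axial height of one vertebral level slab.
#' @slot zBaseMm world z of the inferior S1 slab edge.
#' @export
setClass("PhantomConfig",
  representation(nSubjects = "integer", truth = "data.frame",
                 betweenSubjectCV = "numeric", snr = "numeric",
                 s0 = "numeric", seed = "integer",
                 anat = "list", dixon = "list", dwi = "list",
                 centersMm = "numeric", slabHeightMm = "numeric",
                 zBaseMm = "numeric")
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  tr <- object@truth
  need <- c("muscle", "level", "volume_ml", "fat_fraction_mean",
            "fat_fraction_tail_weight", "lambda1", "lambda2", "lambda3",
            "axis_x", "axis_y", "axis_z")
  if (!all(need %in% names(tr))) {
    msg <- c(msg, paste("truth must contain columns:",
                        paste(need, collapse = ", ")))
  } else {
    if (nrow(tr) != 12L ||
        !identical(sort(paste(tr$muscle, tr$level)),
                   sort(paste(rep(c("multifidus", "erector_spinae"), each = 6),
                              rep(c("L1", "L2", "L3", "L4", "L5", "S1"), 2)))))
      msg <- c(msg, "truth must have one row per muscle x level (12 rows)")
    if (any(tr$volume_ml < 0)) msg <- c(msg, "volumes must be >= 0")
    if (any(tr$fat_fraction_mean < 0 | tr$fat_fraction_mean > 1))
      msg <- c(msg, "fat_fraction_mean must lie in [0, 1]")
    if (any(tr$fat_fraction_tail_weight < 0 | tr$fat_fraction_tail_weight > 1))
      msg <- c(msg, "fat_fraction_tail_weight must lie in [0, 1]")
    lam <- as.matrix(tr[, c("lambda1", "lambda2", "lambda3")])
    if (any(lam <= 0) || any(lam[, 1] < lam[, 2]) || any(lam[, 2] < lam[, 3]))
      msg <- c(msg, "eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 > 0")
    ax <- as.matrix(tr[, c("axis_x", "axis_y", "axis_z")])
    if (any(abs(sqrt(rowSums(ax^2)) - 1) > 1e-6))
      msg <- c(msg, "fiber axes must be unit vectors")
  }
  if (object@betweenSubjectCV < 0) msg <- c(msg, "betweenSubjectCV must be >= 0")
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (object@s0 <= 0) msg <- c(msg, "s0 must be > 0")
  for (nm in c("anat", "dixon", "dwi")) {
    a <- slot(object, nm)
    if (any(a$voxel_size_mm <= 0))
      msg <- c(msg, paste(nm, "voxel sizes must be > 0"))
    if (any(a$grid_shape < 1))
      msg <- c(msg, paste(nm, "grid shape must be positive"))
  }
  if (!is.null(object@dwi$n_directions) && object@dwi$n_directions < 6L)
    msg <- c(msg, "DWI needs at least 6 directions")
  if (object@slabHeightMm <= 0) msg <- c(msg, "slabHeightMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' PhantomDataset: one synthetic subject
#'
#' @slot subject subject index within the study.
#' @slot labels [ImageVolume-class] of integer labels on the anatomical
#'   grid (0 background, 1 multifidus, 2 erector spinae).
#' @slot levelEdges strictly increasing axial world z (mm) of the seven
#'   slab edges delimiting the six vertebral levels (S1 bottom, L1 top).
#' @slot inPhase,outPhase Dixon image pair (phase-corrected, signed
#'   out-of-phase).
#' @slot truthFF ground-truth fat-fraction volume on the anatomical grid.
#' @slot dwi [DwiSeries-class] or NULL when not simulated.
#' @slot truthTensors [TensorField-class] on the DWI grid, or NULL.
#' @slot truth the subject-perturbed truth table actually realised.
#' @export
setClass("PhantomDataset",
  representation(subject = "integer", labels = "ImageVolume",
                 levelEdges = "numeric", inPhase = "ImageVolume",
                 outPhase = "ImageVolume", truthFF = "ImageVolume",
                 dwi = "ANY", truthTensors = "ANY", truth = "data.frame")
)
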