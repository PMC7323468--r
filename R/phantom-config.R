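MUSCLES <- c("multifidus", "erector_spinae")
LEVELS <- c("L1", "L2", "L3", "L4", "L5", "S1")

#' Acquisition geometry for one pulse sequence
#'
#' Defaults mirror the study protocol voxel sizes: high-resolution anatomy
#' at 0.625 x 0.625 x 1 mm, fat-water separation at 1 x 1 x 1 mm, and DWI
#' at 1.5 x 1.5 x 3 mm with 45 diffusion directions at b = 400 s/mm^2.
#' Grid shapes crop the field of view to the paraspinal compartment.
#'
#' @param grid_shape integer length 3, voxels per axis.
#' @param voxel_size_mm positive numeric length 3.
#' @param origin_mm world position (mm) of the first voxel center.
#' @param n_directions number of diffusion-weighted directions (DWI only).
#' @param b_value diffusion weighting (s/mm^2, DWI only).
#' @return a list with the validated fields.
#' @export
acquisitionSpec <- function(grid_shape, voxel_size_mm, origin_mm,
                            n_directions = NULL, b_value = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(origin_mm) == 3L)
  if (!is.null(n_directions) && n_directions < 6L)
    stop("a tensor fit needs at least 6 diffusion directions")
  list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
       origin_mm = as.numeric(origin_mm),
       n_directions = if (is.null(n_directions)) NULL else as.integer(n_directions),
       b_value = if (is.null(b_value)) NULL else as.numeric(b_value))
}

defaultAnatSpec <- function() acquisitionSpec(
  grid_shape = c(312L, 144L, 188L), voxel_size_mm = c(0.625, 0.625, 1),
  origin_mm = c(-97.1875, -44.6875, 0))

defaultDixonSpec <- function() acquisitionSpec(
  grid_shape = c(196L, 90L, 188L), voxel_size_mm = c(1, 1, 1),
  origin_mm = c(-97.5, -44.5, 0))

defaultDwiSpec <- function() acquisitionSpec(
  grid_shape = c(130L, 60L, 62L), voxel_size_mm = c(1.5, 1.5, 3),
  origin_mm = c(-96.75, -44.25, 1), n_directions = 45L, b_value = 400)

#' Default muscle-by-level ground truth table
#'
#' Per-level defaults are constrained so the study's printed aggregates
#' hold exactly on the noiseless phantom: per-muscle level means of volume
#' are 125.8 mL (erector spinae) and 54.0 mL (multifidus); level means of
#' fat signal fraction average 0.228 / 0.205; the pooled two-muscle fat
#' fraction is 0.188 at L1 and 0.338 at S1 and increases strictly with
#' level within each muscle. The erector spinae is the larger muscle from
#' L1-L4 and the smaller one at L5/S1; its fat fraction is the lower one
#' above L3 and the higher one below. Epimuscular tail weights scale with
#' the regional fat fraction so that ~13% of labeled voxels carry a fat
#' fraction above 0.45.
#'
#' Diffusion defaults use eigenvalues typical of skeletal muscle, an
#' oblique (pennate, 22 degrees off superior-inferior) multifidus fiber
#' axis and a near superior-inferior (4 degrees) erector spinae axis, with
#' a mild level modulation peaking at L3.
#'
#' @return data.frame with 12 rows and columns muscle, level, volume_ml,
#'   fat_fraction_mean, fat_fraction_tail_weight, lambda1..3 (mm^2/s),
#'   axis_x/y/z (unit fiber axis).
#' @export
defaultTruthTable <- function() {
  vol_es <- c(150, 175, 190, 140, 65, 34.8)      # mean 125.8 mL
  vol_mf <- c(25, 30, 40, 55, 90, 84)            # mean 54.0 mL
  ff_es <- c(0.187, 0.188, 0.189, 0.196, 0.207, 0.401)  # mean 0.228
  ff_mf <- c(0.189, 0.190, 0.191, 0.192, 0.193, 0.275)  # mean 0.205
  tailw <- function(ff) round(0.6385 * ff, 4)
  lvlf <- c(0.97, 1.00, 1.03, 1.00, 0.97, 0.95)
  ax_mf <- c(sin(22 * pi / 180), 0, cos(22 * pi / 180))
  ax_es <- c(0, sin(4 * pi / 180), cos(4 * pi / 180))
  rbind(
    data.frame(muscle = "multifidus", level = LEVELS, volume_ml = vol_mf,
               fat_fraction_mean = ff_mf,
               fat_fraction_tail_weight = tailw(ff_mf),
               lambda1 = 1.70e-3 * lvlf, lambda2 = 1.30e-3 * lvlf,
               lambda3 = 1.10e-3 * lvlf,
               axis_x = ax_mf[1], axis_y = ax_mf[2], axis_z = ax_mf[3]),
    data.frame(muscle = "erector_spinae", level = LEVELS, volume_ml = vol_es,
               fat_fraction_mean = ff_es,
               fat_fraction_tail_weight = tailw(ff_es),
               lambda1 = 1.95e-3 * lvlf, lambda2 = 1.45e-3 * lvlf,
               lambda3 = 1.25e-3 * lvlf,
               axis_x = ax_es[1], axis_y = ax_es[2], axis_z = ax_es[3])
  )
}

#' Configure a synthetic lumbar-muscle study
#'
#' The configuration (including the seed) fully determines every generated
#' dataset. Between-subject variability is a multiplicative coefficient of
#' variation applied per subject and muscle-by-level region to volumes and
#' fat fractions. Image noise is Rician with sigma = s0 / snr.
#'
#' @param nSubjects number of subjects.
#' @param truth 12-row truth table, see [defaultTruthTable()].
#' @param betweenSubjectCV coefficient of variation (default 0.10).
#' @param snr signal-to-noise ratio (default 40; `Inf` for noiseless).
#' @param s0 reference signal intensity (arbitrary units).
#' @param seed integer master seed.
#' @param anat,dixon,dwi acquisition geometries from [acquisitionSpec()].
#' @param centersMm named numeric: lateral offsets (mm) of the multifidus
#'   and erector spinae tube centers (mirrored left/right).
#' @param slabHeightMm axial height (mm) of each vertebral level slab.
#' @param zBaseMm world z (mm) of the inferior S1 slab edge.
#' @return a validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(nSubjects = 2, seed = 7)
#' cfg
#' @export
phantomConfig <- function(nSubjects = 10L, truth = defaultTruthTable(),
                          betweenSubjectCV = 0.10, snr = 40, s0 = 100,
                          seed = 0L,
                          anat = defaultAnatSpec(),
                          dixon = defaultDixonSpec(),
                          dwi = defaultDwiSpec(),
                          centersMm = c(multifidus = 14.5, erector_spinae = 60),
                          slabHeightMm = 30, zBaseMm = 4) {
  truth$muscle <- as.character(truth$muscle)
  truth$level <- as.character(truth$level)
  new("PhantomConfig", nSubjects = as.integer(nSubjects), truth = truth,
      betweenSubjectCV = as.numeric(betweenSubjectCV), snr = as.numeric(snr),
      s0 = as.numeric(s0), seed = as.integer(seed), anat = anat,
      dixon = dixon, dwi = dwi, centersMm = centersMm,
      slabHeightMm = as.numeric(slabHeightMm), zBaseMm = as.numeric(zBaseMm))
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %d subjects, CV %.2f, SNR %s, seed %d\n",
    object@nSubjects, object@betweenSubjectCV, format(object@snr),
    object@seed))
  cat(sprintf("  anat %s @ %s mm; dixon %s @ %s mm; dwi %s @ %s mm, %d dir, b=%g\n",
              paste(object@anat$grid_shape, collapse = "x"),
              paste(object@anat$voxel_size_mm, collapse = "x"),
              paste(object@dixon$grid_shape, collapse = "x"),
              paste(object@dixon$voxel_size_mm, collapse = "x"),
              paste(object@dwi$grid_shape, collapse = "x"),
              paste(object@dwi$voxel_size_mm, collapse = "x"),
              object@dwi$n_directions, object@dwi$b_value))
})

#' Axial slab edges of the six vertebral levels
#'
#' Returns the seven strictly increasing world-z coordinates delimiting
#' the S1 (bottom) through L1 (top) slabs, each `slabHeightMm` tall; the
#' slab midplanes sit halfway between the endplates of adjacent vertebrae.
#'
#' @param config a [PhantomConfig-class].
#' @return numeric length 7.
#' @export
levelEdges <- function(config) config@zBaseMm + 0:6 * config@slabHeightMm

# per-subject multiplicative perturbation of volumes and fat fractions
subjectTruth <- function(config, subjectIndex) {
  tr <- config@truth
  cv <- config@betweenSubjectCV
  if (cv > 0) {
    withSeed(subjectSeed(config, subjectIndex, "truth"), {
      fv <- pmax(1 + stats::rnorm(nrow(tr), 0, cv), 0.1)
      ff <- pmax(1 + stats::rnorm(nrow(tr), 0, cv), 0.1)
    })
    tr$volume_ml <- tr$volume_ml * fv
    tr$fat_fraction_mean <- pmin(tr$fat_fraction_mean * ff, 1)
  }
  tr
}

# deterministic sub-seeds; kept well below .Machine$integer.max
subjectSeed <- function(config, subjectIndex, stream) {
  off <- switch(stream, truth = 1L, fat = 2L, dixon = 3L, dwi = 4L, 5L)
  (config@seed %% 100000L) * 10000L + subjectIndex * 100L + off
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
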