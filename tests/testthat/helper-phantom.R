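# Shared fixtures built in code. Tiny phantoms scale the truth volumes
# down 40x and shrink all three grids so a full subject simulates in a
# couple of seconds; the full-size default study used by the acceptance
# tests is computed once and cached for the session.

tinyTruth <- function() {
  tr <- defaultTruthTable()
  tr$volume_ml <- tr$volume_ml / 40
  tr
}

tinyConfig <- function(nSubjects = 1L, snr = Inf, cv = 0, seed = 1L,
                       truth = tinyTruth()) {
  phantomConfig(
    nSubjects = nSubjects, truth = truth, betweenSubjectCV = cv,
    snr = snr, seed = seed,
    anat = acquisitionSpec(c(120L, 72L, 100L), c(0.625, 0.625, 1),
                           c(-37.1875, -22.1875, 0)),
    dixon = acquisitionSpec(c(76L, 46L, 100L), c(1, 1, 1),
                            c(-37.5, -22.5, 0)),
    dwi = acquisitionSpec(c(50L, 30L, 33L), c(1.5, 1.5, 3),
                          c(-36.75, -21.75, 1), n_directions = 45L,
                          b_value = 400),
    centersMm = c(multifidus = 6, erector_spinae = 22),
    slabHeightMm = 15, zBaseMm = 2)
}

# a uniform tensor field filling a slab, with all fibers along `axis`
uniformField <- function(dims = c(11L, 11L, 21L), spacing = c(2, 2, 3),
                         axis = c(0, 0, 1),
                         lambda = c(1.7e-3, 1.3e-3, 1.1e-3)) {
  lab <- ImageVolume(array(1L, dims), spacing, c(0, 0, 0))
  tr <- defaultTruthTable()
  tr$axis_x <- axis[1]; tr$axis_y <- axis[2]; tr$axis_z <- axis[3]
  tr$lambda1 <- lambda[1]; tr$lambda2 <- lambda[2]; tr$lambda3 <- lambda[3]
  zmax <- (dims[3] - 1) * spacing[3]
  edges <- seq(-0.5, zmax + 0.5, length.out = 7)
  assignTensorField(lab, edges, tr)
}

tensorToV6 <- function(D) c(D[1, 1], D[2, 2], D[3, 3],
                            D[1, 2], D[1, 3], D[2, 3])

v6ToTensor <- function(v) matrix(c(v[1], v[4], v[5],
                                   v[4], v[2], v[6],
                                   v[5], v[6], v[3]), 3, 3)

randomSPDTensor <- function() {
  lam <- sort(stats::runif(3, 0.2e-3, 2.5e-3), decreasing = TRUE)
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  Q %*% diag(lam) %*% t(Q)
}

# ---- cached full-size acceptance study ------------------------------------

.acceptanceCache <- new.env(parent = emptyenv())

acceptanceStudy <- function() {
  if (is.null(.acceptanceCache$run)) {
    cfg <- phantomConfig(nSubjects = 10L, betweenSubjectCV = 0, snr = 40,
                         seed = 0L)
    .acceptanceCache$run <- phantomRecoveryStudy(cfg, withDti = TRUE,
                                                 keepLast = TRUE)
    .acceptanceCache$config <- cfg
  }
  .acceptanceCache$run
}

acceptanceConfig <- function() {
  acceptanceStudy()
  .acceptanceCache$config
}
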