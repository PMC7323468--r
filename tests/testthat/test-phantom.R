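test_that("geometry produces six slabs, labels {0,1,2}, and exact voxel counts", {
  cfg <- tinyConfig()
  geom <- buildGeometry(cfg, 1)
  lab <- imgData(geom$labels)
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L))
  expect_length(geom$levelEdges, 7L)
  # voxel count per region matches the target volume exactly
  voxVol <- prod(voxelSpacing(geom$labels))
  for (r in seq_len(nrow(cfg@truth))) {
    m <- match(cfg@truth$muscle[r], c("multifidus", "erector_spinae"))
    l <- match(cfg@truth$level[r], c("L1", "L2", "L3", "L4", "L5", "S1"))
    expect_equal(geom$counts[m, l],
                 round(cfg@truth$volume_ml[r] * 1000 / voxVol))
  }
  # volume conservation: slab counts sum to whole-muscle counts
  expect_equal(sum(geom$counts[1, ]), sum(lab == 1L))
  expect_equal(sum(geom$counts[2, ]), sum(lab == 2L))
})

test_that("a 0.390625 mL region on the 0.625 x 0.625 x 1 mm grid holds exactly 1000 voxels", {
  tr <- tinyTruth()
  tr$volume_ml[tr$muscle == "multifidus" & tr$level == "L3"] <- 0.390625
  cfg <- tinyConfig(truth = tr)
  geom <- buildGeometry(cfg, 1)
  expect_identical(geom$counts["multifidus", "L3"], 1000)
})

test_that("an unrepresentable volume raises a configuration error", {
  tr <- tinyTruth()
  tr$volume_ml[1] <- 1e5
  expect_error(buildGeometry(tinyConfig(truth = tr), 1), "field of view")
})

test_that("the phantom is fully deterministic given its configuration", {
  cfg <- tinyConfig(nSubjects = 2, snr = 30, cv = 0.1, seed = 11)
  d1 <- simulateSubject(cfg, 2, withDwi = TRUE)
  d2 <- simulateSubject(cfg, 2, withDwi = TRUE)
  expect_identical(imgData(d1@labels), imgData(d2@labels))
  expect_identical(imgData(d1@inPhase), imgData(d2@inPhase))
  expect_identical(d1@dwi@data, d2@dwi@data)
  expect_identical(d1@truth, d2@truth)
})

test_that("fat field hits each region mean within 0.005 and stays in [0, 1]", {
  cfg <- tinyConfig(seed = 5)
  geom <- buildGeometry(cfg, 1)
  ffv <- assignFatField(geom, cfg, 1)
  ff <- imgData(ffv)
  expect_true(all(ff >= 0 & ff <= 1))
  lab <- imgData(geom$labels)
  lvl <- imgData(sliceLevels(geom$labels, geom$levelEdges))
  for (r in seq_len(nrow(cfg@truth))) {
    m <- match(cfg@truth$muscle[r], c("multifidus", "erector_spinae"))
    l <- match(cfg@truth$level[r], c("L1", "L2", "L3", "L4", "L5", "S1"))
    expect_lt(abs(mean(ff[lab == m & lvl == l]) -
                    cfg@truth$fat_fraction_mean[r]), 0.005)
  }
  # degenerate case: zero mean, zero tail weight -> all zero
  tr0 <- tinyTruth()
  tr0$fat_fraction_mean <- 0
  tr0$fat_fraction_tail_weight <- 0
  cfg0 <- tinyConfig(truth = tr0)
  g0 <- buildGeometry(cfg0, 1)
  f0 <- imgData(assignFatField(g0, cfg0, 1))
  expect_true(all(f0[imgData(g0$labels) > 0] == 0))
})

test_that("tensor field realises D = R diag(l3,l2,l1) R' with the configured axes", {
  # axis (0,0,1): D diagonal with (l3, l2, l1) on (x, y, z)
  tf <- uniformField(axis = c(0, 0, 1), lambda = c(1.8e-3, 1.2e-3, 1.0e-3))
  v <- tf@tensors[5, 5, 10, ]
  expect_equal(v, c(1.0e-3, 1.2e-3, 1.8e-3, 0, 0, 0), tolerance = 1e-15)
  # trace is similarity-invariant for any axis
  ax <- c(1, 2, 2) / 3
  tf2 <- uniformField(axis = ax)
  v2 <- tf2@tensors[5, 5, 10, ]
  expect_equal(sum(v2[1:3]), 1.7e-3 + 1.3e-3 + 1.1e-3, tolerance = 1e-18)
  # principal eigenvector is the configured fiber axis
  D <- v6ToTensor(v2)
  e <- eigen(D, symmetric = TRUE)
  expect_equal(abs(sum(e$vectors[, 1] * ax)), 1, tolerance = 1e-12)
  # non-unit axis is rejected
  tr <- defaultTruthTable()
  tr$axis_z <- 2
  lab <- ImageVolume(array(1L, c(4, 4, 8)), c(1, 1, 1), c(0, 0, 0))
  expect_error(assignTensorField(lab, seq(-0.5, 7.5, length.out = 7), tr),
               "unit vector")
})

test_that("default multifidus and erector spinae fiber axes differ by more than 10 degrees", {
  tr <- defaultTruthTable()
  a1 <- unlist(tr[tr$muscle == "multifidus", c("axis_x", "axis_y", "axis_z")][1, ])
  a2 <- unlist(tr[tr$muscle == "erector_spinae", c("axis_x", "axis_y", "axis_z")][1, ])
  ang <- acos(sum(a1 * a2)) * 180 / pi
  expect_gt(ang, 10)
})

test_that("noiseless Dixon simulation matches its closed form and inverts exactly", {
  # ff = 0.5 -> IP = S0, OP = 0; ff = 0 -> IP = OP = S0
  ffv <- ImageVolume(array(c(0.5, 0, 0.25, 1), c(2, 2, 1)))
  spec <- acquisitionSpec(c(2L, 2L, 1L), c(1, 1, 1), c(0, 0, 0))
  dx <- simulateDixon(ffv, spec, snr = Inf, s0 = 100)
  expect_equal(imgData(dx$inPhase)[1, 1, 1], 100)
  expect_equal(imgData(dx$outPhase)[1, 1, 1], 0)
  expect_equal(imgData(dx$inPhase)[2, 1, 1], 100)
  expect_equal(imgData(dx$outPhase)[2, 1, 1], 100)
  fw <- dixonDecompose(dx$inPhase, dx$outPhase)
  expect_equal(imgData(fw@fatFraction), imgData(dx$ffOnGrid), tolerance = 1e-15)
  expect_error(simulateDixon(ffv, spec, snr = 0), "snr")
})

test_that("noiseless DWI matches exp(-b g'Dg) and b = 0 is unattenuated", {
  tf <- uniformField(dims = c(4L, 4L, 8L), spacing = c(1.5, 1.5, 3),
                     lambda = rep(1.5e-3, 3))
  spec <- acquisitionSpec(c(4L, 4L, 8L), c(1.5, 1.5, 3), c(0, 0, 0),
                          n_directions = 45L, b_value = 400)
  dwi <- simulateDwi(tf, spec, snr = Inf, s0 = 200)
  expect_equal(dwi@data[2, 2, 4, 1], 200)            # b = 0
  # isotropic D: attenuation exp(-b d) in every direction
  expect_equal(as.vector(dwi@data[2, 2, 4, -1]),
               rep(200 * exp(-400 * 1.5e-3), 45), tolerance = 1e-12)
})

test_that("Rician noise converges to the noiseless signal as snr grows", {
  ffv <- ImageVolume(array(0.3, c(6, 6, 4)))
  spec <- acquisitionSpec(c(6L, 6L, 4L), c(1, 1, 1), c(0, 0, 0))
  ref <- simulateDixon(ffv, spec, snr = Inf, s0 = 100)
  hi <- simulateDixon(ffv, spec, snr = 1e9, s0 = 100, seed = 2)
  expect_lt(max(abs(imgData(hi$inPhase) - imgData(ref$inPhase))), 1e-5)
  expect_identical(riceNoise(c(-3, 0, 5), 0), c(-3, 0, 5))
  # sign of a phase-corrected out-of-phase signal is preserved
  set.seed(1)
  expect_true(all(riceNoise(rep(-50, 100), 1) < 0))
})

test_that("gradient scheme is deterministic, unit-norm and well-spread", {
  g1 <- gradientScheme(45)
  g2 <- gradientScheme(45)
  expect_identical(g1, g2)
  expect_equal(sqrt(colSums(g1^2)), rep(1, 45), tolerance = 1e-12)
  dots <- abs(crossprod(g1)); diag(dots) <- 0
  expect_lt(max(dots), cos(10 * pi / 180))  # no near-collinear pair
  # the tensor design built from it is full rank
  A <- cbind(g1[1, ]^2, g1[2, ]^2, g1[3, ]^2, 2 * g1[1, ] * g1[2, ],
             2 * g1[1, ] * g1[3, ], 2 * g1[2, ] * g1[3, ])
  expect_equal(qr(A)$rank, 6L)
})

test_that("written datasets re-read bit-exactly (NIfTI + bvec/bval + CSV)", {
  cfg <- tinyConfig(snr = 25, seed = 9)
  ds <- simulateSubject(cfg, 1, withDwi = TRUE)
  dir <- withr::local_tempdir()
  paths <- writeDataset(ds, dir)
  expect_true(all(file.exists(paths)))
  lab2 <- RNifti::readNifti(paths[["labels"]])
  expect_equal(array(as.numeric(lab2), dim(lab2)),
               array(as.numeric(imgData(ds@labels)), dim(lab2)))
  ip2 <- RNifti::readNifti(paths[["dixon_ip"]])
  expect_identical(array(as.numeric(ip2), dim(ip2)), imgData(ds@inPhase))
  expect_equal(RNifti::pixdim(ip2), voxelSpacing(ds@inPhase))
  dwi2 <- RNifti::readNifti(paths[["dwi"]])
  expect_identical(array(as.numeric(dwi2), dim(dwi2)), ds@dwi@data)
  bv <- unname(as.matrix(read.table(paths[["bvecs"]])))
  expect_equal(bv, unname(ds@dwi@bvecs), tolerance = 1e-12)
  edges <- read.csv(paths[["level_boundaries"]])
  expect_equal(edges$z_mm, ds@levelEdges)
})

test_that("between-subject CV perturbs volumes with the configured spread", {
  cfg <- tinyConfig(nSubjects = 30, cv = 0.1, seed = 4)
  v <- vapply(1:30, function(s)
    lumbarqmri:::subjectTruth(cfg, s)$volume_ml[1], numeric(1))
  expect_gt(sd(v) / mean(v), 0.05)
  expect_lt(sd(v) / mean(v), 0.2)
  cfg0 <- tinyConfig(nSubjects = 3, cv = 0, seed = 4)
  v0 <- vapply(1:3, function(s)
    lumbarqmri:::subjectTruth(cfg0, s)$volume_ml[1], numeric(1))
  expect_equal(v0, rep(cfg0@truth$volume_ml[1], 3))
})
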