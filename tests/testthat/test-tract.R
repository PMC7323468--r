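test_that("a uniform axial field yields straight full-length tracks", {
  tf <- uniformField()                       # 60 mm slab along z
  mask <- ImageVolume(array(1L, c(11, 11, 21)), c(2, 2, 3), c(0, 0, 0))
  cfg <- tractographyConfig(step_mm = 0.75)
  ss <- trackStreamlines(tf, mask, cfg)
  expect_gt(length(ss), 0)
  # the center seed runs the whole slab: 60 mm within one step
  expect_lt(abs(max(trackLengths(ss)) - 60), 2 * cfg$step_mm)
  expect_true(all(pennationAngles(ss) < 0.1))
  # straightness: every point on the center track keeps its x, y
  ctr <- streamlines(ss)[[which.max(trackLengths(ss))]]
  expect_lt(max(abs(sweep(ctr[, 1:2], 2, ctr[1, 1:2]))), 1e-9)
})

test_that("tracking is antisymmetric about the seed in a uniform field", {
  tf <- uniformField()
  mask <- ImageVolume(array(1L, c(11, 11, 21)), c(2, 2, 3), c(0, 0, 0))
  ss <- trackStreamlines(tf, mask, tractographyConfig(step_mm = 1))
  i <- which.max(trackLengths(ss))
  p <- streamlines(ss)[[i]]
  seedRow <- which(apply(p, 1, function(r)
    sum(abs(r - c(10, 10, 30)))) < 1e-6)
  if (length(seedRow) == 1) {
    fwd <- p[seedRow:nrow(p), 3] - p[seedRow, 3]
    bwd <- p[seedRow:1, 3] - p[seedRow, 3]
    n <- min(length(fwd), length(bwd))
    expect_equal(fwd[1:n], -bwd[1:n], tolerance = 1e-9)
  } else succeed("center seed not present under subsampling")
})

test_that("no retained track turns more than the angular threshold", {
  # helical field: direction rotates gently with z
  d <- c(15, 15, 25); sp <- c(2, 2, 2)
  T6 <- array(0, c(d, 6))
  lam <- c(1.8e-3, 1.1e-3, 1.1e-3)
  for (k in seq_len(d[3])) {
    th <- (k - 1) * 6 * pi / 180
    ax <- c(sin(th) * 0.4, cos(th) * 0.4, sqrt(1 - 0.16))
    D <- lumbarqmri:::tensorFromAxis(lam, ax)
    for (c6 in 1:6)
      T6[, , k, c6] <- c(D[1, 1], D[2, 2], D[3, 3],
                         D[1, 2], D[1, 3], D[2, 3])[c6]
  }
  tf <- new("TensorField", tensors = T6, s0 = array(1, d),
            valid = array(TRUE, d), spacing = sp, origin = c(0, 0, 0))
  mask <- ImageVolume(array(1L, d), sp, c(0, 0, 0))
  cfg <- tractographyConfig(angle_threshold_deg = 15, step_mm = 1,
                            min_length_mm = 5, max_seeds = 60L)
  ss <- trackStreamlines(tf, mask, cfg)
  expect_gt(length(ss), 0)
  for (p in streamlines(ss)) {
    steps <- diff(p)
    u <- steps / sqrt(rowSums(steps^2))
    if (nrow(u) > 1) {
      turns <- acos(pmin(pmax(rowSums(u[-1, , drop = FALSE] *
                                        u[-nrow(u), , drop = FALSE]), -1), 1))
      expect_lt(max(turns) * 180 / pi, 15 + 1e-6)
    }
  }
})

test_that("a field turning faster than the threshold per step yields no tracks", {
  # axis tilted 30 degrees off z with its azimuth spinning 45 degrees per
  # 2 mm slice: every step meets a turn well above the 15-degree threshold
  d <- c(7, 7, 20); sp <- c(2, 2, 2)
  T6 <- array(0, c(d, 6))
  lam <- c(1.8e-3, 1.1e-3, 1.1e-3)
  for (k in seq_len(d[3])) {
    th <- (k - 1) * 45 * pi / 180
    D <- lumbarqmri:::tensorFromAxis(lam, c(0.5 * cos(th), 0.5 * sin(th),
                                            sqrt(0.75)))
    for (c6 in 1:6)
      T6[, , k, c6] <- c(D[1, 1], D[2, 2], D[3, 3],
                         D[1, 2], D[1, 3], D[2, 3])[c6]
  }
  tf <- new("TensorField", tensors = T6, s0 = array(1, d),
            valid = array(TRUE, d), spacing = sp, origin = c(0, 0, 0))
  mask <- ImageVolume(array(1L, d), sp, c(0, 0, 0))
  ss <- trackStreamlines(tf, mask,
                         tractographyConfig(min_length_mm = 10, step_mm = 2))
  expect_identical(length(ss), 0L)
})

test_that("min_length filtering, determinism and the empty-mask warning hold", {
  tf <- uniformField(dims = c(5L, 5L, 5L), spacing = c(2, 2, 2))
  mask <- ImageVolume(array(1L, c(5, 5, 5)), c(2, 2, 2), c(0, 0, 0))
  # slab is only 8 mm tall: a 20 mm minimum leaves nothing
  ss <- trackStreamlines(tf, mask, tractographyConfig(min_length_mm = 20))
  expect_identical(length(ss), 0L)
  ssA <- trackStreamlines(tf, mask, tractographyConfig(min_length_mm = 4,
                                                       seeds_per_voxel = 2L),
                          seed = 42)
  ssB <- trackStreamlines(tf, mask, tractographyConfig(min_length_mm = 4,
                                                       seeds_per_voxel = 2L),
                          seed = 42)
  expect_identical(streamlines(ssA), streamlines(ssB))
  expect_true(all(trackLengths(ssA) >= 4))
  emptyMask <- ImageVolume(array(0L, c(5, 5, 5)), c(2, 2, 2), c(0, 0, 0))
  expect_warning(ss0 <- trackStreamlines(tf, emptyMask,
                                         tractographyConfig()), "empty")
  expect_identical(length(ss0), 0L)
})

test_that("consecutive streamline points stay within twice the step", {
  tf <- uniformField(axis = c(0.3746066, 0, 0.9271839))
  mask <- ImageVolume(array(1L, c(11, 11, 21)), c(2, 2, 3), c(0, 0, 0))
  cfg <- tractographyConfig(step_mm = 0.75, max_seeds = 40L)
  ss <- trackStreamlines(tf, mask, cfg)
  for (p in streamlines(ss)) {
    gaps <- sqrt(rowSums(diff(p)^2))
    expect_true(all(gaps <= 2 * cfg$step_mm + 1e-9))
  }
  # pennation of the oblique field matches the 22-degree axis
  expect_equal(median(pennationAngles(ss)), 22, tolerance = 0.5)
})

test_that("trk files round-trip coordinates to 1e-4 mm", {
  tf <- uniformField()
  mask <- ImageVolume(array(1L, c(11, 11, 21)), c(2, 2, 3), c(0, 0, 0))
  ss <- trackStreamlines(tf, mask, tractographyConfig(max_seeds = 20L))
  ref <- ImageVolume(array(0, c(11, 11, 21)), c(2, 2, 3), c(0, 0, 0))
  path <- withr::local_tempfile(fileext = ".trk")
  writeTrk(ss, ref, path)
  rt <- readTrk(path)
  expect_identical(rt$nTracks, length(ss))
  expect_identical(rt$version, 2L)
  expect_equal(rt$voxelSize, c(2, 2, 3), tolerance = 1e-6)
  err <- max(mapply(function(a, b) max(abs(a - b)), streamlines(ss),
                    rt$tracks))
  expect_lt(err, 1e-4)
  # header size sanity: 1000-byte header plus the track payload
  npts <- sum(vapply(streamlines(ss), nrow, 1L))
  expect_identical(file.size(path), 1000 + 4 * length(ss) + 12 * npts)
  expect_error(writeTrk(new("StreamlineSet", tracks = list(),
                            lengthMm = numeric(),
                            meanDirection = matrix(0, 0, 3),
                            pennationDeg = numeric(), refAxis = c(0, 0, 1),
                            stepMm = 1), ref,
                        withr::local_tempfile(fileext = ".trk")), "empty")
})
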