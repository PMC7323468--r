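# Build a DwiSeries directly from a list of per-voxel tensors.
dwiFromTensors <- function(tensors, b = 400, s0 = 150, ndir = 45,
                           g = gradientScheme(ndir)) {
  n <- length(tensors)
  dat <- array(0, c(n, 1, 1, ndir + 1))
  dat[, 1, 1, 1] <- s0
  for (i in seq_len(n)) {
    att <- vapply(seq_len(ndir), function(j)
      exp(-b * drop(t(g[, j]) %*% tensors[[i]] %*% g[, j])), numeric(1))
    dat[i, 1, 1, -1] <- s0 * att
  }
  new("DwiSeries", data = dat, bvecs = cbind(c(0, 0, 0), g),
      bvals = c(0, rep(b, ndir)), spacing = c(1, 1, 1), origin = c(0, 0, 0))
}

test_that("noiseless log-linear fit recovers known tensors to 1e-10 relative error", {
  set.seed(7)
  tensors <- replicate(25, randomSPDTensor(), simplify = FALSE)
  dwi <- dwiFromTensors(tensors)
  fit <- fitTensor(dwi)
  expect_true(all(fit@valid))
  for (i in seq_along(tensors)) {
    got <- v6ToTensor(fit@tensors[i, 1, 1, ])
    expect_lt(max(abs(got - tensors[[i]])) / max(abs(tensors[[i]])), 1e-10)
  }
})

test_that("fitted tensors and FA/MD agree with an independent lm()+eigen() oracle", {
  set.seed(12)
  tensors <- replicate(100, randomSPDTensor(), simplify = FALSE)
  dwi <- dwiFromTensors(tensors, s0 = 90)
  fit <- fitTensor(dwi)
  maps <- eigenMetrics(fit)
  g <- dwi@bvecs[, -1]
  A <- t(rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2, 2 * g[1, ] * g[2, ],
               2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ]) * 400)
  for (i in seq(1, 100, by = 7)) {
    y <- -log(dwi@data[i, 1, 1, -1] / dwi@data[i, 1, 1, 1])
    ref6 <- unname(stats::coef(stats::lm(y ~ A - 1)))
    expect_lt(max(abs(fit@tensors[i, 1, 1, ] - ref6)), 1e-8 * max(abs(ref6)))
    ev <- eigen(v6ToTensor(ref6), symmetric = TRUE, only.values = TRUE)$values
    md <- mean(ev)
    fa <- sqrt(1.5) * sqrt(sum((ev - md)^2) / sum(ev^2))
    expect_equal(imgData(maps@md)[i, 1, 1], md, tolerance = 1e-8)
    expect_equal(imgData(maps@fa)[i, 1, 1], fa, tolerance = 1e-8)
    expect_equal(imgData(maps@lambda1)[i, 1, 1], max(ev), tolerance = 1e-8)
  }
})

test_that("closed-form eigenvalues and principal axes match base eigen()", {
  set.seed(99)
  V6 <- t(vapply(replicate(200, randomSPDTensor(), simplify = FALSE),
                 tensorToV6, numeric(6)))
  got <- lumbarqmri:::symEigenValues3(V6)
  vec <- lumbarqmri:::symEigenVector3(V6, got)
  for (i in seq_len(nrow(V6))) {
    e <- eigen(v6ToTensor(V6[i, ]), symmetric = TRUE)
    expect_equal(got[i, ], e$values, tolerance = 1e-9)
    expect_equal(abs(sum(vec[i, ] * e$vectors[, 1])), 1, tolerance = 1e-7)
  }
  # isotropic and rank-one degenerate values
  iso <- lumbarqmri:::symEigenValues3(matrix(c(2, 2, 2, 0, 0, 0), 1))
  expect_equal(as.vector(iso), c(2, 2, 2))
})

test_that("FA is 0 for isotropic and 1 for single-axis diffusion, exactly", {
  mkField <- function(v6) new("TensorField",
    tensors = array(v6, c(1, 1, 1, 6)), s0 = array(1, c(1, 1, 1)),
    valid = array(TRUE, c(1, 1, 1)), spacing = c(1, 1, 1),
    origin = c(0, 0, 0))
  iso <- eigenMetrics(mkField(c(1.5e-3, 1.5e-3, 1.5e-3, 0, 0, 0)))
  expect_identical(imgData(iso@fa)[1, 1, 1], 0)
  expect_equal(imgData(iso@lambda1)[1, 1, 1], 1.5e-3)
  expect_equal(imgData(iso@lambda3)[1, 1, 1], 1.5e-3)
  axial <- eigenMetrics(mkField(c(1.5e-3, 0, 0, 0, 0, 0)))
  expect_equal(imgData(axial@fa)[1, 1, 1], 1, tolerance = 1e-12)
  zero <- eigenMetrics(mkField(rep(0, 6)))
  expect_identical(imgData(zero@fa)[1, 1, 1], 0)
})

test_that("MD and RD follow their eigenvalue definitions", {
  lam <- c(1.8e-3, 1.2e-3, 1.0e-3)
  f <- new("TensorField", tensors = array(c(lam, 0, 0, 0), c(1, 1, 1, 6)),
           s0 = array(1, c(1, 1, 1)), valid = array(TRUE, c(1, 1, 1)),
           spacing = c(1, 1, 1), origin = c(0, 0, 0))
  m <- eigenMetrics(f)
  expect_equal(imgData(m@md)[1, 1, 1], 1.3333e-3, tolerance = 1e-4)
  expect_equal(imgData(m@rd)[1, 1, 1], 1.1e-3)
  expect_equal(imgData(m@lambda1)[1, 1, 1], 1.8e-3)
})

test_that("FA, MD, RD are invariant under joint rotation of tensor and gradients", {
  set.seed(21)
  D <- randomSPDTensor()
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4)), 3, 3)
  dwi1 <- dwiFromTensors(list(D))
  m1 <- eigenMetrics(fitTensor(dwi1))
  dwi2 <- dwiFromTensors(list(R %*% D %*% t(R)),
                         g = R %*% gradientScheme(45))
  # rotating gradients together with the tensor preserves the signals
  expect_equal(dwi2@data, dwi1@data, tolerance = 1e-12)
  m2 <- eigenMetrics(fitTensor(dwi2))
  for (nm in c("fa", "md", "rd"))
    expect_equal(imgData(slot(m2, nm))[1, 1, 1],
                 imgData(slot(m1, nm))[1, 1, 1], tolerance = 1e-10)
})

test_that("adding isotropic diffusivity strictly decreases FA", {
  set.seed(3)
  D <- randomSPDTensor()
  faOf <- function(D) {
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    m <- eigenMetrics(new("TensorField",
      tensors = array(tensorToV6(D), c(1, 1, 1, 6)),
      s0 = array(1, c(1, 1, 1)), valid = array(TRUE, c(1, 1, 1)),
      spacing = c(1, 1, 1), origin = c(0, 0, 0)))
    imgData(m@fa)[1, 1, 1]
  }
  fas <- vapply(c(0, 2e-4, 6e-4, 2e-3), function(cc)
    faOf(D + cc * diag(3)), numeric(1))
  expect_true(all(diff(fas) < 0))
})

test_that("fit handles invalid voxels, mask grids and degenerate designs", {
  set.seed(5)
  tensors <- replicate(4, randomSPDTensor(), simplify = FALSE)
  dwi <- dwiFromTensors(tensors)
  dwi@data[2, 1, 1, 5] <- 0   # non-positive signal -> invalid voxel
  fit <- fitTensor(dwi)
  expect_false(fit@valid[2, 1, 1])
  expect_true(all(fit@valid[c(1, 3, 4), 1, 1]))
  maps <- eigenMetrics(fit)
  expect_true(is.na(imgData(maps@fa)[2, 1, 1]))
  # a single direction repeated is rank deficient
  g1 <- dwi@bvecs[, 2]
  bad <- dwi
  bad@bvecs <- cbind(c(0, 0, 0), matrix(g1, 3, 45))
  expect_error(fitTensor(bad), "rank deficient")
  # weighted LS agrees with OLS on noiseless data
  fitW <- fitTensor(dwi, weighted = TRUE)
  expect_equal(fitW@tensors[1, 1, 1, ], fit@tensors[1, 1, 1, ],
               tolerance = 1e-8)
})
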