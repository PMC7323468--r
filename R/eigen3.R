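# Closed-form eigendecomposition of symmetric 3x3 matrices, vectorized
# over voxels. Input V6 is an n x 6 matrix with columns
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).

# Sorted eigenvalues (descending) via the trigonometric solution of the
# characteristic polynomial; numerically safe for the near-isotropic case.
symEigenValues3 <- function(V6) {
  V6 <- matrix(as.numeric(V6), ncol = 6)
  xx <- V6[, 1]; yy <- V6[, 2]; zz <- V6[, 3]
  xy <- V6[, 4]; xz <- V6[, 5]; yz <- V6[, 6]
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  # anisotropy below a few ulps of the trace is numerical noise: treat as
  # perfectly isotropic so FA comes out exactly 0
  nz <- p > 4 * .Machine$double.eps * abs(q)
  if (any(nz)) {
    # det((A - qI)/p) / 2, expanded componentwise
    bxx <- (xx[nz] - q[nz]) / p[nz]; byy <- (yy[nz] - q[nz]) / p[nz]
    bzz <- (zz[nz] - q[nz]) / p[nz]
    bxy <- xy[nz] / p[nz]; bxz <- xz[nz] / p[nz]; byz <- yz[nz] / p[nz]
    r <- (bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
            bxz * (bxy * byz - byy * bxz)) / 2
    phi <- acos(pmin(pmax(r, -1), 1)) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

# Principal (largest-eigenvalue) unit eigenvector per row. Uses the
# Cayley-Hamilton identity: the columns of (A - l2 I)(A - l3 I) span the
# l1 eigenspace. Rows with (near-)degenerate l1 ~ l2 fall back to eigen().
symEigenVector3 <- function(V6, values = NULL) {
  V6 <- matrix(as.numeric(V6), ncol = 6)
  if (is.null(values)) values <- symEigenValues3(V6)
  n <- nrow(V6)
  xx <- V6[, 1]; yy <- V6[, 2]; zz <- V6[, 3]
  xy <- V6[, 4]; xz <- V6[, 5]; yz <- V6[, 6]
  l2 <- values[, 2]; l3 <- values[, 3]
  # M = (A - l2 I)(A - l3 I); columns computed componentwise
  m11 <- (xx - l2) * (xx - l3) + xy * xy + xz * xz
  m21 <- xy * (xx - l3) + (yy - l2) * xy + yz * xz
  m31 <- xz * (xx - l3) + yz * xy + (zz - l2) * xz
  m12 <- (xx - l2) * xy + xy * (yy - l3) + xz * yz
  m22 <- xy * xy + (yy - l2) * (yy - l3) + yz * yz
  m32 <- xz * xy + yz * (yy - l3) + (zz - l2) * yz
  m13 <- (xx - l2) * xz + xy * yz + xz * (zz - l3)
  m23 <- xy * xz + (yy - l2) * yz + yz * (zz - l3)
  m33 <- xz * xz + yz * yz + (zz - l2) * (zz - l3)
  n1 <- m11^2 + m21^2 + m31^2
  n2 <- m12^2 + m22^2 + m32^2
  n3 <- m13^2 + m23^2 + m33^2
  best <- max.col(cbind(n1, n2, n3), ties.method = "first")
  v <- matrix(0, n, 3)
  pick <- best == 1L
  v[pick, ] <- cbind(m11, m21, m31)[pick, , drop = FALSE]
  pick <- best == 2L
  v[pick, ] <- cbind(m12, m22, m32)[pick, , drop = FALSE]
  pick <- best == 3L
  v[pick, ] <- cbind(m13, m23, m33)[pick, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  bad <- !(nrm > (abs(values[, 1]) + abs(values[, 3]) + 1e-300) * 1e-9) |
    !is.finite(nrm)
  ok <- !bad
  v[ok, ] <- v[ok, , drop = FALSE] / nrm[ok]
  if (any(bad)) {
    for (i in which(bad)) {
      A <- matrix(c(xx[i], xy[i], xz[i],
                    xy[i], yy[i], yz[i],
                    xz[i], yz[i], zz[i]), 3, 3)
      if (all(is.finite(A))) v[i, ] <- eigen(A, symmetric = TRUE)$vectors[, 1]
    }
  }
  v
}
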