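# Trilinear hexahedral u-p assembly, vectorized over elements.
#
# Displacement and pressure share the trilinear basis (equal-order
# interpolation). 2x2x2 Gauss quadrature.

hex_ref <- local({
  sg <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  tg <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  zg <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(x = c(-g, g), y = c(-g, g), z = c(-g, g)))
  N <- matrix(0, 8, 8)      # [gp, node]
  dN <- array(0, c(8, 8, 3))  # [gp, node, ref-dir]
  for (q in 1:8) {
    xi <- gp[q, 1]; eta <- gp[q, 2]; zet <- gp[q, 3]
    N[q, ] <- (1 + sg * xi) * (1 + tg * eta) * (1 + zg * zet) / 8
    dN[q, , 1] <- sg * (1 + tg * eta) * (1 + zg * zet) / 8
    dN[q, , 2] <- (1 + sg * xi) * tg * (1 + zg * zet) / 8
    dN[q, , 3] <- (1 + sg * xi) * (1 + tg * eta) * zg / 8
  }
  list(N = N, dN = dN)
})

# Per-mesh geometric precomputation: for each Gauss point, the physical
# shape-function gradients dNdx[[q]] (list of 8 arrays ne x 8 x 3) and the
# quadrature weights wdet (ne x 8; unit Gauss weights).
fem_precompute <- function(mesh) {
  if (!is.null(mesh$.pre)) return(mesh$.pre)
  elems <- mesh$elems
  ne <- nrow(elems)
  X <- array(0, c(ne, 8, 3))
  for (a in 1:8) X[, a, ] <- mesh$nodes[elems[, a], , drop = FALSE]
  dNdx <- vector("list", 8)
  detJ <- matrix(0, ne, 8)
  for (q in 1:8) {
    dn <- hex_ref$dN[q, , ]  # 8 x 3
    J <- array(0, c(ne, 3, 3))
    for (i in 1:3) for (j in 1:3)
      J[, i, j] <- X[, , i] %*% dn[, j]
    d <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
         J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
         J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
    detJ[, q] <- d
    inv <- array(0, c(ne, 3, 3))  # inv[ , j, i] = (J^-1)_{ji}
    inv[, 1, 1] <- (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) / d
    inv[, 1, 2] <- (J[, 1, 3] * J[, 3, 2] - J[, 1, 2] * J[, 3, 3]) / d
    inv[, 1, 3] <- (J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]) / d
    inv[, 2, 1] <- (J[, 2, 3] * J[, 3, 1] - J[, 2, 1] * J[, 3, 3]) / d
    inv[, 2, 2] <- (J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]) / d
    inv[, 2, 3] <- (J[, 1, 3] * J[, 2, 1] - J[, 1, 1] * J[, 2, 3]) / d
    inv[, 3, 1] <- (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]) / d
    inv[, 3, 2] <- (J[, 1, 2] * J[, 3, 1] - J[, 1, 1] * J[, 3, 2]) / d
    inv[, 3, 3] <- (J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]) / d
    dd <- array(0, c(ne, 8, 3))
    for (a in 1:8) for (i in 1:3)
      dd[, a, i] <- inv[, 1, i] * dn[a, 1] + inv[, 2, i] * dn[a, 2] +
                    inv[, 3, i] * dn[a, 3]
    dNdx[[q]] <- dd
  }
  list(dNdx = dNdx, detJ = detJ, wdet = detJ)  # unit Gauss weights
}

# Assemble K (elastic), Q (pressure-divergence coupling), H (permeability
# Laplacian) and the gradient-volume operator G0 used by the osmotic terms.
# `props`: list with per-element vectors lambda, mu, k.
fem_assemble <- function(mesh, pre, props) {
  elems <- mesh$elems
  ne <- nrow(elems)
  nn <- nrow(mesh$nodes)
  ndof_u <- 3L * nn

  udof <- function(a, i) 3L * (elems[, a] - 1L) + i

  nK <- ne * 64L * 9L
  iK <- integer(nK); jK <- integer(nK); xK <- numeric(nK)
  nQ <- ne * 64L * 3L
  iQ <- integer(nQ); jQ <- integer(nQ); xQ <- numeric(nQ)
  nH <- ne * 64L
  iH <- integer(nH); jH <- integer(nH); xH <- numeric(nH)

  Kacc <- array(0, c(ne, 8, 8, 3, 3))
  Qacc <- array(0, c(ne, 8, 3, 8))
  Hacc <- array(0, c(ne, 8, 8))
  for (q in 1:8) {
    dd <- pre$dNdx[[q]]
    w <- pre$wdet[, q]
    Nq <- hex_ref$N[q, ]
    wl <- w * props$lambda
    wm <- w * props$mu
    wk <- w * props$k
    for (a in 1:8) {
      da <- dd[, a, ]
      for (b in 1:8) {
        db <- dd[, b, ]
        dot <- da[, 1] * db[, 1] + da[, 2] * db[, 2] + da[, 3] * db[, 3]
        for (i in 1:3) for (j in 1:3) {
          v <- wl * da[, i] * db[, j] + wm * db[, i] * da[, j]
          if (i == j) v <- v + wm * dot
          Kacc[, a, b, i, j] <- Kacc[, a, b, i, j] + v
        }
        Hacc[, a, b] <- Hacc[, a, b] + wk * dot
        Qacc[, a, , b] <- Qacc[, a, , b] + w * Nq[b] * da
      }
    }
  }

  idx <- 0L
  for (a in 1:8) for (b in 1:8) for (i in 1:3) for (j in 1:3) {
    rng <- idx + seq_len(ne)
    iK[rng] <- udof(a, i); jK[rng] <- udof(b, j)
    xK[rng] <- Kacc[, a, b, i, j]
    idx <- idx + ne
  }
  idx <- 0L
  for (a in 1:8) for (i in 1:3) for (b in 1:8) {
    rng <- idx + seq_len(ne)
    iQ[rng] <- udof(a, i); jQ[rng] <- elems[, b]
    xQ[rng] <- Qacc[, a, i, b]
    idx <- idx + ne
  }
  idx <- 0L
  for (a in 1:8) for (b in 1:8) {
    rng <- idx + seq_len(ne)
    iH[rng] <- elems[, a]; jH[rng] <- elems[, b]
    xH[rng] <- Hacc[, a, b]
    idx <- idx + ne
  }

  K <- Matrix::sparseMatrix(i = iK, j = jK, x = xK, dims = c(ndof_u, ndof_u))
  Q <- Matrix::sparseMatrix(i = iQ, j = jQ, x = xQ, dims = c(ndof_u, nn))
  H <- Matrix::sparseMatrix(i = iH, j = jH, x = xH, dims = c(nn, nn))

  # G0: (3n x 8 ne), column per Gauss point, entries dNa_i * sqrt(wdet)
  sw <- sqrt(pre$wdet)
  iG <- integer(ne * 8L * 24L); jG <- integer(ne * 8L * 24L)
  xG <- numeric(ne * 8L * 24L)
  idx <- 0L
  for (q in 1:8) {
    dd <- pre$dNdx[[q]]
    col <- (seq_len(ne) - 1L) * 8L + q
    for (a in 1:8) for (i in 1:3) {
      rng <- idx + seq_len(ne)
      iG[rng] <- udof(a, i); jG[rng] <- col
      xG[rng] <- dd[, a, i] * sw[, q]
      idx <- idx + ne
    }
  }
  G0 <- Matrix::sparseMatrix(i = iG, j = jG, x = xG,
                             dims = c(ndof_u, ne * 8L))
  list(K = K, Q = Q, H = H, G0 = G0, sqrt_wdet = as.numeric(t(sw)))
}
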