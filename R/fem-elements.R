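# Trilinear hexahedral element matrices on cubic voxels of edge h.
# All integrals are exact for the 2x2x2 Gauss rule used.

# local node order: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
.HEX_LC <- matrix(c(-1, -1, -1,
                    1, -1, -1,
                    1,  1, -1,
                    -1,  1, -1,
                    -1, -1,  1,
                    1, -1,  1,
                    1,  1,  1,
                    -1,  1,  1), ncol = 3L, byrow = TRUE)

# Geometric element integrals for a cube of edge h:
#   Q0 (24x8): int dN_a/dx_d N_b dV   (volumetric-strain / pressure coupling, unit alpha)
#   Me (8x8):  int N_a N_b dV         (storage, unit 1/M)
#   Le (8x8):  int grad N_a . grad N_b dV  (permeability / stabilization Laplacian, unit k)
#   Gc (8x3):  dN/dx at the element centroid (strain & Darcy recovery)
#   Bgp:       strain-displacement matrices at the Gauss points (for K)
.hex_geometry <- function(h) {
  g <- 1 / sqrt(3)
  detJ <- (h / 2)^3
  Q0 <- matrix(0, 24L, 8L)
  Me <- matrix(0, 8L, 8L)
  Le <- matrix(0, 8L, 8L)
  Bgp <- vector("list", 8L)
  gp <- 0L
  for (zi in c(-g, g)) for (yi in c(-g, g)) for (xi in c(-g, g)) {
    gp <- gp + 1L
    N <- (1 + .HEX_LC[, 1L] * xi) * (1 + .HEX_LC[, 2L] * yi) *
      (1 + .HEX_LC[, 3L] * zi) / 8
    dN <- cbind(.HEX_LC[, 1L] * (1 + .HEX_LC[, 2L] * yi) * (1 + .HEX_LC[, 3L] * zi),
                .HEX_LC[, 2L] * (1 + .HEX_LC[, 1L] * xi) * (1 + .HEX_LC[, 3L] * zi),
                .HEX_LC[, 3L] * (1 + .HEX_LC[, 1L] * xi) * (1 + .HEX_LC[, 2L] * yi)) /
      8 * (2 / h)                               # dN/dx, 8 x 3
    B <- matrix(0, 6L, 24L)
    ix <- 3L * (1:8) - 2L
    B[1L, ix]      <- dN[, 1L]
    B[2L, ix + 1L] <- dN[, 2L]
    B[3L, ix + 2L] <- dN[, 3L]
    B[4L, ix]      <- dN[, 2L]; B[4L, ix + 1L] <- dN[, 1L]
    B[5L, ix + 1L] <- dN[, 3L]; B[5L, ix + 2L] <- dN[, 2L]
    B[6L, ix]      <- dN[, 3L]; B[6L, ix + 2L] <- dN[, 1L]
    Bgp[[gp]] <- B
    Me <- Me + (N %o% N) * detJ
    Le <- Le + (dN %*% t(dN)) * detJ
    # Q0[3(a-1)+d, b] += dN[a,d] * N[b] * detJ
    for (d in 1:3)
      Q0[ix + (d - 1L), ] <- Q0[ix + (d - 1L), ] + (dN[, d] %o% N) * detJ
  }
  Gc <- .HEX_LC / (4 * h)                        # centroid dN/dx
  list(Q0 = Q0, Me = Me, Le = Le, Gc = Gc, Bgp = Bgp, detJ = detJ, h = h)
}

# isotropic stiffness matrix (24x24) for the cube geometry `geo`
.hex_stiffness <- function(geo, E, nu) {
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(0, 0, 0, mu, mu, mu))
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  K <- matrix(0, 24L, 24L)
  for (B in geo$Bgp) K <- K + t(B) %*% D %*% B * geo$detJ
  K
}

# sparse assembly of an m x m element matrix pattern over element dof tables
# rows: erow (E x m), cols: ecol (E x n), per-label element matrices in `mats`
# (list indexed by label value), optional per-element scale.
.assemble_block <- function(erow, ecol, labels, mats, ndof, scale = NULL) {
  m <- ncol(erow); n <- ncol(ecol)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (lab in sort(unique(labels))) {
    sel <- which(labels == lab)
    ne <- length(sel)
    ke <- as.numeric(mats[[lab]])                # length m*n, column-major
    i <- as.vector(t(erow[sel, rep(seq_len(m), times = n), drop = FALSE]))
    j <- as.vector(t(ecol[sel, rep(seq_len(n), each = m), drop = FALSE]))
    x <- rep(ke, ne)
    if (!is.null(scale)) x <- x * rep(scale[sel], each = m * n)
    ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, x)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
}
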