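# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles rather than calling package internals.

# Coherence-constraint truth table, transcribed directly from the printed
# constraint table: topology S (0 < Ds <= Luc) requires 0 < Dc <= Ds/2;
# topology L (Luc < Ds <= 2 Luc) requires sqrt(Ds^2 - Luc^2) < Dc <= Ds/2.
oracle_table1_feasible <- function(Ds, Dc, Luc) {
  if (Ds <= 0 || Dc <= 0 || Ds > 2 * Luc) return(FALSE)
  if (Ds <= Luc) {
    Dc <= Ds / 2
  } else {
    sqrt(Ds^2 - Luc^2) < Dc & Dc <= Ds / 2
  }
}

# Monte-Carlo point-membership estimate of the solid volume fraction of one
# unit cell (sphere + 3 cylinders subtracted from the cube).
oracle_mc_vf <- function(spec, n = 1e6, seed = 424242) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- matrix(runif(3 * n, -spec$Luc / 2, spec$Luc / 2), ncol = 3L)
  rs2 <- (spec$Ds / 2)^2
  rc2 <- (spec$Dc / 2)^2
  x2 <- p[, 1]^2; y2 <- p[, 2]^2; z2 <- p[, 3]^2
  pore <- (x2 + y2 + z2 <= rs2) | (x2 + y2 <= rc2) |
    (x2 + z2 <= rc2) | (y2 + z2 <= rc2)
  vf <- 1 - mean(pore)
  attr(vf, "sd") <- sqrt(vf * (1 - vf) / n)
  vf
}

# Closed-form 1-D consolidation (single drainage path at the top z = H,
# impermeable base, step total stress sigma): initial excess pressure
# p0 = alpha M sigma / (Ec + alpha^2 M) with Ec the drained confined
# modulus; decay governed by cv = k M Ec / (Ec + alpha^2 M).
oracle_terzaghi <- function(mat, H, sigma, z, t, nterms = 200) {
  Ec <- mat$E * (1 - mat$nu) / ((1 + mat$nu) * (1 - 2 * mat$nu))
  M <- 1 / mat$invM
  alpha <- mat$alpha
  cv <- mat$k_mm * M * Ec / (Ec + alpha^2 * M)
  p0 <- alpha * M * sigma / (Ec + alpha^2 * M)
  s <- 0
  for (m in 0:nterms) {
    Mm <- (2 * m + 1) * pi / 2
    s <- s + 2 / Mm * sin(Mm * (1 - z / H)) * exp(-Mm^2 * cv * t / H^2)
  }
  list(p = p0 * s, cv = cv, p0 = p0)
}

# the 48 octahedral symmetries (axis permutations x sign flips) as 3x3 matrices
oracle_octahedral_group <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (pm in perms) for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
    R <- matrix(0, 3, 3)
    R[cbind(1:3, pm)] <- c(sx, sy, sz)
    out[[length(out) + 1L]] <- R
  }
  out
}

# tiny standard objects reused across files
tiny_scaffold <- function() scaffold_spec(0.5, 0.25, L = 0.637, cells_per_side = 1L)
tiny_load <- function(F_UA = 0.1) load_case("compression", F_UA)

# fabricate a minimal fem_result for pure-arithmetic checks
fake_result <- function(u2, F_UA = 0.1, L = 2.548) {
  structure(list(model = list(extent = c(L, L, L)),
                 times = 1, u2 = u2,
                 load = load_case("compression", F_UA)),
            class = "fem_result")
}
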