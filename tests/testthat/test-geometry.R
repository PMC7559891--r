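test_that("topology classification follows the Ds bands", {
  expect_identical(classify_topology(0.5, 0.637), "S")
  expect_identical(classify_topology(0.637, 0.637), "S")   # closed S boundary
  expect_identical(classify_topology(1.0, 0.637), "L")
  expect_identical(classify_topology(2 * 0.637, 0.637), "L") # closed L boundary
  expect_identical(classify_topology(1.4, 0.637), "invalid")
  expect_error(classify_topology(-0.1, 0.637), "positive")
  expect_error(classify_topology(0.5, 0), "positive")
})

test_that("chord length matches sqrt(Ds^2 - Luc^2) and its domain", {
  expect_equal(chord_length(0.637, 0.637), 0)
  expect_equal(chord_length(2 * 0.637, 0.637), 0.637 * sqrt(3))
  expect_equal(chord_length(0.85, 0.637), sqrt(0.85^2 - 0.637^2))
  expect_equal(chord_length(0.85, 0.637), 0.5628, tolerance = 1e-4)
  expect_error(chord_length(0.5, 0.637), "undefined")
})

test_that("spec constructors reject impossible geometry", {
  expect_error(unit_cell_spec(0.637, 1.4, 0.2), "not allowed")
  expect_error(unit_cell_spec(0.637, -1, 0.2), "positive")
  expect_error(scaffold_spec(0.5, 0.25, cells_per_side = 0), "positive integer")
  sp <- scaffold_spec(0.5, 0.25)
  expect_equal(sp$cell$Luc, 2.548 / 4)
})

test_that("validate_cell reproduces the printed constraints and both dialects", {
  # boundary Dc = Ds/2 is valid
  expect_true(validate_cell(unit_cell_spec(0.637, 0.5, 0.25))$valid)
  # the normalized-stimulus-map geometry: rejected as printed, accepted derived
  v1 <- validate_cell(unit_cell_spec(0.637, 0.425, 0.275, "as_printed"))
  expect_false(v1$valid)
  expect_match(v1$violations, "Ds/2", all = FALSE)
  v2 <- validate_cell(unit_cell_spec(0.637, 0.425, 0.275, "derived"))
  expect_true(v2$valid)
  # topology L lower bound is strict
  C <- chord_length(0.9, 0.637)
  expect_false(validate_cell(unit_cell_spec(0.637, 0.9, C))$valid)
  expect_true(validate_cell(unit_cell_spec(0.637, 0.9, C + 1e-6, "derived"))$valid)
})

test_that("validate_cell truth table matches the independent constraint oracle", {
  Luc <- 0.637
  Dss <- seq(0.05, 2 * Luc, length.out = 20)
  Dcs <- seq(0.02, 0.9, length.out = 20)
  for (Ds in Dss) for (Dc in Dcs) {
    got <- validate_cell(unit_cell_spec(Luc, Ds, Dc, "as_printed"))$valid
    expect_identical(got, oracle_table1_feasible(Ds, Dc, Luc),
                     label = sprintf("Ds=%.3f Dc=%.3f", Ds, Dc))
  }
})

test_that("phase membership: landmark points and domain check", {
  spec <- unit_cell_spec(0.637, 0.5, 0.25)
  expect_identical(phase_at_point(c(0, 0, 0), spec), "pore")
  expect_identical(phase_at_point(c(0, 0, 0.637 / 2), spec), "pore") # cylinder axis
  h <- 0.637 / 2
  expect_identical(phase_at_point(c(h, h, h), spec), "scaffold_solid")
  expect_error(phase_at_point(c(h * 1.1, 0, 0), spec), "outside")
  # corner is solid for every constraint-valid spec of either topology
  # (as_printed caps topology L at Ds < 2*Luc/sqrt(3); derived at Luc*sqrt(2))
  cases <- list(c(0.3, 0.15, 1), c(0.637, 0.3, 1), c(0.7, 0.33, 1),
                c(0.85, 0.58, 2))
  for (cs in cases) {
    dial <- c("as_printed", "derived")[cs[3]]
    sp <- unit_cell_spec(0.637, cs[1], cs[2], dial)
    expect_true(validate_cell(sp)$valid)
    expect_identical(phase_at_point(c(h, h, h), sp), "scaffold_solid")
  }
})

test_that("phase membership is invariant under the 48 octahedral symmetries", {
  spec <- unit_cell_spec(0.637, 0.8, 0.38, "as_printed")
  set.seed(7)
  pts <- matrix(runif(60, -0.637 / 2, 0.637 / 2), ncol = 3L)
  ref <- phase_at_point(pts, spec)
  for (R in oracle_octahedral_group()) {
    expect_identical(phase_at_point(pts %*% t(R), spec), ref)
  }
})

test_that("unit-cell voxelization reproduces the analytic sphere volume", {
  spec <- unit_cell_spec(0.637, 0.637, 1e-6)
  target <- 1 - pi / 6
  errs <- vapply(c(16L, 32L, 64L), function(r)
    abs(volume_fraction(build_unit_cell(spec, r)) - target), numeric(1L))
  expect_lt(errs[3L], 0.01 * target)
  expect_lt(errs[2L], 0.5 * errs[1L])
  expect_lt(errs[3L], 0.5 * errs[2L])
})

test_that("degenerate tiny pores give Vf -> 1 and invalid specs are refused", {
  g <- build_unit_cell(unit_cell_spec(0.637, 1e-3, 1e-4), 8L)
  expect_equal(volume_fraction(g), 1)
  expect_error(build_unit_cell(unit_cell_spec(0.637, 0.425, 0.275), 8L),
               "invalid unit cell spec")
  expect_error(build_unit_cell(unit_cell_spec(0.637, 0.5, 0.25), 3L), ">= 4")
})

test_that("pore space is one 6-connected component touching all faces", {
  for (par in list(c(0.5, 0.25), c(0.9, 0.4), c(1.2, 0.55))) {
    dial <- if (par[1] > 0.637 * sqrt(4 / 3)) "derived" else "as_printed"
    sp <- unit_cell_spec(0.637, par[1], par[2], dial)
    g <- build_unit_cell(sp, 12L, enforce_constraints = FALSE)
    pc <- pore_connectivity(g)
    expect_equal(pc$n_components, 1L, label = paste("Ds =", par[1]))
    expect_true(pc$touches_all_faces)
  }
})

test_that("scaffold assembly tiles the unit cell periodically", {
  spec <- scaffold_spec(0.5, 0.25, L = 4 * 0.637, cells_per_side = 4L)
  res <- 6L
  g <- assemble_scaffold(spec, res)
  cell <- build_unit_cell(spec$cell, res)
  # identity case
  g1 <- assemble_scaffold(scaffold_spec(0.5, 0.25, L = 0.637,
                                        cells_per_side = 1L), res)
  expect_identical(g1$labels, cell$labels)
  # periodicity with period Luc in all axes
  n <- res * 4L
  expect_identical(g$labels[1:res, , ], g$labels[(res + 1):(2 * res), , ])
  expect_identical(g$labels[, 1:res, ], g$labels[, (res + 1):(2 * res), ])
  expect_identical(g$labels[, , 1:res], g$labels[, , (res + 1):(2 * res)])
  # tiling preserves the volume fraction exactly
  expect_equal(volume_fraction(g), volume_fraction(cell))
  # resource cap
  expect_error(assemble_scaffold(spec, res, max_voxels = 100), "max_voxels")
})

test_that("volume fraction is monotone over nested validation geometries", {
  res <- 16L
  vf <- vapply(list(c(0.65, 0.45), c(0.75, 0.5), c(0.85, 0.55)), function(p) {
    volume_fraction(build_unit_cell(unit_cell_spec(0.637, p[1], p[2]), res,
                                    enforce_constraints = FALSE))
  }, numeric(1L))
  expect_true(vf[1] > vf[2] && vf[2] > vf[3])
})

test_that("voxel Vf converges to the Monte-Carlo membership oracle", {
  spec <- unit_cell_spec(0.637, 0.7, 0.33, "as_printed")
  mc <- oracle_mc_vf(spec, n = 2e6)
  e8 <- abs(volume_fraction(build_unit_cell(spec, 8L)) - mc)
  e16 <- abs(volume_fraction(build_unit_cell(spec, 16L)) - mc)
  e32 <- abs(volume_fraction(build_unit_cell(spec, 32L)) - mc)
  noise <- 3 * attr(mc, "sd")
  expect_lt(e16, 0.5 * e8 + noise)
  expect_lt(e32, 0.5 * e16 + noise)
})
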