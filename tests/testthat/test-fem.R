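test_that("material constructor enforces physical ranges", {
  expect_error(material_properties(1000, 0.5, 1e-14, 0.5, 13920, 2300), "nu")
  expect_error(material_properties(-1, 0.3, 1e-14, 0.5, 13920, 2300))
  m <- default_materials()
  expect_equal(m$scaffold_solid$E, 1000)
  expect_equal(m$granulation$k_mm, 1e-2)           # 1e-14 m^4/(Ns) in mm units
  expect_lt(m$granulation$alpha, 1)
  expect_gt(m$granulation$alpha, 0.999)            # soft tissue: alpha ~ 1
})

test_that("model construction: dof counts, encastre set, drainage audit", {
  fx <- generate_fixture("tiny_cell")
  g <- assemble_scaffold(fx$spec, 8L)
  m <- build_fe_model(g, load = fx$load)
  expect_equal(m$nn, 9L^3)
  expect_equal(m$ndof, 4L * 9L^3 + 3L)             # + rigid-plate reference
  # every base-face node has all three displacement components fixed
  b <- m$sets$base_nodes
  expect_length(b, 9L^2)
  expect_true(all(m$fixed[c(3L * b - 2L, 3L * b - 1L, 3L * b)]))
  # no scaffold-labeled exterior face carries a drainage condition
  df <- m$sets$drained_faces
  drained_by_builder <- df[df$label == 2L, ]
  expect_true(nrow(drained_by_builder) > 0)
  gran_nodes <- m$sets$drained_nodes
  # drained nodes all touch at least one granulation element
  gran_elem_nodes <- unique(as.vector(m$conn[m$elabel == 2L, ]))
  expect_true(all(gran_nodes %in% gran_elem_nodes))
  # the top face is sealed: no drained node lies strictly inside the top face
  d <- m$mesh$dims
  interior_top <- setdiff(m$sets$plate_nodes,
                          which(rep(TRUE, m$nn))[0])  # all top nodes
  k_of <- function(id) (id - 1L) %/% ((d[1] + 1L) * (d[2] + 1L))
  i_of <- function(id) (id - 1L) %% (d[1] + 1L)
  j_of <- function(id) ((id - 1L) %/% (d[1] + 1L)) %% (d[2] + 1L)
  top_interior <- interior_top[i_of(interior_top) %in% 1:(d[1] - 1L) &
                               j_of(interior_top) %in% 1:(d[2] - 1L)]
  expect_false(any(top_interior %in% gran_nodes))
  # single-phase grid refused for the scaffold template
  solid <- labeled_grid(array(1L, c(8L, 8L, 8L)), 0.1)
  expect_error(build_fe_model(solid, load = fx$load), "both materials")
})

test_that("load magnitudes follow |F| = F_UA * L^2 and the mode", {
  g <- assemble_scaffold(scaffold_spec(0.5, 0.25), 4L)
  m <- build_fe_model(g, load = load_case("compression", 0.1))
  expect_equal(m$total_force, 0.1 * 2.548^2)
  expect_equal(m$f[m$master_dofs[3L]], -0.1 * 2.548^2)
  m2 <- apply_load_case(m, load_case("shear", 0.2))
  expect_equal(m2$f[m2$master_dofs[1L]], +0.2 * 2.548^2)
  expect_equal(m2$f[m2$master_dofs[3L]], 0)
  # the published shear magnitudes are all accepted
  for (f in c(0.01, 0.05, 0.1, 0.2, 0.5))
    expect_s3_class(load_case("shear", f), "load_case")
  m0 <- apply_load_case(m, load_case("compression", 0))
  expect_true(all(m0$f == 0))
})

test_that("zero load gives zero displacement and pressure everywhere", {
  fx <- generate_fixture("tiny_cell")
  g <- assemble_scaffold(fx$spec, 6L)
  m <- build_fe_model(g, load = load_case("compression", 0))
  r <- solve_consolidation(m)
  expect_equal(max(abs(r$X)), 0)
})

test_that("strain recovery: rigid motion, patch test, face-difference oracle", {
  fx <- generate_fixture("tiny_cell")
  g <- assemble_scaffold(fx$spec, 6L)
  m <- build_fe_model(g, load = fx$load)
  nn <- m$nn
  d <- m$mesh$dims
  coords <- function(id) {
    i <- (id - 1L) %% (d[1] + 1L)
    j <- ((id - 1L) %/% (d[1] + 1L)) %% (d[2] + 1L)
    k <- (id - 1L) %/% ((d[1] + 1L) * (d[2] + 1L))
    cbind(i, j, k) * m$mesh$h
  }
  xyz <- coords(seq_len(nn))
  mk_res <- function(u) structure(list(model = m, times = 1,
                                       X = matrix(c(t(u), numeric(nn + 3L)),
                                                  ncol = 1L),
                                       u2 = 0, load = m$load),
                                  class = "fem_result")
  # rigid translation
  u <- matrix(rep(c(0.3, -0.2, 0.1), each = nn), ncol = 3L)
  expect_equal(max(abs(element_strains(mk_res(u)))), 0)
  # uniform uniaxial stretch u_z = a z  ->  ezz = a exactly
  a <- 0.01
  u <- cbind(0 * xyz[, 1], 0 * xyz[, 2], a * xyz[, 3])
  eps <- element_strains(mk_res(u))
  expect_equal(unname(range(eps[, "ezz"])), c(a, a))
  expect_equal(max(abs(eps[, colnames(eps) != "ezz"])), 0)
  # random nodal field vs the independent face-average central difference
  set.seed(21)
  u <- matrix(rnorm(3L * nn, sd = 1e-3), ncol = 3L)
  eps <- element_strains(mk_res(u))
  conn <- m$conn
  face_diff <- function(vals, plus, minus)
    (rowMeans(matrix(vals[conn[, plus]], ncol = 4L)) -
     rowMeans(matrix(vals[conn[, minus]], ncol = 4L))) / m$mesh$h
  dux_dx <- face_diff(u[, 1], c(2L, 3L, 6L, 7L), c(1L, 4L, 5L, 8L))
  duz_dz <- face_diff(u[, 3], 5:8, 1:4)
  duy_dx <- face_diff(u[, 2], c(2L, 3L, 6L, 7L), c(1L, 4L, 5L, 8L))
  dux_dy <- face_diff(u[, 1], c(3L, 4L, 7L, 8L), c(1L, 2L, 5L, 6L))
  expect_equal(eps[, "exx"], dux_dx, tolerance = 1e-8)
  expect_equal(eps[, "ezz"], duz_dz, tolerance = 1e-8)
  expect_equal(eps[, "exy"], 0.5 * (duy_dx + dux_dy), tolerance = 1e-8)
})

test_that("Darcy velocity: unit conversion, zero field, linearity in k", {
  fx <- generate_fixture("tiny_cell")
  g <- assemble_scaffold(fx$spec, 6L)
  m <- build_fe_model(g, load = fx$load)
  nn <- m$nn
  d <- m$mesh$dims
  kz <- (seq_len(nn) - 1L) %/% ((d[1] + 1L) * (d[2] + 1L))
  z <- kz * m$mesh$h
  mk_res <- function(p) structure(list(model = m, times = 1,
                                       X = matrix(c(numeric(3L * nn), p, 0, 0, 0),
                                                  ncol = 1L),
                                       u2 = 0, load = m$load),
                                  class = "fem_result")
  # uniform pressure -> zero velocity
  expect_equal(max(abs(darcy_velocities(mk_res(rep(2, nn))))), 0)
  # 1 MPa/mm gradient with k = 1e-14 m^4/(Ns) -> |v| = 10 um/s
  v <- darcy_velocities(mk_res(-z))
  gran <- m$elabel == 2L
  expect_equal(unname(v[gran, "vz"]), rep(10, sum(gran)), tolerance = 1e-10)
  # doubling k doubles v
  mats2 <- default_materials()
  mats2$granulation <- material_properties(0.2, 0.167, 2e-14, 0.8, 2300, 2300)
  v2 <- darcy_velocities(mk_res(-z), materials = mats2)
  expect_equal(v2[gran, "vz"], 2 * v[gran, "vz"])
  # seepage velocity is flux / porosity
  vs <- darcy_velocities(mk_res(-z), measure = "seepage")
  expect_equal(vs[gran, "vz"], v[gran, "vz"] / 0.8)
})

test_that("global equilibrium and linear scaling with F_UA", {
  fx <- generate_fixture("tiny_cell")
  g <- assemble_scaffold(fx$spec, 8L)
  m <- build_fe_model(g, load = fx$load)
  r <- solve_consolidation(m)
  expect_lt(abs(r$reaction_base[3L] - m$total_force) / m$total_force, 1e-6)
  # linearity of the model in the load
  m2 <- apply_load_case(m, load_case("compression", 0.2))
  r2 <- solve_consolidation(m2)
  expect_equal(r2$u2, 2 * r$u2, tolerance = 1e-10)
})

test_that("instantaneous response is stiffer than the drained response", {
  fx <- generate_fixture("tiny_cell")
  g <- assemble_scaffold(fx$spec, 6L)
  m <- build_fe_model(g, load = load_case("compression", 0.1, schedule = "step"))
  r <- solve_consolidation(m)
  expect_lte(abs(r$u2[1L]), abs(r$u2[length(r$u2)]) + 1e-15)
  # and |u2| grows monotonically as the fluid drains
  expect_true(all(diff(abs(r$u2)) >= -1e-12))
})

test_that("consolidation matches the closed-form column solution and refines", {
  fx <- generate_fixture("terzaghi_column")
  H <- fx$height
  mat <- fx$material
  ora <- oracle_terzaghi(mat, H, fx$load$F_UA, 0, 1)
  tc <- H^2 / ora$cv
  # early time, fine uniform steps: the spatial error dominates, so mesh
  # refinement must show
  Tv <- 0.05
  times <- tc * seq(Tv / 400, Tv, length.out = 400L)
  err_at <- function(nz) {
    grid <- labeled_grid(array(2L, c(1L, 1L, nz)), H / nz)
    m <- build_fe_model(grid, load = fx$load, bc = "column")
    r <- solve_consolidation(m, times = times)
    ids <- 1L + 4L * (0:nz)
    z <- (0:nz) * H / nz
    pan <- oracle_terzaghi(mat, H, fx$load$F_UA, z, times[length(times)])$p
    pfe <- pore_pressure(r)[ids]
    sqrt(sum((pfe - pan)^2) / sum(pan^2))
  }
  e10 <- err_at(10L)
  e40 <- err_at(40L)
  expect_lt(e40, 0.02)
  expect_lt(e40, e10)           # error decreases with mesh refinement
})

test_that("apparent modulus: homogeneous patch test and arithmetic", {
  fx <- generate_fixture("homogeneous_cube")
  m <- build_fe_model(fx$grid, load = fx$load, bc = "uniaxial")
  r <- solve_elastic(m)
  expect_equal(apparent_modulus(r), 1000, tolerance = 5e-3)
  # direct arithmetic of the definition
  expect_equal(apparent_modulus(fake_result(u2 = 0.001)), 254.8)
  expect_error(apparent_modulus(fake_result(u2 = 0)), "degenerate")
  shear_res <- fake_result(0.001)
  shear_res$load <- load_case("shear", 0.1)
  expect_error(apparent_modulus(shear_res), "compression")
})

test_that("detached thin frames are flagged instead of solved near-singular", {
  sp <- scaffold_spec(0.85, 0.55, L = 2 * 0.637, cells_per_side = 2L)
  g <- assemble_scaffold(sp, 8L, enforce_constraints = FALSE)
  expect_warning(m <- build_fe_model(g, load = load_case("compression", 0.1),
                                     phases = "solid_only"),
                 "no solid load path")
  r <- solve_elastic(m)
  expect_true(is.infinite(r$u2))
  expect_warning(ea <- apparent_modulus(r), "detached")
  expect_equal(ea, 0)
})
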