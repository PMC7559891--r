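test_that("CLI validate/build: exit codes and constraint messages", {
  out <- withr::local_tempdir()
  expect_output(
    code <- run_cli(c("validate", "--ds", "0.5", "--dc", "0.25",
                      "--L", "2.548")),
    "topology S")
  expect_equal(code, 0L)
  expect_output(
    code <- run_cli(c("validate", "--ds", "0.425", "--dc", "0.275",
                      "--L", "2.548")),
    "INVALID")
  expect_equal(code, 2L)
  # sphere larger than twice the cell edge is refused with the rule cited
  expect_message(
    code <- run_cli(c("build", "--ds", "1.4", "--dc", "0.2", "--L", "2.548",
                      "--out", out)),
    "not allowed")
  expect_equal(code, 2L)
  expect_equal(run_cli(c("frobnicate")), 2L)
  expect_equal(suppressMessages(run_cli(c("validate", "--bogus", "1"))), 2L)
})

test_that("CLI build writes grid, surface and manifest", {
  out <- withr::local_tempdir()
  expect_message(
    code <- run_cli(c("build", "--ds", "0.5", "--dc", "0.25", "--L", "0.637",
                      "--cells", "1", "--resolution", "6", "--out", out)),
    "Vf")
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "grid.vti")))
  expect_true(file.exists(file.path(out, "scaffold.stl")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$package, "scaffopt")
  expect_equal(man$config$Ds_mm, 0.5)
  stl <- readLines(file.path(out, "scaffold.stl"))
  expect_identical(stl[1], "solid scaffold")
  nv <- sum(startsWith(trimws(stl), "vertex"))
  expect_equal(nv %% 3, 0)
  expect_gt(nv, 0)
})

test_that("run_config validates keys and merges file with overrides", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(L_mm = 1.0, resolution = 6), f, auto_unbox = TRUE)
  cfg <- run_config(f, Ds_mm = 0.3)
  expect_equal(cfg$L_mm, 1.0)
  expect_equal(cfg$Ds_mm, 0.3)
  expect_equal(cfg$cells_per_side, 4L)
  expect_error(run_config(bogus_key = 1), "unknown config key")
  expect_error(run_config(mode = "torsion"), "mode")
})

test_that("VTK field export round-trips values", {
  skip_if_not_installed("xml2")
  fx <- generate_fixture("tiny_cell")
  g <- assemble_scaffold(fx$spec, 6L)
  m <- build_fe_model(g, load = fx$load)
  r <- solve_consolidation(m)
  field <- compute_stimulus_field(r)
  path <- withr::local_tempfile(fileext = ".vti")
  write_fields_vtk(r, field, path)
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, "//DataArray")
  nm <- xml2::xml_attr(arrays, "Name")
  expect_setequal(nm, c("displacement", "pressure", "label", "S",
                        "S_over_Smax", "phenotype"))
  getv <- function(name) as.numeric(strsplit(trimws(
    xml2::xml_text(arrays[nm == name][[1]])), "\\s+")[[1]])
  # normalization: the maximum of S/S_max is exactly 1
  expect_equal(max(getv("S_over_Smax")), 1)
  # S round-trips within float precision
  Sarr <- getv("S")
  expect_equal(Sarr[field$element], field$S, tolerance = 1e-6)
  # phenotype codes are integers 0..5
  ph <- getv("phenotype")
  expect_true(all(ph == round(ph) & ph >= 0 & ph <= 5))
  # grid export parses too
  p2 <- withr::local_tempfile(fileext = ".vti")
  write_grid_vtk(g, p2)
  lab <- xml2::xml_find_first(xml2::read_xml(p2), "//DataArray")
  expect_equal(as.numeric(strsplit(trimws(xml2::xml_text(lab)), "\\s+")[[1]]),
               as.numeric(g$labels))
})

test_that("fixtures carry the documented geometries", {
  f9 <- generate_fixture("fig9_geometry")
  expect_equal(f9$spec$cell$Ds, 0.425)
  expect_equal(f9$spec$cell$Dc, 0.275)
  expect_equal(f9$load$F_UA, 0.5)
  expect_identical(f9$spec$cell$constraint_dialect, "derived")
  tri <- generate_fixture("section3_triplet")
  expect_equal(tri$pairs$Ds, c(0.85, 0.75, 0.65))
  expect_equal(tri$pairs$Dc, c(0.55, 0.5, 0.45))
  expect_equal(tri$load$F_UA, 0.1)
  hc <- generate_fixture("homogeneous_cube")
  expect_equal(volume_fraction(hc$grid), 1)
  tz <- generate_fixture("terzaghi_column")
  expect_equal(tz$grid$dims, c(1L, 1L, 40L))
  expect_error(generate_fixture("nope"))
})
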