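# Configuration, CLI, file export and deterministic fixtures.
#
# Physical quantities carry their unit in the config key name (L_mm,
# F_UA_MPa, ramp_time_s, ...) to prevent unit bugs.

.default_config <- function() {
  list(
    L_mm = 2.548, cells_per_side = 4L, Ds_mm = 0.5, Dc_mm = 0.25,
    resolution = 13L, constraint_dialect = "as_printed",
    mode = "compression", F_UA_MPa = 0.1, ramp_time_s = 1,
    n_increments = 10L, schedule = "ramp",
    stimulus_a = 0.0375, stimulus_b_um_s = 3.0,
    velocity_measure = "flux", stab_c = 0.25,
    max_evaluations = 60L, seed = 1L, out_dir = ".", log_level = "info"
  )
}

.validate_config <- function(cfg) {
  d <- .default_config()
  unknown <- setdiff(names(cfg), names(d))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(d, cfg)
  num_pos <- c("L_mm", "Ds_mm", "Dc_mm", "F_UA_MPa", "ramp_time_s",
               "stimulus_a", "stimulus_b_um_s")
  for (k in num_pos)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      stop(sprintf("config key '%s' must be a non-negative number", k),
           call. = FALSE)
  if (!cfg$mode %in% c("compression", "shear"))
    stop("config key 'mode' must be 'compression' or 'shear'", call. = FALSE)
  if (!cfg$constraint_dialect %in% c("as_printed", "derived"))
    stop("config key 'constraint_dialect' must be 'as_printed' or 'derived'",
         call. = FALSE)
  cfg$cells_per_side <- as.integer(cfg$cells_per_side)
  cfg$resolution <- as.integer(cfg$resolution)
  cfg
}

#' Build a run configuration
#'
#' Merges a JSON config file (if given) and explicit overrides onto the
#' package defaults (the standard scaffold setup: L = 2.548 mm, 4 cells per
#' side, default material set and load lists) and validates every key.
#'
#' @param config_file optional path to a JSON config file.
#' @param ... key = value overrides (see [run_cli()] for the key list).
#' @return validated named list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file, call. = FALSE)
    cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
  }
  cfg <- modifyList(cfg, list(...))
  structure(.validate_config(cfg), class = "run_config")
}

.write_manifest <- function(cfg, path, extra = list()) {
  man <- c(list(package = "scaffopt",
                version = as.character(utils::packageVersion("scaffopt")),
                config = unclass(cfg),
                config_hash = sum(utf8ToInt(paste(
                  names(cfg), sapply(cfg, paste, collapse = ","),
                  collapse = ";"))),
                seed = cfg$seed),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands:
#' * `validate --ds <mm> --dc <mm> [--L <mm>] [--cells <n>] [--dialect ...]`
#'   — prints the topology and the constraint report; exit 0 if valid,
#'   2 otherwise.
#' * `build` — voxelizes the scaffold; writes `grid.vti`, `scaffold.stl`
#'   and a manifest to `--out`.
#' * `solve` — builds, solves and scores one geometry; writes `fields.vti`,
#'   `summary.csv` and a manifest.
#' * `optimize` — optimizes `(Ds, Dc)` for one load; writes `trace.json`.
#' * `sweep --mode <compression|shear>` — one optimization per default load
#'   magnitude; writes `sweep.csv`.
#'
#' Flags: `--config <file>` (JSON) plus per-key overrides `--ds --dc --L
#' --cells --resolution --dialect --mode --fua --out --seed
#' --max-evaluations`. Exit codes: 0 success, 1 compute failure, 2 invalid
#' arguments/config.
#'
#' @param argv character vector of arguments (default: the process's).
#' @return integer exit code, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(argv)) stop_cli(2L, "usage: scaffopt <validate|build|solve|optimize|sweep> [flags]")
    sub <- argv[[1L]]
    if (!sub %in% c("validate", "build", "solve", "optimize", "sweep"))
      stop_cli(2L, "unknown subcommand: ", sub)
    opts <- .parse_flags(argv[-1L])
    cfg <- tryCatch(
      do.call(run_config, c(list(config_file = opts$config), opts$overrides)),
      error = function(e) stop_cli(2L, conditionMessage(e)))
    switch(sub,
           validate = .cli_validate(cfg),
           build = .cli_build(cfg),
           solve = .cli_solve(cfg),
           optimize = .cli_optimize(cfg),
           sweep = .cli_sweep(cfg))
  }, scaffopt_cli_exit = function(e) e$code,
     error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

stop_cli <- function(code, ...) {
  message(...)
  cond <- structure(class = c("scaffopt_cli_exit", "condition"),
                    list(message = paste0(...), call = NULL, code = code))
  stop(cond)
}

.parse_flags <- function(args) {
  flag_map <- c(ds = "Ds_mm", dc = "Dc_mm", L = "L_mm", cells = "cells_per_side",
                resolution = "resolution", dialect = "constraint_dialect",
                mode = "mode", fua = "F_UA_MPa", out = "out_dir", seed = "seed",
                `max-evaluations` = "max_evaluations")
  overrides <- list()
  config <- NULL
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop_cli(2L, "unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args)) stop_cli(2L, "flag --", key, " needs a value")
    val <- args[[i + 1L]]
    i <- i + 2L
    if (key == "config") { config <- val; next }
    if (!key %in% names(flag_map)) stop_cli(2L, "unknown flag --", key)
    ck <- flag_map[[key]]
    num <- suppressWarnings(as.numeric(val))
    overrides[[ck]] <- if (ck %in% c("constraint_dialect", "mode", "out_dir"))
      val else num
  }
  list(config = config, overrides = overrides)
}

.cli_spec <- function(cfg) {
  scaffold_spec(Ds = cfg$Ds_mm, Dc = cfg$Dc_mm, L = cfg$L_mm,
                cells_per_side = cfg$cells_per_side,
                constraint_dialect = cfg$constraint_dialect)
}

.cli_validate <- function(cfg) {
  spec <- tryCatch(.cli_spec(cfg), error = function(e)
    stop_cli(2L, conditionMessage(e)))
  val <- validate_cell(spec$cell)
  print(val)
  if (val$valid) 0L else 2L
}

.cli_build <- function(cfg) {
  spec <- tryCatch(.cli_spec(cfg), error = function(e)
    stop_cli(2L, conditionMessage(e)))
  val <- validate_cell(spec$cell)
  if (!val$valid)
    stop_cli(2L, "coherence constraints violated:\n  ",
             paste(val$violations, collapse = "\n  "))
  grid <- assemble_scaffold(spec, cfg$resolution)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_grid_vtk(grid, file.path(cfg$out_dir, "grid.vti"))
  write_stl(grid, file.path(cfg$out_dir, "scaffold.stl"))
  .write_manifest(cfg, file.path(cfg$out_dir, "manifest.json"),
                  list(Vf = volume_fraction(grid)))
  message(sprintf("built %d^3 voxel grid, Vf = %.4f",
                  grid$dims[1L], volume_fraction(grid)))
  0L
}

.cli_solve <- function(cfg) {
  spec <- tryCatch(.cli_spec(cfg), error = function(e)
    stop_cli(2L, conditionMessage(e)))
  grid <- assemble_scaffold(spec, cfg$resolution)
  load <- load_case(cfg$mode, cfg$F_UA_MPa, cfg$ramp_time_s,
                    cfg$n_increments, cfg$schedule)
  model <- build_fe_model(grid, load = load, stab_c = cfg$stab_c)
  res <- solve_consolidation(model)
  field <- compute_stimulus_field(
    res, stimulus_model(cfg$stimulus_a, cfg$stimulus_b_um_s),
    measure = cfg$velocity_measure)
  bf <- bone_fraction(field, spec$L)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fields_vtk(res, field, file.path(cfg$out_dir, "fields.vti"))
  summ <- data.frame(phenotype = names(bf$shares),
                     volume_share_percent = as.numeric(bf$shares))
  write.csv(summ, file.path(cfg$out_dir, "summary.csv"), row.names = FALSE)
  .write_manifest(cfg, file.path(cfg$out_dir, "manifest.json"),
                  list(BO_percent = bf$BO_percent))
  message(sprintf("BO%% = %.3f", bf$BO_percent))
  0L
}

.cli_optimize <- function(cfg) {
  scaffold <- scaffold_spec(Ds = cfg$Ds_mm, Dc = cfg$Dc_mm, L = cfg$L_mm,
                            cells_per_side = cfg$cells_per_side,
                            constraint_dialect = cfg$constraint_dialect)
  load <- load_case(cfg$mode, cfg$F_UA_MPa, cfg$ramp_time_s,
                    cfg$n_increments, cfg$schedule)
  oc <- optimizer_config(max_evaluations = cfg$max_evaluations,
                         seed = cfg$seed, resolution = cfg$resolution,
                         constraint_dialect = cfg$constraint_dialect)
  res <- optimize_geometry(scaffold, load, oc)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(Ds_opt = res$Ds_opt, Dc_opt = res$Dc_opt,
                            BO_opt = res$BO_opt, trace = res$trace),
                       file.path(cfg$out_dir, "trace.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(cfg, file.path(cfg$out_dir, "manifest.json"))
  print(res)
  0L
}

.cli_sweep <- function(cfg) {
  scaffold <- scaffold_spec(Ds = cfg$Ds_mm, Dc = cfg$Dc_mm, L = cfg$L_mm,
                            cells_per_side = cfg$cells_per_side,
                            constraint_dialect = cfg$constraint_dialect)
  oc <- optimizer_config(max_evaluations = cfg$max_evaluations,
                         seed = cfg$seed, resolution = cfg$resolution,
                         constraint_dialect = cfg$constraint_dialect)
  tab <- load_sweep(scaffold, cfg$mode, oc)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tab, file.path(cfg$out_dir, "sweep.csv"), row.names = FALSE)
  .write_manifest(cfg, file.path(cfg$out_dir, "manifest.json"))
  message(sprintf("sweep: %d rows (%d failed)", nrow(tab), sum(tab$failed)))
  0L
}

# ---------------------------------------------------------------------------
# VTK XML image-data export (ASCII). Minimal writer: CellData/PointData
# DataArrays on the voxel grid.

.vti_header <- function(dims, h) {
  sprintf(paste0('<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">\n',
                 '  <ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="0 0 0" Spacing="%.9g %.9g %.9g">\n',
                 '    <Piece Extent="0 %d 0 %d 0 %d">\n'),
          dims[1L], dims[2L], dims[3L], h, h, h,
          dims[1L], dims[2L], dims[3L])
}

.vti_array <- function(name, values, ncomp = 1L, type = "Float32") {
  sprintf('        <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n        </DataArray>\n',
          type, name, ncomp,
          paste(format(values, trim = TRUE, digits = 9), collapse = " "))
}

#' Write a labeled grid as VTK XML image data
#'
#' @param grid a [labeled_grid()].
#' @param path output file (conventionally `.vti`).
#' @return the path, invisibly.
#' @export
write_grid_vtk <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(.vti_header(grid$dims, grid$voxel_size), file = con)
  cat("      <CellData>\n", file = con)
  cat(.vti_array("label", as.integer(grid$labels), type = "Int32"), file = con)
  cat("      </CellData>\n    </Piece>\n  </ImageData>\n</VTKFile>\n",
      file = con)
  invisible(path)
}

#' Write solved fields as VTK XML image data
#'
#' Point data: `displacement` (3 components, mm) and `pressure` (MPa, fluid
#' models). Cell data: `label`, and for a supplied stimulus field `S`,
#' `S_over_Smax` and `phenotype` (integer codes 1..5 in the order
#' resorption, mature bone, immature bone, cartilage, fibrous; scaffold
#' voxels carry 0).
#'
#' @param result a `fem_result` on a full voxel grid.
#' @param field optional [compute_stimulus_field()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fields_vtk <- function(result, field = NULL, path) {
  m <- result$model
  if (nrow(m$conn) != prod(m$mesh$dims))
    stop("field export requires a full-grid model (phases = 'both')",
         call. = FALSE)
  x <- result$X[, ncol(result$X)]
  con <- file(path, "w")
  on.exit(close(con))
  cat(.vti_header(m$mesh$dims, m$mesh$h), file = con)
  cat("      <PointData>\n", file = con)
  U <- rbind(x[seq(1L, 3L * m$nn, 3L)], x[seq(2L, 3L * m$nn, 3L)],
             x[seq(3L, 3L * m$nn, 3L)])
  cat(.vti_array("displacement", as.numeric(U), ncomp = 3L), file = con)
  if (m$fluid)
    cat(.vti_array("pressure", x[(3L * m$nn + 1L):(4L * m$nn)]), file = con)
  cat("      </PointData>\n      <CellData>\n", file = con)
  cat(.vti_array("label", m$elabel, type = "Int32"), file = con)
  if (!is.null(field)) {
    ne <- nrow(m$conn)
    Sarr <- numeric(ne); Sarr[field$element] <- field$S
    ph <- integer(ne); ph[field$element] <- as.integer(field$phenotype)
    cat(.vti_array("S", Sarr), file = con)
    cat(.vti_array("S_over_Smax", Sarr / field$S_max), file = con)
    cat(.vti_array("phenotype", ph, type = "Int32"), file = con)
  }
  cat("      </CellData>\n    </Piece>\n  </ImageData>\n</VTKFile>\n",
      file = con)
  invisible(path)
}

#' Write the scaffold surface as ASCII STL
#'
#' Exports the exact boundary surface of the voxelized solid (two triangles
#' per exposed voxel face) for visual inspection and manufacturability
#' checks.
#'
#' @param grid a [labeled_grid()].
#' @param path output file.
#' @return the path, invisibly; the facet count as `attr(, "n_facets")`.
#' @export
write_stl <- function(grid, path) {
  solid <- grid$labels == PHASE_SOLID
  d <- grid$dims; h <- grid$voxel_size
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- solid
  facets <- list()
  n_facets <- 0L
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  core <- which(pad)
  dp <- dim(pad)
  for (dv in dirs) {
    off <- dv[1] + dp[1] * (dv[2] + dp[2] * dv[3])
    exposed <- core[!pad[core + off]]
    if (!length(exposed)) next
    i <- (exposed - 1L) %% dp[1] - 1L       # back to 0-based grid coords
    j <- ((exposed - 1L) %/% dp[1]) %% dp[2] - 1L
    k <- (exposed - 1L) %/% (dp[1] * dp[2]) - 1L
    facets[[length(facets) + 1L]] <- .stl_faces(i, j, k, dv, h)
    n_facets <- n_facets + 2L * length(exposed)
  }
  txt <- c("solid scaffold", unlist(facets), "endsolid scaffold")
  writeLines(txt, path)
  out <- path
  attr(out, "n_facets") <- n_facets
  invisible(out)
}

# triangles for the voxel faces at 0-based voxel coords (i,j,k), outward
# direction dv; vectorized over faces
.stl_faces <- function(i, j, k, dv, h) {
  # corner offsets of the exposed face, ordered CCW seen from outside
  face_corners <- function(dv) {
    if (dv[1] == 1)  return(rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1)))
    if (dv[1] == -1) return(rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0)))
    if (dv[2] == 1)  return(rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0)))
    if (dv[2] == -1) return(rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)))
    if (dv[3] == 1)  return(rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)))
    rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0))
  }
  fc <- face_corners(dv)
  nrm <- sprintf("  facet normal %d %d %d", dv[1], dv[2], dv[3])
  vline <- function(a) sprintf("      vertex %.9g %.9g %.9g",
                               (i + fc[a, 1]) * h, (j + fc[a, 2]) * h,
                               (k + fc[a, 3]) * h)
  vs <- lapply(1:4, vline)
  block <- function(a, b, d)
    rbind(nrm, "    outer loop", vs[[a]], vs[[b]], vs[[d]],
          "    endloop", "  endfacet")
  as.vector(cbind(block(1L, 2L, 3L), block(1L, 3L, 4L)))
}

# ---------------------------------------------------------------------------
# Fixtures

#' Deterministic test fixtures
#'
#' Small, fast configurations exercising the pipeline end to end:
#' * `tiny_cell` — one unit cell (Luc = 0.637 mm), resolution 8,
#'   compression 0.1 MPa.
#' * `terzaghi_column` — single-material 1-D consolidation column
#'   (granulation material, 1 mm tall, 40 elements, top drained).
#' * `homogeneous_cube` — all-solid cube (Vf = 1) under frictionless
#'   uniaxial compression; apparent modulus must equal the material's E.
#' * `fig9_geometry` — the normalized-stimulus-map geometry
#'   Ds = 0.425 mm, Dc = 0.275 mm under 0.5 MPa compression (feasible
#'   under the `derived` dialect only).
#' * `section3_triplet` — the three validation geometries
#'   (0.85, 0.55), (0.75, 0.5), (0.65, 0.45) mm at 0.1 MPa compression,
#'   scaffold-only, built constraint-exempt.
#'
#' @param name fixture name.
#' @return a list with a `config` ([run_config()]-compatible where
#'   applicable) plus fixture-specific builders (`grid`, `specs`, ...).
#' @export
generate_fixture <- function(name = c("tiny_cell", "terzaghi_column",
                                      "homogeneous_cube", "fig9_geometry",
                                      "section3_triplet")) {
  name <- match.arg(name)
  switch(name,
    tiny_cell = {
      cfg <- run_config(L_mm = 0.637, cells_per_side = 1L, Ds_mm = 0.5,
                        Dc_mm = 0.25, resolution = 8L, F_UA_MPa = 0.1)
      list(name = name, config = cfg,
           spec = scaffold_spec(0.5, 0.25, L = 0.637, cells_per_side = 1L),
           load = load_case("compression", 0.1))
    },
    terzaghi_column = {
      nz <- 40L
      height <- 1
      grid <- labeled_grid(array(PHASE_GRAN, c(1L, 1L, nz)),
                           voxel_size = height / nz)
      list(name = name, grid = grid, height = height,
           material = default_materials()$granulation,
           load = load_case("compression", 0.01, schedule = "step"))
    },
    homogeneous_cube = {
      n <- 8L
      grid <- labeled_grid(array(PHASE_SOLID, c(n, n, n)),
                           voxel_size = 0.637 / n)
      list(name = name, grid = grid, E = 1000,
           load = load_case("compression", 0.1), Vf = 1)
    },
    fig9_geometry = {
      cfg <- run_config(Ds_mm = 0.425, Dc_mm = 0.275, F_UA_MPa = 0.5,
                        constraint_dialect = "derived", resolution = 8L)
      list(name = name, config = cfg,
           spec = scaffold_spec(0.425, 0.275, constraint_dialect = "derived"),
           load = load_case("compression", 0.5))
    },
    section3_triplet = {
      pairs <- data.frame(Ds = c(0.85, 0.75, 0.65), Dc = c(0.55, 0.5, 0.45))
      specs <- lapply(seq_len(nrow(pairs)), function(i)
        scaffold_spec(pairs$Ds[i], pairs$Dc[i]))
      list(name = name, pairs = pairs, specs = specs,
           load = load_case("compression", 0.1),
           enforce_constraints = FALSE, phases = "solid_only")
    })
}
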