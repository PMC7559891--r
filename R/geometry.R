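# Parametric unit-cell geometry: implicit CSG membership and voxelization.
#
# The unit cell is a cube of edge Luc from which a centered sphere (diameter
# Ds) and three axis-aligned centered cylinders (diameter Dc) are subtracted.
# Pores are assumed filled by granulation tissue, so every voxel is labeled
# either scaffold_solid or granulation.

#' Unit-cell specification
#'
#' Describes one scaffold unit cell: a cube of edge `Luc` with a centered
#' spherical cavity of diameter `Ds` and three orthogonal centered cylindrical
#' interconnections of diameter `Dc`.
#'
#' Two constraint dialects are supported for the coherence bound on `Dc`
#' (see [validate_cell()]):
#' * `"as_printed"`: upper bound `Dc <= Ds/2` for both topologies;
#' * `"derived"`: upper bound `Dc <= Ds/sqrt(2)` (the diameter at which the
#'   square traced by the cylinder edges in a mid-plane section is inscribed
#'   in the spherical edge).
#'
#' Sphere diameters above `2*Luc` are geometrically meaningless for this
#' motif and are rejected outright.
#'
#' @param Luc cell edge, mm.
#' @param Ds sphere diameter, mm (`0 < Ds <= 2*Luc`).
#' @param Dc cylinder diameter, mm (`> 0`).
#' @param constraint_dialect `"as_printed"` or `"derived"`.
#' @return An object of class `unit_cell_spec`.
#' @seealso [validate_cell()], [build_unit_cell()]
#' @export
#' @examples
#' unit_cell_spec(Luc = 0.637, Ds = 0.5, Dc = 0.25)
unit_cell_spec <- function(Luc, Ds, Dc,
                           constraint_dialect = c("as_printed", "derived")) {
  constraint_dialect <- match.arg(constraint_dialect)
  for (nm in c("Luc", "Ds", "Dc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  if (Ds > 2 * Luc)
    stop(sprintf(
      "Ds = %.4g exceeds 2*Luc = %.4g: sphere diameters above twice the cell edge are not allowed",
      Ds, 2 * Luc), call. = FALSE)
  structure(list(Luc = Luc, Ds = Ds, Dc = Dc,
                 constraint_dialect = constraint_dialect),
            class = "unit_cell_spec")
}

#' Scaffold specification
#'
#' A cubic scaffold of edge `L` tiled by `cells_per_side^3` unit cells with
#' `Luc = L / cells_per_side`.
#'
#' @param Ds,Dc sphere / cylinder diameters, mm.
#' @param L scaffold edge, mm; default 2.548.
#' @param cells_per_side unit cells per edge; default 4.
#' @param constraint_dialect see [unit_cell_spec()].
#' @return An object of class `scaffold_spec` with element `cell`, the
#'   [unit_cell_spec()] of the repeating motif.
#' @export
scaffold_spec <- function(Ds, Dc, L = 2.548, cells_per_side = 4L,
                          constraint_dialect = c("as_printed", "derived")) {
  constraint_dialect <- match.arg(constraint_dialect)
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("'L' must be a single positive number", call. = FALSE)
  cells_per_side <- as.integer(cells_per_side)
  if (is.na(cells_per_side) || cells_per_side < 1L)
    stop("'cells_per_side' must be a positive integer", call. = FALSE)
  cell <- unit_cell_spec(Luc = L / cells_per_side, Ds = Ds, Dc = Dc,
                         constraint_dialect = constraint_dialect)
  structure(list(L = L, cells_per_side = cells_per_side, cell = cell),
            class = "scaffold_spec")
}

#' Classify the unit-cell topology
#'
#' "Small" (S) topology when the sphere stays inside the cell
#' (`0 < Ds <= Luc`); "large" (L) when it pierces the faces
#' (`Luc < Ds <= 2*Luc`). `Ds = 2*Luc` is accepted as the closed upper
#' boundary of topology L; anything above is `"invalid"`.
#'
#' @param Ds sphere diameter, mm.
#' @param Luc cell edge, mm.
#' @return `"S"`, `"L"` or `"invalid"` (vectorized over `Ds`/`Luc`).
#' @export
#' @examples
#' classify_topology(0.5, 0.637)  # "S"
#' classify_topology(1.0, 0.637)  # "L"
classify_topology <- function(Ds, Luc) {
  if (!is.numeric(Ds) || !is.numeric(Luc) || any(!is.finite(Ds)) ||
      any(!is.finite(Luc)) || any(Ds <= 0) || any(Luc <= 0))
    stop("'Ds' and 'Luc' must be positive finite numbers", call. = FALSE)
  out <- ifelse(Ds <= Luc, "S", ifelse(Ds <= 2 * Luc, "L", "invalid"))
  out
}

#' Chord of the sphere at the cell face
#'
#' For topology L the sphere pierces the cell faces; the circle of
#' intersection has diameter `C = sqrt(Ds^2 - Luc^2)`, the chord that the
#' cylinder diameter must exceed for the geometry to stay coherent. At the
#' tangent case `Ds = Luc` the chord is zero; `Ds < Luc` is a domain error
#' (the sphere never reaches the face).
#'
#' @param Ds sphere diameter, mm.
#' @param Luc cell edge, mm.
#' @return chord length, mm (vectorized).
#' @export
chord_length <- function(Ds, Luc) {
  if (any(Ds <= 0) || any(Luc <= 0))
    stop("'Ds' and 'Luc' must be positive", call. = FALSE)
  if (any(Ds < Luc))
    stop("chord is undefined for Ds < Luc (topology S: the sphere does not reach the cell face)",
         call. = FALSE)
  sqrt(pmax(Ds^2 - Luc^2, 0))
}

#' Validate the coherence constraints of a unit cell
#'
#' Checks the cylinder diameter against the topology-dependent coherence
#' constraints. Under the `"as_printed"` dialect: topology S requires
#' `0 < Dc <= Ds/2`; topology L requires `sqrt(Ds^2 - Luc^2) < Dc <= Ds/2`.
#' Under `"derived"` the upper bound `Ds/2` is replaced by `Ds/sqrt(2)`
#' (square-vertex-touching construction). Invalid specs yield
#' `valid = FALSE` with named violations, never an error.
#'
#' @param spec a [unit_cell_spec()] (or [scaffold_spec()], whose cell is
#'   validated).
#' @return list of class `cell_validation` with elements `valid`,
#'   `topology`, `violations` (character), `dialect`.
#' @export
#' @examples
#' validate_cell(unit_cell_spec(0.637, 0.5, 0.25))$valid        # TRUE
#' validate_cell(unit_cell_spec(0.637, 0.425, 0.275))$valid     # FALSE
validate_cell <- function(spec) {
  if (inherits(spec, "scaffold_spec")) spec <- spec$cell
  stopifnot(inherits(spec, "unit_cell_spec"))
  topo <- classify_topology(spec$Ds, spec$Luc)
  dialect <- spec$constraint_dialect
  upper <- if (dialect == "as_printed") spec$Ds / 2 else spec$Ds / sqrt(2)
  upper_lbl <- if (dialect == "as_printed") "Ds/2" else "Ds/sqrt(2)"
  violations <- character(0)
  if (topo == "invalid") {
    violations <- c(violations, sprintf("Ds <= 2*Luc (Ds = %.4g > %.4g)",
                                        spec$Ds, 2 * spec$Luc))
  } else {
    if (spec$Dc > upper)
      violations <- c(violations,
                      sprintf("Dc <= %s (topology %s: Dc = %.4g > %.4g)",
                              upper_lbl, topo, spec$Dc, upper))
    if (topo == "L") {
      C <- chord_length(spec$Ds, spec$Luc)
      if (spec$Dc <= C)
        violations <- c(violations,
                        sprintf("sqrt(Ds^2 - Luc^2) < Dc (topology L: Dc = %.4g <= chord %.4g)",
                                spec$Dc, C))
    }
  }
  structure(list(valid = length(violations) == 0L, topology = topo,
                 violations = violations, dialect = dialect),
            class = "cell_validation")
}

#' @exportS3Method base::print
print.cell_validation <- function(x, ...) {
  cat(sprintf("unit cell: topology %s, dialect %s -> %s\n", x$topology,
              x$dialect, if (x$valid) "valid" else "INVALID"))
  for (v in x$violations) cat("  violated:", v, "\n")
  invisible(x)
}

#' Phase membership of a point in the unit cell
#'
#' Points inside the centered sphere of diameter `Ds` or inside any of the
#' three axis-aligned centered cylinders of diameter `Dc` are pore
#' (granulation after implantation); all other points are scaffold solid.
#' Coordinates are relative to the cell center, so the cell occupies
#' `[-Luc/2, Luc/2]^3`; boundary surfaces count as pore.
#'
#' @param p numeric length-3 point or an `n x 3` matrix of points, mm.
#' @param spec a [unit_cell_spec()].
#' @return character vector, `"pore"` or `"scaffold_solid"`.
#' @export
phase_at_point <- function(p, spec) {
  stopifnot(inherits(spec, "unit_cell_spec"))
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3L)
  if (ncol(p) != 3L) stop("'p' must have 3 columns", call. = FALSE)
  half <- spec$Luc / 2
  if (any(abs(p) > half + 1e-12))
    stop("point(s) outside the unit-cell cube [-Luc/2, Luc/2]^3", call. = FALSE)
  rs2 <- (spec$Ds / 2)^2
  rc2 <- (spec$Dc / 2)^2
  x2 <- p[, 1L]^2; y2 <- p[, 2L]^2; z2 <- p[, 3L]^2
  pore <- (x2 + y2 + z2 <= rs2) |      # sphere
    (x2 + y2 <= rc2) |                 # z-axis cylinder
    (x2 + z2 <= rc2) |                 # y-axis cylinder
    (y2 + z2 <= rc2)                   # x-axis cylinder
  ifelse(pore, "pore", "scaffold_solid")
}

#' Labeled voxel grid
#'
#' Container for the voxelized scaffold: a 3-D integer array of phase labels
#' (1 = scaffold solid, 2 = granulation) on cubic voxels of edge
#' `voxel_size`, origin at the lower corner of the model.
#'
#' @param labels 3-D integer array of phase codes.
#' @param voxel_size voxel edge, mm.
#' @param spec optional generating [unit_cell_spec()] / [scaffold_spec()].
#' @return object of class `labeled_grid` with fields `labels`,
#'   `voxel_size`, `dims`, `extent` (mm, per axis) and `spec`.
#' @export
labeled_grid <- function(labels, voxel_size, spec = NULL) {
  stopifnot(length(dim(labels)) == 3L, voxel_size > 0)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(PHASE_SOLID, PHASE_GRAN)))
    stop("labels must be 1 (scaffold_solid) or 2 (granulation)", call. = FALSE)
  structure(list(labels = labels, voxel_size = voxel_size,
                 dims = dim(labels), extent = dim(labels) * voxel_size,
                 spec = spec),
            class = "labeled_grid")
}

#' @exportS3Method base::print
print.labeled_grid <- function(x, ...) {
  cat(sprintf("labeled_grid: %s voxels, voxel %.4g mm, Vf = %.4f\n",
              paste(x$dims, collapse = " x "), x$voxel_size,
              volume_fraction(x)))
  invisible(x)
}

#' Voxelize one unit cell
#'
#' Samples the implicit CSG membership at voxel centers of a
#' `resolution^3` grid over the cell cube. Pore voxels are labeled
#' granulation (the pore space is assumed filled by granulation tissue
#' immediately after implantation).
#'
#' @param spec a [unit_cell_spec()].
#' @param resolution voxels per cell edge (>= 4).
#' @param enforce_constraints if `TRUE` (default), specs that fail
#'   [validate_cell()] raise an error listing the violations. The worked
#'   validation geometries of the source literature deliberately sit outside
#'   the printed constraint table; build those with `FALSE`.
#' @return a [labeled_grid()] covering the cell.
#' @export
#' @examples
#' g <- build_unit_cell(unit_cell_spec(0.637, 0.5, 0.25), resolution = 8)
#' volume_fraction(g)
build_unit_cell <- function(spec, resolution, enforce_constraints = TRUE) {
  stopifnot(inherits(spec, "unit_cell_spec"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 4L)
    stop("'resolution' must be an integer >= 4", call. = FALSE)
  if (enforce_constraints) {
    val <- validate_cell(spec)
    if (!val$valid)
      stop("invalid unit cell spec:\n  ",
           paste(val$violations, collapse = "\n  "), call. = FALSE)
  }
  labels <- .voxelize_cell(spec, resolution)
  labeled_grid(labels, voxel_size = spec$Luc / resolution, spec = spec)
}

# membership sampled at voxel centers, vectorized by outer sums of squares
.voxelize_cell <- function(spec, res) {
  xc <- ((seq_len(res) - 0.5) / res - 0.5) * spec$Luc
  x2 <- xc^2
  rs2 <- (spec$Ds / 2)^2
  rc2 <- (spec$Dc / 2)^2
  xy2 <- outer(x2, x2, "+")                      # res x res
  sphere <- outer(xy2, x2, "+") <= rs2           # res^3
  cyl_z <- array(xy2 <= rc2, dim = c(res, res, res))
  cyl_y <- aperm(cyl_z, c(1L, 3L, 2L))           # x-z plane circle
  cyl_x <- aperm(cyl_z, c(3L, 1L, 2L))           # y-z plane circle
  pore <- sphere | cyl_x | cyl_y | cyl_z
  array(ifelse(pore, PHASE_GRAN, PHASE_SOLID), dim = c(res, res, res))
}

#' Assemble the full scaffold grid
#'
#' Tiles `cells_per_side^3` unit-cell instances over `[0, L]^3`. The unit
#' cell is mirror-symmetric about its three mid-planes, so the mirrored
#' replication described for the CAD model is identical to plain
#' translation-replication; the equivalence is recorded on the returned
#' grid (`attr(, "replication")`).
#'
#' @param spec a [scaffold_spec()].
#' @param resolution voxels per unit-cell edge.
#' @param enforce_constraints see [build_unit_cell()].
#' @param max_voxels resource cap on the total voxel count (default `2^24`).
#' @return a [labeled_grid()] covering the scaffold cube.
#' @export
assemble_scaffold <- function(spec, resolution, enforce_constraints = TRUE,
                              max_voxels = 2^24) {
  stopifnot(inherits(spec, "scaffold_spec"))
  n <- as.integer(resolution) * spec$cells_per_side
  if (as.numeric(n)^3 > max_voxels)
    stop(sprintf("grid of %d^3 voxels exceeds max_voxels = %g", n, max_voxels),
         call. = FALSE)
  cell <- build_unit_cell(spec$cell, resolution, enforce_constraints)
  idx <- rep(seq_len(resolution), spec$cells_per_side)
  labels <- cell$labels[idx, idx, idx]
  g <- labeled_grid(labels, voxel_size = cell$voxel_size, spec = spec)
  attr(g, "replication") <-
    "mirror-symmetric unit cell: mirrored replication == translation-replication"
  g
}

#' Scaffold volume fraction
#'
#' `Vf = Vs / Vtot`: fraction of the model volume occupied by scaffold
#' solid, estimated as the fraction of scaffold-labeled voxels.
#'
#' @param grid a [labeled_grid()].
#' @return scalar in `[0, 1]`.
#' @export
volume_fraction <- function(grid) {
  stopifnot(inherits(grid, "labeled_grid"))
  mean(grid$labels == PHASE_SOLID)
}

#' Pore-space connectivity
#'
#' Flood-fills the granulation (pore) voxels with 6-connectivity and reports
#' the number of connected components and whether the component containing
#' the cell center reaches all six faces of the grid. Used to verify that
#' the cylindrical interconnections keep the pore space fully connected.
#'
#' @param grid a [labeled_grid()].
#' @return list with `n_components`, `touches_all_faces`.
#' @export
pore_connectivity <- function(grid) {
  stopifnot(inherits(grid, "labeled_grid"))
  d <- grid$dims
  pore <- grid$labels == PHASE_GRAN
  comp <- array(0L, dim = d)
  ncomp <- 0L
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  # linear-index neighbor offsets with face guards
  idx_all <- which(pore)
  remaining <- pore
  while (any(remaining)) {
    ncomp <- ncomp + 1L
    seed <- which(remaining)[1L]
    frontier <- seed
    remaining[seed] <- FALSE
    comp[seed] <- ncomp
    while (length(frontier)) {
      i0 <- (frontier - 1L) %% nx
      j0 <- ((frontier - 1L) %/% nx) %% ny
      k0 <- (frontier - 1L) %/% (nx * ny)
      nb <- c(frontier[i0 > 0L] - 1L, frontier[i0 < nx - 1L] + 1L,
              frontier[j0 > 0L] - nx, frontier[j0 < ny - 1L] + nx,
              frontier[k0 > 0L] - nx * ny, frontier[k0 < nz - 1L] + nx * ny)
      nb <- unique(nb[remaining[nb]])
      if (length(nb)) {
        remaining[nb] <- FALSE
        comp[nb] <- ncomp
      }
      frontier <- nb
    }
  }
  ctr <- comp[max(1L, nx %/% 2L), max(1L, ny %/% 2L), max(1L, nz %/% 2L)]
  touches <- FALSE
  if (ctr > 0L) {
    touches <- any(comp[1L, , ] == ctr) && any(comp[nx, , ] == ctr) &&
      any(comp[, 1L, ] == ctr) && any(comp[, ny, ] == ctr) &&
      any(comp[, , 1L] == ctr) && any(comp[, , nz] == ctr)
  }
  list(n_components = ncomp, touches_all_faces = touches)
}
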