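# Biot poroelastic finite elements on the labeled voxel grid.
#
# u-p formulation with trilinear hexahedra for both displacement and pore
# pressure. Scaffold and granulation elements share nodes, which IS the tie
# constraint (no relative displacement at the interface). Quasi-static,
# small strain, backward-Euler in time. Unit system: mm, N, s, MPa.

.node_id <- function(i, j, k, nx, ny) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)

# local face -> local node columns (ordering of .HEX_LC)
.FACE_NODES <- list(`x-` = c(1L, 4L, 5L, 8L), `x+` = c(2L, 3L, 6L, 7L),
                    `y-` = c(1L, 2L, 5L, 6L), `y+` = c(3L, 4L, 7L, 8L),
                    `z-` = c(1L, 2L, 3L, 4L), `z+` = c(5L, 6L, 7L, 8L))

# hexahedral connectivity for the voxels selected by `phases`
.build_mesh <- function(grid, phases = c("both", "solid_only")) {
  phases <- match.arg(phases)
  d <- grid$dims
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  keep <- if (phases == "solid_only") grid$labels == PHASE_SOLID
          else array(TRUE, dim = d)
  lin <- which(keep)
  if (!length(lin)) stop("no elements selected", call. = FALSE)
  i <- (lin - 1L) %% nx
  j <- ((lin - 1L) %/% nx) %% ny
  k <- (lin - 1L) %/% (nx * ny)
  conn <- cbind(.node_id(i,      j,      k,      nx, ny),
                .node_id(i + 1L, j,      k,      nx, ny),
                .node_id(i + 1L, j + 1L, k,      nx, ny),
                .node_id(i,      j + 1L, k,      nx, ny),
                .node_id(i,      j,      k + 1L, nx, ny),
                .node_id(i + 1L, j,      k + 1L, nx, ny),
                .node_id(i + 1L, j + 1L, k + 1L, nx, ny),
                .node_id(i,      j + 1L, k + 1L, nx, ny))
  list(conn = conn, elabel = as.integer(grid$labels[lin]),
       eijk = cbind(i, j, k), nn = (nx + 1L) * (ny + 1L) * (nz + 1L),
       dims = d, h = grid$voxel_size)
}

#' Build a poroelastic finite-element model from a labeled grid
#'
#' Creates the voxel hexahedral mesh, assembles the Biot system blocks and
#' sets boundary conditions. Three boundary-condition templates exist:
#'
#' * `"plate"` (default, the scaffold setup): all displacement components
#'   clamped on the base `z = 0` (encastre); all nodes of the top face tied
#'   to a rigid, rotation-free reference plate carrying the total force
#'   `|F| = F_UA * L * L`; zero pore pressure (free fluid exudation) on the
#'   exterior granulation faces of the four lateral sides and the bottom;
#'   the top face under the plate is sealed. Scaffold-labeled exterior
#'   faces are never drained.
#' * `"column"`: 1-D consolidation column. `ux = uy = 0` everywhere,
#'   `uz = 0` at the base, uniform traction and `p = 0` at the top
#'   (single drainage path of the full column height).
#' * `"uniaxial"`: frictionless uniaxial compression for homogenization
#'   checks (`uz = 0` at the base, lateral expansion free, uniform top
#'   traction, minimal rigid-body constraints); purely drained/elastic.
#'
#' @param grid a [labeled_grid()].
#' @param materials named list with entries `scaffold_solid`, `granulation`
#'   (see [default_materials()]).
#' @param load a [load_case()].
#' @param bc boundary-condition template, see above.
#' @param phases `"both"` (scaffold + pore-filling granulation) or
#'   `"solid_only"` (granulation removed, e.g. for apparent-modulus runs).
#' @param fluid logical; include the pore-pressure problem. Defaults to
#'   `TRUE` except for `"uniaxial"`/`"solid_only"` models, which are solved
#'   drained-elastic.
#' @param stab_c dimensionless transient pressure-stabilization constant
#'   for the equal-order u/p pair; scales a pressure-Laplacian term
#'   `stab_c * h^2 / (lambda + 2 mu)` that acts only on pressure increments
#'   (vanishes at steady state). Calibrated against the 1-D consolidation
#'   benchmark.
#' @return an object of class `fe_model`.
#' @export
build_fe_model <- function(grid, materials = default_materials(),
                           load = load_case("compression", 0.1),
                           bc = c("plate", "column", "uniaxial"),
                           phases = c("both", "solid_only"),
                           fluid = NULL, stab_c = 0.25) {
  bc <- match.arg(bc)
  phases <- match.arg(phases)
  stopifnot(inherits(grid, "labeled_grid"), inherits(load, "load_case"))
  if (is.null(fluid)) fluid <- !(bc == "uniaxial" || phases == "solid_only")
  mesh <- .build_mesh(grid, phases)
  detached <- FALSE
  if (phases == "solid_only") {
    cc <- .grounded_elements(mesh, bc)
    if (any(!cc$keep)) {
      mesh$conn <- mesh$conn[cc$keep, , drop = FALSE]
      mesh$elabel <- mesh$elabel[cc$keep]
      mesh$eijk <- mesh$eijk[cc$keep, , drop = FALSE]
    }
    detached <- cc$detached
    if (detached)
      warning("no solid load path between base and plate at this resolution: ",
              "the model carries no load (apparent modulus 0)", call. = FALSE)
  }
  labs_present <- sort(unique(mesh$elabel))
  if (bc == "plate" && phases == "both" && length(labs_present) < 2L)
    stop("configuration error: the scaffold model needs both materials ",
         "(grid contains a single phase)", call. = FALSE)
  mats <- list(materials$scaffold_solid, materials$granulation)  # label 1, 2
  for (m in mats) stopifnot(inherits(m, "material_properties"))
  if (any(vapply(mats, function(m) m$nu >= 0.5, logical(1L))))
    stop("Poisson ratio must be < 0.5", call. = FALSE)

  nn <- mesh$nn
  nmaster <- if (bc == "plate") 3L else 0L
  ndof <- 4L * nn + nmaster
  conn <- mesh$conn
  edof_u <- matrix(0L, nrow(conn), 24L)
  for (a in 1:8) edof_u[, (3L * a - 2L):(3L * a)] <-
    cbind(3L * conn[, a] - 2L, 3L * conn[, a] - 1L, 3L * conn[, a])
  edof_p <- 3L * nn + conn

  geo <- .hex_geometry(mesh$h)
  Klist <- lapply(mats, function(m) .hex_stiffness(geo, m$E, m$nu))
  Kf <- .assemble_block(edof_u, edof_u, mesh$elabel, Klist, ndof)
  Qf <- Hf <- Sf <- Lstabf <- NULL
  if (fluid) {
    Qlist <- lapply(mats, function(m) geo$Q0 * m$alpha)
    Hlist <- lapply(mats, function(m) geo$Le * m$k_mm)
    Slist <- lapply(mats, function(m) geo$Me * m$invM)
    taul <- lapply(mats, function(m)
      geo$Le * (stab_c * mesh$h^2 / (m$lambda + 2 * m$mu)))
    Qf <- .assemble_block(edof_u, edof_p, mesh$elabel, Qlist, ndof)
    Hf <- .assemble_block(edof_p, edof_p, mesh$elabel, Hlist, ndof)
    Sf <- .assemble_block(edof_p, edof_p, mesh$elabel, Slist, ndof)
    Lstabf <- .assemble_block(edof_p, edof_p, mesh$elabel, taul, ndof)
  }

  sets <- .boundary_sets(mesh, bc, fluid)
  cons <- .constraints(mesh, bc, fluid, sets, ndof, nmaster)

  model <- structure(list(
    grid = grid, mesh = mesh, materials = materials, mats = mats,
    bc = bc, phases = phases, fluid = fluid, stab_c = stab_c,
    nn = nn, ndof = ndof, nmaster = nmaster,
    master_dofs = if (nmaster) (4L * nn + 1L):(4L * nn + 3L) else integer(0),
    conn = conn, elabel = mesh$elabel, edof_u = edof_u, edof_p = edof_p,
    geo = geo, Kf = Kf, Qf = Qf, Hf = Hf, Sf = Sf, Lstabf = Lstabf,
    sets = sets, fixed = cons$fixed, T = cons$T, nred = cons$nred,
    detached = detached,
    extent = grid$extent), class = "fe_model")
  apply_load_case(model, load)
}

# Connected components of the element set through shared nodes (this is the
# mechanical connectivity of the mesh: voxels touching along edges/corners do
# transmit force). Elements in components anchored to neither the base nor
# the plate are floating rigid bodies and would make the stiffness matrix
# singular; they carry no load and are dropped. `detached` flags the absence
# of any base-to-top load path.
.grounded_elements <- function(mesh, bc) {
  conn <- mesh$conn
  edges <- cbind(as.vector(conn[, 1:7]), as.vector(conn[, 2:8]))
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  memb <- igraph::components(g)$membership
  d <- mesh$dims
  node_k <- function(ids) (ids - 1L) %/% ((d[1L] + 1L) * (d[2L] + 1L))
  used <- sort(unique(as.vector(conn)))
  base_c <- unique(memb[used[node_k(used) == 0L]])
  top_c <- unique(memb[used[node_k(used) == d[3L]]])
  anchored <- if (bc == "plate") union(base_c, top_c) else base_c
  ecomp <- memb[conn[, 1L]]
  list(keep = ecomp %in% anchored,
       detached = bc == "plate" && !length(intersect(base_c, top_c)))
}

# node index planes and drained faces
.boundary_sets <- function(mesh, bc, fluid) {
  d <- mesh$dims
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  active <- logical(mesh$nn)
  active[unique(as.vector(mesh$conn))] <- TRUE
  grid_ids <- function(ii, jj, kk) {
    g <- expand.grid(i = ii, j = jj, k = kk)
    .node_id(g$i, g$j, g$k, nx, ny)
  }
  base_nodes <- grid_ids(0:nx, 0:ny, 0L)
  top_nodes <- grid_ids(0:nx, 0:ny, nz)
  base_nodes <- base_nodes[active[base_nodes]]
  top_nodes <- top_nodes[active[top_nodes]]

  drained_faces <- NULL
  drained_nodes <- integer(0)
  if (fluid && bc == "plate") {
    ij <- mesh$eijk
    face_sel <- list(`x-` = ij[, 1L] == 0L, `x+` = ij[, 1L] == nx - 1L,
                     `y-` = ij[, 2L] == 0L, `y+` = ij[, 2L] == ny - 1L,
                     `z-` = ij[, 3L] == 0L)            # top (z+) sealed
    rows <- list()
    for (f in names(face_sel)) {
      sel <- which(face_sel[[f]])
      if (length(sel))
        rows[[f]] <- data.frame(elem = sel, face = f,
                                label = mesh$elabel[sel])
    }
    drained_faces <- do.call(rbind, rows)
    if (!is.null(drained_faces)) {
      gran <- drained_faces[drained_faces$label == PHASE_GRAN, , drop = FALSE]
      for (r in seq_len(nrow(gran))) {
        lf <- .FACE_NODES[[gran$face[r]]]
        drained_nodes <- c(drained_nodes, mesh$conn[gran$elem[r], lf])
      }
      drained_nodes <- sort(unique(drained_nodes))
      rownames(drained_faces) <- NULL
    }
  } else if (fluid && bc == "column") {
    drained_nodes <- top_nodes
  }
  list(active = active, base_nodes = base_nodes, plate_nodes = top_nodes,
       drained_faces = drained_faces, drained_nodes = drained_nodes)
}

# fixed-dof flags, rigid-plate master map and the reduction matrix T
.constraints <- function(mesh, bc, fluid, sets, ndof, nmaster) {
  nn <- mesh$nn
  d <- mesh$dims
  nx <- d[1L]; ny <- d[2L]
  fixed <- logical(ndof)
  master_of <- integer(ndof)
  inact <- which(!sets$active)
  if (length(inact))
    fixed[c(3L * inact - 2L, 3L * inact - 1L, 3L * inact, 3L * nn + inact)] <- TRUE
  # pressure dofs
  if (fluid) {
    if (length(sets$drained_nodes)) fixed[3L * nn + sets$drained_nodes] <- TRUE
  } else {
    fixed[(3L * nn + 1L):(4L * nn)] <- TRUE
  }
  if (bc == "plate") {
    b <- sets$base_nodes
    fixed[c(3L * b - 2L, 3L * b - 1L, 3L * b)] <- TRUE
    md <- (4L * nn + 1L):(4L * nn + 3L)
    p <- sets$plate_nodes
    master_of[3L * p - 2L] <- md[1L]
    master_of[3L * p - 1L] <- md[2L]
    master_of[3L * p] <- md[3L]
  } else if (bc == "column") {
    allnod <- which(sets$active)
    fixed[c(3L * allnod - 2L, 3L * allnod - 1L)] <- TRUE   # ux = uy = 0
    fixed[3L * sets$base_nodes] <- TRUE                    # uz = 0 at base
  } else { # uniaxial
    fixed[3L * sets$base_nodes] <- TRUE
    n0 <- .node_id(0L, 0L, 0L, nx, ny)
    nx0 <- .node_id(nx, 0L, 0L, nx, ny)
    fixed[c(3L * n0 - 2L, 3L * n0 - 1L, 3L * nx0 - 1L)] <- TRUE
  }
  free <- !fixed & master_of == 0L
  redid <- integer(ndof)
  redid[free] <- seq_len(sum(free))
  slave <- which(master_of > 0L & !fixed)
  redid[slave] <- redid[master_of[slave]]
  rows <- which(!fixed)
  T <- Matrix::sparseMatrix(i = rows, j = redid[rows], x = 1,
                            dims = c(ndof, sum(free)))
  list(fixed = fixed, master_of = master_of, T = T, nred = sum(free))
}

#' Attach (or replace) the load on a finite-element model
#'
#' Compression loads the rigid-plate reference point by `-F_UA * L^2` along
#' z; shear by `+F_UA * L^2` along x. For `"column"`/`"uniaxial"` models a
#' consistent uniform traction is applied to the top face instead.
#'
#' @param model an `fe_model`.
#' @param load a [load_case()].
#' @return the model with load vector, total force and schedule attached.
#' @export
apply_load_case <- function(model, load) {
  stopifnot(inherits(model, "fe_model"), inherits(load, "load_case"))
  f <- numeric(model$ndof)
  total <- load$F_UA * model$extent[1L] * model$extent[2L]
  if (model$bc == "plate") {
    md <- model$master_dofs
    if (load$mode == "compression") f[md[3L]] <- -total
    else f[md[1L]] <- +total
  } else {
    if (load$mode != "compression")
      stop("column/uniaxial templates support compression loading only",
           call. = FALSE)
    top <- which(model$mesh$eijk[, 3L] == model$mesh$dims[3L] - 1L)
    fnod <- -load$F_UA * model$mesh$h^2 / 4
    for (a in .FACE_NODES[["z+"]]) {
      dz <- 3L * model$conn[top, a]
      agg <- tapply(rep(fnod, length(dz)), dz, sum)
      f[as.integer(names(agg))] <- f[as.integer(names(agg))] + as.numeric(agg)
    }
  }
  model$f <- f
  model$load <- load
  model$total_force <- total
  model
}

#' Solve the quasi-static Biot consolidation problem
#'
#' Backward-Euler integration of the coupled u-p system
#' `K u - Q p = f(t)`, `Q' du/dt + S dp/dt + H p = 0` from zero initial
#' conditions, with the load factor following the case's ramp or step
#' schedule. For drained/elastic models (`fluid = FALSE`) a single static
#' solve at full load is performed. The final increment is the scoring
#' state for the mechano-regulation model.
#'
#' @param model an `fe_model` with a load attached.
#' @param times optional increasing vector of solution times, s; defaults
#'   to `n_increments` uniform steps over `ramp_time`.
#' @return object of class `fem_result` with fields `times`, `X` (full dof
#'   solution per increment), `u2` (plate/top displacement along the load
#'   direction per increment, mm), `reaction_base` (3-vector, N) and the
#'   model.
#' @export
solve_consolidation <- function(model, times = NULL) {
  stopifnot(inherits(model, "fe_model"))
  load <- model$load
  if (isTRUE(model$detached)) {
    # no load path: the plate is mechanically detached and its displacement
    # is unbounded; fields in the anchored part are identically zero
    return(structure(list(model = model, times = load$ramp_time,
                          X = matrix(0, model$ndof, 1L), u2 = Inf,
                          reaction_base = c(0, 0, 0), load = load),
                     class = "fem_result"))
  }
  Tm <- model$T
  if (!model$fluid) {
    A <- model$Kf
    Ared <- Matrix::forceSymmetric(Matrix::crossprod(Tm, A %*% Tm))
    rhs <- model$f
    b <- as.vector(Matrix::crossprod(Tm, rhs))
    x <- as.vector(Tm %*% Matrix::solve(Ared, b))
    res <- list(times = load$ramp_time, X = matrix(x, ncol = 1L),
                rhs_final = rhs, A_final = A)
  } else {
    if (is.null(times)) {
      dt <- load$ramp_time / load$n_increments
      times <- dt * seq_len(load$n_increments)
    }
    stopifnot(all(diff(c(0, times)) > 0))
    lf <- if (load$schedule == "ramp") pmin(times / load$ramp_time, 1)
          else rep(1, length(times))
    S2 <- model$Sf + model$Lstabf
    A_base <- model$Kf - model$Qf - Matrix::t(model$Qf) - S2
    Cmat <- -(Matrix::t(model$Qf) + S2)
    X <- matrix(0, model$ndof, length(times))
    xprev <- numeric(model$ndof)
    dt_prev <- NA_real_
    fac <- NULL; A <- NULL
    rhs <- NULL
    for (s in seq_along(times)) {
      dt <- times[s] - if (s == 1L) 0 else times[s - 1L]
      if (is.na(dt_prev) || abs(dt - dt_prev) > 1e-12 * dt) {
        A <- A_base - dt * model$Hf
        Ared <- Matrix::crossprod(Tm, A %*% Tm)
        fac <- Matrix::lu(Ared)
        dt_prev <- dt
      }
      rhs <- lf[s] * model$f + as.vector(Cmat %*% xprev)
      b <- as.vector(Matrix::crossprod(Tm, rhs))
      x <- as.vector(Tm %*% Matrix::solve(fac, b))
      X[, s] <- x
      xprev <- x
    }
    res <- list(times = times, X = X, rhs_final = rhs, A_final = A)
  }
  .finalize_result(model, res)
}

#' Solve a drained (elastic) model
#'
#' Convenience wrapper: static solve of the displacement problem only.
#' @param model an `fe_model` built with `fluid = FALSE`.
#' @return a `fem_result`.
#' @export
solve_elastic <- function(model) {
  if (model$fluid)
    stop("model was built with fluid = TRUE; use solve_consolidation()",
         call. = FALSE)
  solve_consolidation(model)
}

.finalize_result <- function(model, res) {
  X <- res$X
  u2 <- if (model$bc == "plate") {
    md <- model$master_dofs
    dir <- if (model$load$mode == "compression") 3L else 1L
    X[md[dir], ]
  } else {
    top <- model$sets$plate_nodes
    colMeans(X[3L * top, , drop = FALSE])
  }
  # reactions: residual of the full (unreduced) system at the final state
  r_full <- as.vector(res$A_final %*% X[, ncol(X)]) - res$rhs_final
  b <- model$sets$base_nodes
  reaction_base <- c(sum(r_full[3L * b - 2L]), sum(r_full[3L * b - 1L]),
                     sum(r_full[3L * b]))
  structure(list(model = model, times = res$times, X = X, u2 = u2,
                 reaction_base = reaction_base,
                 load = model$load), class = "fem_result")
}

#' @exportS3Method base::print
print.fem_result <- function(x, ...) {
  cat(sprintf("fem_result: %d elements, %d increments, u2(final) = %.4g mm\n",
              nrow(x$model$conn), length(x$times), x$u2[length(x$u2)]))
  invisible(x)
}

#' Element centroid strains
#'
#' Small-strain tensor at each element centroid from the trilinear
#' shape-function gradients.
#'
#' @param result a `fem_result`.
#' @param increment time increment (default: final).
#' @return numeric matrix, one row per element, columns
#'   `exx, eyy, ezz, exy, eyz, ezx` (tensor shear components).
#' @export
element_strains <- function(result, increment = NULL) {
  stopifnot(inherits(result, "fem_result"))
  m <- result$model
  if (is.null(increment)) increment <- ncol(result$X)
  x <- result$X[, increment]
  .strains_from_u(m, x)
}

.strains_from_u <- function(m, x) {
  Gc <- m$geo$Gc                       # 8 x 3
  conn <- m$conn
  E <- nrow(conn)
  Ux <- matrix(x[3L * conn - 2L], E, 8L)
  Uy <- matrix(x[3L * conn - 1L], E, 8L)
  Uz <- matrix(x[3L * conn], E, 8L)
  gx <- Ux %*% Gc; gy <- Uy %*% Gc; gz <- Uz %*% Gc
  out <- cbind(exx = gx[, 1L], eyy = gy[, 2L], ezz = gz[, 3L],
               exy = 0.5 * (gx[, 2L] + gy[, 1L]),
               eyz = 0.5 * (gy[, 3L] + gz[, 2L]),
               ezx = 0.5 * (gz[, 1L] + gx[, 3L]))
  out
}

#' Element Darcy velocities
#'
#' Fluid velocity `v = -k grad p` at each element centroid, reported in
#' micrometres per second. With `measure = "seepage"` the Darcy flux is
#' divided by the porosity (average true fluid velocity); the default is
#' the flux, consistent with the calibration lineage of the stimulus model.
#'
#' @param result a `fem_result` from a fluid model.
#' @param materials material set (defaults to the model's own).
#' @param increment time increment (default: final).
#' @param measure `"flux"` (default) or `"seepage"`.
#' @return matrix, one row per element, columns `vx, vy, vz` in um/s.
#' @export
darcy_velocities <- function(result, materials = NULL, increment = NULL,
                             measure = c("flux", "seepage")) {
  stopifnot(inherits(result, "fem_result"))
  measure <- match.arg(measure)
  m <- result$model
  if (!m$fluid) stop("model has no pore-pressure field", call. = FALSE)
  if (is.null(increment)) increment <- ncol(result$X)
  mats <- if (is.null(materials)) m$mats
          else list(materials$scaffold_solid, materials$granulation)
  x <- result$X[, increment]
  P <- matrix(x[3L * m$nn + m$conn], nrow(m$conn), 8L)
  gp <- P %*% m$geo$Gc                          # MPa/mm
  kvec <- vapply(mats, function(mm) mm$k_mm, numeric(1L))[m$elabel]
  if (measure == "seepage") {
    por <- vapply(mats, function(mm) mm$porosity, numeric(1L))[m$elabel]
    kvec <- kvec / por
  }
  v <- -gp * kvec * 1000                        # mm/s -> um/s
  colnames(v) <- c("vx", "vy", "vz")
  v
}

#' Nodal pore pressure field
#'
#' @param result a `fem_result` from a fluid model.
#' @param increment time increment (default: final).
#' @return numeric vector of nodal pressures, MPa.
#' @export
pore_pressure <- function(result, increment = NULL) {
  m <- result$model
  if (!m$fluid) stop("model has no pore-pressure field", call. = FALSE)
  if (is.null(increment)) increment <- ncol(result$X)
  result$X[(3L * m$nn + 1L):(4L * m$nn), increment]
}

#' Apparent Young's modulus of the scaffold
#'
#' `E_app = F_UA * L / u2`, with `u2` the magnitude of the vertical plate
#' displacement at the final increment of a compression run.
#'
#' @param result a `fem_result` from a compression case.
#' @param F_UA load per unit area, MPa (default: the model's own).
#' @param L model edge, mm (default: the model's own).
#' @return apparent modulus, MPa.
#' @export
apparent_modulus <- function(result, F_UA = NULL, L = NULL) {
  stopifnot(inherits(result, "fem_result"))
  if (result$load$mode != "compression")
    stop("apparent modulus is defined for compression cases", call. = FALSE)
  if (is.null(F_UA)) F_UA <- result$load$F_UA
  if (is.null(L)) L <- result$model$extent[3L]
  u2 <- abs(result$u2[length(result$u2)])
  if (!is.finite(u2)) {
    warning("plate detached from the base (no load path): apparent modulus is 0",
            call. = FALSE)
    return(0)
  }
  if (u2 < .Machine$double.eps * 100)
    stop("degenerate result: plate displacement is numerically zero",
         call. = FALSE)
  F_UA * L / u2
}
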