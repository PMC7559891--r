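# Poroelastic material constants and load cases.

#' Biphasic poroelastic material properties
#'
#' Drained elastic constants of the solid skeleton plus the poroelastic
#' constants needed for the Biot model. Permeability is entered in
#' m^4/(N s) (i.e. intrinsic permeability over fluid viscosity, as usually
#' tabulated for tissues) and converted to mm^4/(N s) at model-build time.
#'
#' Derived quantities (standard linear poroelasticity):
#' drained bulk `K_d = E / (3 (1 - 2 nu))`,
#' Biot coefficient `alpha = 1 - K_d / K_grain`,
#' Biot modulus `1/M = porosity / K_fluid + (alpha - porosity) / K_grain`.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @param k permeability, m^4/(N s).
#' @param porosity fluid volume fraction, in (0, 1).
#' @param K_grain bulk modulus of the solid grains, MPa.
#' @param K_fluid bulk modulus of the pore fluid, MPa.
#' @return object of class `material_properties` including derived fields
#'   `alpha`, `invM` (1/MPa), `k_mm` (mm^4/(N s)), `lambda`, `mu` (MPa).
#' @export
material_properties <- function(E, nu, k, porosity, K_grain, K_fluid) {
  stopifnot(is.numeric(E), E > 0, is.numeric(k), k > 0,
            porosity > 0, porosity < 1, K_grain > 0, K_fluid > 0)
  if (nu < 0 || nu >= 0.5)
    stop("'nu' must satisfy 0 <= nu < 0.5", call. = FALSE)
  Kd <- E / (3 * (1 - 2 * nu))
  alpha <- 1 - Kd / K_grain
  invM <- porosity / K_fluid + (alpha - porosity) / K_grain
  structure(list(E = E, nu = nu, k = k, porosity = porosity,
                 K_grain = K_grain, K_fluid = K_fluid,
                 lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
                 mu = E / (2 * (1 + nu)),
                 Kd = Kd, alpha = alpha, invM = invM,
                 k_mm = k * 1e12),
            class = "material_properties")
}

#' Default material set
#'
#' The material constants used throughout: a stiff scaffold material
#' (E = 1000 MPa) and soft granulation tissue (E = 0.2 MPa) filling the
#' pores, both biphasic poroelastic.
#'
#' | property                  | granulation | scaffold |
#' |---------------------------|------------:|---------:|
#' | Young's modulus, MPa      |         0.2 |     1000 |
#' | Poisson ratio             |       0.167 |      0.3 |
#' | permeability, m^4/(N s)   |       1e-14 |    1e-14 |
#' | porosity                  |         0.8 |      0.5 |
#' | grain bulk modulus, MPa   |        2300 |   13,920 |
#' | fluid bulk modulus, MPa   |        2300 |     2300 |
#'
#' @return named list with entries `scaffold_solid` and `granulation`.
#' @export
default_materials <- function() {
  list(
    scaffold_solid = material_properties(E = 1000, nu = 0.3, k = 1e-14,
                                         porosity = 0.5, K_grain = 13920,
                                         K_fluid = 2300),
    granulation = material_properties(E = 0.2, nu = 0.167, k = 1e-14,
                                      porosity = 0.8, K_grain = 2300,
                                      K_fluid = 2300)
  )
}

#' Load case
#'
#' Uniformly distributed load per unit area `F_UA` applied through a rigid
#' plate tied to the upper face: compression acts along -z, shear along +x.
#' The total force magnitude is `|F| = F_UA * L * L`. The load history is a
#' linear ramp from zero to full over `ramp_time` (`schedule = "ramp"`) or a
#' step applied at the first increment (`schedule = "step"`), integrated
#' with `n_increments` backward-Euler steps.
#'
#' @param mode `"compression"` or `"shear"`.
#' @param F_UA load per unit area, MPa (>= 0).
#' @param ramp_time load-history duration, s.
#' @param n_increments number of implicit time increments.
#' @param schedule `"ramp"` (default) or `"step"`.
#' @return object of class `load_case`.
#' @export
load_case <- function(mode = c("compression", "shear"), F_UA,
                      ramp_time = 1, n_increments = 10L,
                      schedule = c("ramp", "step")) {
  mode <- match.arg(mode)
  schedule <- match.arg(schedule)
  stopifnot(is.numeric(F_UA), length(F_UA) == 1L, F_UA >= 0,
            ramp_time > 0, n_increments >= 1L)
  structure(list(mode = mode, F_UA = F_UA, ramp_time = ramp_time,
                 n_increments = as.integer(n_increments),
                 schedule = schedule),
            class = "load_case")
}

#' Default load magnitudes per mode
#'
#' Compression: 0.05, 0.1, 0.5, 1.0, 1.5 MPa. Shear: 0.01, 0.05, 0.1, 0.2,
#' 0.5 MPa.
#'
#' @param mode `"compression"` or `"shear"`.
#' @return numeric vector of `F_UA` values, MPa.
#' @export
default_loads <- function(mode = c("compression", "shear")) {
  mode <- match.arg(mode)
  if (mode == "compression") c(0.05, 0.1, 0.5, 1.0, 1.5)
  else c(0.01, 0.05, 0.1, 0.2, 0.5)
}
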