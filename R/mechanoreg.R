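# Prendergast mechano-regulation: biophysical stimulus, phenotype
# classification and the mature-bone volume percentage BO%.

#' Stimulus model constants
#'
#' The biophysical stimulus is `S = gamma/a + v/b`, with `gamma` the
#' octahedral shear strain (dimensionless) and `v` the interstitial fluid
#' velocity (um/s). The scale constants `a = 0.0375` and `b = 3 um/s` are
#' the classical mechano-regulation calibration and are user-overridable.
#'
#' @param a strain scale, dimensionless (> 0).
#' @param b velocity scale, um/s (> 0).
#' @return object of class `stimulus_model`.
#' @export
stimulus_model <- function(a = 0.0375, b = 3.0) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "stimulus_model")
}

#' Phenotype thresholds
#'
#' Stimulus ranges determining the predicted tissue fate:
#' resorption below 0.01, mature bone up to 0.53, immature bone up to 1,
#' cartilage up to 3, fibrous tissue above. The printed inequalities are
#' open; bins here are lower-inclusive (`[0, 0.01), [0.01, 0.53),
#' [0.53, 1), [1, 3], (3, Inf)`) — a measure-zero choice.
#'
#' @param resorption_hi,mature_hi,immature_hi,cartilage_hi strictly
#'   increasing dimensionless bounds.
#' @return object of class `phenotype_thresholds`.
#' @export
phenotype_thresholds <- function(resorption_hi = 0.01, mature_hi = 0.53,
                                 immature_hi = 1, cartilage_hi = 3) {
  v <- c(resorption_hi, mature_hi, immature_hi, cartilage_hi)
  if (any(diff(v) <= 0) || any(v <= 0))
    stop("thresholds must be positive and strictly increasing", call. = FALSE)
  structure(list(resorption_hi = resorption_hi, mature_hi = mature_hi,
                 immature_hi = immature_hi, cartilage_hi = cartilage_hi),
            class = "phenotype_thresholds")
}

PHENOTYPE_LEVELS <- c("resorption", "mature_bone", "immature_bone",
                      "cartilage", "fibrous")

#' Octahedral shear strain
#'
#' `gamma = (2/3) sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)` over the
#' principal strains; computed invariantly from the strain deviator, so no
#' eigen decomposition is needed.
#'
#' @param eps either a symmetric 3x3 strain tensor, a length-6 vector, or
#'   an `n x 6` matrix with columns `exx, eyy, ezz, exy, eyz, ezx` (tensor
#'   shear components).
#' @return octahedral shear strain(s), dimensionless.
#' @export
#' @examples
#' octahedral_shear_strain(diag(c(0.01, 0, 0)))  # (2/3) sqrt(2) * 0.01
octahedral_shear_strain <- function(eps) {
  if (is.matrix(eps) && nrow(eps) == 3L && ncol(eps) == 3L) {
    if (max(abs(eps - t(eps))) > 1e-12 * max(1, max(abs(eps))))
      stop("strain tensor must be symmetric", call. = FALSE)
    eps <- matrix(c(eps[1, 1], eps[2, 2], eps[3, 3],
                    eps[1, 2], eps[2, 3], eps[3, 1]), 1L, 6L)
  } else if (is.null(dim(eps))) {
    eps <- matrix(eps, 1L, 6L)
  }
  stopifnot(ncol(eps) == 6L)
  mean_e <- (eps[, 1L] + eps[, 2L] + eps[, 3L]) / 3
  d1 <- eps[, 1L] - mean_e; d2 <- eps[, 2L] - mean_e; d3 <- eps[, 3L] - mean_e
  tr2 <- d1^2 + d2^2 + d3^2 + 2 * (eps[, 4L]^2 + eps[, 5L]^2 + eps[, 6L]^2)
  # sum_{i<j} (ei - ej)^2 = 3 tr(dev^2)
  unname((2 / 3) * sqrt(3 * tr2))
}

#' Biophysical stimulus
#'
#' `S = gamma/a + v/b` (vectorized).
#'
#' @param gamma octahedral shear strain(s), >= 0.
#' @param v interstitial fluid velocity magnitude(s), um/s, >= 0.
#' @param model a [stimulus_model()].
#' @return stimulus value(s), dimensionless.
#' @export
stimulus <- function(gamma, v, model = stimulus_model()) {
  stopifnot(inherits(model, "stimulus_model"))
  if (any(gamma < 0) || any(v < 0))
    stop("'gamma' and 'v' must be non-negative", call. = FALSE)
  gamma / model$a + v / model$b
}

#' Classify the tissue phenotype from the stimulus
#'
#' @param S stimulus value(s), >= 0.
#' @param thresholds a [phenotype_thresholds()].
#' @return factor with levels `resorption, mature_bone, immature_bone,
#'   cartilage, fibrous`.
#' @export
#' @examples
#' classify_phenotype(c(0.005, 0.3, 0.7, 2, 5))
classify_phenotype <- function(S, thresholds = phenotype_thresholds()) {
  stopifnot(inherits(thresholds, "phenotype_thresholds"))
  if (any(S < 0)) stop("'S' must be non-negative", call. = FALSE)
  idx <- ifelse(S < thresholds$resorption_hi, 1L,
         ifelse(S < thresholds$mature_hi, 2L,
         ifelse(S < thresholds$immature_hi, 3L,
         ifelse(S <= thresholds$cartilage_hi, 4L, 5L))))
  factor(PHENOTYPE_LEVELS[idx], levels = PHENOTYPE_LEVELS)
}

#' Stimulus field on the granulation elements
#'
#' Computes, per granulation element of a solved model, the octahedral
#' shear strain, fluid velocity magnitude, stimulus `S` and phenotype,
#' evaluated at the final (peak-load) increment by default or as the
#' maximum over increments.
#'
#' @param result a `fem_result` from a fluid model containing granulation
#'   elements.
#' @param model a [stimulus_model()].
#' @param thresholds a [phenotype_thresholds()].
#' @param measure velocity measure, see [darcy_velocities()].
#' @param over `"final"` (default) or `"max"` (max-over-increments S).
#' @return object of class `stimulus_field`: list with `element` (indices
#'   into the model's element table), `gamma`, `v`, `S`, `phenotype`,
#'   `S_max`, `element_volume` (mm^3).
#' @export
compute_stimulus_field <- function(result, model = stimulus_model(),
                                   thresholds = phenotype_thresholds(),
                                   measure = c("flux", "seepage"),
                                   over = c("final", "max")) {
  stopifnot(inherits(result, "fem_result"))
  measure <- match.arg(measure)
  over <- match.arg(over)
  fem <- result$model
  gran <- which(fem$elabel == PHASE_GRAN)
  if (!length(gran)) stop("model contains no granulation elements", call. = FALSE)
  incs <- if (over == "final") ncol(result$X) else seq_len(ncol(result$X))
  S <- gam <- vm <- rep(0, length(gran))
  for (inc in incs) {
    eps <- element_strains(result, inc)[gran, , drop = FALSE]
    g <- octahedral_shear_strain(eps)
    vel <- darcy_velocities(result, increment = inc, measure = measure)
    v <- sqrt(rowSums(vel[gran, , drop = FALSE]^2))
    Si <- stimulus(g, v, model)
    upd <- Si >= S | inc == incs[1L]
    S[upd] <- Si[upd]; gam[upd] <- g[upd]; vm[upd] <- v[upd]
  }
  structure(list(element = gran, gamma = gam, v = vm, S = S,
                 phenotype = classify_phenotype(S, thresholds),
                 S_max = max(S),
                 element_volume = fem$mesh$h^3),
            class = "stimulus_field")
}

#' @exportS3Method base::print
print.stimulus_field <- function(x, ...) {
  cat(sprintf("stimulus_field: %d granulation elements, S in [%.4g, %.4g]\n",
              length(x$S), min(x$S), x$S_max))
  print(round(100 * table(x$phenotype) / length(x$S), 2))
  invisible(x)
}

#' Mature-bone volume percentage BO%
#'
#' `BO% = 100 * V(mature-bone elements) / L^3`: the percentage of the total
#' model volume occupied by granulation elements whose stimulus falls in
#' the mature-bone range. This is the optimization objective.
#'
#' @param field a [compute_stimulus_field()] result.
#' @param L model edge, mm.
#' @return list of class `bone_fraction` with `BO_percent`,
#'   `qualifying_volume` (mm^3), `Vtot` (mm^3) and the phenotype volume
#'   shares (`shares`, % of total volume).
#' @export
bone_fraction <- function(field, L) {
  stopifnot(inherits(field, "stimulus_field"), L > 0)
  Vtot <- L^3
  vol <- field$element_volume
  qual <- sum(field$phenotype == "mature_bone") * vol
  shares <- 100 * as.numeric(table(field$phenotype)) * vol / Vtot
  names(shares) <- PHENOTYPE_LEVELS
  structure(list(BO_percent = 100 * qual / Vtot, qualifying_volume = qual,
                 Vtot = Vtot, shares = shares),
            class = "bone_fraction")
}

#' @exportS3Method base::print
print.bone_fraction <- function(x, ...) {
  cat(sprintf("BO%% = %.3f (qualifying volume %.4g of %.4g mm^3)\n",
              x$BO_percent, x$qualifying_volume, x$Vtot))
  invisible(x)
}
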