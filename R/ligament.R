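# Constitutive laws and strain kinematics for the one-dimensional elements:
# tension-only nonlinear bundles with a quadratic toe region and linear
# region, plus ordinary linear springs.  Bundles are straight lines between
# their insertion points; there is no wrapping around bone.

#' Tension-only nonlinear ligament force law
#'
#' Piecewise force-strain relation used for every ligament bundle:
#' \deqn{f(\epsilon) = 0                        \quad \epsilon \le 0}
#' \deqn{f(\epsilon) = k\,\epsilon^2/(4\epsilon_l) \quad 0 < \epsilon \le 2\epsilon_l}
#' \deqn{f(\epsilon) = k\,(\epsilon - \epsilon_l)  \quad \epsilon > 2\epsilon_l}
#' with \code{k} the linear-region stiffness in N (per unit strain) and
#' \code{eps_l} the toe-to-linear transition strain.  The law is continuous,
#' C1 at \code{2*eps_l}, non-negative and non-decreasing.
#'
#' @param strain dimensionless strain(s); may be negative (slack)
#' @param k linear-region stiffness, N per unit strain; > 0
#' @param eps_l transition strain, dimensionless; > 0 (default 0.03)
#' @return force in N, same length as \code{strain}
#' @export
blankevoort_force <- function(strain, k, eps_l = 0.03) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("blankevoort_force: k must be a positive scalar")
  if (!is.numeric(eps_l) || length(eps_l) != 1 || !is.finite(eps_l) || eps_l <= 0)
    stop("blankevoort_force: eps_l must be a positive scalar")
  f <- numeric(length(strain))
  toe <- strain > 0 & strain <= 2 * eps_l
  lin <- strain > 2 * eps_l
  f[toe] <- k * strain[toe]^2 / (4 * eps_l)
  f[lin] <- k * (strain[lin] - eps_l)
  f
}

#' Stored elastic energy of the ligament force law
#'
#' Analytic integral of \code{blankevoort_force} over elongation.  The energy
#' is returned per unit reference length times \code{L0}; pass the bundle's
#' reference length to get N.mm.
#' @inheritParams blankevoort_force
#' @param L0 reference length, mm
#' @return energy, N.mm
#' @export
blankevoort_energy <- function(strain, k, eps_l = 0.03, L0 = 1) {
  e <- numeric(length(strain))
  toe <- strain > 0 & strain <= 2 * eps_l
  lin <- strain > 2 * eps_l
  e[toe] <- k * strain[toe]^3 / (12 * eps_l)
  e[lin] <- (2 / 3) * k * eps_l^2 +
    k * ((strain[lin] - eps_l)^2 - eps_l^2) / 2
  L0 * e
}

#' Current length of a bundle in a pose
#' @param bundle bundle element of a \code{knee_model}
#' @param pose named list of body frames
#' @return length, mm
#' @keywords internal
bundle_length <- function(bundle, pose) {
  pf <- world_point(pose, "femur", bundle$femur_site)
  pt <- world_point(pose, "tibia", bundle$tibia_site)
  sqrt(sum((pf - pt)^2))
}

#' Engineering strain of an initialized bundle
#'
#' @param bundle bundle element (with reference length \code{L0} set)
#' @param pose named list of body frames
#' @return (L - L0)/L0, dimensionless; negative when slack
#' @export
bundle_strain <- function(bundle, pose) {
  if (!is.finite(bundle$L0) || is.na(bundle$L0))
    stop("bundle '", bundle$name, "' is not initialized (no reference length); ",
         "call initialize_reference_lengths() first")
  bundle_length(bundle, pose) / bundle$L0 - 1
}

#' Set bundle reference lengths from pre-strains at a reference pose
#'
#' With \code{Lr} the inter-insertion length at the full-extension reference
#' pose and \code{eps_r} the assigned pre-strain, the slack/reference length
#' is \code{L0 = Lr / (1 + eps_r)}, so that \code{bundle_strain} at the
#' reference pose equals the pre-strain exactly.  Linear-spring rest lengths
#' are set to their reference-pose lengths (zero force at reference).
#' Idempotent: re-running with the same pose and pre-strains is a no-op.
#'
#' @param model a \code{knee_model}
#' @param pose reference pose; default the model's stored full-extension pose
#' @param prestrains optional named numeric vector overriding per-bundle
#'   reference strains (names = bundle names)
#' @return the initialized model
#' @export
initialize_reference_lengths <- function(model, pose = model$reference_pose,
                                         prestrains = NULL) {
  stopifnot(inherits(model, "knee_model"))
  if (!is.null(prestrains)) {
    bad <- setdiff(names(prestrains), names(model$bundles))
    if (length(bad)) stop("prestrains given for unknown bundle(s): ",
                          paste(bad, collapse = ", "))
    if (any(prestrains <= -1)) stop("pre-strains must exceed -1")
    for (nm in names(prestrains))
      model$bundles[[nm]]$reference_strain <- as.numeric(prestrains[[nm]])
  }
  for (nm in names(model$bundles)) {
    b <- model$bundles[[nm]]
    Lr <- bundle_length(b, pose)
    if (Lr < 1e-9)
      stop("bundle '", nm, "': zero inter-insertion distance at reference pose")
    model$bundles[[nm]]$L0 <- Lr / (1 + b$reference_strain)
  }
  for (nm in names(model$linear_springs)) {
    sp <- model$linear_springs[[nm]]
    pa <- world_point(pose, sp$body_a, sp$r_a)
    pb <- world_point(pose, sp$body_b, sp$r_b)
    L <- sqrt(sum((pa - pb)^2))
    if (L < 1e-9) stop("spring '", nm, "': zero length at reference pose")
    model$linear_springs[[nm]]$rest_length <- L
  }
  model$initialized <- TRUE
  model
}

#' Axial force in a linear spring
#'
#' \code{f = k (L - rest_length)}, clamped at zero for tension-only springs
#' shorter than their rest length.
#' @param spring spring element of a \code{knee_model} (rest_length set)
#' @param pose named list of body frames
#' @return force, N (>= 0 when tension_only)
#' @export
linear_spring_force <- function(spring, pose) {
  if (!is.finite(spring$rest_length) || is.na(spring$rest_length))
    stop("spring '", spring$name, "' has no rest length; initialize the model first")
  pa <- world_point(pose, spring$body_a, spring$r_a)
  pb <- world_point(pose, spring$body_b, spring$r_b)
  L <- sqrt(sum((pa - pb)^2))
  f <- spring$k_Nmm * (L - spring$rest_length)
  if (isTRUE(spring$tension_only) && f < 0) f <- 0
  f
}

#' Strains of all bundles at a pose
#' @param model initialized \code{knee_model}
#' @param pose named list of body frames
#' @return named numeric vector of strains
#' @export
all_bundle_strains <- function(model, pose) {
  vapply(model$bundles, bundle_strain, numeric(1), pose = pose)
}
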