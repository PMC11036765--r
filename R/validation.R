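# Scripted reproductions of the four passive-motion validation protocols:
# hamstring-loaded flexion sweep, Lachman and anterior drawer (anterior
# tibial force at 30 / 90 deg flexion), and abduction (valgus) moment
# loading, plus the Pearson-r / RMSE curve comparison used to score a model
# curve against a published reference curve.

# common solver settings for protocol sweeps
protocol_free_dofs <- function(which = c("sagittal", "lachman", "abduction")) {
  switch(match.arg(which),
         # translations in the tibial transverse plane + axial rotation
         sagittal = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
         # anterior/compressive translations only
         lachman = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
         # compression + varus/valgus rotation
         abduction = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
}

# carry the previous equilibrium's deviation from the nominal flexed pose
# into the next sweep step (continuation guess)
carry_guess <- function(model, sol_prev, flex_prev, flex_next) {
  base_prev <- flexion_pose(model, flex_prev)
  base_next <- flexion_pose(model, flex_next)
  dev_t <- sol_prev$tibia$t - base_prev$tibia$t
  dev_R <- sol_prev$tibia$R %*% t(base_prev$tibia$R)
  g <- base_next
  g$tibia$t <- g$tibia$t + dev_t
  g$tibia$R <- dev_R %*% g$tibia$R
  g
}

#' Hamstring-loaded flexion sweep
#'
#' Flexion is prescribed in steps up to \code{max_flexion} with the femur
#' grounded and a constant hamstring force applied to the tibia; at each
#' angle the tibial transverse-plane translations and axial rotation
#' equilibrate.  The 0 degree entry is the passive full-extension reference
#' configuration itself (bundle strains equal their pre-strains there); the
#' hamstring load drives the sweep beyond it.  Reports both ACL bundle
#' strains and the internal tibial rotation (screw-home motion).
#'
#' @param model initialized \code{knee_model}
#' @param max_flexion sweep limit, degrees (<= 90)
#' @param n_points sweep resolution (default 21)
#' @param hamstring_N hamstring force, N (default 600)
#' @return data.frame: flexion_deg, strain_AM, strain_PL,
#'   internal_rotation_deg, anterior_translation_mm
#' @export
run_flexion_test <- function(model, max_flexion = 90, n_points = 21,
                             hamstring_N = 600) {
  stopifnot(max_flexion <= 90, max_flexion >= 0)
  angles <- seq(0, max_flexion, length.out = n_points)
  free <- protocol_free_dofs("sagittal")
  sol <- NULL
  out <- vector("list", n_points)
  for (i in seq_along(angles)) {
    th <- angles[i]
    if (th == 0) {
      sol <- flexion_pose(model, 0)
    } else {
      case <- load_case(
        forces = function(pose, model)
          muscle_loads(pose, model, hams_N = hamstring_N),
        free = free, frame = "tibia")
      guess <- if (is.null(sol)) flexion_pose(model, th) else
        carry_guess(model, sol, angles[i - 1], th)
      sol <- tryCatch(solve_static(model, case, guess),
                      error = function(e) stop("flexion sweep failed at ", th,
                                               " deg: ", conditionMessage(e)))
    }
    eps <- all_bundle_strains(model, sol)
    ja <- extract_joint_angles(sol, model$reference_pose)
    out[[i]] <- data.frame(flexion_deg = th,
                           strain_AM = eps[["ACL-AM"]],
                           strain_PL = eps[["ACL-PL"]],
                           internal_rotation_deg = ja$internal_rotation,
                           anterior_translation_mm = ja$anterior_translation)
  }
  do.call(rbind, out)
}

# shared machinery for the anterior-force laxity tests
run_anterior_force_sweep <- function(model, flexion_deg, forces_N) {
  stopifnot(any(forces_N == 0))
  free <- protocol_free_dofs("lachman")
  base <- flexion_pose(model, flexion_deg)
  # settle the unloaded flexed pose first
  settle <- solve_static(model, load_case(free = free, frame = "tibia"), base)
  ord <- order(abs(forces_N), forces_N)     # grow |F| outward from 0
  sols <- vector("list", length(forces_N))
  guess_pos <- settle; guess_neg <- settle
  for (i in ord) {
    Fi <- forces_N[i]
    case <- load_case(
      forces = function(pose, model) {
        list(list(point = world_point(pose, "tibia", c(0, 0, 0)),
                  force = Fi * as.numeric(pose$tibia$R[, 1])))
      },
      free = free, frame = "tibia")
    guess <- if (Fi >= 0) guess_pos else guess_neg
    sol <- tryCatch(solve_static(model, case, guess),
                    error = function(e) stop("anterior-force sweep failed at ",
                                             Fi, " N: ", conditionMessage(e)))
    if (Fi >= 0) guess_pos <- sol else guess_neg <- sol
    sols[[i]] <- sol
  }
  out <- lapply(seq_along(forces_N), function(i) {
    eps <- all_bundle_strains(model, sols[[i]])
    ja <- extract_joint_angles(sols[[i]], settle)
    data.frame(anterior_force_N = forces_N[i],
               strain_AM = eps[["ACL-AM"]], strain_PL = eps[["ACL-PL"]],
               anterior_translation_mm = ja$anterior_translation)
  })
  do.call(rbind, out)[order(forces_N), ]
}

#' Lachman test: anterior tibial force at 30 degrees flexion
#'
#' @param model initialized \code{knee_model}
#' @param flexion flexion angle, degrees (default 30)
#' @param max_force largest anterior force, N (default 200); the sweep runs
#'   from -max_force (posterior) to +max_force through 0
#' @param n_points sweep resolution (default 21)
#' @return data.frame: anterior_force_N, strain_AM, strain_PL,
#'   anterior_translation_mm
#' @export
run_lachman <- function(model, flexion = 30, max_force = 200, n_points = 21) {
  forces <- seq(-max_force, max_force, length.out = n_points)
  if (!any(forces == 0)) forces <- sort(c(0, forces))
  run_anterior_force_sweep(model, flexion, forces)
}

#' Anterior drawer test: anterior tibial force at 90 degrees flexion
#' @inheritParams run_lachman
#' @export
run_drawer <- function(model, flexion = 90, max_force = 200, n_points = 21) {
  run_lachman(model, flexion = flexion, max_force = max_force,
              n_points = n_points)
}

#' Abduction (valgus) moment sweep
#'
#' At a fixed flexion angle, an abduction moment is applied to the tibia and
#' the compressive translation plus varus/valgus rotation equilibrate.
#' Valgus angles are reported relative to the unloaded pose at the same
#' flexion.
#'
#' @param model initialized \code{knee_model}
#' @param flexion flexion angle, degrees (default 25)
#' @param max_moment largest abduction moment, N.m (default 50)
#' @param n_points sweep resolution (default 21)
#' @return data.frame: moment_Nm, valgus_deg, strain_AM, strain_PL, strain_ACL
#'   (the larger bundle strain)
#' @export
run_abduction <- function(model, flexion = 25, max_moment = 50, n_points = 21) {
  stopifnot(max_moment >= 0)
  moments <- seq(0, max_moment, length.out = n_points)
  free <- protocol_free_dofs("abduction")
  base <- flexion_pose(model, flexion)
  settle <- solve_static(model, load_case(free = free, frame = "tibia"), base)
  valgus0 <- extract_joint_angles(settle)$valgus
  sol <- settle
  out <- vector("list", length(moments))
  for (i in seq_along(moments)) {
    Mi <- moments[i] * 1000   # N.m -> N.mm
    # abduction moment about the tibial anterior axis (valgus positive),
    # applied as a force couple that follows the tibia
    case <- load_case(
      forces = local({
        Mi_ <- Mi
        function(pose, model) {
          # valgus is rotation about -X_tibia for a right knee
          z <- as.numeric(pose$tibia$R[, 3])
          arm <- 50
          Fc <- -(Mi_ / (2 * arm)) * as.numeric(pose$tibia$R[, 2])
          p0 <- world_point(pose, "tibia", c(0, 0, 0))
          list(list(point = p0 - arm * z, force = Fc),
               list(point = p0 + arm * z, force = -Fc))
        }
      }),
      free = free, frame = "tibia")
    sol <- tryCatch(solve_static(model, case, sol),
                    error = function(e) stop("abduction sweep failed at ",
                                             moments[i], " N.m: ",
                                             conditionMessage(e)))
    eps <- all_bundle_strains(model, sol)
    ja <- extract_joint_angles(sol)
    out[[i]] <- data.frame(moment_Nm = moments[i],
                           valgus_deg = ja$valgus - valgus0,
                           strain_AM = eps[["ACL-AM"]],
                           strain_PL = eps[["ACL-PL"]],
                           strain_ACL = max(eps[["ACL-AM"]], eps[["ACL-PL"]]))
  }
  do.call(rbind, out)
}

#' Compare a model curve with a reference curve
#'
#' Resamples the reference onto the model curve's abscissa by linear
#' interpolation over the overlapping range and reports the Pearson
#' correlation and root-mean-square error in the curve's own units.
#'
#' @param model_curve,reference_curve two-column data.frames (abscissa,
#'   ordinate)
#' @return list(pearson_r, rmse, n) over the common support
#' @export
compare_curves <- function(model_curve, reference_curve) {
  stopifnot(ncol(model_curve) >= 2, ncol(reference_curve) >= 2)
  xm <- model_curve[[1]]; ym <- model_curve[[2]]
  xr <- reference_curve[[1]]; yr <- reference_curve[[2]]
  lo <- max(min(xm), min(xr)); hi <- min(max(xm), max(xr))
  keep <- xm >= lo & xm <= hi
  if (sum(keep) < 3)
    stop("compare_curves: fewer than 3 points on the common abscissa range")
  yi <- stats::approx(xr, yr, xout = xm[keep])$y
  r <- stats::cor(ym[keep], yi)
  list(pearson_r = r,
       rmse = sqrt(mean((ym[keep] - yi)^2)),
       n = sum(keep))
}
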