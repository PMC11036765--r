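# Quasi-static tibiofemoral mechanics.  The femur is grounded; the tibia is
# the solved 6-DOF body with incremental coordinates q = (dx, dy, dz, wx, wy,
# wz): world-frame translation increments (mm) and a world-frame rotation
# increment vector (rad) applied on the left of the current orientation.
# Prescribed DOFs are masked incremental coordinates.  Equilibrium is found by
# damped Newton iteration on the generalized residual force with a
# backtracking line search; the stiffness matrix comes from central finite
# differences of the analytic residual.

#' Penalty contact force between a sphere and a plane primitive
#'
#' Frictionless, normal-only penalty: magnitude \code{contact_stiffness *
#' penetration}, zero at separation, acting along the plane normal at the
#' sphere's nearest point.  The returned force acts on the sphere's body; the
#' plane's body receives the opposite force at the same point.
#'
#' @param surface a surface element of a \code{knee_model}
#' @param pose named list of body frames
#' @return list(force = length-3 N (on sphere body), point = world mm,
#'   penetration = mm, normal = world unit vector)
#' @export
contact_force <- function(surface, pose) {
  if (!identical(surface$type, "sphere_plane"))
    stop("unsupported surface type '", surface$type, "'")
  c_w <- world_point(pose, surface$sphere_body, surface$center)
  p_w <- world_point(pose, surface$plane_body, surface$point)
  n_w <- as.numeric(pose[[surface$plane_body]]$R %*% surface$normal)
  gap <- sum((c_w - p_w) * n_w) - surface$radius
  pen <- max(0, -gap)
  list(force = surface$contact_stiffness * pen * n_w,
       point = c_w - surface$radius * n_w,
       penetration = pen, normal = n_w)
}

# Generalized force (length 6: force N, moment N.mm about the body origin)
# exerted on one body by all elastic elements and contacts at a pose.
body_elastic_wrench <- function(model, pose, body) {
  t_o <- pose[[body]]$t
  Ftot <- c(0, 0, 0); Mtot <- c(0, 0, 0)
  add <- function(p, F) {
    Ftot <<- Ftot + F
    Mtot <<- Mtot + pracma_cross(p - t_o, F)
  }
  for (b in model$bundles) {
    if (!(body %in% c("femur", "tibia"))) break
    pf <- world_point(pose, "femur", b$femur_site)
    pt <- world_point(pose, "tibia", b$tibia_site)
    d <- pf - pt; L <- sqrt(sum(d^2))
    f <- blankevoort_force(L / b$L0 - 1, b$k_N, b$eps_l)
    if (f > 0) {
      if (body == "tibia") add(pt, f * d / L)
      if (body == "femur") add(pf, -f * d / L)
    }
  }
  for (sp in model$linear_springs) {
    if (sp$body_a != body && sp$body_b != body) next
    pa <- world_point(pose, sp$body_a, sp$r_a)
    pb <- world_point(pose, sp$body_b, sp$r_b)
    d <- pa - pb; L <- sqrt(sum(d^2))
    f <- sp$k_Nmm * (L - sp$rest_length)
    if (isTRUE(sp$tension_only) && f < 0) f <- 0
    if (f != 0) {
      u <- d / L
      if (sp$body_a == body) add(pa, -f * u)
      if (sp$body_b == body) add(pb, f * u)
    }
  }
  for (su in model$surfaces) {
    if (su$sphere_body != body && su$plane_body != body) next
    cf <- contact_force(su, pose)
    if (cf$penetration > 0) {
      if (su$sphere_body == body) add(cf$point, cf$force)
      if (su$plane_body == body) add(cf$point, -cf$force)
    }
  }
  c(Ftot, Mtot)
}

tibia_elastic_wrench <- function(model, pose) {
  body_elastic_wrench(model, pose, "tibia")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a load case
#'
#' @param forces list of \code{list(point = , force = )}: world application
#'   point (mm) and world force vector (N) on the tibia, or a function
#'   \code{function(pose, model)} returning such a list (for pose-dependent
#'   muscle lines of action)
#' @param moment length-3 pure moment on the tibia, N.mm
#' @param free logical length-6 mask over (dx, dy, dz, wx, wy, wz): which
#'   incremental tibia DOFs are solved; masked DOFs are held (prescribed)
#' @param frame basis for the incremental DOFs: "world" (ground axes) or
#'   "tibia" (current tibia axes, so e.g. wy is axial rotation about the
#'   tibial long axis at any flexion angle)
#' @return a \code{load_case} list
#' @export
load_case <- function(forces = list(), moment = c(0, 0, 0),
                      free = rep(TRUE, 6), frame = c("world", "tibia")) {
  stopifnot(length(moment) == 3, length(free) == 6, is.logical(free))
  structure(list(forces = forces, moment = moment, free = free,
                 frame = match.arg(frame)),
            class = "load_case")
}

applied_wrench <- function(case, pose, model) {
  fl <- case$forces
  if (is.function(fl)) fl <- fl(pose, model)
  t_tib <- pose$tibia$t
  Ftot <- c(0, 0, 0); Mtot <- case$moment
  for (f in fl) {
    Ftot <- Ftot + f$force
    Mtot <- Mtot + pracma_cross(f$point - t_tib, f$force)
  }
  c(Ftot, Mtot)
}

residual_force <- function(model, case, pose) {
  tibia_elastic_wrench(model, pose) + applied_wrench(case, pose, model)
}

apply_increment <- function(pose, dq, B = diag(3)) {
  pose$tibia$t <- pose$tibia$t + as.numeric(B %*% dq[1:3])
  if (any(dq[4:6] != 0))
    pose$tibia$R <- rot_exp(as.numeric(B %*% dq[4:6])) %*% pose$tibia$R
  pose
}

increment_basis <- function(case, pose) {
  if (identical(case$frame, "tibia")) pose$tibia$R else diag(3)
}

# residual expressed in the increment basis
residual_local <- function(model, case, pose, B) {
  g <- residual_force(model, case, pose)
  c(crossprod(B, g[1:3]), crossprod(B, g[4:6]))
}

#' Solve quasi-static equilibrium of the tibia
#'
#' Damped Newton iteration on the free incremental DOFs; converged when every
#' free generalized residual component is below \code{tol} (N or N.mm).
#' Deterministic for fixed inputs; the default initial guess is the model's
#' reference pose.
#'
#' @param model initialized \code{knee_model}
#' @param case a \code{load_case}
#' @param guess starting pose (default: the load case is solved from the
#'   model's reference pose)
#' @param tol residual tolerance, N / N.mm (default 1e-6)
#' @param max_iter maximum Newton iterations
#' @return converged pose, with attributes \code{residual} and \code{iterations}
#' @export
solve_static <- function(model, case, guess = model$reference_pose,
                         tol = 1e-6, max_iter = 200) {
  if (!isTRUE(model$initialized))
    stop("model is not initialized; call initialize_reference_lengths() first")
  free <- which(case$free)
  pose <- guess
  if (length(free) == 0) return(pose)
  B <- increment_basis(case, pose)
  g <- residual_local(model, case, pose, B)[free]
  h <- c(rep(1e-6, 3), rep(1e-7, 3))   # finite-difference steps, mm / rad
  lambda <- 0
  stalls <- 0
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < tol) {
      attr(pose, "residual") <- max(abs(g)); attr(pose, "iterations") <- it
      return(pose)
    }
    # stiffness by central differences of the analytic residual
    J <- matrix(0, length(free), length(free))
    for (j in seq_along(free)) {
      dq <- numeric(6); dq[free[j]] <- h[free[j]]
      gp <- residual_local(model, case, apply_increment(pose, dq, B), B)[free]
      gm <- residual_local(model, case, apply_increment(pose, -dq, B), B)[free]
      J[, j] <- (gp - gm) / (2 * h[free[j]])
    }
    ok <- FALSE
    gn_prev <- max(abs(g))
    for (damp in c(lambda, 10^(seq(-6, 8)))) {
      Jd <- J - damp * diag(length(free))
      dqf <- tryCatch(solve(Jd, -g), error = function(e) NULL)
      if (is.null(dqf) || any(!is.finite(dqf))) next
      # backtracking line search on the residual norm
      for (s in 2^-(0:12)) {
        dq <- numeric(6); dq[free] <- s * dqf
        cand <- apply_increment(pose, dq, B)
        Bc <- increment_basis(case, cand)
        gc_ <- residual_local(model, case, cand, Bc)[free]
        if (all(is.finite(gc_)) && max(abs(gc_)) < max(abs(g)) * (1 - 1e-4 * s)) {
          pose <- cand; g <- gc_; B <- Bc; lambda <- damp / 4; ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    # asymptoting without converging (near-singular stiffness) counts as a
    # stall so the escape below can kick in
    if (ok && max(abs(g)) > 0.995 * gn_prev && max(abs(g)) > tol) ok <- FALSE
    if (!ok) {
      # stalled (saddle or locally non-descending kink): move along the most
      # unstable direction of the symmetrised stiffness and keep going
      stalls <- stalls + 1
      if (stalls > 8)
        stop("solve_static: no descent step found at iteration ", it,
             " (residual ", signif(max(abs(g)), 4), ")")
      Js <- 0.5 * (J + t(J))
      dir <- eigen(Js, symmetric = TRUE)$vectors[, 1]
      best <- NULL; best_norm <- Inf
      for (sgn in c(1, -1)) for (mag in c(0.05, 0.2, 0.8)) {
        dq <- numeric(6); dq[free] <- sgn * mag * dir
        cand <- apply_increment(pose, dq, B)
        Bc <- increment_basis(case, cand)
        gc_ <- residual_local(model, case, cand, Bc)[free]
        if (all(is.finite(gc_)) && max(abs(gc_)) < best_norm) {
          best <- list(pose = cand, g = gc_, B = Bc)
          best_norm <- max(abs(gc_))
        }
      }
      if (is.null(best))
        stop("solve_static: no descent step found at iteration ", it,
             " (residual ", signif(max(abs(g)), 4), ")")
      pose <- best$pose; g <- best$g; B <- best$B; lambda <- 1e-2
    }
  }
  stop("solve_static: not converged after ", max_iter,
       " iterations (residual ", signif(max(abs(g)), 4), ")")
}

#' Pose of the knee flexed by a given angle about the transepicondylar axis
#'
#' Rotates the tibia about the model's flexion axis (+Z through the stored
#' axis point); the patella marker co-rotates with the tibia so the extensor
#' linkage (patellar ligament spring) is passive-neutral under pure flexion
#' and engages only through tibial translation.  Positive flexion carries the
#' distal tibia posteriorly.
#' @param model \code{knee_model}
#' @param flexion_deg knee flexion angle, degrees
#' @return pose
#' @export
flexion_pose <- function(model, flexion_deg) {
  pose <- model$reference_pose
  A <- model$flexion_axis_point
  Rz <- rot_axis(-flexion_deg, "z")
  pose$tibia$t <- A + as.numeric(Rz %*% (pose$tibia$t - A))
  pose$tibia$R <- Rz %*% pose$tibia$R
  if (!is.null(pose$patella)) {
    pose$patella$t <- A + as.numeric(Rz %*% (pose$patella$t - A))
    pose$patella$R <- Rz %*% pose$patella$R
  }
  pose
}

#' Clinical joint angles from a pose
#'
#' Floating-axis decomposition of the relative femur-to-tibia rotation
#' \code{R_rel = t(R_femur) \%*\% R_tibia} as \code{Rz(a) Rx(b) Ry(c)}:
#' flexion about the femoral medio-lateral axis, ab/adduction about the
#' floating anterior axis, axial rotation about the tibial long axis.  Signs
#' (right knee): flexion = -a, valgus (abduction) = -b, internal rotation =
#' +c.  Anterior translation is the femur-frame X displacement of the tibia
#' origin from the reference pose.
#'
#' @param pose named list of body frames (femur and tibia required)
#' @param reference_pose pose used as translation datum (optional)
#' @return list(flexion, valgus, internal_rotation) in degrees, plus
#'   \code{anterior_translation} in mm when a reference pose is given
#' @export
extract_joint_angles <- function(pose, reference_pose = NULL) {
  R <- t(pose$femur$R) %*% pose$tibia$R
  sb <- min(1, max(-1, R[3, 2]))
  b <- asin(sb)
  if (abs(cos(b)) < 1e-8) {
    warning("extract_joint_angles: gimbal-degenerate pose (|abduction| ~ 90 deg); ",
            "flexion and axial rotation are not separable")
    a <- atan2(R[2, 1], R[1, 1]); cc <- 0
  } else {
    a <- atan2(-R[1, 2], R[2, 2])
    cc <- atan2(-R[3, 1], R[3, 3])
  }
  out <- list(flexion = -a * 180 / pi,
              valgus = -b * 180 / pi,
              internal_rotation = cc * 180 / pi)
  if (!is.null(reference_pose)) {
    d <- pose$tibia$t - reference_pose$tibia$t
    out$anterior_translation <- sum(d * pose$femur$R[, 1])
  }
  out
}

#' Compose joint angles back into a relative rotation
#'
#' Inverse of the decomposition in \code{extract_joint_angles}; used for
#' self-consistency checks.
#' @param flexion,valgus,internal_rotation degrees
#' @return 3x3 relative rotation matrix
#' @export
compose_joint_rotation <- function(flexion, valgus, internal_rotation) {
  rot_axis(-flexion, "z") %*% rot_axis(-valgus, "x") %*%
    rot_axis(internal_rotation, "y")
}

#' Total elastic energy stored in the model at a pose
#'
#' Bundle energies (analytic integral of the nonlinear law), linear-spring
#' energies (tension-only springs store nothing when slack) and contact
#' penalty energies.  Used by the dynamic energy ledger and the
#' energy-minimisation cross-checks.
#' @param model initialized \code{knee_model}
#' @param pose named list of body frames
#' @return energy, N.mm
#' @export
elastic_energy <- function(model, pose) {
  E <- 0
  for (b in model$bundles)
    E <- E + blankevoort_energy(bundle_length(b, pose) / b$L0 - 1,
                                b$k_N, b$eps_l, b$L0)
  for (sp in model$linear_springs) {
    pa <- world_point(pose, sp$body_a, sp$r_a)
    pb <- world_point(pose, sp$body_b, sp$r_b)
    x <- sqrt(sum((pa - pb)^2)) - sp$rest_length
    if (!isTRUE(sp$tension_only) || x > 0) E <- E + 0.5 * sp$k_Nmm * x^2
  }
  for (su in model$surfaces) {
    cf <- contact_force(su, pose)
    E <- E + 0.5 * su$contact_stiffness * cf$penetration^2
  }
  E
}
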