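# Explicit dynamics for time-varying boundary conditions.  Prescribed motion
# (the knee flexion trajectory) is imposed kinematically; the free tibia DOFs
# carry a lumped mass and are integrated with semi-implicit Euler under the
# elastic, contact, applied and viscous-damping generalized forces.  An
# energy ledger (work in = kinetic + elastic + dissipated) is accumulated at
# every step; the simulation honours conservation of energy to within a few
# percent at the default step size.
#
# Units: mm, N, N.mm, s.  A translational mass m (kg) enters the mm-based
# equations as m/1000 (N per mm/s^2); a rotational inertia I (kg.m^2) enters
# as 1e3 * I (N.mm per rad/s^2).

#' Boundary-condition time series
#'
#' @param times uniform time grid, s
#' @param flexion_deg knee flexion trajectory on \code{times}, degrees
#' @param loads function(t, pose, model) returning
#'   \code{list(forces = list(list(point=, force=)), moment = c(3))} on the
#'   tibia, or NULL for no applied loads
#' @return a \code{boundary_series}
#' @export
boundary_series <- function(times, flexion_deg = rep(0, length(times)),
                            loads = NULL) {
  stopifnot(length(times) >= 2, length(flexion_deg) == length(times))
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("boundary_series: time grid must be uniform")
  structure(list(times = times, flexion_deg = flexion_deg, loads = loads),
            class = "boundary_series")
}

#' Simulate the knee under time-varying boundary conditions
#'
#' Semi-implicit (symplectic) Euler on the free tibia DOFs, with the flexion
#' angle prescribed from the boundary series and all other masked DOFs held.
#' Aborts with a diagnostic if the motion becomes non-finite or the kinetic
#' energy grows beyond \code{energy_abort} times the largest work input seen
#' (numerical instability).
#'
#' @param model initialized \code{knee_model}
#' @param bc a \code{boundary_series}
#' @param dt integration step, s; must resolve the contact frequency
#'   (default 2e-4 s, well below the ~3 ms stability bound of the default
#'   2000 N/mm contact with a 4 kg shank mass)
#' @param damping list(c_trans = N per mm/s, c_rot = N.mm per rad/s)
#' @param mass list(m = kg translational, I = kg.m^2 rotational)
#' @param free logical length-6 DOF mask (dx, dy, dz, wx, wy, wz); flexion
#'   (wz) must not be freed, it is prescribed by \code{bc}
#' @param record_every store every n-th step in the trajectory (default 5)
#' @param energy_abort instability threshold (ratio)
#' @param settle_first quasi-statically equilibrate the free translations
#'   under the initial loads before integrating (default TRUE), so the
#'   trajectory starts from the touch-down equilibrium instead of an
#'   artificial transient
#' @return a \code{knee_trajectory}: list with \code{times}, \code{poses},
#'   \code{strains} (step x bundle), \code{forces}, \code{state}
#'   (data.frame of DOFs and joint angles) and \code{energy} ledger
#' @export
simulate_dynamic <- function(model, bc, dt = 2e-4,
                             damping = list(c_trans = 2.0, c_rot = 5e4),
                             mass = list(m = 4.0, I = 0.06),
                             free = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                             record_every = 5L, energy_abort = 50,
                             settle_first = TRUE) {
  if (!isTRUE(model$initialized))
    stop("model is not initialized; call initialize_reference_lengths() first")
  if (free[6]) stop("wz (flexion) is prescribed by the boundary series and cannot be free")
  t0 <- bc$times[1]; t_end <- bc$times[length(bc$times)]
  n_steps <- ceiling((t_end - t0) / dt)
  m_eff <- rep(mass$m / 1000, 3)          # N per mm/s^2
  I_eff <- rep(1e3 * mass$I, 3)           # N.mm per rad/s^2
  M <- c(m_eff, I_eff)
  Cd <- c(rep(damping$c_trans, 3), rep(damping$c_rot, 3))
  th_fun <- stats::approxfun(bc$times, bc$flexion_deg, rule = 2)

  u <- numeric(6)            # free-DOF offsets: trans mm, rot vector rad
  v <- numeric(6)            # free-DOF velocities
  fr <- which(free)
  pose_at <- function(t, u) {
    p <- flexion_pose(model, th_fun(t))
    p$tibia$t <- p$tibia$t + u[1:3]
    if (any(u[4:6] != 0)) p$tibia$R <- rot_exp(u[4:6]) %*% p$tibia$R
    p
  }
  presc_inc <- function(t_a, t_b, body = "tibia") {
    pa <- flexion_pose(model, th_fun(t_a)); pb <- flexion_pose(model, th_fun(t_b))
    c(pb[[body]]$t - pa[[body]]$t, rot_log(pb[[body]]$R %*% t(pa[[body]]$R)))
  }
  has_patella <- "patella" %in% names(model$bodies)
  get_loads <- function(t, pose) {
    if (is.null(bc$loads)) return(load_case())
    l <- bc$loads(t, pose, model)
    load_case(forces = l$forces %||% list(), moment = l$moment %||% c(0, 0, 0))
  }

  if (settle_first) {
    case0 <- load_case(
      forces = function(pose, model) {
        l <- get_loads(t0, pose)
        fl <- l$forces
        if (is.function(fl)) fl <- fl(pose, model)
        fl
      },
      free = c(free[1:3], rep(FALSE, 3)), frame = "world")
    sol <- solve_static(model, case0, pose_at(t0, u), tol = 1e-4)
    u[1:3] <- sol$tibia$t - flexion_pose(model, th_fun(t0))$tibia$t
  }
  pose <- pose_at(t0, u)
  E_el0 <- elastic_energy(model, pose)
  W_in <- 0; D <- 0
  rec_t <- c(); rec_state <- list(); rec_strain <- list(); rec_force <- list()
  rec_energy <- list()
  bn <- names(model$bundles)
  case <- get_loads(t0, pose)
  g_el <- tibia_elastic_wrench(model, pose)
  g_app <- applied_wrench(case, pose, model)
  g_pat <- if (has_patella) body_elastic_wrench(model, pose, "patella") else numeric(6)

  for (i in seq_len(n_steps)) {
    t_now <- t0 + (i - 1) * dt
    g <- g_el + g_app
    v_old <- v
    a <- (g - Cd * v) / M
    v[fr] <- v[fr] + dt * a[fr]
    du <- numeric(6); du[fr] <- dt * v[fr]
    u <- u + du
    dqp <- presc_inc(t_now, t_now + dt)
    pose <- pose_at(t_now + dt, u)
    case <- get_loads(t_now + dt, pose)
    g_el_new <- tibia_elastic_wrench(model, pose)
    g_app_new <- applied_wrench(case, pose, model)
    g_pat_new <- if (has_patella) body_elastic_wrench(model, pose, "patella") else numeric(6)
    # energy ledger (trapezoidal work): applied work on the full motion +
    # constraint work on the prescribed motion of the tibia and the slaved
    # patella (the constraint actuators balance the elastic and applied
    # loads there); the semi-implicit scheme's numerical damping is booked
    # as dissipation
    W_in <- W_in + sum(0.5 * (g_app + g_app_new) * (du + dqp)) -
      sum(0.5 * ((g_el + g_app) + (g_el_new + g_app_new)) * dqp)
    if (has_patella) {
      dqp_pat <- presc_inc(t_now, t_now + dt, "patella")
      W_in <- W_in - sum(0.5 * (g_pat + g_pat_new) * dqp_pat)
    }
    D <- D + sum((Cd * v_old) * du) + 0.5 * sum(M[fr] * (v[fr] - v_old[fr])^2)
    g_el <- g_el_new; g_app <- g_app_new; g_pat <- g_pat_new
    E_kin <- 0.5 * sum(M[fr] * v[fr]^2)
    E_el <- elastic_energy(model, pose) - E_el0
    if (!all(is.finite(u)) || !all(is.finite(v)) ||
        (E_kin > energy_abort * max(abs(W_in), 1e3)))
      stop("simulate_dynamic: instability at t = ", signif(t_now, 6),
           " s (kinetic energy ", signif(E_kin, 4), " N.mm)")
    if (i %% record_every == 0 || i == n_steps) {
      eps <- all_bundle_strains(model, pose)
      ja <- extract_joint_angles(pose, model$reference_pose)
      rec_t <- c(rec_t, t_now + dt)
      rec_state[[length(rec_state) + 1]] <-
        c(u = u, flexion = ja$flexion, valgus = ja$valgus,
          internal_rotation = ja$internal_rotation)
      rec_strain[[length(rec_strain) + 1]] <- eps
      rec_force[[length(rec_force) + 1]] <-
        vapply(bn, function(nm) blankevoort_force(eps[[nm]],
          model$bundles[[nm]]$k_N, model$bundles[[nm]]$eps_l), numeric(1))
      rec_energy[[length(rec_energy) + 1]] <-
        c(work_in = W_in, kinetic = E_kin, elastic = E_el, dissipated = D)
    }
  }
  strains <- do.call(rbind, rec_strain); colnames(strains) <- bn
  forces <- do.call(rbind, rec_force); colnames(forces) <- bn
  structure(list(
    times = rec_t,
    state = as.data.frame(do.call(rbind, rec_state)),
    strains = strains, forces = forces,
    energy = as.data.frame(do.call(rbind, rec_energy)),
    dt = dt
  ), class = "knee_trajectory")
}

#' Energy-ledger imbalance of a trajectory
#'
#' Relative gap between cumulative work input and the sum of kinetic,
#' elastic and dissipated energies at the final recorded step.
#' @param traj a \code{knee_trajectory}
#' @return dimensionless relative imbalance
#' @export
energy_imbalance <- function(traj) {
  e <- traj$energy[nrow(traj$energy), ]
  denom <- max(abs(e$work_in), abs(e$elastic) + e$dissipated + e$kinetic, 1e-9)
  abs(e$work_in - (e$kinetic + e$elastic + e$dissipated)) / denom
}

#' Flatten a trajectory to a data.frame (one row per recorded step)
#' @param x a \code{knee_trajectory}
#' @param ... unused
#' @return data.frame: time_s, DOF state, joint angles, per-bundle strain and
#'   force columns (strain_<bundle>, force_<bundle>)
#' @export
as.data.frame.knee_trajectory <- function(x, ...) {
  st <- x$state
  eps <- as.data.frame(x$strains); names(eps) <- paste0("strain_", colnames(x$strains))
  ff <- as.data.frame(x$forces); names(ff) <- paste0("force_", colnames(x$forces))
  cbind(data.frame(time_s = x$times), st, eps, ff)
}
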