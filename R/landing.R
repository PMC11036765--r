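# Single-leg jump-landing simulation.  Each participant profile prescribes
# the knee flexion trajectory (sagittal-chain mapping knee = hip + ankle
# dorsiflexion) and applies the muscle forces and the ankle-moment wrench to
# the tibia while the sagittal translations equilibrate dynamically.
# Relative ACL strain uses the bundle length at touch-down (the first profile
# sample) as gauge length; "peak ACL strain" is the larger of the two bundle
# peaks, with both bundles reported.

#' Run one jump-landing simulation
#'
#' @param model initialized \code{knee_model}
#' @param profile a \code{participant_profile}
#' @param ankle_moment apply the time-varying sagittal ankle moment (TRUE,
#'   the study condition) or omit it (FALSE, the comparison arm)
#' @param dt integrator step, s
#' @param shank_length_mm lever arm of the ankle-moment mapping
#' @param ... further arguments to \code{simulate_dynamic}
#' @return a \code{landing_result}: profile id, trajectory, touch-down
#'   lengths, per-bundle relative-strain curves and peaks,
#'   \code{peak_relative_strain} (fraction), \code{time_of_peak}, flag
#' @export
run_landing <- function(model, profile, ankle_moment = TRUE, dt = 2e-4,
                        shank_length_mm = 400, ...) {
  stopifnot(inherits(profile, "participant_profile"))
  if (!isTRUE(model$initialized))
    stop("model is not initialized; call initialize_reference_lengths() first")
  tt <- profile$times
  fq <- stats::approxfun(tt, profile$quad_N, rule = 2)
  fh <- stats::approxfun(tt, profile$hams_N, rule = 2)
  fg <- stats::approxfun(tt, profile$gastroc_N, rule = 2)
  fm <- stats::approxfun(tt, profile$ankle_moment_Nm, rule = 2)
  bc <- boundary_series(
    times = tt, flexion_deg = profile$knee_angle_deg,
    loads = function(t, pose, model) {
      list(forces = muscle_loads(
        pose, model, quad_N = fq(t), hams_N = fh(t), gastroc_N = fg(t),
        ankle_moment_Nm = if (ankle_moment) fm(t) else 0,
        shank_length_mm = shank_length_mm))
    })
  traj <- tryCatch(
    simulate_dynamic(model, bc, dt = dt, ...),
    error = function(e) stop("run_landing failed for profile ", profile$id,
                             ": ", conditionMessage(e)))
  acl <- c("ACL-AM", "ACL-PL")
  rel <- relative_strain_curves(model, traj, touch_down_index = 1L,
                                bundles = acl)
  peaks <- apply(rel, 2, max)
  gov <- acl[which.max(peaks)]
  i_pk <- which.max(rel[, gov])
  structure(list(
    profile_id = profile$id,
    trajectory = traj,
    touch_down_lengths = vapply(acl, function(nm)
      model$bundles[[nm]]$L0 * (1 + traj$strains[1, nm]), numeric(1)),
    relative_strains = rel,
    bundle_peaks = peaks,
    governing_bundle = gov,
    peak_relative_strain = unname(peaks[gov]),
    time_of_peak = traj$times[i_pk],
    ankle_moment_applied = isTRUE(ankle_moment)
  ), class = "landing_result")
}

# relative (touch-down gauge) strain curves for selected bundles:
# eps_rel(t) = (1 + eps_abs(t)) / (1 + eps_abs(td)) - 1
relative_strain_curves <- function(model, traj, touch_down_index = 1L,
                                   bundles = colnames(traj$strains)) {
  eps <- traj$strains[, bundles, drop = FALSE]
  td <- eps[touch_down_index, ]
  sweep(1 + eps, 2, 1 + td, "/") - 1
}

#' Peak relative strain of a trajectory with a touch-down gauge
#'
#' Maximum over the landing phase (t >= touch-down) of
#' \code{(L(t) - L_td) / L_td} per bundle.
#' @param traj a \code{knee_trajectory}
#' @param touch_down_index index of the touch-down sample (gauge)
#' @param bundles bundle names (default: all recorded)
#' @return named numeric vector of peak relative strains (fractions)
#' @export
peak_relative_strain <- function(traj, touch_down_index = 1L,
                                 bundles = colnames(traj$strains)) {
  n <- nrow(traj$strains)
  if (touch_down_index < 1 || touch_down_index > n)
    stop("touch_down_index outside the trajectory")
  if (touch_down_index == n)
    stop("empty landing window after touch-down")
  eps <- traj$strains[touch_down_index:n, bundles, drop = FALSE]
  td <- eps[1, ]
  apply(sweep(1 + eps, 2, 1 + td, "/") - 1, 2, max)
}

#' Cohort summary of landing results
#'
#' Mean and standard deviation of peak relative ACL strain per ankle-moment
#' arm, and the relative reduction \code{1 - mean_on/mean_off}.
#' @param results list of \code{landing_result} covering both arms
#' @return list(table = data.frame(arm, n, mean_peak_strain_pct,
#'   sd_peak_strain_pct), reduction_pct)
#' @export
cohort_landing_summary <- function(results) {
  flag <- vapply(results, `[[`, logical(1), "ankle_moment_applied")
  peak <- vapply(results, `[[`, numeric(1), "peak_relative_strain") * 100
  if (sum(flag) == 0 || sum(!flag) == 0)
    stop("cohort_landing_summary: results must include both ankle-moment arms")
  on <- peak[flag]; off <- peak[!flag]
  if (length(on) < 2 || length(off) < 2)
    stop("cohort_landing_summary: need >= 2 results per arm (sd undefined)")
  if (length(on) != length(off))
    stop("cohort_landing_summary: mismatched arm sizes (", length(on),
         " vs ", length(off), ")")
  tab <- data.frame(
    arm = c("ankle_moment_on", "ankle_moment_off"),
    n = c(length(on), length(off)),
    mean_peak_strain_pct = c(mean(on), mean(off)),
    sd_peak_strain_pct = c(stats::sd(on), stats::sd(off)))
  list(table = tab, reduction_pct = 100 * (1 - mean(on) / mean(off)))
}
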