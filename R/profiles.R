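# Synthetic single-leg jump-landing boundary-condition profiles.  The real
# study drove the knee with ten participants' muscle-force and joint
# kinematic/kinetic curves estimated from motion capture; those raw profiles
# are not published, so this module generates a cohort with the same
# qualitative structure: single-peaked muscle-force bursts shortly after
# touch-down, smooth hip/ankle angle excursions, and hip/ankle moment bursts,
# with participant-to-participant variation drawn around envelope means.
# Curves are piecewise cubic Hermite splines (C1) through onset/peak/decay
# control points; control-point perturbations are Gaussian, truncated at
# +/- 2.5 sd.  The envelope magnitudes are plausible defaults for a
# recreational adult cohort, not digitized study data.

#' Cohort envelope specification
#'
#' Means and standard deviations of the control-point parameters of every
#' boundary-condition curve, plus anthropometrics.  Times in s, forces in N,
#' angles in degrees, moments in N.m; \code{sd = 0} collapses the cohort onto
#' the mean profile.
#'
#' @param n cohort size (default 10)
#' @param seed integer RNG seed
#' @param duration landing-phase window simulated after touch-down, s
#' @param dt_grid profile sampling interval, s
#' @param envelopes named list overriding individual envelope entries; each
#'   entry is \code{c(mean, sd)}
#' @return a \code{cohort_spec}
#' @export
cohort_spec <- function(n = 10, seed = 1, duration = 0.25, dt_grid = 0.005,
                        envelopes = list()) {
  stopifnot(n >= 1, duration > 0, dt_grid > 0)
  env <- list(
    quad_peak = c(2750, 520), quad_tpeak = c(0.060, 0.010),
    hams_peak = c(400, 100), hams_tpeak = c(0.070, 0.012),
    gastroc_peak = c(1000, 250), gastroc_tpeak = c(0.055, 0.010),
    grf_peak_bw = c(2.6, 0.4), grf_tpeak = c(0.045, 0.008),
    hip_angle_start = c(20, 5), hip_angle_max = c(50, 9),
    hip_tmax = c(0.15, 0.02),
    ankle_angle_start = c(-15, 4), ankle_angle_max = c(20, 5),
    ankle_tmax = c(0.12, 0.02),
    hip_moment_peak = c(120, 25), hip_moment_tpeak = c(0.080, 0.012),
    ankle_moment_peak = c(130, 25), ankle_moment_tpeak = c(0.060, 0.010),
    trunk_hip_ratio = c(0.60, 0.08), trunk_offset = c(0, 4),
    body_mass_kg = c(72, 9)
  )
  bad <- setdiff(names(envelopes), names(env))
  if (length(bad))
    stop("cohort_spec: unknown envelope key(s): ", paste(bad, collapse = ", "))
  env[names(envelopes)] <- envelopes
  for (nm in names(env)) {
    e <- env[[nm]]
    if (length(e) != 2 || e[2] < 0)
      stop("cohort_spec: envelope '", nm, "' must be c(mean, sd >= 0)")
  }
  for (nm in c("quad_peak", "hams_peak", "gastroc_peak", "grf_peak_bw",
               "hip_moment_peak", "ankle_moment_peak", "body_mass_kg")) {
    e <- env[[nm]]
    if (e[1] - 2.5 * e[2] < 0)
      stop("cohort_spec: infeasible envelope '", nm,
           "': mean - 2.5 sd is negative")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 duration = duration, dt_grid = dt_grid, envelopes = env),
            class = "cohort_spec")
}

# Latin-hypercube stratified normal deviate for participant `index` and
# envelope parameter `param_idx`.  Each parameter's n strata are assigned to
# the n participants by a seed-dependent permutation, so every cohort is
# representative of the envelope (cohort means sit on the envelope means)
# while participants still span +/- ~2 sd.  The deviates are rescaled to
# unit within-cohort variance and truncated at +/- 2.5 sd.
strat_norm_z <- function(seed, param_idx, n, index) {
  if (n == 1) return(0)                 # a single participant is the mean
  set.seed((seed %% 90000L) * 577L + 131L * param_idx)
  perm <- sample.int(n)
  z_all <- stats::qnorm((seq_len(n) - 0.5) / n)
  z <- z_all[perm[index]] / sqrt(mean(z_all^2))
  min(2.5, max(-2.5, z))
}

# piecewise cubic Hermite interpolation with zero slope at every control
# point (C1, monotone between control values, no overshoot past the peak)
hermite_through <- function(times, xs, ys) {
  out <- numeric(length(times))
  for (j in seq_len(length(xs) - 1)) {
    inseg <- times >= xs[j] & times <= xs[j + 1]
    s <- (times[inseg] - xs[j]) / (xs[j + 1] - xs[j])
    out[inseg] <- ys[j] + (ys[j + 1] - ys[j]) * (3 * s^2 - 2 * s^3)
  }
  out[times < xs[1]] <- ys[1]
  out[times > xs[length(xs)]] <- ys[length(ys)]
  out
}

# C1 single-burst curve through (0, baseline) -> (t_peak, peak) -> (T, tail)
burst_curve <- function(times, t_peak, peak, baseline, tail_frac = 0.35) {
  T_end <- max(times)
  t_peak <- min(max(t_peak, 0.02), T_end - 0.02)
  pmax(0, hermite_through(times, c(0, t_peak, T_end),
                          c(baseline, peak, tail_frac * peak)))
}

# C1 excursion curve through (0, start) -> (t_max, vmax) -> (T, v_end)
excursion_curve <- function(times, start, vmax, t_max, settle = 4) {
  T_end <- max(times)
  t_max <- min(max(t_max, 0.03), T_end - 0.01)
  hermite_through(times, c(0, t_max, T_end),
                  c(start, vmax, vmax - settle * sign(vmax - start)))
}

#' Generate one synthetic participant profile
#'
#' Deterministic given \code{(spec$seed, index, spec$n)}.  Envelope
#' parameters are drawn by Latin-hypercube stratification over the cohort
#' (the seed permutes strata-to-participant assignments), so every cohort is
#' representative of the envelope means while individual participants span
#' the envelope spread.  All summary parameters (angles at peak ground
#' reaction force, maximum knee flexion, peak joint velocity) are computed
#' from the generated curves, never drawn independently.  The knee flexion
#' trajectory follows the documented sagittal-chain mapping
#' knee = hip + ankle dorsiflexion.
#'
#' @param spec a \code{cohort_spec}
#' @param index participant index (1..spec$n)
#' @return a \code{participant_profile}: curves on the uniform grid plus a
#'   \code{summary} list
#' @export
generate_profile <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"), index >= 1, index <= spec$n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  e <- spec$envelopes
  d <- function(nm) {
    z <- strat_norm_z(spec$seed, match(nm, names(e)), spec$n, index)
    e[[nm]][1] + e[[nm]][2] * z
  }

  times <- seq(0, spec$duration, by = spec$dt_grid)
  body_mass <- d("body_mass_kg")
  body_weight_N <- body_mass * 9.81

  quad <- burst_curve(times, d("quad_tpeak"), d("quad_peak"), baseline = 150)
  hams <- burst_curve(times, d("hams_tpeak"), d("hams_peak"), baseline = 80)
  gast <- burst_curve(times, d("gastroc_tpeak"), d("gastroc_peak"), baseline = 100)
  grf <- burst_curve(times, d("grf_tpeak"), d("grf_peak_bw") * body_weight_N,
                     baseline = 30, tail_frac = 0.40)
  hip <- excursion_curve(times, d("hip_angle_start"), d("hip_angle_max"),
                         d("hip_tmax"))
  ankle <- excursion_curve(times, d("ankle_angle_start"), d("ankle_angle_max"),
                           d("ankle_tmax"))
  hip_mom <- burst_curve(times, d("hip_moment_tpeak"), d("hip_moment_peak"),
                         baseline = 10)
  ankle_mom <- burst_curve(times, d("ankle_moment_tpeak"), d("ankle_moment_peak"),
                           baseline = 10)
  trunk <- d("trunk_hip_ratio") * hip + d("trunk_offset")

  knee <- pmax(0, hip + ankle)
  i_grf <- which.max(grf)
  vel <- diff(knee) / spec$dt_grid
  summary <- list(
    trunk_flexion_at_maxGRF = trunk[i_grf],
    hip_flexion_at_maxGRF = hip[i_grf],
    ankle_flexion_at_maxGRF = ankle[i_grf],
    max_knee_flexion = max(knee),
    body_weight_N = body_weight_N,
    peak_grf_N = max(grf),
    peak_knee_flexion_velocity_dps = max(vel),
    peak_quad_N = max(quad), peak_hams_N = max(hams),
    peak_gastroc_N = max(gast),
    peak_hip_moment_Nm = max(hip_mom), peak_ankle_moment_Nm = max(ankle_mom)
  )
  structure(list(
    id = sprintf("P%02d", index), times = times,
    quad_N = quad, hams_N = hams, gastroc_N = gast,
    hip_angle_deg = hip, ankle_angle_deg = ankle,
    knee_angle_deg = knee, trunk_angle_deg = trunk,
    hip_moment_Nm = hip_mom, ankle_moment_Nm = ankle_mom,
    grf_N = grf, body_weight_N = body_weight_N,
    summary = summary
  ), class = "participant_profile")
}

#' Sample a full cohort of landing profiles
#'
#' @param spec a \code{cohort_spec}
#' @param dir optional directory: writes one CSV per profile
#'   (time_s, quad_N, hams_N, gastroc_N, hip_angle_deg, ankle_angle_deg,
#'   hip_moment_Nm, ankle_moment_Nm, grf_N, trunk_angle_deg) plus
#'   \code{cohort_summary.csv} with one row per profile
#' @return list of \code{participant_profile}
#' @export
sample_cohort <- function(spec, dir = NULL) {
  profiles <- lapply(seq_len(spec$n), function(i) generate_profile(spec, i))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in profiles)
      utils::write.csv(profile_to_df(p),
                       file.path(dir, paste0(p$id, ".csv")), row.names = FALSE)
    utils::write.csv(cohort_summary_table(profiles),
                     file.path(dir, "cohort_summary.csv"), row.names = FALSE)
  }
  profiles
}

#' @rdname sample_cohort
#' @param profile a \code{participant_profile}
#' @export
profile_to_df <- function(profile) {
  data.frame(time_s = profile$times, quad_N = profile$quad_N,
             hams_N = profile$hams_N, gastroc_N = profile$gastroc_N,
             hip_angle_deg = profile$hip_angle_deg,
             ankle_angle_deg = profile$ankle_angle_deg,
             hip_moment_Nm = profile$hip_moment_Nm,
             ankle_moment_Nm = profile$ankle_moment_Nm,
             grf_N = profile$grf_N, trunk_angle_deg = profile$trunk_angle_deg)
}

#' Summary table of a cohort (one row per profile)
#' @param profiles list of \code{participant_profile}
#' @return data.frame of the summary parameters
#' @export
cohort_summary_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    cbind(data.frame(id = p$id), as.data.frame(p$summary))))
}
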