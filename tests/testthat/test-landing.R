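make_profile_like <- function(p, ...) {
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

test_that("an all-zero profile produces zero peak relative strain", {
  m <- default_knee_cached()
  spec <- cohort_spec(n = 1, seed = 1, duration = 0.1)
  p <- generate_profile(spec, 1)
  z <- rep(0, length(p$times))
  p0 <- make_profile_like(p, quad_N = z, hams_N = z, gastroc_N = z,
                          hip_angle_deg = z, ankle_angle_deg = z,
                          knee_angle_deg = z, hip_moment_Nm = z,
                          ankle_moment_Nm = z, grf_N = z)
  r <- run_landing(m, p0, ankle_moment = TRUE)
  expect_equal(r$peak_relative_strain, 0, tolerance = 1e-9)
  expect_true(all(abs(r$relative_strains) < 1e-9))
})

test_that("ankle moment reduces the peak strain; more quadriceps never helps", {
  m <- default_knee_cached()
  p <- generate_profile(cohort_spec(n = 1, seed = 6), 1)
  r_on <- run_landing(m, p, ankle_moment = TRUE)
  r_off <- run_landing(m, p, ankle_moment = FALSE)
  expect_lte(r_on$peak_relative_strain, r_off$peak_relative_strain)
  expect_true(r_on$ankle_moment_applied)
  expect_false(r_off$ankle_moment_applied)
  # doubling the quadriceps curve does not decrease the peak
  p2 <- make_profile_like(p, quad_N = 2 * p$quad_N)
  r2 <- run_landing(m, p2, ankle_moment = FALSE)
  expect_gte(r2$peak_relative_strain, r_off$peak_relative_strain - 1e-9)
})

test_that("both ACL bundles are reported and the governing peak is their max", {
  m <- default_knee_cached()
  p <- generate_profile(cohort_spec(n = 1, seed = 8), 1)
  r <- run_landing(m, p, ankle_moment = FALSE)
  expect_named(r$bundle_peaks, c("ACL-AM", "ACL-PL"))
  expect_equal(r$peak_relative_strain, max(r$bundle_peaks))
  expect_true(r$governing_bundle %in% c("ACL-AM", "ACL-PL"))
  expect_gte(r$time_of_peak, min(r$trajectory$times))
  expect_lte(r$time_of_peak, max(r$trajectory$times))
  expect_length(r$touch_down_lengths, 2)
})

test_that("peak relative strain: closed form, scaling invariance, gauge identity", {
  # L_td = 30, max L = 31.05 -> 3.5%
  fake <- list(times = seq(0, 0.1, length.out = 5),
               strains = cbind("ACL-AM" = c(30, 30.6, 31.05, 30.9, 30.2) / 28 - 1))
  class(fake) <- "knee_trajectory"
  expect_equal(unname(peak_relative_strain(fake, 1)), 31.05 / 30 - 1,
               tolerance = 1e-12)
  expect_equal(unname(peak_relative_strain(fake, 1)), 0.035, tolerance = 1e-12)
  # invariant under uniform scaling of all lengths (same strains, other L0)
  fake2 <- fake
  fake2$strains <- cbind("ACL-AM" = (2 * c(30, 30.6, 31.05, 30.9, 30.2)) / 56 - 1)
  expect_equal(peak_relative_strain(fake2, 1), peak_relative_strain(fake, 1),
               tolerance = 1e-12)
  # constant length -> 0
  fake3 <- fake; fake3$strains <- cbind("ACL-AM" = rep(0.02, 5))
  expect_equal(unname(peak_relative_strain(fake3, 1)), 0)
  # gauge identity: (1 + abs(t))/(1 + abs(td)) - 1
  eps_abs <- c(0.021, 0.034, 0.055, 0.041)
  fk <- list(times = 1:4, strains = cbind(b = eps_abs))
  class(fk) <- "knee_trajectory"
  expect_equal(unname(peak_relative_strain(fk, 1)),
               max((1 + eps_abs) / (1 + eps_abs[1]) - 1), tolerance = 1e-12)
  expect_error(peak_relative_strain(fk, 4), "empty landing window")
  expect_error(peak_relative_strain(fk, 9), "outside")
})

test_that("cohort summary: arm means, sds and the reduction formula", {
  mk <- function(peak, on, id) structure(
    list(profile_id = id, peak_relative_strain = peak,
         ankle_moment_applied = on), class = "landing_result")
  res <- c(lapply(1:5, function(i) mk(0.035 + 0.001 * (i - 3), TRUE, i)),
           lapply(1:5, function(i) mk(0.054 + 0.001 * (i - 3), FALSE, i)))
  s <- cohort_landing_summary(res)
  expect_equal(s$table$mean_peak_strain_pct, c(3.5, 5.4), tolerance = 1e-9)
  expect_equal(s$reduction_pct, 100 * (1 - 3.5 / 5.4), tolerance = 1e-9)
  expect_equal(s$reduction_pct, 35.2, tolerance = 0.02)
  # identical arms -> zero reduction
  res0 <- c(lapply(1:3, function(i) mk(0.04 + 0.001 * i, TRUE, i)),
            lapply(1:3, function(i) mk(0.04 + 0.001 * i, FALSE, i)))
  expect_equal(cohort_landing_summary(res0)$reduction_pct, 0, tolerance = 1e-9)
  # single-profile arms: sd undefined
  expect_error(cohort_landing_summary(list(mk(0.03, TRUE, 1), mk(0.05, FALSE, 1))),
               "sd undefined")
  # mismatched arm sizes
  expect_error(cohort_landing_summary(
    c(lapply(1:2, function(i) mk(0.03, TRUE, i)),
      lapply(1:3, function(i) mk(0.05, FALSE, i)))), "mismatched")
  # missing arm
  expect_error(cohort_landing_summary(lapply(1:4, function(i) mk(0.03, TRUE, i))),
               "both ankle-moment arms")
})
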