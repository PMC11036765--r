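test_that("ligament force law: slack, toe, linear branches", {
  expect_equal(blankevoort_force(-0.05, 1000, 0.03), 0)
  expect_equal(blankevoort_force(0, 1000, 0.03), 0)
  # closed-form linear branch: k (eps - eps_l)
  expect_equal(blankevoort_force(0.10, 1000, 0.03), 70)
  # toe branch: k eps^2 / (4 eps_l)
  expect_equal(blankevoort_force(0.02, 1000, 0.03), 1000 * 0.02^2 / 0.12)
  # branch agreement at eps = 2 eps_l (continuity): both give k * eps_l
  k <- 1234; el <- 0.047
  expect_equal(blankevoort_force(2 * el, k, el), k * el, tolerance = 1e-12)
  expect_error(blankevoort_force(0.1, -5, 0.03), "k must be")
  expect_error(blankevoort_force(0.1, 100, 0), "eps_l must be")
})

test_that("force law is continuous, C1 and monotone over random parameters", {
  set.seed(42)
  for (i in 1:200) {
    k <- stats::runif(1, 100, 10000)
    el <- stats::runif(1, 0.005, 0.08)
    # continuity and C1 at the toe-to-linear transition
    h <- 1e-8
    f_lo <- blankevoort_force(2 * el - h, k, el)
    f_hi <- blankevoort_force(2 * el + h, k, el)
    expect_lt(abs(f_hi - f_lo), 1e-3 * k * el + 1e-9)
    d_lo <- (blankevoort_force(2 * el, k, el) - f_lo) / h
    d_hi <- (f_hi - blankevoort_force(2 * el, k, el)) / h
    expect_lt(abs(d_hi - d_lo) / k, 1e-5)
    # monotone non-decreasing for eps >= 0
    eps <- sort(stats::runif(20, 0, 6 * el))
    expect_true(all(diff(blankevoort_force(eps, k, el)) >= 0))
    expect_true(all(blankevoort_force(stats::runif(5, -1, 0), k, el) == 0))
  }
})

test_that("analytic strain energy matches numerical integration of the force", {
  set.seed(7)
  for (i in 1:25) {
    k <- stats::runif(1, 500, 8000)
    el <- stats::runif(1, 0.01, 0.06)
    L0 <- stats::runif(1, 20, 45)
    eps <- stats::runif(1, 0.001, 0.15)
    # E = L0 * integral_0^eps f de
    num <- stats::integrate(function(e) blankevoort_force(e, k, el), 0, eps,
                            rel.tol = 1e-10)$value * L0
    expect_equal(blankevoort_energy(eps, k, el, L0), num,
                 tolerance = 1e-6)
  }
  expect_equal(blankevoort_energy(-0.1, 1000, 0.03, 30), 0)
})

test_that("strain definition and frame invariance", {
  m <- initialize_reference_lengths(build_default_knee())
  b <- m$bundles[["ACL-AM"]]
  expect_equal(bundle_strain(b, m$reference_pose), b$reference_strain,
               tolerance = 1e-12)
  # L = 1.06 L0 -> strain 0.06 on an axis-aligned toy bundle
  mt <- toy_model(bundles = list(list(k = 1000, a = c(0, 0, 0),
                                      b = c(0, -30, 0), prestrain = 0)))
  pose_t <- mt$reference_pose
  pose_t$tibia$t <- c(0, -0.06 * 30, 0)
  expect_equal(bundle_strain(mt$bundles$b1, pose_t), 0.06, tolerance = 1e-12)
  # general definitional identity (L - L0)/L0 at a perturbed pose
  pose <- m$reference_pose
  pose$tibia$t <- pose$tibia$t + c(1.3, -0.7, 0.4)
  L <- kneestrain:::bundle_length(b, pose)
  expect_equal(bundle_strain(b, pose), (L - b$L0) / b$L0, tolerance = 1e-14)
  # rigidly rotating the whole scene leaves strains unchanged
  w <- c(0.3, -0.2, 0.5); R <- rot_exp(w); Tr <- c(5, -3, 2)
  pose2 <- m$reference_pose
  for (nm in names(pose2)) {
    pose2[[nm]]$t <- as.numeric(R %*% pose2[[nm]]$t + Tr)
    pose2[[nm]]$R <- R %*% pose2[[nm]]$R
  }
  expect_equal(all_bundle_strains(m, pose2),
               all_bundle_strains(m, m$reference_pose), tolerance = 1e-12)
})

test_that("reference-length initialization: closed form, exactness, idempotence", {
  # Lr = 31.8, eps_r = 0.10 -> L0 = 28.909090...
  mt <- toy_model(bundles = list(list(k = 1000, a = c(0, 0, 0),
                                      b = c(0, -31.8, 0), prestrain = 0.10)))
  expect_equal(mt$bundles$b1$L0, 31.8 / 1.10, tolerance = 1e-14)
  m <- build_default_knee()
  m1 <- initialize_reference_lengths(m)
  expect_equal(unname(all_bundle_strains(m1, m1$reference_pose)),
               unname(vapply(m1$bundles, `[[`, numeric(1), "reference_strain")),
               tolerance = 1e-12)
  m2 <- initialize_reference_lengths(m1)
  expect_identical(m1, m2)
  # zero pre-strain keeps L0 = Lr
  m3 <- initialize_reference_lengths(m, prestrains = c("ACL-AM" = 0))
  b <- m3$bundles[["ACL-AM"]]
  expect_equal(b$L0, kneestrain:::bundle_length(b, m3$reference_pose),
               tolerance = 1e-14)
  expect_error(initialize_reference_lengths(m, prestrains = c(bogus = 0.1)),
               "unknown bundle")
  # uninitialised bundle raises a state error
  expect_error(bundle_strain(m$bundles[["ACL-AM"]], m$reference_pose),
               "not initialized")
})

test_that("linear springs: Hooke's law with tension-only clamp", {
  mt <- toy_model(springs = list(list(k = 545, a = c(0, 0, 0), b = c(0, -10, 0),
                                      tension_only = TRUE)))
  sp <- mt$linear_springs$s1
  pose <- mt$reference_pose
  expect_equal(linear_spring_force(sp, pose), 0)
  pose$tibia$t <- c(0, -0.5, 0)   # elongate 0.5 mm
  expect_equal(linear_spring_force(sp, pose), 272.5, tolerance = 1e-9)
  pose$tibia$t <- c(0, 0.5, 0)    # shorten: slack
  expect_equal(linear_spring_force(sp, pose), 0)
})
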