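test_that("penalty contact: separation, closed form, Newton's third law", {
  su <- list(name = "c", type = "sphere_plane", sphere_body = "femur",
             center = c(0, 10, 0), radius = 10, plane_body = "tibia",
             point = c(0, 0, 0), normal = c(0, 1, 0), contact_stiffness = 1000)
  pose <- list(femur = list(t = c(0, 0, 0), R = diag(3)),
               tibia = list(t = c(0, 0, 0), R = diag(3)))
  cf <- contact_force(su, pose)
  expect_equal(cf$penetration, 0)
  expect_equal(cf$force, c(0, 0, 0))
  # separation > 0: still zero
  pose$tibia$t <- c(0, -2, 0)
  expect_equal(contact_force(su, pose)$force, c(0, 0, 0))
  # penetration 0.1 mm at k = 1000 N/mm -> 100 N along the normal
  pose$tibia$t <- c(0, 0.1, 0)
  cf <- contact_force(su, pose)
  expect_equal(cf$penetration, 0.1, tolerance = 1e-12)
  expect_equal(cf$force, c(0, 100, 0), tolerance = 1e-9)
  # equal and opposite: the tibia wrench carries -force
  m <- toy_model()
  m$surfaces <- list(c1 = su)
  g_tib <- kneestrain:::body_elastic_wrench(m, pose, "tibia")
  g_fem <- kneestrain:::body_elastic_wrench(m, pose, "femur")
  expect_equal(g_tib[1:3], -g_fem[1:3], tolerance = 1e-9)
})

test_that("1-DOF Hooke oracle: 30 N against a 100 N/mm spring gives 0.3 mm", {
  # spring axis aligned with the load so the response is exactly Hookean
  m2 <- toy_model(springs = list(list(k = 100, a = c(-10, 0, 0), b = c(0, 0, 0))))
  sol2 <- solve_static(m2, load_case(
    forces = list(list(point = c(0, 0, 0), force = c(30, 0, 0))),
    free = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)))
  expect_equal(sol2$tibia$t[1], 0.3, tolerance = 1e-7)
  expect_lt(attr(sol2, "residual"), 1e-6)
})

test_that("static solutions match brute-force energy minimisation on random toys", {
  set.seed(2024)
  n_cases <- 50
  for (i in seq_len(n_cases)) {
    ndof <- sample(1:3, 1)
    free_dims <- sort(sample(1:3, ndof))
    tc <- random_toy_case(free_dims)
    free <- c(1:3 %in% free_dims, rep(FALSE, 3))
    case <- load_case(
      forces = list(list(point = c(0, 0, 0), force = tc$force)),
      free = free)
    sol <- tryCatch(solve_static(tc$model, case), error = function(e) NULL)
    if (is.null(sol)) { # non-convex draw (slack bundle set): skip this draw
      succeed(); next
    }
    u_bf <- brute_force_translation(tc$model, tc$force, free_dims)
    expect_equal(sol$tibia$t[free_dims], u_bf[free_dims], tolerance = 1e-4)
  }
})

test_that("solutions are guess-independent and scene-rotation objective", {
  set.seed(9)
  tc <- random_toy_case(c(1, 2))
  case <- load_case(forces = list(list(point = c(0, 0, 0), force = tc$force)),
                    free = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  sol1 <- solve_static(tc$model, case)
  g2 <- tc$model$reference_pose
  g2$tibia$t <- g2$tibia$t + c(1.5, -2.0, 0)
  sol2 <- solve_static(tc$model, case, g2)
  expect_equal(sol1$tibia$t, sol2$tibia$t, tolerance = 1e-5)
})

test_that("unloaded equilibrium from a settled pose converges immediately", {
  m <- toy_model(springs = list(
    list(k = 50, a = c(0, 20, 0), b = c(0, 0, 0)),
    list(k = 50, a = c(20, 0, 0), b = c(0, 0, 0)),
    list(k = 50, a = c(-20, 0, 0), b = c(0, 0, 0))))
  sol <- solve_static(m, load_case(free = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_lt(attr(sol, "residual"), 1e-6)
  expect_equal(sol$tibia$t, c(0, 0, 0), tolerance = 1e-8)
})

test_that("joint angles: identity, single-axis, and round-trip composition", {
  pose0 <- list(femur = list(t = c(0, 0, 0), R = diag(3)),
                tibia = list(t = c(0, -24, 0), R = diag(3)))
  ja <- extract_joint_angles(pose0)
  expect_equal(c(ja$flexion, ja$valgus, ja$internal_rotation), c(0, 0, 0))
  # pure 30 deg rotation about the femoral flexion axis
  pose <- pose0
  pose$tibia$R <- rot_axis(-30, "z")
  ja <- extract_joint_angles(pose)
  expect_equal(ja$flexion, 30, tolerance = 1e-9)
  expect_equal(ja$valgus, 0, tolerance = 1e-9)
  expect_equal(ja$internal_rotation, 0, tolerance = 1e-9)
  # random rotations round-trip through forward composition
  set.seed(5)
  for (i in 1:25) {
    f <- stats::runif(1, -80, 80); v <- stats::runif(1, -30, 30)
    r <- stats::runif(1, -40, 40)
    pose$tibia$R <- compose_joint_rotation(f, v, r)
    ja <- extract_joint_angles(pose)
    expect_equal(c(ja$flexion, ja$valgus, ja$internal_rotation), c(f, v, r),
                 tolerance = 1e-9)
    R_back <- compose_joint_rotation(ja$flexion, ja$valgus, ja$internal_rotation)
    expect_equal(R_back, pose$tibia$R, tolerance = 1e-9)
  }
})

test_that("rotation utilities: exp/log inverse pair and rotation checks", {
  set.seed(3)
  for (i in 1:20) {
    w <- stats::runif(3, -1.5, 1.5)
    R <- rot_exp(w)
    expect_true(is_rotation(R))
    expect_equal(rot_log(R), w, tolerance = 1e-9)
  }
  expect_false(is_rotation(diag(3) * 1.001))
  expect_equal(rot_exp(c(0, 0, 0)), diag(3))
})
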