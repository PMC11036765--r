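# Test fixtures built in code: a cached initialized default knee and a
# factory for minimal translation-only toy models used by the solver
# oracle tests.

default_knee_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- initialize_reference_lengths(build_default_knee())
    m
  }
})

# A toy "knee" with only femur (grounded) and tibia, connected by linear
# springs (not tension-only, guaranteed convex energy) and optionally taut
# nonlinear bundles; no contact.  Bundle counts are irrelevant for solver
# tests, so the structure is assembled directly.
toy_model <- function(springs = list(), bundles = list()) {
  bodies <- list(femur = rigid_body("femur"),
                 tibia = rigid_body("tibia", c(0, 0, 0)))
  sp <- list()
  for (i in seq_along(springs)) {
    s <- springs[[i]]
    sp[[paste0("s", i)]] <- list(
      name = paste0("s", i), k_Nmm = s$k,
      body_a = "femur", r_a = s$a, body_b = "tibia", r_b = s$b,
      rest_length = s$rest %||% sqrt(sum((s$a - s$b)^2)),
      tension_only = isTRUE(s$tension_only))
  }
  bd <- list()
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    Lr <- sqrt(sum((b$a - b$b)^2))
    bd[[paste0("b", i)]] <- list(
      name = paste0("b", i), ligament = "toy", k_N = b$k,
      reference_strain = b$prestrain, eps_l = b$eps_l %||% 0.03,
      femur_site = b$a, tibia_site = b$b, L0 = Lr / (1 + b$prestrain))
  }
  m <- structure(list(
    schema_version = "1.0", scale = 1,
    bodies = bodies, bundles = bd, linear_springs = sp, surfaces = list(),
    flexion_axis_point = c(0, 0, 0),
    reference_pose = NULL, initialized = TRUE
  ), class = "knee_model")
  m$reference_pose <- stats::setNames(
    lapply(bodies, function(b) list(t = b$position, R = b$rotation)),
    names(bodies))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force energy-minimisation oracle for translation-only toy cases:
# dense grid scan then Nelder-Mead polish of the total potential
# V(u) = E_elastic(pose + u) - F . u
brute_force_translation <- function(model, force, free_dims,
                                    range = 10, n_grid = NULL) {
  if (is.null(n_grid)) n_grid <- c(41, 17, 11)[length(free_dims)]
  V <- function(uf) {
    u <- numeric(3); u[free_dims] <- uf
    pose <- model$reference_pose
    pose$tibia$t <- pose$tibia$t + u
    elastic_energy(model, pose) - sum(force * u)
  }
  grid1 <- seq(-range, range, length.out = n_grid)
  grids <- do.call(expand.grid, rep(list(grid1), length(free_dims)))
  vals <- apply(grids, 1, V)
  start <- as.numeric(grids[which.min(vals), ])
  if (length(free_dims) == 1) {
    h <- grid1[2] - grid1[1]
    opt <- stats::optimize(V, c(start - h, start + h), tol = 1e-12)
    par <- opt$minimum
  } else {
    opt <- stats::optim(start, V, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    opt2 <- stats::optim(opt$par, V, method = "BFGS",
                         control = list(reltol = 1e-14, maxit = 1000))
    par <- if (opt2$value < opt$value) opt2$par else opt$par
  }
  u <- numeric(3); u[free_dims] <- par
  u
}

# random convex translation-only toy: a few stiff linear springs in general
# position plus one or two taut tension-only bundles and a modest force
random_toy_case <- function(free_dims) {
  n_sp <- sample(3:5, 1)
  springs <- lapply(seq_len(n_sp), function(i) {
    a <- stats::runif(3, -40, 40)
    d <- stats::runif(3, -1, 1); d <- d / sqrt(sum(d^2))
    b <- a + stats::runif(1, 10, 25) * d     # well-separated endpoints
    # pre-tensioned (taut) so the net has transverse geometric stiffness
    list(k = stats::runif(1, 20, 120), a = a, b = b,
         rest = stats::runif(1, 0.75, 0.95) * sqrt(sum((a - b)^2)))
  })
  bundles <- lapply(seq_len(sample(1:2, 1)), function(i) {
    a <- stats::runif(3, -40, 40)
    d <- stats::runif(3, -1, 1); d <- d / sqrt(sum(d^2))
    # taut enough that modest deflections stay on the smooth branch
    list(k = stats::runif(1, 1000, 4000), a = a, b = a + 30 * d,
         prestrain = stats::runif(1, 0.08, 0.15))
  })
  force3 <- numeric(3)
  force3[free_dims] <- stats::runif(length(free_dims), -40, 40)
  list(model = toy_model(springs, bundles), force = force3)
}
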