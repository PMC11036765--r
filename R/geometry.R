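# Reduced-order knee geometry: rigid femur/tibia/patella frames, ligament
# bundle insertion sites, linear springs and simple articular surface
# primitives.  Coordinates are right-handed with X anterior, Y proximal,
# Z lateral (a right knee); units are mm, N, N.mm throughout, degrees at the
# user interface.  The femur frame coincides with ground at the full-extension
# reference pose and stays fixed in the validation protocols.

MODEL_SCHEMA_VERSION <- "1.0"

#' Construct a rigid body
#'
#' @param name identifier
#' @param position length-3 numeric, mm, body-frame origin in ground
#' @param rotation 3x3 proper rotation, body axes in ground
#' @return a \code{rigid_body} list
#' @export
rigid_body <- function(name, position = c(0, 0, 0), rotation = diag(3)) {
  if (!is_rotation(rotation))
    stop("rigid_body '", name, "': rotation is not a proper rotation matrix")
  stopifnot(length(position) == 3, all(is.finite(position)))
  structure(list(name = name, position = as.numeric(position),
                 rotation = rotation), class = "rigid_body")
}

#' Reference pose of a set of bodies
#'
#' A pose maps body names to frames (\code{t} translation mm, \code{R}
#' rotation).  The reference pose simply copies each body's stored frame.
#' @param bodies named list of \code{rigid_body}
#' @return named list of frames
#' @keywords internal
pose_from_bodies <- function(bodies) {
  stats::setNames(lapply(bodies, function(b) list(t = b$position, R = b$rotation)),
                  vapply(bodies, `[[`, "", "name"))
}

#' World-frame position of a body-fixed point
#' @param pose pose (named list of frames)
#' @param body body name
#' @param r length-3 local position, mm
#' @return length-3 world position, mm
#' @export
world_point <- function(pose, body, r) {
  fr <- pose[[body]]
  if (is.null(fr)) stop("pose has no frame for body '", body, "'")
  as.numeric(fr$t + fr$R %*% r)
}

#' Default knee geometry parameters
#'
#' Insertion coordinates and surface primitives of the parametric default
#' knee.  The cadaveric digitisation behind the original model is not
#' published, so these sites are placed from published anatomical ranges
#' (ACL length ~28-38 mm running anterior-distal on the tibia to the
#' posterior femoral notch, collaterals spanning the epicondyles to the
#' proximal tibia/fibular head) and adjusted once so the passive bundle
#' kinematics show the canonical behaviour: a near-isometric anteromedial
#' (AM) bundle and a posterolateral (PL) bundle that slackens with flexion.
#' All values are mm in the body frames described above.
#' @return named list of geometry parameters
#' @export
default_knee_geometry <- function() {
  list(
    # transepicondylar flexion axis: point + direction (+Z, lateral)
    flexion_axis_point = c(-4, 6, 0),
    # femoral condyle spheres (femur frame) and tibial plateau plane (tibia frame)
    condyle_radius = 30,
    condyle_centers = list(medial = c(-4, 6, -22), lateral = c(-4, 6, 22)),
    plateau_point = c(0, 0, 0),      # tibia frame; plateau normal +Y
    tibia_origin = c(0, -24, 0),     # tibia frame origin in ground at extension
    contact_stiffness = 2000,        # N/mm penalty, per condyle
    # cruciate insertions: femur-frame / tibia-frame local coordinates
    acl_am_femur = c(-4.3, 6.7, 3), acl_am_tibia = c(10, 2.5, -2),
    acl_pl_femur = c(-7.5, 4.3, 8), acl_pl_tibia = c(13, 1.5, 4),
    pcl_al_femur = c(1.7, -3.9, -6.7), pcl_al_tibia = c(-26, -6, -1),
    pcl_pm_femur = c(-5.5, 3.9, -6.7), pcl_pm_tibia = c(-28, -8, -4),
    # collaterals: three fibres each, femoral epicondyle to distal insertions
    mcl_femur = list(a = c(2, 6, -42), c = c(0, 6, -43), p = c(-4, 6, -42)),
    mcl_tibia = list(a = c(6, -52, -34), c = c(2, -56, -34), p = c(-4, -52, -34)),
    # LCL femoral fibres sit on / just behind the flexion axis so the
    # ligament slackens slightly with flexion
    lcl_femur = list(a = c(-4, 6, 42), c = c(-6, 5, 43), p = c(-9, 4, 42)),
    lcl_tibia = list(a = c(-2, -28, 40), c = c(-5, -30, 40), p = c(-8, -28, 40)),
    # patellar mechanism and meniscal horn anchor points; femur-side anchors
    # lie on the flexion axis (epicondylar line) so these secondary
    # restraints are isometric under pure flexion and resist translations
    patella_center = c(45, 5, 0),          # ground frame at extension
    tibial_tubercle = c(22, -16, 0),       # tibia frame
    pf_ligament_femur = list(medial = c(-4, 6, -40), lateral = c(-4, 6, 40)),
    horn_femur = list(medial = c(-4, 6, -20), lateral = c(-4, 6, 20)),
    horn_tibia = list(medial = c(-6, 1, -20), lateral = c(-6, 1, 20))
  )
}

#' Build the parametric default knee model
#'
#' Assembles the reduced-order right knee: rigid femur (grounded), tibia and a
#' massless patella marker; two-bundle ACL and PCL; three-bundle MCL and LCL;
#' linear springs for the patellar ligament (545 N/mm), medial and lateral
#' patellofemoral ligaments (16 and 12 N/mm) and the meniscal horn stand-ins
#' (180 N/mm); and frictionless sphere-on-plane condyle contact.  Bundle
#' stiffness and reference-strain parameters come from
#' \code{default_bundle_parameters()} unless overridden.
#'
#' The build is deterministic and pure: equal inputs give identical models.
#'
#' @param scale global similarity scale (1 = adult male knee, dimensionless)
#' @param options named list of overrides; recognised keys are
#'   \code{geometry} (a list as from \code{default_knee_geometry}),
#'   \code{bundle_parameters} (a data.frame as from
#'   \code{default_bundle_parameters}) and \code{contact_stiffness} (N/mm)
#' @return an (uninitialised) \code{knee_model}; call
#'   \code{initialize_reference_lengths} before computing forces
#' @export
build_default_knee <- function(scale = 1.0, options = list()) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  allowed <- c("geometry", "bundle_parameters", "contact_stiffness")
  bad <- setdiff(names(options), allowed)
  if (length(bad))
    stop("build_default_knee: unknown option key(s): ", paste(bad, collapse = ", "))

  geo <- options$geometry %||% default_knee_geometry()
  pars <- options$bundle_parameters %||% default_bundle_parameters()
  if (!is.null(options$contact_stiffness)) geo$contact_stiffness <- options$contact_stiffness

  s <- function(v) scale * v
  bodies <- list(
    femur = rigid_body("femur", c(0, 0, 0)),
    tibia = rigid_body("tibia", s(geo$tibia_origin)),
    patella = rigid_body("patella", s(geo$patella_center))
  )

  getp <- function(nm, col) {
    i <- match(nm, pars$bundle)
    if (is.na(i)) stop("bundle parameter table has no row for '", nm, "'")
    pars[[col]][i]
  }
  mk_bundle <- function(nm, lig, fem, tib) {
    list(name = nm, ligament = lig,
         k_N = getp(nm, "k_N"),
         reference_strain = getp(nm, "reference_strain"),
         eps_l = getp(nm, "eps_l"),
         femur_site = s(fem), tibia_site = s(tib), L0 = NA_real_)
  }
  bundles <- list(
    mk_bundle("ACL-AM", "ACL", geo$acl_am_femur, geo$acl_am_tibia),
    mk_bundle("ACL-PL", "ACL", geo$acl_pl_femur, geo$acl_pl_tibia),
    mk_bundle("PCL-AL", "PCL", geo$pcl_al_femur, geo$pcl_al_tibia),
    mk_bundle("PCL-PM", "PCL", geo$pcl_pm_femur, geo$pcl_pm_tibia),
    mk_bundle("MCL-A", "MCL", geo$mcl_femur$a, geo$mcl_tibia$a),
    mk_bundle("MCL-C", "MCL", geo$mcl_femur$c, geo$mcl_tibia$c),
    mk_bundle("MCL-P", "MCL", geo$mcl_femur$p, geo$mcl_tibia$p),
    mk_bundle("LCL-A", "LCL", geo$lcl_femur$a, geo$lcl_tibia$a),
    mk_bundle("LCL-C", "LCL", geo$lcl_femur$c, geo$lcl_tibia$c),
    mk_bundle("LCL-P", "LCL", geo$lcl_femur$p, geo$lcl_tibia$p)
  )
  names(bundles) <- vapply(bundles, `[[`, "", "name")

  mk_spring <- function(nm, k, body_a, r_a, body_b, r_b, tension_only = TRUE) {
    list(name = nm, k_Nmm = k, body_a = body_a, r_a = s(r_a),
         body_b = body_b, r_b = s(r_b), rest_length = NA_real_,
         tension_only = tension_only)
  }
  linear_springs <- list(
    mk_spring("PL", 545, "patella", c(0, -20, 0), "tibia", geo$tibial_tubercle),
    mk_spring("MPFL", 16, "femur", geo$pf_ligament_femur$medial, "patella", c(-5, 0, -15)),
    mk_spring("LPFL", 12, "femur", geo$pf_ligament_femur$lateral, "patella", c(-5, 0, 15)),
    mk_spring("horn-med", 180, "femur", geo$horn_femur$medial, "tibia", geo$horn_tibia$medial),
    mk_spring("horn-lat", 180, "femur", geo$horn_femur$lateral, "tibia", geo$horn_tibia$lateral)
  )
  names(linear_springs) <- vapply(linear_springs, `[[`, "", "name")

  surfaces <- list(
    list(name = "condyle-med", type = "sphere_plane",
         sphere_body = "femur", center = s(geo$condyle_centers$medial),
         radius = s(geo$condyle_radius),
         plane_body = "tibia", point = s(geo$plateau_point), normal = c(0, 1, 0),
         contact_stiffness = geo$contact_stiffness),
    list(name = "condyle-lat", type = "sphere_plane",
         sphere_body = "femur", center = s(geo$condyle_centers$lateral),
         radius = s(geo$condyle_radius),
         plane_body = "tibia", point = s(geo$plateau_point), normal = c(0, 1, 0),
         contact_stiffness = geo$contact_stiffness)
  )
  names(surfaces) <- vapply(surfaces, `[[`, "", "name")

  model <- structure(list(
    schema_version = MODEL_SCHEMA_VERSION,
    scale = scale,
    bodies = bodies,
    bundles = bundles,
    linear_springs = linear_springs,
    surfaces = surfaces,
    flexion_axis_point = s(geo$flexion_axis_point),
    reference_pose = pose_from_bodies(bodies),
    initialized = FALSE
  ), class = "knee_model")
  validate_knee_model(model)
  model
}

#' Validate knee-model invariants
#'
#' Checks the structural contract: femur and tibia present, 2+2+3+3
#' cruciate/collateral bundles, every element endpoint resolving to a defined
#' body, proper rotations, positive stiffnesses and radii.
#' @param model a \code{knee_model}
#' @return the model, invisibly; stops on violation
#' @export
validate_knee_model <- function(model) {
  stopifnot(inherits(model, "knee_model"))
  nm <- names(model$bodies)
  if (!all(c("femur", "tibia") %in% nm))
    stop("knee_model must contain bodies 'femur' and 'tibia'")
  for (b in model$bodies)
    if (!is_rotation(b$rotation)) stop("body '", b$name, "' orientation is not a rotation")
  lig <- vapply(model$bundles, `[[`, "", "ligament")
  counts <- c(ACL = 2L, PCL = 2L, MCL = 3L, LCL = 3L)
  for (l in names(counts))
    if (sum(lig == l) != counts[[l]])
      stop(l, " must have exactly ", counts[[l]], " bundles, found ", sum(lig == l))
  for (bd in model$bundles) {
    if (!all(is.finite(bd$femur_site)) || !all(is.finite(bd$tibia_site)))
      stop("bundle '", bd$name, "': non-finite insertion site")
    if (bd$k_N <= 0) stop("bundle '", bd$name, "': k must be > 0")
    if (bd$eps_l <= 0) stop("bundle '", bd$name, "': eps_l must be > 0")
    if (bd$reference_strain <= -1) stop("bundle '", bd$name, "': reference_strain must exceed -1")
  }
  for (sp in model$linear_springs) {
    if (!all(c(sp$body_a, sp$body_b) %in% nm))
      stop("spring '", sp$name, "': endpoint body not defined")
    if (sp$k_Nmm <= 0) stop("spring '", sp$name, "': k must be > 0")
  }
  for (su in model$surfaces) {
    if (su$radius <= 0) stop("surface '", su$name, "': radius must be > 0")
    if (su$contact_stiffness <= 0) stop("surface '", su$name, "': contact_stiffness must be > 0")
    if (!all(c(su$sphere_body, su$plane_body) %in% nm))
      stop("surface '", su$name, "': body not defined")
  }
  invisible(model)
}

#' Default per-bundle stiffness and reference-strain parameters
#'
#' Stiffness k is the linear-region modulus in N per unit strain; the
#' reference strain is the pre-strain each bundle carries at the
#' full-extension reference pose (ACL AM 6\%, PL 10\%); eps_l is the
#' toe-to-linear transition strain of the piecewise force law (0.03 for all
#' bundles).  ACL values follow the tensile-testing literature on the human
#' ACL; cruciate/collateral values follow the standard one-dimensional
#' ligament-element parameter sets used in rigid-body knee models.  The
#' AM = 6\%, PL = 10\% assignment of the two ACL pre-strains is an inference
#' from the reported flexion behaviour of the two bundles, not an explicitly
#' stated pairing; override via the \code{bundle_parameters} build option to
#' explore the alternative.
#' @return data.frame with columns bundle, k_N, reference_strain, eps_l
#' @export
default_bundle_parameters <- function() {
  path <- system.file("extdata", "bundle_parameters.csv", package = "kneestrain")
  tab <- if (nzchar(path)) {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    bundle_parameter_table()
  }
  for (col in c("k_N", "reference_strain", "eps_l"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab
}

#' @rdname default_bundle_parameters
#' @export
bundle_parameter_table <- function() {
  data.frame(
    bundle = c("ACL-AM", "ACL-PL", "PCL-AL", "PCL-PM",
               "MCL-A", "MCL-C", "MCL-P", "LCL-A", "LCL-C", "LCL-P"),
    k_N = c(5000, 5000, 9000, 9000, 2750, 2750, 2750, 2000, 2000, 2000),
    reference_strain = c(0.06, 0.10, -0.24, -0.03, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    eps_l = rep(0.03, 10),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
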