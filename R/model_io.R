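# JSON serialization of knee models.  The schema is versioned
# ("schema_version") and numbers are written at full precision so that
# save -> load is the identity on every field.
#
# Schema (version 1.0):
# {
#   "schema_version": "1.0",
#   "scale": 1.0,
#   "bodies": [{"name", "frame": {"position": [3], "rotation": [[3x3]]}}],
#   "bundles": [{"name", "ligament", "k_N", "reference_strain", "eps_l",
#                "femur_site": [3], "tibia_site": [3], "L0"}],
#   "linear_springs": [{"name", "k_Nmm", "body_a", "r_a": [3],
#                       "body_b", "r_b": [3], "rest_length", "tension_only"}],
#   "surfaces": [{"name", "type", "sphere_body", "center": [3], "radius",
#                 "plane_body", "point": [3], "normal": [3],
#                 "contact_stiffness"}],
#   "flexion_axis_point": [3],
#   "initialized": bool
# }
# Optional bundle keys default to eps_l = 0.03 and L0 = null (uninitialised).

#' Save a knee model to JSON
#' @param model a \code{knee_model}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "knee_model"))
  doc <- list(
    schema_version = model$schema_version %||% MODEL_SCHEMA_VERSION,
    scale = model$scale %||% 1.0,
    bodies = unname(lapply(model$bodies, function(b) list(
      name = b$name,
      frame = list(position = b$position,
                   rotation = apply(b$rotation, 1, identity, simplify = FALSE))
    ))),
    bundles = unname(lapply(model$bundles, function(b) list(
      name = b$name, ligament = b$ligament, k_N = b$k_N,
      reference_strain = b$reference_strain, eps_l = b$eps_l,
      femur_site = b$femur_site, tibia_site = b$tibia_site,
      L0 = if (is.finite(b$L0)) b$L0 else NULL
    ))),
    linear_springs = unname(lapply(model$linear_springs, function(s) list(
      name = s$name, k_Nmm = s$k_Nmm, body_a = s$body_a, r_a = s$r_a,
      body_b = s$body_b, r_b = s$r_b,
      rest_length = if (is.finite(s$rest_length)) s$rest_length else NULL,
      tension_only = isTRUE(s$tension_only)
    ))),
    surfaces = unname(lapply(model$surfaces, function(s) s)),
    flexion_axis_point = model$flexion_axis_point,
    initialized = isTRUE(model$initialized)
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

need <- function(x, key, where) {
  if (is.null(x[[key]]))
    stop("model JSON schema error: missing required key at ", where, "/", key)
  x[[key]]
}

#' Load a knee model from JSON
#'
#' Applies defaults for optional keys (\code{eps_l = 0.03}, uninitialised
#' \code{L0}/\code{rest_length}); validates required keys (error carries a
#' JSON-pointer-style path) and that every orientation is a proper rotation.
#' Structural ligament-count invariants are enforced only with
#' \code{strict = TRUE}, so minimal hand-written models load.
#'
#' @param path JSON file path
#' @param strict also enforce full \code{validate_knee_model} invariants
#' @return a \code{knee_model}
#' @export
load_model <- function(path, strict = FALSE) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (k in c("bodies", "bundles")) need(doc, k, "")
  bodies <- list()
  for (i in seq_along(doc$bodies)) {
    b <- doc$bodies[[i]]
    where <- paste0("/bodies/", i - 1)
    nm <- need(b, "name", where)
    fr <- need(b, "frame", where)
    pos <- as.numeric(unlist(need(fr, "position", paste0(where, "/frame"))))
    R <- do.call(rbind, lapply(need(fr, "rotation", paste0(where, "/frame")),
                               function(r) as.numeric(unlist(r))))
    if (!is_rotation(R))
      stop("model validation error: orientation of body '", nm,
           "' is not a proper rotation")
    bodies[[nm]] <- rigid_body(nm, pos, R)
  }
  bundles <- list()
  for (i in seq_along(doc$bundles)) {
    b <- doc$bundles[[i]]
    where <- paste0("/bundles/", i - 1)
    nm <- need(b, "name", where)
    bundles[[nm]] <- list(
      name = nm, ligament = need(b, "ligament", where),
      k_N = as.numeric(need(b, "k_N", where)),
      reference_strain = as.numeric(need(b, "reference_strain", where)),
      eps_l = as.numeric(b$eps_l %||% 0.03),
      femur_site = as.numeric(unlist(need(b, "femur_site", where))),
      tibia_site = as.numeric(unlist(need(b, "tibia_site", where))),
      L0 = as.numeric(b$L0 %||% NA_real_)
    )
  }
  springs <- list()
  for (i in seq_along(doc$linear_springs)) {
    s <- doc$linear_springs[[i]]
    where <- paste0("/linear_springs/", i - 1)
    nm <- need(s, "name", where)
    springs[[nm]] <- list(
      name = nm, k_Nmm = as.numeric(need(s, "k_Nmm", where)),
      body_a = need(s, "body_a", where), r_a = as.numeric(unlist(need(s, "r_a", where))),
      body_b = need(s, "body_b", where), r_b = as.numeric(unlist(need(s, "r_b", where))),
      rest_length = as.numeric(s$rest_length %||% NA_real_),
      tension_only = isTRUE(s$tension_only %||% TRUE)
    )
  }
  surfaces <- list()
  for (i in seq_along(doc$surfaces)) {
    s <- doc$surfaces[[i]]
    where <- paste0("/surfaces/", i - 1)
    nm <- need(s, "name", where)
    surfaces[[nm]] <- list(
      name = nm, type = need(s, "type", where),
      sphere_body = need(s, "sphere_body", where),
      center = as.numeric(unlist(need(s, "center", where))),
      radius = as.numeric(need(s, "radius", where)),
      plane_body = need(s, "plane_body", where),
      point = as.numeric(unlist(need(s, "point", where))),
      normal = as.numeric(unlist(need(s, "normal", where))),
      contact_stiffness = as.numeric(need(s, "contact_stiffness", where))
    )
  }
  model <- structure(list(
    schema_version = doc$schema_version %||% MODEL_SCHEMA_VERSION,
    scale = as.numeric(doc$scale %||% 1.0),
    bodies = bodies, bundles = bundles, linear_springs = springs,
    surfaces = surfaces,
    flexion_axis_point = as.numeric(unlist(doc$flexion_axis_point %||% c(0, 0, 0))),
    reference_pose = NULL, initialized = isTRUE(doc$initialized)
  ), class = "knee_model")
  model$reference_pose <- pose_from_bodies(bodies)
  if (strict) validate_knee_model(model)
  model
}
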