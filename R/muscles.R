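# Effective muscle lines of action on the isolated tibia.  The femur is
# grounded, so muscle actions are mapped to equivalent forces on the tibia
# with flexion-dependent directions taken from the sagittal-plane literature:
#
# * Quadriceps act through the patellar tendon at the tibial tubercle.  The
#   tendon leans anteriorly relative to the tibial long axis by about 20 deg
#   near extension and tilts posteriorly as the knee flexes (zero crossing
#   around 50 deg), which is what makes the quadriceps an ACL antagonist at
#   low flexion and protective at deep flexion.
# * Hamstrings insert on the proximal posterior tibia and pull
#   posterior-proximally toward the ischium (a posterior drawer + joint
#   compression; ACL protective).
# * The gastrocnemius spans the knee posteriorly; with the femur grounded its
#   net effect at low flexion is a small anterior shear plus compression
#   (ACL antagonist), represented by a fixed anterior lean.
# * The sagittal ankle (plantar-flexion) moment, dominated by the soleus, is
#   transmitted to the knee as a posterior force on the proximal tibia of
#   magnitude moment / shank length: the soleus rotates the proximal tibia
#   posteriorly.

#' Patellar tendon angle relative to the tibial long axis
#'
#' Empirical sagittal-plane relation: about +20 deg (anterior) at full
#' extension, decreasing roughly linearly with flexion and crossing zero near
#' 80 deg, where the quadriceps stop producing anterior tibial shear.
#' @param flexion_deg knee flexion, degrees
#' @return tendon angle, degrees (positive = anterior lean)
#' @export
patellar_tendon_angle <- function(flexion_deg) {
  20 - 0.25 * flexion_deg
}

# unit vector in the tibia frame leaning `angle_deg` anteriorly from +Y
lean_dir <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(sin(a), cos(a), 0)
}

#' Equivalent tibial forces for a set of muscle force magnitudes
#'
#' @param pose current pose
#' @param model \code{knee_model}
#' @param quad_N,hams_N,gastroc_N muscle force magnitudes, N (>= 0)
#' @param ankle_moment_Nm sagittal ankle moment, N.m (0 to omit)
#' @param shank_length_mm lever arm mapping the ankle moment to a posterior
#'   proximal-tibia force (default 400 mm)
#' @param soleus_share fraction of the plantar-flexion moment produced by the
#'   uniarticular soleus (default 0.55); only this share is transmitted as the
#'   posterior proximal-tibia force, since the biarticular gastrocnemius
#'   contribution is already applied as a muscle force
#' @return list of \code{list(point=, force=)} world-frame loads on the tibia
#' @export
muscle_loads <- function(pose, model, quad_N = 0, hams_N = 0, gastroc_N = 0,
                         ankle_moment_Nm = 0, shank_length_mm = 400,
                         soleus_share = 0.55) {
  Rt <- pose$tibia$R
  flex <- extract_joint_angles(pose)$flexion
  loads <- list()
  s <- model$scale %||% 1
  if (quad_N > 0) {
    d <- as.numeric(Rt %*% lean_dir(patellar_tendon_angle(flex)))
    loads[[length(loads) + 1]] <- list(
      point = world_point(pose, "tibia", s * c(22, -16, 0)), force = quad_N * d)
  }
  if (hams_N > 0) {
    # hamstrings run along the thigh toward the ischium: posterior-proximal
    # in the femur (ground) frame, independent of knee flexion
    d <- lean_dir(-17)
    loads[[length(loads) + 1]] <- list(
      point = world_point(pose, "tibia", s * c(-15, -10, 0)), force = hams_N * d)
  }
  if (gastroc_N > 0) {
    d <- as.numeric(Rt %*% lean_dir(15))
    loads[[length(loads) + 1]] <- list(
      point = world_point(pose, "tibia", s * c(-18, -5, 0)), force = gastroc_N * d)
  }
  if (ankle_moment_Nm != 0) {
    # posterior force on the proximal tibia along -X_tibia (soleus mechanism)
    f <- -(soleus_share * ankle_moment_Nm * 1000 / shank_length_mm) *
      as.numeric(Rt[, 1])
    loads[[length(loads) + 1]] <- list(
      point = world_point(pose, "tibia", s * c(-5, 0, 0)), force = f)
  }
  loads
}
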