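# Closed channel and task vocabularies. Column ordering everywhere in the
# package follows these enumerations, so feature-matrix columns are stable
# and PC loadings comparable across runs.

#' The thirteen movement-screen tasks
#'
#' Seven dynamic screening movements, six of them performed bilaterally, give
#' thirteen trials per athlete: drop jump (symmetric), bird-dog, hop-down,
#' lunge, step-down, L-hop and T-balance.
#'
#' @return Character vector of the 13 canonical task names.
#' @export
omat_tasks <- function() {
  c("drop_jump",
    "bird_dog_left", "bird_dog_right",
    "hop_down_left", "hop_down_right",
    "l_hop_left", "l_hop_right",
    "lunge_left", "lunge_right",
    "step_down_left", "step_down_right",
    "t_balance_left", "t_balance_right")
}

#' Canonical optical-marker channels
#'
#' The 26 whole-body positions used by the optical variant: 14 bilateral
#' joint centres (wrist, elbow, shoulder, foot, ankle, knee, hip), 3 segment
#' centres of gravity (trunk, head, pelvis) and 9 markers (left/right heel,
#' T2, T8, sternum, back/front/left/right head).
#'
#' @return Character vector of 26 channel names in canonical order.
#' @export
opt_channels <- function() {
  c("wrist_L", "wrist_R", "elbow_L", "elbow_R", "shoulder_L", "shoulder_R",
    "foot_L", "foot_R", "ankle_L", "ankle_R", "knee_L", "knee_R",
    "hip_L", "hip_R",
    "trunk_cog", "head_cog", "pelvis_cog",
    "heel_L", "heel_R", "T2", "T8", "sternum",
    "head_back", "head_front", "head_left", "head_right")
}

#' Canonical body segments for the simulated-IMU variant
#'
#' @return Character vector of the 13 segment names in canonical order.
#' @export
simu_segments <- function() {
  c("head", "trunk", "pelvis",
    "upper_arm_L", "upper_arm_R", "forearm_L", "forearm_R",
    "thigh_L", "thigh_R", "shank_L", "shank_R", "foot_L", "foot_R")
}

.axes <- c("x", "y", "z")

# frames x 78 position block column names, axis fastest within channel
.pos_colnames <- function() {
  as.vector(t(outer(opt_channels(), .axes, paste, sep = ".")))
}

.vel_colnames <- function(kind = c("linear_velocity", "angular_velocity")) {
  kind <- match.arg(kind)
  as.vector(t(outer(simu_segments(), paste(kind, .axes, sep = "."),
                    paste, sep = ".")))
}

# Approximate standing-posture offsets for each optical channel, as
# fractions of athlete height in a right-handed frame (x lateral-right,
# y anterior, z vertical-up). Used by the synthetic generator so the trunk
# landmarks span a well-conditioned anatomical frame.
.posture_offsets <- function() {
  m <- rbind(
    wrist_L    = c(-0.22,  0.05, 0.49),
    wrist_R    = c( 0.22,  0.05, 0.49),
    elbow_L    = c(-0.16,  0.01, 0.69),
    elbow_R    = c( 0.16,  0.01, 0.69),
    shoulder_L = c(-0.11,  0.00, 0.82),
    shoulder_R = c( 0.11,  0.00, 0.82),
    foot_L     = c(-0.06,  0.09, 0.02),
    foot_R     = c( 0.06,  0.09, 0.02),
    ankle_L    = c(-0.06,  0.00, 0.04),
    ankle_R    = c( 0.06,  0.00, 0.04),
    knee_L     = c(-0.07,  0.00, 0.28),
    knee_R     = c( 0.07,  0.00, 0.28),
    hip_L      = c(-0.09,  0.00, 0.53),
    hip_R      = c( 0.09,  0.00, 0.53),
    trunk_cog  = c( 0.00,  0.00, 0.67),
    head_cog   = c( 0.00,  0.00, 0.93),
    pelvis_cog = c( 0.00,  0.00, 0.55),
    heel_L     = c(-0.06, -0.05, 0.02),
    heel_R     = c( 0.06, -0.05, 0.02),
    T2         = c( 0.00, -0.06, 0.80),
    T8         = c( 0.00, -0.07, 0.68),
    sternum    = c( 0.00,  0.06, 0.74),
    head_back  = c( 0.00, -0.07, 0.93),
    head_front = c( 0.00,  0.07, 0.93),
    head_left  = c(-0.06,  0.00, 0.93),
    head_right = c( 0.06,  0.00, 0.93))
  colnames(m) <- .axes
  m[opt_channels(), , drop = FALSE]
}
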