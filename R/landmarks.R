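#' Landmark topology of the markerless pose model
#'
#' The tracking front end estimates 33 skeletal landmarks per frame in the
#' MediaPipe Pose index order. All trajectory arrays in this package use this
#' order along their landmark dimension.
#'
#' @return Character vector of the 33 landmark identifiers, in index order
#'   (index 1 = nose ... index 33 = right_foot_index).
#' @export
pose_landmark_names <- function() {
  c(
    "nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index"
  )
}

#' Number of landmarks in the pose topology
#' @return Integer, always 33.
#' @export
n_pose_landmarks <- function() 33L

#' Index of a landmark (or virtual point) in the pose topology
#'
#' Besides the 33 concrete landmarks, the joint table may reference the
#' virtual points `mid_shoulder` and `mid_hip` (segment midpoints) and the
#' world-frame directions `world_up` / `world_down` (the world frame is
#' right-handed, y-up, coordinates in meters).
#'
#' @param name landmark identifier
#' @return Integer index in 1..33 for concrete landmarks; virtual names
#'   return NA (they are resolved geometrically, not by index).
#' @export
landmark_index <- function(name) {
  idx <- match(name, pose_landmark_names())
  idx
}

# Resolve a (possibly virtual) point name to an L x 3 coordinate matrix.
resolve_point <- function(positions, name) {
  nm <- pose_landmark_names()
  if (name %in% nm) {
    return(positions[, match(name, nm), , drop = TRUE])
  }
  switch(name,
    mid_shoulder = (positions[, match("left_shoulder", nm), ] +
                    positions[, match("right_shoulder", nm), ]) / 2,
    mid_hip = (positions[, match("left_hip", nm), ] +
               positions[, match("right_hip", nm), ]) / 2,
    stop("unknown landmark or virtual point: ", name)
  )
}

# Resolve a segment spec (from, to) to an L x 3 matrix of direction vectors.
# Special segments "world_up"/"world_down" yield constant unit vectors.
resolve_segment <- function(positions, from, to) {
  L <- dim(positions)[1]
  if (identical(from, "world")) {
    dir <- switch(to,
      up = c(0, 1, 0),
      down = c(0, -1, 0),
      stop("unknown world direction: ", to)
    )
    return(matrix(dir, nrow = L, ncol = 3, byrow = TRUE))
  }
  p0 <- resolve_point(positions, from)
  p1 <- resolve_point(positions, to)
  if (is.null(dim(p0))) p0 <- matrix(p0, nrow = 1)
  if (is.null(dim(p1))) p1 <- matrix(p1, nrow = 1)
  p1 - p0
}
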