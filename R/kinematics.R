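## 4-DOF shoulder-elbow kinematic model.
##
## Coordinate frame: x lateral (to the patient's left), y anterior, z
## superior.  Zero posture: arm hanging along -z with the elbow extended
## (q1 = q2 = q3 = 0, q4 = pi), palm toward +y.
##
## Rotation composition R(q1,q2,q3) = Ry(q1) Rx(q2) Rz(q3).  The upper-arm
## rest axis is -z, so Rz(q3) leaves the elbow position invariant and q3
## acts only on the forearm plane (external/internal rotation).  Forearm
## direction in the upper-arm frame: (0, sin q4, cos q4), which equals
## (0, sin(pi - q4), -cos(pi - q4)): q4 = pi is full extension, along the
## upper arm.

.rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
.rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
.rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

.asAngleMatrix <- function(q) {
  if (is(q, "JointAngleSeries")) q@angles
  else if (is.null(dim(q))) matrix(q, nrow = 1)
  else as.matrix(q)
}

#' Forward kinematics
#'
#' Maps joint angles to elbow and wrist positions.  Vectorized over time:
#' `elbow = shoulder + lUpper * u(q1, q2)` and
#' `wrist = elbow + lFore * R(q1, q2, q3) %*% (0, sin q4, cos q4)`.
#' Segment lengths are preserved exactly by construction.
#'
#' @param q a [JointAngleSeries-class], a time x 4 matrix, or a length-4
#'   vector of angles (radians).
#' @param geom an [ArmGeometry-class].
#' @param shoulder shoulder position: length-3 vector or time x 3 matrix
#'   (default origin).
#' @return list with `elbow` and `wrist`, each time x 3 (meters).
#' @examples
#' fk <- forwardKinematics(c(0, 0, 0, pi), armGeometry(0.30, 0.25))
#' fk$wrist  # (0, 0, -0.55): straight-down arm
#' @export
forwardKinematics <- function(q, geom, shoulder = c(0, 0, 0)) {
  qm <- .asAngleMatrix(q)
  n <- nrow(qm)
  if (is.null(dim(shoulder))) shoulder <- matrix(shoulder, n, 3, byrow = TRUE)
  s1 <- sin(qm[, 1]); c1 <- cos(qm[, 1])
  s2 <- sin(qm[, 2]); c2 <- cos(qm[, 2])
  s3 <- sin(qm[, 3]); c3 <- cos(qm[, 3])
  s4 <- sin(qm[, 4]); c4 <- cos(qm[, 4])
  ## upper-arm direction u = Ry(q1) Rx(q2) (0,0,-1)
  ux <- -s1 * c2; uy <- s2; uz <- -c1 * c2
  elbow <- shoulder + geom@lUpper * cbind(ux, uy, uz)
  ## forearm direction f = Ry(q1) Rx(q2) Rz(q3) (0, s4, c4)
  ## Rz(q3) (0, s4, c4) = (-s3 s4, c3 s4, c4)
  ax <- -s3 * s4; ay <- c3 * s4; az <- c4
  ## Rx(q2): (ax, c2*ay - s2*az, s2*ay + c2*az)
  bx <- ax; by <- c2 * ay - s2 * az; bz <- s2 * ay + c2 * az
  ## Ry(q1): (c1*bx + s1*bz, by, -s1*bx + c1*bz)
  fx <- c1 * bx + s1 * bz; fy <- by; fz <- -s1 * bx + c1 * bz
  wrist <- elbow + geom@lFore * cbind(fx, fy, fz)
  colnames(elbow) <- colnames(wrist) <- c("x", "y", "z")
  list(elbow = elbow, wrist = wrist)
}

#' Inverse kinematics
#'
#' Recovers joint angles from shoulder/elbow/wrist marker positions.  With
#' `u = (elbow - shoulder)/lUpper`: `q2 = asin(u_y)`,
#' `q1 = atan2(-u_x, -u_z)`; `q4` from the elbow-vertex angle between the
#' two segments (`q4 = pi` at full extension); `q3` from the forearm
#' direction expressed in the shoulder-rotated frame.  At the extension
#' singularity (`q4` within `singularTol` of `pi`) q3 is indeterminate and
#' is carried forward from the last well-defined sample (0 at series
#' start), with a message.
#'
#' @param shoulder,elbow,wrist time x 3 matrices (or length-3 vectors).
#' @param geom an [ArmGeometry-class].
#' @param lengthTol relative tolerance on segment lengths (default 0.05).
#' @param singularTol radians from full extension below which q3 is treated
#'   as indeterminate (default 1e-6).
#' @param fs sampling rate stored in the result (Hz).
#' @return A [JointAngleSeries-class].
#' @export
inverseKinematics <- function(shoulder, elbow, wrist, geom,
                              lengthTol = 0.05, singularTol = 1e-6,
                              fs = 100) {
  toM <- function(p) if (is.null(dim(p))) matrix(p, nrow = 1) else as.matrix(p)
  S <- toM(shoulder); E <- toM(elbow); W <- toM(wrist)
  n <- nrow(S)
  U <- E - S
  V <- W - E
  lu <- sqrt(rowSums(U^2))
  lf <- sqrt(rowSums(V^2))
  badU <- abs(lu - geom@lUpper) > lengthTol * geom@lUpper
  badF <- abs(lf - geom@lFore) > lengthTol * geom@lFore
  if (any(badU | badF))
    stop("segment-length violation beyond ", 100 * lengthTol, "% at sample(s) ",
         paste(head(which(badU | badF), 10), collapse = ", "))
  u <- U / lu
  q2 <- asin(pmax(-1, pmin(1, u[, 2])))
  q1 <- atan2(-u[, 1], -u[, 3])
  ## straight-down gimbal guard: q1 undefined when |u_y| = 1
  q1[abs(abs(u[, 2]) - 1) < 1e-12] <- 0
  ## elbow-vertex angle between (shoulder - elbow) and (wrist - elbow):
  ## pi at full extension
  q4 <- acos(pmax(-1, pmin(1, rowSums((S - E) * (W - E)) / (lu * lf))))
  ## q3: express forearm direction in the frame after undoing Ry(q1) Rx(q2):
  ## v' = Rx(-q2) Ry(-q1) v = Rz(q3) (0, sin q4, cos q4)
  ##    = (-sin q3 sin q4, cos q3 sin q4, cos q4)
  v <- V / lf
  c1 <- cos(q1); s1 <- sin(q1); c2 <- cos(q2); s2 <- sin(q2)
  ## Ry(-q1) v
  ax <- c1 * v[, 1] - s1 * v[, 3]
  ay <- v[, 2]
  az <- s1 * v[, 1] + c1 * v[, 3]
  ## Rx(-q2) .
  bx <- ax
  by <- c2 * ay + s2 * az
  bz <- -s2 * ay + c2 * az
  q3 <- atan2(-bx, by)
  singular <- sin(q4) < sin(singularTol)
  if (any(singular)) {
    message(sum(singular), " sample(s) at the elbow-extension singularity; ",
            "q3 carried forward")
    lastGood <- 0
    for (i in seq_len(n)) {
      if (singular[i]) q3[i] <- lastGood else lastGood <- q3[i]
    }
  }
  jointAngleSeries(cbind(q1, q2, q3, q4), fs = fs)
}

#' Tangential velocity of a 3D marker
#'
#' Central-difference derivative per axis (one-sided at the endpoints),
#' Euclidean norm, then a causal 2nd-order Butterworth low-pass at
#' `smoothCutoff` — raw differentiation of 100 Hz markers amplifies noise,
#' and reach dynamics live well below 5 Hz.
#'
#' @param position time x 3 matrix (meters).
#' @param fs sampling rate (Hz).
#' @param smoothCutoff low-pass cutoff in Hz (default 5); `NULL` or `Inf`
#'   disables smoothing.
#' @return numeric speed series (m/s).
#' @export
tangentialVelocity <- function(position, fs, smoothCutoff = 5) {
  p <- as.matrix(position)
  n <- nrow(p)
  if (n < 3) stop("need at least 3 samples")
  d <- matrix(0, n, ncol(p))
  d[2:(n - 1), ] <- (p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) * (fs / 2)
  d[1, ] <- (p[2, ] - p[1, ]) * fs
  d[n, ] <- (p[n, ] - p[n - 1, ]) * fs
  speed <- sqrt(rowSums(d^2))
  if (!is.null(smoothCutoff) && is.finite(smoothCutoff)) {
    filt <- signal::butter(2, smoothCutoff / (fs / 2), type = "low")
    speed <- as.numeric(signal::filter(filt, speed))
    speed[speed < 0] <- 0
  }
  speed
}

#' Reconstruct 3D marker trajectories from decoded joint angles
#'
#' The trajectory-rendering pathway: decoded q1..q4 plus the patient's arm
#' segment lengths give elbow and wrist paths through forward kinematics.
#' Reconstructions always satisfy the segment lengths exactly, whatever the
#' decoder error.
#'
#' @param q a [JointAngleSeries-class] (possibly decoded, with NA samples).
#' @param geom an [ArmGeometry-class].
#' @param shoulder shoulder position (default origin).
#' @return list with `elbow`, `wrist` (time x 3; NA where angles are NA).
#' @export
reconstructTrajectory <- function(q, geom, shoulder = c(0, 0, 0)) {
  qm <- .asAngleMatrix(q)
  ok <- stats::complete.cases(qm)
  out <- list(elbow = matrix(NA_real_, nrow(qm), 3),
              wrist = matrix(NA_real_, nrow(qm), 3))
  colnames(out$elbow) <- colnames(out$wrist) <- c("x", "y", "z")
  if (any(ok)) {
    shoulderM <- if (is.null(dim(shoulder)))
      matrix(shoulder, sum(ok), 3, byrow = TRUE)
    else as.matrix(shoulder)[ok, , drop = FALSE]
    fk <- forwardKinematics(qm[ok, , drop = FALSE], geom, shoulderM)
    out$elbow[ok, ] <- fk$elbow
    out$wrist[ok, ] <- fk$wrist
  }
  out
}

#' Estimate arm geometry from marker data
#'
#' Median segment lengths over the session.
#'
#' @param markers time x 9 matrix (shoulder xyz, elbow xyz, wrist xyz).
#' @return An [ArmGeometry-class].
#' @export
estimateArmGeometry <- function(markers) {
  m <- as.matrix(markers)
  lu <- sqrt(rowSums((m[, 4:6, drop = FALSE] - m[, 1:3, drop = FALSE])^2))
  lf <- sqrt(rowSums((m[, 7:9, drop = FALSE] - m[, 4:6, drop = FALSE])^2))
  armGeometry(median(lu), median(lf))
}
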