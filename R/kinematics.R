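#' Pairing types of left and right angle functions
#'
#' A periodic ear motion is built from three angle-function pairs, one per
#' rotation axis (roll, pitch, yaw).  Each pair assigns a left-ear and a
#' right-ear angle function drawn from the 0th and 1st Fourier modes.  Six
#' pairing types are available; the names with a `"~"` suffix are the
#' anti-phase pairings in which the right ear takes the sign-flipped
#' function, as observed in the pinnae of horseshoe bats:
#'
#' | pairing    | left ear                  | right ear                  |
#' |------------|---------------------------|----------------------------|
#' | `"0"`      | 0                         | 0                          |
#' | `"CONST~"` | C                         | -C                         |
#' | `"SIN"`    | C sin(2 pi f t)           | C sin(2 pi f t)            |
#' | `"SIN~"`   | C sin(2 pi f t)           | -C sin(2 pi f t)           |
#' | `"COS"`    | C cos(2 pi f t)           | C cos(2 pi f t)            |
#' | `"COS~"`   | C cos(2 pi f t)           | -C cos(2 pi f t)           |
#'
#' @format A character vector of the six pairing names.
#' @export
pairing_types <- c("0", "CONST~", "SIN", "SIN~", "COS", "COS~")

#' Create an angle-function pair for one rotation axis
#'
#' @param pairing One of [pairing_types]: `"0"`, `"CONST~"`, `"SIN"`,
#'   `"SIN~"`, `"COS"`, `"COS~"`.
#' @param amplitude Motion amplitude C in degrees (default 15, the pitch
#'   sweep amplitude seen in horseshoe bats).
#' @param frequency Motion frequency f_e in Hz.  The default 1/0.066 Hz
#'   makes the period T = 66 ms, so the two 33 ms echo listening windows
#'   tile one motion period exactly.
#' @param phase_offset Phase offset in degrees added inside the argument of
#'   the *right* ear's sinusoid only.  Used by the phase-difference sweep;
#'   ignored for `"0"` and `"CONST~"` pairings.
#' @return An object of class `angle_pair`.
#' @examples
#' p <- angle_pair("COS~", amplitude = 15)
#' evaluate_pair(p, 0)  # left +15, right -15
#' @export
angle_pair <- function(pairing, amplitude = 15, frequency = 1 / 0.066,
                       phase_offset = 0) {
  pairing <- match.arg(pairing, pairing_types)
  stopifnot(is.finite(amplitude), is.finite(frequency), frequency > 0,
            is.finite(phase_offset))
  structure(
    list(pairing = pairing, amplitude = amplitude, frequency = frequency,
         phase_offset = phase_offset),
    class = "angle_pair"
  )
}

#' @export
format.angle_pair <- function(x, ...) {
  sprintf("<angle_pair %s, C = %g deg, f_e = %g Hz%s>", x$pairing,
          x$amplitude, x$frequency,
          if (x$phase_offset != 0)
            sprintf(", dPhi = %g deg", x$phase_offset) else "")
}

#' @export
print.angle_pair <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate an angle-function pair at given times
#'
#' Returns the left-ear and right-ear angles (degrees) at time `t`.
#' The anti-phase pairings (`"CONST~"`, `"SIN~"`, `"COS~"`) give
#' `right(t) = -left(t)` when the phase offset is zero.
#'
#' @param pair An [angle_pair()].
#' @param t Time(s) in seconds (vectorised).
#' @return A tibble with columns `t`, `left`, `right` (angles in degrees).
#' @export
evaluate_pair <- function(pair, t) {
  stopifnot(inherits(pair, "angle_pair"), all(is.finite(t)))
  C <- pair$amplitude
  u <- 2 * pi * pair$frequency * t
  du <- pair$phase_offset * pi / 180
  lr <- switch(pair$pairing,
    "0"      = list(l = rep(0, length(t)),  r = rep(0, length(t))),
    "CONST~" = list(l = rep(C, length(t)),  r = rep(-C, length(t))),
    "SIN"    = list(l = C * sin(u),         r = C * sin(u + du)),
    "SIN~"   = list(l = C * sin(u),         r = -C * sin(u + du)),
    "COS"    = list(l = C * cos(u),         r = C * cos(u + du)),
    "COS~"   = list(l = C * cos(u),         r = -C * cos(u + du))
  )
  tibble::tibble(t = t, left = lr$l, right = lr$r)
}

#' Create a periodic ear motion from three angle-function pairs
#'
#' An ear motion `M` is a pair of periodic orientation histories
#' `L_left(t)`, `L_right(t)` built from roll, pitch and yaw angle functions
#' (see [orientation_at()]).  All three pairs must share the same motion
#' frequency.
#'
#' @param roll,pitch,yaw Either [angle_pair()] objects or pairing-name
#'   strings (then built with the shared `amplitude`/`frequency`).
#' @param amplitude,frequency Defaults used when a pairing is given by name.
#' @param phase_offset Right-ear phase offset in degrees applied to pairs
#'   given by name.
#' @return An object of class `ear_motion`.
#' @examples
#' m <- ear_motion("SIN", "COS~", "CONST~")
#' motion_label(m)
#' @export
ear_motion <- function(roll, pitch, yaw, amplitude = 15,
                       frequency = 1 / 0.066, phase_offset = 0) {
  as_pair <- function(x) {
    if (inherits(x, "angle_pair")) x
    else angle_pair(x, amplitude = amplitude, frequency = frequency,
                    phase_offset = phase_offset)
  }
  m <- list(roll = as_pair(roll), pitch = as_pair(pitch), yaw = as_pair(yaw))
  f <- vapply(m, function(p) p$frequency, numeric(1))
  if (diff(range(f)) > 1e-12)
    stop("all three angle-function pairs must share the same frequency",
         call. = FALSE)
  structure(m, class = "ear_motion")
}

#' Parse a 3-token motion label such as "SIN,COS~,CONST~"
#'
#' The label lists the roll, pitch and yaw pairings in that order,
#' separated by commas; a `"~"` suffix marks anti-phase pairings.
#'
#' @param label Character scalar, e.g. `"SIN,COS~,CONST~"`.
#' @inheritParams ear_motion
#' @return An [ear_motion()].
#' @export
parse_motion <- function(label, amplitude = 15, frequency = 1 / 0.066,
                         phase_offset = 0) {
  tok <- trimws(strsplit(label, ",", fixed = TRUE)[[1]])
  if (length(tok) != 3)
    stop("motion label must have 3 comma-separated tokens, got: ", label,
         call. = FALSE)
  ear_motion(tok[1], tok[2], tok[3], amplitude = amplitude,
             frequency = frequency, phase_offset = phase_offset)
}

#' @rdname parse_motion
#' @param motion An [ear_motion()].
#' @export
motion_label <- function(motion) {
  stopifnot(inherits(motion, "ear_motion"))
  paste(motion$roll$pairing, motion$pitch$pairing, motion$yaw$pairing,
        sep = ",")
}

#' @export
format.ear_motion <- function(x, ...) {
  sprintf("<ear_motion [%s], C = (%g, %g, %g) deg, T = %g ms>",
          motion_label(x), x$roll$amplitude, x$pitch$amplitude,
          x$yaw$amplitude, 1000 / x$roll$frequency)
}

#' @export
print.ear_motion <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Motion period in seconds
#' @param motion An [ear_motion()].
#' @export
motion_period <- function(motion) {
  stopifnot(inherits(motion, "ear_motion"))
  1 / motion$roll$frequency
}

#' Elementary rotation matrix about a body axis
#'
#' Right-handed active rotation about the x, y or z axis.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle Rotation angle in degrees.
#' @return A 3x3 rotation matrix (orthogonal, determinant +1).
#' @export
axis_rotation <- function(axis, angle) {
  axis <- match.arg(axis, c("x", "y", "z"))
  if (!is.finite(angle)) stop("angle must be finite", call. = FALSE)
  a <- angle * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0,  0, c_, s_,  0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_,  0, 1, 0,  s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0,  -s_, c_, 0,  0, 0, 1), 3, 3)
  )
}

#' Ear orientation matrix at a given time
#'
#' The orientation of a directional ear is the roll-pitch-yaw composition
#' `L(t) = R_z(theta(t)) R_y(-phi(t)) R_x(-psi(t))`, where `psi`, `phi`,
#' `theta` are the roll, pitch and yaw angle functions of the chosen ear.
#' The columns of `L(t)` are the ear's roll, pitch and yaw axis directions
#' in world coordinates.
#'
#' @param motion An [ear_motion()].
#' @param side `"left"` or `"right"`.
#' @param t Time in seconds (scalar).
#' @return A 3x3 rotation matrix in SO(3).
#' @export
orientation_at <- function(motion, side = c("left", "right"), t) {
  side <- match.arg(side)
  stopifnot(inherits(motion, "ear_motion"), length(t) == 1, is.finite(t))
  ang <- motion_angles(motion, side, t)
  axis_rotation("z", ang[3]) %*%
    axis_rotation("y", -ang[2]) %*%
    axis_rotation("x", -ang[1])
}

# (roll, pitch, yaw) angles in degrees for one ear at times t; returns a
# length-3 vector for scalar t, else a 3-column matrix.
motion_angles <- function(motion, side, t) {
  v <- vapply(motion[c("roll", "pitch", "yaw")], function(p) {
    e <- evaluate_pair(p, t)
    if (side == "left") e$left else e$right
  }, numeric(length(t)))
  if (length(t) == 1) as.numeric(v) else v
}

#' Target direction from azimuth and elevation angles
#'
#' A target direction is parameterised by the azimuth `theta` and elevation
#' `phi` (degrees); its unit direction vector is
#' `n = (cos theta cos phi, sin theta cos phi, sin phi)`.
#'
#' @param theta Azimuth in degrees, in (-90, 90).
#' @param phi Elevation in degrees, in (-90, 90).
#' @return A `direction` object with fields `theta`, `phi` and the unit
#'   vector `n`.
#' @examples
#' direction_from_angles(0, 0)$n   # (1, 0, 0), straight ahead
#' @export
direction_from_angles <- function(theta, phi) {
  stopifnot(length(theta) == 1, length(phi) == 1)
  if (!is.finite(theta) || !is.finite(phi))
    stop("angles must be finite", call. = FALSE)
  if (abs(theta) > 90 || abs(phi) >= 90)
    stop("require |theta| <= 90 and |phi| < 90 degrees", call. = FALSE)
  structure(
    list(theta = theta, phi = phi, n = direction_vectors(theta, phi)[1, ]),
    class = "direction"
  )
}

#' @export
format.direction <- function(x, ...) {
  sprintf("<direction theta = %g, phi = %g deg>", x$theta, x$phi)
}

#' @export
print.direction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Vectorised unit direction vectors; returns an n x 3 matrix.
direction_vectors <- function(theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  cbind(cos(th) * cos(ph), sin(th) * cos(ph), sin(ph))
}

#' Uniform grid of target directions
#'
#' The test grid covers `|theta| <= theta_max`, `|phi| <= phi_max` with
#' `n_theta` x `n_phi` uniformly spaced points.  The default 23 x 23 grid on
#' +/-60 degrees has 5.45 degree increments.
#'
#' @param theta_max,phi_max Half-width of the direction domain in degrees.
#' @param n_theta,n_phi Number of grid points per axis.
#' @return A tibble with columns `theta`, `phi`, `nx`, `ny`, `nz` (one row
#'   per grid direction, phi varying fastest).
#' @export
direction_grid <- function(theta_max = 60, phi_max = 60,
                           n_theta = 23, n_phi = 23) {
  stopifnot(theta_max > 0, phi_max > 0, phi_max < 90,
            n_theta >= 2, n_phi >= 2)
  g <- tidyr::expand_grid(
    theta = seq(-theta_max, theta_max, length.out = n_theta),
    phi = seq(-phi_max, phi_max, length.out = n_phi)
  )
  nv <- direction_vectors(g$theta, g$phi)
  g$nx <- nv[, 1]; g$ny <- nv[, 2]; g$nz <- nv[, 3]
  g
}
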