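#' Orbit of an ear motion in roll-pitch-yaw space
#'
#' Samples the closed curve `(psi(t), phi(t), theta(t))` traced by one
#' ear's roll, pitch and yaw angles over one motion period.
#'
#' @param motion An [ear_motion()].
#' @param side `"left"` or `"right"`.
#' @param n_samples Uniform samples over one period (>= 16).
#' @return A tibble with columns `psi`, `phi`, `theta` (degrees).
#' @export
orbit_points <- function(motion, side = c("left", "right"), n_samples = 64) {
  side <- match.arg(side)
  stopifnot(n_samples >= 16)
  T_s <- motion_period(motion)
  tt <- seq(0, T_s, length.out = n_samples + 1)[-(n_samples + 1)]
  a <- motion_angles(motion, side, tt)
  tibble::tibble(psi = a[, 1], phi = a[, 2], theta = a[, 3])
}

#' Affine dimension of a point set
#'
#' Rank of the centered point cloud, from singular values thresholded
#' relative to the largest one.  The convex hull of a set and its affine
#' span have the same dimension, so this also gives the hull dimension.
#'
#' @param points A matrix or data frame of point coordinates (rows =
#'   points).
#' @param tol Relative singular-value threshold.
#' @return An integer dimension (0 for a single point or zero spread).
#' @export
affine_dimension <- function(points, tol = 1e-8) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0) stop("empty point set", call. = FALSE)
  centred <- sweep(pts, 2, colMeans(pts))
  s <- svd(centred, nu = 0, nv = 0)$d
  if (length(s) == 0 || s[1] <= 0) return(0L)
  sum(s > tol * s[1])
}

# TRUE when the left and right angle functions of a pair coincide
# identically in t.  For the named pairings with zero phase offset this is
# exact from the name (0, SIN, COS are shared; CONST~, SIN~, COS~ are
# sign-flipped); with a phase offset it is decided numerically.
pair_coincident <- function(pair, n_samples = 64, tol = 1e-9) {
  if (pair$phase_offset == 0)
    return(pair$pairing %in% c("0", "SIN", "COS"))
  if (pair$pairing %in% c("0", "CONST~"))
    return(pair$pairing == "0")
  tt <- seq(0, 1 / pair$frequency, length.out = n_samples + 1)
  e <- evaluate_pair(pair, tt)
  max(abs(e$left - e$right)) <= tol * max(1, pair$amplitude)
}

#' Classify an ear motion by its orbit geometry
#'
#' Computes each ear's orbit dimension, the dimension of the convex hull
#' of the union of both orbits, the dimension-pair label, and the four
#' conditions for precise and robust direction detection:
#'
#' 1. the convex hull of the union of the two ear orbits is
#'    three-dimensional;
#' 2. neither orbit degenerates to one dimension (orbit dimension >= 2);
#' 3. the left and right yaw angle functions do not coincide;
#' 4. the left and right pitch angle functions do not coincide.
#'
#' @inheritParams orbit_points
#' @param tol Relative tolerance for [affine_dimension()].
#' @return A one-row tibble: `motion`, `hull_dim`, `orbit_dim_left`,
#'   `orbit_dim_right`, `dimension_pair`, `cond_hull_3d`,
#'   `cond_orbits_2d`, `cond_yaw_distinct`, `cond_pitch_distinct`,
#'   `four_conditions`, `mirror_symmetric`.
#' @examples
#' classify_motion(ear_motion("SIN", "COS~", "CONST~"))  # pair "3-2"
#' @export
classify_motion <- function(motion, n_samples = 64, tol = 1e-8) {
  ol <- as.matrix(orbit_points(motion, "left", n_samples))
  or_ <- as.matrix(orbit_points(motion, "right", n_samples))
  dl <- affine_dimension(ol, tol)
  dr <- affine_dimension(or_, tol)
  hull <- affine_dimension(rbind(ol, or_), tol)
  if (dl != dr)
    warning("left/right orbit dimensions differ (", dl, " vs ", dr, ")")
  c1 <- hull == 3L
  c2 <- dl >= 2L && dr >= 2L
  c3 <- !pair_coincident(motion$yaw, n_samples)
  c4 <- !pair_coincident(motion$pitch, n_samples)
  mirror <- is_mirror_symmetric(motion, n_samples = n_samples)
  tibble::tibble(
    motion = motion_label(motion),
    hull_dim = hull,
    orbit_dim_left = dl,
    orbit_dim_right = dr,
    dimension_pair = paste0(hull, "-", max(dl, dr)),
    cond_hull_3d = c1,
    cond_orbits_2d = c2,
    cond_yaw_distinct = c3,
    cond_pitch_distinct = c4,
    four_conditions = c1 && c2 && c3 && c4,
    mirror_symmetric = mirror
  )
}

#' Do the four ear-motion conditions hold?
#'
#' @inheritParams classify_motion
#' @return `TRUE` when all four conditions of [classify_motion()] hold.
#' @export
satisfies_four_conditions <- function(motion, n_samples = 64, tol = 1e-8) {
  classify_motion(motion, n_samples, tol)$four_conditions
}

#' Is an ear motion mirror-symmetric about the midsagittal plane?
#'
#' Checks the sagittal-mirror identities
#' `psi_l(t + T/2) = -psi_r(t)`, `phi_l(t + T/2) = phi_r(t)`,
#' `theta_l(t + T/2) = -theta_r(t)` at sampled times.  This is the
#' biologically plausible symmetry class: the left ear repeats the
#' reflected right-ear motion half a period later.
#'
#' @inheritParams orbit_points
#' @param tol Absolute tolerance in degrees.
#' @export
is_mirror_symmetric <- function(motion, n_samples = 64, tol = 1e-6) {
  T_s <- motion_period(motion)
  tt <- seq(0, T_s, length.out = n_samples + 1)[-(n_samples + 1)]
  l <- motion_angles(motion, "left", tt + T_s / 2)
  r <- motion_angles(motion, "right", tt)
  max(abs(l[, 1] + r[, 1])) <= tol &&
    max(abs(l[, 2] - r[, 2])) <= tol &&
    max(abs(l[, 3] + r[, 3])) <= tol
}

#' Phase-shifted circular ear motion
#'
#' The family of motions whose left ear traces
#' `(psi, phi, theta) = (C, C cos(2 pi f t), C sin(2 pi f t))` and whose
#' right ear traces `(-C, C cos(2 pi f t + dphi), C sin(2 pi f t + dphi))`.
#' Both orbits are circles of radius `C` in the planes `psi = +/- C`;
#' only the phase difference `dphi` between the simultaneous points
#' varies.  `dphi = 180` gives the motion `[CONST~, COS~, SIN~]`;
#' `dphi = 0` gives `[CONST~, COS, SIN]`.
#'
#' @param amplitude Amplitude C in degrees.
#' @param frequency Motion frequency in Hz.
#' @param delta_phi Right-ear phase offset in degrees.
#' @return An [ear_motion()].
#' @export
phase_shifted_motion <- function(amplitude = 15, frequency = 1 / 0.066,
                                 delta_phi = 180) {
  ear_motion("CONST~", "COS", "SIN", amplitude = amplitude,
             frequency = frequency, phase_offset = delta_phi)
}

#' Enumerate motion patterns
#'
#' All combinations of the six pairing types over the three axes (216
#' patterns), or the 36-pattern family with the pitch pairing fixed (the
#' bat-mimicking case fixes pitch to `"COS~"`).
#'
#' @param pitch Either `NULL` (all six pitch pairings; 216 patterns) or a
#'   single pairing name to fix (36 patterns).
#' @return A tibble with columns `roll`, `pitch`, `yaw`, `label`.
#' @export
motion_patterns <- function(pitch = NULL) {
  p <- if (is.null(pitch)) pairing_types else match.arg(pitch, pairing_types)
  g <- tidyr::expand_grid(roll = pairing_types, pitch = p,
                          yaw = pairing_types)
  g$label <- paste(g$roll, g$pitch, g$yaw, sep = ",")
  g
}

#' Classify every motion pattern in a family
#'
#' Runs [classify_motion()] over a set of motion patterns (by default all
#' 216 pairing combinations).
#'
#' @param patterns A tibble from [motion_patterns()], or `NULL` for all
#'   216.
#' @param amplitude,frequency Shared motion parameters.
#' @inheritParams classify_motion
#' @return A tibble with one row per pattern: `roll`, `pitch`, `yaw` and
#'   the [classify_motion()] columns.
#' @export
classify_all_motions <- function(patterns = NULL, amplitude = 15,
                                 frequency = 1 / 0.066, n_samples = 64,
                                 tol = 1e-8) {
  if (is.null(patterns)) patterns <- motion_patterns()
  purrr::pmap_dfr(
    patterns[, c("roll", "pitch", "yaw")],
    function(roll, pitch, yaw) {
      m <- ear_motion(roll, pitch, yaw, amplitude = amplitude,
                      frequency = frequency)
      dplyr::bind_cols(tibble::tibble(roll = roll, pitch = pitch, yaw = yaw),
                       classify_motion(m, n_samples, tol))
    }
  )
}
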