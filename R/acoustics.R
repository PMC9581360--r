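#' Four-microphone ear geometry
#'
#' Each directional ear is a rectangle of four omnidirectional microphones
#' whose coherently summed output gives an anisotropic hearing directivity.
#' With spacings below half the wavelength the summed envelope is strictly
#' positive for every incidence direction.
#'
#' @param delta_y Horizontal microphone spacing in mm (default `0.49 *
#'   lambda`, slightly below half the echo wavelength; gives a -6 dB
#'   half-amplitude angle of about 43 degrees off-axis).
#' @param delta_z Vertical microphone spacing in mm (same default).
#' @param lambda Echo wavelength in mm.  The default 5 mm corresponds to a
#'   70 kHz constant-frequency echo.
#' @param A Received amplitude at the origin (arbitrary units); cancels in
#'   the interaural level difference.
#' @param d Left-right ear spacing in mm.  Retained for completeness: under
#'   the far-field plane-wave assumption a rigid translation of both ears
#'   leaves the ILD unchanged, so `d` never enters the computation.
#' @return An `ear_geometry` object.
#' @export
ear_geometry <- function(delta_y = 0.49 * lambda, delta_z = 0.49 * lambda,
                         lambda = 5, A = 1, d = 25) {
  stopifnot(lambda > 0, A > 0, d >= 0)
  if (delta_y < 0 || delta_y >= lambda / 2 ||
      delta_z < 0 || delta_z >= lambda / 2)
    stop("require 0 <= delta_y, delta_z < lambda/2 for a positive envelope",
         call. = FALSE)
  structure(
    list(delta_y = delta_y, delta_z = delta_z, lambda = lambda, A = A, d = d),
    class = "ear_geometry"
  )
}

#' @export
format.ear_geometry <- function(x, ...) {
  sprintf("<ear_geometry delta_y = %g, delta_z = %g, lambda = %g mm>",
          x$delta_y, x$delta_z, x$lambda)
}

#' @export
print.ear_geometry <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Sampling specification for ILD signals
#'
#' @param dt Sample interval in ms (default 1).
#' @param T_ms Motion period in ms (default 66: two 33 ms echo listening
#'   windows tile one period).  Must be an integer multiple of `dt`.
#' @return A `sampling_spec` with fields `dt`, `T_ms`, `n_samples` and the
#'   sample instants `times_ms` (= 0, dt, ..., T - dt).
#' @export
sampling_spec <- function(dt = 1, T_ms = 66) {
  stopifnot(dt > 0, T_ms > 0)
  n <- T_ms / dt
  if (abs(n - round(n)) > 1e-9)
    stop("T_ms must be an integer multiple of dt", call. = FALSE)
  n <- as.integer(round(n))
  structure(
    list(dt = dt, T_ms = T_ms, n_samples = n, times_ms = (seq_len(n) - 1) * dt),
    class = "sampling_spec"
  )
}

check_so3 <- function(L, tol = 1e-8) {
  if (!is.matrix(L) || any(dim(L) != 3) ||
      max(abs(crossprod(L) - diag(3))) > tol || abs(det(L) - 1) > tol)
    stop("L must be a rotation matrix in SO(3)", call. = FALSE)
  invisible(L)
}

as_direction_vector <- function(n) {
  if (inherits(n, "direction")) return(n$n)
  stopifnot(is.numeric(n), length(n) == 3)
  n
}

#' Received envelope of a directional ear (closed form)
#'
#' The echo from direction `n` received by the four-microphone ear at
#' orientation `L` has envelope
#' `S_env = 4 A cos(pi delta_y ny_t / lambda) cos(pi delta_z nz_t / lambda)`
#' where `(nx_t, ny_t, nz_t) = t(L) %*% n` is the target direction expressed
#' in the rotating ear frame.
#'
#' @param geometry An [ear_geometry()].
#' @param L 3x3 ear orientation matrix (in SO(3)).
#' @param n Target direction: a [direction_from_angles()] object or a unit
#'   3-vector.
#' @return The envelope amplitude (same units as `geometry$A`).
#' @export
envelope_at <- function(geometry, L, n) {
  stopifnot(inherits(geometry, "ear_geometry"))
  check_so3(L)
  n <- as_direction_vector(n)
  nt <- drop(crossprod(L, n))
  4 * geometry$A *
    cos(pi * geometry$delta_y * nt[2] / geometry$lambda) *
    cos(pi * geometry$delta_z * nt[3] / geometry$lambda)
}

#' Received envelope by explicit phasor summation (oracle)
#'
#' Independent check of [envelope_at()]: places the four omnidirectional
#' microphones at ear-frame offsets `(0, +/- delta_y/2, +/- delta_z/2)`,
#' rotates them by `L`, assigns each the plane-wave phase
#' `2 pi (r_k . n) / lambda`, and returns `A` times the magnitude of the
#' coherent phasor sum.
#'
#' @inheritParams envelope_at
#' @return The envelope amplitude.
#' @export
brute_force_envelope <- function(geometry, L, n) {
  stopifnot(inherits(geometry, "ear_geometry"))
  check_so3(L)
  n <- as_direction_vector(n)
  offsets <- rbind(
    c(0,  geometry$delta_y / 2,  geometry$delta_z / 2),
    c(0,  geometry$delta_y / 2, -geometry$delta_z / 2),
    c(0, -geometry$delta_y / 2,  geometry$delta_z / 2),
    c(0, -geometry$delta_y / 2, -geometry$delta_z / 2)
  )
  r <- offsets %*% t(L)                    # receiver positions, world frame
  phase <- 2 * pi * drop(r %*% n) / geometry$lambda
  geometry$A * Mod(sum(exp(1i * phase)))
}

# Per-ear orientation basis over one sampled period: the pitch-axis and
# yaw-axis directions (columns 2 and 3 of L(t)) as n_t x 3 matrices.  Only
# these two columns enter the envelope.
ear_basis <- function(motion, side, sampling) {
  tt <- sampling$times_ms / 1000
  Y <- matrix(0, length(tt), 3)
  Z <- matrix(0, length(tt), 3)
  for (i in seq_along(tt)) {
    L <- orientation_at(motion, side, tt[i])
    Y[i, ] <- L[, 2]
    Z[i, ] <- L[, 3]
  }
  list(Y = Y, Z = Z)
}

# Precomputed forward-model state for a motion: everything needed to map
# direction vectors to ILD vectors over one period.
forward_model <- function(motion, geometry = ear_geometry(),
                          sampling = sampling_spec()) {
  stopifnot(inherits(motion, "ear_motion"),
            inherits(geometry, "ear_geometry"),
            inherits(sampling, "sampling_spec"))
  T_model <- 1000 * motion_period(motion)
  if (abs(T_model - sampling$T_ms) > 1e-9)
    stop("sampling period T_ms (", sampling$T_ms,
         ") must equal the motion period (", T_model, " ms)", call. = FALSE)
  bl <- ear_basis(motion, "left", sampling)
  br <- ear_basis(motion, "right", sampling)
  list(
    Yl = bl$Y, Zl = bl$Z, Yr = br$Y, Zr = br$Z,
    ky = pi * geometry$delta_y / geometry$lambda,
    kz = pi * geometry$delta_z / geometry$lambda,
    sampling = sampling, geometry = geometry, motion = motion
  )
}

# ILD matrix for a set of direction vectors: n_dir x n_t, in dB.
# `nv` is an n_dir x 3 matrix of unit vectors.
ild_matrix_fm <- function(fm, nv) {
  envl <- cos(fm$ky * fm$Yl %*% t(nv)) * cos(fm$kz * fm$Zl %*% t(nv))
  envr <- cos(fm$ky * fm$Yr %*% t(nv)) * cos(fm$kz * fm$Zr %*% t(nv))
  if (any(envl <= 0) || any(envr <= 0))
    stop("non-positive envelope: degenerate geometry (delta >= lambda/2?)",
         call. = FALSE)
  t(20 * log10(envl / envr))
}

#' Interaural level difference signal over one motion period
#'
#' Samples `P(t; n) = 20 log10(S_env_left / S_env_right)` at the sampling
#' instants.  `P` is independent of the received amplitude `A` and of the
#' target distance because both cancel in the ratio.
#'
#' @param motion An [ear_motion()].
#' @param n Target direction ([direction_from_angles()] or unit 3-vector).
#' @param geometry An [ear_geometry()].
#' @param sampling A [sampling_spec()]; its period must match the motion's.
#' @return A tibble of class `ild_signal` with columns `time_ms`, `ild_db`.
#' @examples
#' m <- ear_motion("SIN", "COS~", "CONST~")
#' s <- ild_signal(m, direction_from_angles(20, 10))
#' head(s)
#' @export
ild_signal <- function(motion, n, geometry = ear_geometry(),
                       sampling = sampling_spec()) {
  fm <- forward_model(motion, geometry, sampling)
  nv <- matrix(as_direction_vector(n), 1, 3)
  out <- tibble::tibble(
    time_ms = sampling$times_ms,
    ild_db = drop(ild_matrix_fm(fm, nv))
  )
  class(out) <- c("ild_signal", class(out))
  out
}

#' Quantize an ILD signal to a finite resolution
#'
#' Rounds each ILD value to the nearest integer multiple of `step`
#' (midpoints round away from zero towards the next multiple, i.e.
#' half-up).  Used to emulate a degraded ILD resolution of 1 dB or 3 dB.
#' `step = 0` returns the input unchanged.
#'
#' @param signal An `ild_signal` tibble (or a numeric vector of dB values).
#' @param step Quantization step in dB, `>= 0`.
#' @return Same type as `signal`.
#' @export
quantize_ild <- function(signal, step) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step < 0)
    stop("step must be a single finite number >= 0", call. = FALSE)
  if (step == 0) return(signal)
  q <- function(x) floor(x / step + 0.5) * step
  if (is.numeric(signal)) return(q(signal))
  stopifnot(is.data.frame(signal), "ild_db" %in% names(signal))
  signal$ild_db <- q(signal$ild_db)
  signal
}

#' @rdname plot_ild
#' @export
autoplot.ild_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$ild_db)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "ILD (dB)") +
    ggplot2::theme_minimal()
}

#' Plot an ILD signal
#'
#' @param object,x An `ild_signal` tibble from [ild_signal()].
#' @param ... Ignored.
#' @export
plot_ild <- function(x, ...) autoplot.ild_signal(x, ...)
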