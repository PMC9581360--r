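#' Training protocol for the learned inverse map
#'
#' The inverse map from ILD signals to direction is approximated by a
#' fully connected network with three ReLU hidden layers and a linear
#' 2-unit output (azimuth, elevation scaled to `[-1, 1]`), trained with a
#' mean squared error loss.  Training draws a fresh batch of uniformly
#' random directions at every step; during the final `n_eval_steps` steps
#' the whole test grid is evaluated after every step and the per-direction
#' guess is the median of those outputs.
#'
#' @param n_train_steps Total training steps (default 5000).
#' @param n_eval_steps Final steps during which the test grid is evaluated
#'   (default 250); must not exceed `n_train_steps`.
#' @param batch_size Fresh random directions per step.
#' @param learning_rate Initial Adam step size.
#' @param learning_rate_end Final Adam step size; the rate decays
#'   exponentially from `learning_rate` to this value over the run, which
#'   settles the worst-case grid error before the evaluation phase.
#' @param hidden_sizes Integer vector of the three hidden-layer widths.
#' @param seed RNG seed making a run bit-reproducible.
#' @param quantization_step ILD resolution in dB applied to both training
#'   and evaluation inputs (0 = full resolution).
#' @param input_scale ILD values (dB) are divided by this constant before
#'   entering the network; 10 keeps typical signals within about
#'   `[-3, 3]`.
#' @return A `training_protocol` object.
#' @export
training_protocol <- function(n_train_steps = 5000, n_eval_steps = 250,
                              batch_size = 256, learning_rate = 2e-3,
                              learning_rate_end = 5e-4,
                              hidden_sizes = c(64, 64, 64), seed = 1,
                              quantization_step = 0, input_scale = 10) {
  stopifnot(n_train_steps >= 1, n_eval_steps >= 1,
            n_eval_steps <= n_train_steps, batch_size >= 1,
            learning_rate > 0, learning_rate_end > 0,
            learning_rate_end <= learning_rate,
            length(hidden_sizes) == 3,
            all(hidden_sizes >= 1), quantization_step >= 0,
            input_scale > 0)
  structure(
    list(n_train_steps = as.integer(n_train_steps),
         n_eval_steps = as.integer(n_eval_steps),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         learning_rate_end = learning_rate_end,
         hidden_sizes = as.integer(hidden_sizes),
         seed = as.integer(seed),
         quantization_step = quantization_step,
         input_scale = input_scale),
    class = "training_protocol"
  )
}

#' Reduced training protocol for quick, ordering-preserving runs
#'
#' Same architecture with 1000 training steps and 50 evaluation steps.
#' Absolute detection errors are slightly larger than under the default
#' protocol but group orderings (good vs deficient motions) are preserved.
#'
#' @inheritParams training_protocol
#' @param ... Passed to [training_protocol()].
#' @export
reduced_protocol <- function(n_train_steps = 1000, n_eval_steps = 50, ...) {
  training_protocol(n_train_steps = n_train_steps,
                    n_eval_steps = n_eval_steps, ...)
}

#' Learn the inverse map from ILD signals to direction
#'
#' Trains the feed-forward regressor of [training_protocol()] on
#' `(discretized ILD vector -> (theta, phi))` examples drawn uniformly
#' from the direction domain under the given ear motion, then reports the
#' per-direction median guesses over the final evaluation steps and the
#' detection error `E`, the maximum over the test grid of
#' `|theta - theta_guess| + |phi - phi_guess|` (degrees).
#'
#' @param motion An [ear_motion()].
#' @param protocol A [training_protocol()].
#' @param geometry An [ear_geometry()].
#' @param sampling A [sampling_spec()].
#' @param grid Test grid from [direction_grid()] (default 23 x 23 on
#'   +/-60 degrees).
#' @return A `detection_fit` object: `report` (tibble with `theta`, `phi`,
#'   `theta_guess`, `phi_guess`, `abs_err_theta`, `abs_err_phi`), `E`
#'   (degrees), `motion`, `protocol`, `final_loss`.
#' @examples
#' \donttest{
#' fit <- train_inverse(ear_motion("SIN", "COS~", "SIN~"),
#'                      protocol = reduced_protocol(seed = 1))
#' glance(fit)
#' }
#' @export
train_inverse <- function(motion, protocol = training_protocol(),
                          geometry = ear_geometry(),
                          sampling = sampling_spec(),
                          grid = direction_grid()) {
  stopifnot(inherits(protocol, "training_protocol"))
  fm <- forward_model(motion, geometry, sampling)
  theta_max <- max(abs(grid$theta))
  phi_max <- max(abs(grid$phi))
  nv <- as.matrix(grid[, c("nx", "ny", "nz")])
  grid_ild <- ild_matrix_fm(fm, nv)
  set.seed(protocol$seed)
  res <- mlp_train_ild(
    fm$Yl, fm$Zl, fm$Yr, fm$Zr, fm$ky, fm$kz, grid_ild,
    theta_max, phi_max,
    protocol$n_train_steps, protocol$n_eval_steps, protocol$batch_size,
    protocol$learning_rate, protocol$learning_rate_end,
    protocol$hidden_sizes[1],
    protocol$hidden_sizes[2], protocol$hidden_sizes[3],
    protocol$quantization_step, protocol$input_scale
  )
  report <- tibble::tibble(
    theta = grid$theta, phi = grid$phi,
    theta_guess = res$guesses[, 1], phi_guess = res$guesses[, 2],
    abs_err_theta = abs(grid$theta - res$guesses[, 1]),
    abs_err_phi = abs(grid$phi - res$guesses[, 2])
  )
  structure(
    list(report = report, E = detection_error(report), motion = motion,
         protocol = protocol, final_loss = res$final_loss),
    class = "detection_fit"
  )
}

#' Detection error E from a per-direction report
#'
#' `E = max over the test grid of |theta - theta_guess| +
#' |phi - phi_guess|`, in degrees.
#'
#' @param report A data frame with columns `theta`, `phi`, `theta_guess`,
#'   `phi_guess` (one row per grid direction).
#' @return The detection error in degrees.
#' @export
detection_error <- function(report) {
  need <- c("theta", "phi", "theta_guess", "phi_guess")
  if (!is.data.frame(report) || !all(need %in% names(report)))
    stop("report must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  err <- abs(report$theta - report$theta_guess) +
    abs(report$phi - report$phi_guess)
  if (anyNA(err)) stop("missing guesses in report", call. = FALSE)
  max(err)
}

#' Median detection error over several seeds
#'
#' Detection error is stochastic under network training; sweeps therefore
#' train each motion under several seeds and report the per-seed errors.
#'
#' @inheritParams train_inverse
#' @param seeds Integer vector of seeds.
#' @return A tibble with one row per seed: `motion`, `seed`, `E`.
#' @export
detection_error_over_seeds <- function(motion, seeds = c(1, 2, 3),
                                       protocol = training_protocol(),
                                       geometry = ear_geometry(),
                                       sampling = sampling_spec(),
                                       grid = direction_grid()) {
  purrr::map_dfr(seeds, function(s) {
    p <- protocol
    p$seed <- as.integer(s)
    fit <- train_inverse(motion, p, geometry, sampling, grid)
    tibble::tibble(motion = motion_label(motion), seed = s, E = fit$E)
  })
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Learned inverse map for %s\n", format(x$motion)))
  cat(sprintf("  protocol: %d steps (%d eval), seed %d, quantization %g dB\n",
              x$protocol$n_train_steps, x$protocol$n_eval_steps,
              x$protocol$seed, x$protocol$quantization_step))
  cat(sprintf("  detection error E = %.2f deg over %d test directions\n",
              x$E, nrow(x$report)))
  invisible(x)
}

#' @export
tidy.detection_fit <- function(x, ...) {
  out <- x$report
  out$motion <- motion_label(x$motion)
  out
}

#' @export
glance.detection_fit <- function(x, ...) {
  tibble::tibble(
    motion = motion_label(x$motion),
    E = x$E,
    median_abs_err_theta = stats::median(x$report$abs_err_theta),
    median_abs_err_phi = stats::median(x$report$abs_err_phi),
    seed = x$protocol$seed,
    n_train_steps = x$protocol$n_train_steps,
    quantization_step = x$protocol$quantization_step,
    final_loss = x$final_loss
  )
}

#' @rdname plot_detection
#' @export
autoplot.detection_fit <- function(object, ...) {
  r <- object$report
  ggplot2::ggplot(r) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$theta, y = .data$phi,
                   xend = .data$theta_guess, yend = .data$phi_guess),
      linewidth = 0.3
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$theta, y = .data$phi),
                        shape = 4, colour = "blue", size = 1) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$theta_guess, y = .data$phi_guess),
      shape = 3, colour = "red", size = 1
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "azimuth (deg)", y = "elevation (deg)",
      title = sprintf("[%s]   E = %.1f deg", motion_label(object$motion),
                      object$E)
    ) +
    ggplot2::theme_minimal()
}

#' Error-line plot of a learned inverse map
#'
#' True test directions (blue crosses), guessed directions (red plusses)
#' and the error lines connecting them.
#'
#' @param object,x A `detection_fit` from [train_inverse()].
#' @param ... Ignored.
#' @export
plot_detection <- function(x, ...) autoplot.detection_fit(x, ...)
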