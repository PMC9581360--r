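#' Showcase experiment: four motions with and without ear movement
#'
#' Evaluates the degree of injection and (optionally) the trained
#' detection error for four representative motions: the static pattern
#' `[0, CONST~, CONST~]`, the dynamic-but-deficient pattern
#' `[0, COS~, CONST~]`, and the two high-performance patterns
#' `[SIN~, COS~, CONST~]` and `[SIN, COS~, SIN~]`.
#'
#' @param seeds Seeds for the training runs (>= 3 recommended; detection
#'   error is stochastic and the aggregate is the median over seeds).
#' @param protocol A [training_protocol()].
#' @param geometry,sampling,grid Forward-model settings shared by all
#'   motions.
#' @param train If `FALSE`, skip network training and report only `I` and
#'   the orbit classification.
#' @return A `sweep_result` tibble: one row per motion with pairing names,
#'   `I`, `dimension_pair`, condition flags, `E_median`/`E_min`/`E_max`
#'   over seeds.  The per-seed errors are in `attr(, "by_seed")`.
#' @export
run_showcase <- function(seeds = c(1, 2, 3), protocol = training_protocol(),
                         geometry = ear_geometry(),
                         sampling = sampling_spec(),
                         grid = direction_grid(), train = TRUE) {
  labels <- c("0,CONST~,CONST~", "0,COS~,CONST~",
              "SIN~,COS~,CONST~", "SIN,COS~,SIN~")
  run_motion_set(labels, seeds, protocol, geometry, sampling, grid, train)
}

#' Exhaustive sweep of the 36 pitch-anti-phase motion patterns
#'
#' All 6 x 6 roll/yaw pairing combinations with the pitch pairing fixed to
#' `"COS~"`, the anti-phase cosine observed in bats.  Computes the degree
#' of injection, orbit classification and (optionally) the trained
#' detection error per pattern.
#'
#' @inheritParams run_showcase
#' @return A `sweep_result` tibble, one row per motion (see
#'   [run_showcase()]).
#' @export
run_pitch_antiphase_sweep <- function(seeds = c(1, 2, 3),
                                      protocol = training_protocol(),
                                      geometry = ear_geometry(),
                                      sampling = sampling_spec(),
                                      grid = direction_grid(),
                                      train = TRUE) {
  labels <- motion_patterns(pitch = "COS~")$label
  run_motion_set(labels, seeds, protocol, geometry, sampling, grid, train)
}

#' General sweep of all 216 pairing combinations
#'
#' Computes the degree of injection and the four-condition classification
#' for every combination of the six pairing types over roll, pitch and
#' yaw.  Network training is run only for the motions passing all four
#' conditions (plus any extra labels in `also_train`), since the degree of
#' injection is the cheap screen for promising motions.
#'
#' @inheritParams run_showcase
#' @param train_passing Train the four-condition motions?
#' @param also_train Extra motion labels to train as controls.
#' @return A `sweep_result` tibble, one row per motion; `E_median` is `NA`
#'   for untrained motions.
#' @export
run_general_sweep <- function(seeds = c(1, 2, 3),
                              protocol = training_protocol(),
                              geometry = ear_geometry(),
                              sampling = sampling_spec(),
                              grid = direction_grid(),
                              train_passing = FALSE, also_train = character()) {
  labels <- motion_patterns()$label
  res <- run_motion_set(labels, seeds, protocol, geometry, sampling, grid,
                        train = FALSE)
  to_train <- union(res$motion[res$four_conditions], also_train)
  if (!train_passing) to_train <- also_train
  if (length(to_train)) {
    tr <- run_motion_set(to_train, seeds, protocol, geometry, sampling,
                         grid, train = TRUE)
    idx <- match(tr$motion, res$motion)
    res$E_median[idx] <- tr$E_median
    res$E_min[idx] <- tr$E_min
    res$E_max[idx] <- tr$E_max
    attr(res, "by_seed") <- attr(tr, "by_seed")
  }
  res
}

#' Robustness of detection against degraded ILD resolution
#'
#' Re-trains the inverse map with the ILD inputs quantized to the given
#' resolutions, for the motions whose baseline (full-resolution) median
#' detection error is below `e_max`.  Reports the error per quantization
#' step and the increase from the first to the last step.
#'
#' @param baseline A `sweep_result` from [run_pitch_antiphase_sweep()]
#'   with training, or `NULL` to compute it here.  Its errors are reused
#'   as the step-0 column, so it should come from the same `protocol`,
#'   `seeds` and grid passed here.
#' @param steps Quantization steps in dB (first entry should be 0, the
#'   full-resolution baseline).
#' @param e_max Baseline error cutoff in degrees for inclusion.
#' @inheritParams run_showcase
#' @return A tibble with one row per motion: `motion`, `I`, one
#'   `E_q<step>` column per step, and `E_increase` (last minus first
#'   step, degrees).
#' @export
run_robustness <- function(baseline = NULL, steps = c(0, 1, 3),
                           e_max = 20, seeds = c(1, 2, 3),
                           protocol = training_protocol(),
                           geometry = ear_geometry(),
                           sampling = sampling_spec(),
                           grid = direction_grid()) {
  stopifnot(length(steps) >= 2, all(steps >= 0))
  if (is.null(baseline))
    baseline <- run_pitch_antiphase_sweep(seeds, protocol, geometry,
                                          sampling, grid, train = TRUE)
  keep <- baseline[!is.na(baseline$E_median) & baseline$E_median < e_max, ]
  out <- keep[, c("motion", "I")]
  for (s in steps) {
    col <- paste0("E_q", s)
    if (s == steps[1] && s == 0) {
      out[[col]] <- keep$E_median
      next
    }
    p <- protocol
    p$quantization_step <- s
    out[[col]] <- vapply(keep$motion, function(lab) {
      stats::median(detection_error_over_seeds(
        parse_motion(lab), seeds, p, geometry, sampling, grid)$E)
    }, numeric(1))
  }
  first_col <- paste0("E_q", steps[1])
  last_col <- paste0("E_q", steps[length(steps)])
  out$E_increase <- out[[last_col]] - out[[first_col]]
  out
}

#' Phase-difference sweep of the circular ear motions
#'
#' Evaluates the [phase_shifted_motion()] family at the given pitch-yaw
#' phase differences: four-condition check, degree of injection, and the
#' trained detection error.
#'
#' @param delta_phis Phase differences in degrees.
#' @inheritParams run_showcase
#' @return A tibble with one row per phase difference: `delta_phi`,
#'   `four_conditions`, `I`, `E_median`.
#' @export
run_phase_sweep <- function(delta_phis = c(0, 45, 90, 135, 180),
                            seeds = c(1, 2, 3),
                            protocol = training_protocol(),
                            geometry = ear_geometry(),
                            sampling = sampling_spec(),
                            grid = direction_grid(), train = TRUE) {
  purrr::map_dfr(delta_phis, function(dp) {
    m <- phase_shifted_motion(delta_phi = dp,
                              frequency = 1000 / sampling$T_ms)
    cls <- classify_motion(m)
    I <- injectivity(m, grid, geometry, sampling)$I
    E_med <- NA_real_
    if (train)
      E_med <- stats::median(detection_error_over_seeds(
        m, seeds, protocol, geometry, sampling, grid)$E)
    tibble::tibble(delta_phi = dp, four_conditions = cls$four_conditions,
                   dimension_pair = cls$dimension_pair, I = I,
                   E_median = E_med)
  })
}

#' Static-control experiment: detection without ear motion
#'
#' Trains the inverse map for the motionless condition `[0, 0, CONST~]`
#' (ears statically splayed in yaw).  The constant ILD still encodes
#' azimuth, but elevation information collapses, so the learned
#' pseudo-inverse shows error lines stretching vertically: the median
#' elevation error far exceeds the median azimuth error.
#'
#' @inheritParams run_showcase
#' @param seed Single training seed.
#' @return The `detection_fit`, with the property summary in
#'   `attr(, "stretch")`: a tibble with `median_abs_err_theta`,
#'   `median_abs_err_phi` and their `ratio`.
#' @export
run_static_control <- function(seed = 1, protocol = training_protocol(),
                               geometry = ear_geometry(),
                               sampling = sampling_spec(),
                               grid = direction_grid()) {
  protocol$seed <- as.integer(seed)
  fit <- train_inverse(ear_motion("0", "0", "CONST~",
                                  frequency = 1000 / sampling$T_ms),
                       protocol, geometry, sampling, grid)
  med_th <- stats::median(fit$report$abs_err_theta)
  med_ph <- stats::median(fit$report$abs_err_phi)
  attr(fit, "stretch") <- tibble::tibble(
    median_abs_err_theta = med_th,
    median_abs_err_phi = med_ph,
    ratio = med_ph / med_th
  )
  fit
}

# Shared driver: classification + injectivity (+ training) for a set of
# motion labels.
run_motion_set <- function(labels, seeds, protocol, geometry, sampling,
                           grid, train) {
  freq <- 1000 / sampling$T_ms
  by_seed <- list()
  res <- purrr::map_dfr(labels, function(lab) {
    m <- parse_motion(lab, frequency = freq)
    cls <- classify_motion(m)
    I <- injectivity(m, grid, geometry, sampling)$I
    E_med <- E_min <- E_max <- NA_real_
    if (train) {
      es <- detection_error_over_seeds(m, seeds, protocol, geometry,
                                       sampling, grid)
      by_seed[[lab]] <<- es
      E_med <- stats::median(es$E); E_min <- min(es$E); E_max <- max(es$E)
    }
    dplyr::bind_cols(
      tibble::tibble(roll = m$roll$pairing, pitch = m$pitch$pairing,
                     yaw = m$yaw$pairing, motion = lab, I = I),
      cls[, c("hull_dim", "orbit_dim_left", "orbit_dim_right",
              "dimension_pair", "cond_hull_3d", "cond_orbits_2d",
              "cond_yaw_distinct", "cond_pitch_distinct",
              "four_conditions", "mirror_symmetric")],
      tibble::tibble(E_median = E_med, E_min = E_min, E_max = E_max)
    )
  })
  attr(res, "by_seed") <- if (length(by_seed))
    dplyr::bind_rows(by_seed) else NULL
  class(res) <- c("sweep_result", class(res))
  res
}

#' Heatmap of a sweep result
#'
#' Roll rows by yaw columns, filled by the chosen metric (degree of
#' injection by default).
#'
#' @param object,x A `sweep_result` tibble.
#' @param metric Column to display (`"I"` or `"E_median"`).
#' @param ... Ignored.
#' @export
autoplot.sweep_result <- function(object, metric = "I", ...) {
  df <- tibble::as_tibble(object)
  df$roll <- factor(df$roll, levels = pairing_types)
  df$yaw <- factor(df$yaw, levels = pairing_types)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$yaw, y = .data$roll,
                                        fill = .data[[metric]])) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "yaw pairing", y = "roll pairing") +
    ggplot2::theme_minimal()
  if (length(unique(df$pitch)) > 1)
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$pitch))
  p
}

#' @rdname autoplot.sweep_result
#' @export
plot_sweep <- function(x, metric = "I", ...) {
  autoplot.sweep_result(x, metric = metric, ...)
}

#' Read an experiment configuration from a YAML file
#'
#' Builds the parameter objects for a run from a plain-text key-value
#' config.  Recognised blocks: `geometry` (fields of [ear_geometry()]),
#' `sampling` ([sampling_spec()]), `grid` ([direction_grid()]),
#' `protocol` ([training_protocol()]), plus `motions` (character vector of
#' labels, or `"all36"` / `"all216"`), `seeds`, and `quantization_steps`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `geometry`, `sampling`, `grid`,
#'   `protocol`, `motions`, `seeds`, `quantization_steps`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(fun, args) do.call(fun, as.list(args %||% list()))
  motions <- cfg$motions %||% character()
  if (length(motions) == 1 && motions %in% c("all36", "all216"))
    motions <- if (motions == "all36")
      motion_patterns(pitch = "COS~")$label else motion_patterns()$label
  list(
    geometry = build(ear_geometry, cfg$geometry),
    sampling = build(sampling_spec, cfg$sampling),
    grid = build(direction_grid, cfg$grid),
    protocol = build(training_protocol, cfg$protocol),
    motions = motions,
    seeds = as.integer(cfg$seeds %||% c(1, 2, 3)),
    quantization_steps = as.numeric(cfg$quantization_steps %||% 0)
  )
}
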