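#' Evaluation function U_M over a direction grid
#'
#' For each grid direction `n`, the evaluation function is the worst-case
#' ratio of direction-space distance to ILD-signal distance,
#' `U(n) = max over other grid directions n' of
#' ||n - n'||_2 / max_t |P(t; n) - P(t; n')|`,
#' with the sup norm taken over the sampled period.  Large or capped values
#' flag directions at which the forward map is (nearly) non-injective, so a
#' well-behaved inverse cannot exist there.  Denominators below `eps_db`
#' are degenerate (two directions producing the same ILD signal); their
#' ratio is replaced by the cap `u_cap`.
#'
#' @param motion An [ear_motion()].
#' @param grid A [direction_grid()] tibble (>= 2 directions).
#' @param geometry An [ear_geometry()].
#' @param sampling A [sampling_spec()].
#' @param eps_db Degeneracy threshold on the ILD sup distance, in dB.
#' @param u_cap Value assigned to degenerate ratios.
#' @return The `grid` tibble with columns `U` (per dB) and `capped`
#'   (logical: the max came from a degenerate pair).
#' @export
evaluation_function_map <- function(motion, grid = direction_grid(),
                                    geometry = ear_geometry(),
                                    sampling = sampling_spec(),
                                    eps_db = 1e-9, u_cap = 1e6) {
  stopifnot(is.data.frame(grid),
            all(c("theta", "phi", "nx", "ny", "nz") %in% names(grid)))
  if (nrow(grid) < 2)
    stop("grid must contain at least 2 directions", call. = FALSE)
  fm <- forward_model(motion, geometry, sampling)
  nv <- as.matrix(grid[, c("nx", "ny", "nz")])
  P <- ild_matrix_fm(fm, nv)
  dP <- pairwise_sup_dist(P)
  dn <- as.matrix(stats::dist(nv))
  degen <- dP < eps_db
  ratio <- dn / dP
  ratio[degen] <- u_cap
  diag(ratio) <- -Inf
  i_max <- max.col(ratio, ties.method = "first")
  grid$U <- ratio[cbind(seq_len(nrow(ratio)), i_max)]
  grid$capped <- degen[cbind(seq_len(nrow(ratio)), i_max)]
  class(grid) <- c("u_map", class(grid))
  grid
}

#' Degree of injection I of an ear motion
#'
#' The reciprocal of the direction-domain integral of the evaluation
#' function, `I = 1 / (sum over grid of U(theta, phi) cos(phi) dtheta
#' dphi)` with angles in radians (rectangle-rule quadrature over the
#' uniform grid).  Large `I` means `U` is small everywhere, i.e. a
#' well-behaved global inverse from ILD signals to direction is expected
#' to exist; small `I` flags non-injective or badly conditioned maps.
#'
#' @param umap A tibble from [evaluation_function_map()] (columns `theta`,
#'   `phi`, `U` on a uniform grid).
#' @return A single positive number.
#' @export
degree_of_injection <- function(umap) {
  stopifnot(is.data.frame(umap), all(c("theta", "phi", "U") %in% names(umap)))
  if (any(umap$U < 0) || all(umap$U == 0))
    stop("U must be non-negative with a positive integral", call. = FALSE)
  th <- sort(unique(umap$theta))
  ph <- sort(unique(umap$phi))
  if (length(th) < 2 || length(ph) < 2)
    stop("degenerate grid", call. = FALSE)
  dth <- (th[2] - th[1]) * pi / 180
  dph <- (ph[2] - ph[1]) * pi / 180
  integral <- sum(umap$U * cos(umap$phi * pi / 180)) * dth * dph
  if (!is.finite(integral) || integral <= 0)
    stop("non-positive or non-finite integral of U", call. = FALSE)
  1 / integral
}

#' Injectivity analysis of an ear motion
#'
#' Convenience wrapper running [evaluation_function_map()] and
#' [degree_of_injection()] for one motion.
#'
#' @inheritParams evaluation_function_map
#' @return An `injectivity_map` object with elements `map` (the U tibble),
#'   `I` (degree of injection), `motion`, and the capped-point count.
#' @examples
#' fit <- injectivity(ear_motion("SIN~", "COS~", "CONST~"),
#'                    grid = direction_grid(n_theta = 9, n_phi = 9))
#' glance(fit)
#' @export
injectivity <- function(motion, grid = direction_grid(),
                        geometry = ear_geometry(),
                        sampling = sampling_spec(),
                        eps_db = 1e-9, u_cap = 1e6) {
  umap <- evaluation_function_map(motion, grid, geometry, sampling,
                                  eps_db = eps_db, u_cap = u_cap)
  structure(
    list(map = umap, I = degree_of_injection(umap), motion = motion,
         n_capped = sum(umap$capped), u_cap = u_cap),
    class = "injectivity_map"
  )
}

#' @export
print.injectivity_map <- function(x, ...) {
  cat(sprintf("Injectivity of %s\n", format(x$motion)))
  cat(sprintf("  grid: %d directions, capped at %d points\n",
              nrow(x$map), x$n_capped))
  cat(sprintf("  degree of injection I = %.4g\n", x$I))
  invisible(x)
}

#' @export
tidy.injectivity_map <- function(x, ...) {
  out <- tibble::as_tibble(x$map)
  out$motion <- motion_label(x$motion)
  out
}

#' @export
glance.injectivity_map <- function(x, ...) {
  tibble::tibble(
    motion = motion_label(x$motion),
    I = x$I,
    n_grid = nrow(x$map),
    n_capped = x$n_capped
  )
}

#' @rdname plot_u_map
#' @export
autoplot.injectivity_map <- function(object, trans = "log10", ...) {
  ggplot2::ggplot(object$map,
                  ggplot2::aes(x = .data$theta, y = .data$phi,
                               fill = .data$U)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "azimuth (deg)", y = "elevation (deg)", fill = "U (per dB)",
      title = sprintf("[%s]   I = %.3g", motion_label(object$motion),
                      object$I)
    ) +
    ggplot2::theme_minimal()
}

#' Colormap of the evaluation function
#'
#' @param object,x An `injectivity_map` from [injectivity()].
#' @param trans Fill scale transform (default `"log10"`).
#' @param ... Ignored.
#' @export
plot_u_map <- function(x, trans = "log10", ...) {
  autoplot.injectivity_map(x, trans = trans, ...)
}
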