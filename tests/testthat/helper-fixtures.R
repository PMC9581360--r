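# Shared fixtures and independently written reference pieces.

# Independent rotation matrices (written out longhand, not via
# axis_rotation) for cross-checking kinematics.
ref_rx <- function(deg) {
  a <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}
ref_ry <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}
ref_rz <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

# Small grids and quick protocols to keep unit tests fast; acceptance
# tests use the full defaults.
small_grid <- function() direction_grid(n_theta = 9, n_phi = 9)

tiny_protocol <- function(seed = 1, ...) {
  training_protocol(n_train_steps = 300, n_eval_steps = 20, seed = seed, ...)
}

random_rotation <- function() {
  axis_rotation("z", stats::runif(1, -180, 180)) %*%
    axis_rotation("y", stats::runif(1, -90, 90)) %*%
    axis_rotation("x", stats::runif(1, -180, 180))
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

run_motion_set_for_test <- function(labels, protocol, grid) {
  earmotion:::run_motion_set(labels, seeds = 1, protocol, ear_geometry(),
                             sampling_spec(), grid, train = TRUE)
}
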