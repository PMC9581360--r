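test_that("axis rotations are proper rotations and match known cases", {
  expect_equal(axis_rotation("z", 0), diag(3), tolerance = 1e-12)
  expect_equal(drop(axis_rotation("z", 90) %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(axis_rotation("x", 37) %*% axis_rotation("x", -37), diag(3),
               tolerance = 1e-12)
  for (ax in c("x", "y", "z")) {
    R <- axis_rotation(ax, 123.4)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  expect_error(axis_rotation("z", NaN), "finite")
})

test_that("angle-function pairs follow the pairing table", {
  # anti-phase cosine at t = 0: left +C, right -C
  e <- evaluate_pair(angle_pair("COS~", amplitude = 15), 0)
  expect_equal(c(e$left, e$right), c(15, -15))
  # shared sine starts at zero on both sides
  e <- evaluate_pair(angle_pair("SIN", amplitude = 40), 0)
  expect_equal(c(e$left, e$right), c(0, 0))
  # anti-phase constant splay, any time
  e <- evaluate_pair(angle_pair("CONST~", amplitude = 15), c(0, 0.01, 0.3))
  expect_equal(e$left, rep(15, 3))
  expect_equal(e$right, rep(-15, 3))
  expect_error(angle_pair("WOBBLE"), "arg")
})

test_that("anti-phase pairings mirror left and right exactly", {
  tt <- seq(0, 0.066, length.out = 37)
  for (p in c("CONST~", "SIN~", "COS~")) {
    e <- evaluate_pair(angle_pair(p), tt)
    expect_equal(e$left, -e$right, tolerance = 1e-12)
  }
})

test_that("phase offset shifts only the right-ear argument", {
  p <- angle_pair("COS", amplitude = 15, phase_offset = 90)
  e <- evaluate_pair(p, 0)
  expect_equal(e$left, 15)
  expect_equal(e$right, 15 * cos(pi / 2), tolerance = 1e-12)
})

test_that("ear orientations are in SO(3), periodic, and match the
           roll-pitch-yaw composition", {
  m <- ear_motion("SIN", "COS~", "CONST~", amplitude = 15)
  # at t = 0 the left ear has psi = 0, phi = 15, theta = 15
  L0 <- orientation_at(m, "left", 0)
  expect_equal(L0, ref_rz(15) %*% ref_ry(-15) %*% ref_rx(0),
               tolerance = 1e-12)
  T_s <- motion_period(m)
  withr::with_seed(42, {
    for (t in stats::runif(20, 0, 3 * T_s)) {
      for (side in c("left", "right")) {
        L <- orientation_at(m, side, t)
        expect_equal(crossprod(L), diag(3), tolerance = 1e-12)
        expect_equal(det(L), 1, tolerance = 1e-12)
        expect_equal(orientation_at(m, side, t + T_s), L, tolerance = 1e-12)
      }
    }
  })
})

test_that("orientation invariants hold across all 216 pairing patterns", {
  pats <- motion_patterns()
  withr::with_seed(7, {
    tt <- stats::runif(5, 0, 0.2)
    for (i in seq_len(nrow(pats))) {
      m <- ear_motion(pats$roll[i], pats$pitch[i], pats$yaw[i])
      side <- sample(c("left", "right"), 1)
      for (t in tt) {
        L <- orientation_at(m, side, t)
        expect_lt(max(abs(crossprod(L) - diag(3))), 1e-12)
        expect_lt(abs(det(L) - 1), 1e-12)
      }
    }
  })
})

test_that("all-zero motion keeps both ears at the identity orientation", {
  m <- ear_motion("0", "0", "0")
  expect_equal(orientation_at(m, "left", 0.0123), diag(3), tolerance = 1e-12)
  expect_equal(orientation_at(m, "right", 0.9), diag(3), tolerance = 1e-12)
})

test_that("direction vectors follow the azimuth/elevation chart", {
  expect_equal(direction_from_angles(0, 0)$n, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(direction_from_angles(90, 0)$n, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(direction_from_angles(0, 89.9)$n,
               c(cos(89.9 * pi / 180), 0, sin(89.9 * pi / 180)),
               tolerance = 1e-12)
  withr::with_seed(3, {
    for (k in 1:25) {
      th <- stats::runif(1, -60, 60); ph <- stats::runif(1, -60, 60)
      d <- direction_from_angles(th, ph)
      expect_equal(sum(d$n^2), 1, tolerance = 1e-12)
      expect_equal(d$n,
                   c(cos(th * pi / 180) * cos(ph * pi / 180),
                     sin(th * pi / 180) * cos(ph * pi / 180),
                     sin(ph * pi / 180)),
                   tolerance = 1e-12)
    }
  })
  expect_error(direction_from_angles(0, 95), "degrees")
})

test_that("motion labels parse and round-trip", {
  m <- parse_motion("SIN,COS~,CONST~")
  expect_s3_class(m, "ear_motion")
  expect_identical(motion_label(m), "SIN,COS~,CONST~")
  expect_identical(m$pitch$pairing, "COS~")
  expect_error(parse_motion("SIN,COS~"), "3 comma-separated")
  expect_error(ear_motion(angle_pair("SIN", frequency = 10),
                          angle_pair("COS~", frequency = 20), "0"),
               "frequency")
})

test_that("direction grids are uniform and carry unit vectors", {
  g <- direction_grid()
  expect_equal(nrow(g), 23 * 23)
  expect_equal(range(g$theta), c(-60, 60))
  expect_equal(diff(sort(unique(g$phi)))[1], 120 / 22, tolerance = 1e-12)
  expect_equal(g$nx^2 + g$ny^2 + g$nz^2, rep(1, nrow(g)), tolerance = 1e-12)
})
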