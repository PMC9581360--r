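test_that("orbits take the expected geometric forms", {
  # all-zero motion: a single point at the origin
  o <- orbit_points(ear_motion("0", "0", "0"), "left")
  expect_true(all(abs(as.matrix(o)) < 1e-12))
  # [SIN, COS~, CONST~] left ear: circle of radius C in the theta = C plane
  o <- orbit_points(ear_motion("SIN", "COS~", "CONST~", amplitude = 15),
                    "left")
  expect_equal(o$psi^2 + o$phi^2, rep(225, nrow(o)), tolerance = 1e-9)
  expect_equal(o$theta, rep(15, nrow(o)))
  # [0, COS~, CONST~] left ear: segment {0} x [-15, 15] x {15}
  o <- orbit_points(ear_motion("0", "COS~", "CONST~", amplitude = 15),
                    "left")
  expect_true(all(o$psi == 0))
  expect_equal(range(o$phi), c(-15, 15))
  expect_true(all(o$theta == 15))
})

test_that("affine dimension identifies points, segments and circles", {
  u <- seq(0, 2 * pi, length.out = 33)[-33]
  circle <- cbind(15 * sin(u), 15 * cos(u), 15)
  segment <- cbind(0, seq(-15, 15, length.out = 20), 15)
  point <- matrix(c(1, 2, 3), 1)
  expect_equal(affine_dimension(circle), 2L)
  expect_equal(affine_dimension(segment), 1L)
  expect_equal(affine_dimension(point), 0L)
  expect_error(affine_dimension(circle[0, ]), "empty")
})

test_that("dimension pairs match the known classifications", {
  expect_equal(classify_motion(ear_motion("SIN", "COS~", "CONST~"))$dimension_pair,
               "3-2")
  expect_equal(classify_motion(ear_motion("0", "COS~", "CONST~"))$dimension_pair,
               "2-1")
  expect_equal(classify_motion(ear_motion("0", "CONST~", "CONST~"))$dimension_pair,
               "1-0")
  expect_true(satisfies_four_conditions(ear_motion("SIN", "COS~", "CONST~")))
  # both orbits fall in the plane psi = theta: hull only 2-dimensional
  cls <- classify_motion(ear_motion("SIN~", "COS~", "SIN~"))
  expect_equal(cls$hull_dim, 2L)
  expect_false(cls$four_conditions)
})

test_that("classification is invariant to sampling density, time origin
           and amplitude scaling", {
  m15 <- ear_motion("SIN", "COS~", "SIN~", amplitude = 15)
  m40 <- ear_motion("SIN", "COS~", "SIN~", amplitude = 40)
  c16 <- classify_motion(m15, n_samples = 16)
  c256 <- classify_motion(m15, n_samples = 256)
  cols <- c("hull_dim", "orbit_dim_left", "orbit_dim_right",
            "dimension_pair", "four_conditions")
  expect_equal(c16[cols], c256[cols])
  expect_equal(classify_motion(m40)[cols], c16[cols])
})

test_that("the combinatorial counts of admissible motions are exact", {
  cls <- classify_all_motions()
  expect_equal(nrow(cls), 216)
  expect_equal(sum(cls$four_conditions), 14L)
  c36 <- cls[cls$pitch == "COS~", ]
  expect_equal(nrow(c36), 36)
  first3 <- c36$cond_hull_3d & c36$cond_orbits_2d & c36$cond_yaw_distinct
  expect_equal(sum(first3), 5L)
  # exactly one of the five high-performance patterns is mirror-symmetric
  expect_equal(c36$motion[first3 & c36$mirror_symmetric],
               "SIN,COS~,CONST~")
  # the counts are amplitude-independent
  cls30 <- classify_all_motions(amplitude = 30)
  expect_equal(sum(cls30$four_conditions), 14L)
})

test_that("four-condition motions fail whenever yaw or pitch coincide", {
  cls <- classify_all_motions()
  coincident <- cls$yaw %in% c("0", "SIN", "COS") |
    cls$pitch %in% c("0", "SIN", "COS")
  expect_true(all(!cls$four_conditions[coincident]))
})

test_that("mirror symmetry follows the half-period sagittal reflection", {
  expect_true(is_mirror_symmetric(ear_motion("SIN", "COS~", "CONST~")))
  expect_false(is_mirror_symmetric(ear_motion("SIN~", "COS~", "CONST~")))
  expect_true(is_mirror_symmetric(ear_motion("0", "0", "0")))
})

test_that("phase-shifted motions interpolate between the two pairings", {
  tt <- seq(0, 0.066, length.out = 23)
  m180 <- phase_shifted_motion(delta_phi = 180)
  ref <- ear_motion("CONST~", "COS~", "SIN~")
  for (side in c("left", "right"))
    expect_equal(earmotion:::motion_angles(m180, side, tt),
                 earmotion:::motion_angles(ref, side, tt),
                 tolerance = 1e-9)
  m0 <- phase_shifted_motion(delta_phi = 0)
  ref0 <- ear_motion("CONST~", "COS", "SIN")
  for (side in c("left", "right"))
    expect_equal(earmotion:::motion_angles(m0, side, tt),
                 earmotion:::motion_angles(ref0, side, tt),
                 tolerance = 1e-9)
  # any phase difference keeps both orbits circles of radius C at
  # psi = +/- C
  for (dp in c(30, 77, 135)) {
    m <- phase_shifted_motion(delta_phi = dp, amplitude = 15)
    for (side in c("left", "right")) {
      o <- orbit_points(m, side)
      expect_equal(o$phi^2 + o$theta^2, rep(225, nrow(o)), tolerance = 1e-9)
      expect_equal(abs(o$psi), rep(15, nrow(o)))
    }
  }
})
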