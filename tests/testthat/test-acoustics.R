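test_that("closed-form envelope agrees with the four-phasor oracle", {
  withr::with_seed(11, {
    for (k in 1:200) {
      geom <- ear_geometry(
        delta_y = stats::runif(1, 0, 0.499) * 5,
        delta_z = stats::runif(1, 0, 0.499) * 5,
        lambda = 5, A = stats::runif(1, 0.1, 10)
      )
      L <- random_rotation()
      n <- random_unit_vector()
      a <- envelope_at(geom, L, n)
      b <- brute_force_envelope(geom, L, n)
      expect_lt(abs(a - b) / max(abs(b), 1e-300), 1e-9)
    }
  })
})

test_that("envelope hits 4A on-axis and for coincident receivers", {
  geom <- ear_geometry(lambda = 5, A = 2.5)
  # direction along the ear's roll axis: zero path differences
  expect_equal(envelope_at(geom, diag(3), c(1, 0, 0)), 4 * 2.5,
               tolerance = 1e-12)
  expect_equal(brute_force_envelope(geom, diag(3), c(1, 0, 0)), 4 * 2.5,
               tolerance = 1e-9)
  # zero spacings: omnidirectional
  geom0 <- ear_geometry(delta_y = 0, delta_z = 0, lambda = 5, A = 1)
  withr::with_seed(5, {
    for (k in 1:10) {
      n <- random_unit_vector()
      expect_equal(envelope_at(geom0, diag(3), n), 4, tolerance = 1e-12)
      expect_equal(brute_force_envelope(geom0, diag(3), n), 4,
                   tolerance = 1e-9)
    }
  })
})

test_that("envelope is strictly positive under the spacing invariant", {
  geom <- ear_geometry()
  withr::with_seed(21, {
    for (k in 1:100)
      expect_gt(envelope_at(geom, random_rotation(), random_unit_vector()),
                0)
  })
})

test_that("geometry validation rejects spacings at or above lambda/2", {
  expect_error(ear_geometry(delta_y = 2.5, lambda = 5), "lambda/2")
  expect_error(ear_geometry(delta_z = -1, lambda = 5), "lambda/2")
  expect_error(envelope_at(ear_geometry(), matrix(1, 3, 3), c(1, 0, 0)),
               "SO\\(3\\)")
})

test_that("ILD signal is periodic, amplitude-invariant and ear-spacing
           invariant", {
  m <- ear_motion("SIN~", "COS~", "CONST~")
  n <- direction_from_angles(25, -40)
  s1 <- ild_signal(m, n, ear_geometry(A = 1))
  s2 <- ild_signal(m, n, ear_geometry(A = 17.3))
  expect_equal(s1$ild_db, s2$ild_db, tolerance = 1e-12)
  s3 <- ild_signal(m, n, ear_geometry(d = 500))
  expect_equal(s1$ild_db, s3$ild_db, tolerance = 1e-12)
  expect_equal(nrow(s1), 66)
  # periodicity: envelope at t and t + T agree (T = one full period)
  fm <- earmotion:::forward_model(m, ear_geometry(), sampling_spec())
  L1 <- orientation_at(m, "left", 0.013)
  L2 <- orientation_at(m, "left", 0.013 + motion_period(m))
  expect_equal(L1, L2, tolerance = 1e-12)
})

test_that("identical left/right motions give identically zero ILD", {
  # SIN/SIN on all axes is not an anti-phase pairing but is constructible
  m <- ear_motion("SIN", "SIN", "SIN")
  withr::with_seed(9, {
    for (k in 1:5) {
      n <- direction_from_angles(stats::runif(1, -60, 60),
                                 stats::runif(1, -60, 60))
      s <- ild_signal(m, n)
      expect_equal(s$ild_db, rep(0, 66), tolerance = 1e-12)
    }
  })
})

test_that("mirror-symmetric motion gives antisymmetric ILD on the
           midsagittal plane", {
  m <- ear_motion("SIN", "COS~", "CONST~")
  expect_true(is_mirror_symmetric(m))
  n <- direction_from_angles(0, 35)     # theta = 0: midsagittal target
  s <- ild_signal(m, n)
  half <- nrow(s) / 2
  shifted <- c(s$ild_db[(half + 1):nrow(s)], s$ild_db[1:half])
  expect_equal(shifted, -s$ild_db, tolerance = 1e-10)
})

test_that("ILD quantization rounds to multiples of the step", {
  expect_equal(quantize_ild(0.4, 1), 0)
  expect_equal(quantize_ild(1.6, 1), 2)
  expect_equal(quantize_ild(c(-0.4, -1.6, 0.5), 1), c(0, -2, 1))
  x <- c(-3.21, 0.77, 12.5)
  expect_identical(quantize_ild(x, 0), x)
  s <- ild_signal(ear_motion("SIN~", "COS~", "CONST~"),
                  direction_from_angles(10, 10))
  q <- quantize_ild(s, 3)
  expect_true(all(abs(q$ild_db / 3 - round(q$ild_db / 3)) < 1e-12))
  expect_error(quantize_ild(s, -1), ">= 0")
})
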