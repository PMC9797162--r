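test_that("path_length matches closed forms and a dense integration oracle", {
  sph <- ellipsoid(c(0, 0, 0), c(5, 5, 5), "tumor")
  expect_equal(path_length(sph, c(0, -100, 0), c(0, 1, 0)), 10)
  expect_equal(path_length(sph, c(20, -100, 0), c(0, 1, 0)), 0)

  ell <- ellipsoid(c(3, -2, 1), c(8, 5, 12), "tumor")
  d <- c(1, 2, 0.5); d <- d / sqrt(sum(d^2))
  o <- c(-20, -10, -4)
  expect_equal(path_length(ell, o, d), chord_oracle(ell, o, d),
               tolerance = 1e-6)

  cyl <- cylinder(c(1, 2, -3), c(0.3, 1, 0.1), 4, 25, "bone")
  d2 <- c(0.2, -0.5, 1); d2 <- d2 / sqrt(sum(d2^2))
  o2 <- c(4, 10, -30)
  expect_equal(path_length(cyl, o2, d2), chord_oracle(cyl, o2, d2),
               tolerance = 1e-5)

  expect_error(ellipsoid(c(0, 0, 0), c(0, 1, 1), "tumor"), "degenerate")
  expect_error(cylinder(c(0, 0, 0), c(0, 0, 0), 1, 1, "bone"), "degenerate")
  expect_error(path_length(sph, c(0, 0, 0), c(0, 2, 0)), "unit vector")
})

test_that("projection follows Beer-Lambert with material precedence", {
  mu <- rbind(tumor = c(high = 0.03, low = 0.05))
  empty <- phantom_spec(list(), mu)
  img <- project(empty, 0, "high", fluence = 7,
                 detector_shape = c(8, 8), pixel_spacing = 1)
  expect_true(all(img == 7))

  one <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(5, 5, 5), "tumor")), mu)
  img1 <- project(one, 0, "high", fluence = 100, u_mm = 0, v_mm = 0)
  expect_equal(img1[1, 1], 100 * exp(-0.03 * 10))

  # full phantom against a fine-step ray-marching oracle on a small grid
  ph <- default_phantom(n_clutter = 4)
  u <- seq(-20, 20, by = 10)
  v <- seq(-20, 20, by = 10)
  for (ang in c(30, 120)) {
    fast <- project(ph, ang, "low", u_mm = u, v_mm = v)
    slow <- exp(-raymarch_oracle(ph, ang, "low", u, v, step = 0.01))
    expect_lt(max(abs(fast - slow) / slow), 1e-3)
  }
})

test_that("projected intensity decreases monotonically in mu", {
  base <- tiny_phantom()
  denser <- base
  denser$mu["tumor", ] <- denser$mu["tumor", ] * 1.5
  a <- project(base, 45, "high", u_mm = seq(-10, 10, 2), v_mm = seq(-8, 8, 2))
  b <- project(denser, 45, "high", u_mm = seq(-10, 10, 2),
               v_mm = seq(-8, 8, 2))
  expect_true(all(b <= a + 1e-12))
  expect_lt(min(b - a), 0)
})

test_that("Poisson noise has the right moments and is seed-reproducible", {
  img <- matrix(100, 100, 100)
  noisy <- add_noise(img, seed = 11)
  expect_equal(mean(noisy), 100, tolerance = 3 * 10 / 100) # 3 sigma of mean
  expect_equal(var(as.vector(noisy)), 100, tolerance = 5)
  expect_identical(noisy, add_noise(img, seed = 11))
  expect_false(identical(noisy, add_noise(img, seed = 12)))
  expect_error(add_noise(matrix(-1, 2, 2), 1), "negative")
})

test_that("simulate_sequence pairs share angle/motion and GT is exact", {
  ph <- tiny_phantom()
  still <- motion_model(amplitude = c(0, 0))
  acq <- acquisition_spec(n_pairs = 5, detector_shape = c(32, 32),
                          pixel_spacing = 2, detector_fwhm = 0, seed = 3)
  sq <- simulate_sequence(ph, still, acq, noise = FALSE)
  expect_length(sq$frames, 5)
  expect_equal(sq$meta$angle_deg, seq(0, 180, length.out = 5))
  # zero amplitude: GT constant (tumor projects on-axis per fixture x/y)
  expect_equal(diff(range(sq$gt$v_mm)), 0)

  # cos waveform closed form: period 4 s, amplitude (0, 10),
  # at t = 1 s the cosine is zero so v equals the baseline
  mo <- motion_model(amplitude = c(0, 10), period = 4, waveform = "cos")
  disp <- motion_displacement(mo, c(0, 1, 2))
  expect_equal(disp[, "v"], c(10, 0, -10), tolerance = 1e-12)
  # independent evaluation of the stated waveform
  t <- seq(0, 3, by = 0.37)
  expect_equal(motion_displacement(mo, t)[, "v"], 10 * cos(2 * pi * t / 4))

  # cos4 stays within [0, amplitude] and is periodic
  mo4 <- motion_model(amplitude = c(2, 8), period = 4, waveform = "cos4")
  d4 <- motion_displacement(mo4, seq(0, 8, by = 0.1))
  expect_true(all(d4[, "v"] >= -1e-12 & d4[, "v"] <= 8 + 1e-12))
  expect_equal(motion_displacement(mo4, 0.3), motion_displacement(mo4, 4.3))

  # default acquisition matches the published protocol
  acq_def <- acquisition_spec()
  expect_identical(acq_def$n_pairs, 450L)
  expect_equal(acq_def$arc_stop - acq_def$arc_start, 180)
  expect_equal(acq_def$frame_rate, 15)
})

test_that("seeded simulation is bit-reproducible", {
  ph <- tiny_phantom()
  mo <- motion_model()
  acq <- acquisition_spec(n_pairs = 2, detector_shape = c(24, 24),
                          pixel_spacing = 2, seed = 99)
  a <- simulate_sequence(ph, mo, acq)
  b <- simulate_sequence(ph, mo, acq)
  expect_identical(a$frames, b$frames)
  expect_identical(a$gt, b$gt)
})

test_that("true cancellation weight removes the targeted material", {
  ph <- tiny_phantom()
  expect_equal(true_cancellation_weight(ph, "bone"), 0.04 / 0.10)
  eq <- ph
  eq$mu["bone", ] <- c(0.05, 0.05001) # (almost) equal mus -> weight ~ 1
  expect_equal(true_cancellation_weight(eq, "bone"), 1, tolerance = 1e-3)

  # end to end: bone cylinder in air cancels below 1e-9 of tissue contrast
  mu <- ph$mu
  solo <- phantom_spec(list(cylinder(c(0, 0, 0), c(1, 0, 0), 5, 40, "bone"),
                            ellipsoid(c(0, 0, -25), c(15, 15, 10),
                                      "soft_tissue")), mu)
  u <- seq(-30, 30, 2)
  v <- seq(-30, 30, 2)
  hi <- project(solo, 90, "high", u_mm = u, v_mm = v)
  lo <- project(solo, 90, "low", u_mm = u, v_mm = v)
  w <- true_cancellation_weight(solo, "bone")
  de <- log(hi) - w * log(lo)
  bone_rows <- which(v > -5 & v < 5)
  tissue_contrast <- diff(range(de))
  expect_lt(diff(range(de[bone_rows, ])), 1e-9 * tissue_contrast)

  # embedded ribs cancel with the differential weight (ideal detector)
  thor <- default_phantom(n_clutter = 0, lungs = FALSE)
  wd <- true_cancellation_weight(thor, "bone", relative_to = "soft_tissue")
  norib <- thor
  norib$materials <- Filter(function(p) p$material != "bone",
                            norib$materials)
  u2 <- seq(-50, 50, 4)
  de_rib <- log(project(thor, 90, "high", u_mm = u2, v_mm = u2)) -
    wd * log(project(thor, 90, "low", u_mm = u2, v_mm = u2))
  de_norib <- log(project(norib, 90, "high", u_mm = u2, v_mm = u2)) -
    wd * log(project(norib, 90, "low", u_mm = u2, v_mm = u2))
  expect_lt(max(abs(de_rib - de_norib)), 1e-9)
})

test_that("phantom_spec enforces its invariants", {
  mu_bad <- rbind(tumor = c(high = 0.05, low = 0.03)) # low < high
  expect_error(phantom_spec(list(), mu_bad), "low energy")
  mu <- rbind(tumor = c(high = 0.02, low = 0.03))
  expect_error(
    phantom_spec(list(ellipsoid(c(95, 0, 0), c(10, 1, 1), "tumor")), mu),
    "outside")
  expect_error(
    phantom_spec(list(ellipsoid(c(0, 0, 0), c(1, 1, 1), "mystery")), mu),
    "missing from mu")
})
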