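test_that("band-pass filter removes DC and matches its transfer function", {
  expect_lt(max(abs(bandpass(matrix(4.2, 16, 16),
                             bandpass_params(0.4, 1.6), 0.5))), 1e-12)
  expect_error(bandpass_params(0.8, 0.8), "exceed")
  expect_error(bandpass_params(0, 1), "sigma_low")

  # pure sinusoids: attenuation matches the closed-form DoG response
  # exp(-2 pi^2 f^2 sl^2) - exp(-2 pi^2 f^2 sh^2), f in cycles/mm
  spacing <- 0.5
  n <- 256
  x <- (seq_len(n) - 1) * spacing
  bp <- bandpass_params(0.6, 2.4)
  for (f in c(0.08, 0.2, 0.45)) {
    img <- matrix(rep(sin(2 * pi * f * x), each = n), n, n)
    out <- bandpass(img, bp, spacing)  # columns vary along u
    mid <- 64:192                      # interior, away from boundaries
    gain <- coef(lm(as.vector(out[128, mid]) ~
                      sin(2 * pi * f * x[mid]) - 1))[[1]]
    expected <- exp(-2 * pi^2 * f^2 * bp$sigma_low^2) -
      exp(-2 * pi^2 * f^2 * bp$sigma_high^2)
    expect_equal(gain, expected, tolerance = 0.02)
  }
})

test_that("band-pass commutes with integer shifts", {
  set.seed(30)
  img <- matrix(rnorm(64 * 64), 64, 64)
  bp <- bandpass_params(0.4, 1.2)
  shift <- function(m, di, dj) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + di):nrow(m), (1 + dj):ncol(m)] <-
      m[1:(nrow(m) - di), 1:(ncol(m) - dj)]
    out
  }
  a <- bandpass(shift(img, 3, 2), bp, 0.5)
  b <- shift(bandpass(img, bp, 0.5), 3, 2)
  interior <- 15:50
  expect_equal(a[interior, interior], b[interior, interior],
               tolerance = 1e-10)
})

test_that("NCC surface matches a brute-force oracle and its invariants", {
  set.seed(21)
  for (rep in 1:10) {
    img <- matrix(rnorm(32 * 32), 32, 32)
    tpl <- matrix(rnorm(64), 8, 8)
    got <- ncc_map(img, tpl)
    expect_equal(got, ncc_oracle(img, tpl), tolerance = 1e-10)
    expect_true(all(got <= 1 + 1e-9) && all(got >= -1 - 1e-9))
  }

  # template excised verbatim: peak exactly 1 at the excision point
  img <- matrix(rnorm(40 * 40), 40, 40)
  tpl <- img[11:20, 16:27]
  surf <- ncc_map(img, tpl)
  pk <- which(surf == max(surf), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(11, 16))
  expect_equal(max(surf), 1, tolerance = 1e-12)

  # affine intensity invariance
  expect_equal(ncc_map(3.7 * img + 11, tpl), surf, tolerance = 1e-9)

  # zero-variance handling
  expect_error(ncc_map(img, matrix(2, 4, 4)), "zero-variance")
  flat <- matrix(1, 20, 20)
  flat[15:20, 15:20] <- matrix(rnorm(36), 6, 6)
  s2 <- ncc_map(flat, matrix(rnorm(16), 4, 4))
  expect_equal(s2[1, 1], 0) # constant window -> NCC defined as 0
})

test_that("templates respect geometry and symmetry", {
  mu <- rbind(soft_tissue = c(high = 0.02, low = 0.03),
              tumor = c(high = 0.03, low = 0.045))
  sph <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(40, 40, 40),
                                     "soft_tissue"),
                           ellipsoid(c(0, 0, 0), c(8, 8, 8), "tumor")), mu)
  bank <- generate_templates(sph, c(0, 45, 90), detector_fwhm = 0)
  # spherical tumor on the rotation axis: identical template at any angle
  expect_equal(bank$templates[["0"]]$pixels, bank$templates[["90"]]$pixels,
               tolerance = 1e-9)
  expect_equal(bank$templates[["0"]]$pixels, bank$templates[["45"]]$pixels,
               tolerance = 1e-9)

  # center offset bookkeeping: offset equals projected center minus crop
  e <- bank$templates[["90"]]
  expect_equal(unname(e$crop["row0"] + e$offset_px["row"]),
               detrack:::v_to_row(e$ref_v_mm, 256, 0.5))

  # ellipsoidal tumor: projected widths at 0 vs 90 degrees follow the
  # closed-form projection of the semi-axes
  ell <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(12, 6, 8), "tumor")), mu)
  b2 <- generate_templates(ell, c(0, 90), margin = 5, detector_fwhm = 0)
  width_px <- function(tpl) {
    f <- tpl$foot
    px <- tpl$pixels[f["row0"]:(f["row0"] + f["nrow"] - 1),
                     f["col0"]:(f["col0"] + f["ncol"] - 1)]
    mid <- px[round(nrow(px) / 2), ]
    rng <- range(which(abs(mid) > 1e-9))
    diff(rng) + 1
  }
  # at 0 deg the u half-extent is semiaxis_y (6 mm), at 90 deg semiaxis_x
  # (12 mm): widths in 0.5 mm pixels ~ 24 and 48
  expect_equal(width_px(b2$templates[["0"]]), 2 * 6 / 0.5, tolerance = 0.1)
  expect_equal(width_px(b2$templates[["90"]]), 2 * 12 / 0.5,
               tolerance = 0.06)

  # tumor projecting outside the detector errors
  far <- phantom_spec(list(ellipsoid(c(0, 90, 0), c(5, 5, 5), "tumor")),
                      mu, volume_extent = c(200, 200, 200))
  expect_error(generate_templates(far, 0), "outside the detector")
})

test_that("noise-free tracking is self-consistent within a pixel", {
  ph <- default_phantom(n_clutter = 0, lungs = FALSE)
  mo <- motion_model()
  acq <- acquisition_spec(n_pairs = 12, detector_fwhm = 0)
  # the geometric check uses the simulator-exact bone-cancelling weight so
  # no rib residual confounds it
  dep <- de_params(w_ST = true_cancellation_weight(
    ph, "bone", relative_to = "soft_tissue"))
  bank <- generate_templates(ph, 0:180, de_params = dep, detector_fwhm = 0)
  sq <- simulate_sequence(ph, mo, acq, noise = FALSE)
  frames <- lapply(seq_along(sq$frames), function(k)
    apply_technique(sq$frames[[k]]$high, sq$frames[[k]]$low, "unprocessed",
                    dep, angle_deg = sq$meta$angle_deg[k]))
  tr <- track_sequence(frames, bank, search_config(), bandpass_params(0.4, 1.6),
                       spec = ph, motion = mo)
  expect_false(any(tr$missing))
  err <- sqrt((tr$u_mm - sq$gt$u_mm)^2 + (tr$v_mm - sq$gt$v_mm)^2)
  expect_lt(max(err), 0.5)  # one 0.5 mm pixel

  # an unattainable NCC threshold declares every frame missing
  cfg1 <- search_config(ncc_threshold = 1)
  tr1 <- track_sequence(frames, bank, cfg1, bandpass_params(0.4, 1.6),
                        spec = ph, motion = mo)
  expect_true(all(tr1$missing))

  # missing fraction is non-decreasing in the threshold
  miss_at <- vapply(c(0, 0.5, 0.9, 1), function(th) {
    cfg <- search_config(ncc_threshold = th)
    compute_missing(track_sequence(frames, bank, cfg,
                                   bandpass_params(0.4, 1.6),
                                   spec = ph, motion = mo))
  }, numeric(1))
  expect_true(all(diff(miss_at) >= 0))
})

test_that("track_frame equals an independent NCC-oracle recomputation", {
  ph <- default_phantom(n_clutter = 0, lungs = FALSE)
  mo <- motion_model()
  acq <- acquisition_spec(n_pairs = 3, fluence_high = 2000,
                          fluence_low = 2000, seed = 77)
  bank <- generate_templates(ph, 0:180)
  sq <- simulate_sequence(ph, mo, acq)
  bp <- bandpass_params(0.6, 2.4)
  cfg <- search_config(ncc_threshold = 0)
  spacing <- acq$pixel_spacing
  for (k in seq_along(sq$frames)) {
    img <- apply_technique(sq$frames[[k]]$high, sq$frames[[k]]$low,
                           "unprocessed")$pixels
    ang <- sq$meta$angle_deg[k]
    got <- track_frame(img, bank, c(0, 0), search_config(ncc_threshold = 0,
                                                         search_half_width = 8),
                       bp, angle_deg = ang)
    # oracle: same window bookkeeping, NCC by double loop
    lk <- detrack:::bank_lookup(bank, ang)
    tpl <- lk$entry
    ftpl <- detrack:::filter_template(tpl, bp, spacing)
    th <- unname(tpl$foot["nrow"]); tw <- unname(tpl$foot["ncol"])
    hw_px <- 8 / spacing
    ec <- detrack:::u_to_col(0, 256, spacing)
    er <- detrack:::v_to_row(0, 256, spacing)
    tl_col <- round(c(floor(ec - hw_px), ceiling(ec + hw_px)) -
                      tpl$offset_px["col"])
    tl_row <- round(c(floor(er - hw_px), ceiling(er + hw_px)) -
                      tpl$offset_px["row"])
    wr <- c(tl_row[1], tl_row[2] + th - 1)
    wc <- c(tl_col[1], tl_col[2] + tw - 1)
    pad <- ceiling(4 * bp$sigma_high / spacing) + 1
    pr <- c(max(1, wr[1] - pad), min(256, wr[2] + pad))
    pc <- c(max(1, wc[1] - pad), min(256, wc[2] + pad))
    win <- bandpass(img[pr[1]:pr[2], pc[1]:pc[2]], bp, spacing)
    win <- win[(wr[1] - pr[1] + 1):(wr[2] - pr[1] + 1),
               (wc[1] - pc[1] + 1):(wc[2] - pc[1] + 1)]
    surf <- ncc_oracle(win, ftpl)
    pk <- which(surf == max(surf), arr.ind = TRUE)
    u_oracle <- detrack:::col_to_u(wc[1] + pk[1, 2] - 1 +
                                     tpl$offset_px["col"], 256, spacing)
    v_oracle <- detrack:::row_to_v(wr[1] + pk[1, 1] - 1 +
                                     tpl$offset_px["row"], 256, spacing)
    expect_equal(got$u_mm, unname(u_oracle))
    expect_equal(got$v_mm, unname(v_oracle))
    expect_equal(got$ncc_peak, max(surf), tolerance = 1e-10)
  }
})

test_that("search windows clip at the detector and can go fully out", {
  ph <- default_phantom(n_clutter = 0, lungs = FALSE)
  bank <- generate_templates(ph, 0:180)
  img <- matrix(rnorm(256 * 256), 256, 256)
  cfg <- search_config(search_half_width = 10, ncc_threshold = -1)
  # expected position far outside the detector -> missing
  r <- track_frame(img, bank, c(500, 500), cfg, bandpass_params(0.4, 1.6),
                   angle_deg = 90)
  expect_true(r$missing)
  # near-corner expectation still returns a result from the clipped window
  r2 <- track_frame(img, bank, c(55, 55), cfg, bandpass_params(0.4, 1.6),
                    angle_deg = 90)
  expect_false(r2$missing)
})
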