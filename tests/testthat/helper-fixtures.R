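# Shared fixtures and independent oracles.

# a tiny two-material phantom: one soft-tissue sphere + one bone cylinder
# + one tumor sphere, used where the full thorax would be overkill
tiny_phantom <- function() {
  mu <- rbind(soft_tissue = c(high = 0.02, low = 0.03),
              bone        = c(high = 0.04, low = 0.10),
              tumor       = c(high = 0.025, low = 0.0371))
  phantom_spec(list(
    ellipsoid(c(0, 0, 0), c(30, 25, 30), "soft_tissue"),
    cylinder(c(0, -10, 8), c(1, 0, 0), 4, 30, "bone"),
    ellipsoid(c(5, 0, 0), c(6, 5, 7), "tumor")
  ), mu, volume_extent = c(100, 100, 100))
}

# independent dense line-integration oracle for a single primitive chord
chord_oracle <- function(primitive, origin, direction, lo = -500, hi = 500,
                         n = 2e6) {
  t <- seq(lo, hi, length.out = n)
  dt <- t[2] - t[1]
  px <- origin[1] + t * direction[1]
  py <- origin[2] + t * direction[2]
  pz <- origin[3] + t * direction[3]
  inside <- if (primitive$type == "ellipsoid") {
    ((px - primitive$center[1]) / primitive$semiaxes[1])^2 +
      ((py - primitive$center[2]) / primitive$semiaxes[2])^2 +
      ((pz - primitive$center[3]) / primitive$semiaxes[3])^2 <= 1
  } else {
    mx <- px - primitive$center[1]
    my <- py - primitive$center[2]
    mz <- pz - primitive$center[3]
    w <- primitive$axis
    par <- mx * w[1] + my * w[2] + mz * w[3]
    per2 <- (mx - par * w[1])^2 + (my - par * w[2])^2 + (mz - par * w[3])^2
    per2 <= primitive$radius^2 & abs(par) <= primitive$half_length
  }
  sum(inside) * dt
}

# voxel ray-marching projector oracle: per-pixel material-resolved
# line integral with step-wise sampling and the same precedence rule
raymarch_oracle <- function(spec, angle_deg, energy, u_mm, v_mm,
                            step = 0.1, t_half = 150) {
  th <- angle_deg * pi / 180
  d <- c(cos(th), sin(th), 0)
  tgrid <- seq(-t_half, t_half, by = step)
  prims <- spec$materials
  prec <- vapply(prims, function(p) detrack:::prim_precedence(p$material),
                 integer(1))
  mu <- vapply(prims, function(p) spec$mu[p$material, energy], numeric(1))
  out <- matrix(0, length(v_mm), length(u_mm))
  for (j in seq_along(u_mm)) for (i in seq_along(v_mm)) {
    p0 <- u_mm[j] * c(-sin(th), cos(th), 0) + c(0, 0, v_mm[i])
    px <- p0[1] + tgrid * d[1]
    py <- p0[2] + tgrid * d[2]
    pz <- p0[3] + tgrid * d[3]
    best_prec <- rep(0L, length(tgrid))
    best_mu <- rep(0, length(tgrid))
    for (k in seq_along(prims)) {
      p <- prims[[k]]
      inside <- if (p$type == "ellipsoid") {
        ((px - p$center[1]) / p$semiaxes[1])^2 +
          ((py - p$center[2]) / p$semiaxes[2])^2 +
          ((pz - p$center[3]) / p$semiaxes[3])^2 <= 1
      } else {
        mx <- px - p$center[1]; my <- py - p$center[2]; mz <- pz - p$center[3]
        w <- p$axis
        par <- mx * w[1] + my * w[2] + mz * w[3]
        per2 <- (mx - par * w[1])^2 + (my - par * w[2])^2 +
          (mz - par * w[3])^2
        per2 <= p$radius^2 & abs(par) <= p$half_length
      }
      take <- inside & prec[k] > best_prec
      best_prec[take] <- prec[k]
      best_mu[take] <- mu[k]
    }
    out[i, j] <- sum(best_mu) * step
  }
  out
}

# reflect-padded filter oracles built from base R
reflect_pad <- function(x, r) {
  # edge-duplicating reflection: ... c b a | a b c ... | z y x
  n <- nrow(x); m <- ncol(x)
  ri <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - seq_len(min(r, n)))
  ci <- c(rev(seq_len(min(r, m))), seq_len(m), m + 1 - seq_len(min(r, m)))
  x[ri, ci]
}

median_filter_oracle <- function(x, k) {
  r <- k %/% 2
  xp <- reflect_pad(x, r)
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) for (i in seq_len(nrow(x)))
    out[i, j] <- median(xp[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# direct double-loop NCC oracle
ncc_oracle <- function(image, templ) {
  h <- nrow(templ); w <- ncol(templ)
  t0 <- templ - mean(templ)
  td <- sqrt(sum(t0^2))
  nH <- nrow(image) - h + 1
  nW <- ncol(image) - w + 1
  out <- matrix(0, nH, nW)
  for (j0 in seq_len(nW)) for (i0 in seq_len(nH)) {
    win <- image[i0:(i0 + h - 1), j0:(j0 + w - 1)]
    w0 <- win - mean(win)
    den <- sqrt(sum(w0^2)) * td
    out[i0, j0] <- if (den <= 1e-12) 0 else sum(w0 * t0) / den
  }
  out
}

# small fast acquisition for end-to-end smoke tests (1 mm pixels keep the
# arithmetic light; kernels in mm scale accordingly)
mini_acq <- function(n_pairs = 4, seed = 1, fluence = 5000) {
  acquisition_spec(n_pairs = n_pairs, fluence_high = fluence,
                   fluence_low = fluence, pixel_spacing = 1,
                   detector_shape = c(128, 128), seed = seed)
}
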