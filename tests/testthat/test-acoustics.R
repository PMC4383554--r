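test_that("MEBR from linear intensities follows the decibel definition", {
  expect_equal(mebr_from_intensities(3.7, 3.7), 0)
  expect_equal(mebr_from_intensities(100 * 2.2, 2.2), 20)
  expect_equal(mebr_from_intensities(5.0119, 1), 7.00, tolerance = 1e-4)
  expect_error(mebr_from_intensities(0, 1), "intensities")
  expect_error(mebr_from_intensities(1, -2), "intensities")
})

test_that("bubble cross-section matches the above-resonance Rayleigh form", {
  f <- 2e6
  a_res <- minnaert_radius(f)
  a <- 5e-6 # 10 um bubble
  closed <- 4 * pi * a^2 / ((a_res / a)^2 - 1)^2
  modal <- bubble_backscatter_cross_section(10, f)
  expect_lt(abs(modal / closed - 1), 0.05)
})

test_that("bubble cross-section approaches the geometric limit at large ka", {
  modal <- bubble_backscatter_cross_section(3000, 2e6)
  geom <- pi * (1.5e-3)^2
  expect_gt(modal / geom, 0.25)
  expect_lt(modal / geom, 4)
})

test_that("bubble cross-section grows with diameter and rejects the domain floor", {
  s <- bubble_backscatter_cross_section(c(20, 100, 1000), 2e6)
  expect_true(all(diff(s) > 0))
  expect_error(bubble_backscatter_cross_section(3, 2e6), "5 um")
})

test_that("the monotone sizing curve stays close to the raw modal series", {
  # diffraction ripples and a handful of extremely narrow internal gas-
  # sphere resonances make the raw series locally non-monotone; the
  # isotonic sizing curve must track it tightly everywhere except inside
  # those narrow notches
  d_um <- exp(seq(log(5.001), log(6400), length.out = 3000))
  s <- bubble_backscatter_cross_section(d_um, 2e6)
  drops <- pmax(0, 1 - s[-1] / s[-length(s)])
  expect_gt(max(drops), 0.01) # local non-monotonicity is real
  dev_db <- abs(isoreg(log(d_um), log(s))$yf - log(s)) * 10 / log(10)
  expect_lt(median(dev_db), 0.05)
  expect_lt(unname(quantile(dev_db, 0.95)), 0.5)
  expect_lt(mean(dev_db > 1), 0.01) # only the narrow notches deviate
})

test_that("blood backscatter follows the H(1-H)^4 packing model", {
  expect_equal(blood_backscatter_coefficient(0, 2e6), 0)
  h <- seq(0.01, 0.95, by = 0.002)
  eta <- blood_backscatter_coefficient(h, 2e6)
  expect_equal(h[which.max(eta)], 0.20, tolerance = 0.005)
  # haematocrit effect on MEBR over the intra-operative range is <= 5 dB
  rng <- blood_backscatter_coefficient(c(0.22, 0.37, 0.30), 2e6)
  expect_lt(10 * log10(max(rng) / min(rng)), 5)
  expect_error(blood_backscatter_coefficient(1, 2e6), "haematocrit")
  expect_error(blood_backscatter_coefficient(-0.1, 2e6), "haematocrit")
})

test_that("forward MEBR is strictly increasing in diameter", {
  for (ctx in list(acoustic_context(),
                   acoustic_context(vessel_diameter = 2.6,
                                    haematocrit = 0.22),
                   acoustic_context(vessel_diameter = 3.5,
                                    haematocrit = 0.37))) {
    d <- exp(seq(log(5.001), log(ctx$vessel_diameter * 1e3 * 0.9999),
                 length.out = 300))
    expect_true(all(diff(forward_mebr(d, ctx)) > 0))
  }
})

test_that("haematocrit sensitivity of forward MEBR is bounded by 5 dB", {
  d <- exp(seq(log(5.001), log(2500), length.out = 40))
  hs <- seq(0.22, 0.37, by = 0.01)
  m <- sapply(hs, function(h) {
    forward_mebr(d, acoustic_context(haematocrit = h))
  })
  spread <- apply(m, 1, function(x) max(x) - min(x))
  expect_true(all(spread <= 5))
  # a +0.08 haematocrit error shifts MEBR by well under 5 dB
  d22 <- forward_mebr(100, acoustic_context(haematocrit = 0.22))
  d30 <- forward_mebr(100, acoustic_context(haematocrit = 0.30))
  expect_lt(abs(d30 - d22), 5)
})

test_that("doubling the sample length lowers MEBR by 10*log10(2) dB", {
  # gate short enough that the insonated-segment cap does not bind
  c1 <- acoustic_context(sample_length = 2, vessel_diameter = 3.0)
  c2 <- acoustic_context(sample_length = 4, vessel_diameter = 3.0)
  expect_equal(forward_mebr(100, c1) - forward_mebr(100, c2),
               10 * log10(2), tolerance = 1e-9)
})

test_that("forward MEBR rejects diameters outside the model domain", {
  ctx <- acoustic_context(vessel_diameter = 3.0)
  expect_error(forward_mebr(4, ctx), "diameter")
  expect_error(forward_mebr(3500, ctx), "diameter")
})

test_that("inversion recovers the diameter to 0.1% across the domain", {
  ctx <- acoustic_context()
  d <- exp(seq(log(6), log(2900), length.out = 60))
  rec <- invert_mebr(forward_mebr(d, ctx), ctx)
  expect_true(all(abs(rec$diameter_um / d - 1) < 1e-3))
  expect_true(all(rec$flag == "ok"))
  expect_true(all(rec$rel_uncertainty == 0.40))
  # also at non-default geometry
  ctx2 <- acoustic_context(vessel_diameter = 2.6, haematocrit = 0.25)
  for (d0 in c(10, 100, 1000)) {
    expect_equal(invert_mebr(forward_mebr(d0, ctx2), ctx2)$diameter_um, d0,
                 tolerance = 1e-3)
  }
})

test_that("out-of-range MEBR clamps with flags instead of erroring", {
  ctx <- acoustic_context()
  low <- invert_mebr(forward_mebr(5, ctx) - 20, ctx)
  expect_equal(low$flag, "clamped_floor")
  expect_equal(low$diameter_um, 5)
  high <- invert_mebr(forward_mebr(3000, ctx) + 20, ctx)
  expect_equal(high$flag, "clamped_ceiling")
  expect_equal(high$diameter_um, 3000)
  expect_error(invert_mebr(NaN, ctx), "finite")
})

test_that("volume conversion is exactly cubic", {
  expect_equal(volume_of(1000), 5.236e-4, tolerance = 1e-4)
  expect_equal(volume_of(100), 5.236e-7, tolerance = 1e-4)
  expect_equal(volume_of(0), 0)
  d <- c(13, 50, 333, 1200)
  expect_equal(volume_of(2 * d), 8 * volume_of(d), tolerance = 1e-12)
  expect_error(volume_of(-1), "diameter")
})

test_that("MEBR noise propagates to diameter error at the curve's slope", {
  # above resonance the cross-section scales ~ d^2 (about 20 dB/decade), so
  # Gaussian MEBR noise of sd s maps to a within-10% recovery fraction of
  # about P(|N(0, s)| < 20*log10(1.1)); check the error model at s = 1 dB
  ctx <- acoustic_context()
  set.seed(64)
  d <- pmin(pmax(sample_mixture_diameters(4000), 5.001), 2999)
  mebr <- forward_mebr(d, ctx) + rnorm(length(d), 0, 1)
  rec <- invert_mebr(mebr, ctx)
  frac10 <- mean(abs(rec$diameter_um / d - 1) <= 0.10)
  predicted <- 2 * pnorm(20 * log10(1.1)) - 1 # ~0.59 for a pure d^2 slope
  expect_lt(abs(frac10 - predicted), 0.10)
  # and noise-free inversion is essentially exact
  rec0 <- invert_mebr(forward_mebr(d, ctx), ctx)
  expect_gt(mean(abs(rec0$diameter_um / d - 1) <= 0.10), 0.999)
})

test_that("sized bubbles satisfy the diameter-volume invariant", {
  ctx <- acoustic_context()
  sb <- invert_mebr(forward_mebr(c(15, 80, 400), ctx), ctx)
  expect_equal(sb$volume_ml, (pi / 6) * (sb$diameter_um * 1e-4)^3,
               tolerance = 1e-9)
})
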