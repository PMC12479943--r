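test_that("decay correction follows the exponential law", {
  rec <- injection_record(N0 = 10, half_life = 100, t = 0, w = 25)
  expect_equal(decay_correct(rec, 0), 10)
  expect_equal(decay_correct(rec, 100), 5)
  # the study's injection: 15 MBq, 18F half-life, 2 h uptake
  rec18 <- injection_record(N0 = 15, t = 120, w = 25)
  expect_equal(decay_correct(rec18), 15 * exp(-log(2) / 109.77 * 120),
               tolerance = 1e-12)
  expect_equal(decay_correct(rec18), 7.0308, tolerance = 1e-4)
  # sequential decay equals one-shot decay
  t1 <- 37.3; t2 <- 81.9
  seq_decay <- decay_correct(injection_record(
    N0 = decay_correct(rec18, t1), half_life = 109.77, t = t2, w = 25))
  expect_equal(seq_decay, decay_correct(rec18, t1 + t2),
               tolerance = 1e-10)
  expect_error(decay_correct(rec, -5), "non-negative")
  expect_error(injection_record(N0 = -1, t = 0, w = 25), "positive")
})

test_that("SUV and SUVR arithmetic", {
  rec <- injection_record(N0 = 15, t = 120, w = 25)
  Nt <- decay_correct(rec)
  expect_equal(as.numeric(compute_suv(Nt / rec$w, rec)), 1)
  expect_equal(as.numeric(compute_suv(0, rec)), 0)
  expect_equal(as.numeric(compute_suv(2.0, rec)), 25 * 2 / Nt,
               tolerance = 1e-12)
  expect_equal(as.numeric(compute_suv(2.0, rec)), 7.11, tolerance = 1e-3)
  # negative concentration clamps to zero SUV but is flagged
  s <- compute_suv(-0.2, rec)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "clamped"))

  expect_equal(compute_suvr(3.7, 3.7), 1)
  expect_equal(compute_suvr(4, 2), 2)
  expect_error(compute_suvr(4, 0), "positive")
})

test_that("calibration fit recovers a known line and the printed ladder", {
  std <- data.frame(intensity = c(1, 2, 3, 4), activity_MBq = c(2, 4, 6, 8))
  cal <- fit_calibration(std, standard_mass_g = 1)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  # the five-step activity ladder with proportional synthetic intensities
  acts <- c(1.5, 0.8, 0.4, 0.2, 0.04)
  mass <- standard_section_mass(1.44)
  gain <- 3
  std5 <- data.frame(intensity = gain * acts / mass, activity_MBq = acts)
  cal5 <- fit_calibration(std5, standard_mass_g = mass)
  recovered <- (cal5$slope * std5$intensity + cal5$intercept) * mass
  expect_equal(recovered, acts, tolerance = 1e-9)

  expect_error(fit_calibration(data.frame(intensity = c(1, 1),
                                          activity_MBq = c(1, 2)),
                               standard_mass_g = 1),
               "degenerate")
})

test_that("calibration slope is essentially unbiased under 1% noise", {
  acts <- c(1.5, 0.8, 0.4, 0.2, 0.04)
  mass <- standard_section_mass(1.44)
  true_slope <- 1 / 3             # conc = intensity / gain, gain = 3
  x0 <- 3 * acts / mass
  set.seed(42)
  slopes <- replicate(200, {
    x <- x0 * (1 + rnorm(5, sd = 0.01))
    fit_calibration(data.frame(intensity = x, activity_MBq = acts),
                    standard_mass_g = mass)$slope
  })
  expect_lt(abs(mean(slopes) / true_slope - 1), 0.005)
})

test_that("circular ROI mask matches the stated geometry", {
  img <- autoradiogram_image(matrix(1, 100, 100), pixel_size = 0.025)
  m <- thalaquant:::roi_mask(img, roi_spec(1.25, 1.25, 0.4))
  # 0.4 mm at 0.025 mm/pixel spans 16 pixels across the widest row
  expect_equal(max(rowSums(m)), 16)
  expect_error(thalaquant:::roi_mask(img, roi_spec(0.1, 0.1, 0.4)),
               "bounds")
})

test_that("roi_activity subtracts background and flags negatives", {
  img <- autoradiogram_image(matrix(50, 200, 200), pixel_size = 0.025)
  cal <- structure(list(slope = 2, intercept = 0, r_squared = 1,
                        standards_used = 5), class = "calibration_curve")
  bg <- roi_spec(1, 1, 0.4, "background")
  r <- roi_activity(img, roi_spec(3, 3, 0.4, "thalamus"), cal, bg)
  expect_equal(as.numeric(r), 0)
  # dim ROI below background is negative and flagged
  x <- matrix(50, 200, 200); x[100:140, 100:140] <- 40
  img2 <- autoradiogram_image(x, pixel_size = 0.025)
  r2 <- roi_activity(img2, roi_spec(3, 3, 0.4, "dim"), cal, bg)
  expect_lt(as.numeric(r2), 0)
  expect_true(attr(r2, "below_background"))
})

test_that("slice aggregation follows the region policies", {
  s <- aggregate_region(c(2, 2, 2), "thalamus")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 0)
  s2 <- aggregate_region(c(1, 2, 3), "thalamus")
  expect_equal(s2$mean, 2)
  expect_equal(s2$sem, 0.5774, tolerance = 1e-4)
  # thalamus policy accepts exactly 3 slices silently, 6 for others
  expect_silent(aggregate_region(c(1, 2, 3), "thalamus"))
  expect_warning(aggregate_region(c(1, 2, 3), "hippocampus"), "6")
  expect_silent(aggregate_region(rep(1.5, 6), "brainstem"))
  expect_error(aggregate_region(numeric(0), "thalamus"), "no slices")
})

test_that("quantification is invariant to a global intensity rescaling", {
  sp <- phantom_spec()
  ph <- generate_phantom_autoradiogram(sp, seed = 1)
  q1 <- quantify_phantom(ph)
  ph2 <- ph
  ph2$image$intensity <- ph$image$intensity * 3.7
  q2 <- quantify_phantom(ph2)
  expect_equal(q2$r, q1$r, tolerance = 1e-9)
  expect_equal(q2$suvr, q1$suvr, tolerance = 1e-9)
})
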