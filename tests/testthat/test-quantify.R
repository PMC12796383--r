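test_that("roi_mean_intensity recovers constant fields and planted means", {
  img <- matrix(7, 10, 10)
  q <- roi_mean_intensity(img, matrix(TRUE, 10, 10), threshold_mode = 1)
  expect_equal(q$mean_intensity, 7)
  expect_equal(q$area_fraction_pct, 100)
  # automatic threshold on a constant ROI keeps every pixel as signal
  q2 <- roi_mean_intensity(img, matrix(TRUE, 10, 10))
  expect_equal(q2$mean_intensity, 7)
  disc <- gen_disc_image(sim_config(seed = 1, noise_cv = 0),
                         a_mean = 100, p_mean = 200, background = 10)
  qa <- roi_mean_intensity(disc$image, disc$mask_a, threshold_mode = 50)
  qp <- roi_mean_intensity(disc$image, disc$mask_p, threshold_mode = 50)
  expect_equal(qa$mean_intensity, 100)
  expect_equal(qp$mean_intensity, 200)
  expect_error(roi_mean_intensity(img, matrix(FALSE, 10, 10)), "empty")
  expect_error(roi_mean_intensity(img, matrix(TRUE, 5, 5)), "shapes")
})

test_that("Otsu-mode quantification separates signal from background", {
  disc <- gen_disc_image(sim_config(seed = 2, noise_cv = 0.05),
                         shape = c(200, 200), a_mean = 100, p_mean = 100,
                         background = 5)
  # ROI spanning signal and background: the histogram is bimodal and the
  # automatic threshold isolates the >= 10^4 signal pixels
  q <- roi_mean_intensity(disc$image, matrix(TRUE, 200, 200))
  expect_gte(sum(disc$mask_pouch), 1e4)
  expect_lt(abs(q$mean_intensity - 100) / 100, 0.01)
  # ROI with nothing above a fixed threshold is flagged
  expect_warning(
    qf <- roi_mean_intensity(matrix(1, 4, 4), matrix(TRUE, 4, 4),
                             threshold_mode = 5), "undefined")
  expect_true(qf$flagged)
  expect_true(is.na(qf$mean_intensity))
})

test_that("mean intensity ignores background added outside the ROI", {
  disc <- gen_disc_image(sim_config(seed = 3, noise_cv = 0))
  img2 <- disc$image
  img2[!disc$mask_pouch] <- img2[!disc$mask_pouch] + 500
  qa1 <- roi_mean_intensity(disc$image, disc$mask_a, threshold_mode = 50)
  qa2 <- roi_mean_intensity(img2, disc$mask_a, threshold_mode = 50)
  expect_equal(qa1$mean_intensity, qa2$mean_intensity)
})

test_that("P/A ratios reproduce planted compartment structure", {
  eq <- gen_disc_image(sim_config(seed = 4, noise_cv = 0),
                       a_mean = 150, p_mean = 150)
  qa <- roi_mean_intensity(eq$image, eq$mask_a, threshold_mode = 50)
  qp <- roi_mean_intensity(eq$image, eq$mask_p, threshold_mode = 50)
  expect_equal(pa_ratio(qa, qp)$value, 1)
  dbl <- gen_disc_image(sim_config(seed = 4, noise_cv = 0),
                        a_mean = 100, p_mean = 200)
  qa2 <- roi_mean_intensity(dbl$image, dbl$mask_a, threshold_mode = 50)
  qp2 <- roi_mean_intensity(dbl$image, dbl$mask_p, threshold_mode = 50)
  expect_equal(pa_ratio(qa2, qp2)$value, 2)
  expect_equal(pa_ratio(qp2, qa2)$value, 1 / pa_ratio(qa2, qp2)$value,
               tolerance = 1e-12)
})

test_that("area fractions follow the planted positive fraction exactly", {
  disc <- gen_disc_image(sim_config(seed = 5, noise_cv = 0),
                         positive_fraction_p = 0.25)
  af <- area_fraction(disc$image, disc$mask_p, threshold_mode = 50)
  expect_equal(af, 100 * disc$truth$n_positive_p / sum(disc$mask_p))
  expect_equal(af, 25, tolerance = 0.5)  # rounding to whole pixels
  expect_equal(area_fraction(disc$image, disc$mask_a,
                             threshold_mode = 50), 100)
  expect_equal(suppressWarnings(
    area_fraction(disc$image, disc$mask_a, threshold_mode = 1e6)), 0)
})

test_that("relative (Otsu) area fraction is invariant under rescaling", {
  disc <- gen_disc_image(sim_config(seed = 6, noise_cv = 0.05),
                         positive_fraction_p = 0.4)
  a1 <- area_fraction(disc$image, disc$mask_p)
  a2 <- area_fraction(disc$image * 12.5, disc$mask_p)
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("red/green ratios are computed per nucleus and scale-invariant", {
  green <- matrix(10, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[3:6, 3:6] <- TRUE; mask[12:15, 12:15] <- TRUE
  rg <- red_green_ratio(green, green, mask)
  expect_equal(nrow(rg$per_nucleus), 2)
  expect_equal(rg$per_nucleus$ratio, c(1, 1))
  rg3 <- red_green_ratio(3 * green, green, mask)
  expect_equal(rg3$summary_mean, 3)
  rg_s <- red_green_ratio(3 * green * 7, green * 7, mask)
  expect_equal(rg_s$per_nucleus$ratio, rg3$per_nucleus$ratio)
  # zero-green nucleus flagged and excluded
  g0 <- green; g0[12:15, 12:15] <- 0
  expect_warning(rg0 <- red_green_ratio(green, g0, mask), "excluded")
  expect_equal(sum(rg0$per_nucleus$excluded), 1)
  expect_equal(rg0$summary_mean, 1)
  expect_error(red_green_ratio(green, green[1:5, ], mask), "shapes")
})

test_that("trichome density enforces the four-ROI protocol", {
  expect_equal(trichome_density(c(10, 10, 10, 10), 1), 10)
  expect_equal(trichome_density(c(8, 10, 12, 10), 2), 5)
  expect_error(trichome_density(c(10, 10), 1), "four")
  expect_equal(trichome_density(c(10, 10), 1, allow_any_count = TRUE), 10)
  expect_error(trichome_density(c(1, 2, 3, 4), 0), "positive")
  # Poisson point pattern at planted density
  set.seed(9)
  lambda <- 50; area <- 4
  counts <- rpois(4, lambda * area)
  est <- trichome_density(counts, area)
  se <- sqrt(lambda / (4 * area))
  expect_lt(abs(est - lambda), 3 * se)
})

test_that("T50 uses exact crossings and linear interpolation", {
  tab <- data.frame(time_h = c(100, 104, 108), pupariated = c(2, 5, 9))
  expect_equal(t50_pupariation(tab, n_larvae = 10), 104)
  tab2 <- data.frame(time_h = c(104, 108), pupariated = c(4, 6))
  expect_equal(t50_pupariation(tab2, n_larvae = 10), 106)
  cen <- data.frame(time_h = c(100, 104), pupariated = c(1, 2))
  expect_warning(t50 <- t50_pupariation(cen, n_larvae = 10), "censored")
  expect_true(is.na(t50))
})

test_that("T50 shifts exactly with a time translation", {
  pt <- gen_pupariation_counts(sim_config(seed = 7), n_larvae = 500,
                               t50_true = 120, spread = 3)
  t50 <- t50_pupariation(pt)
  shifted <- pt; shifted$time_h <- shifted$time_h + 6
  expect_equal(t50_pupariation(shifted, attr(pt, "n_larvae")), t50 + 6,
               tolerance = 1e-9)
})
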