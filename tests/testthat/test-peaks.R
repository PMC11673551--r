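test_that("flat spectra yield no apexes and stage is enforced", {
  sp <- spectrum(nt_grid(), rep(2, length(nt_grid())), "baseline-corrected")
  expect_length(detect_apexes(sp), 0)
  raw <- spectrum(nt_grid(), rep(2, length(nt_grid())), "normalized")
  expect_error(detect_apexes(raw), "baseline-corrected")
})

test_that("the 1% height-and-prominence gate is exact", {
  # 0.9% of max: never reported; 1.1%: always (noise-free)
  below <- gauss_spec(c(200, 300), c(100, 0.9), c(2, 2))
  expect_length(detect_apexes(below), 1)
  above <- gauss_spec(c(200, 300), c(100, 1.1), c(2, 2))
  expect_length(detect_apexes(above), 2)
})

test_that("well-separated planted peaks are found at their centers", {
  centers <- seq(160, 340, by = 20)
  sp <- gauss_spec(centers, seq(50, 1000, length.out = 10), rep(1.5, 10))
  apx <- detect_apexes(sp)
  expect_length(apx, 10)
  expect_true(all(abs(sort(sp$positions[apx]) - centers) <= 0.5))
})

test_that("apex and prominence computation matches a brute-force oracle", {
  set.seed(31)
  for (case in 1:30) {
    n <- sample(20:200, 1)
    y <- cumsum(rnorm(n))
    y <- y - min(y)
    sp <- spectrum(seq_len(n), y, "baseline-corrected")
    oracle <- brute_force_peaks(y)
    keep <- oracle$apexes[y[oracle$apexes] >= 0.01 * max(y) &
                          oracle$prominences >= 0.01 * max(y)]
    expect_identical(detect_apexes(sp), keep)
  }
})

test_that("plateau ties break to the leftmost sample", {
  y <- c(0, 1, 5, 5, 5, 1, 0, 0, 3, 0)
  sp <- spectrum(seq_along(y), y, "baseline-corrected")
  expect_identical(detect_apexes(sp), c(3L, 9L))
})

test_that("Gaussian shape fit recovers planted sigma", {
  sp <- gauss_spec(250, 100, 2)
  apex <- which.max(sp$intensities)
  fit <- fit_peak_shape(sp, apex)
  expect_equal(fit$fit_method, "gaussian")
  expect_lt(abs(fit$sigma_nt - 2), 0.02)
  expect_lt(abs(fit$center_nt - 250), 0.01)
})

test_that("sigma estimates stay within 5% under 1% noise", {
  errs <- vapply(1:100, function(s) {
    sp <- gauss_spec(250, 100, 2, noise_sd = 1, seed = s)
    sm <- gaussian_smooth(spectrum(sp$positions, sp$intensities, "normalized"))
    sm$stage <- "baseline-corrected"
    fit <- fit_peak_shape(sm, which.max(sm$intensities))
    abs(fit$sigma_nt - 2) / 2
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("saturated flat-top peaks take the flagged moment fallback", {
  g <- nt_grid()
  y <- pmin(100 * exp(-(g - 250)^2 / (2 * 4)), 30)  # clipped at 30% height
  sp <- spectrum(g, y, "baseline-corrected")
  apx <- detect_apexes(sp)[1]
  fit <- fit_peak_shape(sp, apx)
  expect_equal(fit$fit_method, "moments")
  expect_gt(fit$sigma_nt, 0)
})

test_that("Simpson integration is exact for quadratics and near-exact for Gaussians", {
  g <- seq(150, 350, by = 0.05)
  sp <- spectrum(g, 3 * g^2 - 2 * g + 1, "baseline-corrected")
  a <- integrate_peak(sp, 200, 300)
  analytic <- (300^3 - 200^3) - (300^2 - 200^2) + 100
  expect_equal(as.numeric(a), analytic, tolerance = 1e-10)

  h <- 100; s <- 2
  spg <- gauss_spec(250, h, s)
  ag <- integrate_peak(spg, 250 - 3 * s, 250 + 3 * s)
  truth <- h * s * sqrt(2 * pi) * (pnorm(3) - pnorm(-3))
  expect_lt(abs(as.numeric(ag) - truth) / truth, 0.005)

  zero <- spectrum(g, numeric(length(g)), "baseline-corrected")
  expect_equal(as.numeric(integrate_peak(zero, 200, 300)), 0)
  expect_error(integrate_peak(spg, 300, 200), "left_nt")
})

test_that("trapezoid fallbacks are taken and flagged", {
  g <- seq(150, 350, by = 0.05)
  sp <- spectrum(g, rep(1, length(g)), "baseline-corrected")
  few <- integrate_peak(sp, 200, 200.07)  # 2 samples
  expect_equal(attr(few, "method"), "trapezoid")
  even <- integrate_peak(sp, 200, 200.15)  # 4 samples, 3 intervals
  expect_equal(attr(even, "method"), "simpson+trapezoid")
  expect_equal(as.numeric(even), 0.15, tolerance = 1e-9)
})

test_that("peak tables carry normalized columns, overlap flags and ordering", {
  single <- build_peak_table(gauss_spec(250, 100, 2))
  expect_equal(nrow(single), 1)
  expect_equal(single$height_mh, 1, tolerance = 1e-9)
  expect_equal(single$area_ta, 1, tolerance = 1e-9)

  # two Gaussians 4 nt apart: +/-3 sigma windows intersect (sigma 1.5 keeps
  # the apexes resolvable as distinct local maxima; at sigma 2 they merge)
  two <- build_peak_table(gauss_spec(c(248, 252), c(100, 90), c(1.5, 1.5)))
  expect_equal(nrow(two), 2)
  expect_true(all(two$overlap_flag))
  expect_true(!is.unsorted(two$apex_nt))

  # well-separated: no flags, area_ta sums to one
  many <- build_peak_table(gauss_spec(seq(170, 330, by = 20),
                                      rep(100, 9), rep(1.5, 9)))
  expect_false(any(many$overlap_flag))
  expect_equal(sum(many$area_ta), 1, tolerance = 1e-9)
})

test_that("quantification is scale-equivariant", {
  sp <- gauss_spec(c(200, 260, 320), c(100, 55, 70), c(2, 1.5, 2.5))
  t1 <- build_peak_table(sp)
  sp2 <- spectrum(sp$positions, sp$intensities * 37, "baseline-corrected")
  t2 <- build_peak_table(sp2)
  expect_equal(t2$apex_nt, t1$apex_nt)
  expect_equal(t2$sigma_nt, t1$sigma_nt, tolerance = 1e-6)
  expect_equal(t2$height_mh, t1$height_mh, tolerance = 1e-9)
  expect_equal(t2$area_ta, t1$area_ta, tolerance = 1e-9)
  expect_equal(t2$height, 37 * t1$height, tolerance = 1e-9)
  expect_equal(t2$area, 37 * t1$area, tolerance = 1e-6)
})

test_that("boundary clipping at the region edge is flagged", {
  sp <- gauss_spec(151, 100, 2)  # left boundary would fall below 150 nt
  tab <- build_peak_table(sp)
  expect_true(tab$clipped[1])
  expect_equal(tab$left_nt[1], 150)
})

test_that("peak table writers round-trip", {
  tab <- build_peak_table(gauss_spec(c(200, 300), c(100, 50), c(2, 2)))
  path <- tempfile(fileext = ".tsv")
  write_peak_table_tsv(tab, path)
  back <- read_peak_table_tsv(path)
  expect_equal(back$apex_nt, tab$apex_nt)
  unlink(path)
  jpath <- tempfile(fileext = ".json")
  write_peak_table_json(tab, jpath)
  js <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(js$peaks$area, tab$area, tolerance = 1e-12)
  unlink(jpath)
})
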