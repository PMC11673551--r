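make_set <- function(spectra, tables = NULL, id = "s") {
  replicate_set(spectra, tables, sample_id = id)
}

test_that("Pearson statistics hit their analytic anchors", {
  sp <- gauss_spec(c(200, 300), c(100, 60), c(2, 2))
  set <- make_set(list(sp, sp))
  expect_equal(pairwise_pearson(set), 1)

  neg <- spectrum(sp$positions, -sp$intensities, "baseline-corrected")
  expect_equal(pairwise_pearson(make_set(list(sp, neg))), -1)

  flat <- spectrum(sp$positions, rep(1, length(sp$positions)),
                   "baseline-corrected")
  expect_error(pairwise_pearson(make_set(list(sp, flat))), "zero-variance")
})

test_that("correlation is invariant under positive affine intensity maps", {
  sp <- gauss_spec(c(200, 260, 320), c(100, 50, 75), c(2, 2, 2))
  aff <- spectrum(sp$positions, 3.2 * sp$intensities + 40, "baseline-corrected")
  expect_equal(pairwise_pearson(make_set(list(sp, aff))), 1, tolerance = 1e-12)
})

test_that("amplitude-jittered low-noise replicates stay above rho 0.99", {
  base <- gauss_spec(seq(165, 335, length.out = 12),
                     1000 * seq(0.1, 1, length.out = 12), rep(1.5, 12))
  set.seed(13)
  reps <- lapply(1:4, function(r) {
    amp <- 1 + rnorm(1, 0, 0.05)
    y <- base$intensities * amp + rnorm(length(base$positions), 0, 10)
    spectrum(base$positions, y, "baseline-corrected")
  })
  expect_gte(pairwise_pearson(make_set(reps)), 0.99)
})

test_that("cross-correlation lags recover planted shifts exactly", {
  sp <- gauss_spec(c(200, 260, 320), c(100, 50, 75), c(2, 2, 2))
  expect_equal(median_xcorr_lag(make_set(list(sp, sp))), 0)

  shift_by <- function(spec, k) {
    y <- spec$intensities
    n <- length(y)
    if (k > 0) y <- c(rep(y[1], k), y[seq_len(n - k)])
    if (k < 0) y <- c(y[(1 - k):n], rep(y[n], -k))
    spectrum(spec$positions, y, "baseline-corrected")
  }
  expect_equal(median_xcorr_lag(make_set(list(sp, shift_by(sp, 7)))), 7)
  # lag = k exactly for shifts within 10% of length
  for (k in c(-20L, 3L, 20L))
    expect_equal(median_xcorr_lag(make_set(list(sp, shift_by(sp, k)))), k)

  # planted shifts {0,2,2,4}: median over all 6 pairwise lags equals the
  # brute-force enumeration over pair differences
  shifts <- c(0L, 2L, 2L, 4L)
  reps <- lapply(shifts, function(k) shift_by(sp, k))
  pair_truth <- c()
  for (i in 1:3) for (j in (i + 1):4)
    pair_truth <- c(pair_truth, shifts[j] - shifts[i])
  expect_equal(median_xcorr_lag(make_set(reps)), median(pair_truth))
})

test_that("peak CV statistics behave at their analytic anchors", {
  sp <- gauss_spec(seq(170, 330, by = 20), rep(100, 9), rep(1.5, 9))
  tab <- build_peak_table(sp)
  set <- make_set(rep(list(sp), 4), rep(list(tab), 4))
  expect_equal(peak_cv(set, "area_ta")$median_cv, 0)
  expect_equal(peak_cv(set, "height_mh")$median_cv, 0)

  # per-replicate global rescaling leaves mh-heights and ta-areas unchanged
  scales <- c(1, 1.3, 0.7, 2.1)
  reps <- lapply(scales, function(a)
    spectrum(sp$positions, a * sp$intensities, "baseline-corrected"))
  set2 <- make_set(reps)
  expect_equal(peak_cv(set2, "height_mh")$median_cv, 0, tolerance = 1e-9)
  expect_equal(peak_cv(set2, "area_ta")$median_cv, 0, tolerance = 1e-9)
})

test_that("incomplete peak groups are excluded from the median but reported", {
  sp1 <- gauss_spec(c(200, 260, 320), c(100, 60, 80), c(2, 2, 2))
  sp2 <- gauss_spec(c(200, 320), c(100, 80), c(2, 2))  # 260 nt peak missing
  t1 <- build_peak_table(sp1); t2 <- build_peak_table(sp2)
  set <- make_set(list(sp1, sp2), list(t1, t2))
  cv <- peak_cv(set, "height_mh")
  expect_equal(nrow(cv$per_peak), 2)
  expect_equal(cv$incomplete$apex_nt, 260, tolerance = 0.1)
})

test_that("3% multiplicative area noise lands near CV 0.03", {
  medians <- vapply(1:50, function(s) {
    set.seed(s)
    sp <- gauss_spec(seq(165, 335, length.out = 15),
                     1000 * seq(0.2, 1, length.out = 15), rep(1.5, 15))
    tab <- build_peak_table(sp)
    tables <- lapply(1:4, function(r) {
      t2 <- tab
      t2$area <- t2$area * (1 + rnorm(nrow(t2), 0, 0.03))
      t2$area_ta <- t2$area / sum(t2$area)
      t2
    })
    peak_cv(make_set(rep(list(sp), 4), tables), "area_ta")$median_cv
  }, numeric(1))
  expect_true(all(medians > 0.005 & medians < 0.06))
  expect_gt(mean(medians > 0.015 & medians < 0.045), 0.9)
})

test_that("the full report composes and degenerate sets behave", {
  sp <- gauss_spec(seq(170, 330, by = 20), 100 * seq(1, 9) / 3, rep(1.5, 9))
  tab <- build_peak_table(sp)
  rep4 <- make_set(rep(list(sp), 4), rep(list(tab), 4), id = "dup")
  r <- build_report(rep4)
  expect_equal(r$pearson_raw, 1)
  expect_equal(r$pearson_mh, 1)
  expect_equal(r$median_lag, 0)
  expect_equal(r$cv_area_ta, 0)
  expect_equal(r$cv_height_mh, 0)

  expect_error(replicate_set(list(sp)), "at least 2")
  expect_error(replicate_set(list()), "at least 2")

  path <- tempfile(fileext = ".tsv")
  write_report_tsv(r, path)
  out <- read.delim(path)
  expect_equal(names(out), c("sample", "pearson_raw", "pearson_mh",
                             "median_lag", "cv_area_ta", "cv_height_mh"))
  unlink(path)
})

test_that("sample-like jittered replicates give a finite, tight report", {
  scene <- scene_spec(seed = 6L, noise_sd = 0.02)
  sim <- simulate_replicates(scene, 4, shift_sd = 5, amp_sd = 0.05)
  specs <- lapply(sim$runs, function(run) {
    map <- fit_migration_map(call_ladder_peaks(run$ladder, liz500_ladder()),
                             liz500_ladder())
    preprocess_spectrum(to_nucleotide_axis(run$glycan, map))
  })
  r <- build_report(make_set(specs, id = "sim"))
  expect_true(all(is.finite(c(r$pearson_raw, r$pearson_mh, r$median_lag,
                              r$cv_area_ta, r$cv_height_mh))))
  expect_lt(r$cv_area_ta, 0.1)
  expect_lt(r$cv_height_mh, 0.1)
})
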