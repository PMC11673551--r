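test_that("aligning a spectrum to itself gives the diagonal at distance 0", {
  sp <- gauss_spec(c(200, 260, 320), c(100, 60, 80), c(2, 2, 2))
  al <- dtw_align(sp, sp)
  expect_equal(al$distance, 0)
  expect_equal(al$path[, 1], al$path[, 2])

  tab <- build_peak_table(sp)
  refs <- reference_peaks(seq_len(nrow(tab)), apex_nt = tab$apex_nt)
  mt <- match_peaks(al, tab, refs, sp, sp)
  expect_equal(sum(mt$pairs$primary), nrow(tab))
  expect_length(mt$unmatched_sample, 0)
  expect_length(mt$unmatched_ref, 0)
})

test_that("a rigid 10-sample shift is absorbed by the warping path", {
  g <- nt_grid(c(150, 250), 0.05)
  y <- 100 * exp(-(g - 180)^2 / 8) + 60 * exp(-(g - 220)^2 / 8)
  ref <- spectrum(g, y, "baseline-corrected")
  smp <- spectrum(g, c(rep(y[1], 10), y[seq_len(length(y) - 10)]),
                  "baseline-corrected")
  al <- dtw_align(smp, ref)
  # every reference apex index maps to apex + 10 on the sample side
  for (apex in c(which.min(abs(g - 180)), which.min(abs(g - 220)))) {
    hit <- al$path[al$path[, 2] == apex, 1]
    expect_true(any(abs(hit - (apex + 10)) <= 1))
  }
})

test_that("constant spectra align at n times the offset without normalization", {
  a <- spectrum(1:50, rep(5, 50), "baseline-corrected")
  b <- spectrum(1:50, rep(3, 50), "baseline-corrected")
  al <- dtw_align(a, b, normalize = FALSE)
  expect_equal(al$distance, 50 * 2)
  expect_error(dtw_align(spectrum(1:2, 1:2, "normalized"),
                         spectrum(1:2, 1:2, "normalized"),
                         normalize = FALSE), NA)
})

test_that("banded DP distance equals exhaustive search on tiny instances", {
  set.seed(17)
  for (case in 1:15) {
    n <- sample(4:8, 1); m <- sample(4:8, 1)
    x <- runif(n); y <- runif(m)
    a <- spectrum(seq_len(n), x, "baseline-corrected")
    b <- spectrum(seq_len(m), y, "baseline-corrected")
    al <- dtw_align(a, b, band_nt = 100, normalize = FALSE)
    expect_equal(al$distance, brute_force_dtw(x, y), tolerance = 1e-12)
    # path validity: monotone, endpoints pinned
    expect_equal(al$path[1, ], c(1, 1), ignore_attr = TRUE)
    expect_equal(al$path[nrow(al$path), ], c(n, m), ignore_attr = TRUE)
    expect_true(all(diff(al$path[, 1]) %in% 0:1))
    expect_true(all(diff(al$path[, 2]) %in% 0:1))
  }
})

test_that("DTW distance is symmetric", {
  a <- gauss_spec(c(200, 300), c(100, 50), c(2, 2))
  b <- gauss_spec(c(202, 298), c(90, 55), c(2, 2))
  expect_equal(dtw_align(a, b)$distance, dtw_align(b, a)$distance,
               tolerance = 1e-9)
})

test_that("smoothly warped simulator pairs are matched almost completely", {
  scene <- scene_spec(peaks = default_scene_peaks(20), seed = 2L)
  pr <- simulate_reference_pair(scene, max_warp = 2)
  smp_tab <- build_peak_table(pr$sample$spectrum)
  al <- dtw_align(pr$sample$spectrum, pr$reference$spectrum)
  mt <- match_peaks(al, smp_tab, pr$reference$ref_peaks,
                    pr$sample$spectrum, pr$reference$spectrum)
  prim <- mt$pairs[mt$pairs$primary, ]
  expect_gte(nrow(prim), 19)
  # planted correspondence: ascending sample peak k belongs to ref_id k+1
  expect_true(all(prim$ref_id == prim$sample_peak + 1))
  # order preservation: no crossing matches
  ord <- prim[order(prim$sample_peak), "ref_id"]
  expect_false(is.unsorted(ord))
})

test_that("an extra sample peak ends up unmatched", {
  scene <- scene_spec(peaks = default_scene_peaks(10), seed = 4L)
  pr <- simulate_reference_pair(scene, max_warp = 1)
  extra_nt <- 250.7  # between planted peaks
  smp <- pr$sample$spectrum
  smp$intensities <- smp$intensities +
    300 * exp(-(smp$positions - extra_nt)^2 / (2 * 1.2^2))
  tab <- build_peak_table(smp)
  al <- dtw_align(smp, pr$reference$spectrum)
  mt <- match_peaks(al, tab, pr$reference$ref_peaks, smp, pr$reference$spectrum)
  extra_peak <- tab$peak[which.min(abs(tab$apex_nt - extra_nt))]
  expect_true(extra_peak %in% mt$unmatched_sample)
})

test_that("annotation transfer assigns structures, NAs and manual overrides", {
  refs <- glycge_reference_structures()
  sp <- gauss_spec(c(200, 260, 320), c(100, 60, 80), c(2, 2, 2))
  tab <- build_peak_table(sp)
  located <- reference_peaks(c(1, 25, 46), apex_nt = c(200, 260, 320),
                             structures = refs$structures[match(c(1, 25, 46), refs$ref_id)])
  al <- dtw_align(sp, sp)
  mt <- match_peaks(al, tab, located, sp, sp)
  ann <- transfer_annotations(mt, located, tab)
  expect_equal(ann$structures[ann$ref_id == "1"], "A4G4S[6,6,6,6]4")
  expect_equal(ann$structures[ann$ref_id == "25"], "FA2G2S[6]1;M5")

  # unmatched peak stays NA
  tab2 <- build_peak_table(gauss_spec(c(200, 240), c(100, 60), c(2, 2)))
  ann2 <- transfer_annotations(NULL, located, tab2)
  expect_true(all(is.na(ann2$structures)))

  # manual overrides: assignment, forced NA, unknown ref error
  ov <- list(list(sample_peak = 0L, ref_id = c(1L, 25L), note = ""),
             list(sample_peak = 1L, ref_id = NA_integer_, note = "artifact"))
  ann3 <- transfer_annotations(NULL, located, tab2, overrides = ov)
  expect_equal(ann3$ref_id[1], "1,25")
  expect_equal(ann3$structures[1], "A4G4S[6,6,6,6]4;FA2G2S[6]1;M5")
  expect_equal(ann3$match_mode[1], "manual")
  expect_true(is.na(ann3$ref_id[2]))
  bad <- list(list(sample_peak = 0L, ref_id = 999L, note = ""))
  expect_error(transfer_annotations(NULL, located, tab2, overrides = bad),
               "unknown ref_id")
})

test_that("the packaged catalog and overrides load and are consistent", {
  refs <- glycge_reference_structures()
  expect_true(all(!duplicated(refs$ref_id)))
  expect_identical(refs$structures[refs$ref_id == 1][[1]], "A4G4S[6,6,6,6]4")
  expect_identical(refs$structures[refs$ref_id == 25][[1]],
                   c("FA2G2S[6]1", "M5"))
  ov <- glycge_manual_overrides()
  sp0 <- ov[[which(vapply(ov, `[[`, integer(1), "sample_peak") == 0L)]]
  expect_true(is.na(sp0$ref_id))
  # every override that assigns refs points at catalogued ids
  for (o in ov)
    if (!all(is.na(o$ref_id)))
      expect_true(all(o$ref_id %in% refs$ref_id))
})

test_that("dtw rejects degenerate inputs", {
  sp <- gauss_spec(200, 100, 2)
  expect_error(dtw_align(sp, spectrum(1:2, c(0, 0), "baseline-corrected")),
               "max-normalize")
})
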