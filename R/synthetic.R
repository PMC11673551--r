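# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default synthetic glycan peak layout
#'
#' Thirty Gaussian peaks across the 150-350 nt glycomic window with
#' heights spanning two orders of magnitude (all above the 1% detection
#' threshold) and widths around 1 nt, loosely emulating the density of a
#' plasma N-glycome profile.
#'
#' @param n number of peaks (default 30).
#' @return data.frame with `center_nt`, `height`, `sigma_nt`.
#' @export
default_scene_peaks <- function(n = 30L) {
  centers <- seq(157, 343, length.out = n)
  # deterministic stagger so spacing is irregular but reproducible;
  # amplitude keeps every gap above ~4.7 nt so peaks stay resolvable
  centers <- centers + 0.8 * sin(seq_len(n) * 2.3)
  heights <- 1000 * (0.05 + 0.95 * (0.5 + 0.5 * sin(seq_len(n) * 1.7))^2)
  heights <- pmax(heights, 60)  # keep everything safely above 1% of max
  sigmas <- 0.7 + 0.3 * (0.5 + 0.5 * cos(seq_len(n) * 0.9))
  data.frame(center_nt = centers, height = heights, sigma_nt = sigmas)
}

#' Specify a synthetic CGE-LIF scene
#'
#' A scene fixes everything the simulator needs: the planted glycan peaks,
#' the (quadratic, strictly monotone) migration law mapping nucleotide
#' size to scan index, the baseline drift model, the noise level, the
#' ladder, and the seed. The default law places the 150-350 nt window
#' roughly in the central half of a 7000-scan acquisition.
#'
#' @param peaks data.frame with `center_nt`, `height`, `sigma_nt`.
#' @param migration coefficients `c(a, b, c)` of
#'   `scan(s) = a + b*s + c*s^2` (s in nt).
#' @param baseline list with `kind` in
#'   `{"constant", "linear", "exponential-decay"}` and `amplitude`
#'   (instrument units).
#' @param noise_sd additive white-noise SD as a fraction of the tallest
#'   planted peak (default 0.01).
#' @param ladder a `ladder_definition` (default [liz500_ladder()]).
#' @param ladder_height,ladder_sigma height (units) and SD (scans) of the
#'   ladder fragments' Gaussians.
#' @param n_scans trace length (default 7000).
#' @param seed RNG seed fixing all randomness.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(peaks = default_scene_peaks(),
                       migration = c(a = 200, b = 14, c = -0.003),
                       baseline = list(kind = "exponential-decay", amplitude = 30),
                       noise_sd = 0.01,
                       ladder = liz500_ladder(),
                       ladder_height = 1000, ladder_sigma = 4,
                       n_scans = 7000L, seed = 1L) {
  stopifnot(is.data.frame(peaks),
            all(c("center_nt", "height", "sigma_nt") %in% names(peaks)),
            inherits(ladder, "ladder_definition"))
  if (length(migration) != 3L) stop("migration must be c(a, b, c)")
  if (!baseline$kind %in% c("constant", "linear", "exponential-decay"))
    stop("unknown baseline kind: ", baseline$kind)
  grid <- seq(35, 500, by = 1)
  d <- migration[2] + 2 * migration[3] * grid
  if (any(d <= 0)) stop("migration law not strictly increasing over [35, 500] nt")
  structure(list(peaks = peaks, migration = unname(migration),
                 baseline = baseline, noise_sd = noise_sd, ladder = ladder,
                 ladder_height = ladder_height, ladder_sigma = ladder_sigma,
                 n_scans = as.integer(n_scans), seed = as.integer(seed)),
            class = "scene_spec")
}

# forward migration law and its derivative
.scene_scan_of_nt <- function(scene, nt)
  scene$migration[1] + scene$migration[2] * nt + scene$migration[3] * nt^2
.scene_dscan_dnt <- function(scene, nt)
  scene$migration[2] + 2 * scene$migration[3] * nt

.scene_baseline <- function(scene, scans) {
  amp <- scene$baseline$amplitude
  n <- scene$n_scans
  switch(scene$baseline$kind,
         constant = rep(amp, length(scans)),
         linear = amp * scans / n,
         `exponential-decay` = amp * exp(-3 * scans / n))
}

#' Simulate one CGE-LIF run
#'
#' The glycan channel is a sum of Gaussians placed at the migration law's
#' images of the planted nucleotide centers (widths scaled by the local
#' law derivative so the nt-axis shape keeps its stated sigma), plus the
#' baseline drift and additive white noise. The ladder channel holds
#' narrow Gaussians at the law's images of the fragment sizes. All
#' randomness derives from the scene seed.
#'
#' @param scene a `scene_spec`.
#' @return list with `glycan` and `ladder` (`raw_trace`s) and `manifest`
#'   (planted truth: peak table with analytic areas, the migration
#'   coefficients, baseline, noise and seed).
#' @export
simulate_run <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  n <- scene$n_scans
  scans <- seq_len(n)
  glycan <- .scene_baseline(scene, scans)
  for (k in seq_len(nrow(scene$peaks))) {
    p <- scene$peaks[k, ]
    mu <- .scene_scan_of_nt(scene, p$center_nt)
    sg <- p$sigma_nt * .scene_dscan_dnt(scene, p$center_nt)
    glycan <- glycan + p$height * exp(-(scans - mu)^2 / (2 * sg^2))
  }
  ladder <- numeric(n)
  for (s in scene$ladder$fragment_sizes) {
    mu <- .scene_scan_of_nt(scene, s)
    ladder <- ladder + scene$ladder_height *
      exp(-(scans - mu)^2 / (2 * scene$ladder_sigma^2))
  }
  hmax <- max(scene$peaks$height)
  noise <- .with_seed(scene$seed, list(
    g = stats::rnorm(n, 0, scene$noise_sd * hmax),
    l = stats::rnorm(n, 0, scene$noise_sd * scene$ladder_height)))
  manifest <- list(
    peaks = transform(scene$peaks,
                      analytic_area = height * sigma_nt * sqrt(2 * pi)),
    migration = scene$migration, baseline = scene$baseline,
    noise_sd = scene$noise_sd, seed = scene$seed, n_scans = n)
  list(glycan = raw_trace(glycan + noise$g, "DATA,1", "synthetic"),
       ladder = raw_trace(ladder + noise$l, "DATA,105", "synthetic"),
       manifest = manifest)
}

#' Simulate technical replicates of one scene
#'
#' Replicates share the scene's planted peaks and migration law; each
#' draws its own glycan-channel time shift (integer scans, emulating
#' injection jitter that survives size calibration because it desynchronizes
#' the dye channels), a global amplitude factor, and a fresh noise
#' realization. All draws are recorded in the manifest.
#'
#' @param scene a `scene_spec`.
#' @param n number of replicates (>= 2).
#' @param shift_sd SD of the integer scan shift (default 3).
#' @param amp_sd SD of the multiplicative amplitude jitter (default 0.05).
#' @return list with `runs` (each a `simulate_run()`-style list) and
#'   `manifest` (scene truth plus a `draws` data.frame with
#'   `replicate`, `shift_points`, `amp_factor`, `noise_seed`).
#' @export
simulate_replicates <- function(scene, n, shift_sd = 3, amp_sd = 0.05) {
  stopifnot(inherits(scene, "scene_spec"))
  if (n < 2L) stop("need at least 2 replicates")
  draws <- .with_seed(scene$seed, data.frame(
    replicate = seq_len(n),
    shift_points = as.integer(round(stats::rnorm(n, 0, shift_sd))),
    amp_factor = pmax(1 + stats::rnorm(n, 0, amp_sd), 0.1),
    noise_seed = sample.int(2^30, n)))
  base <- scene
  base$noise_sd <- 0
  clean <- simulate_run(base)
  runs <- lapply(seq_len(n), function(r) {
    g <- clean$glycan$values * draws$amp_factor[r]
    k <- draws$shift_points[r]
    if (k > 0) g <- c(rep(g[1], k), g[seq_len(length(g) - k)])
    else if (k < 0) g <- c(g[(1 - k):length(g)], rep(g[length(g)], -k))
    hmax <- max(scene$peaks$height) * draws$amp_factor[r]
    noise <- .with_seed(draws$noise_seed[r], list(
      g = stats::rnorm(length(g), 0, scene$noise_sd * hmax),
      l = stats::rnorm(length(g), 0, scene$noise_sd * scene$ladder_height)))
    list(glycan = raw_trace(g + noise$g, "DATA,1",
                            paste0("synthetic-rep", r)),
         ladder = raw_trace(clean$ladder$values + noise$l, "DATA,105",
                            paste0("synthetic-rep", r)))
  })
  manifest <- c(clean$manifest, list(draws = draws, shift_sd = shift_sd,
                                     amp_sd = amp_sd))
  list(runs = runs, manifest = manifest)
}

# Sum-of-Gaussians spectrum directly on the nt grid (no migration detour).
# Emulates pipeline *output*: when noise is added, the spectrum is passed
# through the standard Gaussian denoising so the residual noise level
# matches what baseline-corrected spectra actually carry.
.gaussian_spectrum <- function(peaks, region = c(150, 350), step = 0.05,
                               noise_sd = 0, seed = NULL, sample_id = "") {
  grid <- seq(region[1], region[2], by = step)
  y <- numeric(length(grid))
  for (k in seq_len(nrow(peaks)))
    y <- y + peaks$height[k] *
      exp(-(grid - peaks$center_nt[k])^2 / (2 * peaks$sigma_nt[k]^2))
  if (noise_sd > 0) {
    stopifnot(!is.null(seed))
    y <- y + .with_seed(seed, stats::rnorm(length(y), 0, noise_sd * max(peaks$height)))
  }
  sp <- spectrum(grid, y, stage = "normalized", sample_id = sample_id)
  if (noise_sd > 0) sp <- gaussian_smooth(sp)
  sp$stage <- "baseline-corrected"
  sp
}

#' Simulate a reference/sample spectrum pair under a smooth warp
#'
#' The reference spectrum carries the scene's peaks on the nt grid; the
#' sample spectrum carries the same peaks displaced by a smooth, strictly
#' monotone sinusoidal nt-distortion of amplitude `max_warp`. The true
#' peak correspondence is the identity by construction, giving an exact
#' oracle for DTW-based matching.
#'
#' @param scene a `scene_spec` (its peaks, noise level and seed are used).
#' @param max_warp warp amplitude in nt (default 2).
#' @param warp_period sinusoid period in nt (default 200).
#' @param region,step nucleotide grid.
#' @return list with `reference` and `sample` (each: `spectrum`, planted
#'   `peaks` data.frame, and a located `reference_peaks` list for the
#'   reference), plus `correspondence` (data.frame `sample_peak`,
#'   `ref_id`, both 0-based/id-based in planted order).
#' @export
simulate_reference_pair <- function(scene, max_warp = 2, warp_period = 200,
                                    region = c(150, 350), step = 0.05) {
  stopifnot(inherits(scene, "scene_spec"))
  if (abs(max_warp) * 2 * pi / warp_period >= 1)
    stop("warp is not strictly monotone: reduce max_warp or increase warp_period")
  pk <- scene$peaks
  warp <- function(nt) nt + max_warp * sin(2 * pi * (nt - region[1]) / warp_period)
  pk_s <- pk
  pk_s$center_nt <- warp(pk$center_nt)
  ref_spec <- .gaussian_spectrum(pk, region, step, scene$noise_sd,
                                 seed = scene$seed, sample_id = "reference")
  smp_spec <- .gaussian_spectrum(pk_s, region, step, scene$noise_sd,
                                 seed = scene$seed + 1L, sample_id = "sample")
  ord <- order(pk$center_nt)
  refs <- reference_peaks(ref_id = seq_along(ord),
                          apex_nt = pk$center_nt[ord],
                          structures = rep(list(character(0)), length(ord)))
  list(reference = list(spectrum = ref_spec, peaks = pk, ref_peaks = refs),
       sample = list(spectrum = smp_spec, peaks = pk_s),
       correspondence = data.frame(planted = ord, ref_id = seq_along(ord)))
}

#' Write a simulated run as an ABIF fixture plus manifest
#'
#' Rounds the channels to integers (ABIF stores integer fluorescence
#' counts) and emits the manifest JSON alongside.
#'
#' @param run result of [simulate_run()].
#' @param path output `.fsa` path; the manifest goes to
#'   `paste0(path, ".manifest.json")`.
#' @param glycan_tag,ladder_tag tag specs to write the channels under.
#' @return `path`, invisibly.
#' @export
write_run_abif <- function(run, path, glycan_tag = "DATA,1",
                           ladder_tag = "DATA,105") {
  channels <- stats::setNames(
    list(as.integer(round(run$glycan$values)),
         as.integer(round(run$ladder$values))),
    c(glycan_tag, ladder_tag))
  write_abif(channels, path)
  jsonlite::write_json(run$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
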