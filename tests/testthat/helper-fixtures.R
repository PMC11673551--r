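# Shared fixture builders. Everything is generated in code; no binary
# fixtures ship with the package.

# uniform nt grid over the glycomic region
nt_grid <- function(region = c(150, 350), step = 0.05)
  seq(region[1], region[2], by = step)

# noiseless sum-of-Gaussians spectrum, stage selectable
gauss_spec <- function(centers, heights, sigmas,
                       region = c(150, 350), step = 0.05,
                       stage = "baseline-corrected", noise_sd = 0,
                       seed = 1L) {
  grid <- nt_grid(region, step)
  y <- numeric(length(grid))
  for (k in seq_along(centers))
    y <- y + heights[k] * exp(-(grid - centers[k])^2 / (2 * sigmas[k]^2))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  spectrum(grid, y, stage = stage)
}

# brute-force topological prominence straight from the definition:
# for each strict local maximum, on each side take the minimum between
# the apex and the nearest strictly higher sample (or the signal end);
# prominence is apex height minus the larger of the two minima.
brute_force_peaks <- function(y) {
  n <- length(y)
  apexes <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) apexes <- c(apexes, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(apexes, function(a) {
    higher_left <- which(y[seq_len(a - 1L)] > y[a])
    lmin <- if (length(higher_left)) min(y[(max(higher_left)):a]) else min(y[1:a])
    right_idx <- seq(a + 1L, n)
    higher_right <- right_idx[y[right_idx] > y[a]]
    rmin <- if (length(higher_right)) min(y[a:min(higher_right)]) else min(y[a:n])
    y[a] - max(lmin, rmin)
  }, numeric(1))
  list(apexes = apexes, prominences = prom)
}

# exhaustive DTW over all monotone paths (tiny instances only)
brute_force_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc >= best) return()
    if (i == n && j == m) { best <<- acc; return() }
    if (i < n && j < m) rec(i + 1L, j + 1L, acc)
    if (i < n) rec(i + 1L, j, acc)
    if (j < m) rec(i, j + 1L, acc)
  }
  rec(1L, 1L, 0)
  best
}

# minimal ladder trace: narrow Gaussians at given scan positions
ladder_trace <- function(scans_at, n_scans = 7000, height = 1000, sigma = 4) {
  s <- seq_len(n_scans)
  y <- numeric(n_scans)
  for (mu in scans_at) y <- y + height * exp(-(s - mu)^2 / (2 * sigma^2))
  raw_trace(y, "DATA,105")
}
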