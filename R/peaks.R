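# Strict local maxima with plateau handling: a plateau counts once and its
# apex is the leftmost sample (deterministic tie-break).
.find_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Topological prominence of each apex: height above the higher of the two
# key saddles. On each side, walk to the first strictly higher sample (or
# the signal end) and take the minimum in between; prominence is the apex
# height minus the larger of the two minima.
.prominences <- function(y, apexes) {
  vapply(apexes, function(i) {
    h <- y[i]
    left <- i; lmin <- h
    while (left > 1L) {
      left <- left - 1L
      if (y[left] > h) break
      if (y[left] < lmin) lmin <- y[left]
    }
    right <- i; rmin <- h
    n <- length(y)
    while (right < n) {
      right <- right + 1L
      if (y[right] > h) break
      if (y[right] < rmin) rmin <- y[right]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# Saddle-bounded support of an apex: indices of the nearest strictly higher
# samples (or signal ends) on each side, shrunk to the interior minima.
.apex_saddles <- function(y, i) {
  n <- length(y); h <- y[i]
  l <- i
  while (l > 1L && y[l - 1L] <= h) l <- l - 1L
  r <- i
  while (r < n && y[r + 1L] <= h) r <- r + 1L
  lmin <- if (l < i) l - 1L + which.min(y[l:i]) else i
  rmin <- if (r > i) i - 1L + which.min(y[i:r]) else i
  c(left = lmin, right = rmin)
}

#' Detect peak apexes by height and prominence gating
#'
#' Local maxima of the processed spectrum whose height AND topological
#' prominence both reach `rel_threshold` of the spectrum maximum in the
#' excised region (default 1%). Plateaus report their leftmost sample.
#'
#' @param spec a `spectrum` with stage `"baseline-corrected"`.
#' @param rel_threshold fraction of the region maximum (default 0.01).
#' @return integer vector of apex indices (possibly empty).
#' @export
detect_apexes <- function(spec, rel_threshold = 0.01) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$stage != "baseline-corrected")
    stop("detect_apexes expects a baseline-corrected spectrum, got stage '",
         spec$stage, "'")
  y <- spec$intensities
  mx <- max(y)
  if (mx <= 0) return(integer(0))
  cand <- .find_local_maxima(y)
  if (length(cand) == 0L) return(integer(0))
  prom <- .prominences(y, cand)
  cand[y[cand] >= rel_threshold * mx & prom >= rel_threshold * mx]
}

#' Fit a Gaussian to one peak
#'
#' Nonlinear least squares of `A * exp(-(x - mu)^2 / (2 sigma^2))` over a
#' window bounded by the apex's saddles on each side and capped at 5
#' moment-based sigmas. On non-convergence (e.g. saturated flat-top peaks)
#' falls back to the moment-based sigma estimate and flags it.
#'
#' @param spec a `spectrum`.
#' @param apex apex index from [detect_apexes()].
#' @return list with `center_nt`, `sigma_nt`, `amplitude`, `fit_method`
#'   (`"gaussian"` or `"moments"`).
#' @export
fit_peak_shape <- function(spec, apex) {
  stopifnot(inherits(spec, "spectrum"))
  x <- spec$positions; y <- spec$intensities
  n <- length(y)
  if (apex < 1L || apex > n) stop("apex index out of range")
  step <- spectrum_step(spec)
  sad <- .apex_saddles(y, apex)
  # initial sigma from the half-width at half-maximum: local and immune to
  # the saddle support blowing up for the region's tallest peak (whose
  # prominence saddles span the whole spectrum)
  half <- y[apex] / 2
  dl <- apex - unname(sad["left"])
  if (dl > 0L) {
    below <- which(y[seq(apex - 1L, sad["left"])] < half)
    if (length(below)) dl <- below[1]
  }
  dr <- unname(sad["right"]) - apex
  if (dr > 0L) {
    below <- which(y[seq(apex + 1L, sad["right"])] < half)
    if (length(below)) dr <- below[1]
  }
  sigma0 <- max((dl + dr) / 2 * step / 1.1774, step)
  cap <- as.integer(ceiling(5 * sigma0 / step))
  l <- max(sad["left"], apex - cap)
  r <- min(sad["right"], apex + cap)
  idx <- l:r
  # moment sigma over the capped window, as the non-convergence fallback
  w <- pmax(y[idx] - min(y[idx]), 0)
  if (sum(w) > 0)
    sigma0 <- max(min(sigma0, sqrt(sum(w * (x[idx] - x[apex])^2) / sum(w))), step)
  moments <- list(center_nt = x[apex], sigma_nt = sigma0,
                  amplitude = y[apex], fit_method = "moments")
  if (length(idx) < 5L) return(moments)
  # detector saturation shows as an exact plateau at the apex; a Gaussian
  # cannot represent it, so take the flagged moment fallback directly
  if (apex < n && y[apex + 1L] == y[apex]) return(moments)
  # fit in apex-height units so the result is exactly scale-equivariant
  xx <- x[idx]; yy <- y[idx] / y[apex]
  obj <- function(p) sum((yy - p[1] * exp(-(xx - p[2])^2 / (2 * p[3]^2)))^2)
  # bounded quasi-Newton least squares: unlike nls() this converges cleanly
  # on zero-residual (noiseless) peaks
  fit <- tryCatch(
    stats::optim(c(1, x[apex], sigma0), obj, method = "L-BFGS-B",
                 lower = c(0, x[l], step / 10),
                 upper = c(Inf, x[r], (x[r] - x[l])),
                 control = list(factr = 1e4, maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0L) return(moments)
  list(center_nt = fit$par[2], sigma_nt = fit$par[3],
       amplitude = fit$par[1] * y[apex], fit_method = "gaussian")
}

#' Integrate a peak by composite Simpson's rule
#'
#' Uses the grid samples inside `[left_nt, right_nt]`. When the interval
#' count is even, Simpson's rule covers all but the last interval, which is
#' patched with a trapezoid. Fewer than 3 samples fall back to the
#' trapezoid rule (flagged via the `"method"` attribute).
#'
#' @param spec a `spectrum`.
#' @param left_nt,right_nt integration boundaries in nt.
#' @return area (numeric scalar) with attribute `method` in
#'   `{"simpson", "simpson+trapezoid", "trapezoid"}`.
#' @export
integrate_peak <- function(spec, left_nt, right_nt) {
  stopifnot(inherits(spec, "spectrum"))
  if (left_nt >= right_nt) stop("left_nt must be < right_nt")
  x <- spec$positions
  idx <- which(x >= left_nt - 1e-12 & x <= right_nt + 1e-12)
  if (length(idx) < 2L) stop("fewer than 2 samples inside the integration range")
  y <- spec$intensities[idx]
  h <- spectrum_step(spec)
  m <- length(y)
  if (m < 3L) {
    area <- h * (y[1] + y[2]) / 2
    return(structure(area, method = "trapezoid"))
  }
  n_int <- m - 1L
  if (n_int %% 2L == 0L) {
    area <- .simpson_uniform(y, h)
    structure(area, method = "simpson")
  } else {
    area <- .simpson_uniform(y[seq_len(m - 1L)], h) + h * (y[m - 1L] + y[m]) / 2
    structure(area, method = "simpson+trapezoid")
  }
}

# Composite Simpson on a uniform grid with an even number of intervals.
.simpson_uniform <- function(y, h) {
  m <- length(y)
  stopifnot(m >= 3L, (m - 1L) %% 2L == 0L)
  i <- seq(2L, m - 1L)
  coef <- ifelse(i %% 2L == 0L, 4, 2)
  h / 3 * (y[1] + sum(coef * y[i]) + y[m])
}

#' Build the quantified peak table for one spectrum
#'
#' Composes detection, Gaussian shape fitting, boundary assignment at
#' +/- 3 fitted sigmas (clipped to the region, flagged), Simpson
#' integration, and the two normalized columns: `height_mh` (height over
#' the region maximum height) and `area_ta` (area over the summed area).
#' Adjacent peaks whose boundary intervals intersect are flagged
#' (`overlap_flag`) but never deconvolved or dropped: exclusion is the
#' caller's decision.
#'
#' @param spec a `spectrum` with stage `"baseline-corrected"`.
#' @param rel_threshold detection threshold as a fraction of the region
#'   maximum (default 0.01).
#' @return object of class `peak_table`: a data.frame with columns
#'   `peak`, `apex_nt`, `height`, `prominence`, `sigma_nt`, `left_nt`,
#'   `right_nt`, `area`, `height_mh`, `area_ta`, `overlap_flag`,
#'   `fit_method`, `clipped`; attributes `sample_id`, `region`, `params`.
#' @export
build_peak_table <- function(spec, rel_threshold = 0.01) {
  stopifnot(inherits(spec, "spectrum"))
  apexes <- detect_apexes(spec, rel_threshold)
  region <- range(spec$positions)
  if (length(apexes) == 0L) {
    tab <- data.frame(peak = integer(0), apex_nt = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      sigma_nt = numeric(0), left_nt = numeric(0),
                      right_nt = numeric(0), area = numeric(0),
                      height_mh = numeric(0), area_ta = numeric(0),
                      overlap_flag = logical(0), fit_method = character(0),
                      clipped = logical(0))
    return(structure(tab, class = c("peak_table", "data.frame"),
                     sample_id = spec$sample_id, region = region,
                     params = list(rel_threshold = rel_threshold)))
  }
  y <- spec$intensities
  prom <- .prominences(y, apexes)
  fits <- lapply(apexes, function(a) fit_peak_shape(spec, a))
  apex_nt <- spec$positions[apexes]
  sigma <- vapply(fits, `[[`, numeric(1), "sigma_nt")
  left <- pmax(apex_nt - 3 * sigma, region[1])
  right <- pmin(apex_nt + 3 * sigma, region[2])
  clipped <- (apex_nt - 3 * sigma < region[1]) | (apex_nt + 3 * sigma > region[2])
  area <- mapply(function(l, r) as.numeric(integrate_peak(spec, l, r)), left, right)
  k <- length(apexes)
  overlap <- rep(FALSE, k)
  if (k > 1L) {
    hit <- right[-k] > left[-1L]
    overlap[-k] <- overlap[-k] | hit
    overlap[-1L] <- overlap[-1L] | hit
  }
  tab <- data.frame(
    peak = seq_len(k) - 1L,  # 0-based ids, matching electropherogram convention
    apex_nt = apex_nt,
    height = y[apexes],
    prominence = prom,
    sigma_nt = sigma,
    left_nt = left,
    right_nt = right,
    area = area,
    height_mh = y[apexes] / max(y),
    area_ta = area / sum(area),
    overlap_flag = overlap,
    fit_method = vapply(fits, `[[`, character(1), "fit_method"),
    clipped = clipped)
  structure(tab, class = c("peak_table", "data.frame"),
            sample_id = spec$sample_id, region = region,
            params = list(rel_threshold = rel_threshold))
}

#' @export
print.peak_table <- function(x, ...) {
  sid <- attr(x, "sample_id")
  cat("<peak_table> ", nrow(x), " peaks",
      if (isTRUE(nzchar(sid))) paste0(", sample ", sid),
      ", region [", paste(attr(x, "region"), collapse = ", "), "] nt\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a peak table as TSV
#' @param tab a `peak_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_table_tsv <- function(tab, path) {
  stopifnot(inherits(tab, "peak_table"))
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a peak table as JSON (with provenance)
#' @param tab a `peak_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_table_json <- function(tab, path) {
  stopifnot(inherits(tab, "peak_table"))
  jsonlite::write_json(
    list(sample_id = attr(tab, "sample_id"),
         region = attr(tab, "region"),
         params = attr(tab, "params"),
         peaks = as.data.frame(tab)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a peak table from TSV
#' @param path file path.
#' @param sample_id sample identifier.
#' @param region region attribute `(start, end)` nt.
#' @return a `peak_table`.
#' @export
read_peak_table_tsv <- function(path, sample_id = "", region = c(150, 350)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("peak_table", "data.frame"),
            sample_id = sample_id, region = region, params = list())
}
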