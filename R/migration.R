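#' Size-standard (ladder) definition
#'
#' @param fragment_sizes strictly ascending nucleotide lengths of the
#'   co-injected standard's fragments; at least 4.
#' @param name free-text label.
#' @return object of class `ladder_definition`.
#' @export
ladder_definition <- function(fragment_sizes, name = "custom") {
  fragment_sizes <- as.numeric(fragment_sizes)
  if (length(fragment_sizes) < 4L) stop("a ladder needs at least 4 fragments")
  if (any(diff(fragment_sizes) <= 0)) stop("fragment sizes must be strictly ascending")
  structure(list(fragment_sizes = fragment_sizes, name = name),
            class = "ladder_definition")
}

#' GeneScan-500 LIZ ladder
#'
#' The conventional fragment sizes of the LIZ500 standard. Only the
#' fragments bracketing the glycomic region are strictly required for
#' calibration; the full set is the default.
#' @return a `ladder_definition` with 16 fragments, 35-500 nt.
#' @export
liz500_ladder <- function() {
  ladder_definition(c(35, 50, 75, 100, 139, 150, 160, 200, 250,
                      300, 340, 350, 400, 450, 490, 500), "LIZ500")
}

#' Detect size-standard apexes in a ladder trace
#'
#' Finds local maxima with height and topological prominence of at least
#' `rel_threshold` of the trace maximum, then requires the expected fragment
#' count to stand out unambiguously among the top-prominence candidates.
#' Ambiguity is an error, never a guess: a mis-called ladder would corrupt
#' every downstream position.
#'
#' @param ladder a `raw_trace` of the size-standard channel.
#' @param expected a `ladder_definition`.
#' Candidates closer than `min_sep` scans are merged (tallest kept,
#' leftmost on ties): integer-quantized traces can split one fragment's
#' apex into equal-height twin maxima, and ladder fragments are never
#' that close under any realistic migration law.
#'
#' @param rel_threshold fraction of the ladder maximum (default 0.10).
#' @param min_sep minimum apex separation in scans (default 20).
#' @return integer scan indices, one apex per expected fragment, ascending.
#' @export
call_ladder_peaks <- function(ladder, expected, rel_threshold = 0.10,
                              min_sep = 20L) {
  stopifnot(inherits(ladder, "raw_trace"), inherits(expected, "ladder_definition"))
  n_frag <- length(expected$fragment_sizes)
  y <- ladder$values
  if (length(y) <= 10L * n_frag)
    stop("ladder trace too short (", length(y), " scans) for ", n_frag, " fragments")
  cand <- .find_local_maxima(y)
  if (length(cand) == 0L)
    stop("ladder calibration failure: no local maxima found (flat trace?)")
  prom <- .prominences(y, cand)
  keep <- y[cand] >= rel_threshold * max(y) & prom >= rel_threshold * max(y)
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) > 1L) {
    merged_c <- integer(0); merged_p <- numeric(0)
    for (k in seq_along(cand)) {
      if (length(merged_c) && cand[k] - merged_c[length(merged_c)] < min_sep) {
        if (y[cand[k]] > y[merged_c[length(merged_c)]]) {
          merged_c[length(merged_c)] <- cand[k]
          merged_p[length(merged_p)] <- prom[k]
        }
      } else {
        merged_c <- c(merged_c, cand[k]); merged_p <- c(merged_p, prom[k])
      }
    }
    cand <- merged_c; prom <- merged_p
  }
  if (length(cand) < n_frag)
    stop("ladder calibration failure: found ", length(cand),
         " candidate apexes for ", n_frag, " expected fragments")
  if (length(cand) > n_frag) {
    ord <- order(prom, decreasing = TRUE)
    if (prom[ord[n_frag]] < 2 * prom[ord[n_frag + 1L]])
      stop("ladder calibration failure: ambiguous apex selection (",
           length(cand), " candidates for ", n_frag,
           " fragments with no clear prominence separation)")
    cand <- sort(cand[ord[seq_len(n_frag)]])
  }
  cand
}

#' Fit a monotone scan-to-nucleotide migration map
#'
#' Pairs each called ladder apex with its fragment size and interpolates a
#' strictly monotone mapping from scan index to nucleotide coordinate.
#' `"monotone"` uses a Fritsch-Carlson monotone piecewise cubic (local
#' sizing, the fragment-analysis convention); `"linear"` is piecewise
#' linear for degenerate ladders.
#'
#' @param apexes ascending scan indices from [call_ladder_peaks()].
#' @param expected the matching `ladder_definition`.
#' @param method interpolant kind.
#' @return object of class `migration_map` with `knots` (data.frame
#'   `scan`, `nt`), `kind`, `residuals` (per-knot, nt) and the forward
#'   interpolant.
#' @export
fit_migration_map <- function(apexes, expected,
                              method = c("monotone", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(expected, "ladder_definition"))
  sizes <- expected$fragment_sizes
  if (length(apexes) != length(sizes))
    stop("apex count (", length(apexes), ") != fragment count (", length(sizes), ")")
  if (length(apexes) < 4L) stop("need at least 4 knots to fit a migration map")
  if (any(diff(apexes) <= 0)) stop("apex scan indices must be strictly ascending")
  fwd <- if (method == "monotone") {
    stats::splinefun(apexes, sizes, method = "monoH.FC")
  } else {
    stats::approxfun(apexes, sizes, rule = 1)
  }
  grid <- seq(min(apexes), max(apexes), length.out = 2048L)
  if (any(diff(fwd(grid)) <= 0))
    stop("fitted migration map is not strictly monotone; ladder apexes are",
         " likely mis-called")
  residuals <- fwd(apexes) - sizes  # zero for interpolants, reported anyway
  structure(list(knots = data.frame(scan = apexes, nt = sizes),
                 kind = method, residuals = residuals, fun = fwd),
            class = "migration_map")
}

#' @export
print.migration_map <- function(x, ...) {
  cat("<migration_map> ", nrow(x$knots), " knots (", x$kind, "), ",
      min(x$knots$nt), "-", max(x$knots$nt), " nt, max |residual| ",
      format(max(abs(x$residuals)), digits = 3), " nt\n", sep = "")
  invisible(x)
}

#' Evaluate a migration map at scan indices
#' @param map a `migration_map`.
#' @param scans scan indices.
#' @return nucleotide coordinates.
#' @export
map_scan_to_nt <- function(map, scans) {
  stopifnot(inherits(map, "migration_map"))
  map$fun(scans)
}

#' Construct a spectrum on the nucleotide axis
#'
#' Low-level constructor; most users obtain spectra from
#' [to_nucleotide_axis()].
#'
#' @param positions ascending, uniformly spaced nucleotide coordinates.
#' @param intensities matching signal values.
#' @param stage processing stage label.
#' @param sample_id sample identifier.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(positions, intensities,
                     stage = c("normalized", "smoothed", "baseline-corrected"),
                     sample_id = "") {
  stage <- match.arg(stage)
  positions <- as.numeric(positions); intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities)) stop("positions/intensities length mismatch")
  if (length(positions) < 2L) stop("a spectrum needs at least 2 samples")
  d <- diff(positions)
  if (any(d <= 0)) stop("positions must be strictly ascending")
  if (diff(range(d)) > 1e-9 * mean(d)) stop("positions must be uniformly spaced")
  if (any(!is.finite(intensities))) stop("non-finite intensities")
  structure(list(positions = positions, intensities = intensities,
                 stage = stage, sample_id = sample_id),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", length(x$positions), " points, ",
      format(min(x$positions)), "-", format(max(x$positions)), " nt, stage ",
      x$stage, if (nzchar(x$sample_id)) paste0(", sample ", x$sample_id),
      "\n", sep = "")
  invisible(x)
}

#' Spectrum sampling step (nt)
#' @param spec a `spectrum`.
#' @return scalar nt spacing.
#' @export
spectrum_step <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  (max(spec$positions) - min(spec$positions)) / (length(spec$positions) - 1L)
}

#' Resample a glycan trace onto the nucleotide axis and excise a region
#'
#' Converts every scan index to its nucleotide coordinate through the
#' migration map, then interpolates the intensities onto a uniform grid
#' over `region`. The default region is the 150-350 nt glycomic window.
#'
#' @param glycan a `raw_trace` of the glycan channel.
#' @param map a `migration_map` fitted on the co-migrating ladder channel.
#' @param region closed interval `(start, end)` in nt.
#' @param step grid spacing in nt (default 0.05).
#' @return a `spectrum` with stage `"normalized"`.
#' @export
to_nucleotide_axis <- function(glycan, map, region = c(150, 350), step = 0.05) {
  stopifnot(inherits(glycan, "raw_trace"), inherits(map, "migration_map"))
  if (length(region) != 2L || region[1] >= region[2]) stop("invalid region")
  span <- range(map$knots$nt)
  if (region[1] < span[1] || region[2] > span[2])
    stop("region [", region[1], ", ", region[2], "] nt lies outside the ",
         "calibrated ladder span [", span[1], ", ", span[2],
         "] nt; refusing to extrapolate")
  scans <- seq_along(glycan$values)
  nt_at_scan <- map$fun(scans)
  grid <- seq(region[1], region[2], by = step)
  inten <- stats::approx(nt_at_scan, glycan$values, xout = grid, rule = 1)$y
  if (any(is.na(inten)))
    stop("glycan trace does not cover the requested region on the nt axis")
  spectrum(grid, inten, stage = "normalized", sample_id = glycan$sample_id)
}

#' Serialize a migration map to JSON
#' @param map a `migration_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_migration_map_json <- function(map, path) {
  stopifnot(inherits(map, "migration_map"))
  jsonlite::write_json(
    list(kind = map$kind,
         knots = map$knots,
         residuals = map$residuals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a spectrum as TSV (position, intensity)
#' @param spec a `spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.table(
    data.frame(position = spec$positions, intensity = spec$intensities),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from TSV
#' @param path file path.
#' @param stage processing stage label of the stored spectrum.
#' @param sample_id sample identifier.
#' @return a `spectrum`.
#' @export
read_spectrum_tsv <- function(path, stage = "baseline-corrected", sample_id = "") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  spectrum(df$position, df$intensity, stage = stage, sample_id = sample_id)
}
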