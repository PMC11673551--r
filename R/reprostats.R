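#' Bundle technical replicates for reproducibility analysis
#'
#' @param spectra list of >= 2 `spectrum` objects on identical nucleotide
#'   grids (same region, same step), processed identically.
#' @param peak_tables optional matching list of `peak_table`s; computed
#'   from the spectra when omitted (needed for the CV statistics).
#' @param sample_id biological-sample identifier.
#' @return object of class `replicate_set`.
#' @export
replicate_set <- function(spectra, peak_tables = NULL, sample_id = "") {
  if (!is.list(spectra) || length(spectra) < 2L)
    stop("a replicate set needs at least 2 spectra")
  lapply(spectra, function(s) stopifnot(inherits(s, "spectrum")))
  ref <- spectra[[1]]$positions
  for (s in spectra[-1])
    if (length(s$positions) != length(ref) || max(abs(s$positions - ref)) > 1e-9)
      stop("replicate spectra must share an identical nucleotide grid")
  stages <- unique(vapply(spectra, `[[`, character(1), "stage"))
  if (length(stages) > 1L)
    stop("replicate spectra have mixed processing stages: ",
         paste(stages, collapse = ", "))
  if (!is.null(peak_tables)) {
    if (length(peak_tables) != length(spectra))
      stop("peak_tables must match spectra one-to-one")
    lapply(peak_tables, function(t) stopifnot(inherits(t, "peak_table")))
  }
  structure(list(spectra = spectra, peak_tables = peak_tables,
                 sample_id = sample_id),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("<replicate_set> ", length(x$spectra), " replicates",
      if (nzchar(x$sample_id)) paste0(", sample ", x$sample_id),
      ", ", length(x$spectra[[1]]$positions), " points each\n", sep = "")
  invisible(x)
}

#' Average pairwise Pearson correlation across replicates
#'
#' Mean over all unordered replicate pairs of the Pearson correlation of
#' the intensity vectors; with `normalized = TRUE` each spectrum is
#' divided by its maximum first (the correlation itself is unaffected by
#' positive scaling, but the flag mirrors the reported raw/MH-normalized
#' pair of statistics).
#'
#' @param set a `replicate_set`.
#' @param normalized max-height normalize each spectrum first.
#' @return average Pearson rho (scalar).
#' @export
pairwise_pearson <- function(set, normalized = FALSE) {
  stopifnot(inherits(set, "replicate_set"))
  mats <- lapply(set$spectra, function(s) {
    v <- s$intensities
    if (stats::sd(v) == 0)
      stop("zero-variance spectrum in replicate '", s$sample_id,
           "': Pearson correlation undefined")
    if (normalized) {
      if (max(v) <= 0) stop("cannot max-normalize a non-positive spectrum")
      v <- v / max(v)
    }
    v
  })
  n <- length(mats)
  rhos <- c()
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      rhos <- c(rhos, stats::cor(mats[[i]], mats[[j]]))
  mean(rhos)
}

# integer lag in [-max_lag, max_lag] maximizing the cross-correlation of
# mean-centered, max-normalized u and v; positive = v delayed relative to u
.xcorr_lag <- function(u, v, max_lag) {
  u <- u / max(abs(u)); v <- v / max(abs(v))
  u <- u - mean(u); v <- v - mean(v)
  n <- length(u)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(u[seq_len(n - k)] * v[seq_len(n - k) + k])
    else sum(u[seq_len(n + k) - k] * v[seq_len(n + k)])
  }, numeric(1))
  lags[which.max(cc)]
}

#' Median lag of maximum cross-correlation across replicate pairs
#'
#' For every unordered pair, the integer lag (in measurement points)
#' maximizing the cross-correlation of the mean-centered, max-normalized
#' spectra; the median over all pairs is returned. Sign convention:
#' positive means the second replicate of the pair is delayed relative to
#' the first.
#'
#' @param set a `replicate_set`.
#' @param max_lag search half width in points (default 10% of length).
#' @return median lag (may be half-integer for an even pair count).
#' @export
median_xcorr_lag <- function(set, max_lag = NULL) {
  stopifnot(inherits(set, "replicate_set"))
  n_pts <- length(set$spectra[[1]]$positions)
  if (is.null(max_lag)) max_lag <- max(1L, floor(n_pts / 10))
  n <- length(set$spectra)
  lags <- c()
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      lags <- c(lags, .xcorr_lag(set$spectra[[i]]$intensities,
                                 set$spectra[[j]]$intensities, max_lag))
  stats::median(lags)
}

# pairwise lags of each replicate against replicate 1, in points
.replicate_lags <- function(set, max_lag = NULL) {
  n_pts <- length(set$spectra[[1]]$positions)
  if (is.null(max_lag)) max_lag <- max(1L, floor(n_pts / 10))
  vapply(seq_along(set$spectra), function(j) {
    if (j == 1L) return(0L)
    as.integer(.xcorr_lag(set$spectra[[1]]$intensities,
                          set$spectra[[j]]$intensities, max_lag))
  }, integer(1))
}

#' Per-peak coefficient of variation across replicates
#'
#' Peaks are grouped across replicates by apex proximity after per-replicate
#' lag correction (each replicate's apex positions are shifted back by its
#' cross-correlation lag against the first replicate, then matched greedily
#' within `tol_nt`). For every group present in all replicates, CV =
#' SD/mean of the chosen normalized quantity; the median over groups is the
#' headline statistic. Incomplete groups are reported separately and never
#' enter the median.
#'
#' @param set a `replicate_set` with peak tables (computed on the fly from
#'   the spectra when absent).
#' @param quantity `"area_ta"` (total-area-normalized areas) or
#'   `"height_mh"` (max-height-normalized heights).
#' @param tol_nt matching tolerance in nt (default 1).
#' @return list with `median_cv`, `per_peak` (data.frame `apex_nt`, `cv`,
#'   `n_replicates`), and `incomplete` (same shape, groups missing from
#'   some replicate).
#' @export
peak_cv <- function(set, quantity = c("area_ta", "height_mh"), tol_nt = 1) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(set, "replicate_set"))
  tables <- set$peak_tables
  if (is.null(tables))
    tables <- lapply(set$spectra, build_peak_table)
  step <- spectrum_step(set$spectra[[1]])
  lags <- .replicate_lags(set)
  n_rep <- length(tables)
  # anchor on replicate 1; lag-correct other replicates' apex positions
  anchors <- tables[[1]]$apex_nt
  if (length(anchors) == 0L) stop("no peaks in replicate 1; nothing to match")
  groups <- vector("list", length(anchors))
  for (g in seq_along(anchors)) groups[[g]] <- rep(NA_real_, n_rep)
  used <- lapply(tables, function(t) rep(FALSE, nrow(t)))
  for (g in seq_along(anchors)) {
    groups[[g]][1] <- tables[[1]][[quantity]][g]
    used[[1]][g] <- TRUE
    for (r in seq(2L, n_rep)) {
      pos <- tables[[r]]$apex_nt - lags[r] * step
      d <- abs(pos - anchors[g])
      d[used[[r]]] <- Inf
      k <- which.min(d)
      if (length(k) && is.finite(d[k]) && d[k] <= tol_nt) {
        groups[[g]][r] <- tables[[r]][[quantity]][k]
        used[[r]][k] <- TRUE
      }
    }
  }
  cv_of <- function(v) stats::sd(v) / mean(v)
  complete <- vapply(groups, function(v) !anyNA(v), logical(1))
  if (!any(complete)) stop("no peak group matched across all replicates")
  per_peak <- data.frame(
    apex_nt = anchors[complete],
    cv = vapply(groups[complete], cv_of, numeric(1)),
    n_replicates = n_rep)
  incomplete <- data.frame(
    apex_nt = anchors[!complete],
    cv = vapply(groups[!complete], function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2L) cv_of(v) else NA_real_
    }, numeric(1)),
    n_replicates = vapply(groups[!complete], function(v) sum(!is.na(v)), numeric(1)))
  list(median_cv = stats::median(per_peak$cv), per_peak = per_peak,
       incomplete = incomplete)
}

#' Build the full reproducibility report for one replicate set
#'
#' Composes the pairwise Pearson correlations (raw and max-height
#' normalized), the median lag of maximum cross-correlation, and the
#' median per-peak CVs of total-area-normalized areas and
#' max-height-normalized heights.
#'
#' @param set a `replicate_set`.
#' @return object of class `repro_report`: list with `sample_id`,
#'   `pearson_raw`, `pearson_mh`, `median_lag`, `cv_area_ta`,
#'   `cv_height_mh`, plus the two per-peak CV tables.
#' @export
build_report <- function(set) {
  stopifnot(inherits(set, "replicate_set"))
  cv_a <- peak_cv(set, "area_ta")
  cv_h <- peak_cv(set, "height_mh")
  structure(list(sample_id = set$sample_id,
                 pearson_raw = pairwise_pearson(set, normalized = FALSE),
                 pearson_mh = pairwise_pearson(set, normalized = TRUE),
                 median_lag = median_xcorr_lag(set),
                 cv_area_ta = cv_a$median_cv,
                 cv_height_mh = cv_h$median_cv,
                 per_peak_area = cv_a$per_peak,
                 per_peak_height = cv_h$per_peak),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("<repro_report>",
      if (nzchar(x$sample_id)) paste0(" sample ", x$sample_id), "\n",
      "  Pearson rho (raw):           ", format(x$pearson_raw, digits = 4), "\n",
      "  Pearson rho (MH-normalized): ", format(x$pearson_mh, digits = 4), "\n",
      "  median lag of max xcorr:     ", format(x$median_lag), " points\n",
      "  median CV, TA-norm. areas:   ", format(x$cv_area_ta, digits = 4), "\n",
      "  median CV, MH-norm. heights: ", format(x$cv_height_mh, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Write one or more reproducibility reports as TSV
#'
#' Columns: `sample`, `pearson_raw`, `pearson_mh`, `median_lag`,
#' `cv_area_ta`, `cv_height_mh`.
#'
#' @param reports a `repro_report` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(reports, path) {
  if (inherits(reports, "repro_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(sample = r$sample_id, pearson_raw = r$pearson_raw,
               pearson_mh = r$pearson_mh, median_lag = r$median_lag,
               cv_area_ta = r$cv_area_ta, cv_height_mh = r$cv_height_mh)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-peak CV values as TSV
#' @param cv result of [peak_cv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_cv_tsv <- function(cv, path) {
  utils::write.table(cv$per_peak, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
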