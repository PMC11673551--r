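#' Align two spectra by dynamic time warping
#'
#' Monotone elastic alignment minimizing the accumulated absolute intensity
#' difference, with a Sakoe-Chiba band bounding the warp. Both spectra are
#' max-height normalized before alignment (amplitude differences would
#' otherwise dominate the warping), unless `normalize = FALSE`.
#'
#' @param sample,reference `spectrum` objects on nucleotide axes.
#' @param band_nt Sakoe-Chiba half width in nt (default 10); converted to
#'   samples with the sample spectrum's step. The band is widened
#'   automatically if the two lengths differ by more than it.
#' @param normalize divide each spectrum by its maximum first (default TRUE).
#' @return object of class `dtw_alignment`: list with `path` (two-column
#'   integer matrix of 1-based index pairs, monotone, from `(1,1)` to
#'   `(n,m)`) and `distance`.
#' @export
dtw_align <- function(sample, reference, band_nt = 10, normalize = TRUE) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  x <- sample$intensities; y <- reference$intensities
  if (length(x) < 2L || length(y) < 2L) stop("dtw_align needs >= 2 points per spectrum")
  if (normalize) {
    if (max(x) <= 0 || max(y) <= 0) stop("cannot max-normalize a non-positive spectrum")
    x <- x / max(x); y <- y / max(y)
  }
  window <- as.integer(ceiling(band_nt / spectrum_step(sample)))
  res <- .dtw_core(x, y, window)
  structure(list(path = res$path, distance = res$distance,
                 band_nt = band_nt, normalized = normalize),
            class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat("<dtw_alignment> ", nrow(x$path), " path steps, distance ",
      format(x$distance, digits = 6), ", band +/-", x$band_nt, " nt\n", sep = "")
  invisible(x)
}

#' Construct a reference peak list
#'
#' @param ref_id unique integer identifiers.
#' @param apex_nt apex positions on the reference's nucleotide axis
#'   (`NA` allowed for pure structure catalogs that are only used for
#'   annotation transfer, not DTW matching).
#' @param structures list of character vectors of glycan structures in
#'   Oxford notation; one signal may carry several.
#' @return object of class `reference_peaks` (a data.frame with a
#'   list-column `structures`).
#' @export
reference_peaks <- function(ref_id, apex_nt = NA_real_, structures = list()) {
  ref_id <- as.integer(ref_id)
  if (anyDuplicated(ref_id)) stop("ref_id values must be unique")
  if (length(structures) == 0L) structures <- rep(list(character(0)), length(ref_id))
  stopifnot(length(structures) == length(ref_id))
  df <- data.frame(ref_id = ref_id, apex_nt = as.numeric(apex_nt))
  df$structures <- lapply(structures, as.character)
  structure(df, class = c("reference_peaks", "data.frame"))
}

#' Read a reference peak list from JSON
#'
#' Expected format: a JSON array of objects with fields `ref_id`,
#' `apex_nt` (may be null) and `structures` (array of strings).
#'
#' @param path file path.
#' @return a `reference_peaks` object.
#' @export
read_reference_peaks <- function(path) {
  js <- jsonlite::read_json(path)
  reference_peaks(
    ref_id = vapply(js, function(e) as.integer(e$ref_id), integer(1)),
    apex_nt = vapply(js, function(e) if (is.null(e$apex_nt)) NA_real_ else as.numeric(e$apex_nt), numeric(1)),
    structures = lapply(js, function(e) unlist(e$structures, use.names = FALSE)))
}

#' Packaged plasma N-glycome reference structure catalog
#'
#' Structural annotations in Oxford notation for the reference
#' electropherogram's peak identifiers, as used for annotation transfer.
#' Apex positions are not part of the catalog (the reference spectrum must
#' be supplied by the user for DTW matching).
#' @return a `reference_peaks` object.
#' @export
glycge_reference_structures <- function() {
  read_reference_peaks(system.file("extdata", "reference_structures.json",
                                   package = "glycge", mustWork = TRUE))
}

#' Packaged manual-override list
#'
#' Demonstrates the visual-inspection override mechanism: artifact peaks
#' annotated as unmatched, overlap-artifact exclusions, and matches
#' established visually rather than by the warping path.
#' @return list of overrides as consumed by [transfer_annotations()].
#' @export
glycge_manual_overrides <- function() {
  read_overrides(system.file("extdata", "manual_overrides.json",
                             package = "glycge", mustWork = TRUE))
}

# half-prominence span of an apex (contiguous indices around it with
# intensity >= height - prominence/2)
.half_prom_span <- function(y, i) {
  thr <- y[i] - .prominences(y, i) / 2
  l <- i
  while (l > 1L && y[l - 1L] >= thr && y[l - 1L] <= y[i]) l <- l - 1L
  r <- i; n <- length(y)
  while (r < n && y[r + 1L] >= thr && y[r + 1L] <= y[i]) r <- r + 1L
  c(l, r)
}

#' Establish peak correspondences from a warping path
#'
#' A sample peak matches a reference peak when the optimal warping path
#' connects them. Two interpretations of "connects" are implemented:
#' `"apex"` (default) requires a path pair within +/- 1 sample of both
#' apexes; `"span"` requires a path pair inside both peaks'
#' half-prominence spans. When one sample peak connects to several
#' reference peaks, the pair whose apexes are closest along the path is
#' primary and the others are reported as secondary.
#'
#' @param alignment a `dtw_alignment` from [dtw_align()] over the same axes.
#' @param sample_peaks a `peak_table` for the sample spectrum.
#' @param ref_peaks a `reference_peaks` with non-`NA` `apex_nt`.
#' @param sample_spectrum,ref_spectrum the spectra that were aligned.
#' @param rule `"apex"` or `"span"`.
#' @return object of class `match_table`: list with `pairs` (data.frame
#'   `sample_peak`, `ref_id`, `match_mode`, `primary`), `unmatched_sample`,
#'   `unmatched_ref`, `dtw_distance`, `rule`.
#' @export
match_peaks <- function(alignment, sample_peaks, ref_peaks,
                        sample_spectrum, ref_spectrum,
                        rule = c("apex", "span")) {
  rule <- match.arg(rule)
  stopifnot(inherits(alignment, "dtw_alignment"),
            inherits(sample_peaks, "peak_table"),
            inherits(ref_peaks, "reference_peaks"),
            inherits(sample_spectrum, "spectrum"),
            inherits(ref_spectrum, "spectrum"))
  if (any(is.na(ref_peaks$apex_nt)))
    stop("ref_peaks has NA apex positions; DTW matching needs a located reference peak list")
  path <- alignment$path
  nearest_idx <- function(spec, nt)
    vapply(nt, function(p) which.min(abs(spec$positions - p)), integer(1))
  s_apex <- nearest_idx(sample_spectrum, sample_peaks$apex_nt)
  r_apex <- nearest_idx(ref_spectrum, ref_peaks$apex_nt)
  if (rule == "apex") {
    s_lo <- s_apex - 1L; s_hi <- s_apex + 1L
    r_lo <- r_apex - 1L; r_hi <- r_apex + 1L
  } else {
    s_span <- vapply(s_apex, function(i) .half_prom_span(sample_spectrum$intensities, i), integer(2))
    r_span <- vapply(r_apex, function(i) .half_prom_span(ref_spectrum$intensities, i), integer(2))
    s_lo <- s_span[1, ]; s_hi <- s_span[2, ]
    r_lo <- r_span[1, ]; r_hi <- r_span[2, ]
  }
  pairs <- list()
  for (s in seq_along(s_apex)) {
    on_s <- path[, 1] >= s_lo[s] & path[, 1] <= s_hi[s]
    if (!any(on_s)) next
    cand <- integer(0); score <- numeric(0)
    for (r in seq_along(r_apex)) {
      hit <- on_s & path[, 2] >= r_lo[r] & path[, 2] <= r_hi[r]
      if (any(hit)) {
        cand <- c(cand, r)
        score <- c(score, min(abs(path[hit, 1] - s_apex[s]) +
                              abs(path[hit, 2] - r_apex[r])))
      }
    }
    if (length(cand) == 0L) next
    best <- cand[which.min(score)]
    pairs[[length(pairs) + 1L]] <- data.frame(
      sample_peak = sample_peaks$peak[s],
      ref_id = ref_peaks$ref_id[cand],
      match_mode = "dtw",
      primary = cand == best)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(sample_peak = integer(0), ref_id = integer(0),
               match_mode = character(0), primary = logical(0))
  matched_s <- unique(pairs$sample_peak[pairs$primary])
  matched_r <- unique(pairs$ref_id[pairs$primary])
  structure(list(pairs = pairs,
                 unmatched_sample = setdiff(sample_peaks$peak, matched_s),
                 unmatched_ref = setdiff(ref_peaks$ref_id, matched_r),
                 dtw_distance = alignment$distance,
                 rule = rule),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat("<match_table> ", sum(x$pairs$primary), " primary matches (rule ",
      x$rule, "), ", length(x$unmatched_sample), " unmatched sample peaks, ",
      length(x$unmatched_ref), " unmatched reference peaks, DTW distance ",
      format(x$dtw_distance, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Read a manual-override list from JSON
#'
#' Format: JSON array of objects with `sample_peak` and `ref_id` (an
#' integer, an array of integers, or null to force "unannotated"); an
#' optional free-text `note` is carried through.
#'
#' @param path file path.
#' @return list of overrides.
#' @export
read_overrides <- function(path) {
  js <- jsonlite::read_json(path)
  lapply(js, function(e) list(
    sample_peak = as.integer(e$sample_peak),
    ref_id = if (is.null(e$ref_id)) NA_integer_ else as.integer(unlist(e$ref_id)),
    note = if (is.null(e$note)) "" else as.character(e$note)))
}

#' Transfer structural annotations onto a sample peak table
#'
#' Matched sample peaks receive the reference identifiers and Oxford
#' structures of their primary DTW matches; manual overrides (visual
#' matching) are applied last and recorded with `match_mode = "manual"`.
#' Unmatched peaks carry `NA`.
#'
#' @param match a `match_table` built against `ref_table`, or `NULL` when
#'   annotating from overrides alone.
#' @param ref_table a `reference_peaks` providing the structures.
#' @param sample_peaks the sample `peak_table`.
#' @param overrides optional list from [read_overrides()].
#' @return the `peak_table` with columns `ref_id` (comma-joined ids or
#'   `NA`), `structures` (semicolon-joined Oxford strings or `NA`) and
#'   `match_mode` appended.
#' @export
transfer_annotations <- function(match, ref_table, sample_peaks,
                                 overrides = NULL) {
  stopifnot(inherits(ref_table, "reference_peaks"),
            inherits(sample_peaks, "peak_table"))
  out <- sample_peaks
  out$ref_id <- NA_character_
  out$structures <- NA_character_
  out$match_mode <- NA_character_
  lookup <- function(ids) {
    hit <- match(ids, ref_table$ref_id)
    if (anyNA(hit)) stop("unknown ref_id: ",
                         paste(ids[is.na(hit)], collapse = ", "))
    s <- unlist(ref_table$structures[hit], use.names = FALSE)
    paste(s, collapse = ";")
  }
  if (!is.null(match)) {
    stopifnot(inherits(match, "match_table"))
    prim <- match$pairs[match$pairs$primary, , drop = FALSE]
    for (k in seq_len(nrow(prim))) {
      i <- which(out$peak == prim$sample_peak[k])
      out$ref_id[i] <- as.character(prim$ref_id[k])
      out$structures[i] <- lookup(prim$ref_id[k])
      out$match_mode[i] <- "dtw"
    }
  }
  for (ov in overrides) {
    i <- which(out$peak == ov$sample_peak)
    if (length(i) == 0L) next  # override for a peak absent from this sample
    if (length(ov$ref_id) == 1L && is.na(ov$ref_id)) {
      out$ref_id[i] <- NA_character_
      out$structures[i] <- NA_character_
      out$match_mode[i] <- "manual"
    } else {
      out$ref_id[i] <- paste(ov$ref_id, collapse = ",")
      out$structures[i] <- lookup(ov$ref_id)
      out$match_mode[i] <- "manual"
    }
  }
  out
}
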