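## Quantification of the angiogram: vessel mask, axial band location,
## ISV counting along a dorsal scan line, and control variability.

#' Binarize an angiogram into a vessel mask
#'
#' A pixel belongs to the vessel mask when motion was detected in at least
#' `min_frames` frames (default 2: a pixel moving in a single frame of 20
#' is treated as noise).  Connected components smaller than
#' `min_component_px` pixels (8-connectivity) are removed.
#'
#' @param angiogram an [build_angiogram()] result.
#' @param min_frames minimum per-pixel motion count (1..n_frames).
#' @param min_component_px minimum component area kept, in pixels.
#' @return an object of class `vessel_mask`.
#' @export
binarize_angiogram <- function(angiogram, min_frames = 2,
                               min_component_px = 20) {
  stopifnot(inherits(angiogram, "angiogram"))
  if (min_frames < 1 || min_frames > angiogram$n_frames)
    stopf("`min_frames` must be in 1..n_frames")
  mask <- angiogram$counts >= min_frames
  if (min_component_px > 1 && any(mask)) {
    lab <- .label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_component_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  structure(list(mask = mask, min_frames_per_pixel = min_frames,
                 min_component_px = min_component_px),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %d vessel pixels (count >= %d)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$min_frames_per_pixel))
  invisible(x)
}

#' Locate the axial (artery/vein) band of a vessel mask
#'
#' Finds the rows of the two dominant horizontal flow channels — the
#' dorsal aorta / caudal artery and the posterior cardinal / caudal vein —
#' as the two highest maxima of the row-wise mask occupancy profile,
#' separated by at least `min_gap` rows.  Lack of two such channels
#' indicates absent circulation and raises a classed error carrying the
#' qc flag `"no axial flow detected"`.
#'
#' @param mask a [binarize_angiogram()] result.
#' @param min_gap minimum row separation between the two channels.
#' @param min_occupancy minimum fraction of the image width a channel row
#'   must occupy.
#' @return integer vector `c(row_top, row_bottom)`.
#' @export
locate_axial_band <- function(mask, min_gap = 20, min_occupancy = 0.3) {
  stopifnot(inherits(mask, "vessel_mask"))
  occ <- rowMeans(mask$mask)
  if (all(occ == 0) || max(occ) < min_occupancy)
    stopf("no axial flow detected", class = "axial_flow_error")
  ## a channel appears as a plateau in the occupancy profile (its blur
  ## spreads over several rows); report the half-max plateau center
  peak <- function(o, r) {
    thr <- 0.5 * o[r]
    lo <- r; while (lo > 1 && o[lo - 1] >= thr) lo <- lo - 1
    hi <- r; while (hi < length(o) && o[hi + 1] >= thr) hi <- hi + 1
    c(center = as.integer(round((lo + hi) / 2)), lo = lo, hi = hi)
  }
  p1 <- peak(occ, which.max(occ))
  occ2 <- occ
  occ2[max(1, p1[["lo"]] - min_gap):min(length(occ), p1[["hi"]] + min_gap)] <- -Inf
  r2 <- which.max(occ2)
  if (!is.finite(occ2[r2]) || occ2[r2] < min_occupancy)
    stopf("no axial flow detected", class = "axial_flow_error")
  p2 <- peak(occ, r2)
  band <- sort(c(p1[["center"]], p2[["center"]]))
  names(band) <- c("row_top", "row_bottom")
  band
}

close_gaps <- function(profile, gap_tol) {
  if (gap_tol < 1 || !any(profile)) return(profile)
  r <- rle(profile)
  ends <- cumsum(r$lengths)
  inner <- which(!r$values & r$lengths <= gap_tol)
  inner <- inner[inner > 1 & inner < length(r$values)]
  for (i in inner) profile[(ends[i] - r$lengths[i] + 1):ends[i]] <- TRUE
  profile
}

#' Count intersegmental vessels crossing a scan line
#'
#' ISVs are counted as distinct vertical vessel segments crossing a
#' horizontal scan line placed `scan_offset` rows dorsal of the artery row
#' (`row_top` of the axial band), i.e. towards the DLAV where the ISVs run
#' vertically and axial glare is avoided.  A segment is a run of TRUE
#' columns in the scan-line profile after closing gaps of up to `gap_tol`
#' px; runs shorter than `min_run` px are ignored.  With `side = "both"`
#' a second, ventral scan line between the axial rows distinguishes venous
#' ISVs (which continue to the vein) from arterial ones.
#'
#' @param mask a [binarize_angiogram()] result.
#' @param band axial band from [locate_axial_band()].
#' @param side `"dorsal"` (combined count, the default reported endpoint),
#'   `"ventral"` (venous ISVs only) or `"both"`.
#' @param scan_offset rows above `row_top`; default `max(15, 0.3*row_top)`.
#' @param gap_tol maximum gap closed within a segment, px.
#' @param min_run minimum segment width kept, px.
#' @return an object of class `isv_count_result` with fields `isv_count`,
#'   `isv_column_positions`, `axial_band`, `scan_row`, `qc_flags` and,
#'   for `side = "both"`, `isv_types`.
#' @export
count_isvs <- function(mask, band, side = c("dorsal", "ventral", "both"),
                       scan_offset = NULL, gap_tol = 3, min_run = 5) {
  stopifnot(inherits(mask, "vessel_mask"))
  side <- match.arg(side)
  band <- as.integer(band)
  h <- nrow(mask$mask)
  if (band[1] < 1 || band[2] > h || band[1] >= band[2])
    stopf("axial band outside image")
  scan_offset <- scan_offset %||% max(15L, round(0.3 * band[1]))
  dorsal_row <- band[1] - scan_offset
  ## ventral scan: the row least contaminated by axial blur between the
  ## two channels (venous ISVs cross it, arterial ones end at the artery)
  inner <- (band[1] + 3):(band[2] - 3)
  ventral_row <- if (length(inner))
    inner[which.min(rowMeans(mask$mask)[inner])] else band[1] + 1L
  qc <- character(0)

  scan_runs <- function(row) {
    if (row < 1 || row > h) stopf("scan line outside image")
    profile <- close_gaps(mask$mask[row, ], gap_tol)
    r <- rle(profile)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_run
    data.frame(start = starts[keep], end = ends[keep],
               center = as.integer(round((starts[keep] + ends[keep]) / 2)))
  }

  main_row <- if (side == "ventral") ventral_row else dorsal_row
  runs <- scan_runs(main_row)
  res <- list(isv_count = nrow(runs),
              isv_column_positions = runs$center,
              axial_band = band, scan_row = main_row, side = side,
              qc_flags = qc)
  if (side == "both") {
    vruns <- scan_runs(ventral_row)
    res$isv_types <- vapply(runs$center, function(cc) {
      if (nrow(vruns) && any(abs(vruns$center - cc) <= 3 * gap_tol)) "v"
      else "a"
    }, character(1))
  }
  structure(res, class = "isv_count_result")
}

#' @export
print.isv_count_result <- function(x, ...) {
  cat(sprintf("<isv_count_result> %d ISVs at scan row %d (%s side)\n",
              x$isv_count, x$scan_row, x$side))
  if (!is.null(x$isv_types))
    cat("  types:", paste(x$isv_types, collapse = " "), "\n")
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' Control variability (coefficient of variation)
#'
#' CV of control embryos: the sample standard deviation (n-1 denominator)
#' of the per-embryo values divided by the control mean, pooled across
#' replicates.
#'
#' @param per_embryo_counts numeric vector of per-embryo control values
#'   pooled over at least two replicates.
#' @return an object of class `control_stats` (mean, sd, n, cv).
#' @export
control_cv <- function(per_embryo_counts) {
  x <- as.numeric(per_embryo_counts)
  if (length(x) < 2) stopf("at least 2 control values required")
  m <- mean(x)
  if (m <= 0) stopf("control mean must be > 0 for a CV")
  s <- sd(x)
  structure(list(mean = m, sd = s, n = length(x), cv = s / m),
            class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat(sprintf("<control_stats> n = %d, mean = %.4g, sd = %.4g, cv = %.4g\n",
              x$n, x$mean, x$sd,
              if (is.null(x$cv) || is.na(x$cv)) NA_real_ else x$cv))
  invisible(x)
}

#' Count ISVs in an angiogram (convenience pipeline)
#'
#' Runs [binarize_angiogram()], [locate_axial_band()] and [count_isvs()]
#' with the given settings; on failure to find axial flow, returns a
#' zero-count result flagged `"no axial flow detected"` rather than
#' erroring, which is the appropriate screening behaviour (absent
#' circulation is itself an effect).
#'
#' @param angiogram a [build_angiogram()] result.
#' @param min_frames,min_component_px see [binarize_angiogram()].
#' @param side,scan_offset,gap_tol,min_run see [count_isvs()].
#' @return an `isv_count_result`.
#' @export
quantify_angiogram <- function(angiogram, min_frames = 2,
                               min_component_px = 20,
                               side = "dorsal", scan_offset = NULL,
                               gap_tol = 3, min_run = 5) {
  mask <- binarize_angiogram(angiogram, min_frames, min_component_px)
  band <- tryCatch(locate_axial_band(mask), axial_flow_error = function(e) NULL)
  if (is.null(band)) {
    return(structure(list(isv_count = 0L,
                          isv_column_positions = integer(0),
                          axial_band = c(row_top = NA_integer_,
                                         row_bottom = NA_integer_),
                          scan_row = NA_integer_, side = side,
                          qc_flags = "no axial flow detected"),
                     class = "isv_count_result"))
  }
  count_isvs(mask, band, side = side, scan_offset = scan_offset,
             gap_tol = gap_tol, min_run = min_run)
}
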