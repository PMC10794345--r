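## Core subtraction algorithm: video stack -> angiogram.
##
## Each frame is compared with the mean frame of the sequence; the
## (absolute) difference is Gaussian-blurred and thresholded, and the
## per-pixel sum of the binary masks over all frames is the angiogram.
## Non-moving content (embryo body, background texture) cancels in the
## subtraction; flowing blood cells light up the perfused vessels.

#' Construct a video stack
#'
#' @param frames a numeric 3-D array (height x width x frames) or a list of
#'   equally sized numeric matrices, intensities on a fixed \[0,1\] scale.
#' @param frame_rate_fps acquisition frame rate (metadata only).
#' @return an object of class `video_stack` wrapping the array.
#' @export
video_stack <- function(frames, frame_rate_fps = 20) {
  if (is.list(frames)) {
    if (length(frames) == 0L) stopf("empty frame list")
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stopf("all frames must have the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1, 1], dims[2, 1], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("`frames` must be a height x width x n_frames array")
  if (dim(frames)[3] < 2L) stopf("a video stack needs at least 2 frames")
  rng <- range(frames)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stopf("intensities must be finite and within [0, 1]")
  structure(list(frames = frames, frame_rate_fps = frame_rate_fps),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stack> %d frames of %d x %d px, %.3g fps\n",
              d[3], d[1], d[2], x$frame_rate_fps))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

#' Parameters of the subtraction algorithm
#'
#' Defaults follow the published processing chain: Gaussian blur with
#' sigma = 5 px and a fixed binarization threshold of 0.025 on the \[0,1\]
#' intensity scale.  The absolute difference is used by default so that
#' both darker-than-background cells and brighter glints register; set
#' `use_absolute_difference = FALSE` to threshold the signed dark
#' excursion (reference minus frame) instead.
#'
#' @param gaussian_sigma blur standard deviation in pixels.
#' @param binarize_threshold threshold on the blurred difference, \(0,1\).
#' @param use_absolute_difference logical, see above.
#' @param truncate Gaussian kernel truncation in units of sigma.
#' @param boundary blur boundary rule (reflect).
#' @return an object of class `angiogram_params`.
#' @export
angiogram_params <- function(gaussian_sigma = 5, binarize_threshold = 0.025,
                             use_absolute_difference = TRUE,
                             truncate = 4, boundary = "reflect") {
  if (gaussian_sigma <= 0) stopf("`gaussian_sigma` must be > 0")
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    stopf("`binarize_threshold` must lie strictly between 0 and 1")
  structure(list(gaussian_sigma = gaussian_sigma,
                 binarize_threshold = binarize_threshold,
                 use_absolute_difference = isTRUE(use_absolute_difference),
                 truncate = truncate, boundary = boundary),
            class = "angiogram_params")
}

#' Mean reference frame of a video stack
#'
#' @param stack a [video_stack()].
#' @return numeric matrix: per-pixel arithmetic mean over all frames.
#' @export
compute_reference_frame <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  rowMeans(stack$frames, dims = 2)
}

#' Difference-binarize one frame against the reference
#'
#' Computes the (absolute) difference to the reference frame, blurs it with
#' a Gaussian and thresholds the result.
#'
#' @param frame,reference numeric matrices of identical shape.
#' @param params an [angiogram_params()].
#' @return logical matrix: TRUE where motion was detected.
#' @export
difference_binarize_frame <- function(frame, reference,
                                      params = angiogram_params()) {
  if (!identical(dim(frame), dim(reference)))
    stopf("frame and reference shapes differ")
  d <- if (params$use_absolute_difference) abs(frame - reference)
       else reference - frame
  g <- gaussian_blur(d, params$gaussian_sigma, params$truncate,
                     params$boundary)
  g > params$binarize_threshold
}

#' Build an angiogram from a video stack
#'
#' Per-pixel count of frames in which motion was detected; the
#' reconstructed image of the perfused vessel network.
#'
#' @param stack a [video_stack()].
#' @param params an [angiogram_params()].
#' @return an object of class `angiogram` with elements `counts`
#'   (integer matrix), `n_frames` and `params`.
#' @export
build_angiogram <- function(stack, params = angiogram_params()) {
  stopifnot(inherits(stack, "video_stack"))
  ref <- compute_reference_frame(stack)
  n <- dim(stack$frames)[3]
  counts <- matrix(0L, nrow(ref), ncol(ref))
  for (t in seq_len(n)) {
    m <- difference_binarize_frame(stack$frames[, , t], ref, params)
    counts <- counts + m
  }
  structure(list(counts = counts, n_frames = n, params = params),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf(
    "<angiogram> %d x %d px from %d frames (sigma = %g, threshold = %g)\n",
    nrow(x$counts), ncol(x$counts), x$n_frames,
    x$params$gaussian_sigma, x$params$binarize_threshold))
  cat(sprintf("  moving pixels (count >= 1): %d\n", sum(x$counts > 0)))
  invisible(x)
}

#' @export
as.matrix.angiogram <- function(x, ...) x$counts

#' @export
plot.angiogram <- function(x, ...) {
  z <- t(x$counts)[, nrow(x$counts):1, drop = FALSE]
  image(z, col = gray.colors(64, start = 0, end = 1), axes = FALSE,
        asp = nrow(x$counts) / ncol(x$counts),
        main = "angiogram (motion count)", ...)
  invisible(x)
}
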