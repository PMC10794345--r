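## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library functions do not
#' perturb user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "angiofish_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

#' Discrete Gaussian kernel
#'
#' Normalised symmetric kernel truncated at `truncate` standard deviations
#' (default 4, leaving < 1e-4 of the peak outside the support).
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param truncate truncation radius in units of `sigma`.
#' @return numeric vector of odd length summing to one.
#' @export
gaussian_kernel <- function(sigma, truncate = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stopf("`sigma` must be a single positive number")
  r <- ceiling(truncate * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of an image matrix
#'
#' Separable convolution with a truncated Gaussian; boundary handling is
#' reflect (half-sample symmetric: the edge pixel is mirrored, as in common
#' image-processing defaults).
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param truncate kernel truncation in units of `sigma`.
#' @param boundary boundary rule; only `"reflect"` is implemented.
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma, truncate = 4, boundary = "reflect") {
  boundary <- match.arg(boundary, "reflect")
  if (!is.matrix(img) || !is.numeric(img))
    stopf("`img` must be a numeric matrix")
  .conv_sep_reflect(img, gaussian_kernel(sigma, truncate))
}
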