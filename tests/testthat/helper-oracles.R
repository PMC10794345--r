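# Independent naive reference implementations used as oracles.
# These deliberately avoid the package's separable/C++ code paths.

# brute-force per-pixel mean of a frame array
naive_mean_frame <- function(frames) {
  h <- dim(frames)[1]; w <- dim(frames)[2]; n <- dim(frames)[3]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (t in seq_len(n)) s <- s + frames[i, j, t]
    out[i, j] <- s / n
  }
  out
}

# reflect (half-sample symmetric) index lookup, 1-based
reflect1 <- function(i, n) {
  period <- 2 * n
  j <- (i - 1) %% period
  j <- ifelse(j < 0, j + period, j)
  ifelse(j < n, j + 1, period - j)
}

# direct (non-separable) 2-D convolution with the outer-product Gaussian
# kernel and reflect boundary
naive_gaussian_blur <- function(img, sigma, truncate = 4) {
  k1 <- exp(-((-ceiling(truncate * sigma)):(ceiling(truncate * sigma)))^2 /
              (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  r <- (length(k1) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  pad <- img[reflect1(seq(1 - r, h + r), h),
             reflect1(seq(1 - r, w + r), w), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- sum(k2 * pad[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# naive angiogram: per-frame loop over the definition
naive_angiogram <- function(frames, sigma = 5, threshold = 0.025) {
  ref <- naive_mean_frame(frames)
  counts <- matrix(0L, nrow(ref), ncol(ref))
  for (t in seq_len(dim(frames)[3])) {
    g <- naive_gaussian_blur(abs(frames[, , t] - ref), sigma)
    counts <- counts + (g > threshold)
  }
  counts
}

random_stack <- function(seed, h = 16, w = 16, n = 4) {
  set.seed(seed)
  array(runif(h * w * n), dim = c(h, w, n))
}

# small synthetic video for fast end-to-end tests
small_video <- function(n_isvs, seed, noise_sd = 0.01) {
  layout <- make_vessel_layout(n_isvs, image_shape = c(150, 420), seed = seed)
  simulate_flow_video(layout,
                      flow_sim_config(seed = seed, pixel_noise_sd = noise_sd))
}

# observations table at explicit per-concentration affected fractions
fraction_obs <- function(fractions, conc, n = 16, replicates = 1) {
  rows <- list()
  id <- 0
  for (r in seq_len(replicates)) for (k in seq_along(conc)) {
    n_aff <- round(fractions[k] * n)
    v <- c(rep(1, n_aff), rep(0, n - n_aff))
    for (val in v) {
      id <- id + 1
      rows[[id]] <- data.frame(embryo_id = paste0("e", id),
                               compound = "x",
                               concentration_uM = conc[k], replicate = r,
                               endpoint = "affected", value = val,
                               alive = TRUE, is_control = conc[k] == 0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "endpoint_kind") <- "quantal"
  class(out) <- c("endpoint_observations", "data.frame")
  out
}
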