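## Synthetic generator: ground-truthed flow videos through a parametric
## tail vessel network, and dose-response datasets with known EC50/hill.
##
## The emulated anatomy follows the zebrafish tail at 96 hpf: two axial
## channels (dorsal aorta / caudal artery and posterior cardinal / caudal
## vein) run horizontally, K intersegmental vessels (ISVs) rise vertically
## towards the DLAV row, alternating arterial (ending at the aorta) and
## venous (reaching the vein).  Blood cells are dark particles on a bright
## static textured background; only particles and per-frame pixel noise
## change between frames.

#' Parametric tail-vessel layout
#'
#' Generates a vessel layout with `n_isvs` vertical ISVs, evenly spaced
#' with a little horizontal jitter, between fixed axial rows derived from
#' the image height.  Deterministic given `seed`.
#'
#' @param n_isvs number of intersegmental vessels (>= 0).
#' @param image_shape `c(height, width)` in pixels; the default matches the
#'   1024 x 190 px acquisition geometry (stored height x width).
#' @param seed integer seed controlling the jitter.
#' @param isv_width_px,axial_width_px channel widths in pixels.
#' @return an object of class `vessel_layout`.
#' @export
make_vessel_layout <- function(n_isvs, image_shape = c(190, 1024), seed = 1,
                               isv_width_px = 3, axial_width_px = 6) {
  if (n_isvs < 0) stopf("`n_isvs` must be >= 0")
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  dlav <- max(2L, round(0.20 * h))
  artery <- round(0.62 * h)
  vein <- round(0.80 * h)
  margin <- max(8L, round(0.04 * w))
  usable <- w - 2 * margin
  if (n_isvs > 0 && usable / n_isvs < 3 * isv_width_px)
    stopf("layout infeasible: %d ISVs do not fit a width of %d px",
          n_isvs, w, class = "layout_error")
  cols <- integer(0)
  if (n_isvs > 0) {
    spacing <- usable / (n_isvs + 1)
    centers <- margin + spacing * seq_len(n_isvs)
    cols <- with_seed(seed, {
      jit <- runif(n_isvs, -0.2 * spacing, 0.2 * spacing)
      round(centers + jit)
    })
    ## jitter is bounded by 0.2*spacing so the pairwise gap stays
    ## > 0.6*spacing > isv_width_px; assert the invariant anyway
    if (n_isvs > 1 && min(diff(cols)) <= isv_width_px)
      stopf("layout infeasible: ISV columns closer than their width",
            class = "layout_error")
  }
  structure(list(
    image_height_px = h, image_width_px = w,
    dlav_row = dlav, axial_artery_row = artery, axial_vein_row = vein,
    isv_columns = as.integer(cols),
    isv_types = if (n_isvs > 0) rep_len(c("a", "v"), n_isvs) else character(0),
    isv_width_px = isv_width_px, axial_width_px = axial_width_px
  ), class = "vessel_layout")
}

#' @export
print.vessel_layout <- function(x, ...) {
  cat(sprintf(
    "<vessel_layout> %d x %d px, %d ISVs; DLAV row %d, artery row %d, vein row %d\n",
    x$image_height_px, x$image_width_px, length(x$isv_columns),
    x$dlav_row, x$axial_artery_row, x$axial_vein_row))
  invisible(x)
}

#' Flow-simulation configuration
#'
#' Defaults emulate the acquisition described for the assay (20 frames at
#' 20 fps) with blood-cell scale parameters chosen for a 20x objective
#' with 2x2 binning: particle radius 3 px, 3 px/frame flow speed, about
#' one cell per 25 px of vessel, multiplicative darkening of 0.35.
#'
#' @param n_frames frames per video (>= 2).
#' @param particle_density particles per 100 px of vessel path.
#' @param particle_speed_px_per_frame flow speed.
#' @param particle_radius_px cell radius in pixels.
#' @param particle_contrast multiplicative darkening amplitude in (0, 1\].
#' @param background_texture_sd SD of the static background texture.
#' @param pixel_noise_sd SD of the per-frame i.i.d. pixel noise.
#' @param base_intensity mean background brightness on \[0,1\].
#' @param frame_rate_fps metadata frame rate.
#' @param seed integer; single RNG stream for the whole video.
#' @return an object of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_frames = 20, particle_density = 4,
                            particle_speed_px_per_frame = 3,
                            particle_radius_px = 3, particle_contrast = 0.35,
                            background_texture_sd = 0.05,
                            pixel_noise_sd = 0.01, base_intensity = 0.8,
                            frame_rate_fps = 20, seed = 1) {
  if (n_frames < 2) stopf("`n_frames` must be >= 2")
  if (particle_contrast <= 0 || particle_contrast > 1)
    stopf("`particle_contrast` must be in (0, 1]")
  if (background_texture_sd < 0 || pixel_noise_sd < 0)
    stopf("noise SDs must be >= 0")
  if (particle_density < 0) stopf("`particle_density` must be >= 0")
  structure(as.list(environment()), class = "flow_sim_config")
}

## path matrices (row, col), one point per pixel step along the channel
vessel_paths <- function(layout) {
  w <- layout$image_width_px
  paths <- list(
    artery = cbind(row = rep(layout$axial_artery_row, w), col = seq_len(w)),
    vein   = cbind(row = rep(layout$axial_vein_row, w), col = rev(seq_len(w)))
  )
  for (i in seq_along(layout$isv_columns)) {
    end_row <- if (layout$isv_types[i] == "v") layout$axial_vein_row
               else layout$axial_artery_row
    rows <- seq(layout$dlav_row, end_row)
    paths[[paste0("isv", i)]] <-
      cbind(row = rows, col = rep(layout$isv_columns[i], length(rows)))
  }
  paths
}

#' Simulate a brightfield flow video
#'
#' Renders dark particles flowing along the axial channels and up/down the
#' ISVs of `layout` on a frozen textured background, with per-frame pixel
#' noise.  Reproducible given `config$seed`.
#'
#' @param layout a [make_vessel_layout()] result.
#' @param config a [flow_sim_config()].
#' @return list with elements `stack` (a [video_stack()]) and `truth`
#'   (class `ground_truth`: `skeleton_mask`, `true_isv_count`,
#'   `per_frame_particle_positions`, `layout`).
#' @export
simulate_flow_video <- function(layout, config = flow_sim_config()) {
  stopifnot(inherits(layout, "vessel_layout"),
            inherits(config, "flow_sim_config"))
  h <- layout$image_height_px; w <- layout$image_width_px
  paths <- vessel_paths(layout)
  lens <- vapply(paths, nrow, integer(1))
  if (config$particle_density > 0 && any(lens == 0))
    stopf("zero-length vessel path with nonzero particle density")

  r <- config$particle_radius_px
  dr <- as.integer(round(r))
  disc <- expand.grid(di = -dr:dr, dj = -dr:dr)
  disc <- disc[disc$di^2 + disc$dj^2 <= r^2, , drop = FALSE]

  skel <- matrix(FALSE, h, w)
  for (p in paths) skel[p] <- TRUE

  out <- with_seed(config$seed, {
    background <- clamp01(config$base_intensity +
      matrix(rnorm(h * w, 0, config$background_texture_sd), h, w))
    ## particles: evenly spaced along each path with random phase, all
    ## advancing at the configured speed (wrapping at the path ends)
    offsets <- lapply(seq_along(paths), function(k) {
      np <- round(config$particle_density * lens[k] / 100)
      if (np < 1) return(numeric(0))
      (seq_len(np) - 1) * lens[k] / np + runif(np, 0, lens[k] / np)
    })
    frames <- array(0, dim = c(h, w, config$n_frames))
    pos_by_frame <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      img <- background
      centers <- do.call(rbind, lapply(seq_along(paths), function(k) {
        if (length(offsets[[k]]) == 0) return(NULL)
        s <- (offsets[[k]] + config$particle_speed_px_per_frame * (t - 1)) %%
          lens[k]
        paths[[k]][floor(s) + 1L, , drop = FALSE]
      }))
      if (!is.null(centers) && nrow(centers) > 0) {
        for (q in seq_len(nrow(centers))) {
          ii <- centers[q, 1] + disc$di
          jj <- centers[q, 2] + disc$dj
          ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
          idx <- cbind(ii[ok], jj[ok])
          img[idx] <- img[idx] * (1 - config$particle_contrast)
        }
      }
      if (config$pixel_noise_sd > 0)
        img <- img + matrix(rnorm(h * w, 0, config$pixel_noise_sd), h, w)
      frames[, , t] <- clamp01(img)
      pos_by_frame[[t]] <- centers %||% cbind(row = integer(0), col = integer(0))
    }
    list(frames = frames, pos = pos_by_frame)
  })

  truth <- structure(list(
    skeleton_mask = skel,
    true_isv_count = length(layout$isv_columns),
    per_frame_particle_positions = out$pos,
    layout = layout
  ), class = "ground_truth")
  list(stack = video_stack(out$frames, config$frame_rate_fps), truth = truth)
}

#' Simulate a concentration-response dataset
#'
#' Quantal datasets draw per-embryo Bernoulli outcomes with affected
#' probability following the two-parameter log-logistic
#' p(c) = 1 / (1 + (c/EC50)^-hill); continuous datasets draw per-embryo
#' values with mean `control_mean` / (1 + (c/EC50)^hill) and Gaussian
#' noise `control_sd`.  Controls (concentration 0) are added for every
#' replicate.
#'
#' @param true_ec50 true EC50 in µM (> 0).
#' @param hill Hill slope (> 0; effect increases/decreases monotonically
#'   with concentration).
#' @param concentrations vector of tested concentrations in µM (> 0).
#' @param n_per_conc embryos per concentration per replicate (default 16,
#'   one embryo per well).
#' @param n_replicates independent replicates (default 2).
#' @param kind `"quantal"` (0/1 affected) or `"continuous"`.
#' @param control_mean,control_sd control-level mean and per-embryo SD for
#'   continuous endpoints.
#' @param endpoint endpoint name recorded in the table.
#' @param compound compound name recorded in the table.
#' @param seed integer seed.
#' @return a data.frame of class `endpoint_observations` with columns
#'   embryo_id, compound, concentration_uM, replicate, endpoint, value,
#'   alive, is_control, and attribute `endpoint_kind`.
#' @export
simulate_cr_dataset <- function(true_ec50, hill, concentrations,
                                n_per_conc = 16, n_replicates = 2,
                                kind = c("quantal", "continuous"),
                                control_mean = 20, control_sd = 2,
                                endpoint = NULL, compound = "synthetic",
                                seed = 1) {
  kind <- match.arg(kind)
  if (true_ec50 <= 0) stopf("`true_ec50` must be > 0")
  if (hill == 0) stopf("`hill` must be nonzero (degenerate curve)")
  if (any(concentrations <= 0))
    stopf("`concentrations` must be > 0 (the control at 0 is added)")
  if (n_per_conc < 1) stopf("`n_per_conc` must be >= 1")
  endpoint <- endpoint %||%
    if (kind == "quantal") "affected" else "isv_count"
  conc <- c(0, sort(unique(concentrations)))
  grid <- expand.grid(concentration_uM = conc,
                      replicate = seq_len(n_replicates),
                      well = seq_len(n_per_conc))
  n <- nrow(grid)
  values <- with_seed(seed, {
    if (kind == "quantal") {
      p <- ifelse(grid$concentration_uM == 0, 0,
                  1 / (1 + (grid$concentration_uM / true_ec50)^(-hill)))
      rbinom(n, 1, p)
    } else {
      f <- ifelse(grid$concentration_uM == 0, 1,
                  1 / (1 + (grid$concentration_uM / true_ec50)^hill))
      control_mean * f + rnorm(n, 0, control_sd)
    }
  })
  obs <- data.frame(
    embryo_id = sprintf("e%04d", seq_len(n)),
    compound = compound,
    concentration_uM = grid$concentration_uM,
    replicate = grid$replicate,
    endpoint = endpoint,
    value = values,
    alive = TRUE,
    is_control = grid$concentration_uM == 0
  )
  obs <- obs[order(obs$replicate, obs$concentration_uM), ]
  rownames(obs) <- NULL
  structure(obs, class = c("endpoint_observations", "data.frame"),
            endpoint_kind = kind)
}
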