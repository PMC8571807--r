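#' Configuration of the synthetic vessel phantom
#'
#' Describes a 2-D cross-section through a cylindrical vessel phantom in a
#' water bath: a pulsatile central lumen, a small constant-flow arteriole
#' channel, and two stationary blood channels (intraplaque-hemorrhage
#' stand-ins) embedded in a tissue-mimicking wall. Defaults follow the
#' physical mock-loop design the simulator emulates: a 3-mm lumen pulsating
#' at 1 Hz with ~9% wall strain, an arteriole channel of 0.25--1.0 mm, two
#' 1-mm hemorrhage channels, and 300 frames at frame rates in the
#' 10--30 Hz range.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of class `"PhantomConfig"`.
#'
#' @details Geometry (mm, in-plane): the lumen sits at the center of a
#'   12.8 x 12.8 mm field of view (128 x 128 px at 0.1 mm pitch); the
#'   arteriole and hemorrhage channels lie on a 2.5-mm circle around the
#'   lumen center at configurable angles (0 deg = directly above the lumen,
#'   angles increasing towards the probe-right side). Flow is modelled as
#'   speckle decorrelation: consecutive frames of flow-region speckle have
#'   correlation `1 - flow_decorrelation`. Photoacoustic sources coincide
#'   with blood-containing regions and are attenuated by an exponential
#'   depth fluence plus shadowing behind optically absorbing regions.
#'   `seed` fixes all randomness; identical configurations are
#'   bit-reproducible.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    image_dim = c(128L, 128L),
    pixel_pitch_mm = c(0.1, 0.1),
    lumen_center_mm = NULL,          # defaults to the FOV center
    lumen_diameter_mm = 3,
    phantom_diameter_mm = 8,
    pulse_freq_hz = 1,
    wall_strain = 0.09,
    arteriole_diameter_mm = 0.5,
    arteriole_angle_deg = 0,
    arteriole_radius_mm = 2.5,
    iph_diameter_mm = 1,
    iph_angles_deg = c(120, 240),
    iph_radius_mm = 2.5,
    n_frames = 300L,
    frame_rate_hz = 30,
    flow_decorrelation = 0.7,
    speckle_grain_px = 2,
    noise_sigma = 0.005,
    us_amp_background = 0.1,
    us_amp_wall = 1.0,
    us_amp_flow = 0.5,
    us_amp_iph = 0.5,
    pa_amp_iph = 1.0,
    pa_amp_flow = 1.0,
    pa_amp_background = 0.02,
    fluence_decay_mm = 10,
    shadow_factor = 0.25,
    floor_db = -60,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown phantom configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (is.null(cfg$lumen_center_mm)) {
    cfg$lumen_center_mm <- cfg$image_dim * cfg$pixel_pitch_mm / 2
  }
  class(cfg) <- "PhantomConfig"
  cfg
}

#' Rotate the arteriole channel about the lumen center
#'
#' Produces an orientation variant of a phantom configuration, emulating a
#' physical rotation of the phantom that changes where the arteriole sits
#' relative to the illumination. All other fields are untouched;
#' fluence-dependent PA amplitudes follow automatically because fluence is
#' computed from geometry at simulation time.
#'
#' @param config A [phantom_config()].
#' @param angle_deg New arteriole angle in degrees (0 = above the lumen,
#'   90 = right, 180 = below). Typical presets: 0, 90, 120, 180.
#' @return The modified `PhantomConfig`.
#' @export
orientation_variants <- function(config, angle_deg) {
  stopifnot(inherits(config, "PhantomConfig"))
  config$arteriole_angle_deg <- angle_deg
  config
}

# Center of a satellite channel (mm), angle 0 pointing up (shallower depth).
channel_center_mm <- function(config, angle_deg, radius_mm) {
  a <- angle_deg * pi / 180
  config$lumen_center_mm + radius_mm * c(-cos(a), sin(a))
}

# Pixel-center coordinate grids in mm.
coord_grids_mm <- function(config) {
  H <- config$image_dim[1L]; W <- config$image_dim[2L]
  y <- (seq_len(H) - 0.5) * config$pixel_pitch_mm[1L]
  x <- (seq_len(W) - 0.5) * config$pixel_pitch_mm[2L]
  list(y = matrix(y, H, W), x = matrix(x, H, W, byrow = TRUE))
}

disc_mask <- function(grids, center_mm, diameter_mm) {
  (grids$y - center_mm[1L])^2 + (grids$x - center_mm[2L])^2 <=
    (diameter_mm / 2)^2
}

# Smoothed complex white-noise field whose modulus is fully developed
# speckle; normalized to unit complex variance.
speckle_field <- function(H, W, grain_px) {
  z <- complex(real = stats::rnorm(H * W), imaginary = stats::rnorm(H * W))
  z <- matrix(z, H, W)
  if (grain_px > 0) {
    Kr <- gauss_band(H, grain_px)
    Kc <- t(gauss_band(W, grain_px))
    z <- Kr %*% z %*% Kc
  }
  z / stats::sd(c(Re(z), Im(z))) / sqrt(2)
}

# Bilinear sample of matrix `m` at fractional pixel coordinates (clamped).
bilinear_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0
  m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + H] * (1 - fr) * fc + m[i00 + H + 1] * fr * fc
}

#' Simulate interleaved US/PA frame stacks of the vessel phantom
#'
#' Generates co-registered ultrasound and photoacoustic multiframe stacks
#' with exact ground-truth region labels. The ultrasound stack combines a
#' static speckle background, a tissue wall undergoing radial sinusoidal
#' displacement (pulsation), flow regions with per-frame speckle
#' decorrelation, and additive Gaussian sensor noise; the photoacoustic
#' stack places temporally stationary sources at the hemorrhage channels
#' and decorrelating sources at the flow channels, attenuated by an
#' exponential depth fluence with shadowing behind absorbers. Both stacks
#' are log-compressed.
#'
#' @param config A [phantom_config()].
#' @return List with `us` and `pa` (`FrameStack`s on the `log_dB` scale),
#'   `truth` (class `"GroundTruth"`: logical masks `flow`, `iph`, `wall`,
#'   mutually disjoint), and `config`.
#' @export
simulate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "PhantomConfig"))
  H <- config$image_dim[1L]; W <- config$image_dim[2L]
  nf <- as.integer(config$n_frames)
  set.seed(config$seed)
  grids <- coord_grids_mm(config)

  lumen_r <- config$lumen_diameter_mm / 2
  phantom_r <- config$phantom_diameter_mm / 2
  lumen <- disc_mask(grids, config$lumen_center_mm, config$lumen_diameter_mm)
  art_c <- channel_center_mm(config, config$arteriole_angle_deg,
                             config$arteriole_radius_mm)
  arteriole <- disc_mask(grids, art_c, config$arteriole_diameter_mm)
  iph_centers <- lapply(config$iph_angles_deg, channel_center_mm,
                        config = config, radius_mm = config$iph_radius_mm)
  iph <- Reduce(`|`, lapply(iph_centers, disc_mask, grids = grids,
                            diameter_mm = config$iph_diameter_mm))

  # declared channels must not intersect
  centers <- c(list(config$lumen_center_mm, art_c), iph_centers)
  radii <- c(lumen_r, config$arteriole_diameter_mm / 2,
             rep(config$iph_diameter_mm / 2, length(iph_centers)))
  for (i in seq_along(centers)) {
    for (j in seq_len(i - 1L)) {
      if (sqrt(sum((centers[[i]] - centers[[j]])^2)) <=
          radii[i] + radii[j]) {
        stop("declared phantom regions overlap", call. = FALSE)
      }
    }
  }

  rho_grid <- sqrt((grids$y - config$lumen_center_mm[1L])^2 +
                     (grids$x - config$lumen_center_mm[2L])^2)
  wall <- rho_grid <= phantom_r & !lumen & !arteriole & !iph
  flow <- lumen | arteriole

  tex <- Mod(speckle_field(H, W, config$speckle_grain_px))
  tex <- tex / mean(tex)
  tex_pa <- Mod(speckle_field(H, W, config$speckle_grain_px))
  tex_pa <- tex_pa / mean(tex_pa)

  # static amplitude map (overwritten per frame for wall and flow pixels)
  base <- matrix(config$us_amp_background, H, W)
  base[iph] <- config$us_amp_iph * tex[iph]
  base[!iph & !wall & !flow] <- config$us_amp_background *
    tex[!iph & !wall & !flow]

  # wall displacement geometry: radial offset decaying from the inner to
  # the outer wall, texture sampled bilinearly from the static field
  wall_idx <- which(wall)
  wall_rho <- rho_grid[wall_idx]
  wall_uy <- (grids$y[wall_idx] - config$lumen_center_mm[1L]) / wall_rho
  wall_ux <- (grids$x[wall_idx] - config$lumen_center_mm[2L]) / wall_rho
  # incompressible thick-wall kinematics: radial displacement ~ 1/rho, so
  # the whole wall moves (no artificially static outer rim)
  wall_falloff <- lumen_r / wall_rho
  cy_px <- config$lumen_center_mm[1L] / config$pixel_pitch_mm[1L] + 0.5
  cx_px <- config$lumen_center_mm[2L] / config$pixel_pitch_mm[2L] + 0.5

  rho_t <- 1 - config$flow_decorrelation
  flow_idx <- which(flow)
  env_norm <- sqrt(pi) / 2      # mean of |z| for unit-variance complex z
  Fus <- speckle_field(H, W, config$speckle_grain_px)
  Fpa <- speckle_field(H, W, config$speckle_grain_px)

  depth_mm <- grids$y
  absorber <- flow | iph
  path_mm <- apply(absorber, 2L, function(col) {
    c(0, cumsum(col[-length(col)])) * config$pixel_pitch_mm[1L]
  })
  fluence <- exp(-depth_mm / config$fluence_decay_mm) *
    config$shadow_factor^path_mm

  us_lin <- array(0, c(H, W, nf))
  pa_lin <- array(0, c(H, W, nf))
  for (t in seq_len(nf)) {
    phase <- sin(2 * pi * config$pulse_freq_hz * (t - 1L) /
                   config$frame_rate_hz)
    u_mm <- config$wall_strain * lumen_r * phase * wall_falloff
    rho_src <- wall_rho - u_mm
    src_r <- cy_px + (rho_src * wall_uy) / config$pixel_pitch_mm[1L]
    src_c <- cx_px + (rho_src * wall_ux) / config$pixel_pitch_mm[2L]

    if (t > 1L) {
      Fus <- rho_t * Fus + sqrt(1 - rho_t^2) *
        speckle_field(H, W, config$speckle_grain_px)
      Fpa <- rho_t * Fpa + sqrt(1 - rho_t^2) *
        speckle_field(H, W, config$speckle_grain_px)
    }

    frame <- base
    frame[wall_idx] <- config$us_amp_wall * bilinear_sample(tex, src_r, src_c)
    frame[flow_idx] <- config$us_amp_flow * Mod(Fus[flow_idx]) / env_norm
    if (config$noise_sigma > 0) {
      frame <- frame + stats::rnorm(H * W, sd = config$noise_sigma)
    }
    us_lin[, , t] <- pmax(frame, 0)

    pa <- matrix(config$pa_amp_background, H, W) * tex_pa
    pa[iph] <- config$pa_amp_iph * tex_pa[iph]
    pa[flow_idx] <- config$pa_amp_flow * Mod(Fpa[flow_idx]) / env_norm
    pa <- pa * fluence
    if (config$noise_sigma > 0) {
      pa <- pa + stats::rnorm(H * W, sd = config$noise_sigma)
    }
    pa_lin[, , t] <- pmax(pa, 0)
  }

  mk <- function(arr, modality) {
    log_compress(
      frame_stack(arr, modality = modality, scale = "linear_envelope",
                  frame_rate_hz = config$frame_rate_hz,
                  pixel_pitch_mm = config$pixel_pitch_mm,
                  provenance = list(simulated = TRUE, seed = config$seed)),
      floor_db = config$floor_db)
  }
  truth <- structure(list(flow = flow, iph = iph, wall = wall),
                     class = "GroundTruth")
  list(us = mk(us_lin, "US"), pa = mk(pa_lin, "PA"), truth = truth,
       config = config)
}
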