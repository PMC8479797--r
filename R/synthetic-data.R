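# Synthetic roller experiments: ground-truth trajectory and image generators
# used to exercise every downstream stage without microscopy videos.

#' Specification of a single synthetic roller
#'
#' @param roller_id Integer label, unique within an experiment.
#' @param diameter Bead diameter D in micrometres; nominal beads are 10 um.
#' @param true_rp Ground-truth rolling parameter in `[0, 1]`: the fraction of
#'   the maximum theoretical displacement `pi * D * tau * omega` realised per
#'   actuation before scatter and noise.
#' @param is_dimer Logical; `TRUE` marks two magnetically stuck beads that
#'   move rigidly with erratic rolling and must be excluded by QC.
#' @param start_position Numeric length-2, starting `(x, y)` in micrometres.
#'
#' @return An object of class `roller_spec`.
#' @export
roller_spec <- function(roller_id, diameter = 10, true_rp, is_dimer = FALSE,
                        start_position = c(0, 0)) {
  stopifnot(length(roller_id) == 1, length(diameter) == 1,
            length(true_rp) == 1, length(start_position) == 2)
  if (!is.finite(diameter) || diameter <= 0)
    stop("'diameter' must be > 0 um", call. = FALSE)
  if (!is.finite(true_rp) || true_rp < 0 || true_rp > 1)
    stop("'true_rp' must lie in [0, 1]", call. = FALSE)
  structure(list(roller_id = as.integer(roller_id), diameter = diameter,
                 true_rp = true_rp, is_dimer = isTRUE(is_dimer),
                 start_position = as.numeric(start_position)),
            class = "roller_spec")
}

#' Magnetic actuation protocol
#'
#' Describes the field schedule: the field rotates clockwise (CW) at `omega`
#' for `tau` seconds, rests for `off_period` seconds, rotates
#' counter-clockwise (CCW) for `tau` seconds, rests again, and the whole
#' CW/CCW cycle repeats `n_cycles` times, giving `2 * n_cycles` actuation
#' windows.  The defaults are the standard schedule: 1 Hz, 5 s on, 5 s off,
#' 18 cycles (36 windows).
#'
#' @param omega Rotational frequency of the field in Hz.
#' @param tau Actuation period in seconds.
#' @param off_period Field-off settling time between actuations, seconds.
#' @param n_cycles Number of CW+CCW repeats.
#' @param first_direction `"CW"` or `"CCW"`; direction of the first window.
#'
#' @return An object of class `actuation_protocol`.
#' @export
actuation_protocol <- function(omega = 1, tau = 5, off_period = 5,
                               n_cycles = 18, first_direction = c("CW", "CCW")) {
  first_direction <- match.arg(first_direction)
  if (!is.finite(omega) || omega <= 0) stop("'omega' must be > 0 Hz", call. = FALSE)
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be > 0 s", call. = FALSE)
  if (!is.finite(off_period) || off_period < 0)
    stop("'off_period' must be >= 0 s", call. = FALSE)
  if (n_cycles < 0 || n_cycles != round(n_cycles))
    stop("'n_cycles' must be a non-negative integer", call. = FALSE)
  structure(list(omega = omega, tau = tau, off_period = off_period,
                 n_cycles = as.integer(n_cycles),
                 first_direction = first_direction),
            class = "actuation_protocol")
}

#' @export
print.actuation_protocol <- function(x, ...) {
  cat(sprintf(
    "Actuation protocol: omega = %g Hz, tau = %g s, off = %g s, %d %s/%s cycles (%d windows)\n",
    x$omega, x$tau, x$off_period, x$n_cycles, x$first_direction,
    setdiff(c("CW", "CCW"), x$first_direction), 2L * x$n_cycles))
  invisible(x)
}

#' Noise model for the synthetic generator
#'
#' @param rp_scatter_sd SD of the Gaussian per-actuation scatter of the
#'   realised rolling parameter around `true_rp` (unitless).  Realised values
#'   are truncated at 0, since a displacement magnitude cannot be negative.
#' @param tracking_sd Per-frame centroid localisation error in micrometres
#'   (isotropic Gaussian); subpixel tracking at ~1 um/pixel achieves ~0.1 um.
#' @param drift_rate Slow stage drift along x, micrometres per second.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rp_scatter_sd = 0, tracking_sd = 0, drift_rate = 0,
                        seed = 1L) {
  if (rp_scatter_sd < 0 || tracking_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(rp_scatter_sd = rp_scatter_sd, tracking_sd = tracking_sd,
                 drift_rate = drift_rate, seed = as.integer(seed)),
            class = "noise_model")
}

# Run expr with a temporary RNG state so generators are reproducible without
# clobbering the caller's random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Condition presets carrying measured mean rolling parameters
#'
#' One row per experimental condition, named for the roller/surface pair, with
#' the condition's mean rolling parameter and reported SEM, the interaction
#' family it belongs to, and the per-actuation scatter SD the generator uses
#' (`min(0.07, mean/3)`; the cap keeps zero-truncation of the Gaussian scatter
#' negligible for weakly rolling conditions).
#'
#' @return A data frame with columns `name`, `family`, `mean_rp`,
#'   `published_sem`, `rp_scatter_sd`.
#' @seealso [metris_preset()] for a single named preset,
#'   [simulate_condition()] to generate trajectories from one.
#' @export
metris_presets <- function() {
  p <- data.frame(
    name = c("biotin_streptavidin", "avidin_null",
             "dido1_h3k4me3", "dido1_h3k4me2", "dido1_h3k4me1",
             "orc1_h4k20me2", "orc1_h4k20me1", "orc1_h4k20me3", "orc1_h4",
             "ube2d1_uhrf1_ubl", "ube2d1_ubiquitin",
             "uhrf1_sra_ubl", "uhrf1_sra_ubl_w2v", "uhrf1_sra_ubiquitin"),
    family = c("anchor", "anchor",
               rep("dido1", 3), rep("orc1", 4), rep("ubl", 5)),
    mean_rp = c(0.918, 0.081,
                0.233, 0.213, 0.176,
                0.263, 0.226, 0.215, 0.202,
                0.131, 0.108, 0.119, 0.098, 0.085),
    published_sem = c(0.002, 0.004,
                      0.012, 0.010, 0.005,
                      0.011, 0.008, 0.005, 0.005,
                      0.005, 0.004, 0.004, 0.002, NA),
    stringsAsFactors = FALSE)
  p$rp_scatter_sd <- pmin(0.07, p$mean_rp / 3)
  p
}

#' Look up one condition preset by name
#'
#' @param name Preset name; see [metris_presets()] for the catalogue.
#' @return A one-row list with fields `name`, `family`, `mean_rp`,
#'   `published_sem`, `rp_scatter_sd`.
#' @export
metris_preset <- function(name) {
  p <- metris_presets()
  i <- match(name, p$name)
  if (is.na(i))
    stop("unknown preset '", name, "'; see metris_presets()", call. = FALSE)
  as.list(p[i, ])
}

new_track_table <- function(df, rollers, condition) {
  rownames(df) <- NULL
  structure(df, rollers = rollers, condition = condition,
            class = c("track_table", "data.frame"))
}

#' Roller metadata attached to a track table
#'
#' @param tracks A `track_table`.
#' @return A data frame with one row per roller: `roller_id`, `diameter_um`
#'   (bead diameter used in the rolling-parameter denominator),
#'   `est_diameter_um` (apparent diameter a tracker would measure; larger for
#'   dimers), `is_dimer` (ground truth when synthetic, `NA` otherwise) and
#'   `flagged` (link-ambiguity flag from tracking).
#' @export
roller_metadata <- function(tracks) {
  meta <- attr(tracks, "rollers")
  if (is.null(meta)) {
    ids <- unique(tracks$roller_id)
    n <- length(ids)
    meta <- data.frame(roller_id = ids, diameter_um = rep(NA_real_, n),
                       est_diameter_um = rep(NA_real_, n),
                       is_dimer = rep(NA, n), flagged = rep(FALSE, n))
  }
  meta
}

#' Generate synthetic roller trajectories
#'
#' Simulates per-frame positions under the rolling model: within each
#' actuation window the roller translates along the x (rolling) axis by
#' `sign * realised_rp * pi * D * tau * omega`, where the sign is `+1` for CW
#' and `-1` for CCW windows and `realised_rp = max(0, true_rp + N(0,
#' rp_scatter_sd))` is drawn independently per window.  Between actuations the
#' roller is stationary.  Per-frame Gaussian localisation noise and a linear
#' stage drift along x are added on top.
#'
#' @param rollers A list of [roller_spec()] objects (or a single one).  An
#'   empty list yields an empty table.
#' @param protocol An [actuation_protocol()].
#' @param noise A [noise_model()].
#' @param condition Condition label stored with every row.
#' @param frame_rate Frames per second of the simulated video; only the
#'   window-boundary positions matter for displacement analysis.
#' @param t0 Start of the first actuation relative to the first frame, s.
#'
#' @return A `track_table`: data frame with columns `roller_id`, `frame`
#'   (0-based), `time_s`, `x_um`, `y_um`, `condition`, carrying roller
#'   metadata retrievable with [roller_metadata()].
#' @seealso [simulate_condition()], [segment_actuations()]
#' @export
generate_trajectories <- function(rollers, protocol, noise = noise_model(),
                                  condition = "synthetic", frame_rate = 10,
                                  t0 = 0) {
  if (inherits(rollers, "roller_spec")) rollers <- list(rollers)
  stopifnot(inherits(protocol, "actuation_protocol"),
            inherits(noise, "noise_model"))
  if (!all(vapply(rollers, inherits, logical(1), "roller_spec")))
    stop("'rollers' must be roller_spec objects", call. = FALSE)
  if (frame_rate <= 0) stop("'frame_rate' must be > 0", call. = FALSE)

  n_win <- 2L * protocol$n_cycles
  total <- t0 + n_win * (protocol$tau + protocol$off_period)
  nf <- round(total * frame_rate)
  times <- (0:nf) / frame_rate

  empty <- data.frame(roller_id = integer(), frame = integer(),
                      time_s = numeric(), x_um = numeric(), y_um = numeric(),
                      condition = character(), stringsAsFactors = FALSE)
  if (length(rollers) == 0)
    return(new_track_table(empty, rollers = roller_metadata(empty)[0, ],
                           condition = condition))

  dir_sign <- rep_len(if (protocol$first_direction == "CW") c(1, -1) else c(-1, 1),
                      n_win)
  win_start <- t0 + (seq_len(n_win) - 1) * (protocol$tau + protocol$off_period)

  with_seed(noise$seed, {
    rows <- vector("list", length(rollers))
    meta <- vector("list", length(rollers))
    for (i in seq_along(rollers)) {
      r <- rollers[[i]]
      scatter_sd <- if (r$is_dimer) 5 * noise$rp_scatter_sd + 0.05
                    else noise$rp_scatter_sd
      realised <- pmax(0, r$true_rp + stats::rnorm(n_win, 0, scatter_sd))
      disp <- dir_sign * realised * pi * r$diameter * protocol$tau * protocol$omega

      # knots of the piecewise-linear x(t): constant in off periods,
      # linear ramp across each actuation window
      kt <- c(0, as.vector(rbind(win_start, win_start + protocol$tau)), total)
      kx <- c(r$start_position[1],
              as.vector(rbind(c(r$start_position[1],
                                r$start_position[1] + cumsum(disp))[seq_len(n_win)],
                              r$start_position[1] + cumsum(disp))),
              r$start_position[1] + sum(disp))
      keep <- !duplicated(kt)
      x <- if (n_win > 0) stats::approx(kt[keep], kx[keep], xout = times,
                                        rule = 2)$y
           else rep(r$start_position[1], length(times))
      x <- x + noise$drift_rate * times +
        stats::rnorm(length(times), 0, noise$tracking_sd)
      y <- r$start_position[2] + stats::rnorm(length(times), 0, noise$tracking_sd)

      rows[[i]] <- data.frame(roller_id = r$roller_id, frame = 0:nf,
                              time_s = times, x_um = x, y_um = y,
                              condition = condition, stringsAsFactors = FALSE)
      meta[[i]] <- data.frame(
        roller_id = r$roller_id, diameter_um = r$diameter,
        # a dimer's fused blob measures ~1.55x a single bead's diameter
        est_diameter_um = r$diameter * if (r$is_dimer) 1.55 else 1,
        is_dimer = r$is_dimer, flagged = FALSE)
    }
    new_track_table(do.call(rbind, rows), rollers = do.call(rbind, meta),
                    condition = condition)
  })
}

#' Simulate a full condition from a preset
#'
#' Convenience wrapper: builds `n_rollers` nominal 10-um rollers (plus
#' optional dimers) whose ground-truth rolling parameter is the preset mean,
#' then calls [generate_trajectories()] with the preset's per-actuation
#' scatter and the given localisation noise.
#'
#' @param preset Preset name (see [metris_presets()]) or a list as returned by
#'   [metris_preset()].
#' @param n_rollers Number of well-behaved rollers; the standard experiment
#'   measures about 10.
#' @param n_dimers Number of additional dimer artifacts to include.
#' @param protocol An [actuation_protocol()].
#' @param seed Integer seed.
#' @param tracking_sd Localisation noise, um per frame (default 0.1).
#' @param drift_rate Stage drift along x, um/s.
#' @param diameter Bead diameter, um.
#' @param frame_rate Frames per second.
#'
#' @return A `track_table` (see [generate_trajectories()]).
#' @examples
#' tr <- simulate_condition("dido1_h3k4me3", n_rollers = 3,
#'                          protocol = actuation_protocol(n_cycles = 2),
#'                          seed = 42)
#' head(tr)
#' @export
simulate_condition <- function(preset, n_rollers = 10, n_dimers = 0,
                               protocol = actuation_protocol(), seed = 1,
                               tracking_sd = 0.1, drift_rate = 0,
                               diameter = 10, frame_rate = 10) {
  if (is.character(preset)) preset <- metris_preset(preset)
  n_tot <- n_rollers + n_dimers
  rollers <- lapply(seq_len(n_tot), function(i)
    roller_spec(i, diameter = diameter, true_rp = preset$mean_rp,
                is_dimer = i > n_rollers,
                start_position = c(200, 40 * i)))
  noise <- noise_model(rp_scatter_sd = preset$rp_scatter_sd,
                       tracking_sd = tracking_sd, drift_rate = drift_rate,
                       seed = seed)
  generate_trajectories(rollers, protocol, noise, condition = preset$name,
                        frame_rate = frame_rate)
}

#' Render a track table into a synthetic image stack
#'
#' Draws each roller as a dark disc with a soft (logistic) edge on a bright
#' background, one frame per time point, emulating bright-field microscopy of
#' opaque beads.  Dimers are drawn as two overlapping discs.
#'
#' @param tracks A `track_table`.
#' @param fov Field of view `(width, height)` in micrometres.
#' @param pixel_size Micrometres per pixel (default 1).
#' @param psf_radius Softness of the disc edge in micrometres.
#' @param background_level Background intensity in `[0, 1]`.
#' @param shot_noise_sd SD of additive Gaussian intensity noise per pixel.
#' @param seed Integer seed for the intensity noise.
#'
#' @return An object of class `image_stack`: a list with `frames` (list of
#'   matrices, rows = y, columns = x, values in `[0, 1]`), `pixel_size`, and
#'   `times`.
#' @seealso [track_particles()], [write_image_stack()]
#' @export
render_image_stack <- function(tracks, fov = c(256, 128), pixel_size = 1,
                               psf_radius = 1, background_level = 0.85,
                               shot_noise_sd = 0, seed = 1L) {
  stopifnot(pixel_size > 0, length(fov) == 2)
  meta <- roller_metadata(tracks)
  nx <- ceiling(fov[1] / pixel_size)
  ny <- ceiling(fov[2] / pixel_size)
  frames_idx <- sort(unique(tracks$frame))
  px_x <- (seq_len(nx) - 1) * pixel_size  # 0-based pixel centres
  px_y <- (seq_len(ny) - 1) * pixel_size
  depth <- background_level - 0.1

  out <- max(tracks$x_um < 0 | tracks$x_um > fov[1] |
             tracks$y_um < 0 | tracks$y_um > fov[2])
  if (out > 0) {
    bad <- which(tracks$x_um < 0 | tracks$x_um > fov[1] |
                 tracks$y_um < 0 | tracks$y_um > fov[2])[1]
    stop(sprintf("roller %s leaves the field of view at frame %d",
                 tracks$roller_id[bad], tracks$frame[bad]), call. = FALSE)
  }

  disc <- function(img, cx, cy, radius) {
    w <- max(psf_radius, pixel_size) * 4 + radius
    ix <- which(px_x >= cx - w & px_x <= cx + w)
    iy <- which(px_y >= cy - w & px_y <= cy + w)
    if (!length(ix) || !length(iy)) return(img)
    rr <- sqrt(outer((px_y[iy] - cy)^2, (px_x[ix] - cx)^2, "+"))
    img[iy, ix] <- img[iy, ix] + 1 / (1 + exp((rr - radius) / (0.5 * psf_radius)))
    img
  }

  with_seed(seed, {
    frames <- lapply(frames_idx, function(f) {
      sub <- tracks[tracks$frame == f, ]
      cov <- matrix(0, ny, nx)
      for (j in seq_len(nrow(sub))) {
        m <- meta[match(sub$roller_id[j], meta$roller_id), ]
        rad <- m$diameter_um / 2
        if (isTRUE(m$is_dimer)) {
          cov <- disc(cov, sub$x_um[j], sub$y_um[j] - 0.55 * m$diameter_um, rad)
          cov <- disc(cov, sub$x_um[j], sub$y_um[j] + 0.55 * m$diameter_um, rad)
        } else {
          cov <- disc(cov, sub$x_um[j], sub$y_um[j], rad)
        }
      }
      img <- background_level - depth * pmin(cov, 1)
      if (shot_noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, shot_noise_sd), ny, nx)
      pmin(pmax(img, 0), 1)
    })
    structure(list(frames = frames, pixel_size = pixel_size,
                   times = sort(unique(tracks$time_s))),
              class = "image_stack")
  })
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' @param stack An `image_stack` (see [render_image_stack()]).
#' @param path File path.
#' @return `read_image_stack()` returns an `image_stack`; the writer returns
#'   `path` invisibly.
#' @param pixel_size,frame_rate Geometry and timing to attach on read (a TIFF
#'   carries neither).
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size = 1, frame_rate = 10) {
  frames <- tiff::readTIFF(path, all = TRUE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 times = (seq_along(frames) - 1) / frame_rate),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image stack: %d frames of %d x %d px (%g um/px)\n",
              length(x$frames), d[2], d[1], x$pixel_size))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' Reads a YAML file with optional top-level blocks `protocol` (fields of
#' [actuation_protocol()]), `noise` (fields of [noise_model()]), `preset`
#' and `seed`.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `protocol`, `noise`, `preset`, `seed` (missing
#'   blocks fall back to defaults / `NULL`).
#' @export
read_metris_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  protocol <- do.call(actuation_protocol, as.list(cfg$protocol))
  noise <- if (is.null(cfg$noise)) noise_model()
           else do.call(noise_model, as.list(cfg$noise))
  list(protocol = protocol, noise = noise, preset = cfg$preset,
       seed = cfg$seed)
}

#' @rdname read_metris_config
#' @param protocol An [actuation_protocol()] to serialise.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "actuation_protocol"))
  yaml::write_yaml(list(protocol = unclass(protocol)), path)
  invisible(path)
}
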