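# Microscopy-like origin-track generator. Emulates the phenomenology the
# track pipeline assumes: two origin foci imaged at 10-s intervals for
# 40-60 min in rod cells, overlapped at midcell for a stochastic cohesion
# period, then separating along the long axis with stochastic bursts and
# reversals toward the quarter-cell positions, with restricted transverse
# motion, localization noise and rigid stage drift. Ground truth is returned
# alongside the spot table so estimator consistency can be checked.

#' Parameters of the synthetic-track generator
#'
#' Defaults emulate typical imaging conditions for these experiments: 10-s frames over 50 min,
#' rod cells ~3 um long and 1 um wide, origins overlapped (< 0.2 um) at
#' midcell for a stochastic cohesion period, then translocating toward the
#' quarter-cell positions at ~0.03 um/min net speed with occasional jumps and
#' transient reversals, strongly confined transverse motion, ~40 nm
#' localization noise (centroid precision, well below the 250-nm optical
#' resolution), and slow rigid stage drift.
#'
#' @param frame_interval_s frame interval, seconds.
#' @param duration_min movie length, minutes (typically 40-60).
#' @param cell_length_um,cell_width_um cell dimensions, micrometres.
#' @param cohesion_mean_min mean of the (exponential, truncated) cohesion
#'   duration, minutes.
#' @param speed_um_min net separation speed during translocation, um/min.
#' @param burst_rate_per_min rate of jump-like separation bursts.
#' @param burst_mean_um mean (exponential) burst magnitude, um.
#' @param reversal_prob per-frame probability of entering a reversal.
#' @param reversal_mean_frames mean (geometric) reversal duration, frames.
#' @param axial_jitter_sd_um SD of the per-origin axial jitter about the
#'   deterministic separation, um.
#' @param transverse_sd_um stationary SD of each origin's transverse
#'   (Ornstein-Uhlenbeck) confinement, um.
#' @param transverse_tau_s relaxation time of the transverse OU process.
#' @param loc_noise_sd_um localization noise SD per coordinate, um.
#' @param drift_sd_um per-frame SD of the rigid stage-drift random walk, um.
#' @param drift_rot_sd per-frame SD of a rigid rotation about the image
#'   origin, radians (0 = translation-only drift).
#' @param intensity_single mean single-focus intensity, a.u.
#' @param intensity_cv multiplicative intensity noise (coefficient of
#'   variation).
#' @param merged_cohesion emit a single merged focus at ~2x intensity during
#'   cohesion which then splits (exercises the intensity pairing rule);
#'   otherwise two overlapping tracks are emitted throughout.
#' @param field_um side of the square field over which cells are scattered
#'   (keeps pairs unambiguous in multi-pair datasets).
#' @return An object of class `synth_track_params`.
#' @export
synth_track_params <- function(frame_interval_s = 10, duration_min = 50,
                               cell_length_um = 3, cell_width_um = 1,
                               cohesion_mean_min = 8, speed_um_min = 0.03,
                               burst_rate_per_min = 0.2, burst_mean_um = 0.08,
                               reversal_prob = 0.02, reversal_mean_frames = 6,
                               axial_jitter_sd_um = 0.03,
                               transverse_sd_um = 0.06, transverse_tau_s = 30,
                               loc_noise_sd_um = 0.04, drift_sd_um = 0.01,
                               drift_rot_sd = 0, intensity_single = 100,
                               intensity_cv = 0.1, merged_cohesion = FALSE,
                               field_um = 200) {
  p <- as.list(environment())
  stopifnot(p$frame_interval_s > 0, p$duration_min > 0,
            p$cell_width_um < p$cell_length_um,
            all(unlist(p[c("speed_um_min", "burst_rate_per_min",
                           "burst_mean_um", "reversal_prob",
                           "axial_jitter_sd_um", "transverse_sd_um",
                           "loc_noise_sd_um", "drift_sd_um",
                           "intensity_cv")]) >= 0))
  structure(p, class = "synth_track_params")
}

# one OU path with stationary sd and relaxation tau, n points at interval dt
.ou_path <- function(n, sd, tau, dt) {
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  b <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd)
  for (i in 2:n) x[i] <- a * x[i - 1] + b * rnorm(1)
  x
}

#' Generate one synthetic origin-track pair
#'
#' Simulates ground-truth origin positions in cell coordinates through
#' cohesion -> translocation (directed motion plus bursts and reversals) ->
#' plateau at the quarter-cell positions, adds transverse OU confinement and
#' localization noise, applies rigid stage drift, converts to image
#' coordinates and emits intensities.
#'
#' @param params a [synth_track_params()].
#' @param seed RNG seed; `(params, seed)` determines the output exactly.
#' @param pair_id integer pair label; the two track ids are
#'   `2*pair_id - 1` and `2*pair_id`.
#' @return A list: `spots` (a [spot_table()]) and `truth` (generating speed,
#'   cohesion frames, plateau frame, per-frame true positions).
#' @export
generate_track_pair <- function(params = synth_track_params(), seed = 1,
                                pair_id = 1) {
  stopifnot(inherits(params, "synth_track_params"))
  with_seed(seed, {
    dt <- params$frame_interval_s
    nf <- floor(params$duration_min * 60 / dt) + 1
    frames <- 0:(nf - 1)
    v_s <- params$speed_um_min / 60          # um per second
    sep_max <- params$cell_length_um / 2     # quarter positions

    coh_frames <- ceiling(pmin(pmax(rexp(1, 1 / (params$cohesion_mean_min * 60)),
                                    60), 0.6 * params$duration_min * 60) / dt)
    if (params$cohesion_mean_min == 0) coh_frames <- 0L

    # separation ground truth
    s <- numeric(nf)
    dir <- 1
    rev_left <- 0L
    plateau_frame <- NA_integer_
    for (i in seq_len(nf - 1)) {
      if (i <= coh_frames) {
        s[i + 1] <- 0
        next
      }
      if (!is.na(plateau_frame)) {
        s[i + 1] <- s[i]
        next
      }
      if (rev_left > 0L) {
        dir <- -1
        rev_left <- rev_left - 1L
      } else {
        dir <- 1
        if (params$reversal_prob > 0 && runif(1) < params$reversal_prob)
          rev_left <- rgeom(1, 1 / max(params$reversal_mean_frames, 1)) + 1L
      }
      ds <- dir * v_s * dt
      if (params$burst_rate_per_min > 0 &&
          runif(1) < params$burst_rate_per_min * dt / 60)
        ds <- ds + rexp(1, 1 / params$burst_mean_um)
      s[i + 1] <- max(0, s[i] + ds)
      if (s[i + 1] >= sep_max) {
        s[i + 1] <- sep_max
        plateau_frame <- i + 1L
      }
    }

    jit1 <- if (params$axial_jitter_sd_um > 0)
      .ou_path(nf, params$axial_jitter_sd_um, 3 * dt, dt) else numeric(nf)
    jit2 <- if (params$axial_jitter_sd_um > 0)
      .ou_path(nf, params$axial_jitter_sd_um, 3 * dt, dt) else numeric(nf)
    x1 <- s / 2 + jit1
    x2 <- -s / 2 + jit2
    y1 <- .ou_path(nf, params$transverse_sd_um, params$transverse_tau_s, dt)
    y2 <- .ou_path(nf, params$transverse_sd_um, params$transverse_tau_s, dt)

    # cell placement in the field + rigid stage drift
    ctr <- runif(2, 0.1 * params$field_um, 0.9 * params$field_um)
    drift <- cbind(cumsum(rnorm(nf, sd = params$drift_sd_um)),
                   cumsum(rnorm(nf, sd = params$drift_sd_um)))
    theta <- if (params$drift_rot_sd > 0)
      cumsum(rnorm(nf, sd = params$drift_rot_sd)) else numeric(nf)

    to_image <- function(x, y) {
      px <- ctr[1] + x
      py <- ctr[2] + y
      if (params$drift_rot_sd > 0) {
        rx <- px * cos(theta) - py * sin(theta)
        ry <- px * sin(theta) + py * cos(theta)
        px <- rx; py <- ry
      }
      cbind(px + drift[, 1], py + drift[, 2])
    }
    noise <- function(n) {
      if (params$loc_noise_sd_um > 0) rnorm(n, sd = params$loc_noise_sd_um)
      else numeric(n)
    }
    p1 <- to_image(x1, y1)
    p1 <- p1 + cbind(noise(nf), noise(nf))
    p2 <- to_image(x2, y2)
    p2 <- p2 + cbind(noise(nf), noise(nf))

    inten <- function(level, n) {
      if (params$intensity_cv > 0)
        level * exp(rnorm(n, sd = params$intensity_cv))
      else rep(level, n)
    }
    id1 <- 2L * pair_id - 1L
    id2 <- 2L * pair_id

    if (params$merged_cohesion && coh_frames > 0) {
      # a single ~2x focus during cohesion, splitting into two tracks
      merged <- data.frame(track = id1, frame = frames[seq_len(coh_frames)],
                           x = (p1[seq_len(coh_frames), 1] +
                                  p2[seq_len(coh_frames), 1]) / 2,
                           y = (p1[seq_len(coh_frames), 2] +
                                  p2[seq_len(coh_frames), 2]) / 2,
                           intensity = inten(2 * params$intensity_single,
                                             coh_frames))
      rest <- (coh_frames + 1):nf
      df <- rbind(merged,
                  data.frame(track = id1, frame = frames[rest],
                             x = p1[rest, 1], y = p1[rest, 2],
                             intensity = inten(params$intensity_single,
                                               length(rest))),
                  data.frame(track = id2, frame = frames[rest],
                             x = p2[rest, 1], y = p2[rest, 2],
                             intensity = inten(params$intensity_single,
                                               length(rest))))
    } else {
      df <- rbind(data.frame(track = id1, frame = frames, x = p1[, 1],
                             y = p1[, 2],
                             intensity = inten(params$intensity_single, nf)),
                  data.frame(track = id2, frame = frames, x = p2[, 1],
                             y = p2[, 2],
                             intensity = inten(params$intensity_single, nf)))
    }
    truth <- list(pair_id = pair_id, speed_um_min = params$speed_um_min,
                  cohesion_frames = coh_frames,
                  plateau_frame = plateau_frame,
                  transverse_sd_um = params$transverse_sd_um,
                  sep_true = s, x1 = x1, x2 = x2, y1 = y1, y2 = y2)
    list(spots = spot_table(df, dt = dt), truth = truth)
  })
}

#' Generate a multi-pair synthetic dataset
#'
#' Concatenates `n_pairs` independent origin pairs (cells scattered over the
#' imaging field, unique track ids) into one spot table. Deterministic under
#' `(params, seed)`.
#'
#' @param n_pairs number of origin pairs (`>= 1`).
#' @param params a [synth_track_params()].
#' @param seed RNG seed.
#' @return A list: `spots` (combined [spot_table()]) and `truth` (list of
#'   per-pair ground truths).
#' @export
generate_dataset <- function(n_pairs, params = synth_track_params(), seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_pairs))
  out <- lapply(seq_len(n_pairs), function(i)
    generate_track_pair(params, seed = sub_seeds[i], pair_id = i))
  spots <- do.call(rbind, lapply(out, function(o) as.data.frame(o$spots)))
  spots$time_s <- NULL
  list(spots = spot_table(spots, dt = params$frame_interval_s),
       truth = lapply(out, function(o) o$truth))
}
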