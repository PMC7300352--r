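# Experimental-side pipeline: pair origin foci from spot-tracking exports,
# build per-pair separation clouds, rotate onto the cloud's principal axes,
# and compute displacement statistics. All stages are invariant under rigid
# motion of the input coordinates (stage drift, cell sliding), because only
# position differences within a frame enter the analysis.

#' Construct / validate a spot table
#'
#' A spot table holds one row per detected focus: track id, frame index,
#' x/y position (micrometres, image coordinates) and intensity. The frame
#' interval defaults to the 10-s acquisition of the time-lapse movies.
#'
#' @param df data frame with columns `track`, `frame`, `x`, `y`, `intensity`.
#' @param dt frame interval in seconds.
#' @return The validated data frame, class `spot_table`, with attribute `dt`.
#' @export
spot_table <- function(df, dt = 10) {
  need <- c("track", "frame", "x", "y", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("track", "frame")]) > 0)
    stop("integrity error: duplicate (track, frame) rows")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite coordinates in spot table")
  df <- df[order(df$track, df$frame), , drop = FALSE]
  df$time_s <- df$frame * dt
  rownames(df) <- NULL
  structure(df, class = c("spot_table", "data.frame"), dt = dt)
}

#' Read a TrackMate-style spot CSV
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the internal names
#'   `track`, `frame`, `x`, `y`, `intensity` to the file's column headers.
#' @param dt frame interval, seconds.
#' @return A [spot_table()].
#' @export
read_spot_csv <- function(path,
                          column_map = c(track = "TRACK_ID", frame = "FRAME",
                                         x = "POSITION_X", y = "POSITION_Y",
                                         intensity = "MEAN_INTENSITY"),
                          dt = 10) {
  raw <- read.csv(path, check.names = FALSE)
  miss <- setdiff(unname(column_map), names(raw))
  if (length(miss) > 0)
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df <- data.frame(track = raw[[column_map[["track"]]]],
                   frame = raw[[column_map[["frame"]]]],
                   x = raw[[column_map[["x"]]]],
                   y = raw[[column_map[["y"]]]],
                   intensity = raw[[column_map[["intensity"]]]])
  spot_table(df, dt = dt)
}

#' Write a spot table as TrackMate-style CSV
#'
#' Values are written at full precision; a write-then-read round trip
#' reproduces coordinates to better than 1e-9 um.
#'
#' @param table a [spot_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spot_csv <- function(table, path) {
  out <- data.frame(TRACK_ID = table$track, FRAME = table$frame,
                    POSITION_X = format(table$x, digits = 17, trim = TRUE),
                    POSITION_Y = format(table$y, digits = 17, trim = TRUE),
                    MEAN_INTENSITY = format(table$intensity, digits = 17,
                                            trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair origin foci
#'
#' Pairs of origins are followed from the time they are overlapping, which is
#' detected either by close proximity (two tracks closer than `d_max`) or by
#' a fluorescence level at least `intensity_ratio` times that of a single
#' origin followed by a split into two tracks. The single-origin reference
#' level is the per-movie median spot intensity. Pairs extend from the
#' qualifying frame to the last frame both tracks share.
#'
#' @param table a [spot_table()] (one movie).
#' @param d_max proximity threshold, micrometres (default 0.2 um).
#' @param intensity_ratio intensity-doubling threshold (default 2).
#' @return A list of `origin_track_pair` objects; empty when no pair
#'   qualifies. Each pair holds two aligned series `t1`, `t2` (data frames
#'   `frame`, `time_s`, `x`, `y`, `intensity`), `start_frame` and `rule`
#'   (`"proximity"` or `"intensity"`).
#' @export
pair_origins <- function(table, d_max = 0.2, intensity_ratio = 2.0) {
  stopifnot(inherits(table, "spot_table"))
  dt <- attr(table, "dt")
  ref <- median(table$intensity)
  tracks <- split(table, table$track)
  ids <- names(tracks)
  pairs <- list()
  used <- character(0)

  # proximity rule: earliest frame at which two tracks are closer than d_max
  cand <- list()
  if (length(ids) >= 2) {
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        a <- tracks[[i]]; b <- tracks[[j]]
        common <- intersect(a$frame, b$frame)
        if (length(common) == 0) next
        ai <- a[match(common, a$frame), ]
        bi <- b[match(common, b$frame), ]
        d <- sqrt((ai$x - bi$x)^2 + (ai$y - bi$y)^2)
        hit <- which(d < d_max)
        if (length(hit) > 0) {
          cand[[length(cand) + 1]] <- list(i = ids[i], j = ids[j],
                                           frame = common[hit[1]],
                                           d = d[hit[1]], rule = "proximity")
        }
      }
    }
  }
  # intensity rule: a track bright enough to be two overlapped origins that
  # later coexists with (splits into) a second track
  if (length(ids) >= 2) {
    for (i in seq_along(ids)) {
      a <- tracks[[i]]
      bright <- a$frame[a$intensity >= intensity_ratio * ref]
      if (length(bright) == 0) next
      for (j in seq_along(ids)) {
        if (j == i) next
        b <- tracks[[j]]
        if (min(b$frame) <= min(bright)) next  # not a split: b existed before
        split_frame <- min(b$frame)
        common <- intersect(a$frame, b$frame)
        if (length(common) == 0) next
        cand[[length(cand) + 1]] <- list(i = ids[i], j = ids[j],
                                         frame = split_frame, d = Inf,
                                         rule = "intensity")
      }
    }
  }
  if (length(cand) == 0) return(list())
  ord <- order(vapply(cand, function(c) c$frame, 0),
               vapply(cand, function(c) c$d, 0))
  multiway <- FALSE
  for (k in ord) {
    cc <- cand[[k]]
    if (cc$i %in% used || cc$j %in% used) {
      multiway <- TRUE
      next
    }
    a <- tracks[[cc$i]]; b <- tracks[[cc$j]]
    common <- intersect(a$frame, b$frame)
    common <- sort(common[common >= cc$frame])
    # trim to the gap-free leading stretch so both series cover every frame
    if (length(common) == 0) next
    gaps <- which(diff(common) != 1)
    keep <- if (length(gaps) == 0) common else common[seq_len(gaps[1])]
    ai <- a[match(keep, a$frame), c("frame", "time_s", "x", "y", "intensity")]
    bi <- b[match(keep, b$frame), c("frame", "time_s", "x", "y", "intensity")]
    rownames(ai) <- rownames(bi) <- NULL
    pairs[[length(pairs) + 1]] <-
      structure(list(t1 = ai, t2 = bi, start_frame = cc$frame,
                     rule = cc$rule, tracks = c(cc$i, cc$j)),
                class = "origin_track_pair")
    used <- c(used, cc$i, cc$j)
  }
  if (multiway)
    warning("ambiguous multi-way proximity: nearest-pair greedy matching used")
  pairs
}

#' @export
print.origin_track_pair <- function(x, ...) {
  cat(sprintf("origin_track_pair: tracks %s & %s, %d frames from frame %d (%s rule)\n",
              x$tracks[1], x$tracks[2], nrow(x$t1), x$start_frame, x$rule))
  invisible(x)
}

#' Per-frame separation vectors of an origin pair
#'
#' @param pair an `origin_track_pair`.
#' @return Data frame `frame`, `time_s`, `dx`, `dy`: the difference vector
#'   (position 1 minus position 2) in image coordinates.
#' @export
separation_cloud <- function(pair) {
  stopifnot(inherits(pair, "origin_track_pair"))
  data.frame(frame = pair$t1$frame, time_s = pair$t1$time_s,
             dx = pair$t1$x - pair$t2$x, dy = pair$t1$y - pair$t2$y)
}

#' Principal-axis transform of a separation cloud
#'
#' Rotates the cloud of separation vectors onto the orthonormal eigenvectors
#' of its second-moment matrix about the mean: the long axis (larger
#' variance, "longest extension") becomes x and the perpendicular becomes y.
#' The long axis is oriented so the final frame's x is non-negative. Because
#' only within-frame differences enter, the output is invariant under rigid
#' rotation/translation of the input coordinates (stage or cell drift).
#'
#' @param cloud output of [separation_cloud()] (needs `>= 3` distinct
#'   points).
#' @return A list: `x`, `y` (projections per frame), `time_s`, `frame`,
#'   `axes` (2 x 2 matrix, columns = long and short axis).
#' @export
principal_axis_transform <- function(cloud) {
  pts <- cbind(cloud$dx, cloud$dy)
  if (nrow(unique(pts)) < 3)
    stop("need at least 3 distinct points for a principal-axis transform")
  ctr <- colMeans(pts)
  M <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  eg <- eigen(M, symmetric = TRUE)
  if (eg$values[2] > 0 && eg$values[1] / eg$values[2] < 1.01) {
    warning("separation cloud nearly isotropic: principal axes ambiguous, ",
            "using image axes")
    axes <- diag(2)
  } else {
    axes <- eg$vectors  # columns ordered by decreasing variance
  }
  x <- pts %*% axes[, 1]
  y <- pts %*% axes[, 2]
  if (x[length(x)] < 0) {
    x <- -x
    axes[, 1] <- -axes[, 1]
  }
  list(x = as.numeric(x), y = as.numeric(y), time_s = cloud$time_s,
       frame = cloud$frame, axes = axes)
}

#' Mean displacement versus time lag
#'
#' For each lag `n` (tau = n * dt), the mean over all tracks and all start
#' frames of `|s(t + n*dt) - s(t)|`, pooling overlapping windows.
#'
#' @param series_list list of numeric vectors (one per track), sampled at the
#'   frame interval.
#' @param max_lag largest lag, in frames.
#' @param dt frame interval, seconds.
#' @return An object of class `lag_displacement`: data frame `lag_frames`,
#'   `lag_s`, `mean_disp`, `n_obs`; attribute `per_track` holds one mean-
#'   displacement matrix row per track.
#' @export
lag_displacement <- function(series_list, max_lag, dt = 10) {
  if (is.numeric(series_list)) series_list <- list(series_list)
  if (any(vapply(series_list, length, 0L) <= max_lag))
    stop("every series must be longer than max_lag")
  per <- matrix(NA_real_, nrow = length(series_list), ncol = max_lag)
  nobs <- integer(max_lag)
  pooled <- numeric(max_lag)
  for (n in seq_len(max_lag)) {
    all_d <- c()
    for (k in seq_along(series_list)) {
      s <- series_list[[k]]
      d <- abs(s[(1 + n):length(s)] - s[seq_len(length(s) - n)])
      per[k, n] <- mean(d)
      all_d <- c(all_d, d)
    }
    pooled[n] <- mean(all_d)
    nobs[n] <- length(all_d)
  }
  structure(data.frame(lag_frames = seq_len(max_lag),
                       lag_s = seq_len(max_lag) * dt,
                       mean_disp = pooled, n_obs = nobs),
            class = c("lag_displacement", "data.frame"), per_track = per)
}

#' Ordinary least-squares trend of a separation series
#'
#' @param time time values.
#' @param x separation values.
#' @return A list: `slope` (per unit of `time`), `intercept`, `r_squared`,
#'   `slope_se`.
#' @export
linear_trend <- function(time, x) {
  if (length(time) < 3) stop("need at least 3 points")
  fit <- lm(x ~ time)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, slope_se = sm$coefficients[2, 2])
}

#' Run the full track pipeline on a spot table
#'
#' Pairs origins, builds each pair's separation cloud, rotates onto principal
#' axes, and computes the linear trend and a lag-displacement curve per axis.
#'
#' @param table a [spot_table()].
#' @param d_max,intensity_ratio pairing thresholds, see [pair_origins()].
#' @param max_lag largest displacement lag in frames (default: a third of
#'   the shortest paired series).
#' @return A list with `pairs` (per-pair lists: `pair`, `cloud`, `series`,
#'   `trend`), and pooled `lag_x`, `lag_y` curves (when `>= 1` pair).
#' @export
analyze_tracks <- function(table, d_max = 0.2, intensity_ratio = 2.0,
                           max_lag = NULL) {
  prs <- pair_origins(table, d_max = d_max, intensity_ratio = intensity_ratio)
  if (length(prs) == 0) return(list(pairs = list(), lag_x = NULL, lag_y = NULL))
  dt <- attr(table, "dt")
  per <- lapply(prs, function(pr) {
    cloud <- separation_cloud(pr)
    ser <- principal_axis_transform(cloud)
    trend <- linear_trend(ser$time_s, ser$x)
    list(pair = pr, cloud = cloud, series = ser, trend = trend)
  })
  xs <- lapply(per, function(p) p$series$x)
  ys <- lapply(per, function(p) p$series$y)
  if (is.null(max_lag))
    max_lag <- max(1L, floor(min(vapply(xs, length, 0L)) / 3))
  keep <- vapply(xs, length, 0L) > max_lag
  list(pairs = per,
       lag_x = if (any(keep)) lag_displacement(xs[keep], max_lag, dt) else NULL,
       lag_y = if (any(keep)) lag_displacement(ys[keep], max_lag, dt) else NULL)
}

#' Estimate the separation speed from a principal-axis series
#'
#' Fits an OLS slope to the translocation window of `x(t)`: from the detected
#' onset of separation (last time the median-smoothed series is below
#' `onset_level`) to the first time it reaches 90% of its final level (or the
#' series end when it never plateaus). Used for parameter-recovery checks
#' against the synthetic-track generator.
#'
#' @param time_s time values, seconds.
#' @param x long-axis separation, micrometres.
#' @param onset_level separation regarded as "still overlapping"
#'   (micrometres).
#' @return A list: `speed_um_min`, `onset_s` (zero-separation crossing of the
#'   fitted line, an unbiased onset estimate), `window` (index range).
#' @export
estimate_separation_speed <- function(time_s, x, onset_level = 0.15) {
  n <- length(x)
  sm <- if (n >= 7) stats::runmed(x, 5) else x
  final <- median(sm[max(1, n - max(3, n %/% 10)):n])
  onset_idx <- which(sm < onset_level)
  i0 <- if (length(onset_idx) > 0) max(onset_idx) else 1L
  hi <- which(sm >= 0.9 * final)
  i1 <- if (length(hi) > 0 && final > onset_level) min(hi[hi > i0], n) else n
  if (!is.finite(i1) || i1 - i0 < 3) {
    i0 <- 1L
    i1 <- n
  }
  tr <- linear_trend(time_s[i0:i1], x[i0:i1])
  # onset = where the fitted translocation line crosses zero separation
  # (a threshold crossing would lag the true onset by threshold/speed)
  onset <- if (is.finite(tr$slope) && tr$slope > 0)
    -tr$intercept / tr$slope else time_s[i0]
  onset <- min(max(onset, time_s[1]), time_s[n])
  list(speed_um_min = tr$slope * 60, onset_s = onset, window = c(i0, i1))
}
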