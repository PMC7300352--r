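# Segregation statistics: overlap measure, origin separation series,
# ensemble averages, final normalized positions, and step-size statistics.

#' Degree of separation of two chromosomes
#'
#' The longitudinal overlap of the two chromosomes' x-extent intervals,
#' divided by the longitudinal extent of the shorter chromosome. 1 means the
#' shorter chromosome lies entirely within the longer one's span; 0 means the
#' extents are disjoint (fully segregated).
#'
#' @param coords_a,coords_b bead coordinates of each chromosome: either a
#'   numeric vector of x positions or a matrix whose first column is x.
#' @return The overlap fraction (`>= 0`; 0 = fully segregated).
#' @examples
#' degree_of_separation(c(0, 2), c(3, 5))  # 0
#' degree_of_separation(c(0, 2), c(1, 4))  # 0.5
#' @export
degree_of_separation <- function(coords_a, coords_b) {
  xa <- if (is.matrix(coords_a)) coords_a[, 1] else coords_a
  xb <- if (is.matrix(coords_b)) coords_b[, 1] else coords_b
  if (length(xa) < 1 || length(xb) < 1) stop("chromosomes must be non-empty")
  ext_a <- max(xa) - min(xa)
  ext_b <- max(xb) - min(xb)
  if (ext_a <= 0 || ext_b <= 0)
    stop("undefined metric: zero-extent chromosome")
  overlap <- max(0, min(max(xa), max(xb)) - max(min(xa), min(xb)))
  overlap / min(ext_a, ext_b)
}

#' Origin-origin separation series of a simulated trajectory
#'
#' Per sampled frame, the absolute separation of the two origins along the
#' cell long axis (`dx`) and the transverse axis (`dy`), converted to
#' micrometres. Frames before the first duplication event carry `dx = dy = 0`
#' (the single shared origin).
#'
#' @param traj a `sim_trajectory` from [run_replication_sim()].
#' @param replication_only drop post-replication frames (default `TRUE`,
#'   matching analyses over the replication period).
#' @return An object of class `separation_series`: data frame with `time_s`,
#'   `dx`, `dy` (micrometres) and attribute `source = "simulation"`.
#' @export
ori_separation_series <- function(traj, replication_only = TRUE) {
  stopifnot(inherits(traj, "sim_trajectory"))
  fr <- traj$frames
  if (replication_only) fr <- fr[seq_len(traj$repl_end_frame), , drop = FALSE]
  if (any(is.na(fr$ori1_x)))
    stop("data integrity: missing ori position in a frame")
  um <- traj$d_b_um
  dx <- abs(fr$ori1_x - fr$ori2_x) * um
  dy <- abs(fr$ori1_y - fr$ori2_y) * um
  dx[is.na(dx)] <- 0
  dy[is.na(dy)] <- 0
  out <- data.frame(time_s = fr$time_s, dx = dx, dy = dy)
  structure(out, class = c("separation_series", "data.frame"),
            source = "simulation")
}

#' Pointwise ensemble average of separation series
#'
#' Resamples every series onto a common time grid by linear interpolation and
#' returns the pointwise mean and standard error of the mean (SD/sqrt(n)) of
#' `dx` and `dy`.
#'
#' @param series_list a list of `separation_series` (or data frames with
#'   `time_s`, `dx`, `dy`); at least 2.
#' @param grid optional common time grid (seconds); defaults to the coarsest
#'   series' times restricted to the overlap of all series.
#' @return An object of class `ensemble_summary`: data frame `time_s`,
#'   `mean_dx`, `sem_dx`, `mean_dy`, `sem_dy`, with attribute `n_tracks`.
#' @export
ensemble_average <- function(series_list, grid = NULL) {
  if (length(series_list) < 2) stop("need at least 2 series")
  t0 <- max(vapply(series_list, function(s) min(s$time_s), 0))
  t1 <- min(vapply(series_list, function(s) max(s$time_s), 0))
  if (t1 <= t0) stop("series have no overlapping time range")
  if (is.null(grid)) {
    npt <- min(vapply(series_list, nrow, 0L))
    grid <- seq(t0, t1, length.out = npt)
  }
  dx <- sapply(series_list, function(s) approx(s$time_s, s$dx, xout = grid)$y)
  dy <- sapply(series_list, function(s) approx(s$time_s, s$dy, xout = grid)$y)
  n <- length(series_list)
  out <- data.frame(time_s = grid,
                    mean_dx = rowMeans(dx), sem_dx = apply(dx, 1, sd) / sqrt(n),
                    mean_dy = rowMeans(dy), sem_dy = apply(dy, 1, sd) / sqrt(n))
  structure(out, class = c("ensemble_summary", "data.frame"), n_tracks = n)
}

#' Plot an ensemble summary with SEM error bars
#'
#' @param x an `ensemble_summary`.
#' @param every draw an error bar every `every` points.
#' @param ... passed to [plot()].
#' @export
plot.ensemble_summary <- function(x, every = 10, ...) {
  plot(x$time_s / 60, x$mean_dx, type = "l", col = "darkgreen",
       xlab = "time (min)", ylab = "mean ori-ori distance (um)",
       ylim = range(0, x$mean_dx + x$sem_dx), ...)
  idx <- seq(1, nrow(x), by = every)
  arrows(x$time_s[idx] / 60, x$mean_dx[idx] - x$sem_dx[idx],
         x$time_s[idx] / 60, x$mean_dx[idx] + x$sem_dx[idx],
         angle = 90, code = 3, length = 0.02, col = "darkgreen")
  lines(x$time_s / 60, x$mean_dy, col = "orange")
  legend("topleft", c("x (long axis)", "y"), col = c("darkgreen", "orange"),
         lty = 1, bty = "n")
  invisible(x)
}

#' Final normalized origin positions
#'
#' For each run, both origin x-positions at the last replication frame are
#' mapped into the unit cell via `(x + L/2) / L` (0 and 1 are the poles) and
#' the larger/smaller are identified per run. Returns the across-run means
#' and SEMs of the high and low positions.
#'
#' @param trajs a list of `sim_trajectory` objects, each complete through the
#'   end of replication.
#' @return A list: `mean_high`, `mean_low`, `sem_high`, `sem_low`,
#'   `per_run` (data frame with one row per run).
#' @export
final_normalized_positions <- function(trajs) {
  per <- lapply(trajs, function(tr) {
    fr <- tr$frames[tr$repl_end_frame, ]
    L <- fr$cell_length_db
    p1 <- (fr$ori1_x + L / 2) / L
    p2 <- (fr$ori2_x + L / 2) / L
    data.frame(high = max(p1, p2), low = min(p1, p2))
  })
  per <- do.call(rbind, per)
  n <- nrow(per)
  list(mean_high = mean(per$high), mean_low = mean(per$low),
       sem_high = sd(per$high) / sqrt(n), sem_low = sd(per$low) / sqrt(n),
       per_run = per)
}

#' Step-size statistics of separation series
#'
#' Pools the signed per-frame increments of the long-axis separation over all
#' series and summarizes their distribution: a histogram density
#' (Freedman-Diaconis binning), a Gaussian fit by maximum likelihood,
#' probability-plot pairs (empirical quantiles vs fitted-normal quantiles),
#' and a Shapiro-Wilk normality statistic. Shapiro-Wilk accepts at most
#' 5,000 observations; larger pooled samples are thinned deterministically to
#' 5,000 evenly spaced values for the test (the fit uses all steps).
#'
#' Leading frames in which the separation is structurally zero (before the
#' daughter origin exists there is a single shared focus) carry no step
#' information and are excluded up to the last zero frame, so the first real
#' step of each series is retained.
#'
#' @param series_list list of `separation_series` (or data frames with `dx`).
#' @param min_steps minimum pooled step count.
#' @return An object of class `step_stats`: `steps`, `pdf` (data frame
#'   `mid`, `density`), `fit` (`mean`, `sd`), `prob_plot` (data frame
#'   `empirical`, `theoretical`), `normality` (`W`, `p_value`, `n_tested`),
#'   `degenerate` flag.
#' @export
step_size_stats <- function(series_list, min_steps = 100) {
  if (inherits(series_list, "separation_series")) series_list <- list(series_list)
  steps <- unlist(lapply(series_list, function(s) {
    dx <- s$dx
    first <- which(dx != 0)[1]
    if (!is.na(first) && first > 1) dx <- dx[(first - 1):length(dx)]
    diff(dx)
  }), use.names = FALSE)
  if (length(steps) < min_steps)
    stop(sprintf("insufficient steps: %d < %d", length(steps), min_steps))
  if (sd(steps) == 0) {
    return(structure(list(steps = steps, pdf = NULL, fit = NULL,
                          prob_plot = NULL, normality = NULL,
                          degenerate = TRUE),
                     class = "step_stats"))
  }
  h <- hist(steps, breaks = "FD", plot = FALSE)
  n <- length(steps)
  fit <- list(mean = mean(steps), sd = sd(steps) * sqrt((n - 1) / n))
  qs <- sort(steps)
  theo <- qnorm(ppoints(n), mean = fit$mean, sd = fit$sd)
  test_sample <- if (n > 5000) qs[round(seq(1, n, length.out = 5000))] else steps
  sw <- shapiro.test(test_sample)
  structure(list(steps = steps,
                 pdf = data.frame(mid = h$mids, density = h$density),
                 fit = fit,
                 prob_plot = data.frame(empirical = qs, theoretical = theo),
                 normality = list(W = unname(sw$statistic),
                                  p_value = sw$p.value,
                                  n_tested = length(test_sample)),
                 degenerate = FALSE),
            class = "step_stats")
}

#' @export
print.step_stats <- function(x, ...) {
  if (x$degenerate) {
    cat("step_stats: degenerate (all steps identical), no fit performed\n")
    return(invisible(x))
  }
  cat(sprintf("step_stats: %d pooled steps\n", length(x$steps)))
  cat(sprintf("  Gaussian fit: mean %.4g, sd %.4g um\n", x$fit$mean, x$fit$sd))
  cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.3g (n tested = %d)\n",
              x$normality$W, x$normality$p_value, x$normality$n_tested))
  invisible(x)
}

#' Plot step-size PDF with Gaussian fit, and the probability plot
#'
#' @param x a `step_stats` object.
#' @param which `"pdf"`, `"probability"` or `"both"`.
#' @param ... passed to plotting functions.
#' @export
plot.step_stats <- function(x, which = c("both", "pdf", "probability"), ...) {
  which <- match.arg(which)
  if (x$degenerate) stop("degenerate step distribution; nothing to plot")
  if (which == "both") {
    op <- par(mfrow = c(1, 2))
    on.exit(par(op))
  }
  if (which %in% c("both", "pdf")) {
    plot(x$pdf$mid, x$pdf$density, type = "s", xlab = "step size (um)",
         ylab = "density", ...)
    xs <- seq(min(x$steps), max(x$steps), length.out = 200)
    lines(xs, dnorm(xs, x$fit$mean, x$fit$sd), col = "red")
  }
  if (which %in% c("both", "probability")) {
    plot(x$prob_plot$theoretical, x$prob_plot$empirical,
         xlab = "normal quantiles", ylab = "empirical quantiles",
         col = adjustcolor("blue", 0.4), pch = 16, cex = 0.5, ...)
    abline(0, 1, col = "red")
  }
  invisible(x)
}
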