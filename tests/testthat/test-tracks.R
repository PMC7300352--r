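test_that("pairing fires by proximity exactly at the 0.2-um threshold", {
  # two tracks converging: distance 0.25 until frame 11, 0.15 from frame 12
  nf <- 30
  d <- c(rep(0.25, 12), rep(0.15, nf - 12))  # frames 0..29, frame 12 first < 0.2
  x1 <- rep(0, nf); y1 <- rep(0, nf)
  x2 <- d; y2 <- rep(0, nf)
  tab <- two_track_table(x1, y1, x2, y2)
  prs <- pair_origins(tab, d_max = 0.2)
  expect_length(prs, 1)
  expect_equal(prs[[1]]$start_frame, 12)
  expect_equal(prs[[1]]$rule, "proximity")
  # pair extends to the last common frame
  expect_equal(max(prs[[1]]$t1$frame), nf - 1)

  # exactly at the threshold: 0.2 is NOT "less than 0.2 um"
  tab_eq <- two_track_table(x1, y1, rep(0.2, nf), y2)
  expect_length(pair_origins(tab_eq, d_max = 0.2), 0)
  tab_in <- two_track_table(x1, y1, rep(0.2 - 1e-9, nf), y2)
  expect_length(pair_origins(tab_in, d_max = 0.2), 1)
})

test_that("pairing fires by intensity doubling at a split", {
  # a single bright track (2.3x median) splits at frame 30; the two daughter
  # tracks are never in sub-0.2-um proximity, so only the intensity rule fires
  df <- rbind(
    data.frame(track = 1L, frame = 0:29, x = 0, y = 0, intensity = 230),
    data.frame(track = 1L, frame = 30:59, x = seq(0.125, 1, length.out = 30),
               y = 0, intensity = 100),
    data.frame(track = 2L, frame = 30:59, x = -seq(0.125, 1, length.out = 30),
               y = 0, intensity = 100),
    # far-away singles defining the single-focus reference level
    data.frame(track = 3L, frame = 0:59, x = 50, y = 50, intensity = 100),
    data.frame(track = 4L, frame = 0:59, x = 80, y = 10, intensity = 100))
  tab <- spot_table(df)
  prs <- pair_origins(tab)
  expect_length(prs, 1)
  expect_equal(prs[[1]]$start_frame, 30)
  expect_equal(prs[[1]]$rule, "intensity")
  # exactly 2x the median fires; just below does not
  df2 <- df; df2$intensity[df2$track == 1L & df2$frame < 30] <- 200
  expect_length(pair_origins(spot_table(df2)), 1)
  df3 <- df; df3$intensity[df3$track == 1L & df3$frame < 30] <- 200 - 1e-6
  expect_length(pair_origins(spot_table(df3)), 0)
})

test_that("tracks that never meet either rule yield no pairs", {
  nf <- 40
  tab <- two_track_table(rep(0, nf), rep(0, nf), rep(0.5, nf), rep(0, nf))
  expect_length(pair_origins(tab), 0)
})

test_that("separation clouds are per-frame differences; label swap negates them", {
  nf <- 10
  tab <- two_track_table(seq(1, 2, length.out = nf), rep(0, nf),
                         rep(0, nf), rep(0, nf))
  pr <- pair_origins(tab, d_max = 2)[[1]]
  cl <- separation_cloud(pr)
  expect_equal(cl$dx[1], 1 - 0)
  expect_equal(cl$dx[nf], 2)
  # identical series -> all-zero cloud
  tabz <- two_track_table(rep(1, nf), rep(2, nf), rep(1, nf), rep(2, nf))
  prz <- pair_origins(tabz, d_max = 0.2)[[1]]
  expect_true(all(separation_cloud(prz)$dx == 0))
  # swapping origin labels negates the cloud
  pr_sw <- pr
  pr_sw$t1 <- pr$t2; pr_sw$t2 <- pr$t1
  expect_equal(separation_cloud(pr_sw)$dx, -cl$dx)
})

test_that("principal axes recover the separation direction to within a degree", {
  set.seed(5)
  n <- 200
  long <- seq(0, 2, length.out = n) + rnorm(n, 0, 0.05)
  short <- rnorm(n, 0, 0.03)
  ang <- 30 * pi / 180
  cloud <- data.frame(frame = seq_len(n), time_s = seq_len(n) * 10,
                      dx = long * cos(ang) - short * sin(ang),
                      dy = long * sin(ang) + short * cos(ang))
  tf <- principal_axis_transform(cloud)
  got <- atan2(tf$axes[2, 1], tf$axes[1, 1]) * 180 / pi
  expect_lt(min(abs(got - 30), abs(got + 150)), 1)
  # orientation convention: final x >= 0
  expect_gte(tf$x[n], 0)
  # rotating the inputs leaves x(t), y(t) unchanged up to sign
  th <- 57 * pi / 180
  cloud2 <- within(cloud, {
    dx2 <- dx * cos(th) - dy * sin(th)
    dy <- dx * sin(th) + dy * cos(th)
    dx <- dx2
    rm(dx2)
  })
  tf2 <- principal_axis_transform(cloud2)
  expect_equal(tf2$x, tf$x, tolerance = 1e-9)
  expect_equal(abs(tf2$y), abs(tf$y), tolerance = 1e-9)
  # circularly symmetric cloud: ambiguity warning
  tt <- seq(0, 2 * pi, length.out = 401)[-401]
  iso <- data.frame(frame = seq_along(tt), time_s = seq_along(tt),
                    dx = cos(tt), dy = sin(tt))
  expect_warning(principal_axis_transform(iso), "isotropic")
})

test_that("lag displacement is exact for ballistic and constant motion", {
  v <- 0.02
  s <- v * (0:100) * 10
  lc <- lag_displacement(list(s), max_lag = 20, dt = 10)
  expect_equal(lc$mean_disp, v * lc$lag_s, tolerance = 1e-12)
  lc0 <- lag_displacement(list(rep(3, 50)), max_lag = 10)
  expect_true(all(lc0$mean_disp == 0))
  expect_error(lag_displacement(list(s), max_lag = 101), "longer than")
})

test_that("random-walk lag curve matches the folded-normal oracle", {
  set.seed(9)
  sigma <- 0.05
  walks <- replicate(100, cumsum(rnorm(101, 0, sigma)), simplify = FALSE)
  lc <- lag_displacement(walks, max_lag = 10, dt = 10)
  # E|N(0, n sigma^2)| = sigma sqrt(n) sqrt(2/pi)
  oracle <- sigma * sqrt(lc$lag_frames) * sqrt(2 / pi)
  expect_equal(lc$mean_disp, oracle, tolerance = 0.05)
})

test_that("linear trends behave like OLS should", {
  t <- 0:999
  tr <- suppressWarnings(linear_trend(t, 0.01 * t))  # exact fit
  expect_equal(tr$slope, 0.01, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1)
  # translation invariance
  tr2 <- suppressWarnings(linear_trend(t, 0.01 * t + 5))
  expect_equal(tr2$slope, 0.01, tolerance = 1e-12)
  # pure noise: slope within 3 SEs in nearly all repetitions
  set.seed(13)
  ok <- vapply(1:200, function(i) {
    fit <- linear_trend(t, rnorm(1000))
    abs(fit$slope) < 3 * fit$slope_se
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("the full pipeline is invariant under rigid motion and label swaps", {
  # synthetic pair, no drift in the generator; apply rigid motions afterwards
  pars <- synth_track_params(loc_noise_sd_um = 0.02, drift_sd_um = 0,
                             cohesion_mean_min = 3, duration_min = 40)
  tab <- generate_track_pair(pars, seed = 31)$spots
  base <- analyze_tracks(tab)$pairs[[1]]

  # rotation + constant translation + per-frame common drift
  set.seed(77)
  drift <- matrix(cumsum(rnorm(2 * length(unique(tab$frame)), 0, 0.05)),
                  ncol = 2)
  moved <- apply_rigid_motion(tab, theta = 1.1, shift = drift)
  got <- analyze_tracks(moved)$pairs[[1]]
  expect_lt(max(abs(abs(got$series$x) - abs(base$series$x))), 1e-6)
  expect_lt(max(abs(abs(got$series$y) - abs(base$series$y))), 1e-6)

  # label swap: swap the two track ids
  sw <- as.data.frame(tab)
  sw$track <- ifelse(sw$track == 1, 2L, 1L)
  sw <- spot_table(sw[, c("track", "frame", "x", "y", "intensity")])
  got2 <- analyze_tracks(sw)$pairs[[1]]
  expect_equal(abs(got2$series$x), abs(base$series$x), tolerance = 1e-9)
  expect_equal(abs(got2$series$y), abs(base$series$y), tolerance = 1e-9)
  expect_equal(got2$pair$start_frame, base$pair$start_frame)
})

test_that("simulation output fed through the track pipeline matches dx(t)", {
  # build a spot table from a simulated trajectory's two ori positions with
  # the cell axis along image x; pipeline x(t) must equal the metrics dx(t)
  cfg <- tiny_config(n_beads = 12)
  tr <- run_replication_sim(cfg, seed = 5)
  fr <- tr$frames[seq_len(tr$repl_end_frame), ]
  fr <- fr[!is.na(fr$ori2_x), ]
  fr <- fr[seq_len(nrow(fr)) > 5, ]  # drop frames before both oris exist
  um <- tr$d_b_um
  # cell axis along image x; transverse motion suppressed so the separation
  # cloud's long axis is exactly the cell axis
  tab <- spot_table(data.frame(
    track = rep(1:2, each = nrow(fr)),
    frame = rep(seq_len(nrow(fr)) - 1L, 2),
    x = c(fr$ori1_x, fr$ori2_x) * um,
    y = 0,
    intensity = 100))
  res <- analyze_tracks(tab, d_max = Inf)
  ser <- res$pairs[[1]]$series
  dx <- abs(fr$ori1_x - fr$ori2_x) * um
  expect_equal(abs(ser$x), dx, tolerance = 1e-9)
})
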