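test_that("degree of separation matches the interval definition and an oracle", {
  expect_equal(degree_of_separation(c(0, 2), c(3, 5)), 0)
  expect_equal(degree_of_separation(c(0, 2), c(0, 2)), 1)
  expect_equal(degree_of_separation(c(0, 2), c(1, 4)), 0.5)
  expect_error(degree_of_separation(c(1, 1), c(0, 2)), "zero-extent")
  expect_error(degree_of_separation(numeric(0), c(0, 2)), "non-empty")

  # brute-force min/max interval oracle on random configurations
  oracle <- function(xa, xb) {
    lo <- max(min(xa), min(xb)); hi <- min(max(xa), max(xb))
    max(0, hi - lo) / min(max(xa) - min(xa), max(xb) - min(xb))
  }
  set.seed(11)
  for (i in 1:25) {
    xa <- runif(sample(2:200, 1), -10, 10)
    xb <- runif(sample(2:200, 1), -12, 8)
    expect_identical(degree_of_separation(xa, xb), oracle(xa, xb))
    # matrices: first column is x
    expect_identical(degree_of_separation(cbind(xa, 0, 0), cbind(xb, 0, 0)),
                     oracle(xa, xb))
  }
})

# minimal hand-made trajectory for series tests
fake_traj <- function(ori1_x, ori2_x, ori1_y = 0 * ori1_x, ori2_y = 0 * ori2_x,
                      L = 60) {
  n <- length(ori1_x)
  frames <- data.frame(step = seq_len(n), time_s = seq_len(n) * 10,
                       ori1_x = ori1_x, ori1_y = ori1_y, ori1_z = 0,
                       ori2_x = ori2_x, ori2_y = ori2_y, ori2_z = 0,
                       chr1_xmin = -10, chr1_xmax = 10,
                       chr2_xmin = -10, chr2_xmax = 10,
                       cell_length_db = L, cell_radius_db = 6,
                       n_beads = 2, frame = seq_len(n))
  structure(list(frames = frames, repl_end_frame = n, final_state = NULL,
                 censored = FALSE, config = NULL, seed = 0, d_b_um = 0.075),
            class = "sim_trajectory")
}

test_that("origin separation series converts to micrometres and handles symmetry", {
  tr <- fake_traj(ori1_x = c(-1, -2), ori2_x = c(1, 2))
  s <- ori_separation_series(tr)
  expect_equal(s$dx, c(0.15, 0.30))
  # mirrored trajectory gives the identical series
  tr2 <- fake_traj(ori1_x = c(1, 2), ori2_x = c(-1, -2))
  expect_equal(ori_separation_series(tr2)$dx, s$dx)
  # frames before the first duplication: single shared ori, dx = 0
  tr3 <- fake_traj(ori1_x = c(0, 1), ori2_x = c(NA, 2))
  expect_equal(ori_separation_series(tr3)$dx, c(0, 0.075))
})

test_that("ensemble averages are pointwise means with SEM = SD/sqrt(n)", {
  mk <- function(dx) structure(data.frame(time_s = 1:10 * 10, dx = dx, dy = 0),
                               class = c("separation_series", "data.frame"))
  a <- mk(rep(1, 10)); b <- mk(rep(3, 10))
  ens <- ensemble_average(list(a, b))
  expect_equal(ens$mean_dx, rep(2, nrow(ens)))
  expect_equal(ens$sem_dx, rep(1, nrow(ens)))  # sd = sqrt(2), /sqrt(2) = 1
  # identical series: mean = series, SEM = 0
  ens2 <- ensemble_average(list(a, a))
  expect_equal(ens2$mean_dx, rep(1, nrow(ens2)))
  expect_equal(ens2$sem_dx, rep(0, nrow(ens2)))
  # order invariance
  expect_equal(as.data.frame(ensemble_average(list(b, a))),
               as.data.frame(ens))
  expect_error(ensemble_average(list(a)), "at least 2")
})

test_that("final normalized positions map poles to 0 and 1 and order per run", {
  # oris exactly at the two poles
  tr <- fake_traj(ori1_x = 30, ori2_x = -30, L = 60)
  fp <- final_normalized_positions(list(tr, tr))
  expect_equal(fp$mean_high, 1.0)
  expect_equal(fp$mean_low, 0.0)
  # per-run high/low identification: labels don't matter
  tr2 <- fake_traj(ori1_x = -15, ori2_x = 15, L = 60)
  fp2 <- final_normalized_positions(list(tr, tr2))
  expect_equal(fp2$per_run$high, c(1.0, 0.75))
  expect_equal(fp2$per_run$low, c(0.0, 0.25))
  # mirror-symmetric ensemble: high + low = 1
  expect_equal(fp2$mean_high + fp2$mean_low, 1.0)
})

test_that("step statistics recover a seeded normal and flag degenerate input", {
  set.seed(21)
  sigma <- 0.04
  n <- 10000
  dx <- cumsum(c(0.5, rnorm(n, 0, sigma)))
  ser <- structure(data.frame(time_s = seq_along(dx) * 10, dx = dx, dy = 0),
                   class = c("separation_series", "data.frame"))
  st <- step_size_stats(list(ser))
  expect_false(st$degenerate)
  expect_equal(st$fit$sd, sigma, tolerance = 0.10)
  expect_equal(st$fit$mean, 0, tolerance = 3 * sigma / sqrt(n))
  # Shapiro-Wilk on thinned sample; truly normal steps should not be rejected
  expect_lte(st$normality$n_tested, 5000)
  expect_gt(st$normality$p_value, 0.01)
  # probability plot near the diagonal in the bulk
  q <- st$prob_plot
  mid <- abs(q$theoretical) < 2 * sigma
  expect_lt(max(abs(q$empirical[mid] - q$theoretical[mid])), 4 * sigma / 10)

  cs <- structure(data.frame(time_s = 1:200 * 10, dx = rep(1, 200), dy = 0),
                  class = c("separation_series", "data.frame"))
  expect_true(step_size_stats(list(cs))$degenerate)
  expect_error(step_size_stats(list(cs[1:5, ])), "insufficient")
})
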