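# Shared fixtures and independent oracles used across the suite.

# Brute-force R re-implementation of the total force field: double loop over
# all pairs, explicit wall and bond terms. Independent of the compiled path.
brute_force_forces <- function(pos, radii, bonds, cell_r, cell_l, eps = 1,
                               k = matched_spring_constant(eps, 1), r0 = 1) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pos[i, ] - pos[j, ]
      r <- sqrt(sum(d^2))
      if (r >= 6) next  # model pair cutoff (6 d_b)
      de <- radii[i] + radii[j]
      u <- eps * (de / r) * exp(-r / de)
      fm <- u * (1 / r + 1 / de)
      f[i, ] <- f[i, ] + fm * d / r
    }
  }
  for (e in seq_len(nrow(bonds))) {
    i <- bonds[e, 1]; j <- bonds[e, 2]
    d <- pos[i, ] - pos[j, ]
    r <- sqrt(sum(d^2))
    fm <- -k * (r - r0) / r
    f[i, ] <- f[i, ] + fm * d
    f[j, ] <- f[j, ] - fm * d
  }
  wca_f <- function(dist, sig) {
    rcut <- 2^(1 / 6) * sig
    if (dist >= rcut) return(0)
    s6 <- (sig / dist)^6
    4 * eps * (12 * s6^2 - 6 * s6) / dist
  }
  for (i in seq_len(n)) {
    rho <- sqrt(pos[i, 2]^2 + pos[i, 3]^2)
    fm <- wca_f(cell_r - rho, radii[i])
    if (fm > 0 && rho > 0) {
      f[i, 2] <- f[i, 2] - fm * pos[i, 2] / rho
      f[i, 3] <- f[i, 3] - fm * pos[i, 3] / rho
    }
    fm <- wca_f(cell_l / 2 - abs(pos[i, 1]), radii[i])
    if (fm > 0) f[i, 1] <- f[i, 1] - fm * sign(pos[i, 1])
  }
  f
}

# Build a sim_state by hand from positions (d_b units) for force tests.
make_state <- function(pos, bonds = NULL, radii = NULL,
                       cell = cell_geometry(length_db = 200, radius_db = 100)) {
  n <- nrow(pos)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  if (is.null(radii)) radii <- rep(0.5, n)
  structure(list(pos = pos, vel = matrix(0, n, 3), radii = radii,
                 radii_target = radii, bonds = bonds,
                 chromosome = rep(1L, n), ori = 1L, ter_index = 1L,
                 daughter = NULL, tether = NULL, cell = cell, time_tau = 0),
            class = "sim_state")
}

# Small, fast simulation configuration for unit tests (not the standard
# conditions; those are exercised in the acceptance tests).
tiny_config <- function(n_beads = 12, ...) {
  sim_config(n_beads = n_beads, steps_per_event = 300, equil_steps = 200,
             post_steps_cap = 2000, seg_check_stride = 1000, ...)
}

# Constructed spot table: two tracks with prescribed positions.
two_track_table <- function(x1, y1, x2, y2, i1 = 100, i2 = 100, dt = 10) {
  nf <- length(x1)
  spot_table(data.frame(
    track = rep(c(1L, 2L), each = nf),
    frame = rep(seq_len(nf) - 1L, 2),
    x = c(x1, x2), y = c(y1, y2),
    intensity = c(rep(i1, length.out = nf), rep(i2, length.out = nf))), dt = dt)
}

# rigid motion of a spot table: rotation by theta about the origin plus a
# per-frame translation (n_frames x 2 matrix or length-2 vector)
apply_rigid_motion <- function(tab, theta = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy <- cbind(tab$x, tab$y) %*% t(R)
  if (is.matrix(shift)) {
    idx <- match(tab$frame, sort(unique(tab$frame)))
    xy <- xy + shift[idx, , drop = FALSE]
  } else {
    xy <- sweep(xy, 2, -shift)
  }
  df <- data.frame(track = tab$track, frame = tab$frame, x = xy[, 1],
                   y = xy[, 2], intensity = tab$intensity)
  spot_table(df, dt = attr(tab, "dt"))
}
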