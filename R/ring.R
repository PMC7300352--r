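# Starting configuration: a closed self-avoiding ring polymer on a cubic
# lattice, projected into the cylindrical cell and equilibrated.

#' Cylindrical cell geometry
#'
#' The cell is a cylinder with its long axis along x and the origin of
#' coordinates at the cell centre. The newborn cell measures 43 d_b x
#' 5.64 d_b (3.23 um x 0.42 um); during replication it grows to 5.10 um
#' length and 0.45 um radius (see [grow_cell()]).
#'
#' @param length_db,radius_db axial extent and radius in `d_b` units.
#' @param d_b_um physical size of one blob diameter in micrometres.
#' @return An object of class `cell_geometry` with fields in both `d_b`
#'   units and micrometres.
#' @export
cell_geometry <- function(length_db = 43, radius_db = 5.64, d_b_um = DB_UM) {
  stopifnot(length_db > 0, radius_db > 0)
  structure(list(length_db = length_db, radius_db = radius_db,
                 length_um = length_db * d_b_um, radius_um = radius_db * d_b_um,
                 d_b_um = d_b_um),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cylindrical cell: length %.2f d_b (%.3f um), radius %.2f d_b (%.3f um)\n",
              x$length_db, x$length_um, x$radius_db, x$radius_um))
  invisible(x)
}

# unit lattice directions
.lattice_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

.site_key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")

#' Generate a closed self-avoiding ring on a cubic lattice
#'
#' Starts from the minimal four-site square ring and grows it two beads at a
#' time by kink insertion: a randomly chosen bond `a-b` is replaced by the
#' path `a-u-v-b` with `u = a + d`, `v = b + d` for a random unit direction
#' `d` perpendicular to the bond; moves that would multiply occupy a lattice
#' site are discarded. The result is a closed, self-avoiding ring of exactly
#' `n_beads` sites with unit bonds. The replication origin (ori) is bead 1
#' and the terminus (ter) is the contour-antipodal bead `n_beads/2 + 1`.
#'
#' @param n_beads even integer `>= 4`.
#' @param seed RNG seed.
#' @param max_attempts rejected insertions tolerated within one growth pass
#'   before restarting from the minimal ring; after 50 failed passes the
#'   generation aborts with an error (callers may retry with a new seed).
#' @return An object of class `ring_config`: integer lattice coordinates
#'   (`n_beads` x 3), closed-ring `bonds`, `ori_index`, `ter_index`.
#' @export
generate_ring_saw <- function(n_beads, seed = 1, max_attempts = 10000) {
  if (n_beads %% 2 != 0 || n_beads < 4)
    stop("n_beads must be an even integer >= 4")
  with_seed(seed, {
    coords <- NULL
    for (pass in 1:50) {
      coords <- .grow_ring(n_beads, max_attempts)
      if (!is.null(coords)) break
    }
    if (is.null(coords))
      stop("ring generation failed: target length not reached within max_attempts")
    n <- nrow(coords)
    bonds <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
    structure(list(coords = coords, bonds = bonds,
                   ori_index = 1L, ter_index = as.integer(n_beads / 2 + 1)),
              class = "ring_config")
  })
}

# one growth attempt; NULL on failure (caller restarts, same RNG stream)
.grow_ring <- function(n_beads, max_attempts) {
  coords <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L))
  occupied <- new.env(hash = TRUE, parent = emptyenv())
  for (k in .site_key(coords)) assign(k, TRUE, envir = occupied)
  rejects <- 0L
  while (nrow(coords) < n_beads) {
    n <- nrow(coords)
    i <- sample.int(n, 1L)
    j <- if (i == n) 1L else i + 1L
    a <- coords[i, ]; b <- coords[j, ]
    step <- b - a
    perp <- .lattice_dirs[rowSums(abs(.lattice_dirs) * rep(abs(step), each = 6)) == 0, ,
                          drop = FALSE]
    d <- perp[sample.int(nrow(perp), 1L), ]
    u <- a + d; v <- b + d
    ku <- paste(u, collapse = ","); kv <- paste(v, collapse = ",")
    if (exists(ku, envir = occupied) || exists(kv, envir = occupied)) {
      rejects <- rejects + 1L
      if (rejects >= max_attempts) return(NULL)
      next
    }
    assign(ku, TRUE, envir = occupied)
    assign(kv, TRUE, envir = occupied)
    coords <- rbind(coords[seq_len(i), , drop = FALSE], u, v,
                    if (j != 1L) coords[j:n, , drop = FALSE])
    rownames(coords) <- NULL
  }
  coords
}

#' Validate a ring configuration
#'
#' Checks closure (bead i bonded to i+1 modulo N with unit lattice bonds) and
#' self-avoidance (all lattice sites distinct).
#'
#' @param ring a `ring_config`.
#' @return `TRUE` invisibly; stops with a message describing the violation.
#' @export
validate_ring <- function(ring) {
  co <- ring$coords
  n <- nrow(co)
  if (anyDuplicated(.site_key(co)) > 0)
    stop("ring is not self-avoiding: duplicated lattice site")
  steps <- co[c(seq_len(n)[-1], 1L), ] - co
  if (any(rowSums(abs(steps)) != 1))
    stop("ring is not closed with unit bonds")
  invisible(TRUE)
}

#' Embed a lattice ring in the cylindrical cell
#'
#' Centres the ring on the cell centre and applies a single isotropic scale
#' factor so that every bead lies strictly inside the wall with clearance of
#' at least `0.5 * d_b` (no anisotropic squash, to avoid biasing the initial
#' elongation). A compressed start raises bead-bead repulsion, which the
#' subsequent equilibration relaxes. Velocities are drawn from the
#' Maxwell-Boltzmann distribution at temperature `eps / k_B`.
#'
#' @param ring a `ring_config`.
#' @param cell a [cell_geometry()].
#' @param p a [potential_params()].
#' @param seed RNG seed for the thermal velocities.
#' @return A `sim_state`: `pos`, `vel`, `radii`, `bonds`, `chromosome`
#'   labels, `ori` bead indices, `ter_index`, `cell`, `time_tau`.
#' @export
embed_in_cylinder <- function(ring, cell = cell_geometry(),
                              p = potential_params(), seed = 1) {
  co <- ring$coords
  co <- sweep(co, 2, colMeans(co))
  clear <- 0.5 * p$d_b
  rho <- sqrt(co[, 2]^2 + co[, 3]^2)
  s_rad <- if (max(rho) > 0) (cell$radius_db - clear) / max(rho) * 0.999 else Inf
  s_ax <- if (max(abs(co[, 1])) > 0)
    (cell$length_db / 2 - clear) / max(abs(co[, 1])) * 0.999 else Inf
  s <- min(1, s_rad, s_ax)
  if (s < 0.05)
    stop("embedding error: ring too extended to fit the cell after isotropic scaling")
  pos <- co * s
  n <- nrow(pos)
  vel <- with_seed(seed, matrix(rnorm(3 * n, sd = sqrt(p$eps)), ncol = 3))
  structure(list(pos = pos, vel = vel,
                 radii = rep(0.5 * p$d_b, n),
                 radii_target = rep(0.5 * p$d_b, n),
                 bonds = ring$bonds,
                 chromosome = rep(1L, n),
                 ori = ring$ori_index, ter_index = ring$ter_index,
                 daughter = NULL, tether = NULL,
                 cell = cell, time_tau = 0),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: %d beads, %d bonds, %d chromosome(s), t = %.2f tau\n",
              nrow(x$pos), nrow(x$bonds), length(unique(x$chromosome)), x$time_tau))
  print(x$cell)
  invisible(x)
}

#' Equilibrate an embedded configuration
#'
#' Integrates the freshly embedded ring for `n_steps` Langevin steps (the
#' default 10^3 steps of 0.01 tau) to relax the high initial repulsion of
#' compressed neighbours, logging kinetic, bonded, nonbonded and total
#' energies at every step. A stationarity measure (relative difference
#' between the third- and final-quarter total-energy means) is attached; a
#' warning is raised when it exceeds 10%.
#'
#' @param state a `sim_state`.
#' @param p [potential_params()].
#' @param ip [integrator_params()].
#' @param n_steps number of time steps (0 returns the state unchanged with
#'   an empty log).
#' @param seed RNG seed for the thermostat noise.
#' @return A list: `state` (equilibrated) and `energy_log` (data frame with
#'   columns `step`, `kinetic`, `bonded`, `nonbonded`, `total`).
#' @export
equilibrate <- function(state, p = potential_params(), ip = integrator_params(),
                        n_steps = 1000, seed = 1) {
  stopifnot(inherits(state, "sim_state"), n_steps >= 0)
  if (n_steps == 0) {
    return(list(state = state,
                energy_log = data.frame(step = integer(0), kinetic = numeric(0),
                                        bonded = numeric(0), nonbonded = numeric(0),
                                        total = numeric(0))))
  }
  sp <- derive_seed_pair(seed, 0)
  out <- cpp_integrate(state$pos, state$vel, state$radii, state$radii,
                       state$bonds,
                       state$cell$radius_db, state$cell$radius_db,
                       state$cell$length_db, state$cell$length_db,
                       p$eps, p$k, p$r0, p$d_b, pair_cutoff = 6,
                       dt = ip$dt, gamma = ip$gamma, kT = ip$temperature,
                       mass = ip$m_b, n_steps = n_steps, sample_stride = 0,
                       log_energies = TRUE,
                       tether_idx = integer(0), tether_point = numeric(0),
                       tether_k = 0, tether_flat = 0,
                       seed1 = sp[1], seed2 = sp[2])
  state$pos <- out$pos
  state$vel <- out$vel
  state$time_tau <- state$time_tau + n_steps * ip$dt
  elog <- data.frame(step = seq_len(n_steps), kinetic = out$energy_log[, 1],
                     bonded = out$energy_log[, 2], nonbonded = out$energy_log[, 3],
                     total = out$energy_log[, 4])
  q <- floor(n_steps / 4)
  m3 <- mean(elog$total[(2 * q + 1):(3 * q)])
  m4 <- mean(elog$total[(3 * q + 1):(4 * q)])
  stat <- abs(m4 - m3) / max(abs(m3), .Machine$double.eps)
  if (stat >= 0.10)
    warning(sprintf("equilibration may not be stationary: quarter-mean drift %.1f%%",
                    100 * stat))
  attr(elog, "stationarity") <- stat
  list(state = state, energy_log = elog)
}
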