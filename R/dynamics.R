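# Thermostatted integration and orchestration of full replication -
# segregation runs. The integrator is the BAOAB splitting of Langevin
# velocity Verlet: deterministic half-kicks and half-drifts around an exact
# Ornstein-Uhlenbeck friction/noise substep, which satisfies
# fluctuation-dissipation at the set temperature. Trajectories are
# bit-reproducible from (config, seed).

#' Integrator parameters
#'
#' @param dt time step in tau (default 0.01 tau).
#' @param gamma friction coefficient, reduced units `sqrt(m_b * eps) / d_b`
#'   (default 5, which makes the motion overdamped).
#' @param temperature thermostat temperature in `k_B*T` (= eps).
#' @param m_b bead mass (1 reduced unit).
#' @param pair_cutoff centre-centre cutoff for the screened-Coulomb pair
#'   interaction, in `d_b` (the interaction decays as `exp(-r/d_b)`; beyond
#'   the default 6 d_b it is below 5e-4 k_BT).
#' @return An object of class `integrator_params`.
#' @export
integrator_params <- function(dt = 0.01, gamma = 5, temperature = 1, m_b = 1,
                              pair_cutoff = 6) {
  stopifnot(dt > 0, gamma >= 0, temperature >= 0, m_b > 0)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 m_b = m_b, pair_cutoff = pair_cutoff),
            class = "integrator_params")
}

# low-level chunk integration with growth ramps; returns updated state plus
# raw samples
.integrate_chunk <- function(state, p, ip, n_steps, sample_stride, seed, chunk,
                             cell_end = NULL, grow_radii = TRUE,
                             log_energies = FALSE) {
  radii_end <- state$radii
  if (grow_radii && !is.null(state$growing) && length(state$growing) > 0)
    radii_end[state$growing] <- state$radii_target[state$growing]
  cell1 <- if (is.null(cell_end)) state$cell else cell_end
  tether <- state$tether
  if (is.null(tether))
    tether <- list(idx = integer(0), point = numeric(0), k = 0, flat = 0)
  sp <- derive_seed_pair(seed, chunk)
  out <- cpp_integrate(state$pos, state$vel, state$radii, radii_end,
                       state$bonds,
                       state$cell$radius_db, cell1$radius_db,
                       state$cell$length_db, cell1$length_db,
                       p$eps, p$k, p$r0, p$d_b, ip$pair_cutoff,
                       dt = ip$dt, gamma = ip$gamma, kT = ip$temperature,
                       mass = ip$m_b, n_steps = n_steps,
                       sample_stride = sample_stride,
                       log_energies = log_energies,
                       tether_idx = tether$idx, tether_point = tether$point,
                       tether_k = tether$k, tether_flat = tether$flat,
                       seed1 = sp[1], seed2 = sp[2])
  state$pos <- out$pos
  state$vel <- out$vel
  state$radii <- as.numeric(out$radii)
  state$cell <- cell1
  state$time_tau <- state$time_tau + n_steps * ip$dt
  if (grow_radii) state$growing <- NULL
  list(state = state, samples = out$samples, sample_steps = out$sample_steps,
       energy_log = out$energy_log)
}

#' Single Langevin velocity-Verlet step
#'
#' Advances a `sim_state` by `n_steps` BAOAB Langevin steps with fixed bead
#' radii and cell geometry. With `temperature = 0` and `gamma = 0` this is
#' plain velocity Verlet. The same `(state, seed)` yields a bit-identical
#' result.
#'
#' @param state a `sim_state`.
#' @param p [potential_params()].
#' @param ip [integrator_params()].
#' @param n_steps number of steps.
#' @param seed RNG seed for the thermostat noise.
#' @return The advanced `sim_state`.
#' @export
lv_step <- function(state, p = potential_params(), ip = integrator_params(),
                    n_steps = 1, seed = 1) {
  stopifnot(inherits(state, "sim_state"))
  .integrate_chunk(state, p, ip, n_steps, sample_stride = 0, seed = seed,
                   chunk = 0, grow_radii = FALSE)$state
}

#' Simulation configuration
#'
#' Collects the physical and numerical parameters of a replication-
#' segregation run, with the standard conditions as defaults: an 80-bead chromosome,
#' `eps = 1 k_BT`, time step 0.01 tau, friction 5, replication rescaled to
#' 3,600 s, factory model, cell growing from 3.23 x 0.42 um to
#' 5.10 x 0.45 um.
#'
#' @param n_beads beads per chromosome (even, `>= 4`).
#' @param model replication model, `"factory"` or `"track"`.
#' @param eps interaction strength, `k_B*T`.
#' @param dt integrator time step, tau.
#' @param gamma friction coefficient, reduced units.
#' @param total_seconds rescaled duration of replication.
#' @param steps_per_event integration steps per duplication interval (the
#'   affine time map assigns each interval `total_seconds / (n_beads/2)`
#'   seconds regardless).
#' @param frame_interval_s sampling interval of the trajectory, rescaled
#'   seconds.
#' @param equil_steps equilibration steps before replication starts.
#' @param post_steps_cap cap on post-replication integration; runs that do
#'   not fully segregate within it are flagged censored, not dropped.
#' @param seg_check_stride how often (steps) segregation is re-tested after
#'   replication.
#' @param store_frames keep full per-bead positions for every sampled frame
#'   (needed for trajectory export; origin/extent summaries are always kept).
#' @param d_b_um physical blob diameter, micrometres.
#' @param max_dt_halvings automatic time-step halvings tolerated after an
#'   energy blow-up before the run fails.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_beads = 80, model = c("factory", "track"), eps = 1,
                       dt = 0.01, gamma = 5, total_seconds = 3600,
                       steps_per_event = 5000, frame_interval_s = 10,
                       equil_steps = 1000, post_steps_cap = 1e6,
                       seg_check_stride = 5000, store_frames = FALSE,
                       d_b_um = DB_UM, max_dt_halvings = 3) {
  model <- match.arg(model)
  structure(list(n_beads = as.integer(n_beads), model = model, eps = eps,
                 dt = dt, gamma = gamma, total_seconds = total_seconds,
                 steps_per_event = as.integer(steps_per_event),
                 frame_interval_s = frame_interval_s,
                 equil_steps = as.integer(equil_steps),
                 post_steps_cap = post_steps_cap,
                 seg_check_stride = as.integer(seg_check_stride),
                 store_frames = isTRUE(store_frames), d_b_um = d_b_um,
                 max_dt_halvings = as.integer(max_dt_halvings)),
            class = "sim_config")
}

# summarize a block of sampled positions into trajectory frames
.frames_from_samples <- function(samples, sample_steps, state, step0,
                                 sec_per_step, n_total_steps, cfg) {
  n <- nrow(state$pos)
  ns <- length(sample_steps)
  if (ns == 0) return(NULL)
  ori1 <- state$ori[1]
  ori2 <- if (length(state$ori) > 1) state$ori[2] else NA_integer_
  is2 <- state$chromosome == 2L
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    pos <- samples[((s - 1) * n + 1):(s * n), , drop = FALSE]
    gstep <- step0 + sample_steps[s]
    frac <- min(gstep / n_total_steps, 1)
    cell <- grow_cell(frac, cfg$d_b_um)
    x1 <- pos[!is2, 1]
    x2 <- pos[is2, 1]
    out[[s]] <- data.frame(
      step = gstep, time_s = gstep * sec_per_step,
      ori1_x = pos[ori1, 1], ori1_y = pos[ori1, 2], ori1_z = pos[ori1, 3],
      ori2_x = if (is.na(ori2)) NA_real_ else pos[ori2, 1],
      ori2_y = if (is.na(ori2)) NA_real_ else pos[ori2, 2],
      ori2_z = if (is.na(ori2)) NA_real_ else pos[ori2, 3],
      chr1_xmin = min(x1), chr1_xmax = max(x1),
      chr2_xmin = if (any(is2)) min(x2) else NA_real_,
      chr2_xmax = if (any(is2)) max(x2) else NA_real_,
      cell_length_db = cell$length_db, cell_radius_db = cell$radius_db,
      n_beads = n)
  }
  frames <- do.call(rbind, out)
  full <- NULL
  if (cfg$store_frames) {
    full <- lapply(seq_len(ns), function(s) {
      list(pos = samples[((s - 1) * n + 1):(s * n), , drop = FALSE],
           chromosome = state$chromosome, radii = state$radii)
    })
  }
  list(frames = frames, full = full)
}

#' Run a full replication-segregation simulation
#'
#' Executes the three-part protocol: (1) generate a self-avoiding ring,
#' embed it in the newborn cell and equilibrate for 10^3 steps; (2) replicate
#' bead by bead over `n_beads / 2` evenly spaced duplication events spanning
#' 3,600 rescaled seconds, integrating between events while new beads and the
#' cell grow (factory model: the templates of the upcoming event are drawn to
#' the midcell factory by a stiff transient tether); (3) continue integrating
#' after replication until the chromosomes are completely segregated
#' (degree of separation 0) or the step cap is reached (censored flag).
#' On an energy blow-up the run restarts with a halved time step, up to
#' `max_dt_halvings` times.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; (config, seed) fully determines the trajectory.
#' @return An object of class `sim_trajectory`: `frames` (per-frame origin
#'   positions, chromosome x-extents, cell geometry, times in rescaled
#'   seconds), `final_state`, `repl_end_frame` (index of the last frame of
#'   replication), `censored`, `config`, `seed`, `equilibration` energy log.
#' @export
run_replication_sim <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$dt
  for (halving in 0:config$max_dt_halvings) {
    res <- tryCatch(
      .run_replication_once(config, seed, dt),
      error = function(e) {
        if (grepl("energy divergence", conditionMessage(e))) e else stop(e)
      })
    if (!inherits(res, "error")) return(res)
    dt <- dt / 2
  }
  stop(sprintf("run failure: persistent energy blow-up after %d time-step halvings",
               config$max_dt_halvings))
}

.run_replication_once <- function(config, seed, dt) {
  p <- potential_params(eps = config$eps, d_b = 1)
  ip <- integrator_params(dt = dt, gamma = config$gamma,
                          temperature = config$eps)
  n <- config$n_beads
  n_events <- n %/% 2L
  spe <- config$steps_per_event
  n_repl_steps <- n_events * spe
  sec_per_step <- config$total_seconds / n_repl_steps
  stride <- max(1L, as.integer(round(config$frame_interval_s / sec_per_step)))

  ring <- generate_ring_saw(n, seed = seed)
  state <- embed_in_cylinder(ring, grow_cell(0, config$d_b_um), p, seed = seed)
  eq <- equilibrate(state, p, ip, n_steps = config$equil_steps, seed = seed)
  state <- eq$state
  state$time_tau <- 0  # replication clock starts after equilibration

  schedule <- make_schedule(n, config$total_seconds, config$model)
  frames <- list()
  full <- list()
  gstep <- 0L
  for (e in seq_len(n_events)) {
    if (config$model == "factory") {
      state$tether <- list(idx = c(schedule$events$template_a[e],
                                   schedule$events$template_b[e]),
                           point = schedule$factory_position,
                           k = 10 * p$k, flat = 1 * p$d_b)
    }
    cell_end <- grow_cell(e / n_events, config$d_b_um)
    ck <- .integrate_chunk(state, p, ip, spe, sample_stride = stride,
                           seed = seed, chunk = e, cell_end = cell_end)
    state <- ck$state
    fr <- .frames_from_samples(ck$samples, ck$sample_steps, state, gstep,
                               sec_per_step, n_repl_steps, config)
    if (!is.null(fr)) {
      frames[[length(frames) + 1L]] <- fr$frames
      if (config$store_frames) full <- c(full, fr$full)
    }
    gstep <- gstep + spe
    # chunk-end frame if the stride did not land on the interval boundary
    if (spe %% stride != 0L) {
      fr <- .frames_from_samples(matrix(state$pos, ncol = 3), n_steps_tail(spe),
                                 state, gstep - spe, sec_per_step,
                                 n_repl_steps, config)
      frames[[length(frames) + 1L]] <- fr$frames
      if (config$store_frames) {
        full <- c(full, list(list(pos = state$pos, chromosome = state$chromosome,
                                  radii = state$radii)))
      }
    }
    state$tether <- NULL
    state <- apply_duplication(state, e, schedule, p, seed = seed + 7919L * e)
  }
  repl_frames <- do.call(rbind, frames)
  repl_end_frame <- nrow(repl_frames)

  # post-replication: integrate until fully segregated or the cap is hit;
  # the final event's beads grow during the first chunk
  censored <- FALSE
  post_steps <- 0L
  repeat {
    dsep <- .state_degree_of_separation(state)
    if (dsep == 0) break
    if (post_steps >= config$post_steps_cap) {
      censored <- TRUE
      break
    }
    nstep <- as.integer(min(config$seg_check_stride,
                            config$post_steps_cap - post_steps))
    if (nstep <= 0) { censored <- TRUE; break }
    ck <- .integrate_chunk(state, p, ip, nstep, sample_stride = stride,
                           seed = seed, chunk = 100000L + post_steps)
    state <- ck$state
    fr <- .frames_from_samples(ck$samples, ck$sample_steps, state, gstep,
                               sec_per_step, n_repl_steps, config)
    if (!is.null(fr)) {
      frames[[length(frames) + 1L]] <- fr$frames
      if (config$store_frames) full <- c(full, fr$full)
    }
    gstep <- gstep + nstep
    post_steps <- post_steps + nstep
  }

  all_frames <- do.call(rbind, frames)
  all_frames$frame <- seq_len(nrow(all_frames))
  rownames(all_frames) <- NULL
  structure(list(frames = all_frames, repl_end_frame = repl_end_frame,
                 final_state = state, censored = censored,
                 equilibration = eq$energy_log,
                 full_frames = if (config$store_frames) full else NULL,
                 config = config, seed = seed,
                 schedule = schedule, d_b_um = config$d_b_um),
            class = "sim_trajectory")
}

# helper: pseudo sample-step vector for a single chunk-end frame
n_steps_tail <- function(spe) spe

.state_degree_of_separation <- function(state) {
  x1 <- state$pos[state$chromosome == 1L, 1]
  x2 <- state$pos[state$chromosome == 2L, 1]
  if (length(x2) < 2) return(NA_real_)
  degree_of_separation(x1, x2)
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("sim_trajectory: %s model, %d beads/chromosome, seed %d\n",
              x$config$model, x$config$n_beads, x$seed))
  cat(sprintf("  %d frames (%d during replication), censored = %s\n",
              nrow(x$frames), x$repl_end_frame, x$censored))
  dsep <- .state_degree_of_separation(x$final_state)
  cat(sprintf("  final degree of separation: %.3f\n", dsep))
  invisible(x)
}

#' Plot origin separation of a single run
#'
#' @param x a `sim_trajectory`.
#' @param ... passed to [plot()].
#' @export
plot.sim_trajectory <- function(x, ...) {
  s <- ori_separation_series(x)
  plot(s$time_s / 60, s$dx, type = "l", xlab = "time (min)",
       ylab = "ori-ori distance (um)", col = "steelblue", ...)
  lines(s$time_s / 60, s$dy, col = "tomato")
  legend("topleft", legend = c("x (long axis)", "y"), bty = "n",
         col = c("steelblue", "tomato"), lty = 1)
  invisible(x)
}

#' Entropic segregation of two initially overlapping rings
#'
#' Initializes two complete ring chromosomes of `n_beads` each, fully
#' overlapping inside the newborn cell (the second ring's beads are offset by
#' 0.3 d_b from the first so no two centres coincide), and integrates at
#' fixed cell geometry until the degree of separation first reaches 0. Used
#' for the chain-length scaling study over N in {20, 40, 50, 60, 80}.
#'
#' @param n_beads beads per ring.
#' @param seed integer seed (same seed, same segregation time).
#' @param config a [sim_config()]; `seg_check_stride` sets the test
#'   granularity and `post_steps_cap` the censoring cap.
#' @param state optional pre-built two-ring `sim_state` (e.g. rings already
#'   placed in disjoint halves); when given, `n_beads` is ignored.
#' @return A list: `time_tau` (first-passage time to full segregation),
#'   `steps`, `censored`, `series` (degree of separation vs time at the test
#'   granularity), `state`.
#' @export
segregate_overlapping_pair <- function(n_beads = 80, seed = 1,
                                       config = sim_config(n_beads = n_beads),
                                       state = NULL) {
  p <- potential_params(eps = config$eps, d_b = 1)
  ip <- integrator_params(dt = config$dt, gamma = config$gamma,
                          temperature = config$eps)
  if (is.null(state)) {
    ring <- generate_ring_saw(n_beads, seed = seed)
    state <- embed_in_cylinder(ring, grow_cell(0, config$d_b_um), p, seed = seed)
    n <- nrow(state$pos)
    offs <- with_seed(seed + 1L, {
      u <- matrix(rnorm(3 * n), ncol = 3)
      0.3 * u / sqrt(rowSums(u^2))
    })
    pos2 <- state$pos + offs
    # keep the copy inside the wall
    rho <- sqrt(pos2[, 2]^2 + pos2[, 3]^2)
    shrink <- pmin(1, (state$cell$radius_db - 0.5) / pmax(rho, 1e-9))
    pos2[, 2] <- pos2[, 2] * shrink
    pos2[, 3] <- pos2[, 3] * shrink
    pos2[, 1] <- pmax(pmin(pos2[, 1], state$cell$length_db / 2 - 0.5),
                      -state$cell$length_db / 2 + 0.5)
    state$pos <- rbind(state$pos, pos2)
    state$vel <- rbind(state$vel,
                       with_seed(seed + 2L, matrix(rnorm(3 * n, sd = sqrt(p$eps)),
                                                   ncol = 3)))
    state$radii <- rep(0.5 * p$d_b, 2 * n)
    state$radii_target <- state$radii
    state$bonds <- rbind(state$bonds, state$bonds + n)
    state$chromosome <- rep(c(1L, 2L), each = n)
    state$ori <- c(state$ori, state$ori + n)
  }
  series <- data.frame(time_tau = 0,
                       degree_of_separation = .state_degree_of_separation(state))
  steps <- 0L
  censored <- FALSE
  while (series$degree_of_separation[nrow(series)] > 0) {
    if (steps >= config$post_steps_cap) {
      censored <- TRUE
      break
    }
    nstep <- as.integer(min(config$seg_check_stride,
                            config$post_steps_cap - steps))
    state <- .integrate_chunk(state, p, ip, nstep, sample_stride = 0,
                              seed = seed, chunk = 5e5 + steps,
                              grow_radii = FALSE)$state
    steps <- steps + nstep
    series <- rbind(series,
                    data.frame(time_tau = steps * ip$dt,
                               degree_of_separation = .state_degree_of_separation(state)))
  }
  list(time_tau = if (censored) NA_real_ else steps * ip$dt,
       steps = steps, censored = censored, series = series, state = state)
}
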