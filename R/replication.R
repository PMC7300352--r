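# Bead-by-bead chromosome duplication under the factory or track model,
# while the cell grows. Two replication forks advance symmetrically from the
# origin (bead 1) toward the terminus; each duplication event copies one
# template bead per fork. The partially replicated chromosome is a theta
# structure: the daughter arc stays bonded to the template at both fork
# junctions until the final event, when it closes into a second ring.

#' Build a replication schedule
#'
#' Replication of an `n_beads` ring is divided into `n_beads / 2` evenly
#' spaced duplication events spanning `total_seconds` (3,600 s by default).
#' Event `e` copies the template beads at contour positions `e` (fork A,
#' moving ori -> ter one way) and `n_beads - e + 1` (fork B, the other way),
#' so the origin (bead 1) is copied at the first event and the terminus at
#' the final event, where the forks meet.
#'
#' @param n_beads even integer `>= 4`: beads per chromosome.
#' @param total_seconds overall replication time in (rescaled) seconds.
#' @param model `"factory"` (replisome fixed at midcell) or `"track"`
#'   (forks travel with the chromosome).
#' @param factory_position fixed replisome position (d_b units), used only
#'   in factory mode; defaults to the cell centre and does not move as the
#'   cell grows.
#' @return An object of class `replication_schedule`: data frame `events`
#'   (`event`, `template_a`, `template_b`, `time_s`), `interval_seconds`,
#'   `model`, `factory_position`, `n_beads`.
#' @export
make_schedule <- function(n_beads, total_seconds = 3600,
                          model = c("factory", "track"),
                          factory_position = c(0, 0, 0)) {
  if (n_beads %% 2 != 0 || n_beads < 4)
    stop("n_beads must be an even integer >= 4")
  model <- match.arg(model)
  n_events <- n_beads / 2
  e <- seq_len(n_events)
  events <- data.frame(event = e,
                       template_a = e,
                       template_b = n_beads - e + 1L,
                       time_s = e * total_seconds / n_events)
  structure(list(events = events,
                 interval_seconds = total_seconds / n_events,
                 total_seconds = total_seconds,
                 model = model, factory_position = factory_position,
                 n_beads = as.integer(n_beads)),
            class = "replication_schedule")
}

#' @export
print.replication_schedule <- function(x, ...) {
  cat(sprintf("Replication schedule (%s model): %d events, %.1f s apart (total %.0f s)\n",
              x$model, nrow(x$events), x$interval_seconds, x$total_seconds))
  invisible(x)
}

#' Linear growth ramp for a newly replicated bead
#'
#' New beads appear with radius `0.1 * d_b / 2` and grow linearly to the full
#' bead radius `d_b / 2` over one duplication interval (newly built DNA is
#' assumed compacted right after synthesis); the radius is clamped at full
#' size thereafter.
#'
#' @param t_in_interval time since the bead was created, in tau.
#' @param interval_tau duration of one duplication interval, in tau.
#' @param d_b blob diameter.
#' @return Bead radius at `t_in_interval`.
#' @export
bead_growth <- function(t_in_interval, interval_tau, d_b = 1) {
  stopifnot(all(t_in_interval >= 0), interval_tau > 0)
  frac <- pmin(t_in_interval / interval_tau, 1)
  r_start <- 0.1 * d_b / 2
  r_full <- d_b / 2
  r_start + frac * (r_full - r_start)
}

#' Cell geometry during replication
#'
#' The cell grows during replication: its length interpolates linearly from
#' 3.23 um to 5.10 um and its radius from 0.42 um to 0.45 um as a function of
#' the fraction of replication completed. Endpoints are returned exactly.
#'
#' @param t_fraction fraction of replication completed, in `[0, 1]`.
#' @param d_b_um physical blob diameter in micrometres.
#' @return A [cell_geometry()] at that stage of growth.
#' @export
grow_cell <- function(t_fraction, d_b_um = DB_UM) {
  stopifnot(all(t_fraction >= 0), all(t_fraction <= 1))
  len_um <- 3.23 + t_fraction * (5.10 - 3.23)
  rad_um <- 0.42 + t_fraction * (0.45 - 0.42)
  # d_b-unit extents interpolate between the reduced-unit values the
  # simulation is specified in (43 x 5.64 -> 68 x 6.0)
  len_db <- 43 + t_fraction * (5.10 / d_b_um - 43)
  rad_db <- 5.64 + t_fraction * (0.45 / d_b_um - 5.64)
  g <- cell_geometry(length_db = len_db, radius_db = rad_db, d_b_um = d_b_um)
  g$length_um <- len_um
  g$radius_um <- rad_um
  g
}

# daughter bead id for template t (NA if not yet replicated)
.daughter_of <- function(state, template) {
  if (is.null(state$daughter)) return(NA_integer_)
  state$daughter[template]
}

.remove_bond <- function(bonds, i, j) {
  keep <- !((bonds[, 1] == i & bonds[, 2] == j) | (bonds[, 1] == j & bonds[, 2] == i))
  bonds[keep, , drop = FALSE]
}

# random point strictly inside the cell near `centre` (within `dist`),
# drawn on the sphere of radius dist
.place_near <- function(centre, dist, cell, clearance) {
  for (i in 1:200) {
    u <- rnorm(3)
    pnt <- centre + dist * u / sqrt(sum(u^2))
    rho <- sqrt(pnt[2]^2 + pnt[3]^2)
    if (rho < cell$radius_db - clearance &&
        abs(pnt[1]) < cell$length_db / 2 - clearance) return(pnt)
  }
  centre
}

#' Apply one duplication event
#'
#' Creates the two new beads of the given event (initial radius
#' `0.1 * d_b / 2`), bonds them into the daughter arc, and moves the fork
#' junction bonds one bead forward so the replicated portion forms a theta
#' structure. At the final event the daughter ring is closed and the theta
#' resolves into two disjoint rings labelled chromosome 1 (template) and 2
#' (daughter). Placement: under the track model each new bead appears at its
#' template's position plus a random offset of `0.5 * d_b`; under the factory
#' model new beads appear adjacent to the fixed factory position (the
#' templates having been drawn there by the transient tether during the
#' preceding interval).
#'
#' @param state a `sim_state`.
#' @param event event number (must be the next unapplied event).
#' @param schedule a [make_schedule()] object.
#' @param p [potential_params()].
#' @param seed RNG seed for placement and thermal velocities of new beads.
#' @return The updated `sim_state`.
#' @export
apply_duplication <- function(state, event, schedule, p = potential_params(),
                              seed = 1) {
  n <- schedule$n_beads
  done <- if (is.null(state$events_applied)) 0L else state$events_applied
  if (event != done + 1L)
    stop(sprintf("scheduling error: event %d applied out of order (next is %d)",
                 event, done + 1L))
  ev <- schedule$events[event, ]
  ta <- ev$template_a
  tb <- ev$template_b
  if (is.null(state$daughter)) state$daughter <- rep(NA_integer_, n)

  with_seed(seed, {
    r_new <- 0.1 * p$d_b / 2
    clearance <- 0.5 * p$d_b
    place <- function(template) {
      if (schedule$model == "factory")
        .place_near(schedule$factory_position, 0.5 * p$d_b, state$cell, clearance)
      else
        .place_near(state$pos[template, ], 0.5 * p$d_b, state$cell, clearance)
    }
    id_a <- nrow(state$pos) + 1L
    id_b <- nrow(state$pos) + 2L
    state$pos <- rbind(state$pos, place(ta), place(tb))
    state$vel <- rbind(state$vel, matrix(rnorm(6, sd = sqrt(p$eps)), ncol = 3))
    state$radii <- c(state$radii, r_new, r_new)
    state$radii_target <- c(state$radii_target, 0.5 * p$d_b, 0.5 * p$d_b)
    state$chromosome <- c(state$chromosome, 2L, 2L)
    state$daughter[ta] <- id_a
    state$daughter[tb] <- id_b

    final <- event == n / 2
    if (event == 1L) {
      # first daughter fragment: copies of ori and of its contour neighbour
      state$bonds <- rbind(state$bonds, c(id_a, id_b))
      # junction bonds to the templates just ahead of each fork
      if (!final) state$bonds <- rbind(state$bonds, c(id_a, ta + 1L), c(id_b, tb - 1L))
      state$ori <- c(state$ori, id_a)  # daughter chromosome's ori
    } else {
      da_prev <- state$daughter[ta - 1L]
      db_prev <- state$daughter[tb + 1L]
      # extend the daughter arc
      state$bonds <- rbind(state$bonds, c(id_a, da_prev), c(id_b, db_prev))
      # advance the junctions: drop old, add new
      state$bonds <- .remove_bond(state$bonds, da_prev, ta)
      state$bonds <- .remove_bond(state$bonds, db_prev, tb)
      if (!final) state$bonds <- rbind(state$bonds, c(id_a, ta + 1L), c(id_b, tb - 1L))
    }
    if (final) {
      # forks meet: close the daughter ring
      state$bonds <- rbind(state$bonds, c(id_a, id_b))
      state$ter2_index <- id_b
    }
    state$events_applied <- as.integer(event)
    state$growing <- c(id_a, id_b)  # beads that grow during the next interval
    state
  })
}

#' Validate replication topology
#'
#' During replication every bead must have exactly two bonds except the (at
#' most four) fork-junction beads, which may have three; after completion
#' every bead has exactly two bonds and the bead set splits into two disjoint
#' rings of `n_beads` each.
#'
#' @param state a `sim_state`.
#' @param n_beads beads per chromosome.
#' @return Invisibly, the bond-degree vector; stops on violation.
#' @export
validate_topology <- function(state, n_beads) {
  nb <- nrow(state$pos)
  deg <- tabulate(c(state$bonds[, 1], state$bonds[, 2]), nbins = nb)
  complete <- nb == 2L * n_beads &&
    !is.null(state$events_applied) && state$events_applied == n_beads / 2
  if (complete) {
    if (any(deg != 2)) stop("topology error: non-ring bead after completion")
  } else {
    if (any(deg > 3)) stop("topology error: bead with more than 3 bonds")
    if (sum(deg == 3) > 4) stop("topology error: more than 4 junction beads")
    if (any(deg < 2) && nb > n_beads) {
      # the two newest beads may transiently be arc ends only at event 1
      bad <- which(deg < 2)
      if (any(bad <= n_beads)) stop("topology error: template bead under-bonded")
    }
  }
  invisible(deg)
}
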