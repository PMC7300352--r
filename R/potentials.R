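# Pairwise, wall and bond interactions, in reduced units (k_B*T = 1,
# d_b = 1 unless overridden).  All potentials here are purely repulsive:
# excluded volume between compacted-DNA blobs is modelled as a screened
# Coulomb (Debye-Hueckel) repulsion, wall confinement as a WCA potential,
# and chain connectivity as harmonic springs.

#' Interaction parameters for the bead-spring chromosome model
#'
#' Bundles the energies and length scales governing blob-blob repulsion,
#' bead-wall confinement and bonds. The bond spring constant defaults to the
#' matched value for which the elastic energy at extension `d_b` equals the
#' blob-blob repulsion at separation `d_b` (see
#' [matched_spring_constant()]), giving `k = 0.74` for `eps = 1`.
#'
#' @param eps interaction strength in units of `k_B*T`.
#' @param d_b blob diameter, the basic length unit (1 reduced unit =
#'   0.075 um physical).
#' @param k bond spring constant, `k_B*T / d_b^2`.
#' @param r0 bond rest length; equals `d_b`.
#' @param sigma WCA length scale; equals `d_b` for bead-sized objects.
#' @param r_cut WCA cutoff, `2^(1/6) * sigma` (required for the shifted
#'   potential to vanish continuously at the cutoff).
#' @param c_shift dimensionless WCA shift factor (0.25).
#' @param r_off WCA radial offset.
#' @return An object of class `potential_params`.
#' @examples
#' p <- potential_params()
#' round(p$k, 2)  # 0.74
#' @export
potential_params <- function(eps = 1, d_b = 1,
                             k = matched_spring_constant(eps, d_b),
                             r0 = d_b, sigma = d_b,
                             r_cut = 2^(1 / 6) * sigma,
                             c_shift = 0.25, r_off = 0) {
  stopifnot(eps > 0, d_b > 0, k > 0, sigma > 0)
  if (abs(r_cut - 2^(1 / 6) * sigma) > 1e-12 * sigma)
    stop("r_cut must equal 2^(1/6) * sigma for a continuous WCA potential")
  structure(list(eps = eps, d_b = d_b, k = k, r0 = r0, sigma = sigma,
                 r_cut = r_cut, c_shift = c_shift, r_off = r_off),
            class = "potential_params")
}

#' @export
print.potential_params <- function(x, ...) {
  cat("Bead-spring interaction parameters (reduced units):\n")
  cat(sprintf("  eps = %g k_BT, d_b = %g, k = %.4f k_BT/d_b^2, r0 = %g\n",
              x$eps, x$d_b, x$k, x$r0))
  cat(sprintf("  WCA: sigma = %g, r_cut = %.6f, c_shift = %g, r_off = %g\n",
              x$sigma, x$r_cut, x$c_shift, x$r_off))
  invisible(x)
}

#' Screened-Coulomb (Debye-Hueckel) blob-blob repulsion
#'
#' `U(r) = eps * (d_b / r) * exp(-r / d_b)`. The returned force is the radial
#' magnitude `-dU/dr`, positive outward (always repulsive).
#'
#' @param r centre-centre distance(s), same length unit as `p$d_b`.
#' @param p a [potential_params()] object.
#' @return A list with numeric vectors `energy` and `force`.
#' @examples
#' debye_huckel(1, potential_params())$energy  # exp(-1)
#' @export
debye_huckel <- function(r, p = potential_params()) {
  if (any(r <= 0)) stop("invalid geometry: r must be > 0")
  u <- p$eps * (p$d_b / r) * exp(-r / p$d_b)
  f <- u * (1 / r + 1 / p$d_b)
  list(energy = u, force = f)
}

#' Weeks-Chandler-Andersen (WCA) potential
#'
#' The repulsive part of the Lennard-Jones potential, cut at
#' `r_cut = 2^(1/6) * sigma` and shifted by `c_shift * 4 * eps` so the energy
#' vanishes continuously at the cutoff. Used for bead-wall confinement.
#'
#' @inheritParams debye_huckel
#' @return A list with numeric vectors `energy` and `force` (radial magnitude,
#'   `-dU/dr`, zero at and beyond the cutoff).
#' @examples
#' wca(1, potential_params())$energy          # 4 * (1 - 1 + 0.25) = 1
#' wca(2^(1/6), potential_params())$energy    # 0 at the cutoff
#' @export
wca <- function(r, p = potential_params()) {
  if (any(r <= p$r_off)) stop("invalid geometry: r must exceed r_off")
  d <- r - p$r_off
  s6 <- (p$sigma / d)^6
  u <- 4 * p$eps * (s6^2 - s6 + p$c_shift)
  f <- 4 * p$eps * (12 * s6^2 - 6 * s6) / d
  beyond <- r >= p$r_cut + p$r_off
  u[beyond] <- 0
  f[beyond] <- 0
  list(energy = u, force = f)
}

#' Harmonic bond potential
#'
#' `U(r) = 0.5 * k * (r - r0)^2`; the force is the restoring force directed
#' toward the rest length (positive when the bond is stretched).
#'
#' @param r bond length(s), `>= 0`.
#' @inheritParams debye_huckel
#' @return A list with numeric vectors `energy` and `force`.
#' @export
harmonic_bond <- function(r, p = potential_params()) {
  if (any(r < 0)) stop("bond length must be >= 0")
  ext <- r - p$r0
  list(energy = 0.5 * p$k * ext^2, force = p$k * ext)
}

#' Matched bond spring constant
#'
#' Chooses the spring constant so that the elastic energy at extension `d_b`
#' equals the blob-blob repulsion at separation `d_b`:
#' `0.5 * k * d_b^2 = eps * exp(-1)`, i.e. `k = 2 * eps * exp(-1) / d_b^2`.
#' For `eps = 1`, `d_b = 1` this is 0.7358, printed as 0.74.
#'
#' @param eps interaction strength in `k_B*T`.
#' @param d_b blob diameter.
#' @return The spring constant in `k_B*T / d_b^2`.
#' @examples
#' round(matched_spring_constant(1, 1), 2)  # 0.74
#' @export
matched_spring_constant <- function(eps = 1, d_b = 1) {
  stopifnot(eps > 0, d_b > 0)
  2 * eps * exp(-1) / d_b^2
}

#' Total forces on every bead of a simulation state
#'
#' Sums pairwise Debye-Hueckel repulsion over all bead pairs (with effective
#' diameter `R_i + R_j`, so part-grown beads are softer), WCA wall forces from
#' the cylindrical boundary (lateral surface and both flat end caps, using the
#' distance from the bead centre to the nearest wall), harmonic bond forces,
#' and any active factory tethers. Pair forces obey Newton's third law.
#'
#' @param state a `sim_state` (see [embed_in_cylinder()]).
#' @param p a [potential_params()] object.
#' @return A list with `forces` (N x 3 matrix) and `energy` (components
#'   `pair`, `bond`, `wall`, `tether`).
#' @export
total_forces <- function(state, p = potential_params()) {
  stopifnot(inherits(state, "sim_state"))
  tether <- state$tether
  if (is.null(tether))
    tether <- list(idx = integer(0), point = c(0, 0, 0), k = 0, flat = 0)
  cpp_total_forces(state$pos, state$radii, state$bonds,
                   state$cell$radius_db, state$cell$length_db,
                   p$eps, p$k, p$r0, p$d_b, pair_cutoff = 6,
                   tether_idx = tether$idx, tether_point = tether$point,
                   tether_k = tether$k, tether_flat = tether$flat)
}
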