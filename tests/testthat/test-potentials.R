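test_that("screened-Coulomb repulsion evaluates to its closed form", {
  p <- potential_params()
  expect_equal(debye_huckel(1, p)$energy, exp(-1), tolerance = 1e-12)
  expect_equal(debye_huckel(2, p)$energy, 0.5 * exp(-2), tolerance = 1e-12)
  expect_lt(debye_huckel(50, p)$energy, 1e-20)
  expect_error(debye_huckel(0, p), "invalid geometry")
  expect_error(debye_huckel(-1, p), "invalid geometry")
})

test_that("WCA potential is the shifted repulsive LJ branch, zero at cutoff", {
  p <- potential_params()
  expect_equal(wca(1, p)$energy, 4 * (1 - 1 + 0.25), tolerance = 1e-12)
  expect_equal(wca(2^(1 / 6), p)$energy, 0, tolerance = 1e-12)
  expect_equal(wca(2, p)$energy, 0)
  expect_equal(wca(2, p)$force, 0)
  # continuity approaching the cutoff from below
  expect_lt(wca(2^(1 / 6) - 1e-8, p)$energy, 1e-6)
  expect_error(wca(0, p), "r_off")
  # r_off shifts the whole curve
  p2 <- potential_params(r_off = 0.5)
  expect_equal(wca(1.5, p2)$energy, wca(1, p)$energy, tolerance = 1e-12)
})

test_that("harmonic bond is symmetric about the rest length", {
  p <- potential_params(k = 0.74, r0 = 1)
  expect_equal(harmonic_bond(1, p)$energy, 0)
  expect_equal(harmonic_bond(2, p)$energy, 0.37, tolerance = 1e-12)
  expect_equal(harmonic_bond(0, p)$energy, 0.37, tolerance = 1e-12)
})

test_that("matched spring constant balances bond and repulsion energies", {
  expect_equal(round(matched_spring_constant(1, 1), 2), 0.74)
  expect_equal(matched_spring_constant(1, 1), 2 * exp(-1), tolerance = 1e-12)
  # energy-matching condition holds by construction
  k <- matched_spring_constant(1, 1)
  expect_equal(0.5 * k * 1^2, debye_huckel(1)$energy, tolerance = 1e-12)
  # linear in eps, inverse-square in d_b
  expect_equal(round(matched_spring_constant(2, 1), 2), 1.47)
  expect_equal(matched_spring_constant(1, 2), matched_spring_constant(1, 1) / 4)
})

test_that("energies and forces are consistent (numerical derivative) and repulsive", {
  p <- potential_params()
  h <- 1e-6
  for (r in c(0.4, 0.8, 1.0, 1.5, 3.0)) {
    num <- -(debye_huckel(r + h, p)$energy - debye_huckel(r - h, p)$energy) / (2 * h)
    expect_equal(debye_huckel(r, p)$force, num, tolerance = 1e-6)
    expect_gt(debye_huckel(r, p)$energy, 0)
    expect_gt(debye_huckel(r, p)$force, 0)
  }
  for (r in c(0.5, 0.8, 0.95, 1.05)) {  # inside the WCA cutoff
    num <- -(wca(r + h, p)$energy - wca(r - h, p)$energy) / (2 * h)
    expect_equal(wca(r, p)$force, num, tolerance = 1e-5)
    expect_gte(wca(r, p)$energy, 0)
    expect_gte(wca(r, p)$force, 0)
  }
  for (r in c(0.2, 0.9, 1.4)) {
    num <- -(harmonic_bond(r + h, p)$energy - harmonic_bond(r - h, p)$energy) / (2 * h)
    # harmonic_bond reports the restoring force toward r0
    expect_equal(-harmonic_bond(r, p)$force, num, tolerance = 1e-6)
  }
})

test_that("invariants of the parameter container are enforced", {
  expect_error(potential_params(eps = -1))
  expect_error(potential_params(r_cut = 1.2246), "r_cut")
  p <- potential_params(sigma = 2)
  expect_equal(p$r_cut, 2^(1 / 6) * 2, tolerance = 1e-12)
  expect_equal(wca(p$r_cut + p$r_off, p)$energy, 0)
})

test_that("total_forces matches a brute-force double-loop oracle", {
  cellr <- 4; celll <- 16
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:20, 1)
    pos <- cbind(runif(n, -celll / 2 + 0.7, celll / 2 - 0.7),
                 runif(n, -2, 2), runif(n, -2, 2))
    keep <- sqrt(pos[, 2]^2 + pos[, 3]^2) < cellr - 0.7
    pos[!keep, 2:3] <- pos[!keep, 2:3] * 0.3
    radii <- runif(n, 0.3, 0.5)
    bonds <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
    st <- make_state(pos, bonds, radii,
                     cell_geometry(length_db = celll, radius_db = cellr))
    got <- total_forces(st)$forces
    want <- brute_force_forces(pos, radii, bonds, cellr, celll)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pair forces obey Newton's third law and walls act as expected", {
  # two beads on the axis, far from any wall
  st <- make_state(rbind(c(-0.5, 0, 0), c(0.5, 0, 0)))
  f <- total_forces(st)$forces
  expect_equal(f[1, ], -f[2, ], tolerance = 1e-14)
  expect_equal(f[1, 1], -debye_huckel(1)$force, tolerance = 1e-12)
  # single bead at the centre of a huge cell: no force at all
  st1 <- make_state(matrix(c(0, 0, 0), 1, 3))
  expect_equal(max(abs(total_forces(st1)$forces)), 0)
  # symmetric three-bead ring: zero net force
  ang <- 2 * pi * (0:2) / 3
  st3 <- make_state(cbind(cos(ang), sin(ang), 0))
  expect_equal(colSums(total_forces(st3)$forces), c(0, 0, 0), tolerance = 1e-13)
  # bead near the lateral wall is pushed back toward the axis
  stw <- make_state(matrix(c(0, 3.8, 0), 1, 3),
                    cell = cell_geometry(length_db = 40, radius_db = 4))
  fw <- total_forces(stw)$forces
  expect_lt(fw[1, 2], 0)
  # bead outside the wall raises a confinement violation naming the bead
  sto <- make_state(matrix(c(0, 4.5, 0), 1, 3),
                    cell = cell_geometry(length_db = 40, radius_db = 4))
  expect_error(total_forces(sto), "bead 1")
})
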