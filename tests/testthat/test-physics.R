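# Physics module: charge-penetration Coulomb, volume-scaled dispersion,
# valence correction, Ewald summation and total-energy assembly.

test_that("charge-penetration Coulomb has the right limits and symmetry", {
  # damping: f(0) = 0, monotone, -> 1
  r <- seq(0.01, 10, length.out = 200)
  fa <- 1 - exp(-3 * r)
  expect_true(all(diff(fa) > 0))
  expect_lt(1 - fa[length(fa)], 1e-12)
  # long range: bare point-charge Coulomb
  e50 <- coulomb_cp(1, 1, 1, 1, 50, alpha = 3, beta = 2)
  expect_lt(abs(e50 - 332.0637 / 50) / (332.0637 / 50), 1e-3)
  # symmetry under atom swap
  e_ab <- coulomb_cp(0.3, -0.2, 1, 6, 1.7, 3, 2)
  e_ba <- coulomb_cp(-0.2, 0.3, 6, 1, 1.7, 3, 2)
  expect_equal(e_ab, e_ba, tolerance = 1e-14)
  expect_error(coulomb_cp(1, 1, 1, 1, 0, 3, 2), "positive")
  # finite at short range used in training data
  expect_true(is.finite(coulomb_cp(0.4, -0.4, 1, 6, 0.3, 3, 2)))
})

test_that("vdW radii scale with the cube root of the volume ratio", {
  fp <- free_atom_params(8)
  expect_equal(vdw_radius(1, 8), fp$rvdw_free)
  expect_equal(vdw_radius(8, 8), 2 * fp$rvdw_free)
  rr <- vdw_radius(c(0.9, 1.0, 1.1), 8)
  expect_true(all(diff(rr) > 0))
  expect_error(vdw_radius(-1, 8), "positive")
})

test_that("dispersion reduces to free-atom C6 in the homonuclear limit", {
  fp <- free_atom_params(8)
  R <- 25
  e <- ts_dispersion(1, 1, 8, 8, R)
  # damping is ~1 at 25 A, so E * R^6 -> -C6_free
  expect_lt(abs(-e * R^6 - fp$c6_free) / fp$c6_free, 1e-3)
  # scaled homonuclear: C6 * ratio^2
  e2 <- ts_dispersion(1.3, 1.3, 8, 8, R)
  expect_lt(abs(-e2 * R^6 - fp$c6_free * 1.3^2) / (fp$c6_free * 1.3^2), 1e-3)
  # sigmoid damping monotone from 0 to 1
  r <- seq(0.05, 30, length.out = 400)
  ratio_e <- ts_dispersion(rep(1, 400), rep(1, 400), 8, 8, r) * -r^6 / fp$c6_free
  expect_true(all(diff(ratio_e) > -1e-12))
  expect_lt(ratio_e[1], 1e-6)
  expect_gt(ratio_e[400], 1 - 1e-6)
  expect_error(ts_dispersion(1, 1, 2, 2, 3), "no free-atom")
})

test_that("heteronuclear C6 follows the combination rule", {
  fp <- free_atom_params(c(8, 1))
  R <- 30
  e <- ts_dispersion(1, 1, 8, 1, R)
  c6o <- fp$c6_free[1]; c6h <- fp$c6_free[2]
  ao <- fp$alpha_free[1]; ah <- fp$alpha_free[2]
  c6oh <- 2 * c6o * c6h / ((ah / ao) * c6o + (ao / ah) * c6h)
  expect_lt(abs(-e * R^6 - c6oh) / c6oh, 1e-3)
})

test_that("charge scaling preserves neutrality and linearity", {
  expect_equal(scale_charges(c(0.5, -0.5), 1), c(0.5, -0.5))
  expect_equal(scale_charges(c(0.5, -0.5), 1.2), c(0.6, -0.6))
  expect_equal(sum(scale_charges(c(0.3, 0.2, -0.5), 7.7)), 0)
})

test_that("valence correction matches hand-computed single- and two-neighbor cases", {
  w <- 0.01
  sp <- function(x) w * log(1 + exp(x / w))
  # H (N = 1) at q = +0.97, one neighbor drained everything
  sys <- atomic_system(c(1, 8), rbind(c(0, 0, 0), c(1, 0, 0)))
  g <- build_pair_graph(sys, 5.2)  # pairs: (1,2), (2,1)
  ex <- ifelse(g$src == 1, 0.97, -0.97)
  q <- c(0.97, -0.97)
  qc <- correct_valence(q, ex, g, element_valence(c(1, 8)))
  h <- sp(0.97 - 0.95)
  drained <- sp(0.97)
  phi <- drained / (drained + 1e-4)
  expect_equal(qc[1], 0.97 - h * phi, tolerance = 1e-12)
  expect_equal(qc[2], -0.97 + h * phi, tolerance = 1e-12)
  expect_equal(sum(qc), sum(q), tolerance = 1e-14)

  # two neighbors drained 0.6 and 0.37: give-back proportional to drain
  sys3 <- atomic_system(c(1, 8, 8), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  g3 <- build_pair_graph(sys3, 5.2)
  ex3 <- numeric(n_pairs(g3))
  ex3[g3$src == 1 & g3$dst == 2] <- 0.6
  ex3[g3$src == 2 & g3$dst == 1] <- -0.6
  ex3[g3$src == 1 & g3$dst == 3] <- 0.37
  ex3[g3$src == 3 & g3$dst == 1] <- -0.37
  q3 <- c(0.97, -0.6, -0.37)
  qc3 <- correct_valence(q3, ex3, g3, element_valence(c(1, 8, 8)))
  d2 <- sp(0.6); d3 <- sp(0.37); tot <- d2 + d3
  expect_equal(qc3[2] - q3[2], h * d2 / (tot + 1e-4), tolerance = 1e-9)
  expect_equal(qc3[3] - q3[3], h * d3 / (tot + 1e-4), tolerance = 1e-9)
  expect_equal(sum(qc3), sum(q3), tolerance = 1e-14)

  # inactive constraint: charges well inside the bound pass through
  q_ok <- c(0.4, -0.4)
  ex_ok <- ifelse(g$src == 1, 0.4, -0.4)
  expect_equal(correct_valence(q_ok, ex_ok, g, element_valence(c(1, 8))), q_ok,
               tolerance = 1e-12)

  # degenerate: hole but no draining neighbor -> warning, unchanged
  ex_bad <- ifelse(g$src == 1, -0.2, 0.2)
  expect_warning(qc_bad <- correct_valence(c(0.97, -0.97), ex_bad, g,
                                           element_valence(c(1, 8))),
                 "no draining neighbor")
  expect_equal(qc_bad[1], 0.97, tolerance = 1e-6)
})

test_that("Ewald matches the isolated pair in a large box", {
  sys <- atomic_system(c(11, 17), rbind(c(0, 0, 0), c(3, 0, 0)),
                       cell = diag(3) * 100)
  e <- ewald_coulomb(sys, c(1, -1), accuracy = 1e-7)
  exact <- -332.0637 / 3
  expect_lt(abs(e - exact) / abs(exact), 1e-4)
  expect_error(ewald_coulomb(sys, c(1, -0.5)), "neutral")
})

test_that("Ewald matches a brute-force lattice sum for a rock-salt cell", {
  a <- 5.64
  frac <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5),
                c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5), c(0.5, 0.5, 0.5))
  q <- c(1, 1, 1, 1, -1, -1, -1, -1)
  pos <- frac %*% (diag(3) * a)
  sys <- atomic_system(c(rep(11, 4), rep(17, 4)), pos, cell = diag(3) * a)
  e <- ewald_coulomb(sys, q, accuracy = 1e-7)
  # brute force: direct sum grouped by complete (neutral, moment-free) cells
  nmax <- 8
  eb <- 0
  for (i in -nmax:nmax) for (j in -nmax:nmax) for (k in -nmax:nmax) {
    if (sqrt(i^2 + j^2 + k^2) > nmax) next
    sh <- c(i, j, k) * a
    for (p1 in 1:8) for (p2 in 1:8) {
      d <- pos[p2, ] + sh - pos[p1, ]
      r <- sqrt(sum(d^2))
      if (r < 1e-9) next
      eb <- eb + 0.5 * 332.0637 * q[p1] * q[p2] / r
    }
  }
  expect_lt(abs(e - eb) / abs(eb), 1e-4)
  # cross-check against the literature Madelung constant for this lattice
  e_madelung <- -4 * 1.7475646 * 332.0637 / (a / 2)
  expect_lt(abs(e - e_madelung) / abs(e_madelung), 1e-4)
  # splitting-parameter independence at fixed accuracy target
  e1 <- ewald_coulomb(sys, q, accuracy = 1e-7, kappa = 0.7)
  e2 <- ewald_coulomb(sys, q, accuracy = 1e-7, kappa = 1.4)
  expect_lt(abs(e1 - e2) / abs(e1), 1e-6)
})

test_that("the energy breakdown is additive and rotation invariant", {
  set.seed(33)
  m <- tiny_model()
  sys <- random_cluster(5)
  eb <- total_energy_forces(m, sys, forces = FALSE)
  expect_equal(eb$E_total,
               eb$E_nn + eb$E_coulomb + eb$E_dispersion + eb$E_reference,
               tolerance = 1e-12)
  Q <- random_rotation()
  ebr <- total_energy_forces(m, atomic_system(sys$species, sys$positions %*% t(Q)),
                             forces = FALSE)
  expect_lt(abs(ebr$E_total - eb$E_total) / abs(eb$E_total), 1e-8)
  # translation invariance
  ebt <- total_energy_forces(m, atomic_system(sys$species, sys$positions + 5),
                             forces = FALSE)
  expect_lt(abs(ebt$E_total - eb$E_total) / max(abs(eb$E_total), 1), 1e-10)
})

test_that("forces are the exact negative gradient of each energy term", {
  set.seed(34)
  m <- tiny_model()
  sys <- random_cluster(4)
  h <- 1e-4
  for (phys in c(FALSE, TRUE)) {
    eb <- total_energy_forces(m, sys, include_physics = phys)
    Ffd <- sys$positions * 0
    for (i in seq_len(4)) for (k in 1:3) {
      Pp <- sys$positions; Pp[i, k] <- Pp[i, k] + h
      Pm <- sys$positions; Pm[i, k] <- Pm[i, k] - h
      Ep <- total_energy_forces(m, atomic_system(sys$species, Pp),
                                forces = FALSE, include_physics = phys)$E_total
      Em <- total_energy_forces(m, atomic_system(sys$species, Pm),
                                forces = FALSE, include_physics = phys)$E_total
      Ffd[i, k] <- -(Ep - Em) / (2 * h)
    }
    expect_lt(max(abs(eb$forces - Ffd)) / max(abs(Ffd)), 1e-5)
    expect_lt(max(abs(colSums(eb$forces))), 1e-6)
  }
})

test_that("periodic total energies include Ewald electrostatics and dispersion tail", {
  m <- tiny_model(seed = 17)
  # small water-like box
  pos <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
               c(3.1, 3.1, 3.1), c(4.06, 3.1, 3.1), c(2.86, 4.03, 3.1))
  sys <- atomic_system(c(8, 1, 1, 8, 1, 1), pos, cell = diag(3) * 6.2)
  eb <- total_energy_forces(m, sys, forces = FALSE)
  expect_true(is.finite(eb$E_total))
  expect_lt(abs(sum(eb$charges)), 1e-10)
  # periodic forces against finite differences
  eb2 <- total_energy_forces(m, sys, forces = TRUE)
  h <- 1e-4
  i <- 2; k <- 1
  Pp <- pos; Pp[i, k] <- Pp[i, k] + h
  Pm <- pos; Pm[i, k] <- Pm[i, k] - h
  Ep <- total_energy_forces(m, atomic_system(sys$species, Pp, cell = sys$cell),
                            forces = FALSE)$E_total
  Em <- total_energy_forces(m, atomic_system(sys$species, Pm, cell = sys$cell),
                            forces = FALSE)$E_total
  expect_lt(abs(eb2$forces[i, k] + (Ep - Em) / (2 * h)) /
              max(abs(eb2$forces)), 1e-5)
})

test_that("dissociation scans relax to the reference asymptote", {
  m <- tiny_model(seed = 19)
  scan <- dissociation_scan(m, 8, 1, c(1.0, 3.0, 15.0))
  ref <- reference_energy(m, c(8, 1))
  expect_identical(scan$E_total[3], ref)
  expect_gt(abs(scan$E_total[1] - ref), 1e-6)
  # averaged-encoding fictitious element scan runs end to end
  avg <- average_encoding(species_encoding(1:54))
  scan_avg <- dissociation_scan(m, 8, 8, c(1.0, 15.0),
                                encodings = rbind(avg, avg))
  expect_true(all(is.finite(scan_avg$E_total)))
})
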