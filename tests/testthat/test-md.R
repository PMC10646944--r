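# BAOAB Langevin dynamics and the trajectory analyses.

harmonic_potential <- function(k) {
  function(system) {
    x <- system$positions
    list(energy = 0.5 * k * sum(x^2), forces = -k * x)
  }
}

test_that("a vanishing time step leaves the state essentially unchanged", {
  sys <- atomic_system(1, matrix(c(1, 0, 0), 1, 3))
  st <- md_state(sys, temperature = 300, friction = 0.01, seed = 2)
  st2 <- baoab_step(st, harmonic_potential(50), dt = 1e-10)
  expect_lt(max(abs(st2$system$positions - st$system$positions)), 1e-9)
  expect_lt(max(abs(st2$velocities - st$velocities)), 1e-6)
})

test_that("at T = 0 the damped oscillator relaxes monotonically to the minimum", {
  sys <- atomic_system(1, matrix(c(1.5, 0, 0), 1, 3))
  st <- md_state(sys, velocities = matrix(0, 1, 3), temperature = 0,
                 friction = 0.05, seed = 3)
  pot <- harmonic_potential(50)
  etot <- numeric(200)
  for (s in 1:200) {
    st <- baoab_step(st, pot, dt = 0.5)
    etot[s] <- st$energy + st$kinetic
  }
  expect_true(all(diff(etot) <= 1e-10))
  expect_lt(etot[200], 0.05 * etot[1])
})

test_that("thermostatted harmonic dynamics recover equipartition", {
  sys <- atomic_system(6, matrix(0.2, 1, 3))
  st <- md_state(sys, temperature = 300, friction = 0.02, seed = 4)
  pot <- harmonic_potential(100)
  n <- 60000
  ke <- numeric(n)
  for (s in seq_len(n)) {
    st <- baoab_step(st, pot, dt = 0.5)
    ke[s] <- st$kinetic
  }
  kbt2 <- 0.0019872041 * 300 / 2
  expect_lt(abs(mean(ke[5001:n]) / 3 - kbt2) / kbt2, 0.05)
})

test_that("free particles show no systematic momentum drift", {
  set.seed(5)
  n <- 30
  sys <- atomic_system(rep(18, n), matrix(runif(3 * n, 0, 10), n, 3),
                       cell = diag(3) * 10)
  st <- md_state(sys, temperature = 300, friction = 0.01, seed = 6)
  pot <- function(system) list(energy = 0, forces = system$positions * 0)
  drift <- numeric(0)
  for (s in 1:2000) {
    st <- baoab_step(st, pot, dt = 0.5)
    if (s %% 200 == 0) drift <- rbind(drift, colSums(st$masses * st$velocities))
  }
  # thermal scale of the total momentum: sqrt(N m kB T)
  scale <- sqrt(n * 39.948 * 0.0019872041 * 300 * 4.184e-4)
  expect_lt(max(abs(drift)), 6 * scale)
})

test_that("the RDF normalization satisfies the counting identity and the delta case", {
  # two fixed atoms at distance d: a single occupied bin
  cell <- diag(3) * 12
  traj <- structure(list(frames = list(rbind(c(0, 0, 0), c(2.5, 0, 0))),
                         species = c(18, 18), cell = cell, dt_frame = 1),
                    class = "md_trajectory")
  g <- radial_distribution(traj, c(18, 18), r_max = 5, n_bins = 50)
  occupied <- which(g$g > 0)
  expect_length(occupied, 1)
  expect_lt(abs(g$r[occupied] - 2.5), 0.1)
  expect_error(radial_distribution(traj, c(18, 18), r_max = 7), "half the smallest")
  # counting identity: integral of rho g 4 pi r^2 dr = neighbors within r_max
  set.seed(7)
  n <- 40
  frames <- lapply(1:20, function(f) matrix(runif(3 * n, 0, 12), n, 3))
  traj2 <- structure(list(frames = frames, species = rep(18, n), cell = cell,
                          dt_frame = 1),
                     class = "md_trajectory")
  g2 <- radial_distribution(traj2, c(18, 18), r_max = 5, n_bins = 60)
  dr <- diff(g2$r[1:2])
  rho <- (n - 1) / det(cell)     # partner density per central atom
  integral <- sum(g2$g * 4 * pi * g2$r^2 * rho * dr)
  # direct average neighbor count
  counts <- vapply(frames, function(pos) {
    d <- as.matrix(stats::dist(pos))
    fr <- pos %*% solve(cell)
    cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dd <- fr[j, ] - fr[i, ]; dd <- dd - round(dd)
      r <- sqrt(sum((dd %*% cell)^2))
      if (r < 5) cnt <- cnt + 2
    }
    cnt / n
  }, numeric(1))
  expect_lt(abs(integral - mean(counts)) / mean(counts), 0.05)
})

test_that("ideal-gas RDF is flat at unity within counting noise", {
  set.seed(8)
  n <- 60
  cell <- diag(3) * 10
  frames <- lapply(1:40, function(f) matrix(runif(3 * n, 0, 10), n, 3))
  traj <- structure(list(frames = frames, species = rep(18, n), cell = cell,
                         dt_frame = 1),
                    class = "md_trajectory")
  g <- radial_distribution(traj, c(18, 18), r_max = 4.5, n_bins = 15)
  keep <- g$r > 1   # skip the lowest-count bin
  expect_lt(max(abs(g$g[keep] - 1)), 0.15)
})

test_that("dipole spectra locate injected frequencies and respect neutrality", {
  # constant dipole: all weight at zero frequency
  nf <- 512; dt <- 1
  frames <- lapply(1:nf, function(f) rbind(c(1, 0, 0), c(-1, 0, 0)))
  charges <- lapply(1:nf, function(f) c(0.5, -0.5))
  traj <- structure(list(frames = frames, charges = charges, dt_frame = dt,
                         species = c(1, 1), cell = NULL),
                    class = "md_trajectory")
  sp <- dipole_spectrum(traj)
  expect_lt(max(sp$intensity[-1]), 1e-10 + 1e-6 * max(sp$intensity[1], 1e-30))

  # oscillating charge separation at frequency nu
  nu_cm <- 1500                      # target line position in 1/cm
  c_cm_fs <- 2.99792458e-5
  nu_fs <- nu_cm * c_cm_fs           # cycles per fs
  frames2 <- lapply(1:nf, function(f) {
    rbind(c(1 + 0.3 * sin(2 * pi * nu_fs * f * dt), 0, 0), c(-1, 0, 0))
  })
  traj2 <- structure(list(frames = frames2, charges = charges, dt_frame = dt,
                          species = c(1, 1), cell = NULL),
                     class = "md_trajectory")
  sp2 <- dipole_spectrum(traj2)
  peak <- sp2$freq[which.max(sp2$intensity[-1]) + 1]
  bin <- diff(sp2$freq[1:2])
  expect_lt(abs(peak - nu_cm), bin + 1e-9)
  # doubling the trajectory length keeps the peak within one (finer) bin
  frames4 <- lapply(1:(2 * nf), function(f) {
    rbind(c(1 + 0.3 * sin(2 * pi * nu_fs * f * dt), 0, 0), c(-1, 0, 0))
  })
  traj4 <- structure(list(frames = frames4, charges = rep(charges, 2),
                          dt_frame = dt, species = c(1, 1), cell = NULL),
                     class = "md_trajectory")
  sp4 <- dipole_spectrum(traj4)
  peak4 <- sp4$freq[which.max(sp4$intensity[-1]) + 1]
  expect_lt(abs(peak4 - nu_cm), bin + 1e-9)

  # neutral systems: the dipole is origin independent
  M0 <- colSums(frames2[[5]] * charges[[5]])
  M1 <- colSums((frames2[[5]] + 7) * charges[[5]])
  expect_equal(M0, M1, tolerance = 1e-12)
  traj_noq <- traj2; traj_noq$charges <- NULL
  expect_error(dipole_spectrum(traj_noq), "charges")
})

test_that("the model potential drives stable short NVT dynamics", {
  m <- nnp_model(model_config(n_scalar = 8, n_channels = 2, l_max = 1,
                              n_layers = 1, mlp2b_hidden = c(8, 8),
                              latent_hidden = c(8, 8), head_hidden = c(8, 4)),
                 seed = 23, ref_energies = synthetic_reference_energies())
  pos <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
               c(3.0, 0, 0), c(3.96, 0, 0), c(2.76, 0.93, 0))
  sys <- atomic_system(c(8, 1, 1, 8, 1, 1), pos)
  st <- md_state(sys, temperature = 300, friction = 0.05, seed = 9)
  traj <- simulate_nvt(st, model_potential(m), n_steps = 400, dt = 0.5,
                       stride = 20, log_charges = TRUE)
  expect_true(all(vapply(traj$frames, function(p) all(is.finite(p)), logical(1))))
  expect_true(all(is.finite(traj$energies)))
  expect_length(traj$charges, length(traj$frames))
  expect_equal(length(traj$frames), 21)
})
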