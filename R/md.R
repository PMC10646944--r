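# NVT molecular dynamics with the BAOAB Langevin splitting, plus the
# trajectory analyses: partial radial distribution functions and the
# dipole time-correlation spectrum.
#
# Units: positions A, velocities A/fs, masses amu, time fs, temperature K.
# Kinetic energy (kcal/mol) = 0.5 m v^2 / 4.184e-4; acceleration (A/fs^2)
# = F (kcal/mol/A) / m * 4.184e-4.

#' Construct an MD state
#'
#' @param system an `atomic_system`.
#' @param velocities N x 3 matrix (A/fs); default: Maxwell-Boltzmann at
#'   `temperature`.
#' @param temperature thermostat temperature (K).
#' @param friction thermostat friction (1/fs).
#' @param masses per-atom masses (amu); default from the element table.
#' @param seed RNG seed for velocity initialization and the thermostat.
#' @return object of class `md_state`.
#' @export
md_state <- function(system, velocities = NULL, temperature = 300,
                     friction = 0.01, masses = NULL, seed = 1) {
  if (is.null(masses)) masses <- .element_masses[system$species]
  stopifnot(all(masses > 0), all(is.finite(system$positions)))
  set.seed(seed)
  n <- length(system$species)
  if (is.null(velocities)) {
    sigma <- sqrt(.kB * temperature * .acc_unit / masses)
    velocities <- matrix(stats::rnorm(3 * n), n, 3) * sigma
  }
  structure(list(system = system, velocities = velocities, masses = masses,
                 temperature = temperature, friction = friction, time = 0),
            class = "md_state")
}

#' One BAOAB integration step
#'
#' Half kick, half drift, exact Ornstein-Uhlenbeck velocity refresh, half
#' drift, half kick. The OU step uses the exact exponential coefficients
#' c1 = exp(-friction dt), c2 = sqrt(1 - c1^2) sigma_v, so the thermostat
#' is exact for any time step.
#'
#' @param state an `md_state`.
#' @param potential function(atomic_system) returning a list with `energy`
#'   and `forces` (kcal/mol, kcal/mol/A).
#' @param dt time step (fs).
#' @param cached_forces optional forces from the previous step's end (saves
#'   one evaluation).
#' @return updated `md_state` with `forces`, `energy`, `kinetic` fields.
#' @export
baoab_step <- function(state, potential, dt, cached_forces = NULL) {
  stopifnot(dt > 0)
  m <- state$masses
  v <- state$velocities
  x <- state$system$positions
  F0 <- cached_forces
  if (is.null(F0)) {
    ev <- potential(state$system)
    F0 <- ev$forces
  }
  if (!all(is.finite(F0))) {
    bad <- which(!apply(is.finite(F0), 1, all))[1]
    stop("non-finite force on atom ", bad)
  }
  v <- v + 0.5 * dt * F0 / m * .acc_unit            # B
  x <- x + 0.5 * dt * v                              # A
  c1 <- exp(-state$friction * dt)                    # O
  sigma <- sqrt(.kB * state$temperature * .acc_unit / m)
  v <- c1 * v + sqrt(1 - c1^2) * sigma * matrix(stats::rnorm(length(v)), nrow(v), 3)
  x <- x + 0.5 * dt * v                              # A
  sys <- atomic_system(state$system$species, x, cell = state$system$cell,
                       periodic = state$system$periodic)
  ev <- potential(sys)
  if (!all(is.finite(ev$forces))) {
    bad <- which(!apply(is.finite(ev$forces), 1, all))[1]
    stop("non-finite force on atom ", bad)
  }
  v <- v + 0.5 * dt * ev$forces / m * .acc_unit      # B
  state$system <- sys
  state$velocities <- v
  state$time <- state$time + dt
  state$forces <- ev$forces
  state$energy <- ev$energy
  state$charges <- ev$charges
  state$kinetic <- 0.5 * sum(m * rowSums(v^2)) / .acc_unit
  state
}

#' Run NVT dynamics
#'
#' Repeated [baoab_step()]s with optional periodic wrapping of the stored
#' frames (coordinates are propagated unwrapped internally so dipole and
#' transport quantities stay continuous).
#'
#' @param state initial `md_state`.
#' @param potential see [baoab_step()].
#' @param n_steps number of steps.
#' @param dt time step (fs, default 0.5).
#' @param stride store every `stride`-th frame.
#' @param log_charges store the potential's per-atom charges per frame
#'   (for dipole spectra; requires the potential to return `charges`).
#' @param progress print a line every `progress` steps (0 = quiet).
#' @return object of class `md_trajectory`: list with `frames` (list of
#'   position matrices), `velocities`, `charges`, `times`, `energies`,
#'   `kinetic`, `cell`, `species`, `dt_frame`.
#' @export
simulate_nvt <- function(state, potential, n_steps, dt = 0.5, stride = 1L,
                         log_charges = FALSE, progress = 0) {
  frames <- list(state$system$positions)
  vels <- list(state$velocities)
  times <- state$time
  energies <- numeric(0); kin <- numeric(0); qlog <- list()
  ev <- potential(state$system)
  energies <- ev$energy
  kin <- 0.5 * sum(state$masses * rowSums(state$velocities^2)) / .acc_unit
  if (log_charges) {
    if (is.null(ev$charges)) stop("potential does not provide charges")
    qlog[[1]] <- ev$charges
  }
  cf <- ev$forces
  if (n_steps > 0) for (s in seq_len(n_steps)) {
    state <- baoab_step(state, potential, dt, cached_forces = cf)
    cf <- state$forces
    if (s %% stride == 0L) {
      frames[[length(frames) + 1L]] <- state$system$positions
      vels[[length(vels) + 1L]] <- state$velocities
      times <- c(times, state$time)
      energies <- c(energies, state$energy)
      kin <- c(kin, state$kinetic)
      if (log_charges) qlog[[length(qlog) + 1L]] <- state$charges
    }
    if (progress > 0 && s %% progress == 0L) {
      message(sprintf("step %d / %d: E = %.4f, KE = %.4f", s, n_steps,
                      state$energy, state$kinetic))
    }
  }
  structure(list(frames = frames, velocities = vels,
                 charges = if (length(qlog)) qlog else NULL,
                 times = times, energies = energies, kinetic = kin,
                 cell = state$system$cell, species = state$system$species,
                 dt_frame = dt * stride, final_state = state),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory: %d frames, %d atoms, frame spacing %g fs>\n",
              length(x$frames), length(x$species), x$dt_frame))
  invisible(x)
}

#' Partial radial distribution function
#'
#' Histogram of minimum-image pair distances for a species pair, normalized
#' by the ideal-gas shell expectation and the frame count, so g(r) -> 1 at
#' large r for homogeneous systems.
#'
#' @param traj an `md_trajectory` with a periodic cell.
#' @param species_pair length-2 vector of atomic numbers (or symbols),
#'   e.g. c("O", "H").
#' @param r_max maximum distance (must not exceed half the smallest cell
#'   height).
#' @param n_bins number of bins.
#' @param frames frame indices to use (default all).
#' @return data.frame with bin centers `r` and `g`.
#' @export
radial_distribution <- function(traj, species_pair, r_max, n_bins = 100,
                                frames = NULL) {
  if (is.null(traj$cell)) stop("radial_distribution requires a periodic trajectory")
  if (is.character(species_pair)) species_pair <- element_z(species_pair)
  heights <- cell_heights(traj$cell)
  if (r_max > min(heights) / 2 + 1e-9) {
    stop("r_max exceeds half the smallest cell height")
  }
  if (is.null(frames)) frames <- seq_along(traj$frames)
  ia <- which(traj$species == species_pair[1])
  ib <- which(traj$species == species_pair[2])
  if (!length(ia) || !length(ib)) stop("species not present in trajectory")
  inv <- solve(traj$cell)
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  same <- species_pair[1] == species_pair[2]
  for (f in frames) {
    pos <- traj$frames[[f]]
    d <- pos[rep(ib, each = length(ia)), , drop = FALSE] -
         pos[rep(ia, times = length(ib)), , drop = FALSE]
    # minimum image through fractional wrapping
    fr <- d %*% inv
    fr <- fr - round(fr)
    d <- fr %*% traj$cell
    rr <- sqrt(rowSums(d^2))
    if (same) rr <- rr[rep(ib, each = length(ia)) != rep(ia, times = length(ib))]
    rr <- rr[rr > 0 & rr < r_max]
    counts <- counts + tabulate(findInterval(rr, edges, rightmost.closed = TRUE),
                                nbins = n_bins)
  }
  V <- abs(det(traj$cell))
  n_pairs_tot <- if (same) length(ia) * (length(ia) - 1L) else length(ia) * length(ib)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  ideal <- n_pairs_tot * shell / V * length(frames)
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2, g = counts / ideal)
}

#' Dipole time-correlation spectrum
#'
#' Total dipole M(t) = sum q_i(t) r_i(t) per frame; the spectrum is the
#' discrete Fourier transform of the Hann-windowed dipole autocorrelation
#' function. The frequency axis is in 1/cm.
#'
#' @param traj an `md_trajectory` carrying per-frame charges.
#' @param dt frame spacing in fs (default from the trajectory).
#' @return data.frame with `freq` (1/cm) and `intensity` (arbitrary units).
#' @export
dipole_spectrum <- function(traj, dt = NULL) {
  if (is.null(traj$charges)) stop("trajectory has no per-frame charges")
  if (is.null(dt)) dt <- traj$dt_frame
  M <- t(vapply(seq_along(traj$frames), function(f) {
    colSums(traj$frames[[f]] * traj$charges[[f]])
  }, numeric(3)))
  nf <- nrow(M)
  nlag <- floor(nf / 2)
  acf3 <- sapply(1:3, function(k) {
    x <- M[, k] - mean(M[, k])
    vapply(0:(nlag - 1L), function(lag) {
      mean(x[1:(nf - lag)] * x[(1 + lag):nf])
    }, numeric(1))
  })
  ac <- rowSums(acf3)
  w <- 0.5 * (1 + cos(pi * (0:(nlag - 1L)) / nlag))   # Hann half-window
  sp <- abs(stats::fft(ac * w))[1:floor(nlag / 2)]
  c_cm_fs <- 2.99792458e-5   # speed of light in cm/fs
  freq <- (seq_along(sp) - 1L) / (nlag * dt) / c_cm_fs
  data.frame(freq = freq, intensity = sp)
}

#' Model-based potential closure for MD
#'
#' Wraps a model into the `potential(system)` interface used by the
#' integrator, returning energy, forces and the fluctuating charges.
#'
#' @param model an `nnp_model`.
#' @param include_physics include the long-range terms.
#' @return function(system) -> list(energy, forces, charges).
#' @export
model_potential <- function(model, include_physics = TRUE) {
  function(system) {
    eb <- total_energy_forces(model, system, forces = TRUE,
                              include_physics = include_physics)
    list(energy = eb$E_total, forces = eb$forces, charges = eb$charges)
  }
}
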