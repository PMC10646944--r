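# Shared test fixtures: random geometries, rotation matrices and
# independently constructed Wigner rotation matrices for the real
# spherical-harmonic basis (l = 1 from the Cartesian rotation itself, l = 2
# from the action on symmetric traceless matrices).

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Wigner matrix for l = 1 in the (y, z, x) real ordering
wigner_d1 <- function(Q) {
  s <- c(2, 3, 1)
  M <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) M[i, j] <- Q[s[i], s[j]]
  M
}

# Wigner matrix for l = 2 via the symmetric-traceless matrix representation
wigner_d2 <- function(Q) {
  E <- function(i, j) { m <- matrix(0, 3, 3); m[i, j] <- 1; m }
  Ms <- list(sqrt(15) / 2 * (E(1, 2) + E(2, 1)),
             sqrt(15) / 2 * (E(2, 3) + E(3, 2)),
             sqrt(5) / 2 * (3 * E(3, 3) - diag(3)),
             sqrt(15) / 2 * (E(1, 3) + E(3, 1)),
             sqrt(15) / 2 * (E(1, 1) - E(2, 2)))
  D <- matrix(0, 5, 5)
  for (k in 1:5) {
    Tm <- t(Q) %*% Ms[[k]] %*% Q
    for (kp in 1:5) D[k, kp] <- sum(Ms[[kp]] * Tm) / sum(Ms[[kp]]^2)
  }
  D
}

wigner_block <- function(Q, l, parity_sign = 1) {
  D <- switch(as.character(l),
              "0" = matrix(1, 1, 1),
              "1" = wigner_d1(Q),
              "2" = wigner_d2(Q),
              stop("no Wigner oracle for l > 2"))
  parity_sign * D
}

# random compact cluster with all atoms inside the cutoff of each other
random_cluster <- function(n = 6, species_pool = c(1, 6, 7, 8), spread = 1.6,
                           min_sep = 0.75) {
  repeat {
    pos <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
    if (n < 2 || min(stats::dist(pos)) > min_sep) break
  }
  atomic_system(sample(species_pool, n, replace = TRUE), pos)
}

# small, fast model configuration used across tests
tiny_config <- function(...) {
  model_config(n_scalar = 16, n_channels = 3, l_max = 2, n_layers = 2,
               mlp2b_hidden = c(8, 16), latent_hidden = c(16, 16),
               head_hidden = c(16, 8), ...)
}

tiny_model <- function(seed = 42, ...) {
  nnp_model(tiny_config(...), seed = seed,
            ref_energies = synthetic_reference_energies())
}

# reduced configuration of the desk-scale training experiments
reduced_config <- function() {
  model_config(n_scalar = 32, n_channels = 4, l_max = 1, n_layers = 1,
               mlp2b_hidden = c(32, 32), latent_hidden = c(64, 64),
               head_hidden = c(64, 32))
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(abs(b), 1e-300)
}
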