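# The equivariant pair embedding: two-body features, interaction layers,
# rotation/inversion equivariance, strict locality and smoothness.

test_that("two-body embedding vanishes at the cutoff and is direction-sensitive", {
  m <- tiny_model()
  # pair just inside the cutoff: x2b suppressed by the envelope
  near <- atomic_system(c(8, 1), rbind(c(0, 0, 0), c(m$config$r_c - 1e-6, 0, 0)))
  e_near <- embed_pairs(m, near)
  expect_lt(max(abs(e_near$x2b)), 1e-12)
  # unlike species: the directed pair (i, j) differs from (j, i)
  oh <- atomic_system(c(8, 1), rbind(c(0, 0, 0), c(1.0, 0, 0)))
  e <- embed_pairs(m, oh)
  expect_gt(max(abs(e$x2b[1, ] - e$x2b[2, ])), 1e-8)
  expect_equal(ncol(e$x2b), m$config$n_scalar)
  expect_equal(ncol(e$tensors[["1o"]]), m$config$n_channels * 3)
})

test_that("scalar embedding is invariant and tensors are equivariant under rotation", {
  set.seed(11)
  m <- tiny_model()
  C <- m$config$n_channels
  sys <- random_cluster(5)
  e0 <- embed_pairs(m, sys)
  for (rep in 1:5) {
    Q <- random_rotation()
    er <- embed_pairs(m, atomic_system(sys$species, sys$positions %*% t(Q)))
    expect_lt(max_rel_err(er$x, e0$x), 1e-10)
    for (key in names(e0$tensors)) {
      l <- as.integer(substr(key, 1, 1))
      D <- wigner_block(Q, l)
      dl <- 2 * l + 1
      for (ch in seq_len(C)) {
        cols <- (seq_len(dl) - 1) * C + ch
        expect_lt(max(abs(er$tensors[[key]][, cols] -
                          e0$tensors[[key]][, cols] %*% t(D))),
                  1e-10 * max(1, max(abs(e0$tensors[[key]]))))
      }
    }
  }
})

test_that("tensor blocks flip with their parity under inversion", {
  set.seed(12)
  m <- tiny_model()
  sys <- random_cluster(5)
  e0 <- embed_pairs(m, sys)
  ei <- embed_pairs(m, atomic_system(sys$species, -sys$positions))
  expect_lt(max_rel_err(ei$x, e0$x), 1e-10)
  for (key in names(e0$tensors)) {
    p <- ifelse(substr(key, 2, 2) == "e", 1, -1)
    expect_lt(max(abs(ei$tensors[[key]] - p * e0$tensors[[key]])),
              1e-10 * max(1, max(abs(e0$tensors[[key]]))))
  }
})

test_that("embedding is strictly local and bitwise stable to distant perturbations", {
  m <- tiny_model()
  # two dimers far beyond the cutoff of each other
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(30, 0, 0), c(31, 0, 0))
  sys1 <- atomic_system(c(8, 1, 8, 1), pos)
  pos2 <- pos; pos2[4, ] <- pos2[4, ] + c(0.3, 0.2, -0.1)  # perturb far dimer
  sys2 <- atomic_system(c(8, 1, 8, 1), pos2)
  e1 <- embed_pairs(m, sys1)
  e2 <- embed_pairs(m, sys2)
  # pairs (1,2) and (2,1) are rows 1:2 in both graphs (sorted ordering)
  expect_identical(e1$x[1:2, ], e2$x[1:2, ])
  expect_identical(e1$x2b[1:2, ], e2$x2b[1:2, ])
})

test_that("atomic properties vary continuously as a neighbor crosses the cutoff", {
  m <- tiny_model()
  r_c <- m$config$r_c
  probe <- function(d) {
    sys <- atomic_system(c(8, 1, 1), rbind(c(0, 0, 0), c(1, 0, 0), c(d, 0, 0)))
    atomic_properties(m, sys)
  }
  below <- probe(r_c - 1e-4)
  above <- probe(r_c + 1e-4)
  expect_lt(max(abs(below$local_energy - above$local_energy)), 1e-6)
  expect_lt(max(abs(below$charge - above$charge)), 1e-6)
})

test_that("the mixing coefficient interpolates between scalar propagation and update", {
  m <- tiny_model()
  sys <- atomic_system(c(8, 1), rbind(c(0, 0, 0), c(1.0, 0, 0)))
  # alpha -> 1: scalars pass through all layers unchanged
  m1 <- m
  for (L in seq_len(m$config$n_layers)) {
    m1$params[[paste0("layer", L, ".alpha_raw")]] <- matrix(40, 1, 1)
  }
  e1 <- embed_pairs(m1, sys)
  expect_lt(max(abs(e1$x - e1$x2b)), 1e-6)
  # alpha -> 0: output is the latent-path update, not the previous scalars
  m0 <- m
  for (L in seq_len(m$config$n_layers)) {
    m0$params[[paste0("layer", L, ".alpha_raw")]] <- matrix(-40, 1, 1)
  }
  e0 <- embed_pairs(m0, sys)
  expect_gt(max(abs(e0$x - e0$x2b)), 1e-4)
})

test_that("permuting identical atoms permutes the pair embeddings", {
  set.seed(13)
  pos <- matrix(rnorm(9, sd = 0.9), 3, 3)
  pos <- pos * 1.4
  sys <- atomic_system(c(1, 1, 1), pos)
  m <- tiny_model()
  e <- embed_pairs(m, sys)
  perm <- c(3L, 1L, 2L)
  sysp <- atomic_system(c(1, 1, 1), pos[perm, ])
  ep <- embed_pairs(m, sysp)
  # map pair (i, j) of the original to (inv[i], inv[j]) of the permuted graph
  inv <- order(perm)
  for (k in seq_along(e$graph$src)) {
    i2 <- inv[e$graph$src[k]]; j2 <- inv[e$graph$dst[k]]
    k2 <- which(ep$graph$src == i2 & ep$graph$dst == j2)
    expect_equal(e$x[k, ], ep$x[k2, ], tolerance = 1e-10)
  }
})

test_that("isolated atoms produce an empty embedding without failure", {
  m <- tiny_model()
  iso <- atomic_system(c(6, 8), rbind(c(0, 0, 0), c(50, 0, 0)))
  e <- embed_pairs(m, iso)
  expect_equal(nrow(e$x), 0)
  props <- atomic_properties(m, iso)
  expect_equal(props$charge, c(0, 0))
  expect_equal(props$local_energy, c(0, 0))
  expect_equal(props$volume_ratio, rep(log(1 + exp(0)), 2))  # softplus(0)
})

test_that("checkpoint save/load reproduces the model exactly", {
  m <- tiny_model(seed = 9)
  sys <- random_cluster(4)
  e <- total_energy_forces(m, sys, forces = FALSE)
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  e2 <- total_energy_forces(m2, sys, forces = FALSE)
  expect_identical(e2$E_total, e$E_total)
  # shape validation catches corrupted archives
  ck <- readRDS(f)
  ck$params[["embed2b.W"]] <- ck$params[["embed2b.W"]][, -1]
  f2 <- tempfile(fileext = ".ckpt")
  saveRDS(ck, f2)
  expect_error(load_checkpoint(f2), "shape mismatch")
})
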