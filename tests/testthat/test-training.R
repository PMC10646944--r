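# Losses, regularizer, optimizer policies, freezing and the stage runner.

test_that("stage-1 loss reproduces the printed weights and hand arithmetic", {
  rec <- list(energy = 10, forces = matrix(0, 2, 3),
              charges = c(0.1, -0.1), volume_ratios = c(1, 1))
  perfect <- list(energy = 10, forces = matrix(0, 2, 3),
                  charges = c(0.1, -0.1), volume_ratios = c(1, 1))
  expect_equal(stage1_loss(perfect, rec), 0)
  # unit energy error with lambda_E = 0.001 and everything else exact
  off <- perfect; off$energy <- 11
  expect_equal(stage1_loss(off, rec), 0.001)
  # mixed residuals: hand-computed weighted sum
  mix <- perfect
  mix$energy <- 12                       # dE = 2
  mix$forces[1, 1] <- 0.5                # one component of six
  mix$charges <- c(0.11, -0.1)           # dq = 0.01 on one of two atoms
  expected <- 0.001 * 4 + 1 * (0.5^2 / 6) + 1000 * (0.01^2 / 2)
  expect_equal(stage1_loss(mix, rec), expected, tolerance = 1e-12)
  bad <- rec; bad$charges <- NULL
  expect_error(stage1_loss(perfect, bad), "charges")
})

test_that("stage-2/3 losses weight interaction residuals as printed", {
  rec_i <- list(kind = "interaction", energy = -3, monomers = list(1:3, 4:6))
  expect_equal(stage23_loss(list(interaction = -3), rec_i), 0)
  expect_equal(stage23_loss(list(interaction = -2.8), rec_i),
               5 * 0.2^2, tolerance = 1e-12)
  rec_i$monomers <- NULL
  expect_error(stage23_loss(list(interaction = -3), rec_i), "monomer")
  rec_t <- list(kind = "total", energy = 5, forces = matrix(0, 1, 3))
  expect_equal(stage23_loss(list(energy = 6, forces = matrix(0, 1, 3)), rec_t),
               0.01 * 1)
})

test_that("interaction energies are invariant to reference-energy shifts", {
  set.seed(41)
  ds <- synthetic_dataset(list(templates = list("water_dimer"), counts = 1), seed = 3)
  rec <- ds[[1]]
  eval_int <- function(model) {
    dimer <- atomic_system(rec$species, rec$positions)
    m1 <- atomic_system(rec$species[1:3], rec$positions[1:3, ])
    m2 <- atomic_system(rec$species[4:6], rec$positions[4:6, ])
    total_energy_forces(model, dimer, forces = FALSE)$E_total -
      total_energy_forces(model, m1, forces = FALSE)$E_total -
      total_energy_forces(model, m2, forces = FALSE)$E_total
  }
  m <- tiny_model(seed = 3)
  refs <- synthetic_reference_energies()
  m_shift <- nnp_model(tiny_config(), seed = 3, ref_energies = refs + 100)
  expect_equal(eval_int(m), eval_int(m_shift), tolerance = 1e-9)
})

test_that("covariance regularizer detects correlation and ignores mean shifts", {
  set.seed(42)
  x <- matrix(rnorm(200), 50, 4)
  dup <- cbind(x, x[, 1])          # perfectly correlated extra feature
  expect_gt(covariance_regularizer(dup), 0.5)
  shifted <- sweep(x, 2, c(10, -5, 3, 100), "+")
  expect_equal(covariance_regularizer(x), covariance_regularizer(shifted),
               tolerance = 1e-9)
  expect_equal(covariance_regularizer(x[1, , drop = FALSE]), 0)
  # independent features: decreasing trend with 10x batch growth
  r_small <- mean(replicate(10, covariance_regularizer(matrix(rnorm(80), 20, 4))))
  r_big <- mean(replicate(10, covariance_regularizer(matrix(rnorm(800), 200, 4))))
  expect_lt(r_big, r_small)
  # the tape version agrees with the reference implementation
  expect_equal(ad_value(.ad_cov_offdiag(ad_const(x)))[1],
               covariance_regularizer(x), tolerance = 1e-10)
})

test_that("AdamW applies weight decay per parameter group", {
  params <- list("head.e.W1" = matrix(1, 2, 2), "layer1.latent.W1" = matrix(1, 2, 2))
  grads <- list("head.e.W1" = matrix(0, 2, 2), "layer1.latent.W1" = matrix(0, 2, 2))
  st <- adamw_init(params)
  out <- adamw_step(params, grads, st, lr = 0.1,
                    weight_decay = list(embedding = 0, output = 0.5, physics = 0))
  # zero gradient: only decay acts, and only on the output group
  expect_equal(out$params[["head.e.W1"]], matrix(1 - 0.1 * 0.5, 2, 2))
  expect_equal(out$params[["layer1.latent.W1"]], matrix(1, 2, 2))
  expect_equal(param_group("ff.eps"), "physics")
  expect_equal(param_group("mlp2b.W1"), "embedding")
})

test_that("frozen parameter groups stay bitwise identical through a stage", {
  set.seed(43)
  ds <- synthetic_dataset(list(templates = list(list(z = c(8, 1))), counts = 24,
                               deformation = 0.4), seed = 7)
  m <- nnp_model(reduced_config(), seed = 4,
                 ref_energies = synthetic_reference_energies())
  cfgs <- stage_config(weights = list(E = 0.01, F = 0), batch_size = 8,
                       max_epochs = 2, frozen = c("^mlp2b", "^embed2b", "^layer", "^ff"),
                       cov_weight = 0)
  res <- train_stage(m, ds, cfgs, seed = 5)
  frozen <- grep("^(mlp2b|embed2b|layer|ff)", names(m$params), value = TRUE)
  for (nm in frozen) expect_identical(res$model$params[[nm]], m$params[[nm]])
  heads <- grep("^head\\.e", names(m$params), value = TRUE)
  expect_gt(max(vapply(heads, function(nm) {
    max(abs(res$model$params[[nm]] - m$params[[nm]]))
  }, numeric(1))), 0)
})

test_that("the logged loss decomposes bitwise into its components", {
  ds <- synthetic_dataset(list(templates = list(list(z = c(8, 1))), counts = 6,
                               deformation = 0.3), seed = 9)
  m <- nnp_model(reduced_config(), seed = 6,
                 ref_energies = synthetic_reference_energies())
  units <- .prep_records(ds, m$config$r_c)
  merged <- .merge_units(units)
  pn <- lapply(m$params, ad_leaf)
  out <- .batch_forward(m, merged, pn, FALSE, TRUE)
  bl <- .batch_loss(m, merged, ds, out, list(E = 0.001, F = 1, q = 1000, v = 1000),
                    cov_weight = 1e-3)
  total <- ad_value(bl$total)[1]
  parts <- vapply(bl$parts, function(p) ad_value(p)[1], numeric(1))
  expect_identical(total, sum(parts))
  expect_setequal(names(parts), c("energy", "forces", "charges", "volumes",
                                  "covariance"))
})

test_that("training reduces the loss and the schedule runs end to end", {
  ds <- synthetic_dataset(list(templates = list(list(z = c(8, 1))), counts = 40,
                               deformation = 0.4), seed = 13)
  m <- nnp_model(reduced_config(), seed = 8,
                 ref_energies = synthetic_reference_energies())
  stages <- list(
    stage_config(weights = list(E = 0.001, F = 1, q = 1000, v = 1000),
                 batch_size = 16, max_epochs = 6, cov_weight = 1e-4, clip = 50),
    stage_config(weights = list(E = 0.01, F = 0), include_physics = TRUE,
                 frozen = c("^mlp2b", "^embed2b", "^layer", "^head\\.(q|v)"),
                 batch_size = 16, max_epochs = 2, cov_weight = 0, lr = 1e-4, lr_stop = 1e-6)
  )
  res <- run_schedule(m, ds, stages, seed = 3)
  h <- res$history
  expect_equal(sort(unique(h$stage)), c(1, 2))
  h1 <- h[h$stage == 1, ]
  expect_lt(h1$train[nrow(h1)], h1$train[1])
  # best-validation curve is monotone non-increasing by construction
  expect_true(all(diff(h1$best_val) <= 0))
  expect_error(train_stage(m, list(), stages[[1]]), "empty dataset")
})

test_that("interaction records train through the dimer-minus-monomer path", {
  ds <- synthetic_dataset(list(templates = list("water_dimer"), counts = 6), seed = 17)
  m <- nnp_model(reduced_config(), seed = 9,
                 ref_energies = synthetic_reference_energies())
  cfgs <- stage_config(weights = list(E = 0, F = 0, DES = 5),
                       include_physics = TRUE, batch_size = 6, max_epochs = 2,
                       cov_weight = 0, lr = 1e-4, lr_stop = 1e-6,
                       frozen = c("^head\\.(q|v)"))
  res <- train_stage(m, ds, cfgs, seed = 11)
  expect_true(all(is.finite(res$history$train)))
  expect_true("val_interaction" %in% names(res$history))
})
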