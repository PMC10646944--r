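# Multi-stage training: weighted multi-target losses, covariance
# regularization of the scalar embedding, AdamW with per-group weight
# decay, parameter freezing, and a plateau learning-rate schedule.
#
# Records are merged into batches as disconnected multi-molecule systems
# (atom and pair indices offset), so one tape evaluation yields per-molecule
# energies, per-atom forces/charges/volumes for the whole batch.
# Interaction-energy records contribute three molecules (dimer + both
# monomers); their prediction is the model-consistent difference.

#' Stage-1 loss on one record or batch
#'
#' Weighted sum of squared errors on total energy, forces (mean over
#' components), charges and volume ratios (mean over atoms). For a batch,
#' every term is averaged over records. Missing labels raise an error
#' naming the field.
#'
#' @param predictions list with `energy`, `forces`, `charges`,
#'   `volume_ratios`.
#' @param record a training record (same fields as labels).
#' @param weights list with `E`, `F`, `q`, `v` (defaults 0.001, 1, 1000, 1000).
#' @return scalar loss.
#' @export
stage1_loss <- function(predictions, record,
                        weights = list(E = 0.001, F = 1, q = 1000, v = 1000)) {
  for (f in c("energy", "forces", "charges", "volume_ratios")) {
    if (is.null(record[[f]])) stop("record is missing label: ", f)
  }
  weights$E * mean((predictions$energy - record$energy)^2) +
    weights$F * mean((predictions$forces - record$forces)^2) +
    weights$q * mean((predictions$charges - record$charges)^2) +
    weights$v * mean((predictions$volume_ratios - record$volume_ratios)^2)
}

#' Stage-2/3 losses on full-model energies
#'
#' Stage 2: squared errors on the physics-augmented total energy and
#' forces. Stage 3 adds interaction-energy records (dimer minus monomers,
#' both evaluated with the same model), weighted by `DES`; constant shifts
#' of all total energies cancel in the interaction term.
#'
#' @param predictions list with `energy`, optional `forces`, optional
#'   `interaction`.
#' @param record record with matching labels (`energy`; for interaction
#'   records the label is the interaction energy and `monomers` must be
#'   present).
#' @param weights list with `E`, `F`, `DES` (defaults 0.01, 0.1, 5).
#' @return scalar loss.
#' @export
stage23_loss <- function(predictions, record,
                         weights = list(E = 0.01, F = 0.1, DES = 5)) {
  if (identical(record$kind, "interaction")) {
    if (is.null(record$monomers)) stop("interaction record is missing monomer partitions")
    return(weights$DES * mean((predictions$interaction - record$energy)^2))
  }
  loss <- weights$E * mean((predictions$energy - record$energy)^2)
  if (!is.null(record$forces) && !is.null(predictions$forces) && weights$F > 0) {
    loss <- loss + weights$F * mean((predictions$forces - record$forces)^2)
  }
  loss
}

#' Covariance regularizer of embedding features
#'
#' Sum of squared off-diagonal entries of the sample covariance matrix of
#' the features over a batch; zero for uncorrelated features, invariant to
#' mean shifts. Batches smaller than 2 return 0 (covariance undefined).
#'
#' @param features n x d matrix (rows = batch members).
#' @return scalar.
#' @export
covariance_regularizer <- function(features) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) return(0)
  C <- stats::cov(features)
  sum(C^2) - sum(diag(C)^2)
}

.ad_cov_offdiag <- function(x) {
  n <- nrow(x$v); d <- ncol(x$v)
  if (n < 2) return(ad_const(matrix(0, 1, 1)))
  xc <- ad_sub(x, ad_repeatrow(ad_kmul(ad_colsum(x), 1 / n), n))
  S <- ad_kmul(ad_matmul(xc, xc, ta = TRUE), 1 / (n - 1))
  ad_sub(ad_sum(ad_pow(S, 2)),
         ad_sum(ad_pow(ad_mul(S, ad_const(diag(d))), 2)))
}

# ---- batching -------------------------------------------------------------

# expand records into evaluation units: each total record is one molecule;
# each interaction record contributes dimer + monomer A + monomer B
.prep_records <- function(records, r_c) {
  units <- list()
  for (k in seq_along(records)) {
    r <- records[[k]]
    if (identical(r$kind, "interaction")) {
      ia <- r$monomers[[1]]; ib <- r$monomers[[2]]
      units[[length(units) + 1L]] <- list(
        record = k, role = "dimer", species = r$species, pos = r$positions)
      units[[length(units) + 1L]] <- list(
        record = k, role = "monoA", species = r$species[ia],
        pos = r$positions[ia, , drop = FALSE])
      units[[length(units) + 1L]] <- list(
        record = k, role = "monoB", species = r$species[ib],
        pos = r$positions[ib, , drop = FALSE])
    } else {
      units[[length(units) + 1L]] <- list(
        record = k, role = "total", species = r$species, pos = r$positions)
    }
  }
  for (u in seq_along(units)) {
    units[[u]]$graph <- build_pair_graph(
      atomic_system(units[[u]]$species, units[[u]]$pos), r_c)
  }
  units
}

# merge a set of units into one disconnected system + merged pair graph
.merge_units <- function(units) {
  n_atoms <- vapply(units, function(u) length(u$species), integer(1))
  at_off <- cumsum(c(0L, n_atoms))
  pr_off <- cumsum(c(0L, vapply(units, function(u) n_pairs(u$graph), integer(1))))
  species <- unlist(lapply(units, function(u) u$species))
  pos <- do.call(rbind, lapply(units, function(u) u$pos))
  mol_id <- rep(seq_along(units), n_atoms)
  src <- integer(0); dst <- integer(0); rev <- integer(0)
  disp <- matrix(0, 0, 3); sh <- matrix(0, 0, 3); dist <- numeric(0)
  for (u in seq_along(units)) {
    g <- units[[u]]$graph
    src <- c(src, g$src + at_off[u]); dst <- c(dst, g$dst + at_off[u])
    rev <- c(rev, g$rev + pr_off[u])
    disp <- rbind(disp, g$displacement); sh <- rbind(sh, g$shift)
    dist <- c(dist, g$distance)
  }
  graph <- structure(list(src = src, dst = dst, displacement = disp,
                          distance = dist, shift = sh, rev = rev,
                          cutoff = units[[1]]$graph$cutoff,
                          n_atoms = length(species)),
                     class = "pair_graph")
  list(species = species, pos = pos, mol_id = mol_id, graph = graph,
       units = units)
}

# evaluate a merged batch on the tape; returns nodes and label bookkeeping
.batch_forward <- function(model, merged, pn, include_physics, need_forces) {
  pos <- ad_leaf(merged$pos)
  out <- .total_tape(model, merged$species, pos, merged$graph, pn,
                     mol_id = merged$mol_id, include_physics = include_physics)
  forces <- NULL
  if (need_forces) {
    forces <- ad_neg(ad_backward(out$E_total, list(pos))[[1L]])
  }
  c(out, list(pos = pos, forces = forces))
}

# assemble the tape loss for a batch given stage weights
.batch_loss <- function(model, merged, records, out, weights, cov_weight) {
  units <- merged$units
  roles <- vapply(units, function(u) u$role, character(1))
  recs <- vapply(units, function(u) u$record, integer(1))
  parts <- list()

  tot <- which(roles == "total")
  if (length(tot) && (weights$E %||% 0) > 0) {
    lab <- vapply(tot, function(u) records[[recs[u]]]$energy, numeric(1))
    dE <- ad_sub(ad_gather(out$E_mol, tot), ad_const(matrix(lab, ncol = 1)))
    parts$energy <- ad_kmul(ad_sum(ad_pow(dE, 2)), weights$E / length(tot))
  }
  if (length(tot) && (weights$F %||% 0) > 0 && !is.null(out$forces)) {
    keep_atoms <- which(merged$mol_id %in% tot)
    labF <- do.call(rbind, lapply(tot, function(u) records[[recs[u]]]$forces))
    dF <- ad_sub(ad_gather(out$forces, keep_atoms), ad_const(labF))
    parts$forces <- ad_kmul(ad_sum(ad_pow(dF, 2)), weights$F / length(labF))
  }
  if (length(tot) && (weights$q %||% 0) > 0) {
    keep_atoms <- which(merged$mol_id %in% tot)
    labq <- unlist(lapply(tot, function(u) records[[recs[u]]]$charges))
    dq <- ad_sub(ad_gather(out$q_raw, keep_atoms), ad_const(matrix(labq, ncol = 1)))
    parts$charges <- ad_kmul(ad_sum(ad_pow(dq, 2)), weights$q / length(labq))
  }
  if (length(tot) && (weights$v %||% 0) > 0) {
    keep_atoms <- which(merged$mol_id %in% tot)
    labv <- unlist(lapply(tot, function(u) records[[recs[u]]]$volume_ratios))
    dv <- ad_sub(ad_gather(out$vol, keep_atoms), ad_const(matrix(labv, ncol = 1)))
    parts$volumes <- ad_kmul(ad_sum(ad_pow(dv, 2)), weights$v / length(labv))
  }
  dimers <- which(roles == "dimer")
  if (length(dimers) && (weights$DES %||% 0) > 0) {
    # interaction = E(dimer) - E(monoA) - E(monoB), same model
    Tm <- matrix(0, length(dimers), length(units))
    lab <- numeric(length(dimers))
    for (d in seq_along(dimers)) {
      rk <- recs[dimers[d]]
      Tm[d, which(recs == rk & roles == "dimer")] <- 1
      Tm[d, which(recs == rk & roles %in% c("monoA", "monoB"))] <- -1
      lab[d] <- records[[rk]]$energy
    }
    dI <- ad_sub(ad_matmul(ad_const(Tm), out$E_mol), ad_const(matrix(lab, ncol = 1)))
    parts$interaction <- ad_kmul(ad_sum(ad_pow(dI, 2)), weights$DES / length(dimers))
  }
  if (cov_weight > 0 && !is.null(out$x_embed)) {
    parts$covariance <- ad_kmul(.ad_cov_offdiag(out$x_embed), cov_weight)
  }
  loss <- ad_const(matrix(0, 1, 1))
  for (p in parts) loss <- ad_add(loss, p)
  list(total = loss, parts = parts)
}

# ---- optimizer ------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t; b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    wd <- weight_decay[[param_group(nm)]] %||% 0
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, state = state)
}

# ---- stage runner ---------------------------------------------------------

#' Configuration of one training stage
#'
#' @param weights loss weights: `E`, `F`, `q`, `v`, `DES` (unused terms 0).
#' @param include_physics evaluate the full physics-augmented energy.
#' @param frozen character vector of regular expressions; parameters whose
#'   names match any of them are frozen (values and optimizer state
#'   untouched).
#' @param lr initial learning rate.
#' @param lr_stop stop the stage when the plateau schedule drives the
#'   learning rate below this.
#' @param patience,factor plateau scheduler: multiply lr by `factor` when
#'   the training loss has not improved for `patience` epochs.
#' @param batch_size records per mini-batch.
#' @param max_epochs hard epoch cap.
#' @param weight_decay named list per parameter group (`embedding`,
#'   `output`, `physics`).
#' @param cov_weight weight of the covariance regularizer.
#' @param val_frac validation fraction (random split, fixed by seed).
#' @param clip global-norm gradient clipping threshold (stabilizes batches
#'   dominated by steep repulsive-wall forces).
#' @return a `stage_config` list.
#' @export
stage_config <- function(weights = list(E = 0.001, F = 1, q = 1000, v = 1000),
                         include_physics = FALSE, frozen = character(0),
                         lr = 1e-3, lr_stop = 1e-4, patience = 10, factor = 0.8,
                         batch_size = 256, max_epochs = 100,
                         weight_decay = list(embedding = 0, output = 0.5, physics = 0),
                         cov_weight = 1e-3, val_frac = 0.1, clip = 100) {
  stopifnot(lr_stop < lr, all(unlist(weights) >= 0))
  structure(as.list(environment()), class = "stage_config")
}

#' Train one stage
#'
#' Mini-batch AdamW with per-group weight decay, optional parameter
#' freezing and a plateau learning-rate scheduler; fully deterministic
#' given the seed.
#'
#' @param model an `nnp_model`.
#' @param records training records (see [synthetic_dataset()]).
#' @param config a [stage_config()].
#' @param seed integer controlling the validation split and batch
#'   shuffling.
#' @param verbose print per-epoch progress.
#' @return list with the trained `model` and a `history` data.frame
#'   (epoch, lr, train loss, validation loss, best validation loss).
#' @export
train_stage <- function(model, records, config, seed = 1, verbose = FALSE) {
  if (length(records) == 0L) stop("empty dataset")
  set.seed(seed)
  units_all <- .prep_records(records, model$config$r_c)
  rec_of_unit <- vapply(units_all, function(u) u$record, integer(1))

  n_rec <- length(records)
  n_val <- max(1L, round(config$val_frac * n_rec))
  val_rec <- sort(sample(n_rec, n_val))
  train_rec <- setdiff(seq_len(n_rec), val_rec)
  if (length(train_rec) == 0L) stop("no training records after validation split")

  frozen_mask <- rep(FALSE, length(model$params))
  names(frozen_mask) <- names(model$params)
  for (pat in config$frozen) frozen_mask <- frozen_mask | grepl(pat, names(frozen_mask))
  trainable <- names(model$params)[!frozen_mask]
  if (length(trainable) == 0L) stop("all parameters are frozen")

  need_forces <- (config$weights$F %||% 0) > 0
  opt <- adamw_init(model$params[trainable])
  lr <- config$lr
  best_train <- Inf; since_best <- 0L
  history <- NULL
  best_val <- Inf

  eval_batch <- function(rec_idx, params, with_grad) {
    units <- units_all[rec_of_unit %in% rec_idx]
    merged <- .merge_units(units)
    pn <- lapply(names(params), function(nm) {
      if (with_grad && nm %in% trainable) ad_leaf(params[[nm]]) else ad_const(params[[nm]])
    })
    names(pn) <- names(params)
    out <- .batch_forward(model, merged, pn, config$include_physics, need_forces)
    bl <- .batch_loss(model, merged, records, out, config$weights, config$cov_weight)
    list(loss = bl$total, parts = bl$parts, pn = pn)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_rec)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      eb <- eval_batch(b, model$params, with_grad = TRUE)
      grads <- ad_grad(eb$loss, eb$pn[trainable])
      names(grads) <- trainable
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (is.finite(config$clip) && gnorm > config$clip) {
        grads <- lapply(grads, function(g) g * (config$clip / gnorm))
      }
      step <- adamw_step(model$params[trainable], grads, opt, lr, config$weight_decay)
      model$params[trainable] <- step$params
      opt <- step$state
      epoch_loss <- epoch_loss + ad_value(eb$loss)[1] * length(b)
    }
    epoch_loss <- epoch_loss / length(train_rec)
    val_eval <- eval_batch(val_rec, model$params, FALSE)
    val_loss <- ad_value(val_eval$loss)[1]
    val_parts <- vapply(val_eval$parts, function(p) ad_value(p)[1], numeric(1))
    if (!is.finite(epoch_loss) || !is.finite(val_loss)) {
      stop(sprintf("non-finite loss at epoch %d (train %.3g, val %.3g)",
                   epoch, epoch_loss, val_loss))
    }
    best_val <- min(best_val, val_loss)
    hrow <- data.frame(epoch = epoch, lr = lr, train = epoch_loss,
                       val = val_loss, best_val = best_val)
    for (nm in names(val_parts)) hrow[[paste0("val_", nm)]] <- val_parts[[nm]]
    history <- rbind(history, hrow)
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e train %.5g val %.5g", epoch, lr,
                      epoch_loss, val_loss))
    }
    if (epoch_loss < best_train * (1 - 1e-4)) {
      best_train <- epoch_loss; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) {
        lr <- lr * config$factor
        since_best <- 0L
      }
    }
    if (lr < config$lr_stop) break
  }
  list(model = model, history = history)
}

#' Run a multi-stage training schedule
#'
#' Executes stages in order, carrying the model (and its physics
#' parameters) from one stage to the next. The canonical schedule is:
#' network-only energies/forces/charges/volumes with force-dominated
#' weights, then rebalanced weights; physics-augmented retraining of the
#' energy head with the embedding and charge/volume heads frozen, then
#' unfrozen; interaction-energy refinement with the physics parameters
#' trainable; optional system-specific refinement with extra records.
#'
#' @param model an `nnp_model`.
#' @param datasets list of record lists, one per stage (recycled if one).
#' @param stages list of [stage_config()]s.
#' @param seed integer.
#' @param verbose print progress.
#' @return list with the final `model` and combined `history` (stage column
#'   added).
#' @export
run_schedule <- function(model, datasets, stages, seed = 1, verbose = FALSE) {
  if (is.list(datasets) && length(datasets) &&
      is.list(datasets[[1]]) && !is.null(datasets[[1]]$species)) {
    datasets <- list(datasets)  # a single record list was passed
  }
  datasets <- rep_len(datasets, length(stages))
  history <- NULL
  for (s in seq_along(stages)) {
    res <- train_stage(model, datasets[[s]], stages[[s]], seed = seed + s, verbose = verbose)
    model <- res$model
    h <- res$history; h$stage <- s
    if (is.null(history)) {
      history <- h
    } else {
      # stages log different loss components; align columns before binding
      for (nm in setdiff(names(history), names(h))) h[[nm]] <- NA_real_
      for (nm in setdiff(names(h), names(history))) history[[nm]] <- NA_real_
      history <- rbind(history, h[names(history)])
    }
  }
  list(model = model, history = history)
}

#' The canonical four-stage schedule
#'
#' Stage weights follow the standard procedure: stage 1a trains the bare
#' network on energies, forces, charges and volumes with force-dominated
#' weights (E 0.001, F 1, q 1000, v 1000), stage 1b rebalances to (E 0.01,
#' F 0.1); stage 2 activates the physics terms, freezing the embedding and
#' the charge/volume heads, then unfreezes; stage 3 adds
#' interaction-energy records (E 0.1, DES 5) with the physics parameters
#' trainable; stage 4 refines on system-specific records.
#'
#' @param scale shrink batch sizes/epoch caps for desk-scale runs.
#' @return list of [stage_config()]s.
#' @export
default_schedule <- function(scale = 1) {
  b <- function(x) max(8L, as.integer(x * scale))
  list(
    stage_config(weights = list(E = 0.001, F = 1, q = 1000, v = 1000),
                 batch_size = b(256), max_epochs = b(100)),
    stage_config(weights = list(E = 0.01, F = 0.1, q = 1000, v = 1000),
                 batch_size = b(256), max_epochs = b(100), lr = 5e-4),
    stage_config(weights = list(E = 0.01, F = 0.1), include_physics = TRUE,
                 frozen = c("^mlp2b", "^embed2b", "^layer", "^head\\.(q|v)", "^ff"),
                 batch_size = b(256), max_epochs = b(50), lr = 5e-4),
    stage_config(weights = list(E = 0.1, F = 0, DES = 5), include_physics = TRUE,
                 frozen = c("^mlp2b", "^embed2b", "^layer", "^head\\.(q|v)"),
                 batch_size = b(64), max_epochs = b(50), lr = 2e-4, lr_stop = 1e-5)
  )
}

#' Root-mean-square energy error of a model on records
#'
#' @param model an `nnp_model`.
#' @param records training records (total-energy records only).
#' @param include_physics evaluate the full energy (default) or network only.
#' @return RMSE in kcal/mol.
#' @export
energy_rmse <- function(model, records, include_physics = TRUE) {
  records <- Filter(function(r) !identical(r$kind, "interaction"), records)
  err <- vapply(records, function(r) {
    sys <- atomic_system(r$species, r$positions)
    eb <- total_energy_forces(model, sys, forces = FALSE,
                              include_physics = include_physics)
    eb$E_total - r$energy
  }, numeric(1))
  sqrt(mean(err^2))
}
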