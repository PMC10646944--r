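# Forward evaluation of the pair embedding and output heads on the
# differentiation tape. Everything downstream of the atomic coordinates is
# a tape node, so energies differentiate exactly into forces.
#
# Tensor-feature layout: one matrix per (l, parity) block with n_pairs rows
# and n_channels * (2l+1) columns, grouped m-major (columns (m-1)*C+1..m*C
# hold all channels of component m), so column slices per m are cheap.

.pair_geometry_tape <- function(pos_node, graph, cfg) {
  d <- ad_add(ad_sub(ad_gather(pos_node, graph$dst), ad_gather(pos_node, graph$src)),
              ad_const(graph$shift))
  R <- ad_sqrt(ad_rowsum(ad_mul(d, d)))
  list(d = d, R = R,
       u = ad_divrows(d, R),
       fc = ad_envelope(R, cfg$r_c, cfg$p_env),
       B = ad_bessel(R, cfg$n_basis, cfg$r_c, cfg$p_env))
}

.mlp_nodes <- function(pnodes, prefix) {
  i <- 1L; W <- list(); b <- list()
  repeat {
    wn <- paste0(prefix, ".W", i)
    if (is.null(pnodes[[wn]])) break
    W[[i]] <- pnodes[[wn]]
    bn <- pnodes[[paste0(prefix, ".b", i)]]
    b[[i]] <- if (is.null(bn)) NULL else bn
    i <- i + 1L
  }
  list(W = W, b = b)
}

.run_mlp <- function(x, pnodes, prefix) {
  mp <- .mlp_nodes(pnodes, prefix)
  ad_mlp(x, mp$W, mp$b)
}

# environment-or-pair tensor block built from per-l channel weights and
# spherical harmonics: cbind over m of (weights_l scaled by Y_l[, m])
.weighted_harmonics <- function(w_l, Y_l) {
  dl <- ncol(Y_l$v)
  ad_cbind(lapply(seq_len(dl), function(m) ad_mulrows(w_l, ad_cols(Y_l, m, m))))
}

# one interaction layer; emb holds x (scalars) and V (named tensor blocks)
.interaction_layer <- function(emb, L, model, pn, geo, graph, Y, n_atoms) {
  cfg <- model$config
  C <- cfg$n_channels
  lm <- model$meta$layers[[L]]
  pre <- paste0("layer", L)

  # (a) environment tensor for each source atom
  u <- ad_matmul(emb$x, pn[[paste0(pre, ".embed.W")]])
  gamma_pair <- vector("list", cfg$l_max + 1L)
  for (l in 0:cfg$l_max) {
    w_l <- ad_mulrows(ad_cols(u, l * C + 1L, (l + 1L) * C), geo$fc)
    g_atom <- ad_scatter(.weighted_harmonics(w_l, Y[[l + 1L]]), graph$src, n_atoms)
    gamma_pair[[l + 1L]] <- ad_gather(g_atom, graph$src)
  }

  # (b) channel-wise tensor products along all symmetry-allowed paths
  latent <- list()
  for (pp in lm$paths) {
    A <- gamma_pair[[pp$l1 + 1L]]
    B <- emb$V[[pp$key2]]
    nz <- coupling_nonzeros(pp$l1, pp$l2, pp$l)
    per_m <- vector("list", 2L * pp$l + 1L)
    for (m in seq_len(2L * pp$l + 1L)) {
      rows <- which(nz$m == m)
      acc <- NULL
      for (r in rows) {
        m1 <- nz$m1[r]; m2 <- nz$m2[r]
        term <- ad_kmul(ad_mul(ad_cols(A, (m1 - 1L) * C + 1L, m1 * C),
                               ad_cols(B, (m2 - 1L) * C + 1L, m2 * C)),
                        nz$coef[r])
        acc <- if (is.null(acc)) term else ad_add(acc, term)
      }
      per_m[[m]] <- if (is.null(acc)) ad_const(matrix(0, n_pairs(graph), C)) else acc
    }
    latent[[pp$keyout]] <- c(latent[[pp$keyout]], list(per_m))
  }

  # (c) scalar update with normalization-preserving mixing
  scalar_blocks <- lapply(latent[[irrep_key(0, 1)]], function(pm) pm[[1L]])
  y <- .run_mlp(ad_cbind(c(list(emb$x), scalar_blocks)), pn, paste0(pre, ".latent"))
  alpha <- ad_sigmoid(pn[[paste0(pre, ".alpha_raw")]])
  comp <- ad_sqrt(ad_kadd(ad_neg(ad_mul(alpha, alpha)), 1))
  x_new <- ad_add(ad_smul(emb$x, alpha), ad_smul(y, comp))

  # (d) per-irrep linear recombination over channels and paths
  V_new <- list()
  for (key in names(lm$by_out)) {
    Wn <- pn[[paste0(pre, ".path.", key)]]
    fan <- nrow(Wn$v)
    l <- lm$out_irreps$l[match(key, lm$out_irreps$key)]
    blocks <- latent[[key]]
    out_m <- lapply(seq_len(2L * l + 1L), function(m) {
      Lm <- ad_cbind(lapply(blocks, function(pm) pm[[m]]))
      ad_kmul(ad_matmul(Lm, Wn), 1 / sqrt(fan))
    })
    V_new[[key]] <- ad_cbind(out_m)
  }

  list(x = x_new, V = V_new)
}

# full embedding on the tape; returns pair nodes plus retained two-body scalars
.embed_tape <- function(model, species, pos_node, graph) {
  cfg <- model$config
  C <- cfg$n_channels
  n_atoms <- length(species)
  pn <- lapply(model$params, ad_leaf)  # default: fresh leaves (no training)
  .embed_tape_with(model, species, pos_node, graph, pn)
}

.embed_tape_with <- function(model, species, pos_node, graph, pn, encodings = NULL) {
  cfg <- model$config
  C <- cfg$n_channels
  n_atoms <- length(species)
  geo <- .pair_geometry_tape(pos_node, graph, cfg)
  Y <- ad_spherical_harmonics(geo$u, cfg$l_max)

  enc <- if (is.null(encodings)) {
    species_encoding(species, cfg$d_row, cfg$d_col, cfg$gamma_row, cfg$gamma_col)
  } else {
    as.matrix(encodings)
  }
  if (nrow(enc) != n_atoms || ncol(enc) != cfg$d_row + cfg$d_col) {
    stop("encoding override has the wrong shape")
  }
  pair_in <- ad_cbind(ad_const(enc[graph$src, , drop = FALSE]),
                      ad_const(enc[graph$dst, , drop = FALSE]),
                      geo$B)
  x2b <- ad_mulrows(.run_mlp(pair_in, pn, "mlp2b"), geo$fc)

  u2 <- ad_matmul(x2b, pn[["embed2b.W"]])
  V <- list()
  for (l in 0:cfg$l_max) {
    w_l <- ad_cols(u2, l * C + 1L, (l + 1L) * C)
    V[[irrep_key(l, (-1)^l)]] <- .weighted_harmonics(w_l, Y[[l + 1L]])
  }

  emb <- list(x = x2b, V = V)
  for (L in seq_len(cfg$n_layers)) {
    emb <- .interaction_layer(emb, L, model, pn, geo, graph, Y, n_atoms)
  }
  list(x2b = x2b, x = emb$x, V = emb$V, geo = geo, pn = pn)
}

.heads_tape <- function(emb, pn) {
  inp <- ad_cbind(emb$x2b, emb$x)
  list(e = .run_mlp(inp, pn, "head.e"),
       dq = .run_mlp(inp, pn, "head.q"),
       u = .run_mlp(inp, pn, "head.v"))
}

# per-atom aggregation: local energies, antisymmetrized charge exchange,
# positive volume ratios. Pair outputs are weighted by the cutoff envelope
# so every atomic property is smooth as pairs cross r_c.
.aggregate_tape <- function(heads, geo, graph, n_atoms, short_env = NULL) {
  w <- geo$fc
  if (!is.null(short_env)) w <- ad_mul(w, short_env)
  e_w <- ad_mul(heads$e, w)
  ex <- ad_mul(ad_sub(heads$dq, ad_gather(heads$dq, graph$rev)), w)
  u_w <- ad_mul(heads$u, w)
  list(E = ad_scatter(e_w, graph$src, n_atoms),
       q = ad_scatter(ex, graph$src, n_atoms),
       vol = ad_softplus(ad_scatter(u_w, graph$src, n_atoms)),
       exchange = ex)
}

# ---- numeric user-facing wrappers ----------------------------------------

#' Pairwise equivariant embedding of a system
#'
#' Runs the two-body initialization and all interaction layers, returning
#' the final scalar embedding, the tensor blocks and the retained two-body
#' scalars for every directed pair.
#'
#' @param model an `nnp_model`.
#' @param system an `atomic_system`.
#' @param graph optional precomputed `pair_graph`.
#' @param encodings optional per-atom species-encoding matrix overriding
#'   the periodic-table encoding (e.g. a perturbed or averaged encoding).
#' @return list with `x2b`, `x` (n_pairs x n_scalar matrices), `tensors`
#'   (named list of n_pairs x (C*(2l+1)) matrices keyed by irrep, columns
#'   m-major), and the `graph`.
#' @export
embed_pairs <- function(model, system, graph = NULL, encodings = NULL) {
  if (is.null(graph)) graph <- build_pair_graph(system, model$config$r_c)
  if (n_pairs(graph) == 0L) {
    return(list(x2b = matrix(0, 0, model$config$n_scalar),
                x = matrix(0, 0, model$config$n_scalar),
                tensors = list(), graph = graph))
  }
  pn <- lapply(model$params, ad_leaf)
  emb <- .embed_tape_with(model, system$species, ad_const(system$positions),
                          graph, pn, encodings)
  list(x2b = ad_value(emb$x2b), x = ad_value(emb$x),
       tensors = lapply(emb$V, ad_value), graph = graph)
}

#' Output heads on pair embeddings
#'
#' Three independent MLPs (local energy, charge exchange, volume) applied to
#' the concatenation of the two-body and final scalar embeddings. Outputs
#' are raw (no cutoff weighting, no constraints).
#'
#' @param model an `nnp_model`.
#' @param x2b,x_final n_pairs x n_scalar matrices from [embed_pairs()].
#' @return list of n_pairs x 1 matrices `e`, `dq`, `u`.
#' @export
head_forward <- function(model, x2b, x_final) {
  if (is.null(x2b) || is.null(x_final)) stop("both embeddings are required")
  if (!all(dim(x2b) == dim(x_final))) stop("embedding dimension mismatch")
  pn <- lapply(model$params, ad_leaf)
  out <- .heads_tape(list(x2b = ad_const(x2b), x = ad_const(x_final)), pn)
  lapply(out, ad_value)
}

#' Aggregate pair outputs into atomic properties
#'
#' Local energies are summed on the source atom; charge outputs are
#' antisymmetrized over pair direction before summation (exact charge
#' exchange, so total charge is zero by construction); volume sums pass
#' through a softplus so ratios are strictly positive. All pair terms are
#' weighted by the cutoff envelope.
#'
#' @param model an `nnp_model`.
#' @param outputs list with `e`, `dq`, `u` per-pair columns (from
#'   [head_forward()]).
#' @param graph the `pair_graph` the outputs were computed on.
#' @param n_atoms number of atoms.
#' @return list with per-atom `local_energy`, `charge`, `volume_ratio`.
#' @export
aggregate_pairs <- function(model, outputs, graph, n_atoms) {
  if (n_pairs(graph) == 0L) {
    return(list(local_energy = rep(0, n_atoms), charge = rep(0, n_atoms),
                volume_ratio = rep(.softplus(0), n_atoms)))
  }
  fc <- poly_envelope(graph$distance, model$config$r_c, model$config$p_env)
  geo <- list(fc = ad_const(matrix(fc, ncol = 1)))
  agg <- .aggregate_tape(lapply(outputs, ad_wrap), geo, graph, n_atoms)
  list(local_energy = as.vector(ad_value(agg$E)),
       charge = as.vector(ad_value(agg$q)),
       volume_ratio = as.vector(ad_value(agg$vol)))
}

#' Atomic properties predicted by the network
#'
#' Full pipeline from geometry to per-atom local energy (kcal/mol), raw
#' network charge (e; sums to zero per system) and volume ratio.
#'
#' @param model an `nnp_model`.
#' @param system an `atomic_system`.
#' @return list with `local_energy`, `charge`, `volume_ratio` vectors.
#' @export
atomic_properties <- function(model, system) {
  graph <- build_pair_graph(system, model$config$r_c)
  n_atoms <- length(system$species)
  if (n_pairs(graph) == 0L) {
    return(list(local_energy = rep(0, n_atoms), charge = rep(0, n_atoms),
                volume_ratio = rep(.softplus(0), n_atoms)))
  }
  emb <- .embed_tape(model, system$species, ad_const(system$positions), graph)
  agg <- .aggregate_tape(.heads_tape(emb, emb$pn), emb$geo, graph, n_atoms)
  list(local_energy = as.vector(ad_value(agg$E)),
       charge = as.vector(ad_value(agg$q)),
       volume_ratio = as.vector(ad_value(agg$vol)))
}

#' Isolated-atom reference energy of a composition
#'
#' Sum of the constant per-element reference energies; this is the energy
#' the model dissociates to when every atom loses its neighbors.
#'
#' @param model an `nnp_model`.
#' @param species atomic numbers or element symbols.
#' @return total reference energy (kcal/mol).
#' @export
reference_energy <- function(model, species) {
  if (length(species) == 0L) return(0)
  if (is.character(species)) species <- element_z(species)
  sym <- .element_symbols[periodic_coords(species)$z]
  sum(model$ref_energies[sym])
}
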