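# Physics module: the network's charges and volume ratios parameterize
# damped charge-penetration electrostatics and volume-scaled pairwise
# dispersion; periodic electrostatics go through Ewald summation. All terms
# are built on the differentiation tape so forces are exact gradients.
#
# Units: kcal/mol, Angstrom, elementary charge; k_e = 332.0637 kcal A/(mol e^2).

# ---- charge pipeline ------------------------------------------------------

#' Scale charges by the universal factor
#'
#' @param q charges (e), summing to zero.
#' @param eps dimensionless scaling (> 0); compensates the lack of
#'   higher-order multipoles in the permanent electrostatics.
#' @return scaled charges (neutrality preserved).
#' @export
scale_charges <- function(q, eps) {
  stopifnot(eps > 0)
  q * eps
}

# smooth positive part with width w: w * softplus(x / w); ~0 well below 0,
# ~x well above, C-infinity everywhere
.smooth_plus <- function(x, w) w * .softplus(x / w)
.ad_smooth_plus <- function(x, w) ad_kmul(ad_softplus(ad_kmul(x, 1 / w)), w)

# tape core of the valence correction; q and ex (per directed pair signed
# exchange, positive = src lost electrons through this pair) are nodes
.valence_tape <- function(q, ex, graph, n_valence, max_frac, width) {
  n <- length(n_valence)
  hole <- .ad_smooth_plus(ad_sub(q, ad_const(matrix(max_frac * n_valence, ncol = 1))),
                          width)
  drained <- .ad_smooth_plus(ex, width)           # per-pair electrons taken by dst
  tot <- ad_scatter(drained, graph$src, n)        # per-atom total drained
  # the give-back fraction tot/(tot + tiny) fades out smoothly when the
  # neighbors collectively drained a negligible amount (degenerate case:
  # a hole with no donors is left uncorrected)
  tiny <- 1e-4
  inv <- ad_pow(ad_kadd(tot, tiny), -1)
  give <- ad_mul(ad_gather(ad_mul(hole, inv), graph$src), drained)  # per-pair give-back
  # src atom regains electrons (charge down by hole * tot/(tot+tiny)),
  # each draining neighbor returns its share (charge up); sum is exactly zero
  q_new <- ad_add(ad_sub(q, ad_mul(hole, ad_mul(tot, inv))),
                  ad_scatter(give, graph$dst, n))
  list(q = q_new, hole = hole, tot = tot)
}

#' Valence-shell charge correction
#'
#' An atom cannot lose more than `max_frac` of its valence electrons. The
#' excess ("valence hole") is computed with a smooth positive part of width
#' `width` (so forces stay continuous) and transferred back from the
#' neighbors that drained charge, proportionally to the amount each
#' drained, in a single pass. Total charge is conserved exactly. If an atom
#' has a hole but no neighbor donated charge, its charge is left unchanged
#' and a warning is emitted.
#'
#' @param q per-atom charges (e), after scaling.
#' @param exchange per-directed-pair signed exchange amounts (the values
#'   whose per-source-atom sums are `q`).
#' @param graph the `pair_graph`.
#' @param n_valence per-atom valence electron counts.
#' @param max_frac maximum fraction of the valence shell that may be lost.
#' @param width smoothing width (e).
#' @return corrected charges.
#' @export
correct_valence <- function(q, exchange, graph, n_valence,
                            max_frac = 0.95, width = 0.01) {
  out <- .valence_tape(ad_const(matrix(q, ncol = 1)),
                       ad_const(matrix(exchange, ncol = 1)),
                       graph, n_valence, max_frac, width)
  hole <- as.vector(ad_value(out$hole))
  tot <- as.vector(ad_value(out$tot))
  stranded <- hole > width & tot < 1e-6
  if (any(stranded)) {
    warning(sprintf("valence hole on atom(s) %s with no draining neighbor; left uncorrected",
                    paste(which(stranded), collapse = ", ")))
  }
  as.vector(ad_value(out$q))
}

# ---- charge-penetration Coulomb ------------------------------------------

# tape form of the damped pair energy; qi, qj, R nodes; Ni, Nj const vectors
.coulomb_cp_tape <- function(qi, qj, Ni, Nj, R, alpha, beta) {
  fa <- ad_kadd(ad_neg(ad_exp(ad_neg(ad_smul(R, alpha)))), 1)
  fb <- ad_kadd(ad_neg(ad_exp(ad_neg(ad_smul(R, beta)))), 1)
  pi_ <- ad_sub(Ni, qi)   # electron populations
  pj_ <- ad_sub(Nj, qj)
  core <- ad_mul(Ni, Nj)
  cross <- ad_mul(ad_add(ad_mul(Ni, pj_), ad_mul(Nj, pi_)), fa)
  ee <- ad_mul(ad_mul(pi_, pj_), fb)
  ad_kmul(ad_mul(ad_add(ad_sub(core, cross), ee), ad_pow(R, -1)), .ke_coulomb)
}

#' Charge-penetration Coulomb pair energy
#'
#' Damped Coulomb interaction between two atoms with fluctuating net
#' charges q and valence populations N: the nuclear (valence-core) term is
#' undamped, nucleus-electron cross terms are damped by f_a(R) = 1 -
#' exp(-alpha R) and the electron-electron term by f_b(R) = 1 - exp(-beta
#' R). Symmetric in the two atoms; tends to the bare point-charge energy
#' k_e q_i q_j / R at long range.
#'
#' @param q_i,q_j net charges (e).
#' @param n_i,n_j valence electron counts.
#' @param R distance(s) (Angstrom, > 0).
#' @param alpha,beta damping rates (1/Angstrom, > 0).
#' @return pair energy (kcal/mol); vectorized over R (and charges).
#' @export
coulomb_cp <- function(q_i, q_j, n_i, n_j, R, alpha, beta) {
  if (any(R <= 0)) stop("R must be positive")
  stopifnot(alpha > 0, beta > 0)
  k <- max(length(R), length(q_i))
  cvec <- function(x) ad_const(matrix(rep_len(x, k), ncol = 1))
  as.vector(ad_value(.coulomb_cp_tape(cvec(q_i), cvec(q_j), cvec(n_i), cvec(n_j),
                                      cvec(R), ad_const(alpha), ad_const(beta))))
}

# ---- dispersion -----------------------------------------------------------

#' Environment-dependent van der Waals radius
#'
#' Free-atom radius scaled by the cube root of the atom-in-molecule volume
#' ratio (volumes scale radii cubed): equals the free radius at ratio 1 and
#' grows monotonically with the ratio.
#'
#' @param volume_ratio positive volume ratio(s) v / v_free.
#' @param z atomic number(s).
#' @return radius in Angstrom.
#' @export
vdw_radius <- function(volume_ratio, z) {
  if (any(volume_ratio <= 0)) stop("volume ratio must be positive")
  free_atom_params(z)$rvdw_free * volume_ratio^(1 / 3)
}

# tape dispersion for a pair set; ratio_i/j, R nodes; free-atom params const
.dispersion_tape <- function(ratio_i, ratio_j, fi, fj, R, gamma, s) {
  c6i <- ad_mulrows(ad_mul(ratio_i, ratio_i), ad_const(matrix(fi$c6_free, ncol = 1)))
  c6j <- ad_mulrows(ad_mul(ratio_j, ratio_j), ad_const(matrix(fj$c6_free, ncol = 1)))
  ai <- ad_mulrows(ratio_i, ad_const(matrix(fi$alpha_free, ncol = 1)))
  aj <- ad_mulrows(ratio_j, ad_const(matrix(fj$alpha_free, ncol = 1)))
  num <- ad_kmul(ad_mul(c6i, c6j), 2)
  den <- ad_add(ad_mul(ad_div(aj, ai), c6i), ad_mul(ad_div(ai, aj), c6j))
  c6ij <- ad_div(num, den)
  ri <- ad_mulrows(ad_pow(ratio_i, 1 / 3), ad_const(matrix(fi$rvdw_free, ncol = 1)))
  rj <- ad_mulrows(ad_pow(ratio_j, 1 / 3), ad_const(matrix(fj$rvdw_free, ncol = 1)))
  rsum <- ad_smul(ad_add(ri, rj), s)
  arg <- ad_smul(ad_kadd(ad_div(R, rsum), -1), gamma)
  damp <- ad_sigmoid(arg)
  ad_neg(ad_mul(damp, ad_mul(c6ij, ad_pow(R, -6))))
}

#' Tkatchenko-Scheffler pair dispersion energy
#'
#' Homonuclear C6 coefficients and polarizabilities are scaled by the
#' atom-in-molecule volume ratios (C6 quadratically, polarizability
#' linearly); the heteronuclear C6 follows the standard combination rule
#' C6_ij = 2 C6_ii C6_jj / ((a_j/a_i) C6_ii + (a_i/a_j) C6_jj). The -C6/R^6
#' attraction is damped by a sigmoid in R / (s (r_i + r_j)) with
#' environment-scaled vdW radii, monotone from 0 (R -> 0) to 1 (R -> inf).
#'
#' @param ratio_i,ratio_j volume ratios (> 0).
#' @param z_i,z_j atomic numbers.
#' @param R distance(s) (Angstrom).
#' @param gamma sigmoid steepness.
#' @param s radius scaling of the damping onset.
#' @return pair energy (kcal/mol), vectorized over R.
#' @export
ts_dispersion <- function(ratio_i, ratio_j, z_i, z_j, R, gamma = 20, s = 0.94) {
  if (any(R <= 0) || any(ratio_i <= 0) || any(ratio_j <= 0)) {
    stop("distances and volume ratios must be positive")
  }
  k <- max(length(R), length(ratio_i))
  fi <- free_atom_params(rep_len(z_i, k)); fj <- free_atom_params(rep_len(z_j, k))
  cvec <- function(x) ad_const(matrix(rep_len(x, k), ncol = 1))
  as.vector(ad_value(.dispersion_tape(cvec(ratio_i), cvec(ratio_j), fi, fj,
                                      cvec(R), ad_const(gamma), ad_const(s))))
}

# smooth long-range switch: 1 below r1, cosine ramp to 0 at r2 (C^1)
.ad_lr_switch <- function(R, Rval, r1, r2) {
  below <- as.numeric(Rval < r1)
  mid <- as.numeric(Rval >= r1 & Rval < r2)
  ramp <- ad_kmul(ad_kadd(ad_cos(ad_kmul(ad_kadd(R, -r1), pi / (r2 - r1))), 1), 0.5)
  ad_add(ad_const(matrix(below, ncol = 1)),
         ad_mul(ad_const(matrix(mid, ncol = 1)), ramp))
}

# ---- Ewald ----------------------------------------------------------------

.erfcinv <- function(a) {
  stats::uniroot(function(x) .erfc(x) - a, c(1e-8, 30), tol = 1e-12)$root
}

.ewald_setup <- function(cell, accuracy, kappa = NULL) {
  h <- cell_heights(cell)
  if (is.null(kappa)) kappa <- 3.0 / min(h)
  x <- .erfcinv(accuracy)
  r_cut <- x / kappa
  k_max <- 2 * kappa * sqrt(-log(accuracy))
  Brec <- 2 * pi * t(solve(cell))
  nmax <- ceiling(k_max / (2 * pi) * apply(cell, 1, function(a) sqrt(sum(a^2))))
  g <- as.matrix(expand.grid(-nmax[1]:nmax[1], -nmax[2]:nmax[2], -nmax[3]:nmax[3]))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  K <- g %*% Brec
  k2 <- rowSums(K^2)
  keep <- k2 <= k_max^2
  list(kappa = kappa, r_cut = r_cut, K = K[keep, , drop = FALSE],
       k2 = k2[keep], V = abs(det(cell)))
}

# tape Ewald energy; pos and q are nodes, the rest is fixed numeric setup
.ewald_tape <- function(pos, q, species, cell, setup) {
  n <- nrow(pos$v)
  dummy <- atomic_system(rep(1L, n), ad_value(pos), cell = cell)
  g <- build_pair_graph(dummy, setup$r_cut)
  e_real <- ad_const(matrix(0, 1, 1))
  if (n_pairs(g) > 0) {
    d <- ad_add(ad_sub(ad_gather(pos, g$dst), ad_gather(pos, g$src)),
                ad_const(g$shift))
    R <- ad_sqrt(ad_rowsum(ad_mul(d, d)))
    qq <- ad_mul(ad_gather(q, g$src), ad_gather(q, g$dst))
    e_real <- ad_kmul(ad_sum(ad_mul(qq, ad_mul(ad_erfc(ad_kmul(R, setup$kappa)),
                                               ad_pow(R, -1)))),
                      0.5 * .ke_coulomb)
  }
  phase <- ad_matmul(pos, ad_const(setup$K), tb = TRUE)
  Cs <- ad_colsum(ad_mulrows(ad_cos(phase), q))
  Ss <- ad_colsum(ad_mulrows(ad_sin(phase), q))
  w <- exp(-setup$k2 / (4 * setup$kappa^2)) / setup$k2
  e_rec <- ad_kmul(ad_sum(ad_mul(ad_add(ad_mul(Cs, Cs), ad_mul(Ss, Ss)),
                                 ad_const(matrix(w, nrow = 1)))),
                   2 * pi * .ke_coulomb / setup$V)
  e_self <- ad_kmul(ad_sum(ad_mul(q, q)), -.ke_coulomb * setup$kappa / sqrt(pi))
  ad_add(ad_add(e_real, e_rec), e_self)
}

#' Ewald summation for periodic point charges
#'
#' Real-space, reciprocal-space and self terms; the splitting parameter and
#' both cutoffs are chosen automatically from the accuracy target (the
#' result is independent of the splitting parameter within that target).
#' Lattice images are enumerated explicitly, so cells smaller than the
#' real-space cutoff are handled exactly.
#'
#' @param system a periodic `atomic_system`.
#' @param charges per-atom charges (e); must sum to zero.
#' @param accuracy relative accuracy target.
#' @param kappa optional splitting parameter override (1/Angstrom).
#' @return electrostatic energy (kcal/mol).
#' @export
ewald_coulomb <- function(system, charges, accuracy = 1e-6, kappa = NULL) {
  if (!system$periodic) stop("ewald_coulomb requires a periodic system")
  if (abs(sum(charges)) > 1e-8) stop("cell is not charge-neutral")
  setup <- .ewald_setup(system$cell, accuracy, kappa)
  e <- .ewald_tape(ad_const(system$positions), ad_const(matrix(charges, ncol = 1)),
                   system$species, system$cell, setup)
  ad_value(e)[1]
}

# ---- total energy assembly -----------------------------------------------

# physics pair lists (numeric, fixed before the tape): all same-molecule
# i < j pairs for Coulomb; the subset within r_disp for dispersion
.physics_pairs <- function(pos, mol_id, r_disp) {
  n <- nrow(pos)
  if (n < 2) return(list(ci = integer(0), cj = integer(0), di = integer(0), dj = integer(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- mol_id[i] == mol_id[j]
  i <- i[same]; j <- j[same]
  R <- sqrt(rowSums((pos[j, , drop = FALSE] - pos[i, , drop = FALSE])^2))
  keep <- R < r_disp
  list(ci = i, cj = j, di = i[keep], dj = j[keep])
}

# assemble every energy node; returns tape nodes for totals and breakdown
.total_tape <- function(model, species, pos_node, graph, pn,
                        cell = NULL, periodic = FALSE, mol_id = NULL,
                        include_physics = TRUE, encodings = NULL) {
  cfg <- model$config
  ff <- model$ff
  n_atoms <- length(species)
  if (is.null(mol_id)) mol_id <- rep(1L, n_atoms)
  n_mol <- max(mol_id)
  if (periodic && n_mol > 1) stop("periodic evaluation supports a single system")

  sym <- .element_symbols[species]
  ref_atom <- model$ref_energies[sym]
  # per-molecule sums use base sum() so an isolated system reproduces
  # reference_energy() bitwise (the dissociation asymptote is exact)
  e_ref_mol <- ad_const(matrix(vapply(seq_len(n_mol), function(mm) {
    sum(ref_atom[mol_id == mm])
  }, numeric(1)), ncol = 1))

  have_pairs <- n_pairs(graph) > 0
  if (have_pairs) {
    emb <- .embed_tape_with(model, species, pos_node, graph, pn, encodings)
    short_env <- NULL
    if (!is.null(cfg$short_range_cutoff)) {
      inside <- as.numeric(graph$distance < cfg$short_range_cutoff)
      short_env <- ad_mul(ad_envelope(emb$geo$R, cfg$short_range_cutoff, cfg$p_env),
                          ad_const(matrix(inside, ncol = 1)))
    }
    agg <- .aggregate_tape(.heads_tape(emb, pn), emb$geo, graph, n_atoms, short_env)
    e_nn_mol <- ad_scatter(agg$E, mol_id, n_mol)
    q_raw <- agg$q
    vol <- agg$vol
    exch <- agg$exchange
  } else {
    e_nn_mol <- ad_const(matrix(0, n_mol, 1))
    q_raw <- ad_const(matrix(0, n_atoms, 1))
    vol <- ad_const(matrix(.softplus(0), n_atoms, 1))
    exch <- NULL
  }

  zero_mol <- ad_const(matrix(0, n_mol, 1))
  e_coul_mol <- zero_mol
  e_disp_mol <- zero_mol
  q_final <- q_raw

  if (include_physics) {
    q_s <- ad_smul(q_raw, pn[["ff.eps"]])
    if (have_pairs) {
      corr <- .valence_tape(q_s, ad_smul(exch, pn[["ff.eps"]]), graph,
                            element_valence(species),
                            ff$valence_max_frac, ff$valence_width)
      q_final <- corr$q
    } else {
      q_final <- q_s
    }
    Nv <- element_valence(species)
    fp <- free_atom_params(species)
    pos_val <- ad_value(pos_node)

    if (!periodic) {
      pp <- .physics_pairs(pos_val, mol_id, ff$r_disp)
      if (length(pp$ci) > 0) {
        # bare point-charge Coulomb over all pairs; the charge-penetration
        # correction is short-ranged and switched off smoothly at r_c
        d <- ad_sub(ad_gather(pos_node, pp$cj), ad_gather(pos_node, pp$ci))
        R <- ad_sqrt(ad_rowsum(ad_mul(d, d)))
        qq <- ad_mul(ad_gather(q_final, pp$ci), ad_gather(q_final, pp$cj))
        e_bare <- ad_kmul(ad_mul(qq, ad_pow(R, -1)), .ke_coulomb)
        e_coul_mol <- ad_scatter(e_bare, mol_id[pp$ci], n_mol)
      }
      if (have_pairs) {
        cpc <- .cp_correction_tape(model, pos_node, graph, q_final, Nv, pn)
        e_coul_mol <- ad_add(e_coul_mol,
                             ad_kmul(ad_scatter(cpc, mol_id[graph$src], n_mol), 0.5))
      }
      if (length(pp$di) > 0) {
        d <- ad_sub(ad_gather(pos_node, pp$dj), ad_gather(pos_node, pp$di))
        R <- ad_sqrt(ad_rowsum(ad_mul(d, d)))
        Rval <- sqrt(rowSums((pos_val[pp$dj, , drop = FALSE] -
                              pos_val[pp$di, , drop = FALSE])^2))
        e_d <- .dispersion_tape(ad_gather(vol, pp$di), ad_gather(vol, pp$dj),
                                fp[pp$di, ], fp[pp$dj, ], R,
                                pn[["ff.gamma"]], pn[["ff.s"]])
        sw <- .ad_lr_switch(R, Rval, ff$r_disp - ff$disp_switch, ff$r_disp)
        e_disp_mol <- ad_scatter(ad_mul(e_d, sw), mol_id[pp$di], n_mol)
      }
    } else {
      setup <- .ewald_setup(cell, 1e-6)
      e_coul <- .ewald_tape(pos_node, q_final, species, cell, setup)
      # charge-penetration correction (short-ranged) on the neighbor graph
      if (have_pairs) {
        cpc <- .cp_correction_tape(model, pos_node, graph, q_final, Nv, pn)
        e_coul <- ad_add(e_coul, ad_kmul(ad_sum(cpc), 0.5))
      }
      e_coul_mol <- e_coul
      # dispersion: direct sum within r_disp (with images) + continuum tail
      dsys <- atomic_system(species, pos_val, cell = cell)
      dg <- build_pair_graph(dsys, ff$r_disp)
      if (n_pairs(dg) > 0) {
        d <- ad_add(ad_sub(ad_gather(pos_node, dg$dst), ad_gather(pos_node, dg$src)),
                    ad_const(dg$shift))
        R <- ad_sqrt(ad_rowsum(ad_mul(d, d)))
        e_d <- .dispersion_tape(ad_gather(vol, dg$src), ad_gather(vol, dg$dst),
                                fp[dg$src, ], fp[dg$dst, ], R,
                                pn[["ff.gamma"]], pn[["ff.s"]])
        sw <- .ad_lr_switch(R, dg$distance, ff$r_disp - ff$disp_switch, ff$r_disp)
        e_disp_mol <- ad_kmul(ad_sum(ad_mul(e_d, sw)), 0.5)
      }
      # tail: continuum - sum_ij C6_ij / (3 V r_cut^3) * 2 pi (all ordered pairs)
      allp <- expand.grid(i = seq_len(n_atoms), j = seq_len(n_atoms))
      c6sum <- .dispersion_c6_tape(ad_gather(vol, allp$i), ad_gather(vol, allp$j),
                                   fp[allp$i, ], fp[allp$j, ])
      tail <- ad_kmul(ad_sum(c6sum), -2 * pi / (3 * abs(det(cell)) * ff$r_disp^3))
      e_disp_mol <- ad_add(e_disp_mol, tail)
    }
  }

  e_mol <- ad_add(ad_add(e_nn_mol, e_coul_mol), ad_add(e_disp_mol, e_ref_mol))
  list(E_total = ad_sum(e_mol), E_mol = e_mol,
       E_nn = ad_sum(e_nn_mol), E_coul = ad_sum(e_coul_mol),
       E_disp = ad_sum(e_disp_mol), E_ref = ad_sum(e_ref_mol),
       q_raw = q_raw, q = q_final, vol = vol,
       x_embed = if (have_pairs) emb$x else NULL)
}

# per-directed-pair (CP - bare point charge) correction, switched smoothly
# to zero over the last Angstrom before r_c so the total Coulomb energy is
# C^1 and exactly point-charge-like beyond the neighbor cutoff
.cp_correction_tape <- function(model, pos_node, graph, q_final, Nv, pn) {
  cfg <- model$config
  R <- .pair_geometry_tape(pos_node, graph, cfg)$R
  qi <- ad_gather(q_final, graph$src); qj <- ad_gather(q_final, graph$dst)
  cp <- .coulomb_cp_tape(qi, qj,
                         ad_const(matrix(Nv[graph$src], ncol = 1)),
                         ad_const(matrix(Nv[graph$dst], ncol = 1)),
                         R, pn[["ff.alpha"]], pn[["ff.beta"]])
  bare <- ad_kmul(ad_mul(ad_mul(qi, qj), ad_pow(R, -1)), .ke_coulomb)
  sw <- .ad_lr_switch(R, graph$distance, cfg$r_c - 1, cfg$r_c)
  ad_mul(ad_sub(cp, bare), sw)
}

# combination-rule C6 only (for the periodic tail correction)
.dispersion_c6_tape <- function(ratio_i, ratio_j, fi, fj) {
  c6i <- ad_mulrows(ad_mul(ratio_i, ratio_i), ad_const(matrix(fi$c6_free, ncol = 1)))
  c6j <- ad_mulrows(ad_mul(ratio_j, ratio_j), ad_const(matrix(fj$c6_free, ncol = 1)))
  ai <- ad_mulrows(ratio_i, ad_const(matrix(fi$alpha_free, ncol = 1)))
  aj <- ad_mulrows(ratio_j, ad_const(matrix(fj$alpha_free, ncol = 1)))
  ad_div(ad_kmul(ad_mul(c6i, c6j), 2),
         ad_add(ad_mul(ad_div(aj, ai), c6i), ad_mul(ad_div(ai, aj), c6j)))
}

#' Total potential energy and forces
#'
#' Assembles the full hybrid energy: network local energies, isolated-atom
#' references, charge-penetration Coulomb (Ewald under periodic boundary
#' conditions) and volume-scaled dispersion (with a smooth long-range
#' switch; periodic systems add the continuum tail correction beyond the
#' dispersion cutoff). Forces are the exact negative gradient of the
#' implemented energy, obtained by reverse-mode differentiation through
#' every term, including the dependence of charges and volumes on the
#' geometry.
#'
#' @param model an `nnp_model`.
#' @param system an `atomic_system`.
#' @param forces compute forces (default TRUE).
#' @param include_physics include the Coulomb/dispersion terms (FALSE gives
#'   the bare network + reference energy).
#' @param encodings optional per-atom species-encoding override (supports
#'   perturbed-encoding and average-encoding experiments).
#' @return object of class `energy_breakdown` with `E_total`, `E_nn`,
#'   `E_coulomb`, `E_dispersion`, `E_reference` (kcal/mol), per-atom
#'   `forces` (kcal/mol/A), `charges` (e, final) and `volume_ratio`.
#' @export
total_energy_forces <- function(model, system, forces = TRUE,
                                include_physics = TRUE, encodings = NULL) {
  graph <- build_pair_graph(system, model$config$r_c)
  pos <- ad_leaf(system$positions)
  pn <- lapply(model$params, ad_leaf)
  out <- .total_tape(model, system$species, pos, graph, pn,
                     cell = system$cell, periodic = system$periodic,
                     include_physics = include_physics, encodings = encodings)
  F <- NULL
  if (forces) {
    F <- -ad_grad(out$E_total, list(pos))[[1]]
  }
  structure(list(E_total = ad_value(out$E_total)[1],
                 E_nn = ad_value(out$E_nn)[1],
                 E_coulomb = ad_value(out$E_coul)[1],
                 E_dispersion = ad_value(out$E_disp)[1],
                 E_reference = ad_value(out$E_ref)[1],
                 forces = F,
                 charges = as.vector(ad_value(out$q)),
                 charges_raw = as.vector(ad_value(out$q_raw)),
                 volume_ratio = as.vector(ad_value(out$vol))),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown (kcal/mol): total %.6f = nn %.6f + coulomb %.6f + dispersion %.6f + reference %.6f>\n",
              x$E_total, x$E_nn, x$E_coulomb, x$E_dispersion, x$E_reference))
  invisible(x)
}

#' Diatomic dissociation scan
#'
#' Evaluates the total energy of a two-atom system over a grid of
#' separations; with encodings supplied instead of atomic numbers this also
#' drives interpolated or averaged "fictitious element" scans.
#'
#' @param model an `nnp_model`.
#' @param z1,z2 atomic numbers of the two atoms.
#' @param distances separations (Angstrom).
#' @param encodings optional 2-row species-encoding override (e.g. the
#'   average encoding for a fictitious-element scan).
#' @return data.frame with `R` and the energy breakdown per separation.
#' @export
dissociation_scan <- function(model, z1, z2, distances, encodings = NULL) {
  rows <- lapply(distances, function(R) {
    sys <- atomic_system(c(z1, z2), rbind(c(0, 0, 0), c(R, 0, 0)))
    eb <- total_energy_forces(model, sys, forces = FALSE, encodings = encodings)
    data.frame(R = R, E_total = eb$E_total, E_nn = eb$E_nn,
               E_coulomb = eb$E_coulomb, E_dispersion = eb$E_dispersion,
               E_reference = eb$E_reference)
  })
  do.call(rbind, rows)
}
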