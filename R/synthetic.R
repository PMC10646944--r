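# Synthetic labeled training data.
#
# Generates monomer and dimer geometries (template + Gaussian internal
# deformations + random rigid placement) labeled by an analytic surrogate
# oracle: a sum of Morse bond terms, damped point-charge Coulomb and damped
# -C6/R^6 dispersion between nonbonded pairs, all strictly pairwise-radial
# so forces have a simple exact closed form. Charges follow a fixed
# electronegativity-balancing rule (neutral per molecule); volume ratios
# are a smooth decreasing function of coordination. Records mimic the
# structure of coupled-cluster training sets: total energies referenced to
# isolated-atom constants, per-atom forces, charges and volume ratios, plus
# dimer interaction-energy records carrying their monomer partitions.

.surrogate_bonds <- data.frame(
  pair = c("H-H", "O-H", "H-F", "C-H", "N-H", "O-O", "C-C", "C-O", "S-H"),
  D = c(109, 118, 135, 104, 93, 54, 85, 91, 87),     # well depth, kcal/mol
  a = c(1.94, 2.20, 2.22, 1.90, 2.05, 2.50, 1.95, 2.10, 1.85),  # 1/A
  r0 = c(0.741, 0.9572, 0.917, 1.09, 1.01, 1.21, 1.54, 1.43, 1.34))

.surrogate_chi <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98, S = 2.58)

# isolated-atom reference energies of the surrogate (kcal/mol); magnitudes
# on the coupled-cluster scale so dissociation asymptotes are realistic
.surrogate_ref_hartree <- c(H = -0.5, C = -37.8, N = -54.6, O = -75.1,
                            F = -99.7, S = -398.1)

#' Isolated-atom reference energies of the synthetic oracle
#'
#' @param symbols element symbols (default: all the oracle supports).
#' @return named numeric vector (kcal/mol).
#' @export
synthetic_reference_energies <- function(symbols = names(.surrogate_ref_hartree)) {
  .surrogate_ref_hartree[symbols] * .hartree_kcal
}

.bond_key <- function(s1, s2) {
  paste(sort(c(s1, s2)), collapse = "-")
}

.bond_params <- function(s1, s2) {
  key1 <- paste(s1, s2, sep = "-"); key2 <- paste(s2, s1, sep = "-")
  i <- match(key1, .surrogate_bonds$pair)
  if (is.na(i)) i <- match(key2, .surrogate_bonds$pair)
  if (is.na(i)) return(list(D = 100, a = 2.0, r0 = 1.2))  # generic fallback
  as.list(.surrogate_bonds[i, c("D", "a", "r0")])
}

.surrogate_charges <- function(symbols, k = 0.8) {
  chi <- .surrogate_chi[symbols]
  if (anyNA(chi)) stop("surrogate has no electronegativity for: ",
                       paste(symbols[is.na(chi)], collapse = ", "))
  unname(k * (mean(chi) - chi))
}

# smooth coordination number and the volume-ratio rule
.surrogate_volumes <- function(pos, mol_id) {
  n <- nrow(pos)
  coord <- numeric(n)
  if (n > 1) {
    D <- as.matrix(stats::dist(pos))
    sw <- 1 / (1 + exp(6 * (D - 2.2)))
    diag(sw) <- 0
    same <- outer(mol_id, mol_id, "==")
    coord <- rowSums(sw * same)
  }
  1 / (1 + 0.3 * coord)
}

# surrogate energy and analytic forces for one (possibly multi-molecule)
# geometry: Morse on bonded pairs, damped Coulomb + dispersion on the rest
.surrogate_eval <- function(symbols, pos, bonds, mol_id, charges) {
  n <- nrow(pos)
  E <- sum(synthetic_reference_energies(symbols))
  F <- matrix(0, n, 3)
  bkey <- if (nrow(bonds)) paste(bonds$i, bonds$j) else character(0)
  add_pair <- function(i, j, dE_dR, E_pair) {
    dvec <- pos[j, ] - pos[i, ]
    R <- sqrt(sum(dvec^2))
    u <- dvec / R
    E <<- E + E_pair
    F[i, ] <<- F[i, ] + dE_dR * u
    F[j, ] <<- F[j, ] - dE_dR * u
  }
  for (i in seq_len(max(n - 1, 0))) for (j in seq((i + 1), n)) {
    if (j > n) break
    dvec <- pos[j, ] - pos[i, ]
    R <- sqrt(sum(dvec^2))
    if (paste(i, j) %in% bkey) {
      bp <- .bond_params(symbols[i], symbols[j])
      ex <- exp(-bp$a * (R - bp$r0))
      Em <- bp$D * (1 - ex)^2 - bp$D          # -D at the minimum, 0 dissociated
      dE <- 2 * bp$D * (1 - ex) * bp$a * ex
      add_pair(i, j, dE, Em)
    } else {
      qq <- .ke_coulomb * charges[i] * charges[j]
      fd <- 1 - exp(-2 * R)
      Ec <- qq * fd / R
      dEc <- qq * (2 * exp(-2 * R) / R - fd / R^2)
      fpi <- free_atom_params(element_z(symbols[c(i, j)]))
      c6 <- 2 * prod(fpi$c6_free) /
        (fpi$alpha_free[2] / fpi$alpha_free[1] * fpi$c6_free[1] +
         fpi$alpha_free[1] / fpi$alpha_free[2] * fpi$c6_free[2])
      rs <- 0.94 * sum(fpi$rvdw_free)
      sg <- stats::plogis(20 * (R / rs - 1))
      Ed <- -sg * c6 / R^6
      dsg <- sg * (1 - sg) * 20 / rs
      dEd <- -dsg * c6 / R^6 + 6 * sg * c6 / R^7
      add_pair(i, j, dEc + dEd, Ec + Ed)
    }
  }
  # add_pair accumulates +dE/dR along u into F[i], which is -dE/dr_i = force
  list(energy = E, forces = F)
}

.rand_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

.template_geometry <- function(template, deformation) {
  if (is.list(template) && !is.null(template$z)) {
    # diatomic specified by atomic numbers
    sym <- .element_symbols[template$z]
    bp <- .bond_params(sym[1], sym[2])
    R <- max(0.65 * bp$r0, bp$r0 + stats::rnorm(1, sd = deformation))
    pos <- rbind(c(0, 0, 0), c(R, 0, 0))
    bonds <- data.frame(i = 1L, j = 2L)
    return(list(symbols = sym, pos = pos, bonds = bonds))
  }
  if (identical(template, "water")) {
    r <- 0.9572; th <- 104.52 * pi / 180
    pos <- rbind(c(0, 0, 0),
                 c(r, 0, 0),
                 c(r * cos(th), r * sin(th), 0))
    pos <- pos + matrix(stats::rnorm(9, sd = deformation), 3, 3)
    return(list(symbols = c("O", "H", "H"), pos = pos,
                bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L))))
  }
  stop("unknown template: ", if (is.character(template)) template else "(list)")
}

#' Generate a synthetic labeled dataset
#'
#' @param config list with fields: `templates` (list; each entry either
#'   `"water"`, `"water_dimer"`, or `list(z = c(z1, z2))` for a diatomic),
#'   `counts` (records per template), `deformation` (Gaussian internal
#'   deformation, Angstrom; default 0.35).
#' @param seed integer; the generator is fully deterministic given the seed.
#' @return list of training records; each has `species`, `positions`,
#'   `energy` (kcal/mol), `forces`, `charges` (neutral per molecule),
#'   `volume_ratios`, `kind` ("total" or "interaction") and, for dimers,
#'   `monomers` (the two index sets) with `energy` holding the interaction
#'   energy.
#' @export
synthetic_dataset <- function(config, seed = 1) {
  set.seed(seed)
  deformation <- config$deformation %||% 0.35
  counts <- config$counts
  if (length(counts) == 1L) counts <- rep(counts, length(config$templates))
  records <- list()
  for (t in seq_along(config$templates)) {
    template <- config$templates[[t]]
    for (rep in seq_len(counts[t])) {
      if (identical(template, "water_dimer")) {
        g1 <- .template_geometry("water", deformation)
        g2 <- .template_geometry("water", deformation)
        p1 <- g1$pos %*% t(.rand_rotation())
        p2 <- g2$pos %*% t(.rand_rotation())
        sep <- stats::runif(1, 2.6, 4.2)
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        p1 <- sweep(p1, 2, colMeans(p1))
        p2 <- sweep(p2, 2, colMeans(p2)) + matrix(sep * dir, 3, 3, byrow = TRUE)
        sym <- c(g1$symbols, g2$symbols)
        pos <- rbind(p1, p2)
        bonds <- rbind(g1$bonds, data.frame(i = g2$bonds$i + 3L, j = g2$bonds$j + 3L))
        mol <- rep(1:2, each = 3)
        q <- c(.surrogate_charges(g1$symbols), .surrogate_charges(g2$symbols))
        ed <- .surrogate_eval(sym, pos, bonds, mol, q)
        e1 <- .surrogate_eval(g1$symbols, p1, g1$bonds, rep(1L, 3), q[1:3])
        e2 <- .surrogate_eval(g2$symbols, p2, g2$bonds, rep(1L, 3), q[4:6])
        records[[length(records) + 1L]] <- list(
          species = element_z(sym), positions = pos,
          energy = ed$energy - e1$energy - e2$energy,
          forces = ed$forces, charges = q,
          volume_ratios = .surrogate_volumes(pos, rep(1L, 6)),
          kind = "interaction", monomers = list(1:3, 4:6),
          template = "water_dimer")
      } else {
        g <- .template_geometry(template, deformation)
        pos <- g$pos %*% t(.rand_rotation())
        q <- .surrogate_charges(g$symbols)
        ed <- .surrogate_eval(g$symbols, pos, g$bonds, rep(1L, nrow(pos)), q)
        records[[length(records) + 1L]] <- list(
          species = element_z(g$symbols), positions = pos,
          energy = ed$energy, forces = ed$forces, charges = q,
          volume_ratios = .surrogate_volumes(pos, rep(1L, nrow(pos))),
          kind = "total", monomers = NULL,
          template = if (is.character(template)) template else
            paste0("diatomic-", paste(g$symbols, collapse = "")))
      }
    }
  }
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surrogate oracle energy/forces of a geometry
#'
#' Exposes the analytic surrogate used to label synthetic records, for
#' consistency checks (e.g. forces against finite differences).
#'
#' @param species atomic numbers or symbols.
#' @param positions N x 3 matrix.
#' @param bonds data.frame with columns `i`, `j` (bonded pairs; Morse).
#' @return list with `energy` (kcal/mol) and `forces`.
#' @export
surrogate_oracle <- function(species, positions, bonds) {
  if (!is.character(species)) species <- .element_symbols[species]
  q <- .surrogate_charges(species)
  .surrogate_eval(species, as.matrix(positions), bonds,
                  rep(1L, length(species)), q)
}

# ---- dataset files (JSON-lines) ------------------------------------------

#' Write / read training records as JSON-lines
#'
#' One JSON object per line with named arrays per record: a plain-text,
#' stream-friendly dataset container.
#'
#' @param records list of training records.
#' @param path file path.
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(r, digits = NA, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln)
    r$species <- as.integer(r$species)
    r$positions <- matrix(as.numeric(r$positions), ncol = 3)
    if (!is.null(r$forces)) r$forces <- matrix(as.numeric(r$forces), ncol = 3)
    if (!is.null(r$monomers)) {
      mm <- r$monomers
      r$monomers <- if (is.matrix(mm)) {
        lapply(seq_len(nrow(mm)), function(i) as.integer(mm[i, ]))
      } else {
        lapply(mm, as.integer)
      }
    }
    r
  })
}
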