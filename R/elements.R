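# Periodic-table data for H (Z = 1) through Xe (Z = 54).
#
# Groups follow the 18-column IUPAC convention (H in group 1, He in group
# 18). Valence counts are electrons outside the previous noble-gas core
# (d-block: s + d electrons). Masses are standard atomic weights (amu).

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe")

.element_masses <- c(
  1.008, 4.003, 6.94, 9.012, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948,
  39.098, 40.078, 44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933,
  58.693, 63.546, 65.38, 69.723, 72.630, 74.922, 78.971, 79.904, 83.798,
  85.468, 87.62, 88.906, 91.224, 92.906, 95.95, 97.0, 101.07, 102.906,
  106.42, 107.868, 112.414, 114.818, 118.710, 121.760, 127.60, 126.904,
  131.293)

.element_period <- function(z) {
  findInterval(z, c(1, 3, 11, 19, 37)) # period start Z: 1, 3, 11, 19, 37
}

.element_group <- function(z) {
  starts <- c(1L, 3L, 11L, 19L, 37L)
  p <- .element_period(z)
  pos <- as.integer(z) - starts[p] + 1L   # position within the period
  len <- c(2L, 8L, 8L, 18L, 18L)[p]
  if (len == 2L) return(if (pos == 1L) 1L else 18L)   # H, He
  if (len == 8L) return(if (pos <= 2L) pos else pos + 10L)  # s + p blocks
  pos                                      # 18-wide periods map directly
}

.max_z <- 54L

#' Periodic-table coordinates of an element
#'
#' Maps an atomic number to its period (row) and 18-column IUPAC group.
#' Supported range: H (1) through Xe (54); lanthanides are outside the
#' supported table.
#'
#' @param atomic_number integer atomic number(s) in 1..54.
#' @return data.frame with columns `z`, `symbol`, `row`, `col`.
#' @examples
#' periodic_coords(c(1, 8))  # H: (1, 1); O: (2, 16)
#' @export
periodic_coords <- function(atomic_number) {
  z <- as.integer(atomic_number)
  bad <- z < 1L | z > .max_z | is.na(z)
  if (any(bad)) {
    stop("unsupported atomic number(s): ", paste(atomic_number[bad], collapse = ", "),
         " (supported elements: H through Xe, Z = 1..54)")
  }
  data.frame(z = z,
             symbol = .element_symbols[z],
             row = vapply(z, .element_period, integer(1)),
             col = vapply(z, .element_group, integer(1)))
}

#' Element lookup table
#'
#' @param z atomic number(s); default all supported elements.
#' @return data.frame with symbol, mass (amu), period, group.
#' @export
element_info <- function(z = seq_len(.max_z)) {
  pc <- periodic_coords(z)
  pc$mass <- .element_masses[pc$z]
  pc
}

element_z <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(symbol[is.na(z)], collapse = ", "))
  z
}

# Valence electron count (electrons outside the previous noble-gas core).
element_valence <- function(z) {
  pc <- periodic_coords(z)
  g <- pc$col
  p <- pc$row
  v <- ifelse(g <= 12L, g, ifelse(p <= 3L & g >= 13L, g - 10L, g - 10L))
  # He has 2 valence electrons despite sitting in group 18
  v[pc$z == 2L] <- 2L
  # second/third period p-block: group - 10 already correct; groups 1-2 fine
  as.integer(v)
}

# Free-atom reference parameters for the dispersion/electrostatics module.
# Values from the standard free-atom tables used by volume-scaled dispersion
# models: polarizability (a.u.), C6 (Ha a0^6), vdW radius (a0); converted to
# the package units (A^3, kcal/mol A^6, A) below.
.free_atom_au <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "S"),
  alpha  = c(4.50, 12.0, 7.40, 5.40, 3.80, 19.6),
  c6     = c(6.50, 46.6, 24.2, 15.6, 9.52, 134.0),
  rvdw   = c(3.10, 3.59, 3.34, 3.19, 3.04, 3.86))

.bohr <- 0.52917721067
.hartree_kcal <- 627.509474

#' Free-atom parameter table
#'
#' Per-element free-atom reference values used by the physics module:
#' valence electron count, polarizability (A^3), C6 dispersion coefficient
#' (kcal/mol A^6) and van der Waals radius (A).
#'
#' @param z atomic numbers.
#' @return data.frame, one row per atom.
#' @export
free_atom_params <- function(z) {
  pc <- periodic_coords(z)
  i <- match(pc$symbol, .free_atom_au$symbol)
  if (anyNA(i)) stop("no free-atom dispersion parameters for element(s): ",
                     paste(unique(pc$symbol[is.na(i)]), collapse = ", "),
                     " (available: ", paste(.free_atom_au$symbol, collapse = ", "), ")")
  data.frame(z = pc$z, symbol = pc$symbol,
             n_valence = element_valence(pc$z),
             alpha_free = .free_atom_au$alpha[i] * .bohr^3,
             c6_free = .free_atom_au$c6[i] * .hartree_kcal * .bohr^6,
             rvdw_free = .free_atom_au$rvdw[i] * .bohr)
}

# physical constants (package units: kcal/mol, Angstrom, e, fs, amu, K)
.ke_coulomb <- 332.0637     # kcal A / (mol e^2)
.kB <- 0.0019872041         # kcal / (mol K)
.acc_unit <- 4.184e-4       # (kcal/mol/A) / amu -> A/fs^2
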