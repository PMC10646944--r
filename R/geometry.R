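# Atomic systems and directed neighbor graphs.
#
# Units: coordinates in Angstrom throughout. Periodic systems carry a 3x3
# cell matrix (rows are lattice vectors); neighbor searches enumerate
# explicit lattice images so cells smaller than twice the cutoff are
# handled exactly.

#' Construct an atomic system
#'
#' @param species atomic numbers or element symbols.
#' @param positions N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell optional 3 x 3 lattice matrix (rows = lattice vectors, Angstrom).
#' @param periodic logical; defaults to `!is.null(cell)`.
#' @return object of class `atomic_system`.
#' @export
atomic_system <- function(species, positions, cell = NULL, periodic = !is.null(cell)) {
  if (is.character(species)) species <- element_z(species)
  species <- as.integer(species)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be N x 3")
  if (nrow(positions) != length(species)) stop("species/positions length mismatch")
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  if (periodic) {
    if (is.null(cell)) stop("periodic system needs a cell")
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3L, 3L))) stop("cell must be 3 x 3")
    if (abs(det(cell)) < 1e-10) stop("cell is singular")
  }
  structure(list(species = species, positions = positions,
                 cell = cell, periodic = isTRUE(periodic)),
            class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  cat(sprintf("<atomic_system: %d atoms (%s)%s>\n", length(x$species),
              paste(unique(.element_symbols[x$species]), collapse = ","),
              if (x$periodic) " periodic" else ""))
  invisible(x)
}

# perpendicular heights of the cell (distance between opposite faces)
cell_heights <- function(cell) {
  v <- abs(det(cell))
  a1 <- cell[1, ]; a2 <- cell[2, ]; a3 <- cell[3, ]
  crossp <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  c(v / sqrt(sum(crossp(a2, a3)^2)),
    v / sqrt(sum(crossp(a3, a1)^2)),
    v / sqrt(sum(crossp(a1, a2)^2)))
}

# integer lattice shifts whose images can fall within r_c of the home cell
.image_shifts <- function(cell, r_c) {
  h <- cell_heights(cell)
  nmax <- ceiling(r_c / h)
  g <- expand.grid(a = -nmax[1]:nmax[1], b = -nmax[2]:nmax[2], c = -nmax[3]:nmax[3])
  as.matrix(g) %*% cell
}

#' Build the directed neighbor graph within a cutoff
#'
#' All directed pairs (i, j) with 0 < R_ij < r_c (half-open; self pairs at
#' zero image shift excluded). For periodic systems, lattice images within
#' the cutoff are enumerated explicitly, so small cells are exact. Pairs are
#' ordered deterministically by (src, dst, image).
#'
#' @param system an `atomic_system`.
#' @param r_c cutoff radius (Angstrom, > 0).
#' @param min_dist hard floor below which atoms are considered overlapping.
#' @return object of class `pair_graph`: integer vectors `src`, `dst`,
#'   per-pair `displacement` (n x 3, dst - src convention), `distance`,
#'   `shift` (Cartesian image offsets), `rev` (index of the reverse pair),
#'   `cutoff`, `n_atoms`.
#' @export
build_pair_graph <- function(system, r_c, min_dist = 1e-6) {
  stopifnot(inherits(system, "atomic_system"), r_c > 0)
  pos <- system$positions
  n <- nrow(pos)
  if (system$periodic) {
    shifts <- .image_shifts(system$cell, r_c)
  } else {
    shifts <- matrix(0, 1, 3)
  }
  src <- integer(0); dst <- integer(0)
  disp <- matrix(0, 0, 3); sh <- matrix(0, 0, 3)
  if (n > 0) {
    for (s in seq_len(nrow(shifts))) {
      sv <- shifts[s, ]
      # displacement from i to image of j: pos[j] + sv - pos[i]
      dx <- outer(rep(1, n), pos[, 1] + sv[1]) - outer(pos[, 1], rep(1, n))
      dy <- outer(rep(1, n), pos[, 2] + sv[2]) - outer(pos[, 2], rep(1, n))
      dz <- outer(rep(1, n), pos[, 3] + sv[3]) - outer(pos[, 3], rep(1, n))
      d2 <- dx * dx + dy * dy + dz * dz
      keep <- d2 < r_c^2
      if (all(sv == 0)) diag(keep) <- FALSE
      idx <- which(keep, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      i <- idx[, 1]; j <- idx[, 2]
      dd <- sqrt(d2[idx])
      if (any(dd < min_dist)) {
        k <- which.min(dd)
        stop(sprintf("atoms %d and %d overlap (distance %.2e A)", i[k], j[k], dd[k]))
      }
      src <- c(src, i); dst <- c(dst, j)
      disp <- rbind(disp, cbind(dx[idx], dy[idx], dz[idx]))
      sh <- rbind(sh, matrix(sv, nrow(idx), 3, byrow = TRUE))
    }
  }
  ord <- order(src, dst, sh[, 1], sh[, 2], sh[, 3])
  src <- src[ord]; dst <- dst[ord]; disp <- disp[ord, , drop = FALSE]
  sh <- sh[ord, , drop = FALSE]
  # reverse-pair index: (i, j, s) <-> (j, i, -s)
  key <- paste(src, dst, round(sh[, 1], 8), round(sh[, 2], 8), round(sh[, 3], 8))
  rkey <- paste(dst, src, round(-sh[, 1], 8), round(-sh[, 2], 8), round(-sh[, 3], 8))
  rev <- match(rkey, key)
  if (anyNA(rev)) stop("internal error: pair graph is not symmetric")
  structure(list(src = as.integer(src), dst = as.integer(dst),
                 displacement = disp, distance = sqrt(rowSums(disp^2)),
                 shift = sh, rev = as.integer(rev),
                 cutoff = r_c, n_atoms = n),
            class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  cat(sprintf("<pair_graph: %d directed pairs, %d atoms, r_c = %g A>\n",
              length(x$src), x$n_atoms, x$cutoff))
  invisible(x)
}

n_pairs <- function(graph) length(graph$src)

# ---- file I/O -------------------------------------------------------------

#' Read an (extended) XYZ file
#'
#' Supports plain XYZ and the extended-XYZ comment-line dialect with a
#' `Lattice="ax ay az bx by bz cx cy cz"` entry. Multi-frame files return a
#' list of systems.
#'
#' @param path file path.
#' @return an `atomic_system`, or a list of them for multi-frame files.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    comment <- lines[i + 1L]
    cell <- NULL
    m <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
    if (length(m) == 1L && nzchar(m)) {
      vals <- as.numeric(strsplit(gsub('Lattice="|"', "", m), "\\s+")[[1]])
      cell <- matrix(vals, 3, 3, byrow = TRUE)
    }
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    sym <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    z <- suppressWarnings(as.integer(sym))
    species <- if (anyNA(z)) element_z(sym) else z
    frames[[length(frames) + 1L]] <- atomic_system(species, xyz, cell = cell)
    i <- i + 2L + n
  }
  if (length(frames) == 1L) frames[[1L]] else frames
}

#' Write an (extended) XYZ file
#'
#' @param systems an `atomic_system` or list of them (trajectory frames).
#' @param path output path.
#' @param comment per-frame comment (recycled); the lattice entry is added
#'   automatically for periodic systems.
#' @export
write_xyz <- function(systems, path, comment = "") {
  if (inherits(systems, "atomic_system")) systems <- list(systems)
  comment <- rep_len(comment, length(systems))
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_along(systems)) {
    sys <- systems[[f]]
    cmt <- comment[f]
    if (sys$periodic) {
      cmt <- sprintf('Lattice="%s" %s',
                     paste(format(t(sys$cell), trim = TRUE), collapse = " "), cmt)
    }
    writeLines(as.character(nrow(sys$positions)), con)
    writeLines(cmt, con)
    writeLines(sprintf("%-2s %16.8f %16.8f %16.8f",
                       .element_symbols[sys$species],
                       sys$positions[, 1], sys$positions[, 2], sys$positions[, 3]),
               con)
  }
  invisible(path)
}

#' Read coordinates and species from a PDB file
#'
#' Only element identities and coordinates are used (no connectivity).
#' Requires the bio3d package.
#'
#' @param path PDB file path.
#' @return an `atomic_system`.
#' @export
read_pdb_system <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_system requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  elty <- pdb$atom$elesy
  if (is.null(elty) || all(!nzchar(trimws(elty)))) {
    # fall back to the first letter(s) of the atom name
    elty <- gsub("[0-9 ]", "", pdb$atom$elety)
    elty <- paste0(substr(elty, 1, 1), tolower(substr(elty, 2, 2)))
    elty <- sub("^([A-Z][a-z]?).*", "\\1", elty)
  }
  elty <- trimws(elty)
  elty <- paste0(toupper(substr(elty, 1, 1)), tolower(substring(elty, 2)))
  atomic_system(element_z(elty), cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z))
}
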