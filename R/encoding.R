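# Smooth positional encoding of chemical species.
#
# An element's period (row) and 18-column group (col) are each embedded with
# interleaved sine/cosine waves of geometrically spaced frequencies, the
# same scheme used for token positions in sequence models: component 2i is
# sin(c / gamma^(2i/d)) and component 2i+1 is cos(c / gamma^(2i/d)). The two
# blocks are concatenated (row block first). The map is smooth in (row, col)
# treated as real numbers, so nearby elements get nearby encodings and one
# can interpolate between (or average over) species.

.sincos_encode <- function(x, d, gamma) {
  k <- seq_len(d) - 1L                 # 0-based component index
  i2 <- k - (k %% 2L)                  # frequency exponent uses the pair index
  freq <- gamma^(-i2 / d)
  arg <- outer(x, freq)
  out <- matrix(0, length(x), d)
  even <- (k %% 2L) == 0L
  out[, even] <- sin(arg[, even, drop = FALSE])
  out[, !even] <- cos(arg[, !even, drop = FALSE])
  out
}

#' Encode periodic-table coordinates
#'
#' @param coords data.frame with columns `row`, `col` (real-valued allowed:
#'   the encoding is a smooth function of the coordinates).
#' @param d_row,d_col encoding dimensions for the row and column blocks.
#' @param gamma_row,gamma_col frequency parameters (> 1).
#' @return matrix, one row per input, `d_row + d_col` columns (row block
#'   first); every component lies in \[-1, 1\].
#' @export
encode_species <- function(coords, d_row = 5, d_col = 10,
                           gamma_row = 100, gamma_col = 1000) {
  stopifnot(d_row >= 1, d_col >= 1, gamma_row > 1, gamma_col > 1)
  cbind(.sincos_encode(coords$row, d_row, gamma_row),
        .sincos_encode(coords$col, d_col, gamma_col))
}

#' Species encoding by atomic number
#'
#' Convenience wrapper: look up periodic-table coordinates and encode them.
#' Encodings are deterministic, so identical species always share one.
#'
#' @inheritParams encode_species
#' @param z atomic number(s), 1..54.
#' @return matrix of encodings, one row per atomic number.
#' @export
species_encoding <- function(z, d_row = 5, d_col = 10,
                             gamma_row = 100, gamma_col = 1000) {
  encode_species(periodic_coords(z), d_row, d_col, gamma_row, gamma_col)
}

#' Componentwise average of species encodings
#'
#' The mean encoding behaves like any other species encoding and can stand
#' in for a fictitious "average element" (e.g. to probe what a model has
#' learned independently of chemistry).
#'
#' @param encodings matrix of encodings (rows) or list of equal-length vectors.
#' @return numeric vector, the componentwise mean.
#' @export
average_encoding <- function(encodings) {
  if (is.list(encodings) && !is.data.frame(encodings)) {
    if (length(encodings) == 0L) stop("empty list of encodings")
    d <- lengths(encodings)
    if (length(unique(d)) != 1L) stop("encodings have differing dimensions")
    encodings <- do.call(rbind, encodings)
  }
  if (is.null(dim(encodings))) encodings <- matrix(encodings, nrow = 1L)
  if (nrow(encodings) == 0L) stop("empty set of encodings")
  colMeans(encodings)
}

#' Euclidean distance distributions in encoding space
#'
#' Computes all unordered element-element distances, and the distance from
#' each element to the average encoding of the set.
#'
#' @param z atomic numbers (at least 2).
#' @inheritParams encode_species
#' @return list with `pair` (choose(n,2) distances) and `to_average`
#'   (n distances).
#' @export
encoding_distances <- function(z, d_row = 5, d_col = 10,
                               gamma_row = 100, gamma_col = 1000) {
  if (length(z) < 2L) stop("need at least 2 elements")
  enc <- species_encoding(z, d_row, d_col, gamma_row, gamma_col)
  avg <- average_encoding(enc)
  list(pair = as.vector(stats::dist(enc)),
       to_average = sqrt(rowSums(sweep(enc, 2L, avg)^2)))
}
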