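# Radial basis, polynomial cutoff envelope and real spherical harmonics.
#
# The radial basis is the sinc-like Bessel basis B_n(R) = sqrt(2/r_c)
# sin(n pi R / r_c) / R multiplied by a polynomial envelope u_p(R/r_c) whose
# value is 1 at 0, 0 at the cutoff, with its first p-1 derivatives vanishing
# there, so every fingerprint goes smoothly and exactly to zero at r_c.
#
# Real spherical harmonics use "component" normalization (the mean square of
# every component over the unit sphere is 1, i.e. |Y_l|^2 = 2l+1 on average),
# the convention common in equivariant-network practice; the m ordering is
# the standard real one (l = 1: y, z, x). Supported l = 0, 1, 2.
#
# Numeric versions (plain matrices) serve graph construction and tests; the
# ad_* versions build the same quantities on the differentiation tape so
# forces flow through them.

.envelope_coef <- function(p) {
  # u(x) = 1 - (p+1)(p+2)/2 x^p + p(p+2) x^(p+1) - p(p+1)/2 x^(p+2)
  c(a = -(p + 1) * (p + 2) / 2, b = p * (p + 2), d = -p * (p + 1) / 2)
}

#' Polynomial cutoff envelope
#'
#' @param r distances (Angstrom).
#' @param r_c cutoff.
#' @param p smoothness parameter (>= 2): the first p-1 derivatives vanish at r_c.
#' @return envelope values; exactly 0 for r >= r_c, 1 at r = 0.
#' @export
poly_envelope <- function(r, r_c, p = 3) {
  stopifnot(p >= 2)
  x <- r / r_c
  cf <- .envelope_coef(p)
  out <- 1 + cf["a"] * x^p + cf["b"] * x^(p + 1) + cf["d"] * x^(p + 2)
  out[x >= 1] <- 0
  unname(out)
}

ad_envelope <- function(r, r_c, p = 3) {
  # tape version; assumes all distances < r_c (graph-guaranteed)
  x <- ad_kmul(r, 1 / r_c)
  cf <- .envelope_coef(p)
  ad_kadd(ad_add(ad_add(ad_kmul(ad_pow(x, p), cf[["a"]]),
                        ad_kmul(ad_pow(x, p + 1), cf[["b"]])),
                 ad_kmul(ad_pow(x, p + 2), cf[["d"]])), 1)
}

#' Bessel radial basis with polynomial envelope
#'
#' @param r distances (all < r_c for meaningful output).
#' @param n_basis number of basis functions.
#' @inheritParams poly_envelope
#' @return length(r) x n_basis matrix; rows vanish smoothly at r_c.
#' @export
bessel_basis <- function(r, n_basis, r_c, p = 3) {
  stopifnot(n_basis >= 1)
  n <- seq_len(n_basis)
  env <- poly_envelope(r, r_c, p)
  B <- sqrt(2 / r_c) * sin(outer(r, n * pi / r_c)) / r
  B * env
}

ad_bessel <- function(r, n_basis, r_c, p = 3) {
  env <- ad_envelope(r, r_c, p)
  rinv <- ad_pow(r, -1)
  cols <- lapply(seq_len(n_basis), function(n) {
    ad_mul(ad_kmul(ad_sin(ad_kmul(r, n * pi / r_c)), sqrt(2 / r_c)), rinv)
  })
  ad_mulrows(ad_cbind(cols), env)
}

#' Real spherical harmonics of unit vectors
#'
#' Component-normalized real spherical harmonics for l = 0..l_max evaluated
#' on rows of a matrix of unit vectors. Under inversion the l-block picks up
#' the parity factor (-1)^l.
#'
#' @param u n x 3 matrix of unit vectors.
#' @param l_max maximum rotational order (0, 1 or 2).
#' @return list of length l_max + 1; element l+1 is an n x (2l+1) matrix.
#' @export
real_spherical_harmonics <- function(u, l_max) {
  u <- as.matrix(u)
  if (any(rowSums(u^2) < 1e-20)) stop("zero vector passed to spherical harmonics")
  if (l_max > 2) stop("spherical harmonics implemented for l_max <= 2")
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  out <- list(matrix(1, nrow(u), 1))
  if (l_max >= 1) {
    out[[2]] <- sqrt(3) * cbind(y, z, x)
  }
  if (l_max >= 2) {
    out[[3]] <- cbind(sqrt(15) * x * y,
                      sqrt(15) * y * z,
                      (sqrt(5) / 2) * (3 * z^2 - 1),
                      sqrt(15) * x * z,
                      (sqrt(15) / 2) * (x^2 - y^2))
  }
  out
}

# tape version: u is an adnode (n x 3 of unit vectors)
ad_spherical_harmonics <- function(u, l_max) {
  n <- nrow(u$v)
  x <- ad_cols(u, 1L, 1L); y <- ad_cols(u, 2L, 2L); z <- ad_cols(u, 3L, 3L)
  out <- list(ad_const(matrix(1, n, 1)))
  if (l_max >= 1) {
    out[[2]] <- ad_kmul(ad_cbind(y, z, x), sqrt(3))
  }
  if (l_max >= 2) {
    out[[3]] <- ad_cbind(
      ad_kmul(ad_mul(x, y), sqrt(15)),
      ad_kmul(ad_mul(y, z), sqrt(15)),
      ad_kmul(ad_kadd(ad_kmul(ad_mul(z, z), 3), -1), sqrt(5) / 2),
      ad_kmul(ad_mul(x, z), sqrt(15)),
      ad_kmul(ad_sub(ad_mul(x, x), ad_mul(y, y)), sqrt(15) / 2))
  }
  if (l_max > 2) stop("spherical harmonics implemented for l_max <= 2")
  out
}
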