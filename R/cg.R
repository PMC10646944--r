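# Coupling coefficients for real spherical tensors.
#
# The interaction layers combine two equivariant features of rotational
# orders l1 and l2 into order l (|l1-l2| <= l <= l1+l2) through the unique
# equivariant bilinear map. Its coefficients are the Clebsch-Gordan
# coefficients transformed to the real spherical-harmonic basis: the complex
# coefficients come from the standard closed-form (Racah) sum, and the
# complex-to-real change of basis uses the usual unitary with
# Condon-Shortley phases. The resulting real tensor is either purely real or
# purely imaginary; the nonzero part is kept. Each coupling tensor has
# squared Frobenius norm 2l+1 (inherited from CG orthonormality), so
# coupled features stay at unit scale.

.cg_cache <- new.env(parent = emptyenv())

.lfact <- function(n) lgamma(n + 1)

# complex <l1 m1 l2 m2 | l m> (Condon-Shortley convention)
.cg_complex <- function(l1, m1, l2, m2, l, m) {
  if (m1 + m2 != m) return(0)
  if (l < abs(l1 - l2) || l > l1 + l2) return(0)
  if (abs(m1) > l1 || abs(m2) > l2 || abs(m) > l) return(0)
  pref <- 0.5 * (log(2 * l + 1) +
                 .lfact(l1 + l2 - l) + .lfact(l1 - l2 + l) + .lfact(-l1 + l2 + l) -
                 .lfact(l1 + l2 + l + 1) +
                 .lfact(l + m) + .lfact(l - m) + .lfact(l1 + m1) + .lfact(l1 - m1) +
                 .lfact(l2 + m2) + .lfact(l2 - m2))
  kmin <- max(0, l2 - l - m1, l1 + m2 - l)
  kmax <- min(l1 + l2 - l, l1 - m1, l2 + m2)
  if (kmax < kmin) return(0)
  s <- 0
  for (k in kmin:kmax) {
    s <- s + (-1)^k * exp(pref - .lfact(k) - .lfact(l1 + l2 - l - k) -
                          .lfact(l1 - m1 - k) - .lfact(l2 + m2 - k) -
                          .lfact(l - l2 + m1 + k) - .lfact(l - l1 - m2 + k))
  }
  s
}

# unitary mapping complex harmonics to real ones: Y^R = U %*% Y^C
.real_unitary <- function(l) {
  dim <- 2L * l + 1L
  U <- matrix(0 + 0i, dim, dim)
  idx <- function(m) m + l + 1L
  U[idx(0L), idx(0L)] <- 1
  if (l > 0) for (mu in 1:l) {
    U[idx(mu), idx(mu)] <- (-1)^mu / sqrt(2)
    U[idx(mu), idx(-mu)] <- 1 / sqrt(2)
    U[idx(-mu), idx(-mu)] <- 1i / sqrt(2)
    U[idx(-mu), idx(mu)] <- -1i * (-1)^mu / sqrt(2)
  }
  U
}

#' Real-basis coupling tensor
#'
#' @param l1,l2 input rotational orders.
#' @param l output order (must satisfy the triangle inequality).
#' @return array (2l1+1) x (2l2+1) x (2l+1) of real coupling coefficients.
#' @export
real_coupling <- function(l1, l2, l) {
  key <- paste(l1, l2, l)
  hit <- .cg_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (l < abs(l1 - l2) || l > l1 + l2) stop("triangle inequality violated")
  d1 <- 2L * l1 + 1L; d2 <- 2L * l2 + 1L; d <- 2L * l + 1L
  C <- array(0, c(d1, d2, d))
  for (m1 in -l1:l1) for (m2 in -l2:l2) {
    m <- m1 + m2
    if (abs(m) <= l) C[m1 + l1 + 1, m2 + l2 + 1, m + l + 1] <- .cg_complex(l1, m1, l2, m2, l, m)
  }
  U1 <- .real_unitary(l1); U2 <- .real_unitary(l2); Ul <- .real_unitary(l)
  R <- array(0 + 0i, c(d1, d2, d))
  # R[a,b,c] = sum Ul[c,m] C[m1,m2,m] Conj(U1[a,m1]) Conj(U2[b,m2])
  for (cc in seq_len(d)) {
    M <- matrix(0 + 0i, d1, d2)
    for (m in seq_len(d)) {
      if (Ul[cc, m] == 0) next
      M <- M + Ul[cc, m] * (Conj(U1) %*% C[, , m] %*% t(Conj(U2)))
    }
    R[, , cc] <- M
  }
  re <- max(abs(Re(R))); im <- max(abs(Im(R)))
  out <- if (im > re) Im(R) else Re(R)
  if (min(re, im) > 1e-10 * max(re, im)) stop("coupling tensor neither real nor imaginary")
  out[abs(out) < 1e-14] <- 0
  .cg_cache[[key]] <- out
  out
}

# sparse (m1, m2, m, coef) representation used by the layer loop
coupling_nonzeros <- function(l1, l2, l) {
  R <- real_coupling(l1, l2, l)
  nz <- which(abs(R) > 0, arr.ind = TRUE)
  data.frame(m1 = nz[, 1], m2 = nz[, 2], m = nz[, 3], coef = R[nz])
}
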