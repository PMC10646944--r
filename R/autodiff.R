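# Minimal reverse-mode differentiation tape on dense matrices.
#
# Every value is a node holding a numeric matrix. Operations build a DAG;
# ad_backward() propagates adjoints in reverse topological order. The
# vector-Jacobian product of every primitive is itself expressed with tape
# primitives, so gradients are differentiable again (double backward), which
# is what force-matching losses need: d/dtheta of dE/dR.
#
# This is deliberately small: only the primitives the potential needs, all
# shapes are explicit matrices (scalars are 1x1), broadcasting is restricted
# to the dedicated row/column/scalar primitives.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_is <- function(x) inherits(x, "adnode")

new_adnode <- function(value, op, parents = list(), extra = NULL) {
  if (!is.matrix(value)) stop("adnode value must be a matrix")
  if (!is.double(value)) storage.mode(value) <- "double"
  .ad$id <- .ad$id + 1L
  node <- new.env(parent = emptyenv())
  node$v <- value
  node$op <- op
  node$pa <- parents
  node$ex <- extra
  node$id <- .ad$id
  class(node) <- "adnode"
  node
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.double(x), ncol = 1L)
}

#' @noRd
ad_const <- function(x) new_adnode(as_mat(x), "const")
ad_leaf  <- function(x) new_adnode(as_mat(x), "leaf")
ad_wrap  <- function(x) if (ad_is(x)) x else ad_const(x)

ad_value <- function(x) if (ad_is(x)) x$v else as_mat(x)

#' @export
print.adnode <- function(x, ...) {
  cat(sprintf("<adnode %s [%d x %d] id=%d>\n", x$op, nrow(x$v), ncol(x$v), x$id))
  invisible(x)
}

# ---- elementwise arithmetic (same shape, or via the *_row/*_scalar forms) ----

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  if (nrow(a$v) != nrow(b$v) || ncol(a$v) != ncol(b$v)) stop("shape mismatch in add")
  new_adnode(a$v + b$v, "add", list(a, b))
}

ad_sub <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  if (nrow(a$v) != nrow(b$v) || ncol(a$v) != ncol(b$v)) stop("shape mismatch in sub")
  new_adnode(a$v - b$v, "sub", list(a, b))
}

ad_neg <- function(a) new_adnode(-a$v, "neg", list(a))

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  if (nrow(a$v) != nrow(b$v) || ncol(a$v) != ncol(b$v)) stop("shape mismatch in mul")
  new_adnode(a$v * b$v, "mul", list(a, b))
}

# multiply by a 1x1 node (scalar broadcast)
ad_smul <- function(a, s) {
  s <- ad_wrap(s)
  if (length(s$v) != 1L) stop("smul expects a 1x1 scalar node")
  new_adnode(a$v * s$v[1L], "smul", list(a, s))
}

# multiply/add by a plain numeric constant
ad_kmul <- function(a, k) new_adnode(a$v * k, "kmul", list(a), extra = list(k = k))
ad_kadd <- function(a, k) new_adnode(a$v + k, "kadd", list(a), extra = list(k = k))

# scale row i of A by c[i] (c is n x 1)
ad_mulrows <- function(a, c) {
  c <- ad_wrap(c)
  if (nrow(a$v) != nrow(c$v) || ncol(c$v) != 1L) stop("mulrows shape mismatch")
  new_adnode(a$v * as.vector(c$v), "mulrows", list(a, c))
}

# add a 1 x m row vector to every row of A (bias)
ad_addrow <- function(a, r) {
  r <- ad_wrap(r)
  if (nrow(r$v) != 1L || ncol(a$v) != ncol(r$v)) stop("addrow shape mismatch")
  new_adnode(sweep(a$v, 2L, as.vector(r$v), "+"), "addrow", list(a, r))
}

ad_div <- function(a, b) ad_mul(a, ad_pow(b, -1))
ad_divrows <- function(a, c) ad_mulrows(a, ad_pow(c, -1))

# ---- matrix product ----

ad_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  av <- if (ta) t(a$v) else a$v
  bv <- if (tb) t(b$v) else b$v
  new_adnode(av %*% bv, "matmul", list(a, b), extra = list(ta = ta, tb = tb))
}

# ---- reductions and broadcasts ----

ad_sum <- function(a) new_adnode(matrix(sum(a$v)), "sum", list(a),
                                 extra = list(n = nrow(a$v), m = ncol(a$v)))
ad_rowsum <- function(a) new_adnode(matrix(rowSums(a$v), ncol = 1L), "rowsum",
                                    list(a), extra = list(m = ncol(a$v)))
ad_colsum <- function(a) new_adnode(matrix(colSums(a$v), nrow = 1L), "colsum",
                                    list(a), extra = list(n = nrow(a$v)))
ad_fill <- function(s, n, m) {
  s <- ad_wrap(s); if (length(s$v) != 1L) stop("fill expects a scalar node")
  new_adnode(matrix(s$v[1L], n, m), "fill", list(s))
}
ad_repeatrow <- function(r, n) {
  if (nrow(r$v) != 1L) stop("repeatrow expects a row vector")
  new_adnode(matrix(as.vector(r$v), n, ncol(r$v), byrow = TRUE), "repeatrow", list(r))
}
ad_repeatcol <- function(c, m) {
  if (ncol(c$v) != 1L) stop("repeatcol expects a column vector")
  new_adnode(matrix(as.vector(c$v), nrow(c$v), m), "repeatcol", list(c))
}

# ---- indexing ----

ad_gather <- function(a, idx) {
  idx <- as.integer(idx)
  new_adnode(a$v[idx, , drop = FALSE], "gather", list(a),
             extra = list(idx = idx, n = nrow(a$v)))
}

# rowsum of A into n bins given per-row bin index (scatter-add)
ad_scatter <- function(a, idx, n) {
  idx <- as.integer(idx)
  out <- matrix(0, n, ncol(a$v))
  acc <- rowsum(a$v, group = idx, reorder = FALSE)
  out[as.integer(rownames(acc)), ] <- acc
  new_adnode(out, "scatter", list(a), extra = list(idx = idx, n = n))
}

ad_cols <- function(a, from, to) {
  new_adnode(a$v[, from:to, drop = FALSE], "cols", list(a),
             extra = list(from = from, to = to, m = ncol(a$v)))
}

ad_cbind <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !ad_is(args[[1L]])) args <- args[[1L]]
  args <- lapply(args, ad_wrap)
  widths <- vapply(args, function(x) ncol(x$v), integer(1))
  new_adnode(do.call(cbind, lapply(args, function(x) x$v)), "cbindn", args,
             extra = list(widths = widths))
}

# ---- scalar nonlinearities ----

ad_sin  <- function(a) new_adnode(sin(a$v),  "sin",  list(a))
ad_cos  <- function(a) new_adnode(cos(a$v),  "cos",  list(a))
ad_exp  <- function(a) new_adnode(exp(a$v),  "exp",  list(a))
ad_log  <- function(a) new_adnode(log(a$v),  "log",  list(a))
ad_sqrt <- function(a) new_adnode(sqrt(a$v), "sqrt", list(a))
ad_pow  <- function(a, k) new_adnode(a$v^k, "pow", list(a), extra = list(k = k))

ad_sigmoid <- function(a) new_adnode(stats::plogis(a$v), "sigmoid", list(a))

.softplus <- function(x) ifelse(x > 33, x, log1p(exp(pmin(x, 33))))
ad_softplus <- function(a) new_adnode(.softplus(a$v), "softplus", list(a))

.erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
ad_erfc <- function(a) new_adnode(.erfc(a$v), "erfc", list(a))

ad_silu <- function(a) ad_mul(a, ad_sigmoid(a))

# ---- backward ----

.ad_vjp <- list(
  add     = function(nd, g) list(g, g),
  sub     = function(nd, g) list(g, ad_neg(g)),
  neg     = function(nd, g) list(ad_neg(g)),
  mul     = function(nd, g) list(ad_mul(g, nd$pa[[2L]]), ad_mul(g, nd$pa[[1L]])),
  smul    = function(nd, g) list(ad_smul(g, nd$pa[[2L]]),
                                 ad_sum(ad_mul(g, nd$pa[[1L]]))),
  kmul    = function(nd, g) list(ad_kmul(g, nd$ex$k)),
  kadd    = function(nd, g) list(g),
  mulrows = function(nd, g) list(ad_mulrows(g, nd$pa[[2L]]),
                                 ad_rowsum(ad_mul(g, nd$pa[[1L]]))),
  addrow  = function(nd, g) list(g, ad_colsum(g)),
  matmul  = function(nd, g) {
    a <- nd$pa[[1L]]; b <- nd$pa[[2L]]; ta <- nd$ex$ta; tb <- nd$ex$tb
    da <- if (!ta) ad_matmul(g, b, tb = !tb) else ad_matmul(b, g, ta = tb, tb = TRUE)
    db <- if (!tb) ad_matmul(a, g, ta = !ta) else ad_matmul(g, a, ta = TRUE, tb = ta)
    list(da, db)
  },
  sum     = function(nd, g) list(ad_fill(g, nd$ex$n, nd$ex$m)),
  rowsum  = function(nd, g) list(ad_repeatcol(g, nd$ex$m)),
  colsum  = function(nd, g) list(ad_repeatrow(g, nd$ex$n)),
  fill    = function(nd, g) list(ad_sum(g)),
  repeatrow = function(nd, g) list(ad_colsum(g)),
  repeatcol = function(nd, g) list(ad_rowsum(g)),
  gather  = function(nd, g) list(ad_scatter(g, nd$ex$idx, nd$ex$n)),
  scatter = function(nd, g) list(ad_gather(g, nd$ex$idx)),
  cols    = function(nd, g) list(ad_padcols(g, nd$ex$from, nd$ex$m)),
  padcols = function(nd, g) list(ad_cols(g, nd$ex$from, nd$ex$from + ncol(nd$pa[[1L]]$v) - 1L)),
  cbindn  = function(nd, g) {
    w <- nd$ex$widths; out <- vector("list", length(w)); at <- 0L
    for (i in seq_along(w)) { out[[i]] <- ad_cols(g, at + 1L, at + w[i]); at <- at + w[i] }
    out
  },
  sin     = function(nd, g) list(ad_mul(g, ad_cos(nd$pa[[1L]]))),
  cos     = function(nd, g) list(ad_neg(ad_mul(g, ad_sin(nd$pa[[1L]])))),
  exp     = function(nd, g) list(ad_mul(g, nd)),
  log     = function(nd, g) list(ad_div(g, nd$pa[[1L]])),
  sqrt    = function(nd, g) list(ad_kmul(ad_mul(g, ad_pow(nd$pa[[1L]], -0.5)), 0.5)),
  pow     = function(nd, g) list(ad_kmul(ad_mul(g, ad_pow(nd$pa[[1L]], nd$ex$k - 1)), nd$ex$k)),
  sigmoid = function(nd, g) list(ad_mul(g, ad_mul(nd, ad_kadd(ad_neg(nd), 1)))),
  softplus = function(nd, g) list(ad_mul(g, ad_sigmoid(nd$pa[[1L]]))),
  erfc    = function(nd, g) list(ad_kmul(ad_mul(g, ad_exp(ad_neg(ad_pow(nd$pa[[1L]], 2)))),
                                         -2 / sqrt(pi)))
)

# place a block of columns into a wider zero matrix (adjoint of ad_cols)
ad_padcols <- function(a, from, total) {
  out <- matrix(0, nrow(a$v), total)
  out[, from:(from + ncol(a$v) - 1L)] <- a$v
  new_adnode(out, "padcols", list(a), extra = list(from = from, total = total))
}

# iterative topological order of the sub-DAG reachable from root
.ad_topo <- function(root) {
  order <- vector("list", 256L); no <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L)); ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) { ns <- ns - 1L; next }
      seen[[key]] <- TRUE
      stack[[ns]]$stage <- 2L
      for (p in nd$pa) {
        if (is.null(seen[[as.character(p$id)]])) {
          ns <- ns + 1L
          stack[[ns]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      no <- no + 1L
      if (no > length(order)) order <- c(order, vector("list", length(order)))
      order[[no]] <- nd
      ns <- ns - 1L
    }
  }
  order[seq_len(no)]
}

#' Reverse-mode gradients of a scalar tape node.
#'
#' @param root scalar (1x1) output node.
#' @param leaves list of nodes to differentiate with respect to.
#' @param grad_root adjoint seed for root (defaults to 1).
#' @return list of adnodes, one per leaf (zero-valued where unreachable).
#'   Gradients are themselves tape nodes and can be differentiated again.
#' @noRd
ad_backward <- function(root, leaves, grad_root = NULL) {
  if (is.null(grad_root)) grad_root <- ad_const(matrix(1, nrow(root$v), ncol(root$v)))
  topo <- .ad_topo(root)
  adj <- new.env(parent = emptyenv())
  adj[[as.character(root$id)]] <- grad_root
  for (i in rev(seq_along(topo))) {
    nd <- topo[[i]]
    g <- adj[[as.character(nd$id)]]
    if (is.null(g) || length(nd$pa) == 0L) next
    fn <- .ad_vjp[[nd$op]]
    if (is.null(fn)) stop("no vjp for op ", nd$op)
    gs <- fn(nd, g)
    for (j in seq_along(nd$pa)) {
      gp <- gs[[j]]
      if (is.null(gp)) next
      key <- as.character(nd$pa[[j]]$id)
      prev <- adj[[key]]
      adj[[key]] <- if (is.null(prev)) gp else ad_add(prev, gp)
    }
  }
  lapply(leaves, function(lf) {
    g <- adj[[as.character(lf$id)]]
    if (is.null(g)) ad_const(matrix(0, nrow(lf$v), ncol(lf$v))) else g
  })
}

# numeric convenience: gradient values only
ad_grad <- function(root, leaves) lapply(ad_backward(root, leaves), ad_value)

# affine layer helper: X W + b (b may be NULL)
ad_affine <- function(x, W, b = NULL) {
  out <- ad_matmul(x, W)
  if (!is.null(b)) out <- ad_addrow(out, b)
  out
}

# multilayer perceptron on the tape; params: list(W1,b1,W2,b2,...) as adnodes
ad_mlp <- function(x, weights, biases, act = ad_silu, final_act = FALSE) {
  n <- length(weights)
  for (i in seq_len(n)) {
    x <- ad_affine(x, weights[[i]], biases[[i]])
    if (i < n || final_act) x <- act(x)
  }
  x
}
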