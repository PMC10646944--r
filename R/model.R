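# Model construction: hyperparameters, parameter initialization and the
# equivariant-embedding bookkeeping (which rotational/parity blocks exist at
# each layer and which tensor-product paths connect them).
#
# The embedding operates on directed atom pairs. Each pair carries a scalar
# (invariant) feature vector x_ij and tensor features V_ij^{nlp} indexed by
# channel n, rotational order l and parity p. A layer (i) sums per-neighbor
# weighted spherical harmonics into an environment tensor for the source
# atom, (ii) couples it with each pair's tensors through all
# symmetry-allowed paths, (iii) updates the scalars through a latent MLP
# with a normalization-preserving mixing coefficient, and (iv) linearly
# recombines channels/paths back to a fixed-width tensor set.

#' Model hyperparameter configuration
#'
#' Defaults are the production-size architecture: 15-dimensional positional
#' species encoding (5 row + 10 column), 10 Bessel basis functions with
#' cutoff 5.2 A and envelope smoothness p = 3, 256 scalar features, 10
#' tensor channels up to l_max = 2, 3 interaction layers, two-body MLP with
#' hidden layers (64, 128), latent MLPs (256, 256), and output heads with
#' hidden layers (256, 128, 64, 32, 16) acting on the concatenated two-body
#' and final scalar embeddings.
#'
#' @param ... overrides for any of the fields listed above.
#' @return a `model_config` list.
#' @export
model_config <- function(...) {
  cfg <- list(
    d_row = 5, d_col = 10, gamma_row = 100, gamma_col = 1000,
    n_basis = 10, r_c = 5.2, p_env = 3,
    n_scalar = 256, n_channels = 10, l_max = 2, n_layers = 3,
    mlp2b_hidden = c(64, 128),
    latent_hidden = c(256, 256),
    head_hidden = c(256, 128, 64, 32, 16),
    alpha_init = 1 / sqrt(2),
    short_range_cutoff = NULL   # optional extra output cutoff (off by default)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$l_max <= 2, cfg$n_layers >= 1)
  class(cfg) <- "model_config"
  cfg
}

irrep_key <- function(l, p) paste0(l, if (p > 0) "e" else "o")

# the tensor-product paths from (environment x pair-tensor) given the pair
# tensor's irrep set; environment irreps are (l1, (-1)^l1), l1 = 0..l_max
.layer_paths <- function(in_irreps, l_max) {
  paths <- list()
  for (l1 in 0:l_max) {
    p1 <- (-1)^l1
    for (k2 in seq_len(nrow(in_irreps))) {
      l2 <- in_irreps$l[k2]; p2 <- in_irreps$p[k2]
      for (l in abs(l1 - l2):min(l_max, l1 + l2)) {
        paths[[length(paths) + 1L]] <- list(
          l1 = l1, l2 = l2, p2 = p2, key2 = irrep_key(l2, p2),
          l = l, p = p1 * p2, keyout = irrep_key(l, p1 * p2))
      }
    }
  }
  paths
}

.paths_out_irreps <- function(paths) {
  ks <- unique(vapply(paths, function(pp) pp$keyout, character(1)))
  data.frame(l = as.integer(substr(ks, 1, 1)),
             p = ifelse(substr(ks, 2, 2) == "e", 1, -1),
             key = ks)
}

.two_body_irreps <- function(l_max) {
  data.frame(l = 0:l_max, p = (-1)^(0:l_max),
             key = vapply(0:l_max, function(l) irrep_key(l, (-1)^l), character(1)))
}

# per-layer irrep sets and path tables, fixed at build time
.model_meta <- function(cfg) {
  irreps <- .two_body_irreps(cfg$l_max)
  layers <- vector("list", cfg$n_layers)
  for (L in seq_len(cfg$n_layers)) {
    paths <- .layer_paths(irreps, cfg$l_max)
    out_irreps <- .paths_out_irreps(paths)
    # per output irrep: the path indices feeding it
    by_out <- split(seq_along(paths), vapply(paths, function(pp) pp$keyout, character(1)))
    scalar_paths <- by_out[[irrep_key(0, 1)]]
    layers[[L]] <- list(in_irreps = irreps, paths = paths,
                        out_irreps = out_irreps, by_out = by_out,
                        scalar_paths = scalar_paths,
                        n_scalar_latent = length(scalar_paths) * cfg$n_channels)
    irreps <- out_irreps
  }
  list(layers = layers, final_irreps = irreps)
}

.rand_mat <- function(n, m, scale = 1 / sqrt(n)) matrix(stats::rnorm(n * m, sd = scale), n, m)

.init_mlp <- function(sizes, prefix, bias = TRUE) {
  out <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    out[[paste0(prefix, ".W", i)]] <- .rand_mat(sizes[i], sizes[i + 1L])
    if (bias) out[[paste0(prefix, ".b", i)]] <- matrix(0, 1, sizes[i + 1L])
  }
  out
}

#' Default physics-module parameters
#'
#' Universal parameters of the long-range terms: `eps` scales all predicted
#' charges (compensating the lack of higher multipoles), `alpha` and `beta`
#' (1/A) are the charge-penetration damping rates of the nucleus-electron
#' and electron-electron terms, `gamma` and `s` shape the sigmoid dispersion
#' damping (steepness and radius scaling, literature Tkatchenko-Scheffler
#' values by default). `r_disp` is the dispersion cutoff with a smooth
#' switch over the final `disp_switch` Angstrom.
#'
#' @param ... overrides.
#' @return named list of parameters.
#' @export
ff_parameters <- function(...) {
  ff <- list(eps = 1.0, alpha = 3.0, beta = 2.0, gamma = 20.0, s = 0.94,
             r_disp = 12.0, disp_switch = 1.0,
             valence_max_frac = 0.95, valence_width = 0.01)
  over <- list(...)
  bad <- setdiff(names(over), names(ff))
  if (length(bad)) stop("unknown ff parameter(s): ", paste(bad, collapse = ", "))
  ff[names(over)] <- over
  ff
}

#' Construct a hybrid neural-network/force-field potential model
#'
#' Initializes all trainable parameters (scaled-Gaussian weights, zero
#' biases) behind a single seed.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @param ref_energies named numeric vector of isolated-atom reference
#'   energies (kcal/mol) keyed by element symbol; elements absent from the
#'   table default to 0 for H..Xe.
#' @param ff physics-module parameters, see [ff_parameters()].
#' @return object of class `nnp_model`.
#' @export
nnp_model <- function(config = model_config(), seed = 1,
                      ref_energies = NULL, ff = ff_parameters()) {
  cfg <- config
  set.seed(seed)
  meta <- .model_meta(cfg)
  enc_dim <- cfg$d_row + cfg$d_col
  C <- cfg$n_channels
  nl <- cfg$l_max + 1L
  params <- list()

  params <- c(params, .init_mlp(c(2 * enc_dim + cfg$n_basis, cfg$mlp2b_hidden, cfg$n_scalar),
                                "mlp2b"))
  params[["embed2b.W"]] <- .rand_mat(cfg$n_scalar, C * nl)

  for (L in seq_len(cfg$n_layers)) {
    lm <- meta$layers[[L]]
    pre <- paste0("layer", L)
    params[[paste0(pre, ".embed.W")]] <- .rand_mat(cfg$n_scalar, C * nl)
    params <- c(params, .init_mlp(c(cfg$n_scalar + lm$n_scalar_latent,
                                    cfg$latent_hidden, cfg$n_scalar),
                                  paste0(pre, ".latent")))
    params[[paste0(pre, ".alpha_raw")]] <- matrix(stats::qlogis(cfg$alpha_init), 1, 1)
    for (key in names(lm$by_out)) {
      fan <- length(lm$by_out[[key]]) * C
      params[[paste0(pre, ".path.", key)]] <- .rand_mat(fan, C, scale = 1)
    }
  }

  head_in <- 2L * cfg$n_scalar
  for (h in c("e", "q", "v")) {
    params <- c(params, .init_mlp(c(head_in, cfg$head_hidden, 1L), paste0("head.", h)))
  }

  for (nm in c("eps", "alpha", "beta", "gamma", "s")) {
    params[[paste0("ff.", nm)]] <- matrix(ff[[nm]], 1, 1)
  }

  refs <- stats::setNames(rep(0, .max_z), .element_symbols)
  if (!is.null(ref_energies)) {
    unknown <- setdiff(names(ref_energies), .element_symbols)
    if (length(unknown)) stop("reference energies for unknown element(s): ",
                              paste(unknown, collapse = ", "))
    refs[names(ref_energies)] <- ref_energies
  }

  structure(list(config = cfg, params = params, meta = meta,
                 ref_energies = refs, ff = ff),
            class = "nnp_model")
}

#' Number of trainable parameters
#'
#' @param model an `nnp_model`.
#' @return integer count over all weight matrices, biases, mixing
#'   coefficients and physics-module parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.nnp_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<nnp_model: %d scalar features, %d channels, l_max = %d, ",
                     "%d layers, r_c = %g A, %s parameters>\n"),
              cfg$n_scalar, cfg$n_channels, cfg$l_max, cfg$n_layers, cfg$r_c,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# parameter group membership, used by weight-decay and freezing policies
param_group <- function(name) {
  if (grepl("^head\\.", name)) return("output")
  if (grepl("^ff\\.", name)) return("physics")
  "embedding"
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single archive holding the hyperparameter config, all
#' named weight arrays, the reference-energy table and the physics
#' parameters. On load, array shapes are validated against the config.
#'
#' @param model an `nnp_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               ref_energies = model$ref_energies, ff = model$ff), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[names(ck$config) %in% names(model_config())])
  template <- nnp_model(cfg, seed = 1,
                        ff = do.call(ff_parameters, ck$ff))
  if (!setequal(names(template$params), names(ck$params))) {
    stop("checkpoint parameter names do not match the stored config")
  }
  for (nm in names(ck$params)) {
    if (!all(dim(template$params[[nm]]) == dim(ck$params[[nm]]))) {
      stop("checkpoint shape mismatch for parameter ", nm)
    }
  }
  template$params <- ck$params
  template$ref_energies <- ck$ref_energies
  template
}
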