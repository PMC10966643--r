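# User-facing encoder surface: per-complex node states and single message
# passes. forward_batch() in model.R inlines the same computations over
# concatenated batches for speed; test-egnn.R asserts that encode() equals
# init_states() followed by n_passes message_pass() applications, which keeps
# the two code paths pinned together.

#' Node states of a complex
#'
#' Scalar features are E(3)-invariant; directional features are sets of
#' 3-vectors that co-rotate with the input frame.
#'
#' @param scalar n_atoms x n_s matrix of invariant features.
#' @param dir n_atoms x n_f x 3 array of directional features.
#' @return a `node_states` object.
#' @export
node_states <- function(scalar, dir) {
  stopifnot(is.matrix(scalar), length(dim(dir)) == 3,
            nrow(scalar) == dim(dir)[1], dim(dir)[3] == 3)
  structure(list(scalar = scalar, dir = dir), class = "node_states")
}

#' @export
print.node_states <- function(x, ...) {
  cat(sprintf("<node_states: %d atoms, n_s = %d, n_f = %d>\n",
              nrow(x$scalar), ncol(x$scalar), dim(x$dir)[2]))
  invisible(x)
}

dir_to_mats <- function(dir) {
  d <- dim(dir)
  list(x = matrix(dir[, , 1], d[1], d[2]),
       y = matrix(dir[, , 2], d[1], d[2]),
       z = matrix(dir[, , 3], d[1], d[2]))
}

mats_to_dir <- function(Dx, Dy, Dz) {
  n <- nrow(Dx)
  arr <- array(0, c(n, ncol(Dx), 3))
  arr[, , 1] <- Dx
  arr[, , 2] <- Dy
  arr[, , 3] <- Dz
  arr
}

# The element embedding table implied by the embedding network parameters.
embedding_table <- function(params) {
  a1e <- silu(addbias(params[["emb.W1"]], params[["emb.b1"]]))
  addbias(a1e %*% params[["emb.W2"]], params[["emb.b2"]])
}

#' Initial node states from atomic identities
#'
#' Scalar features are the element embedding (a small dense network applied
#' to the one-hot atomic identity); directional features start at exactly
#' zero, so an atom with no neighbors keeps zero directional features through
#' any number of passes.
#'
#' @param elements integer atomic numbers (must be in `cfg$vocab`).
#' @param params model parameters (see [init_params()]).
#' @param cfg a [model_config()].
#' @return a [node_states()] object.
#' @export
init_states <- function(elements, params, cfg = model_config()) {
  zi <- match(as.integer(elements), cfg$vocab)
  if (anyNA(zi)) check_vocabulary(elements, cfg$vocab)
  tab <- embedding_table(params)
  n <- length(elements)
  node_states(tab[zi, , drop = FALSE],
              array(0, c(n, cfg$n_f, 3)))
}

# One synchronous equivariant message-passing update over given edges.
egnn_layer <- function(h, Dx, Dy, Dz, edges, rbf, u, W1, b1, W2, b2,
                       n_s, n_f) {
  n <- nrow(h)
  if (nrow(edges) == 0) return(list(h = h, Dx = Dx, Dy = Dy, Dz = Dz))
  i <- edges[, 1]
  j <- edges[, 2]
  nrm <- sqrt(Dx * Dx + Dy * Dy + Dz * Dz + .NRM_EPS)
  fe <- cbind(h[i, , drop = FALSE], h[j, , drop = FALSE], rbf,
              nrm[i, , drop = FALSE], nrm[j, , drop = FALSE])
  out <- addbias(silu(addbias(fe %*% W1, b1)) %*% W2, b2)
  m_s <- out[, seq_len(n_s), drop = FALSE]
  g_v <- out[, n_s + seq_len(n_f), drop = FALSE]
  g_d <- out[, n_s + n_f + seq_len(n_f), drop = FALSE]
  list(
    h = h + scatter_add(m_s, i, n),
    Dx = Dx + scatter_add(g_v * u[, 1] + g_d * Dx[j, , drop = FALSE], i, n),
    Dy = Dy + scatter_add(g_v * u[, 2] + g_d * Dy[j, , drop = FALSE], i, n),
    Dz = Dz + scatter_add(g_v * u[, 3] + g_d * Dz[j, , drop = FALSE], i, n)
  )
}

#' Apply one message-passing layer
#'
#' Scalar updates aggregate messages from neighbors within the same molecule;
#' directional updates aggregate gated unit interatomic vectors and gated
#' neighbor directional features. All message-network inputs are invariants
#' (scalars, Bessel-expanded distance, directional norms), so the update is
#' exactly E(3)-equivariant. Ligand and protein graphs share weights but
#' never exchange messages.
#'
#' @param states a [node_states()] for every atom of `x`.
#' @param graph a [build_graphs()] result for `x`.
#' @param x the [atomic_complex()] (coordinates supply edge directions).
#' @param params model parameters.
#' @param layer layer index (selects the layer's weights).
#' @param cfg a [model_config()].
#' @return updated [node_states()].
#' @export
message_pass <- function(states, graph, x, params, layer = 1,
                         cfg = model_config()) {
  stopifnot(inherits(states, "node_states"), layer >= 1,
            layer <= cfg$n_passes)
  if (nrow(states$scalar) != n_atoms(x)) {
    stop("states and complex disagree on atom count")
  }
  d <- dir_to_mats(states$dir)
  edges <- rbind(graph$ligand_edges, graph$protein_edges)
  rbf <- rbind(graph$rbf_lig, graph$rbf_pro)
  u <- if (nrow(edges) > 0) {
    dr <- x$coords[edges[, 1], , drop = FALSE] -
      x$coords[edges[, 2], , drop = FALSE]
    dr / pmax(sqrt(rowSums(dr * dr)), 1e-6)
  } else {
    matrix(0, 0, 3)
  }
  res <- egnn_layer(states$scalar, d$x, d$y, d$z, edges, rbf, u,
                    params[[paste0("msg", layer, ".W1")]],
                    params[[paste0("msg", layer, ".b1")]],
                    params[[paste0("msg", layer, ".W2")]],
                    params[[paste0("msg", layer, ".b2")]],
                    cfg$n_s, cfg$n_f)
  node_states(res$h, mats_to_dir(res$Dx, res$Dy, res$Dz))
}

#' Encode a complex into final node states
#'
#' [init_states()] followed by `n_passes` applications of [message_pass()].
#'
#' @param x an [atomic_complex()].
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @param graph optional precomputed [build_graphs()] result.
#' @return a [node_states()] object.
#' @export
encode <- function(x, params, cfg = model_config(), graph = NULL) {
  if (is.null(graph)) graph <- build_graphs(x, cfg$r_msg, cfg$r_pair,
                                            radial_basis_config(cfg$n_rbf,
                                                                cfg$r_msg,
                                                                cfg$envelope))
  states <- init_states(x$elements, params, cfg)
  for (l in seq_len(cfg$n_passes)) {
    states <- message_pass(states, graph, x, params, l, cfg)
  }
  states
}

#' Invariant feature vector of one ligand-protein atom pair
#'
#' Concatenation, ligand block first (the expression is deliberately not
#' symmetrized in i and j): scalar features of both atoms, the Bessel
#' expansion of the pair distance, magnitudes of both atoms' directional
#' features, the n_f scalar products between corresponding directional
#' features, and the cosine of the angle between corresponding directional
#' features (defined 0 when either vector's norm is below 1e-12). Length is
#' `2 n_s + n_rbf + 4 n_f`.
#'
#' @param state_i ligand-atom state: list/row with `scalar` (n_s) and `dir`
#'   (n_f x 3 matrix).
#' @param state_j protein-atom state, same layout.
#' @param r_ij pair distance, Angstrom (<= r_pair).
#' @param cfg a [model_config()].
#' @return numeric feature vector.
#' @export
pair_feature_vector <- function(state_i, state_j, r_ij, cfg = model_config()) {
  stopifnot(r_ij > 0, r_ij <= cfg$r_pair)
  rbf <- bessel_basis(r_ij, radial_basis_config(cfg$n_rbf, cfg$r_pair,
                                                cfg$envelope))[1, ]
  ss_i <- rowSums(state_i$dir^2)
  ss_j <- rowSums(state_j$dir^2)
  nrm_i <- sqrt(ss_i + .NRM_EPS)
  nrm_j <- sqrt(ss_j + .NRM_EPS)
  dotf <- rowSums(state_i$dir * state_j$dir)
  ok <- ss_i >= .NRM_EPS^2 & ss_j >= .NRM_EPS^2
  cosf <- ifelse(ok, dotf / (nrm_i * nrm_j), 0)
  c(state_i$scalar, state_j$scalar, rbf, nrm_i, nrm_j, dotf, cosf)
}

#' Per-ligand-atom free-energy contributions
#'
#' Each contribution is `c_L` times a small dense network of the atom's
#' scalar features, with weights shared across all atoms.
#'
#' @param states [node_states()] restricted to (or indexed at) ligand atoms.
#' @param params model parameters.
#' @param cfg a [model_config()].
#' @return numeric vector of pK contributions, one per atom in `states`.
#' @export
atomic_readout <- function(states, params, cfg = model_config()) {
  h <- states$scalar
  a1 <- silu(addbias(h %*% params[["atm.W1"]], params[["atm.b1"]]))
  a2 <- silu(addbias(a1 %*% params[["atm.W2"]], params[["atm.b2"]]))
  cfg$c_L * (drop(a2 %*% params[["atm.W3"]]) + params[["atm.b3"]])
}
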