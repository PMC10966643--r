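# Model definition: configuration, parameter initialization, the batched
# forward pass (embedding -> equivariant message passing -> atom and atom-pair
# readouts) and its hand-written reverse-mode gradients.
#
# Node states carry n_s invariant scalar features and n_f directional
# features, each a 3-vector, stored as three n_atoms x n_f matrices (one per
# Cartesian component) so every operation stays a dense matrix op. Message
# networks only ever see invariants (scalar features, the Bessel-expanded
# distance, and norms of directional features); directional states are built
# from gated unit interatomic vectors and gated neighbor vectors, which makes
# every scalar output exactly rotation/translation invariant and every
# directional feature exactly equivariant, by construction.

.NRM_EPS <- 1e-12 # inside sqrt: safe norms with zero gradient at zero vectors

#' Model configuration
#'
#' Architecture hyperparameters for the encoder and readouts. Defaults are
#' sized for single-CPU desk scale; reported accuracy for this architecture
#' family is convergent or insensitive to depth/width, so widths are kept
#' small.
#'
#' @param n_s scalar feature width per atom.
#' @param n_f number of directional (3-vector) features per atom.
#' @param n_passes number of message-passing layers.
#' @param n_rbf Bessel radial basis size.
#' @param r_msg intra-molecular message cutoff, Angstrom.
#' @param r_pair ligand-protein pair readout cutoff, Angstrom.
#' @param envelope smooth cutoff envelope order (0 disables).
#' @param msg_hidden hidden width of the per-edge message network.
#' @param readout_hidden hidden width of the two readout networks.
#' @param c_L fixed scaling constant on atomic readout contributions.
#' @param c_P fixed scaling constant on pair readout contributions.
#' @param vocab allowed atomic numbers (ordered embedding table rows).
#' @return object of class `eq_model_config`.
#' @export
model_config <- function(n_s = 16, n_f = 4, n_passes = 3, n_rbf = 8,
                         r_msg = 5, r_pair = 5, envelope = 5,
                         msg_hidden = 32, readout_hidden = 64,
                         c_L = 0.1, c_P = 0.1,
                         vocab = default_vocabulary()) {
  stopifnot(n_s >= 1, n_f >= 1, n_passes >= 1, n_rbf >= 1,
            r_msg > 0, r_pair > 0, msg_hidden >= 1, readout_hidden >= 1)
  structure(list(
    n_s = as.integer(n_s), n_f = as.integer(n_f),
    n_passes = as.integer(n_passes), n_rbf = as.integer(n_rbf),
    r_msg = r_msg, r_pair = r_pair, envelope = as.integer(envelope),
    msg_hidden = as.integer(msg_hidden),
    readout_hidden = as.integer(readout_hidden),
    c_L = c_L, c_P = c_P, vocab = as.integer(vocab)
  ), class = "eq_model_config")
}

# Fingerprint of the architecture-defining fields; checked before transfer
# learning or prediction so an incompatible checkpoint fails loudly.
config_hash <- function(cfg) {
  key <- paste(cfg$n_s, cfg$n_f, cfg$n_passes, cfg$n_rbf, cfg$r_msg,
               cfg$r_pair, cfg$envelope, cfg$msg_hidden, cfg$readout_hidden,
               cfg$c_L, cfg$c_P, paste(cfg$vocab, collapse = ","), sep = "|")
  h <- fnv1a(key)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

msg_dims <- function(cfg) {
  list(d_in = 2 * cfg$n_s + cfg$n_rbf + 2 * cfg$n_f,
       d_out = cfg$n_s + 2 * cfg$n_f)
}

pair_dim <- function(cfg) 2 * cfg$n_s + cfg$n_rbf + 4 * cfg$n_f

#' Initialize model parameters
#'
#' All dense layers get Glorot-style random weights except the output layers
#' of both readout networks, which are zero-initialized: a fresh model
#' therefore predicts exactly its shift parameter (set to the training-label
#' mean at training time) for any input.
#'
#' @param cfg an [model_config()].
#' @param seed integer seed (the caller's RNG state is untouched).
#' @return named list of parameter arrays.
#' @export
init_params <- function(cfg, seed = 1) {
  with_local_seed(seed, {
    V <- length(cfg$vocab)
    md <- msg_dims(cfg)
    w <- cfg$readout_hidden
    p <- list(
      emb.W1 = init_dense(V, cfg$n_s), emb.b1 = numeric(cfg$n_s),
      emb.W2 = init_dense(cfg$n_s, cfg$n_s), emb.b2 = numeric(cfg$n_s)
    )
    for (l in seq_len(cfg$n_passes)) {
      p[[paste0("msg", l, ".W1")]] <- init_dense(md$d_in, cfg$msg_hidden)
      p[[paste0("msg", l, ".b1")]] <- numeric(cfg$msg_hidden)
      p[[paste0("msg", l, ".W2")]] <- init_dense(cfg$msg_hidden, md$d_out)
      p[[paste0("msg", l, ".b2")]] <- numeric(md$d_out)
    }
    p <- c(p, list(
      atm.W1 = init_dense(cfg$n_s, w), atm.b1 = numeric(w),
      atm.W2 = init_dense(w, w), atm.b2 = numeric(w),
      atm.W3 = matrix(0, w, 1), atm.b3 = 0,
      par.W1 = init_dense(pair_dim(cfg), w), par.b1 = numeric(w),
      par.W2 = init_dense(w, w), par.b2 = numeric(w),
      par.W3 = matrix(0, w, 1), par.b3 = 0,
      shift = 0
    ))
    p
  })
}

# ---- batching --------------------------------------------------------------

# Concatenate a list of complexes into one disconnected batch graph.
# `coords_list` optionally overrides each complex's coordinates (online
# augmentation); in "ligand_only" mode protein atoms are dropped entirely.
build_batch <- function(complexes, cfg, mode = c("full", "ligand_only"),
                        coords_list = NULL) {
  mode <- match.arg(mode)
  rbf_cfg <- radial_basis_config(cfg$n_rbf, cfg$r_msg, cfg$envelope)
  nC <- length(complexes)
  acc <- list(z = vector("list", nC), edges = vector("list", nC),
              erbf = vector("list", nC), eu = vector("list", nC),
              pairs = vector("list", nC), prbf = vector("list", nC),
              pr = vector("list", nC), pcx = vector("list", nC),
              lig = vector("list", nC), lcx = vector("list", nC),
              lig_local = vector("list", nC),
              pair_local = vector("list", nC))
  offset <- 0L
  n_intra <- 0L
  n_cross <- 0L
  for (k in seq_len(nC)) {
    x <- complexes[[k]]
    co <- if (is.null(coords_list)) x$coords else coords_list[[k]]
    orig <- seq_along(x$elements)
    if (mode == "ligand_only") {
      keep <- which(x$membership == "ligand")
      x <- atomic_complex(x$elements[keep], co[keep, , drop = FALSE],
                          x$membership[keep], x$label, x$id)
      co <- x$coords
      orig <- keep
    } else if (!is.null(coords_list)) {
      x <- atomic_complex(x$elements, co, x$membership, x$label, x$id)
    }
    g <- build_graphs(x, cfg$r_msg, cfg$r_pair, rbf_cfg)
    e <- rbind(g$ligand_edges, g$protein_edges)
    erbf <- rbind(g$rbf_lig, g$rbf_pro)
    if (nrow(e) > 0) {
      dr <- co[e[, 1], , drop = FALSE] - co[e[, 2], , drop = FALSE]
      rr <- sqrt(rowSums(dr * dr))
      eu <- dr / pmax(rr, 1e-6)
    } else {
      eu <- matrix(0, 0, 3)
    }
    zi <- match(x$elements, cfg$vocab)
    if (anyNA(zi)) check_vocabulary(x$elements, cfg$vocab)
    li <- which(x$membership == "ligand")
    acc$z[[k]] <- zi
    acc$edges[[k]] <- e + offset
    acc$erbf[[k]] <- erbf
    acc$eu[[k]] <- eu
    acc$pairs[[k]] <- g$cross_pairs + offset
    acc$prbf[[k]] <- g$rbf_cross
    acc$pr[[k]] <- g$r_cross
    acc$pcx[[k]] <- rep(k, nrow(g$cross_pairs))
    acc$lig[[k]] <- li + offset
    acc$lcx[[k]] <- rep(k, length(li))
    acc$lig_local[[k]] <- orig[li]
    acc$pair_local[[k]] <- cbind(orig[g$cross_pairs[, 1]], orig[g$cross_pairs[, 2]])
    n_intra <- n_intra + nrow(e)
    n_cross <- n_cross + nrow(g$cross_pairs)
    offset <- offset + length(x$elements)
  }
  list(
    n_atoms = offset,
    n_complex = nC,
    z_idx = unlist(acc$z, use.names = FALSE),
    edges = do.call(rbind, acc$edges),
    edge_rbf = do.call(rbind, acc$erbf),
    edge_u = do.call(rbind, acc$eu),
    pairs = do.call(rbind, acc$pairs),
    pair_rbf = do.call(rbind, acc$prbf),
    pair_r = unlist(acc$pr, use.names = FALSE),
    pair_complex = unlist(acc$pcx, use.names = FALSE),
    lig_rows = unlist(acc$lig, use.names = FALSE),
    lig_complex = unlist(acc$lcx, use.names = FALSE),
    lig_local = unlist(acc$lig_local, use.names = FALSE),
    pair_local = do.call(rbind, acc$pair_local),
    labels = vapply(complexes, function(x) x$label, numeric(1)),
    ids = vapply(complexes, function(x) x$id, character(1)),
    mode = mode,
    n_intra_edges = n_intra,
    n_cross_pairs = n_cross
  )
}

# Number of per-edge network evaluations of one forward pass (the cost proxy
# behind the ligand-only speed claim).
edge_evaluations <- function(batch, cfg) {
  cfg$n_passes * batch$n_intra_edges + batch$n_cross_pairs
}

# ---- forward ---------------------------------------------------------------

# Returns per-complex totals and per-atom/per-pair contributions; with
# keep_cache = TRUE all intermediates needed by backward_batch are retained.
forward_batch <- function(params, batch, cfg, training = FALSE, dropout = 0,
                          keep_cache = FALSE) {
  n <- batch$n_atoms
  n_s <- cfg$n_s
  n_f <- cfg$n_f
  use_drop <- training && dropout > 0

  # element embedding (2-layer dense net applied to the one-hot table)
  z1e <- addbias(params[["emb.W1"]], params[["emb.b1"]])
  a1e <- silu(z1e)
  emb_table <- addbias(a1e %*% params[["emb.W2"]], params[["emb.b2"]])
  h <- emb_table[batch$z_idx, , drop = FALSE]
  Dx <- Dy <- Dz <- matrix(0, n, n_f)

  e_i <- batch$edges[, 1]
  e_j <- batch$edges[, 2]
  u <- batch$edge_u
  layer_caches <- if (keep_cache) vector("list", cfg$n_passes) else NULL

  for (l in seq_len(cfg$n_passes)) {
    W1 <- params[[paste0("msg", l, ".W1")]]
    b1 <- params[[paste0("msg", l, ".b1")]]
    W2 <- params[[paste0("msg", l, ".W2")]]
    b2 <- params[[paste0("msg", l, ".b2")]]
    nrm <- sqrt(Dx * Dx + Dy * Dy + Dz * Dz + .NRM_EPS)
    fe <- cbind(h[e_i, , drop = FALSE], h[e_j, , drop = FALSE], batch$edge_rbf,
                nrm[e_i, , drop = FALSE], nrm[e_j, , drop = FALSE])
    z1 <- addbias(fe %*% W1, b1)
    a1 <- silu(z1)
    out <- addbias(a1 %*% W2, b2)
    m_s <- out[, seq_len(n_s), drop = FALSE]
    g_v <- out[, n_s + seq_len(n_f), drop = FALSE]
    g_d <- out[, n_s + n_f + seq_len(n_f), drop = FALSE]
    if (keep_cache) {
      layer_caches[[l]] <- list(h = h, Dx = Dx, Dy = Dy, Dz = Dz, nrm = nrm,
                                fe = fe, z1 = z1, a1 = a1, g_d = g_d)
    }
    h <- h + scatter_add(m_s, e_i, n)
    Dx <- Dx + scatter_add(g_v * u[, 1] + g_d * Dx[e_j, , drop = FALSE], e_i, n)
    Dy <- Dy + scatter_add(g_v * u[, 2] + g_d * Dy[e_j, , drop = FALSE], e_i, n)
    Dz <- Dz + scatter_add(g_v * u[, 3] + g_d * Dz[e_j, , drop = FALSE], e_i, n)
  }

  ss <- Dx * Dx + Dy * Dy + Dz * Dz
  nrmF <- sqrt(ss + .NRM_EPS)

  # atomic readout over ligand atoms
  lig <- batch$lig_rows
  hl <- h[lig, , drop = FALSE]
  za1 <- addbias(hl %*% params[["atm.W1"]], params[["atm.b1"]])
  aa1 <- silu(za1)
  mask_a1 <- mask_a2 <- NULL
  if (use_drop) {
    mask_a1 <- matrix(stats::runif(length(aa1)) >= dropout, nrow(aa1))
    aa1 <- aa1 * mask_a1 / (1 - dropout)
  }
  za2 <- addbias(aa1 %*% params[["atm.W2"]], params[["atm.b2"]])
  aa2 <- silu(za2)
  if (use_drop) {
    mask_a2 <- matrix(stats::runif(length(aa2)) >= dropout, nrow(aa2))
    aa2 <- aa2 * mask_a2 / (1 - dropout)
  }
  atom_contrib <- cfg$c_L * (drop(aa2 %*% params[["atm.W3"]]) + params[["atm.b3"]])

  # pair readout over ligand-protein cross pairs
  P <- if (is.null(batch$pairs)) 0L else nrow(batch$pairs)
  pair_cache <- NULL
  mask_p1 <- mask_p2 <- NULL
  if (P > 0) {
    p_i <- batch$pairs[, 1]
    p_j <- batch$pairs[, 2]
    Dxi <- Dx[p_i, , drop = FALSE]; Dxj <- Dx[p_j, , drop = FALSE]
    Dyi <- Dy[p_i, , drop = FALSE]; Dyj <- Dy[p_j, , drop = FALSE]
    Dzi <- Dz[p_i, , drop = FALSE]; Dzj <- Dz[p_j, , drop = FALSE]
    dotf <- Dxi * Dxj + Dyi * Dyj + Dzi * Dzj
    nrm_i <- nrmF[p_i, , drop = FALSE]
    nrm_j <- nrmF[p_j, , drop = FALSE]
    mask <- (ss[p_i, , drop = FALSE] >= .NRM_EPS^2) &
      (ss[p_j, , drop = FALSE] >= .NRM_EPS^2)
    inv <- matrix(0, P, n_f)
    inv[mask] <- 1 / (nrm_i * nrm_j)[mask]
    cosf <- dotf * inv
    fp <- cbind(h[p_i, , drop = FALSE], h[p_j, , drop = FALSE], batch$pair_rbf,
                nrm_i, nrm_j, dotf, cosf)
    zp1 <- addbias(fp %*% params[["par.W1"]], params[["par.b1"]])
    ap1 <- silu(zp1)
    if (use_drop) {
      mask_p1 <- matrix(stats::runif(length(ap1)) >= dropout, nrow(ap1))
      ap1 <- ap1 * mask_p1 / (1 - dropout)
    }
    zp2 <- addbias(ap1 %*% params[["par.W2"]], params[["par.b2"]])
    ap2 <- silu(zp2)
    if (use_drop) {
      mask_p2 <- matrix(stats::runif(length(ap2)) >= dropout, nrow(ap2))
      ap2 <- ap2 * mask_p2 / (1 - dropout)
    }
    pair_contrib <- cfg$c_P * (drop(ap2 %*% params[["par.W3"]]) + params[["par.b3"]])
    if (keep_cache) {
      pair_cache <- list(fp = fp, zp1 = zp1, ap1 = ap1, zp2 = zp2, ap2 = ap2,
                         dotf = dotf, cosf = cosf, inv = inv,
                         nrm_i = nrm_i, nrm_j = nrm_j,
                         mask_p1 = mask_p1, mask_p2 = mask_p2)
    }
  } else {
    pair_contrib <- numeric(0)
  }

  total <- rep(params[["shift"]], batch$n_complex)
  if (length(lig) > 0) {
    total <- total + drop(scatter_add(matrix(atom_contrib, ncol = 1),
                                      batch$lig_complex, batch$n_complex))
  }
  if (P > 0) {
    total <- total + drop(scatter_add(matrix(pair_contrib, ncol = 1),
                                      batch$pair_complex, batch$n_complex))
  }

  cache <- NULL
  if (keep_cache) {
    cache <- list(z1e = z1e, a1e = a1e, layers = layer_caches,
                  h = h, Dx = Dx, Dy = Dy, Dz = Dz, ss = ss, nrmF = nrmF,
                  hl = hl, za1 = za1, aa1 = aa1, za2 = za2, aa2 = aa2,
                  mask_a1 = mask_a1, mask_a2 = mask_a2,
                  pair = pair_cache, dropout = if (use_drop) dropout else 0)
  }

  list(total = total, atom_contrib = atom_contrib, pair_contrib = pair_contrib,
       scalars = h, dir = list(x = Dx, y = Dy, z = Dz),
       n_edge_evals = edge_evaluations(batch, cfg), cache = cache)
}

# ---- backward --------------------------------------------------------------

# Gradients of a scalar loss with respect to every parameter, given
# dL/d(total) per complex and the forward cache.
backward_batch <- function(params, batch, cfg, fwd, dtotal) {
  cache <- fwd$cache
  if (is.null(cache)) stop("forward_batch must be run with keep_cache = TRUE")
  n <- batch$n_atoms
  n_s <- cfg$n_s
  n_f <- cfg$n_f
  n_rbf <- cfg$n_rbf
  drp <- cache$dropout
  grads <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  grads[["shift"]] <- sum(dtotal)

  dh <- matrix(0, n, n_s)
  dDx <- dDy <- dDz <- matrix(0, n, n_f)

  # atomic readout backward
  lig <- batch$lig_rows
  if (length(lig) > 0) {
    douta <- cfg$c_L * dtotal[batch$lig_complex]
    grads[["atm.b3"]] <- sum(douta)
    grads[["atm.W3"]] <- crossprod(cache$aa2, matrix(douta, ncol = 1))
    daa2 <- matrix(douta, ncol = 1) %*% t(params[["atm.W3"]])
    if (!is.null(cache$mask_a2)) daa2 <- daa2 * cache$mask_a2 / (1 - drp)
    dza2 <- daa2 * dsilu(cache$za2)
    grads[["atm.W2"]] <- crossprod(cache$aa1, dza2)
    grads[["atm.b2"]] <- colSums(dza2)
    daa1 <- dza2 %*% t(params[["atm.W2"]])
    if (!is.null(cache$mask_a1)) daa1 <- daa1 * cache$mask_a1 / (1 - drp)
    dza1 <- daa1 * dsilu(cache$za1)
    grads[["atm.W1"]] <- crossprod(cache$hl, dza1)
    grads[["atm.b1"]] <- colSums(dza1)
    dh <- dh + scatter_add(dza1 %*% t(params[["atm.W1"]]), lig, n)
  }

  # pair readout backward
  P <- if (is.null(batch$pairs)) 0L else nrow(batch$pairs)
  if (P > 0) {
    pc <- cache$pair
    p_i <- batch$pairs[, 1]
    p_j <- batch$pairs[, 2]
    doutp <- cfg$c_P * dtotal[batch$pair_complex]
    grads[["par.b3"]] <- sum(doutp)
    grads[["par.W3"]] <- crossprod(pc$ap2, matrix(doutp, ncol = 1))
    dap2 <- matrix(doutp, ncol = 1) %*% t(params[["par.W3"]])
    if (!is.null(pc$mask_p2)) dap2 <- dap2 * pc$mask_p2 / (1 - drp)
    dzp2 <- dap2 * dsilu(pc$zp2)
    grads[["par.W2"]] <- crossprod(pc$ap1, dzp2)
    grads[["par.b2"]] <- colSums(dzp2)
    dap1 <- dzp2 %*% t(params[["par.W2"]])
    if (!is.null(pc$mask_p1)) dap1 <- dap1 * pc$mask_p1 / (1 - drp)
    dzp1 <- dap1 * dsilu(pc$zp1)
    grads[["par.W1"]] <- crossprod(pc$fp, dzp1)
    grads[["par.b1"]] <- colSums(dzp1)
    dfp <- dzp1 %*% t(params[["par.W1"]])

    ofs <- 0L
    take <- function(k) {
      cols <- ofs + seq_len(k)
      ofs <<- ofs + k
      dfp[, cols, drop = FALSE]
    }
    dh_i <- take(n_s)
    dh_j <- take(n_s)
    take(n_rbf) # distance basis: no trainable inputs upstream
    dnrm_i <- take(n_f)
    dnrm_j <- take(n_f)
    ddot <- take(n_f)
    dcos <- take(n_f)

    dh <- dh + scatter_add(dh_i, p_i, n) + scatter_add(dh_j, p_j, n)
    # cos = dot * inv, inv = mask / (|i||j|)
    ddot <- ddot + dcos * pc$inv
    dnrm_i <- dnrm_i - dcos * pc$cosf / pc$nrm_i
    dnrm_j <- dnrm_j - dcos * pc$cosf / pc$nrm_j
    # dot flows to the directional features of both atoms
    Dx <- cache$Dx; Dy <- cache$Dy; Dz <- cache$Dz
    dDx <- dDx + scatter_add(ddot * Dx[p_j, , drop = FALSE], p_i, n) +
      scatter_add(ddot * Dx[p_i, , drop = FALSE], p_j, n)
    dDy <- dDy + scatter_add(ddot * Dy[p_j, , drop = FALSE], p_i, n) +
      scatter_add(ddot * Dy[p_i, , drop = FALSE], p_j, n)
    dDz <- dDz + scatter_add(ddot * Dz[p_j, , drop = FALSE], p_i, n) +
      scatter_add(ddot * Dz[p_i, , drop = FALSE], p_j, n)
    # norms flow to directional features node-wise
    dnrm_node <- scatter_add(dnrm_i, p_i, n) + scatter_add(dnrm_j, p_j, n)
    dDx <- dDx + dnrm_node * Dx / cache$nrmF
    dDy <- dDy + dnrm_node * Dy / cache$nrmF
    dDz <- dDz + dnrm_node * Dz / cache$nrmF
  }

  # message layers, reverse order
  e_i <- batch$edges[, 1]
  e_j <- batch$edges[, 2]
  u <- batch$edge_u
  for (l in rev(seq_len(cfg$n_passes))) {
    lc <- cache$layers[[l]]
    if (length(e_i) == 0) next
    W1 <- params[[paste0("msg", l, ".W1")]]
    W2 <- params[[paste0("msg", l, ".W2")]]
    dhi_e <- dh[e_i, , drop = FALSE]
    dDxi <- dDx[e_i, , drop = FALSE]
    dDyi <- dDy[e_i, , drop = FALSE]
    dDzi <- dDz[e_i, , drop = FALSE]
    dgv <- dDxi * u[, 1] + dDyi * u[, 2] + dDzi * u[, 3]
    dgd <- dDxi * lc$Dx[e_j, , drop = FALSE] +
      dDyi * lc$Dy[e_j, , drop = FALSE] +
      dDzi * lc$Dz[e_j, , drop = FALSE]
    # gated-neighbor path into the layer-input directional states
    dDx <- dDx + scatter_add(lc$g_d * dDxi, e_j, n)
    dDy <- dDy + scatter_add(lc$g_d * dDyi, e_j, n)
    dDz <- dDz + scatter_add(lc$g_d * dDzi, e_j, n)
    dout <- cbind(dhi_e, dgv, dgd)
    grads[[paste0("msg", l, ".W2")]] <- crossprod(lc$a1, dout)
    grads[[paste0("msg", l, ".b2")]] <- colSums(dout)
    da1 <- dout %*% t(W2)
    dz1 <- da1 * dsilu(lc$z1)
    grads[[paste0("msg", l, ".W1")]] <- crossprod(lc$fe, dz1)
    grads[[paste0("msg", l, ".b1")]] <- colSums(dz1)
    dfe <- dz1 %*% t(W1)
    dh <- dh + scatter_add(dfe[, seq_len(n_s), drop = FALSE], e_i, n) +
      scatter_add(dfe[, n_s + seq_len(n_s), drop = FALSE], e_j, n)
    nrm_cols_i <- 2 * n_s + n_rbf + seq_len(n_f)
    nrm_cols_j <- 2 * n_s + n_rbf + n_f + seq_len(n_f)
    dnrm_l <- scatter_add(dfe[, nrm_cols_i, drop = FALSE], e_i, n) +
      scatter_add(dfe[, nrm_cols_j, drop = FALSE], e_j, n)
    dDx <- dDx + dnrm_l * lc$Dx / lc$nrm
    dDy <- dDy + dnrm_l * lc$Dy / lc$nrm
    dDz <- dDz + dnrm_l * lc$Dz / lc$nrm
  }

  # embedding backward
  V <- length(cfg$vocab)
  dtable <- scatter_add(dh, batch$z_idx, V)
  grads[["emb.W2"]] <- crossprod(cache$a1e, dtable)
  grads[["emb.b2"]] <- colSums(dtable)
  da1e <- dtable %*% t(params[["emb.W2"]])
  dz1e <- da1e * dsilu(cache$z1e)
  grads[["emb.W1"]] <- dz1e
  grads[["emb.b1"]] <- colSums(dz1e)

  grads
}

# ---- prediction ------------------------------------------------------------

#' Predict the pK of one complex with a full contribution breakdown
#'
#' @param ckpt an `eq_checkpoint` (from [train_direct()] and friends).
#' @param x an [atomic_complex()].
#' @param mode `"full"` (atom + pair readouts) or `"ligand_only"` (atomic
#'   readout over the ligand graph only; protein atoms may be absent).
#' @return a `prediction_breakdown`: list with `id`, `total`, `shift`,
#'   `atom_contribs` (per ligand atom, named by atom index) and
#'   `pair_contribs` (data.frame `i`, `j`, `r_ij`, `value`).
#' @export
predict_complex <- function(ckpt, x, mode = c("full", "ligand_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ckpt, "eq_checkpoint"), inherits(x, "atomic_complex"))
  if (sum(x$membership == "ligand") == 0) stop("complex has no ligand atoms")
  batch <- build_batch(list(x), ckpt$cfg, mode)
  fwd <- forward_batch(ckpt$params, batch, ckpt$cfg)
  pc <- if (length(fwd$pair_contrib) > 0) {
    data.frame(i = batch$pair_local[, 1], j = batch$pair_local[, 2],
               r_ij = batch$pair_r, value = fwd$pair_contrib)
  } else {
    data.frame(i = integer(), j = integer(), r_ij = numeric(), value = numeric())
  }
  structure(list(
    id = x$id, total = fwd$total[1], shift = ckpt$params[["shift"]],
    atom_contribs = stats::setNames(fwd$atom_contrib,
                                    as.character(batch$lig_local)),
    pair_contribs = pc, mode = mode
  ), class = "prediction_breakdown")
}

#' @export
print.prediction_breakdown <- function(x, ...) {
  cat(sprintf("<prediction '%s' [%s]: total pK = %.4f (shift %.4f, %d atoms, %d pairs)>\n",
              x$id, x$mode, x$total, x$shift, length(x$atom_contribs),
              nrow(x$pair_contribs)))
  invisible(x)
}

# Batched totals for a list of complexes under a checkpoint or ensemble.
# Ensembles return the member mean; `sd` carries the ensemble spread.
predict_dataset <- function(model, complexes, mode = NULL, chunk = 256) {
  if (inherits(model, "eq_ensemble")) {
    member_preds <- vapply(model$members, function(m) {
      predict_dataset(m, complexes, mode = mode, chunk = chunk)$pred
    }, numeric(length(complexes)))
    if (length(complexes) == 1) member_preds <- matrix(member_preds, nrow = 1)
    return(data.frame(
      id = vapply(complexes, function(x) x$id, character(1)),
      pred = rowMeans(member_preds),
      sd = apply(member_preds, 1, stats::sd)
    ))
  }
  stopifnot(inherits(model, "eq_checkpoint"))
  if (is.null(mode)) mode <- model$mode %||% "full"
  idx_chunks <- split(seq_along(complexes),
                      ceiling(seq_along(complexes) / chunk))
  preds <- unlist(lapply(idx_chunks, function(ix) {
    batch <- build_batch(complexes[ix], model$cfg, mode)
    forward_batch(model$params, batch, model$cfg)$total
  }), use.names = FALSE)
  data.frame(id = vapply(complexes, function(x) x$id, character(1)),
             pred = preds, sd = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- checkpoints -----------------------------------------------------------

new_checkpoint <- function(params, cfg, label_mean, seed, mode = "full",
                           fold = NA_integer_, loss_history = numeric(),
                           optimizer = NULL) {
  structure(list(params = params, cfg = cfg, label_mean = label_mean,
                 seed = seed, mode = mode, fold = fold,
                 config_hash = config_hash(cfg),
                 loss_history = loss_history, optimizer = optimizer),
            class = "eq_checkpoint")
}

#' @export
print.eq_checkpoint <- function(x, ...) {
  cat(sprintf("<eq_checkpoint: hash %s, shift %.4f, %d params tensors%s>\n",
              x$config_hash, x$params[["shift"]], length(x$params),
              if (is.na(x$fold)) "" else sprintf(", fold %d", x$fold)))
  invisible(x)
}

#' Save a checkpoint as portable JSON
#'
#' Arrays are stored as hex-float strings so reloaded parameters are
#' bit-identical and predictions reproduce exactly. Optimizer state is not
#' serialized: continued training (transfer learning) always restarts with
#' fresh momenta.
#'
#' @param ckpt an `eq_checkpoint`.
#' @param path output path.
#' @export
save_checkpoint <- function(ckpt, path) {
  ser <- lapply(ckpt$params, function(p) {
    list(dims = if (is.matrix(p)) dim(p) else length(p),
         data = sprintf("%a", as.numeric(p)))
  })
  obj <- list(
    format = "eqbind-checkpoint-1",
    version = as.character(utils::packageVersion("eqbind")),
    config = unclass(ckpt$cfg),
    config_hash = ckpt$config_hash,
    label_mean = ckpt$label_mean,
    seed = ckpt$seed,
    mode = ckpt$mode,
    fold = ckpt$fold,
    loss_history = ckpt$loss_history,
    params = ser
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint JSON path.
#' @return an `eq_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "eqbind-checkpoint-1") {
    stop("not an eqbind checkpoint: ", path)
  }
  cfgl <- obj$config
  cfg <- model_config(cfgl$n_s, cfgl$n_f, cfgl$n_passes, cfgl$n_rbf,
                      cfgl$r_msg, cfgl$r_pair, cfgl$envelope,
                      cfgl$msg_hidden, cfgl$readout_hidden,
                      cfgl$c_L, cfgl$c_P, cfgl$vocab)
  params <- lapply(obj$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dims) == 2) matrix(v, p$dims[1], p$dims[2]) else v
  })
  ck <- new_checkpoint(params, cfg, obj$label_mean, obj$seed,
                       mode = obj$mode %||% "full",
                       fold = if (is.null(obj$fold) || is.na(obj$fold)) NA_integer_ else obj$fold,
                       loss_history = as.numeric(obj$loss_history))
  if (ck$config_hash != obj$config_hash) {
    stop("checkpoint config hash mismatch (corrupted file?): ", path)
  }
  ck
}
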