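# Numerical primitives shared by the encoder, readouts and optimizer:
# activations, scatter-add aggregation, parameter initialization, Adam, a
# small string hash for config fingerprints, and seed fan-out.

sigmoid <- function(z) 1 / (1 + exp(-z))

silu <- function(z) z * sigmoid(z)

# d silu / d z = sigma(z) * (1 + z * (1 - sigma(z)))
dsilu <- function(z) {
  s <- sigmoid(z)
  s * (1 + z * (1 - s))
}

# Fast column-wise bias add (sweep() pays an aperm on every call).
addbias <- function(M, b) M + rep(b, each = nrow(M))

# Sum rows of M into an n-row matrix by integer destination index.
scatter_add <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  if (length(idx) == 0) return(out)
  rs <- rowsum(M, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Glorot-style normal initialization for a dense weight matrix.
init_dense <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  list(m = zero_like, v = zero_like, t = 0L)
}

# One Adam step with linear learning-rate warm-up over `warmup` steps.
adam_step <- function(params, grads, state, lr, warmup = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  lr_t <- if (warmup > 0) lr * min(1, t / warmup) else lr
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- hashing & seeds -------------------------------------------------------

# 32-bit FNV-1a over the bytes of a string, in double arithmetic.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- (h - (h %% 256)) + bitwXor(as.integer(h %% 256), b)
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

# Deterministically derive a 31-bit sub-seed for a named random stream.
derive_seed <- function(seed, tag) {
  as.integer(fnv1a(paste0(seed, "/", tag)) %% 2147483629 + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
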