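# Shared fixtures and helpers for the suite.
#
# .shared is a lazy cache for the two expensive artifacts (the parameter
# recovery model and its datasets) reused across acceptance tests.

.shared <- new.env(parent = emptyenv())

# Small architecture used by most unit tests (fast; n_s = 8 / n_f = 4 also
# matches the documented pair-feature length example).
tiny_cfg <- function(...) {
  defaults <- list(n_s = 8, n_f = 4, n_rbf = 8, msg_hidden = 12,
                   readout_hidden = 10)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Parameters with randomized (non-zero) readout output layers so gradients
# and contributions are non-trivial.
live_params <- function(cfg, seed = 99) {
  p <- init_params(cfg, seed)
  set.seed(seed + 1)
  p[["atm.W3"]][] <- rnorm(length(p[["atm.W3"]]), sd = 0.3)
  p[["par.W3"]][] <- rnorm(length(p[["par.W3"]]), sd = 0.3)
  p[["atm.b3"]] <- 0.05
  p[["par.b3"]] <- -0.07
  p[["shift"]] <- 5.5
  p
}

live_checkpoint <- function(cfg = tiny_cfg(), seed = 99) {
  eqbind:::new_checkpoint(live_params(cfg, seed), cfg, label_mean = 5.5,
                          seed = seed)
}

# A deterministic mid-sized test complex.
fixture_complex <- function(seed = 1, n_protein = 12, n_ligand = 6) {
  make_complex(n_protein, n_ligand, seed = seed)
}

# Uniform random rotation matrix (det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_motion <- function(x, R, shift_vec) {
  atomic_complex(x$elements, sweep(x$coords %*% t(R), 2, shift_vec, "+"),
                 x$membership, x$label, x$id)
}

# Noise-free oracle used wherever exact labels matter.
exact_oracle <- function() oracle_params(sigma = 0)

# Append a shell of protein atoms at distance [r_min, r_max] from `center`.
with_far_shell <- function(x, center, n, r_min, r_max, seed = 1) {
  set.seed(seed)
  d <- matrix(rnorm(3 * n), n, 3)
  d <- d / sqrt(rowSums(d * d))
  shell <- sweep(d * runif(n, r_min, r_max), 2, center, "+")
  atomic_complex(c(x$elements, rep(6L, n)), rbind(x$coords, shell),
                 c(x$membership, rep("protein", n)), x$label, x$id)
}

path_to_fixture <- function(name) {
  system.file("extdata", name, package = "eqbind", mustWork = TRUE)
}
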