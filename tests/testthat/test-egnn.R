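# Encoder: initialization, equivariance, locality, permutation symmetry.

test_that("init_states embeds by element and zeroes directional features", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  s <- init_states(c(6L, 7L, 6L), p, cfg)
  expect_identical(s$scalar[1, ], s$scalar[3, ]) # equal Z -> identical rows
  expect_false(isTRUE(all.equal(s$scalar[1, ], s$scalar[2, ]))) # C vs N differ
  expect_true(all(s$dir == 0))
  expect_error(init_states(118L, p, cfg), "vocabulary")
})

test_that("encode equals init_states + repeated message_pass (pinning test)", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  x <- fixture_complex(seed = 10)
  g <- build_graphs(x, cfg$r_msg, cfg$r_pair,
                    radial_basis_config(cfg$n_rbf, cfg$r_msg, cfg$envelope))
  s <- init_states(x$elements, p, cfg)
  for (l in seq_len(cfg$n_passes)) s <- message_pass(s, g, x, p, l, cfg)
  e <- encode(x, p, cfg)
  expect_equal(e$scalar, s$scalar, tolerance = 1e-12)
  expect_equal(e$dir, s$dir, tolerance = 1e-12)

  # and both agree with the batched forward pass used in training
  b <- eqbind:::build_batch(list(x), cfg)
  f <- eqbind:::forward_batch(p, b, cfg)
  expect_equal(f$scalars, e$scalar, tolerance = 1e-12)
  expect_equal(f$dir$x, matrix(e$dir[, , 1], nrow(e$scalar)), tolerance = 1e-12)
})

test_that("scalars are E(3)-invariant and directional features equivariant", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  for (s in 1:12) {
    set.seed(s)
    x <- fixture_complex(seed = s, n_protein = 10, n_ligand = 5)
    e0 <- encode(x, p, cfg)
    R <- random_rotation()
    tv <- runif(3, -20, 20)
    er <- encode(rigid_motion(x, R, tv), p, cfg)
    expect_lt(max(abs(er$scalar - e0$scalar)) / max(1, max(abs(e0$scalar))),
              1e-5)
    for (a in seq_len(n_atoms(x))) {
      v0 <- matrix(e0$dir[a, , ], cfg$n_f, 3) %*% t(R)
      vr <- matrix(er$dir[a, , ], cfg$n_f, 3)
      expect_lt(max(abs(v0 - vr)), 1e-5 * max(1, max(abs(v0))))
    }
  }
})

test_that("pure translation changes nothing beyond float reassociation", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  x <- fixture_complex(seed = 2)
  e0 <- encode(x, p, cfg)
  et <- encode(rigid_motion(x, diag(3), c(10, -3, 7)), p, cfg)
  expect_lt(max(abs(e0$scalar - et$scalar)), 1e-6)
  expect_lt(max(abs(e0$dir - et$dir)), 1e-6)
})

test_that("an isolated atom keeps zero directional features", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  # one ligand atom 100 Angstrom from a protein blob: no edges touch it
  x <- make_complex(8, 3, seed = 5)
  far <- atomic_complex(c(x$elements, 6L),
                        rbind(x$coords, c(100, 100, 100)),
                        c(x$membership, "ligand"))
  e <- encode(far, p, cfg)
  expect_true(all(e$dir[n_atoms(far), , ] == 0))
})

test_that("protein removal never changes ligand states (disconnection)", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  x <- fixture_complex(seed = 6, n_protein = 14, n_ligand = 6)
  li <- which(x$membership == "ligand")
  e_full <- encode(x, p, cfg)
  lig_only <- atomic_complex(x$elements[li], x$coords[li, ], x$membership[li])
  e_lig <- encode(lig_only, p, cfg)
  expect_equal(e_full$scalar[li, ], e_lig$scalar, tolerance = 1e-12)
  expect_equal(e_full$dir[li, , ], e_lig$dir, tolerance = 1e-12)
})

test_that("permuting atom storage order permutes encoder output rows", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  x <- fixture_complex(seed = 11)
  set.seed(1)
  perm <- sample(n_atoms(x))
  xp <- atomic_complex(x$elements[perm], x$coords[perm, ], x$membership[perm])
  e0 <- encode(x, p, cfg)
  ep <- encode(xp, p, cfg)
  expect_equal(ep$scalar, e0$scalar[perm, ], tolerance = 1e-9)
  expect_equal(ep$dir, e0$dir[perm, , ], tolerance = 1e-9)
})

test_that("atoms beyond the receptive field cannot influence ligand states", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  x <- make_complex(10, 5, seed = 21)
  # receptive field for ligand states is n_passes * r_msg = 15 Angstrom;
  # append a protein atom chain beyond 16 Angstrom from every ligand atom
  centroid <- colMeans(x$coords[x$membership == "ligand", ])
  extra <- sweep(matrix(c(17, 0, 0, 18, 0, 0), 2, 3, byrow = TRUE), 2,
                 centroid, "+")
  xa <- atomic_complex(c(x$elements, 6L, 6L), rbind(x$coords, extra),
                       c(x$membership, "protein", "protein"))
  li <- which(x$membership == "ligand")
  e0 <- encode(x, p, cfg)
  ea <- encode(xa, p, cfg)
  expect_lt(max(abs(ea$scalar[li, ] - e0$scalar[li, ])), 1e-6)
  expect_lt(max(abs(ea$dir[li, , ] - e0$dir[li, , ])), 1e-6)
})

test_that("near-coincident atoms give finite outputs (distance floor)", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  co <- rbind(c(0, 0, 0), c(0, 0, 1e-9), c(1.5, 0, 0))
  expect_message(
    e <- encode(atomic_complex(c(6, 6, 7), co, rep("ligand", 3)), p, cfg),
    "floored")
  expect_true(all(is.finite(e$scalar)) && all(is.finite(e$dir)))
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(n_s = 6, n_f = 3, n_rbf = 5, msg_hidden = 7,
                      readout_hidden = 6, n_passes = 2)
  p <- live_params(cfg, seed = 13)
  ds <- make_global_dataset(2, seed = 31, params = exact_oracle())
  b <- eqbind:::build_batch(ds, cfg)
  y <- vapply(ds, function(x) x$label, numeric(1))
  lossfn <- function(pp) {
    mean((eqbind:::forward_batch(pp, b, cfg)$total - y)^2)
  }
  fwd <- eqbind:::forward_batch(p, b, cfg, keep_cache = TRUE)
  gr <- eqbind:::backward_batch(p, b, cfg, fwd,
                                2 * (fwd$total - y) / length(y))
  set.seed(5)
  for (nm in names(p)) {
    for (ix in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      eps <- 1e-5
      pp <- p
      pp[[nm]][ix] <- pp[[nm]][ix] + eps
      lp <- lossfn(pp)
      pp[[nm]][ix] <- pp[[nm]][ix] - 2 * eps
      lm <- lossfn(pp)
      fd <- (lp - lm) / (2 * eps)
      an <- gr[[nm]][ix]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-3,
                label = sprintf("gradient of %s[%d] (fd %.3e vs an %.3e)",
                                nm, ix, fd, an))
    }
  }
})
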