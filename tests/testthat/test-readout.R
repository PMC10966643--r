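# Readout: breakdown conservation, pair features, invariance, locality.

test_that("a fresh model predicts exactly the training-label mean", {
  cfg <- tiny_cfg()
  p <- init_params(cfg, seed = 1) # zero-initialized readout output layers
  p[["shift"]] <- mean(c(5, 6, 7))
  ck <- eqbind:::new_checkpoint(p, cfg, label_mean = 6, seed = 1)
  for (s in 1:3) {
    b <- predict_complex(ck, fixture_complex(seed = s))
    expect_identical(b$total, 6)
    expect_true(all(b$atom_contribs == 0))
    expect_true(all(b$pair_contribs$value == 0))
  }
})

test_that("the breakdown is conserved: total = shift + atoms + pairs", {
  ck <- live_checkpoint()
  for (s in 1:5) {
    x <- fixture_complex(seed = s)
    b <- predict_complex(ck, x)
    expect_equal(b$total,
                 b$shift + sum(b$atom_contribs) + sum(b$pair_contribs$value),
                 tolerance = 1e-6)
    expect_gt(nrow(b$pair_contribs), 0)
    # pair distances in the breakdown are within the cutoff
    expect_true(all(b$pair_contribs$r_ij <= ck$cfg$r_pair))
  }
})

test_that("a distant ligand yields no pair contributions", {
  ck <- live_checkpoint()
  x <- make_complex(10, 4, seed = 2)
  li <- which(x$membership == "ligand")
  co <- x$coords
  co[li, ] <- co[li, ] + 100
  far <- atomic_complex(x$elements, co, x$membership)
  b <- predict_complex(ck, far)
  expect_equal(nrow(b$pair_contribs), 0)
  expect_equal(b$total, b$shift + sum(b$atom_contribs), tolerance = 1e-9)
})

test_that("ligand-only mode drops pairs and needs fewer edge evaluations", {
  ck <- live_checkpoint()
  x <- fixture_complex(seed = 9)
  bl <- predict_complex(ck, x, mode = "ligand_only")
  expect_equal(nrow(bl$pair_contribs), 0)
  bfull <- eqbind:::build_batch(list(x), ck$cfg, "full")
  blig <- eqbind:::build_batch(list(x), ck$cfg, "ligand_only")
  expect_lt(eqbind:::edge_evaluations(blig, ck$cfg),
            eqbind:::edge_evaluations(bfull, ck$cfg))
  # ligand-only works without any protein atoms at all
  lig <- make_complex(0, 5, seed = 4)
  expect_s3_class(predict_complex(ck, lig, mode = "ligand_only"),
                  "prediction_breakdown")
})

test_that("predicted totals are invariant under random rigid motions", {
  ck <- live_checkpoint()
  x <- fixture_complex(seed = 12)
  t0 <- predict_complex(ck, x)$total
  set.seed(3)
  for (k in 1:10) {
    xr <- rigid_motion(x, random_rotation(), runif(3, -50, 50))
    expect_lt(abs(predict_complex(ck, xr)$total - t0), 1e-5)
  }
})

test_that("atomic readout scales linearly in c_L and sees only scalars", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  x <- fixture_complex(seed = 7)
  st <- encode(x, p, cfg)
  li <- which(x$membership == "ligand")
  lig_states <- node_states(st$scalar[li, , drop = FALSE],
                            st$dir[li, , , drop = FALSE])
  a1 <- atomic_readout(lig_states, p, cfg)
  cfg2 <- tiny_cfg(c_L = 2 * cfg$c_L)
  expect_equal(atomic_readout(lig_states, p, cfg2), 2 * a1, tolerance = 1e-12)
  # zeroing directional features changes nothing
  lig_states$dir[] <- 0
  expect_equal(atomic_readout(lig_states, p, cfg), a1, tolerance = 1e-12)
})

test_that("pair feature vector has the documented layout and identities", {
  cfg <- tiny_cfg() # n_s = 8, n_f = 4, n_rbf = 8
  set.seed(8)
  si <- list(scalar = rnorm(8), dir = matrix(rnorm(12), 4, 3))
  sj <- list(scalar = rnorm(8), dir = matrix(rnorm(12), 4, 3))
  v <- pair_feature_vector(si, sj, r_ij = 3.2, cfg)
  expect_length(v, 2 * 8 + 8 + 2 * 4 + 4 + 4) # = 40
  nrm_i <- v[25:28]; nrm_j <- v[29:32]; dotf <- v[33:36]; cosf <- v[37:40]
  # cosine definition: dot = cos * |i| * |j|
  expect_equal(dotf, cosf * nrm_i * nrm_j, tolerance = 1e-6)
  # ligand block first: swapping i and j changes the vector
  vswap <- pair_feature_vector(sj, si, r_ij = 3.2, cfg)
  expect_false(isTRUE(all.equal(v, vswap)))
  expect_equal(v[1:8], si$scalar)
  expect_equal(vswap[1:8], sj$scalar)
  # zero-norm convention: cosine is 0, not NaN
  sz <- list(scalar = rnorm(8), dir = matrix(0, 4, 3))
  vz <- pair_feature_vector(si, sz, r_ij = 3.2, cfg)
  expect_equal(vz[37:40], rep(0, 4))
})

test_that("forward pair features equal pair_feature_vector (pinning test)", {
  cfg <- tiny_cfg()
  p <- live_params(cfg)
  x <- fixture_complex(seed = 14)
  b <- eqbind:::build_batch(list(x), cfg)
  f <- eqbind:::forward_batch(p, b, cfg, keep_cache = TRUE)
  st <- encode(x, p, cfg)
  k <- 1 # first cross pair
  i <- b$pairs[k, 1]; j <- b$pairs[k, 2]
  v <- pair_feature_vector(list(scalar = st$scalar[i, ],
                                dir = matrix(st$dir[i, , ], cfg$n_f, 3)),
                           list(scalar = st$scalar[j, ],
                                dir = matrix(st$dir[j, , ], cfg$n_f, 3)),
                           b$pair_r[k], cfg)
  expect_equal(unname(f$cache$pair$fp[k, ]), unname(v), tolerance = 1e-9)
})

test_that("deleting protein atoms beyond the receptive field is inert", {
  ck <- live_checkpoint()
  cfg <- ck$cfg
  rf <- cfg$n_passes * cfg$r_msg + cfg$r_pair
  for (s in 1:5) {
    x <- make_complex(12, 5, seed = s + 40)
    centroid <- colMeans(x$coords[x$membership == "ligand", , drop = FALSE])
    # bridge of protein atoms from the pocket out past the receptive field
    chain <- t(vapply(seq(8, rf + 6, by = 2.5),
                      function(d) centroid + c(d, 0, 0), numeric(3)))
    xa <- atomic_complex(c(x$elements, rep(6L, nrow(chain))),
                         rbind(x$coords, chain),
                         c(x$membership, rep("protein", nrow(chain))))
    li <- which(xa$membership == "ligand")
    dmin <- sqrt(eqbind:::cross_dist2(xa$coords, xa$coords[li, , drop = FALSE]))
    outside <- which(apply(dmin, 1, min) > rf & xa$membership == "protein")
    expect_gt(length(outside), 0)
    trimmed <- atomic_complex(xa$elements[-outside],
                              xa$coords[-outside, ],
                              xa$membership[-outside])
    expect_lt(abs(predict_complex(ck, xa)$total -
                    predict_complex(ck, trimmed)$total), 1e-6)
  }
})

test_that("duplicating a complex doubles contributions but not the shift", {
  ck <- live_checkpoint()
  x <- fixture_complex(seed = 18)
  b1 <- predict_complex(ck, x)
  dup <- atomic_complex(rep(x$elements, 2),
                        rbind(x$coords, x$coords + 500),
                        rep(x$membership, 2))
  b2 <- predict_complex(ck, dup)
  # the shift is per-system: counted once, not twice
  expect_equal(b2$total, 2 * (b1$total - b1$shift) + b1$shift,
               tolerance = 1e-6)
})
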