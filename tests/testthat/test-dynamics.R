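test_that("mode-subset MSFs reduce to the pseudoinverse diagonal", {
  k3 <- decompose(build_kirchhoff(k3_structure()), "gnm")
  expect_equal(msf_subset(k3, 1:2), rep(2 / 9, 3))
  expect_equal(msf_subset(k3), diag(MASS::ginv(build_kirchhoff(k3_structure()))))

  s <- make_structure("compact_random", n = 20, seed = 4)
  sp <- decompose(build_kirchhoff(s), "gnm")
  expect_lt(max(abs(msf_subset(sp) - diag(MASS::ginv(build_kirchhoff(s))))),
            1e-8)
  expect_true(all(msf_subset(sp, global_mode_indices(20)) >= 0))
  expect_error(msf_subset(sp, 0L), "out of range")

  # cyclic symmetry: uniform MSF on a ring
  ring <- decompose(build_kirchhoff(make_structure("ring", 12, 9.5)), "gnm")
  msf <- msf_subset(ring)
  expect_lt(diff(range(msf)), 1e-10)
})

test_that("PRS self-response is 1 and symmetric fixtures respond uniformly", {
  s <- make_structure("compact_random", n = 12, seed = 8)
  pr <- prs(decompose(build_hessian(s), "anm"))
  expect_equal(unname(diag(pr$matrix)), rep(1, 12))

  # crown ring (alternating z) is non-planar but fully site-symmetric, so
  # every residue must respond identically
  n <- 12
  th <- 2 * pi * (seq_len(n) - 1) / n
  crown <- coords_structure(cbind(6 * cos(th), 6 * sin(th),
                                  1.5 * (-1)^(seq_len(n))))
  p <- enm_params(anm_cutoff = 10)  # reach third neighbors: rigid network
  prr <- prs(decompose(build_hessian(crown, p), "anm", p))
  expect_lt(diff(range(prr$effectiveness)), 1e-8)
  expect_lt(diff(range(prr$sensitivity)), 1e-8)
})

test_that("PRS covariance form matches the explicit-force oracle", {
  s <- make_structure("compact_random", n = 8, seed = 6)
  h <- build_hessian(s)
  pr <- prs(decompose(h, "anm"))
  oracle <- prs_by_forces(h, 8, m = 20)
  oracle_norm <- oracle / diag(oracle)
  expect_lt(max(abs(pr$matrix - oracle_norm) / abs(oracle_norm)), 0.02)
})

test_that("PRS profiles are invariant under rigid rotation and translation", {
  s <- make_structure("compact_random", n = 10, seed = 12)
  xyz <- cbind(s$x, s$y, s$z)
  th <- 0.7; ph <- 1.1
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  moved <- coords_structure(xyz %*% rz %*% rx +
                              matrix(c(5, -3, 11), 10, 3, byrow = TRUE))
  pr1 <- prs(decompose(build_hessian(s), "anm"))
  pr2 <- prs(decompose(build_hessian(moved), "anm"))
  expect_lt(max(abs(pr1$effectiveness - pr2$effectiveness)), 1e-8)
  expect_lt(max(abs(pr1$sensitivity - pr2$sensitivity)), 1e-8)
})

test_that("pair stiffness: one-term mode sum, symmetry, positivity, naive-loop oracle", {
  # two nodes joined by one spring: the single nonzero mode has eigenvalue
  # 2*gamma, so the deformation-weighted average collapses to that value
  s2 <- coords_structure(cbind(c(0, 5), 0, 0))
  for (gamma in c(1, 2.2)) {
    p <- enm_params(gamma = gamma)
    # collinear two-node geometry: 5 rigid-body modes, not 6
    sp <- decompose(build_hessian(s2, p), "anm", p, n_zero_expected = 5L)
    st <- mech_stiffness(sp, s2)
    expect_equal(st$matrix[1, 2], 2 * gamma, tolerance = 1e-12)
    expect_equal(st$matrix[1, 2], max(sp$values), tolerance = 1e-12)
  }

  s <- make_structure("compact_random", n = 10, seed = 21)
  sp <- decompose(build_hessian(s), "anm")
  st <- mech_stiffness(sp, s)
  expect_equal(st$matrix, t(st$matrix))
  expect_true(all(st$matrix >= 0))
  expect_lt(max(abs(st$matrix - stiffness_naive(sp, cbind(s$x, s$y, s$z)))),
            1e-10)
  expect_equal(st$per_residue, rowSums(st$matrix) / 9)
  expect_equal(mech_stiffness(sp, s, stat = "max")$per_residue,
               apply(st$matrix, 1, max))
})

test_that("two-node ANM spectrum fixes the Hessian eigenvalue at 2*gamma", {
  # documents the eigenvalue entering the one-term stiffness sum
  h <- build_hessian(coords_structure(cbind(c(0, 5), 0, 0)),
                     enm_params(gamma = 3))
  expect_equal(max(eigen(h, symmetric = TRUE)$values), 6, tolerance = 1e-12)
})

test_that("ESSA crowding shifts are zero without side chains and Z-scored with them", {
  bare <- make_structure("compact_random", n = 20, seed = 14)
  expect_warning(out <- essa(bare), "side-chain")
  expect_equal(out$zscore, rep(0, 20))

  dressed <- make_structure("compact_random", n = 20, seed = 14,
                            sidechain = "cb")
  out <- expect_no_warning_value(essa(dressed))
  expect_equal(mean(out$zscore), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(out$zscore^2)), 1, tolerance = 1e-10)
  expect_true(all(out$raw_shift >= 0))   # crowding can only stiffen the GNM

  # a residue whose whole neighborhood is glycine gets a zero raw shift:
  # put one dressed cluster far from a bare one, bridged within the cutoff
  xyz <- rbind(cbind(0:7 * 3.8, 0, 0), cbind(8:19 * 3.8, 0, 0))
  s <- coords_structure(xyz)
  s$resid <- c(rep("GLY", 8), rep("ALA", 12))
  for (i in 9:20) {
    s$sidechain[[i]] <- matrix(c(xyz[i, 1], 1.53, 0), 1, 3,
                               dimnames = list("CB", c("x", "y", "z")))
  }
  out <- essa(s)
  expect_equal(out$raw_shift[1], 0)      # neighbors of residue 1 are all GLY
  expect_gt(out$raw_shift[20], 0)

  expect_error(essa(make_structure("compact_random", n = 8, seed = 1,
                                   sidechain = "cb")), "at least")
})

test_that("hinge detection finds slow-mode sign crossovers", {
  # Fiedler vector of a path graph is a sampled half-cosine: one crossover
  # at the chain midpoint
  path <- make_structure("path", n = 20, spacing = 9.5)
  sp <- decompose(build_kirchhoff(path), "gnm")
  expect_equal(hinges(sp, 1), c(10L, 11L))

  # sign flip of the eigenvector leaves the hinge set unchanged
  flipped <- sp
  flipped$vectors <- -flipped$vectors
  expect_equal(hinges(flipped, 1), hinges(sp, 1))

  # orthogonality to the constant zero mode forces >= 1 crossover per mode
  s <- make_structure("compact_random", n = 15, seed = 31)
  sp <- decompose(build_kirchhoff(s), "gnm")
  for (k in 1:14) expect_gte(length(hinges_single <- hinges(sp, k)), 1)

  # degenerate slowest pair on a ring: sampled sinusoids with exactly two
  # sign changes when counted around the cycle
  ring <- decompose(build_kirchhoff(make_structure("ring", 12, 9.5)), "gnm")
  for (k in 1:2) {
    u <- ring$vectors[, 1 + k]
    v <- u[abs(u) > 1e-10]          # a node can sit exactly on a zero
    expect_equal(sum(v * v[c(seq_along(v)[-1], 1)] < 0), 2)
  }
})

test_that("Z-scoring uses the population standard deviation", {
  expect_equal(zscore_profile(c(1, 2, 3)),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_warning(z <- zscore_profile(rep(4, 5)), "Constant")
  expect_equal(z, rep(0, 5))
  set.seed(1)
  v <- rnorm(40, 7, 3)
  z <- zscore_profile(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
})

test_that("the six tracks depend on geometry, not residue numbering", {
  s <- make_structure("compact_random", n = 16, seed = 18, sidechain = "cb")
  s2 <- s
  s2$resno <- s2$resno + 100L   # renumber, same geometry and order
  p1 <- residue_dynamics(s)
  p2 <- residue_dynamics(s2)
  for (tr in c("msf_global", "msf_local", "effectiveness", "sensitivity",
               "stiffness", "essa")) {
    expect_equal(p1[[tr]], p2[[tr]], tolerance = 1e-12)
  }
  expect_equal(attr(p1, "hinge_residues"), attr(p2, "hinge_residues"))
})
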