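# Independent oracles used to check the analytical implementations.

# toy structure straight from coordinates
coords_structure <- function(xyz, chain = "A") {
  as_cg_structure(data.frame(
    chain = chain, resno = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

k3_structure <- function() coords_structure(cbind(c(0, 4, 8), 0, 0))

# circulant closed form for the nearest-neighbor ring Laplacian
ring_eigenvalues <- function(n) sort(2 - 2 * cos(2 * pi * (seq_len(n) - 1) / n))

# total harmonic pair energy of the ANM spring network at displaced coords
anm_energy <- function(xyz0, disp, cutoff, gamma) {
  n <- nrow(xyz0)
  xyz <- xyz0 + disp
  d0 <- as.matrix(dist(xyz0))
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d0[i, j] >= cutoff) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      e <- e + 0.5 * gamma * (dij - d0[i, j])^2
    }
  }
  e
}

# central finite-difference Hessian of the pair potential
fd_hessian <- function(xyz0, cutoff, gamma, h = 1e-4) {
  n3 <- 3 * nrow(xyz0)
  H <- matrix(0, n3, n3)
  base <- matrix(0, nrow(xyz0), 3)
  pert <- function(k, eps) {
    d <- base
    d[ceiling(k / 3), ((k - 1) %% 3) + 1] <- eps
    d
  }
  for (a in seq_len(n3)) {
    for (b in a:n3) {
      epp <- anm_energy(xyz0, pert(a, h) + pert(b, h), cutoff, gamma)
      epm <- anm_energy(xyz0, pert(a, h) + pert(b, -h), cutoff, gamma)
      emp <- anm_energy(xyz0, pert(a, -h) + pert(b, h), cutoff, gamma)
      emm <- anm_energy(xyz0, pert(a, -h) + pert(b, -h), cutoff, gamma)
      H[a, b] <- H[b, a] <- (epp - epm - emp + emm) / (4 * h^2)
    }
  }
  H
}

# quasi-uniform unit vectors on the sphere (Fibonacci lattice)
fibonacci_directions <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# PRS by explicitly applied forces: perturb each residue along m directions,
# solve the linear response through the dense pseudoinverse, and average the
# squared response magnitudes of every residue
prs_by_forces <- function(hessian, n, m = 20) {
  hinv <- MASS::ginv(hessian)
  dirs <- fibonacci_directions(m)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    rows <- (3 * (i - 1) + 1):(3 * i)
    for (k in seq_len(m)) {
      f <- numeric(3 * n)
      f[rows] <- dirs[k, ]
      dr <- hinv %*% f
      resp <- rowSums(matrix(dr, ncol = 3, byrow = TRUE)^2)
      s[i, ] <- s[i, ] + resp / m
    }
  }
  s
}

# pair stiffness by a deliberately naive per-mode, per-pair loop
stiffness_naive <- function(spectrum, xyz) {
  n <- nrow(xyz)
  kBT <- spectrum$params$kBT
  ks <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rhat <- (xyz[j, ] - xyz[i, ]) / sqrt(sum((xyz[j, ] - xyz[i, ])^2))
      num <- 0; den <- 0
      for (k in seq.int(spectrum$n_zero + 1, length(spectrum$values))) {
        lam <- spectrum$values[k]
        u <- matrix(spectrum$vectors[, k], ncol = 3, byrow = TRUE)
        a <- abs(sum(rhat * (u[i, ] - u[j, ])))
        d <- sqrt(kBT / lam) * a
        num <- num + d * lam
        den <- den + d
      }
      ks[i, j] <- ks[j, i] <- if (den > 0) num / den else 0
    }
  }
  ks
}

expect_no_warning_value <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    stop("unexpected warning: ", conditionMessage(w))
  })
}
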