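#' Elastic-network model parameters
#'
#' Bundles the tunable constants of the Gaussian (GNM) and anisotropic (ANM)
#' network models. The GNM connects C-alpha pairs closer than `gnm_cutoff`
#' (10 Angstrom is the conventional choice for direct inter-residue contact);
#' the ANM uses the looser `anm_cutoff` (15 Angstrom) because its directional
#' springs need a denser contact graph to avoid spurious floppy modes.
#' `gamma` is the uniform spring constant and `kBT` the thermal energy; both
#' are kept at 1 by default since every downstream feature is consumed either
#' as a Z-score or as a ratio, so absolute units drop out.
#'
#' @param gnm_cutoff GNM contact cutoff in Angstrom.
#' @param anm_cutoff ANM contact cutoff in Angstrom.
#' @param gamma Uniform spring force constant (arbitrary units, > 0).
#' @param kBT Thermal energy prefactor (arbitrary units, > 0).
#' @return A list of class `enm_params`.
#' @export
#' @examples
#' enm_params()
#' enm_params(gnm_cutoff = 7.3)
enm_params <- function(gnm_cutoff = 10, anm_cutoff = 15, gamma = 1, kBT = 1) {
  stopifnot(
    is.numeric(gnm_cutoff), length(gnm_cutoff) == 1L, gnm_cutoff > 0,
    is.numeric(anm_cutoff), length(anm_cutoff) == 1L, anm_cutoff > 0,
    is.numeric(gamma), length(gamma) == 1L, gamma > 0,
    is.numeric(kBT), length(kBT) == 1L, kBT > 0
  )
  structure(
    list(gnm_cutoff = gnm_cutoff, anm_cutoff = anm_cutoff,
         gamma = gamma, kBT = kBT),
    class = "enm_params"
  )
}

#' @export
print.enm_params <- function(x, ...) {
  cat("<enm_params> gnm_cutoff:", x$gnm_cutoff, "A, anm_cutoff:",
      x$anm_cutoff, "A, gamma:", x$gamma, ", kBT:", x$kBT, "\n")
  invisible(x)
}

ca_matrix <- function(structure) {
  m <- cbind(structure$x, structure$y, structure$z)
  storage.mode(m) <- "double"
  m
}

# connected components of an undirected adjacency matrix (logical, N x N)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

stop_if_disconnected <- function(adj, what) {
  comp <- graph_components(adj)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    abort(paste0(
      what, " contact graph is disconnected (", max(comp),
      " components of sizes ", paste(sizes, collapse = ", "),
      "); network fluctuations are undefined. Increase the cutoff or fix ",
      "the input structure."
    ))
  }
  invisible(TRUE)
}

#' Build the GNM Kirchhoff (connectivity) matrix
#'
#' Off-diagonal entry (i, j) is `-gamma` when the C-alpha atoms of residues i
#' and j lie within `gnm_cutoff` of each other, zero otherwise; the diagonal
#' holds `gamma` times the coordination number, so every row sums to zero
#' (a weighted graph Laplacian).
#'
#' @param structure A `cg_structure` (see [read_pdb()]) or any data frame
#'   with numeric `x`, `y`, `z` columns, one row per residue.
#' @param params An [enm_params()] object.
#' @return A symmetric N x N numeric matrix.
#' @export
build_kirchhoff <- function(structure, params = enm_params()) {
  xyz <- ca_matrix(structure)
  n <- nrow(xyz)
  if (n < 2L) abort("Need at least 2 residues to build a network.")
  d <- as.matrix(stats::dist(xyz))
  adj <- d < params$gnm_cutoff
  diag(adj) <- FALSE
  stop_if_disconnected(adj, "GNM")
  k <- -params$gamma * adj
  diag(k) <- params$gamma * colSums(adj)
  dimnames(k) <- NULL
  k
}

#' Build the ANM Hessian matrix
#'
#' Standard anisotropic-network-model Hessian: for each contacting pair the
#' 3 x 3 off-diagonal super-element is `-gamma * d d^T / |d|^2` with `d` the
#' inter-residue coordinate difference, and diagonal super-elements are minus
#' the sum of the off-diagonal blocks in their row. The result is the exact
#' Hessian of the harmonic pair potential evaluated at the input geometry,
#' and annihilates rigid-body translations and rotations.
#'
#' @inheritParams build_kirchhoff
#' @return A symmetric 3N x 3N numeric matrix, coordinates ordered
#'   (x1, y1, z1, x2, ...).
#' @export
build_hessian <- function(structure, params = enm_params()) {
  xyz <- ca_matrix(structure)
  n <- nrow(xyz)
  if (n < 2L) abort("Need at least 2 residues to build a network.")
  d <- as.matrix(stats::dist(xyz))
  adj <- d < params$anm_cutoff
  diag(adj) <- FALSE
  if (any(d[adj] < 1e-8)) abort("Coincident residues: ANM geometry undefined.")
  stop_if_disconnected(adj, "ANM")
  h <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (!adj[i, j]) next
      dv <- xyz[j, ] - xyz[i, ]
      blk <- -params$gamma * tcrossprod(dv) / sum(dv^2)
      ii <- (3L * (i - 1L) + 1L):(3L * i)
      jj <- (3L * (j - 1L) + 1L):(3L * j)
      h[ii, jj] <- blk
      h[jj, ii] <- blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  h
}

#' Spectral decomposition of a network matrix
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order, so
#' mode 1 is the lowest-frequency (most collective) internal motion and the
#' last mode the most local one. Eigenvalues below `1e-8 * max(eigenvalue)`
#' are counted as zero (rigid-body) modes: a connected GNM graph must have
#' exactly one, a connected non-collinear ANM network exactly six.
#'
#' @param m Symmetric matrix from [build_kirchhoff()] or [build_hessian()].
#' @param kind `"gnm"` or `"anm"`.
#' @param params The [enm_params()] used to build `m` (carried along so that
#'   downstream fluctuation amplitudes can apply the `kBT` prefactor).
#' @param n_zero_expected Override for the expected zero-mode count, for
#'   deliberately degenerate fixtures (e.g. a two-node ANM, whose collinear
#'   geometry leaves 5 rigid-body modes instead of 6).
#' @return A `mode_spectrum` object: list with `values` (ascending),
#'   `vectors` (columns aligned with `values`), `n_zero`, `kind`, `n_atoms`,
#'   `params`.
#' @export
decompose <- function(m, kind = c("gnm", "anm"), params = enm_params(),
                      n_zero_expected = NULL) {
  kind <- match.arg(kind)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    abort("Matrix must be symmetric.")
  e <- eigen(m, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  tol <- 1e-8 * max(abs(values))
  n_zero <- sum(abs(values) < tol)
  expected <- n_zero_expected %||% if (kind == "gnm") 1L else 6L
  if (n_zero != expected) {
    abort(paste0(
      "Expected ", expected, " zero mode(s) for a ", toupper(kind),
      " network but found ", n_zero,
      "; the contact graph is probably disconnected or the coordinates ",
      "(near-)collinear."
    ))
  }
  n_atoms <- if (kind == "gnm") nrow(m) else nrow(m) %/% 3L
  structure(
    list(values = values, vectors = vectors, n_zero = n_zero, kind = kind,
         n_atoms = n_atoms, zero_tol = tol, params = params),
    class = "mode_spectrum"
  )
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat("<mode_spectrum> kind:", x$kind, "| atoms:", x$n_atoms,
      "| modes:", length(x$values), "| zero modes:", x$n_zero, "\n")
  cat("  nonzero eigenvalue range: [",
      format(min(nonzero_mode_values(x))), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' @method tidy mode_spectrum
#' @export
tidy.mode_spectrum <- function(x, ...) {
  tibble(
    mode = seq_along(x$values) - x$n_zero,
    eigenvalue = x$values,
    zero = abs(x$values) < x$zero_tol
  )
}

nonzero_mode_indices <- function(spectrum) {
  seq.int(spectrum$n_zero + 1L, length(spectrum$values))
}

nonzero_mode_values <- function(spectrum) {
  spectrum$values[nonzero_mode_indices(spectrum)]
}

# translate 1-based nonzero-mode numbering (mode 1 = slowest internal mode)
# into column indices of the eigenvector matrix
mode_columns <- function(spectrum, modes) {
  cols <- modes + spectrum$n_zero
  if (any(modes < 1L) || any(cols > length(spectrum$values)))
    abort("Mode index out of range.")
  cols
}

#' Mode-subset pseudoinverse of a network matrix
#'
#' Accumulates `kBT * sum(lambda_k^-1 u_k u_k^T)` over the requested nonzero
#' modes. With all nonzero modes this equals `kBT` times the Moore-Penrose
#' pseudoinverse, whose diagonal gives the residue mean-square fluctuations.
#' (The spring constant `gamma` already scales the input matrix, so the
#' thermal prefactor reduces to `kBT`.)
#'
#' @param spectrum A `mode_spectrum`.
#' @param modes Integer vector of nonzero-mode indices (1 = slowest internal
#'   mode). Default: all nonzero modes. An empty vector yields a zero matrix.
#' @param diag_only Return only the diagonal as a vector?
#' @return Matrix (or its diagonal) of covariance contributions.
#' @export
pinv_modes <- function(spectrum, modes = NULL, diag_only = FALSE) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  if (is.null(modes)) modes <- seq_len(length(spectrum$values) - spectrum$n_zero)
  n <- nrow(spectrum$vectors)
  if (length(modes) == 0L) {
    out <- matrix(0, n, n)
    return(if (diag_only) diag(out) else out)
  }
  cols <- mode_columns(spectrum, modes)
  lam <- spectrum$values[cols]
  if (any(abs(lam) < spectrum$zero_tol))
    abort("Mode subset contains a zero (rigid-body) mode.")
  u <- spectrum$vectors[, cols, drop = FALSE]
  kBT <- spectrum$params$kBT
  if (diag_only) {
    kBT * drop((u^2) %*% (1 / lam))
  } else {
    kBT * (u %*% (t(u) / lam))
  }
}

#' Indices of the global (slowest) and local (fastest) GNM modes
#'
#' The softest `fraction` of the N - 1 internal GNM modes defines the global
#' modes; the same number taken from the high-frequency end defines the local
#' modes. The count is `max(1, round-half-up(fraction * (N - 1)))`: for
#' N = 200 and the default 2% this selects modes 1-4 (global) and 196-199
#' (local).
#'
#' @param n_residues Number of residues N (>= 3).
#' @param fraction Fraction of the N - 1 internal modes to keep.
#' @return Integer vector of nonzero-mode indices.
#' @export
global_mode_indices <- function(n_residues, fraction = 0.02) {
  stopifnot(n_residues >= 3L, fraction > 0, fraction <= 1)
  count <- max(1L, as.integer(floor(fraction * (n_residues - 1L) + 0.5)))
  seq_len(count)
}

#' @rdname global_mode_indices
#' @export
local_mode_indices <- function(n_residues, fraction = 0.02) {
  count <- length(global_mode_indices(n_residues, fraction))
  seq.int(n_residues - count, n_residues - 1L)
}
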