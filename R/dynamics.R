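#' Mean-square fluctuations over a GNM mode subset
#'
#' `MSF_i = kBT * sum_k lambda_k^-1 (u_k)_i^2` over the requested nonzero
#' modes of the Kirchhoff matrix. With all N - 1 internal modes this is the
#' diagonal of the full pseudoinverse; restricted to the softest modes it
#' isolates the collective (global) motions, restricted to the stiffest ones
#' the localized high-frequency (local) motions whose peaks flag tightly
#' packed, kinetically hot residues.
#'
#' @param spectrum A GNM `mode_spectrum`.
#' @param modes Nonzero-mode indices (1 = slowest internal mode).
#' @return Numeric vector of per-residue MSFs.
#' @export
msf_subset <- function(spectrum, modes = NULL) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  if (spectrum$kind != "gnm") abort("MSF profiles are defined on GNM spectra.")
  pinv_modes(spectrum, modes, diag_only = TRUE)
}

#' Perturbation response scanning: effectiveness and sensitivity
#'
#' Linear-response probing of the ANM: the displacement response to a force
#' at residue i is `H^+ F`. The N x N response-magnitude map `S[i, j]`
#' accumulates the squared elements of the 3 x 3 block (j, i) of the Hessian
#' pseudoinverse, i.e. the mean-square displacement of residue j under
#' isotropically averaged unit perturbations at residue i (up to a constant
#' 1/3 that cancels in the normalization). Each row is divided by its
#' diagonal element so the self-response is 1; the row-i mean is the
#' *effectiveness* of residue i as a signal broadcaster and the column-j
#' mean the *sensitivity* of residue j as a receiver.
#'
#' @param spectrum An ANM `mode_spectrum`.
#' @return List with `matrix` (normalized response map), `effectiveness`,
#'   `sensitivity` (per-residue vectors).
#' @export
prs <- function(spectrum) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  if (spectrum$kind != "anm") abort("PRS is defined on ANM spectra.")
  n <- spectrum$n_atoms
  cov <- pinv_modes(spectrum)                 # 3N x 3N
  sq <- cov^2
  # collapse 3x3 blocks: S[i, j] = sum of squared elements of block (i, j)
  collapse <- matrix(0, 3L * n, n)
  for (j in seq_len(n)) collapse[(3L * (j - 1L) + 1L):(3L * j), j] <- 1
  s <- t(collapse) %*% sq %*% collapse
  if (any(diag(s) <= 0))
    abort("Zero diagonal in the PRS response map (degenerate network).")
  norm <- s / diag(s)                         # divide each row by its diagonal
  list(
    matrix = norm,
    effectiveness = rowMeans(norm),
    sensitivity = colMeans(norm)
  )
}

#' Pairwise mechanical stiffness under uniaxial tension
#'
#' Effective force constant `<kappa_ij>` of each residue pair against
#' stretching along the inter-residue axis, computed as a mode-weighted
#' average over the nonzero ANM modes: each mode contributes its stiffness
#' `lambda_k` weighted by the deformation it produces along the pulling
#' axis, `d_ij^k = sqrt(kBT / lambda_k) * |r_hat_ij . (u_j^k - u_i^k)|`
#' (the projection equals `cos(alpha) * |u_i^k - u_j^k|` with `alpha` the
#' angle between the axis and the mode-induced change of the inter-residue
#' vector). Pairs deformed only by soft modes are compliant; pairs whose
#' separation is modulated by stiff modes resist tension.
#'
#' @param spectrum An ANM `mode_spectrum`.
#' @param structure The structure the spectrum was computed from.
#' @param stat Per-residue reduction of the pair matrix: `"mean"` (default)
#'   or `"max"` over partners j != i.
#' @return List with `matrix` (N x N symmetric `<kappa_ij>`, zero diagonal)
#'   and `per_residue` (reduced profile).
#' @export
mech_stiffness <- function(spectrum, structure, stat = c("mean", "max")) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  if (spectrum$kind != "anm") abort("Mechanical stiffness needs an ANM spectrum.")
  stat <- match.arg(stat)
  n <- spectrum$n_atoms
  xyz <- ca_matrix(structure)
  if (nrow(xyz) != n) abort("Structure does not match the spectrum size.")
  dmat <- as.matrix(stats::dist(xyz))
  if (any(dmat[upper.tri(dmat)] < 1e-8))
    abort("Coincident residues: pulling axis undefined.")
  kBT <- spectrum$params$kBT
  cols <- nonzero_mode_indices(spectrum)
  px <- outer(xyz[, 1], xyz[, 1], "-") / dmat  # r_hat components (i<-j), NaN diag
  py <- outer(xyz[, 2], xyz[, 2], "-") / dmat
  pz <- outer(xyz[, 3], xyz[, 3], "-") / dmat
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (c0 in cols) {
    lam <- spectrum$values[c0]
    u <- matrix(spectrum$vectors[, c0], ncol = 3L, byrow = TRUE)
    dx <- outer(u[, 1], u[, 1], "-")           # u_i - u_j, componentwise
    dy <- outer(u[, 2], u[, 2], "-")
    dz <- outer(u[, 3], u[, 3], "-")
    a <- abs(px * dx + py * dy + pz * dz)      # |r_hat . (u_i - u_j)|
    d <- sqrt(kBT / lam) * a
    num <- num + d * lam
    den <- den + d
  }
  kappa <- num / den
  kappa[!is.finite(kappa)] <- 0   # diagonal, and pairs no mode deforms
  diag(kappa) <- 0
  per <- switch(stat,
    mean = rowSums(kappa) / (n - 1L),
    max = apply(kappa, 1L, max)
  )
  list(matrix = kappa, per_residue = per)
}

#' Essential site scanning (ESSA) profile
#'
#' Mimics ligand binding at each residue by crowding its neighborhood: the
#' GNM is rebuilt with extra nodes at the side-chain heavy-atom positions of
#' every residue whose C-alpha lies within the GNM cutoff of the scanned
#' residue (itself included; glycines contribute none), and the mean percent
#' upshift of the 10 softest nonzero eigenvalues relative to the
#' unperturbed model is recorded. The per-residue shifts are then Z-scored
#' over the protein, so a high score marks a site whose occlusion would
#' most alter the global dynamics.
#'
#' @param structure A `cg_structure` (side chains used when present).
#' @param params An [enm_params()].
#' @param n_soft Number of softest nonzero modes monitored (default 10).
#' @return List with `zscore` and `raw_shift` (percent) per residue.
#' @export
essa <- function(structure, params = enm_params(), n_soft = 10L) {
  n <- nrow(structure)
  if (n < n_soft + 2L)
    abort(paste0("ESSA needs at least ", n_soft + 2L, " residues (",
                 n_soft, " nonzero soft modes)."))
  xyz <- ca_matrix(structure)
  base <- decompose(build_kirchhoff(structure, params), "gnm", params)
  lam0 <- nonzero_mode_values(base)[seq_len(n_soft)]
  sc <- structure$sidechain
  sc_sizes <- vapply(sc, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  if (sum(sc_sizes) == 0L) {
    warn("No side-chain atoms present; ESSA raw shifts are all zero.")
    return(list(zscore = rep(0, n), raw_shift = rep(0, n)))
  }
  dmat <- as.matrix(stats::dist(xyz))
  cutoff <- params$gnm_cutoff
  raw <- numeric(n)
  for (r in seq_len(n)) {
    nb <- which(dmat[r, ] < cutoff)            # includes r itself
    extra <- do.call(rbind, sc[nb])
    if (is.null(extra) || nrow(extra) == 0L) {
      raw[r] <- 0
      next
    }
    aug <- rbind(xyz, unname(extra[, 1:3, drop = FALSE]))
    d <- as.matrix(stats::dist(aug))
    adj <- d < cutoff
    diag(adj) <- FALSE
    k <- -params$gamma * adj
    diag(k) <- params$gamma * colSums(adj)
    ev <- sort(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
    tol <- 1e-8 * max(abs(ev))
    lam1 <- ev[ev > tol][seq_len(n_soft)]
    raw[r] <- mean((lam1 - lam0) / lam0) * 100
  }
  list(zscore = zscore_profile(raw), raw_shift = raw)
}

#' Hinge residues of the global GNM modes
#'
#' A hinge is a residue flanking a sign crossover of a slow-mode eigenvector
#' along the sequence: both residues on either side of each crossover are
#' reported, and the sets are unioned over the first `n_global` nonzero
#' modes. Hinges anchor the collective motions, so deleting one is expected
#' to perturb the global dynamics.
#'
#' @param spectrum A GNM `mode_spectrum`.
#' @param n_global Number of slowest nonzero modes scanned.
#' @return Sorted integer vector of hinge residue indices.
#' @export
hinges <- function(spectrum, n_global = 1L) {
  stopifnot(inherits(spectrum, "mode_spectrum"), n_global >= 1L)
  if (spectrum$kind != "gnm") abort("Hinges are defined on GNM spectra.")
  out <- integer(0)
  for (k in seq_len(n_global)) {
    u <- spectrum$vectors[, mode_columns(spectrum, k)]
    cross <- which(u[-length(u)] * u[-1L] < 0)
    out <- c(out, cross, cross + 1L)
  }
  sort(unique(out))
}

#' Z-score a per-residue profile
#'
#' Standardizes a feature track over all residues of the protein using the
#' population (ddof = 0) standard deviation. A constant track yields an
#' all-zero profile with a warning.
#'
#' @param values Numeric vector (length >= 2).
#' @return Numeric vector of Z-scores.
#' @export
zscore_profile <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    warn("Constant profile: Z-scores set to zero.")
    return(rep(0, length(values)))
  }
  (values - mu) / sigma
}

#' Compute all six per-residue intrinsic-dynamics profiles
#'
#' Orchestrates the full dynamic characterization of a wild-type structure:
#' GNM mean-square fluctuations in the softest and stiffest 2% of modes,
#' perturbation-response effectiveness and sensitivity, mechanical
#' stiffness, essential-site (ESSA) Z-scores, and the global-mode hinge
#' set. Returns one row per residue with both raw tracks and their
#' whole-protein Z-scores.
#'
#' @param structure A `cg_structure`; secondary structure is assigned if
#'   missing.
#' @param params An [enm_params()].
#' @param mode_fraction Fraction of internal GNM modes treated as global
#'   (and, mirrored, local); default 2%.
#' @param stiffness_stat `"mean"` or `"max"` reduction of the pair
#'   stiffness map.
#' @return A `residue_profiles` tibble with columns `chain`, `resno`, `ins`,
#'   `resid`, `ss`, the six tracks, their `z_*` counterparts, and
#'   `is_hinge`; the hinge index set, parameters and mode counts are kept
#'   as attributes.
#' @export
residue_dynamics <- function(structure, params = enm_params(),
                             mode_fraction = 0.02,
                             stiffness_stat = c("mean", "max")) {
  stiffness_stat <- match.arg(stiffness_stat)
  structure <- assign_secondary_structure(structure)
  n <- nrow(structure)
  if (n < 3L) abort("Need at least 3 residues.")
  gnm <- decompose(build_kirchhoff(structure, params), "gnm", params)
  anm <- decompose(build_hessian(structure, params), "anm", params)
  gmodes <- global_mode_indices(n, mode_fraction)
  lmodes <- local_mode_indices(n, mode_fraction)
  msf_g <- msf_subset(gnm, gmodes)
  msf_l <- msf_subset(gnm, lmodes)
  pr <- prs(anm)
  st <- mech_stiffness(anm, structure, stat = stiffness_stat)
  es <- essa(structure, params)
  hinge_set <- hinges(gnm, n_global = length(gmodes))
  prof <- tibble(
    chain = structure$chain, resno = structure$resno, ins = structure$ins,
    resid = structure$resid, ss = structure$ss,
    msf_global = msf_g, msf_local = msf_l,
    effectiveness = pr$effectiveness, sensitivity = pr$sensitivity,
    stiffness = st$per_residue, essa = es$zscore,
    z_msf_global = zscore_profile(msf_g),
    z_msf_local = zscore_profile(msf_l),
    z_effectiveness = zscore_profile(pr$effectiveness),
    z_sensitivity = zscore_profile(pr$sensitivity),
    z_stiffness = zscore_profile(st$per_residue),
    z_essa = es$zscore,  # the ESSA score is already a whole-protein Z-score
    is_hinge = seq_len(n) %in% hinge_set
  )
  attr(prof, "hinge_residues") <- hinge_set
  attr(prof, "params") <- params
  attr(prof, "mode_fraction") <- mode_fraction
  attr(prof, "n_global_modes") <- length(gmodes)
  attr(prof, "source_id") <- attr(structure, "source_id")
  class(prof) <- unique(c("residue_profiles", class(prof)))
  prof
}

#' @export
print.residue_profiles <- function(x, ...) {
  cat("<residue_profiles> ", attr(x, "source_id") %||% "?", ": ", nrow(x),
      " residues, ", length(attr(x, "hinge_residues")), " hinge(s), ",
      attr(x, "n_global_modes"), " global mode(s)\n", sep = "")
  NextMethod()
}
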