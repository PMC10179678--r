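#' Generate toy coarse-grained structures with known network spectra
#'
#' Builds small C-alpha geometries for exercising the elastic-network
#' machinery: `"ring"` and `"path"` layouts have analytically known GNM
#' spectra at nearest-neighbor connectivity (circulant and path-graph
#' Laplacians), `"helix"` is an ideal alpha-helical trace (rise 1.5
#' Angstrom, 100 degrees per residue, radius 2.3 Angstrom) and
#' `"compact_random"` is a seeded self-avoiding walk with 3.8 Angstrom
#' virtual bonds confined to a compact ball, the closest stand-in for a
#' small globular fold. Coordinates are rounded to 0.001 Angstrom so that
#' the emitted PDB text ([pdb_text()]) round-trips exactly and is
#' byte-identical for a fixed seed.
#'
#' @param kind One of `"ring"`, `"path"`, `"helix"`, `"compact_random"`.
#' @param n Number of residues (>= 3).
#' @param spacing Nearest-neighbor C-alpha distance for ring/path layouts
#'   (Angstrom). Pick it just under the GNM cutoff to realize pure
#'   nearest-neighbor connectivity.
#' @param seed Seed for the `compact_random` walk (ignored otherwise).
#' @param sidechain `"none"` (glycine-like trace) or `"cb"` to attach one
#'   beta-carbon-like heavy atom per residue, pointing away from the local
#'   backbone, so that side-chain-dependent scores (ESSA) are exercised.
#' @return A `cg_structure` tibble (chain `"A"`, residues numbered from 1).
#' @export
make_structure <- function(kind = c("ring", "path", "helix", "compact_random"),
                           n = 12L, spacing = 3.8, seed = 1L,
                           sidechain = c("none", "cb")) {
  kind <- match.arg(kind)
  sidechain <- match.arg(sidechain)
  stopifnot(n >= 3L, spacing > 0)
  xyz <- switch(kind,
    ring = {
      r <- spacing / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1L) / n
      cbind(r * cos(th), r * sin(th), 0)
    },
    path = cbind(spacing * (seq_len(n) - 1L), 0, 0),
    helix = {
      th <- (seq_len(n) - 1L) * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n) - 1L))
    },
    compact_random = local_seed(seed, compact_walk(n, step = 3.8,
                                                   min_sep = 3.0))
  )
  xyz <- round(xyz, 3L)
  df <- tibble(
    chain = "A", resno = seq_len(n),
    resid = if (sidechain == "none") "GLY" else "ALA",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
  )
  s <- as_cg_structure(df, source_id = paste0("synthetic-", kind, "-", n))
  if (sidechain == "cb") {
    for (i in seq_len(n)) {
      lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
      mid <- colMeans(xyz[c(lo, hi), , drop = FALSE])
      dirv <- xyz[i, ] - mid
      if (sqrt(sum(dirv^2)) < 1e-6) dirv <- c(0, 0, 1)
      cb <- round(xyz[i, ] + 1.53 * dirv / sqrt(sum(dirv^2)), 3L)
      m <- matrix(cb, 1L, 3L, dimnames = list("CB", c("x", "y", "z")))
      s$sidechain[[i]] <- m
    }
  }
  s
}

# seeded self-avoiding walk biased toward the origin; restarts if trapped
compact_walk <- function(n, step, min_sep, max_radius = NULL) {
  max_radius <- max_radius %||% (step * max(2.5, n^(1/3) * 1.1))
  for (attempt in 1:50) {
    pos <- matrix(NA_real_, n, 3L)
    pos[1L, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:200) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        # pull the walk back toward the origin as it strays
        pull <- -pos[i - 1L, ] / max_radius
        dirv <- u + pull
        dirv <- dirv / sqrt(sum(dirv^2))
        cand <- pos[i - 1L, ] + step * dirv
        prev <- pos[seq_len(i - 2L), , drop = FALSE]
        clear <- i == 2L ||
          min(rowSums(sweep(prev, 2L, cand)^2)) >= min_sep^2
        if (clear && sqrt(sum(cand^2)) <= max_radius) {
          pos[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  abort("Could not build a self-avoiding compact walk; relax the spacing.")
}

#' Generate a positive-unlabeled feature table with known ground truth
#'
#' Draws class-conditional Gaussian features: hidden positives are shifted
#' by `effect_size` standard deviations on each of the first
#' `n_informative` coordinates, negatives sit at the origin, and all other
#' coordinates are pure noise. Labeling follows the selected-completely-
#' at-random assumption: the observed table contains `n_pos_labeled`
#' labeled positives (`s = 1`) and `n_unlabeled` unlabeled rows (`s = 0`)
#' of which a Binomial(`n_unlabeled`, `pi_u`) draw are hidden positives.
#' The hidden truth `y` is returned for oracle checks, and the implied
#' labeling frequency `P(s = 1 | y = 1)` is recorded as attributes
#' `c_expected` (from the requested counts) and `c_true` (from the
#' realized draw).
#'
#' @param n_pos_labeled Number of labeled positives. Default `NULL`:
#'   derived from `c` as `round(c / (1 - c) * pi_u * n_unlabeled)`.
#' @param n_unlabeled Number of unlabeled rows.
#' @param pi_u Fraction of hidden positives among the unlabeled.
#' @param c Target labeling frequency, used only to derive
#'   `n_pos_labeled` when that is `NULL`.
#' @param n_features,n_informative Total and informative feature counts
#'   (`n_informative` defaults to `min(5, n_features)`).
#' @param effect_size Standardized mean separation per informative
#'   coordinate (2.0 = well separated preset; 0.5 = hard preset).
#' @param seed Seed for all draws.
#' @return Tibble with `segment_id`, `s` (observed label), `y` (hidden
#'   truth), `region` and features `f01`, `f02`, ...; generative
#'   parameters are stored as attributes.
#' @export
make_pu_table <- function(n_pos_labeled = NULL, n_unlabeled = 1842L,
                          pi_u = 0.2, c = 0.3, n_features = 10L,
                          n_informative = NULL, effect_size = 2,
                          seed = 1L) {
  n_informative <- n_informative %||% min(5L, n_features)
  stopifnot(pi_u >= 0, pi_u <= 1, n_informative <= n_features,
            n_features >= 1L)
  if (is.null(n_pos_labeled)) {
    stopifnot(!is.null(c), c > 0, c <= 1)
    n_pos_labeled <- max(2L, as.integer(round(c / (1 - min(c, 1 - 1e-9)) *
                                                pi_u * n_unlabeled)))
  }
  local_seed(seed, {
    hidden <- stats::rbinom(n_unlabeled, 1L, pi_u)
    n <- n_pos_labeled + n_unlabeled
    y <- c(rep(1L, n_pos_labeled), hidden)
    s <- c(rep(1L, n_pos_labeled), rep(0L, n_unlabeled))
    mu <- c(rep(effect_size, n_informative),
            rep(0, n_features - n_informative))
    x <- matrix(stats::rnorm(n * n_features), n, n_features)
    x <- x + outer(y, mu)
    region <- sample(c("loop", "non-loop"), n, replace = TRUE)
    out <- tibble(
      segment_id = sprintf("seg%06d", seq_len(n)),
      s = s, y = y, region = region
    )
    feat <- as_tibble(as.data.frame(x))
    names(feat) <- sprintf("f%02d", seq_len(n_features))
    out <- dplyr::bind_cols(out, feat)
    c_exp <- n_pos_labeled / (n_pos_labeled + pi_u * n_unlabeled)
    attr(out, "pu_truth") <- list(
      n_pos_labeled = n_pos_labeled, n_unlabeled = n_unlabeled,
      n_hidden_positive = sum(hidden), pi_u = pi_u,
      c_expected = c_exp,
      c_true = n_pos_labeled / (n_pos_labeled + sum(hidden)),
      n_features = n_features, n_informative = n_informative,
      effect_size = effect_size, seed = seed
    )
    out
  })
}

#' End-to-end toy deletion case
#'
#' A compact random structure of 60 residues with beta-carbon-like side
#' chains and four deletion segments of lengths 2, 5, 11 and 23 (spanning
#' the modeled 2..23 range), none touching the chain termini. Used as the
#' smallest input that exercises the whole per-residue -> per-segment
#' feature path.
#'
#' @param seed Seed for the structure generator.
#' @return List with `structure` (secondary structure assigned) and
#'   `segments` (resolved segment tibble).
#' @export
make_toy_deletion_case <- function(seed = 42L) {
  s <- make_structure("compact_random", n = 60L, seed = seed,
                      sidechain = "cb")
  s <- assign_secondary_structure(s)
  spans <- list(c(5L, 6L), c(15L, 19L), c(25L, 35L), c(36L, 58L))
  segments <- dplyr::bind_rows(lapply(spans, function(sp)
    resolve_segment(s, "A", sp[1L], sp[2L])))
  list(structure = s, segments = segments)
}

# place atom D given A-B-C positions and internal coordinates (NeRF)
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nv <- nv / sqrt(sum(nv^2))
  mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + cbind(bc, mv, nv) %*% d2
}

#' Ideal-geometry polyalanine backbone
#'
#' Builds an N/CA/C/O backbone with standard bond lengths and angles at
#' fixed (phi, psi) torsions (omega held trans). `phi = -57, psi = -47`
#' produces an ideal alpha helix whose backbone hydrogen-bond pattern is
#' satisfied by construction; `phi = -139, psi = 135` an isolated extended
#' strand. Used to exercise the hydrogen-bond-based secondary-structure
#' assignment on geometry with a known answer.
#'
#' @param n Number of residues.
#' @param phi,psi Backbone torsions in degrees, applied uniformly.
#' @return A `cg_structure` with the `bb` backbone list-column filled.
#' @export
synthetic_backbone <- function(n, phi = -57, psi = -47) {
  stopifnot(n >= 3L)
  Nc <- matrix(NA_real_, n, 3L)
  CAc <- matrix(NA_real_, n, 3L)
  Cc <- matrix(NA_real_, n, 3L)
  Oc <- matrix(NA_real_, n, 3L)
  Nc[1L, ] <- c(0, 0, 0)
  CAc[1L, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  Cc[1L, ] <- CAc[1L, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    Nc[i, ] <- nerf_place(Nc[i - 1L, ], CAc[i - 1L, ], Cc[i - 1L, ],
                          1.329, 116.2, psi)
    CAc[i, ] <- nerf_place(CAc[i - 1L, ], Cc[i - 1L, ], Nc[i, ],
                           1.458, 121.7, 180)
    Cc[i, ] <- nerf_place(Cc[i - 1L, ], Nc[i, ], CAc[i, ],
                          1.525, 111.2, phi)
  }
  for (i in seq_len(n)) {
    Oc[i, ] <- nerf_place(Nc[i, ], CAc[i, ], Cc[i, ], 1.231, 120.8,
                          psi + 180)
  }
  df <- tibble(
    chain = "A", resno = seq_len(n), resid = "GLY",
    x = CAc[, 1L], y = CAc[, 2L], z = CAc[, 3L]
  )
  s <- as_cg_structure(df, source_id = paste0("synthetic-backbone-", n))
  for (i in seq_len(n)) {
    s$bb[[i]] <- rbind(N = Nc[i, ], C = Cc[i, ], O = Oc[i, ])
    colnames(s$bb[[i]]) <- c("x", "y", "z")
  }
  s
}
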