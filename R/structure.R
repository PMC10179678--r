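BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

#' Build a coarse-grained structure tibble
#'
#' The package represents a protein chain as a tibble with one row per
#' residue: `chain`, `resno`, `ins` (insertion code, `""` if none), `resid`
#' (3-letter code), the C-alpha coordinates `x`, `y`, `z` (Angstrom), a
#' secondary-structure label `ss` (`"loop"` or `"non-loop"`), a list-column
#' `sidechain` of k x 3 heavy-atom coordinate matrices (may be 0-row, e.g.
#' glycine), and a list-column `bb` of backbone N/C/O coordinates (3 x 3
#' matrix with those rownames, or `NULL` when only C-alphas are known).
#'
#' @param df Data frame with at least `chain`, `resno`, `x`, `y`, `z`.
#' @param source_id Identifier recorded on the object (file/PDB id + chain).
#' @return A `cg_structure` tibble.
#' @export
as_cg_structure <- function(df, source_id = "structure") {
  df <- as_tibble(df)
  need <- c("chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  if (!"ins" %in% names(df)) df$ins <- ""
  df$ins[is.na(df$ins)] <- ""
  if (!"resid" %in% names(df)) df$resid <- "ALA"
  if (!"ss" %in% names(df)) df$ss <- NA_character_
  if (!"sidechain" %in% names(df)) {
    df$sidechain <- lapply(seq_len(nrow(df)), function(i) {
      matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("x", "y", "z")))
    })
  }
  if (!"bb" %in% names(df)) df$bb <- vector("list", nrow(df))
  key <- paste(df$chain, df$resno, df$ins)
  if (anyDuplicated(key))
    abort("Duplicate (chain, resno, insertion) residue keys.")
  df <- df[, c("chain", "resno", "ins", "resid", "x", "y", "z", "ss",
               "sidechain", "bb")]
  attr(df, "source_id") <- source_id
  class(df) <- unique(c("cg_structure", class(df)))
  df
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("<cg_structure> ", attr(x, "source_id") %||% "?", ": ", nrow(x),
      " residues, chains {", paste(unique(x$chain), collapse = ", "),
      "}\n", sep = "")
  NextMethod()
}

is_hydrogen <- function(elety, elesy) {
  sy <- toupper(trimws(elesy))
  known <- !is.na(sy) & nzchar(sy)
  out <- logical(length(elety))
  out[known] <- sy[known] %in% c("H", "D")
  # fall back on the atom name: optional leading digit then H/D
  out[!known] <- grepl("^[0-9]*[HD]", toupper(trimws(elety[!known])))
  out
}

#' Read a PDB file into a coarse-grained structure
#'
#' Parses ATOM records of one chain and one model into a [as_cg_structure()]
#' tibble. Alternate locations are resolved to the highest-occupancy record
#' (ties broken by altloc identifier, so 'A' wins); HETATM records are
#' skipped except selenomethionine (MSE), which is treated as MET; residues
#' without a C-alpha are dropped with a warning. Hydrogens are ignored.
#'
#' @param path PDB file path.
#' @param chain Chain identifier. Defaults to the only chain present; an
#'   error lists the available chains otherwise.
#' @param model Model number for multi-model files (default: first).
#' @return A `cg_structure` tibble with `ss` unset (see
#'   [assign_secondary_structure()]).
#' @export
read_pdb <- function(path, chain = NULL, model = 1L) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atoms <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models)
    abort(paste0("Model ", model, " requested but file has ", n_models, "."))
  coords <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  atoms$x <- coords[, 1L]; atoms$y <- coords[, 2L]; atoms$z <- coords[, 3L]

  keep <- atoms$type == "ATOM" | (atoms$type == "HETATM" & atoms$resid == "MSE")
  atoms <- atoms[keep, , drop = FALSE]
  if (!nrow(atoms)) abort("No ATOM records (or MSE) found.")
  atoms$resid[atoms$resid == "MSE"] <- "MET"
  atoms <- atoms[!is_hydrogen(atoms$elety, atoms$elesy), , drop = FALSE]

  chains <- sort(unique(atoms$chain))
  if (is.null(chain)) {
    if (length(chains) > 1L)
      abort(paste0("File has multiple chains {",
                   paste(chains, collapse = ", "), "}; pick one."))
    chain <- chains
  }
  if (!chain %in% chains)
    abort(paste0("Chain '", chain, "' not found; available chains: {",
                 paste(chains, collapse = ", "), "}."))
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  # altloc: within each (residue, atom name), keep highest occupancy,
  # ties by altloc id so 'A' precedes 'B'
  akey <- paste(atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  pick <- order(akey, -atoms$o, atoms$alt)
  best <- pick[!duplicated(akey[pick])]
  atoms <- atoms[sort(best), , drop = FALSE]  # keep original file order

  rkey <- paste(atoms$resno, atoms$insert, sep = "\r")
  rows <- lapply(unique(rkey), function(k) {
    a <- atoms[rkey == k, , drop = FALSE]
    ca <- a[a$elety == "CA", , drop = FALSE]
    if (!nrow(ca)) return(NULL)
    sc <- a[!(a$elety %in% BACKBONE_ATOMS), , drop = FALSE]
    scm <- cbind(x = sc$x, y = sc$y, z = sc$z)
    rownames(scm) <- sc$elety
    bb <- NULL
    bba <- a[match(c("N", "C", "O"), a$elety), , drop = FALSE]
    if (!anyNA(bba$elety)) {
      bb <- cbind(x = bba$x, y = bba$y, z = bba$z)
      rownames(bb) <- c("N", "C", "O")
    }
    tibble(
      chain = chain, resno = ca$resno[1L], ins = ca$insert[1L],
      resid = ca$resid[1L], x = ca$x[1L], y = ca$y[1L], z = ca$z[1L],
      sidechain = list(scm), bb = list(bb)
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warn(paste0(dropped, " residue(s) without a C-alpha dropped."))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) abort("No residues with C-alpha atoms in this chain.")
  out <- dplyr::bind_rows(rows)
  as_cg_structure(out, source_id = paste0(basename(path), ":", chain))
}

#' Serialize a coarse-grained structure as PDB text
#'
#' Writes one ATOM record per C-alpha plus one per stored side-chain heavy
#' atom (named rows of the `sidechain` matrices). Good enough to round-trip
#' through [read_pdb()]; not a general-purpose PDB writer.
#'
#' @param structure A `cg_structure`.
#' @return Character vector of PDB lines (including `END`).
#' @export
pdb_text <- function(structure) {
  lines <- character(0)
  serial <- 0L
  fmt <- function(serial, name, resid, chain, resno, ins, xyz) {
    pad_name <- if (nchar(name) < 4L) paste0(" ", name) else name
    sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, pad_name, resid, chain, resno,
            if (nzchar(ins)) ins else " ", xyz[1L], xyz[2L], xyz[3L], 1, 0)
  }
  for (i in seq_len(nrow(structure))) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, "CA", structure$resid[i], structure$chain[i],
                          structure$resno[i], structure$ins[i],
                          c(structure$x[i], structure$y[i], structure$z[i])))
    sc <- structure$sidechain[[i]]
    if (!is.null(sc) && nrow(sc)) {
      nm <- rownames(sc) %||% paste0("S", seq_len(nrow(sc)))
      for (j in seq_len(nrow(sc))) {
        serial <- serial + 1L
        lines <- c(lines, fmt(serial, nm[j], structure$resid[i],
                              structure$chain[i], structure$resno[i],
                              structure$ins[i], sc[j, ]))
      }
    }
  }
  c(lines, "END")
}

#' @rdname pdb_text
#' @param path Output file path.
#' @return `write_pdb()` returns `path` invisibly.
#' @export
write_pdb <- function(structure, path) {
  writeLines(pdb_text(structure), path)
  invisible(path)
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Kabsch-Sander style electrostatic H-bond energies between backbone
# N-H (donor, row) and C=O (acceptor, column); TRUE where E < -0.5 kcal/mol.
backbone_hbonds <- function(structure) {
  n <- nrow(structure)
  getbb <- function(i, atom) structure$bb[[i]][atom, ]
  ca <- ca_matrix(structure)
  hb <- matrix(FALSE, n, n)
  # amide H placed along the previous residue's O->C direction
  hpos <- vector("list", n)
  for (i in 2:n) {
    co <- getbb(i - 1L, "C") - getbb(i - 1L, "O")
    hpos[[i]] <- getbb(i, "N") + co / sqrt(sum(co^2))
  }
  q <- 0.084 * 332
  for (i in 2:n) {            # donor NH of residue i
    for (j in seq_len(n)) {   # acceptor CO of residue j
      if (abs(i - j) < 2L) next
      if (sum((ca[i, ] - ca[j, ])^2) > 81) next  # 9 A screen
      Ni <- getbb(i, "N"); Hi <- hpos[[i]]
      Cj <- getbb(j, "C"); Oj <- getbb(j, "O")
      e <- q * (1 / sqrt(sum((Oj - Ni)^2)) + 1 / sqrt(sum((Cj - Hi)^2)) -
                  1 / sqrt(sum((Oj - Hi)^2)) - 1 / sqrt(sum((Cj - Ni)^2)))
      hb[i, j] <- e < -0.5
    }
  }
  hb
}

ss_from_backbone <- function(structure) {
  n <- nrow(structure)
  hb <- backbone_hbonds(structure)
  nonloop <- logical(n)
  # n-turns: CO of j bonded to NH of j + m; two consecutive turns -> helix
  for (m in c(3L, 4L, 5L)) {
    turn <- rep(FALSE, n)
    idx <- seq_len(n - m)
    turn[idx] <- hb[cbind(idx + m, idx)]
    for (j in seq_len(n - m - 1L)) {
      if (turn[j] && turn[j + 1L]) nonloop[(j + 1L):(j + m)] <- TRUE
    }
  }
  # beta bridges (parallel / antiparallel), marked on both partners
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[j, i - 1L] && hb[i + 1L, j]) || (hb[i, j - 1L] && hb[j + 1L, i])
      anti <- (hb[j, i] && hb[i, j]) ||
        (hb[j + 1L, i - 1L] && hb[i + 1L, j - 1L])
      if (par || anti) nonloop[c(i, j)] <- TRUE
    }
  }
  ifelse(nonloop, "non-loop", "loop")
}

# C-alpha-only fallback: virtual dihedrals flag helices; extended residues
# count as strand only when spatially paired with another extended stretch.
ss_from_ca <- function(structure) {
  n <- nrow(structure)
  ca <- ca_matrix(structure)
  if (n < 5L) return(rep("loop", n))
  tau <- rep(NA_real_, n)        # dihedral of window (i-1, i, i+1, i+2)
  d13 <- rep(NA_real_, n)        # CA(i-1)..CA(i+2) span
  for (i in 2:(n - 2L)) {
    tau[i] <- dihedral_deg(ca[i - 1L, ], ca[i, ], ca[i + 1L, ], ca[i + 2L, ])
    d13[i] <- sqrt(sum((ca[i + 2L, ] - ca[i - 1L, ])^2))
  }
  helix_win <- !is.na(tau) & abs(tau) > 35 & abs(tau) < 80 &
    d13 > 4.2 & d13 < 6.2
  nonloop <- logical(n)
  for (i in 2:(n - 3L)) {
    if (helix_win[i] && helix_win[i + 1L])
      nonloop[(i - 1L):(i + 3L)] <- TRUE
  }
  extended <- !is.na(tau) & abs(tau) > 140
  ext_idx <- which(extended)
  if (length(ext_idx) > 1L) {
    d <- as.matrix(stats::dist(ca[ext_idx, , drop = FALSE]))
    sep <- abs(outer(ext_idx, ext_idx, "-"))
    paired <- (d < 6) & (sep >= 3L)
    nonloop[ext_idx[rowSums(paired) > 0]] <- TRUE
  }
  ifelse(nonloop, "non-loop", "loop")
}

#' Assign loop / non-loop labels
#'
#' Labels every residue `"loop"` or `"non-loop"`. When complete backbone
#' N/C/O coordinates are available a Kabsch-Sander-style hydrogen-bond
#' assignment is used (helical turns and beta bridges map to non-loop);
#' with a C-alpha-only trace a virtual-dihedral heuristic detects helices
#' and spatially paired extended strands. Labels already present are kept
#' unless `overwrite = TRUE`. Deterministic for a fixed input.
#'
#' @param structure A `cg_structure`.
#' @param overwrite Recompute labels even if `ss` is already set?
#' @return The structure with its `ss` column filled.
#' @export
assign_secondary_structure <- function(structure, overwrite = FALSE) {
  if (!overwrite && !anyNA(structure$ss)) return(structure)
  n <- nrow(structure)
  if (n < 5L) {
    structure$ss <- rep("loop", n)
    return(structure)
  }
  has_bb <- all(vapply(structure$bb, function(b) !is.null(b) && !anyNA(b),
                       logical(1)))
  structure$ss <- if (has_bb) ss_from_backbone(structure) else
    ss_from_ca(structure)
  structure
}

#' Resolve a deletion segment against a structure
#'
#' Maps inclusive first/last residue keys to a contiguous index range and
#' derives the segment's region: `"loop"` only when every member residue is
#' loop-labeled, `"non-loop"` otherwise. Segments touching the first or last
#' residue of the chain are rejected (terminal deletions are out of scope of
#' the model). Lengths outside the 2..23 range covered by the training
#' regime only raise a warning.
#'
#' @param structure A `cg_structure` with `ss` assigned.
#' @param chain Chain identifier.
#' @param first,last Author residue numbers (inclusive).
#' @param ins_first,ins_last Insertion codes of the two keys.
#' @param region Optional externally supplied region label
#'   (`"loop"`/`"non-loop"`), which overrides the computed one.
#' @return One-row tibble: `chain`, `first_res`, `last_res`, `n_AA`,
#'   `region`, and a list-column `residue_indices` of row indices into
#'   `structure`.
#' @export
resolve_segment <- function(structure, chain, first, last,
                            ins_first = "", ins_last = "", region = NULL) {
  idx_chain <- which(structure$chain == chain)
  if (!length(idx_chain))
    abort(paste0("Chain '", chain, "' not in structure; available: {",
                 paste(unique(structure$chain), collapse = ", "), "}."))
  find_key <- function(resno, ins) {
    i <- which(structure$chain == chain & structure$resno == resno &
                 structure$ins == ins)
    if (!length(i))
      abort(paste0("Residue key (", chain, ", ", resno,
                   if (nzchar(ins)) paste0(", '", ins, "'") else "",
                   ") not found."))
    i[1L]
  }
  i1 <- find_key(first, ins_first)
  i2 <- find_key(last, ins_last)
  if (i1 > i2) abort("First residue key follows the last one in chain order.")
  if (i1 == min(idx_chain) || i2 == max(idx_chain))
    abort("Segment touches a chain terminus; terminal deletions are not modeled.")
  idx <- seq.int(i1, i2)
  n_aa <- length(idx)
  if (n_aa < 2L || n_aa > 23L)
    warn(paste0("Segment length ", n_aa,
                " is outside the modeled range 2..23."))
  computed <- if (all(structure$ss[idx] == "loop")) "loop" else "non-loop"
  if (!is.null(region) && !is.na(region)) {
    region <- match.arg(region, c("loop", "non-loop"))
  } else {
    region <- computed
  }
  tibble(
    chain = chain, first_res = first, last_res = last, n_AA = n_aa,
    region = region, residue_indices = list(idx)
  )
}

#' Read / write deletion-segment tables
#'
#' Segment tables are CSV files with header
#' `source_id,chain,first_res,last_res` plus optional `region`
#' (`loop`/`non-loop`, overrides the computed label) and `label`
#' (`positive`/`unlabeled`).
#'
#' @param path CSV file path.
#' @return A tibble of segments.
#' @export
read_segment_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("source_id", "chain", "first_res", "last_res")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort(paste0("Segment table missing columns: ", paste(miss, collapse = ", ")))
  if ("region" %in% names(tab)) {
    bad <- !is.na(tab$region) & !tab$region %in% c("loop", "non-loop")
    if (any(bad)) abort("Segment table 'region' must be loop or non-loop.")
  }
  if ("label" %in% names(tab)) {
    bad <- !is.na(tab$label) & !tab$label %in% c("positive", "unlabeled")
    if (any(bad)) abort("Segment table 'label' must be positive or unlabeled.")
  }
  tab
}

#' @rdname read_segment_table
#' @param segments Tibble of segments.
#' @export
write_segment_table <- function(segments, path) {
  keep <- intersect(c("source_id", "chain", "first_res", "last_res",
                      "region", "label"), names(segments))
  readr::write_csv(segments[, keep], path)
  invisible(path)
}

#' Tally a segment table by label and region
#'
#' Audit helper for externally curated deletion cohorts: counts segments by
#' `label` (positive / unlabeled) overall and within each `region`.
#'
#' @param segments Tibble from [read_segment_table()] with `label` (and
#'   optionally `region`) columns.
#' @return Tibble with `region` (`"all"` first), `positive`, `unlabeled`.
#' @export
cohort_counts <- function(segments) {
  if (!"label" %in% names(segments))
    abort("Segment table has no 'label' column to tally.")
  tally <- function(tab, name) tibble(
    region = name,
    positive = sum(tab$label == "positive", na.rm = TRUE),
    unlabeled = sum(tab$label == "unlabeled", na.rm = TRUE)
  )
  out <- tally(segments, "all")
  if ("region" %in% names(segments)) {
    for (r in sort(unique(segments$region)))
      out <- dplyr::bind_rows(out, tally(segments[segments$region %in% r, ],
                                         r))
  }
  out
}

#' C-alpha RMSD between two structures
#'
#' Optimally superposes the C-alpha traces (least-squares fit) and returns
#' the root-mean-square deviation in Angstrom. With `paired_only = TRUE`
#' (default) the shorter structure is compared against the equally long
#' leading stretch of the other; for unrelated chains supply your own
#' residue pairing by subsetting beforehand.
#'
#' @param a,b `cg_structure` tibbles.
#' @param fit Superpose before measuring? (`FALSE`: RMSD in the given
#'   frames.)
#' @return RMSD in Angstrom (numeric scalar).
#' @export
ca_rmsd <- function(a, b, fit = TRUE) {
  n <- min(nrow(a), nrow(b))
  if (n < 3L) abort("Need at least 3 paired residues.")
  xa <- as.vector(t(ca_matrix(a)[seq_len(n), ]))
  xb <- as.vector(t(ca_matrix(b)[seq_len(n), ]))
  idx <- seq_len(3L * n)
  if (fit) xb <- bio3d::fit.xyz(fixed = xa, mobile = xb,
                                fixed.inds = idx, mobile.inds = idx)
  bio3d::rmsd(xa, xb)
}
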