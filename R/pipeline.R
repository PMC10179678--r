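#' Declarative run configuration
#'
#' Gathers every tunable of the feature pipeline and classifier in one
#' validated object. The configuration is hashed ([config_hash()]) and the
#' hash is stamped into every output file, so tables computed under
#' different elastic-network parameters refuse to mix silently.
#'
#' @param params An [enm_params()] object.
#' @param mode_fraction Fraction of internal GNM modes treated as global /
#'   local (default 2%).
#' @param hinge_flank Hinge co-localization window in residues (default 0).
#' @param stiffness_stat Per-residue reduction of the pair stiffness map.
#' @param num_trees,mtry Random-forest size and features per split.
#' @param cv_folds Cross-validation folds (5 or 10).
#' @param threshold Decision threshold on the stage-2 probability.
#' @param region_scope Segment subset a classifier is trained on.
#' @param seed Root seed for all randomness.
#' @return A `run_config` list.
#' @export
run_config <- function(params = enm_params(), mode_fraction = 0.02,
                       hinge_flank = 0L, stiffness_stat = c("mean", "max"),
                       num_trees = 500L, mtry = NULL, cv_folds = 10L,
                       threshold = 0.5,
                       region_scope = c("all", "loop", "non-loop"),
                       seed = 1L) {
  stiffness_stat <- match.arg(stiffness_stat)
  region_scope <- match.arg(region_scope)
  stopifnot(
    inherits(params, "enm_params"),
    mode_fraction > 0, mode_fraction <= 1,
    hinge_flank >= 0L, num_trees >= 1L,
    cv_folds %in% c(5L, 10L),
    threshold > 0, threshold < 1
  )
  structure(
    list(params = params, mode_fraction = mode_fraction,
         hinge_flank = as.integer(hinge_flank),
         stiffness_stat = stiffness_stat, num_trees = as.integer(num_trees),
         mtry = mtry, cv_folds = as.integer(cv_folds), threshold = threshold,
         region_scope = region_scope, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> hash:", config_hash(x), "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; used for provenance stamping of
#' output tables.
#'
#' @param config A [run_config()].
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(tbl, path, config) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# deldyn_config_hash: ", config_hash(config)), con,
             sep = "\n")
  drop <- names(tbl)[vapply(tbl, is.list, logical(1))]
  readr::write_csv(tbl[, setdiff(names(tbl), drop)], con)
  invisible(path)
}

#' Read a feature table, checking configuration provenance
#'
#' Refuses to load a table whose stamped configuration hash differs from
#' the supplied configuration (pass `config = NULL` to skip the check).
#'
#' @param path CSV written by [run_pipeline()] or [write_stamped_csv()].
#' @param config The [run_config()] the caller intends to use.
#' @return A tibble.
#' @export
read_stamped_csv <- function(path, config = NULL) {
  first <- readLines(path, n = 1L)
  stamped <- sub("^# deldyn_config_hash: ", "", first)
  if (!is.null(config)) {
    want <- config_hash(config)
    if (!startsWith(first, "# deldyn_config_hash: ") || stamped != want)
      abort(paste0(
        "Configuration mismatch for '", path, "': file was computed under ",
        if (startsWith(first, "#")) stamped else "an unstamped configuration",
        " but the current configuration hashes to ", want,
        ". Recompute the table or load it with config = NULL."
      ))
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run the feature pipeline end to end
#'
#' For every (structure, chain) referenced by the segment table: parse the
#' PDB file, assign secondary structure, compute the six per-residue
#' dynamics profiles, aggregate them over each deletion segment, and write
#' one per-residue profile CSV per chain plus a combined per-segment
#' feature CSV. Outputs are stamped with the configuration hash and the
#' run is fully deterministic, so re-running with identical inputs
#' reproduces identical files.
#'
#' @param config A [run_config()].
#' @param pdb_files Named character vector mapping `source_id` values of
#'   the segment table to PDB file paths.
#' @param segments Segment table (tibble or CSV path; see
#'   [read_segment_table()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the feature tibble and the written paths.
#' @export
run_pipeline <- function(config, pdb_files, segments, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(segments) && length(segments) == 1L)
    segments <- read_segment_table(segments)
  pdb_files <- unlist(pdb_files)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  feature_rows <- list()
  profile_paths <- character(0)
  for (sid in unique(segments$source_id)) {
    path <- unname(pdb_files[sid])
    if (length(path) != 1L || is.null(path) || is.na(path))
      abort(paste0("No PDB file supplied for source_id '", sid, "'."))
    if (!file.exists(path))
      abort(paste0("PDB file not found for '", sid, "': ", path))
    seg_s <- segments[segments$source_id == sid, , drop = FALSE]
    for (ch in unique(seg_s$chain)) {
      s <- tryCatch(
        assign_secondary_structure(read_pdb(path, chain = ch)),
        error = function(e) abort(paste0(
          "Stage structure_io failed for ", sid, ":", ch, " -- ",
          conditionMessage(e)))
      )
      prof <- tryCatch(
        residue_dynamics(s, params = config$params,
                         mode_fraction = config$mode_fraction,
                         stiffness_stat = config$stiffness_stat),
        error = function(e) abort(paste0(
          "Stage dynamics failed for ", sid, ":", ch, " -- ",
          conditionMessage(e)))
      )
      ppath <- file.path(out_dir, paste0("profiles_", sid, "_", ch, ".csv"))
      write_stamped_csv(prof, ppath, config)
      profile_paths <- c(profile_paths, ppath)
      seg_c <- seg_s[seg_s$chain == ch, , drop = FALSE]
      resolved <- dplyr::bind_rows(lapply(seq_len(nrow(seg_c)), function(i) {
        tryCatch(
          resolve_segment(s, ch, seg_c$first_res[i], seg_c$last_res[i],
                          region = if ("region" %in% names(seg_c))
                            seg_c$region[i] else NULL),
          error = function(e) abort(paste0(
            "Stage segment resolution failed for ", sid, ":", ch, " ",
            seg_c$first_res[i], "-", seg_c$last_res[i], " -- ",
            conditionMessage(e)))
        )
      }))
      feats <- segment_features(
        prof, resolved,
        labels = if ("label" %in% names(seg_c)) seg_c$label else NULL,
        hinge_flank = config$hinge_flank
      )
      feats$source_id <- sid
      feats$segment_id <- paste(sid, ch, feats$first_res, feats$last_res,
                                sep = ":")
      feature_rows[[paste(sid, ch)]] <- feats
    }
  }
  features <- dplyr::bind_rows(feature_rows)
  fpath <- file.path(out_dir, "segment_features.csv")
  write_stamped_csv(features, fpath, config)
  invisible(list(features = features, feature_csv = fpath,
                 profile_csvs = profile_paths,
                 config_hash = config_hash(config)))
}
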