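DYNAMICS_TRACKS <- c("effectiveness", "essa", "msf_global", "msf_local",
                     "sensitivity", "stiffness")
SEGMENT_STATS <- c("max", "mean", "min", "z_max", "z_mean", "z_min")

#' Canonical names of the 37 segment features
#'
#' Six summary statistics (min/max/mean of the raw track and of its
#' whole-protein Z-scores) for each of the six dynamics profiles, sorted
#' alphabetically by (track, statistic) so serialized vectors are stable,
#' plus the binary `hinge_colocalized` flag last.
#'
#' @return Character vector of length 37.
#' @export
dynamics_feature_names <- function() {
  nm <- as.vector(outer(DYNAMICS_TRACKS, SEGMENT_STATS, paste, sep = "_"))
  c(sort(nm), "hinge_colocalized")
}

#' Aggregate per-residue profiles over a deletion segment
#'
#' Reduces the six dynamics tracks of [residue_dynamics()] to the
#' 37-component feature vector of one deletion segment: min, max and mean of
#' each raw track over the segment residues, the same three statistics of
#' the whole-protein Z-scored track (never re-normalized within the
#' segment), and a flag recording whether the segment contains a
#' global-mode hinge residue.
#'
#' @param profiles A `residue_profiles` tibble.
#' @param segment One-row tibble from [resolve_segment()] (needs
#'   `residue_indices`, `region` and the key columns).
#' @param hinge_flank Hinge co-localization window: a segment counts as
#'   hinge-co-localized when it comes within `hinge_flank` residues of a
#'   hinge (0 = the hinge itself must be deleted).
#' @return One-row tibble: segment metadata followed by the 37 features in
#'   [dynamics_feature_names()] order.
#' @export
aggregate_segment <- function(profiles, segment, hinge_flank = 0L) {
  idx <- segment$residue_indices[[1L]]
  if (!length(idx)) abort("Empty segment.")
  if (any(idx < 1L) || any(idx > nrow(profiles)))
    abort("Segment indices outside the profile table.")
  vals <- list()
  for (tr in DYNAMICS_TRACKS) {
    raw <- profiles[[tr]][idx]
    z <- profiles[[paste0("z_", tr)]][idx]
    vals[[paste0(tr, "_min")]] <- min(raw)
    vals[[paste0(tr, "_max")]] <- max(raw)
    vals[[paste0(tr, "_mean")]] <- mean(raw)
    vals[[paste0(tr, "_z_min")]] <- min(z)
    vals[[paste0(tr, "_z_max")]] <- max(z)
    vals[[paste0(tr, "_z_mean")]] <- mean(z)
  }
  hinge_set <- attr(profiles, "hinge_residues")
  if (hinge_flank > 0L)
    hinge_set <- unique(unlist(lapply(hinge_set, function(h)
      seq.int(h - hinge_flank, h + hinge_flank))))
  vals[["hinge_colocalized"]] <- as.numeric(any(idx %in% hinge_set))
  meta <- tibble(
    source_id = attr(profiles, "source_id") %||% NA_character_,
    chain = segment$chain, first_res = segment$first_res,
    last_res = segment$last_res, n_AA = segment$n_AA,
    region = segment$region
  )
  dplyr::bind_cols(meta, as_tibble(vals[dynamics_feature_names()]))
}

#' Feature matrix for a set of deletion segments
#'
#' @param profiles A `residue_profiles` tibble.
#' @param segments Tibble of resolved segments ([resolve_segment()] rows).
#' @param labels Optional per-segment labels (`"positive"`, `"unlabeled"`);
#'   recycled `"unknown"` when absent.
#' @inheritParams aggregate_segment
#' @return Tibble with one row per segment: `segment_id`, `label`, metadata
#'   and the 37 features.
#' @export
segment_features <- function(profiles, segments, labels = NULL,
                             hinge_flank = 0L) {
  rows <- lapply(seq_len(nrow(segments)), function(i)
    aggregate_segment(profiles, segments[i, ], hinge_flank = hinge_flank))
  out <- dplyr::bind_rows(rows)
  out$label <- if (is.null(labels)) "unknown" else labels
  out$segment_id <- paste(out$source_id, out$chain, out$first_res,
                          out$last_res, sep = ":")
  dplyr::relocate(out, "segment_id", "label")
}

#' Merge an externally computed feature table
#'
#' Joins opaque per-segment features (e.g. sequence/structure/environment
#' descriptors computed elsewhere) onto the dynamics feature matrix by
#' `segment_id`. All external feature columns are prefixed (default
#' `ext_`), so name collisions with the dynamics features are impossible
#' and nothing is silently overwritten. Segments without an external row
#' are dropped with a warning; non-numeric external features are an error.
#'
#' @param features Output of [segment_features()].
#' @param external Data frame keyed by `segment_id` whose remaining columns
#'   are numeric features.
#' @param prefix Prefix applied to external column names.
#' @param drop_cols External columns to drop before merging (e.g.
#'   loop-specific descriptors when building an all-regions table).
#' @return The combined tibble.
#' @export
merge_external <- function(features, external, prefix = "ext_",
                           drop_cols = character()) {
  external <- as_tibble(external)
  if (!nrow(external) || ncol(external) < 2L) {
    warn("Empty external table; returning dynamics features unchanged.")
    return(features)
  }
  if (!"segment_id" %in% names(external))
    abort("External table needs a 'segment_id' column.")
  external <- external[, setdiff(names(external), drop_cols), drop = FALSE]
  feat_cols <- setdiff(names(external), "segment_id")
  not_num <- feat_cols[!vapply(external[feat_cols], is.numeric, logical(1))]
  if (length(not_num))
    abort(paste0("Non-numeric external feature(s): ",
                 paste(not_num, collapse = ", ")))
  names(external)[match(feat_cols, names(external))] <-
    paste0(prefix, feat_cols)
  missing <- setdiff(features$segment_id, external$segment_id)
  if (length(missing)) {
    warn(paste0(length(missing),
                " segment(s) without an external row were excluded."))
    features <- features[!features$segment_id %in% missing, , drop = FALSE]
  }
  dplyr::inner_join(features, external, by = "segment_id")
}
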