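# Gallery identity classification.
#
# Identities follow the branching rules used for termite foraging tunnels:
#   i.   galleries originating from the start point are primary (rank 1);
#   ii.  a gallery emerging from the side of a pre-existing gallery is a
#        descendant: its rank is the parent's rank + 1;
#   iii. at a split, the branch with the shallower angle keeps the parent's
#        identity (a drawing convention the user follows; validated, not
#        enforced, by split_inheritance_check());
#   iv.  where a gallery merges into a pre-existing gallery its polyline ends
#        (reported as merged_end).

split_galleries <- function(points_df) {
  if (!is.data.frame(points_df) || !all(c("gallery_id", "x", "y") %in% names(points_df))) {
    abort("`points_df` must have columns gallery_id, x, y.")
  }
  id <- as.character(points_df$gallery_id)
  x <- as.numeric(points_df$x)
  y <- as.numeric(points_df$y)
  idx <- split(seq_along(id), factor(id, levels = sort(unique(id))))
  lapply(idx, function(i) cbind(x = x[i], y = y[i]))
}

#' Find the parent gallery of a branch
#'
#' A gallery descends from the pre-existing gallery whose polyline is nearest
#' to its start point, provided that distance is strictly below the contact
#' threshold. Ties are broken by smallest distance, then by
#' lexicographically first gallery id.
#'
#' @param points_df Gallery polylines for one image as a data frame
#'   `(gallery_id, x, y)`, points in drawing order.
#' @param gallery_id Id of the gallery whose parent is sought.
#' @param threshold_px Contact threshold in pixels.
#' @return A one-row tibble `(parent_id, attach_arclength_px, distance_px)`;
#'   `parent_id` is `NA` when no gallery is within the threshold.
#' @export
find_parent <- function(points_df, gallery_id, threshold_px) {
  gals <- split_galleries(points_df)
  if (!gallery_id %in% names(gals)) {
    abort(sprintf("No gallery %s in `points_df`.", sQuote(gallery_id)))
  }
  find_parent_impl(gals, gallery_id, threshold_px)
}

find_parent_impl <- function(gals, gallery_id, threshold_px) {
  start <- gals[[gallery_id]][1, , drop = FALSE]
  other_ids <- setdiff(names(gals), gallery_id)
  if (length(other_ids) == 0) {
    return(tibble(parent_id = NA_character_, attach_arclength_px = NA_real_,
                  distance_px = NA_real_))
  }
  dist <- numeric(length(other_ids))
  arc <- numeric(length(other_ids))
  for (j in seq_along(other_ids)) {
    d <- ptpd_impl(start, gals[[other_ids[j]]])
    dist[j] <- d$distance
    arc[j] <- d$arclength
  }
  # ids are already sorted, so which.min's first-minimum rule is the
  # smallest-distance-then-lexicographic tie-break
  i <- which.min(dist)
  if (dist[i] < threshold_px) {
    tibble(parent_id = other_ids[i], attach_arclength_px = arc[i],
           distance_px = dist[i])
  } else {
    tibble(parent_id = NA_character_, attach_arclength_px = NA_real_,
           distance_px = NA_real_)
  }
}

#' Assign identity ranks to an image's galleries
#'
#' Applies the branching rules to one image: galleries starting at an
#' entrance point (or, when no entrance points are given, galleries with no
#' parent in contact) are primary (rank 1); every descendant's rank is its
#' parent's rank + 1, resolved by iterating to a fixed point. A gallery whose
#' end point touches another gallery is flagged `merged_end`. Galleries whose
#' rank cannot be resolved (circular parentage, or no entrance and no parent
#' when entrances are given) are flagged `unclassified` with a warning, never
#' silently ranked.
#'
#' The result does not depend on the row order of `points_df`; rows are
#' returned sorted by `gallery_id`.
#'
#' @inheritParams find_parent
#' @param entrance_points Optional entrance coordinates (n x 2 matrix or x/y
#'   data frame) in the same frame as `points_df`, or `NULL`.
#' @return A tibble with one row per gallery: `gallery_id`, `rank`,
#'   `parent_id`, `attach_arclength_px`, `merged_end`, `length_px`,
#'   `unclassified`.
#' @export
assign_identities <- function(points_df, threshold_px, entrance_points = NULL) {
  gals <- split_galleries(points_df)
  ids <- names(gals)
  n <- length(ids)
  if (n == 0) {
    return(tibble(
      gallery_id = character(), rank = integer(), parent_id = character(),
      attach_arclength_px = numeric(), merged_end = logical(),
      length_px = numeric(), unclassified = logical()
    ))
  }
  if (anyDuplicated(points_df$gallery_id[!duplicated(points_df$gallery_id)])) {
    abort("Gallery ids must be unique within an image.")
  }
  ent <- if (is.null(entrance_points)) NULL else as_xy(entrance_points, "entrance_points")

  parents <- lapply(ids, function(id) find_parent_impl(gals, id, threshold_px))
  parent_id <- vapply(parents, function(p) p$parent_id, character(1))
  attach_arc <- vapply(parents, function(p) p$attach_arclength_px, numeric(1))

  at_entrance <- vapply(seq_len(n), function(i) {
    if (is.null(ent)) return(FALSE)
    start <- gals[[i]][1, ]
    any(sqrt((ent[, 1] - start[1])^2 + (ent[, 2] - start[2])^2) < threshold_px)
  }, logical(1))

  is_primary <- if (is.null(ent)) is.na(parent_id) else at_entrance
  parent_id[is_primary] <- NA_character_
  attach_arc[is_primary] <- NA_real_

  rank <- ifelse(is_primary, 1L, NA_integer_)
  for (iter in seq_len(n)) {
    changed <- FALSE
    for (i in which(is.na(rank))) {
      p <- match(parent_id[i], ids)
      if (!is.na(p) && !is.na(rank[p])) {
        rank[i] <- rank[p] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unclassified <- is.na(rank)
  if (any(unclassified)) {
    warn(sprintf(
      "Could not resolve the identity of gallery(ies) %s (circular or orphaned parentage).",
      paste(sQuote(ids[unclassified]), collapse = ", ")
    ))
  }

  merged_end <- vapply(seq_len(n), function(i) {
    end <- gals[[i]][nrow(gals[[i]]), , drop = FALSE]
    any(vapply(seq_len(n)[-i], function(j) {
      ptpd_impl(end, gals[[j]])$distance < threshold_px
    }, logical(1)))
  }, logical(1))

  tibble(
    gallery_id = ids,
    rank = rank,
    parent_id = parent_id,
    attach_arclength_px = attach_arc,
    merged_end = merged_end,
    length_px = unname(vapply(gals, polyline_length, numeric(1))),
    unclassified = unclassified
  )
}

#' Which branch of a split keeps the parent identity?
#'
#' At a split, the branch whose direction deviates least from the incoming
#' direction of the parent retains the parent's identity; the other branch is
#' a descendant. This helper validates that a drawing follows the convention
#' (and drives the synthetic generator's ground truth); it does not
#' re-segment the user's polylines.
#'
#' @param parent_dir Incoming direction of the parent at the split, `c(x, y)`.
#' @param child_dirs A 2-row matrix (or 2-row x/y data frame) of outgoing
#'   branch directions.
#' @return Index (1 or 2) of the identity-retaining branch. Exact ties return
#'   1 with a warning.
#' @export
split_inheritance_check <- function(parent_dir, child_dirs) {
  p <- as.numeric(as_xy(parent_dir, "parent_dir")[1, ])
  cd <- as_xy(child_dirs, "child_dirs")
  if (nrow(cd) != 2) abort("`child_dirs` must contain exactly 2 directions.")
  if (sqrt(sum(p^2)) == 0 || any(sqrt(cd[, 1]^2 + cd[, 2]^2) == 0)) {
    abort("Direction vectors must be nonzero.")
  }
  pn <- p / sqrt(sum(p^2))
  ang <- vapply(1:2, function(i) {
    v <- cd[i, ] / sqrt(sum(cd[i, ]^2))
    acos(pmin(1, pmax(-1, sum(pn * v))))
  }, numeric(1))
  if (isTRUE(all.equal(ang[1], ang[2]))) {
    warn("Both branches deviate equally from the parent direction; keeping the first.")
    return(1L)
  }
  which.min(ang)
}

#' Pool per-rank lengths into the reporting categories
#'
#' Summaries report ranks 1, 2, 3 separately and pool rank 4 and deeper into
#' one category; the per-gallery table keeps the true ranks.
#'
#' @param classified Output of [assign_identities()].
#' @param mm_per_px Calibration factor applied to lengths.
#' @return A one-row tibble `(len1_mm, len2_mm, len3_mm, len4plus_mm,
#'   total_mm)`.
#' @export
rank_length_summary <- function(classified, mm_per_px = 1) {
  # scale each gallery first, then sum, so totals are bit-identical to
  # re-aggregating the per-gallery mm column
  len_mm <- classified$length_px * mm_per_px
  r <- classified$rank
  tibble(
    len1_mm = sum(len_mm[!is.na(r) & r == 1L]),
    len2_mm = sum(len_mm[!is.na(r) & r == 2L]),
    len3_mm = sum(len_mm[!is.na(r) & r == 3L]),
    len4plus_mm = sum(len_mm[!is.na(r) & r >= 4L]),
    total_mm = sum(len_mm)
  )
}
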