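# Temporal logic across an image series: copy-forward of skipped images,
# zero records for empty images, the append-mode consistency check, and the
# per-image time series of per-rank lengths, counts and growth increments.

#' Resolve a group's series (copy-forward of skipped images)
#'
#' A skipped image inherits a deep copy of the nearest preceding analyzed or
#' empty image's galleries; inheritance is transitive across runs of skipped
#' images. Reference points and scale lines absent from an image are also
#' inherited from the nearest preceding image that has one (the scale object
#' is typically traced once per sequence). An empty image resolves to zero
#' galleries. The first image of a group may not be skipped.
#'
#' Materialization is idempotent: resolving an already-resolved series again
#' changes nothing.
#'
#' @param project A `gallery_project`.
#' @param group_id Image group id.
#' @return The group's annotations, in serial order, fully resolved.
#' @export
materialize_series <- function(project, group_id) {
  anns <- group_annotations(project, group_id)
  prev <- NULL
  prev_ref <- NULL
  prev_scale <- NULL
  out <- vector("list", length(anns))
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    if (a$status == "skipped") {
      if (is.null(prev)) {
        abort(sprintf(
          "Group %s: serial %d is skipped but has no preceding image to inherit from.",
          group_id, a$serial
        ))
      }
      a$galleries <- prev$galleries
      if (is.null(a$ref_point)) a$ref_point <- prev_ref
      if (is.null(a$scale_line)) a$scale_line <- prev_scale
    } else {
      if (a$status == "empty") a$galleries <- empty_galleries()
      if (is.null(a$scale_line) && !is.null(prev_scale)) a$scale_line <- prev_scale
    }
    if (!is.null(a$ref_point)) prev_ref <- a$ref_point
    if (!is.null(a$scale_line)) prev_scale <- a$scale_line
    prev <- a
    out[[i]] <- a
  }
  out
}

ref_corrected_galleries <- function(ann) {
  translate_to_ref(ann$galleries, ann$ref_point)
}

ann_mm_per_px <- function(ann, scale_mm) {
  if (is.null(ann$scale_line)) 1 else scale_factor(ann$scale_line, scale_mm)
}

#' Check that galleries only extend between two images
#'
#' Under append mode, every gallery of the earlier image must reappear in the
#' later one with its (reference-corrected) points as a prefix of the later
#' polyline, each vertex within `tol_px`. Shortened, missing or re-routed
#' galleries are returned as violations — data, not errors, so batch runs can
#' report them with provenance. When the later image has `append_mode =
#' FALSE` (the "not appending" escape for backfilled structures), every
#' change is permitted and no violations are returned.
#'
#' @param prev,curr Two resolved annotations (see [materialize_series()]),
#'   `prev` the earlier one.
#' @param tol_px Per-vertex tolerance in pixels; defaults to the project
#'   threshold at the call sites. Re-clicked inherited points may jitter, so
#'   exact equality is not required.
#' @return A tibble of violations `(gallery_id, reason)`; zero rows when
#'   consistent.
#' @export
check_append_consistency <- function(prev, curr, tol_px) {
  no_violation <- tibble(gallery_id = character(), reason = character())
  if (!isTRUE(curr$append_mode)) {
    return(no_violation)
  }
  pg <- ref_corrected_galleries(prev)
  cg <- ref_corrected_galleries(curr)
  out <- list()
  for (id in unique(pg$gallery_id)) {
    p <- pg[pg$gallery_id == id, ]
    q <- cg[cg$gallery_id == id, ]
    if (nrow(q) == 0) {
      out[[length(out) + 1]] <- tibble(gallery_id = id, reason = "gallery disappeared")
    } else if (nrow(q) < nrow(p)) {
      out[[length(out) + 1]] <- tibble(gallery_id = id, reason = "gallery shortened")
    } else {
      d <- sqrt((p$x - q$x[seq_len(nrow(p))])^2 + (p$y - q$y[seq_len(nrow(p))])^2)
      if (any(d > tol_px)) {
        shrunk <- polyline_length(q[, c("x", "y")]) <
          polyline_length(p[, c("x", "y")]) - tol_px
        out[[length(out) + 1]] <- tibble(
          gallery_id = id,
          reason = if (shrunk) "gallery shortened" else "earlier points moved"
        )
      }
    }
  }
  if (length(out) == 0) no_violation else bind_rows(out)
}

#' Append-consistency violations across a whole group
#'
#' Runs [check_append_consistency()] over every consecutive pair of the
#' resolved series.
#'
#' @inheritParams materialize_series
#' @param tol_px Per-vertex tolerance; defaults to the project threshold.
#' @return A tibble `(group_id, serial, gallery_id, reason)`, where `serial`
#'   is the later image of the offending pair.
#' @export
check_group_consistency <- function(project, group_id, tol_px = project$threshold_px) {
  series <- materialize_series(project, group_id)
  out <- list()
  if (length(series) >= 2) {
    for (i in seq_len(length(series) - 1)) {
      v <- check_append_consistency(series[[i]], series[[i + 1]], tol_px)
      if (nrow(v) > 0) {
        v$group_id <- group_id
        v$serial <- series[[i + 1]]$serial
        out[[length(out) + 1]] <- v
      }
    }
  }
  if (length(out) == 0) {
    tibble(group_id = character(), serial = integer(),
           gallery_id = character(), reason = character())
  } else {
    bind_rows(out)[, c("group_id", "serial", "gallery_id", "reason")]
  }
}

# Full analysis of one resolved annotation: classification + network.
analyze_annotation <- function(ann, project, group_id) {
  gal <- ref_corrected_galleries(ann)
  mm_per_px <- ann_mm_per_px(ann, project$scale_mm)
  ent <- project$entrance_points[[group_id]]
  classified <- assign_identities(gal, project$threshold_px, ent)
  net <- build_network(gal, project$threshold_px, classified = classified,
                       entrance_points = ent, mm_per_px = mm_per_px)
  list(classified = classified, net = net, mm_per_px = mm_per_px, galleries = gal)
}

#' Per-image time series of a group
#'
#' One record per serial, in order: per-rank lengths (ranks 1-3 and ">= 4"
#' pooled), total length, gallery and node/edge counts — all in mm via each
#' image's scale line — and the growth increment over the previous serial
#' (the first serial's increment is its own total). Skipped images reproduce
#' their predecessor's record with a zero increment; empty images yield
#' all-zero metrics.
#'
#' @inheritParams materialize_series
#' @return A tibble with columns `group_id`, `serial`, `status`, `total_mm`,
#'   `len1_mm`, `len2_mm`, `len3_mm`, `len4plus_mm`, `n_galleries`,
#'   `n_nodes`, `n_edges`, `growth_mm`.
#' @export
compute_series <- function(project, group_id) {
  series <- materialize_series(project, group_id)
  prev_total <- 0
  out <- vector("list", length(series))
  for (i in seq_along(series)) {
    ann <- series[[i]]
    res <- withCallingHandlers(
      analyze_annotation(ann, project, group_id),
      warning = function(w) {
        warn(sprintf("[%s serial %d] %s", group_id, ann$serial, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    lens <- rank_length_summary(res$classified, res$mm_per_px)
    s <- network_summary(res$net)
    out[[i]] <- tibble(
      group_id = group_id,
      serial = ann$serial,
      status = ann$status,
      total_mm = lens$total_mm,
      len1_mm = lens$len1_mm, len2_mm = lens$len2_mm,
      len3_mm = lens$len3_mm, len4plus_mm = lens$len4plus_mm,
      n_galleries = length(unique(res$classified$gallery_id)),
      n_nodes = s$n_nodes, n_edges = s$n_edges,
      growth_mm = lens$total_mm - prev_total
    )
    prev_total <- lens$total_mm
  }
  bind_rows(out)
}

#' Plot the temporal development of total length
#'
#' @param records Per-image records from [compute_series()] (rows from
#'   several groups may be bound together).
#' @return A ggplot of total length (mm) against serial, one line per group.
#' @export
plot_series <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$serial, y = .data$total_mm,
    colour = .data$group_id, group = .data$group_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "image serial", y = "total gallery length (mm)",
                  colour = "group") +
    ggplot2::theme_minimal()
}
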