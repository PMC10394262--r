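# Reduction of classified galleries to a graph of typed nodes and measured
# edges. Candidate nodes are gallery start/end points plus branch attachment
# and merge points projected onto the gallery they touch; candidates within
# the snapping threshold collapse into one node, and every gallery polyline
# is split into edges at the interior nodes lying on it, so edge lengths are
# measured along the drawn skeleton and sum exactly to the gallery lengths.

node_type_levels <- c("entrance", "intersection", "end")

#' Build the gallery network of one image
#'
#' @param points_df Gallery polylines `(gallery_id, x, y)` in the
#'   reference-corrected frame.
#' @param threshold_px Snapping threshold in pixels.
#' @param classified Output of [assign_identities()] for the same galleries;
#'   computed on the fly when `NULL`. Must contain no unclassified gallery.
#' @param entrance_points Optional entrance coordinates (same frame).
#' @param mm_per_px Calibration factor for the `_mm` columns.
#' @return A `gallery_network`: a list with tibbles `nodes` (`node_id`, `x`,
#'   `y`, `x_mm`, `y_mm`, `degree`, `type`) and `edges` (`node_a`, `node_b`,
#'   `gallery_id`, `length_px`, `length_mm`). Node types: `entrance` (the
#'   cluster contains an entrance point), `end` (degree 1), `intersection`
#'   (anything else).
#' @export
build_network <- function(points_df, threshold_px, classified = NULL,
                          entrance_points = NULL, mm_per_px = 1) {
  if (is.null(classified)) {
    classified <- assign_identities(points_df, threshold_px, entrance_points)
  }
  if (any(classified$unclassified)) {
    abort(paste(
      "Cannot build a network with unclassified galleries",
      sprintf("(%s);", paste(sQuote(classified$gallery_id[classified$unclassified]), collapse = ", ")),
      "see the warnings raised by assign_identities()."
    ))
  }
  gals <- split_galleries(points_df)
  ids <- names(gals)
  ent <- if (is.null(entrance_points)) NULL else as_xy(entrance_points, "entrance_points")

  cand <- list()
  for (id in ids) {
    m <- gals[[id]]
    L <- polyline_length(m)
    cand[[length(cand) + 1]] <- tibble(
      x = c(m[1, 1], m[nrow(m), 1]), y = c(m[1, 2], m[nrow(m), 2]),
      on_gallery = id, arclength = c(0, L), is_entrance = FALSE
    )
  }
  # branch attachment points, projected onto the parent
  att <- classified[!is.na(classified$parent_id), , drop = FALSE]
  if (nrow(att) > 0) {
    for (k in seq_len(nrow(att))) {
      p <- point_at_arclength(gals[[att$parent_id[k]]], att$attach_arclength_px[k])
      cand[[length(cand) + 1]] <- tibble(
        x = p[["x"]], y = p[["y"]],
        on_gallery = att$parent_id[k], arclength = att$attach_arclength_px[k],
        is_entrance = FALSE
      )
    }
  }
  # merge points: a gallery's end projected onto the gallery it runs into
  mrg <- classified[classified$merged_end, , drop = FALSE]
  if (nrow(mrg) > 0) {
    for (k in seq_len(nrow(mrg))) {
      end <- gals[[mrg$gallery_id[k]]]
      end <- end[nrow(end), ]
      hits <- imap(gals[setdiff(ids, mrg$gallery_id[k])], function(m, id) {
        d <- point_to_polyline_distance(end, m)
        tibble(on_gallery = id, arclength = d$arclength, distance = d$distance,
               x = d$closest[["x"]], y = d$closest[["y"]])
      }) |> bind_rows() |> arrange(.data$distance, .data$on_gallery)
      best <- hits[1, ]
      if (best$distance < threshold_px) {
        cand[[length(cand) + 1]] <- tibble(
          x = best$x, y = best$y,
          on_gallery = best$on_gallery, arclength = best$arclength,
          is_entrance = FALSE
        )
      }
    }
  }
  if (!is.null(ent) && nrow(ent) > 0) {
    cand[[length(cand) + 1]] <- tibble(
      x = ent[, 1], y = ent[, 2],
      on_gallery = NA_character_, arclength = NA_real_, is_entrance = TRUE
    )
  }

  if (length(cand) == 0) {
    return(new_gallery_network(
      nodes = tibble(node_id = character(), x = numeric(), y = numeric(),
                     x_mm = numeric(), y_mm = numeric(), degree = integer(),
                     type = character()),
      edges = tibble(node_a = character(), node_b = character(),
                     gallery_id = character(), length_px = numeric(),
                     length_mm = numeric()),
      mm_per_px = mm_per_px
    ))
  }

  cand <- bind_rows(cand)
  cand <- snap_endpoints(cand, threshold_px)

  # entrance markers only type clusters; a cluster with no gallery point in
  # it (e.g. an unused entrance, or any entrance on an empty image) is not a
  # node of the drawn structure
  used <- cand |>
    group_by(.data$cluster) |>
    summarise(keep = any(!.data$is_entrance), .groups = "drop")
  cand <- cand[cand$cluster %in% used$cluster[used$keep], , drop = FALSE]
  if (nrow(cand) == 0) {
    return(new_gallery_network(
      nodes = tibble(node_id = character(), x = numeric(), y = numeric(),
                     x_mm = numeric(), y_mm = numeric(), degree = integer(),
                     type = character()),
      edges = tibble(node_a = character(), node_b = character(),
                     gallery_id = character(), length_px = numeric(),
                     length_mm = numeric()),
      mm_per_px = mm_per_px
    ))
  }

  centers <- cluster_centers(cand)
  node_ids <- sprintf("N%d", centers$cluster)

  edges <- list()
  for (id in ids) {
    on_g <- cand[!is.na(cand$on_gallery) & cand$on_gallery == id, ]
    on_g <- on_g |> arrange(.data$arclength)
    # drop coincident split positions (same physical point seen twice)
    keep <- c(TRUE, diff(on_g$arclength) > 1e-9)
    on_g <- on_g[keep, ]
    if (nrow(on_g) < 2) next
    for (k in seq_len(nrow(on_g) - 1)) {
      edges[[length(edges) + 1]] <- tibble(
        node_a = sprintf("N%d", on_g$cluster[k]),
        node_b = sprintf("N%d", on_g$cluster[k + 1]),
        gallery_id = id,
        length_px = on_g$arclength[k + 1] - on_g$arclength[k]
      )
    }
  }
  edges <- if (length(edges) == 0) {
    tibble(node_a = character(), node_b = character(),
           gallery_id = character(), length_px = numeric())
  } else {
    bind_rows(edges)
  }
  edges$length_mm <- edges$length_px * mm_per_px

  degree <- table(c(edges$node_a, edges$node_b))
  deg <- as.integer(degree[node_ids])
  deg[is.na(deg)] <- 0L

  has_entrance <- vapply(centers$cluster, function(cl) {
    any(cand$is_entrance[cand$cluster == cl])
  }, logical(1))
  type <- ifelse(has_entrance, "entrance", ifelse(deg == 1L, "end", "intersection"))

  nodes <- tibble(
    node_id = node_ids,
    x = centers$x, y = centers$y,
    x_mm = centers$x * mm_per_px, y_mm = centers$y * mm_per_px,
    degree = deg, type = type
  )
  new_gallery_network(nodes = nodes, edges = edges, mm_per_px = mm_per_px)
}

new_gallery_network <- function(nodes, edges, mm_per_px) {
  structure(
    list(nodes = nodes, edges = edges, mm_per_px = mm_per_px),
    class = "gallery_network"
  )
}

#' @export
print.gallery_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<gallery_network> %d nodes (%d entrance, %d intersection, %d end), %d edges, total %.2f mm\n",
    s$n_nodes, s$n_entrance, s$n_intersection, s$n_end, s$n_edges, s$total_length_mm
  ))
  invisible(x)
}

#' Summary counts of a gallery network
#'
#' @param net A `gallery_network`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_entrance`,
#'   `n_intersection`, `n_end`, `total_length_px`, `total_length_mm`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "gallery_network"))
  tibble(
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_entrance = sum(net$nodes$type == "entrance"),
    n_intersection = sum(net$nodes$type == "intersection"),
    n_end = sum(net$nodes$type == "end"),
    total_length_px = sum(net$edges$length_px),
    total_length_mm = sum(net$edges$length_mm)
  )
}

#' Glance at a gallery network
#'
#' Same one-row summary as [network_summary()].
#'
#' @param x A `gallery_network`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.gallery_network <- function(x, ...) network_summary(x)

#' Tidy the edge list of a gallery network
#'
#' @param x A `gallery_network`.
#' @param ... Unused.
#' @return The edge tibble, one row per edge.
#' @exportS3Method generics::tidy
tidy.gallery_network <- function(x, ...) x$edges

#' Plot a gallery network
#'
#' Edges are drawn along straight node-to-node chords; nodes are coloured by
#' type (entrance purple, intersection green, end yellow). The y axis is
#' reversed to match image coordinates.
#'
#' @param object A `gallery_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gallery_network <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges |>
    left_join(nodes |> select(node_a = "node_id", xa = "x", ya = "y"), by = "node_a") |>
    left_join(nodes |> select(node_b = "node_id", xb = "x", yb = "y"), by = "node_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      linewidth = 0.4, colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type),
      size = 2
    ) +
    ggplot2::scale_colour_manual(values = node_palette(), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "node type") +
    ggplot2::theme_minimal()
}

node_palette <- function() {
  c(entrance = "#7D26CD", intersection = "#2CA02C", end = "#FFD500")
}
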