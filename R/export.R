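# User-facing outputs: the four tidy CSV tables and overlay renderings.
#
# Two coordinate frames coexist deliberately: overlays are drawn in RAW pixel
# coordinates so they register with the photograph, while all CSV tables are
# reference-corrected and mm-scaled.

#' Run the full post-analysis over a project
#'
#' For every group: resolves the series (copy-forward), checks append-mode
#' consistency, classifies galleries, builds the per-image network, and
#' assembles the per-image, per-gallery, node and edge tables. Violations and
#' unclassified galleries are surfaced as warnings carrying
#' `(group, serial, gallery_id)` provenance, never silently dropped.
#'
#' @param project A `gallery_project`.
#' @param outdir If not `NULL`, the four CSVs are written there (see
#'   [write_tables()]); with `overlay = TRUE` an overlay PNG per analyzed
#'   image goes to `file.path(outdir, "overlays")`.
#' @param overlay Render overlay images?
#' @return A `gallery_bundle`: a list of tibbles `per_image`, `per_gallery`,
#'   `nodes`, `edges`, and `violations` (append-mode violations).
#' @export
postprocess_project <- function(project, outdir = NULL, overlay = FALSE) {
  stopifnot(inherits(project, "gallery_project"))
  per_image <- list()
  per_gallery <- list()
  nodes <- list()
  edges <- list()
  violations <- list()

  for (g in names(project$groups)) {
    viol <- check_group_consistency(project, g)
    if (nrow(viol) > 0) {
      violations[[length(violations) + 1]] <- viol
      for (k in seq_len(nrow(viol))) {
        warn(sprintf("[%s serial %d] append-mode violation: gallery %s %s",
                     viol$group_id[k], viol$serial[k],
                     sQuote(viol$gallery_id[k]), viol$reason[k]))
      }
    }
    series <- materialize_series(project, g)
    prev_total <- 0
    for (ann in series) {
      res <- withCallingHandlers(
        analyze_annotation(ann, project, g),
        warning = function(w) {
          warn(sprintf("[%s serial %d] %s", g, ann$serial, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      cls <- res$classified
      lens <- rank_length_summary(cls, res$mm_per_px)
      s <- network_summary(res$net)
      per_image[[length(per_image) + 1]] <- tibble(
        group = g, serial = ann$serial,
        total_mm = lens$total_mm,
        len1_mm = lens$len1_mm, len2_mm = lens$len2_mm,
        len3_mm = lens$len3_mm, len4plus_mm = lens$len4plus_mm,
        n_galleries = length(unique(cls$gallery_id)),
        n_nodes = s$n_nodes, n_edges = s$n_edges,
        growth_mm = lens$total_mm - prev_total
      )
      prev_total <- lens$total_mm
      if (nrow(cls) > 0) {
        per_gallery[[length(per_gallery) + 1]] <- tibble(
          group = g, serial = ann$serial,
          gallery_id = cls$gallery_id, rank = cls$rank,
          parent_id = cls$parent_id,
          length_mm = cls$length_px * res$mm_per_px,
          merged_end = cls$merged_end
        )
      }
      if (nrow(res$net$nodes) > 0) {
        nodes[[length(nodes) + 1]] <- tibble(
          group = g, serial = ann$serial,
          node_id = res$net$nodes$node_id,
          x_mm = res$net$nodes$x_mm, y_mm = res$net$nodes$y_mm,
          type = res$net$nodes$type
        )
      }
      if (nrow(res$net$edges) > 0) {
        edges[[length(edges) + 1]] <- tibble(
          group = g, serial = ann$serial,
          node_a = res$net$edges$node_a, node_b = res$net$edges$node_b,
          gallery_id = res$net$edges$gallery_id,
          length_mm = res$net$edges$length_mm
        )
      }
      if (overlay && !is.null(outdir)) {
        ovdir <- file.path(outdir, "overlays")
        dir.create(ovdir, showWarnings = FALSE, recursive = TRUE)
        render_overlay(
          ann$galleries, classified = cls, network = res$net,
          path = file.path(ovdir, sprintf("%s_%02d.png", g, ann$serial))
        )
      }
    }
  }

  bundle <- structure(
    list(
      per_image = bind_or_empty(per_image, per_image_prototype()),
      per_gallery = bind_or_empty(per_gallery, per_gallery_prototype()),
      nodes = bind_or_empty(nodes, nodes_prototype()),
      edges = bind_or_empty(edges, edges_prototype()),
      violations = bind_or_empty(violations, tibble(
        group_id = character(), serial = integer(),
        gallery_id = character(), reason = character()
      ))
    ),
    class = "gallery_bundle"
  )
  if (!is.null(outdir)) {
    write_tables(bundle, outdir)
  }
  bundle
}

bind_or_empty <- function(lst, prototype) {
  if (length(lst) == 0) prototype else bind_rows(lst)
}

per_image_prototype <- function() {
  tibble(group = character(), serial = integer(), total_mm = numeric(),
         len1_mm = numeric(), len2_mm = numeric(), len3_mm = numeric(),
         len4plus_mm = numeric(), n_galleries = integer(),
         n_nodes = integer(), n_edges = integer(), growth_mm = numeric())
}
per_gallery_prototype <- function() {
  tibble(group = character(), serial = integer(), gallery_id = character(),
         rank = integer(), parent_id = character(), length_mm = numeric(),
         merged_end = logical())
}
nodes_prototype <- function() {
  tibble(group = character(), serial = integer(), node_id = character(),
         x_mm = numeric(), y_mm = numeric(), type = character())
}
edges_prototype <- function() {
  tibble(group = character(), serial = integer(), node_a = character(),
         node_b = character(), gallery_id = character(), length_mm = numeric())
}

#' @export
print.gallery_bundle <- function(x, ...) {
  cat(sprintf(
    "<gallery_bundle> %d image record(s), %d gallery row(s), %d node(s), %d edge(s), %d violation(s)\n",
    nrow(x$per_image), nrow(x$per_gallery), nrow(x$nodes), nrow(x$edges), nrow(x$violations)
  ))
  invisible(x)
}

#' Write the four result tables as CSV
#'
#' Headers are fixed: `per_image.csv`
#' (`group,serial,total_mm,len1_mm,len2_mm,len3_mm,len4plus_mm,n_galleries,n_nodes,n_edges,growth_mm`),
#' `per_gallery.csv` (`group,serial,gallery_id,rank,parent_id,length_mm,merged_end`),
#' `nodes.csv` (`group,serial,node_id,x_mm,y_mm,type`) and `edges.csv`
#' (`group,serial,node_a,node_b,gallery_id,length_mm`). Numeric fields keep
#' full double precision (they survive a read-write round trip bit-exactly);
#' rows are sorted by `(group, serial, gallery_id)` so repeated runs are
#' byte-identical.
#'
#' @param bundle A `gallery_bundle` from [postprocess_project()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_tables <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "gallery_bundle"))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) {
    abort(sprintf("Cannot create output directory %s.", sQuote(outdir)))
  }
  paths <- c(
    per_image = file.path(outdir, "per_image.csv"),
    per_gallery = file.path(outdir, "per_gallery.csv"),
    nodes = file.path(outdir, "nodes.csv"),
    edges = file.path(outdir, "edges.csv")
  )
  # doubles are pre-formatted with 17 significant digits, which IEEE-754
  # guarantees to round-trip bit-exactly through write + parse
  write_exact <- function(tbl, path) {
    tbl <- dplyr::mutate(tbl, dplyr::across(
      dplyr::where(is.double),
      function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    ))
    readr::write_csv(tbl, path, progress = FALSE)
  }
  write_exact(bundle$per_image |> arrange(.data$group, .data$serial),
              paths[["per_image"]])
  write_exact(bundle$per_gallery |> arrange(.data$group, .data$serial, .data$gallery_id),
              paths[["per_gallery"]])
  write_exact(bundle$nodes |> arrange(.data$group, .data$serial, .data$node_id),
              paths[["nodes"]])
  write_exact(bundle$edges |> arrange(.data$group, .data$serial, .data$node_a, .data$node_b, .data$gallery_id),
              paths[["edges"]])
  invisible(paths)
}

#' Colour assigned to each identity rank
#'
#' Ranks 1-4 get fixed distinct colours; deeper ranks cycle through the same
#' palette.
#'
#' @param rank Integer rank(s), >= 1.
#' @return Hex colour(s).
#' @export
rank_palette <- function(rank) {
  pal <- c("#E41A1C", "#377EB8", "#FF7F00", "#A65628")
  pal[((rank - 1) %% length(pal)) + 1]
}

#' Render an overlay image of classified galleries
#'
#' Strokes every gallery in its rank colour over the source photograph (when
#' given) or over a white canvas sized to the annotations' bounding box plus
#' a margin. Optionally draws the network's nodes coloured purple
#' (entrance), green (intersection) and yellow (end). Drawing uses raw pixel
#' coordinates so the overlay registers with the photograph.
#'
#' @param galleries Raw-pixel polylines `(gallery_id, x, y)`.
#' @param classified Output of [assign_identities()] for these galleries
#'   (computed with the default threshold when `NULL`).
#' @param network Optional `gallery_network` whose nodes to draw. Note the
#'   network is built in the reference-corrected frame; pass `ref_point` so
#'   its nodes are shifted back into raw pixels.
#' @param path Output PNG path.
#' @param image Optional background: path to a PNG photograph.
#' @param ref_point The annotation's reference point, used only to place
#'   network nodes back in raw pixels.
#' @param margin Canvas margin in pixels when no background image is given.
#' @param line_width Stroke width.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(galleries, classified = NULL, network = NULL,
                           path, image = NULL, ref_point = NULL,
                           margin = 20, line_width = 3) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("Package `png` is required for overlay rendering.")
  }
  bg <- NULL
  if (!is.null(image)) {
    bg <- png::readPNG(image)
    width <- ncol(bg)
    height <- nrow(bg)
    x0 <- 0; y0 <- 0
  } else if (nrow(galleries) > 0) {
    x0 <- floor(min(galleries$x) - margin)
    y0 <- floor(min(galleries$y) - margin)
    width <- ceiling(max(galleries$x) + margin) - x0
    height <- ceiling(max(galleries$y) + margin) - y0
  } else {
    x0 <- 0; y0 <- 0; width <- 2 * margin; height <- 2 * margin
  }
  if (is.null(classified) && nrow(galleries) > 0) {
    classified <- assign_identities(galleries, threshold_px = 10)
  }

  grDevices::png(path, width = width, height = height, antialias = "none")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = c(x0, x0 + width), ylim = c(y0 + height, y0),
                 axes = FALSE, xlab = "", ylab = "", asp = NA)
  if (!is.null(bg)) {
    graphics::rasterImage(bg, 0, height, width, 0)
  } else {
    graphics::rect(x0, y0 + height, x0 + width, y0, col = "white", border = NA)
  }
  if (nrow(galleries) > 0) {
    for (id in unique(galleries$gallery_id)) {
      g <- galleries[galleries$gallery_id == id, ]
      r <- classified$rank[classified$gallery_id == id]
      col <- if (length(r) == 1 && !is.na(r)) rank_palette(r) else "grey50"
      graphics::lines(g$x, g$y, col = col, lwd = line_width)
    }
  }
  if (!is.null(network) && nrow(network$nodes) > 0) {
    nd <- network$nodes
    rx <- if (is.null(ref_point)) c(0, 0) else as.numeric(as_xy(ref_point)[1, ])
    graphics::points(nd$x + rx[1], nd$y + rx[2], pch = 19, cex = 1.2,
                     col = node_palette()[nd$type])
  }
  invisible(path)
}
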