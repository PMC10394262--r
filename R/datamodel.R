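# Core data model: the image naming convention, the in-memory project state
# holding every user annotation, and its versioned JSON serialization.
#
# Coordinates are always stored RAW (as clicked, image origin top-left, y
# increasing downward); reference-point alignment happens at analysis time.

PROJECT_FORMAT_VERSION <- "1.0"

empty_galleries <- function() {
  tibble(gallery_id = character(), x = numeric(), y = numeric())
}

#' Parse image file names into group id and serial
#'
#' Image sequences follow the `<group>_<serial>.<ext>` convention, e.g.
#' `TunnelA_00.jpg`, `TunnelA_01.jpg`, ..., `TunnelB_00.jpg`. The group id is
#' everything before the *last* underscore (so ids may themselves contain
#' underscores), and the serial is the integer after it (leading zeros
#' allowed).
#'
#' @param filenames Character vector of file names (paths allowed; only the
#'   base name is parsed).
#' @return A tibble with columns `filename`, `group_id`, `serial`, sorted by
#'   `(group_id, serial)`.
#' @examples
#' parse_image_name(c("TunnelA_00.jpg", "colony_1_12.jpg"))
#' @export
parse_image_name <- function(filenames) {
  if (!is.character(filenames)) abort("`filenames` must be a character vector.")
  base <- basename(filenames)
  stem <- sub("\\.[^.]+$", "", base)
  bad_ext <- stem == base
  has_us <- grepl("_", stem, fixed = TRUE)
  tail_tok <- sub("^.*_", "", stem)
  numeric_tail <- grepl("^[0-9]+$", tail_tok)
  ok <- !bad_ext & has_us & numeric_tail
  if (any(!ok)) {
    abort(sprintf(
      "Malformed image name(s): %s. Expected `<group>_<serial>.<ext>` with a numeric serial.",
      paste(sQuote(base[!ok]), collapse = ", ")
    ))
  }
  tibble(
    filename = filenames,
    group_id = sub("_[0-9]+$", "", stem),
    serial = as.integer(tail_tok)
  ) |>
    arrange(.data$group_id, .data$serial)
}

#' Create an empty annotation project
#'
#' A project holds every user annotation for one or more image groups, plus
#' the two global analysis parameters: the snapping threshold (pixels) and
#' the real-world length of the scale object (mm).
#'
#' @param threshold_px Snapping/contact threshold in pixels. Two gallery lines
#'   are in contact, and two endpoints are the same node, when their distance
#'   is strictly below this value.
#' @param scale_mm Real-world length of the scale object in millimetres.
#' @return A `gallery_project` object.
#' @export
new_project <- function(threshold_px = 10, scale_mm = 1) {
  if (!is.numeric(threshold_px) || length(threshold_px) != 1 || threshold_px <= 0) {
    abort("`threshold_px` must be a single positive number.")
  }
  if (!is.numeric(scale_mm) || length(scale_mm) != 1 || scale_mm <= 0) {
    abort("`scale_mm` must be a single positive number.")
  }
  structure(
    list(
      format_version = PROJECT_FORMAT_VERSION,
      threshold_px = as.numeric(threshold_px),
      scale_mm = as.numeric(scale_mm),
      groups = list(),
      entrance_points = list()
    ),
    class = "gallery_project"
  )
}

new_annotation <- function(serial, status, ref_point, scale_line, append_mode, galleries) {
  list(
    serial = as.integer(serial),
    status = status,
    ref_point = ref_point,
    scale_line = scale_line,
    append_mode = isTRUE(append_mode),
    galleries = galleries
  )
}

validate_galleries_tbl <- function(galleries) {
  if (!is.data.frame(galleries) ||
      !all(c("gallery_id", "x", "y") %in% names(galleries))) {
    abort("`galleries` must be a data frame with columns gallery_id, x, y.")
  }
  galleries <- as_tibble(galleries)[, c("gallery_id", "x", "y")]
  galleries$gallery_id <- as.character(galleries$gallery_id)
  if (nrow(galleries) > 0) {
    if (!all(is.finite(galleries$x)) || !all(is.finite(galleries$y))) {
      abort("Gallery coordinates must be finite.")
    }
    counts <- table(galleries$gallery_id)
    if (any(counts < 2)) {
      abort(sprintf(
        "Every gallery needs at least 2 points; offending: %s.",
        paste(names(counts)[counts < 2], collapse = ", ")
      ))
    }
    n <- nrow(galleries)
    same_gal <- galleries$gallery_id[-1] == galleries$gallery_id[-n]
    same_pt <- galleries$x[-1] == galleries$x[-n] & galleries$y[-1] == galleries$y[-n]
    if (any(same_gal & same_pt)) {
      abort("Consecutive points of a gallery must be distinct.")
    }
  }
  galleries
}

#' Add one image's annotation to a project
#'
#' @param project A `gallery_project`.
#' @param group_id Image group (experiment) id.
#' @param serial Non-negative integer position of the image in its sequence.
#' @param status One of `"analyzed"` (galleries traced), `"skipped"` (no
#'   change since the previous image; its annotation is inherited at analysis
#'   time), `"empty"` (no gallery present; zero records are produced).
#' @param galleries Traced polylines as a data frame `(gallery_id, x, y)`,
#'   points in drawing order within each gallery. Must be empty for
#'   `"skipped"` and `"empty"` images.
#' @param ref_point Clicked reference landmark `c(x, y)`, or `NULL` when the
#'   camera is fixed (the image's top-left corner is used).
#' @param scale_line Two endpoints of the traced scale object (2x2 matrix or
#'   2-row data frame), or `NULL` to inherit the previous image's line.
#' @param append_mode `TRUE` (default) asserts galleries only extend over
#'   time; set `FALSE` when re-tracing after backfilling shortens structures.
#' @return The project with the annotation inserted (serials kept sorted).
#' @export
add_annotation <- function(project, group_id, serial,
                           status = c("analyzed", "skipped", "empty"),
                           galleries = empty_galleries(),
                           ref_point = NULL, scale_line = NULL,
                           append_mode = TRUE) {
  stopifnot(inherits(project, "gallery_project"))
  status <- match.arg(status)
  if (!is.numeric(serial) || length(serial) != 1 || serial < 0 || serial != floor(serial)) {
    abort("`serial` must be a single non-negative integer.")
  }
  galleries <- validate_galleries_tbl(galleries)
  if (status %in% c("skipped", "empty") && nrow(galleries) > 0) {
    abort(sprintf("A %s image must not carry galleries.", status))
  }
  if (!is.null(ref_point)) ref_point <- as.numeric(as_xy(ref_point, "ref_point")[1, ])
  if (!is.null(scale_line)) {
    scale_line <- as_xy(scale_line, "scale_line")
    if (nrow(scale_line) != 2) abort("`scale_line` must have exactly 2 points.")
  }
  anns <- project$groups[[group_id]] %||% list()
  serials <- vapply(anns, function(a) a$serial, integer(1))
  if (as.integer(serial) %in% serials) {
    abort(sprintf("Group %s already has an annotation for serial %d.", group_id, serial))
  }
  anns <- c(anns, list(new_annotation(serial, status, ref_point, scale_line, append_mode, galleries)))
  anns <- anns[order(vapply(anns, function(a) a$serial, integer(1)))]
  project$groups[[group_id]] <- anns
  project
}

#' Set the entrance points of an image group
#'
#' Entrance points mark where galleries originate (e.g. the arena entrance
#' holes). They are given in the reference-corrected frame: the coordinates a
#' click would have after subtracting the image's reference point. Galleries
#' whose start lies within the threshold of an entrance point are classified
#' as primary.
#'
#' @param project A `gallery_project`.
#' @param group_id Image group id.
#' @param points Entrance coordinates (n x 2 matrix or x/y data frame).
#' @return The updated project.
#' @export
set_entrance_points <- function(project, group_id, points) {
  stopifnot(inherits(project, "gallery_project"))
  project$entrance_points[[group_id]] <- as_xy(points, "points")
  project
}

group_annotations <- function(project, group_id) {
  anns <- project$groups[[group_id]]
  if (is.null(anns)) {
    abort(sprintf("No group %s in this project.", sQuote(group_id)))
  }
  anns
}

#' @export
print.gallery_project <- function(x, ...) {
  n_img <- sum(vapply(x$groups, length, integer(1)))
  cat(sprintf(
    "<gallery_project v%s> %d group(s), %d image(s); threshold %g px, scale object %g mm\n",
    x$format_version, length(x$groups), n_img, x$threshold_px, x$scale_mm
  ))
  for (g in names(x$groups)) {
    serials <- vapply(x$groups[[g]], function(a) a$serial, integer(1))
    cat(sprintf("  %s: serials %s\n", g, paste(serials, collapse = ", ")))
  }
  invisible(x)
}

ann_to_record <- function(a) {
  rec <- list(
    serial = a$serial,
    status = a$status,
    append_mode = a$append_mode
  )
  rec$ref_point <- if (is.null(a$ref_point)) NULL else as.numeric(a$ref_point)
  rec$scale_line <- if (is.null(a$scale_line)) NULL else unname(a$scale_line)
  ids <- unique(a$galleries$gallery_id)
  rec$galleries <- lapply(ids, function(id) {
    g <- a$galleries[a$galleries$gallery_id == id, ]
    list(id = id, points = unname(cbind(g$x, g$y)))
  })
  rec
}

record_to_ann <- function(rec) {
  ref_point <- if (is.null(rec$ref_point)) NULL else as.numeric(unlist(rec$ref_point))
  scale_line <- if (is.null(rec$scale_line)) {
    NULL
  } else {
    m <- do.call(rbind, lapply(rec$scale_line, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m
  }
  gals <- rec$galleries %||% list()
  galleries <- if (length(gals) == 0) {
    empty_galleries()
  } else {
    bind_rows(lapply(gals, function(g) {
      pts <- do.call(rbind, lapply(g$points, function(p) as.numeric(unlist(p))))
      tibble(gallery_id = as.character(g$id), x = pts[, 1], y = pts[, 2])
    }))
  }
  new_annotation(
    serial = rec$serial, status = rec$status,
    ref_point = ref_point, scale_line = scale_line,
    append_mode = isTRUE(rec$append_mode), galleries = galleries
  )
}

#' Save a project to a versioned JSON file
#'
#' All user annotations (reference points, scale lines, galleries, statuses)
#' are written to a single human-readable JSON file. Coordinates are written
#' with 17 significant digits so that [load_project()] reproduces the saved
#' state bit-exactly. Skipped images store no gallery copy; the inheritance
#' is materialized at analysis time by [materialize_series()].
#'
#' @param project A `gallery_project`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "gallery_project"))
  doc <- list(
    format_version = project$format_version,
    threshold_px = project$threshold_px,
    scale_mm = project$scale_mm,
    groups = lapply(project$groups, function(anns) lapply(anns, ann_to_record))
  )
  if (length(project$entrance_points) > 0) {
    doc$entrance_points <- lapply(project$entrance_points, unname)
  }
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a project saved by [save_project()]
#'
#' @param path Path to a project JSON file.
#' @return A `gallery_project` identical to the saved one.
#' @export
load_project <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      abort(sprintf("Corrupt project file %s: %s", sQuote(path), conditionMessage(e)))
    }
  )
  if (is.null(doc$format_version) || is.null(doc$threshold_px) || is.null(doc$groups)) {
    abort(sprintf("Corrupt project file %s: missing required fields.", sQuote(path)))
  }
  if (!identical(as.character(doc$format_version), PROJECT_FORMAT_VERSION)) {
    abort(sprintf(
      "Project file %s has format version %s; this build reads version %s.",
      sQuote(path), doc$format_version, PROJECT_FORMAT_VERSION
    ))
  }
  project <- new_project(threshold_px = doc$threshold_px, scale_mm = doc$scale_mm %||% 1)
  project$groups <- lapply(doc$groups, function(recs) lapply(recs, record_to_ann))
  if (!is.null(doc$entrance_points)) {
    project$entrance_points <- lapply(doc$entrance_points, function(pts) {
      m <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
      colnames(m) <- c("x", "y")
      m
    })
  }
  project
}
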