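# Seeded generator of branching gallery growth sequences with full ground
# truth. It emulates the geometry of excavation time series — nested
# branching growth from a single entrance, a repositioned camera between
# shots, a scale object in frame — so every downstream module can be tested
# against known ranks, parents, lengths and node/edge counts without any
# real photograph. It is a geometric fixture generator, not a behavioural
# model of any species.

#' Parameters for the synthetic growth generator
#'
#' Defaults describe a typical desk-scale tunnelling arena: a 1200 px square
#' arena photographed over `n_steps` hourly images, tips advancing ~45 px per
#' step with small heading jitter (continuations stay shallow), new branches
#' leaving their parent at ~50 degrees (clearly steeper than continuations,
#' so the shallow-angle drawing convention holds by construction), a camera
#' repositioned by a few pixels between shots, and a 200 px scale bar of
#' 100 mm (0.5 mm/px).
#'
#' @param seed Integer seed; the same seed reproduces the output byte for
#'   byte.
#' @param n_steps Images per group (serials `0 .. n_steps - 1`).
#' @param n_groups Number of image groups (experiments).
#' @param elongation_mean_px,elongation_sd_px Tip advance per step (pixels).
#' @param branch_prob Probability per step that one new descendant gallery
#'   is started.
#' @param max_rank Deepest identity rank the generator will create.
#' @param max_galleries Cap on galleries per group.
#' @param arena_px Arena width and height in pixels.
#' @param ref_jitter_px SD of the simulated camera shift between images.
#' @param scale_len_px Pixel length of the scale bar drawn in every image.
#' @param scale_mm Real-world length of the scale bar (mm).
#' @param threshold_px Snapping threshold the project will carry.
#' @param heading_jitter_deg SD of the heading change of a continuing tip.
#' @param branch_angle_deg Mean departure angle of a new branch.
#' @param hard_mode By default branch points keep at least twice the
#'   threshold away from every existing node so snapping is unambiguous;
#'   `hard_mode = TRUE` relaxes the separation below the threshold to probe
#'   tie-breaking behaviour.
#' @return A `growth_params` list.
#' @export
growth_params <- function(seed = 1, n_steps = 20, n_groups = 1,
                          elongation_mean_px = 45, elongation_sd_px = 10,
                          branch_prob = 0.25, max_rank = 5,
                          max_galleries = 40, arena_px = c(1200, 1200),
                          ref_jitter_px = 4, scale_len_px = 200,
                          scale_mm = 100, threshold_px = 10,
                          heading_jitter_deg = 6, branch_angle_deg = 50,
                          hard_mode = FALSE) {
  stopifnot(
    n_steps >= 1, n_groups >= 1, elongation_mean_px > 0,
    branch_prob >= 0, branch_prob <= 1, max_rank >= 1,
    max_galleries >= 1, all(arena_px > 0), scale_len_px > 0,
    scale_mm > 0, threshold_px > 0
  )
  structure(
    list(
      seed = as.integer(seed), n_steps = as.integer(n_steps),
      n_groups = as.integer(n_groups),
      elongation_mean_px = elongation_mean_px,
      elongation_sd_px = elongation_sd_px,
      branch_prob = branch_prob, max_rank = as.integer(max_rank),
      max_galleries = as.integer(max_galleries), arena_px = arena_px,
      ref_jitter_px = ref_jitter_px, scale_len_px = scale_len_px,
      scale_mm = scale_mm, threshold_px = threshold_px,
      heading_jitter_deg = heading_jitter_deg,
      branch_angle_deg = branch_angle_deg,
      hard_mode = isTRUE(hard_mode)
    ),
    class = "growth_params"
  )
}

deg2rad <- function(d) d * pi / 180

# minimum distance from point p to a pool of segments (ax, ay, bx, by, g),
# optionally excluding one gallery index; Inf when nothing to compare
seg_pool_dist <- function(p, segs, skip = 0L) {
  use <- segs[, 5] != skip
  if (!any(use)) return(Inf)
  ax <- segs[use, 1]; ay <- segs[use, 2]
  dx <- segs[use, 3] - ax; dy <- segs[use, 4] - ay
  len2 <- dx * dx + dy * dy
  t <- ((p[1] - ax) * dx + (p[2] - ay) * dy) / pmax(len2, 1e-300)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2))
}

#' Generate a synthetic growth sequence with ground truth
#'
#' Grows one primary gallery per group from a central entrance; tips advance
#' each step with small heading jitter and occasionally spawn a descendant
#' from the side of an existing gallery. Each image stores raw pixel
#' coordinates shifted by a per-serial camera offset, with the matching
#' reference point and a scale line, so the output exercises alignment,
#' calibration, append-mode inheritance and classification end to end. A
#' tip that cannot advance without approaching another gallery stops, which
#' keeps all separations above the snapping threshold (unless `hard_mode`).
#'
#' @param params A [growth_params()] object.
#' @return A list with `project` (a `gallery_project`, entrance points set)
#'   and `truth`, itself a list of tibbles: `galleries` (`group`,
#'   `gallery_id`, `rank`, `parent_id`, `attach_arclength_px`, `birth_step`)
#'   and `per_serial` (`group`, `serial`, `n_galleries`, `total_mm`,
#'   `len1_mm`, `len2_mm`, `len3_mm`, `len4plus_mm`, `n_nodes`, `n_edges`).
#' @export
synth_growth <- function(params = growth_params()) {
  stopifnot(inherits(params, "growth_params"))
  set.seed(params$seed)
  p <- params
  mm_per_px <- p$scale_mm / p$scale_len_px
  min_sep <- if (p$hard_mode) 0.8 * p$threshold_px else 2 * p$threshold_px
  margin <- 60

  project <- new_project(threshold_px = p$threshold_px, scale_mm = p$scale_mm)
  truth_gal <- list()
  truth_ser <- list()

  for (gi in seq_len(p$n_groups)) {
    group <- sprintf("synth%s", group_suffix(gi))
    landmark <- c(40, 40)
    entrance <- p$arena_px / 2
    project <- set_entrance_points(project, group, rbind(entrance - landmark))

    # gallery state in true (unshifted) coordinates
    pts <- list()       # matrices of points
    heading <- c(stats::runif(1, 0, 2 * pi))
    rank <- c(1L)
    parent <- c(NA_character_)
    attach <- c(NA_real_)
    birth <- c(0L)
    active <- c(TRUE)
    step0 <- entrance + first_step_length(p) * c(cos(heading[1]), sin(heading[1]))
    pts[[1]] <- rbind(entrance, step0)
    # flat pool of drawn segments (ax, ay, bx, by, gallery index) so
    # clearance checks are one vectorised pass
    segs <- matrix(c(entrance, step0, 1), nrow = 1)

    in_arena <- function(q) {
      q[1] > margin && q[1] < p$arena_px[1] - margin &&
        q[2] > margin && q[2] < p$arena_px[2] - margin
    }

    for (serial in 0:(p$n_steps - 1)) {
      if (serial > 0) {
        # elongate every active tip
        for (k in seq_along(pts)) {
          if (!active[k]) next
          advanced <- FALSE
          for (try in 1:5) {
            hdg <- heading[k] + stats::rnorm(1, 0, deg2rad(p$heading_jitter_deg))
            len <- max(5, stats::rnorm(1, p$elongation_mean_px, p$elongation_sd_px))
            tip <- pts[[k]][nrow(pts[[k]]), ]
            q <- tip + len * c(cos(hdg), sin(hdg))
            mid <- (tip + q) / 2
            if (in_arena(q) &&
                seg_pool_dist(q, segs, skip = k) >= min_sep &&
                seg_pool_dist(mid, segs, skip = k) >= min_sep) {
              pts[[k]] <- rbind(pts[[k]], q)
              segs <- rbind(segs, c(tip, q, k))
              heading[k] <- hdg
              advanced <- TRUE
              break
            }
          }
          if (!advanced) active[k] <- FALSE
        }
        # possibly start one descendant gallery
        if (length(pts) < p$max_galleries && stats::runif(1) < p$branch_prob) {
          eligible <- which(rank < p$max_rank)
          if (length(eligible) > 0) {
            k <- eligible[sample.int(length(eligible), 1)]
            L <- polyline_length(pts[[k]])
            s <- stats::runif(1, 0.2 * L, 0.8 * L)
            at <- point_at_arclength(pts[[k]], s)
            side <- sample(c(-1, 1), 1)
            dir_par <- direction_at_arclength(pts[[k]], s)
            ang <- atan2(dir_par[2], dir_par[1]) +
              side * deg2rad(p$branch_angle_deg + stats::rnorm(1, 0, 5))
            len <- max(5, stats::rnorm(1, p$elongation_mean_px, p$elongation_sd_px))
            q <- at + len * c(cos(ang), sin(ang))
            mid <- (at + q) / 2
            # the attachment must sit clear of every existing node and every
            # other gallery, and the first segment must leave the parent
            ends_k <- rbind(pts[[k]][1, ], pts[[k]][nrow(pts[[k]]), ])
            other_attach <- attach[!is.na(parent) & parent == gallery_label(k)]
            clear_of_ends <- min(sqrt((ends_k[, 1] - at[1])^2 + (ends_k[, 2] - at[2])^2)) >= min_sep
            clear_of_sibs <- length(other_attach) == 0 || min(abs(other_attach - s)) >= min_sep
            if (clear_of_ends && clear_of_sibs && in_arena(q) &&
                seg_pool_dist(at, segs, skip = k) >= min_sep &&
                seg_pool_dist(q, segs) >= min_sep &&
                seg_pool_dist(mid, segs, skip = k) >= min_sep) {
              pts[[length(pts) + 1]] <- rbind(at, q)
              segs <- rbind(segs, c(at, q, length(pts)))
              heading <- c(heading, ang)
              rank <- c(rank, rank[k] + 1L)
              parent <- c(parent, gallery_label(k))
              attach <- c(attach, s)
              birth <- c(birth, serial)
              active <- c(active, TRUE)
            }
          }
        }
      }

      # write this serial's annotation (raw = true + camera shift)
      shift <- stats::rnorm(2, 0, p$ref_jitter_px)
      n_per <- vapply(pts, nrow, integer(1))
      gal_tbl <- tibble::new_tibble(list(
        gallery_id = rep(vapply(seq_along(pts), gallery_label, character(1)), n_per),
        x = unname(unlist(lapply(pts, function(m) m[, 1]))) + shift[1],
        y = unname(unlist(lapply(pts, function(m) m[, 2]))) + shift[2]
      ), nrow = sum(n_per))
      project <- add_annotation(
        project, group, serial,
        status = "analyzed", galleries = gal_tbl,
        ref_point = landmark + shift,
        scale_line = rbind(c(60, 20), c(60 + p$scale_len_px, 20)) +
          rbind(shift, shift),
        append_mode = TRUE
      )

      # ground-truth bookkeeping for this serial
      len_mm <- vapply(pts, polyline_length, numeric(1)) * mm_per_px
      truth_ser[[length(truth_ser) + 1]] <- tibble(
        group = group, serial = serial,
        n_galleries = length(pts),
        total_mm = sum(len_mm),
        len1_mm = sum(len_mm[rank == 1L]),
        len2_mm = sum(len_mm[rank == 2L]),
        len3_mm = sum(len_mm[rank == 3L]),
        len4plus_mm = sum(len_mm[rank >= 4L]),
        n_nodes = 1L + length(pts) + sum(!is.na(parent)),
        n_edges = length(pts) + sum(!is.na(parent))
      )
    }

    truth_gal[[length(truth_gal) + 1]] <- tibble(
      group = group,
      gallery_id = vapply(seq_along(pts), gallery_label, character(1)),
      rank = rank, parent_id = parent,
      attach_arclength_px = attach, birth_step = birth
    )
  }

  list(
    project = project,
    truth = list(
      galleries = bind_rows(truth_gal),
      per_serial = bind_rows(truth_ser)
    )
  )
}

gallery_label <- function(k) sprintf("g%02d", k)

# spreadsheet-style group suffix: A..Z, AA, AB, ...
group_suffix <- function(i) {
  s <- ""
  while (i > 0) {
    r <- (i - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    i <- (i - 1) %/% 26
  }
  s
}

first_step_length <- function(p) {
  max(5, stats::rnorm(1, p$elongation_mean_px, p$elongation_sd_px))
}

#' Render synthetic images for a generated project
#'
#' Writes one PNG per annotation — galleries as dark strokes on a white
#' canvas — named by the `<group>_<serial>.png` convention, so the files
#' round-trip through [parse_image_name()] and feed end-to-end runs that
#' expect an image directory.
#'
#' @param project A `gallery_project` (typically from [synth_growth()]).
#' @param outdir Output directory, created if needed.
#' @param canvas_px Canvas width/height; defaults to the coordinate bounding
#'   box plus a margin.
#' @return Character vector of the written paths, invisibly.
#' @export
render_synthetic_images <- function(project, outdir, canvas_px = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in names(project$groups)) {
    for (ann in project$groups[[g]]) {
      path <- file.path(outdir, sprintf("%s_%02d.png", g, ann$serial))
      size <- canvas_px
      if (is.null(size)) {
        if (nrow(ann$galleries) > 0) {
          size <- c(ceiling(max(ann$galleries$x)) + 40,
                    ceiling(max(ann$galleries$y)) + 40)
        } else {
          size <- c(200, 200)
        }
      }
      grDevices::png(path, width = size[1], height = size[2], antialias = "none")
      graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
      graphics::plot(NA, xlim = c(0, size[1]), ylim = c(size[2], 0),
                     axes = FALSE, xlab = "", ylab = "", asp = NA)
      graphics::rect(0, size[2], size[1], 0, col = "white", border = NA)
      if (nrow(ann$galleries) > 0) {
        for (id in unique(ann$galleries$gallery_id)) {
          gal <- ann$galleries[ann$galleries$gallery_id == id, ]
          graphics::lines(gal$x, gal$y, col = "grey20", lwd = 3)
        }
      }
      grDevices::dev.off()
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}
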