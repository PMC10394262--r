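test_that("an empty project exports four header-only CSVs", {
  outdir <- withr::local_tempdir()
  bundle <- postprocess_project(new_project(), outdir = outdir)
  tabs <- read_tables_back(outdir)
  expect_equal(nrow(tabs$per_image), 0)
  expect_equal(nrow(tabs$per_gallery), 0)
  expect_equal(names(tabs$per_image),
               c("group", "serial", "total_mm", "len1_mm", "len2_mm", "len3_mm",
                 "len4plus_mm", "n_galleries", "n_nodes", "n_edges", "growth_mm"))
  expect_equal(names(tabs$per_gallery),
               c("group", "serial", "gallery_id", "rank", "parent_id",
                 "length_mm", "merged_end"))
  expect_equal(names(tabs$nodes),
               c("group", "serial", "node_id", "x_mm", "y_mm", "type"))
  expect_equal(names(tabs$edges),
               c("group", "serial", "node_a", "node_b", "gallery_id", "length_mm"))
})

test_that("a one-gallery project exports one row whose length is the image total", {
  p <- new_project(threshold_px = 5, scale_mm = 10)
  p <- add_annotation(p, "g", 0,
                      galleries = tibble::tibble(gallery_id = "A",
                                                 x = c(0, 30), y = c(0, 40)),
                      scale_line = rbind(c(0, 0), c(100, 0)))
  outdir <- withr::local_tempdir()
  postprocess_project(p, outdir = outdir)
  tabs <- read_tables_back(outdir)
  expect_equal(nrow(tabs$per_gallery), 1)
  expect_equal(tabs$per_gallery$length_mm, 5) # 50 px at 0.1 mm/px
  expect_equal(tabs$per_image$total_mm, tabs$per_gallery$length_mm)
})

test_that("CSVs round-trip and re-aggregate to the per-image totals exactly", {
  gen <- synth_growth(growth_params(seed = 51, n_steps = 12, n_groups = 2,
                                    branch_prob = 0.5))
  outdir <- withr::local_tempdir()
  bundle <- postprocess_project(gen$project, outdir = outdir)
  tabs <- read_tables_back(outdir)

  # round trip: parse(write(x)) = x (rows are written sorted)
  expect_equal(as.data.frame(tabs$per_image),
               as.data.frame(dplyr::arrange(bundle$per_image, group, serial)))
  expect_equal(as.data.frame(tabs$per_gallery),
               as.data.frame(dplyr::arrange(bundle$per_gallery, group, serial, gallery_id)))

  # per-gallery lengths re-aggregate bit-for-bit to the per-image totals
  agg <- tabs$per_gallery |>
    dplyr::group_by(group, serial) |>
    dplyr::summarise(total = sum(length_mm), .groups = "drop")
  joined <- dplyr::left_join(tabs$per_image, agg, by = c("group", "serial"))
  joined$total[is.na(joined$total)] <- 0
  expect_identical(joined$total_mm, joined$total)

  # edge lengths re-aggregate to the totals too (within float tolerance)
  eagg <- tabs$edges |>
    dplyr::group_by(group, serial) |>
    dplyr::summarise(total = sum(length_mm), .groups = "drop")
  j2 <- dplyr::inner_join(tabs$per_image, eagg, by = c("group", "serial"))
  expect_equal(j2$total_mm, j2$total, tolerance = 1e-9)
})

test_that("repeated exports are byte-identical", {
  gen <- synth_growth(growth_params(seed = 52, n_steps = 8, branch_prob = 0.5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  postprocess_project(gen$project, outdir = d1)
  postprocess_project(gen$project, outdir = d2)
  for (f in c("per_image.csv", "per_gallery.csv", "nodes.csv", "edges.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

png_colors <- function(path) {
  a <- png::readPNG(path)
  unique(apply(matrix(a, ncol = dim(a)[3]), 1,
               function(r) grDevices::rgb(r[1], r[2], r[3])))
}

test_that("an overlay with no galleries is an untouched white canvas", {
  f <- withr::local_tempfile(fileext = ".png")
  render_overlay(empty_galleries(), path = f)
  expect_identical(png_colors(f), "#FFFFFF")
})

test_that("overlays stroke each identity rank in its own colour", {
  f <- withr::local_tempfile(fileext = ".png")
  pts <- chain_fixture() # ranks 1, 2, 3
  cl <- assign_identities(pts, 5, entrance_points = rbind(c(0, 0)))
  render_overlay(pts, classified = cl, path = f)
  cols <- png_colors(f)
  expect_true(all(toupper(rank_palette(1:3)) %in% cols))
  expect_false(toupper(rank_palette(4)) %in% cols)
})

test_that("network overlays draw one green blob per intersection", {
  f <- withr::local_tempfile(fileext = ".png")
  pts <- branch_fixture()
  cl <- assign_identities(pts, 2)
  net <- build_network(pts, 2, classified = cl)
  render_overlay(pts, classified = cl, network = net, path = f)
  a <- png::readPNG(f)
  green <- grDevices::col2rgb("#2CA02C")[, 1] / 255
  mask <- abs(a[, , 1] - green[1]) < 0.01 &
    abs(a[, , 2] - green[2]) < 0.01 &
    abs(a[, , 3] - green[3]) < 0.01
  expect_gt(sum(mask), 0)
  # count 4-connected components of the green mask
  lab <- matrix(0L, nrow(mask), ncol(mask))
  blobs <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      blobs <- blobs + 1L
      queue <- list(c(i, j)); lab[i, j] <- blobs
      while (length(queue) > 0) {
        q <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ii <- q[1] + d[1]; jj <- q[2] + d[2]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- blobs
            queue <- c(queue, list(c(ii, jj)))
          }
        }
      }
    }
  }
  expect_equal(blobs, 1L)
})
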