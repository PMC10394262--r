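test_that("skipped images inherit the previous image's galleries transitively", {
  p <- new_project(threshold_px = 2, scale_mm = 10)
  g0 <- tibble::tibble(gallery_id = c("A", "A", "B", "B"),
                       x = c(0, 5, 2, 2), y = c(0, 0, 0.5, 4))
  p <- add_annotation(p, "g", 0, galleries = g0,
                      scale_line = rbind(c(0, 10), c(50, 10)))
  p <- add_annotation(p, "g", 1, status = "skipped")
  p <- add_annotation(p, "g", 2, status = "skipped")
  series <- materialize_series(p, "g")
  expect_equal(series[[2]]$galleries, g0)
  expect_equal(series[[3]]$galleries, g0)
  # the inherited scale line travels with the copy
  expect_equal(series[[3]]$scale_line, series[[1]]$scale_line)
  # statuses are preserved
  expect_equal(vapply(series, function(a) a$status, character(1)),
               c("analyzed", "skipped", "skipped"))
})

test_that("empty images resolve to zero galleries and a first skip is an error", {
  p <- new_project()
  p <- add_annotation(p, "g", 0, status = "empty")
  p <- add_annotation(p, "g", 1, status = "empty")
  series <- materialize_series(p, "g")
  expect_equal(nrow(series[[1]]$galleries), 0)
  expect_equal(nrow(series[[2]]$galleries), 0)

  p2 <- new_project()
  p2 <- add_annotation(p2, "g", 0, status = "skipped")
  expect_error(materialize_series(p2, "g"), "no preceding image")
  expect_error(materialize_series(p, "nope"), "No group")
})

test_that("materialization is idempotent", {
  p <- toy_project()
  s1 <- materialize_series(p, "toy")
  # write the resolved annotations back and materialize again
  p2 <- p
  p2$groups[["toy"]] <- s1
  s2 <- materialize_series(p2, "toy")
  expect_equal(s2, s1)
})

test_that("append-mode consistency accepts extension and flags shortening", {
  mk <- function(xs, append = TRUE) {
    list(serial = 0L, status = "analyzed", ref_point = NULL, scale_line = NULL,
         append_mode = append,
         galleries = tibble::tibble(gallery_id = "A", x = xs, y = rep(0, length(xs))))
  }
  prev <- mk(c(0, 5))
  expect_equal(nrow(check_append_consistency(prev, mk(c(0, 5, 9)), 1)), 0)
  v <- check_append_consistency(prev, mk(c(0, 3)), 1)
  expect_equal(nrow(v), 1)
  expect_match(v$reason, "shortened")
  # the not-appending escape permits the same shortening
  expect_equal(nrow(check_append_consistency(prev, mk(c(0, 3), append = FALSE), 1)), 0)
  # a disappeared gallery is a violation too
  gone <- mk(c(0, 5)); gone$galleries <- gone$galleries[0, ]
  expect_equal(check_append_consistency(prev, gone, 1)$reason, "gallery disappeared")
})

test_that("reference correction happens before the prefix comparison", {
  prev <- list(serial = 0L, status = "analyzed", ref_point = c(10, 10),
               scale_line = NULL, append_mode = TRUE,
               galleries = tibble::tibble(gallery_id = "A",
                                          x = c(10, 15), y = c(10, 10)))
  # same structure re-clicked after a 100 px camera shift
  curr <- list(serial = 1L, status = "analyzed", ref_point = c(110, 110),
               scale_line = NULL, append_mode = TRUE,
               galleries = tibble::tibble(gallery_id = "A",
                                          x = c(110, 115, 120), y = c(110, 110, 110)))
  expect_equal(nrow(check_append_consistency(prev, curr, 1)), 0)
})

test_that("the per-image series reports lengths, counts and increments", {
  rec <- compute_series(toy_project(), "toy")
  expect_equal(rec$serial, 0:2)
  # scale: 100 px line for 10 mm -> 0.1 mm/px
  expect_equal(rec$total_mm[1], 5 * 0.1)
  # skipped serial 1 duplicates serial 0 with zero growth
  expect_equal(rec$total_mm[2], rec$total_mm[1])
  expect_equal(rec$growth_mm[2], 0)
  expect_equal(rec$n_galleries, c(1L, 1L, 2L))
  # first serial's increment is its own total
  expect_equal(rec$growth_mm[1], rec$total_mm[1])
  expect_equal(rec$growth_mm[3], rec$total_mm[3] - rec$total_mm[2])
})

test_that("an all-empty series yields all-zero records", {
  p <- new_project()
  for (i in 0:2) p <- add_annotation(p, "g", i, status = "empty")
  rec <- compute_series(p, "g")
  expect_equal(nrow(rec), 3)
  num <- c("total_mm", "len1_mm", "len2_mm", "len3_mm", "len4plus_mm", "growth_mm")
  expect_true(all(as.matrix(rec[, num]) == 0))
  expect_true(all(rec$n_galleries == 0))
  expect_true(all(rec$n_nodes == 0))
})

test_that("series totals match the generator's cumulative ground truth", {
  gen <- synth_growth(growth_params(seed = 41, n_steps = 20, branch_prob = 0.5))
  rec <- compute_series(gen$project, "synthA")
  truth <- gen$truth$per_serial
  expect_equal(rec$serial, truth$serial)
  expect_lt(max(abs(rec$total_mm - truth$total_mm)), 1e-6)
  expect_lt(max(abs(rec$len2_mm - truth$len2_mm)), 1e-6)
  expect_equal(rec$n_nodes, truth$n_nodes)
  expect_equal(rec$n_edges, truth$n_edges)
  # append mode with no violations: totals monotone, increments >= 0
  expect_equal(nrow(check_group_consistency(gen$project, "synthA")), 0)
  expect_true(all(diff(rec$total_mm) >= 0))
  expect_true(all(rec$growth_mm >= 0))
})
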