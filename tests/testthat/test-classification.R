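test_that("a branch's parent is the nearest gallery within the contact threshold", {
  pts <- branch_fixture() # B starts at (5, 0.5) on A = (0,0)-(10,0)
  hit <- find_parent(pts, "B", threshold_px = 2)
  expect_equal(hit$parent_id, "A")
  expect_equal(hit$attach_arclength_px, 5)
  # too far away: no parent
  far <- dplyr::bind_rows(
    tibble::tibble(gallery_id = "A", x = c(0, 10), y = c(0, 0)),
    tibble::tibble(gallery_id = "B", x = c(5, 5), y = c(10, 20))
  )
  expect_true(is.na(find_parent(far, "B", threshold_px = 2)$parent_id))
})

test_that("equidistant parents tie-break to the lexicographically first id", {
  pts <- dplyr::bind_rows(
    tibble::tibble(gallery_id = "C", x = c(0, 10), y = c(0, 0)),
    tibble::tibble(gallery_id = "A", x = c(0, 10), y = c(2, 2)),
    tibble::tibble(gallery_id = "B", x = c(5, 5), y = c(1, 30)) # 1 px from both
  )
  expect_equal(find_parent(pts, "B", threshold_px = 2)$parent_id, "A")
})

test_that("identity ranks follow the branching rules", {
  # a single gallery from the entrance is primary
  one <- tibble::tibble(gallery_id = "A", x = c(0, 50), y = c(0, 0))
  cl1 <- assign_identities(one, 5, entrance_points = rbind(c(0, 0)))
  expect_equal(cl1$rank, 1L)
  expect_true(is.na(cl1$parent_id))

  # A from entrance, B off mid-A, C off mid-B: ranks 1, 2, 3
  cl3 <- assign_identities(chain_fixture(), 5, entrance_points = rbind(c(0, 0)))
  expect_equal(cl3$rank[match(c("A", "B", "C"), cl3$gallery_id)], c(1L, 2L, 3L))
  expect_equal(cl3$parent_id[match(c("B", "C"), cl3$gallery_id)], c("A", "B"))
  # without entrance points, parentless galleries are primary
  cl3b <- assign_identities(chain_fixture(), 5)
  expect_equal(cl3b$rank[match(c("A", "B", "C"), cl3b$gallery_id)], c(1L, 2L, 3L))
})

test_that("a gallery ending on another gallery is a merge, not a reparent", {
  # B starts mid-A and loops back to end on A again
  pts <- dplyr::bind_rows(
    tibble::tibble(gallery_id = "A", x = c(0, 100), y = c(0, 0)),
    tibble::tibble(gallery_id = "B", x = c(30, 30, 60, 60), y = c(0, 40, 40, 1))
  )
  cl <- assign_identities(pts, 3, entrance_points = rbind(c(0, 0)))
  b <- cl[cl$gallery_id == "B", ]
  expect_equal(b$rank, 2L)
  expect_equal(b$parent_id, "A")
  expect_true(b$merged_end)
  expect_false(cl$merged_end[cl$gallery_id == "A"])
})

test_that("circular parentage is flagged unclassified with a warning", {
  # two galleries each starting on the other, neither at the entrance
  pts <- dplyr::bind_rows(
    tibble::tibble(gallery_id = "A", x = c(20, 20), y = c(16, 60)),
    tibble::tibble(gallery_id = "B", x = c(19, 60), y = c(15, 15))
  )
  expect_warning(
    cl <- assign_identities(pts, 5, entrance_points = rbind(c(500, 500))),
    "Could not resolve"
  )
  expect_true(all(cl$unclassified))
  expect_true(all(is.na(cl$rank)))
})

test_that("classification is invariant under rigid motion and row order", {
  pts <- chain_fixture()
  ent <- rbind(c(0, 0))
  base <- assign_identities(pts, 5, ent)
  # translate + rotate everything (galleries and entrances together)
  th <- 0.61
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- as.matrix(pts[, c("x", "y")]) %*% t(R)
  moved <- tibble::tibble(gallery_id = pts$gallery_id,
                          x = rot[, 1] + 20, y = rot[, 2] - 13)
  ent_m <- cbind(ent %*% t(R))
  ent_m[, 1] <- ent_m[, 1] + 20; ent_m[, 2] <- ent_m[, 2] - 13
  moved_cl <- assign_identities(moved, 5, ent_m)
  expect_equal(moved_cl$rank, base$rank)
  expect_equal(moved_cl$parent_id, base$parent_id)
  expect_equal(moved_cl$length_px, base$length_px, tolerance = 1e-9)
  # reordering whole galleries gives the identical (sorted) result
  shuffled <- dplyr::bind_rows(split(pts, pts$gallery_id)[c("C", "A", "B")])
  expect_equal(assign_identities(shuffled, 5, ent), base)
})

test_that("per-rank lengths partition the total length", {
  gen <- synth_growth(growth_params(seed = 21, n_steps = 15, branch_prob = 0.6))
  ann <- materialize_series(gen$project, "synthA")
  last <- ann[[length(ann)]]
  cl <- assign_identities(translate_to_ref(last$galleries, last$ref_point),
                          gen$project$threshold_px,
                          gen$project$entrance_points[["synthA"]])
  s <- rank_length_summary(cl, mm_per_px = 0.5)
  expect_equal(s$len1_mm + s$len2_mm + s$len3_mm + s$len4plus_mm, s$total_mm,
               tolerance = 1e-12)
  expect_equal(s$total_mm, sum(cl$length_px) * 0.5, tolerance = 1e-12)
})

test_that("the shallower branch keeps the parent identity", {
  deg <- function(a) c(cos(a * pi / 180), sin(a * pi / 180))
  expect_equal(split_inheritance_check(c(1, 0), rbind(deg(10), deg(60))), 1L)
  expect_equal(split_inheritance_check(c(1, 0), rbind(deg(60), deg(10))), 2L)
  expect_warning(
    idx <- split_inheritance_check(c(1, 0), rbind(deg(45), deg(-45))),
    "equally"
  )
  expect_equal(idx, 1L)
  expect_error(split_inheritance_check(c(0, 0), rbind(deg(1), deg(2))), "nonzero")
})

test_that("random splits agree with an atan2 angle oracle", {
  set.seed(6)
  for (i in 1:100) {
    pd <- runif(1, 0, 2 * pi)
    c1 <- pd + runif(1, -2.5, 2.5)
    c2 <- pd + runif(1, -2.5, 2.5)
    dirs <- rbind(c(cos(c1), sin(c1)), c(cos(c2), sin(c2)))
    wrap <- function(a) abs(atan2(sin(a - pd), cos(a - pd)))
    want <- which.min(c(wrap(c1), wrap(c2)))
    if (abs(wrap(c1) - wrap(c2)) < 1e-9) next
    expect_equal(split_inheritance_check(c(cos(pd), sin(pd)), dirs), want)
  }
})
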