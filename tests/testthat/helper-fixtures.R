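# Shared fixtures and independent oracles for the test suite.

# --- independent oracles ----------------------------------------------------

# polyline length by an explicit per-segment loop (no vectorisation shared
# with the implementation)
oracle_polyline_length <- function(xy) {
  total <- 0
  for (i in seq_len(nrow(xy) - 1)) {
    total <- total + sqrt((xy[i + 1, 1] - xy[i, 1])^2 + (xy[i + 1, 2] - xy[i, 2])^2)
  }
  total
}

# minimum point-to-polyline distance by dense arc-length sampling
oracle_polyline_distance <- function(p, xy, n_samples = 1e4) {
  seg <- diff(xy)
  seg_len <- sqrt(seg[, 1]^2 + seg[, 2]^2)
  cum <- c(0, cumsum(seg_len))
  s <- seq(0, cum[length(cum)], length.out = n_samples)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(xy) - 1)
  t <- (s - cum[idx]) / seg_len[idx]
  sx <- xy[idx, 1] + t * seg[idx, 1]
  sy <- xy[idx, 2] + t * seg[idx, 2]
  d <- sqrt((p[1] - sx)^2 + (p[2] - sy)^2)
  i <- which.min(d)
  list(distance = d[i], arclength = s[i])
}

# single-linkage partition under dist < threshold via igraph components
oracle_snap_partition <- function(xy, threshold) {
  n <- nrow(xy)
  adj <- as.matrix(stats::dist(xy)) < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# canonical form of a partition labelling: list of sorted member index sets,
# sorted by first member, so two labelings compare as set partitions
canonical_partition <- function(labels) {
  parts <- split(seq_along(labels), labels)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# number of independent cycles of a gallery_network, via igraph
network_cycles <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = net$nodes$node_id
  )
  igraph::ecount(g) - igraph::vcount(g) + igraph::components(g)$no
}

network_components <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = net$nodes$node_id
  )
  igraph::components(g)$no
}

# --- hand-built fixtures ----------------------------------------------------

# one straight gallery with a perpendicular branch off its middle: A runs
# (0,0)->(10,0), B starts at (5, 0.5) (on A within threshold 2) and runs up
branch_fixture <- function() {
  dplyr::bind_rows(
    tibble::tibble(gallery_id = "A", x = c(0, 10), y = c(0, 0)),
    tibble::tibble(gallery_id = "B", x = c(5, 5), y = c(0.5, 8))
  )
}

# a three-rank chain: A from the entrance, B off A's middle, C off B's middle
chain_fixture <- function() {
  dplyr::bind_rows(
    tibble::tibble(gallery_id = "A", x = c(0, 100), y = c(0, 0)),
    tibble::tibble(gallery_id = "B", x = c(50, 50), y = c(0, 60)),
    tibble::tibble(gallery_id = "C", x = c(50, 90), y = c(30, 30))
  )
}

# chain_fixture plus a gallery that starts on A and merges back into B,
# closing one cycle
merge_fixture <- function() {
  dplyr::bind_rows(
    chain_fixture(),
    tibble::tibble(gallery_id = "D", x = c(80, 80, 51), y = c(0, 45, 45))
  )
}

# build a small project by hand: one group, three serials
toy_project <- function() {
  p <- new_project(threshold_px = 2, scale_mm = 10)
  g0 <- tibble::tibble(gallery_id = "A", x = c(0, 5), y = c(0, 0))
  g2 <- tibble::tibble(gallery_id = c("A", "A", "B", "B"),
                       x = c(0, 9, 4, 4), y = c(0, 0, 0.5, 6))
  p <- add_annotation(p, "toy", 0, status = "analyzed", galleries = g0,
                      scale_line = rbind(c(0, 20), c(100, 20)))
  p <- add_annotation(p, "toy", 1, status = "skipped")
  p <- add_annotation(p, "toy", 2, status = "analyzed", galleries = g2)
  p
}

# read the exported tables back with base R's correctly-rounded strtod
# parser, so the 17-significant-digit decimals reproduce the doubles exactly
read_tables_back <- function(outdir) {
  list(
    per_image = tibble::as_tibble(utils::read.csv(
      file.path(outdir, "per_image.csv"),
      colClasses = c(group = "character", serial = "integer",
                     total_mm = "numeric", len1_mm = "numeric",
                     len2_mm = "numeric", len3_mm = "numeric",
                     len4plus_mm = "numeric", n_galleries = "integer",
                     n_nodes = "integer", n_edges = "integer",
                     growth_mm = "numeric")
    )),
    per_gallery = tibble::as_tibble(utils::read.csv(
      file.path(outdir, "per_gallery.csv"),
      colClasses = c(group = "character", serial = "integer",
                     gallery_id = "character", rank = "integer",
                     parent_id = "character", length_mm = "numeric",
                     merged_end = "logical")
    )),
    nodes = tibble::as_tibble(utils::read.csv(
      file.path(outdir, "nodes.csv"),
      colClasses = c(group = "character", serial = "integer",
                     node_id = "character", x_mm = "numeric",
                     y_mm = "numeric", type = "character")
    )),
    edges = tibble::as_tibble(utils::read.csv(
      file.path(outdir, "edges.csv"),
      colClasses = c(group = "character", serial = "integer",
                     node_a = "character", node_b = "character",
                     gallery_id = "character", length_mm = "numeric")
    ))
  )
}

# run the packaged command-line script in a fresh R process, propagating the
# test session's library paths
run_cli <- function(args) {
  script <- system.file("cli", "gallerytrack.R", package = "gallerytrack")
  out <- suppressWarnings(system2(
    "Rscript", c(shQuote(script), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
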